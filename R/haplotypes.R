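# Haplotype collapsing and sharing reports.

#' Collapse aligned sequences into unique haplotypes
#'
#' Identity is exact string equality over all columns: the gap counts as a
#' state and ambiguity codes never match anything, including themselves
#' (sequences containing ambiguity codes therefore always stay distinct;
#' a warning is emitted so they can be pre-resolved). Labels `H01, H02, ...`
#' are assigned by descending total multiplicity, ties broken by the
#' smallest member id, so the result is invariant to input order.
#'
#' @param aln a `dna_alignment`.
#' @param metadata optional specimen table supplying per-specimen
#'   `multiplicity` (defaults to 1 for absent specimens).
#' @return an object of class `haplotype_table`: data.frame with columns
#'   `haplotype`, `representative` (sequence string), `members`
#'   (list-column of ids), `n_members`, `total` (summed multiplicity).
#' @export
collapse_haplotypes <- function(aln, metadata = NULL) {
  seqs <- aln_strings(aln)
  # deterministic: sort ids before grouping so representatives and tie-breaks
  # never depend on input order
  seqs <- seqs[order(names(seqs))]
  amb <- vapply(seqs, function(s)
    grepl(paste0("[^", paste(c(DNA_BASES, "-"), collapse = ""), "]"), s),
    logical(1))
  if (any(amb))
    warning("sequences with ambiguity codes never merge: ",
            paste(names(seqs)[amb], collapse = ", "))
  key <- seqs
  key[amb] <- paste0(key[amb], "\r", names(seqs)[amb])  # force uniqueness
  groups <- split(names(seqs), factor(key, levels = unique(key)))
  mult <- .multiplicity_lookup(metadata)
  tab <- data.frame(
    representative = vapply(groups, function(g) unname(seqs[[g[1]]]), character(1)),
    n_members = lengths(groups),
    total = vapply(groups, function(g) sum(mult(g)), numeric(1)),
    stringsAsFactors = FALSE)
  tab$members <- unname(groups)
  ord <- order(-tab$total, vapply(groups, function(g) min(g), character(1)))
  tab <- tab[ord, ]
  tab$haplotype <- sprintf("H%02d", seq_len(nrow(tab)))
  rownames(tab) <- NULL
  structure(tab[, c("haplotype", "representative", "members", "n_members",
                    "total")],
            class = c("haplotype_table", "data.frame"),
            marker = aln$marker)
}

.multiplicity_lookup <- function(metadata) {
  if (is.null(metadata)) return(function(g) rep(1, length(g)))
  m <- metadata$multiplicity
  if (is.null(m)) m <- rep(1L, nrow(metadata))
  if (any(m < 1)) stop("multiplicity must be >= 1")
  names(m) <- metadata$id
  function(g) {
    out <- m[g]
    out[is.na(out)] <- 1
    unname(out)
  }
}

#' Recompute haplotype totals from specimen multiplicities
#'
#' Leaves sequence content and membership untouched; only the `total`
#' column is recomputed as the sum of member multiplicities.
#'
#' @param table a `haplotype_table`.
#' @param metadata specimen table with `id` and `multiplicity`.
#' @return the updated `haplotype_table`.
#' @export
expand_multiplicities <- function(table, metadata) {
  mult <- .multiplicity_lookup(metadata)
  table$total <- vapply(table$members, function(g) sum(mult(g)), numeric(1))
  table
}

#' Haplotypes shared across groups
#'
#' Lists haplotypes whose members span at least two groups of a grouping
#' variable (ocean, basin or depth stratum). Members without a group value
#' are excluded with a warning.
#'
#' @param table a `haplotype_table`.
#' @param metadata specimen table with `id` and the grouping column.
#' @param group_by name of the grouping column in `metadata`; for
#'   `"stratum"` the groups are derived from `depth_m` against `depth_cut`.
#' @param depth_cut depth (m) separating bathyal from abyssal when
#'   `group_by = "stratum"`.
#' @return data.frame with `haplotype`, `n_groups`, `groups`
#'   (comma-separated group set), restricted to haplotypes spanning >= 2
#'   groups.
#' @export
shared_haplotypes <- function(table, metadata, group_by = "basin",
                              depth_cut = 3000) {
  if (identical(group_by, "stratum")) {
    grp <- ifelse(metadata$depth_m <= depth_cut, "bathyal", "abyssal")
  } else {
    if (!group_by %in% names(metadata))
      stop("metadata has no column '", group_by, "'")
    grp <- as.character(metadata[[group_by]])
  }
  names(grp) <- metadata$id
  rows <- lapply(seq_len(nrow(table)), function(i) {
    g <- grp[table$members[[i]]]
    if (anyNA(g)) {
      warning("members without a '", group_by, "' value excluded: ",
              paste(table$members[[i]][is.na(g)], collapse = ", "))
      g <- g[!is.na(g)]
    }
    u <- sort(unique(unname(g)))
    data.frame(haplotype = table$haplotype[i], n_groups = length(u),
               groups = paste(u, collapse = ","), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[out$n_groups >= 2L, , drop = FALSE]
}

#' Haplotype table as an alignment of representatives
#'
#' @param table a `haplotype_table`.
#' @return a `dna_alignment` whose records are the haplotype representatives.
#' @export
haplotypes_as_alignment <- function(table) {
  seqs <- table$representative
  names(seqs) <- table$haplotype
  suppressWarnings(dna_alignment(seqs, marker = attr(table, "marker")))
}

#' Export a haplotype table as TSV
#' @param table a `haplotype_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(table, path) {
  out <- data.frame(haplotype = table$haplotype,
                    representative = table$representative,
                    members = vapply(table$members, paste, character(1),
                                     collapse = ","),
                    total = table$total, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
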