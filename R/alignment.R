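#' @keywords internal
"_PACKAGE"

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-", "?")
DNA_BASES <- c("A", "C", "G", "T")

#' Construct an aligned set of DNA sequences
#'
#' An alignment is stored as a character matrix (rows = records, columns =
#' sites) of uppercase IUPAC symbols plus the gap character `-`. All records
#' must have identical length and unique ids.
#'
#' @param seqs named character vector of equal-length sequence strings, or a
#'   character matrix with one row per record and rownames as ids.
#' @param marker marker label (e.g. `"COI"`, `"16S"`, `"28S"`).
#' @param descriptions optional free-text descriptions, recycled or named by id.
#' @return an object of class `dna_alignment`.
#' @export
dna_alignment <- function(seqs, marker = "marker", descriptions = NULL) {
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
  } else {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
      stop("all sequences must be named by a non-empty id")
    }
    if (anyDuplicated(names(seqs))) {
      stop("duplicate sequence ids: ",
           paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
    }
    seqs <- toupper(seqs)
    lens <- nchar(seqs)
    if (any(lens == 0L)) stop("empty sequences: ",
                              paste(names(seqs)[lens == 0L], collapse = ", "))
    if (length(unique(lens)) > 1L) {
      tab <- sort(table(lens), decreasing = TRUE)
      modal <- as.integer(names(tab)[1L])
      bad <- names(seqs)[lens != modal]
      stop("alignment error: unequal sequence lengths (expected ", modal,
           "): ", paste(bad, collapse = ", "))
    }
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(mat) <- names(seqs)
  }
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop("alignment rows must carry unique ids")
  bad_sym <- setdiff(unique(as.vector(mat)), IUPAC_CODES)
  if (length(bad_sym) > 0L)
    stop("non-IUPAC symbols in alignment: ", paste(bad_sym, collapse = " "))
  desc <- rep("", nrow(mat))
  names(desc) <- rownames(mat)
  if (!is.null(descriptions)) {
    if (!is.null(names(descriptions))) {
      desc[names(descriptions)] <- descriptions
    } else {
      desc[] <- rep_len(descriptions, nrow(mat))
    }
  }
  structure(list(mat = mat, marker = marker, descriptions = desc),
            class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("<dna_alignment> marker:", x$marker, "-", nrow(x$mat), "sequences x",
      ncol(x$mat), "columns\n")
  invisible(x)
}

#' @export
dim.dna_alignment <- function(x) dim(x$mat)

#' Alignment ids
#' @param aln a `dna_alignment`.
#' @return character vector of record ids, in alignment order.
#' @export
aln_ids <- function(aln) rownames(aln$mat)

#' Number of alignment columns
#' @param aln a `dna_alignment`.
#' @return integer site count.
#' @export
n_columns <- function(aln) ncol(aln$mat)

#' Sequences as strings
#' @param aln a `dna_alignment`.
#' @return named character vector of sequence strings.
#' @export
aln_strings <- function(aln) {
  out <- apply(aln$mat, 1L, paste, collapse = "")
  names(out) <- rownames(aln$mat)
  out
}

#' Subset an alignment by id
#' @param aln a `dna_alignment`.
#' @param ids record ids to keep (order respected).
#' @return a `dna_alignment` restricted to `ids`.
#' @export
aln_subset <- function(aln, ids) {
  missing <- setdiff(ids, aln_ids(aln))
  if (length(missing) > 0L)
    stop("ids not in alignment: ", paste(missing, collapse = ", "))
  dna_alignment(aln$mat[ids, , drop = FALSE], marker = aln$marker,
                descriptions = aln$descriptions[ids])
}

#' Read an aligned FASTA file
#'
#' Records are uppercased and validated as IUPAC DNA; order is preserved
#' from the file. Unequal lengths, duplicate ids and empty files are errors.
#'
#' @param path FASTA file path.
#' @param marker marker label attached to the alignment.
#' @return a `dna_alignment`.
#' @export
read_fasta <- function(path, marker = "marker") {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- suppressWarnings(ape::read.FASTA(path))
  if (is.null(recs) || length(recs) == 0L) stop("empty FASTA file: ", path)
  seqs <- vapply(as.character(recs), function(s) paste(toupper(s), collapse = ""),
                 character(1))
  # keep only the first whitespace-separated token as the id, rest = description
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  names(seqs) <- ids
  names(desc) <- ids
  dna_alignment(seqs, marker = marker, descriptions = desc)
}

#' Write an alignment as FASTA
#'
#' Ids are written verbatim; sequence lines wrap at 80 columns.
#'
#' @param aln a `dna_alignment`.
#' @param path output file path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path, width = 80L) {
  seqs <- aln_strings(aln)
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    hdr <- if (nzchar(aln$descriptions[[id]]))
      paste(id, aln$descriptions[[id]]) else id
    writeLines(paste0(">", hdr), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a specimen metadata table
#'
#' Tab-separated with a named header; expected columns are
#' `id locality basin lat lon depth_m source multiplicity acc_coi acc_16s acc_28s`
#' (missing values `n.d.`). Only `id` is mandatory. A parenthetical specimen
#' count in the id (e.g. `"ATL-NE1 (10)"`) is stripped into `multiplicity`
#' when no multiplicity column is present; depth ranges (`"3860-4570"`) are
#' collapsed to their midpoint.
#'
#' @param path TSV file path.
#' @return a `data.frame` with one row per specimen; depths in metres
#'   (positive downward), multiplicity >= 1.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("n.d.", "NA", ""))
  names(df) <- tolower(names(df))
  if (!"id" %in% names(df)) stop("metadata is missing the 'id' column")
  df$id <- as.character(df$id)
  paren <- regmatches(df$id, regexpr("\\(\\s*[0-9]+\\s*\\)\\s*$", df$id))
  has_paren <- grepl("\\(\\s*[0-9]+\\s*\\)\\s*$", df$id)
  paren_mult <- rep(NA_integer_, nrow(df))
  paren_mult[has_paren] <- as.integer(gsub("[^0-9]", "", paren))
  df$id <- trimws(sub("\\(\\s*[0-9]+\\s*\\)\\s*$", "", df$id))
  if (anyDuplicated(df$id))
    stop("duplicate specimen ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (!"multiplicity" %in% names(df)) {
    df$multiplicity <- ifelse(is.na(paren_mult), 1L, paren_mult)
  } else {
    df$multiplicity <- as.integer(df$multiplicity)
    df$multiplicity[is.na(df$multiplicity)] <- 1L
  }
  if (any(df$multiplicity < 1L)) stop("multiplicity must be >= 1")
  if ("depth_m" %in% names(df)) {
    dep <- as.character(df$depth_m)
    # a depth given as a range is collapsed to its midpoint
    rng <- grepl("^[0-9.]+\\s*[-–]\\s*[0-9.]+$", dep)
    mid <- function(s) mean(as.numeric(strsplit(s, "[-–]")[[1]]))
    dep_num <- suppressWarnings(as.numeric(dep))
    dep_num[rng] <- vapply(dep[rng], mid, numeric(1))
    if (any(!is.na(dep_num) & dep_num <= 0))
      stop("depth_m must be positive where present")
    df$depth_m <- dep_num
  } else {
    df$depth_m <- NA_real_
  }
  for (col in c("lat", "lon")) {
    if (col %in% names(df)) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df
}

#' Write a specimen metadata table
#' @param metadata data.frame as returned by [read_metadata()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  out <- metadata
  out[] <- lapply(out, function(x) ifelse(is.na(x), "n.d.", as.character(x)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify alignment columns
#'
#' Counts constant, variable, singleton and parsimony-informative sites.
#' Columns are classified from their unambiguous calls (`A`, `C`, `G`, `T`)
#' only: a site is variable when at least two distinct unambiguous states are
#' present, and parsimony-informative when at least two distinct unambiguous
#' states each occur in at least two sequences. Variable sites that are not
#' informative are singletons. Columns with fewer than two unambiguous calls
#' count as constant.
#'
#' @param aln a `dna_alignment` with at least two records.
#' @return a list with `n_sites`, `n_constant`, `n_variable`, `n_singleton`,
#'   `n_parsimony_informative`.
#' @export
count_site_classes <- function(aln) {
  if (nrow(aln$mat) < 2L)
    stop("site classification requires at least 2 sequences")
  n_sites <- ncol(aln$mat)
  variable <- 0L
  informative <- 0L
  for (j in seq_len(n_sites)) {
    col <- aln$mat[, j]
    col <- col[col %in% DNA_BASES]
    if (length(col) < 2L) next
    tab <- table(col)
    if (length(tab) >= 2L) {
      variable <- variable + 1L
      if (sum(tab >= 2L) >= 2L) informative <- informative + 1L
    }
  }
  list(n_sites = n_sites,
       n_constant = n_sites - variable,
       n_variable = variable,
       n_singleton = variable - informative,
       n_parsimony_informative = informative)
}

# stop codons by translation table; the invertebrate mitochondrial code has
# no TGA stop (TGA = Trp) and reassigns AGA/AGG to Ser
.stop_codons <- function(code_table) {
  switch(code_table,
         "invertebrate_mitochondrial" = c("TAA", "TAG"),
         "standard" = c("TAA", "TAG", "TGA"),
         stop("unknown code table: ", code_table))
}

#' Screen a protein-coding alignment for pseudogene signatures
#'
#' Translates each sequence in a fixed reading frame and flags internal stop
#' codons; also counts ambiguous (non-`ACGT`) calls per sequence. When
#' `frame` is `NULL` the frame minimising the total number of internal stops
#' across the alignment is used.
#'
#' @param aln a `dna_alignment` for a protein-coding marker.
#' @param code_table `"invertebrate_mitochondrial"` (default) or `"standard"`.
#' @param frame reading-frame offset 0, 1 or 2, or `NULL` to auto-detect.
#' @return a `data.frame` with columns `id`, `frame`, `has_internal_stop`,
#'   `n_internal_stops`, `n_ambiguous_calls`.
#' @export
check_coding <- function(aln, code_table = "invertebrate_mitochondrial",
                         frame = NULL) {
  stops <- .stop_codons(code_table)
  count_stops <- function(s, f) {
    s <- gsub("-", "", s, fixed = TRUE)
    if (nchar(s) < f + 6L) return(0L)
    s <- substr(s, f + 1L, nchar(s))
    n_cod <- nchar(s) %/% 3L
    if (n_cod < 2L) return(0L)
    starts <- seq(1L, by = 3L, length.out = n_cod - 1L)  # internal codons only
    sum(substring(s, starts, starts + 2L) %in% stops)
  }
  seqs <- aln_strings(aln)
  if (is.null(frame)) {
    totals <- vapply(0:2, function(f)
      sum(vapply(seqs, count_stops, integer(1), f = f)), integer(1))
    frame <- which.min(totals) - 1L
  }
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  n_stop <- vapply(seqs, count_stops, integer(1), f = frame)
  n_amb <- vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    sum(!ch %in% c(DNA_BASES, "-"))
  }, integer(1))
  data.frame(id = names(seqs), frame = frame,
             has_internal_stop = n_stop > 0L,
             n_internal_stops = n_stop,
             n_ambiguous_calls = n_amb,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Concatenate marker alignments
#'
#' Joins per-marker alignments specimen-wise in the order given. Specimens
#' missing a marker are dropped (default) or padded with a missing symbol.
#' Block boundaries are recorded in the `"blocks"` attribute as a
#' `data.frame` with `marker`, `start`, `end`, mapping every output column
#' to exactly one (marker, column) pair.
#'
#' @param alignments list of `dna_alignment` objects.
#' @param join_policy `"drop"` or `"pad"`.
#' @param pad_char symbol used under the pad policy (default `"N"`).
#' @return a `dna_alignment` labelled `"concatenated"`, with a `"blocks"`
#'   attribute.
#' @export
concatenate_markers <- function(alignments, join_policy = c("drop", "pad"),
                                pad_char = "N") {
  join_policy <- match.arg(join_policy)
  stopifnot(length(alignments) >= 1L)
  id_sets <- lapply(alignments, aln_ids)
  if (join_policy == "drop") {
    ids <- Reduce(intersect, id_sets)
    if (length(ids) == 0L)
      stop("no specimens shared across all markers under the drop policy")
  } else {
    ids <- Reduce(union, id_sets)
  }
  widths <- vapply(alignments, n_columns, integer(1))
  blocks <- data.frame(
    marker = vapply(alignments, function(a) a$marker, character(1)),
    start = cumsum(c(1L, widths[-length(widths)])),
    end = cumsum(widths), stringsAsFactors = FALSE)
  parts <- lapply(alignments, function(a) {
    s <- character(length(ids))
    names(s) <- ids
    present <- intersect(ids, aln_ids(a))
    s[present] <- aln_strings(a)[present]
    s[!nzchar(s)] <- strrep(pad_char, n_columns(a))
    s
  })
  joined <- do.call(paste0, parts)
  names(joined) <- ids
  out <- dna_alignment(joined, marker = "concatenated")
  attr(out, "blocks") <- blocks
  out
}
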