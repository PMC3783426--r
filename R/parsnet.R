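# Statistical-parsimony haplotype networks: parsimony-probability
# connection limit, step distances, network assembly and summaries.

#' Probability that a j-step connection is non-homoplasious
#'
#' Model: for a pair of lineages under the neutral coalescent, the number of
#' substitutions at a site is geometric with per-site parameter
#' `theta` (pairwise expected hits per site); states change as in the
#' Jukes-Cantor model. Given two haplotypes of length `m` differing at `j`
#' sites, `theta` is estimated from the observed proportion
#' (`theta = p / (1 - 4p/3)`, `p = j/m`) and the probability of parsimony is
#' the probability that every differing site carries exactly one hit and
#' every identical site carries none:
#' `P(j) = P(1 hit | differ)^j * P(0 hits | same)^(m-j)`.
#'
#' @param j number of observed differences (vectorised).
#' @param m number of sites.
#' @return probability in `[0, 1]`; 0 where `j/m >= 3/4` (saturation).
#' @export
parsimony_probability <- function(j, m) {
  stopifnot(m >= 1)
  vapply(j, function(jj) {
    if (jj == 0) return(1)
    p <- jj / m
    if (p >= 0.75) return(0)
    theta <- p / (1 - 4 * p / 3)
    a <- theta / (1 + theta)          # geometric ratio; P(k hits) = (1-a) a^k
    p1_and_diff <- (1 - a) * a        # one hit always changes the state
    p0_and_same <- (1 - a)
    # P(site differs) marginal equals p by construction of theta-hat
    (p1_and_diff / p)^jj * (p0_and_same / (1 - p))^(m - jj)
  }, numeric(1))
}

#' Statistical-parsimony connection limit
#'
#' The largest number of mutational steps `j_max` for which the probability
#' of a non-homoplasious (parsimonious) connection is at least `threshold`
#' (default 0.95), given the sequence length. `fixed_limit` bypasses the
#' probability computation.
#'
#' @param n_sites alignment length used for the limit.
#' @param threshold parsimony probability threshold in (0, 1).
#' @param fixed_limit optional integer overriding the computed limit.
#' @return an object of class `connection_limit`: `j_max`, `threshold`,
#'   `n_sites`, `prob` (probability curve for `j = 1 .. j_max + 1`),
#'   `fixed` flag.
#' @export
connection_limit <- function(n_sites, threshold = 0.95, fixed_limit = NULL) {
  stopifnot(n_sites >= 1)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1")
  if (!is.null(fixed_limit)) {
    j_max <- as.integer(fixed_limit)
    prob <- parsimony_probability(seq_len(j_max + 1L), n_sites)
  } else {
    j_max <- 0L
    repeat {
      if (parsimony_probability(j_max + 1L, n_sites) < threshold) break
      j_max <- j_max + 1L
      if (j_max >= n_sites) break
    }
    prob <- parsimony_probability(seq_len(j_max + 1L), n_sites)
  }
  structure(list(j_max = j_max, threshold = threshold, n_sites = n_sites,
                 prob = prob, fixed = !is.null(fixed_limit)),
            class = "connection_limit")
}

#' @export
print.connection_limit <- function(x, ...) {
  cat("<connection_limit> j_max =", x$j_max, "at threshold", x$threshold,
      "for", x$n_sites, "sites", if (x$fixed) "(fixed)" else "", "\n")
  invisible(x)
}

#' Mutational step distance between two haplotypes
#'
#' Counts differing sites. Under `gap_mode = "fifth_state"` a gap
#' mismatching a base (or a base mismatching a gap) counts as one step;
#' under `"missing"` sites where either sequence has a gap are excluded.
#' Ambiguity codes are always treated as missing.
#'
#' @param a,b equal-length sequence strings or residue vectors.
#' @param gap_mode `"fifth_state"` (default) or `"missing"`.
#' @return integer step count.
#' @export
hap_distance <- function(a, b, gap_mode = c("fifth_state", "missing")) {
  gap_mode <- match.arg(gap_mode)
  if (is.character(a) && length(a) == 1L) a <- strsplit(toupper(a), "")[[1]]
  if (is.character(b) && length(b) == 1L) b <- strsplit(toupper(b), "")[[1]]
  if (length(a) != length(b)) stop("sequences must have equal aligned length")
  states <- c(DNA_BASES, if (gap_mode == "fifth_state") "-")
  ok <- a %in% states & b %in% states
  sum(a[ok] != b[ok])
}

.hap_step_matrix <- function(table, gap_mode) {
  aln <- haplotypes_as_alignment(table)
  n <- nrow(table)
  m <- matrix(0L, n, n, dimnames = list(table$haplotype, table$haplotype))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        m[i, j] <- m[j, i] <- hap_distance(aln$mat[i, ], aln$mat[j, ],
                                           gap_mode = gap_mode)
      }
    }
  }
  m
}

#' Assemble statistical-parsimony haplotype networks
#'
#' Haplotype pairs are processed in order of increasing step distance
#' (ties by haplotype label) while the distance does not exceed the
#' connection limit. Within each distance round, every pair joining two
#' distinct components is linked, so equal-length alternative connections
#' are all retained (loops allowed); pairs already connected by strictly
#' shorter links are skipped as non-minimal. The resulting components are
#' the networks, sorted by number of haplotypes (ties by smallest label);
#' haplotypes beyond the limit from everything else form singleton
#' networks. Hypothetical intermediate haplotypes (for edges of more than
#' one step) are materialised only on export.
#'
#' @param table a `haplotype_table` (see [collapse_haplotypes()]).
#' @param limit a `connection_limit`, or `NULL` to compute one from the
#'   alignment length at the default 95 percent threshold.
#' @param gap_mode passed to [hap_distance()].
#' @return a list of class `parsimony_networks`; each element is a list
#'   with `haplotypes`, `edges` (data.frame `from`, `to`, `steps`),
#'   `n_haplotypes`, `total` (summed multiplicity). The `limit` used is
#'   attached as an attribute.
#' @export
build_networks <- function(table, limit = NULL,
                           gap_mode = c("fifth_state", "missing")) {
  gap_mode <- match.arg(gap_mode)
  if (is.null(limit))
    limit <- connection_limit(nchar(table$representative[1]))
  stopifnot(inherits(limit, "connection_limit"))
  sm <- .hap_step_matrix(table, gap_mode)
  labs <- table$haplotype
  n <- length(labs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  edges <- list()
  if (n >= 2L) {
    ut <- which(upper.tri(sm), arr.ind = TRUE)
    pr <- data.frame(i = ut[, 1], j = ut[, 2], steps = sm[ut])
    pr <- pr[pr$steps <= limit$j_max, , drop = FALSE]
    pr <- pr[order(pr$steps, labs[pr$i], labs[pr$j]), , drop = FALSE]
    for (s in sort(unique(pr$steps))) {
      round_pairs <- pr[pr$steps == s, , drop = FALSE]
      # component membership frozen at the start of the round: all minimal
      # (equal-length) alternative connections are retained
      comp_before <- vapply(seq_len(n), find, integer(1))
      keep <- comp_before[round_pairs$i] != comp_before[round_pairs$j]
      round_pairs <- round_pairs[keep, , drop = FALSE]
      for (r in seq_len(nrow(round_pairs))) {
        i <- round_pairs$i[r]; j <- round_pairs$j[r]
        edges[[length(edges) + 1L]] <-
          data.frame(from = labs[i], to = labs[j], steps = s,
                     stringsAsFactors = FALSE)
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(labs, comp)
  ord <- order(-lengths(groups), vapply(groups, min, character(1)))
  groups <- groups[ord]
  edge_df <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), steps = integer(),
               stringsAsFactors = FALSE)
  nets <- lapply(groups, function(g) {
    e <- edge_df[edge_df$from %in% g & edge_df$to %in% g, , drop = FALSE]
    rownames(e) <- NULL
    list(haplotypes = g,
         edges = e,
         n_haplotypes = length(g),
         total = sum(table$total[match(g, table$haplotype)]))
  })
  names(nets) <- sprintf("N%02d", seq_along(nets))
  structure(nets, class = "parsimony_networks", limit = limit,
            gap_mode = gap_mode, table = table)
}

#' @export
print.parsimony_networks <- function(x, ...) {
  lim <- attr(x, "limit")
  cat("<parsimony_networks>", length(x), "networks (connection limit",
      lim$j_max, "steps)\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %d haplotypes (total %g), %d links\n", nm,
                x[[nm]]$n_haplotypes, x[[nm]]$total, nrow(x[[nm]]$edges)))
  }
  invisible(x)
}

#' Summarise networks against specimen metadata
#'
#' Per network: haplotype count, total multiplicity, basins, depth range
#' and a stratum call against a depth cut (default 3,000 m): `"bathyal"`
#' when all members are at or above the cut, `"abyssal"` when all are
#' below, `"spans_cut"` otherwise. Members without depth are excluded from
#' the stratum call with a warning.
#'
#' @param networks a `parsimony_networks` object.
#' @param metadata specimen table with `id`, `depth_m` and optionally
#'   `basin`.
#' @param depth_cut stratum cut depth in metres.
#' @return a `data.frame` with one row per network.
#' @export
network_summary <- function(networks, metadata, depth_cut = 3000) {
  table <- attr(networks, "table")
  depth <- stats::setNames(metadata$depth_m, metadata$id)
  basin <- if ("basin" %in% names(metadata))
    stats::setNames(as.character(metadata$basin), metadata$id) else NULL
  rows <- lapply(names(networks), function(nm) {
    net <- networks[[nm]]
    members <- unlist(table$members[match(net$haplotypes, table$haplotype)])
    d <- depth[members]
    if (anyNA(d)) {
      warning("members without depth excluded from stratum call: ",
              paste(members[is.na(d)], collapse = ", "))
      d <- d[!is.na(d)]
    }
    stratum <- if (length(d) == 0L) NA_character_
    else if (all(d <= depth_cut)) "bathyal"
    else if (all(d > depth_cut)) "abyssal"
    else "spans_cut"
    data.frame(network = nm, n_haplotypes = net$n_haplotypes,
               total = net$total,
               basins = if (is.null(basin)) NA_character_ else
                 paste(sort(unique(stats::na.omit(basin[members]))), collapse = ","),
               depth_min = if (length(d)) min(d) else NA_real_,
               depth_max = if (length(d)) max(d) else NA_real_,
               stratum = stratum, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export networks with hypothetical intermediates
#'
#' Writes either a GraphML file or a TSV edge list (`from to steps`).
#' Multi-step links are subdivided by unlabelled hypothetical nodes
#' (`hyp1, hyp2, ...`), one per intermediate mutational step, matching the
#' usual display of statistical-parsimony networks.
#'
#' @param networks a `parsimony_networks` object.
#' @param path output file path.
#' @param format `"graphml"` or `"edges"`.
#' @return `path`, invisibly.
#' @export
export_networks <- function(networks, path, format = c("graphml", "edges")) {
  format <- match.arg(format)
  table <- attr(networks, "table")
  nodes <- data.frame(name = table$haplotype, total = table$total,
                      observed = TRUE, stringsAsFactors = FALSE)
  edges <- list()
  hyp_i <- 0L
  for (nm in names(networks)) {
    e <- networks[[nm]]$edges
    for (r in seq_len(nrow(e))) {
      s <- e$steps[r]
      if (s <= 1L) {
        edges[[length(edges) + 1L]] <- data.frame(
          from = e$from[r], to = e$to[r], steps = 1L, stringsAsFactors = FALSE)
      } else {
        chain <- c(e$from[r],
                   sprintf("hyp%d", hyp_i + seq_len(s - 1L)), e$to[r])
        hyp_i <- hyp_i + s - 1L
        for (k in seq_len(s)) {
          edges[[length(edges) + 1L]] <- data.frame(
            from = chain[k], to = chain[k + 1L], steps = 1L,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  edge_df <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), steps = integer())
  hyp_nodes <- setdiff(unique(c(edge_df$from, edge_df$to)), nodes$name)
  if (length(hyp_nodes) > 0L) {
    nodes <- rbind(nodes, data.frame(name = hyp_nodes, total = 0,
                                     observed = FALSE, stringsAsFactors = FALSE))
  }
  if (format == "edges") {
    utils::write.table(edge_df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(edge_df, directed = FALSE,
                                       vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
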