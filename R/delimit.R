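# Distance-based species-delimitation decisions: barcoding gap, 4x
# criterion, threshold clustering, clade merging, partition comparison and
# the bathymetric-break scan.

#' Validate a clade partition
#'
#' A partition is a named character vector mapping specimen/haplotype ids
#' to clade labels; every id must be labelled.
#'
#' @param x named character vector (or coercible factor/list).
#' @return the validated partition (class `clade_partition`).
#' @export
as_partition <- function(x) {
  if (inherits(x, "clade_partition")) return(x)
  x <- vapply(x, as.character, character(1))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("partition must be a named vector (id -> clade label)")
  if (anyNA(x) || any(!nzchar(x))) stop("every id must carry a clade label")
  if (anyDuplicated(names(x)))
    stop("duplicate ids in partition: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  structure(x, class = "clade_partition")
}

#' Read/write a partition TSV (`id<TAB>clade`)
#' @param path file path.
#' @return a `clade_partition`.
#' @export
read_partition <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_partition(stats::setNames(as.character(df$clade), df$id))
}

#' @rdname read_partition
#' @param partition a `clade_partition`.
#' @export
write_partition <- function(partition, path) {
  utils::write.table(data.frame(id = names(partition),
                                clade = as.character(partition)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.pair_distances <- function(dm, partition) {
  partition <- as_partition(partition)
  ids <- dm_ids(dm)
  miss <- setdiff(ids, names(partition))
  if (length(miss) > 0L)
    stop("ids without a clade assignment: ", paste(miss, collapse = ", "))
  lab <- partition[ids]
  v <- dm$values
  ut <- which(upper.tri(v), arr.ind = TRUE)
  data.frame(a = ids[ut[, 1]], b = ids[ut[, 2]],
             clade_a = unname(lab[ut[, 1]]), clade_b = unname(lab[ut[, 2]]),
             d = v[ut], stringsAsFactors = FALSE)
}

#' Barcoding-gap test
#'
#' Reports the highest within-clade distance and the lowest between-clade
#' distance over all pairs; a gap is present when `min_inter > max_intra`.
#' With no within-clade pairs at all (only singleton clades) the status is
#' `"undecidable"`.
#'
#' @param dm a `divergence_matrix`.
#' @param partition clade assignment covering every id in `dm`.
#' @return a list of class `gap_report`: `max_intra`, `min_inter`,
#'   `gap_present`, `gap_interval` (`c(max_intra, min_inter)` when present,
#'   else `NULL`), `status` (`"decided"` or `"undecidable"`).
#' @export
barcoding_gap <- function(dm, partition) {
  pd <- .pair_distances(dm, partition)
  if (length(unique(c(pd$clade_a, pd$clade_b))) < 2L)
    stop("barcoding gap requires >= 2 clades")
  intra <- pd$d[pd$clade_a == pd$clade_b]
  inter <- pd$d[pd$clade_a != pd$clade_b]
  if (length(intra) == 0L) {
    return(structure(list(max_intra = NA_real_, min_inter = min(inter),
                          gap_present = NA, gap_interval = NULL,
                          status = "undecidable"),
                     class = "gap_report"))
  }
  max_intra <- max(intra)
  min_inter <- min(inter)
  present <- min_inter > max_intra
  structure(list(max_intra = max_intra, min_inter = min_inter,
                 gap_present = present,
                 gap_interval = if (present) c(max_intra, min_inter) else NULL,
                 status = "decided"),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  if (identical(x$status, "undecidable")) {
    cat("<gap_report> undecidable (no within-clade pairs); min inter =",
        signif(x$min_inter, 4), "\n")
  } else {
    cat("<gap_report> max intra =", signif(x$max_intra, 4),
        "| min inter =", signif(x$min_inter, 4),
        "| gap", if (x$gap_present) "PRESENT" else "ABSENT", "\n")
  }
  invisible(x)
}

#' 4x criterion
#'
#' For every clade pair (A, B): pass iff the minimum between-pair distance
#' strictly exceeds four times the larger of the two clades' maximum
#' within-clade distances. Singleton clades contribute a maximum
#' within-clade distance of 0. The global verdict is the conjunction over
#' all pairs; the test is invariant to rescaling all distances.
#'
#' @inheritParams barcoding_gap
#' @param factor multiplier on the within-clade maximum (default 4).
#' @return a list of class `four_x_report`: `pairs` (data.frame with
#'   `clade_a`, `clade_b`, `min_inter`, `max_intra`, `ratio`, `pass`) and
#'   `global_pass`.
#' @export
four_x <- function(dm, partition, factor = 4) {
  pd <- .pair_distances(dm, partition)
  partition <- as_partition(partition)
  clades <- sort(unique(as.character(partition[dm_ids(dm)])))
  if (length(clades) < 2L) stop("4x criterion requires >= 2 clades")
  intra_max <- vapply(clades, function(cl) {
    d <- pd$d[pd$clade_a == cl & pd$clade_b == cl]
    if (length(d) == 0L) 0 else max(d)
  }, numeric(1))
  combs <- utils::combn(clades, 2L)
  rows <- apply(combs, 2L, function(pr) {
    sel <- (pd$clade_a == pr[1] & pd$clade_b == pr[2]) |
      (pd$clade_a == pr[2] & pd$clade_b == pr[1])
    mi <- min(pd$d[sel])
    mx <- max(intra_max[pr[1]], intra_max[pr[2]])
    data.frame(clade_a = pr[1], clade_b = pr[2], min_inter = mi,
               max_intra = mx, ratio = if (mx > 0) mi / mx else Inf,
               pass = mi > factor * mx, stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  structure(list(pairs = pairs, global_pass = all(pairs$pass),
                 factor = factor),
            class = "four_x_report")
}

#' @export
print.four_x_report <- function(x, ...) {
  cat("<four_x_report>", nrow(x$pairs), "clade pairs; global",
      if (x$global_pass) "PASS" else "FAIL",
      sprintf("(factor %g)\n", x$factor))
  invisible(x)
}

#' Single-linkage threshold clustering
#'
#' Clades are the connected components of the graph joining all id pairs
#' with distance `<= threshold`. Labels `C01, C02, ...` are assigned by
#' decreasing component size, ties broken by smallest member id.
#'
#' @param dm a `divergence_matrix`.
#' @param threshold non-negative distance threshold.
#' @return a `clade_partition`.
#' @export
threshold_clusters <- function(dm, threshold) {
  stopifnot(threshold >= 0)
  ids <- dm_ids(dm)
  v <- dm$values
  # union-find over ids
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(length(ids) - 1L)) {
    for (j in seq(i + 1L, length(ids))) {
      if (!is.na(v[i, j]) && v[i, j] <= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_along(ids), find, integer(1))
  groups <- split(ids, comp)
  ord <- order(-lengths(groups), vapply(groups, min, character(1)))
  groups <- groups[ord]
  lab <- character(length(ids))
  names(lab) <- ids
  for (k in seq_along(groups)) lab[groups[[k]]] <- sprintf("C%02d", k)
  as_partition(lab)
}

#' Merge clades into one
#'
#' @param partition a `clade_partition`.
#' @param labels clade labels to merge (all must exist).
#' @param new_label label for the merged clade (default: labels joined
#'   with `"+"`).
#' @return the updated `clade_partition`.
#' @export
merge_clades <- function(partition, labels, new_label = NULL) {
  partition <- as_partition(partition)
  unknown <- setdiff(labels, unique(as.character(partition)))
  if (length(unknown) > 0L)
    stop("unknown clade labels: ", paste(unknown, collapse = ", "))
  if (is.null(new_label)) new_label <- paste(sort(unique(labels)), collapse = "+")
  out <- as.character(partition)
  names(out) <- names(partition)
  out[out %in% labels] <- new_label
  as_partition(out)
}

#' Compare two partitions on their shared ids
#'
#' Restricted to ids present in both, reports whether the partitions are
#' equal, one refines the other, or they conflict. A conflicting pair is a
#' pair of ids grouped together in one partition and apart in the other.
#'
#' @param pA,pB `clade_partition` objects.
#' @return a list of class `congruence_report`: `relation` (one of
#'   `"equal"`, `"pA_refines_pB"`, `"pB_refines_pA"`, `"conflict"`),
#'   `n_shared`, `conflicts` (data.frame `id_a`, `id_b`, `together_in`).
#' @export
compare_partitions <- function(pA, pB) {
  pA <- as_partition(pA); pB <- as_partition(pB)
  shared <- intersect(names(pA), names(pB))
  if (length(shared) == 0L) stop("partitions share no ids")
  a <- as.character(pA[shared]); b <- as.character(pB[shared])
  conflicts <- list()
  a_in_b <- TRUE   # pA refines pB: together in A => together in B
  b_in_a <- TRUE
  n <- length(shared)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        ta <- a[i] == a[j]; tb <- b[i] == b[j]
        if (ta && !tb) {
          a_in_b <- FALSE
          conflicts[[length(conflicts) + 1L]] <-
            data.frame(id_a = shared[i], id_b = shared[j], together_in = "pA",
                       stringsAsFactors = FALSE)
        } else if (tb && !ta) {
          b_in_a <- FALSE
          conflicts[[length(conflicts) + 1L]] <-
            data.frame(id_a = shared[i], id_b = shared[j], together_in = "pB",
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  relation <- if (a_in_b && b_in_a) "equal"
  else if (a_in_b) "pA_refines_pB"
  else if (b_in_a) "pB_refines_pA"
  else "conflict"
  conf_df <- if (length(conflicts)) do.call(rbind, conflicts) else
    data.frame(id_a = character(), id_b = character(),
               together_in = character(), stringsAsFactors = FALSE)
  structure(list(relation = relation, n_shared = n, conflicts = conf_df),
            class = "congruence_report")
}

#' @export
print.congruence_report <- function(x, ...) {
  cat("<congruence_report>", x$relation, "on", x$n_shared, "shared ids;",
      nrow(x$conflicts), "disagreeing pairs\n")
  invisible(x)
}

#' Bathymetric-break scan
#'
#' Searches for depth thresholds that separate all clades into disjoint
#' above/below sets. Candidate thresholds default to midpoints between
#' consecutive distinct specimen depths; a clade "spans" a threshold iff it
#' has members strictly above and strictly below it. The report gives the
#' maximal contiguous interval of separating thresholds, expressed as the
#' open depth interval `(d_lo, d_hi)` between the bracketing specimen
#' depths; an empty interval means no break. Specimens without depth are
#' excluded with a warning.
#'
#' @param partition a `clade_partition`.
#' @param metadata specimen table with `id` and `depth_m`.
#' @param thresholds `"auto"` (midpoints) or a numeric vector of candidate
#'   cut depths.
#' @return a list of class `depth_break_report`: `break_found`,
#'   `interval` (`c(d_lo, d_hi)` or `NULL`), `all_intervals` (data.frame of
#'   every maximal valid run), `clade_depths` (per-clade min/max),
#'   `status` (`"ok"`, `"degenerate_single_clade"`, or `"no_depth_spread"`).
#' @export
depth_break <- function(partition, metadata, thresholds = "auto") {
  partition <- as_partition(partition)
  depth <- stats::setNames(metadata$depth_m, metadata$id)
  ids <- names(partition)
  miss_meta <- setdiff(ids, names(depth))
  if (length(miss_meta) > 0L)
    stop("ids missing from metadata: ", paste(miss_meta, collapse = ", "))
  d <- depth[ids]
  if (anyNA(d)) {
    warning("ids without depth excluded: ",
            paste(ids[is.na(d)], collapse = ", "))
    ids <- ids[!is.na(d)]
    d <- d[ids]
  }
  if (length(ids) == 0L)
    return(structure(list(break_found = FALSE, interval = NULL,
                          all_intervals = NULL, clade_depths = NULL,
                          status = "no_depth_spread"),
                     class = "depth_break_report"))
  lab <- as.character(partition[ids])
  clade_depths <- do.call(rbind, lapply(sort(unique(lab)), function(cl) {
    dd <- d[lab == cl]
    data.frame(clade = cl, n = length(dd), depth_min = min(dd),
               depth_max = max(dd), stringsAsFactors = FALSE)
  }))
  degenerate <- length(unique(lab)) < 2L
  dep_sorted <- sort(unique(d))
  if (length(dep_sorted) < 2L) {
    return(structure(list(break_found = FALSE, interval = NULL,
                          all_intervals = NULL, clade_depths = clade_depths,
                          status = "no_depth_spread"),
                     class = "depth_break_report"))
  }
  if (identical(thresholds, "auto")) {
    cand <- (dep_sorted[-1] + dep_sorted[-length(dep_sorted)]) / 2
  } else {
    cand <- sort(as.numeric(thresholds))
  }
  spans <- vapply(cand, function(ct) {
    any(clade_depths$depth_min < ct & clade_depths$depth_max > ct)
  }, logical(1))
  valid <- !spans
  runs <- rle(valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ivs <- list()
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    lo_cut <- cand[starts[k]]; hi_cut <- cand[ends[k]]
    d_lo <- max(d[d < lo_cut])
    d_hi <- min(d[d > hi_cut])
    ivs[[length(ivs) + 1L]] <- data.frame(d_lo = d_lo, d_hi = d_hi,
                                          width = d_hi - d_lo)
  }
  all_iv <- if (length(ivs)) do.call(rbind, ivs) else NULL
  if (is.null(all_iv)) {
    interval <- NULL
  } else {
    best <- all_iv[order(-all_iv$width, all_iv$d_lo)[1L], ]
    interval <- c(best$d_lo, best$d_hi)
  }
  structure(list(break_found = !is.null(interval) && !degenerate,
                 interval = interval, all_intervals = all_iv,
                 clade_depths = clade_depths,
                 status = if (degenerate) "degenerate_single_clade" else "ok"),
            class = "depth_break_report")
}

#' @export
print.depth_break_report <- function(x, ...) {
  if (x$status == "degenerate_single_clade") {
    cat("<depth_break_report> single clade: every threshold trivially valid\n")
  } else if (!x$break_found) {
    cat("<depth_break_report> no separating depth threshold\n")
  } else {
    cat(sprintf("<depth_break_report> break between %.0f and %.0f m\n",
                x$interval[1], x$interval[2]))
  }
  invisible(x)
}
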