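# Orchestration: per-marker and combined analyses, report assembly and
# export.

#' Default pipeline configuration
#'
#' @param distance `"K2P"` or `"p"`.
#' @param gap_mode gap handling for step distances (`"fifth_state"` or
#'   `"missing"`).
#' @param depth_cut bathyal/abyssal cut depth (m).
#' @param parsimony_threshold connection-limit probability threshold.
#' @param fixed_limit optional fixed connection limit (steps).
#' @param ultra_tol relative ultrametricity tolerance for GMYC input trees.
#' @param seed seed echoed into reports.
#' @return a named list of effective settings.
#' @export
pipeline_config <- function(distance = "K2P", gap_mode = "fifth_state",
                            depth_cut = 3000, parsimony_threshold = 0.95,
                            fixed_limit = NULL, ultra_tol = 1e-6,
                            seed = NA_integer_) {
  list(distance = distance, gap_mode = gap_mode, depth_cut = depth_cut,
       parsimony_threshold = parsimony_threshold, fixed_limit = fixed_limit,
       ultra_tol = ultra_tol, seed = seed)
}

.stage <- function(report, name, value, params = NULL) {
  report$stages[[name]] <- list(result = value, params = params)
  report
}

.skip_stage <- function(report, name, reason) {
  report$skipped[[name]] <- reason
  report
}

#' Run the full per-marker analysis
#'
#' Stage order: haplotype collapsing, site classes, pairwise divergences,
#' barcoding gap, 4x criterion, parsimony networks, depth break, and GMYC
#' with likelihood-ratio test when a tree is supplied. When no partition is
#' given one is proposed by single-linkage clustering at the detected gap
#' midpoint (and tagged `"proposed"`); stages whose inputs are unavailable
#' are skipped with a logged reason.
#'
#' @param aln a `dna_alignment` (or FASTA path).
#' @param metadata specimen table (or TSV path) covering all alignment ids.
#' @param partition optional clade assignment; `NULL` to propose one.
#' @param tree optional ultrametric `phylo` (or Newick path) for GMYC.
#' @param config settings from [pipeline_config()].
#' @return a list of class `marker_report` with elements `marker`,
#'   `stages` (named results with their parameters), `skipped`,
#'   `partition_origin`, `config`.
#' @export
run_marker <- function(aln, metadata, partition = NULL, tree = NULL,
                       config = pipeline_config()) {
  if (is.character(aln)) aln <- read_fasta(aln)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  if (is.character(tree)) tree <- ape::read.tree(tree)
  orphans <- setdiff(aln_ids(aln), metadata$id)
  if (length(orphans) > 0L)
    stop("alignment ids missing from metadata: ",
         paste(orphans, collapse = ", "))
  report <- structure(list(marker = aln$marker, stages = list(),
                           skipped = list(), config = config),
                      class = "marker_report")
  haps <- collapse_haplotypes(aln, metadata)
  report <- .stage(report, "haplotypes", haps)
  report <- .stage(report, "site_classes", count_site_classes(aln))
  dm <- distance_matrix(aln, model = config$distance, on_saturation = "mask")
  report <- .stage(report, "distances",
                   list(n = length(dm_ids(dm)),
                        max = max(dm$values, na.rm = TRUE),
                        n_saturated = nrow(dm$saturated)),
                   params = list(model = config$distance,
                                 gap_policy = dm$gap_policy))
  report$distance_matrix <- dm
  if (is.null(partition)) {
    # propose clades from the distance distribution itself: cluster at the
    # midpoint of the barcoding gap of the all-singletons partition... a
    # partition is needed first, so propose from threshold scanning: use
    # the largest empty interval in the pairwise distance distribution
    dvec <- sort(dm$values[upper.tri(dm$values)])
    gaps <- diff(dvec)
    if (length(gaps) == 0L || max(gaps) <= 0) {
      report <- .skip_stage(report, "partition",
                            "no distance spread to propose clades from")
      partition <- NULL
    } else {
      cut <- dvec[which.max(gaps)] + max(gaps) / 2
      partition <- threshold_clusters(dm, cut)
      report$partition_origin <- list(origin = "proposed",
                                      threshold = cut)
    }
  } else {
    partition <- as_partition(partition)
    report$partition_origin <- list(origin = "supplied")
  }
  if (!is.null(partition)) {
    report$partition <- partition
    report <- .stage(report, "clade_summary",
                     intra_inter_summary(dm, partition))
    if (length(unique(as.character(partition))) >= 2L) {
      report <- .stage(report, "barcoding_gap", barcoding_gap(dm, partition))
      report <- .stage(report, "four_x", four_x(dm, partition))
    } else {
      report <- .skip_stage(report, "barcoding_gap", "single clade")
      report <- .skip_stage(report, "four_x", "single clade")
    }
    db <- tryCatch(depth_break(partition, metadata),
                   warning = function(w) suppressWarnings(
                     depth_break(partition, metadata)),
                   error = function(e) NULL)
    if (is.null(db)) report <- .skip_stage(report, "depth_break",
                                           "depths unavailable")
    else report <- .stage(report, "depth_break", db,
                          params = list(thresholds = "auto"))
  }
  lim <- connection_limit(n_columns(aln),
                          threshold = config$parsimony_threshold,
                          fixed_limit = config$fixed_limit)
  nets <- build_networks(haps, lim, gap_mode = config$gap_mode)
  report <- .stage(report, "networks",
                   list(networks = nets,
                        summary = suppressWarnings(
                          network_summary(nets, metadata,
                                          depth_cut = config$depth_cut))),
                   params = list(j_max = lim$j_max,
                                 threshold = config$parsimony_threshold,
                                 gap_mode = config$gap_mode,
                                 depth_cut = config$depth_cut))
  if (is.null(tree)) {
    report <- .skip_stage(report, "gmyc", "skipped: no tree")
  } else {
    null_fit <- fit_null(tree, ultra_tol = config$ultra_tol)
    alt_fit <- fit_gmyc(tree, ultra_tol = config$ultra_tol)
    report <- .stage(report, "gmyc",
                     list(null = null_fit, fit = alt_fit,
                          lrt = gmyc_lrt(null_fit, alt_fit)),
                     params = list(ultra_tol = config$ultra_tol))
  }
  report
}

#' @export
print.marker_report <- function(x, ...) {
  cat("<marker_report>", x$marker, "- stages:",
      paste(names(x$stages), collapse = ", "), "\n")
  if (length(x$skipped))
    cat("  skipped:", paste(names(x$skipped), unlist(x$skipped),
                            sep = " (", collapse = "), "), ")\n")
  invisible(x)
}

#' Run the combined multi-marker analysis
#'
#' Concatenates the markers (drop policy), collapses to unique
#' concatenated haplotypes, runs the distance-based stages on the
#' concatenated alignment, and reports cross-marker congruence of the
#' per-marker proposed partitions.
#'
#' @param alignments list of >= 2 `dna_alignment` objects.
#' @param metadata specimen table covering the shared ids.
#' @param partition optional clade assignment for the shared specimens.
#' @param config settings from [pipeline_config()].
#' @return a list of class `combined_report`.
#' @export
run_combined <- function(alignments, metadata, partition = NULL,
                         config = pipeline_config()) {
  if (length(alignments) < 2L)
    stop("combined analysis requires >= 2 markers")
  conc <- concatenate_markers(alignments, join_policy = "drop")
  report <- structure(list(markers = vapply(alignments, function(a) a$marker,
                                            character(1)),
                           blocks = attr(conc, "blocks"),
                           stages = list(), skipped = list(),
                           config = config),
                      class = "combined_report")
  report <- .stage(report, "concatenation",
                   list(n_specimens = length(aln_ids(conc)),
                        n_columns = n_columns(conc)))
  haps <- collapse_haplotypes(conc, metadata)
  report <- .stage(report, "haplotypes", haps)
  report <- .stage(report, "site_classes", count_site_classes(conc))
  sub_part <- if (!is.null(partition))
    as_partition(as_partition(partition)[aln_ids(conc)]) else NULL
  marker_rep <- run_marker(conc, metadata, partition = sub_part,
                           config = config)
  report <- .stage(report, "combined_marker", marker_rep)
  per_marker_parts <- lapply(alignments, function(a) {
    r <- run_marker(a, metadata, config = config)
    r$partition
  })
  per_marker_parts <- Filter(Negate(is.null), per_marker_parts)
  if (length(per_marker_parts) >= 2L) {
    pairs <- utils::combn(seq_along(per_marker_parts), 2L)
    cong <- apply(pairs, 2L, function(pr) {
      cmp <- compare_partitions(per_marker_parts[[pr[1]]],
                                per_marker_parts[[pr[2]]])
      data.frame(marker_a = alignments[[pr[1]]]$marker,
                 marker_b = alignments[[pr[2]]]$marker,
                 relation = cmp$relation,
                 n_conflicting_pairs = nrow(cmp$conflicts),
                 stringsAsFactors = FALSE)
    })
    report <- .stage(report, "congruence", do.call(rbind, cong))
  } else {
    report <- .skip_stage(report, "congruence",
                          "fewer than two per-marker partitions proposed")
  }
  report
}

#' @export
print.combined_report <- function(x, ...) {
  cat("<combined_report> markers:", paste(x$markers, collapse = "+"), "\n")
  invisible(x)
}

.jsonable <- function(x) {
  if (inherits(x, "clade_partition")) return(as.list(unclass(x)))
  if (inherits(x, "dna_alignment")) return(list(n = nrow(x$mat),
                                                n_columns = ncol(x$mat)))
  if (inherits(x, "divergence_matrix")) return(list(model = x$model,
                                                    n = nrow(x$values)))
  if (inherits(x, "parsimony_networks")) {
    lim <- attr(x, "limit")
    return(list(n_networks = length(x), j_max = lim$j_max,
                sizes = vapply(x, function(n) n$n_haplotypes, integer(1))))
  }
  if (inherits(x, "haplotype_table")) {
    return(list(n_haplotypes = nrow(x), totals = x$total))
  }
  if (inherits(x, "phylo")) return(list(n_tips = length(x$tip.label)))
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), .jsonable))
  x
}

#' Write a report to disk
#'
#' Exports the report as machine-readable JSON, Table-2-style TSV tables
#' (clade, intra min/max/mean, inter min/max/mean) where a clade summary is
#' present, and a plain-text summary. Empty/skipped sections are listed,
#' not expanded; ordering is deterministic.
#'
#' @param report a `marker_report` or `combined_report`.
#' @param outdir output directory (created if needed).
#' @param formats subset of `c("json", "tsv", "txt")`.
#' @return the output directory, invisibly.
#' @export
write_reports <- function(report, outdir, formats = c("json", "tsv", "txt")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tag <- if (inherits(report, "marker_report")) report$marker else "combined"
  if ("json" %in% formats) {
    jsonlite::write_json(.jsonable(report),
                         file.path(outdir, paste0(tag, "_report.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  if ("tsv" %in% formats && !is.null(report$stages$clade_summary)) {
    cs <- report$stages$clade_summary$result
    tab <- data.frame(clade = cs$clade,
                      intra_range = sprintf("%.3f-%.3f", cs$intra_min,
                                            cs$intra_max),
                      intra_mean = round(cs$intra_mean, 3),
                      inter_range = sprintf("%.3f-%.3f", cs$inter_min,
                                            cs$inter_max),
                      inter_mean = round(cs$inter_mean, 3))
    utils::write.table(tab, file.path(outdir, paste0(tag, "_clades.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if ("txt" %in% formats) {
    con <- file(file.path(outdir, paste0(tag, "_summary.txt")), "w")
    sink(con)
    on.exit({ sink(); close(con) })
    print(report)
    for (nm in names(report$stages)) {
      cat("\n==", nm, "==\n")
      res <- report$stages[[nm]]$result
      if (is.data.frame(res) || inherits(res, "haplotype_table")) {
        print(utils::head(as.data.frame(res)[, setdiff(names(res), "members")],
                          30))
      } else if (!is.null(attr(class(res), "package")) || is.list(res)) {
        utils::str(res, max.level = 1, give.attr = FALSE)
      } else print(res)
    }
  }
  invisible(outdir)
}
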