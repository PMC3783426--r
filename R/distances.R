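# Pairwise divergence under the Kimura 2-parameter model and clade-wise
# intra/inter summaries.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Count transitions and transversions between two aligned sequences
#'
#' Sites where either sequence carries a gap or an ambiguity code are
#' excluded (pairwise deletion). Transitions are A<->G and C<->T; all other
#' base mismatches are transversions.
#'
#' @param a,b equal-length sequence strings or character vectors of residues.
#' @return a list of class `subst_counts` with `n_compared`,
#'   `n_transitions`, `n_transversions`, and the proportions `P` and `Q`.
#' @export
count_substitutions <- function(a, b) {
  if (is.character(a) && length(a) == 1L) a <- strsplit(toupper(a), "")[[1]]
  if (is.character(b) && length(b) == 1L) b <- strsplit(toupper(b), "")[[1]]
  if (length(a) != length(b))
    stop("sequences must have equal aligned length")
  ok <- a %in% DNA_BASES & b %in% DNA_BASES
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0L) stop("no comparable sites (pairwise deletion removed all)")
  diff <- a != b
  ti <- diff & ((a %in% PURINES & b %in% PURINES) |
                (a %in% PYRIMIDINES & b %in% PYRIMIDINES))
  structure(list(n_compared = n,
                 n_transitions = sum(ti),
                 n_transversions = sum(diff) - sum(ti),
                 P = sum(ti) / n,
                 Q = (sum(diff) - sum(ti)) / n),
            class = "subst_counts")
}

#' Kimura 2-parameter distance
#'
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` with `P` and `Q` the
#' transition and transversion proportions. Saturated pairs (arguments of
#' the logarithm non-positive) raise an explicit error rather than
#' returning a non-finite value.
#'
#' @param counts a `subst_counts` object, or a transition proportion `P`
#'   when `Q` is supplied.
#' @param Q transversion proportion (only when `counts` is numeric `P`).
#' @return distance in expected substitutions per site.
#' @export
k2p_distance <- function(counts, Q = NULL) {
  if (inherits(counts, "subst_counts")) {
    P <- counts$P; Q <- counts$Q
  } else {
    P <- counts
    if (is.null(Q)) stop("Q must be supplied when P is given directly")
  }
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("distance undefined (saturated): 1-2P-Q = ", signif(w1, 4),
         ", 1-2Q = ", signif(w2, 4))
  -0.5 * log(w1 * sqrt(w2))
}

#' Uncorrected p-distance
#'
#' Proportion of differing sites among pairwise-comparable sites.
#'
#' @inheritParams k2p_distance
#' @return distance as a proportion of differing sites.
#' @export
p_distance <- function(counts, Q = NULL) {
  if (inherits(counts, "subst_counts")) return(counts$P + counts$Q)
  if (is.null(Q)) stop("Q must be supplied when P is given directly")
  counts + Q
}

#' Pairwise divergence matrix
#'
#' Computes all pairwise distances in an alignment under pairwise deletion
#' of gap/ambiguity sites. Saturated pairs (K2P undefined) are an aggregate
#' error by default, or masked as `NA` with a recorded pair list.
#'
#' @param aln a `dna_alignment` with >= 2 records.
#' @param model `"K2P"` (default) or `"p"`.
#' @param on_saturation `"error"` (default) or `"mask"`.
#' @return an object of class `divergence_matrix`: list with `values`
#'   (symmetric numeric matrix, zero diagonal), `model`, `gap_policy`, and
#'   `saturated` (data.frame of masked pairs).
#' @export
distance_matrix <- function(aln, model = c("K2P", "p"),
                            on_saturation = c("error", "mask")) {
  model <- match.arg(model)
  on_saturation <- match.arg(on_saturation)
  ids <- aln_ids(aln)
  if (length(ids) < 2L) stop("distance matrix requires >= 2 sequences")
  n <- length(ids)
  vals <- matrix(0, n, n, dimnames = list(ids, ids))
  sat <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      cnt <- count_substitutions(aln$mat[i, ], aln$mat[j, ])
      d <- if (model == "p") {
        p_distance(cnt)
      } else {
        tryCatch(k2p_distance(cnt), error = function(e) {
          sat[[length(sat) + 1L]] <<- data.frame(
            id_a = ids[i], id_b = ids[j], P = cnt$P, Q = cnt$Q,
            stringsAsFactors = FALSE)
          NA_real_
        })
      }
      vals[i, j] <- vals[j, i] <- d
    }
  }
  sat_df <- if (length(sat)) do.call(rbind, sat) else
    data.frame(id_a = character(), id_b = character(),
               P = numeric(), Q = numeric(), stringsAsFactors = FALSE)
  if (nrow(sat_df) > 0L && on_saturation == "error")
    stop("saturated pairs (K2P undefined): ",
         paste(paste(sat_df$id_a, sat_df$id_b, sep = "/"), collapse = ", "))
  structure(list(values = vals, model = model,
                 gap_policy = "pairwise_deletion", saturated = sat_df),
            class = "divergence_matrix")
}

#' @export
print.divergence_matrix <- function(x, ...) {
  cat("<divergence_matrix>", x$model, "model,", nrow(x$values), "ids,",
      "gap policy:", x$gap_policy, "\n")
  if (nrow(x$saturated)) cat("  masked saturated pairs:", nrow(x$saturated), "\n")
  invisible(x)
}

#' Ids of a divergence matrix
#' @param dm a `divergence_matrix`.
#' @return character vector of ids.
#' @export
dm_ids <- function(dm) rownames(dm$values)

#' Build a divergence matrix from raw values
#'
#' Mainly for tests and for importing externally computed matrices; the
#' matrix must be symmetric with a zero diagonal.
#'
#' @param values symmetric numeric matrix with dimnames.
#' @param model model tag.
#' @return a `divergence_matrix`.
#' @export
as_divergence_matrix <- function(values, model = "K2P") {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-12)
    stop("matrix is not symmetric")
  if (any(diag(values) != 0)) stop("diagonal must be zero")
  structure(list(values = values, model = model, gap_policy = "as_supplied",
                 saturated = data.frame(id_a = character(), id_b = character(),
                                        P = numeric(), Q = numeric())),
            class = "divergence_matrix")
}

#' Export a divergence matrix
#'
#' @param dm a `divergence_matrix`.
#' @param path output path.
#' @param format `"tsv"` (square, ids in first row/column) or `"phylip"`
#'   (square PHYLIP).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  v <- dm$values
  if (format == "tsv") {
    df <- data.frame(id = rownames(v), v, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(v)), con)
    for (i in seq_len(nrow(v))) {
      writeLines(paste(formatC(rownames(v)[i], width = -10),
                       paste(sprintf("%.6f", v[i, ]), collapse = "  ")), con)
    }
  }
  invisible(path)
}

#' Clade-wise intra- and interclade divergence summary
#'
#' For each clade, summarises within-clade pairwise distances (min, max,
#' unweighted mean over pairs) and distances from clade members to all
#' non-members. Intraclade statistics are `NA` for singleton clades.
#'
#' @param dm a `divergence_matrix`.
#' @param partition named character vector mapping every id in `dm` to a
#'   clade label (see [as_partition()]).
#' @return a `data.frame` with one row per clade: `clade`, `n`, `intra_min`,
#'   `intra_max`, `intra_mean`, `inter_min`, `inter_max`, `inter_mean`.
#' @export
intra_inter_summary <- function(dm, partition) {
  partition <- as_partition(partition)
  ids <- dm_ids(dm)
  miss <- setdiff(ids, names(partition))
  if (length(miss) > 0L)
    stop("ids without a clade assignment: ", paste(miss, collapse = ", "))
  lab <- partition[ids]
  v <- dm$values
  clades <- sort(unique(lab))
  rows <- lapply(clades, function(cl) {
    memb <- ids[lab == cl]
    other <- ids[lab != cl]
    if (length(memb) >= 2L) {
      intra <- v[memb, memb][upper.tri(v[memb, memb])]
      istat <- c(min(intra), max(intra), mean(intra))
    } else {
      istat <- c(NA_real_, NA_real_, NA_real_)
    }
    if (length(other) >= 1L) {
      inter <- as.vector(v[memb, other, drop = FALSE])
      estat <- c(min(inter), max(inter), mean(inter))
    } else {
      estat <- c(NA_real_, NA_real_, NA_real_)
    }
    data.frame(clade = cl, n = length(memb),
               intra_min = istat[1], intra_max = istat[2], intra_mean = istat[3],
               inter_min = estat[1], inter_max = estat[2], inter_mean = estat[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
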