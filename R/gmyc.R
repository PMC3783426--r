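# Single-threshold general mixed Yule-coalescent delimitation on
# ultrametric trees, one-process null model, likelihood-ratio test, and a
# UPGMA fallback tree builder.
#
# Model: a threshold height T separates a diversification (Yule-type)
# regime, whose lineages are all species-level lineages, from a
# within-species regime in which each multi-tip cluster (maximal subtree
# rooted at or below T) is a coalescent-type set sharing (lambda2, p2).
# Branching events at node heights t_1 > ... > t_(n-1) partition time into
# waiting intervals; each interval contributes b_i * exp(-b_i * x_i) with
# b_i the summed generalised rate lambda * n^p of every active process
# (above T: lambda1 * LTT^p1; below T: lambda1 * n_entities^p1 plus
# lambda2 * sum_k n_k^p2 over active clusters). The one-process null model
# is the T = 0 boundary, so the mixed fit is never below the null.

#' UPGMA tree from a divergence matrix
#'
#' Average-linkage clustering; node height is half the merge distance, so
#' the cophenetic distance of the tree reproduces an ultrametric input
#' matrix exactly. Ids are sorted before clustering so ties break by the
#' smallest member label.
#'
#' @param dm a `divergence_matrix`.
#' @return an ultrametric `phylo` tree.
#' @export
upgma_tree <- function(dm) {
  ids <- sort(dm_ids(dm))
  if (length(ids) < 2L) stop("UPGMA requires >= 2 ids")
  v <- dm$values[ids, ids]
  if (anyNA(v)) stop("divergence matrix contains masked (NA) entries")
  hc <- stats::hclust(stats::as.dist(v), method = "average")
  ape::as.phylo(hc)
}

# node heights (time before present) for an ultrametric tree, with strict
# parent > child ordering enforced by a tiny downward perturbation of
# zero-length internal edges (1e-10 of tree height)
.node_heights <- function(tree, ultra_tol = 1e-6) {
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  n_tip <- length(tree$tip.label)
  if (n_tip < 3L) stop("tree must have >= 3 tips")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  depths <- ape::node.depth.edgelength(tree)  # root-to-node path lengths
  tip_depth <- depths[seq_len(n_tip)]
  span <- max(depths)
  if (span <= 0) stop("tree has zero height")
  if (max(tip_depth) - min(tip_depth) > ultra_tol * span)
    stop("tree is not ultrametric within tolerance (relative spread ",
         signif((max(tip_depth) - min(tip_depth)) / span, 3), ")")
  h <- max(tip_depth) - depths  # heights; tips ~ 0
  h[seq_len(n_tip)] <- 0
  # strictify: child strictly below parent
  eps <- 1e-10 * span
  parent_of <- integer(2L * n_tip - 1L)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  for (node in (n_tip + 1L):(2L * n_tip - 1L)) {
    p <- parent_of[node]
    if (p != 0L && h[node] >= h[p]) h[node] <- h[p] - eps
  }
  list(tree = tree, heights = h, n_tip = n_tip,
       parent_of = parent_of, root = n_tip + 1L)
}

# children lists and internal-node / tip descendants of every internal node
.tree_index <- function(th) {
  tree <- th$tree
  n_tip <- th$n_tip
  kids <- vector("list", 2L * n_tip - 1L)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[e, 2])
  }
  tip_desc <- vector("list", 2L * n_tip - 1L)
  int_desc <- vector("list", 2L * n_tip - 1L)
  # nodes sorted by increasing height guarantee children are visited first
  internal <- (n_tip + 1L):(2L * n_tip - 1L)
  for (node in internal[order(th$heights[internal])]) {
    td <- integer(0); idn <- node
    for (k in kids[[node]]) {
      if (k <= n_tip) td <- c(td, k)
      else { td <- c(td, tip_desc[[k]]); idn <- c(idn, int_desc[[k]]) }
    }
    tip_desc[[node]] <- td
    int_desc[[node]] <- idn
  }
  list(kids = kids, tip_desc = tip_desc, int_desc = int_desc)
}

# threshold classification: cluster roots, singleton tips, entity counts
.threshold_groups <- function(th, idx, T) {
  n_tip <- th$n_tip
  h <- th$heights
  internal <- (n_tip + 1L):(2L * n_tip - 1L)
  cl_roots <- internal[vapply(internal, function(v) {
    h[v] <= T && (v == th$root || h[th$parent_of[v]] > T)
  }, logical(1))]
  in_cluster <- unique(unlist(idx$tip_desc[cl_roots]))
  singles <- setdiff(seq_len(n_tip), in_cluster)
  list(cluster_roots = cl_roots, singleton_tips = singles,
       n_clusters = length(cl_roots),
       n_entities = length(cl_roots) + length(singles))
}

# interval structure for the mixed likelihood at threshold T: successive
# branching events t_1 > ... > t_(n-1); each inter-event waiting time ends
# at an event and contributes b_i * exp(-b_i * x_i), with b_i the summed
# rate of the processes active during the interval
.gmyc_structure <- function(th, idx, T) {
  h <- th$heights
  internal <- (th$n_tip + 1L):(2L * th$n_tip - 1L)
  ev <- sort(h[internal], decreasing = TRUE)
  m <- length(ev)                     # n_tip - 1 events
  grp <- .threshold_groups(th, idx, T)
  bpts <- ev
  ends_event <- rep(TRUE, m)
  if (T < ev[1] && T > ev[m]) {
    pos <- sum(ev > T)                # split the interval containing T
    bpts <- c(ev[seq_len(pos)], T, ev[(pos + 1L):m])
    ends_event <- c(rep(TRUE, pos), FALSE, rep(TRUE, m - pos))
  }
  K <- grp$n_clusters
  nseg <- length(bpts) - 1L
  x <- numeric(nseg); nY <- numeric(nseg)
  ends <- logical(nseg)
  M <- matrix(0, nseg, max(K, 1L))
  cl_h <- h[grp$cluster_roots]
  cl_int_h <- lapply(grp$cluster_roots, function(v) h[idx$int_desc[[v]]])
  for (s in seq_len(nseg)) {
    hi <- bpts[s]; lo <- bpts[s + 1L]
    x[s] <- hi - lo
    ends[s] <- ends_event[s + 1L]
    tm <- (hi + lo) / 2
    if (tm > T) {
      nY[s] <- 1 + sum(ev > tm)       # every crossing lineage is species-level
    } else {
      nY[s] <- grp$n_entities         # species-level lineages persist below T
      if (K > 0L) {
        for (k in seq_len(K)) {
          if (tm < cl_h[k]) M[s, k] <- 1 + sum(cl_int_h[[k]] > tm)
        }
      }
    }
  }
  list(x = x, nY = nY, M = M, Mpos = M > 0, ends = ends, K = K,
       n_events = sum(ends), grp = grp, T = T)
}

.LAMBDA_BOUNDS <- c(1e-8, 1e6)
.P_BOUNDS <- c(0, 10)
.LOGL_BOUNDS <- log(.LAMBDA_BOUNDS)

# log-likelihood of the mixed model on a precomputed structure
.gmyc_ll <- function(st, lambda1, p1, lambda2, p2) {
  A <- st$nY^p1
  C <- if (st$K > 0L) rowSums((st$M^p2) * st$Mpos) else 0
  b <- lambda1 * A + lambda2 * C
  if (any(b <= 0)) return(-Inf)
  sum(log(b[st$ends])) - sum(b * st$x)
}

# maximise the mixed likelihood on a structure: deterministic multi-start
# box-constrained quasi-Newton, followed by a Nelder-Mead polish
.fit_structure <- function(st, n_starts = 3L) {
  ev_n <- st$n_events
  lam0 <- function(w) {
    denom <- sum(w * st$x)
    if (denom <= 0) 1 else max(min(ev_n / denom, 1e5), 1e-7)
  }
  l1 <- lam0(st$nY)
  has_coal <- st$K > 0L && any(st$M > 0)
  if (has_coal) {
    l2 <- lam0(rowSums(st$M * st$Mpos))
    starts <- list(c(log(l1), 1, log(l2), 1),
                   c(log(l1), 0.5, log(l2), 2.5),
                   c(log(l1), 2, log(l2), 0.5))[seq_len(n_starts)]
    fn <- function(par) -.gmyc_ll(st, exp(par[1]), par[2], exp(par[3]), par[4])
    lower <- c(.LOGL_BOUNDS[1], .P_BOUNDS[1], .LOGL_BOUNDS[1], .P_BOUNDS[1])
    upper <- c(.LOGL_BOUNDS[2], .P_BOUNDS[2], .LOGL_BOUNDS[2], .P_BOUNDS[2])
  } else {
    starts <- list(c(log(l1), 1), c(log(l1), 0.5), c(log(l1), 2))[seq_len(n_starts)]
    fn <- function(par) -.gmyc_ll(st, exp(par[1]), par[2], 0, 1)
    lower <- c(.LOGL_BOUNDS[1], .P_BOUNDS[1])
    upper <- c(.LOGL_BOUNDS[2], .P_BOUNDS[2])
  }
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      stats::optim(s0, fn, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimiser failed to converge at threshold ",
                          signif(st$T, 6))
  polish <- tryCatch(
    stats::optim(best$par, function(par) fn(pmin(pmax(par, lower), upper)),
                 method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value < best$value) {
    polish$par <- pmin(pmax(polish$par, lower), upper)
    best <- polish
  }
  par <- best$par
  list(lambda1 = exp(par[1]), p1 = par[2],
       lambda2 = if (has_coal) exp(par[3]) else NA_real_,
       p2 = if (has_coal) par[4] else NA_real_,
       logLik = -best$value)
}

#' Branching schedule under a threshold
#'
#' Returns the inter-event interval bookkeeping used by the mixed
#' likelihood: per interval, its duration, the number of
#' diversification-process lineages, the pooled coalescent lineage count,
#' per-cluster counts, and whether the interval ends at a branching event
#' (the interval containing the threshold is split at it). Also reports
#' the entity grouping at the threshold.
#'
#' @param tree an ultrametric `phylo`.
#' @param T threshold height (time before present).
#' @param ultra_tol relative ultrametricity tolerance.
#' @return a list with `intervals` (data.frame `duration`, `n_yule`,
#'   `n_coalescent`, `ends_at_event`), `cluster_counts` (interval-by-
#'   cluster matrix or `NULL`), `n_clusters`, `n_entities`.
#' @export
branching_schedule <- function(tree, T, ultra_tol = 1e-6) {
  th <- .node_heights(tree, ultra_tol)
  idx <- .tree_index(th)
  st <- .gmyc_structure(th, idx, T)
  list(intervals = data.frame(
         duration = st$x, n_yule = st$nY,
         n_coalescent = if (st$K > 0L) rowSums(st$M) else 0,
         ends_at_event = st$ends),
       cluster_counts = if (st$K > 0L) st$M else NULL,
       n_clusters = st$grp$n_clusters, n_entities = st$grp$n_entities)
}

#' Mixed-model log-likelihood at fixed parameters
#'
#' Evaluates the threshold likelihood directly; used for worked examples
#' and cross-checks of the fitting engine.
#'
#' @inheritParams branching_schedule
#' @param lambda1,p1 diversification-process rate and exponent.
#' @param lambda2,p2 coalescent-process rate and exponent (shared across
#'   within-species clusters).
#' @return log-likelihood (scalar).
#' @export
gmyc_loglik <- function(tree, T, lambda1, p1, lambda2 = 0, p2 = 1,
                        ultra_tol = 1e-6) {
  th <- .node_heights(tree, ultra_tol)
  idx <- .tree_index(th)
  st <- .gmyc_structure(th, idx, T)
  .gmyc_ll(st, lambda1, p1, lambda2, p2)
}

#' Fit the one-process null model
#'
#' A single generalised branching process over the whole tree (all
#' specimens one species): each inter-event waiting time `x_i` with `n_i`
#' lineages contributes `b_i * exp(-b_i * x_i)`, `b_i = lambda * n_i^p`.
#' At the profile optimum the rate satisfies
#' `lambda = n_events / sum(n_i^p * x_i)`.
#'
#' @param tree an ultrametric `phylo` with >= 3 tips.
#' @param ultra_tol relative ultrametricity tolerance.
#' @param n_starts deterministic optimiser starts.
#' @return a list of class `gmyc_null_fit`: `lambda`, `p`, `logLik`,
#'   `n_tips`.
#' @export
fit_null <- function(tree, ultra_tol = 1e-6, n_starts = 3L) {
  th <- .node_heights(tree, ultra_tol)
  idx <- .tree_index(th)
  st <- .gmyc_structure(th, idx, 0)
  fit <- .fit_structure(st, n_starts)
  structure(list(lambda = fit$lambda1, p = fit$p1, logLik = fit$logLik,
                 n_tips = th$n_tip),
            class = "gmyc_null_fit")
}

#' @export
print.gmyc_null_fit <- function(x, ...) {
  cat(sprintf("<gmyc_null_fit> lambda = %.4g, p = %.3f, lnL = %.4f\n",
              x$lambda, x$p, x$logLik))
  invisible(x)
}

#' Fit the single-threshold mixed Yule-coalescent model
#'
#' Profiles the threshold `T` over midpoints between consecutive distinct
#' node heights plus the boundary `T = 0` (the all-singletons case, which
#' coincides with the one-process null model, so the maximised mixed
#' likelihood can never fall below the null's). At each candidate the four
#' parameters (diversification `lambda1, p1`; shared coalescent
#' `lambda2, p2`) are maximised from three deterministic starts with a
#' simplex polish. The threshold support set is every candidate within 2
#' log-likelihood units of the maximum.
#'
#' @param tree an ultrametric `phylo` with >= 4 tips.
#' @param ultra_tol relative ultrametricity tolerance.
#' @param n_starts deterministic optimiser starts per candidate.
#' @return a list of class `gmyc_fit`: `lambda1`, `p1` (diversification),
#'   `lambda2`, `p2` (coalescent), `threshold`, `logLik`, `n_clusters`
#'   (multi-tip groups), `n_entities` (clusters + singletons),
#'   `support_interval` (range of supported thresholds), `profile`
#'   (data.frame per candidate), `partition` (tip id -> entity label),
#'   `n_tips`.
#' @export
fit_gmyc <- function(tree, ultra_tol = 1e-6, n_starts = 3L) {
  th <- .node_heights(tree, ultra_tol)
  if (th$n_tip < 4L) stop("GMYC fit requires >= 4 tips")
  idx <- .tree_index(th)
  hs <- sort(unique(th$heights[(th$n_tip + 1L):(2L * th$n_tip - 1L)]),
             decreasing = TRUE)
  cands <- sort(c(0, (hs[-1] + hs[-length(hs)]) / 2))
  prof <- vector("list", length(cands))
  for (i in seq_along(cands)) {
    st <- .gmyc_structure(th, idx, cands[i])
    fit <- .fit_structure(st, n_starts)
    prof[[i]] <- data.frame(T = cands[i], logLik = fit$logLik,
                            n_clusters = st$grp$n_clusters,
                            n_entities = st$grp$n_entities,
                            lambda1 = fit$lambda1, p1 = fit$p1,
                            lambda2 = fit$lambda2, p2 = fit$p2)
  }
  prof <- do.call(rbind, prof)
  best <- which.max(prof$logLik)
  support <- prof$T[prof$logLik >= prof$logLik[best] - 2]
  grp <- .threshold_groups(th, idx, prof$T[best])
  part <- .entity_partition(th, idx, grp)
  structure(list(lambda1 = prof$lambda1[best], p1 = prof$p1[best],
                 lambda2 = prof$lambda2[best], p2 = prof$p2[best],
                 threshold = prof$T[best], logLik = prof$logLik[best],
                 n_clusters = prof$n_clusters[best],
                 n_entities = prof$n_entities[best],
                 support_interval = range(support),
                 profile = prof, partition = part, n_tips = th$n_tip),
            class = "gmyc_fit")
}

.entity_partition <- function(th, idx, grp) {
  labels <- th$tree$tip.label
  groups <- c(lapply(grp$cluster_roots, function(v) labels[idx$tip_desc[[v]]]),
              lapply(grp$singleton_tips, function(v) labels[v]))
  ord <- order(-lengths(groups), vapply(groups, min, character(1)))
  groups <- groups[ord]
  out <- character(length(labels))
  names(out) <- labels
  for (k in seq_along(groups)) out[groups[[k]]] <- sprintf("G%02d", k)
  as_partition(out)
}

#' @export
print.gmyc_fit <- function(x, ...) {
  cat(sprintf(paste0("<gmyc_fit> lnL = %.4f at threshold %.4g; %d clusters, ",
                     "%d entities (of %d tips)\n"),
              x$logLik, x$threshold, x$n_clusters, x$n_entities, x$n_tips))
  cat(sprintf("  support interval: [%.4g, %.4g]\n",
              x$support_interval[1], x$support_interval[2]))
  invisible(x)
}

#' Likelihood-ratio test of the mixed model against the null
#'
#' Statistic `2 * (lnL_GMYC - lnL_null)`, referred to a chi-square with
#' `df` degrees of freedom (default 3: the threshold plus one extra rate
#' and one extra exponent).
#'
#' @param null a `gmyc_null_fit`, or a numeric null log-likelihood.
#' @param fit a `gmyc_fit`, or a numeric alternative log-likelihood.
#' @param df chi-square degrees of freedom.
#' @return a list of class `gmyc_lrt`: `statistic`, `df`, `p_value`.
#' @export
gmyc_lrt <- function(null, fit, df = 3) {
  ln0 <- if (is.numeric(null)) null else null$logLik
  ln1 <- if (is.numeric(fit)) fit else fit$logLik
  stat <- 2 * (ln1 - ln0)
  if (stat < -1e-6)
    stop("negative likelihood-ratio statistic (", signif(stat, 4),
         "): optimiser failure in one of the fits")
  stat <- max(stat, 0)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df = df, lower.tail = FALSE)),
            class = "gmyc_lrt")
}

#' @export
print.gmyc_lrt <- function(x, ...) {
  cat(sprintf("<gmyc_lrt> 2*dlnL = %.5f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
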