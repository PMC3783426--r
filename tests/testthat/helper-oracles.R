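# Independent brute-force oracles and random-instance generators used
# across the suite. Oracles deliberately use naive per-element loops and
# never call the code paths they check.

rand_alignment <- function(n, L, alphabet = c("A", "C", "G", "T"),
                           marker = "sim") {
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(alphabet, L, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- sprintf("seq%02d", seq_len(n))
  suppressWarnings(dna_alignment(seqs, marker = marker))
}

# exhaustive per-column site classifier
oracle_site_classes <- function(mat) {
  n_sites <- ncol(mat)
  n_var <- 0L; n_inf <- 0L
  for (j in seq_len(n_sites)) {
    col <- mat[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    states <- unique(col)
    if (length(col) >= 2L && length(states) >= 2L) {
      n_var <- n_var + 1L
      counts <- vapply(states, function(s) sum(col == s), integer(1))
      if (sum(counts >= 2L) >= 2L) n_inf <- n_inf + 1L
    }
  }
  list(n_sites = n_sites, n_constant = n_sites - n_var, n_variable = n_var,
       n_singleton = n_var - n_inf, n_parsimony_informative = n_inf)
}

# site-by-site substitution counter
oracle_substitutions <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  ti_pairs <- list(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  n <- 0L; ti <- 0L; tv <- 0L
  for (i in seq_along(a)) {
    if (a[i] %in% c("A", "C", "G", "T") && b[i] %in% c("A", "C", "G", "T")) {
      n <- n + 1L
      if (a[i] != b[i]) {
        is_ti <- any(vapply(ti_pairs, function(p)
          p[1] == a[i] && p[2] == b[i], logical(1)))
        if (is_ti) ti <- ti + 1L else tv <- tv + 1L
      }
    }
  }
  list(n_compared = n, n_transitions = ti, n_transversions = tv)
}

# transitive closure over the <= threshold graph
oracle_components <- function(values, threshold) {
  n <- nrow(values)
  adj <- !is.na(values) & values <= threshold
  diag(adj) <- TRUE
  reach <- adj
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (reach[i, k] && reach[k, j]) reach[i, j] <- TRUE
  comp <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) { nxt <- nxt + 1L; comp[reach[i, ]] <- nxt }
  }
  comp
}

# pair-enumeration intra/inter summary
oracle_summary <- function(values, labels) {
  ids <- rownames(values)
  out <- list()
  for (cl in sort(unique(labels))) {
    intra <- c(); inter <- c()
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i < j) {
        d <- values[i, j]
        if (labels[i] == cl && labels[j] == cl) intra <- c(intra, d)
        else if (xor(labels[i] == cl, labels[j] == cl)) inter <- c(inter, d)
      }
    }
    out[[cl]] <- list(intra = intra, inter = inter)
  }
  out
}

# naive UPGMA: repeatedly merge the closest pair, averaging distances
# weighted by cluster sizes; returns the cophenetic matrix
oracle_upgma_cophenetic <- function(values) {
  ids <- rownames(values)
  n <- length(ids)
  clusters <- as.list(seq_len(n))
  d <- values
  active <- rep(TRUE, n)
  coph <- matrix(0, n, n, dimnames = list(ids, ids))
  dmat <- d
  sizes <- rep(1L, n)
  idx <- seq_len(n)
  while (sum(active) > 1L) {
    act <- which(active)
    best <- c(NA, NA); bd <- Inf
    for (i in act) for (j in act) if (i < j && dmat[i, j] < bd) {
      bd <- dmat[i, j]; best <- c(i, j)
    }
    i <- best[1]; j <- best[2]
    for (a in clusters[[i]]) for (b in clusters[[j]]) {
      coph[a, b] <- coph[b, a] <- bd
    }
    # average-linkage update into slot i
    for (k in act) {
      if (k != i && k != j) {
        dmat[i, k] <- dmat[k, i] <-
          (sizes[i] * dmat[i, k] + sizes[j] * dmat[j, k]) / (sizes[i] + sizes[j])
      }
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
  }
  coph
}

# random ultrametric-ish distance matrix from random cluster heights
rand_distance_matrix <- function(n, scale = 0.1) {
  m <- matrix(0, n, n)
  pts <- stats::runif(n)
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    m[i, j] <- m[j, i] <- abs(pts[i] - pts[j]) * scale + stats::runif(1, 0, 0.01)
  }
  m <- (m + t(m)) / 2
  dimnames(m) <- list(sprintf("t%02d", seq_len(n)), sprintf("t%02d", seq_len(n)))
  m
}

# truncated-series evaluation of the parsimony-probability model: number
# of hits per site geometric with ratio a = theta/(1+theta); state change
# per Jukes-Cantor. Computes P(1 hit | differ)^j * P(0 | same)^(m-j) by
# explicit series for P(differ | k) instead of the closed forms
oracle_parsimony_prob <- function(j, m, kmax = 200) {
  p <- j / m
  if (p >= 0.75) return(0)
  theta <- p / (1 - 4 * p / 3)
  a <- theta / (1 + theta)
  pk <- (1 - a) * a^(0:kmax)
  p_diff_k <- 0.75 * (1 - (-1 / 3)^(0:kmax))
  p_diff <- sum(pk * p_diff_k)
  p_same <- sum(pk * (1 - p_diff_k))
  p1_diff <- pk[2] * p_diff_k[2] / p_diff
  p0_same <- pk[1] * (1 - p_diff_k[1]) / p_same
  p1_diff^j * p0_same^(m - j)
}

# small ultrametric tree with chosen node heights, as newick
toy_tree <- function(newick) ape::read.tree(text = newick)
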