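# Coalescent-within-Yule synthetic datasets with the statistical structure
# the delimitation analyses assume: a few strongly separated species-level
# clades (interclade divergence an order of magnitude above intraclade),
# each clade confined to a bathyal or abyssal depth stratum.

#' Simulation configuration
#'
#' Defaults describe the "paper-like" preset: 9 species (2 bathyal, 7
#' abyssal, strata separated at 3,000 m), 45 specimens, three markers with
#' lengths 658/489/1274 and relative substitution rates chosen so the fast
#' mitochondrial markers accumulate percent-level interclade divergence
#' while the slow nuclear marker stays sub-percent. Species divergence
#' times span `species_depth_range` (expected substitutions per site at
#' rate 1) and the within-species coalescent is scaled so the expected
#' pairwise within-species divergence is `theta`; with the defaults the
#' interclade:intraclade mean divergence ratio comfortably exceeds 10.
#'
#' @param n_species number of species-level clades `S`.
#' @param n_per_species per-species sample sizes (recycled to `S`).
#' @param marker_lengths named integer vector of alignment lengths.
#' @param marker_rates named relative substitution rates (same names).
#' @param kappa transition/transversion rate ratio of the K80 generator.
#' @param theta expected pairwise within-species divergence (substitutions
#'   per site at rate 1).
#' @param species_depth_range range of species-tree node heights, in
#'   expected substitutions per site at rate 1.
#' @param strata per-species stratum labels (`"bathyal"`/`"abyssal"`,
#'   recycled to `S`).
#' @param stratum_ranges named list of depth ranges (m) per stratum.
#' @param seed integer seed; mandatory, all randomness flows from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_species = 9L,
                       n_per_species = c(10L, 8L, 6L, 5L, 4L, 4L, 1L, 3L, 4L),
                       marker_lengths = c(COI = 658L, `16S` = 489L, `28S` = 1274L),
                       marker_rates = c(COI = 1, `16S` = 0.4, `28S` = 0.05),
                       kappa = 4,
                       theta = 0.0015,
                       species_depth_range = c(0.03, 0.065),
                       strata = c("bathyal", "bathyal", rep("abyssal", 7L)),
                       stratum_ranges = list(bathyal = c(800, 2743),
                                             abyssal = c(3070, 4700)),
                       seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  stopifnot(n_species >= 1L, all(n_per_species >= 1L),
            all(marker_lengths >= 10L), kappa > 0, theta >= 0,
            identical(names(marker_lengths), names(marker_rates)))
  structure(list(n_species = as.integer(n_species),
                 n_per_species = rep_len(as.integer(n_per_species), n_species),
                 marker_lengths = marker_lengths,
                 marker_rates = marker_rates,
                 kappa = kappa, theta = theta,
                 species_depth_range = species_depth_range,
                 strata = rep_len(strata, n_species),
                 stratum_ranges = stratum_ranges,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# monotone map of species-tree node heights into [lo, hi]; preserves the
# child < parent ordering, hence yields a valid ultrametric tree
.rescale_heights <- function(tree, lo, hi) {
  n_tip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  h <- max(depths[seq_len(n_tip)]) - depths
  h[seq_len(n_tip)] <- 0
  internal <- (n_tip + 1L):(2L * n_tip - 1L)
  hmin <- min(h[internal]); hmax <- max(h[internal])
  hnew <- h
  hnew[internal] <- if (hmax > hmin)
    lo + (h[internal] - hmin) / (hmax - hmin) * (hi - lo) else hi
  tree$edge.length <- hnew[tree$edge[, 1]] - hnew[tree$edge[, 2]]
  tree
}

# newick of a coalescent genealogy for one species, scaled so the expected
# pairwise coalescence time is `theta2` (theta/2 in divergence units)
.species_genealogy <- function(label, n, theta2) {
  tips <- sprintf("%s_%02d", label, seq_len(n))
  if (n == 1L) return(list(newick = tips, height = 0, tips = tips))
  g <- ape::rcoal(n, tip.label = tips)
  g$edge.length <- g$edge.length * theta2
  height <- max(ape::node.depth.edgelength(g)[seq_len(n)])
  nwk <- ape::write.tree(g)
  nwk <- sub(";$", "", nwk)
  list(newick = nwk, height = height, tips = tips)
}

#' Simulate the true genealogy and partition
#'
#' A Yule species tree of `S` tips, with node heights mapped into
#' `species_depth_range`, carries an independent within-species coalescent
#' genealogy grafted at each species tip (expected pairwise coalescence
#' time `theta / 2`, i.e. expected pairwise divergence `theta` at rate 1).
#' With `S = 1` the tree is a pure coalescent genealogy. Uses the current
#' RNG state; seed management is the caller's (see [make_dataset()]).
#'
#' @param config a `sim_config`.
#' @param species_tree optional pre-drawn species tree (`phylo` with tips
#'   `SPTIP001`, ...), so several markers can resample within-species
#'   genealogies on the same species-level history.
#' @return a list with `tree` (ultrametric `phylo`, tips `s01_01`, ...),
#'   `partition` (true clade assignment, class `clade_partition`),
#'   `species` (per-species tip sets) and `species_tree`.
#' @export
simulate_tree <- function(config, species_tree = NULL) {
  S <- config$n_species
  theta2 <- config$theta / 2
  sp_labels <- sprintf("s%02d", seq_len(S))
  gene <- lapply(seq_len(S), function(k)
    .species_genealogy(sp_labels[k], config$n_per_species[k], theta2))
  sp_tree <- species_tree
  if (S == 1L) {
    tree <- if (config$n_per_species[1] >= 2L)
      ape::read.tree(text = paste0(gene[[1]]$newick, ";"))
    else stop("S = 1 requires n_per_species >= 2")
  } else {
    if (is.null(sp_tree)) {
      sp_tree <- ape::rphylo(S, birth = 1, death = 0)
      sp_tree$tip.label <- sprintf("SPTIP%03d", seq_len(S))
      sp_tree <- .rescale_heights(sp_tree, config$species_depth_range[1],
                                  config$species_depth_range[2])
    }
    tip_edge <- sp_tree$edge.length[match(seq_len(S), sp_tree$edge[, 2])]
    nwk <- ape::write.tree(sp_tree)
    for (k in seq_len(S)) {
      # redraw genealogies too deep for their species branch (rare under
      # sensible theta / species-depth settings; bounded retries)
      tries <- 0L
      while (gene[[k]]$height >= 0.9 * tip_edge[k] && tries < 100L) {
        gene[[k]] <- .species_genealogy(sp_labels[k],
                                        config$n_per_species[k], theta2)
        tries <- tries + 1L
      }
      stem <- tip_edge[k] - gene[[k]]$height
      if (stem <= 0)
        stop("coalescent genealogy deeper than its species branch; ",
             "increase species_depth_range relative to theta")
      piece <- if (config$n_per_species[k] == 1L)
        sprintf("%s:%.10f", gene[[k]]$tips, tip_edge[k])
      else sprintf("%s:%.10f", gene[[k]]$newick, stem)
      nwk <- sub(sprintf("SPTIP%03d:[0-9.eE+-]+", k), piece, nwk)
    }
    tree <- ape::read.tree(text = nwk)
  }
  species <- lapply(gene, function(g) g$tips)
  names(species) <- sp_labels
  part <- as_partition(stats::setNames(
    rep(sp_labels, vapply(species, length, integer(1))), unlist(species)))
  list(tree = tree, partition = part, species = species,
       species_tree = sp_tree)
}

# K80 transition probabilities for branch length t (expected substitutions
# per site), kappa = alpha/beta with alpha + 2 beta = 1
.k80_probs <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  p_ti <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1          # each of the two transversion targets
  c(same = 1 - p_ti - 2 * p_tv, ti = p_ti, tv = p_tv)
}

#' Evolve sequences along a tree under the K80 model
#'
#' Two-parameter (Kimura-80) substitution simulation with equal base
#' frequencies: branch lengths are interpreted as expected substitutions
#' per site multiplied by `rate`. The expected K2P distance between two
#' tips approximates `rate` times their path length.
#'
#' @param tree a `phylo` with branch lengths.
#' @param L alignment length (sites, iid).
#' @param kappa transition/transversion rate ratio.
#' @param rate rate multiplier applied to all branches.
#' @param seed integer seed (the function sets the RNG).
#' @param marker marker label for the returned alignment.
#' @return a `dna_alignment` over the tree's tip labels.
#' @export
evolve_sequences <- function(tree, L, kappa = 4, rate = 1, seed,
                             marker = "sim") {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  set.seed(as.integer(seed))
  bases <- DNA_BASES                  # A C G T
  partner <- c(3L, 4L, 1L, 2L)        # A<->G, C<->T
  n_tip <- length(tree$tip.label)
  n_node <- 2L * n_tip - 1L
  tree <- ape::reorder.phylo(tree, "cladewise")   # parents before children
  states <- matrix(0L, n_node, L)
  root <- n_tip + 1L
  states[root, ] <- sample.int(4L, L, replace = TRUE)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    pr <- .k80_probs(tree$edge.length[e] * rate, kappa)
    u <- stats::runif(L)
    cur <- states[par, ]
    out <- cur
    is_ti <- u >= pr["same"] & u < pr["same"] + pr["ti"]
    out[is_ti] <- partner[cur[is_ti]]
    is_tv <- u >= pr["same"] + pr["ti"]
    if (any(is_tv)) {
      # the two transversion targets of each base, picked uniformly
      tv_choice <- stats::runif(sum(is_tv)) < 0.5
      tv_targets <- rbind(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L))
      out[is_tv] <- ifelse(tv_choice, tv_targets[cur[is_tv], 1],
                           tv_targets[cur[is_tv], 2])
    }
    states[child, ] <- out
  }
  seqs <- apply(states[seq_len(n_tip), , drop = FALSE], 1L,
                function(row) paste(bases[row], collapse = ""))
  names(seqs) <- tree$tip.label
  dna_alignment(seqs, marker = marker)
}

#' Generate a complete synthetic multi-marker dataset
#'
#' Draws the species-level genealogy once, then an independent
#' within-species genealogy per marker (free recombination between loci)
#' on the same species tree, evolves each marker at its own rate, assigns
#' every species a depth stratum and samples specimen depths uniformly
#' within the stratum range. All randomness derives from `config$seed`.
#'
#' @param config a `sim_config`.
#' @param dir optional output directory; when given, writes FASTA per
#'   marker, `metadata.tsv`, `partition.tsv`, `tree_<marker>.nwk` and
#'   `config.json`.
#' @return a list of class `synthetic_dataset`: `alignments` (named list
#'   of `dna_alignment`), `metadata` (specimen table), `partition` (true
#'   clades), `trees` (per-marker genealogies), `tree` (the first marker's
#'   genealogy, the dataset's reference ultrametric tree), `config`.
#' @export
make_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  marker_seeds <- sample.int(.Machine$integer.max - 1L,
                             length(config$marker_lengths) * 2L)
  sim <- simulate_tree(config)
  trees <- list()
  alignments <- list()
  # all markers share the species-level history; within-species genealogies
  # are redrawn per marker (free recombination between loci)
  for (i in seq_along(config$marker_lengths)) {
    mk <- names(config$marker_lengths)[i]
    set.seed(marker_seeds[2L * i - 1L])
    trees[[mk]] <- if (i == 1L) sim$tree else
      simulate_tree(config, species_tree = sim$species_tree)$tree
    alignments[[mk]] <- evolve_sequences(
      trees[[mk]], L = config$marker_lengths[[i]], kappa = config$kappa,
      rate = config$marker_rates[[i]], seed = marker_seeds[2L * i],
      marker = mk)
  }
  ids <- names(sim$partition)
  sp_of <- as.character(sim$partition)
  stratum <- config$strata[match(sp_of, sprintf("s%02d", seq_len(config$n_species)))]
  set.seed(marker_seeds[1L] %% 1000003L + 7L)
  depth <- vapply(stratum, function(s) {
    r <- config$stratum_ranges[[s]]
    stats::runif(1, r[1], r[2])
  }, numeric(1))
  metadata <- data.frame(
    id = ids,
    locality = paste0("sim-", sp_of),
    basin = paste0("basin-", sp_of),
    lat = round(stats::runif(length(ids), -60, 80), 3),
    lon = round(stats::runif(length(ids), -180, 180), 3),
    depth_m = round(depth),
    source = "synthetic",
    multiplicity = 1L,
    stringsAsFactors = FALSE)
  out <- structure(list(alignments = alignments, metadata = metadata,
                        partition = sim$partition, trees = trees,
                        tree = trees[[1L]], config = config),
                   class = "synthetic_dataset")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (mk in names(alignments)) {
      write_fasta(alignments[[mk]], file.path(dir, paste0(mk, ".fasta")))
      ape::write.tree(trees[[mk]], file.path(dir, paste0("tree_", mk, ".nwk")))
    }
    write_metadata(metadata, file.path(dir, "metadata.tsv"))
    write_partition(sim$partition, file.path(dir, "partition.tsv"))
    cfg <- config
    class(cfg) <- NULL
    cfg$stratum_ranges <- lapply(cfg$stratum_ranges, as.numeric)
    jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE)
  }
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>", x$config$n_species, "species,",
      nrow(x$metadata), "specimens, markers:",
      paste(names(x$alignments), collapse = ", "), "\n")
  invisible(x)
}
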