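# Substitution counting, K2P / p-distance, matrix assembly and clade
# summaries.

test_that("substitution counts match the per-site oracle and handle gaps", {
  a <- "ACGTACGTACGTACGTACGT"
  g <- "GCGTACGTACGTACGTACGA"  # A->G transition at 1, T->A transversion at 20
  cnt <- count_substitutions(a, g)
  expect_identical(cnt$n_transitions, 1L)
  expect_identical(cnt$n_transversions, 1L)
  expect_identical(cnt$n_compared, 20L)
  ident <- count_substitutions(a, a)
  expect_equal(ident$P, 0)
  expect_equal(ident$Q, 0)
  # pairwise deletion excludes gap/ambiguity sites
  cnt2 <- count_substitutions("AC-TN", "ACGTA")
  expect_identical(cnt2$n_compared, 3L)
  expect_error(count_substitutions("---", "ACG"), "no comparable sites")
  expect_error(count_substitutions("ACGT", "ACG"), "equal")
  set.seed(11)
  for (rep in 1:30) {
    x <- paste(sample(c("A", "C", "G", "T", "-", "N"), 40, TRUE), collapse = "")
    y <- paste(sample(c("A", "C", "G", "T", "-", "N"), 40, TRUE), collapse = "")
    got <- count_substitutions(x, y)
    want <- oracle_substitutions(x, y)
    expect_identical(got$n_compared, want$n_compared)
    expect_identical(got$n_transitions, want$n_transitions)
    expect_identical(got$n_transversions, want$n_transversions)
  }
})

test_that("K2P evaluates its closed form, errors at saturation, bounds p-distance", {
  expect_equal(k2p_distance(0, Q = 0), 0)
  # P=0.1, Q=0.05: d = -0.5*log(0.75*sqrt(0.9))
  expect_equal(k2p_distance(0.1, Q = 0.05), -0.5 * log(0.75 * sqrt(0.9)),
               tolerance = 1e-12)
  expect_equal(k2p_distance(0.1, Q = 0.05), 0.17018, tolerance = 1e-4)
  expect_error(k2p_distance(0.5, Q = 0), "saturated")
  expect_error(k2p_distance(0.2, Q = 0.5), "saturated")
  # transversion-free limit reduces to -0.5*log(1-2P) on a grid
  for (P in seq(0.01, 0.4, by = 0.05)) {
    expect_equal(k2p_distance(P, Q = 0), -0.5 * log(1 - 2 * P),
                 tolerance = 1e-12)
  }
  # monotone in P and Q; p-distance never exceeds K2P
  grid <- expand.grid(P = seq(0, 0.3, 0.03), Q = seq(0, 0.2, 0.02))
  d <- mapply(function(P, Q) k2p_distance(P, Q = Q), grid$P, grid$Q)
  pd <- grid$P + grid$Q
  expect_true(all(d >= pd - 1e-12))
  for (Q0 in unique(grid$Q)) {
    dQ <- d[grid$Q == Q0][order(grid$P[grid$Q == Q0])]
    expect_true(all(diff(dQ) > 0))
  }
  for (P0 in unique(grid$P)) {
    dP <- d[grid$P == P0][order(grid$Q[grid$P == P0])]
    expect_true(all(diff(dP) > 0))
  }
  expect_equal(p_distance(0.05, Q = 0.05), 0.1)
})

test_that("distance matrices agree with ape's K80 implementation", {
  set.seed(23)
  cfg <- sim_config(n_species = 3L, n_per_species = 4L,
                    strata = c("bathyal", "abyssal", "abyssal"), seed = 23)
  ds <- make_dataset(cfg)
  aln <- ds$alignments$COI
  dm <- distance_matrix(aln, model = "K2P")
  bin <- ape::as.DNAbin(strsplit(tolower(aln_strings(aln)), ""))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE))
  expect_equal(unname(dm$values), unname(ref[dm_ids(dm), dm_ids(dm)]),
               tolerance = 1e-9)
  # symmetry, zero diagonal, composition with count_substitutions
  expect_identical(dm$values, t(dm$values))
  expect_true(all(diag(dm$values) == 0))
  i <- dm_ids(dm)[2]; j <- dm_ids(dm)[7]
  expect_equal(dm$values[i, j],
               k2p_distance(count_substitutions(aln$mat[i, ], aln$mat[j, ])))
})

test_that("saturated pairs error by default and can be masked", {
  aln <- dna_alignment(c(a = "AAAAAAAAAA", b = "GGGGGGGGGG", c = "AAAAAAAAAG"))
  expect_error(distance_matrix(aln), "saturated")
  dm <- distance_matrix(aln, on_saturation = "mask")
  expect_identical(nrow(dm$saturated), 2L)   # a-b and b-c both saturate
  expect_true(is.na(dm$values["a", "b"]))
  expect_false(is.na(dm$values["a", "c"]))
})

test_that("clade summaries equal exhaustive pair enumeration and respect labels", {
  # constant-matrix toy: intra 0.01, inter 0.10
  v <- matrix(0.10, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  v[1, 2] <- v[2, 1] <- v[3, 4] <- v[4, 3] <- 0.01
  diag(v) <- 0
  dm <- as_divergence_matrix(v)
  part <- as_partition(c(a = "X", b = "X", c = "Y", d = "Y"))
  s <- intra_inter_summary(dm, part)
  expect_equal(s$intra_mean, c(0.01, 0.01))
  expect_equal(s$inter_mean, c(0.10, 0.10))
  # singleton clade reports intra as NA
  s2 <- intra_inter_summary(dm, as_partition(c(a = "X", b = "X", c = "Y",
                                               d = "Z")))
  expect_true(is.na(s2$intra_mean[s2$clade == "Z"]))
  expect_identical(s2$n[s2$clade == "Z"], 1L)
  set.seed(37)
  for (rep in 1:10) {
    n <- sample(5:9, 1)
    v <- rand_distance_matrix(n)
    labs <- sample(c("p", "q", "r"), n, replace = TRUE)
    part <- as_partition(stats::setNames(labs, rownames(v)))
    got <- intra_inter_summary(as_divergence_matrix(v), part)
    want <- oracle_summary(v, labs)
    for (cl in got$clade) {
      w <- want[[cl]]
      if (length(w$intra) > 0) {
        expect_equal(got$intra_mean[got$clade == cl], mean(w$intra))
        expect_equal(got$intra_max[got$clade == cl], max(w$intra))
      }
      expect_equal(got$inter_min[got$clade == cl], min(w$inter))
      expect_equal(got$inter_mean[got$clade == cl], mean(w$inter))
    }
    # invariance under relabeling and permutation
    perm <- sample(rownames(v))
    got2 <- intra_inter_summary(
      as_divergence_matrix(v[perm, perm]),
      as_partition(stats::setNames(paste0("cl_", labs), rownames(v))[perm]))
    expect_equal(got2$intra_mean[order(got2$clade)],
                 got$intra_mean[order(got$clade)])
  }
})

test_that("distance matrices export to TSV and PHYLIP", {
  v <- rand_distance_matrix(4)
  dm <- as_divergence_matrix(v)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(dm, tsv, format = "tsv")
  back <- utils::read.delim(tsv, check.names = FALSE)
  expect_equal(as.numeric(back[2, 2]), v[2, 1])
  phy <- withr::local_tempfile(fileext = ".phy")
  write_distance_matrix(dm, phy, format = "phylip")
  expect_match(readLines(phy)[1], "^\\s*4$")
})
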