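# Coalescent-within-Yule generator: determinism, tree structure,
# sequence evolution and dataset assembly.

test_that("configs validate their inputs and require a seed", {
  expect_error(sim_config(), "seed")
  cfg <- sim_config(seed = 1)
  expect_identical(cfg$n_species, 9L)
  expect_identical(sum(cfg$n_per_species), 45L)
  expect_identical(unname(cfg$marker_lengths), c(658L, 489L, 1274L))
  expect_error(sim_config(seed = 1, kappa = -1))
  expect_error(sim_config(seed = 1, marker_lengths = c(COI = 5L),
                          marker_rates = c(COI = 1)))
})

test_that("simulated trees are ultrametric with species-consistent tips", {
  cfg <- sim_config(seed = 3)
  set.seed(3)
  sim <- simulate_tree(cfg)
  expect_s3_class(sim$tree, "phylo")
  expect_identical(length(sim$tree$tip.label), 45L)
  expect_true(ape::is.ultrametric(sim$tree, tol = 1e-6))
  expect_identical(length(unique(sim$partition)), 9L)
  # species are monophyletic on the true genealogy
  for (sp in names(sim$species)) {
    tips <- sim$species[[sp]]
    if (length(tips) >= 2) {
      m <- ape::getMRCA(sim$tree, tips)
      expect_setequal(ape::extract.clade(sim$tree, m)$tip.label, tips)
    }
  }
  # single species: pure coalescent genealogy
  cfg1 <- sim_config(n_species = 1L, n_per_species = 6L, strata = "abyssal",
                     seed = 5)
  set.seed(5)
  sim1 <- simulate_tree(cfg1)
  expect_identical(length(sim1$tree$tip.label), 6L)
  expect_true(ape::is.ultrametric(sim1$tree, tol = 1e-6))
})

test_that("coalescent depth follows the theta*(1 - 1/n) expectation", {
  cfg <- sim_config(n_species = 1L, n_per_species = 8L, strata = "abyssal",
                    theta = 0.004, seed = 11)
  set.seed(11)
  depths <- replicate(500, {
    sim <- simulate_tree(cfg)
    max(ape::node.depth.edgelength(sim$tree))
  })
  want <- cfg$theta * (1 - 1 / 8)
  expect_equal(mean(depths), want, tolerance = 0.1)
})

test_that("theta near zero collapses within-species heights", {
  cfg <- sim_config(theta = 1e-8, seed = 13)
  set.seed(13)
  sim <- simulate_tree(cfg)
  th <- bathydelim:::.node_heights(sim$tree)
  for (sp in names(sim$species)) {
    tips <- sim$species[[sp]]
    if (length(tips) >= 2) {
      expect_lt(th$heights[ape::getMRCA(sim$tree, tips)], 1e-6)
    }
  }
})

test_that("sequence evolution is seed-deterministic and rate-0 is constant", {
  tre <- ape::rcoal(6)
  a1 <- evolve_sequences(tre, L = 100, kappa = 4, rate = 1, seed = 7)
  a2 <- evolve_sequences(tre, L = 100, kappa = 4, rate = 1, seed = 7)
  expect_identical(aln_strings(a1), aln_strings(a2))
  a3 <- evolve_sequences(tre, L = 100, kappa = 4, rate = 1, seed = 8)
  expect_false(identical(aln_strings(a1), aln_strings(a3)))
  a0 <- evolve_sequences(tre, L = 50, kappa = 4, rate = 0, seed = 7)
  expect_identical(length(unique(aln_strings(a0))), 1L)
})

test_that("estimated K2P distances track true path lengths with small bias", {
  # two tips at a known distance; average relative bias over replicates
  set.seed(17)
  for (d_true in c(0.05, 0.15)) {
    tre <- ape::read.tree(text = sprintf("(a:%f,b:%f);", d_true / 2, d_true / 2))
    est <- replicate(60, {
      aln <- evolve_sequences(tre, L = 2000, kappa = 4, rate = 1,
                              seed = sample.int(1e6, 1))
      k2p_distance(count_substitutions(aln$mat["a", ], aln$mat["b", ]))
    })
    expect_lt(abs(mean(est) - d_true) / d_true, 0.05)
  }
})

test_that("datasets are reproducible, stratified, and internally consistent", {
  cfg <- sim_config(seed = 19)
  ds1 <- make_dataset(cfg)
  ds2 <- make_dataset(cfg)
  expect_identical(lapply(ds1$alignments, aln_strings),
                   lapply(ds2$alignments, aln_strings))
  expect_identical(ds1$metadata, ds2$metadata)
  # depths respect the stratum assignment of each species
  strat <- cfg$strata[match(as.character(ds1$partition[ds1$metadata$id]),
                            sprintf("s%02d", 1:9))]
  rng <- cfg$stratum_ranges
  expect_true(all(ds1$metadata$depth_m[strat == "bathyal"] <=
                    rng$bathyal[2] + 0.5))
  expect_true(all(ds1$metadata$depth_m[strat == "abyssal"] >=
                    rng$abyssal[1] - 0.5))
  # all markers cover the same specimens; partition covers all ids
  for (mk in names(ds1$alignments)) {
    expect_setequal(aln_ids(ds1$alignments[[mk]]), ds1$metadata$id)
  }
  expect_setequal(names(ds1$partition), ds1$metadata$id)
  # file export writes every advertised artefact
  dir <- withr::local_tempdir()
  make_dataset(cfg, dir = dir)
  expect_true(all(file.exists(file.path(dir,
    c("COI.fasta", "16S.fasta", "28S.fasta", "metadata.tsv",
      "partition.tsv", "tree_COI.nwk", "config.json")))))
  back <- read_fasta(file.path(dir, "COI.fasta"), marker = "COI")
  expect_identical(aln_strings(back), aln_strings(ds1$alignments$COI))
})

test_that("the default preset yields the assumed divergence structure", {
  ds <- make_dataset(sim_config(seed = 29))
  dm <- distance_matrix(ds$alignments$COI)
  s <- intra_inter_summary(dm, ds$partition)
  # interclade means at least an order of magnitude above intraclade means
  ratio <- mean(s$inter_mean) / mean(s$intra_mean, na.rm = TRUE)
  expect_gte(ratio, 10)
  # a designed negative control: deep within-species variation against a
  # shallow species split defeats the 4x rule
  cfg_bad <- sim_config(n_species = 2L, n_per_species = 6L,
                        theta = 0.01, species_depth_range = c(0.02, 0.025),
                        strata = c("bathyal", "bathyal"), seed = 31)
  ds_bad <- make_dataset(cfg_bad)
  dm_bad <- distance_matrix(ds_bad$alignments$COI, on_saturation = "mask")
  fx <- four_x(dm_bad, ds_bad$partition)
  expect_false(fx$global_pass)
})
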