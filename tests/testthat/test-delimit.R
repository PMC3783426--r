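# Barcoding gap, 4x criterion, threshold clustering, clade merging,
# partition comparison and the bathymetric-break scan.

mk_dm <- function(v) as_divergence_matrix(v)

test_that("barcoding gap separates intra from inter and flags degenerate cases", {
  v <- matrix(0.1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  v[1, 2] <- v[2, 1] <- 0.01; v[3, 4] <- v[4, 3] <- 0.02
  diag(v) <- 0
  part <- as_partition(c(a = "X", b = "X", c = "Y", d = "Y"))
  g <- barcoding_gap(mk_dm(v), part)
  expect_true(g$gap_present)
  expect_equal(g$max_intra, 0.02)
  expect_equal(g$min_inter, 0.1)
  expect_equal(g$gap_interval, c(0.02, 0.1))
  # all-identical sequences: min_inter == max_intra == 0, no gap
  z <- matrix(0, 4, 4, dimnames = dimnames(v))
  gz <- barcoding_gap(mk_dm(z), part)
  expect_false(gz$gap_present)
  # singleton-only clades are undecidable
  singletons <- as_partition(c(a = "1", b = "2", c = "3", d = "4"))
  gs <- barcoding_gap(mk_dm(v), singletons)
  expect_identical(gs$status, "undecidable")
  expect_error(barcoding_gap(mk_dm(v), as_partition(c(a = "X", b = "X",
                                                      c = "X", d = "X"))),
               "2 clades")
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(6:10, 1)
    v <- rand_distance_matrix(n)
    labs <- sample(c("p", "q"), n, replace = TRUE)
    if (length(unique(labs)) < 2) labs[1] <- setdiff(c("p", "q"), labs[1])
    part <- as_partition(stats::setNames(labs, rownames(v)))
    g <- barcoding_gap(mk_dm(v), part)
    same <- outer(labs, labs, "==")
    ut <- upper.tri(v)
    expect_equal(g$max_intra, suppressWarnings(max(v[ut & same])))
    expect_equal(g$min_inter, min(v[ut & !same]))
  }
})

test_that("the 4x rule uses strict inequality on per-pair intra maxima", {
  v <- matrix(0.05, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  v[1, 2] <- v[2, 1] <- 0.01; v[3, 4] <- v[4, 3] <- 0.01
  diag(v) <- 0
  part <- as_partition(c(a = "X", b = "X", c = "Y", d = "Y"))
  fx <- four_x(mk_dm(v), part)
  expect_true(fx$global_pass)
  expect_equal(fx$pairs$ratio, 5)
  # ratio exactly 4 fails (strict)
  v2 <- v; v2[v2 == 0.05] <- 0.04
  fx2 <- four_x(mk_dm(v2), part)
  expect_false(fx2$global_pass)
  expect_equal(fx2$pairs$ratio, 4)
  # scale invariance
  fx3 <- four_x(mk_dm(v * 13), part)
  expect_equal(fx3$pairs$ratio, fx$pairs$ratio)
  expect_identical(fx3$global_pass, fx$global_pass)
  # singleton clades use intra max 0 and pass whenever separated
  p2 <- as_partition(c(a = "X", b = "X", c = "Y", d = "Z"))
  fx4 <- four_x(mk_dm(v), p2)
  expect_true(all(fx4$pairs$pass[fx4$pairs$max_intra == 0]))
})

test_that("threshold clustering equals brute-force transitive closure", {
  set.seed(53)
  for (rep in 1:10) {
    n <- sample(6:10, 1)
    v <- rand_distance_matrix(n)
    thr <- stats::runif(1, 0, 0.08)
    part <- threshold_clusters(mk_dm(v), thr)
    want <- oracle_components(v, thr)
    got <- as.integer(factor(as.character(part[rownames(v)]),
                             levels = unique(as.character(part[rownames(v)]))))
    expect_identical(length(unique(got)), length(unique(want)))
    expect_true(all(outer(got, got, "==") == outer(want, want, "==")))
  }
  v <- rand_distance_matrix(5)
  expect_identical(length(unique(threshold_clusters(mk_dm(v), 0))), 5L)
  expect_identical(length(unique(threshold_clusters(mk_dm(v), max(v)))), 1L)
})

test_that("clade merging relabels exactly the requested clades", {
  part <- as_partition(c(a = "Eg4", b = "Eg5", c = "Eg1", d = "Eg4"))
  merged <- merge_clades(part, c("Eg4", "Eg5"))
  expect_identical(length(unique(merged)), 2L)
  expect_identical(unname(merged[["a"]]), unname(merged[["b"]]))
  expect_identical(unname(merged[["c"]]), "Eg1")
  self <- merge_clades(part, "Eg1")
  expect_identical(length(unique(self)), length(unique(part)))
  expect_error(merge_clades(part, "Eg9"), "unknown")
})

test_that("partition comparison classifies equality, refinement and conflict", {
  pA <- as_partition(c(a = "1", b = "1", c = "2", d = "2"))
  expect_identical(compare_partitions(pA, pA)$relation, "equal")
  # relabeled copy is still equal
  pB <- as_partition(c(a = "x", b = "x", c = "y", d = "y"))
  expect_identical(compare_partitions(pA, pB)$relation, "equal")
  pC <- as_partition(c(a = "1", b = "2", c = "3", d = "3"))
  expect_identical(compare_partitions(pC, pB)$relation, "pA_refines_pB")
  expect_identical(compare_partitions(pB, pC)$relation, "pB_refines_pA")
  pD <- as_partition(c(a = "1", b = "2", c = "2", d = "1"))
  cmp <- compare_partitions(pA, pD)
  expect_identical(cmp$relation, "conflict")
  expect_true(nrow(cmp$conflicts) > 0)
  expect_error(compare_partitions(pA, as_partition(c(z = "1"))), "share no ids")
  # co-membership oracle on random partitions
  set.seed(61)
  for (rep in 1:10) {
    ids <- sprintf("i%02d", 1:7)
    a <- stats::setNames(sample(c("u", "v", "w"), 7, TRUE), ids)
    b <- stats::setNames(sample(c("u", "v"), 7, TRUE), ids)
    cmp <- compare_partitions(as_partition(a), as_partition(b))
    n_conf <- 0L
    for (i in 1:6) for (j in (i + 1):7) {
      if (xor(a[i] == a[j], b[i] == b[j])) n_conf <- n_conf + 1L
    }
    expect_identical(nrow(cmp$conflicts), n_conf)
  }
})

test_that("depth-break scan finds the separating interval between strata", {
  md <- data.frame(
    id = c("a1", "a2", "b1", "b2"),
    depth_m = c(800, 2743, 3070, 4693))
  part <- as_partition(c(a1 = "X", a2 = "X", b1 = "Y", b2 = "Y"))
  db <- depth_break(part, md)
  expect_true(db$break_found)
  expect_equal(db$interval, c(2743, 3070))
  # spanning clade blocks thresholds inside its range
  md2 <- data.frame(id = c("a1", "a2", "b1"), depth_m = c(2900, 3100, 5000))
  p2 <- as_partition(c(a1 = "X", a2 = "X", b1 = "Y"))
  db2 <- depth_break(p2, md2)
  expect_true(is.null(db2$interval) ||
                db2$interval[1] >= 3100 || db2$interval[2] <= 2900)
  # single clade is degenerate
  p3 <- as_partition(c(a1 = "X", a2 = "X"))
  db3 <- depth_break(p3, md[1:2, ])
  expect_identical(db3$status, "degenerate_single_clade")
  expect_false(db3$break_found)
  # all-same-depth has no spread
  md4 <- data.frame(id = c("a1", "b1"), depth_m = c(1000, 1000))
  p4 <- as_partition(c(a1 = "X", b1 = "Y"))
  expect_identical(depth_break(p4, md4)$status, "no_depth_spread")
  # row order of the metadata does not matter
  db5 <- depth_break(part, md[c(3, 1, 4, 2), ])
  expect_equal(db5$interval, db$interval)
  # midpoint enumeration against explicit candidate list
  db6 <- depth_break(part, md, thresholds = c(1000, 2900, 3500))
  expect_true(db6$break_found)
})

test_that("gap presence links to threshold clustering at an interior cut", {
  set.seed(71)
  cfg <- sim_config(n_species = 4L, n_per_species = 5L,
                    strata = c("bathyal", "abyssal", "abyssal", "abyssal"),
                    seed = 71)
  ds <- make_dataset(cfg)
  dm <- distance_matrix(ds$alignments$COI)
  g <- barcoding_gap(dm, ds$partition)
  expect_true(g$gap_present)
  for (t in c(g$gap_interval[1] * 1.01 + g$gap_interval[2] * 0.0,
              mean(g$gap_interval), g$gap_interval[2] * 0.99)) {
    part <- threshold_clusters(dm, t)
    expect_identical(compare_partitions(part, ds$partition)$relation, "equal")
  }
})

test_that("partitions round-trip through TSV", {
  part <- as_partition(c(a = "X", b = "Y"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_partition(part, path)
  expect_identical(as.character(read_partition(path)), c("X", "Y"))
})
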