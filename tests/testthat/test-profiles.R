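# Binding-profile analysis: Jaccard distances, distinct-profile counting,
# pair-category distributions and Mann-Whitney comparisons.

test_that("jaccard distance on hand-countable sets", {
  expect_equal(jaccard_distance(c(1L, 2L, 0L), c(1L, 2L, 0L)), 0)
  expect_equal(jaccard_distance(c(2L, 0L, 0L), c(0L, 1L, 2L)), 1)
  # A = {t1, t2}, B = {t2, t3} -> 1 - 1/3
  expect_equal(jaccard_distance(c(1L, 2L, 0L), c(0L, 1L, 1L)), 2 / 3)
  both_empty <- jaccard_distance(c(0L, 0L), c(0L, 0L))
  expect_equal(as.numeric(both_empty), 0)
  expect_true(attr(both_empty, "empty_pair"))
  expect_error(jaccard_distance(c(1L, 0L), c(1L, 0L, 2L)), "length")
  expect_error(jaccard_distance(c(a = 1L), c(b = 1L)), "target")
  expect_error(jaccard_distance(3L, 0L), "values")
})

test_that("jaccard distance is a metric on ternary vectors", {
  set.seed(42)
  for (rep in 1:100) {
    p <- sample(0:2, 8, replace = TRUE)
    q <- sample(0:2, 8, replace = TRUE)
    r <- sample(0:2, 8, replace = TRUE)
    if (sum(p + q) == 0 || sum(q + r) == 0 || sum(p + r) == 0) next
    dpq <- as.numeric(jaccard_distance(p, q))
    dqp <- as.numeric(jaccard_distance(q, p))
    dqr <- as.numeric(jaccard_distance(q, r))
    dpr <- as.numeric(jaccard_distance(p, r))
    expect_identical(dpq, dqp)
    expect_true(dpq >= 0 && dpq <= 1)
    expect_lte(dpr, dpq + dqr + 1e-12)
  }
})

test_that("distinct profiles are counted on full ternary vectors", {
  profiles <- rbind(a = c(1L, 2L, 0L), b = c(1L, 2L, 0L), c = c(1L, 1L, 0L),
                    d = c(0L, 1L, 2L))
  expect_equal(count_distinct_profiles(c("a", "b"), profiles), 1)
  expect_equal(count_distinct_profiles(c("a", "c", "d"), profiles), 3)
  # weak vs strong at a single target already makes profiles distinct
  expect_equal(count_distinct_profiles(c("b", "c"), profiles), 2)
  expect_equal(count_distinct_profiles(c("a", "b", "c"), profiles),
               count_distinct_profiles(c("c", "b", "a"), profiles))
  expect_error(count_distinct_profiles(c("a", "zz"), profiles), "zz")
})

test_that("distinct-profile breakdown matches the generator truth table", {
  lib0 <- generate_library(synthetic_library_config(
    n_families = 40, stereo_sensitivity = 0, undefined_fraction = 0,
    seed = 4))
  recs0 <- standardize_molecules(lib0$molecules$id, lib0$molecules$smiles)
  bd0 <- distinct_profile_breakdown(
    identify_stereoisomer_groups(recs0)$groups, lib0$profiles)
  expect_true(all(bd0$n_distinct_profiles == 1))
  expect_true(all(bd0$proportion == 1))

  lib1 <- generate_library(synthetic_library_config(
    n_families = 40, isomers_per_family = c(2, 2), stereo_sensitivity = 1,
    undefined_fraction = 0, seed = 4))
  recs1 <- standardize_molecules(lib1$molecules$id, lib1$molecules$smiles)
  bd1 <- distinct_profile_breakdown(
    identify_stereoisomer_groups(recs1)$groups, lib1$profiles)
  expect_true(all(bd1$n_distinct_profiles[bd1$group_size == 2] == 2))

  # intermediate sensitivity: size-2 proportions equal the truth table
  lib <- generate_library(synthetic_library_config(
    n_families = 120, isomers_per_family = c(2, 2), stereo_sensitivity = 0.1,
    undefined_fraction = 0, seed = 8))
  recs <- standardize_molecules(lib$molecules$id, lib$molecules$smiles)
  bd <- distinct_profile_breakdown(
    identify_stereoisomer_groups(recs)$groups, lib$profiles)
  prop2 <- bd$proportion[bd$group_size == 2 & bd$n_distinct_profiles == 2]
  expect_equal(prop2, mean(lib$truth$profile_differs))
})

test_that("pair categories behave as defined", {
  lib <- fix_small_library()
  recs <- fix_small_records()
  groups <- identify_stereoisomer_groups(recs)$groups
  pairs <- suppressWarnings(pair_category_distances(
    recs, groups, lib$profiles, n_random_pairs = 2000, seed = 31))
  expect_true(all(pairs$category %in% c("stereoisomer", "share0",
                                        "share_ge1")))
  # share0 pairs have disjoint bound sets, hence distance exactly 1
  expect_true(all(pairs$jaccard[pairs$category == "share0"] == 1))
  expect_true(all(pairs$jaccard >= 0 & pairs$jaccard <= 1))
  means <- tapply(pairs$jaccard, pairs$category, mean)
  expect_lt(means[["stereoisomer"]], means[["share_ge1"]])
  expect_lt(means[["share_ge1"]], means[["share0"]])
  again <- suppressWarnings(pair_category_distances(
    recs, groups, lib$profiles, n_random_pairs = 2000, seed = 31))
  expect_identical(pairs, again)
})

test_that("a shared common target forces share_ge1 distances to zero", {
  profiles <- matrix(0L, 4, 3,
                     dimnames = list(paste0("m", 1:4), paste0("T", 1:3)))
  profiles[, 1] <- 2L  # every compound binds exactly one common target
  recs <- data.frame(id = rownames(profiles))
  groups <- data.frame(group_id = character(0), connectivity_key = character(0),
                       member_id = character(0))
  pairs <- suppressWarnings(pair_category_distances(
    recs, groups, profiles, n_random_pairs = 10, seed = 1))
  expect_true(all(pairs$category == "share_ge1"))
  expect_true(all(pairs$jaccard == 0))
})

test_that("binarization can only merge profiles, never split them", {
  lib <- fix_small_library()
  tr <- lib$truth
  bin_differs <- vapply(seq_len(nrow(tr)), function(r) {
    as.numeric(jaccard_distance(lib$profiles[tr$id_a[r], ],
                                lib$profiles[tr$id_b[r], ])) > 0
  }, logical(1))
  expect_lte(mean(bin_differs), mean(tr$profile_differs))
})

test_that("mann-whitney comparison matches rank arithmetic", {
  res <- compare_distributions(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  same <- compare_distributions(1:1000, 1:1000)
  expect_gt(same$p_value, 0.9)
  shifted <- compare_distributions(rnorm(1000), rnorm(1000) + 10)
  expect_lt(shifted$p_value, 1e-10)
  expect_error(compare_distributions(numeric(0), 1), "non-empty")
})
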