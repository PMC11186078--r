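# Synthetic library generator: configuration validation, determinism,
# mutation semantics, signature geometry and on-disk round trips.

test_that("config validation rejects unsatisfiable settings", {
  expect_error(synthetic_library_config(isomers_per_family = c(3, 4),
                                        stereocenters_per_family = c(1, 3)),
               "unsatisfiable")
  expect_error(synthetic_library_config(stereo_sensitivity = 1.2),
               "probability")
  expect_error(synthetic_library_config(n_targets = 0), "count")
  expect_error(synthetic_library_config(n_families = 10000), "capacity")
  expect_s3_class(synthetic_library_config(), "synthetic_library_config")
})

test_that("generation is deterministic given the seed", {
  cfg <- synthetic_library_config(n_families = 15, seed = 9)
  lib1 <- generate_library(cfg)
  lib2 <- generate_library(cfg)
  expect_identical(lib1, lib2)
  lib3 <- generate_library(synthetic_library_config(n_families = 15, seed = 10))
  expect_false(identical(lib1$profiles, lib3$profiles))
})

test_that("zero stereo-sensitivity yields identical within-family profiles", {
  lib <- generate_library(synthetic_library_config(
    n_families = 40, stereo_sensitivity = 0, seed = 3))
  expect_true(nrow(lib$truth) > 0)
  expect_false(any(lib$truth$profile_differs))
})

test_that("full stereo-sensitivity makes every pair differ at every target", {
  lib <- generate_library(synthetic_library_config(
    n_families = 40, isomers_per_family = c(2, 2), stereo_sensitivity = 1,
    undefined_fraction = 0, seed = 3))
  expect_true(all(lib$truth$profile_differs))
  for (r in seq_len(nrow(lib$truth))) {
    pa <- lib$profiles[lib$truth$id_a[r], ]
    pb <- lib$profiles[lib$truth$id_b[r], ]
    expect_true(all(pa != pb))
  }
})

test_that("distinct-profile pair fraction matches 1-(1-p)^T", {
  # base-vs-isomer pairs only (2 isomers per family); binomial CI around the
  # closed-form Bernoulli complement
  p <- 0.01
  Tn <- 50
  lib <- generate_library(synthetic_library_config(
    n_families = 200, isomers_per_family = c(2, 2), n_targets = Tn,
    stereo_sensitivity = p, undefined_fraction = 0, seed = 11))
  theory <- 1 - (1 - p)^Tn
  expect_equal(theory, 0.395, tolerance = 0.01)
  phat <- mean(lib$truth$profile_differs)
  n <- nrow(lib$truth)
  expect_lt(abs(phat - theory), 1.96 * sqrt(theory * (1 - theory) / n))
})

test_that("truth table flags agree with the ternary vectors", {
  lib <- fix_small_library()
  for (r in seq_len(nrow(lib$truth))) {
    differs <- any(lib$profiles[lib$truth$id_a[r], ] !=
                     lib$profiles[lib$truth$id_b[r], ])
    expect_identical(differs, lib$truth$profile_differs[r])
  }
})

test_that("every fully defined compound has a nonzero profile", {
  lib <- generate_library(synthetic_library_config(
    n_families = 100, stereo_sensitivity = 0.9, seed = 5))
  defined <- lib$molecules$id[lib$molecules$fully_defined]
  expect_true(all(rowSums(lib$profiles[defined, , drop = FALSE] > 0) >= 1))
})

test_that("profile-differing pairs are farther apart in signature space", {
  lib <- generate_library(synthetic_library_config(
    n_families = 100, stereo_sensitivity = 0.1, seed = 17))
  D <- stereoactivity:::pairwise_cosine(lib$signatures)
  d <- D[cbind(match(lib$truth$id_a, rownames(D)),
               match(lib$truth$id_b, rownames(D)))]
  expect_gt(mean(d[lib$truth$profile_differs]),
            mean(d[!lib$truth$profile_differs]))
})

test_that("library round-trips losslessly through disk", {
  lib <- fix_small_library()
  dir <- withr::local_tempdir()
  manifest <- write_library(lib, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_equal(manifest$n_molecules, nrow(lib$molecules))
  back <- read_library(dir)
  expect_identical(back$profiles, lib$profiles)
  expect_identical(back$molecules, lib$molecules)
  expect_identical(back$truth$profile_differs, lib$truth$profile_differs)
  expect_lt(max(abs(back$signatures - lib$signatures)), 1e-12)
  expect_equal(unclass(back$config), unclass(lib$config))
})

test_that("a 1-family/2-isomer library writes 2 structures and 1 truth row", {
  lib <- generate_library(synthetic_library_config(
    n_families = 1, isomers_per_family = c(2, 2), undefined_fraction = 0,
    seed = 1))
  dir <- withr::local_tempdir()
  write_library(lib, dir)
  expect_equal(nrow(read_smi(file.path(dir, "molecules.smi"))), 2)
  expect_equal(nrow(read.table(file.path(dir, "truth.tsv"), header = TRUE)), 1)
})

test_that("an empty library writes a valid manifest and headed files", {
  lib <- generate_library(synthetic_library_config(n_families = 0))
  dir <- withr::local_tempdir()
  manifest <- write_library(lib, dir)
  expect_equal(manifest$n_molecules, 0)
  profs <- read_profiles(file.path(dir, "profiles.tsv"))
  expect_equal(nrow(profs), 0)
  expect_equal(ncol(profs), 50)
  back <- read_library(dir)
  expect_equal(nrow(back$molecules), 0)
})
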