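# kNN recapitulation benchmark: percentile cutoffs, pair construction,
# AUROC arithmetic and mode comparisons.

test_that("the percentile cutoff follows order statistics on a known grid", {
  grid <- as.numeric(1:1e6)
  cut <- nn_cutoff(grid, 0.001)
  expect_gt(cut, 10)
  expect_lt(cut, 11)
  expect_equal(mean(grid < cut), 1e-5)
  expect_equal(nn_cutoff(c(1, 2, 3), 50), 2)
  expect_warning(nn_cutoff(rep(5, 100), 1), "degenerate")
  expect_warning(nn_cutoff(1:10, 0.001), "coarse")
  expect_error(nn_cutoff(numeric(0), 1), "empty")
})

test_that("positives are exactly the intra-cluster pairs of a 2-cluster space", {
  # two tight clusters far apart: below-cutoff pairs must all be intra-cluster
  set.seed(1)
  X <- rbind(matrix(rnorm(20 * 3, sd = 0.01), ncol = 3) + 5,
             matrix(rnorm(20 * 3, sd = 0.01), ncol = 3) - 5)
  rownames(X) <- paste0(rep(c("a", "b"), each = 20), 1:20)
  D <- as.matrix(dist(X))
  cfg <- eval_config(nn_percentile = 40, n_subsample = 40,
                     n_repetitions = 1, seed = 2)
  pairs <- build_eval_pairs(D, cfg)
  pos <- pairs$repetitions[[1]]
  pos <- pos[pos$label == 1, ]
  cluster <- substr(pos$id_a, 1, 1)
  expect_true(all(substr(pos$id_b, 1, 1) == cluster))
  expect_true(all(D[cbind(pos$id_a, pos$id_b)] < pairs$cutoff))
})

test_that("stringent negatives lie inside the near-miss band", {
  bench <- fix_bench()
  cfg <- eval_config(nn_percentile = 0.1, negative_mode = "stringent",
                     stringent_band_multiplier = 10, n_subsample = 180,
                     n_repetitions = 5, seed = 3)
  pairs <- build_eval_pairs(bench$ref_dist, cfg)
  for (rp in pairs$repetitions) {
    neg <- rp[rp$label == 0, ]
    d <- bench$ref_dist[cbind(neg$id_a, neg$id_b)]
    expect_true(all(d > pairs$cutoff & d <= 10 * pairs$cutoff))
    expect_equal(sum(rp$label == 1), sum(rp$label == 0))  # balanced
  }
  again <- build_eval_pairs(bench$ref_dist, cfg)
  expect_identical(pairs, again)
})

test_that("AUROC is 1 when the candidate space is the reference space", {
  bench <- fix_bench()
  cfg <- eval_config(nn_percentile = 0.1, negative_mode = "random",
                     n_subsample = 180, n_repetitions = 5, seed = 4)
  pairs <- build_eval_pairs(bench$ref_dist, cfg)
  res <- recapitulation_auroc(pairs, bench$ref_dist, "self")
  expect_equal(res$mean_auroc, 1)
  expect_equal(res$mean_auroc, mean(res$per_repetition_auroc))
  expect_gt(res$n_positive_pairs, 0)
})

test_that("random candidate distances score near chance", {
  set.seed(7)
  n <- 200
  ref <- matrix(runif(n * n), n)
  ref[lower.tri(ref)] <- t(ref)[lower.tri(ref)]
  diag(ref) <- 0
  rownames(ref) <- colnames(ref) <- paste0("c", 1:n)
  cand <- matrix(runif(n * n), n)
  cand[lower.tri(cand)] <- t(cand)[lower.tri(cand)]
  diag(cand) <- 0
  dimnames(cand) <- dimnames(ref)
  cfg <- eval_config(nn_percentile = 10, n_subsample = n,
                     n_repetitions = 10, seed = 8)
  pairs <- build_eval_pairs(ref, cfg)
  res <- recapitulation_auroc(pairs, cand, "noise")
  expect_gt(sum(vapply(pairs$repetitions, nrow, integer(1))), 1000)
  expect_lt(abs(res$mean_auroc - 0.5), 0.05)
})

test_that("AUROC is invariant under monotone transforms of distances", {
  bench <- fix_bench()
  cfg <- eval_config(nn_percentile = 0.1, n_subsample = 180,
                     n_repetitions = 3, seed = 5)
  pairs <- build_eval_pairs(bench$ref_dist, cfg)
  r1 <- recapitulation_auroc(pairs, bench$geo_dist, "geo3d")
  r2 <- recapitulation_auroc(pairs, sqrt(bench$geo_dist), "geo3d-sqrt")
  expect_equal(r1$per_repetition_auroc, r2$per_repetition_auroc)
})

test_that("missing descriptors are reported by compound id", {
  bench <- fix_bench()
  cfg <- eval_config(nn_percentile = 0.1, n_subsample = 180,
                     n_repetitions = 2, seed = 6)
  pairs <- build_eval_pairs(bench$ref_dist, cfg)
  keep <- seq_len(floor(nrow(bench$geo_dist) / 2))
  truncated <- bench$geo_dist[keep, keep]
  expect_error(recapitulation_auroc(pairs, truncated, "geo3d"),
               "no candidate descriptor")
})

test_that("stringent negatives are at most as easy as random ones", {
  # statistical expectation across >= 5 seeds on a synthetic geometry where
  # the candidate is a noisy version of the reference
  set.seed(10)
  n <- 150
  X <- matrix(rnorm(n * 5), n)
  rownames(X) <- paste0("c", 1:n)
  ref <- as.matrix(dist(X))
  cand <- as.matrix(dist(X + matrix(rnorm(n * 5, sd = 1.2), n)))
  dimnames(cand) <- dimnames(ref)
  # the near-miss band must be narrower than the distance range for the
  # stringent pool to differ from the random one in this euclidean geometry
  aurocs <- vapply(1:6, function(seed) {
    r <- run_knn_benchmark(ref, list(c = cand),
                           eval_config(5, "random", n_subsample = 120,
                                       n_repetitions = 5, seed = seed))
    s <- run_knn_benchmark(ref, list(c = cand),
                           eval_config(5, "stringent",
                                       stringent_band_multiplier = 1.5,
                                       n_subsample = 120,
                                       n_repetitions = 5, seed = seed))
    c(random = r$c$mean_auroc, stringent = s$c$mean_auroc)
  }, numeric(2))
  # neither mode saturates (the comparison is informative) ...
  expect_lt(mean(aurocs["stringent", ]), 0.99)
  # ... and near-miss negatives are strictly harder on average
  expect_gt(mean(aurocs["random", ] - aurocs["stringent", ]), 0)
})

test_that("identical-signature fractions capture the 2D collapse", {
  bench <- fix_bench()
  tr <- bench$lib$truth
  expect_equal(identical_signature_fraction(tr, bench$fp2d), 1)
  expect_equal(identical_signature_fraction(tr, bench$geo3d), 0)
  expect_warning(
    frac <- identical_signature_fraction(tr[0, ], bench$fp2d),
    "empty")
  expect_equal(frac, 0)
})
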