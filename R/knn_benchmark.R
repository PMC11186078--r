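# Nearest-neighbor recapitulation benchmark.
#
# A reference bioactivity space (continuous signatures, cosine distances)
# defines nearest-neighbor pairs through a percentile cutoff of its distance
# distribution. A candidate descriptor is scored by how well its distances
# rank those positive pairs below negatives (AUROC), with negatives drawn
# either uniformly (random mode) or from a near-miss band just outside the
# cutoff (stringent mode), over seeded subsampled repetitions.

#' Evaluation configuration for the kNN benchmark
#'
#' @param nn_percentile percentile (in percent units) of the reference
#'   distance distribution defining nearest neighbors; 0.001 leaves tail mass
#'   1e-5 below the cutoff, 0.1 leaves 1e-3.
#' @param negative_mode `"random"` (uniform among non-neighbor pairs) or
#'   `"stringent"` (near-misses with reference distance in
#'   `(cutoff, stringent_band_multiplier * cutoff]`).
#' @param stringent_band_multiplier upper edge of the near-miss band, as a
#'   multiple of the cutoff.
#' @param n_subsample compounds drawn per repetition.
#' @param n_repetitions number of subsampled repetitions.
#' @param seed RNG seed.
#' @return a validated `eval_config` list.
#' @export
eval_config <- function(nn_percentile = 0.1, negative_mode = "random",
                        stringent_band_multiplier = 10, n_subsample = 2500,
                        n_repetitions = 10, seed = 1) {
  cfg <- list(nn_percentile = nn_percentile,
              negative_mode = match.arg(negative_mode,
                                        c("random", "stringent")),
              stringent_band_multiplier = stringent_band_multiplier,
              n_subsample = as.integer(n_subsample),
              n_repetitions = as.integer(n_repetitions),
              seed = seed)
  assert_that(cfg$nn_percentile > 0 && cfg$nn_percentile < 100,
              "nn_percentile must lie strictly between 0 and 100")
  assert_that(cfg$stringent_band_multiplier > 1,
              "stringent_band_multiplier must exceed 1")
  assert_that(cfg$n_subsample >= 2, "n_subsample must be >= 2")
  assert_that(cfg$n_repetitions >= 1, "n_repetitions must be >= 1")
  structure(cfg, class = "eval_config")
}

#' Nearest-neighbor distance cutoff at a percentile
#'
#' Empirical quantile (linear interpolation) of a sample of reference-space
#' distances at level `percentile / 100`. The fraction of the sample strictly
#' below the cutoff approximates `percentile / 100`.
#'
#' @param distances numeric sample of reference distances.
#' @param percentile percentile in percent units (e.g. 0.001).
#' @return numeric cutoff.
#' @export
nn_cutoff <- function(distances, percentile) {
  assert_that(length(distances) > 0, "empty distance sample")
  assert_that(percentile > 0 && percentile < 100,
              "percentile must lie strictly between 0 and 100")
  if (length(distances) < 100 / percentile) {
    warning("distance sample smaller than 1/(percentile/100); ",
            "the cutoff estimate will be coarse", call. = FALSE)
  }
  cut <- unname(stats::quantile(distances, percentile / 100, type = 7,
                                names = FALSE))
  if (sum(distances < cut) == 0) {
    warning("no distances fall strictly below the cutoff (degenerate sample)",
            call. = FALSE)
  }
  cut
}

# Reference distance sample for cutoff estimation: all pairwise distances when
# there are at most `max_sample` pairs, else a seeded sample of that size.
reference_distance_sample <- function(D, max_sample = 1e6, seed = 1) {
  n <- nrow(D)
  total <- n * (n - 1) / 2
  if (total <= max_sample) {
    return(D[upper.tri(D)])
  }
  with_seed(derive_seed(seed, 911), {
    i <- sample.int(n, max_sample, replace = TRUE)
    j <- sample.int(n - 1, max_sample, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)
    D[cbind(i, j)]
  })
}

#' Build labeled positive/negative pair sets per repetition
#'
#' Per repetition, `n_subsample` compounds are drawn; positives are the pairs
#' among them with reference distance below the cutoff, negatives are sampled
#' per `negative_mode`, and classes are balanced by downsampling the larger
#' one. Repetitions without positives are skipped with a warning.
#'
#' @param reference_dist symmetric reference distance matrix with compound
#'   rownames.
#' @param cfg an [eval_config()].
#' @return list with `cutoff` and `repetitions`, the latter a list of
#'   data.frames (`id_a`, `id_b`, `label` with 1 = positive).
#' @export
build_eval_pairs <- function(reference_dist, cfg) {
  assert_that(inherits(cfg, "eval_config"), "cfg must be an eval_config")
  n <- nrow(reference_dist)
  assert_that(n >= cfg$n_subsample,
              paste0("reference space has ", n, " compounds but n_subsample = ",
                     cfg$n_subsample))
  ids <- rownames(reference_dist) %||% as.character(seq_len(n))

  cutoff <- nn_cutoff(reference_distance_sample(reference_dist,
                                                seed = cfg$seed),
                      cfg$nn_percentile)
  band_hi <- cfg$stringent_band_multiplier * cutoff

  reps <- vector("list", cfg$n_repetitions)
  for (r in seq_len(cfg$n_repetitions)) {
    reps[[r]] <- with_seed(derive_seed(cfg$seed, 101, r), {
      sub <- sort(sample.int(n, cfg$n_subsample))
      prs <- index_pairs(length(sub))
      d <- reference_dist[cbind(sub[prs[, 1]], sub[prs[, 2]])]
      pos <- which(d < cutoff)
      neg_pool <- if (cfg$negative_mode == "stringent") {
        which(d > cutoff & d <= band_hi)
      } else {
        which(d >= cutoff)
      }
      if (length(pos) == 0 || length(neg_pool) == 0) {
        NULL
      } else {
        k <- min(length(pos), length(neg_pool))
        if (length(pos) > k) pos <- sample(pos, k)
        neg <- if (length(neg_pool) > k) sample(neg_pool, k) else neg_pool
        sel <- c(pos, neg)
        data.frame(id_a = ids[sub[prs[sel, 1]]],
                   id_b = ids[sub[prs[sel, 2]]],
                   label = rep(c(1L, 0L), c(length(pos), length(neg))),
                   stringsAsFactors = FALSE)
      }
    })
  }
  skipped <- vapply(reps, is.null, logical(1))
  if (any(skipped)) {
    warning(sum(skipped), " repetition(s) without usable positive/negative ",
            "pairs were skipped", call. = FALSE)
  }
  if (all(skipped)) {
    stop("no repetition produced both positive and negative pairs",
         call. = FALSE)
  }
  list(cutoff = cutoff, repetitions = reps[!skipped])
}

#' AUROC of a candidate descriptor on labeled pair sets
#'
#' For each repetition, candidate distances are looked up for every labeled
#' pair and the AUROC is the midrank (tie-corrected) probability that a
#' positive pair has smaller candidate distance than a negative pair.
#'
#' @param pairs output of [build_eval_pairs()].
#' @param candidate_dist symmetric candidate distance matrix with rownames
#'   covering all paired compounds.
#' @param descriptor_kind label stored in the result.
#' @return a `knn_benchmark_result` list: `descriptor_kind`,
#'   `per_repetition_auroc`, `mean_auroc`, `n_positive_pairs`,
#'   `n_negative_pairs`, `cutoff_distance`.
#' @export
recapitulation_auroc <- function(pairs, candidate_dist,
                                 descriptor_kind = "candidate") {
  ids <- rownames(candidate_dist)
  aurocs <- numeric(0)
  n_pos <- 0L
  n_neg <- 0L
  for (rep_pairs in pairs$repetitions) {
    ia <- match(rep_pairs$id_a, ids)
    ib <- match(rep_pairs$id_b, ids)
    bad <- is.na(ia) | is.na(ib)
    if (any(bad)) {
      stop("no candidate descriptor for compound(s): ",
           paste(unique(c(rep_pairs$id_a[bad & is.na(ia)],
                          rep_pairs$id_b[bad & is.na(ib)])), collapse = ", "),
           call. = FALSE)
    }
    d <- candidate_dist[cbind(ia, ib)]
    lab <- rep_pairs$label
    aurocs <- c(aurocs, auroc_midrank(d, lab))
    n_pos <- n_pos + sum(lab == 1)
    n_neg <- n_neg + sum(lab == 0)
  }
  structure(list(descriptor_kind = descriptor_kind,
                 per_repetition_auroc = aurocs,
                 mean_auroc = mean(aurocs),
                 n_positive_pairs = n_pos,
                 n_negative_pairs = n_neg,
                 cutoff_distance = pairs$cutoff),
            class = "knn_benchmark_result")
}

#' @export
print.knn_benchmark_result <- function(x, ...) {
  cat("<knn_benchmark_result> ", x$descriptor_kind, ": mean AUROC ",
      sprintf("%.3f", x$mean_auroc), " over ",
      length(x$per_repetition_auroc), " repetition(s) (",
      x$n_positive_pairs, " pos / ", x$n_negative_pairs, " neg pairs, ",
      "cutoff ", sprintf("%.4g", x$cutoff_distance), ")\n", sep = "")
  invisible(x)
}

# Midrank AUROC: probability that a positive pair's distance ranks below a
# negative pair's (ties counted half).
auroc_midrank <- function(d, label) {
  np <- sum(label == 1)
  nn <- sum(label == 0)
  assert_that(np > 0 && nn > 0, "both classes must be non-empty")
  r <- rank(-d)  # smaller distance -> larger rank value
  (sum(r[label == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Fraction of pairs with numerically identical descriptor vectors
#'
#' Shares of pairs whose descriptor cosine distance falls below `tol`;
#' quantifies descriptor collapse on stereoisomer pairs.
#'
#' @param pairs data.frame with columns `id_a`, `id_b`.
#' @param vectors numeric matrix (compound x dim) with rownames covering the
#'   paired compounds.
#' @param tol cosine-distance tolerance under which two vectors count as
#'   identical.
#' @return numeric fraction in `[0, 1]`; 0 with a warning for an empty pair
#'   list.
#' @export
identical_signature_fraction <- function(pairs, vectors, tol = 1e-6) {
  if (nrow(pairs) == 0) {
    warning("empty pair list; identical fraction defined as 0", call. = FALSE)
    return(0)
  }
  d <- vapply(seq_len(nrow(pairs)), function(k) {
    cosine_distance(vectors[pairs$id_a[k], ], vectors[pairs$id_b[k], ])
  }, numeric(1))
  mean(d < tol)
}

#' Run the benchmark for several candidate descriptors
#'
#' @param reference_dist symmetric reference distance matrix.
#' @param candidate_dists named list of candidate distance matrices.
#' @param cfg an [eval_config()].
#' @return named list of `knn_benchmark_result`, one per candidate.
#' @export
run_knn_benchmark <- function(reference_dist, candidate_dists, cfg) {
  pairs <- build_eval_pairs(reference_dist, cfg)
  out <- lapply(names(candidate_dists), function(nm) {
    recapitulation_auroc(pairs, candidate_dists[[nm]], nm)
  })
  stats::setNames(out, names(candidate_dists))
}
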