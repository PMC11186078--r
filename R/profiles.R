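# Within-group bioactivity divergence: distinct ternary profiles, Jaccard
# distance distributions by pair category, and Mann-Whitney comparisons.
#
# Binding profiles are ternary vectors over a shared target list
# (0 no binding, 1 weak, 2 strong). Jaccard distances are computed on
# binarized profiles (bound = value >= 1); profile distinctness is assessed on
# the full ternary vectors, so a weak-vs-strong difference at a single target
# makes two profiles distinct even though their bound-target sets coincide.

#' Jaccard distance between two binding profiles
#'
#' Profiles are binarized (value >= 1 means the target is bound) and the
#' distance is `1 - |A n B| / |A u B|` over the bound-target sets. When both
#' sets are empty the distance is 0 by convention and the result carries the
#' attribute `empty_pair = TRUE`, flagging the pair for exclusion from
#' distribution summaries.
#'
#' @param p,q integer vectors with values in \{0, 1, 2\} over the same ordered
#'   target list (names, when present, must agree).
#' @return numeric distance in `[0, 1]`.
#' @examples
#' jaccard_distance(c(1, 2, 0), c(0, 1, 1))  # A = {1,2}, B = {2,3} -> 2/3
#' @export
jaccard_distance <- function(p, q) {
  assert_that(length(p) == length(q), "profiles differ in length")
  if (!is.null(names(p)) && !is.null(names(q))) {
    assert_that(identical(names(p), names(q)),
                "profiles are indexed by different target lists")
  }
  assert_that(all(p %in% 0:2) && all(q %in% 0:2),
              "profile values must be in {0, 1, 2}")
  a <- p >= 1
  b <- q >= 1
  uni <- sum(a | b)
  if (uni == 0) {
    return(structure(0, empty_pair = TRUE))
  }
  1 - sum(a & b) / uni
}

#' Number of distinct binding profiles within a stereoisomer group
#'
#' Distinctness is exact equality of the full ternary vectors (not the
#' binarized sets), so members that differ only in a weak-vs-strong annotation
#' count as distinct.
#'
#' @param member_ids character vector of group member compound ids.
#' @param profiles integer matrix (compound x target) with rownames covering
#'   all members.
#' @return integer in `[1, length(member_ids)]`.
#' @export
count_distinct_profiles <- function(member_ids, profiles) {
  missing <- setdiff(member_ids, rownames(profiles))
  if (length(missing) > 0) {
    stop("no binding profile for member(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- profiles[member_ids, , drop = FALSE]
  length(unique(apply(m, 1, paste, collapse = ",")))
}

#' Distinct-profile breakdown by group size
#'
#' For each group size, the distribution of the number of distinct ternary
#' profiles among groups of that size.
#'
#' @param groups the `groups` data.frame from
#'   [identify_stereoisomer_groups()].
#' @param profiles integer matrix (compound x target).
#' @return data.frame with columns `group_size`, `n_distinct_profiles`,
#'   `n_groups`, `proportion` (proportions sum to 1 within each size).
#' @export
distinct_profile_breakdown <- function(groups, profiles) {
  members <- group_members(groups)
  if (length(members) == 0) {
    return(data.frame(group_size = integer(0), n_distinct_profiles = integer(0),
                      n_groups = integer(0), proportion = numeric(0)))
  }
  size <- vapply(members, length, integer(1))
  ndis <- vapply(members, count_distinct_profiles, integer(1),
                 profiles = profiles)
  agg <- as.data.frame(table(group_size = size, n_distinct_profiles = ndis),
                       stringsAsFactors = FALSE)
  agg <- agg[agg$Freq > 0, , drop = FALSE]
  agg$group_size <- as.integer(agg$group_size)
  agg$n_distinct_profiles <- as.integer(agg$n_distinct_profiles)
  names(agg)[names(agg) == "Freq"] <- "n_groups"
  per_size <- tapply(agg$n_groups, agg$group_size, sum)
  agg$proportion <- agg$n_groups / as.vector(per_size[as.character(agg$group_size)])
  agg <- agg[order(agg$group_size, agg$n_distinct_profiles), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Jaccard distances for stereoisomer and random pair categories
#'
#' Enumerates all stereoisomer pairs (within groups) exhaustively and samples
#' up to `n_random_pairs` non-stereoisomer pairs for each of two random
#' categories: pairs sharing no bound target (`share0`) and pairs sharing at
#' least one (`share_ge1`). Pairs whose bound-target sets are both empty are
#' excluded. Deterministic given `seed`.
#'
#' @param records data.frame with at least an `id` column listing the
#'   compounds to consider (typically the registry table).
#' @param groups the `groups` data.frame from
#'   [identify_stereoisomer_groups()].
#' @param profiles integer matrix (compound x target) covering all ids.
#' @param n_random_pairs sampling cap per random category.
#' @param seed RNG seed for pair sampling.
#' @return data.frame with columns `id_a`, `id_b`, `category`
#'   (`stereoisomer`, `share0`, `share_ge1`) and `jaccard`.
#' @export
pair_category_distances <- function(records, groups, profiles,
                                    n_random_pairs = 100000, seed = 1) {
  ids <- records$id
  missing <- setdiff(ids, rownames(profiles))
  assert_that(length(missing) == 0,
              paste0("profiles missing for: ",
                     paste(head(missing, 5), collapse = ", ")))
  B <- profiles[ids, , drop = FALSE] >= 1

  members <- group_members(groups)
  stereo_pairs <- do.call(rbind, lapply(members, function(mem) {
    prs <- index_pairs(length(mem))
    cbind(mem[prs[, 1]], mem[prs[, 2]])
  }))

  idx <- stats::setNames(seq_along(ids), ids)
  in_group_pair <- character(0)
  if (!is.null(stereo_pairs) && nrow(stereo_pairs) > 0) {
    in_group_pair <- pair_key(idx[stereo_pairs[, 1]], idx[stereo_pairs[, 2]])
  }

  # candidate non-stereoisomer pairs, classified by shared bound targets
  n <- length(ids)
  prs <- index_pairs(n)
  keys <- pair_key(prs[, 1], prs[, 2])
  keep <- !(keys %in% in_group_pair)
  prs <- prs[keep, , drop = FALSE]
  shared <- rowSums(B[prs[, 1], , drop = FALSE] &
                      B[prs[, 2], , drop = FALSE])
  nonempty <- rowSums(B[prs[, 1], , drop = FALSE] |
                        B[prs[, 2], , drop = FALSE]) > 0

  sample_category <- function(cand, label) {
    if (nrow(cand) == 0) {
      return(NULL)
    }
    if (nrow(cand) > n_random_pairs) {
      pick <- with_seed(derive_seed(seed, match(label, c("share0", "share_ge1"))),
                        sample.int(nrow(cand), n_random_pairs))
      cand <- cand[pick, , drop = FALSE]
    } else if (nrow(cand) < n_random_pairs) {
      warning("only ", nrow(cand), " ", label, " pairs available (",
              n_random_pairs, " requested)", call. = FALSE)
    }
    data.frame(id_a = ids[cand[, 1]], id_b = ids[cand[, 2]],
               category = label, stringsAsFactors = FALSE)
  }

  out <- rbind(
    if (!is.null(stereo_pairs) && nrow(stereo_pairs) > 0) {
      data.frame(id_a = stereo_pairs[, 1], id_b = stereo_pairs[, 2],
                 category = "stereoisomer", stringsAsFactors = FALSE)
    },
    sample_category(prs[shared == 0 & nonempty, , drop = FALSE], "share0"),
    sample_category(prs[shared >= 1, , drop = FALSE], "share_ge1")
  )
  if (is.null(out)) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      category = character(0), jaccard = numeric(0)))
  }
  ia <- B[out$id_a, , drop = FALSE]
  ib <- B[out$id_b, , drop = FALSE]
  inter <- rowSums(ia & ib)
  uni <- rowSums(ia | ib)
  out$jaccard <- ifelse(uni == 0, 0, 1 - inter / uni)
  rownames(out) <- NULL
  out
}

pair_key <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = ":")
}

#' Two-sided Mann-Whitney comparison of two distance samples
#'
#' Wraps the rank-sum test with tie correction and normal approximation for
#' large samples.
#'
#' @param x,y numeric samples (non-empty).
#' @return list with elements `U` (statistic for `x`) and `p_value`.
#' @export
compare_distributions <- function(x, y) {
  assert_that(length(x) > 0 && length(y) > 0, "samples must be non-empty")
  res <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))
  list(U = unname(res$statistic), p_value = res$p.value)
}
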