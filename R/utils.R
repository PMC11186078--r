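# Internal helpers: seeded RNG streams, argument checks, small utilities.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Derive a child seed from a root seed and integer keys
#'
#' Stable multiplicative hash (exact in double arithmetic, all intermediates
#' below 2^53) so that per-family random streams do not depend on the order in
#' which families are generated. Result lies in `[1, 2^31 - 2]` and is safe to
#' pass to [set.seed()].
#' @noRd
derive_seed <- function(root, ...) {
  m <- 2147483647  # 2^31 - 1
  keys <- list(root, ...)
  h <- 374761393
  for (k in keys) {
    if (is.character(k)) {
      k <- vapply(k, function(s) sum(utf8ToInt(s) *
                                       seq_along(utf8ToInt(s))), numeric(1))
    }
    for (kk in k) {
      h <- (h * 48271 + (as.double(kk) %% m) + 11) %% m
      h <- (h * 69621) %% m
    }
  }
  as.integer(h %% (m - 2)) + 1L
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# All unordered pairs i < j of a vector of indices, as a 2-column matrix.
index_pairs <- function(n) {
  if (n < 2) return(matrix(integer(0), ncol = 2))
  j <- sequence(seq_len(n - 1))
  i <- rep(seq_len(n - 1) + 1L, seq_len(n - 1))
  cbind(j, i)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1
}
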