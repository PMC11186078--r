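# Descriptor families contrasted by the evaluation:
#  - fp2d: hashed extended-connectivity fingerprints (ECFP, radius 2 by
#    default) computed on the stereo-stripped constitution — stereo-blind by
#    construction, so stereoisomers collapse onto identical vectors;
#  - geo3d: a chirality-aware geometric descriptor of a single conformer,
#    concatenating USR-style distance-distribution moments from four reference
#    points with signed-tetrahedral-volume moments that change sign under
#    reflection, so enantiomeric geometries never collapse.

#' 2D circular fingerprints (stereo-blind)
#'
#' Hashed extended-connectivity fingerprints computed with Open Babel on the
#' stereo-stripped canonical SMILES, folded to `n_bits`. Any two
#' stereoisomers of one constitution receive bitwise identical fingerprints.
#'
#' @param records record `data.frame` from [standardize_molecules()].
#' @param radius circular fingerprint radius (2 corresponds to ECFP4).
#' @param n_bits folded fingerprint length.
#' @return binary matrix (molecules x bits) with rownames `records$id` and
#'   attribute `kind = "fp2d"`.
#' @export
fingerprint_2d <- function(records, radius = 2, n_bits = 2048) {
  assert_that(is.data.frame(records) && nrow(records) > 0,
              "records must be a non-empty data.frame")
  assert_that(radius %in% 0:5, "radius must be in 0..5")
  fptype <- paste0("ECFP", 2 * radius)

  smi <- tempfile("fp-", fileext = ".smi")
  on.exit(unlink(smi), add = TRUE)
  ob_write_smi(records$canonical_smiles_nostereo, records$id, smi)
  out <- ob_run(c(smi, "-ofpt", paste0("-xf", fptype),
                  "-xN", as.character(n_bits), "-xh"))

  fp <- parse_fpt_output(out, n_bits)
  missing <- setdiff(records$id, rownames(fp))
  assert_that(length(missing) == 0,
              paste0("fingerprint computation failed for: ",
                     paste(missing, collapse = ", ")))
  fp <- fp[records$id, , drop = FALSE]
  structure(fp, kind = "fp2d")
}

# Parse Open Babel 'fpt' text output: records start with '>title', hex lines
# follow (comparison chatter lines are ignored).
parse_fpt_output <- function(lines, n_bits) {
  starts <- grep("^>", lines)
  assert_that(length(starts) > 0, "no fingerprint records in obabel output")
  titles <- sub("^>\\s*(\\S+).*$", "\\1", lines[starts])
  ends <- c(starts[-1] - 1, length(lines))
  hex_per_mol <- vapply(seq_along(starts), function(k) {
    body <- lines[(starts[k] + 1):ends[k]]
    body <- body[grepl("^[0-9a-f ]+$", body) & nzchar(trimws(body))]
    gsub(" ", "", paste(body, collapse = ""))
  }, character(1))
  n_hex <- n_bits / 4
  assert_that(all(nchar(hex_per_mol) == n_hex),
              "unexpected fingerprint width in obabel output")
  bits <- matrix(0L, length(titles), n_bits)
  lut <- matrix(0L, 16, 4)
  for (v in 0:15) {
    lut[v + 1, ] <- as.integer(bitwAnd(v, c(8L, 4L, 2L, 1L)) > 0)
  }
  for (k in seq_along(titles)) {
    vals <- strtoi(strsplit(hex_per_mol[k], "")[[1]], 16L)
    bits[k, ] <- as.integer(t(lut[vals + 1, , drop = FALSE]))
  }
  rownames(bits) <- titles
  bits
}

# number of USR-style moment components (4 reference points x 3 moments)
GEO3D_MOMENT_LENGTH <- 12L
# number of signed-volume chirality components
GEO3D_CHIRAL_LENGTH <- 3L

#' Chirality-aware 3D geometric descriptor
#'
#' Concatenates (a) distance-distribution moments (mean, standard deviation,
#' cube-rooted third central moment) of all heavy atoms from four reference
#' points — the centroid, the atom closest to it, the atom farthest from it,
#' and the atom farthest from that — with (b) moments of signed tetrahedral
#' volumes over atom quadruples (mean, median and third central moment of
#' volumes normalized by their mean magnitude). Block (a) is invariant to all
#' rigid motions including reflection; block (b) is rotation/translation
#' invariant but changes sign under reflection, which is what separates
#' enantiomeric conformers. All quadruples are used when there are at most
#' `max_quadruples`; otherwise a seeded sample of that size.
#'
#' @param conf a `conformer3d` from [generate_conformers()].
#' @param max_quadruples cap on the number of atom quadruples.
#' @param sample_seed seed for quadruple sampling (derived per atom count, so
#'   the descriptor is deterministic).
#' @return numeric vector of length 15 with attribute `kind = "geo3d"`.
#' @export
descriptor_3d <- function(conf, max_quadruples = 5000, sample_seed = 1) {
  assert_that(inherits(conf, "conformer3d"), "conf must be a conformer3d")
  X <- conf$coordinates
  n <- nrow(X)
  assert_that(n >= 1, "conformer has no atoms")

  moments3 <- function(d) {
    m <- mean(d)
    s <- if (length(d) > 1) stats::sd(d) else 0
    mc3 <- mean((d - m)^3)
    c(m, s, sign(mc3) * abs(mc3)^(1 / 3))
  }
  ctd <- colMeans(X)
  d_ctd <- sqrt(colSums((t(X) - ctd)^2))
  # deterministic tie-breaks: lowest atom index wins
  cst <- X[which.min(d_ctd), ]
  fct <- X[which.max(d_ctd), ]
  d_fct <- sqrt(colSums((t(X) - fct)^2))
  ftf <- X[which.max(d_fct), ]
  d_cst <- sqrt(colSums((t(X) - cst)^2))
  d_ftf <- sqrt(colSums((t(X) - ftf)^2))
  moment_block <- c(moments3(d_ctd), moments3(d_cst),
                    moments3(d_fct), moments3(d_ftf))

  chiral_block <- rep(0, GEO3D_CHIRAL_LENGTH)
  if (n >= 4) {
    quads <- sample_quadruples(n, max_quadruples, sample_seed)
    v <- vapply(seq_len(nrow(quads)), function(r) {
      q <- quads[r, ]
      signed_volume(X[q[2], ] - X[q[1], ],
                    X[q[3], ] - X[q[1], ],
                    X[q[4], ] - X[q[1], ])
    }, numeric(1))
    s <- mean(abs(v))
    if (s > 1e-12) {
      z <- v / s
      mz <- mean(z)
      chiral_block <- c(mz, stats::median(z), mean((z - mz)^3))
    }
  }
  structure(c(moment_block, chiral_block), kind = "geo3d")
}

sample_quadruples <- function(n, max_quadruples, sample_seed) {
  total <- choose(n, 4)
  if (total <= max_quadruples) {
    return(t(utils::combn(n, 4)))
  }
  with_seed(derive_seed(sample_seed, n), {
    t(replicate(max_quadruples, sort(sample.int(n, 4))))
  })
}

#' Descriptor matrix for a set of conformers
#'
#' @param conformers list of `conformer3d` objects.
#' @param ... passed to [descriptor_3d()].
#' @return numeric matrix (molecules x 15) with attribute `kind = "geo3d"`.
#' @export
descriptor_3d_matrix <- function(conformers, ...) {
  vals <- t(vapply(conformers, function(cf) as.numeric(descriptor_3d(cf, ...)),
                   numeric(GEO3D_MOMENT_LENGTH + GEO3D_CHIRAL_LENGTH)))
  rownames(vals) <- vapply(conformers, `[[`, "", "molecule_id")
  structure(vals, kind = "geo3d")
}

#' Cosine distance between two descriptor vectors
#'
#' `1 - a.b / (|a||b|)`, clipped to `[0, 2]`. Vectors must be of the same
#' descriptor kind (when both carry a `kind` attribute) and non-zero.
#'
#' @param a,b numeric vectors.
#' @return numeric distance in `[0, 2]`.
#' @export
cosine_distance <- function(a, b) {
  ka <- attr(a, "kind")
  kb <- attr(b, "kind")
  if (!is.null(ka) && !is.null(kb)) {
    assert_that(identical(ka, kb),
                paste0("descriptor kinds differ: ", ka, " vs ", kb))
  }
  a <- as.numeric(a)
  b <- as.numeric(b)
  assert_that(length(a) == length(b), "vectors differ in length")
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  assert_that(na > 0 && nb > 0, "cosine distance undefined for zero vectors")
  min(max(1 - sum(a * b) / (na * nb), 0), 2)
}

# All pairwise cosine distances of the rows of a matrix (dense, symmetric).
pairwise_cosine <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  assert_that(all(nrm > 0), "zero rows in descriptor matrix")
  S <- (M %*% t(M)) / outer(nrm, nrm)
  D <- 1 - S
  D[D < 1e-12] <- 0  # snap float dust so identical vectors tie exactly
  D[D > 2] <- 2
  diag(D) <- 0
  dimnames(D) <- list(rownames(M), rownames(M))
  D
}
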