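# Single-conformer 3D generation.
#
# One conformer is generated per molecule by classical distance-geometry
# embedding: holonomic distance bounds are derived from connectivity (bond
# lengths from covalent radii, 1-3 distances from idealized valence angles,
# van der Waals lower bounds elsewhere), smoothed by triangle inequalities,
# metrized by seeded uniform sampling, embedded by eigendecomposition of the
# centered Gram matrix, and refined by SMACOF majorization. Tetrahedral parity
# is enforced from the MDL parity flags, the geometry is relaxed with MMFF94
# (steepest descent, Open Babel) and the result is validated by an InChIKey
# round trip; molecules whose stereochemistry does not round-trip are
# re-embedded with a fresh derived seed. The whole procedure is deterministic
# given `embed_seed`.

# covalent radii (Angstrom) for bond-length estimates
COV_RADII <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
               Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39,
               Se = 1.20, As = 1.19)
# van der Waals radii (Angstrom) for non-bonded lower bounds
VDW_RADII <- c(H = 1.10, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
               Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98,
               Se = 1.90, As = 1.85)

radius_of <- function(symbols, table, default) {
  r <- table[symbols]
  r[is.na(r)] <- default
  unname(r)
}

#' Generate one optimized 3D conformer per molecule
#'
#' Embeds each molecule in 3D by seeded distance geometry, relaxes the
#' coordinates with the MMFF94 force field (Open Babel, bounded iteration
#' count) and validates that the stereochemistry of the resulting geometry
#' reproduces the molecule's InChIKey, re-embedding with a derived retry seed
#' on mismatch. Hydrogens are present during embedding and optimization and
#' removed before export. Molecules with partially defined stereochemistry are
#' refused: a conformer of an ambiguous stereo assignment would silently pick
#' one isomer.
#'
#' @param records record `data.frame` from [standardize_molecules()]. All rows
#'   must have `stereo_status` other than `"partially_defined"`.
#' @param embed_seed integer seed controlling the embedding; the same seed
#'   reproduces identical coordinates.
#' @param max_attempts maximum number of re-embedding attempts per molecule
#'   before giving up with an error.
#' @param mmff_steps iteration cap for MMFF94 steepest-descent minimization;
#'   non-convergence within the cap is accepted.
#' @return A list of `conformer3d` objects, one per record, each with fields
#'   `molecule_id`, `atom_symbols` (heavy atoms only), `coordinates`
#'   (N x 3 matrix, Angstrom), `optimized`, `embed_seed`.
#' @export
generate_conformers <- function(records, embed_seed = 1L, max_attempts = 8L,
                                mmff_steps = 1000L) {
  assert_that(is.data.frame(records) && nrow(records) > 0,
              "records must be a non-empty data.frame")
  bad <- records$id[records$stereo_status == "partially_defined"]
  if (length(bad) > 0) {
    stop("refusing to generate conformers for partially defined ",
         "stereochemistry: ", paste(bad, collapse = ", "), call. = FALSE)
  }

  topo <- molecule_topologies(records)
  n <- nrow(records)
  coords <- vector("list", n)
  optimized <- rep(FALSE, n)
  pending <- seq_len(n)
  attempt <- 1L

  while (length(pending) > 0 && attempt <= max_attempts) {
    embedded <- lapply(pending, function(k) {
      t <- topo[[k]]
      # metrization is seeded by the constitution (connectivity key), so
      # stereoisomers of one constitution share the sampled distance matrix
      # and differ only through their stereo corrections, not through
      # independent rotamer draws
      seed <- derive_seed(embed_seed, records$connectivity_key[k], attempt)
      embed_distance_geometry(t$symbols, t$bonds, t$parity, seed)
    })
    # Minimize all pending molecules in one obabel call, then check the
    # stereo round trip per molecule.
    res <- minimize_and_validate(records[pending, , drop = FALSE],
                                 topo[pending], embedded, mmff_steps)
    ok <- res$ok
    for (w in seq_along(pending)) {
      if (ok[w]) {
        coords[[pending[w]]] <- res$coords[[w]]
        optimized[pending[w]] <- res$optimized[w]
      }
    }
    pending <- pending[!ok]
    attempt <- attempt + 1L
  }
  if (length(pending) > 0) {
    stop("3D embedding failed after ", max_attempts, " attempts for: ",
         paste(records$id[pending], collapse = ", "), call. = FALSE)
  }

  out <- vector("list", n)
  for (k in seq_len(n)) {
    t <- topo[[k]]
    heavy <- t$symbols != "H"
    xyz <- coords[[k]][heavy, , drop = FALSE]
    rownames(xyz) <- NULL
    remap <- cumsum(heavy)
    hb <- t$bonds[heavy[t$bonds[, 1]] & heavy[t$bonds[, 2]], , drop = FALSE]
    hb[, 1] <- remap[hb[, 1]]
    hb[, 2] <- remap[hb[, 2]]
    out[[k]] <- structure(
      list(molecule_id = records$id[k],
           atom_symbols = t$symbols[heavy],
           coordinates = xyz,
           bonds = hb,
           optimized = optimized[k],
           embed_seed = as.integer(embed_seed)),
      class = "conformer3d")
  }
  names(out) <- records$id
  out
}

#' @export
print.conformer3d <- function(x, ...) {
  cat("<conformer3d> ", x$molecule_id, ": ", length(x$atom_symbols),
      " heavy atoms, ", if (x$optimized) "MMFF94-optimized" else "unoptimized",
      " (embed_seed ", x$embed_seed, ")\n", sep = "")
  invisible(x)
}

# Extract per-molecule topology (atom symbols incl. explicit H, bond table,
# MDL tetrahedral parity flags) by converting SMILES to a 0D SDF with explicit
# hydrogens and parsing it with ChemmineR.
molecule_topologies <- function(records) {
  smi <- tempfile("topo-", fileext = ".smi")
  sdf <- tempfile("topo-", fileext = ".sdf")
  on.exit(unlink(c(smi, sdf)), add = TRUE)
  ob_write_smi(records$canonical_smiles, records$id, smi)
  ob_run(c(smi, "-osdf", "-O", sdf, "-h"))
  sdfset <- ChemmineR::read.SDFset(sdf)
  assert_that(length(sdfset) == nrow(records),
              "SDF conversion lost molecules while reading topology")
  ids <- ChemmineR::sdfid(sdfset)
  assert_that(identical(ids, records$id),
              "SDF record order does not match input records")
  lapply(seq_along(sdfset), function(k) {
    ab <- ChemmineR::atomblock(sdfset[[k]])
    bb <- ChemmineR::bondblock(sdfset[[k]])
    symbols <- sub("_[0-9]+$", "", rownames(ab))
    bonds <- if (nrow(bb) > 0) {
      cbind(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
            order = as.integer(bb[, 3]))
    } else {
      matrix(integer(0), ncol = 3,
             dimnames = list(NULL, c("from", "to", "order")))
    }
    list(symbols = symbols, bonds = bonds, parity = as.integer(ab[, "C7"]))
  })
}

# Distance-geometry embedding of one molecule. Returns an n x 3 matrix of
# coordinates for all atoms (hydrogens included). Deterministic given seed.
embed_distance_geometry <- function(symbols, bonds, parity, seed) {
  n <- length(symbols)
  if (n == 1) return(matrix(0, 1, 3))
  bl <- bounds_matrices(symbols, bonds)
  with_seed(seed, {
    D <- matrix(runif(n * n, bl$L, bl$U), n, n)
    D[lower.tri(D)] <- t(D)[lower.tri(D)]
    diag(D) <- 0
    X <- embed_from_distances(D)
    X <- smacof_refine(X, bl$L, bl$U, iters = 60)
    enforce_parity(X, bonds, parity, bl$L, bl$U)
  })
}

# Distance bounds from covalent geometry: exact bonds and 1-3 distances,
# van der Waals lower bounds, triangle-smoothed upper bounds.
bounds_matrices <- function(symbols, bonds) {
  n <- length(symbols)
  rc <- radius_of(symbols, COV_RADII, 0.9)
  rv <- radius_of(symbols, VDW_RADII, 1.7)
  order_factor <- c(1, 0.87, 0.78, 0.91)  # single, double, triple, aromatic

  L <- 0.8 * outer(rv, rv, "+")
  U <- matrix(60, n, n)
  blen <- matrix(0, n, n)
  deg <- integer(n)
  maxord <- rep(1L, n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]; o <- bonds[b, 3]
    d <- (rc[i] + rc[j]) * order_factor[min(o, 4)]
    blen[i, j] <- blen[j, i] <- d
    L[i, j] <- L[j, i] <- U[i, j] <- U[j, i] <- d
    deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
    maxord[i] <- max(maxord[i], o); maxord[j] <- max(maxord[j], o)
  }
  # idealized valence angle at each center: sp3 109.47, sp2 120, sp 180
  angle_at <- ifelse(maxord >= 3 | deg <= 1, pi,
                     ifelse(maxord >= 2, 120 * pi / 180, 109.47 * pi / 180))
  for (j in seq_len(n)) {
    nb <- sort(unique(c(bonds[bonds[, 1] == j, 2], bonds[bonds[, 2] == j, 1])))
    if (length(nb) < 2) next
    th <- angle_at[j]
    prs <- index_pairs(length(nb))
    for (r in seq_len(nrow(prs))) {
      i <- nb[prs[r, 1]]; k <- nb[prs[r, 2]]
      d <- sqrt(blen[i, j]^2 + blen[k, j]^2 -
                  2 * blen[i, j] * blen[k, j] * cos(th))
      L[i, k] <- L[k, i] <- U[i, k] <- U[k, i] <- d
    }
  }
  diag(L) <- diag(U) <- 0
  # triangle smoothing of upper bounds (vectorized Floyd pass)
  for (k in seq_len(n)) {
    U <- pmin(U, outer(U[, k], U[k, ], "+"))
  }
  # one inverse-triangle pass on lower bounds, then consistency
  for (k in seq_len(n)) {
    L <- pmax(L, outer(L[, k], -U[k, ], "+"))
    L <- pmax(L, outer(-U[, k], L[k, ], "+"))
  }
  bad <- L > U
  L[bad] <- U[bad]
  list(L = L, U = U)
}

# Classical EMBED step: distances -> centered Gram matrix -> top-3 spectral
# coordinates.
embed_from_distances <- function(D) {
  n <- nrow(D)
  D2 <- D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% D2 %*% J
  eg <- eigen(G, symmetric = TRUE)
  lam <- pmax(eg$values[1:3], 0)
  X <- eg$vectors[, 1:3, drop = FALSE] %*% diag(sqrt(lam), 3)
  # break exact degeneracy (collinear/planar embeddings)
  X + matrix(runif(n * 3, -1e-4, 1e-4), n, 3)
}

# SMACOF majorization toward the distance band [L, U]: targets are current
# distances clamped into their bounds, weights uniform.
smacof_refine <- function(X, L, U, iters = 50) {
  n <- nrow(X)
  for (it in seq_len(iters)) {
    Dm <- as.matrix(dist(X))
    Tg <- pmin(pmax(Dm, L), U)
    R <- ifelse(Dm > 1e-9, Tg / Dm, 0)
    B <- -R
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- (B %*% X) / n
  }
  X
}

# Enforce MDL tetrahedral parity: parity 1 corresponds to a positive signed
# volume det(n2-n1, n3-n1, n4-n1) over the four neighbor atoms sorted by atom
# index, parity 2 to a negative one (calibrated against stereo-correct Open
# Babel geometries). A wrong center is corrected by swapping the positions of
# two of its terminal substituents — never atoms that are themselves
# stereocenters, so adjacent centers stay untouched — followed by a short
# bounds refinement; the InChIKey round trip downstream guards the result.
enforce_parity <- function(X, bonds, parity, L, U) {
  centers <- which(parity %in% c(1L, 2L))
  if (length(centers) == 0) return(X)
  n <- nrow(X)
  deg <- integer(n)
  for (b in seq_len(nrow(bonds))) {
    deg[bonds[b, 1]] <- deg[bonds[b, 1]] + 1L
    deg[bonds[b, 2]] <- deg[bonds[b, 2]] + 1L
  }
  is_center <- seq_len(n) %in% centers
  neighbors <- lapply(centers, function(ct) {
    sort(unique(c(bonds[bonds[, 1] == ct, 2], bonds[bonds[, 2] == ct, 1])))
  })
  parity_ok <- function(X) {
    vapply(seq_along(centers), function(w) {
      nb <- neighbors[[w]]
      if (length(nb) != 4) return(TRUE)
      sv <- signed_volume(X[nb[2], ] - X[nb[1], ],
                          X[nb[3], ] - X[nb[1], ],
                          X[nb[4], ] - X[nb[1], ])
      want <- if (parity[centers[w]] == 1L) 1 else -1
      sign(sv) == want
    }, logical(1))
  }
  for (round in 1:6) {
    ok <- parity_ok(X)
    if (all(ok)) break
    for (w in which(!ok)) {
      nb <- neighbors[[w]]
      if (length(nb) != 4) next
      # exchange the directions of the two lowest-degree non-stereocenter
      # substituents (e.g. H and a halogen) while preserving their bond
      # lengths: flips the parity of this center only, with the gentlest
      # possible geometric perturbation
      cand <- nb[!is_center[nb]]
      cand <- cand[order(deg[cand], cand)]
      if (length(cand) < 2) cand <- nb[order(deg[nb], nb)]
      a <- cand[1]; b <- cand[2]
      ct <- centers[w]
      va <- X[a, ] - X[ct, ]
      vb <- X[b, ] - X[ct, ]
      la <- sqrt(sum(va^2))
      lb <- sqrt(sum(vb^2))
      if (la > 1e-9 && lb > 1e-9) {
        X[a, ] <- X[ct, ] + vb / lb * la
        X[b, ] <- X[ct, ] + va / la * lb
      } else {
        tmp <- X[a, ]; X[a, ] <- X[b, ]; X[b, ] <- tmp
      }
    }
    X <- smacof_refine(X, L, U, iters = 12)
  }
  X
}

signed_volume <- function(v1, v2, v3) {
  det(cbind(v1, v2, v3))
}

# Write embedded coordinates for the pending molecules to an SDF, minimize all
# of them with MMFF94 in one obabel call, and validate each result by InChIKey
# round trip. Molecules whose minimization fails keep their embedded
# coordinates with optimized = FALSE (a warning is emitted); molecules whose
# stereo does not round-trip are reported as not ok for re-embedding.
minimize_and_validate <- function(records, topos, embedded, mmff_steps) {
  sdf_in <- tempfile("embed-", fileext = ".sdf")
  sdf_min <- tempfile("minim-", fileext = ".sdf")
  on.exit(unlink(c(sdf_in, sdf_min)), add = TRUE)
  write_v2000(records$id, topos, embedded, sdf_in)
  ok_min <- TRUE
  tryCatch(ob_minimize_sdf(sdf_in, sdf_min, steps = mmff_steps),
           error = function(e) ok_min <<- FALSE)

  n <- nrow(records)
  coords <- embedded
  optimized <- rep(FALSE, n)
  if (ok_min && file.exists(sdf_min)) {
    minset <- tryCatch(ChemmineR::read.SDFset(sdf_min),
                       error = function(e) NULL)
    if (!is.null(minset)) {
      mids <- ChemmineR::sdfid(minset)
      for (k in seq_len(n)) {
        w <- match(records$id[k], mids)
        if (!is.na(w)) {
          ab <- ChemmineR::atomblock(minset[[w]])
          if (nrow(ab) == nrow(embedded[[k]])) {
            coords[[k]] <- unname(ab[, 1:3, drop = FALSE])
            optimized[k] <- TRUE
          }
        }
      }
    }
  }
  if (!all(optimized)) {
    warning("MMFF94 optimization unavailable for ",
            sum(!optimized), " molecule(s); keeping unoptimized embedding",
            call. = FALSE)
  }

  # stereo validation: InChIKey of the 3D geometry must match the record's
  sdf_chk <- tempfile("check-", fileext = ".sdf")
  on.exit(unlink(sdf_chk), add = TRUE)
  write_v2000(records$id, topos, coords, sdf_chk)
  keys <- ob_sdf_to_lines(sdf_chk, "inchikey")
  if (length(keys) == n) {
    ok <- keys == records$inchikey
  } else {
    ok <- rep(FALSE, n)
  }
  list(ok = ok, coords = coords, optimized = optimized)
}

# Minimal V2000 writer for molecules with explicit coordinates (no stereo
# flags: the 3D coordinates themselves define the stereochemistry).
write_v2000 <- function(ids, topos, coords, path) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (k in seq_along(ids)) {
    t <- topos[[k]]
    X <- coords[[k]]
    n <- length(t$symbols)
    nb <- nrow(t$bonds)
    writeLines(c(ids[k], " stereoactivity 3D", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       X[, 1], X[, 2], X[, 3], t$symbols), con)
    if (nb > 0) {
      writeLines(sprintf("%3d%3d%3d  0  0  0  0",
                         t$bonds[, 1], t$bonds[, 2], t$bonds[, 3]), con)
    }
    writeLines(c("M  END", "$$$$"), con)
  }
  path
}

#' Export conformers to SDF and flat CSV
#'
#' Writes heavy-atom-only conformers as a V2000 SDF and as a flat CSV with one
#' row per atom (`molecule_id`, `atom_index`, `element`, `x`, `y`, `z`).
#'
#' @param conformers list of `conformer3d` objects from
#'   [generate_conformers()].
#' @param sdf_path,csv_path output paths (`NULL` to skip either).
#' @return invisibly, a character vector of the written paths.
#' @export
write_conformers <- function(conformers, sdf_path = NULL, csv_path = NULL) {
  written <- character(0)
  if (!is.null(sdf_path)) {
    topos <- lapply(conformers, function(cf) {
      list(symbols = cf$atom_symbols, bonds = cf$bonds)
    })
    write_v2000(vapply(conformers, `[[`, "", "molecule_id"), topos,
                lapply(conformers, `[[`, "coordinates"), sdf_path)
    written <- c(written, sdf_path)
  }
  if (!is.null(csv_path)) {
    rows <- do.call(rbind, lapply(conformers, function(cf) {
      data.frame(molecule_id = cf$molecule_id,
                 atom_index = seq_along(cf$atom_symbols),
                 element = cf$atom_symbols,
                 x = cf$coordinates[, 1],
                 y = cf$coordinates[, 2],
                 z = cf$coordinates[, 3],
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(rows, csv_path, row.names = FALSE, quote = FALSE)
    written <- c(written, csv_path)
  }
  invisible(written)
}
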