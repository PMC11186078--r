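# Synthetic bioactivity-library generator.
#
# Emulates the data regime of a target-binding bioactivity space: families of
# stereoisomers sharing one constitution, ternary binding profiles (0 none /
# 1 weak / 2 strong) whose within-family divergence is controlled by a
# stereo-sensitivity parameter, and 128-dimensional continuous signatures
# correlated with the profiles. Everything is deterministic given the seed;
# per-family child streams are derived by stable hashing so family content
# does not depend on generation order.

# Scaffold part pools. Constitutions are assembled as
#   LEFT + SPACER + k stereocenters "[C@H](sub)" + RIGHT
# with pool members chosen by mixed-radix decomposition of the family index,
# so every family has a unique constitution. Left and right terminations are
# disjoint (and stay distinct under any spacer), which guarantees that each
# backbone carbon bearing a substituent has four distinct neighbor subtrees,
# i.e. is a genuine tetrahedral stereocenter, and that no meso symmetry can
# arise.
SCAFFOLD_LEFT <- c("CC", "OCC", "NCC", "SCC")
SCAFFOLD_RIGHT <- c("CO", "CN", "C(C)C", "CC#N")
SCAFFOLD_SPACER <- c("", "C", "CC", "CCC")
SCAFFOLD_SUBS <- c("F", "Cl", "Br", "I", "OC", "N", "O", "SC")

# per-differing-target contribution to the signature offset magnitude
SIGNATURE_OFFSET_PER_TARGET <- 0.5
# marginal probability that a target is active in a family base profile
BASE_ACTIVITY_RATE <- 0.15

#' Configuration for the synthetic library generator
#'
#' @param n_families number of constitutional scaffolds (each a stereoisomer
#'   family). At most 512 (the scaffold pool capacity).
#' @param stereocenters_per_family integer range `c(lo, hi)` of tetrahedral
#'   stereocenters per family.
#' @param isomers_per_family integer range `c(lo, hi)` of emitted stereoisomers
#'   per family; capped per family at `2^k` for `k` sampled stereocenters.
#' @param n_targets number of protein-target columns in the binding matrix.
#' @param stereo_sensitivity probability in `[0, 1]` that a given target's
#'   ternary activity value differs between a stereoisomer and its family base
#'   isomer.
#' @param weak_strong_ratio fraction of active entries annotated weak (1)
#'   rather than strong (2).
#' @param undefined_fraction fraction of emitted molecules re-emitted with one
#'   stereocenter's assignment erased (standing in for racemic or partially
#'   characterized registry entries).
#' @param signature_dim dimensionality of the continuous signatures.
#' @param signature_noise_sd per-dimension Gaussian noise on signatures.
#' @param seed root RNG seed.
#' @return A validated `synthetic_library_config` list.
#' @export
synthetic_library_config <- function(n_families = 150,
                                     stereocenters_per_family = c(1, 3),
                                     isomers_per_family = c(2, 4),
                                     n_targets = 50,
                                     stereo_sensitivity = 0.01,
                                     weak_strong_ratio = 0.5,
                                     undefined_fraction = 0.1,
                                     signature_dim = 128,
                                     signature_noise_sd = 0.02,
                                     seed = 42) {
  cfg <- list(n_families = n_families,
              stereocenters_per_family = as.integer(stereocenters_per_family),
              isomers_per_family = as.integer(isomers_per_family),
              n_targets = n_targets,
              stereo_sensitivity = stereo_sensitivity,
              weak_strong_ratio = weak_strong_ratio,
              undefined_fraction = undefined_fraction,
              signature_dim = signature_dim,
              signature_noise_sd = signature_noise_sd,
              seed = seed)
  validate_library_config(cfg)
  structure(cfg, class = "synthetic_library_config")
}

validate_library_config <- function(cfg) {
  assert_that(length(cfg$n_families) == 1 && cfg$n_families >= 0 &&
                cfg$n_families == floor(cfg$n_families),
              "n_families must be a non-negative integer")
  assert_that(cfg$n_families <= 512,
              "n_families exceeds the scaffold pool capacity (512)")
  st <- cfg$stereocenters_per_family
  iso <- cfg$isomers_per_family
  assert_that(length(st) == 2 && all(st >= 1) && st[1] <= st[2],
              "stereocenters_per_family must be an increasing range >= 1")
  assert_that(st[2] <= 3, "at most 3 stereocenters per family are supported")
  assert_that(length(iso) == 2 && all(iso >= 2) && iso[1] <= iso[2],
              "isomers_per_family must be an increasing range >= 2")
  assert_that(iso[1] <= 2^st[1],
              paste0("unsatisfiable config: at least ", iso[1], " isomers ",
                     "requested but families may have as few as ", st[1],
                     " stereocenter(s), i.e. ", 2^st[1], " stereoisomers"))
  assert_that(is_count(cfg$n_targets), "n_targets must be a count >= 1")
  for (p in c("stereo_sensitivity", "weak_strong_ratio",
              "undefined_fraction")) {
    assert_that(is_prob(cfg[[p]]), paste0(p, " must be a probability in [0,1]"))
  }
  assert_that(is_count(cfg$signature_dim), "signature_dim must be a count")
  assert_that(length(cfg$signature_noise_sd) == 1 && cfg$signature_noise_sd >= 0,
              "signature_noise_sd must be non-negative")
  assert_that(length(cfg$seed) == 1 && is.finite(cfg$seed),
              "seed must be a finite number")
  invisible(cfg)
}

#' Generate a synthetic stereoisomer library
#'
#' Builds `n_families` constitutionally distinct scaffolds, enumerates distinct
#' stereocenter configurations per family, draws one base binding profile per
#' family and mutates it per additional isomer (each target independently with
#' probability `stereo_sensitivity`; mutations always change the ternary
#' value, and mutation indicators are coupled across isomers through their
#' shared flipped stereocenters, so that profile divergence tracks
#' configuration divergence while per-target marginals stay exact). Signatures
#' are the family base vector plus a per-isomer offset whose magnitude scales
#' with the isomer's profile Hamming distance from the family base, plus
#' i.i.d. Gaussian noise. A fraction of molecules is re-emitted with one
#' stereocenter erased.
#'
#' @param config a [synthetic_library_config()].
#' @return A `synthetic_library` list with elements `molecules` (data.frame:
#'   `id`, `smiles`, `family`, `n_centers`, `config`, `fully_defined`),
#'   `profiles` (compound x target integer matrix with values 0/1/2),
#'   `signatures` (compound x dim numeric matrix), `family_labels` (named
#'   integer vector), `truth` (data.frame of within-family pairs: `id_a`,
#'   `id_b`, `family`, `same_family`, `profile_differs`), and `config`.
#' @examples
#' lib <- generate_library(synthetic_library_config(n_families = 5, seed = 1))
#' head(lib$molecules)
#' @export
generate_library <- function(config) {
  if (!inherits(config, "synthetic_library_config")) {
    config <- do.call(synthetic_library_config, config)
  }
  validate_library_config(config)
  fam_data <- lapply(seq_len(config$n_families), function(f) {
    generate_family(config, f)
  })

  molecules <- if (length(fam_data) > 0) {
    do.call(rbind, c(lapply(fam_data, `[[`, "molecules"),
                     list(make.row.names = FALSE)))
  } else {
    data.frame(id = character(0), smiles = character(0),
               family = integer(0), n_centers = integer(0),
               config = character(0), fully_defined = logical(0),
               stringsAsFactors = FALSE)
  }
  profiles <- do.call(rbind, lapply(fam_data, `[[`, "profiles"))
  signatures <- do.call(rbind, lapply(fam_data, `[[`, "signatures"))
  if (is.null(profiles)) {
    profiles <- matrix(integer(0), nrow = 0, ncol = config$n_targets,
                       dimnames = list(NULL, target_names(config$n_targets)))
  }
  if (is.null(signatures)) {
    signatures <- matrix(numeric(0), nrow = 0, ncol = config$signature_dim,
                         dimnames = list(NULL,
                                         signature_names(config$signature_dim)))
  }
  truth <- build_truth_table(molecules, profiles)

  structure(list(molecules = molecules,
                 profiles = profiles,
                 signatures = signatures,
                 family_labels = stats::setNames(molecules$family,
                                                 molecules$id),
                 truth = truth,
                 config = config),
            class = "synthetic_library")
}

#' @export
print.synthetic_library <- function(x, ...) {
  cat("<synthetic_library> ", nrow(x$molecules), " molecules in ",
      length(unique(x$molecules$family)), " families; ",
      ncol(x$profiles), " targets, ", ncol(x$signatures),
      "-dim signatures\n", sep = "")
  invisible(x)
}

target_names <- function(n) sprintf("T%03d", seq_len(n))
signature_names <- function(n) sprintf("S%03d", seq_len(n))

# One family: scaffold, configurations, profiles, signatures.
generate_family <- function(config, f) {
  st <- config$stereocenters_per_family
  iso <- config$isomers_per_family
  Tn <- config$n_targets
  s <- config$stereo_sensitivity

  with_seed(derive_seed(config$seed, 7001, f), {
    k <- if (st[1] == st[2]) st[1] else sample(st[1]:st[2], 1)
    m_req <- if (iso[1] == iso[2]) iso[1] else sample(iso[1]:iso[2], 1)
    m <- min(m_req, 2^k)

    parts <- scaffold_parts(f - 1, k)

    # distinct configuration assignments; index 1 (all-'@') is the base isomer
    all_cfg <- as.matrix(expand.grid(rep(list(0:1), k)))[, k:1, drop = FALSE]
    pick <- if (m - 1 == nrow(all_cfg) - 1) {
      2:nrow(all_cfg)
    } else {
      sort(sample(2:nrow(all_cfg), m - 1))
    }
    cfgs <- all_cfg[c(1, pick), , drop = FALSE]

    # family base ternary profile (sparse; at least one active target)
    active <- runif(Tn) < BASE_ACTIVITY_RATE
    if (!any(active)) active[sample.int(Tn, 1)] <- TRUE
    base_prof <- integer(Tn)
    base_prof[active] <- ifelse(runif(sum(active)) < config$weak_strong_ratio,
                                1L, 2L)

    # mutation machinery: per-(target, stereocenter) uniforms couple mutation
    # indicators across isomers; the mutated value is drawn once per target.
    U <- matrix(runif(Tn * k), Tn, k)
    V <- vapply(seq_len(Tn), function(t) {
      alt <- setdiff(0:2, base_prof[t])
      alt[sample.int(2, 1)]
    }, numeric(1))
    # keep profiles nonzero under any mutation pattern: the first active
    # target mutates to the nonzero alternative
    t_star <- which(active)[1]
    V[t_star] <- if (base_prof[t_star] == 1L) 2L else 1L

    profs <- matrix(rep(base_prof, m), nrow = m, byrow = TRUE)
    for (j in seq_len(m)[-1]) {
      flips <- which(cfgs[j, ] != cfgs[1, ])
      h <- length(flips)
      theta <- 1 - (1 - s)^(1 / h)
      u_min <- apply(U[, flips, drop = FALSE], 1, min)
      mut <- u_min < theta
      profs[j, mut] <- V[mut]
    }
    storage.mode(profs) <- "integer"

    # signatures: family base + configuration-aligned offset scaled by the
    # isomer's profile Hamming distance from the base, + noise
    d <- config$signature_dim
    base_sig <- rnorm(d)
    W <- matrix(rnorm(d * k), d, k)
    W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
    sigs <- matrix(0, m, d)
    for (j in seq_len(m)) {
      flips <- which(cfgs[j, ] != cfgs[1, ])
      h_p <- sum(profs[j, ] != base_prof)
      off <- 0
      if (length(flips) > 0 && h_p > 0) {
        dir <- rowSums(W[, flips, drop = FALSE])
        dir <- dir / sqrt(sum(dir^2))
        off <- SIGNATURE_OFFSET_PER_TARGET * h_p * dir
      }
      sigs[j, ] <- base_sig + off + rnorm(d, sd = config$signature_noise_sd)
    }

    # erase one stereocenter on a fraction of molecules
    erased <- runif(m) < config$undefined_fraction
    erase_at <- ifelse(erased, sample.int(k, m, replace = TRUE), NA_integer_)

    ids <- sprintf("F%04d_I%02d", f, seq_len(m))
    smiles <- vapply(seq_len(m), function(j) {
      assemble_smiles(parts, cfgs[j, ], erase_at[j])
    }, character(1))
    cfg_str <- vapply(seq_len(m), function(j) {
      chars <- ifelse(cfgs[j, ] == 0, "R", "S")
      if (erased[j]) chars[erase_at[j]] <- "?"
      paste(chars, collapse = "")
    }, character(1))

    rownames(profs) <- rownames(sigs) <- ids
    colnames(profs) <- target_names(Tn)
    colnames(sigs) <- signature_names(d)
    list(
      molecules = data.frame(id = ids, smiles = smiles, family = f,
                             n_centers = k, config = cfg_str,
                             fully_defined = !erased,
                             stringsAsFactors = FALSE),
      profiles = profs,
      signatures = sigs
    )
  })
}

# Mixed-radix selection of scaffold parts for family index `idx0` (0-based).
scaffold_parts <- function(idx0, k) {
  nl <- length(SCAFFOLD_LEFT)
  nr <- length(SCAFFOLD_RIGHT)
  ns <- length(SCAFFOLD_SPACER)
  nb <- length(SCAFFOLD_SUBS)
  cap <- nl * nr * ns * nb^k
  assert_that(idx0 < cap, "family index exceeds scaffold pool capacity")
  i <- idx0
  left <- SCAFFOLD_LEFT[i %% nl + 1]; i <- i %/% nl
  right <- SCAFFOLD_RIGHT[i %% nr + 1]; i <- i %/% nr
  spacer <- SCAFFOLD_SPACER[i %% ns + 1]; i <- i %/% ns
  subs <- character(k)
  for (c_ix in seq_len(k)) {
    subs[c_ix] <- SCAFFOLD_SUBS[i %% nb + 1]
    i <- i %/% nb
  }
  list(left = left, right = right, spacer = spacer, subs = subs)
}

# SMILES for one isomer; cfg is a 0/1 vector over centers (0 = '@'),
# erase_at an optional center whose assignment is left undefined.
assemble_smiles <- function(parts, cfg, erase_at = NA) {
  centers <- vapply(seq_along(cfg), function(c_ix) {
    sub <- parts$subs[c_ix]
    if (!is.na(erase_at) && c_ix == erase_at) {
      paste0("C(", sub, ")")
    } else {
      tag <- if (cfg[c_ix] == 0) "@" else "@@"
      paste0("[C", tag, "H](", sub, ")")
    }
  }, character(1))
  paste0(parts$left, parts$spacer, paste(centers, collapse = ""), parts$right)
}

build_truth_table <- function(molecules, profiles) {
  if (nrow(molecules) == 0) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      family = integer(0), same_family = logical(0),
                      profile_differs = logical(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(split(molecules$id, molecules$family), function(ids) {
    if (length(ids) < 2) return(NULL)
    prs <- index_pairs(length(ids))
    data.frame(id_a = ids[prs[, 1]], id_b = ids[prs[, 2]],
               stringsAsFactors = FALSE)
  })
  tr <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(tr)) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      family = integer(0), same_family = logical(0),
                      profile_differs = logical(0), stringsAsFactors = FALSE))
  }
  tr$family <- molecules$family[match(tr$id_a, molecules$id)]
  tr$same_family <- TRUE
  tr$profile_differs <- rowSums(profiles[tr$id_a, , drop = FALSE] !=
                                  profiles[tr$id_b, , drop = FALSE]) > 0
  tr
}
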