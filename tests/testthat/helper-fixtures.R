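# Shared fixtures, built once per test run and cached. All chemistry fixtures
# are generated programmatically; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# Penicillamine-style enantiomer pair plus assorted edge-case molecules.
fix_registry_records <- function() {
  cached("registry_records", function() {
    standardize_molecules(
      c("pen_S", "pen_R", "benzene", "pen_undef", "ala_iso", "acetate",
        "tma", "two_def", "two_partial", "ala_spell1", "ala_spell2"),
      c("CC(C)(S)[C@@H](N)C(=O)O",   # (S)-penicillamine
        "CC(C)(S)[C@H](N)C(=O)O",    # (R)-penicillamine
        "c1ccccc1",
        "CC(C)(S)C(N)C(=O)O",        # racemic penicillamine
        "[13CH3][C@H](N)C(=O)O",     # isotope-labeled alanine
        "CC(=O)[O-]",
        "C[N+](C)(C)C",
        "O[C@H](F)[C@H](Cl)CC",      # two assigned centers
        "O[C@H](F)C(Cl)CC",          # one of two assigned
        "C[C@H](N)C(=O)O",           # same molecule, two spellings
        "OC(=O)[C@@H](N)C"))
  })
}

# Small library used by grouping / profile tests (mixed sizes, some erased).
fix_small_library <- function() {
  cached("small_library", function() {
    generate_library(synthetic_library_config(
      n_families = 30, stereocenters_per_family = c(1, 3),
      isomers_per_family = c(2, 4), n_targets = 25,
      stereo_sensitivity = 0.15, undefined_fraction = 0.15, seed = 101))
  })
}

fix_small_records <- function() {
  cached("small_records", function() {
    lib <- fix_small_library()
    standardize_molecules(lib$molecules$id, lib$molecules$smiles)
  })
}

# Stereo-sensitive benchmark bundle: library, registry, conformers,
# descriptors and distance matrices. The heaviest fixture (conformers for
# ~230 molecules); reused by descriptor, benchmark and acceptance tests.
fix_bench <- function() {
  cached("bench", function() {
    lib <- generate_library(synthetic_library_config(
      n_families = 120, stereocenters_per_family = c(2, 3),
      isomers_per_family = c(4, 4), stereo_sensitivity = 0.2,
      undefined_fraction = 0, seed = 42))
    recs <- standardize_molecules(lib$molecules$id, lib$molecules$smiles)
    confs <- generate_conformers(recs, embed_seed = 1)
    fp <- fingerprint_2d(recs)
    geo <- descriptor_3d_matrix(confs)
    ids <- recs$id
    list(lib = lib, records = recs, conformers = confs,
         fp2d = fp, geo3d = geo,
         ref_dist = stereoactivity:::pairwise_cosine(lib$signatures[ids, ]),
         fp_dist = stereoactivity:::pairwise_cosine(fp[ids, ]),
         geo_dist = stereoactivity:::pairwise_cosine(geo[ids, ]))
  })
}

# Small conformer set for geometry tests.
fix_confs <- function() {
  cached("conf_basic", function() {
    recs <- standardize_molecules(
      c("ala_S", "ala_R", "methane", "benzene", "pen_S"),
      c("C[C@H](N)O", "C[C@@H](N)O", "C", "c1ccccc1",
        "CC(C)(S)[C@@H](N)C(=O)O"))
    list(records = recs, confs = generate_conformers(recs, embed_seed = 7))
  })
}

# Brute-force O(n^2) stereoisomer grouping oracle: pairwise comparison of the
# stereo-stripped canonical SMILES and filter fields, no hashing. Returns a
# sorted list of sorted member-id vectors.
oracle_grouping <- function(records) {
  rec <- records[order(records$id), , drop = FALSE]
  rec <- rec[!duplicated(rec$inchikey), , drop = FALSE]
  rec <- rec[rec$stereo_status == "fully_defined" & !rec$has_isotope, ,
             drop = FALSE]
  n <- nrow(rec)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      same <- rec$canonical_smiles_nostereo[i] ==
        rec$canonical_smiles_nostereo[j] &&
        rec$protonation_char[i] == rec$protonation_char[j] &&
        rec$formal_charge[i] == rec$formal_charge[j]
      if (same) parent[find(j)] <- find(i)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  classes <- split(rec$id, comp)
  classes <- classes[vapply(classes, length, integer(1)) >= 2]
  unname(classes[order(vapply(classes, `[`, "", 1))])
}

# Group membership of an identify_stereoisomer_groups() result in the same
# normalized shape as the oracle.
groups_as_sets <- function(groups) {
  classes <- lapply(stereoactivity:::group_members(groups), sort)
  unname(classes[order(vapply(classes, `[`, "", 1))])
}

# Rigid rotation + translation of a conformer, for invariance tests.
rigid_transform <- function(conf, seed) {
  tr <- with(list(), {
    set.seed(seed)
    q <- matrix(rnorm(9), 3)
    Q <- qr.Q(qr(q))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]  # proper rotation only
    list(Q = Q, t = rnorm(3, sd = 5))
  })
  conf$coordinates <- conf$coordinates %*% tr$Q +
    matrix(tr$t, nrow(conf$coordinates), 3, byrow = TRUE)
  conf
}

mirror_conformer <- function(conf) {
  conf$coordinates[, 1] <- -conf$coordinates[, 1]
  conf
}
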