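# Molecule standardization: structure keys, stereo-definition status,
# charge/isotope flags, and agreement with an independent InChI implementation.

test_that("enantiomers share the connectivity key but not the stereo block", {
  recs <- fix_registry_records()
  pen <- recs[recs$id %in% c("pen_S", "pen_R"), ]
  expect_equal(length(unique(pen$connectivity_key)), 1)
  expect_equal(length(unique(pen$stereo_block)), 2)
  expect_true(all(grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", recs$inchikey)))
  expect_true(all(pen$stereo_status == "fully_defined"))
  expect_equal(pen$n_potential_stereocenters, c(1L, 1L))
})

test_that("keys agree with an independent InChI implementation", {
  # oracle: RDKit's InChI bindings, a code base unrelated to Open Babel
  out <- suppressWarnings(system2("python", c("-c", shQuote(paste0(
    "from rdkit import Chem\n",
    "for smi in ['CC(C)(S)[C@@H](N)C(=O)O','CC(C)(S)[C@H](N)C(=O)O']:\n",
    "    print(Chem.MolToInchiKey(Chem.MolFromSmiles(smi)))"))),
    stdout = TRUE, stderr = FALSE))
  recs <- fix_registry_records()
  expect_identical(unname(out),
                   recs$inchikey[match(c("pen_S", "pen_R"), recs$id)])
})

test_that("achiral molecules are classified achiral", {
  recs <- fix_registry_records()
  benz <- recs[recs$id == "benzene", ]
  expect_equal(benz$n_potential_stereocenters, 0L)
  expect_identical(benz$stereo_status, "achiral")
  expect_identical(benz$formula, "C6H6")
})

test_that("equivalent SMILES spellings standardize identically", {
  recs <- fix_registry_records()
  sp <- recs[recs$id %in% c("ala_spell1", "ala_spell2"), ]
  expect_equal(length(unique(sp$canonical_smiles)), 1)
  expect_equal(length(unique(sp$inchikey)), 1)
})

test_that("standardization is idempotent on canonical SMILES", {
  recs <- fix_registry_records()
  again <- standardize_molecules(paste0(recs$id, "_2"),
                                 recs$canonical_smiles)
  expect_identical(again$canonical_smiles, recs$canonical_smiles)
  expect_identical(again$inchikey, recs$inchikey)
})

test_that("unparseable structures raise an error naming the input", {
  expect_error(standardize_molecules(c("ok", "bad"), c("CCO", "C1CC")),
               "bad")
  expect_error(standardize_molecules(c("a", "a"), c("C", "CC")), "unique")
})

test_that("charge, protonation and isotope flags are populated", {
  recs <- fix_registry_records()
  expect_equal(recs$formal_charge[recs$id == "acetate"], -1L)
  expect_equal(recs$formal_charge[recs$id == "tma"], 1L)
  expect_true(recs$has_isotope[recs$id == "ala_iso"])
  expect_false(any(recs$has_isotope[recs$id %in% c("pen_S", "pen_R")]))
  expect_identical(recs$protonation_char[recs$id == "pen_S"], "N")
})

test_that("stereo-definition status follows assigned/potential counts", {
  recs <- fix_registry_records()
  expect_identical(recs$stereo_status[recs$id == "two_def"], "fully_defined")
  expect_identical(recs$stereo_status[recs$id == "two_partial"],
                   "partially_defined")
  expect_identical(recs$stereo_status[recs$id == "pen_undef"],
                   "partially_defined")
  expect_equal(recs$n_assigned_stereocenters[recs$id == "two_partial"], 1L)
  expect_equal(recs$n_potential_stereocenters[recs$id == "two_partial"], 2L)
  # E/Z double-bond stereo counts toward the potential total
  ez <- standardize_molecules(c("trans", "undef"), c("C/C=C/C", "CC=CC"))
  expect_equal(ez$n_potential_stereocenters, c(1L, 1L))
  expect_equal(ez$n_assigned_stereocenters, c(1L, 0L))
  expect_identical(ez$stereo_status, c("fully_defined", "partially_defined"))
})

test_that("generator erasures are classified partially defined", {
  lib <- generate_library(synthetic_library_config(
    n_families = 250, isomers_per_family = c(2, 2), undefined_fraction = 0.2,
    seed = 23))
  recs <- standardize_molecules(lib$molecules$id, lib$molecules$smiles)
  # exact agreement with the generator's truth flags
  expect_identical(recs$stereo_status == "fully_defined",
                   lib$molecules$fully_defined[match(recs$id,
                                                     lib$molecules$id)])
  phat <- mean(recs$stereo_status == "partially_defined")
  n <- nrow(recs)
  expect_lt(abs(phat - 0.2), 1.96 * sqrt(0.2 * 0.8 / n))
})

test_that("connectivity keys are invariant to stereo descriptors", {
  lib <- fix_small_library()
  recs <- fix_small_records()
  fam <- lib$molecules$family[match(recs$id, lib$molecules$id)]
  keys_per_family <- tapply(recs$connectivity_key, fam,
                            function(x) length(unique(x)))
  expect_true(all(keys_per_family == 1))
  # stereo-stripped canonical forms equal <=> connectivity keys equal
  nostereo_map <- tapply(recs$canonical_smiles_nostereo,
                         recs$connectivity_key,
                         function(x) length(unique(x)))
  expect_true(all(nostereo_map == 1))
  key_map <- tapply(recs$connectivity_key, recs$canonical_smiles_nostereo,
                    function(x) length(unique(x)))
  expect_true(all(key_map == 1))
})
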