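# Compound registry: standardization, structure keys and stereo-definition
# status. Stereoisomer relationships are detected through InChIKey blocks: the
# first 14 characters hash the molecular connectivity (shared by all
# stereoisomers of one constitution), the second block encodes stereochemistry
# and isotopes, and the final character encodes protonation.

INCHIKEY_PATTERN <- "^[A-Z]{14}-[A-Z]{10}-[A-Z]$"

#' Standardize a batch of molecules
#'
#' Parses each SMILES with Open Babel and computes, per molecule: canonical
#' SMILES (with and without stereo descriptors), InChIKey and its connectivity /
#' stereo / protonation blocks, molecular formula, formal charge, isotope flag,
#' and the number of potential and assigned stereocenters (tetrahedral centers
#' plus stereogenic double bonds, counted by the InChI engine with undefined
#' centers marked). The stereo-definition status classifies each molecule as
#' `achiral` (no potential stereocenters), `fully_defined` (all assigned) or
#' `partially_defined` (at least one unassigned), the latter standing for
#' racemic or incompletely characterized registry entries.
#'
#' @param ids character vector of unique compound identifiers.
#' @param smiles character vector of SMILES strings, same length as `ids`.
#' @return A `data.frame` with one row per molecule and columns `id`,
#'   `smiles_in`, `canonical_smiles`, `canonical_smiles_nostereo`, `inchikey`,
#'   `connectivity_key`, `stereo_block`, `protonation_char`, `formula`,
#'   `formal_charge`, `has_isotope`, `n_potential_stereocenters`,
#'   `n_assigned_stereocenters`, `stereo_status`.
#' @examples
#' \dontrun{
#' recs <- standardize_molecules(
#'   c("pen_S", "pen_R"),
#'   c("CC(C)(S)[C@@H](N)C(=O)O", "CC(C)(S)[C@H](N)C(=O)O"))
#' recs$connectivity_key  # identical: same constitution
#' recs$stereo_block      # different: enantiomers
#' }
#' @export
standardize_molecules <- function(ids, smiles) {
  assert_that(length(ids) == length(smiles) && length(ids) > 0,
              "ids and smiles must be non-empty vectors of equal length")
  assert_that(!anyDuplicated(ids), "ids must be unique")
  ids <- as.character(ids)
  smiles <- as.character(smiles)

  can <- ob_smiles_to_titled(smiles, ids, "can")
  missing <- setdiff(ids, names(can))
  if (length(missing) > 0) {
    bad <- paste(sprintf("%s ('%s')", missing,
                         smiles[match(missing, ids)]), collapse = ", ")
    stop("cannot parse structure(s): ", bad, call. = FALSE)
  }
  can <- can[ids]

  nostereo <- ob_smiles_to_titled(smiles, ids, "can", "-xi")[ids]
  inchikey <- ob_smiles_to_lines(smiles, ids, "inchikey")
  # Non-standard InChI with the SUU option: undefined stereocenters appear in
  # the /t (tetrahedral) and /b (double bond) layers marked with '?'.
  inchi_suu <- ob_smiles_to_lines(smiles, ids, "inchi", c("-xX", "SUU"))

  failed <- ids[is.na(inchikey) | is.na(inchi_suu) |
                  !grepl(INCHIKEY_PATTERN, inchikey)]
  if (length(failed) > 0) {
    stop("InChI computation failed for: ", paste(failed, collapse = ", "),
         call. = FALSE)
  }

  layers <- lapply(inchi_suu, parse_inchi_layers)
  n_pot <- vapply(layers, function(l) l$n_potential, integer(1))
  n_asg <- vapply(layers, function(l) l$n_assigned, integer(1))

  rec <- data.frame(
    id = ids,
    smiles_in = smiles,
    canonical_smiles = unname(can),
    canonical_smiles_nostereo = unname(nostereo),
    inchikey = unname(inchikey),
    connectivity_key = substr(inchikey, 1, 14),
    stereo_block = substr(inchikey, 16, 23),
    protonation_char = substr(inchikey, 27, 27),
    formula = vapply(layers, function(l) l$formula, character(1)),
    formal_charge = vapply(layers, function(l) l$formal_charge, integer(1)),
    has_isotope = vapply(layers, function(l) l$has_isotope, logical(1)),
    n_potential_stereocenters = n_pot,
    n_assigned_stereocenters = n_asg,
    stringsAsFactors = FALSE
  )
  rownames(rec) <- NULL
  rec$stereo_status <- assess_stereo_definition(rec)
  rec
}

#' Standardize a single molecule
#'
#' Convenience wrapper around [standardize_molecules()] for one structure.
#'
#' @param id compound identifier.
#' @param smiles SMILES string.
#' @return A one-row `data.frame`; see [standardize_molecules()].
#' @export
standardize_molecule <- function(id, smiles) {
  standardize_molecules(id, smiles)
}

#' Classify stereo-definition status
#'
#' A molecule is `achiral` when it has no potential stereocenters,
#' `fully_defined` when every potential stereocenter carries an assignment,
#' and `partially_defined` otherwise (including molecules with no assignments
#' at all, i.e. racemic registry entries). Only fully defined molecules are
#' eligible for stereoisomer groups; partially defined ones are filtered out so
#' that downstream comparisons never involve racemic mixtures.
#'
#' @param rec a record `data.frame` as returned by [standardize_molecules()]
#'   (one or more rows).
#' @return character vector, one of `"achiral"`, `"fully_defined"`,
#'   `"partially_defined"` per row.
#' @export
assess_stereo_definition <- function(rec) {
  assert_that(all(c("n_potential_stereocenters", "n_assigned_stereocenters")
                  %in% names(rec)),
              "rec must carry stereocenter counts (see standardize_molecules)")
  n_pot <- rec$n_potential_stereocenters
  n_asg <- rec$n_assigned_stereocenters
  assert_that(all(n_asg <= n_pot), "n_assigned must not exceed n_potential")
  ifelse(n_pot == 0, "achiral",
         ifelse(n_asg == n_pot, "fully_defined", "partially_defined"))
}

# Parse the layers of an InChI string (generated with the SUU option so that
# undefined stereo elements are present and marked '?').
#
# Extracted fields: formula; formal charge (sum of /q and /p contributions);
# isotope flag (/i layer); counts of potential and assigned stereo elements
# from the /t (tetrahedral) and /b (double-bond) layers. Multi-component
# structures use ';' separators inside layers; all components are counted.
parse_inchi_layers <- function(inchi) {
  assert_that(is.character(inchi) && length(inchi) == 1 &&
                startsWith(inchi, "InChI="),
              paste0("not an InChI string: ", inchi))
  body <- sub("^InChI=1S?/", "", inchi)
  segs <- strsplit(body, "/", fixed = TRUE)[[1]]
  formula <- segs[1]

  get_layer <- function(prefix) {
    hit <- segs[startsWith(segs, prefix) &
                  !startsWith(segs, paste0(prefix, prefix))]
    if (length(hit) == 0) return(NULL)
    sub(paste0("^", prefix), "", hit[1])
  }
  sum_signed <- function(layer) {
    if (is.null(layer)) return(0L)
    toks <- unlist(strsplit(layer, ";", fixed = TRUE))
    toks <- toks[nzchar(toks)]
    total <- 0L
    for (tk in toks) {
      # components may carry a multiplier, e.g. "2*+1"
      mult <- 1L
      if (grepl("^[0-9]+\\*", tk)) {
        mult <- as.integer(sub("\\*.*$", "", tk))
        tk <- sub("^[0-9]+\\*", "", tk)
      }
      v <- suppressWarnings(as.integer(tk))
      if (!is.na(v)) total <- total + mult * v
    }
    total
  }
  count_stereo <- function(layer) {
    if (is.null(layer)) return(c(pot = 0L, asg = 0L))
    comps <- unlist(strsplit(layer, ";", fixed = TRUE))
    toks <- unlist(lapply(comps, function(cp) {
      mult <- 1L
      if (grepl("^[0-9]+\\*", cp)) {
        mult <- as.integer(sub("\\*.*$", "", cp))
        cp <- sub("^[0-9]+\\*", "", cp)
      }
      rep(strsplit(cp, ",", fixed = TRUE)[[1]], mult)
    }))
    toks <- toks[nzchar(toks)]
    pot <- length(toks)
    asg <- sum(!grepl("\\?$", toks))
    c(pot = pot, asg = as.integer(asg))
  }

  tcount <- count_stereo(get_layer("t"))
  bcount <- count_stereo(get_layer("b"))
  list(
    formula = formula,
    formal_charge = as.integer(sum_signed(get_layer("q")) +
                                 sum_signed(get_layer("p"))),
    has_isotope = !is.null(get_layer("i")),
    n_potential = as.integer(tcount["pot"] + bcount["pot"]),
    n_assigned = as.integer(tcount["asg"] + bcount["asg"])
  )
}
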