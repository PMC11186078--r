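# Stereoisomer group identification.
#
# Molecules are bucketed by the 14-character InChIKey connectivity block and
# retained only when their differences are exclusively stereochemical: equal
# stereo-stripped canonical SMILES (guarding the hash against collisions),
# equal protonation character and formal charge, no isotopes, and exhaustive
# stereo characterization (fully defined), so that no comparison involves a
# racemic or partially characterized entry. Buckets with >= 2 survivors become
# stereoisomer groups; everything removed is reported with a machine-readable
# reason.

EXCLUSION_REASONS <- c("duplicate", "partially_defined", "achiral_duplicate",
                       "isotope", "charge_mismatch", "protonation_mismatch",
                       "constitution_mismatch", "singleton")

#' Identify stereoisomer groups in a standardized library
#'
#' @param records record `data.frame` from [standardize_molecules()].
#' @return A list with elements:
#'   \describe{
#'     \item{groups}{data.frame with one row per group member: `group_id`,
#'       `connectivity_key`, `member_id`; `group_id` is derived from the
#'       connectivity key, so the partition is invariant to input order.}
#'     \item{excluded}{data.frame `molecule_id`, `reason` with reasons in
#'       `duplicate`, `partially_defined`, `achiral_duplicate`, `isotope`,
#'       `charge_mismatch`, `protonation_mismatch`, `constitution_mismatch`,
#'       `singleton`.}
#'   }
#' @examples
#' \dontrun{
#' recs <- standardize_molecules(
#'   c("pen_S", "pen_R"),
#'   c("CC(C)(S)[C@@H](N)C(=O)O", "CC(C)(S)[C@H](N)C(=O)O"))
#' identify_stereoisomer_groups(recs)$groups
#' }
#' @export
identify_stereoisomer_groups <- function(records) {
  assert_that(is.data.frame(records), "records must be a data.frame")
  req <- c("id", "inchikey", "connectivity_key", "canonical_smiles_nostereo",
           "protonation_char", "formal_charge", "has_isotope", "stereo_status",
           "stereo_block")
  assert_that(all(req %in% names(records)),
              "records lack required registry columns")

  empty_groups <- data.frame(group_id = character(0),
                             connectivity_key = character(0),
                             member_id = character(0),
                             stringsAsFactors = FALSE)
  excluded <- data.frame(molecule_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  if (nrow(records) == 0) {
    return(list(groups = empty_groups, excluded = excluded))
  }

  drop <- function(ids, reason) {
    if (length(ids) > 0) {
      excluded <<- rbind(excluded,
                         data.frame(molecule_id = ids, reason = reason,
                                    stringsAsFactors = FALSE))
    }
  }

  # collapse full-InChIKey duplicates, keeping the lexicographically smallest id
  rec <- records[order(records$id), , drop = FALSE]
  dup <- duplicated(rec$inchikey)
  drop(rec$id[dup], "duplicate")
  rec <- rec[!dup, , drop = FALSE]

  drop(rec$id[rec$has_isotope], "isotope")
  rec <- rec[!rec$has_isotope, , drop = FALSE]
  drop(rec$id[rec$stereo_status == "partially_defined"], "partially_defined")
  rec <- rec[rec$stereo_status != "partially_defined", , drop = FALSE]

  group_rows <- list()
  for (bucket in split(seq_len(nrow(rec)), rec$connectivity_key)) {
    b <- rec[bucket, , drop = FALSE]
    # achiral molecules cannot be stereoisomers of anything (meso forms carry
    # defined stereocenters and are retained as fully_defined members)
    achiral <- b$stereo_status == "achiral"
    drop(b$id[achiral & nrow(b) > 1], "achiral_duplicate")
    if (nrow(b) == 1 && achiral[1]) next
    b <- b[!achiral, , drop = FALSE]
    if (nrow(b) == 0) next

    # modal sub-bucket on the exclusivity fields; non-modal members are
    # excluded with the first field that disagrees
    subkey <- paste(b$canonical_smiles_nostereo, b$protonation_char,
                    b$formal_charge, sep = "\r")
    tab <- table(subkey)
    modal <- names(tab)[tab == max(tab)]
    modal <- sort(modal)[1]
    in_modal <- subkey == modal
    if (any(!in_modal)) {
      ref <- b[in_modal, , drop = FALSE][1, ]
      for (w in which(!in_modal)) {
        reason <- if (b$formal_charge[w] != ref$formal_charge) {
          "charge_mismatch"
        } else if (b$protonation_char[w] != ref$protonation_char) {
          "protonation_mismatch"
        } else {
          "constitution_mismatch"
        }
        drop(b$id[w], reason)
      }
      b <- b[in_modal, , drop = FALSE]
    }
    if (nrow(b) < 2) {
      drop(b$id, "singleton")
      next
    }
    assert_that(!anyDuplicated(b$stereo_block),
                paste0("stereo blocks collide within connectivity bucket ",
                       b$connectivity_key[1]))
    group_rows[[length(group_rows) + 1]] <-
      data.frame(group_id = paste0("SG_", b$connectivity_key[1]),
                 connectivity_key = b$connectivity_key[1],
                 member_id = sort(b$id),
                 stringsAsFactors = FALSE)
  }

  groups <- if (length(group_rows) > 0) {
    do.call(rbind, c(group_rows, list(make.row.names = FALSE)))
  } else {
    empty_groups
  }
  groups <- groups[order(groups$group_id, groups$member_id), , drop = FALSE]
  rownames(groups) <- NULL
  excluded <- excluded[order(excluded$molecule_id), , drop = FALSE]
  rownames(excluded) <- NULL
  list(groups = groups, excluded = excluded)
}

#' Histogram of stereoisomer group sizes
#'
#' @param groups the `groups` data.frame from
#'   [identify_stereoisomer_groups()].
#' @return named integer vector mapping group size to number of groups.
#' @export
group_size_histogram <- function(groups) {
  if (nrow(groups) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  sizes <- table(groups$group_id)
  assert_that(all(sizes >= 2), "groups must have >= 2 members")
  hist <- table(as.integer(sizes))
  stats::setNames(as.integer(hist), names(hist))
}

# Sizes per group id, used by several consumers.
group_sizes <- function(groups) {
  if (nrow(groups) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(groups$group_id)
  stats::setNames(as.integer(tab), names(tab))
}

# Members per group id, as a named list.
group_members <- function(groups) {
  if (nrow(groups) == 0) return(list())
  split(groups$member_id, groups$group_id)
}
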