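# Thin wrapper around the Open Babel command-line tool (obabel), which supplies
# the standard chemistry primitives: SMILES canonicalization, InChI/InChIKey
# computation, ECFP fingerprints and MMFF94 force-field minimization. All calls
# are batched (one process per conversion, not per molecule).

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) {
    stop("The 'obabel' executable (Open Babel >= 3.0) was not found on PATH; ",
         "it is required for all chemistry operations.", call. = FALSE)
  }
  unname(p)
}

# Run obabel on an input file, returning stdout lines. stderr (Open Babel
# warnings) is captured and discarded unless capture_stderr = TRUE.
ob_run <- function(args, capture_stderr = FALSE) {
  err <- tempfile("obabel-err-", fileext = ".txt")
  on.exit(unlink(err), add = TRUE)
  out <- suppressWarnings(system2(obabel_path(), args, stdout = TRUE, stderr = err))
  status <- attr(out, "status") %||% 0L
  if (status != 0 && length(out) == 0) {
    msg <- tryCatch(readLines(err, warn = FALSE), error = function(e) character(0))
    stop("obabel failed (status ", status, "): ",
         paste(utils::tail(msg, 3), collapse = " "), call. = FALSE)
  }
  if (capture_stderr) {
    attr(out, "stderr") <- tryCatch(readLines(err, warn = FALSE),
                                    error = function(e) character(0))
  }
  out
}

# Write a .smi file (SMILES + id, whitespace-separated, no header).
ob_write_smi <- function(smiles, ids, path) {
  assert_that(length(smiles) == length(ids), "smiles and ids differ in length")
  writeLines(paste(smiles, ids), path)
  path
}

# Convert SMILES to a title-carrying line format ("can" or "smi").
# Returns a named character vector (id -> output string); ids missing from the
# output failed to convert.
ob_smiles_to_titled <- function(smiles, ids, outformat = "can",
                                extra = character(0)) {
  smi <- tempfile("mols-", fileext = ".smi")
  on.exit(unlink(smi), add = TRUE)
  ob_write_smi(smiles, ids, smi)
  out <- ob_run(c(smi, paste0("-o", outformat), extra))
  out <- out[nzchar(trimws(out))]
  if (length(out) == 0) return(stats::setNames(character(0), character(0)))
  parts <- regmatches(out, regexpr("^\\S+", out))
  titles <- trimws(sub("^\\S+\\s*", "", out))
  stats::setNames(parts, titles)
}

# Convert SMILES to a line format that does not carry titles (inchi, inchikey).
# Output is matched to input by order; if any molecule fails in batch mode the
# call falls back to per-molecule conversion so failures can be attributed.
ob_smiles_to_lines <- function(smiles, ids, outformat, extra = character(0)) {
  smi <- tempfile("mols-", fileext = ".smi")
  on.exit(unlink(smi), add = TRUE)
  ob_write_smi(smiles, ids, smi)
  out <- ob_run(c(smi, paste0("-o", outformat), extra))
  out <- out[nzchar(trimws(out))]
  if (length(out) == length(smiles)) {
    return(stats::setNames(trimws(out), ids))
  }
  # Rare path: attribute failures molecule by molecule.
  res <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (k in seq_along(ids)) {
    one <- tempfile("mol-", fileext = ".smi")
    ob_write_smi(smiles[k], ids[k], one)
    o <- ob_run(c(one, paste0("-o", outformat), extra))
    o <- o[nzchar(trimws(o))]
    if (length(o) >= 1) res[k] <- trimws(o[1])
    unlink(one)
  }
  res
}

# Convert an SDF file to a titled line format (canonical SMILES / InChIKey per
# record). Returns a character vector in record order; count mismatches are the
# caller's responsibility (titles are returned as names when available).
ob_sdf_to_lines <- function(sdf_path, outformat, extra = character(0)) {
  out <- ob_run(c(sdf_path, paste0("-o", outformat), extra))
  trimws(out[nzchar(trimws(out))])
}

# MMFF94 (steepest-descent) minimization of all records of an SDF file.
# Returns the path of the minimized SDF. Deterministic for fixed input.
ob_minimize_sdf <- function(sdf_in, sdf_out, steps = 1000,
                            forcefield = "MMFF94") {
  ob_run(c(sdf_in, "-osdf", "-O", sdf_out, "--minimize",
           "--ff", forcefield, "--steps", as.character(steps), "--sd"))
  sdf_out
}
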