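# Readers and writers for the library's on-disk formats: .smi structure lists,
# TSV profile matrices, CSV signature matrices, TSV truth tables and a JSON
# manifest with checksums.

#' Read a .smi structure file
#'
#' Whitespace-separated SMILES + identifier, one molecule per line, no header.
#'
#' @param path file path.
#' @return data.frame with columns `id`, `smiles`.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(id = character(0), smiles = character(0),
                      stringsAsFactors = FALSE))
  }
  smiles <- regmatches(lines, regexpr("^\\S+", lines))
  id <- trimws(sub("^\\S+\\s*", "", lines))
  assert_that(all(nzchar(id)), paste0("missing identifiers in ", path))
  data.frame(id = id, smiles = smiles, stringsAsFactors = FALSE)
}

#' Write a .smi structure file
#' @param id,smiles equal-length character vectors.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_smi <- function(id, smiles, path) {
  writeLines(paste(smiles, id), path)
  invisible(path)
}

#' Read / write a ternary profile matrix (TSV)
#'
#' Rows are compounds, columns targets; cells are integers in \{0, 1, 2\}.
#' @param path file path.
#' @return integer matrix with compound rownames.
#' @export
read_profiles <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "")
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  assert_that(nrow(m) == 0 || all(m %in% 0:2),
              paste0("profile values outside {0,1,2} in ", path))
  m
}

#' @rdname read_profiles
#' @param profiles integer matrix (compound x target).
#' @export
write_profiles <- function(profiles, path) {
  df <- data.frame(compound_id = rownames(profiles) %||% character(0),
                   profiles, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a continuous signature matrix (CSV)
#' @param path file path.
#' @return numeric matrix with compound rownames.
#' @export
read_signatures <- function(path) {
  df <- utils::read.csv(path, header = TRUE, row.names = 1,
                        check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

#' @rdname read_signatures
#' @param signatures numeric matrix (compound x dimension).
#' @export
write_signatures <- function(signatures, path) {
  df <- data.frame(compound_id = rownames(signatures) %||% character(0),
                   format(signatures, digits = 17, trim = TRUE,
                          scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic library to disk
#'
#' Emits structures (`molecules.smi`), compound annotations
#' (`molecules.tsv`), the ternary profile matrix (`profiles.tsv`), the
#' signature matrix (`signatures.csv`), the within-family truth table
#' (`truth.tsv`) and a JSON manifest carrying the generator configuration and
#' MD5 checksums of every file. The written tree round-trips losslessly
#' through [read_library()].
#'
#' @param lib a `synthetic_library` from [generate_library()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest as a list.
#' @export
write_library <- function(lib, out_dir) {
  assert_that(inherits(lib, "synthetic_library"),
              "lib must be a synthetic_library")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assert_that(dir.exists(out_dir), paste0("cannot create directory ", out_dir))

  paths <- c(structures = file.path(out_dir, "molecules.smi"),
             molecules = file.path(out_dir, "molecules.tsv"),
             profiles = file.path(out_dir, "profiles.tsv"),
             signatures = file.path(out_dir, "signatures.csv"),
             truth = file.path(out_dir, "truth.tsv"))
  ok <- tryCatch({
    write_smi(lib$molecules$id, lib$molecules$smiles, paths["structures"])
    utils::write.table(lib$molecules, paths["molecules"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_profiles(lib$profiles, paths["profiles"])
    write_signatures(lib$signatures, paths["signatures"])
    utils::write.table(lib$truth, paths["truth"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) {
    stop("failed to write library under '", out_dir, "': ",
         conditionMessage(e), call. = FALSE)
  })

  manifest <- list(
    format = "stereoactivity-library/1",
    config = unclass(lib$config),
    n_molecules = nrow(lib$molecules),
    n_families = length(unique(lib$molecules$family)),
    files = lapply(stats::setNames(nm = names(paths)), function(nm) {
      list(file = basename(paths[[nm]]),
           md5 = unname(tools::md5sum(paths[[nm]])))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a synthetic library written by [write_library()]
#' @param in_dir directory containing the library files.
#' @return a `synthetic_library` list.
#' @export
read_library <- function(in_dir) {
  man_path <- file.path(in_dir, "manifest.json")
  assert_that(file.exists(man_path), paste0("no manifest.json in ", in_dir))
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  molecules <- utils::read.table(file.path(in_dir, "molecules.tsv"),
                                 header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE,
                                 comment.char = "", quote = "",
                                 colClasses = c(id = "character",
                                                smiles = "character",
                                                config = "character"))
  profiles <- read_profiles(file.path(in_dir, "profiles.tsv"))
  signatures <- read_signatures(file.path(in_dir, "signatures.csv"))
  truth <- utils::read.table(file.path(in_dir, "truth.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE,
                             comment.char = "", quote = "",
                             colClasses = c(id_a = "character",
                                            id_b = "character"))
  cfg <- manifest$config
  cfg$stereocenters_per_family <- as.integer(cfg$stereocenters_per_family)
  cfg$isomers_per_family <- as.integer(cfg$isomers_per_family)
  config <- structure(cfg, class = "synthetic_library_config")
  validate_library_config(config)
  structure(list(molecules = molecules,
                 profiles = profiles,
                 signatures = signatures,
                 family_labels = stats::setNames(molecules$family,
                                                 molecules$id),
                 truth = truth,
                 config = config),
            class = "synthetic_library")
}
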