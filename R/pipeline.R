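# End-to-end orchestration: generate (or load) a library, standardize, group,
# analyze profiles, generate conformers, compute descriptors and run the kNN
# recapitulation benchmark, writing per-stage artifacts and a machine-readable
# report.

PIPELINE_STAGES <- c("generate", "standardize", "group", "profiles",
                     "conformers", "descriptors", "benchmark")

#' Pipeline run configuration
#'
#' @param out_dir directory for all artifacts.
#' @param stages character vector of stages to run, in
#'   generate/standardize/group/profiles/conformers/descriptors/benchmark
#'   order; `"all"` selects every stage. Stage dependencies are enforced: each
#'   requested stage requires the outputs of its predecessors, produced either
#'   in the same run or found in `out_dir` / supplied as inputs.
#' @param library_config a [synthetic_library_config()] for the generate
#'   stage.
#' @param eval_random,eval_stringent [eval_config()]s for the benchmark stage
#'   (random and stringent negative modes).
#' @param smi_path,profiles_path optional user-supplied structure list (.smi)
#'   and profile matrix (TSV), used instead of the generate stage.
#' @param n_random_pairs sampling cap per random pair category in the profile
#'   analysis stage.
#' @param embed_seed conformer embedding seed.
#' @param seed root seed for all stage-level randomness.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir,
                       stages = "all",
                       library_config = synthetic_library_config(),
                       eval_random = NULL,
                       eval_stringent = NULL,
                       smi_path = NULL,
                       profiles_path = NULL,
                       n_random_pairs = 100000,
                       embed_seed = 1,
                       seed = 42) {
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  assert_that(all(stages %in% PIPELINE_STAGES),
              paste0("unknown stage(s): ",
                     paste(setdiff(stages, PIPELINE_STAGES), collapse = ", ")))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  structure(list(out_dir = out_dir, stages = stages,
                 library_config = library_config,
                 eval_random = eval_random, eval_stringent = eval_stringent,
                 smi_path = smi_path, profiles_path = profiles_path,
                 n_random_pairs = n_random_pairs,
                 embed_seed = embed_seed, seed = seed),
            class = "run_config")
}

#' Run the stereochemistry/bioactivity pipeline
#'
#' Executes the requested stages in dependency order. Every stage writes its
#' artifacts under `cfg$out_dir` and contributes one entry (counts,
#' parameters, seeds, wall time) to `report.json`. Rerunning with an identical
#' configuration reproduces all non-timing outputs byte-identically.
#'
#' @param cfg a [run_config()].
#' @return invisibly, the report as a list.
#' @export
run_pipeline <- function(cfg) {
  assert_that(inherits(cfg, "run_config"), "cfg must be a run_config")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list()
  state <- new.env(parent = emptyenv())

  timed_stage <- function(name, fun) {
    if (!(name %in% cfg$stages)) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    entry <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    entry$wall_time_s <- round(proc.time()[["elapsed"]] - t0, 3)
    report[[name]] <<- entry
  }

  timed_stage("generate", function() {
    lib <- generate_library(cfg$library_config)
    state$library <- lib
    write_library(lib, file.path(cfg$out_dir, "library"))
    list(n_molecules = nrow(lib$molecules),
         n_families = length(unique(lib$molecules$family)),
         seed = cfg$library_config$seed)
  })

  timed_stage("standardize", function() {
    input <- pipeline_structures(cfg, state)
    recs <- standardize_molecules(input$id, input$smiles)
    state$records <- recs
    utils::write.csv(recs, file.path(cfg$out_dir, "registry.csv"),
                     row.names = FALSE)
    list(n_molecules = nrow(recs),
         n_fully_defined = sum(recs$stereo_status == "fully_defined"),
         n_partially_defined = sum(recs$stereo_status == "partially_defined"),
         n_achiral = sum(recs$stereo_status == "achiral"))
  })

  timed_stage("group", function() {
    recs <- pipeline_records(cfg, state)
    res <- identify_stereoisomer_groups(recs)
    state$groups <- res$groups
    utils::write.table(res$groups, file.path(cfg$out_dir, "groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$excluded, file.path(cfg$out_dir, "exclusions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    hist <- group_size_histogram(res$groups)
    list(n_groups = length(unique(res$groups$group_id)),
         n_compounds_in_groups = nrow(res$groups),
         n_excluded = nrow(res$excluded),
         size_histogram = as.list(hist))
  })

  timed_stage("profiles", function() {
    recs <- pipeline_records(cfg, state)
    groups <- pipeline_groups(cfg, state)
    profiles <- pipeline_profiles(cfg, state)
    breakdown <- distinct_profile_breakdown(groups, profiles)
    pairs <- pair_category_distances(recs, groups, profiles,
                                     n_random_pairs = cfg$n_random_pairs,
                                     seed = cfg$seed)
    utils::write.table(pairs, file.path(cfg$out_dir, "pair_distances.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary <- profile_summary(pairs)
    cnt <- summarize_counts(groups, profiles)
    jsonlite::write_json(
      list(breakdown = breakdown, categories = summary, counts = cnt),
      file.path(cfg$out_dir, "profile_summary.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
    state$profile_counts <- cnt
    c(cnt, list(categories = summary))
  })

  timed_stage("conformers", function() {
    recs <- pipeline_records(cfg, state)
    eligible <- recs[recs$stereo_status != "partially_defined", , drop = FALSE]
    confs <- generate_conformers(eligible, embed_seed = cfg$embed_seed)
    state$conformers <- confs
    write_conformers(confs,
                     sdf_path = file.path(cfg$out_dir, "conformers.sdf"),
                     csv_path = file.path(cfg$out_dir, "conformers.csv"))
    list(n_conformers = length(confs),
         n_optimized = sum(vapply(confs, `[[`, TRUE, "optimized")),
         embed_seed = cfg$embed_seed)
  })

  timed_stage("descriptors", function() {
    recs <- pipeline_records(cfg, state)
    eligible <- recs[recs$stereo_status != "partially_defined", , drop = FALSE]
    fp <- fingerprint_2d(eligible)
    state$fp2d <- fp
    utils::write.csv(data.frame(compound_id = rownames(fp), fp,
                                check.names = FALSE),
                     file.path(cfg$out_dir, "fp2d.csv"), row.names = FALSE)
    confs <- state$conformers
    assert_that(!is.null(confs),
                "descriptors stage requires the conformers stage")
    geo <- descriptor_3d_matrix(confs)
    state$geo3d <- geo
    utils::write.csv(data.frame(compound_id = rownames(geo),
                                format(geo, digits = 17, trim = TRUE),
                                check.names = FALSE),
                     file.path(cfg$out_dir, "geo3d.csv"), row.names = FALSE)
    list(n_fp2d = nrow(fp), n_geo3d = nrow(geo),
         fp_bits = ncol(fp), geo_length = ncol(geo))
  })

  timed_stage("benchmark", function() {
    lib <- state$library
    assert_that(!is.null(lib),
                "benchmark stage requires signatures from the generate stage")
    groups <- pipeline_groups(cfg, state)
    grouped_ids <- intersect(rownames(state$geo3d), groups$member_id)
    sig <- lib$signatures
    common <- intersect(rownames(sig), rownames(state$geo3d))
    ref <- pairwise_cosine(sig[common, , drop = FALSE])
    cands <- list(fp2d = pairwise_cosine(state$fp2d[common, , drop = FALSE]),
                  geo3d = pairwise_cosine(state$geo3d[common, , drop = FALSE]))

    cfg_r <- cfg$eval_random %||%
      eval_config(nn_percentile = 0.1, negative_mode = "random",
                  n_subsample = min(length(common), 2500),
                  seed = cfg$seed)
    cfg_s <- cfg$eval_stringent %||%
      eval_config(nn_percentile = 0.1, negative_mode = "stringent",
                  n_subsample = min(length(common), 2500),
                  seed = cfg$seed)
    res_r <- run_knn_benchmark(ref, cands, cfg_r)
    res_s <- run_knn_benchmark(ref, cands, cfg_s)

    stereo_pairs <- lib$truth[lib$truth$id_a %in% grouped_ids &
                                lib$truth$id_b %in% grouped_ids, , drop = FALSE]
    ident_fp <- identical_signature_fraction(stereo_pairs, state$fp2d)
    ident_geo <- identical_signature_fraction(stereo_pairs, state$geo3d)

    strip <- function(res) {
      lapply(res, function(x) {
        list(mean_auroc = x$mean_auroc,
             per_repetition_auroc = x$per_repetition_auroc,
             n_positive_pairs = x$n_positive_pairs,
             n_negative_pairs = x$n_negative_pairs,
             cutoff_distance = x$cutoff_distance)
      })
    }
    out <- list(random = strip(res_r), stringent = strip(res_s),
                fp2d_identical_fraction = ident_fp,
                geo3d_identical_fraction = ident_geo,
                n_compounds = length(common),
                n_stereoisomer_pairs = nrow(stereo_pairs))
    jsonlite::write_json(out, file.path(cfg$out_dir, "benchmark.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    out
  })

  report$config <- list(stages = cfg$stages, seed = cfg$seed,
                        embed_seed = cfg$embed_seed,
                        library_config = unclass(cfg$library_config))
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(report)
}

# --- stage input resolution ------------------------------------------------

pipeline_structures <- function(cfg, state) {
  if (!is.null(state$library)) {
    return(state$library$molecules[, c("id", "smiles")])
  }
  if (!is.null(cfg$smi_path)) {
    return(read_smi(cfg$smi_path))
  }
  lib_dir <- file.path(cfg$out_dir, "library")
  if (file.exists(file.path(lib_dir, "manifest.json"))) {
    lib <- read_library(lib_dir)
    state$library <- lib
    return(lib$molecules[, c("id", "smiles")])
  }
  stop("no structures available: run the generate stage or supply smi_path",
       call. = FALSE)
}

pipeline_records <- function(cfg, state) {
  if (!is.null(state$records)) return(state$records)
  reg <- file.path(cfg$out_dir, "registry.csv")
  if (file.exists(reg)) {
    recs <- utils::read.csv(reg, stringsAsFactors = FALSE,
                            colClasses = c(id = "character"))
    state$records <- recs
    return(recs)
  }
  stop("no standardized records available: run the standardize stage",
       call. = FALSE)
}

pipeline_groups <- function(cfg, state) {
  if (!is.null(state$groups)) return(state$groups)
  path <- file.path(cfg$out_dir, "groups.tsv")
  if (file.exists(path)) {
    g <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "", colClasses = "character")
    state$groups <- g
    return(g)
  }
  stop("no stereoisomer groups available: run the group stage", call. = FALSE)
}

pipeline_profiles <- function(cfg, state) {
  if (!is.null(state$library)) return(state$library$profiles)
  if (!is.null(cfg$profiles_path)) return(read_profiles(cfg$profiles_path))
  path <- file.path(cfg$out_dir, "library", "profiles.tsv")
  if (file.exists(path)) return(read_profiles(path))
  stop("no binding profiles available: run the generate stage or supply ",
       "profiles_path", call. = FALSE)
}

# Per-category summary of a pair-distance table.
profile_summary <- function(pairs) {
  cats <- split(pairs$jaccard, pairs$category)
  summ <- lapply(cats, function(d) {
    list(n = length(d), mean = mean(d), median = stats::median(d))
  })
  combs <- utils::combn(names(cats), 2, simplify = FALSE)
  tests <- lapply(combs, function(cc) {
    mw <- compare_distributions(cats[[cc[1]]], cats[[cc[2]]])
    list(x = cc[1], y = cc[2], U = mw$U, p_value = mw$p_value)
  })
  list(per_category = summ, mann_whitney = tests)
}

#' Headline counts and percentages for a grouped, profiled library
#'
#' Computes the summary quantities of the grouping/profile analysis:
#' compounds in groups, group count, groups with at least two distinct
#' ternary profiles, stereoisomer pair counts, the percentage of pairs with
#' distinct profiles (1 decimal), and the percentage of size-2 groups
#' (nearest integer). With zero groups all percentages are `NA` (reported as
#' null in JSON), never 0.
#'
#' @param groups the `groups` data.frame from
#'   [identify_stereoisomer_groups()].
#' @param profiles integer matrix (compound x target).
#' @return list of counts and percentages.
#' @export
summarize_counts <- function(groups, profiles) {
  members <- group_members(groups)
  n_groups <- length(members)
  if (n_groups == 0) {
    return(list(n_compounds_in_groups = 0L, n_groups = 0L,
                n_groups_distinct_profiles = 0L, n_stereoisomer_pairs = 0L,
                n_pairs_distinct = 0L, pct_pairs_distinct = NA_real_,
                pct_groups_size2 = NA_real_))
  }
  sizes <- vapply(members, length, integer(1))
  ndis <- vapply(members, count_distinct_profiles, integer(1),
                 profiles = profiles)
  pair_counts <- vapply(members, function(mem) {
    prs <- index_pairs(length(mem))
    if (nrow(prs) == 0) return(c(0L, 0L))
    differs <- vapply(seq_len(nrow(prs)), function(r) {
      any(profiles[mem[prs[r, 1]], ] != profiles[mem[prs[r, 2]], ])
    }, logical(1))
    c(length(differs), sum(differs))
  }, integer(2))
  n_pairs <- sum(pair_counts[1, ])
  n_pairs_distinct <- sum(pair_counts[2, ])
  list(
    n_compounds_in_groups = sum(sizes),
    n_groups = n_groups,
    n_groups_distinct_profiles = sum(ndis >= 2),
    n_stereoisomer_pairs = n_pairs,
    n_pairs_distinct = n_pairs_distinct,
    pct_pairs_distinct = round(100 * n_pairs_distinct / n_pairs, 1),
    pct_groups_size2 = round(100 * sum(sizes == 2) / n_groups)
  )
}

#' Percentage helpers used in reports
#'
#' `pct_pairs_distinct()` rounds to 1 decimal (pair percentages);
#' `pct_groups_of_size()` rounds to the nearest integer (group-share
#' percentages). Both return `NA` for a zero denominator.
#'
#' @param n_distinct,n_pairs,n_size,n_groups integer counts.
#' @return numeric percentage.
#' @export
pct_pairs_distinct <- function(n_distinct, n_pairs) {
  if (n_pairs == 0) return(NA_real_)
  round(100 * n_distinct / n_pairs, 1)
}

#' @rdname pct_pairs_distinct
#' @export
pct_groups_of_size <- function(n_size, n_groups) {
  if (n_groups == 0) return(NA_real_)
  round(100 * n_size / n_groups)
}
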