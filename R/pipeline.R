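#' Build and validate a pipeline configuration
#'
#' A configuration gathers input paths, the feature registry, analysis
#' thresholds, and the master seed for a [run_pipeline()] call. It can be
#' given as an R list or as a YAML file with the same field names.
#'
#' Fields: `mirna`, `mrna`, `annotation`, `pairs` (input TSV paths; all
#' optional when the `simulate` stage runs first), `edges` and `terms`
#' (optional TSV paths for the network and enrichment stages), `features`
#' (character vector; default: every feature present in the annotation),
#' `alpha` (default 0.05), `fold` (default 2), `n_perm` (default 200),
#' `p_threshold` (default 1e-3), `seed` (default 1), and `simulate` (a
#' list with `n` samples per stratum for the bundled demo design, see
#' [demo_dataset_spec()]).
#'
#' @param config A named list, or the path of a YAML file.
#' @param registry Feature registry (default
#'   [default_feature_registry()]).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = list(), registry = default_feature_registry()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (inherits(config, "pipeline_config")) return(config)
  defaults <- list(alpha = 0.05, fold = 2.0, n_perm = 200L,
                   p_threshold = 1e-3, seed = 1L)
  cfg <- utils::modifyList(defaults, config)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) {
    abort("`alpha` must lie in (0, 1).", class = "mmpv_error_config")
  }
  if (cfg$fold <= 1) abort("`fold` must be > 1.", class = "mmpv_error_config")
  if (cfg$n_perm < 1) abort("`n_perm` must be >= 1.", class = "mmpv_error_config")
  if (cfg$p_threshold <= 0 || cfg$p_threshold > 1) {
    abort("`p_threshold` must lie in (0, 1].", class = "mmpv_error_config")
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$registry <- registry
  structure(cfg, class = "pipeline_config")
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

stage_artifact <- function(out_dir, name) file.path(out_dir, name)

require_artifact <- function(path, needed_by, produced_by) {
  if (!file.exists(path)) {
    abort(sprintf("Stage '%s' needs '%s'; run stage '%s' first.",
                  needed_by, basename(path), produced_by),
          class = "mmpv_error_dependency")
  }
  path
}

#' Run the MMPV pipeline
#'
#' Orchestrates the analysis as named stages sharing one configuration and
#' one output directory: `simulate` (write a demo dataset),
#' `detect` (MMPV detection per feature), `de` (SAM permutation
#' differential expression and DE-MMPV selection), `overlap`
#' (cross-feature counts), `enrich` (hypergeometric term enrichment of
#' each feature's MMPV mRNAs against the pair-list background), and
#' `network` (PPI degree report). Each stage writes TSV/JSON artifacts; a
#' `manifest.json` records the configuration echo, the seed, row counts,
#' and an md5 hash per output file. Identical configuration and seed give
#' byte-identical numeric outputs.
#'
#' Stages read their inputs from earlier stages' artifacts in `out_dir`
#' when those stages are not part of the same call; a missing dependency
#' raises an error naming the stage to run first.
#'
#' @param config A [pipeline_config()] (list, YAML path, or validated
#'   object).
#' @param stages Character subset of
#'   `c("simulate", "detect", "de", "overlap", "enrich", "network")`, run
#'   in that order.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, stages, out_dir) {
  cfg <- pipeline_config(config)
  all_stages <- c("simulate", "detect", "de", "overlap", "enrich", "network")
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0L) {
    abort(sprintf("Unknown stage '%s'.", bad[1L]), class = "mmpv_error_config")
  }
  stages <- all_stages[all_stages %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  counts <- list()

  if ("simulate" %in% stages) {
    pipeline_log("simulate", "seed %d", cfg$seed)
    n <- (cfg$simulate %||% list())$n %||% 50L
    sim <- simulate_dataset(demo_dataset_spec(seed = cfg$seed, n = n))
    write_expression_matrix(sim$mirna, stage_artifact(out_dir, "mirna.tsv"))
    write_expression_matrix(sim$mrna, stage_artifact(out_dir, "mrna.tsv"))
    readr::write_tsv(sim$annotation, stage_artifact(out_dir, "annotation.tsv"),
                     progress = FALSE)
    readr::write_tsv(sim$pairs, stage_artifact(out_dir, "pairs.tsv"),
                     progress = FALSE)
    write_truth_table(sim$truth, stage_artifact(out_dir, "truth.tsv"))
    outputs <- c(outputs, file.path(out_dir, c("mirna.tsv", "mrna.tsv",
                                               "annotation.tsv", "pairs.tsv",
                                               "truth.tsv")))
    cfg$mirna <- stage_artifact(out_dir, "mirna.tsv")
    cfg$mrna <- stage_artifact(out_dir, "mrna.tsv")
    cfg$annotation <- stage_artifact(out_dir, "annotation.tsv")
    cfg$pairs <- stage_artifact(out_dir, "pairs.tsv")
  }

  load_inputs <- function(stage) {
    for (f in c("mirna", "mrna", "annotation", "pairs")) {
      if (is.null(cfg[[f]])) {
        cfg[[f]] <<- require_artifact(stage_artifact(out_dir, paste0(f, ".tsv")),
                                      stage, "simulate")
      }
    }
    list(mirna = read_expression_matrix(cfg$mirna),
         mrna = read_expression_matrix(cfg$mrna),
         annotation = read_sample_annotations(cfg$annotation, cfg$registry),
         pairs = read_pair_list(cfg$pairs))
  }

  features_of <- function(annotation) {
    cfg$features %||% intersect(cfg$registry$feature, unique(annotation$feature))
  }

  mmpv_path <- function(feat) stage_artifact(out_dir, sprintf("mmpv_%s.tsv", feat))

  read_mmpv_artifact <- function(feat, stage) {
    readr::read_tsv(require_artifact(mmpv_path(feat), stage, "detect"),
                    col_types = readr::cols(
                      mirna_id = readr::col_character(),
                      mrna_id = readr::col_character(),
                      healthy_sign = readr::col_character(),
                      mmpv_class = readr::col_character(),
                      pattern = readr::col_character(),
                      feature = readr::col_character(),
                      .default = readr::col_double()),
                    progress = FALSE)
  }

  if ("detect" %in% stages) {
    inp <- load_inputs("detect")
    feats <- features_of(inp$annotation)
    summary <- list()
    for (feat in feats) {
      res <- detect_mmpvs(inp$pairs, inp$mirna, inp$mrna, inp$annotation, feat,
                          registry = cfg$registry, alpha = cfg$alpha,
                          fold = cfg$fold)
      readr::write_tsv(res$mmpvs, mmpv_path(feat), progress = FALSE)
      outputs <- c(outputs, mmpv_path(feat))
      summary[[feat]] <- c(as.list(glance(res))[c("n_fold_change",
                                                  "n_sign_change", "n_total")],
                           list(dropped = as.list(res$dropped)))
      pipeline_log("detect", "%s: %d MMPVs (%d sign, %d fold)", feat,
                   res$counts$n_total, res$counts$n_sign_change,
                   res$counts$n_fold_change)
      counts[[paste0("mmpv_", feat)]] <- res$counts$n_total
    }
    sj <- stage_artifact(out_dir, "mmpv_summary.json")
    jsonlite::write_json(summary, sj, auto_unbox = TRUE, pretty = TRUE)
    outputs <- c(outputs, sj)
  }

  if ("de" %in% stages) {
    inp <- load_inputs("de")
    feats <- features_of(inp$annotation)
    for (feat in feats) {
      mmpvs <- read_mmpv_artifact(feat, "de")
      mt <- differential_table(inp$mirna, inp$annotation, feat,
                               registry = cfg$registry, n_perm = cfg$n_perm,
                               alpha = cfg$alpha,
                               seed = substream_seed(cfg$seed, 101L))
      gt <- differential_table(inp$mrna, inp$annotation, feat,
                               registry = cfg$registry, n_perm = cfg$n_perm,
                               alpha = cfg$alpha,
                               seed = substream_seed(cfg$seed, 102L))
      de <- select_de_mmpvs(mmpvs, mt, gt, alpha = cfg$alpha)
      paths <- stage_artifact(out_dir, sprintf(c("de_mirna_%s.tsv",
                                                 "de_mrna_%s.tsv",
                                                 "de_mmpv_%s.tsv"), feat))
      readr::write_tsv(mt, paths[1L], progress = FALSE)
      readr::write_tsv(gt, paths[2L], progress = FALSE)
      readr::write_tsv(de, paths[3L], progress = FALSE)
      outputs <- c(outputs, paths)
      pipeline_log("de", "%s: %d DE-MMPVs", feat, nrow(de))
      counts[[paste0("de_mmpv_", feat)]] <- nrow(de)
    }
  }

  if ("overlap" %in% stages) {
    inp <- load_inputs("overlap")
    feats <- features_of(inp$annotation)
    sets <- purrr::map(rlang::set_names(feats), read_mmpv_artifact, stage = "overlap")
    ov <- tidy(overlap_counts(sets))
    readr::write_tsv(ov, stage_artifact(out_dir, "overlap.tsv"), progress = FALSE)
    outputs <- c(outputs, stage_artifact(out_dir, "overlap.tsv"))
    pipeline_log("overlap", "%d feature pairs", nrow(ov))
  }

  if ("enrich" %in% stages) {
    if (is.null(cfg$terms)) {
      abort("Stage 'enrich' needs `terms` (a term-map TSV) in the config.",
            class = "mmpv_error_dependency")
    }
    inp <- load_inputs("enrich")
    term_map <- read_term_map(cfg$terms)
    background <- unique(inp$pairs$mrna_id)
    feats <- features_of(inp$annotation)
    for (feat in feats) {
      mmpvs <- read_mmpv_artifact(feat, "enrich")
      target <- intersect(unique(mmpvs$mrna_id), background)
      enr <- enrich_terms(target, background, term_map,
                          p_threshold = cfg$p_threshold)
      path <- stage_artifact(out_dir, sprintf("enrichment_%s.tsv", feat))
      readr::write_tsv(enr, path, progress = FALSE)
      outputs <- c(outputs, path)
      pipeline_log("enrich", "%s: %d enriched terms", feat, nrow(enr))
    }
  }

  if ("network" %in% stages) {
    if (is.null(cfg$edges)) {
      abort("Stage 'network' needs `edges` (a PPI edge-list TSV) in the config.",
            class = "mmpv_error_dependency")
    }
    inp <- load_inputs("network")
    graph <- read_edge_list(cfg$edges)
    feats <- features_of(inp$annotation)
    sets <- purrr::map(rlang::set_names(feats), read_mmpv_artifact, stage = "network")
    rep <- degree_report(sets, graph)
    readr::write_tsv(rep, stage_artifact(out_dir, "degree_report.tsv"),
                     progress = FALSE)
    outputs <- c(outputs, stage_artifact(out_dir, "degree_report.tsv"))
    pipeline_log("network", "%d features tested", nrow(rep))
  }

  outputs <- unique(outputs)
  manifest <- list(
    package = "mmpv",
    version = as.character(utils::packageVersion("mmpv")),
    seed = cfg$seed,
    stages = stages,
    config = unclass(cfg)[setdiff(names(cfg), "registry")],
    counts = counts,
    files = purrr::map(rlang::set_names(basename(outputs), basename(outputs)),
                       function(f) {
                         list(md5 = unname(tools::md5sum(file.path(out_dir, f))),
                              rows = length(readr::read_lines(file.path(out_dir, f),
                                                              progress = FALSE)) - 1L)
                       }))
  jsonlite::write_json(manifest, stage_artifact(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
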