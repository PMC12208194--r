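#' Run the full score -> classify -> contrast pipeline
#'
#' Executes the whole analysis in order and writes every intermediate
#' artifact plus a run manifest to `out_dir`: pathway collection, fly and
#' query expression and score matrices, the per-sample similarity
#' classification with a one-line summary, the clinical contrasts (age,
#' log2 mutation load, mean methylation beta), the mutation-event
#' enrichment landscape and the two-group log-rank test. Deterministic
#' given the seed: re-running the same configuration reproduces
#' byte-identical data files.
#'
#' The configuration is a flat list (or a YAML file holding one) with
#' either a `simulation` block of [simulation_config()] arguments or an
#' `inputs` block with paths `fly_expr`, `query_expr`, `pathways` (plus
#' optionally `cohort`); optional `score` (`alpha`, `tie_rule`,
#' `normalize`), `classify` (`threshold`, `adjust`, `require_positive`,
#' `reference_samples`, `reference_aggregate`) and `contrast`
#' (`alpha_highlight`, `min_recurrence`) blocks override the defaults. A
#' top-level `seed` is required when simulating.
#'
#' @param config A list, or path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the classification (`similarity`), the
#'   contrast tables, the manifest and the paths of everything written.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("`config` must be a list or a YAML path",
                             call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  score_cfg <- utils::modifyList(
    list(alpha = 0.25, tie_rule = "average", normalize = FALSE),
    config$score %||% list())
  cls_cfg <- utils::modifyList(
    list(threshold = 1e-6, adjust = "BH", require_positive = TRUE,
         reference_samples = NULL, reference_aggregate = "mean"),
    config$classify %||% list())
  con_cfg <- utils::modifyList(
    list(alpha_highlight = 1e-3, min_recurrence = 2L),
    config$contrast %||% list())

  # stage: inputs (simulate or load)
  if (!is.null(config$simulation)) {
    sim_args <- config$simulation
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    if (is.null(sim_args$seed))
      stop("config missing key `seed` (required for simulation)",
           call. = FALSE)
    sim <- simulate_cohort(do.call(simulation_config, sim_args))
    fly_expr <- sim$fly_expr; query_expr <- sim$query_expr
    pathways <- sim$pathways; cohort <- sim$cohort
    paths$truth <- file.path(out_dir, "truth.tsv")
    write_truth_tsv(sim$truth, paths$truth)
    paths$fly_expr <- file.path(out_dir, "fly_expr.tsv")
    paths$query_expr <- file.path(out_dir, "query_expr.tsv")
    write_expression_tsv(fly_expr, paths$fly_expr)
    write_expression_tsv(query_expr, paths$query_expr)
    paths$pathways <- file.path(out_dir, "pathways.tsv")
    write_pathway_collection(pathways, paths$pathways)
    paths$cohort <- file.path(out_dir, "cohort.tsv")
    write_cohort_tsv(cohort, paths$cohort)
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    for (key in c("fly_expr", "query_expr", "pathways"))
      if (is.null(inp[[key]]))
        stop("config missing key `inputs$", key, "`", call. = FALSE)
    fly_expr <- read_expression_tsv(inp$fly_expr, species = "fly")
    query_expr <- read_expression_tsv(inp$query_expr, species = "human")
    pathways <- read_pathway_collection(inp$pathways)
    cohort <- if (!is.null(inp$cohort)) read_cohort_tsv(inp$cohort)
  } else {
    stop("config missing key `simulation` or `inputs`", call. = FALSE)
  }

  # stage: score
  fly_scores <- score_matrix(
    fly_expr, restrict_to_measured(pathways, fly_expr),
    alpha = score_cfg$alpha, tie_rule = score_cfg$tie_rule,
    normalize = score_cfg$normalize)
  query_scores <- score_matrix(
    query_expr, restrict_to_measured(pathways, query_expr),
    alpha = score_cfg$alpha, tie_rule = score_cfg$tie_rule,
    normalize = score_cfg$normalize)
  paths$fly_scores <- file.path(out_dir, "fly_scores.tsv")
  paths$query_scores <- file.path(out_dir, "query_scores.tsv")
  write_scores_tsv(fly_scores, paths$fly_scores)
  write_scores_tsv(query_scores, paths$query_scores)

  # stage: classify
  reference <- build_reference(fly_scores,
                               samples = cls_cfg$reference_samples,
                               aggregate = cls_cfg$reference_aggregate)
  similarity <- classify_cohort(query_scores, reference,
                                threshold = cls_cfg$threshold,
                                adjust = cls_cfg$adjust,
                                require_positive = cls_cfg$require_positive)
  paths$similarity <- file.path(out_dir, "classification.tsv")
  write_similarity_tsv(similarity, paths$similarity)
  summ <- glance(similarity)
  paths$summary <- file.path(out_dir, "classification_summary.txt")
  writeLines(sprintf("n_similar\t%d\tn_total\t%d", summ$n_similar,
                     summ$n_total),
             con = paths$summary)

  # stage: contrasts (only with a cohort table in hand)
  contrasts <- NULL; landscape <- NULL; logrank <- NULL
  if (!is.null(cohort)) {
    contrasts <- dplyr::bind_rows(
      group_contrast(cohort, similarity, "age"),
      suppressWarnings(
        group_contrast(cohort, similarity, "mutation_count",
                       transform = "log2")),
      group_contrast(cohort, similarity, "mean_beta"))
    paths$contrasts <- file.path(out_dir, "contrasts.tsv")
    write_contrasts_tsv(contrasts, paths$contrasts)
    landscape <- mutation_landscape(cohort, similarity,
                                    alpha_highlight = con_cfg$alpha_highlight,
                                    min_recurrence = con_cfg$min_recurrence)
    paths$landscape <- file.path(out_dir, "mutation_landscape.tsv")
    write_landscape_tsv(landscape, paths$landscape)
    if (all(c("survival_time", "event") %in% names(cohort)) &&
        sum(cohort$event, na.rm = TRUE) > 0) {
      joined <- dplyr::inner_join(tibble::as_tibble(cohort),
                                  tibble::as_tibble(similarity),
                                  by = "sample_id")
      logrank <- logrank_test(joined$survival_time, joined$event,
                              joined$label)
    }
  }

  manifest <- list(
    command = "run_pipeline",
    parameters = list(score = score_cfg, classify = cls_cfg,
                      contrast = con_cfg,
                      simulation = config$simulation),
    seed = config$seed %||% config$simulation$seed,
    tool_version = as.character(utils::packageVersion("crossmetsig")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input_checksums = as.list(tools::md5sum(unlist(paths))))
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")

  invisible(list(similarity = similarity, contrasts = contrasts,
                 landscape = landscape, logrank = logrank,
                 manifest = manifest, paths = paths))
}

write_truth_tsv <- function(truth, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("sample_id\tsimilar",
               sprintf("%s\t%s", truth$sample_id,
                       ifelse(truth$similar, "TRUE", "FALSE"))),
             con, sep = "\n")
  invisible(path)
}

write_contrasts_tsv <- function(contrasts, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(contrasts), collapse = "\t"),
               sprintf("%s\t%s\t%.15g\t%.15g\t%d\t%d\t%.15g\t%.6e",
                       contrasts$variable, contrasts$transform,
                       contrasts$mean_similar, contrasts$mean_other,
                       contrasts$n_similar, contrasts$n_other,
                       contrasts$t, contrasts$p)), con, sep = "\n")
  invisible(path)
}

write_landscape_tsv <- function(landscape, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- paste(names(landscape), collapse = "\t")
  if (nrow(landscape))
    lines <- c(lines,
               sprintf("%s\t%d\t%d\t%d\t%d\t%.15g\t%.6e\t%s\t%s",
                       landscape$gene, landscape$a, landscape$b,
                       landscape$c, landscape$d, landscape$odds_ratio,
                       landscape$p,
                       ifelse(is.na(landscape$direction), "NA",
                              landscape$direction),
                       ifelse(landscape$highlight, "TRUE", "FALSE")))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
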