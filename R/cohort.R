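#' Per-sample clinical and mutation annotation table
#'
#' Validates a per-sample cohort table: unique sample ids, methylation beta
#' in `[0, 1]`, non-negative survival times and mutation counts. Missing
#' fields stay `NA` — nothing is imputed. `mutation_events` is a list-column
#' of gene-symbol character vectors.
#'
#' @param x A data frame with a `sample_id` column and any of `age`,
#'   `mutation_count`, `mean_beta`, `mutation_events`, `survival_time`,
#'   `event`, `cancer_type`.
#' @return A validated tibble of class `cohort_tbl`.
#' @export
cohort_table <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"sample_id" %in% names(x))
    stop("cohort table needs a sample_id column", call. = FALSE)
  if (anyDuplicated(x$sample_id))
    stop("duplicate sample_id(s): ",
         paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", "),
         call. = FALSE)
  if ("mean_beta" %in% names(x)) {
    bad <- stats::na.omit(x$mean_beta)
    if (any(bad < 0 | bad > 1))
      stop("mean_beta must lie in [0, 1]", call. = FALSE)
  }
  if ("survival_time" %in% names(x) &&
      any(stats::na.omit(x$survival_time) < 0))
    stop("survival_time must be >= 0", call. = FALSE)
  if ("mutation_count" %in% names(x) &&
      any(stats::na.omit(x$mutation_count) < 0))
    stop("mutation_count must be >= 0", call. = FALSE)
  if ("mutation_events" %in% names(x) && !is.list(x$mutation_events))
    x$mutation_events <- strsplit(
      ifelse(is.na(x$mutation_events), "", x$mutation_events), ";",
      fixed = TRUE)
  structure(x, class = c("cohort_tbl", class(x)))
}

#' Read / write a cohort table as TSV
#'
#' One row per sample; `mutation_events` serialized as a semicolon-joined
#' gene list (a deliberate simplification of MAF), `NA` for missing.
#'
#' @param path File path.
#' @return A `cohort_tbl` (read) or `path` invisibly (write).
#' @export
read_cohort_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  cohort_table(df)
}

#' @rdname read_cohort_tsv
#' @param cohort A `cohort_tbl`.
#' @export
write_cohort_tsv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_tbl"))
  out <- tibble::as_tibble(cohort)
  if ("mutation_events" %in% names(out))
    out$mutation_events <- vapply(out$mutation_events, paste,
                                  character(1), collapse = ";")
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(out), collapse = "\t"),
             do.call(paste, c(lapply(out, function(col) {
               if (is.numeric(col)) ifelse(is.na(col), "NA",
                                           sprintf("%.15g", col))
               else ifelse(is.na(col), "NA", as.character(col))
             }), sep = "\t")))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact P for the 2x2 contingency table
#' `(a, b; c, d)` — conventionally mutated/similar, mutated/non-similar,
#' wild-type/similar, wild-type/non-similar — by the minimum-likelihood
#' convention (sum of hypergeometric probabilities of all tables with the
#' margins fixed and probability at most the observed one). The odds ratio
#' is reported as the cross-product `ad/bc` (`Inf` when `bc = 0` and
#' `a*d > 0`). A zero margin means no association is testable: `p = 1` and
#' `odds_ratio = NA` with `undefined_or = TRUE`.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return A list: `odds_ratio`, `p`, `undefined_or`.
#' @examples
#' fisher_exact(5, 5, 5, 5)    # OR 1, p 1
#' fisher_exact(10, 0, 0, 10)  # p = 2 / choose(20, 10)
#' @export
fisher_exact <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("cell counts must be non-negative integers", call. = FALSE)
  if (sum(counts) == 0)
    stop("degenerate table: all cells zero", call. = FALSE)
  if ((a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0))
    return(list(odds_ratio = NA_real_, p = 1, undefined_or = TRUE))
  tab <- matrix(c(a, c, b, d), nrow = 2)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  or <- if (b * c == 0) Inf else (a * d) / (b * c)
  list(odds_ratio = or, p = min(p, 1), undefined_or = FALSE)
}

#' Mutation-event enrichment screen between similarity groups
#'
#' For every gene mutated in at least `min_recurrence` samples, builds the
#' 2x2 table of mutation status against the similar / non-similar label and
#' applies [fisher_exact()]. Direction is read off the `ad/bc` odds ratio:
#' above 1 the event is enriched in the similar group, otherwise depleted.
#' Genes with `p < alpha_highlight` are flagged.
#'
#' @param cohort A `cohort_tbl` with a `mutation_events` list-column.
#' @param labels A `similarity_tbl` from [classify_cohort()], or any data
#'   frame with `sample_id` and `label` columns.
#' @param alpha_highlight Highlight threshold on the Fisher P; default
#'   `1e-3`.
#' @param min_recurrence Minimum number of mutated samples for a gene to be
#'   tested (default 2; singletons cannot approach the highlight threshold
#'   and only inflate the screen).
#' @return A tibble of class `mutation_landscape_tbl`: `gene`, cell counts
#'   `a`, `b`, `c`, `d`, `odds_ratio`, `p`, `direction`, `highlight`,
#'   sorted by `p`.
#' @export
mutation_landscape <- function(cohort, labels, alpha_highlight = 1e-3,
                               min_recurrence = 2L) {
  stopifnot(inherits(cohort, "cohort_tbl"))
  lab <- tibble::as_tibble(labels)[, c("sample_id", "label")]
  joined <- dplyr::inner_join(tibble::as_tibble(cohort), lab,
                              by = "sample_id")
  if (nrow(joined) == 0L)
    stop("no overlap between labelled samples and the cohort table",
         call. = FALSE)
  if (!"mutation_events" %in% names(joined))
    stop("cohort table has no mutation_events column", call. = FALSE)
  sim <- joined$label == "similar"
  n_sim <- sum(sim); n_other <- sum(!sim)
  ev <- joined$mutation_events
  genes <- sort(unique(unlist(ev)))
  genes <- genes[nzchar(genes)]
  if (length(genes)) {
    mut_n <- vapply(genes, function(g)
      sum(vapply(ev, function(e) g %in% e, TRUE)), 0L)
    genes <- genes[mut_n >= min_recurrence]
  }
  rows <- purrr::map(genes, function(g) {
    has <- vapply(ev, function(e) g %in% e, TRUE)
    a <- sum(has & sim); b <- sum(has & !sim)
    ft <- fisher_exact(a, b, n_sim - a, n_other - b)
    tibble::tibble(gene = g, a = a, b = b, c = n_sim - a, d = n_other - b,
                   odds_ratio = ft$odds_ratio, p = ft$p,
                   direction = if (isTRUE(ft$undefined_or)) NA_character_
                   else if (ft$odds_ratio > 1) "enriched_in_similar"
                   else "depleted_in_similar",
                   highlight = ft$p < alpha_highlight)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out <- dplyr::arrange(out, .data$p, .data$gene)
  structure(out, class = c("mutation_landscape_tbl", class(out)),
            alpha_highlight = alpha_highlight,
            min_recurrence = min_recurrence,
            n_similar = n_sim, n_other = n_other)
}

#' Plot a mutation-enrichment landscape
#'
#' -log10 Fisher P per gene, signed by direction (enriched in the similar
#' group up, depleted down); highlighted events in red/blue.
#'
#' @param object A `mutation_landscape_tbl`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mutation_landscape_tbl <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(!is.na(.data$direction)) |>
    dplyr::mutate(
      signed = ifelse(.data$direction == "enriched_in_similar", 1, -1) *
        -log10(pmax(.data$p, 1e-300)),
      class = dplyr::case_when(
        .data$highlight & .data$direction == "enriched_in_similar" ~
          "enriched",
        .data$highlight ~ "depleted",
        TRUE ~ "ns"))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$gene, -abs(.data$signed)),
                                   y = .data$signed, colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(enriched = "#c0392b",
                                            depleted = "#2b6cc0",
                                            ns = "grey65")) +
    ggplot2::labs(x = NULL, colour = NULL,
                  y = expression(signed ~ -log[10] ~ P),
                  title = "Mutation events by similarity group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Welch t-test contrast of a clinical variable between groups
#'
#' Compares a per-sample variable between the similar and non-similar
#' groups with an unpaired two-tailed Welch (unequal-variance) t-test,
#' optionally after a log2 transform. Missing values are dropped per group
#' with the retained counts reported; under `log2`, non-positive values are
#' excluded with a warning (no pseudo-count is applied unless given).
#'
#' @param cohort A `cohort_tbl`.
#' @param labels Data frame with `sample_id` and `label`.
#' @param var Name of the numeric cohort column to contrast.
#' @param transform `"identity"` or `"log2"`.
#' @param pseudocount Added before the log2 transform (default 0).
#' @param var_equal If `TRUE`, use the pooled-variance Student test instead
#'   of Welch.
#' @return One-row tibble: `variable`, `transform`, `mean_similar`,
#'   `mean_other`, `n_similar`, `n_other`, `t`, `p`.
#' @export
group_contrast <- function(cohort, labels, var,
                           transform = c("identity", "log2"),
                           pseudocount = 0, var_equal = FALSE) {
  transform <- match.arg(transform)
  stopifnot(inherits(cohort, "cohort_tbl"))
  if (!var %in% names(cohort))
    stop("cohort table has no column '", var, "'", call. = FALSE)
  lab <- tibble::as_tibble(labels)[, c("sample_id", "label")]
  joined <- dplyr::inner_join(tibble::as_tibble(cohort), lab,
                              by = "sample_id")
  vals <- joined[[var]]
  keep <- !is.na(vals)
  if (transform == "log2") {
    shifted <- vals + pseudocount
    pos <- keep & shifted > 0
    if (any(keep & !pos))
      warning(sum(keep & !pos), " non-positive value(s) excluded before ",
              "log2", call. = FALSE)
    keep <- pos
    vals <- log2(shifted)
  }
  g_sim <- vals[keep & joined$label == "similar"]
  g_oth <- vals[keep & joined$label == "non_similar"]
  if (length(g_sim) < 2L || length(g_oth) < 2L)
    stop("each group needs >= 2 non-missing values (have ",
         length(g_sim), " and ", length(g_oth), ")", call. = FALSE)
  tt <- stats::t.test(g_sim, g_oth, var.equal = var_equal)
  tibble::tibble(variable = var, transform = transform,
                 mean_similar = mean(g_sim), mean_other = mean(g_oth),
                 n_similar = length(g_sim), n_other = length(g_oth),
                 t = unname(tt$statistic), p = tt$p.value)
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank statistic (observed minus expected events
#' over the pooled risk sets), with P from the chi-square distribution with
#' 1 degree of freedom.
#'
#' @param time Non-negative survival/censoring times.
#' @param event Event indicator (1/TRUE = event, 0/FALSE = censored).
#' @param group Two-level grouping vector.
#' @return A list: `chi_square`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  if (any(time < 0)) stop("times must be >= 0", call. = FALSE)
  event <- as.integer(as.logical(event))
  if (sum(event) == 0L)
    stop("no events observed: log-rank statistic undefined", call. = FALSE)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stop("exactly two groups required", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chi <- unname(sd$chisq)
  list(chi_square = chi,
       p = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Convenience count of similarity labels per cancer type
#'
#' @param cohort A `cohort_tbl` with a `cancer_type` column.
#' @param labels Data frame with `sample_id` and `label`.
#' @return Tibble: `cancer_type`, `n_similar`, `n_total`, `frac_similar`.
#' @export
cancer_type_summary <- function(cohort, labels) {
  stopifnot(inherits(cohort, "cohort_tbl"))
  lab <- tibble::as_tibble(labels)[, c("sample_id", "label")]
  dplyr::inner_join(tibble::as_tibble(cohort), lab, by = "sample_id") |>
    dplyr::group_by(.data$cancer_type) |>
    dplyr::summarise(n_similar = sum(.data$label == "similar"),
                     n_total = dplyr::n(),
                     frac_similar = .data$n_similar / .data$n_total,
                     .groups = "drop")
}
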