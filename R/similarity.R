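#' Build the fly-tumor reference pathway signature
#'
#' Aggregates per-pathway enrichment scores over a set of fly tumor samples
#' into the reference vector that query samples are correlated against.
#' Which samples enter the reference and how they are aggregated is recorded
#' in the result's provenance.
#'
#' @param fly_scores An `enrichment_scores` matrix for the fly cohort.
#' @param samples Optional character vector restricting to a subset of fly
#'   samples (e.g. late-stage tumors); default uses all columns.
#' @param aggregate `"mean"` (default) or `"median"` across samples.
#' @return A `reference_signature`: pathway ids, one aggregate score per
#'   pathway, and provenance.
#' @export
build_reference <- function(fly_scores, samples = NULL,
                            aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(fly_scores, "enrichment_scores"))
  all_samples <- colnames(fly_scores$scores)
  if (is.null(samples)) samples <- all_samples
  if (length(samples) == 0L)
    stop("empty sample subset for the reference", call. = FALSE)
  missing <- setdiff(samples, all_samples)
  if (length(missing))
    stop("reference sample(s) not in the score matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  m <- fly_scores$scores[, samples, drop = FALSE]
  agg <- if (aggregate == "mean") rowMeans(m) else
    apply(m, 1L, stats::median)
  if (nrow(m) < 3L)
    stop("a reference needs >= 3 pathways (the correlation test needs ",
         "at least 1 degree of freedom)", call. = FALSE)
  structure(list(pathway_ids = rownames(m), scores = unname(agg),
                 provenance = list(samples = samples,
                                   aggregate = aggregate)),
            class = "reference_signature")
}

#' @export
print.reference_signature <- function(x, ...) {
  cat(sprintf("<reference_signature> %d pathways, %s of %d sample(s)\n",
              length(x$pathway_ids), x$provenance$aggregate,
              length(x$provenance$samples)))
  invisible(x)
}

#' Tidy a reference signature
#'
#' @param x A `reference_signature`.
#' @param ... Unused.
#' @return Tibble with columns `pathway_id`, `score`.
#' @export
tidy.reference_signature <- function(x, ...) {
  tibble::tibble(pathway_id = x$pathway_ids, score = x$scores)
}

#' Pearson correlation test of one sample against the reference
#'
#' Computes the sample Pearson correlation `r` over the K conserved
#' pathways and its two-sided P-value from the t transform
#' \eqn{t = r \sqrt{(K-2)/(1-r^2)}} with `K - 2` degrees of freedom. A
#' perfectly (anti-)correlated vector yields a P floored at the smallest
#' positive double rather than exactly 0.
#'
#' @param scores Numeric vector of the sample's pathway scores; if named,
#'   reordered to match the reference's pathway ids.
#' @param reference A `reference_signature`.
#' @return A list with elements `r` and `p_raw`.
#' @export
pearson_similarity <- function(scores, reference) {
  stopifnot(inherits(reference, "reference_signature"))
  if (!is.null(names(scores))) {
    if (!setequal(names(scores), reference$pathway_ids))
      stop("pathway set mismatch; symmetric difference: ",
           paste(c(setdiff(names(scores), reference$pathway_ids),
                   setdiff(reference$pathway_ids, names(scores))),
                 collapse = ", "), call. = FALSE)
    scores <- scores[reference$pathway_ids]
  }
  k <- length(reference$pathway_ids)
  if (length(scores) != k)
    stop("score vector length differs from the reference", call. = FALSE)
  if (k < 3L) stop("correlation test needs >= 3 pathways", call. = FALSE)
  if (stats::sd(scores) == 0 || stats::sd(reference$scores) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  r <- stats::cor(scores, reference$scores)
  denom <- max(1 - r^2, 0)
  tstat <- r * sqrt((k - 2) / denom)    # Inf when |r| = 1
  p <- 2 * stats::pt(abs(tstat), df = k - 2, lower.tail = FALSE)
  list(r = r, p_raw = max(p, .Machine$double.xmin))
}

#' Multiple-testing adjustment of raw P-values
#'
#' Standard step-up Benjamini-Hochberg (default) or Bonferroni adjustment;
#' output order matches input order and BH monotone capping is enforced.
#'
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @param method `"BH"` (alias `"benjamini_hochberg"`) or `"bonferroni"`.
#' @return Adjusted P-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "benjamini_hochberg",
                                         "bonferroni")) {
  method <- match.arg(method)
  if (method == "benjamini_hochberg") method <- "BH"
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("P-values must all lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = method)
}

#' Classify query samples as metabolically similar / non-similar
#'
#' For every query sample, correlates its conserved-pathway score vector
#' with the fly-tumor reference ([pearson_similarity()]), adjusts the raw
#' P-values across the cohort ([adjust_pvalues()]), and labels a sample
#' `similar` when its adjusted P falls below `threshold` *and* the
#' correlation is positive (an anti-correlated sample passing a two-sided
#' test is not metabolically similar; set `require_positive = FALSE` to
#' drop the sign rule).
#'
#' @param query_scores An `enrichment_scores` matrix for the query cohort;
#'   its pathway set must equal the reference's (rows are reordered
#'   internally by id).
#' @param reference A `reference_signature`.
#' @param threshold Adjusted-P cutoff; default `1e-6`.
#' @param adjust Multiple-testing method, see [adjust_pvalues()].
#' @param require_positive Require `r > 0` for the similar label.
#' @return A tibble of class `similarity_tbl` with columns `sample_id`,
#'   `r`, `p_raw`, `p_adj`, `label`; classification parameters are stored
#'   as attributes and summarized by [glance.similarity_tbl()].
#' @export
classify_cohort <- function(query_scores, reference, threshold = 1e-6,
                            adjust = "BH", require_positive = TRUE) {
  stopifnot(inherits(query_scores, "enrichment_scores"),
            inherits(reference, "reference_signature"))
  qids <- rownames(query_scores$scores)
  if (!setequal(qids, reference$pathway_ids))
    stop("pathway set mismatch between query and reference; symmetric ",
         "difference: ",
         paste(c(setdiff(qids, reference$pathway_ids),
                 setdiff(reference$pathway_ids, qids)), collapse = ", "),
         call. = FALSE)
  m <- query_scores$scores[reference$pathway_ids, , drop = FALSE]
  res <- purrr::map(seq_len(ncol(m)), function(j)
    pearson_similarity(m[, j], reference))
  r <- vapply(res, `[[`, 0, "r")
  p_raw <- vapply(res, `[[`, 0, "p_raw")
  p_adj <- adjust_pvalues(p_raw, method = adjust)
  similar <- p_adj < threshold & (!require_positive | r > 0)
  out <- tibble::tibble(sample_id = colnames(m), r = r, p_raw = p_raw,
                        p_adj = p_adj,
                        label = ifelse(similar, "similar", "non_similar"))
  structure(out, class = c("similarity_tbl", class(out)),
            threshold = threshold, adjust = adjust,
            require_positive = require_positive,
            reference_provenance = reference$provenance)
}

#' One-row summary of a similarity classification
#'
#' @param x A `similarity_tbl` from [classify_cohort()].
#' @param ... Unused.
#' @return A one-row tibble: `n_similar`, `n_total`, `frac_similar`,
#'   `threshold`, `adjust`.
#' @export
glance.similarity_tbl <- function(x, ...) {
  tibble::tibble(n_similar = sum(x$label == "similar"),
                 n_total = nrow(x),
                 frac_similar = mean(x$label == "similar"),
                 threshold = attr(x, "threshold"),
                 adjust = attr(x, "adjust"))
}

#' Plot the adjusted-P distribution of a similarity classification
#'
#' Histogram of -log10 adjusted P-values, similar samples highlighted in
#' red, with a dashed line at the classification threshold.
#'
#' @param object A `similarity_tbl`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.similarity_tbl <- function(object, ...) {
  thr <- attr(object, "threshold")
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(pmax(.data$p_adj, 1e-300)),
                                   fill = .data$label)) +
    ggplot2::geom_histogram(bins = 60, boundary = 0) +
    ggplot2::geom_vline(xintercept = -log10(thr), linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(similar = "#c0392b",
                                          non_similar = "grey60")) +
    ggplot2::labs(x = expression(-log[10] ~ "adjusted P"), y = "samples",
                  fill = NULL,
                  title = "Metabolic similarity to the fly-tumor reference") +
    ggplot2::theme_minimal()
}

#' Write a similarity classification as TSV
#'
#' Probabilities are serialized in scientific notation with 6 significant
#' digits; full double precision is kept internally.
#'
#' @param x A `similarity_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(x, path) {
  stopifnot(inherits(x, "similarity_tbl"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("sample_id\tr\tp_raw\tp_adj\tlabel",
               sprintf("%s\t%.6f\t%.6e\t%.6e\t%s", x$sample_id, x$r,
                       x$p_raw, x$p_adj, x$label)), con, sep = "\n")
  invisible(path)
}
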