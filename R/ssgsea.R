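#' Single-sample gene-set enrichment score (ssGSEA running sum)
#'
#' Computes the per-sample enrichment statistic for one gene set: genes are
#' ranked by descending abundance; with rank-from-the-bottom weights
#' \eqn{r_j} (the highest-expressed gene gets weight \eqn{N}), the score is
#' \deqn{ES = \sum_{i=1}^{N} \left[ P_G(i) - P_{NG}(i) \right],}
#' where \eqn{P_G(i) = \sum_{j \le i, j \in G} r_j^\alpha / \sum_{j \in G}
#' r_j^\alpha} is the weighted cumulative fraction of set genes encountered
#' by position \eqn{i}, and \eqn{P_{NG}(i) = |\{j \le i, j \notin G\}| /
#' (N - |G|)} the unweighted one for non-set genes. The statistic depends on
#' the abundances only through their ranks, so any within-sample monotone
#' transform (e.g. log of strictly positive values) leaves it unchanged.
#'
#' Ties: the gene order of the running sum is always abundance-descending
#' with input-order tie breaking; `tie_rule` controls the rank *weights* —
#' `"average"` gives tied genes the mean of their positional weights (the
#' default), `"stable"` assigns strictly positional weights `N..1`.
#'
#' @param values Named numeric vector of finite abundances for one sample
#'   (names are gene identifiers).
#' @param gene_set Character vector of set genes; must intersect the gene
#'   universe in a non-empty strict subset.
#' @param alpha Non-negative rank-weighting exponent; `0.25` by default (the
#'   original ssGSEA weighting).
#' @param tie_rule `"average"` or `"stable"`; see Details.
#' @return A single numeric score.
#' @examples
#' v <- c(g1 = 4, g2 = 3, g3 = 2, g4 = 1)
#' enrichment_score(v, "g1", alpha = 1)  # 2
#' @export
enrichment_score <- function(values, gene_set, alpha = 0.25,
                             tie_rule = c("average", "stable")) {
  tie_rule <- match.arg(tie_rule)
  if (!is.numeric(values) || is.null(names(values)))
    stop("`values` must be a named numeric vector", call. = FALSE)
  if (any(!is.finite(values)))
    stop("non-finite abundance value(s)", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("`alpha` must be a single number >= 0", call. = FALSE)
  n <- length(values)
  member <- names(values) %in% gene_set
  m <- sum(member)
  if (m == 0L || m == n)
    stop("statistic undefined: gene set must be a non-empty strict subset ",
         "of the measured gene universe", call. = FALSE)
  ord <- order(-values)                  # stable: ties keep input order
  memb_o <- member[ord]
  w <- if (tie_rule == "average")
    rank(values, ties.method = "average")[ord]
  else
    n:1
  wa <- w^alpha
  # closed form for the double sum: each position j contributes its
  # cumulative term to the N - j + 1 running-sum positions at or after it
  mult <- n - seq_len(n) + 1
  in_w <- wa * memb_o
  sum(in_w * mult) / sum(in_w) - sum(mult[!memb_o]) / (n - m)
}

#' Score an expression matrix over a pathway collection
#'
#' Applies [enrichment_score()] to every (pathway, sample) pair. The
#' collection must already be restricted to measured genes for the matrix's
#' species (see [restrict_to_measured()]); pathway gene sets that are empty
#' or cover the whole gene universe raise an error naming the pathway.
#'
#' @param expr An `expr_matrix`.
#' @param collection A `pathway_collection` restricted to `expr`'s genes.
#' @param alpha,tie_rule Passed to the per-cell statistic.
#' @param normalize If `TRUE`, min-max normalize the whole score matrix to
#'   `[0, 1]` (a shared affine transform; it leaves downstream Pearson
#'   correlations unchanged). Off by default.
#' @return An `enrichment_scores` object: a pathways x samples numeric
#'   matrix in `$scores` with scoring parameters recorded in `$params`.
#' @export
score_matrix <- function(expr, collection, alpha = 0.25,
                         tie_rule = c("average", "stable"),
                         normalize = FALSE) {
  tie_rule <- match.arg(tie_rule)
  stopifnot(inherits(expr, "expr_matrix"))
  sets <- species_gene_sets(collection, expr$species)
  genes <- rownames(expr$values)
  n <- length(genes)
  idx <- lapply(sets, function(g) {
    i <- match(g, genes)
    if (anyNA(i))
      stop("pathway gene(s) absent from the expression matrix; run ",
           "restrict_to_measured() first", call. = FALSE)
    i
  })
  sizes <- lengths(idx)
  bad <- names(idx)[sizes == 0L | sizes == n]
  if (length(bad))
    stop("statistic undefined for pathway ", paste(bad, collapse = ", "),
         ": empty set or empty complement", call. = FALSE)
  mult <- n - seq_len(n) + 1
  tot_mult <- n * (n + 1) / 2
  scores <- matrix(NA_real_, length(idx), ncol(expr$values),
                   dimnames = list(names(idx), colnames(expr$values)))
  for (s in seq_len(ncol(expr$values))) {
    v <- expr$values[, s]
    if (any(!is.finite(v)))
      stop("non-finite abundance in sample ", colnames(expr$values)[s],
           call. = FALSE)
    ord <- order(-v)
    pos_of <- integer(n); pos_of[ord] <- seq_len(n)
    w <- if (tie_rule == "average")
      rank(v, ties.method = "average") else (n + 1) - pos_of
    wa <- w^alpha
    wmul <- wa * mult[pos_of]   # per original gene index
    dmul <- mult[pos_of]
    for (p in seq_along(idx)) {
      i <- idx[[p]]
      scores[p, s] <- sum(wmul[i]) / sum(wa[i]) -
        (tot_mult - sum(dmul[i])) / (n - sizes[p])
    }
  }
  if (normalize) {
    rng <- range(scores)
    if (diff(rng) > 0) scores <- (scores - rng[1]) / diff(rng)
  }
  structure(list(scores = scores,
                 params = list(alpha = alpha, tie_rule = tie_rule,
                               normalize = normalize,
                               species = expr$species)),
            class = "enrichment_scores")
}

#' @export
print.enrichment_scores <- function(x, ...) {
  cat(sprintf(
    "<enrichment_scores> %d pathways x %d samples (alpha = %g, tie_rule = %s, normalize = %s)\n",
    nrow(x$scores), ncol(x$scores), x$params$alpha, x$params$tie_rule,
    x$params$normalize))
  invisible(x)
}

#' Tidy an enrichment score matrix into a long tibble
#'
#' @param x An `enrichment_scores` object.
#' @param ... Unused.
#' @return Tibble with columns `pathway_id`, `sample`, `score`.
#' @export
tidy.enrichment_scores <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "pathway_id") |>
    tidyr::pivot_longer(-"pathway_id", names_to = "sample",
                        values_to = "score")
}

#' Read / write enrichment score matrices as TSV
#'
#' Pathways as rows, samples as columns; scoring parameters are serialized
#' into `#`-prefixed header comment lines so provenance survives the round
#' trip.
#'
#' @param x An `enrichment_scores` object.
#' @param path File path.
#' @return `write_scores_tsv()` returns `path` invisibly;
#'   `read_scores_tsv()` returns an `enrichment_scores` object.
#' @export
write_scores_tsv <- function(x, path) {
  stopifnot(inherits(x, "enrichment_scores"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- sprintf("# %s=%s", names(x$params),
                 vapply(x$params, as.character, ""))
  body <- vapply(seq_len(nrow(x$scores)), function(i)
    paste(c(rownames(x$scores)[i], sprintf("%.15g", x$scores[i, ])),
          collapse = "\t"), character(1))
  writeLines(c(hdr,
               paste(c("pathway_id", colnames(x$scores)), collapse = "\t"),
               body), con, sep = "\n")
  invisible(path)
}

#' @rdname write_scores_tsv
#' @export
read_scores_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  params <- list(alpha = 0.25, tie_rule = "average", normalize = FALSE,
                 species = NA_character_)
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) params[[kv[1]]] <- utils::type.convert(kv[2], as.is = TRUE)
  }
  df <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  structure(list(scores = m, params = params), class = "enrichment_scores")
}

#' Least-squares slope of a gene-expression time course
#'
#' Ordinary least-squares slope of expression on time (expression units per
#' day), the summary used to colour per-gene expression trends across tumor
#' ages.
#'
#' @param day Numeric vector of time points (days); at least two distinct.
#' @param value Numeric vector of expression values, same length.
#' @return The slope, a single number.
#' @examples
#' timecourse_slope(c(0, 1), c(0, 1))  # 1
#' @export
timecourse_slope <- function(day, value) {
  if (length(day) != length(value) || length(day) < 2L)
    stop("`day` and `value` must be equal-length vectors of >= 2 points",
         call. = FALSE)
  if (length(unique(day)) < 2L)
    stop("all time points identical: slope undefined", call. = FALSE)
  unname(stats::coef(stats::lm(value ~ day))[2L])
}
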