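#' Construct a gene-by-sample expression matrix
#'
#' A light container around a numeric matrix of non-negative abundance values
#' (FPKM, TPM or similar), with genes as rows, samples as columns and a
#' species tag. All downstream scoring is rank-based within each sample, so
#' any within-sample monotone abundance scale is acceptable.
#'
#' @param values Numeric matrix, genes x samples, with unique non-empty
#'   rownames (gene identifiers) and colnames (sample identifiers). All
#'   values must be finite and >= 0.
#' @param species Single string tagging the species (e.g. `"fly"`,
#'   `"human"`); matched against the species column of a
#'   [pathway_collection()].
#' @return An object of class `expr_matrix`.
#' @examples
#' m <- matrix(abs(rnorm(6)), 3, 2,
#'             dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
#' expression_matrix(m, species = "fly")
#' @export
expression_matrix <- function(values, species) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames", call. = FALSE)
  if (!is.character(species) || length(species) != 1L || !nzchar(species))
    stop("`species` must be a single non-empty string", call. = FALSE)
  gene_ids <- trimws(rownames(values))
  sample_ids <- trimws(colnames(values))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(gene_ids)) || any(!nzchar(sample_ids)))
    stop("gene and sample identifiers must be non-empty", call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression values must all be finite", call. = FALSE)
  if (any(values < 0))
    stop("expression values must be non-negative", call. = FALSE)
  if (nrow(values) < 2L)
    stop("an expression matrix needs at least 2 genes", call. = FALSE)
  if (ncol(values) < 1L)
    stop("an expression matrix needs at least 1 sample", call. = FALSE)
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, species = species), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, species = %s\n",
              nrow(x$values), ncol(x$values), x$species))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Tidy an expression matrix into a long tibble
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `sample`, `abundance`, `species`.
#' @export
tidy.expr_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample",
                        values_to = "abundance") |>
    dplyr::mutate(species = x$species)
}

#' Read / write an expression matrix as TSV
#'
#' The TSV dialect is: UTF-8, Unix newlines, tab-separated, header row of
#' sample identifiers, first column `gene_id`, `NA` for missing (not allowed
#' in a valid matrix). Values are written with 15 significant digits so a
#' write-then-read round trip is stable well past 12 significant digits.
#'
#' @param path File path.
#' @param species Species tag to attach on read.
#' @return [read_expression_tsv()] returns an `expr_matrix`;
#'   [write_expression_tsv()] returns `path` invisibly.
#' @export
read_expression_tsv <- function(path, species) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("expression TSV needs a gene_id column plus >= 1 sample column: ",
         path, call. = FALSE)
  sample_ids <- colnames(df)[-1]
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicated sample column(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))
      stop(sprintf("non-numeric cell in %s: column '%s', data row %d",
                   path, sample_ids[j],
                   if (length(bad)) bad[1] else NA_integer_), call. = FALSE)
    }
    neg <- which(col < 0)
    if (length(neg))
      stop(sprintf("negative value in %s: column '%s', data row %d",
                   path, sample_ids[j], neg[1]), call. = FALSE)
  }
  m <- as.matrix(vals)
  rownames(m) <- as.character(df[[1]])
  expression_matrix(m, species = species)
}

#' @rdname read_expression_tsv
#' @param expr An `expr_matrix`.
#' @export
write_expression_tsv <- function(expr, path) {
  stopifnot(inherits(expr, "expr_matrix"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- paste(c("gene_id", colnames(expr$values)), collapse = "\t")
  body <- vapply(seq_len(nrow(expr$values)), function(i) {
    paste(c(rownames(expr$values)[i],
            sprintf("%.15g", expr$values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}
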