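#' Conserved metabolic pathway collections
#'
#' A pathway collection is a tibble of `(pathway_id, species, gene)` rows
#' describing curated gene sets per species, modelled on hand-curated
#' conserved-pathway tables (KEGG / Metabolic Atlas style). A pathway is
#' *conserved* when it has a non-empty gene set for every species tag seen
#' in the collection; non-conserved pathways are excluded on construction
#' with a warning, because the cross-species correlation is only defined
#' over pathways scoreable in both cohorts. Ortholog correspondence is
#' carried implicitly by the curated table, never computed here.
#'
#' @param x A data frame with character columns `pathway_id`, `species`,
#'   `gene` (extra columns are kept).
#' @param min_genes Minimum per-species gene-set size for a pathway to be
#'   retained (default 1, i.e. no minimum).
#' @param source Free-text provenance string stored as an attribute.
#' @param species_tags Species the collection is declared for; defaults to
#'   the tags observed in `x`. Passing the full expected set (e.g.
#'   `c("fly", "human")`) lets conservation be enforced even when one
#'   species is entirely absent from the input.
#' @return A tibble of class `pathway_collection`.
#' @export
pathway_collection <- function(x, min_genes = 1L, source = "user",
                               species_tags = NULL) {
  x <- tibble::as_tibble(x)
  need <- c("pathway_id", "species", "gene")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("pathway table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- dplyr::mutate(x, dplyr::across(dplyr::all_of(need), trimws))
  if (any(!nzchar(x$gene)) || any(!nzchar(x$pathway_id)) ||
      any(!nzchar(x$species)))
    stop("pathway_id, species and gene must be non-empty strings",
         call. = FALSE)
  x <- dplyr::distinct(x, dplyr::across(dplyr::all_of(need)),
                       .keep_all = TRUE)
  tags <- sort(unique(c(x$species, species_tags)))
  per <- dplyr::count(x, .data$pathway_id, .data$species)
  keep <- per |>
    dplyr::filter(.data$n >= min_genes) |>
    dplyr::count(.data$pathway_id, name = "n_species") |>
    dplyr::filter(.data$n_species == length(tags))
  dropped <- setdiff(unique(x$pathway_id), keep$pathway_id)
  if (length(dropped)) {
    warning(length(dropped), " pathway(s) not conserved across species tags {",
            paste(tags, collapse = ", "), "} (or below min_genes) and excluded: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "", call. = FALSE)
    x <- dplyr::filter(x, .data$pathway_id %in% keep$pathway_id)
  }
  structure(x, class = c("pathway_collection", class(x)),
            species_tags = tags, source = source)
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway_collection> %d conserved pathway(s), species: %s\n",
              length(unique(x$pathway_id)),
              paste(attr(x, "species_tags"), collapse = ", ")))
  NextMethod()
}

#' Read a pathway collection from GMT or long-TSV
#'
#' Two on-disk formats are supported. *GMT*: the standard tab-separated
#' gene-set format (set name, description, then gene symbols), one file per
#' species, so `path` and `species` may be vectors of equal length.
#' *long-TSV*: a header row `pathway_id<TAB>species<TAB>gene` followed by one
#' row per (pathway, species, gene) triple.
#'
#' Gene identifiers are matched downstream by exact string equality after
#' whitespace trimming (case preserved); no symbol-alias resolution is
#' attempted — the curated table fixes the mapping.
#'
#' @param path File path(s).
#' @param format `"gmt"` or `"long_tsv"`; `"auto"` guesses from the
#'   extension.
#' @param species For GMT input, the species tag(s) of each file; ignored
#'   for long-TSV (taken from the column). If `NULL`, the tag is inferred
#'   from the filename suffix before the extension (e.g. `sets_fly.gmt`).
#' @inheritParams pathway_collection
#' @return A `pathway_collection`.
#' @export
read_pathway_collection <- function(path, format = c("auto", "gmt", "long_tsv"),
                                    species = NULL, min_genes = 1L,
                                    species_tags = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (all(grepl("\\.gmt$", path, ignore.case = TRUE)))
      "gmt" else "long_tsv"
  for (p in path) if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  if (format == "gmt") {
    if (is.null(species))
      species <- sub("\\.[^.]*$", "", basename(path)) |>
        (\(s) sub("^.*[_.]", "", s))()
    if (length(species) != length(path))
      stop("`species` must have one tag per GMT file", call. = FALSE)
    rows <- purrr::map2(path, species, read_gmt_one)
    tab <- dplyr::bind_rows(rows)
  } else {
    if (length(path) != 1L)
      stop("long-TSV input is a single file", call. = FALSE)
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("pathway_id", "species", "gene")
    if (!all(need %in% names(tab)))
      stop("long-TSV header must contain pathway_id, species, gene: ", path,
           call. = FALSE)
    bad <- which(!nzchar(trimws(tab$gene)) | is.na(tab$gene))
    if (length(bad))
      stop(sprintf("malformed line %d in %s: empty gene field",
                   bad[1] + 1L, path), call. = FALSE)
  }
  if (nrow(tab) == 0L)
    stop("empty pathway collection: ", paste(path, collapse = ", "),
         call. = FALSE)
  pathway_collection(tab, min_genes = min_genes,
                     source = paste(path, collapse = ";"),
                     species_tags = species_tags)
}

read_gmt_one <- function(path, species) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short))
    stop(sprintf("malformed line %d in %s: a GMT record needs name, description and >= 1 gene",
                 short[1], path), call. = FALSE)
  ids <- vapply(fields, `[[`, "", 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate pathway id(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  purrr::map2(fields, ids, function(f, id) {
    tibble::tibble(pathway_id = id, pathway_name = f[[2L]],
                   species = species, gene = f[-(1:2)])
  }) |> dplyr::bind_rows()
}

#' Write a pathway collection as long-TSV
#'
#' @param collection A `pathway_collection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pathway_collection <- function(collection, path) {
  stopifnot(inherits(collection, "pathway_collection"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("pathway_id\tspecies\tgene",
               sprintf("%s\t%s\t%s", collection$pathway_id,
                       collection$species, collection$gene)),
             con, sep = "\n")
  invisible(path)
}

#' Per-species gene sets of a collection
#'
#' @param collection A `pathway_collection`.
#' @param species A species tag present in the collection.
#' @return Named list mapping pathway_id to a character vector of genes.
#' @export
species_gene_sets <- function(collection, species) {
  stopifnot(inherits(collection, "pathway_collection"))
  if (!species %in% attr(collection, "species_tags"))
    stop("species '", species, "' not in collection (has: ",
         paste(attr(collection, "species_tags"), collapse = ", "), ")",
         call. = FALSE)
  sub <- collection[collection$species == species, , drop = FALSE]
  split(sub$gene, factor(sub$pathway_id, levels = unique(sub$pathway_id)))
}

#' Restrict a pathway collection to genes measured in an expression matrix
#'
#' Intersects each pathway's gene set for `expr`'s species with the genes of
#' `expr`. Pathways whose intersection is empty, or equals the full measured
#' gene universe, are dropped entirely (for all species): the enrichment
#' running-sum statistic is undefined for an empty set or an empty
#' complement. The drop report is attached as attribute `"dropped"` (a
#' tibble with columns `pathway_id`, `reason`) and retrievable with
#' [dropped_pathways()]. The operation is idempotent.
#'
#' @param collection A `pathway_collection`.
#' @param expr An `expr_matrix` whose species tag occurs in `collection`.
#' @return The restricted `pathway_collection`.
#' @export
restrict_to_measured <- function(collection, expr) {
  stopifnot(inherits(collection, "pathway_collection"),
            inherits(expr, "expr_matrix"))
  sp <- expr$species
  if (!sp %in% attr(collection, "species_tags"))
    stop("expression species '", sp, "' not among collection species tags",
         call. = FALSE)
  universe <- rownames(expr$values)
  tags <- attr(collection, "species_tags")
  src <- attr(collection, "source")
  is_sp <- collection$species == sp
  keep_row <- !is_sp | collection$gene %in% universe
  restricted <- collection[keep_row, , drop = FALSE]
  sizes <- table(restricted$pathway_id[restricted$species == sp])
  all_ids <- unique(collection$pathway_id)
  n_meas <- as.integer(sizes[all_ids])
  n_meas[is.na(n_meas)] <- 0L
  reason <- rep(NA_character_, length(all_ids))
  reason[n_meas == 0L] <- "no measured genes"
  reason[n_meas == length(universe)] <- "empty complement"
  drop_ids <- all_ids[!is.na(reason)]
  out <- restricted[!restricted$pathway_id %in% drop_ids, , drop = FALSE]
  out <- structure(out, class = c("pathway_collection",
                                  class(tibble::as_tibble(out))),
                   species_tags = tags, source = src,
                   dropped = tibble::tibble(
                     pathway_id = drop_ids,
                     reason = reason[!is.na(reason)]))
  out
}

#' @rdname restrict_to_measured
#' @export
dropped_pathways <- function(collection) {
  attr(collection, "dropped") %||%
    tibble::tibble(pathway_id = character(), reason = character())
}
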