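#' Metabolite concentration normalization (nmol/g of sample)
#'
#' Converts a machine-reported LC-MS concentration to a per-mass tissue
#' concentration. With the machine concentration `c_machine` in umol/l, the
#' preparation dilution factor, the sample volume `v_f` in ul and the sample
#' mass `m_s` in mg, the final concentration is
#' \deqn{C_M = \frac{c_{machine} \times dilution \times V_F}{M_s}}
#' in nmol/g. The formula is the unique dimensionally consistent
#' combination of the stated units: umol/l x ul = pmol, and pmol/mg =
#' nmol/g, so no unit constants are needed.
#'
#' @param c_machine Machine-reported concentration, umol/l (>= 0).
#' @param dilution Dilution factor applied in sample preparation (>= 1).
#' @param v_f Final sample volume, ul (> 0).
#' @param m_s Sample mass, mg (> 0).
#' @return Concentration in nmol/g; vectorized over its arguments.
#' @examples
#' metabolite_concentration(2, 1, 100, 50)  # 4 nmol/g
#' @export
metabolite_concentration <- function(c_machine, dilution, v_f, m_s) {
  if (any(!is.finite(c_machine)) || any(c_machine < 0))
    stop("c_machine must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(dilution)) || any(dilution < 1))
    stop("dilution must be >= 1", call. = FALSE)
  if (any(!is.finite(v_f)) || any(v_f <= 0))
    stop("v_f must be > 0", call. = FALSE)
  if (any(!is.finite(m_s)) || any(m_s <= 0))
    stop("m_s must be > 0", call. = FALSE)
  c_machine * dilution * v_f / m_s
}

#' Wilcoxon rank-sum test between two groups
#'
#' Two-sided rank-sum comparison of two samples. The exact distribution is
#' used when the pooled size is at most 20 and there are no ties;
#' otherwise the normal approximation with tie correction (and continuity
#' correction) is used. The branch taken is reported.
#'
#' @param group_a,group_b Numeric vectors, each non-empty.
#' @return A list: `W` (rank-sum statistic of `group_a`), `p_two_sided`,
#'   `method` (`"exact"` or `"normal_approx"`).
#' @examples
#' wilcoxon_rank_sum(1:4, 5:8)$p_two_sided  # 2/70
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  n <- length(group_a) + length(group_b)
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- n <= 20L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = !exact))
  list(W = unname(wt$statistic), p_two_sided = wt$p.value,
       method = if (exact) "exact" else "normal_approx")
}

#' Fold change of metabolite concentration between genotypes
#'
#' Ratio of the mutant replicate mean to the control replicate mean
#' (optionally of geometric means, for log-scale colouring), with an
#' optional log2 return scale.
#'
#' @param mutant,control Numeric replicate vectors; the control mean must
#'   be positive.
#' @param geometric Use geometric rather than arithmetic means (requires
#'   strictly positive values).
#' @param log2_scale Return log2 of the ratio.
#' @return A single number.
#' @export
fold_change <- function(mutant, control, geometric = FALSE,
                        log2_scale = FALSE) {
  if (length(mutant) == 0L || length(control) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  if (geometric) {
    if (any(mutant <= 0) || any(control <= 0))
      stop("geometric means require strictly positive values",
           call. = FALSE)
    fc <- exp(mean(log(mutant)) - mean(log(control)))
  } else {
    mc <- mean(control)
    if (!is.finite(mc) || mc <= 0)
      stop("control mean must be positive", call. = FALSE)
    fc <- mean(mutant) / mc
  }
  if (log2_scale) log2(fc) else fc
}

#' Per-metabolite genotype comparison of a replicate table
#'
#' Applies Eq.-style concentration normalization
#' ([metabolite_concentration()]) to every replicate row, then for each
#' metabolite compares the two genotypes with [wilcoxon_rank_sum()] and
#' reports the mutant/control [fold_change()].
#'
#' @param measurements A tibble of replicate measurements with columns
#'   `metabolite_id`, `genotype`, `replicate`, `c_machine`, `dilution`,
#'   `v_f`, `m_s` (as produced by [simulate_metabolite_table()] or read
#'   from TSV).
#' @param control,mutant Genotype labels of the two groups.
#' @return A tibble of class `metabolite_contrast_tbl`: `metabolite_id`,
#'   `mean_control`, `mean_mutant` (nmol/g), `fold_change`, `W`, `p`,
#'   `method`.
#' @export
compare_genotypes <- function(measurements, control = "control",
                              mutant = "mutant") {
  m <- tibble::as_tibble(measurements)
  need <- c("metabolite_id", "genotype", "c_machine", "dilution", "v_f",
            "m_s")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("measurement table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(c(control, mutant) %in% m$genotype))
    stop("genotype labels not found in the table: ",
         paste(setdiff(c(control, mutant), m$genotype), collapse = ", "),
         call. = FALSE)
  m$conc <- metabolite_concentration(m$c_machine, m$dilution, m$v_f, m$m_s)
  out <- m |>
    dplyr::filter(.data$genotype %in% c(control, mutant)) |>
    dplyr::group_by(.data$metabolite_id) |>
    dplyr::group_modify(function(d, key) {
      a <- d$conc[d$genotype == mutant]
      b <- d$conc[d$genotype == control]
      wt <- wilcoxon_rank_sum(a, b)
      tibble::tibble(mean_control = mean(b), mean_mutant = mean(a),
                     fold_change = fold_change(a, b),
                     W = wt$W, p = wt$p_two_sided, method = wt$method)
    }) |>
    dplyr::ungroup()
  structure(out, class = c("metabolite_contrast_tbl", class(out)),
            control = control, mutant = mutant)
}

#' Plot metabolite fold changes with significance
#'
#' Log2 fold change per metabolite, bars coloured by rank-sum P below /
#' above 0.05.
#'
#' @param object A `metabolite_contrast_tbl` from [compare_genotypes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metabolite_contrast_tbl <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(l2fc = log2(.data$fold_change),
                  sig = ifelse(.data$p < 0.05, "p < 0.05", "ns"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$metabolite_id, .data$l2fc),
    y = .data$l2fc, fill = .data$sig)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c("p < 0.05" = "#c0392b",
                                          ns = "grey60")) +
    ggplot2::labs(x = NULL, y = expression(log[2] ~ "fold change"),
                  fill = NULL,
                  title = "Metabolite concentration changes") +
    ggplot2::theme_minimal()
}
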