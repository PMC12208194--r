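#' Configuration for the synthetic tumor-cohort simulator
#'
#' Bundles and validates every parameter of [simulate_cohort()]. The
#' defaults emulate the statistical structure of the cross-species study
#' design: 72 conserved metabolic pathways with exact 1:1 synthetic
#' orthologs in distinct namespaces (fly `fg####`, human `HG####`), a small
#' fly tumor reference cohort, a large query cohort of which a 7% planted
#' subpopulation shares the fly tumors' per-pathway expression-shift
#' vector, mutation events over-represented in that subpopulation, and
#' group-shifted age / mutation-load / methylation / survival
#' distributions.
#'
#' @param n_genes_per_species Genes per species (default 2400; pathway gene
#'   sets are drawn disjoint, so it must be at least the maximum total
#'   pathway size plus some background genes).
#' @param n_pathways Number of conserved pathways (default 72).
#' @param genes_per_pathway Length-2 integer range of pathway sizes
#'   (default 8-25).
#' @param n_fly_samples Fly tumor reference samples (default 6).
#' @param n_query_samples Query tumor samples (default 2000).
#' @param similar_fraction Planted fraction of metabolically similar query
#'   samples (default 0.07).
#' @param pathway_effect_sd Magnitude of the shared per-pathway
#'   log-expression shift, in units of the baseline within-gene
#'   log-expression standard deviation (default 3).
#' @param n_mutation_genes Number of unplanted (null) mutation genes
#'   (default 50).
#' @param planted_enriched_genes Named numeric vector of planted mutation
#'   genes and their target odds ratios (default `c(mutA = 8)`).
#' @param age_means Mean patient age (years) for the similar and
#'   non-similar groups (default 45 / 60; shared sd 15).
#' @param mutation_count_lognormal List of `(meanlog, sdlog)` per group for
#'   the mutation-load distribution (default meanlog `log(20)` vs
#'   `log(80)`, sdlog 1).
#' @param beta_params List of Beta shape pairs per group for per-sample
#'   mean methylation (default similar `(10, 12)`, other `(14, 10)`).
#' @param survival_hazards Per-day exponential event hazards per group
#'   (default both `1/1500`: no survival difference, matching the
#'   predominantly null survival contrast).
#' @param seed Mandatory integer seed; a documented sub-stream scheme
#'   derives one sub-seed per generated table, so adding a table never
#'   perturbs earlier draws.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes_per_species = 2400L,
                              n_pathways = 72L,
                              genes_per_pathway = c(8L, 25L),
                              n_fly_samples = 6L,
                              n_query_samples = 2000L,
                              similar_fraction = 0.07,
                              pathway_effect_sd = 3,
                              n_mutation_genes = 50L,
                              planted_enriched_genes = c(mutA = 8),
                              age_means = c(similar = 45, other = 60),
                              mutation_count_lognormal = list(
                                similar = c(meanlog = log(20), sdlog = 1),
                                other = c(meanlog = log(80), sdlog = 1)),
                              beta_params = list(
                                similar = c(10, 12), other = c(14, 10)),
                              survival_hazards = c(similar = 1 / 1500,
                                                   other = 1 / 1500),
                              seed) {
  if (missing(seed) || is.null(seed))
    stop("`seed` is mandatory: the simulator never runs unseeded",
         call. = FALSE)
  cfg <- list(n_genes_per_species = as.integer(n_genes_per_species),
              n_pathways = as.integer(n_pathways),
              genes_per_pathway = as.integer(genes_per_pathway),
              n_fly_samples = as.integer(n_fly_samples),
              n_query_samples = as.integer(n_query_samples),
              similar_fraction = similar_fraction,
              pathway_effect_sd = pathway_effect_sd,
              n_mutation_genes = as.integer(n_mutation_genes),
              planted_enriched_genes = planted_enriched_genes,
              age_means = age_means,
              mutation_count_lognormal = mutation_count_lognormal,
              beta_params = beta_params,
              survival_hazards = survival_hazards,
              seed = as.integer(seed))
  counts <- c(cfg$n_genes_per_species, cfg$n_pathways,
              cfg$genes_per_pathway, cfg$n_fly_samples,
              cfg$n_query_samples)
  if (any(counts <= 0L)) stop("all counts must be > 0", call. = FALSE)
  if (length(cfg$genes_per_pathway) != 2L ||
      cfg$genes_per_pathway[1] > cfg$genes_per_pathway[2])
    stop("genes_per_pathway must be an increasing length-2 range",
         call. = FALSE)
  if (cfg$similar_fraction < 0 || cfg$similar_fraction > 1)
    stop("similar_fraction must lie in [0, 1]", call. = FALSE)
  if (cfg$pathway_effect_sd < 0)
    stop("pathway_effect_sd must be >= 0", call. = FALSE)
  if (cfg$n_pathways * cfg$genes_per_pathway[2] >=
      cfg$n_genes_per_species)
    stop("n_genes_per_species must exceed the maximum total pathway size ",
         "(pathway gene sets are disjoint and must not cover the ",
         "universe)", call. = FALSE)
  if (!is.null(cfg$planted_enriched_genes) &&
      length(cfg$planted_enriched_genes) &&
      is.null(names(cfg$planted_enriched_genes)))
    stop("planted_enriched_genes must be a named vector of odds ratios",
         call. = FALSE)
  structure(cfg, class = "simulation_config")
}

# sub-stream seeds: one deterministic 31-bit sub-seed per output table,
# so table k's draws are independent of how many tables follow it
substream_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 104729) %% 2147483647)
}

#' Simulate a cross-species tumor cohort
#'
#' Generates everything the pipeline consumes, fully in silico: a conserved
#' pathway collection over exact 1:1 synthetic orthologs, a fly tumor
#' reference expression matrix, a query expression matrix with a planted
#' metabolically-similar subpopulation, ground-truth labels and a clinical
#' / mutation cohort table.
#'
#' Expression is log-normal: gene `g` in sample `s` has
#' `log x = mu_g + shift + N(0, 1)`, with per-species baselines
#' `mu_g ~ N(log 50, 1)` drawn independently per species. Each pathway
#' draws one shift `delta_p = +/- pathway_effect_sd` (sign equiprobable);
#' the shift is applied to the pathway's genes in every fly tumor sample
#' and, through the ortholog map, in every planted similar query sample.
#' Non-similar query samples get baseline plus independent noise only.
#' Pathway gene sets are disjoint, so the gene-level shift is unambiguous.
#' Clinical covariates and mutation events are drawn per group from the
#' configured distributions; planted mutation genes multiply their
#' mutation odds by the target odds ratio in the similar group.
#'
#' @param config A [simulation_config()].
#' @return A list: `fly_expr`, `query_expr` (both `expr_matrix`),
#'   `pathways` (`pathway_collection`), `truth` (tibble `sample_id`,
#'   `similar`), `cohort` (`cohort_tbl`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  n_g <- cfg$n_genes_per_species
  fly_genes <- sprintf("fg%04d", seq_len(n_g))
  hum_genes <- sprintf("HG%04d", seq_len(n_g))

  # table 1: pathway membership and shift vector
  set.seed(substream_seed(cfg$seed, 1L))
  sizes <- sample(seq(cfg$genes_per_pathway[1], cfg$genes_per_pathway[2]),
                  cfg$n_pathways, replace = TRUE)
  member_idx <- split(sample.int(n_g, sum(sizes)),
                      rep(seq_len(cfg$n_pathways), sizes))
  pw_ids <- sprintf("PW%02d", seq_len(cfg$n_pathways))
  delta <- sample(c(-1, 1), cfg$n_pathways, replace = TRUE) *
    cfg$pathway_effect_sd
  gene_shift <- numeric(n_g)               # disjoint sets: direct assign
  for (p in seq_len(cfg$n_pathways)) gene_shift[member_idx[[p]]] <- delta[p]
  pathways <- pathway_collection(
    tibble::tibble(
      pathway_id = rep(rep(pw_ids, sizes), 2L),
      species = rep(c("fly", "human"), each = sum(sizes)),
      gene = c(fly_genes[unlist(member_idx)],
               hum_genes[unlist(member_idx)])),
    source = "synthetic")

  # table 2: per-species gene baselines
  set.seed(substream_seed(cfg$seed, 2L))
  mu_fly <- stats::rnorm(n_g, log(50), 1)
  mu_hum <- stats::rnorm(n_g, log(50), 1)

  # table 3: fly tumor expression
  set.seed(substream_seed(cfg$seed, 3L))
  fly_vals <- exp(mu_fly + gene_shift +
                    matrix(stats::rnorm(n_g * cfg$n_fly_samples), n_g))
  dimnames(fly_vals) <- list(fly_genes,
                             sprintf("fly_t%02d", seq_len(cfg$n_fly_samples)))
  fly_expr <- expression_matrix(fly_vals, species = "fly")

  # table 4: query expression + truth labels
  set.seed(substream_seed(cfg$seed, 4L))
  n_q <- cfg$n_query_samples
  n_sim <- round(cfg$similar_fraction * n_q)
  sim_idx <- if (n_sim > 0) sort(sample.int(n_q, n_sim)) else integer(0)
  similar <- seq_len(n_q) %in% sim_idx
  q_vals <- matrix(stats::rnorm(n_g * n_q), n_g) + mu_hum
  if (length(sim_idx))
    q_vals[, sim_idx] <- q_vals[, sim_idx] + gene_shift
  q_vals <- exp(q_vals)
  sample_ids <- sprintf("q%05d", seq_len(n_q))
  dimnames(q_vals) <- list(hum_genes, sample_ids)
  query_expr <- expression_matrix(q_vals, species = "human")
  truth <- tibble::tibble(sample_id = sample_ids, similar = similar)

  # table 5: clinical covariates
  set.seed(substream_seed(cfg$seed, 5L))
  grp <- ifelse(similar, "similar", "other")
  age <- pmax(1, stats::rnorm(
    n_q, mean = cfg$age_means[grp], sd = 15))
  mcl <- cfg$mutation_count_lognormal
  mutation_count <- as.integer(round(stats::rlnorm(
    n_q,
    meanlog = vapply(grp, function(g) mcl[[g]][["meanlog"]], 0),
    sdlog = vapply(grp, function(g) mcl[[g]][["sdlog"]], 0))))
  bp <- cfg$beta_params
  mean_beta <- stats::rbeta(
    n_q,
    shape1 = vapply(grp, function(g) bp[[g]][1], 0),
    shape2 = vapply(grp, function(g) bp[[g]][2], 0))
  cancer_type <- sample(sprintf("type%02d", 1:8), n_q, replace = TRUE)

  # table 6: mutation events
  set.seed(substream_seed(cfg$seed, 6L))
  null_genes <- sprintf("mg%03d", seq_len(cfg$n_mutation_genes))
  base_p <- stats::runif(cfg$n_mutation_genes, 0.02, 0.15)
  names(base_p) <- null_genes
  planted <- cfg$planted_enriched_genes
  p_planted_other <- rep(0.10, length(planted))
  names(p_planted_other) <- names(planted)
  event_mat <- matrix(FALSE, n_q,
                      cfg$n_mutation_genes + length(planted),
                      dimnames = list(NULL, c(null_genes, names(planted))))
  for (g in null_genes)
    event_mat[, g] <- stats::runif(n_q) < base_p[[g]]
  for (g in names(planted)) {
    p0 <- p_planted_other[[g]]
    odds_sim <- (p0 / (1 - p0)) * planted[[g]]
    p_sim <- odds_sim / (1 + odds_sim)
    event_mat[, g] <- stats::runif(n_q) < ifelse(similar, p_sim, p0)
  }
  mutation_events <- apply(event_mat, 1L,
                           function(row) colnames(event_mat)[row],
                           simplify = FALSE)

  # table 7: survival
  set.seed(substream_seed(cfg$seed, 7L))
  hz <- cfg$survival_hazards[grp]
  t_event <- stats::rexp(n_q, rate = hz)
  admin_censor <- 3650
  event <- t_event <= admin_censor
  survival_time <- pmin(t_event, admin_censor)

  cohort <- cohort_table(tibble::tibble(
    sample_id = sample_ids, age = age,
    mutation_count = mutation_count, mean_beta = mean_beta,
    mutation_events = mutation_events,
    survival_time = survival_time, event = event,
    cancer_type = cancer_type))

  list(fly_expr = fly_expr, query_expr = query_expr, pathways = pathways,
       truth = truth, cohort = cohort)
}

#' Simulate an LC-MS metabolite replicate table
#'
#' Replicate-level machine measurements for a control and a mutant
#' genotype, with multiplicative genotype effects and log-normal
#' measurement noise. True per-mass concentrations are drawn per
#' metabolite, then back-converted to the machine scale through the same
#' unit chain that [metabolite_concentration()] inverts, so normalizing
#' the simulated table recovers the intended concentrations up to noise.
#'
#' @param n_metabolites Number of metabolites.
#' @param n_replicates Replicates per genotype (default 4, >= 2).
#' @param genotype_effects Numeric vector (length 1 or `n_metabolites`) of
#'   multiplicative mutant/control concentration ratios (default 1: null).
#' @param seed Mandatory integer seed.
#' @param noise_sdlog Log-normal measurement noise sd (default 0.2).
#' @return A tibble of replicate measurements with columns
#'   `metabolite_id`, `genotype`, `replicate`, `c_machine`, `dilution`,
#'   `v_f`, `m_s`.
#' @export
simulate_metabolite_table <- function(n_metabolites, n_replicates = 4L,
                                      genotype_effects = 1, seed,
                                      noise_sdlog = 0.2) {
  if (missing(seed) || is.null(seed))
    stop("`seed` is mandatory", call. = FALSE)
  if (n_replicates < 2L)
    stop("n_replicates must be >= 2", call. = FALSE)
  if (!length(genotype_effects) %in% c(1L, n_metabolites) ||
      any(!is.finite(genotype_effects)) || any(genotype_effects <= 0))
    stop("genotype_effects must be positive, length 1 or n_metabolites",
         call. = FALSE)
  effects <- rep_len(genotype_effects, n_metabolites)
  set.seed(substream_seed(as.integer(seed), 11L))
  met_ids <- sprintf("met%03d", seq_len(n_metabolites))
  base_conc <- stats::rlnorm(n_metabolites, log(10), 1)   # nmol/g
  rows <- purrr::map(seq_len(n_metabolites), function(i) {
    purrr::map(c("control", "mutant"), function(geno) {
      true_c <- base_conc[i] * if (geno == "mutant") effects[i] else 1
      m_s <- stats::runif(n_replicates, 40, 60)            # mg of larvae
      v_f <- 100; dilution <- 1
      noisy <- true_c * stats::rlnorm(n_replicates, 0, noise_sdlog)
      tibble::tibble(metabolite_id = met_ids[i], genotype = geno,
                     replicate = seq_len(n_replicates),
                     c_machine = noisy * m_s / (v_f * dilution),
                     dilution = dilution, v_f = v_f, m_s = m_s)
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}
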