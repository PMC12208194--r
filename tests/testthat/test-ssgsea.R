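test_that("enrichment score matches the hand-enumerated running sum", {
  v <- c(g1 = 4, g2 = 3, g3 = 2, g4 = 1)
  # G = top gene, alpha = 1: (1-0) + (1-1/3) + (1-2/3) + (1-1) = 2
  expect_equal(enrichment_score(v, "g1", alpha = 1), 2)
  # G = bottom gene of the same instance, against the brute-force oracle
  expect_equal(enrichment_score(v, "g4", alpha = 1),
               oracle_enrichment_score(v, "g4", alpha = 1),
               tolerance = 1e-12)
})

test_that("enrichment score agrees with the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    v <- random_sample_values(n)
    m <- sample(seq_len(n - 1), 1)
    gs <- sample(names(v), m)
    alpha <- sample(c(0, 0.25, 1, 2), 1)
    expect_equal(enrichment_score(v, gs, alpha = alpha),
                 oracle_enrichment_score(v, gs, alpha = alpha),
                 tolerance = 1e-12)
  }
})

test_that("the score is rank-invariant and deterministic", {
  set.seed(7)
  v <- random_sample_values(30)
  gs <- names(v)[sample(30, 8)]
  base <- enrichment_score(v, gs)
  # strictly monotone transforms leave the score bit-identical
  expect_identical(enrichment_score(log(v), gs), base)
  expect_identical(enrichment_score(rank(v), gs), base)
  expect_identical(enrichment_score(v^3, gs), base)
  expect_identical(enrichment_score(v, gs), base)
})

test_that("tied abundances are handled by the declared tie rules", {
  v <- c(a = 5, b = 3, c = 3, d = 1)
  # average weights: b and c share (3 + 2) / 2 = 2.5
  got <- enrichment_score(v, c("b", "c"), alpha = 1, tie_rule = "average")
  expect_equal(got, oracle_enrichment_score(v, c("b", "c"), alpha = 1,
                                            tie_rule = "average"),
               tolerance = 1e-12)
  # stable rule: strictly positional weights 4..1
  got_s <- enrichment_score(v, c("b", "c"), alpha = 1, tie_rule = "stable")
  expect_equal(got_s, oracle_enrichment_score(v, c("b", "c"), alpha = 1,
                                              tie_rule = "stable"),
               tolerance = 1e-12)
  # with all set genes tied, average weighting makes the set-side
  # cumulative identical for either within-tie order of members
  v2 <- c(a = 5, b = 3, c = 3, d = 1)
  v2_swapped <- c(a = 5, c = 3, b = 3, d = 1)
  expect_equal(
    enrichment_score(v2, c("b", "c"), alpha = 1),
    enrichment_score(v2_swapped, c("b", "c"), alpha = 1))
})

test_that("degenerate gene sets and bad abundances are rejected", {
  v <- c(g1 = 2, g2 = 1)
  expect_error(enrichment_score(v, character(0)), "statistic undefined")
  expect_error(enrichment_score(v, c("g1", "g2")), "statistic undefined")
  expect_error(enrichment_score(v, "absent"), "statistic undefined")
  expect_error(enrichment_score(c(g1 = NA_real_, g2 = 1), "g1"),
               "non-finite")
  expect_error(enrichment_score(v, "g1", alpha = -1), "alpha")
})

test_that("score_matrix composes per-cell scores and respects column order", {
  set.seed(21)
  n_g <- 80
  genes <- sprintf("HG%03d", seq_len(n_g))
  m <- matrix(rlnorm(n_g * 15), n_g, 15,
              dimnames = list(genes, sprintf("s%02d", 1:15)))
  expr <- expression_matrix(m, "human")
  col <- pathway_collection(tibble::tibble(
    pathway_id = rep(sprintf("PW%02d", 1:6), each = 7),
    species = "human",
    gene = genes[sample(n_g, 42)]))
  sm <- score_matrix(expr, col, alpha = 0.25)
  sets <- species_gene_sets(col, "human")
  for (p in names(sets))
    for (s in colnames(m))
      expect_equal(sm$scores[p, s],
                   enrichment_score(m[, s], sets[[p]], alpha = 0.25),
                   tolerance = 1e-12)
  # permuting sample order permutes columns identically
  perm <- sample(ncol(m))
  sm2 <- score_matrix(expression_matrix(m[, perm], "human"), col)
  expect_identical(sm2$scores, score_matrix(expr, col)$scores[, perm])
  # params recorded for provenance
  expect_equal(sm$params$alpha, 0.25)
  expect_equal(sm$params$tie_rule, "average")
  # 1 pathway x 1 sample composition
  one <- score_matrix(
    expression_matrix(m[, 1, drop = FALSE], "human"),
    pathway_collection(tibble::tibble(pathway_id = "PW01",
                                      species = "human",
                                      gene = sets[["PW01"]])))
  expect_equal(dim(one$scores), c(1L, 1L))
  expect_equal(one$scores[1, 1],
               enrichment_score(m[, 1], sets[["PW01"]]),
               tolerance = 1e-12)
})

test_that("min-max normalization is an affine rescale to [0, 1]", {
  set.seed(3)
  genes <- sprintf("g%02d", 1:40)
  m <- matrix(rlnorm(40 * 6), 40, 6,
              dimnames = list(genes, sprintf("s%d", 1:6)))
  expr <- expression_matrix(m, "fly")
  col <- pathway_collection(tibble::tibble(
    pathway_id = rep(c("P1", "P2", "P3"), each = 5), species = "fly",
    gene = genes[1:15]))
  raw <- score_matrix(expr, col)$scores
  nrm <- score_matrix(expr, col, normalize = TRUE)$scores
  expect_equal(range(nrm), c(0, 1))
  expect_equal(nrm, (raw - min(raw)) / diff(range(raw)),
               tolerance = 1e-12)
})

test_that("score TSV round trip preserves values and params", {
  set.seed(5)
  genes <- sprintf("g%02d", 1:30)
  expr <- expression_matrix(
    matrix(rlnorm(30 * 4), 30, 4,
           dimnames = list(genes, paste0("s", 1:4))), "fly")
  col <- pathway_collection(tibble::tibble(
    pathway_id = rep(c("P1", "P2"), each = 6), species = "fly",
    gene = genes[1:12]))
  sm <- score_matrix(expr, col, alpha = 0.5)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_scores_tsv(sm, tmp)
  back <- read_scores_tsv(tmp)
  expect_equal(back$scores, sm$scores, tolerance = 1e-12)
  expect_equal(back$params$alpha, 0.5)
  expect_equal(back$params$species, "fly")
})

test_that("timecourse slope equals the closed-form least-squares estimate", {
  expect_equal(timecourse_slope(c(0, 1), c(0, 1)), 1)
  expect_equal(timecourse_slope(c(4, 8, 14), c(2, 2, 2)), 0)
  x <- c(4, 8, 14); y <- c(1, 2, 4)
  closed <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(timecourse_slope(x, y), closed, tolerance = 1e-12)
  expect_error(timecourse_slope(c(2, 2), c(1, 5)), "identical")
  expect_error(timecourse_slope(1, 1), ">= 2")
})
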