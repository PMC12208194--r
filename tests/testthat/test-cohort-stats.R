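test_that("Fisher exact P matches exhaustive enumeration and closed forms", {
  bal <- fisher_exact(5, 5, 5, 5)
  expect_equal(bal$odds_ratio, 1)
  expect_equal(bal$p, 1)
  ext <- fisher_exact(10, 0, 0, 10)
  expect_equal(ext$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(ext$odds_ratio, Inf)
  set.seed(31)
  for (i in 1:150) {
    cells <- as.vector(stats::rmultinom(1, sample(4:60, 1), rep(1/4, 4)))
    if (any(c(cells[1] + cells[2], cells[3] + cells[4],
              cells[1] + cells[3], cells[2] + cells[4]) == 0)) next
    got <- fisher_exact(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got$p,
                 oracle_fisher_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
    expect_equal(got$odds_ratio,
                 if (cells[2] * cells[3] == 0) Inf
                 else cells[1] * cells[4] / (cells[2] * cells[3]))
  }
})

test_that("Fisher exact is symmetric under simultaneous row and column swaps", {
  set.seed(32)
  for (i in 1:25) {
    x <- sample(0:12, 4, replace = TRUE)
    if (any(c(x[1] + x[2], x[3] + x[4], x[1] + x[3], x[2] + x[4]) == 0))
      next
    a <- fisher_exact(x[1], x[2], x[3], x[4])
    b <- fisher_exact(x[4], x[3], x[2], x[1])    # both rows and cols swapped
    expect_equal(a$p, b$p, tolerance = 1e-12)
    expect_equal(a$odds_ratio, b$odds_ratio)
  }
  # zero margin: nothing testable
  z <- fisher_exact(0, 0, 4, 6)
  expect_equal(z$p, 1)
  expect_true(z$undefined_or)
  expect_error(fisher_exact(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact(0, 0, 0, 0), "degenerate")
})

make_label_tbl <- function(sample_id, similar) {
  tibble::tibble(sample_id = sample_id,
                 label = ifelse(similar, "similar", "non_similar"))
}

test_that("mutation landscape screens recurrent genes with direction and highlight", {
  cohort <- cohort_table(tibble::tibble(
    sample_id = sprintf("s%02d", 1:20),
    mutation_events = c(list(c("gSim", "gBoth")), list("gSim"),
                        rep(list("gBoth"), 4), rep(list(character(0)), 13),
                        list("gOnce"))))
  labels <- make_label_tbl(cohort$sample_id, c(rep(TRUE, 5), rep(FALSE, 15)))
  res <- mutation_landscape(cohort, labels, alpha_highlight = 0.2)
  # gSim mutated only in similar samples (2 occurrences)
  expect_equal(res$direction[res$gene == "gSim"], "enriched_in_similar")
  expect_equal(res$odds_ratio[res$gene == "gSim"], Inf)
  # singleton gOnce excluded by the recurrence rule; never-mutated absent
  expect_false("gOnce" %in% res$gene)
  expect_true(all(res$a + res$b + res$c + res$d == 20))
  expect_error(mutation_landscape(cohort,
                                  make_label_tbl("zz", TRUE)),
               "no overlap")
})

test_that("a planted enriched mutation attains the minimum P among null genes", {
  set.seed(33)
  hits <- 0L
  for (rep_i in 1:20) {
    n <- 500
    similar <- seq_len(n) <= 35
    p0 <- runif(50, 0.02, 0.15)
    events <- lapply(seq_len(n), function(s) {
      g <- sprintf("mg%03d", which(runif(50) < p0))
      odds <- (0.1 / 0.9) * 8
      p_pl <- if (similar[s]) odds / (1 + odds) else 0.1
      if (runif(1) < p_pl) g <- c(g, "planted")
      g
    })
    cohort <- cohort_table(tibble::tibble(
      sample_id = sprintf("s%03d", seq_len(n)),
      mutation_events = events))
    res <- mutation_landscape(cohort,
                              make_label_tbl(cohort$sample_id, similar))
    if (res$gene[which.min(res$p)] == "planted") hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("group contrasts run Welch on transformed values and handle missing", {
  cohort <- cohort_table(tibble::tibble(
    sample_id = sprintf("s%d", 1:8),
    age = c(1, 2, 3, 1, 2, 3, NA, NA),
    mutation_count = c(2L, 4L, 8L, 2L, 4L, 8L, 0L, 16L)))
  labels <- make_label_tbl(cohort$sample_id,
                           c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                             TRUE, FALSE))
  # identical value lists in both groups -> t = 0, p = 1
  same <- group_contrast(cohort[1:6, ], labels, "age")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # log2 of (2,4,8) vs (2,4,8) -> identical after transform -> t = 0
  lg <- group_contrast(cohort[1:6, ], labels, "mutation_count",
                       transform = "log2")
  expect_equal(lg$t, 0)
  expect_equal(lg$mean_similar, mean(log2(c(2, 4, 8))))
  # zero counts are excluded before log2 with a warning
  expect_warning(
    z <- group_contrast(cohort, labels, "mutation_count",
                        transform = "log2"),
    "non-positive")
  expect_equal(z$n_similar + z$n_other, 7L)
  expect_error(group_contrast(cohort[c(1, 5, 6), ], labels, "age"),
               ">= 2")
})

test_that("Welch t and P match the closed-form computation", {
  set.seed(34)
  x <- rnorm(50, 1); y <- rnorm(50)
  cohort <- cohort_table(tibble::tibble(
    sample_id = sprintf("s%03d", 1:100), age = c(x, y)))
  labels <- make_label_tbl(cohort$sample_id, rep(c(TRUE, FALSE), each = 50))
  got <- group_contrast(cohort, labels, "age")
  want <- oracle_welch(x, y)
  expect_equal(got$t, want$t, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
})

test_that("log-rank statistic matches a hand-built risk-set table", {
  # byte-identical groups -> chi-square 0, p 1
  t0 <- c(3, 5, 8, 12); e0 <- c(1, 0, 1, 1)
  lr <- logrank_test(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 4))
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)
  # group b = group a with doubled times, no censoring, n = 6
  ta <- c(2, 5, 9); tb <- ta * 2
  time <- c(ta, tb); event <- rep(1, 6)
  grp <- rep(c("a", "b"), each = 3)
  got <- logrank_test(time, event, grp)
  expect_equal(got$chi_square,
               oracle_logrank_chisq(time, event, grp == "a"),
               tolerance = 1e-10)
  expect_error(logrank_test(c(1, 2), c(0, 0), c("a", "b")), "no events")
  expect_error(logrank_test(c(-1, 2), c(1, 1), c("a", "b")), ">= 0")
})

test_that("cohort TSV round trip keeps semicolon-joined mutation lists", {
  cohort <- cohort_table(tibble::tibble(
    sample_id = c("s1", "s2"), age = c(40.5, NA),
    mean_beta = c(0.41, 0.62),
    mutation_events = list(c("TP53", "IDH1"), character(0)),
    survival_time = c(120, 800), event = c(TRUE, FALSE),
    cancer_type = c("glioma", "thymoma")))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_tsv(cohort, tmp)
  back <- read_cohort_tsv(tmp)
  expect_equal(back$mutation_events[[1]], c("TP53", "IDH1"))
  expect_equal(back$mutation_events[[2]], character(0))
  expect_equal(back$age, cohort$age)
  expect_equal(back$mean_beta, cohort$mean_beta, tolerance = 1e-12)
  expect_error(cohort_table(tibble::tibble(sample_id = c("a", "a"))),
               "duplicate")
  expect_error(cohort_table(tibble::tibble(sample_id = "a",
                                           mean_beta = 1.2)),
               "\\[0, 1\\]")
})
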