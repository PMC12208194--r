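make_scores <- function(m, species = "human") {
  structure(list(scores = m,
                 params = list(alpha = 0.25, tie_rule = "average",
                               normalize = FALSE, species = species)),
            class = "enrichment_scores")
}

test_that("build_reference aggregates fly samples with recorded provenance", {
  set.seed(11)
  m <- matrix(rnorm(72 * 3), 72, 3,
              dimnames = list(sprintf("PW%02d", 1:72), c("f1", "f2", "f3")))
  fs <- make_scores(m, "fly")
  ref1 <- build_reference(fs, samples = "f2")
  expect_equal(ref1$scores, unname(m[, "f2"]))
  two_m <- m[, 1:2] * 0
  two_m[, 2] <- 2                      # per-pathway scores (0, 2) -> mean 1
  two <- build_reference(make_scores(two_m, "fly"))
  expect_equal(two$scores, rep(1, 72))
  # median vs mean on a 3-sample fixture with an outlier column
  m[, 3] <- m[, 3] + 50
  fs <- make_scores(m, "fly")
  expect_equal(build_reference(fs, aggregate = "median")$scores,
               unname(apply(m, 1, median)))
  expect_equal(build_reference(fs, aggregate = "mean")$scores,
               unname(rowMeans(m)))
  expect_equal(build_reference(fs)$provenance,
               list(samples = c("f1", "f2", "f3"), aggregate = "mean"))
  expect_error(build_reference(fs, samples = character(0)), "empty")
  expect_error(build_reference(fs, samples = "nope"), "not in the score")
})

test_that("pearson similarity reproduces r extremes and the t-transform P", {
  set.seed(12)
  ref <- build_reference(make_scores(
    matrix(rnorm(72), 72, 1, dimnames = list(sprintf("PW%02d", 1:72), "f1")),
    "fly"))
  self <- pearson_similarity(ref$scores, ref)
  expect_equal(self$r, 1)
  expect_equal(self$p_raw, .Machine$double.xmin)  # underflow-safe floor
  anti <- pearson_similarity(-2 * ref$scores + 3, ref)
  expect_equal(anti$r, -1)
  expect_error(pearson_similarity(rep(1, 72), ref), "zero variance")
  # quadrature oracle for the t CDF on random K = 72 pairs
  for (i in 1:30) {
    x <- rnorm(72)
    got <- pearson_similarity(x, ref)
    expect_equal(got$p_raw, oracle_pearson_p(got$r, 72),
                 tolerance = 1e-10)
  }
  # named vectors are aligned by pathway id before correlating
  x <- rnorm(72); names(x) <- sprintf("PW%02d", 1:72)
  shuf <- sample(x)
  expect_equal(pearson_similarity(shuf, ref)$r,
               pearson_similarity(x, ref)$r)
  bad <- x; names(bad)[1] <- "PWXX"
  expect_error(pearson_similarity(bad, ref), "mismatch")
})

test_that("BH and Bonferroni adjustments match an independent step-up", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_pvalues(0.2), 0.2)          # m = 1 unchanged
  expect_equal(adjust_pvalues(c(0.01, 0.5), "bonferroni"), c(0.02, 1))
  set.seed(13)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjust_pvalues(p), oracle_bh(p), tolerance = 1e-14)
  }
  expect_error(adjust_pvalues(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("classification applies the adjusted-P threshold and sign rule", {
  set.seed(14)
  k <- 72
  pw <- sprintf("PW%02d", 1:k)
  refv <- rnorm(k)
  ref <- build_reference(make_scores(
    matrix(refv, k, 1, dimnames = list(pw, "f1")), "fly"))
  q <- cbind(strong = refv + rnorm(k, sd = 0.3),    # similar
             anti = -refv + rnorm(k, sd = 0.3),     # anti-correlated
             null = rnorm(k))
  rownames(q) <- pw
  cls <- classify_cohort(make_scores(q), ref)
  expect_s3_class(cls, "similarity_tbl")
  expect_equal(cls$label[cls$sample_id == "strong"], "similar")
  # strongly negative r stays non-similar however small the P
  expect_lt(cls$r[cls$sample_id == "anti"], -0.9)
  expect_equal(cls$label[cls$sample_id == "anti"], "non_similar")
  expect_equal(cls$label[cls$sample_id == "null"], "non_similar")
  expect_true(all(cls$p_adj >= cls$p_raw))
  # dropping the sign rule lets the anti-correlated sample through
  cls2 <- classify_cohort(make_scores(q), ref, require_positive = FALSE)
  expect_equal(cls2$label[cls2$sample_id == "anti"], "similar")
  # glance summarizes counts and parameters
  g <- glance(cls)
  expect_equal(g$n_total, 3L)
  expect_equal(g$n_similar, sum(cls$label == "similar"))
  expect_equal(g$threshold, 1e-6)
  # pathway set mismatch errors with the symmetric difference
  q2 <- q; rownames(q2)[1] <- "PWXX"
  expect_error(classify_cohort(make_scores(q2), ref), "PWXX")
})

test_that("similar-count is monotone in threshold and affine-invariant", {
  set.seed(15)
  k <- 72; pw <- sprintf("PW%02d", 1:k)
  refv <- rnorm(k)
  ref <- build_reference(make_scores(
    matrix(refv, k, 1, dimnames = list(pw, "f1")), "fly"))
  q <- sapply(1:40, function(i)
    refv * runif(1, 0, 1.5) + rnorm(k, sd = runif(1, 0.3, 2)))
  dimnames(q) <- list(pw, sprintf("s%02d", 1:40))
  counts <- sapply(c(1e-8, 1e-6, 1e-4, 1e-2, 1),
                   function(th) glance(classify_cohort(
                     make_scores(q), ref, threshold = th))$n_similar)
  expect_true(all(diff(counts) >= 0))
  # a shared affine transform of all score vectors changes nothing
  cls_a <- classify_cohort(make_scores(q), ref)
  cls_b <- classify_cohort(make_scores(q * 3.7 - 2), ref)
  expect_equal(cls_b$r, cls_a$r, tolerance = 1e-12)
  expect_equal(cls_b$label, cls_a$label)
})

test_that("similarity TSV serialization keeps 6-significant-digit probabilities", {
  set.seed(16)
  k <- 10; pw <- sprintf("PW%02d", 1:k)
  ref <- build_reference(make_scores(
    matrix(rnorm(k), k, 1, dimnames = list(pw, "f1")), "fly"))
  q <- matrix(rnorm(k * 3), k, 3, dimnames = list(pw, c("a", "b", "c")))
  cls <- classify_cohort(make_scores(q), ref)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_tsv(cls, tmp)
  back <- read.delim(tmp)
  expect_equal(back$sample_id, cls$sample_id)
  expect_equal(back$p_raw, as.numeric(sprintf("%.6e", cls$p_raw)))
  expect_equal(back$label, cls$label)
})
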