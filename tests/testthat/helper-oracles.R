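# Independent oracle implementations used across the suite. Each one
# materializes the textbook definition directly (running sums, exhaustive
# enumeration, closed forms) and shares no code with the package internals.

# ssGSEA: materialize both cumulative distributions explicitly and sum
# their difference over every ranked position.
oracle_enrichment_score <- function(values, gene_set, alpha,
                                    tie_rule = "average") {
  n <- length(values)
  member <- names(values) %in% gene_set
  ord <- order(-values)
  memb <- member[ord]
  w <- if (tie_rule == "average")
    rank(values, ties.method = "average")[ord] else n:1
  wa <- w^alpha
  p_g <- cumsum(wa * memb) / sum(wa * memb)
  p_ng <- cumsum(!memb) / (n - sum(memb))
  sum(p_g - p_ng)
}

# two-sided Pearson P by numerical integration of the t density
oracle_pearson_p <- function(r, k) {
  tstat <- abs(r) * sqrt((k - 2) / (1 - r^2))
  dens <- function(x) stats::dt(x, df = k - 2)
  2 * stats::integrate(dens, lower = tstat, upper = Inf,
                       rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# independently coded step-up BH (explicit loop, no p.adjust)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  pmin(q, 1)[order(o)]
}

# two-sided Fisher P by exhaustive enumeration of all tables with the
# observed margins, summing probabilities at most the observed one
# (standard minimum-likelihood convention, relative slack 1e-7)
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, ks) * choose(r2, c1 - ks) / choose(r1 + r2, c1)
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-sided rank-sum P by enumeration of all rank assignments (no ties)
oracle_wilcoxon_p <- function(a, b) {
  na <- length(a); n <- na + length(b)
  stopifnot(!anyDuplicated(c(a, b)))
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  subsets <- utils::combn(n, na)
  us <- colSums(matrix(seq_len(n)[subsets], nrow = na)) -
    na * (na + 1) / 2
  mu <- na * (n - na) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Welch t-test from the textbook formulas
oracle_welch <- function(x, y) {
  vx <- stats::var(x) / length(x); vy <- stats::var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df = df))
}

# two-group log-rank chi-square from an explicit risk-set table
oracle_logrank_chisq <- function(time, event, in_g1) {
  ts <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in ts) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & in_g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & in_g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# small helper: named abundance vector with distinct values
random_sample_values <- function(n, prefix = "g") {
  v <- stats::rlnorm(n)
  names(v) <- sprintf("%s%03d", prefix, seq_len(n))
  v
}

# tiny three-row conserved collection used in several io tests
toy_collection <- function() {
  pathway_collection(tibble::tibble(
    pathway_id = c("P1", "P1", "P1", "P1"),
    species = c("fly", "fly", "human", "human"),
    gene = c("gA", "gB", "GA", "GB")))
}
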