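# Shared small fixtures, built once per test run.

# A modest cohort with boosted carrier frequencies so every group has
# carriers of both sexes even at desk scale.
test_config <- function(seed = 101, n = 10000) {
  sim_config(
    n_males = n, n_females = n,
    carrier_freq = c(ALL_P = 0.01, ALL_C = 0.02, ALL_U = 0.005),
    seed = seed
  )
}

the_cohort <- local({
  co <- generate_cohort(test_config())
  score_cohort(co)
})

# Brute-force Benjamini-Hochberg step-up oracle: the adjusted p-value of
# hypothesis i is the smallest level alpha at which the step-up procedure
# (largest k with p_(k) <= k * alpha / m) rejects H_i. Candidate alphas are
# enumerated exhaustively from the p-values themselves.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  candidates <- sort(unique(pmin(ps * m / seq_len(m), 1)))
  rejected_at <- rep(NA_real_, m)
  for (alpha in candidates) {
    k <- which(ps <= seq_len(m) * alpha / m)
    if (!length(k)) next
    kmax <- max(k)
    newly <- seq_len(kmax)[is.na(rejected_at[seq_len(kmax)])]
    rejected_at[newly] <- alpha
  }
  out <- numeric(m)
  out[o] <- ifelse(is.na(rejected_at), 1, rejected_at)
  out
}

# Trapezoidal area under the empirical ROC curve (threshold sweep oracle).
auc_trapezoid <- function(scores, labels) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[labels == 0] >= t), numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Exhaustive Youden scan over a dense threshold grid (oracle for
# youden_cutoff's midpoint scan).
youden_bruteforce <- function(scores, labels) {
  grid <- sort(unique(c(scores - 1e-9, scores + 1e-9,
                        (min(scores) - 1):(max(scores) + 1))))
  j <- vapply(grid, function(t) {
    mean(scores[labels == 1] > t) + mean(scores[labels == 0] <= t) - 1
  }, numeric(1))
  max(j)
}

cv_covariates <- c("age", "diabetes", "dyslipidemia", "hypertension",
                   "obesity", "smoking")
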