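make_2x2 <- function(a, b, c_, d) {
  # a exposed cases, b exposed non-cases, c_ unexposed cases, d unexposed
  data.frame(
    outcome = c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d)),
    exposure = c(rep(1, a + b), rep(0, c_ + d))
  )
}

test_that("analysis sets are sex-matched and exclude homozygous females", {
  co <- the_cohort
  af <- build_analysis_set(co, "ALL_C", "female")
  n_homo <- sum(co$sex == "female" & co$ac_ALL_C == 2)
  expect_gt(n_homo, 0)  # boosted frequency guarantees some at this seed
  expect_equal(af$excluded_homozygous, n_homo)
  expect_true(all(af$data$sex == "female"))
  expect_true(all(af$data$ac_ALL_C[af$data$exposure == 1] == 1))
  # she appears nowhere: no case or control row carries two alleles
  expect_true(all(af$data$ac_ALL_C != 2))
  # controls carry zero alleles across every analyzed group
  ctrl <- af$data[af$data$exposure == 0, ]
  expect_true(all(ctrl$ac_ALL_P == 0 & ctrl$ac_ALL_C == 0 &
                    ctrl$ac_ALL_U == 0))

  am <- build_analysis_set(co, "ALL_P", "male")
  expect_true(all(am$data$sex == "male"))
  zyg <- classify_zygosity(am$data$sex, am$data$ac_ALL_P)
  expect_false(any(zyg == "heterozygous"))
})

test_that("an all-wild-type cohort yields an empty set with a warning", {
  cfg <- sim_config(n_males = 300, n_females = 300,
                    carrier_freq = c(ALL_P = 0), seed = 4)
  co <- generate_cohort(cfg)
  expect_warning(aset <- build_analysis_set(co, "ALL_P", "male"),
                 "no male carriers")
  expect_true(aset$empty)
  expect_equal(aset$n_cases, 0)
  expect_error(build_analysis_set(co, "NOPE", "male"), "not present")
})

test_that("the unadjusted logistic OR equals the 2x2 cross-product ratio", {
  d <- make_2x2(20, 80, 10, 90)
  res <- fit_logistic(d, "outcome")
  expect_equal(res$effect, (20 * 90) / (80 * 10), tolerance = 1e-6)
  expect_lt(res$ci_low, res$effect)
  expect_gt(res$ci_high, res$effect)

  bal <- fit_logistic(make_2x2(50, 50, 50, 50), "outcome")
  expect_equal(bal$effect, 1, tolerance = 1e-8)
  expect_true(bal$ci_low < 1 && bal$ci_high > 1)

  set.seed(41)
  for (i in 1:12) {
    cells <- sample(5:60, 4, TRUE)
    d <- make_2x2(cells[1], cells[2], cells[3], cells[4])
    res <- fit_logistic(d, "outcome")
    expect_equal(res$effect, (cells[1] * cells[4]) / (cells[2] * cells[3]),
                 tolerance = 1e-6)
  }
})

test_that("covariate adjustment removes pure confounding", {
  set.seed(42)
  n <- 50000
  conf <- rbinom(n, 1, 0.4)
  exposure <- rbinom(n, 1, plogis(-2 + 1.5 * conf))
  outcome <- rbinom(n, 1, plogis(-2 + 1.2 * conf))  # exposure-independent
  d <- data.frame(outcome, exposure, conf)
  crude <- fit_logistic(d, "outcome")
  adj <- fit_logistic(d, "outcome", covariates = "conf")
  expect_gt(crude$effect, 1.1)  # confounding inflates the crude OR
  expect_true(adj$ci_low <= 1 && adj$ci_high >= 1)
})

test_that("complete-case handling drops and counts rows with missing data", {
  d <- make_2x2(20, 80, 10, 90)
  d$outcome[1:5] <- NA
  d$cov <- rnorm(nrow(d))
  d$cov[6:8] <- NA
  res <- fit_logistic(d, "outcome", covariates = "cov")
  expect_equal(res$n_dropped, 8)
  expect_equal(res$n_cases + res$n_controls, nrow(d) - 8)
})

test_that("separation is flagged with infinite bounds, not an error", {
  d <- make_2x2(30, 0, 5, 95)  # no exposed non-cases
  res <- fit_logistic(d, "outcome")
  expect_true(isTRUE(res$separation))
  expect_equal(res$ci_high, Inf)
})

test_that("the proportional-odds fit reduces to logistic on two levels", {
  set.seed(43)
  n <- 4000
  exposure <- rbinom(n, 1, 0.3)
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.7 * exposure + 0.4 * x))
  d <- data.frame(y = y, exposure = exposure, x = x)
  lg <- fit_logistic(d, "y", covariates = "x")
  or_ <- fit_ordinal(d, "y", covariates = "x")
  expect_equal(or_$effect, lg$effect, tolerance = 1e-4)
  expect_equal(or_$p_raw, lg$p_raw, tolerance = 1e-3)
  expect_error(fit_ordinal(data.frame(y = rep(1, 50),
                                      exposure = rbinom(50, 1, 0.5)), "y"),
               "single observed level")
})

test_that("the ordinal fit recovers a known common odds ratio", {
  set.seed(44)
  n <- 50000
  exposure <- rbinom(n, 1, 0.3)
  # proportional-odds data: latent logistic + exposure shift of log(2)
  latent <- rlogis(n) + log(2) * exposure
  y <- cut(latent, c(-Inf, -1, 1, 2.5, Inf), labels = FALSE)
  d <- data.frame(y = y, exposure = exposure)
  res <- fit_ordinal(d, "y")
  expect_true(res$ci_low <= 2 && res$ci_high >= 2)
  expect_lt(abs(log(res$effect) - log(2)), 0.15)
})

test_that("linear fits recover slopes and honor statin adjustment", {
  set.seed(45)
  n <- 10000
  exposure <- rbinom(n, 1, 0.3)
  y <- 2 * exposure + rnorm(n)
  d <- data.frame(y = y, exposure = exposure,
                  statin_use = rbinom(n, 1, 0.2))
  res <- fit_linear(d, "y")
  se <- (res$ci_high - res$effect) / qnorm(0.975)
  expect_lt(abs(res$effect - 2), 4 * se)
  expect_false("statin_use" %in% res$covariates)

  res2 <- fit_linear(d, "y", statin_adjust = TRUE)
  expect_true("statin_use" %in% res2$covariates)

  d$noise <- rnorm(n)
  res3 <- fit_linear(d, "noise")
  expect_true(res3$ci_low <= 0 && res3$ci_high >= 0)

  expect_error(fit_linear(data.frame(y = rep(1, 20),
                                     exposure = rbinom(20, 1, 0.5)), "y"),
               "zero variance")
  d$dup <- d$exposure
  expect_error(fit_linear(d, "y", covariates = "dup"), "collinear")
})

test_that("from-scratch BH matches hand-derived values and both oracles", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.011, 0.02, 0.04, 0.5)),
               c(0.025, 0.0275, 1 / 30, 0.05, 0.5), tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(46)
  grid <- c(0.001, 0.005, 0.01, 0.02, 0.04, 0.049, 0.05, 0.2, 0.5, 0.9, 1)
  for (m in 1:6) {
    for (i in 1:12) {
      p <- sample(grid, m, replace = TRUE)
      adj <- bh_adjust(p)
      expect_equal(adj, p.adjust(p, "BH"), tolerance = 1e-12)
      expect_equal(adj, bh_bruteforce(p), tolerance = 1e-12)
      expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
      o <- order(p)
      expect_true(all(diff(adj[o]) >= -1e-15))  # nondecreasing in sorted order
    }
  }
})

test_that("VIFs follow the 1/(1-R^2) closed form", {
  set.seed(47)
  # exactly orthogonal, centered predictors
  X <- stats::poly(1:40, 3)
  v <- vif(X)
  expect_equal(unname(v), rep(1, 3), tolerance = 1e-10)

  x1 <- rnorm(200)
  x2 <- x1 + rnorm(200, sd = 0.01)
  x3 <- rnorm(200)
  v2 <- vif(cbind(x1, x2, x3))
  expect_gt(v2[["x1"]], 100)
  expect_gt(v2[["x2"]], 100)
  expect_lt(v2[["x3"]], 2)

  expect_error(vif(cbind(x1 = 1:3)), "two predictors")
  expect_error(vif(matrix(rnorm(6), 2, 3)), "more rows")
  # exact collinearity flagged as infinite
  v3 <- vif(cbind(a = x1, b = 2 * x1, c = x3))
  expect_true(is.infinite(v3[["a"]]) && is.infinite(v3[["b"]]))
})

test_that("VIFs agree with an established implementation", {
  skip_if_not_installed("car")
  set.seed(48)
  d <- data.frame(y = rnorm(300), a = rnorm(300), b = rnorm(300))
  d$c <- 0.6 * d$a + rnorm(300, sd = 0.5)
  ours <- vif(d[c("a", "b", "c")])
  theirs <- car::vif(lm(y ~ a + b + c, d))
  expect_equal(unname(ours), unname(theirs[c("a", "b", "c")]),
               tolerance = 1e-8)
})

test_that("adjusted association sets carry BH-corrected p-values", {
  res <- suppressWarnings(run_associations(the_cohort))
  expect_true(all(res$p_adjusted >= res$p_raw - 1e-15))
  expect_true(all(res$p_adjusted <= 1))
  expect_true(all(res$ci_low <= res$effect & res$effect <= res$ci_high))
  expect_setequal(unique(res$sex), c("male", "female"))
  # pathogenic carriers show the FD phenotype signal at this effect size
  allp_m <- res[res$group == "ALL_P" & res$sex == "male", ]
  expect_gt(allp_m$effect, 1)
})

test_that("stratified models keep carriers in-stratum against full controls", {
  co <- the_cohort
  cv <- fit_cv_model(co)
  co <- cv_score_and_stratify(cv, co)
  strat <- suppressMessages(run_stratified(co, groups = c("ALL_P", "ALL_C")))
  expect_true(all(strat$cv_stratum %in% c("high", "low")))
  # the control denominator is the full same-sex wild-type population
  byg <- split(strat, list(strat$group, strat$sex))
  for (b in byg) {
    if (nrow(b) == 2) expect_equal(b$n_controls[1], b$n_controls[2])
  }
  # stratified models are unadjusted by design
  expect_true(all(strat$model == "logistic"))
})
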