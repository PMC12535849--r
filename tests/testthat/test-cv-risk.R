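# direct logistic simulation, independent of the cohort generator
simulate_logistic_frame <- function(n, beta, seed) {
  set.seed(seed)
  d <- data.frame(
    age = sample(40:70, n, TRUE),
    diabetes = rbinom(n, 1, 0.10),
    dyslipidemia = rbinom(n, 1, 0.15),
    hypertension = rbinom(n, 1, 0.30),
    obesity = rbinom(n, 1, 0.25),
    smoking = rbinom(n, 1, 0.45)
  )
  eta <- beta[["intercept"]] + as.matrix(d) %*% beta[names(d)]
  d$fdf_high <- rbinom(n, 1, plogis(eta))
  d
}

test_that("the CV model recovers known generating coefficients", {
  beta <- c(intercept = -6, age = 0.05, diabetes = log(1.8),
            dyslipidemia = log(1.4), hypertension = log(2),
            obesity = log(1.5), smoking = log(1.5))
  d <- simulate_logistic_frame(100000, beta, seed = 31)
  m <- fit_cv_model(d)
  se <- summary(m$fit)$coefficients[, "Std. Error"]
  est <- coef(m$fit)
  truth <- c(beta[["intercept"]], beta[cv_covariates])
  expect_true(all(abs(est - truth) < 4 * se))
  expect_equal(m$score_threshold, 1.92)
})

test_that("a null outcome yields near-zero coefficients", {
  beta <- c(intercept = -2.5, age = 0, diabetes = 0, dyslipidemia = 0,
            hypertension = 0, obesity = 0, smoking = 0)
  d <- simulate_logistic_frame(60000, beta, seed = 32)
  m <- fit_cv_model(d)
  co <- summary(m$fit)$coefficients
  expect_true(all(abs(co[-1, "Estimate"]) < 4 * co[-1, "Std. Error"]))
})

test_that("degenerate CV-model inputs error", {
  d <- simulate_logistic_frame(500, c(intercept = -2, age = 0, diabetes = 0,
                                      dyslipidemia = 0, hypertension = 0,
                                      obesity = 0, smoking = 0), seed = 33)
  d$fdf_high <- 0
  expect_error(fit_cv_model(d), "constant outcome")
  expect_error(fit_cv_model(d[1:8, ]), "too few")
})

test_that("stratification puts exactly a quarter of distinct scores high", {
  beta <- c(intercept = -3, age = 0.06, diabetes = 0.5, dyslipidemia = 0.3,
            hypertension = 0.7, obesity = 0.4, smoking = 0.4)
  d <- simulate_logistic_frame(5000, beta, seed = 34)
  m <- fit_cv_model(d)
  # 100 distinct uniform scores -> exactly 25 above the 75th percentile
  ref <- data.frame(age = seq(40, 70, length.out = 100), diabetes = 0,
                    dyslipidemia = 0, hypertension = 0, obesity = 0,
                    smoking = 0, fdf_high = 0)
  s <- cv_score_and_stratify(m, ref)
  expect_equal(sum(s$cv_stratum == "high"), 25)
  expect_equal(sum(s$cv_stratum == "low"), 75)

  # all-equal scores -> everyone low (strict inequality), with a warning
  tied <- ref
  tied$age <- 55
  expect_warning(s2 <- cv_score_and_stratify(m, tied), "identical")
  expect_true(all(s2$cv_stratum == "low"))

  # order-preserving rescale of the coefficients leaves strata unchanged
  m2 <- m
  m2$fit$coefficients <- 2 * m$fit$coefficients + 0.3
  s3 <- cv_score_and_stratify(m2, ref)
  expect_identical(s$cv_stratum, s3$cv_stratum)
})

test_that("subjects with missing covariates are left unstratified", {
  beta <- c(intercept = -3, age = 0.06, diabetes = 0.5, dyslipidemia = 0.3,
            hypertension = 0.7, obesity = 0.4, smoking = 0.4)
  d <- simulate_logistic_frame(2000, beta, seed = 35)
  m <- fit_cv_model(d)
  d$age[1:10] <- NA
  expect_message(s <- cv_score_and_stratify(m, d), "unstratified")
  expect_true(all(is.na(s$cv_stratum[1:10])))
  expect_true(all(!is.na(s$cv_stratum[-(1:10)])))
  # partition: every scored subject is in exactly one stratum
  expect_true(all(s$cv_stratum[-(1:10)] %in% c("high", "low")))
})

test_that("ROC metrics match their closed forms and the trapezoid oracle", {
  sep <- roc_metrics(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(sep$auc, 1)

  set.seed(36)
  sc <- rnorm(20000)
  lb <- rbinom(20000, 1, 0.5)  # labels independent of scores
  expect_lt(abs(roc_metrics(sc, lb)$auc - 0.5), 0.02)

  direct <- roc_metrics(c(1, 2, 3, 4), c(0, 0, 1, 1), threshold = 2.5)
  expect_equal(direct$sensitivity, 1)
  expect_equal(direct$specificity, 1)

  for (i in 1:10) {
    s <- sample(1:6, 40, TRUE)  # heavy ties
    l <- rbinom(40, 1, 0.4)
    if (length(unique(l)) < 2) next
    expect_equal(roc_metrics(s, l)$auc, auc_trapezoid(s, l),
                 tolerance = 1e-12)
    # AUC invariant under strictly monotone transforms
    expect_equal(roc_metrics(exp(s / 2), l)$auc, roc_metrics(s, l)$auc)
  }
  expect_error(roc_metrics(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(37)
  s <- c(rnorm(300), rnorm(300, 0.8))
  l <- rep(0:1, each = 300)
  ours <- roc_metrics(s, l)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-10)
})
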