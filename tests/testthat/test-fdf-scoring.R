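test_that("renal scoring follows the KDIGO-style bands with the max rule", {
  map <- default_scoring_map()
  expect_equal(as.numeric(score_renal(100, 10, map)), 0)
  expect_equal(as.numeric(score_renal(25, 10, map)), 4)
  expect_equal(as.numeric(score_renal(100, 400, map)), 4)
  expect_equal(as.numeric(score_renal(75, 100, map)), 1)
  expect_equal(as.numeric(score_renal(45, 100, map)), 2)
  expect_error(score_renal(-1, 10), "negative")
  # missing labs make the renal score missing, never zero
  expect_true(is.na(score_renal(NA, 10)))
  expect_true(is.na(score_renal(100, NA)))
  # sub-components are exposed for per-component analyses
  r <- score_renal(c(75, 100), c(10, 400))
  expect_equal(attr(r, "egfr_points"), c(1, 0))
  expect_equal(attr(r, "uacr_points"), c(0, 4))
})

test_that("flag domains score the highest severity present, not a sum", {
  map <- default_scoring_map()
  w <- map$cardiac_weights
  expect_equal(score_flag_domain(0, w, map), 0)
  expect_equal(score_flag_domain(4, w, map), 4)
  expect_equal(score_flag_domain(c(2, NA, 3), w, map), c(2, 0, 3))
  expect_error(score_flag_domain(7, w, map), "severity")
})

test_that("pain scoring imputes the lowest category for all-missing items", {
  map <- default_scoring_map()
  res <- score_pain(data.frame(a = NA, b = NA, c = NA), map$pain_weights, map)
  expect_equal(res$points, 0)
  expect_true(res$imputed)
  res2 <- score_pain(data.frame(a = 3, b = 0, c = NA), map$pain_weights, map)
  expect_equal(res2$points, 4)  # maximal chronic-pain response
  expect_false(res2$imputed)
  res3 <- score_pain(data.frame(a = NA, b = 1, c = NA), map$pain_weights, map)
  expect_equal(res3$points, 1)
  expect_false(res3$imputed)
})

test_that("FDF total and flag behave at the dichotomization boundary", {
  map <- default_scoring_map()
  t0 <- total_fdf(data.frame(pain = 0, renal = 0, cardiac = 0,
                             cerebrovascular = 0), map)
  expect_equal(t0$total, 0)
  expect_false(t0$high_flag)
  # one maxed domain never crosses the threshold
  t4 <- total_fdf(data.frame(pain = 4, renal = 0, cardiac = 0,
                             cerebrovascular = 0), map)
  expect_equal(t4$total, 4)
  expect_false(t4$high_flag)
  t5 <- total_fdf(data.frame(pain = 4, renal = 1, cardiac = 0,
                             cerebrovascular = 0), map)
  expect_equal(t5$total, 5)
  expect_true(t5$high_flag)
  expect_error(total_fdf(data.frame(pain = 5, renal = 0, cardiac = 0,
                                    cerebrovascular = 0), map), "outside")
})

test_that("exhaustively, a high flag means total > 4 and >= 2 involved domains", {
  map <- default_scoring_map()
  grid <- expand.grid(pain = 0:4, renal = 0:4, cardiac = 0:4,
                      cerebrovascular = 0:4)
  res <- total_fdf(grid, map)
  expect_equal(nrow(res), 5^4)
  expect_identical(res$high_flag, res$total > 4)
  nonzero <- rowSums(grid > 0)
  expect_true(all(nonzero[res$high_flag] >= 2))
  # monotonicity: raising any one domain never lowers the total or
  # flips the flag from true to false
  bump <- grid
  bump$pain <- pmin(bump$pain + 1, 4)
  res_b <- total_fdf(bump, map)
  expect_true(all(res_b$total >= res$total))
  expect_true(all(res_b$high_flag >= res$high_flag))
})

test_that("Youden cutoff matches its examples and a brute-force scan", {
  scores <- c(rep(0, 10), rep(10, 10))
  labels <- rep(c(0, 1), each = 10)
  y <- youden_cutoff(scores, labels)
  expect_equal(y$threshold, 5)
  expect_equal(y$J, 1)

  y2 <- youden_cutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(y2$threshold, 2.5)
  expect_equal(y2$J, 1)

  set.seed(8)
  same <- c(rnorm(4000), rnorm(4000))
  lab <- rep(0:1, each = 4000)
  y3 <- youden_cutoff(same, lab)
  expect_lt(y3$J, 0.06)

  for (i in 1:15) {
    sc <- sample(0:8, 60, replace = TRUE)
    lb <- rbinom(60, 1, plogis((sc - 4) / 2))
    if (length(unique(lb)) < 2) next
    expect_equal(youden_cutoff(sc, lb)$J, youden_bruteforce(sc, lb),
                 tolerance = 1e-12)
  }
  expect_error(youden_cutoff(1:5, rep(1, 5)), "both classes")
})

test_that("cohort scoring attaches consistent FDF columns", {
  co <- the_cohort
  expect_true(all(c("fdf_pain", "fdf_renal", "fdf_cardiac",
                    "fdf_cerebrovascular", "fdf_total", "fdf_high") %in%
                    names(co)))
  ok <- !is.na(co$fdf_total)
  expect_equal(co$fdf_total[ok],
               (co$fdf_pain + co$fdf_renal + co$fdf_cardiac +
                  co$fdf_cerebrovascular)[ok])
  expect_true(all(co$fdf_total[ok] >= 0 & co$fdf_total[ok] <= 16))
  expect_identical(co$fdf_high[ok], co$fdf_total[ok] > 4)
  # pain imputation rate equals the all-items-missing rate
  pain_cols <- grep("^pain_[0-9]+$", names(co), value = TRUE)
  allmiss <- unname(rowSums(!is.na(co[pain_cols])) == 0)
  expect_identical(co$pain_imputed, allmiss)
  expect_true(all(co$fdf_pain[allmiss] == 0))
})
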