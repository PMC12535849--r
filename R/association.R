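#' Build a sex-matched analysis set for one variant group
#'
#' Cases are hemizygous males or heterozygous females of the group;
#' controls are same-sex subjects carrying zero variants across \emph{all}
#' analyzed groups (wild type for the whole gene). Homozygous females are
#' counted and excluded entirely; carriers of other groups are excluded from
#' the control pool by the all-zero requirement.
#'
#' @param cohort cohort data.frame with \code{ac_<group>} allele-count
#'   columns.
#' @param group variant group name (e.g. \code{"ALL_P"}).
#' @param sex \code{"male"} or \code{"female"}.
#' @return Object of class \code{analysis_set}: \code{data} (rows with an
#'   \code{exposure} 0/1 column), \code{n_cases}, \code{n_controls},
#'   \code{excluded_homozygous}, \code{group}, \code{sex}, \code{empty}.
#' @export
build_analysis_set <- function(cohort, group, sex = c("male", "female")) {
  sex <- match.arg(sex)
  col <- paste0("ac_", group)
  if (!col %in% names(cohort)) {
    stop(sprintf("group '%s' not present in the cohort", group),
         call. = FALSE)
  }
  ac_cols <- grep("^ac_", names(cohort), value = TRUE)
  zyg <- classify_zygosity(cohort$sex, cohort[[col]])
  in_sex <- cohort$sex == sex
  homoz <- in_sex & zyg == "homozygous"
  carrier_level <- if (sex == "male") "hemizygous" else "heterozygous"
  case <- in_sex & zyg == carrier_level
  wild_all <- rowSums(as.matrix(cohort[ac_cols])) == 0
  control <- in_sex & wild_all
  dat <- cohort[case | control, , drop = FALSE]
  dat$exposure <- as.integer(case[case | control])
  n_cases <- sum(case)
  if (n_cases == 0L) {
    warning(sprintf("no %s carriers of group '%s': empty analysis set",
                    sex, group), call. = FALSE)
  }
  structure(
    list(data = dat, n_cases = n_cases, n_controls = sum(control),
         excluded_homozygous = sum(homoz), group = group, sex = sex,
         empty = n_cases == 0L),
    class = "analysis_set")
}

wald_result <- function(est, se, p, exp_scale, n_cases, n_controls,
                        n_dropped, model, covariates, z = stats::qnorm(0.975)) {
  lo <- est - z * se
  hi <- est + z * se
  if (exp_scale) {
    eff <- exp(est); lo <- exp(lo); hi <- exp(hi)
  } else {
    eff <- est
  }
  structure(
    list(effect = eff, ci_low = lo, ci_high = hi, p_raw = p,
         p_adjusted = NA_real_, n_cases = n_cases, n_controls = n_controls,
         n_dropped = n_dropped, model = model, covariates = covariates,
         conf_level = "2.5-97.5 percent (Wald)"),
    class = "association_result")
}

#' @export
as.data.frame.association_result <- function(x, ...) {
  data.frame(model = x$model, effect = x$effect, ci_low = x$ci_low,
             ci_high = x$ci_high, p_raw = x$p_raw,
             p_adjusted = x$p_adjusted, n_cases = x$n_cases,
             n_controls = x$n_controls, n_dropped = x$n_dropped,
             covariates = paste(x$covariates, collapse = "+"),
             stringsAsFactors = FALSE)
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s model: effect %.4g [%.4g, %.4g], p = %.3g (BH %.3g)\n",
              x$model, x$effect, x$ci_low, x$ci_high, x$p_raw,
              x$p_adjusted))
  cat(sprintf("  cases %d, controls %d, dropped %d; covariates: %s\n",
              x$n_cases, x$n_controls, x$n_dropped,
              if (length(x$covariates)) paste(x$covariates, collapse = ", ")
              else "none"))
  invisible(x)
}

model_frame_cc <- function(data, outcome, exposure, covariates) {
  vars <- c(outcome, exposure, covariates)
  miss <- setdiff(vars, names(data))
  if (length(miss)) {
    stop(sprintf("data lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  dat <- data[vars]
  cc <- stats::complete.cases(dat)
  list(data = dat[cc, , drop = FALSE], n_dropped = sum(!cc))
}

#' Logistic carrier-versus-control association
#'
#' Maximum-likelihood logistic regression of a binary outcome on exposure
#' (carrier status) plus covariates; effect reported as the odds ratio with
#' the interval formed by the 2.5 and 97.5 percent points of the
#' coefficient's sampling distribution, exponentiated. Rows with any missing
#' variable are dropped and counted. (Quasi-)separation is flagged by
#' infinite interval bounds rather than an error.
#'
#' @param data data.frame of analysis rows.
#' @param outcome binary outcome column name.
#' @param exposure exposure column name (0/1).
#' @param covariates covariate column names.
#' @return An \code{association_result} (OR scale).
#' @export
fit_logistic <- function(data, outcome, exposure = "exposure",
                         covariates = character()) {
  mf <- model_frame_cc(data, outcome, exposure, covariates)
  dat <- mf$data
  if (!nrow(dat)) stop("no complete-case rows", call. = FALSE)
  y <- dat[[outcome]]
  if (length(unique(y)) < 2L) {
    stop("outcome has a single observed class", call. = FALSE)
  }
  form <- stats::reformulate(c(exposure, covariates), response = outcome)
  fit <- suppressWarnings(stats::glm(form, data = dat,
                                     family = stats::binomial()))
  co <- summary(fit)$coefficients
  est <- co[exposure, "Estimate"]
  se <- co[exposure, "Std. Error"]
  p <- co[exposure, "Pr(>|z|)"]
  res <- wald_result(est, se, p, TRUE,
                     n_cases = sum(dat[[exposure]] == 1),
                     n_controls = sum(dat[[exposure]] == 0),
                     n_dropped = mf$n_dropped, model = "logistic",
                     covariates = covariates)
  if (abs(est) > 15 || se > 100) {  # separation marker
    res$ci_low <- 0
    res$ci_high <- Inf
    res$separation <- TRUE
  }
  res
}

#' Proportional-odds ordinal association
#'
#' Fits a proportional-odds model (cumulative-logit, \code{MASS::polr}) and
#' reports the common odds ratio for the exposure with the same interval and
#' complete-case contract as \code{\link{fit_logistic}}. With a two-level
#' outcome the fit reduces to binary logistic regression.
#'
#' @inheritParams fit_logistic
#' @return An \code{association_result} (OR scale).
#' @export
fit_ordinal <- function(data, outcome, exposure = "exposure",
                        covariates = character()) {
  mf <- model_frame_cc(data, outcome, exposure, covariates)
  dat <- mf$data
  y <- dat[[outcome]]
  if (length(unique(y[!is.na(y)])) < 2L) {
    stop("ordinal outcome has a single observed level", call. = FALSE)
  }
  dat[[outcome]] <- factor(y, ordered = TRUE)
  form <- stats::reformulate(c(exposure, covariates), response = outcome)
  if (nlevels(droplevels(dat[[outcome]])) == 2L) {
    # the two-level cumulative-logit model is exactly binary logistic
    dat[[outcome]] <- as.integer(dat[[outcome]]) - 1L
    fit <- suppressWarnings(stats::glm(form, data = dat,
                                       family = stats::binomial()))
    co <- summary(fit)$coefficients
    est <- co[exposure, "Estimate"]
    se <- co[exposure, "Std. Error"]
  } else {
    fit <- suppressWarnings(MASS::polr(form, data = dat, Hess = TRUE))
    est <- stats::coef(fit)[[exposure]]
    se <- sqrt(diag(stats::vcov(fit))[[exposure]])
  }
  p <- 2 * stats::pnorm(-abs(est / se))
  wald_result(est, se, p, TRUE,
              n_cases = sum(dat[[exposure]] == 1),
              n_controls = sum(dat[[exposure]] == 0),
              n_dropped = mf$n_dropped, model = "ordinal",
              covariates = covariates)
}

#' Linear carrier-versus-control association for continuous traits
#'
#' Least-squares regression of a continuous trait on exposure plus the
#' covariate set; for lipid traits \code{statin_adjust = TRUE} adds statin
#' use to the covariates. Group means and SDs are reported alongside for
#' trait-table output.
#'
#' @inheritParams fit_logistic
#' @param statin_adjust add \code{statin_use} to the covariates (lipids).
#' @return An \code{association_result} (slope scale) with a
#'   \code{group_stats} data.frame attached.
#' @export
fit_linear <- function(data, outcome, exposure = "exposure",
                       covariates = character(), statin_adjust = FALSE) {
  if (statin_adjust) covariates <- union(covariates, "statin_use")
  mf <- model_frame_cc(data, outcome, exposure, covariates)
  dat <- mf$data
  if (!nrow(dat)) stop("no complete-case rows", call. = FALSE)
  if (stats::var(dat[[outcome]]) == 0) {
    stop("outcome has zero variance", call. = FALSE)
  }
  form <- stats::reformulate(c(exposure, covariates), response = outcome)
  fit <- stats::lm(form, data = dat)
  if (anyNA(stats::coef(fit))) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("collinear design: aliased column(s) %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  co <- summary(fit)$coefficients
  est <- co[exposure, "Estimate"]
  se <- co[exposure, "Std. Error"]
  p <- co[exposure, "Pr(>|t|)"]
  res <- wald_result(est, se, p, FALSE,
                     n_cases = sum(dat[[exposure]] == 1),
                     n_controls = sum(dat[[exposure]] == 0),
                     n_dropped = mf$n_dropped, model = "linear",
                     covariates = covariates)
  agg <- stats::aggregate(dat[[outcome]], list(exposure = dat[[exposure]]),
                          function(v) c(mean = mean(v), sd = stats::sd(v),
                                        n = length(v)))
  res$group_stats <- data.frame(exposure = agg$exposure,
                                mean = agg$x[, "mean"], sd = agg$x[, "sd"],
                                n = agg$x[, "n"])
  res
}

#' Benjamini-Hochberg adjusted p-values (from scratch)
#'
#' Step-up FDR adjustment implemented directly: with order statistics
#' \eqn{p_{(1)} \le \dots \le p_{(m)}}, the adjusted value is
#' \eqn{adj_{(i)} = \min_{j \ge i} (p_{(j)} m / j)}, capped at 1 and mapped
#' back to the input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p)
  ps <- p[o]
  scaled <- ps * m / seq_len(m)
  adj_sorted <- rev(cummin(rev(scaled)))
  adj_sorted <- pmin(adj_sorted, 1)
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

#' Variance inflation factors
#'
#' \eqn{VIF_k = 1/(1 - R^2_k)} from regressing predictor k on the remaining
#' predictors (with intercept). Exactly collinear columns get \code{Inf}.
#'
#' @param x numeric matrix or data.frame of predictors (no outcome column).
#' @return Named numeric vector of VIFs, one per column.
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least two predictors", call. = FALSE)
  if (nrow(x) <= ncol(x)) {
    stop("need more rows than predictors", call. = FALSE)
  }
  out <- vapply(seq_len(ncol(x)), function(k) {
    yk <- x[, k]
    Xk <- cbind(1, x[, -k, drop = FALSE])
    fit <- stats::lm.fit(Xk, yk)
    tss <- sum((yk - mean(yk))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(x)
  out
}

#' Adjusted carrier associations across groups and sexes (forest-plot set)
#'
#' Runs the sex-matched logistic model of the FDF high flag (or any binary
#' outcome) on carrier status for every (group, sex), adjusted for the
#' cardiovascular covariate set, then applies Benjamini-Hochberg across the
#' full result set.
#'
#' @param cohort scored cohort.
#' @param groups variant group names; default: every \code{ac_*} column.
#' @param outcome binary outcome column.
#' @param covariates adjustment set.
#' @return data.frame, one row per (group, sex): OR, interval, raw and
#'   BH-adjusted p, counts.
#' @export
run_associations <- function(cohort,
                             groups = sub("^ac_", "",
                                          grep("^ac_", names(cohort),
                                               value = TRUE)),
                             outcome = "fdf_high",
                             covariates = c("age", "diabetes", "dyslipidemia",
                                            "hypertension", "obesity",
                                            "smoking")) {
  rows <- list()
  for (g in groups) {
    for (s in c("male", "female")) {
      aset <- suppressWarnings(build_analysis_set(cohort, g, s))
      if (aset$empty) next
      res <- try(fit_logistic(aset$data, outcome, "exposure", covariates),
                 silent = TRUE)
      if (inherits(res, "try-error")) next
      row <- as.data.frame(res)
      row$group <- g
      row$sex <- s
      row$excluded_homozygous <- aset$excluded_homozygous
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$p_adjusted <- bh_adjust(out$p_raw)
  out[c("group", "sex", "model", "effect", "ci_low", "ci_high", "p_raw",
        "p_adjusted", "n_cases", "n_controls", "n_dropped",
        "excluded_homozygous", "covariates")]
}

#' Carrier associations stratified by cardiovascular risk
#'
#' For each (group, sex, CV stratum): carriers in that stratum versus the
#' \emph{full} same-sex wild-type control population, fitted \emph{without}
#' cardiovascular covariates (the stratification replaces the adjustment).
#' Benjamini-Hochberg is applied across the full result set. Empty
#' stratum-group cells are skipped with a message.
#'
#' @param cohort scored cohort with \code{cv_stratum} assigned (see
#'   \code{\link{cv_score_and_stratify}}).
#' @param groups variant group names.
#' @param outcome binary outcome column.
#' @return data.frame, one row per (group, sex, stratum).
#' @export
run_stratified <- function(cohort,
                           groups = sub("^ac_", "",
                                        grep("^ac_", names(cohort),
                                             value = TRUE)),
                           outcome = "fdf_high") {
  if (!"cv_stratum" %in% names(cohort)) {
    stop("cohort has no 'cv_stratum' column; run cv_score_and_stratify first",
         call. = FALSE)
  }
  rows <- list()
  for (g in groups) {
    for (s in c("male", "female")) {
      aset <- suppressWarnings(build_analysis_set(cohort, g, s))
      if (aset$empty) next
      for (st in c("high", "low")) {
        d <- aset$data
        keep <- d$exposure == 0 |
          (!is.na(d$cv_stratum) & d$cv_stratum == st)
        d <- d[keep, , drop = FALSE]
        if (sum(d$exposure == 1) == 0L) {
          message(sprintf("no %s carriers of '%s' in the %s-CV stratum: skipped",
                          s, g, st))
          next
        }
        res <- try(fit_logistic(d, outcome, "exposure", character()),
                   silent = TRUE)
        if (inherits(res, "try-error")) next
        row <- as.data.frame(res)
        row$group <- g
        row$sex <- s
        row$cv_stratum <- st
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$p_adjusted <- bh_adjust(out$p_raw)
  out[c("group", "sex", "cv_stratum", "model", "effect", "ci_low", "ci_high",
        "p_raw", "p_adjusted", "n_cases", "n_controls", "n_dropped")]
}
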