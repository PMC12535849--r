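#' Fit the cardiovascular risk score model
#'
#' Maximum-likelihood logistic regression of a binary outcome (default: the
#' Fabry phenotype flag \code{fdf_high}) on the six cardiovascular/renal risk
#' covariates: age plus diabetes, dyslipidemia, hypertension, obesity and
#' smoking. The per-subject risk score is the linear predictor (log-odds
#' scale), which is the scale on which the published operating threshold
#' (1.92) lives. The model's discriminative value is conventionally assessed
#' by its power to predict pathogenic-carrier status via
#' \code{\link{roc_metrics}}.
#'
#' @param cohort cohort data.frame with outcome and predictor columns.
#' @param outcome name of the binary outcome column.
#' @param predictors predictor column names.
#' @param score_threshold stored operating threshold (log-odds scale).
#' @param quantile_cut stratification quantile (default 0.75).
#' @return Object of class \code{cv_risk_model}: \code{fit} (the glm),
#'   \code{coefficients}, \code{predictors}, \code{outcome},
#'   \code{score_threshold}, \code{quantile_cut}, \code{n_used},
#'   \code{n_dropped}.
#' @export
fit_cv_model <- function(cohort, outcome = "fdf_high",
                         predictors = c("age", "diabetes", "dyslipidemia",
                                        "hypertension", "obesity", "smoking"),
                         score_threshold = default_scoring_map()$cv_score_threshold,
                         quantile_cut = 0.75) {
  miss <- setdiff(c(outcome, predictors), names(cohort))
  if (length(miss)) {
    stop(sprintf("cohort lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  dat <- cohort[c(outcome, predictors)]
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  if (nrow(dat) < length(predictors) + 10L) {
    stop("too few complete-case rows to fit the CV model", call. = FALSE)
  }
  y <- dat[[outcome]]
  if (length(unique(y)) < 2L) {
    stop("constant outcome: the CV model cannot be fitted", call. = FALSE)
  }
  form <- stats::reformulate(predictors, response = outcome)
  fit <- stats::glm(form, data = dat, family = stats::binomial())
  if (any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)) {
    stop(paste("(quasi-)separation detected in the CV model;",
               "consider penalized fitting or a different outcome coding"),
         call. = FALSE)
  }
  structure(
    list(fit = fit, coefficients = stats::coef(fit),
         predictors = predictors, outcome = outcome,
         score_threshold = score_threshold, quantile_cut = quantile_cut,
         n_used = nrow(dat), n_dropped = sum(!cc)),
    class = "cv_risk_model")
}

#' Score a cohort and stratify at the quantile cut
#'
#' Computes the per-subject CV risk score (log-odds linear predictor) and
#' assigns stratum \code{"high"} strictly above the empirical quantile
#' (default 75th percentile) of the scores in the reference cohort; subjects
#' exactly at the cut go to \code{"low"}. The cut is computed once on the
#' supplied reference population and reused, so carrier subsets can be
#' stratified against population quartiles. Subjects with missing covariates
#' get \code{NA} score and stratum (excluded, with a message).
#'
#' @param model a \code{cv_risk_model}.
#' @param cohort cohort to score.
#' @param cut optional precomputed cut value (reference-population quantile).
#' @return The cohort with \code{cv_score} and \code{cv_stratum} columns and
#'   a \code{"cv_cut"} attribute.
#' @export
cv_score_and_stratify <- function(model, cohort, cut = NULL) {
  stopifnot(inherits(model, "cv_risk_model"))
  score <- as.numeric(stats::predict(model$fit, newdata = cohort,
                                     type = "link",
                                     na.action = stats::na.pass))
  n_miss <- sum(is.na(score))
  if (n_miss) {
    message(sprintf("%d subject(s) with missing covariates left unstratified",
                    n_miss))
  }
  if (is.null(cut)) {
    cut <- as.numeric(stats::quantile(score, model$quantile_cut,
                                      na.rm = TRUE, names = FALSE))
    if (isTRUE(max(score, na.rm = TRUE) == min(score, na.rm = TRUE))) {
      warning("all CV scores identical: every subject stratified 'low'",
              call. = FALSE)
    }
  }
  stratum <- ifelse(score > cut, "high", "low")
  cohort$cv_score <- score
  cohort$cv_stratum <- stratum
  attr(cohort, "cv_cut") <- cut
  cohort
}

#' ROC metrics: rank-based AUC, sensitivity and specificity at a threshold
#'
#' AUC uses the Mann-Whitney rank formulation with mid-rank tie correction:
#' \deqn{AUC = (R_1 - n_1(n_1+1)/2) / (n_1 n_0)} where \eqn{R_1} is the rank
#' sum of the cases. Sensitivity and specificity are computed under the
#' classification rule \code{score > threshold}.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1/TRUE = case).
#' @param threshold operating threshold; \code{NA} skips sens/spec.
#' @return list with \code{auc}, \code{sensitivity}, \code{specificity},
#'   \code{threshold}, \code{n_cases}, \code{n_controls}.
#' @export
roc_metrics <- function(scores, labels, threshold = NA) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.integer(labels[keep])
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute ROC metrics",
         call. = FALSE)
  }
  r <- rank(scores)  # mid-ranks handle ties
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  sens <- spec <- NA_real_
  if (!is.na(threshold)) {
    sens <- sum(scores > threshold & labels == 1L) / n1
    spec <- sum(scores <= threshold & labels == 0L) / n0
  }
  list(auc = auc, sensitivity = sens, specificity = spec,
       threshold = threshold, n_cases = n1, n_controls = n0)
}
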