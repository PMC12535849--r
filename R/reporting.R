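#' Carrier proportion at printed precision
#'
#' \code{n_carriers / (n_carriers + n_wildtype)} rounded half-even (banker's
#' rounding, R's \code{round}) to \code{digits} decimals, matching how
#' summary tables print sex-relative carrier proportions.
#'
#' @param n_carriers,n_wildtype non-negative counts (not both zero).
#' @param digits decimals to round to.
#' @return The rounded proportion.
#' @export
carrier_proportion <- function(n_carriers, n_wildtype, digits = 4L) {
  if (any(c(n_carriers, n_wildtype) < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (n_carriers + n_wildtype == 0) {
    stop("carrier and wild-type counts are both zero", call. = FALSE)
  }
  round(n_carriers / (n_carriers + n_wildtype), digits)
}

#' Cohort summary table (carriers and proportions per group and sex)
#'
#' One row per variant group with hemizygous-male / heterozygous-female
#' carrier counts, wild-type counts (zero alleles across all groups),
#' sex-relative proportions, and homozygous females reported separately
#' (excluded from carrier counts).
#'
#' @param cohort cohort data.frame with \code{ac_*} columns.
#' @param groups variant group names.
#' @param digits rounding for printed proportions.
#' @return data.frame of summary rows.
#' @export
cohort_counts_table <- function(cohort,
                                groups = sub("^ac_", "",
                                             grep("^ac_", names(cohort),
                                                  value = TRUE)),
                                digits = 4L) {
  ac_cols <- grep("^ac_", names(cohort), value = TRUE)
  wild_all <- rowSums(as.matrix(cohort[ac_cols])) == 0
  rows <- lapply(groups, function(g) {
    zyg <- classify_zygosity(cohort$sex, cohort[[paste0("ac_", g)]])
    cm <- sum(zyg == "hemizygous")
    cf <- sum(zyg == "heterozygous")
    hf <- sum(zyg == "homozygous")
    wm <- sum(wild_all & cohort$sex == "male")
    wf <- sum(wild_all & cohort$sex == "female")
    data.frame(
      group = g,
      carriers_male = cm, wildtype_male = wm,
      prop_male = carrier_proportion(cm, wm, digits),
      carriers_female = cf, wildtype_female = wf,
      prop_female = carrier_proportion(cf, wf, digits),
      homozygous_female = hf,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Continuous-trait table (mean +/- SD with adjusted p-values)
#'
#' For one (group, sex): control and carrier mean and SD for each trait, the
#' covariate-adjusted linear-model p-value, and Benjamini-Hochberg adjustment
#' across the traits. Lipid traits are additionally adjusted for statin use.
#'
#' @param cohort scored cohort.
#' @param group variant group.
#' @param sex \code{"male"} or \code{"female"}.
#' @param traits trait column names.
#' @param lipid_traits subset of \code{traits} receiving statin adjustment.
#' @param covariates adjustment set.
#' @return data.frame, one row per trait.
#' @export
trait_table <- function(cohort, group, sex,
                        traits = c("bmi", "sbp", "dbp", "urea", "creatinine",
                                   "cystatin_c", "egfr", "u_creatinine",
                                   "uacr", "u_albumin", "glucose", "hba1c",
                                   "urate", "cholesterol", "triglycerides",
                                   "hdl", "apob", "lpa"),
                        lipid_traits = c("cholesterol", "triglycerides",
                                         "hdl", "apob", "lpa"),
                        covariates = c("age", "diabetes", "dyslipidemia",
                                       "hypertension", "obesity",
                                       "smoking")) {
  aset <- build_analysis_set(cohort, group, sex)
  if (aset$empty) {
    warning("empty analysis set: no trait table", call. = FALSE)
    return(NULL)
  }
  rows <- lapply(traits, function(tr) {
    res <- try(fit_linear(aset$data, tr, "exposure", covariates,
                          statin_adjust = tr %in% lipid_traits),
               silent = TRUE)
    if (inherits(res, "try-error")) return(NULL)
    gs <- res$group_stats
    ctrl <- gs[gs$exposure == 0, ]
    carr <- gs[gs$exposure == 1, ]
    data.frame(trait = tr,
               control_mean = ctrl$mean, control_sd = ctrl$sd,
               carrier_mean = carr$mean, carrier_sd = carr$sd,
               slope = res$effect, p_raw = res$p_raw,
               n_carriers = res$n_cases, n_controls = res$n_controls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$p_adjusted <- bh_adjust(out$p_raw)
  out$group <- group
  out$sex <- sex
  out
}

#' Run the full pipeline on a cohort (or simulate one)
#'
#' End-to-end driver: simulate (when no cohort is given), map ICD-10 codes,
#' score the FDF domains, fit and evaluate the cardiovascular risk model,
#' stratify at the 75th percentile, run the adjusted carrier associations
#' and the CV-stratified associations, and build the summary and trait
#' tables. Deterministic under a fixed config seed. When \code{out_dir} is
#' given every table is written as TSV.
#'
#' @param config a \code{\link{sim_config}} (used when \code{cohort} is
#'   NULL).
#' @param cohort optional pre-built cohort.
#' @param registry ICD-10 registry.
#' @param map scoring map.
#' @param out_dir optional output directory for TSV reports.
#' @param trait_groups groups for which trait tables are produced (linear
#'   models across 18 traits are the slow part; default: pathogenic only).
#' @return A report bundle: \code{cohort} (scored), \code{counts},
#'   \code{cv_model}, \code{cv_roc}, \code{youden}, \code{associations},
#'   \code{stratified}, \code{trait_tables}.
#' @export
run_full_analysis <- function(config = sim_config(), cohort = NULL,
                              registry = default_code_registry(),
                              map = default_scoring_map(), out_dir = NULL,
                              trait_groups = "ALL_P") {
  if (is.null(cohort)) cohort <- generate_cohort(config)
  cohort <- score_cohort(cohort, registry, map)
  counts <- cohort_counts_table(cohort)

  cv <- fit_cv_model(cohort)
  cohort <- cv_score_and_stratify(cv, cohort)

  # discriminative value of the CV score for pathogenic-carrier status
  groups <- sub("^ac_", "", grep("^ac_", names(cohort), value = TRUE))
  cv_roc <- youden <- NULL
  if ("ALL_P" %in% groups && sum(cohort$ac_ALL_P > 0) > 0) {
    lab <- as.integer(cohort$ac_ALL_P > 0)
    ok <- !is.na(cohort$cv_score)
    cv_roc <- roc_metrics(cohort$cv_score[ok], lab[ok],
                          threshold = cv$score_threshold)
    ok2 <- !is.na(cohort$fdf_total)
    if (length(unique(lab[ok2])) == 2L) {
      youden <- youden_cutoff(cohort$fdf_total[ok2], lab[ok2])
    }
  }

  assoc <- run_associations(cohort)
  strat <- run_stratified(cohort)
  traits <- lapply(intersect(trait_groups, groups), function(g) {
    list(male = trait_table(cohort, g, "male"),
         female = trait_table(cohort, g, "female"))
  })
  names(traits) <- intersect(trait_groups, groups)

  bundle <- list(cohort = cohort, counts = counts, cv_model = cv,
                 cv_roc = cv_roc, youden = youden, associations = assoc,
                 stratified = strat, trait_tables = traits)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) {
      if (!is.null(x)) {
        utils::write.table(x, file.path(out_dir, f), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    }
    wt(counts, "cohort_counts.tsv")
    wt(assoc, "associations.tsv")
    wt(strat, "stratified_associations.tsv")
    for (g in names(traits)) {
      wt(traits[[g]]$male, sprintf("traits_%s_male.tsv", g))
      wt(traits[[g]]$female, sprintf("traits_%s_female.tsv", g))
    }
    cvline <- data.frame(term = names(cv$coefficients),
                         estimate = as.numeric(cv$coefficients))
    wt(cvline, "cv_model_coefficients.tsv")
    if (!is.null(cv_roc)) {
      wt(data.frame(auc = cv_roc$auc, sensitivity = cv_roc$sensitivity,
                    specificity = cv_roc$specificity,
                    threshold = cv_roc$threshold), "cv_roc.tsv")
    }
  }
  bundle
}
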