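#' Default laboratory calibration table
#'
#' Per-sex means and standard deviations used to calibrate simulated laboratory
#' panels, anchored to the wild-type (control) columns of large genotyped
#' biobank cohorts. Right-skewed analytes (urinary creatinine, uACR, urinary
#' albumin, triglycerides, lipoprotein(a)) are drawn from moment-matched
#' log-normal distributions; the remainder from positive-truncated normals.
#' Urinary albumin is derived from uACR and urinary creatinine (see
#' \code{\link{sample_labs}}) so that the albumin/creatinine ratio stays
#' internally consistent.
#'
#' @return A data.frame with columns \code{lab}, \code{sex}, \code{mean},
#'   \code{sd}, \code{family} (\code{"normal"}, \code{"lognormal"} or
#'   \code{"derived"}).
#' @export
default_lab_calibration <- function() {
  # male mean/sd, female mean/sd, sampling family
  spec <- list(
    bmi           = c(27.834, 4.21, 27.075, 5.14, "normal"),
    sbp           = c(142.706, 18.47, 137.197, 20.22, "normal"),
    dbp           = c(84.005, 10.54, 80.677, 10.556, "normal"),
    urea          = c(5.613, 1.45, 5.23, 1.33, "normal"),
    creatinine    = c(81.745, 19.10, 64.373, 13.79, "normal"),
    cystatin_c    = c(0.943, 0.18, 0.878, 0.167, "normal"),
    egfr          = c(100.58, 20.32, 100.438, 20.42, "normal"),
    u_creatinine  = c(10881, 6116, 7186, 4953, "lognormal"),
    uacr          = c(20.527, 43.21, 20.993, 38.42, "lognormal"),
    u_albumin     = c(37.028, 152.25, 24.444, 95.71, "derived"),
    glucose       = c(5.189, 1.40, 5.068, 1.07, "normal"),
    hba1c         = c(36.515, 7.60, 35.807, 5.97, "normal"),
    urate         = c(354.62, 71.748, 271.06, 66.27, "normal"),
    cholesterol   = c(5.479, 1.13, 5.874, 1.12, "normal"),
    triglycerides = c(1.98, 1.155, 1.554, 0.86, "lognormal"),
    hdl           = c(1.279, 0.312, 1.593, 0.37, "normal"),
    apob          = c(1.026, 0.239, 1.037, 0.23, "normal"),
    lpa           = c(43.855, 49.02, 45.279, 49.37, "lognormal")
  )
  labs <- names(spec)
  out <- do.call(rbind, lapply(labs, function(l) {
    v <- spec[[l]]
    data.frame(
      lab = l,
      sex = c("male", "female"),
      mean = as.numeric(v[c(1, 3)]),
      sd = as.numeric(v[c(2, 4)]),
      family = v[5],
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Simulation configuration for a synthetic biobank cohort
#'
#' Builds a validated configuration object for \code{\link{generate_cohort}}.
#' Defaults emulate the structure of a large genotyped adult cohort:
#' X-linked carrier frequencies per variant group, ICD-10-coded cardiovascular
#' risk factors with age-dependent prevalence, Fabry clinical-domain events
#' generated from a logistic liability with carrier main effects and a
#' carrier-by-high-cardiovascular-risk interaction, laboratory panels
#' calibrated per sex, and realistic missingness (heaviest on pain items).
#'
#' The liability for each of the cardiac, cerebrovascular and pain domains is
#' \deqn{logit P = b_d + s (age - 55) + \sum_f \beta_f RF_f +
#'   \beta_{main} C + \beta_{int} C H}
#' where \eqn{C} indicates carrier status (attenuated in females by
#' \code{xinactivation_attenuation}) and \eqn{H} the latent high
#' cardiovascular-burden indicator (top quartile of the risk-factor
#' liability). The renal domain is driven by the laboratory panel: carriers
#' of groups listed in \code{uacr_multiplier} receive a multiplicative shift
#' of the uACR location.
#'
#' @param n_males,n_females cohort size per sex.
#' @param carrier_freq named vector of per-group allele frequencies. For an
#'   X-linked gene the male carrier proportion equals the allele frequency and
#'   the female heterozygote proportion is \eqn{2q(1-q)}.
#' @param effect_model named list per group:
#'   \code{list(beta_main = c(cardiac=, cerebrovascular=, pain=),
#'   beta_interaction = scalar)}, log-odds scale.
#' @param riskfactor_model named list per factor with \code{intercept} and
#'   \code{age_slope} on the logit scale.
#' @param domain_model baseline intercepts per domain, age slope, and
#'   risk-factor log-odds shared across domains.
#' @param xinactivation_attenuation multiplier in (0, 1] applied to female
#'   carrier effects (single-parameter X-inactivation model).
#' @param uacr_multiplier named vector: multiplicative shift of the uACR
#'   location for carriers of the named groups (females attenuated).
#' @param lab_calibration data.frame as \code{\link{default_lab_calibration}}.
#' @param missingness_rates named vector of per-field missingness
#'   probabilities; fields not listed use \code{0}.
#' @param age_range integer range of simulated ages (years).
#' @param high_cv_quantile latent high-CV cut (fraction of liability).
#' @param seed integer RNG seed.
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_males = 50000,
                       n_females = 50000,
                       carrier_freq = c(ALL_P = 0.00014, ALL_C = 0.0075,
                                        ALL_U = 0.0005),
                       effect_model = default_effect_model(names(carrier_freq)),
                       riskfactor_model = default_riskfactor_model(),
                       domain_model = default_domain_model(),
                       xinactivation_attenuation = 0.5,
                       uacr_multiplier = c(ALL_P = 4.1),
                       lab_calibration = default_lab_calibration(),
                       missingness_rates = default_missingness_rates(),
                       age_range = c(40L, 70L),
                       high_cv_quantile = 0.75,
                       seed = 1L) {
  cfg <- structure(
    list(
      n_males = n_males, n_females = n_females,
      carrier_freq = carrier_freq,
      effect_model = effect_model,
      riskfactor_model = riskfactor_model,
      domain_model = domain_model,
      xinactivation_attenuation = xinactivation_attenuation,
      uacr_multiplier = uacr_multiplier,
      lab_calibration = lab_calibration,
      missingness_rates = missingness_rates,
      age_range = age_range,
      high_cv_quantile = high_cv_quantile,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

#' Default per-group carrier effect model
#'
#' Pathogenic carriers (\code{ALL_P}) raise every Fabry domain unconditionally
#' (odds ratio 5); conflicting-interpretation (\code{ALL_C}) and
#' uncertain-significance (\code{ALL_U}) carriers have no main effect but an
#' odds ratio of 3 restricted to subjects with a high latent cardiovascular
#' burden. Groups not named here get null effects.
#'
#' @param groups character vector of group names.
#' @return Named list of effect specifications.
#' @export
default_effect_model <- function(groups = c("ALL_P", "ALL_C", "ALL_U")) {
  zero <- c(cardiac = 0, cerebrovascular = 0, pain = 0)
  out <- lapply(groups, function(g) {
    if (identical(g, "ALL_P")) {
      list(beta_main = c(cardiac = log(5), cerebrovascular = log(5),
                         pain = log(5)),
           beta_interaction = 0)
    } else if (g %in% c("ALL_C", "ALL_U")) {
      list(beta_main = zero, beta_interaction = log(3))
    } else {
      list(beta_main = zero, beta_interaction = 0)
    }
  })
  names(out) <- groups
  out
}

#' Default risk-factor prevalence model (logit scale, age in years)
#' @return Named list with \code{intercept} and \code{age_slope} per factor.
#' @export
default_riskfactor_model <- function() {
  list(
    hypertension = list(intercept = -4.0, age_slope = 0.055),
    diabetes     = list(intercept = -5.5, age_slope = 0.060),
    dyslipidemia = list(intercept = -4.5, age_slope = 0.050),
    obesity      = list(intercept = stats::qlogis(0.25), age_slope = 0),
    smoking      = list(intercept = stats::qlogis(0.45), age_slope = 0)
  )
}

#' Default Fabry-domain liability model
#' @return List with per-domain baseline intercepts, a shared age slope and
#'   risk-factor log-odds.
#' @export
default_domain_model <- function() {
  list(
    baseline = c(cardiac = -4.0, cerebrovascular = -4.6, pain = -1.8),
    age_slope = 0.05,
    riskfactor_betas = c(hypertension = log(2), diabetes = log(1.8),
                         dyslipidemia = log(1.4), obesity = log(1.5),
                         smoking = log(1.5))
  )
}

#' Default missingness rates per field
#'
#' Pain-questionnaire items are missing at a high rate (the feature the
#' pain imputation rule exists for); laboratory fields at low rates, urinary
#' measures slightly higher.
#' @return Named numeric vector of missingness probabilities.
#' @export
default_missingness_rates <- function() {
  c(pain_1 = 0.70, pain_2 = 0.70, pain_3 = 0.70,
    uacr = 0.05, u_albumin = 0.05, u_creatinine = 0.05,
    egfr = 0.02, bmi = 0.01, sbp = 0.02, dbp = 0.02,
    urea = 0.02, creatinine = 0.02, cystatin_c = 0.02,
    glucose = 0.02, hba1c = 0.02, urate = 0.02,
    cholesterol = 0.02, triglycerides = 0.02, hdl = 0.02,
    apob = 0.03, lpa = 0.03)
}

config_error <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

#' Validate a simulation configuration
#' @param cfg a \code{sim_config} object.
#' @return Invisibly \code{TRUE}; errors name the offending field.
#' @export
validate_sim_config <- function(cfg) {
  for (f in c("n_males", "n_females")) {
    n <- cfg[[f]]
    if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 ||
        n != floor(n)) {
      config_error(f, "must be a positive integer")
    }
  }
  q <- cfg$carrier_freq
  if (is.null(names(q)) || any(!nzchar(names(q)))) {
    config_error("carrier_freq", "must be a named vector")
  }
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1)) {
    config_error("carrier_freq", "frequencies must lie in [0, 1]")
  }
  if (!all(names(q) %in% names(cfg$effect_model))) {
    config_error("effect_model", "must cover every carrier_freq group")
  }
  for (g in names(cfg$effect_model)) {
    em <- cfg$effect_model[[g]]
    if (!all(c("beta_main", "beta_interaction") %in% names(em))) {
      config_error("effect_model", sprintf(
        "group '%s' needs beta_main and beta_interaction", g))
    }
    if (any(!is.finite(c(em$beta_main, em$beta_interaction)))) {
      config_error("effect_model", sprintf("non-finite effect for '%s'", g))
    }
  }
  a <- cfg$xinactivation_attenuation
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a <= 0 || a > 1) {
    config_error("xinactivation_attenuation", "must lie in (0, 1]")
  }
  lc <- cfg$lab_calibration
  need <- c("lab", "sex", "mean", "sd", "family")
  if (!is.data.frame(lc) || !all(need %in% names(lc))) {
    config_error("lab_calibration",
                 "must be a data.frame with lab/sex/mean/sd/family")
  }
  if (any(lc$sd < 0) || any(!is.finite(lc$sd))) {
    config_error("lab_calibration", "SDs must be non-negative and finite")
  }
  if (any(lc$mean <= 0 & lc$family == "lognormal")) {
    config_error("lab_calibration", "log-normal labs need positive means")
  }
  m <- cfg$missingness_rates
  if (length(m) && (any(!is.finite(m)) || any(m < 0) || any(m > 1))) {
    config_error("missingness_rates", "probabilities must lie in [0, 1]")
  }
  hq <- cfg$high_cv_quantile
  if (!is.numeric(hq) || hq <= 0 || hq >= 1) {
    config_error("high_cv_quantile", "must lie in (0, 1)")
  }
  if (any(cfg$uacr_multiplier <= 0)) {
    config_error("uacr_multiplier", "multipliers must be positive")
  }
  if (cfg$age_range[1] >= cfg$age_range[2]) {
    config_error("age_range", "must be an increasing range")
  }
  invisible(TRUE)
}

#' Default ICD-10 code registry
#'
#' Maps ICD-10 code prefixes (upper-cased, dots stripped) to Fabry clinical
#' domains and to cardiovascular/renal risk factors, with per-prefix severity
#' levels used by the domain scorer. The exact code lists behind published
#' biobank analyses are rarely deposited, so this registry is a documented,
#' editable reconstruction: cardiomyopathy (I42) and stroke (I60-I63) carry
#' the highest severity, heart failure and conduction/arrhythmia codes lower
#' levels, and risk factors follow conventional ICD-10 blocks (E10-E14
#' diabetes, E78 dyslipidemia, I10-I15 hypertension, E66 obesity, F17/Z72.0
#' smoking).
#'
#' @return An object of class \code{code_registry}.
#' @export
default_code_registry <- function() {
  reg <- structure(
    list(
      domain_codes = list(
        cardiac = c("I42", "I50", "I44", "I45", "I46", "I47", "I48", "I49"),
        cerebrovascular = c("I60", "I61", "I62", "I63", "I64", "G45"),
        renal = c("N18")
      ),
      riskfactor_codes = list(
        diabetes = c("E10", "E11", "E12", "E13", "E14"),
        dyslipidemia = c("E78"),
        hypertension = c("I10", "I11", "I12", "I13", "I15"),
        obesity = c("E66"),
        smoking = c("F17", "Z720")
      ),
      severity_weights = c(
        I42 = 4, I50 = 3, I46 = 3, I44 = 2, I45 = 2, I47 = 2, I48 = 2, I49 = 2,
        I60 = 4, I61 = 4, I63 = 4, I62 = 3, I64 = 3, G45 = 2,
        N18 = 2
      )
    ),
    class = "code_registry"
  )
  validate_code_registry(reg)
  reg
}

#' Validate an ICD-10 code registry
#'
#' Checks that no prefix is assigned to two risk factors and that every prefix
#' is syntactically valid ICD-10 (letter, two digits, optional subcode).
#' @param registry a \code{code_registry}.
#' @return Invisibly \code{TRUE}.
#' @export
validate_code_registry <- function(registry) {
  need <- c("domain_codes", "riskfactor_codes", "severity_weights")
  if (!all(need %in% names(registry))) {
    config_error("registry", "missing domain_codes/riskfactor_codes/severity_weights")
  }
  rf <- unlist(registry$riskfactor_codes, use.names = FALSE)
  if (anyDuplicated(rf)) {
    config_error("riskfactor_codes", sprintf(
      "prefix assigned to two risk factors: %s",
      paste(unique(rf[duplicated(rf)]), collapse = ", ")))
  }
  all_pref <- c(rf, unlist(registry$domain_codes, use.names = FALSE))
  bad <- all_pref[!grepl("^[A-Z][0-9]{2}[0-9A-Z]*$", all_pref)]
  if (length(bad)) {
    config_error("registry", sprintf("invalid ICD-10 prefix(es): %s",
                                     paste(unique(bad), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Default FDF scoring map
#'
#' Banding and weights for the four FDF domains (pain, renal, cardiac,
#' cerebrovascular), each capped at \code{domain_max = 4}, with the total
#' dichotomized strictly above \code{dichotomization_threshold = 4} so that a
#' high flag requires at least two involved domains. Renal bands follow
#' KDIGO-style staging: eGFR >= 90 scores 0, 60-89 scores 1, 30-59 scores 2,
#' < 30 scores 4; uACR < 30 scores 0, 30-300 scores 1, > 300 scores 4; the
#' renal score is the maximum of the two components. \code{youden_reference}
#' stores the published real-data ROC-optimal cutoff (4.4) as a reference
#' value only; \code{cv_score_threshold} stores the published cardiovascular
#' score operating threshold (1.92, log-odds scale).
#'
#' @return An object of class \code{scoring_map}.
#' @export
default_scoring_map <- function() {
  structure(
    list(
      renal_egfr = list(breaks = c(90, 60, 30), points = c(0, 1, 2, 4)),
      renal_uacr = list(breaks = c(30, 300), points = c(0, 1, 4)),
      cardiac_weights = c("1" = 1, "2" = 2, "3" = 3, "4" = 4),
      cerebrovascular_weights = c("1" = 1, "2" = 2, "3" = 3, "4" = 4),
      pain_weights = c("0" = 0, "1" = 1, "2" = 2, "3" = 4),
      domain_max = 4,
      dichotomization_threshold = 4,
      youden_reference = 4.4,
      cv_score_threshold = 1.92
    ),
    class = "scoring_map"
  )
}

#' Read or write an analysis configuration (registry + scoring map) as YAML
#'
#' @param path file path.
#' @param registry,scoring_map objects to serialize.
#' @return \code{read_analysis_config} returns
#'   \code{list(registry, scoring_map)}.
#' @export
write_analysis_config <- function(path, registry = default_code_registry(),
                                  scoring_map = default_scoring_map()) {
  yaml::write_yaml(list(registry = unclass(registry),
                        scoring_map = unclass(scoring_map)), path)
  invisible(path)
}

#' @rdname write_analysis_config
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  reg <- raw$registry
  reg$severity_weights <- unlist(reg$severity_weights)
  reg$domain_codes <- lapply(reg$domain_codes, as.character)
  reg$riskfactor_codes <- lapply(reg$riskfactor_codes, as.character)
  reg <- structure(reg, class = "code_registry")
  validate_code_registry(reg)
  sm <- raw$scoring_map
  for (f in c("cardiac_weights", "cerebrovascular_weights", "pain_weights")) {
    sm[[f]] <- unlist(sm[[f]])
  }
  sm$renal_egfr <- lapply(sm$renal_egfr, unlist)
  sm$renal_uacr <- lapply(sm$renal_uacr, unlist)
  list(registry = reg,
       scoring_map = structure(sm, class = "scoring_map"))
}
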