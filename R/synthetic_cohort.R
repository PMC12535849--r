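#' Sample X-linked allele counts
#'
#' Males carry one X chromosome and are sampled with a single allele draw
#' (count 0 or 1, i.e. hemizygous when 1); females with two independent draws
#' (0, 1 or 2), so the heterozygote fraction follows Hardy-Weinberg
#' \eqn{2q(1-q)}.
#'
#' @param sex character vector of \code{"male"}/\code{"female"}.
#' @param freq allele frequency in [0, 1].
#' @param seed optional integer seed; \code{NULL} uses the current RNG state.
#' @return Integer vector of allele counts, same length as \code{sex}.
#' @export
assign_genotypes <- function(sex, freq, seed = NULL) {
  if (!is.numeric(freq) || length(freq) != 1L || is.na(freq) ||
      freq < 0 || freq > 1) {
    stop("allele frequency must lie in [0, 1]", call. = FALSE)
  }
  if (!all(sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(sex)
  ac <- integer(n)
  male <- sex == "male"
  ac[male] <- stats::rbinom(sum(male), 1L, freq)
  ac[!male] <- stats::rbinom(sum(!male), 2L, freq)
  ac
}

# moment-matched log-normal parameters from a mean/sd on the natural scale
lnorm_params <- function(mean, sd) {
  sigma2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

# positive-truncated normal draws (vectorized mean), rejection sampling;
# calibrations keep mean/sd well away from zero so rejection is rare
rtruncnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  tries <- 0L
  while (length(bad) && tries < 100L) {
    x[bad] <- stats::rnorm(length(bad), if (length(mean) > 1L) mean[bad] else mean, sd)
    bad <- bad[x[bad] <= 0]
    tries <- tries + 1L
  }
  if (length(bad)) x[bad] <- .Machine$double.eps
  x
}

#' Sample a laboratory panel
#'
#' Draws one value per subject for each calibrated lab. Symmetric labs use a
#' positive-truncated normal; right-skewed labs (uACR, triglycerides,
#' lipoprotein(a), urinary creatinine) a moment-matched log-normal. Carriers
#' flagged in \code{uacr_shift} receive a multiplicative shift of the uACR
#' location (renal involvement of pathogenic variants). Urinary albumin is
#' derived from uACR and urinary creatinine (unit-converted, with log-normal
#' noise) so the three stay mutually consistent. Statin use is sampled given
#' dyslipidemia status when provided.
#'
#' @param context data.frame with at least \code{sex}; optionally
#'   \code{dyslipidemia} (0/1) and \code{uacr_shift} (per-subject
#'   multiplicative uACR factor, default 1).
#' @param calibration calibration table, see
#'   \code{\link{default_lab_calibration}}.
#' @param seed optional integer seed.
#' @return data.frame of lab columns plus \code{statin_use}.
#' @export
sample_labs <- function(context, calibration = default_lab_calibration(),
                        seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (any(calibration$sd < 0) || any(!is.finite(calibration$sd))) {
    config_error("lab_calibration", "SDs must be non-negative")
  }
  n <- nrow(context)
  sexes <- context$sex
  shift <- context$uacr_shift
  if (is.null(shift)) shift <- rep(1, n)
  out <- data.frame(row.names = seq_len(n))
  labs <- unique(calibration$lab)
  for (l in labs) {
    fam <- calibration$family[calibration$lab == l][1]
    if (fam == "derived") next
    x <- numeric(n)
    for (s in c("male", "female")) {
      row <- calibration[calibration$lab == l & calibration$sex == s, ]
      idx <- which(sexes == s)
      if (!length(idx)) next
      mu <- rep(row$mean, length(idx))
      if (l == "uacr") mu <- mu * shift[idx]
      if (row$sd == 0) {
        x[idx] <- mu
      } else if (fam == "lognormal") {
        # multiplicative shift applied on the location, spread preserved
        p <- lnorm_params(row$mean, row$sd)
        x[idx] <- stats::rlnorm(length(idx), p$meanlog + log(mu / row$mean),
                                p$sdlog)
      } else {
        x[idx] <- rtruncnorm_pos(length(idx), mu, row$sd)
      }
    }
    out[[l]] <- x
  }
  if (all(c("uacr", "u_creatinine") %in% names(out))) {
    # uACR mg/g * urinary creatinine (umol/L -> g/L; creatinine 113.12 g/mol)
    ucr_gl <- out$u_creatinine * 113.12e-6
    out$u_albumin <- out$uacr * ucr_gl * stats::rlnorm(n, 0, 0.1)
  }
  dys <- context$dyslipidemia
  if (is.null(dys)) dys <- rep(0L, n)
  out$statin_use <- stats::rbinom(n, 1L, ifelse(dys > 0, 0.7, 0.1))
  out
}

#' Generate a synthetic biobank cohort
#'
#' Draws a full cohort under a \code{\link{sim_config}}: sex and age,
#' X-linked allele counts per variant group, age-dependent cardiovascular
#' risk factors, a latent high-CV-burden indicator (top quartile of the
#' risk-factor liability), Fabry clinical-domain events from the logistic
#' liability (carrier main effects plus carrier-by-high-CV interaction,
#' female effects attenuated), ICD-10 code lists, calibrated laboratory
#' panels with a uACR shift for pathogenic carriers, pain-questionnaire items
#' and configured missingness. Output is byte-identical for identical
#' (config, seed).
#'
#' @param config a \code{\link{sim_config}}.
#' @return A data.frame of class \code{c("fdf_cohort", "data.frame")}, one
#'   row per subject, with a \code{"truth"} attribute recording the realized
#'   generating parameters.
#' @export
generate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_males + config$n_females
  sex <- c(rep("male", config$n_males), rep("female", config$n_females))
  age <- sample(seq(config$age_range[1], config$age_range[2]), n,
                replace = TRUE)
  groups <- names(config$carrier_freq)
  ac <- sapply(groups, function(g) {
    assign_genotypes(sex, config$carrier_freq[[g]])
  })
  if (is.null(dim(ac))) ac <- matrix(ac, nrow = n)
  colnames(ac) <- paste0("ac_", groups)

  # risk factors: Bernoulli with logit linear in age
  rf_names <- names(config$riskfactor_model)
  rf <- sapply(rf_names, function(f) {
    m <- config$riskfactor_model[[f]]
    stats::rbinom(n, 1L, stats::plogis(m$intercept + m$age_slope * age))
  })
  colnames(rf) <- rf_names

  # latent cardiovascular burden: the risk-factor/age part of the liability
  dm <- config$domain_model
  rb <- dm$riskfactor_betas
  cv_lin <- dm$age_slope * (age - 55) +
    as.numeric(rf[, names(rb), drop = FALSE] %*% rb)
  cv_high <- cv_lin > stats::quantile(cv_lin, config$high_cv_quantile)

  # per-domain carrier contribution (female effects attenuated)
  att <- ifelse(sex == "female", config$xinactivation_attenuation, 1)
  domains <- names(dm$baseline)
  carrier_lin <- matrix(0, n, length(domains),
                        dimnames = list(NULL, domains))
  for (g in groups) {
    carrier <- ac[, paste0("ac_", g)] > 0
    if (!any(carrier)) next
    em <- config$effect_model[[g]]
    for (d in domains) {
      bm <- if (d %in% names(em$beta_main)) em$beta_main[[d]] else 0
      carrier_lin[, d] <- carrier_lin[, d] +
        carrier * att * (bm + em$beta_interaction * cv_high)
    }
  }

  event <- sapply(domains, function(d) {
    p <- stats::plogis(dm$baseline[[d]] + cv_lin + carrier_lin[, d])
    stats::rbinom(n, 1L, p)
  })
  colnames(event) <- domains

  # labs, with pathogenic-carrier uACR shift (attenuated in females)
  uacr_shift <- rep(1, n)
  for (g in names(config$uacr_multiplier)) {
    col <- paste0("ac_", g)
    if (!col %in% colnames(ac)) next
    carrier <- ac[, col] > 0
    uacr_shift[carrier] <- uacr_shift[carrier] *
      config$uacr_multiplier[[g]]^att[carrier]
  }
  labctx <- data.frame(sex = sex, dyslipidemia = rf[, "dyslipidemia"],
                       uacr_shift = uacr_shift)
  labs <- sample_labs(labctx, config$lab_calibration)

  # ICD-10 code assembly (vectorized): risk factors, domain events with
  # severity-tiered codes, chronic kidney disease when simulated eGFR < 60
  rf_codes <- c(hypertension = "I10", diabetes = "E11",
                dyslipidemia = "E78.0", obesity = "E66.9", smoking = "F17.2")
  parts <- lapply(intersect(names(rf_codes), rf_names), function(f) {
    ifelse(rf[, f] == 1L, rf_codes[[f]], "")
  })
  cardiac_codes <- c("I42.1", "I50.0", "I48.0", "I45.9")
  cardiac_probs <- c(0.35, 0.25, 0.25, 0.15)
  card <- character(n)
  idx <- which(event[, "cardiac"] == 1L)
  if (length(idx)) card[idx] <- sample(cardiac_codes, length(idx), TRUE,
                                       cardiac_probs)
  cereb_codes <- c("I63.9", "I61.9", "G45.9", "I64")
  cereb_probs <- c(0.50, 0.15, 0.20, 0.15)
  cereb <- character(n)
  idx <- which(event[, "cerebrovascular"] == 1L)
  if (length(idx)) cereb[idx] <- sample(cereb_codes, length(idx), TRUE,
                                        cereb_probs)
  ckd <- ifelse(!is.na(labs$egfr) & labs$egfr < 60, "N18.3", "")
  parts <- c(parts, list(card, cereb, ckd))
  icd10 <- do.call(paste, c(parts, sep = ";"))
  icd10 <- gsub(";{2,}", ";", icd10)
  icd10 <- gsub("^;|;$", "", icd10)

  # pain questionnaire: three ordinal items 0-3; events push levels up
  pain_ev <- event[, "pain"]
  pain <- sapply(1:3, function(k) {
    lev <- integer(n)
    ev <- pain_ev == 1L
    lev[ev] <- sample(1:3, sum(ev), TRUE, prob = c(0.40, 0.35, 0.25))
    lev[!ev] <- sample(0:1, sum(!ev), TRUE, prob = c(0.92, 0.08))
    lev
  })
  colnames(pain) <- paste0("pain_", 1:3)

  cohort <- data.frame(
    id = sprintf("S%07d", seq_len(n)),
    sex = sex, age = age,
    ac, rf, icd10 = icd10, labs, pain,
    stringsAsFactors = FALSE
  )

  # configured missingness, missing-at-random per field
  for (f in names(config$missingness_rates)) {
    r <- config$missingness_rates[[f]]
    if (r <= 0 || !f %in% names(cohort)) next
    cohort[[f]][stats::runif(n) < r] <- NA
  }

  attr(cohort, "truth") <- list(
    seed = config$seed,
    carrier_freq = as.list(config$carrier_freq),
    effect_model = config$effect_model,
    xinactivation_attenuation = config$xinactivation_attenuation,
    uacr_multiplier = as.list(config$uacr_multiplier),
    domain_model = dm,
    high_cv_quantile = config$high_cv_quantile,
    n_high_cv = sum(cv_high)
  )
  class(cohort) <- c("fdf_cohort", "data.frame")
  cohort
}

#' Write / read a cohort as TSV with a YAML truth sidecar
#'
#' The cohort table is written as tab-separated text; the truth record (the
#' realized generating parameters attached by \code{\link{generate_cohort}})
#' goes to \code{<path>.truth.yaml} when present.
#'
#' @param cohort a cohort data.frame.
#' @param path output TSV path.
#' @return \code{write_cohort}: invisibly, the path. \code{read_cohort}: the
#'   cohort with any truth sidecar re-attached.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  truth <- attr(cohort, "truth")
  if (!is.null(truth)) {
    # named atomic vectors become YAML maps, not bare sequences
    namify <- function(x) {
      if (is.list(x)) {
        lapply(x, namify)
      } else if (!is.null(names(x)) && length(x) > 1L) {
        as.list(x)
      } else x
    }
    yaml::write_yaml(namify(truth), paste0(path, ".truth.yaml"))
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE, na.strings = "",
                              colClasses = NA)
  sidecar <- paste0(path, ".truth.yaml")
  if (file.exists(sidecar)) {
    attr(cohort, "truth") <- yaml::read_yaml(sidecar)
  }
  class(cohort) <- c("fdf_cohort", "data.frame")
  cohort
}
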