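#' Score the renal FDF domain from eGFR and uACR
#'
#' Points are the maximum of the eGFR band and the uACR band, capped at the
#' domain maximum. Under the default KDIGO-style bands: eGFR >= 90 scores 0,
#' 60-89 scores 1, 30-59 scores 2, < 30 scores 4; uACR < 30 scores 0, 30-300
#' scores 1, > 300 scores 4. Missing inputs make the renal score missing
#' (subjects are excluded from models needing it, never imputed to 0 — only
#' the pain domain uses imputation).
#'
#' @param egfr eGFR in mL/min (vectorized; NA allowed).
#' @param uacr uACR in mg/g (vectorized; NA allowed).
#' @param map a \code{\link{default_scoring_map}}-style scoring map.
#' @return Numeric vector of points in [0, domain_max], with components
#'   attached as attributes \code{"egfr_points"} and \code{"uacr_points"}
#'   for per-component analyses.
#' @export
score_renal <- function(egfr, uacr, map = default_scoring_map()) {
  if (any(egfr < 0, na.rm = TRUE) || any(uacr < 0, na.rm = TRUE)) {
    stop("negative renal lab value", call. = FALSE)
  }
  band <- function(x, breaks, points, decreasing) {
    # decreasing = TRUE: lower values are worse (eGFR); FALSE: higher worse
    idx <- rep(1L, length(x))
    for (b in breaks) {
      if (decreasing) idx <- idx + (x < b) else idx <- idx + (x > b)
    }
    out <- points[idx]
    out[is.na(x)] <- NA_real_
    out
  }
  ep <- band(egfr, map$renal_egfr$breaks, map$renal_egfr$points, TRUE)
  up <- band(uacr, map$renal_uacr$breaks, map$renal_uacr$points, FALSE)
  pts <- pmin(pmax(ep, up), map$domain_max)
  pts[is.na(ep) | is.na(up)] <- NA_real_
  attr(pts, "egfr_points") <- ep
  attr(pts, "uacr_points") <- up
  pts
}

#' Score a flag-based FDF domain (cardiac or cerebrovascular)
#'
#' Points equal the weight of the highest severity level present (max rule,
#' never a sum), 0 when the domain is unflagged, capped at the domain
#' maximum.
#'
#' @param severity numeric vector of per-subject highest severity (0 or NA =
#'   no flag), as produced by \code{\link{map_cohort_codes}}.
#' @param weights named vector mapping severity level to points.
#' @param map scoring map supplying \code{domain_max}.
#' @return Numeric vector of points.
#' @export
score_flag_domain <- function(severity, weights, map = default_scoring_map()) {
  sev <- severity
  sev[is.na(sev)] <- 0
  pts <- numeric(length(sev))
  nz <- sev > 0
  if (any(nz)) {
    key <- as.character(sev[nz])
    unknown <- !key %in% names(weights)
    if (any(unknown)) {
      stop(sprintf("severity level(s) %s not in the scoring weights",
                   paste(unique(key[unknown]), collapse = ", ")),
           call. = FALSE)
    }
    pts[nz] <- weights[key]
  }
  pmin(pts, map$domain_max)
}

#' Score the pain FDF domain with impute-to-lowest for missing items
#'
#' Points come from the highest reported pain category across the
#' questionnaire items; when every item is missing the lowest category
#' (0 points) is inferred and the result flagged as imputed.
#'
#' @param pain_items matrix or data.frame of ordinal pain responses (rows =
#'   subjects), NAs allowed.
#' @param weights named vector mapping response level to points.
#' @param map scoring map supplying \code{domain_max}.
#' @return data.frame with \code{points} and logical \code{imputed}.
#' @export
score_pain <- function(pain_items, weights = default_scoring_map()$pain_weights,
                       map = default_scoring_map()) {
  m <- as.matrix(pain_items)
  all_missing <- apply(m, 1L, function(r) all(is.na(r)))
  hi <- suppressWarnings(apply(m, 1L, max, na.rm = TRUE))
  hi[all_missing] <- 0
  key <- as.character(hi)
  unknown <- !key %in% names(weights)
  if (any(unknown)) {
    stop(sprintf("pain level(s) %s not in the scoring weights",
                 paste(unique(key[unknown]), collapse = ", ")),
         call. = FALSE)
  }
  data.frame(points = pmin(as.numeric(weights[key]), map$domain_max),
             imputed = all_missing)
}

#' Combine domain scores into the FDF total and high flag
#'
#' The total is the sum of the four domain scores (pain, renal, cardiac,
#' cerebrovascular), each in [0, domain_max]; the high flag is strictly
#' \code{total > dichotomization_threshold} (default > 4), which with a
#' domain maximum of 4 guarantees every flagged subject has at least two
#' involved domains.
#'
#' @param domain_scores data.frame with columns \code{pain}, \code{renal},
#'   \code{cardiac}, \code{cerebrovascular}.
#' @param map scoring map.
#' @param pain_imputed optional logical vector carried through.
#' @return data.frame: domain scores, \code{total}, \code{high_flag},
#'   \code{pain_imputed}.
#' @export
total_fdf <- function(domain_scores, map = default_scoring_map(),
                      pain_imputed = NULL) {
  need <- c("pain", "renal", "cardiac", "cerebrovascular")
  if (!all(need %in% names(domain_scores))) {
    stop("domain_scores needs pain/renal/cardiac/cerebrovascular columns",
         call. = FALSE)
  }
  ds <- domain_scores[need]
  rng <- range(as.matrix(ds), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > map$domain_max) {
    stop(sprintf("domain score outside [0, %s]", map$domain_max),
         call. = FALSE)
  }
  total <- ds$pain + ds$renal + ds$cardiac + ds$cerebrovascular
  out <- data.frame(ds, total = total,
                    high_flag = !is.na(total) &
                      total > map$dichotomization_threshold)
  out$high_flag[is.na(total)] <- NA
  out$pain_imputed <- if (is.null(pain_imputed)) NA else pain_imputed
  out
}

#' Compute FDF scores for a whole cohort
#'
#' Maps ICD-10 codes (if not already mapped), scores the four domains and
#' appends \code{fdf_pain}, \code{fdf_renal} (with \code{fdf_renal_egfr} /
#' \code{fdf_renal_uacr} components), \code{fdf_cardiac},
#' \code{fdf_cerebrovascular}, \code{fdf_total}, \code{fdf_high} and
#' \code{pain_imputed} columns.
#'
#' @param cohort cohort data.frame.
#' @param registry ICD-10 code registry.
#' @param map scoring map.
#' @return The cohort with FDF columns appended.
#' @export
score_cohort <- function(cohort, registry = default_code_registry(),
                         map = default_scoring_map()) {
  if (!"cardiac_severity" %in% names(cohort)) {
    cohort <- map_cohort_codes(cohort, registry)
  }
  pain_cols <- grep("^pain_[0-9]+$", names(cohort), value = TRUE)
  if (!length(pain_cols)) stop("cohort has no pain_* items", call. = FALSE)
  pain <- score_pain(cohort[pain_cols], map$pain_weights, map)
  renal <- score_renal(cohort$egfr, cohort$uacr, map)
  cohort$fdf_pain <- pain$points
  cohort$pain_imputed <- pain$imputed
  cohort$fdf_renal <- as.numeric(renal)
  cohort$fdf_renal_egfr <- attr(renal, "egfr_points")
  cohort$fdf_renal_uacr <- attr(renal, "uacr_points")
  cohort$fdf_cardiac <- score_flag_domain(cohort$cardiac_severity,
                                          map$cardiac_weights, map)
  cohort$fdf_cerebrovascular <- score_flag_domain(
    cohort$cerebrovascular_severity, map$cerebrovascular_weights, map)
  tot <- total_fdf(
    data.frame(pain = cohort$fdf_pain, renal = cohort$fdf_renal,
               cardiac = cohort$fdf_cardiac,
               cerebrovascular = cohort$fdf_cerebrovascular),
    map, pain_imputed = pain$imputed)
  cohort$fdf_total <- tot$total
  cohort$fdf_high <- tot$high_flag
  cohort
}

#' ROC-optimal cutoff by the Youden index
#'
#' Scans the midpoints of adjacent distinct score values (classification rule
#' \code{score > threshold}) and returns the threshold maximizing
#' J = sensitivity + specificity - 1; ties are broken toward the lower
#' threshold.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1 or logical), 1 = case.
#' @return list with \code{threshold}, \code{J}, \code{sensitivity},
#'   \code{specificity}.
#' @export
youden_cutoff <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.integer(labels[keep])
  if (length(unique(labels)) < 2L) {
    stop("labels must contain both classes", call. = FALSE)
  }
  u <- sort(unique(scores))
  if (length(u) < 2L) {
    return(list(threshold = u[1], J = 0,
                sensitivity = mean(scores[labels == 1] > u[1]),
                specificity = mean(scores[labels == 0] <= u[1])))
  }
  thr <- (u[-length(u)] + u[-1]) / 2
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  sens <- vapply(thr, function(t) sum(scores > t & labels == 1L) / n1,
                 numeric(1))
  spec <- vapply(thr, function(t) sum(scores <= t & labels == 0L) / n0,
                 numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1]  # ties -> lowest threshold
  list(threshold = thr[best], J = j[best],
       sensitivity = sens[best], specificity = spec[best])
}
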