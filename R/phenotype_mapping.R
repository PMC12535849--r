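#' Normalize ICD-10 code strings
#'
#' Upper-cases and strips dots and whitespace. Codes that do not then match
#' the ICD-10 shape (letter, two digits, optional subcode) are dropped with a
#' warning rather than failing the run.
#'
#' @param codes character vector of raw codes.
#' @return Normalized codes; malformed entries removed.
#' @export
normalize_icd10 <- function(codes) {
  codes <- codes[!is.na(codes) & nzchar(codes)]
  norm <- gsub("[.[:space:]]", "", toupper(codes))
  ok <- grepl("^[A-Z][0-9]{2}[0-9A-Z]*$", norm)
  if (any(!ok)) {
    warning(sprintf("skipping malformed ICD-10 code(s): %s",
                    paste(unique(codes[!ok]), collapse = ", ")),
            call. = FALSE)
  }
  norm[ok]
}

#' Classify X-linked zygosity from sex and allele count
#'
#' Males: 0 is wild type, 1 hemizygous (a male allele count of 2 is a data
#' error on the X chromosome). Females: 0 wild type, 1 heterozygous,
#' 2 homozygous. Homozygous females are excluded from sex-matched
#' association sets downstream.
#'
#' @param sex character vector (\code{"male"}/\code{"female"}).
#' @param allele_count integer vector of variant allele counts.
#' @return Factor with levels wild_type, hemizygous, heterozygous, homozygous.
#' @export
classify_zygosity <- function(sex, allele_count) {
  if (length(sex) != length(allele_count)) {
    stop("sex and allele_count must have equal length", call. = FALSE)
  }
  if (any(allele_count < 0, na.rm = TRUE)) {
    stop("negative allele count", call. = FALSE)
  }
  if (any(sex == "male" & allele_count > 1, na.rm = TRUE)) {
    stop("male allele count of 2 is impossible for an X-linked variant",
         call. = FALSE)
  }
  if (any(allele_count > 2, na.rm = TRUE)) {
    stop("allele count above 2", call. = FALSE)
  }
  z <- ifelse(allele_count == 0, "wild_type",
       ifelse(sex == "male", "hemizygous",
       ifelse(allele_count == 1, "heterozygous", "homozygous")))
  factor(z, levels = c("wild_type", "hemizygous", "heterozygous",
                       "homozygous"))
}

# classify one vector of unique normalized codes against registry prefixes;
# returns a data.frame: domain, riskfactor, severity per code (NA if none)
classify_codes <- function(codes, registry) {
  n <- length(codes)
  domain <- rep(NA_character_, n)
  severity <- rep(0, n)
  riskfactor <- rep(NA_character_, n)
  for (d in names(registry$domain_codes)) {
    for (p in registry$domain_codes[[d]]) {
      hit <- startsWith(codes, p)
      if (!any(hit)) next
      sev <- if (p %in% names(registry$severity_weights)) {
        registry$severity_weights[[p]]
      } else 1
      domain[hit & is.na(domain)] <- d
      better <- hit & !is.na(domain) & domain == d & severity < sev
      severity[better] <- sev
    }
  }
  severity[is.na(domain)] <- NA_real_
  for (f in names(registry$riskfactor_codes)) {
    for (p in registry$riskfactor_codes[[f]]) {
      hit <- startsWith(codes, p) & is.na(riskfactor)
      riskfactor[hit] <- f
    }
  }
  data.frame(code = codes, domain = domain, severity = severity,
             riskfactor = riskfactor, stringsAsFactors = FALSE)
}

#' Map one subject's ICD-10 codes to Fabry-domain and risk-factor flags
#'
#' Codes are normalized (upper-cased, dots stripped) and matched by prefix
#' against the registry: \code{"I42"} matches \code{"I42.1"} but not
#' \code{"I4"}. Unknown codes are ignored; malformed codes are skipped with
#' a warning. A domain flag carries the highest severity level seen among
#' its matching codes.
#'
#' @param codes character vector of ICD-10 codes for one subject.
#' @param registry a \code{\link{default_code_registry}}-style registry.
#' @return list with \code{domain_flags} (named logical),
#'   \code{domain_severity} (named numeric, 0 when unflagged) and
#'   \code{riskfactor_flags} (named logical).
#' @export
map_codes <- function(codes, registry = default_code_registry()) {
  validate_code_registry(registry)
  norm <- normalize_icd10(codes)
  cls <- classify_codes(unique(norm), registry)
  domains <- names(registry$domain_codes)
  dsev <- vapply(domains, function(d) {
    s <- cls$severity[!is.na(cls$domain) & cls$domain == d]
    if (length(s)) max(s) else 0
  }, numeric(1))
  rfs <- names(registry$riskfactor_codes)
  rflag <- vapply(rfs, function(f) {
    any(!is.na(cls$riskfactor) & cls$riskfactor == f)
  }, logical(1))
  list(domain_flags = dsev > 0, domain_severity = dsev,
       riskfactor_flags = rflag)
}

#' Map ICD-10 codes for a whole cohort
#'
#' Vectorized version of \code{\link{map_codes}}: the cohort's
#' semicolon-delimited \code{icd10} column is parsed once, unique codes are
#' classified once against the registry, and per-subject flags are
#' aggregated. Risk-factor columns already present in the cohort (e.g. from
#' the generator) are left untouched; mapped flags are added with an
#' \code{icd_} prefix for risk factors and as \code{<domain>_severity} /
#' \code{<domain>_flag} for Fabry domains.
#'
#' @param cohort cohort data.frame with an \code{icd10} column.
#' @param registry code registry.
#' @param sep delimiter inside the \code{icd10} column.
#' @return The cohort with mapping columns appended.
#' @export
map_cohort_codes <- function(cohort, registry = default_code_registry(),
                             sep = ";") {
  validate_code_registry(registry)
  if (!"icd10" %in% names(cohort)) {
    stop("cohort has no 'icd10' column", call. = FALSE)
  }
  raw <- cohort$icd10
  raw[is.na(raw)] <- ""
  split <- strsplit(raw, sep, fixed = TRUE)
  lens <- lengths(split)
  flat <- toupper(gsub("[.[:space:]]", "", unlist(split, use.names = FALSE)))
  subj <- rep.int(seq_along(split), lens)
  keep <- nzchar(flat) & grepl("^[A-Z][0-9]{2}[0-9A-Z]*$", flat)
  flat <- flat[keep]
  subj <- subj[keep]
  ucodes <- unique(flat)
  cls <- classify_codes(ucodes, registry)
  idx <- match(flat, ucodes)

  n <- nrow(cohort)
  for (d in names(registry$domain_codes)) {
    sev <- ifelse(!is.na(cls$domain[idx]) & cls$domain[idx] == d,
                  cls$severity[idx], 0)
    agg <- rep(0, n)
    if (length(sev)) {
      m <- tapply(sev, subj, max)
      agg[as.integer(names(m))] <- as.numeric(m)
    }
    cohort[[paste0(d, "_severity")]] <- agg
    cohort[[paste0(d, "_flag")]] <- agg > 0
  }
  for (f in names(registry$riskfactor_codes)) {
    hit <- !is.na(cls$riskfactor[idx]) & cls$riskfactor[idx] == f
    agg <- rep(FALSE, n)
    if (length(hit)) {
      m <- tapply(hit, subj, any)
      agg[as.integer(names(m))] <- as.logical(m)
    }
    cohort[[paste0("icd_", f)]] <- agg
  }
  cohort
}
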