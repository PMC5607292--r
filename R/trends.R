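#' Project a mean pattern count forward with a yearly rate
#'
#' A continuous-time NB trend fit reports a multiplicative rate per year:
#' a rate r applied to a baseline mean m gives m*r after one year. For
#' whole years the projection is iterated year by year with rounding to two
#' decimals at each step (the reporting convention for these tables); for
#' fractional years the continuous exponent is used.
#'
#' @param baseline_mean mean pattern count at baseline.
#' @param rate_per_year multiplicative rate (> 0).
#' @param years projection horizon in years.
#' @return projected mean, rounded to 2 decimals.
#' @examples
#' project_rate(4.46, 0.96, 1)  # 4.28
#' project_rate(4.46, 0.96, 2)  # 4.11
#' @export
project_rate <- function(baseline_mean, rate_per_year, years) {
  stopifnot(rate_per_year > 0, baseline_mean >= 0, years >= 0)
  if (years == as.integer(years)) {
    m <- round(baseline_mean, 2)
    for (k in seq_len(as.integer(years))) m <- round(m * rate_per_year, 2)
    m
  } else {
    round(baseline_mean * rate_per_year^years, 2)
  }
}

#' Per-patient trend estimates and their correlations
#'
#' For each patient separately: the multiplicative rate of change per year
#' in pattern diversity from a patient-level negative binomial regression
#' of counts on years (no random effect; falls back to Poisson when the NB
#' dispersion is inestimable, e.g. for flat or equidispersed counts), the
#' change in percent methylation per year from a linear fit, and the change
#' in polyp count per year from a linear fit. The three pairwise Pearson
#' correlations are computed across patients, both groups pooled (group is
#' kept as a label).
#'
#' @param crypts crypt-level data.frame (`patient_id`, `group`,
#'   `timepoint_years`, `diversity`, `percent_methylation`).
#' @param polyps per-patient polyp counts: data.frame with `patient_id`,
#'   `timepoint_years`, `polyps`.
#' @return list with `trends` (one row per patient) and `correlations`
#'   (pair, r, n).
#' @export
per_patient_trends <- function(crypts, polyps) {
  pts <- unique(crypts$patient_id)
  rows <- lapply(pts, function(pid) {
    d <- crypts[crypts$patient_id == pid & !is.na(crypts$diversity), ]
    if (length(unique(d$timepoint_years)) < 2) {
      warning("patient ", pid, ": <2 timepoints; excluded", call. = FALSE)
      return(NULL)
    }
    if (all(d$diversity == 0)) {
      warning("patient ", pid, ": all-zero counts, rate undefined; excluded",
              call. = FALSE)
      return(NULL)
    }
    nbfit <- tryCatch(
      MASS::glm.nb(diversity ~ timepoint_years, data = d),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(nbfit)) {
      nbfit <- glm(diversity ~ timepoint_years, data = d,
                   family = poisson())
    }
    rate <- exp(coef(nbfit)[["timepoint_years"]])
    pm <- lm(percent_methylation ~ timepoint_years, data = d)
    dpm <- coef(pm)[["timepoint_years"]]
    pp <- polyps[polyps$patient_id == pid, ]
    dpolyp <- if (nrow(pp) >= 2) {
      coef(lm(polyps ~ timepoint_years, data = pp))[["timepoint_years"]]
    } else NA_real_
    data.frame(patient_id = pid, group = d$group[1],
               rate_patterns_per_year = rate,
               delta_percent_per_year = dpm,
               delta_polyps_per_year = dpolyp,
               stringsAsFactors = FALSE)
  })
  trends <- do.call(rbind, rows)
  pair_cor <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3) return(c(r = NA_real_, n = sum(ok)))
    c(r = cor(a[ok], b[ok]), n = sum(ok))
  }
  cors <- rbind(
    data.frame(pair = "patterns_vs_polyps",
               t(pair_cor(trends$rate_patterns_per_year,
                          trends$delta_polyps_per_year))),
    data.frame(pair = "percent_vs_polyps",
               t(pair_cor(trends$delta_percent_per_year,
                          trends$delta_polyps_per_year))),
    data.frame(pair = "patterns_vs_percent",
               t(pair_cor(trends$rate_patterns_per_year,
                          trends$delta_percent_per_year)))
  )
  list(trends = trends, correlations = cors)
}

#' Age-adjusted companion fits
#'
#' Refits the mixed trend model with baseline patient age as an additional
#' fixed covariate and returns it side by side with the unadjusted fit. If
#' ages are missing the adjustment is refused (with a notice) and only the
#' unadjusted fit is returned; if age is constant across patients the
#' covariate is inestimable and dropped with a warning.
#'
#' @param data crypt-level data.frame.
#' @param ages data.frame with `patient_id` and `age`.
#' @param outcome outcome column.
#' @param model `"nb_mixed"` or `"linear_mixed"`.
#' @param time_coding `"continuous"` or `"categorical"`.
#' @param nodes quadrature nodes (NB model).
#' @return list with `unadjusted` and `adjusted` (`NULL` when refused or
#'   dropped) `trend_fit`s.
#' @export
adjust_for_age <- function(data, ages, outcome,
                           model = c("nb_mixed", "linear_mixed"),
                           time_coding = c("continuous", "categorical"),
                           nodes = 25) {
  model <- match.arg(model)
  time_coding <- match.arg(time_coding)
  fit1 <- if (model == "nb_mixed") {
    fit_nb_mixed(data, outcome, time_coding, nodes)
  } else {
    fit_lmm(data, outcome, time_coding)
  }
  if (is.null(ages) || !all(unique(data$patient_id) %in% ages$patient_id) ||
      anyNA(ages$age)) {
    message("ages missing for some patients; running unadjusted only")
    return(list(unadjusted = fit1, adjusted = NULL))
  }
  data$age <- ages$age[match(data$patient_id, ages$patient_id)]
  if (length(unique(data$age)) == 1L) {
    warning("age constant across patients; covariate dropped", call. = FALSE)
    return(list(unadjusted = fit1, adjusted = fit1))
  }
  fit2 <- if (model == "nb_mixed") {
    fit_nb_mixed(data, outcome, time_coding, nodes, covariates = "age")
  } else {
    fit_lmm(data, outcome, time_coding, covariates = "age")
  }
  list(unadjusted = fit1, adjusted = fit2)
}
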