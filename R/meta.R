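# Inverse-variance pooling of AF-recurrence effects (risk ratios and
# hazard ratios) with DerSimonian-Laird random effects, Cochran's Q / I2
# heterogeneity, and the contact-force subgroup split.

Z95 <- 1.959964  # two-sided 95% normal quantile, as used in the CI formulas

#' Log risk ratio of AF recurrence from arm-level counts
#'
#' Treatment arm is CBA, control arm is RFA. A continuity correction `cc`
#' is added to all four cells only when at least one event cell is zero.
#'
#' @param events_t,n_t Events and size of the CBA arm.
#' @param events_c,n_c Events and size of the RFA arm.
#' @param cc Continuity correction (default 0.5), applied to all four cells
#'   only when `events_t` or `events_c` is zero.
#' @param study_id Label carried into the result.
#' @param subgroup RFA-type label: `"CF"`, `"non-CF"` or `"unknown"`.
#' @return One-row data frame with columns `study_id`, `measure`,
#'   `log_effect`, `se`, `subgroup`.
#' @examples
#' rr_effect(10, 100, 20, 100)  # log RR = log(0.5), se = sqrt(0.13)
#' @export
rr_effect <- function(events_t, n_t, events_c, n_c, cc = 0.5,
                      study_id = NA_character_, subgroup = "unknown") {
  if (n_t <= 0 || n_c <= 0) stop("arm sizes must be positive", call. = FALSE)
  if (events_t < 0 || events_c < 0 || events_t > n_t || events_c > n_c) {
    stop("event counts must lie in [0, arm size]", call. = FALSE)
  }
  a <- events_t; b <- n_t; c <- events_c; d <- n_c
  if (a == 0 || c == 0) {
    if (cc <= 0) {
      stop("zero event cell with no continuity correction: ",
           "log risk ratio undefined", call. = FALSE)
    }
    a <- a + cc; c <- c + cc; b <- b + cc; d <- d + cc
  }
  data.frame(
    study_id = study_id,
    measure = "RR",
    log_effect = log((a / b) / (c / d)),
    se = sqrt(1 / a - 1 / b + 1 / c - 1 / d),
    subgroup = subgroup,
    stringsAsFactors = FALSE
  )
}

#' Log hazard ratio from a reported HR and 95% confidence interval
#'
#' The standard error is back-calculated from the interval width on the log
#' scale: `(log(ucl) - log(lcl)) / (2 * 1.959964)`.
#'
#' @param hr,lcl,ucl Hazard ratio and its 95% confidence limits.
#' @param study_id,subgroup As in [rr_effect()].
#' @return One-row data frame with columns as in [rr_effect()].
#' @export
hr_effect <- function(hr, lcl, ucl,
                      study_id = NA_character_, subgroup = "unknown") {
  if (any(c(hr, lcl, ucl) <= 0)) {
    stop("hazard ratio and confidence limits must be positive", call. = FALSE)
  }
  if (lcl > hr || hr > ucl) {
    stop("confidence limits must bracket the hazard ratio", call. = FALSE)
  }
  se <- (log(ucl) - log(lcl)) / (2 * Z95)
  if (se <= 0) stop("degenerate (zero-width) confidence interval", call. = FALSE)
  data.frame(
    study_id = study_id,
    measure = "HR",
    log_effect = log(hr),
    se = se,
    subgroup = subgroup,
    stringsAsFactors = FALSE
  )
}

check_estimates <- function(estimates, min_k = 1) {
  need <- c("study_id", "measure", "log_effect", "se", "subgroup")
  if (!is.data.frame(estimates) || !all(need %in% names(estimates))) {
    stop("estimates must be a data frame with columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  k <- nrow(estimates)
  if (k < min_k) {
    if (min_k >= 2) {
      stop("at least ", min_k, " studies required; ",
           "use the fixed-effect model for a single study", call. = FALSE)
    }
    stop("no estimates supplied", call. = FALSE)
  }
  if (length(unique(estimates$measure)) > 1) {
    stop("mixed effect measures; pool RR and HR separately", call. = FALSE)
  }
  if (any(!is.finite(estimates$log_effect)) || any(estimates$se <= 0)) {
    stop("estimates require finite log_effect and se > 0", call. = FALSE)
  }
  estimates
}

pooled_result <- function(measure, method, log_pooled, se_pooled,
                          q, df, tau2, k) {
  structure(list(
    measure = measure,
    method = method,
    log_pooled = log_pooled,
    se_pooled = se_pooled,
    ci95 = exp(log_pooled + c(-1, 1) * Z95 * se_pooled),
    q = q,
    df = df,
    p_q = if (df > 0) stats::pchisq(q, df, lower.tail = FALSE) else NA_real_,
    i2 = if (q > 0) max(0, (q - df) / q) else 0,
    tau2 = tau2,
    k = k
  ), class = "pooled_result")
}

#' Fixed-effect (inverse-variance) pooling
#'
#' @param estimates Data frame of per-study effects as produced by
#'   [rr_effect()] / [hr_effect()] (rows bound together).
#' @return A `pooled_result`: pooled log effect, its SE, the 95% CI on the
#'   ratio scale, Cochran's Q, degrees of freedom, Q's p-value, I2, tau2
#'   (0 for the fixed model) and the number of studies `k`.
#' @export
pool_fixed <- function(estimates) {
  estimates <- check_estimates(estimates, min_k = 1)
  w <- 1 / estimates$se^2
  y <- estimates$log_effect
  mu <- sum(w * y) / sum(w)
  q <- sum(w * (y - mu)^2)
  pooled_result(estimates$measure[1], "fixed",
                log_pooled = mu, se_pooled = sqrt(1 / sum(w)),
                q = q, df = nrow(estimates) - 1L, tau2 = 0,
                k = nrow(estimates))
}

#' DerSimonian-Laird random-effects pooling
#'
#' Between-study variance is the moment estimator
#' `tau2 = max(0, (Q - df) / (S1 - S2/S1))` with fixed-effect weights
#' (`S1 = sum(w)`, `S2 = sum(w^2)`); the pooled estimate then uses weights
#' `1 / (se^2 + tau2)`. Q, I2 and the Q p-value are reported from the
#' fixed-effect weights, as is conventional.
#'
#' @inheritParams pool_fixed
#' @return A `pooled_result` with `method = "random_DL"`.
#' @export
pool_random_dl <- function(estimates) {
  estimates <- check_estimates(estimates, min_k = 2)
  w <- 1 / estimates$se^2
  y <- estimates$log_effect
  mu_f <- sum(w * y) / sum(w)
  q <- sum(w * (y - mu_f)^2)
  df <- nrow(estimates) - 1L
  s1 <- sum(w)
  s2 <- sum(w^2)
  tau2 <- max(0, (q - df) / (s1 - s2 / s1))
  ws <- 1 / (estimates$se^2 + tau2)
  pooled_result(estimates$measure[1], "random_DL",
                log_pooled = sum(ws * y) / sum(ws),
                se_pooled = sqrt(1 / sum(ws)),
                q = q, df = df, tau2 = tau2, k = nrow(estimates))
}

#' Cochran's Q and the I2 inconsistency index
#'
#' @inheritParams pool_fixed
#' @return List with `q`, `df`, `p_q` and `i2 = max(0, (q - df)/q)`
#'   (0 when `q` is 0).
#' @export
heterogeneity <- function(estimates) {
  res <- pool_fixed(check_estimates(estimates, min_k = 2))
  list(q = res$q, df = res$df, p_q = res$p_q, i2 = res$i2)
}

#' Pool within contact-force subgroups
#'
#' Splits the estimates into the CF-RFA and non-CF-RFA comparator subgroups
#' and pools each independently (fixed and, where at least two studies,
#' random effects). Studies whose RFA type could not be determined are
#' excluded from both subgroups.
#'
#' @inheritParams pool_fixed
#' @return Named list with elements `CF` and `non-CF`; each is `NULL` when
#'   the subgroup is empty, otherwise a list with elements `fixed` and
#'   `random` (`random` is `NULL` for a single-study subgroup).
#' @export
subgroup_pool <- function(estimates) {
  estimates <- check_estimates(estimates, min_k = 1)
  out <- list()
  for (g in c("CF", "non-CF")) {
    sub <- estimates[estimates$subgroup == g, , drop = FALSE]
    out[[g]] <- if (nrow(sub) == 0) NULL else list(
      fixed = pool_fixed(sub),
      random = if (nrow(sub) >= 2) pool_random_dl(sub) else NULL
    )
  }
  out
}

#' Per-study effects from a study table
#'
#' Converts a table of study records (see [read_studies()]) into per-study
#' log effects: arm-level counts for the risk-ratio measure, reported
#' HR + CI for the hazard-ratio measure. Studies lacking the requested
#' measure, or with follow-up shorter than `min_followup` months, are
#' dropped.
#'
#' @param studies Data frame of study records.
#' @param measure `"RR"` or `"HR"`.
#' @param cc Continuity correction for zero cells (RR only).
#' @param min_followup Minimum follow-up in months for inclusion (default 6).
#' @return Data frame of effect estimates.
#' @export
effects_from_studies <- function(studies, measure = c("RR", "HR"),
                                 cc = 0.5, min_followup = 6) {
  measure <- match.arg(measure)
  studies <- check_studies(studies)
  studies <- studies[studies$followup_months >= min_followup, , drop = FALSE]
  rows <- lapply(seq_len(nrow(studies)), function(i) {
    s <- studies[i, ]
    if (measure == "RR") {
      if (is.na(s$events_cba) || is.na(s$events_rfa)) return(NULL)
      rr_effect(s$events_cba, s$n_cba, s$events_rfa, s$n_rfa, cc = cc,
                study_id = s$study_id, subgroup = s$rfa_type)
    } else {
      if (is.na(s$hr)) return(NULL)
      hr_effect(s$hr, s$hr_lcl, s$hr_ucl,
                study_id = s$study_id, subgroup = s$rfa_type)
    }
  })
  do.call(rbind, rows)
}

check_studies <- function(studies) {
  need <- c("study_id", "design", "n_cba", "events_cba", "n_rfa",
            "events_rfa", "hr", "hr_lcl", "hr_ucl", "rfa_type",
            "followup_months")
  if (!is.data.frame(studies) || !all(need %in% names(studies))) {
    stop("study table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(studies$design %in% c("RCT", "PSM"))) {
    stop("design must be RCT or PSM", call. = FALSE)
  }
  if (!all(studies$rfa_type %in% c("CF", "non-CF", "unknown"))) {
    stop("rfa_type must be CF, non-CF or unknown", call. = FALSE)
  }
  has_counts <- !is.na(studies$events_cba) & !is.na(studies$events_rfa)
  has_hr <- !is.na(studies$hr) & !is.na(studies$hr_lcl) & !is.na(studies$hr_ucl)
  if (any(!has_counts & !has_hr)) {
    stop("every study needs event counts or an HR with CI", call. = FALSE)
  }
  bad <- which(has_counts & (studies$events_cba > studies$n_cba |
                             studies$events_rfa > studies$n_rfa))
  if (length(bad)) {
    stop("events exceed arm size for study: ",
         paste(studies$study_id[bad], collapse = ", "), call. = FALSE)
  }
  bad <- which(has_hr & (studies$hr_lcl > studies$hr |
                         studies$hr > studies$hr_ucl))
  if (length(bad)) {
    stop("HR outside its CI for study: ",
         paste(studies$study_id[bad], collapse = ", "), call. = FALSE)
  }
  studies
}

#' Read a study table from CSV
#'
#' Expected columns: `study_id, design, n_cba, events_cba, n_rfa,
#' events_rfa, hr, hr_lcl, hr_ucl, rfa_type, followup_months`; empty cells
#' are permitted where a measure is absent.
#'
#' @param path CSV file path.
#' @return Validated study data frame.
#' @export
read_studies <- function(path) {
  st <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cx in c("n_cba", "events_cba", "n_rfa", "events_rfa")) {
    if (cx %in% names(st)) st[[cx]] <- as.integer(st[[cx]])
  }
  for (cx in c("hr", "hr_lcl", "hr_ucl", "followup_months")) {
    if (cx %in% names(st)) st[[cx]] <- as.numeric(st[[cx]])
  }
  check_studies(st)
}

#' Write a study table to CSV
#' @param studies Study data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_studies <- function(studies, path) {
  utils::write.csv(check_studies(studies), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Forest-plot-ready table of study effects and pooled rows
#'
#' @param estimates Data frame of per-study effects.
#' @param models Which pooled rows to append: any of `"fixed"`, `"random"`.
#' @return Data frame with columns `study`, `ratio`, `ci_low`, `ci_high`,
#'   `weight_pct` (fixed-effect inverse-variance weights, summing to 100
#'   over the studies).
#' @export
forest_table <- function(estimates, models = c("fixed", "random")) {
  estimates <- check_estimates(estimates, min_k = 1)
  w <- 1 / estimates$se^2
  tab <- data.frame(
    study = estimates$study_id,
    ratio = exp(estimates$log_effect),
    ci_low = exp(estimates$log_effect - Z95 * estimates$se),
    ci_high = exp(estimates$log_effect + Z95 * estimates$se),
    weight_pct = 100 * w / sum(w),
    stringsAsFactors = FALSE
  )
  if ("fixed" %in% models) {
    f <- pool_fixed(estimates)
    tab <- rbind(tab, data.frame(study = "Pooled (fixed)",
                                 ratio = exp(f$log_pooled),
                                 ci_low = f$ci95[1], ci_high = f$ci95[2],
                                 weight_pct = NA_real_))
  }
  if ("random" %in% models && nrow(estimates) >= 2) {
    r <- pool_random_dl(estimates)
    tab <- rbind(tab, data.frame(study = "Pooled (random, DL)",
                                 ratio = exp(r$log_pooled),
                                 ci_low = r$ci95[1], ci_high = r$ci95[2],
                                 weight_pct = NA_real_))
  }
  rownames(tab) <- NULL
  tab
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("Pooled %s (%s, k = %d): %.3f [%.3f, %.3f]\n",
              x$measure, x$method, x$k, exp(x$log_pooled),
              x$ci95[1], x$ci95[2]))
  cat(sprintf("  Q = %.3f (df = %d, p = %s), I2 = %.1f%%, tau2 = %.4f\n",
              x$q, x$df,
              if (is.na(x$p_q)) "NA" else sprintf("%.3f", x$p_q),
              100 * x$i2, x$tau2))
  invisible(x)
}
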