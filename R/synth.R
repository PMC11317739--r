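# Synthetic-data generators: meta-analysis study sets with known truth
# (the trial-level inputs behind the published forest plots are not
# deposited) and parametric Gompertz-Makeham life tables (no specific
# national table is named). Both are fixtures with stated truth, used for
# parameter-recovery and property testing.

#' Specification for a synthetic meta-analysis study set
#'
#' Defaults emulate the published evidence base: 18 studies (12 randomized
#' trials, 6 propensity-matched cohorts), per-arm sizes 25-375, baseline
#' AF-recurrence risk 0.2-0.45 over follow-up, a true risk ratio of 0.93
#' with modest between-study heterogeneity, and a contact-force RFA share
#' of 8/14 among studies with a determinable RFA type.
#'
#' @param k Number of studies.
#' @param true_log_rr True mean log risk ratio (CBA vs RFA).
#' @param tau2 Between-study variance of the log risk ratio.
#' @param baseline_risk `c(low, high)` range of the RFA-arm recurrence risk.
#' @param n_per_arm `c(low, high)` range of per-arm sample sizes.
#' @param cf_fraction Probability a study's comparator is contact-force RFA.
#' @param rct_fraction Probability a study is an RCT (else PSM cohort).
#' @param seed Integer seed for reproducible generation.
#' @return A `meta_sim_spec` list.
#' @export
meta_sim_spec <- function(k = 18, true_log_rr = log(0.93), tau2 = 0.01,
                          baseline_risk = c(0.20, 0.45),
                          n_per_arm = c(25, 375), cf_fraction = 8 / 14,
                          rct_fraction = 12 / 18, seed = 1L) {
  stopifnot(k >= 1, tau2 >= 0,
            length(baseline_risk) == 2, baseline_risk[1] <= baseline_risk[2],
            baseline_risk[1] > 0, baseline_risk[2] < 1,
            length(n_per_arm) == 2, n_per_arm[1] <= n_per_arm[2],
            n_per_arm[1] >= 1,
            cf_fraction >= 0, cf_fraction <= 1,
            rct_fraction >= 0, rct_fraction <= 1)
  structure(list(k = as.integer(k), true_log_rr = true_log_rr, tau2 = tau2,
                 baseline_risk = baseline_risk, n_per_arm = n_per_arm,
                 cf_fraction = cf_fraction, rct_fraction = rct_fraction,
                 seed = as.integer(seed)), class = "meta_sim_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Simulate a meta-analysis study set with known truth
#'
#' Per study: a baseline (RFA-arm) risk and per-arm sizes are drawn
#' uniformly from their ranges, a study-level log risk ratio is drawn from
#' `Normal(true_log_rr, tau2)`, events are binomial in each arm with the
#' CBA-arm risk equal to the baseline risk times the study's risk ratio
#' (capped below 1), and the comparator RFA type is contact-force with
#' probability `cf_fraction`. Generation is reproducible under the spec's
#' seed and leaves the global random stream untouched.
#'
#' @param spec A `meta_sim_spec`.
#' @return A study data frame as accepted by [effects_from_studies()].
#' @export
simulate_meta_dataset <- function(spec = meta_sim_spec()) {
  stopifnot(inherits(spec, "meta_sim_spec"))
  with_seed(spec$seed, {
    k <- spec$k
    base <- stats::runif(k, spec$baseline_risk[1], spec$baseline_risk[2])
    theta <- stats::rnorm(k, spec$true_log_rr, sqrt(spec$tau2))
    n_rfa <- as.integer(round(stats::runif(k, spec$n_per_arm[1], spec$n_per_arm[2])))
    n_cba <- as.integer(round(stats::runif(k, spec$n_per_arm[1], spec$n_per_arm[2])))
    risk_cba <- pmin(0.999, base * exp(theta))
    data.frame(
      study_id = sprintf("study_%02d", seq_len(k)),
      design = ifelse(stats::runif(k) < spec$rct_fraction, "RCT", "PSM"),
      n_cba = n_cba,
      events_cba = stats::rbinom(k, n_cba, risk_cba),
      n_rfa = n_rfa,
      events_rfa = stats::rbinom(k, n_rfa, base),
      hr = NA_real_, hr_lcl = NA_real_, hr_ucl = NA_real_,
      rfa_type = ifelse(stats::runif(k) < spec$cf_fraction, "CF", "non-CF"),
      followup_months = 12,
      stringsAsFactors = FALSE
    )
  })
}

#' Specification for a parametric life table
#'
#' Gompertz-Makeham hazard: `qx(age) = min(1, a + b * exp(c * age))`, with
#' the male column scaled by a constant excess-mortality multiplier.
#' Defaults are tuned so a mixed-sex cohort entering at age 64.6 has a
#' remaining life expectancy of roughly two decades, a realistic scale for
#' a contemporary high-income population; this is a synthetic fixture, not
#' a published national table.
#'
#' @param makeham_a Age-independent annual hazard component.
#' @param gompertz_b,gompertz_c Gompertz level and slope.
#' @param male_excess Multiplier on the male column.
#' @param max_age Final table age; its row is forced to probability 1.
#' @return A `life_table_spec` list.
#' @export
life_table_spec <- function(makeham_a = 5e-4, gompertz_b = 1e-5,
                            gompertz_c = 0.1, male_excess = 1.6,
                            max_age = 110L) {
  stopifnot(makeham_a >= 0, gompertz_b >= 0, gompertz_c >= 0,
            male_excess > 0, max_age > 0)
  structure(list(makeham_a = makeham_a, gompertz_b = gompertz_b,
                 gompertz_c = gompertz_c, male_excess = male_excess,
                 max_age = as.integer(max_age)), class = "life_table_spec")
}

#' Generate a parametric life table
#'
#' @param spec A `life_table_spec`.
#' @return A validated life table (ages 0 to `max_age`) as accepted by
#'   [run_markov()].
#' @examples
#' lt <- make_life_table()
#' blended_mortality(64.6, 0.67, lt)
#' @export
make_life_table <- function(spec = life_table_spec()) {
  stopifnot(inherits(spec, "life_table_spec"))
  age <- 0:spec$max_age
  qx <- pmin(1, spec$makeham_a + spec$gompertz_b * exp(spec$gompertz_c * age))
  lt <- data.frame(
    age = age,
    qx_male = pmin(1, qx * spec$male_excess),
    qx_female = qx
  )
  lt$qx_male[length(age)] <- 1
  lt$qx_female[length(age)] <- 1
  validate_life_table(lt)
}
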