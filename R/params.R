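#' @keywords internal
"_PACKAGE"

# Complication labels shared by the probability and cost maps.
SAE_TYPES <- c("esophageal", "tamponade", "pv_stenosis",
               "phrenic_palsy", "vascular", "groin")

MP_PROB_FIELDS <- c(
  "male_fraction", "p_recur_first", "p_reablate_2nd", "p_reablate_3rd",
  "mix_2nd_rfa_after_rfa", "mix_2nd_rfa_after_cba",
  "mix_3rd_rfa_after_rfa", "mix_3rd_rfa_after_cba",
  "p_is_tree", "p_death_tree",
  "p_recur_markov_y12", "p_recur_markov_later", "p_is_markov",
  "p_is_death_28d", "p_is_death_1y_survivors", "p_death_post_is"
)

MP_COST_FIELDS <- c(
  "cost_proc_rfa", "cost_proc_cba", "cost_is_nonfatal", "cost_is_fatal",
  "cost_state_af_pos", "cost_state_af_neg", "cost_state_post_is"
)

MP_SCALAR_FIELDS <- c(
  "start_age", MP_PROB_FIELDS, "rr_recur_reablation", MP_COST_FIELDS,
  "discount_rate", "jpy_per_usd"
)

MP_ALL_FIELDS <- c(MP_SCALAR_FIELDS, "sae_probs_rfa", "sae_probs_cba",
                   "sae_costs", "dsa_ranges")

mp_defaults <- function() {
  list(
    start_age = 64.6,
    male_fraction = 0.67,
    p_recur_first = 0.268,
    rr_recur_reablation = 1.61,
    p_reablate_2nd = 0.78,
    p_reablate_3rd = 0.37,
    mix_2nd_rfa_after_rfa = 0.983,
    mix_2nd_rfa_after_cba = 0.964,
    mix_3rd_rfa_after_rfa = 0.979,
    mix_3rd_rfa_after_cba = 1.00,
    sae_probs_rfa = c(esophageal = 0.005, tamponade = 0.010,
                      pv_stenosis = 0.010, phrenic_palsy = 0,
                      vascular = 0.020, groin = 0.010),
    sae_probs_cba = c(esophageal = 0.005, tamponade = 0.004,
                      pv_stenosis = 0.010, phrenic_palsy = 0.010,
                      vascular = 0.020, groin = 0.010),
    p_is_tree = 0.007,
    p_death_tree = 0.012,
    p_recur_markov_y12 = 0.077,
    p_recur_markov_later = 0.041,
    p_is_markov = 0.0024,
    p_is_death_28d = 0.073,
    p_is_death_1y_survivors = 0.127,
    p_death_post_is = 0.085,
    cost_proc_rfa = 2256516,
    cost_proc_cba = 2609223,
    sae_costs = c(esophageal = 3261455, tamponade = 160598,
                  pv_stenosis = 1679342, phrenic_palsy = 15230,
                  vascular = 107065, groin = 107065),
    cost_is_nonfatal = 1127624,
    cost_is_fatal = 2429749,
    cost_state_af_pos = 172780,
    cost_state_af_neg = 36373,
    cost_state_post_is = 67486,
    discount_rate = 0.02,
    jpy_per_usd = 150,
    dsa_ranges = default_dsa_ranges()
  )
}

#' Default one-way sensitivity ranges
#'
#' The published deterministic-sensitivity bounds for every varied model
#' input: 95% confidence limits where the source reported them, otherwise
#' +/-20% of the base value, and 0--4% for the discount rate. Complication
#' probabilities shared by both procedures (`sae_prob_<type>`) are varied
#' jointly; procedure-specific entries carry a `_rfa`/`_cba` suffix. The
#' proportion of third ablations performed by RFA after a second CBA has no
#' published range and is not varied.
#'
#' @return Named list; each element is `c(low, high)` in the parameter's
#'   own units (probabilities as proportions, costs in JPY).
#' @export
default_dsa_ranges <- function() {
  list(
    start_age                 = c(63.9, 65.3),
    male_fraction             = c(0.638, 0.702),
    p_recur_first             = c(0.214, 0.322),
    rr_recur_reablation       = c(1.29, 1.93),
    p_reablate_2nd            = c(0.735, 0.825),
    p_reablate_3rd            = c(0.214, 0.526),
    mix_2nd_rfa_after_rfa     = c(0.978, 0.988),
    mix_2nd_rfa_after_cba     = c(0.952, 0.976),
    mix_3rd_rfa_after_rfa     = c(0.961, 0.997),
    sae_prob_esophageal       = c(0.004, 0.006),
    sae_prob_tamponade_rfa    = c(0.008, 0.012),
    sae_prob_tamponade_cba    = c(0.003, 0.005),
    sae_prob_pv_stenosis      = c(0.008, 0.012),
    sae_prob_phrenic_palsy_cba = c(0.008, 0.012),
    sae_prob_vascular         = c(0.016, 0.024),
    sae_prob_groin            = c(0.008, 0.012),
    p_is_tree                 = c(0.006, 0.008),
    p_death_tree              = c(0.010, 0.014),
    p_recur_markov_y12        = c(0.062, 0.092),
    p_recur_markov_later      = c(0.033, 0.049),
    p_is_markov               = c(0.002, 0.003),
    p_is_death_28d            = c(0.058, 0.088),
    p_is_death_1y_survivors   = c(0.102, 0.152),
    p_death_post_is           = c(0.068, 0.102),
    cost_proc_rfa             = c(2247957, 2265075),
    cost_proc_cba             = c(2600718, 2617728),
    sae_cost_esophageal       = c(2067117, 4455793),
    sae_cost_tamponade        = c(157987, 163211),
    sae_cost_pv_stenosis      = c(1152122, 2206562),
    sae_cost_phrenic_palsy    = c(12184, 18276),
    sae_cost_vascular         = c(105325, 108807),
    sae_cost_groin            = c(105325, 108807),
    cost_is_nonfatal          = c(862765, 1392483),
    cost_is_fatal             = c(179672, 4679826),
    cost_state_af_pos         = c(138224, 207336),
    cost_state_af_neg         = c(33975, 38771),
    cost_state_post_is        = c(21579, 113393),
    discount_rate             = c(0, 0.04)
  )
}

#' Construct the model parameter set
#'
#' Builds the complete input set of the cost-minimization model: the initial
#' cohort (starting age 64.6 years, 67% male), decision-tree probabilities
#' (first-ablation recurrence 26.8%, re-ablation recurrence relative risk
#' 1.61, re-ablation uptake 78%/37%, repeat-procedure RFA/CBA proportions),
#' per-procedure serious-adverse-event probabilities, per-procedure ischemic
#' stroke (0.7%) and death (1.2%) risks, annual Markov probabilities,
#' procedure and event unit costs in JPY, annual health-state management
#' costs, a 2%/year discount rate and the one-way sensitivity ranges.
#' Defaults reproduce the published base case; any field can be overridden.
#'
#' @param ... Named overrides of any parameter field (see [mp_field_names()]).
#' @return A validated object of class `model_params`.
#' @examples
#' p <- model_params()
#' p$cost_proc_cba - p$cost_proc_rfa  # 352707 JPY
#' model_params(discount_rate = 0)
#' @export
model_params <- function(...) {
  p <- mp_defaults()
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("all overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(dots), MP_ALL_FIELDS)
    if (length(unknown)) {
      stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    for (nm in names(dots)) p[[nm]] <- dots[[nm]]
    # Overrides may move a base value outside its default sensitivity
    # bracket; unless the caller supplied dsa_ranges explicitly, widen the
    # affected ranges so the bracket invariant still holds.
    if (!"dsa_ranges" %in% names(dots)) {
      for (nm in names(p$dsa_ranges)) {
        base <- dsa_base_value(p, nm)
        rng <- p$dsa_ranges[[nm]]
        p$dsa_ranges[[nm]] <- c(min(rng[1], base), max(rng[2], base))
      }
    }
  }
  validate_params(p)
}

#' Parameter field names
#' @return Character vector of the fields accepted by [model_params()].
#' @export
mp_field_names <- function() MP_ALL_FIELDS

#' Validate a model parameter set
#'
#' Checks that every probability lies in \[0, 1\], every cost is
#' non-negative, the discount rate lies in \[0, 1), the complication maps
#' cover the six complication types for both procedures, and every
#' sensitivity range brackets its base value.
#'
#' @param p A list of parameter fields.
#' @return The validated `model_params` object (invisibly usable in pipes).
#' @export
validate_params <- function(p) {
  missing <- setdiff(MP_ALL_FIELDS, names(p))
  if (length(missing)) {
    stop("missing parameter field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(p), MP_ALL_FIELDS)
  if (length(extra)) {
    stop("unknown parameter field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  for (nm in MP_SCALAR_FIELDS) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("field ", nm, " must be a single finite number", call. = FALSE)
    }
  }
  for (nm in MP_PROB_FIELDS) {
    v <- p[[nm]]
    if (v < 0 || v > 1) {
      stop("probability field ", nm, " out of [0, 1]: ", v, call. = FALSE)
    }
  }
  for (nm in c("sae_probs_rfa", "sae_probs_cba")) {
    v <- p[[nm]]
    if (!is.numeric(v) || !setequal(names(v), SAE_TYPES)) {
      stop(nm, " must be a named vector over: ",
           paste(SAE_TYPES, collapse = ", "), call. = FALSE)
    }
    p[[nm]] <- v[SAE_TYPES]
    if (any(v < 0 | v > 1)) {
      stop("probability field ", nm, " out of [0, 1]", call. = FALSE)
    }
  }
  if (!is.numeric(p$sae_costs) || !setequal(names(p$sae_costs), SAE_TYPES)) {
    stop("sae_costs must be a named vector over: ",
         paste(SAE_TYPES, collapse = ", "), call. = FALSE)
  }
  p$sae_costs <- p$sae_costs[SAE_TYPES]
  if (any(p$sae_costs < 0)) stop("sae_costs must be >= 0", call. = FALSE)
  for (nm in MP_COST_FIELDS) {
    if (p[[nm]] < 0) stop("cost field ", nm, " must be >= 0", call. = FALSE)
  }
  if (p$rr_recur_reablation < 0) {
    stop("rr_recur_reablation must be >= 0", call. = FALSE)
  }
  if (p$discount_rate < 0 || p$discount_rate >= 1) {
    stop("discount_rate must lie in [0, 1)", call. = FALSE)
  }
  if (p$jpy_per_usd <= 0) stop("jpy_per_usd must be > 0", call. = FALSE)
  if (p$start_age <= 0) stop("start_age must be > 0", call. = FALSE)
  if (!is.list(p$dsa_ranges) || is.null(names(p$dsa_ranges))) {
    stop("dsa_ranges must be a named list of c(low, high)", call. = FALSE)
  }
  for (nm in names(p$dsa_ranges)) {
    rng <- as.numeric(p$dsa_ranges[[nm]])
    if (length(rng) != 2 || any(!is.finite(rng)) || rng[1] > rng[2]) {
      stop("dsa_ranges[", nm, "] must be c(low, high) with low <= high",
           call. = FALSE)
    }
    base <- dsa_base_value(p, nm)
    if (base < rng[1] - 1e-12 || base > rng[2] + 1e-12) {
      stop("dsa_ranges[", nm, "]: base value ", base,
           " outside [", rng[1], ", ", rng[2], "]", call. = FALSE)
    }
    p$dsa_ranges[[nm]] <- rng
  }
  structure(p, class = "model_params")
}

# Map a sensitivity-range name to the base value it varies.
dsa_base_value <- function(p, name) {
  if (name %in% MP_SCALAR_FIELDS) return(p[[name]])
  if (grepl("^sae_prob_", name)) {
    stem <- sub("^sae_prob_", "", name)
    if (grepl("_rfa$", stem)) return(unname(p$sae_probs_rfa[sub("_rfa$", "", stem)]))
    if (grepl("_cba$", stem)) return(unname(p$sae_probs_cba[sub("_cba$", "", stem)]))
    return(unname(p$sae_probs_rfa[stem]))  # joint RFA/CBA row
  }
  if (grepl("^sae_cost_", name)) {
    return(unname(p$sae_costs[sub("^sae_cost_", "", name)]))
  }
  stop("unknown sensitivity parameter: ", name, call. = FALSE)
}

#' Set one sensitivity parameter to a given value
#'
#' Returns a copy of `p` with the parameter named as in
#' [default_dsa_ranges()] set to `value`. Joint rows (complication
#' probabilities shared by RFA and CBA) are applied to both procedures.
#' Probability values outside \[0, 1\] are clipped with a warning.
#'
#' @param p A `model_params` object.
#' @param name Sensitivity-parameter name.
#' @param value New value in the parameter's units.
#' @return A validated `model_params` object.
#' @export
apply_dsa_value <- function(p, name, value) {
  stopifnot(inherits(p, "model_params"))
  is_prob <- name %in% MP_PROB_FIELDS || grepl("^sae_prob_", name)
  if (is_prob && (value < 0 || value > 1)) {
    clipped <- min(1, max(0, value))
    warning("clipping ", name, " from ", value, " to ", clipped)
    value <- clipped
  }
  q <- unclass(p)
  if (name %in% MP_SCALAR_FIELDS) {
    q[[name]] <- value
  } else if (grepl("^sae_prob_", name)) {
    stem <- sub("^sae_prob_", "", name)
    if (grepl("_rfa$", stem)) {
      q$sae_probs_rfa[sub("_rfa$", "", stem)] <- value
    } else if (grepl("_cba$", stem)) {
      q$sae_probs_cba[sub("_cba$", "", stem)] <- value
    } else {
      q$sae_probs_rfa[stem] <- value
      q$sae_probs_cba[stem] <- value
    }
  } else if (grepl("^sae_cost_", name)) {
    q$sae_costs[sub("^sae_cost_", "", name)] <- value
  } else {
    stop("unknown sensitivity parameter: ", name, call. = FALSE)
  }
  # The perturbed value may legitimately fall outside its own DSA bracket.
  rng <- q$dsa_ranges[[name]]
  if (!is.null(rng)) {
    q$dsa_ranges[[name]] <- c(min(rng[1], value), max(rng[2], value))
  }
  validate_params(q)
}

#' Recurrence probability after a repeat ablation
#'
#' The recurrence risk after a re-ablation is the first-ablation recurrence
#' probability scaled by the re-ablation relative risk, capped at 1 so that
#' sensitivity extremes cannot produce an invalid cohort.
#'
#' @param p A `model_params` object.
#' @return A probability; `min(1, p_recur_first * rr_recur_reablation)`.
#' @examples
#' effective_recurrence_after_reablation(model_params())  # 0.43148
#' @export
effective_recurrence_after_reablation <- function(p) {
  stopifnot(inherits(p, "model_params"))
  min(1, p$p_recur_first * p$rr_recur_reablation)
}

#' Read model parameters from a YAML configuration
#'
#' The configuration is a flat key/value file mirroring the model-input
#' table: scalar fields at top level, the complication probability/cost maps
#' as nested mappings, and `dsa_ranges` as a mapping from parameter name to
#' `[low, high]`. Every field is required and unknown keys are rejected, so
#' a configuration diffs line-by-line against the printed table. The
#' bundled default is at
#' `system.file("extdata", "params_default.yaml", package = "afablcma")`.
#'
#' @param path Path to a YAML file.
#' @return A validated `model_params` object.
#' @export
load_params <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  for (nm in c("sae_probs_rfa", "sae_probs_cba", "sae_costs")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  if (!is.null(raw$dsa_ranges)) {
    raw$dsa_ranges <- lapply(raw$dsa_ranges, as.numeric)
  }
  validate_params(raw)
}

#' Write model parameters to a YAML configuration
#'
#' Inverse of [load_params()]: `load_params(dump_params(p))` reproduces `p`
#' field-for-field.
#'
#' @param p A `model_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
dump_params <- function(p, path) {
  stopifnot(inherits(p, "model_params"))
  out <- unclass(p)
  for (nm in c("sae_probs_rfa", "sae_probs_cba", "sae_costs")) {
    out[[nm]] <- as.list(out[[nm]])
  }
  out$dsa_ranges <- lapply(out$dsa_ranges, as.numeric)
  writeLines(yaml::as.yaml(out, precision = 15), path)
  invisible(path)
}

#' Tabulate the parameter set with its sensitivity ranges
#'
#' @param p A `model_params` object.
#' @return A data frame with columns `parameter`, `base`, `dsa_low`,
#'   `dsa_high` (NA where a parameter is not varied).
#' @export
params_table <- function(p) {
  stopifnot(inherits(p, "model_params"))
  scalars <- data.frame(
    parameter = MP_SCALAR_FIELDS,
    base = vapply(MP_SCALAR_FIELDS, function(nm) p[[nm]], numeric(1)),
    stringsAsFactors = FALSE
  )
  maps <- rbind(
    data.frame(parameter = paste0("sae_prob_", SAE_TYPES, "_rfa"),
               base = unname(p$sae_probs_rfa), stringsAsFactors = FALSE),
    data.frame(parameter = paste0("sae_prob_", SAE_TYPES, "_cba"),
               base = unname(p$sae_probs_cba), stringsAsFactors = FALSE),
    data.frame(parameter = paste0("sae_cost_", SAE_TYPES),
               base = unname(p$sae_costs), stringsAsFactors = FALSE)
  )
  tab <- rbind(scalars, maps)
  tab$dsa_low <- NA_real_
  tab$dsa_high <- NA_real_
  for (nm in names(p$dsa_ranges)) {
    rng <- p$dsa_ranges[[nm]]
    hit <- tab$parameter == nm
    if (!any(hit) && grepl("^sae_prob_", nm)) {
      # joint RFA/CBA rows expand to both procedure-specific rows
      hit <- tab$parameter %in% paste0(nm, c("_rfa", "_cba"))
    }
    tab$dsa_low[hit] <- rng[1]
    tab$dsa_high[hit] <- rng[2]
  }
  rownames(tab) <- NULL
  tab
}

#' @export
print.model_params <- function(x, ...) {
  cat("Cost-minimization model parameters (",
      length(MP_SCALAR_FIELDS) + 3 * length(SAE_TYPES),
      " values, JPY costs)\n", sep = "")
  cat("  cohort: start age ", x$start_age, ", ",
      round(100 * x$male_fraction, 1), "% male\n", sep = "")
  cat("  procedure costs: RFA ", format(x$cost_proc_rfa, big.mark = ","),
      " / CBA ", format(x$cost_proc_cba, big.mark = ","), "\n", sep = "")
  cat("  discount rate: ", 100 * x$discount_rate, "%/year; ",
      length(x$dsa_ranges), " sensitivity ranges\n", sep = "")
  invisible(x)
}
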