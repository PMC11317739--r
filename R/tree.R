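# Two-year decision tree: first ablation at model entry, optional repeat
# ablations at 6 and 18 months, per-procedure complications, ischemic
# stroke and death. Emits discounted intervention / complication / stroke
# costs and the cohort distribution handed to the Markov model.

#' Define an ablation strategy
#'
#' A strategy fixes the first procedure (RFA or CBA) and carries the
#' repeat-procedure mixes: every re-ablation is RFA or CBA with constant
#' claims-data proportions that depend on the preceding procedure.
#'
#' @param name `"RFA_first"` or `"CBA_first"` (case-insensitive; `"rfa"` /
#'   `"cba"` accepted).
#' @param p A `model_params` object supplying the repeat-procedure mixes.
#' @return An object of class `strategy`.
#' @export
strategy <- function(name, p) {
  stopifnot(inherits(p, "model_params"))
  key <- toupper(sub("_first$", "", tolower(name)))
  if (!key %in% c("RFA", "CBA")) {
    stop("strategy must be RFA_first or CBA_first", call. = FALSE)
  }
  structure(list(
    name = paste0(key, "_first"),
    first_proc = key,
    mix_2nd_rfa = if (key == "RFA") p$mix_2nd_rfa_after_rfa else p$mix_2nd_rfa_after_cba,
    mix_3rd_rfa_after_rfa = p$mix_3rd_rfa_after_rfa,
    mix_3rd_rfa_after_cba = p$mix_3rd_rfa_after_cba
  ), class = "strategy")
}

# Probability that the procedure performed at a stage is RFA.
stage_rfa_share <- function(stage, strat) {
  switch(stage,
    `1` = as.numeric(strat$first_proc == "RFA"),
    `2` = strat$mix_2nd_rfa,
    `3` = strat$mix_2nd_rfa * strat$mix_3rd_rfa_after_rfa +
          (1 - strat$mix_2nd_rfa) * strat$mix_3rd_rfa_after_cba,
    stop("stage must be 1, 2 or 3", call. = FALSE)
  )
}

#' Expected procedure cost at a decision-tree stage
#'
#' Stage 1 is the strategy's first procedure at its unit cost; stages 2 and
#' 3 are mixes of the RFA and CBA unit costs under the repeat-procedure
#' proportions (stage 3 propagates the stage-2 procedure distribution
#' through the third-procedure proportions).
#'
#' @param stage 1, 2 or 3.
#' @param strat A `strategy`.
#' @param p A `model_params` object.
#' @return Expected cost in JPY of the procedure performed at that stage.
#' @export
procedure_cost_mix <- function(stage, strat, p) {
  stopifnot(inherits(strat, "strategy"), inherits(p, "model_params"))
  share <- stage_rfa_share(stage, strat)
  share * p$cost_proc_rfa + (1 - share) * p$cost_proc_cba
}

#' Expected complication cost of one procedure
#'
#' Sum over the six complication types of the per-procedure probability
#' times the unit cost. Ischemic stroke and procedural death are accounted
#' separately (stroke costs feed the fatal/non-fatal stroke buckets).
#'
#' @param proc `"RFA"` or `"CBA"`.
#' @param p A `model_params` object.
#' @return Expected complication cost in JPY per procedure.
#' @export
per_procedure_sae_cost <- function(proc, p) {
  stopifnot(inherits(p, "model_params"))
  proc <- toupper(proc)
  probs <- switch(proc, RFA = p$sae_probs_rfa, CBA = p$sae_probs_cba,
                  stop("proc must be RFA or CBA", call. = FALSE))
  sum(probs * p$sae_costs)
}

#' Probabilities of reaching the repeat-ablation stages
#'
#' The second ablation requires recurrence after the first procedure and
#' uptake of a second procedure; the third additionally requires recurrence
#' after the second (at the relative-risk-scaled probability) and uptake of
#' a third. No mortality attrition is applied between stages.
#'
#' @param p A `model_params` object.
#' @return `c(p_stage2, p_stage3)`.
#' @export
stage_probabilities <- function(p) {
  stopifnot(inherits(p, "model_params"))
  p2 <- p$p_recur_first * p$p_reablate_2nd
  p3 <- p2 * effective_recurrence_after_reablation(p) * p$p_reablate_3rd
  c(p_stage2 = p2, p_stage3 = p3)
}

#' Run the two-year decision tree
#'
#' Expected-value evaluation of the tree: procedures at entry, 6 months and
#' 18 months, weighted by the stage probabilities. The entry and 6-month
#' procedures are undiscounted; the 18-month procedure is discounted one
#' full year. Each procedure performed carries the per-procedure
#' complication, ischemic-stroke (split fatal / non-fatal at the 28-day
#' case fatality) and death risks. The surviving cohort is handed to the
#' Markov model split into a year-2 subcohort and a year-3 subcohort (the
#' third-ablation patients).
#'
#' @param strat A `strategy`, or a strategy name accepted by [strategy()].
#' @param p A `model_params` object.
#' @return An object of class `tree_outcome`: discounted cost components
#'   (`cost_intervention`, `cost_sae`, `cost_is_fatal`, `cost_is_nonfatal`),
#'   the overall Markov `entry_distribution` over
#'   `AF-`, `AF+`, `IS`, `Post-IS`, `Dead`, the per-subcohort distributions
#'   and weights (`entry_year2`, `entry_year3`, `w_year3`), and the stage
#'   probabilities `procedures_expected`.
#' @examples
#' p <- model_params()
#' run_tree("RFA_first", p)$cost_intervention  # ~2,803,539 JPY
#' @export
run_tree <- function(strat, p) {
  stopifnot(inherits(p, "model_params"))
  if (!inherits(strat, "strategy")) strat <- strategy(strat, p)
  ps <- c(1, unname(stage_probabilities(p)))
  disc <- c(1, 1, 1 / (1 + p$discount_rate))

  sae_rfa <- per_procedure_sae_cost("RFA", p)
  sae_cba <- per_procedure_sae_cost("CBA", p)
  share <- vapply(1:3, stage_rfa_share, numeric(1), strat = strat)
  proc_cost <- share * p$cost_proc_rfa + (1 - share) * p$cost_proc_cba
  sae_cost <- share * sae_rfa + (1 - share) * sae_cba

  cost_intervention <- sum(ps * proc_cost * disc)
  cost_sae <- sum(ps * sae_cost * disc)

  p_fatal <- p$p_is_death_28d
  is_weight <- sum(ps * disc) * p$p_is_tree
  cost_is_fatal <- is_weight * p_fatal * p$cost_is_fatal
  cost_is_nonfatal <- is_weight * (1 - p_fatal) * p$cost_is_nonfatal

  # Markov-entry split. Third-ablation patients (fraction ps[3]) enter in
  # year 3 having had three procedures; everyone else enters in year 2.
  # Per-procedure stroke/death fractions are overlaid on the AF+/AF- split
  # proportionally (expected-value accounting, no attrition between stages).
  p_recur2 <- effective_recurrence_after_reablation(p)
  w3 <- ps[3]
  entry3 <- entry_split(af_pos_raw = p_recur2, n_proc = 3, p = p)
  raw_af_pos2 <- p$p_recur_first * (1 - p$p_reablate_2nd) +
    ps[2] * p_recur2 * (1 - p$p_reablate_3rd)
  if (w3 < 1) {
    n_proc2 <- (sum(ps) - 3 * w3) / (1 - w3)  # expected procedures, year-2 subcohort
    entry2 <- entry_split(af_pos_raw = raw_af_pos2 / (1 - w3),
                          n_proc = n_proc2, p = p)
  } else {
    entry2 <- entry_split(0, 0, p)
  }
  entry <- w3 * entry3 + (1 - w3) * entry2

  structure(list(
    strategy = strat$name,
    cost_intervention = cost_intervention,
    cost_sae = cost_sae,
    cost_is_fatal = cost_is_fatal,
    cost_is_nonfatal = cost_is_nonfatal,
    entry_distribution = entry,
    entry_year2 = entry2,
    entry_year3 = entry3,
    w_year3 = w3,
    procedures_expected = ps
  ), class = "tree_outcome")
}

# State split at Markov entry for a subcohort with n_proc procedures and a
# raw (pre-overlay) AF-recurrence fraction. Stroke dominates AF status;
# death removes patients from all other states.
entry_split <- function(af_pos_raw, n_proc, p) {
  dead <- n_proc * (p$p_death_tree + p$p_is_tree * p$p_is_death_28d)
  is_surv <- n_proc * p$p_is_tree * (1 - p$p_is_death_28d)
  alive_no_is <- 1 - dead - is_surv
  if (alive_no_is < 0) {
    stop("tree stroke/death probabilities exceed the cohort", call. = FALSE)
  }
  af_pos <- af_pos_raw * alive_no_is
  c(`AF-` = alive_no_is - af_pos, `AF+` = af_pos, IS = is_surv,
    `Post-IS` = 0, Dead = dead)
}

#' @export
print.tree_outcome <- function(x, ...) {
  cat("Decision-tree outcome,", x$strategy, "\n")
  cat(sprintf("  intervention cost: %12.0f JPY\n", x$cost_intervention))
  cat(sprintf("  complication cost: %12.0f JPY\n", x$cost_sae))
  cat(sprintf("  stroke cost (fatal/non-fatal): %.0f / %.0f JPY\n",
              x$cost_is_fatal, x$cost_is_nonfatal))
  cat("  Markov entry:",
      paste(sprintf("%s %.4f", names(x$entry_distribution),
                    x$entry_distribution), collapse = ", "), "\n")
  invisible(x)
}
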