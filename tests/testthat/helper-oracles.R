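# Independent oracles and shared fixtures for the test suite.

# Brute-force inverse-variance pooling: explicit elementwise arithmetic,
# kept deliberately separate from the package's vectorized implementation.
brute_force_pool <- function(y, se, random = FALSE) {
  k <- length(y)
  w <- num <- 0
  for (i in seq_len(k)) {
    wi <- 1 / (se[i] * se[i])
    w <- w + wi
    num <- num + wi * y[i]
  }
  mu <- num / w
  q <- 0
  for (i in seq_len(k)) q <- q + (y[i] - mu)^2 / (se[i] * se[i])
  tau2 <- 0
  if (random && k >= 2) {
    s1 <- s2 <- 0
    for (i in seq_len(k)) {
      s1 <- s1 + 1 / se[i]^2
      s2 <- s2 + 1 / se[i]^4
    }
    tau2 <- max(0, (q - (k - 1)) / (s1 - s2 / s1))
    w <- num <- 0
    for (i in seq_len(k)) {
      wi <- 1 / (se[i]^2 + tau2)
      w <- w + wi
      num <- num + wi * y[i]
    }
    mu <- num / w
  }
  list(mu = mu, se = sqrt(1 / w), q = q, tau2 = tau2)
}

as_estimates <- function(y, se, measure = "RR") {
  data.frame(study_id = sprintf("s%d", seq_along(y)),
             measure = rep(measure, length(y)),
             log_effect = y, se = se,
             subgroup = rep("unknown", length(y)),
             stringsAsFactors = FALSE)
}

# Individual-level Monte-Carlo simulation of the decision tree: the same
# branch structure as run_tree but evaluated by sampling patients, used as
# an independent check on the expected-value engine.
microsim_tree <- function(strategy_name, p, n = 1e5, seed = 42) {
  set.seed(seed)
  first <- toupper(sub("_first$", "", tolower(strategy_name)))
  mix2 <- if (first == "RFA") p$mix_2nd_rfa_after_rfa else p$mix_2nd_rfa_after_cba
  p_recur2 <- effective_recurrence_after_reablation(p)
  disc3 <- 1 / (1 + p$discount_rate)

  rec1 <- stats::rbinom(n, 1, p$p_recur_first) == 1
  re2 <- rec1 & stats::rbinom(n, 1, p$p_reablate_2nd) == 1
  rec2 <- re2 & stats::rbinom(n, 1, p_recur2) == 1
  re3 <- rec2 & stats::rbinom(n, 1, p$p_reablate_3rd) == 1

  proc2_rfa <- re2 & stats::runif(n) < mix2
  mix3 <- ifelse(proc2_rfa, p$mix_3rd_rfa_after_rfa, p$mix_3rd_rfa_after_cba)
  proc3_rfa <- re3 & stats::runif(n) < mix3

  proc_cost <- function(is_rfa) {
    ifelse(is_rfa, p$cost_proc_rfa, p$cost_proc_cba)
  }
  sae_draw <- function(active, is_rfa) {
    # complication costs for the subset of patients undergoing a procedure
    out <- numeric(n)
    idx <- which(active)
    if (!length(idx)) return(out)
    pr_mat <- rbind(p$sae_probs_rfa, p$sae_probs_cba)[2 - is_rfa[idx], , drop = FALSE]
    hits <- matrix(stats::runif(length(idx) * ncol(pr_mat)),
                   nrow = length(idx)) < pr_mat
    out[idx] <- as.numeric(hits %*% p$sae_costs)
    out
  }

  cost_interv <- proc_cost(first == "RFA") +
    ifelse(re2, proc_cost(proc2_rfa), 0) +
    ifelse(re3, proc_cost(proc3_rfa), 0) * disc3
  cost_sae <- sae_draw(rep(TRUE, n), rep(first == "RFA", n)) +
    sae_draw(re2, proc2_rfa) +
    sae_draw(re3, proc3_rfa) * disc3

  list(
    intervention_mean = mean(cost_interv),
    intervention_se = stats::sd(cost_interv) / sqrt(n),
    sae_mean = mean(cost_sae),
    sae_se = stats::sd(cost_sae) / sqrt(n)
  )
}

# Flat life table: constant annual death probability, closed at the top.
const_life_table <- function(qx, max_age = 110) {
  lt <- data.frame(age = 0:max_age, qx_male = qx, qx_female = qx)
  lt$qx_male[max_age + 1] <- 1
  lt$qx_female[max_age + 1] <- 1
  lt
}

# Random parameter set drawn uniformly within the sensitivity ranges.
draw_params_in_ranges <- function(p = model_params()) {
  for (nm in names(p$dsa_ranges)) {
    rng <- p$dsa_ranges[[nm]]
    p <- apply_dsa_value(p, nm, stats::runif(1, rng[1], rng[2]))
  }
  p
}
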