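# Lifetime annual-cycle Markov cohort model over the states
# AF- (free of AF symptoms), AF+ (recurrent AF symptoms), IS (incident
# ischemic stroke year), Post-IS (stroke sequela) and Dead, with
# age-dependent background mortality from a life table.

MARKOV_STATES <- c("AF-", "AF+", "IS", "Post-IS", "Dead")

#' Validate a life table
#'
#' A life table is a data frame with columns `age` (consecutive integer
#' years from 0), `qx_male` and `qx_female` (annual death probabilities).
#' Probabilities must lie in \[0, 1\], be non-decreasing above age 60, and
#' the final row must close the table at 1.
#'
#' @param lt Data frame.
#' @return The validated life table.
#' @export
validate_life_table <- function(lt) {
  need <- c("age", "qx_male", "qx_female")
  if (!is.data.frame(lt) || !all(need %in% names(lt))) {
    stop("life table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!identical(as.integer(lt$age), seq(min(lt$age), max(lt$age)))) {
    stop("life-table ages must be consecutive integers", call. = FALSE)
  }
  for (cx in c("qx_male", "qx_female")) {
    q <- lt[[cx]]
    if (any(q < 0 | q > 1)) stop(cx, " outside [0, 1]", call. = FALSE)
    above60 <- q[lt$age >= 60]
    if (length(above60) > 1 && any(diff(above60) < -1e-12)) {
      stop(cx, " must be non-decreasing above age 60", call. = FALSE)
    }
    if (q[length(q)] != 1) {
      stop(cx, " must close at 1 in the final row", call. = FALSE)
    }
  }
  lt
}

#' Read / write a life table CSV
#'
#' @param path CSV path with columns `age, qx_male, qx_female`.
#' @return [read_life_table()]: the validated life table;
#'   [write_life_table()]: `path`, invisibly.
#' @export
read_life_table <- function(path) {
  validate_life_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_life_table
#' @param lt A life table data frame.
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(validate_life_table(lt), path, row.names = FALSE)
  invisible(path)
}

#' Sex-blended background mortality
#'
#' Annual death probability at a given age for a cohort with a fixed male
#' fraction; non-integer ages use the floor-age row, and ages beyond the
#' table are absorbing (probability 1).
#'
#' @param age Age in years (may be non-integer).
#' @param male_fraction Proportion of males in the cohort.
#' @param lt A life table.
#' @return A probability.
#' @export
blended_mortality <- function(age, male_fraction, lt) {
  row <- match(floor(age), lt$age)
  if (is.na(row)) return(1)
  male_fraction * lt$qx_male[row] + (1 - male_fraction) * lt$qx_female[row]
}

#' One-cycle transition probabilities from a state
#'
#' Background death (at the blended life-table probability) is applied
#' first; ischemic stroke and AF recurrence then partition the survivors.
#' From AF-, recurrence occurs at the first-two-Markov-years probability in
#' cycles 1-2 (years since Markov entry) and the later probability
#' afterwards; once symptoms recur there is no return to AF- and no further
#' ablation. The IS state resolves within the cycle: death is the 28-day
#' case fatality plus the one-year mortality among 28-day survivors, and
#' the remainder moves to Post-IS (no repeat stroke is modelled). Post-IS
#' mortality is the disease-specific annual probability, floored at the
#' general-population rate so the state is never safer than the background.
#'
#' @param state One of `"AF-"`, `"AF+"`, `"IS"`, `"Post-IS"`, `"Dead"`.
#' @param cycle_index Years since Markov entry (1-based).
#' @param age Cohort age during the cycle.
#' @param p A `model_params` object.
#' @param lt A life table.
#' @return Named probability vector over the five states, summing to 1.
#' @export
transition_row <- function(state, cycle_index, age, p, lt) {
  stopifnot(inherits(p, "model_params"))
  qx <- blended_mortality(age, p$male_fraction, lt)
  out <- stats::setNames(numeric(5), MARKOV_STATES)
  if (state == "Dead") {
    out["Dead"] <- 1
  } else if (state == "AF-") {
    p_rec <- if (cycle_index <= 2) p$p_recur_markov_y12 else p$p_recur_markov_later
    if (p$p_is_markov + p_rec > 1) {
      stop("stroke + recurrence probabilities exceed 1 in cycle ",
           cycle_index, call. = FALSE)
    }
    out["Dead"] <- qx
    out["IS"] <- (1 - qx) * p$p_is_markov
    out["AF+"] <- (1 - qx) * p_rec
    out["AF-"] <- (1 - qx) * (1 - p$p_is_markov - p_rec)
  } else if (state == "AF+") {
    out["Dead"] <- qx
    out["IS"] <- (1 - qx) * p$p_is_markov
    out["AF+"] <- (1 - qx) * (1 - p$p_is_markov)
  } else if (state == "IS") {
    p_die <- p$p_is_death_28d + (1 - p$p_is_death_28d) * p$p_is_death_1y_survivors
    out["Dead"] <- p_die
    out["Post-IS"] <- 1 - p_die
  } else if (state == "Post-IS") {
    p_die <- max(p$p_death_post_is, qx)
    out["Dead"] <- p_die
    out["Post-IS"] <- 1 - p_die
  } else {
    stop("unknown state: ", state, call. = FALSE)
  }
  out
}

#' Run the lifetime Markov model
#'
#' Cycles the cohort annually from its Markov entry year (year 2, or year 3
#' for the third-ablation subcohort) until the cohort reaches
#' `horizon_age`. Each cycle accrues annual management costs on the states
#' occupied at the start of the cycle (AF-, AF+ and Post-IS carry state
#' costs; IS occupancy carries none since stroke costs are event-based) and
#' fatal / non-fatal event costs on incident stroke transitions, split at
#' the 28-day case fatality. Entrants already in the IS state (decision-tree
#' stroke survivors, costed in the tree) accrue no second event cost. All
#' costs are discounted by `(1 + r)^-(year - 1)`, continuing the decision
#' tree's year numbering; the cohort ages one year per cycle with a fixed
#' sex mix.
#'
#' @param entry A `tree_outcome` from [run_tree()], or a named fraction
#'   vector over the five states (then assumed to enter in year 2).
#' @param p A `model_params` object.
#' @param lt A life table.
#' @param horizon_age Stop once the cohort's (floored) age exceeds this
#'   (default 110; the table closes at probability 1 there).
#' @return An object of class `markov_trace`: `trace` (per-year state
#'   occupancy and discounted per-cycle bucket costs) and `totals`
#'   (cumulative discounted JPY per bucket: `af_neg`, `af_pos`, `is_fatal`,
#'   `is_nonfatal`, `post_is`).
#' @export
run_markov <- function(entry, p, lt, horizon_age = 110) {
  stopifnot(inherits(p, "model_params"))
  lt <- validate_life_table(lt)
  if (inherits(entry, "tree_outcome")) {
    parts <- list(list(dist = entry$entry_year2, year = 2, w = 1 - entry$w_year3),
                  list(dist = entry$entry_year3, year = 3, w = entry$w_year3))
  } else {
    if (!setequal(names(entry), MARKOV_STATES)) {
      stop("entry must be a tree_outcome or a named vector over: ",
           paste(MARKOV_STATES, collapse = ", "), call. = FALSE)
    }
    parts <- list(list(dist = entry[MARKOV_STATES], year = 2, w = 1))
  }
  for (pt in parts) {
    if (pt$w > 0 && abs(sum(pt$dist) - 1) > 1e-9) {
      stop("entry distribution must sum to 1", call. = FALSE)
    }
    if (pt$w > 0 && horizon_age <= p$start_age + pt$year - 1) {
      stop("horizon_age below the Markov entry year", call. = FALSE)
    }
  }

  buckets <- c("af_neg", "af_pos", "is_fatal", "is_nonfatal", "post_is")
  rows <- list()
  for (pt in parts) {
    if (pt$w == 0) next
    s <- pt$dist * pt$w
    t <- pt$year
    repeat {
      age <- p$start_age + (t - 1)
      if (floor(age) > horizon_age || sum(s[MARKOV_STATES != "Dead"]) < 1e-15) break
      cycle_index <- t - pt$year + 1
      disc <- (1 + p$discount_rate)^-(t - 1)
      tm <- t(vapply(MARKOV_STATES, transition_row, numeric(5),
                     cycle_index = cycle_index, age = age, p = p, lt = lt))
      new_is <- s["AF-"] * tm["AF-", "IS"] + s["AF+"] * tm["AF+", "IS"]
      cost <- c(
        af_neg = unname(s["AF-"]) * p$cost_state_af_neg,
        af_pos = unname(s["AF+"]) * p$cost_state_af_pos,
        is_fatal = unname(new_is) * p$p_is_death_28d * p$cost_is_fatal,
        is_nonfatal = unname(new_is) * (1 - p$p_is_death_28d) * p$cost_is_nonfatal,
        post_is = unname(s["Post-IS"]) * p$cost_state_post_is
      ) * disc
      rows[[length(rows) + 1]] <-
        c(year = t, stats::setNames(as.numeric(s), MARKOV_STATES), cost)
      s <- drop(s %*% tm)
      t <- t + 1
    }
  }
  if (!length(rows)) {
    # entire cohort already absorbed at entry: nothing accrues
    empty <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), 1 + 5 + length(buckets)),
      c("year", MARKOV_STATES, buckets)), check.names = FALSE)
    return(structure(list(trace = empty,
                          totals = stats::setNames(numeric(length(buckets)),
                                                   buckets)),
                     class = "markov_trace"))
  }
  tab <- as.data.frame(do.call(rbind, rows))
  # Merge the year-2 and year-3 subcohorts on the shared model years.
  agg <- stats::aggregate(tab[-1], by = list(year = tab$year), FUN = sum)
  agg <- agg[order(agg$year), ]
  rownames(agg) <- NULL
  totals <- colSums(agg[, buckets, drop = FALSE])
  structure(list(trace = agg, totals = totals), class = "markov_trace")
}

#' @export
print.markov_trace <- function(x, ...) {
  cat("Markov trace over", nrow(x$trace), "cycles (years",
      min(x$trace$year), "-", max(x$trace$year), ")\n")
  cat("  discounted totals (JPY):\n")
  for (nm in names(x$totals)) {
    cat(sprintf("    %-12s %12.0f\n", nm, x$totals[[nm]]))
  }
  invisible(x)
}
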