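test_that("blended mortality mixes the sex columns at the floor age", {
  lt <- make_life_table(life_table_spec(makeham_a = 0, gompertz_b = 1e-4,
                                        gompertz_c = 0.09, male_excess = 1))
  expect_equal(blended_mortality(65, 0.67, lt), 1e-4 * exp(0.09 * 65))
  expect_equal(blended_mortality(65.9, 0.67, lt), 1e-4 * exp(0.09 * 65))
  expect_identical(blended_mortality(120, 0.67, lt), 1)
  lt2 <- make_life_table()
  expect_equal(blended_mortality(70, 1, lt2), lt2$qx_male[lt2$age == 70])
  expect_equal(blended_mortality(70, 0, lt2), lt2$qx_female[lt2$age == 70])
})

test_that("transition rows implement the stated competing-risk composition", {
  p <- model_params()
  lt0 <- const_life_table(0)
  # zero-mortality AF- row in the first Markov years
  row <- transition_row("AF-", 1, 70, p, lt0)
  expect_equal(unname(row["AF+"]), 0.077)
  expect_equal(unname(row["IS"]), 0.0024)
  expect_equal(unname(row["AF-"]), 1 - 0.077 - 0.0024)
  expect_equal(unname(row["Dead"]), 0)
  # later-year recurrence after the second Markov year
  row3 <- transition_row("AF-", 3, 70, p, lt0)
  expect_equal(unname(row3["AF+"]), 0.041)
  # stroke-year state composes 28-day and 1-year conditional mortality
  is_row <- transition_row("IS", 1, 70, p, lt0)
  expect_equal(unname(is_row["Dead"]), 0.073 + 0.927 * 0.127)
  expect_equal(unname(is_row["Post-IS"]), 1 - (0.073 + 0.927 * 0.127))
  # death is absorbing
  expect_identical(unname(transition_row("Dead", 1, 70, p, lt0)["Dead"]), 1)
  # Post-IS mortality is floored at the background rate
  lt_high <- const_life_table(0.5)
  expect_equal(unname(transition_row("Post-IS", 1, 70, p, lt_high)["Dead"]), 0.5)
  expect_equal(unname(transition_row("Post-IS", 1, 70, p, lt0)["Dead"]), 0.085)
})

test_that("transition rows are stochastic across states, ages and draws", {
  set.seed(31)
  lt <- make_life_table()
  for (i in 1:10) {
    p <- draw_params_in_ranges()
    for (st in c("AF-", "AF+", "IS", "Post-IS", "Dead")) {
      for (age in c(65, 80, 95, 109)) {
        row <- transition_row(st, sample(1:5, 1), age, p, lt)
        expect_equal(sum(row), 1, tolerance = 1e-12)
        expect_true(all(row >= 0))
      }
    }
  }
})

test_that("degenerate entries produce the expected traces", {
  p <- model_params()
  lt <- make_life_table()
  dead <- c(`AF-` = 0, `AF+` = 0, IS = 0, `Post-IS` = 0, Dead = 1)
  mk <- run_markov(dead, p, lt)
  expect_true(all(mk$totals == 0))
  expect_error(run_markov(dead, p, lt, horizon_age = 60), "horizon")
})

test_that("undiscounted immortal AF+ cohort accrues an exact annuity", {
  p <- model_params(start_age = 60, discount_rate = 0, p_is_markov = 0)
  lt0 <- const_life_table(0)
  entry <- c(`AF-` = 0, `AF+` = 1, IS = 0, `Post-IS` = 0, Dead = 0)
  mk <- run_markov(entry, p, lt0, horizon_age = 70)  # exactly 10 cycles
  expect_identical(nrow(mk$trace), 10L)
  expect_equal(unname(mk$totals["af_pos"]), 10 * 172780)
  expect_equal(sum(mk$totals) - unname(mk$totals["af_pos"]), 0)
})

test_that("constant-mortality cohort matches the closed-form annuity", {
  qx <- 0.05
  p <- model_params(p_is_markov = 0, p_recur_markov_y12 = 0,
                    p_recur_markov_later = 0)
  lt <- const_life_table(qx)
  entry <- c(`AF-` = 1, `AF+` = 0, IS = 0, `Post-IS` = 0, Dead = 0)
  mk <- run_markov(entry, p, lt, horizon_age = 100)
  n <- nrow(mk$trace)
  r <- p$discount_rate
  # survivors decay geometrically; costs discounted from model year 2
  j <- 0:(n - 1)
  expected <- sum(p$cost_state_af_neg * (1 - qx)^j / (1 + r)^(j + 1))
  expect_equal(unname(mk$totals["af_neg"]), expected, tolerance = 1e-9)
  occupancy <- mk$trace[["AF-"]]
  expect_equal(occupancy, (1 - qx)^j, tolerance = 1e-12)
})

test_that("cohort is conserved and death is monotone along the trace", {
  p <- model_params()
  lt <- make_life_table()
  tr <- run_markov(run_tree("RFA_first", p), p, lt)$trace
  sums <- rowSums(tr[, c("AF-", "AF+", "IS", "Post-IS", "Dead")])
  # the year-3 subcohort joins the trace in year 3
  expect_equal(sums[1], 1 - run_tree("RFA_first", p)$w_year3, tolerance = 1e-12)
  expect_equal(sums[-1], rep(1, nrow(tr) - 1), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(diff(tr$Dead) >= -1e-12))
})

test_that("total Markov cost is non-increasing in the discount rate", {
  lt <- make_life_table()
  totals <- vapply(c(0, 0.02, 0.05, 0.1), function(r) {
    p <- model_params(discount_rate = r)
    sum(run_markov(run_tree("RFA_first", p), p, lt)$totals)
  }, numeric(1))
  expect_true(all(diff(totals) < 0))
})

test_that("life tables validate and round-trip through CSV", {
  lt <- make_life_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_life_table(lt, path)
  expect_equal(read_life_table(path), lt)
  bad <- lt; bad$qx_male[50] <- 1.2
  expect_error(validate_life_table(bad), "qx_male")
  bad2 <- lt; bad2$qx_female[nrow(lt)] <- 0.9
  expect_error(validate_life_table(bad2), "close at 1")
  bad3 <- lt[-40, ]
  expect_error(validate_life_table(bad3), "consecutive")
})
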