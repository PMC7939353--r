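test_that("discount factors follow the end-of-cycle convention", {
  expect_equal(discount_factor(0.03, 0), 1 / 1.03)
  expect_equal(discount_factor(0.03, 0), 0.970874, tolerance = 1e-6)
  expect_equal(discount_factor(0, 0:14), rep(1, 15))
  expect_equal(discount_factor(0.03, 14), 1.03^-15)
  expect_error(discount_factor(0.03, -1), ">= 0")
})

test_that("degenerate single-state models match the closed-form annuity", {
  # u * sum_{t=1..15} 1.03^-t = u * 11.93793509...
  annuity <- sum(1.03^-(1:15))
  expect_equal(annuity, 11.9379, tolerance = 1e-5)
  for (u in c(1, 0.8, 0.3)) {
    res <- run_cohort(single_state_spec(u = u))$result
    expect_equal(res$total_qaly, u * annuity, tolerance = 1e-12)
    expect_equal(res$os_15y, 1)
  }
  # zero discount, utility 1, no death: one QALY per cycle
  res0 <- run_cohort(single_state_spec(u = 1, rate = 0))$result
  expect_equal(res0$total_qaly, 15)

  # start-of-cycle rewards shift the discount exponent by one cycle
  res_s <- run_cohort(single_state_spec(u = 1, timing = "start"))$result
  expect_equal(res_s$total_qaly, sum(1.03^-(0:14)), tolerance = 1e-12)

  # half-cycle correction lands between the two conventions
  res_h <- run_cohort(single_state_spec(u = 1, half_cycle = TRUE))$result
  expect_gt(res_h$total_qaly, sum(1.03^-(1:15)))
  expect_lt(res_h$total_qaly, sum(1.03^-(0:14)))
})

test_that("transition matrices encode the fixture schedules and gates", {
  soc <- get_fixture("SOC")
  nm <- names(soc$states)

  # contralateral-breast events cannot happen before year 6: no entries
  # into the state from anywhere (its own diagonal is a residual stay term)
  M3 <- build_transition_matrix(soc, 3)$matrix
  expect_equal(unname(M3[setdiff(nm, "CLBreast"), "CLBreast"]),
               rep(0, length(nm) - 1L))
  M5 <- build_transition_matrix(soc, 5)$matrix
  expect_equal(unname(M5["NED", "CLBreast"]), 0.0038)

  # cardiac-state occupants face the printed late toxicity mortality
  M12 <- build_transition_matrix(soc, 12)$matrix
  expect_equal(unname(M12["Cardiac", "Death_Tox"]), 0.0053)
  M8 <- build_transition_matrix(soc, 8)$matrix
  expect_equal(unname(M8["Cardiac", "Death_Tox"]), 0)

  # period-cumulative conversion: 12.25% over 5 years
  expect_equal(unname(M3["NED", "Metastasis"]), 1 - (1 - 0.1225)^(1 / 5))
  # annual rows pass through as printed
  expect_equal(unname(M3["Metastasis", "Death_BC"]), 0.232)

  # row-stochastic with identity death rows at every cycle
  for (t in 0:14) {
    M <- build_transition_matrix(soc, t)$matrix
    expect_equal(unname(rowSums(M)), rep(1, length(nm)), tolerance = 1e-12)
    expect_true(all(M >= 0 & M <= 1))
    for (d in c("Death_BC", "Death_Tox", "Death_Other"))
      expect_equal(unname(M[d, ]), as.numeric(nm == d))
  }
  expect_error(build_transition_matrix(soc, 15), "out of range")
  expect_error(build_transition_matrix(soc, -1), "out of range")

  # no exits at all -> identity matrix
  only <- single_state_spec()
  M1 <- build_transition_matrix(only, 0)$matrix
  expect_equal(dim(M1), c(1L, 1L))
  expect_equal(as.numeric(M1), 1)
})

test_that("rows whose exits exceed one are rescaled proportionally", {
  spec <- single_state_spec()
  spec$states <- c(spec$states, list(health_state(
    "D", is_death = TRUE, death_category = "other_cause")))
  names(spec$states)[2] <- "D"
  spec$states$NED$utility <- piecewise(0, 15, 0.8)
  spec$transitions <- list(
    transition("NED", "D", piecewise(0, 15, 0.7)),
    transition("NED", "D", piecewise(0, 15, 0.6), id = "second_exit"))
  expect_identical(nrow(validate_spec(spec)), 0L)
  bt <- build_transition_matrix(spec, 0)
  expect_equal(unname(bt$matrix["NED", "D"]), 1)
  expect_equal(attr(bt$matrix, "rescaled_rows"), 1L)
})

test_that("generated models build row-stochastic matrices at every cycle", {
  for (seed in 1:500) {
    spec <- generate_model(generator_config(seed = seed, horizon = 8L))
    cm <- wbrtcea:::compile_model(spec)
    for (t in seq_len(cm$horizon)) {
      M <- cm$Ms[[t]]
      expect_equal(unname(rowSums(M)), rep(1, nrow(M)), tolerance = 1e-12)
      expect_true(all(M >= 0 & M <= 1 + 1e-15))
    }
  }
})

test_that("cohort occupancy is conserved and death states only grow", {
  check <- function(spec) {
    trace <- run_cohort(spec)$trace
    expect_equal(unname(rowSums(trace$occupancy)),
                 rep(1, nrow(trace$occupancy)), tolerance = 1e-10)
    dead <- vapply(spec$states, `[[`, TRUE, "is_death")
    dsum <- rowSums(trace$occupancy[, dead, drop = FALSE])
    expect_true(all(diff(dsum) >= -1e-12))
  }
  check(get_fixture("SOC"))
  for (seed in 1:20) check(generate_model(generator_config(seed = seed)))
})

test_that("raising a death probability never increases total QALYs", {
  for (seed in c(3, 11, 27)) {
    spec <- generate_model(generator_config(seed = seed))
    dead <- names(Filter(function(s) s$is_death, spec$states))
    into_death <- which(vapply(spec$transitions,
                               function(tr) tr$to %in% dead, TRUE))
    base_q <- run_cohort(spec)$result$total_qaly
    for (i in into_death) {
      worse <- spec
      worse$transitions[[i]]$prob$value <-
        pmin(1, worse$transitions[[i]]$prob$value * 1.5)
      expect_lte(run_cohort(worse)$result$total_qaly, base_q + 1e-12)
    }
  }
})

test_that("microsimulation oracle agrees with the cohort engine", {
  soc <- get_fixture("SOC")
  cohort <- get_result("SOC")
  ms <- microsim_oracle(soc, n_patients = 40000, seed = 11)
  expect_lt(abs(ms$result$total_qaly - cohort$total_qaly), 3 * ms$se_qaly)
  expect_lt(abs(ms$result$total_cost - cohort$total_cost), 3 * ms$se_cost)

  # determinism under a fixed seed
  ms2 <- microsim_oracle(soc, n_patients = 500, seed = 99)
  ms3 <- microsim_oracle(soc, n_patients = 500, seed = 99)
  expect_identical(ms2, ms3)

  # immediate certain death: zero QALYs both ways
  dead <- single_state_spec(u = 0.9)
  dead$states <- c(dead$states, list(health_state(
    "D", is_death = TRUE, death_category = "other_cause")))
  names(dead$states)[2] <- "D"
  dead$transitions <- list(transition("NED", "D", piecewise(0, 15, 1)))
  expect_equal(run_cohort(dead)$result$total_qaly, 0)
  expect_equal(microsim_oracle(dead, 200, seed = 1)$result$total_qaly, 0)

  # random generated models, three-standard-error agreement
  for (seed in 1:20) {
    spec <- generate_model(generator_config(seed = seed))
    cohort <- run_cohort(spec)$result
    ms <- microsim_oracle(spec, n_patients = 4000, seed = seed + 1000)
    expect_lt(abs(ms$result$total_qaly - cohort$total_qaly),
              3 * ms$se_qaly + 1e-9)
    expect_lt(abs(ms$result$total_cost - cohort$total_cost),
              3 * ms$se_cost + 1e-9)
  }
})

test_that("calibration enumerates all interpretation assignments and finds the benchmark optimum", {
  soc <- get_fixture("SOC")
  cal <- calibrate_interpretation(soc)
  expect_identical(nrow(cal$table), 16L)  # 2^4 flagged rows
  # the winning assignment reads the metastasis row as period-cumulative and
  # matches the shipped default
  expect_identical(unname(cal$best[["metastasis"]]), "period_cumulative")
  expect_identical(unname(cal$best),
                   c("annual", "period_cumulative", "period_cumulative",
                     "annual")[match(names(cal$best),
                                     c("recurrence", "metastasis",
                                       "progression", "met_death"))])

  # scoring against a configuration's own outputs makes it the zero-score winner
  assignment <- c(recurrence = "period_cumulative",
                  metastasis = "annual",
                  progression = "annual",
                  met_death = "period_cumulative")
  own <- run_cohort(apply_interpretation(soc, assignment))$result
  cal2 <- calibrate_interpretation(
    soc, targets = list(cost = own$total_cost, qaly = own$total_qaly,
                        os = own$os_15y, bc_mort = own$bc_mortality_15y))
  expect_equal(cal2$best_score, 0)
  expect_identical(cal2$best[names(assignment)], assignment)
})

test_that("cohort trace exports one row per cycle", {
  run <- run_cohort(get_fixture("SOC"))
  df <- trace_as_data_frame(run$trace)
  expect_identical(nrow(df), 16L)
  expect_true(all(c("cycle", "NED", "Death_BC", "discounted_cost",
                    "discounted_qaly") %in% names(df)))
  expect_equal(sum(df$discounted_qaly, na.rm = TRUE), run$result$total_qaly)
})
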