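# Cohort engine: compiles a model_spec into per-cycle transition matrices and
# reward arrays, evolves the cohort, and accumulates discounted costs/QALYs.

#' Discount factor for cycle rewards
#'
#' Rewards of cycle `t` (0-based) accrue on the post-transition occupancy and
#' are discounted by `(1 + rate)^-(t + 1)`.
#'
#' @param rate annual discount rate.
#' @param t cycle index, `t >= 0`.
#' @return numeric discount factor.
#' @export
discount_factor <- function(rate, t) {
  if (any(t < 0)) stop("t must be >= 0")
  (1 + rate)^-(t + 1)
}

# annualize one schedule piece: period-cumulative P over L cycles becomes the
# constant annual probability 1 - (1 - P)^(1/L)
annualize_piece <- function(value, len, interpretation) {
  if (interpretation == "period_cumulative") 1 - (1 - value)^(1 / len)
  else value
}

# per-cycle annual probability vector for one transition
transition_prob_vector <- function(tr, spec) {
  H <- spec$config$horizon_cycles
  out <- numeric(H)
  if (!is.null(tr$param_ref)) {
    p <- spec$technique$side_effect_probs[[tr$param_ref]]
    if (is.null(p))
      stop("transition '", tr$id, "' references missing side-effect parameter '",
           tr$param_ref, "'")
    out[] <- p$base
  } else if (!is.null(tr$prob) && nrow(tr$prob) > 0L) {
    for (i in seq_len(nrow(tr$prob))) {
      s <- max(tr$prob$start[i], 0L); e <- min(tr$prob$end[i], H)
      if (e > s)
        out[(s + 1L):e] <- annualize_piece(tr$prob$value[i],
                                           tr$prob$end[i] - tr$prob$start[i],
                                           tr$interpretation)
    }
  }
  gate <- spec$states[[tr$to]]$earliest_entry_cycle
  if (gate > 0L) out[seq_len(min(gate, H))] <- 0
  out
}

transition_active <- function(tr, spec) {
  if (identical(tr$id, "progression") && !spec$config$recurrence_progresses)
    return(FALSE)
  if (identical(tr$from, "Recurrence") && identical(tr$to, "Death_BC") &&
      !spec$config$recurrence_bc_death)
    return(FALSE)
  TRUE
}

# Compile a spec into dense arrays. Returns list with:
#   EX [S,S,H] off-diagonal annual exit probabilities (diag zero)
#   U  [S,H] utilities, entry_cost/annual_cost [S], disc [H], ...
compile_model <- function(spec) {
  H <- spec$config$horizon_cycles
  nm <- state_names(spec)
  S <- length(nm)
  idx <- stats::setNames(seq_len(S), nm)
  is_death <- vapply(spec$states, `[[`, TRUE, "is_death")
  category <- vapply(spec$states, `[[`, "", "death_category")

  EX <- array(0, dim = c(S, S, H), dimnames = list(nm, nm, NULL))
  for (tr in spec$transitions) {
    if (!transition_active(tr, spec)) next
    EX[idx[tr$from], idx[tr$to], ] <-
      EX[idx[tr$from], idx[tr$to], ] + transition_prob_vector(tr, spec)
  }
  if (!is.null(spec$other_cause_mortality)) {
    d_other <- which(is_death & category == "other_cause")
    if (length(d_other) != 1L)
      stop("other_cause_mortality requires exactly one other_cause death state")
    oc <- pw_value(spec$other_cause_mortality, seq_len(H) - 1L)
    for (s in which(!is_death)) EX[s, d_other, ] <- EX[s, d_other, ] + oc
  }
  EX[is_death, , ] <- 0  # death states are absorbing

  U <- matrix(0, S, H, dimnames = list(nm, NULL))
  for (s in seq_len(S))
    if (!is_death[s])
      U[s, ] <- pw_value(spec$states[[s]]$utility, seq_len(H) - 1L)

  Ms <- vector("list", H)
  rescaled <- 0L
  for (t in seq_len(H)) {
    sl <- EX[, , t]
    if (!is.matrix(sl)) sl <- matrix(sl, S, S, dimnames = list(nm, nm))
    Ms[[t]] <- slice_to_matrix(sl)
    rescaled <- rescaled + attr(Ms[[t]], "rescaled_rows")
  }

  list(EX = EX, Ms = Ms, rescaled_rows = rescaled, U = U,
       disc_end = (1 + spec$config$discount_rate)^-(seq_len(H)),
       entry_cost = vapply(spec$states, `[[`, 0, "entry_cost"),
       annual_cost = vapply(spec$states, `[[`, 0, "annual_cost"),
       upfront = spec$technique$upfront_cost,
       disc_rate = spec$config$discount_rate,
       horizon = H, state_names = nm, idx = idx,
       is_death = is_death, category = category,
       initial = which(vapply(spec$states, `[[`, TRUE, "is_initial"))[1L],
       half_cycle = spec$config$half_cycle_correction,
       timing = spec$config$reward_timing,
       strategy = spec$technique$name)
}

# turn one cycle's exit slice into a row-stochastic matrix, rescaling rows
# whose exits exceed 1 (possible under extreme sensitivity draws)
slice_to_matrix <- function(ex_slice) {
  rs <- rowSums(ex_slice)
  over <- rs > 1
  if (any(over)) {
    ex_slice[over, ] <- ex_slice[over, , drop = FALSE] / rs[over]
    rs[over] <- 1
  }
  M <- ex_slice
  diag(M) <- diag(M) + (1 - rs)
  attr(M, "rescaled_rows") <- sum(over)
  M
}

#' Build the transition matrix for one cycle
#'
#' Assembles the row-stochastic one-cycle transition matrix from the model's
#' schedules: period-cumulative values are converted to constant annual
#' probabilities, entries into gated states are zero before their earliest
#' entry cycle, background mortality applies from every alive state, each
#' row's stay probability is the residual `1 - sum(exits)`, and death rows are
#' identity rows. Rows whose exits would sum above 1 (possible under extreme
#' sensitivity draws) are rescaled proportionally; the number of rescaled rows
#' is attached as attribute `"rescaled_rows"`.
#'
#' @param spec a [model_spec()].
#' @param cycle cycle index in `[0, horizon)`.
#' @return a list with elements `cycle` and `matrix`.
#' @export
build_transition_matrix <- function(spec, cycle) {
  H <- spec$config$horizon_cycles
  if (cycle < 0 || cycle >= H) stop("cycle out of range [0, ", H, ")")
  cm <- compile_model(spec)
  list(cycle = as.integer(cycle), matrix = cm$Ms[[cycle + 1L]])
}

# core evolution over a compiled model; side-effect overrides allow the
# sensitivity machinery to reuse one compilation across many evaluations
evolve_compiled <- function(cm, need_trace = TRUE) {
  H <- cm$horizon; S <- length(cm$state_names)
  r <- cm$disc_rate
  occ <- numeric(S); occ[cm$initial] <- 1
  trace_occ <- if (need_trace) matrix(0, H + 1L, S,
                                      dimnames = list(NULL, cm$state_names))
  if (need_trace) trace_occ[1L, ] <- occ
  entries_tr <- if (need_trace) matrix(0, H, S, dimnames = list(NULL, cm$state_names))
  cost_cycle <- numeric(H); qaly_cycle <- numeric(H)
  total_cost <- cm$upfront
  rescaled <- cm$rescaled_rows
  for (t in seq_len(H) - 1L) {
    M <- cm$Ms[[t + 1L]]
    newocc <- as.vector(occ %*% M)
    entries <- newocc - occ * diag(M)
    d_end <- (1 + r)^-(t + 1)
    if (cm$half_cycle) {
      basis <- 0.5 * (occ + newocc); d <- (1 + r)^-(t + 0.5)
    } else if (cm$timing == "start") {
      basis <- occ; d <- (1 + r)^-t
    } else {
      basis <- newocc; d <- d_end
    }
    qaly_cycle[t + 1L] <- sum(basis * cm$U[, t + 1L]) * d
    cost_cycle[t + 1L] <- sum(basis * cm$annual_cost) * d +
      sum(entries * cm$entry_cost) * d_end
    occ <- newocc
    if (need_trace) {
      trace_occ[t + 2L, ] <- occ
      entries_tr[t + 1L, ] <- entries
    }
  }
  total_cost <- total_cost + sum(cost_cycle)
  total_qaly <- sum(qaly_cycle)
  res <- strategy_result(
    strategy = cm$strategy,
    total_cost = total_cost, total_qaly = total_qaly,
    os_15y = sum(occ[!cm$is_death]),
    bc_mortality_15y = sum(occ[cm$is_death & cm$category == "breast_cancer"]),
    tox_mortality_15y = sum(occ[cm$is_death & cm$category == "toxicity"]),
    other_mortality_15y = sum(occ[cm$is_death & cm$category == "other_cause"]))
  trace <- NULL
  if (need_trace) {
    trace <- list(occupancy = trace_occ, entries = entries_tr,
                  discounted_cost_by_cycle = cost_cycle,
                  discounted_qaly_by_cycle = qaly_cycle,
                  rescaled_rows = rescaled)
    class(trace) <- "cohort_trace"
  }
  list(trace = trace, result = res)
}

strategy_result <- function(strategy, total_cost, total_qaly, os_15y,
                            bc_mortality_15y, tox_mortality_15y,
                            other_mortality_15y = NA_real_, config = NULL) {
  x <- list(strategy = strategy, total_cost = total_cost,
            total_qaly = total_qaly, os_15y = os_15y,
            bc_mortality_15y = bc_mortality_15y,
            tox_mortality_15y = tox_mortality_15y,
            other_mortality_15y = other_mortality_15y, config = config)
  class(x) <- "strategy_result"
  x
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result> %s: cost $%.0f, %.4f QALY, OS %.1f%%, BC mortality %.1f%%\n",
              x$strategy, x$total_cost, x$total_qaly, 100 * x$os_15y,
              100 * x$bc_mortality_15y))
  invisible(x)
}

#' Run the cohort model
#'
#' Evolves the full cohort through the Markov model cycle by cycle. The whole
#' cohort starts in the initial state; cycle-`t` rewards accrue on the
#' post-transition occupancy with discount factor `(1 + r)^-(t + 1)` (see
#' `reward_timing` and `half_cycle_correction` in [model_config()] for the
#' alternatives); entry costs are charged on the fraction newly entering a
#' state that cycle; the upfront treatment cost is added undiscounted at
#' cycle 0.
#'
#' @param spec a valid [model_spec()].
#' @return a list with components `trace` (class `cohort_trace`: per-cycle
#'   occupancy, new entries, discounted cost/QALY increments) and `result`
#'   (class `strategy_result`: discounted totals plus 15-year survival and
#'   cause-specific mortality fractions).
#' @export
run_cohort <- function(spec) {
  viol <- validate_spec(spec)
  if (nrow(viol) > 0L)
    stop("invalid model spec: ", paste(viol$field, viol$rule, collapse = "; "))
  out <- evolve_compiled(compile_model(spec), need_trace = TRUE)
  out$result$config <- spec$config
  out
}

#' Export a cohort trace as a per-cycle data frame
#'
#' @param trace the `trace` component of [run_cohort()] output.
#' @return a `data.frame` with one row per cycle (including cycle 0), state
#'   occupancies, and the discounted cost/QALY accrued in the cycle.
#' @export
trace_as_data_frame <- function(trace) {
  H <- length(trace$discounted_cost_by_cycle)
  data.frame(cycle = 0:H, trace$occupancy,
             discounted_cost = c(NA, trace$discounted_cost_by_cycle),
             discounted_qaly = c(NA, trace$discounted_qaly_by_cycle),
             check.names = FALSE)
}

#' Patient-level microsimulation oracle
#'
#' Simulates individual trajectories by categorical sampling from the same
#' per-cycle transition matrices the cohort engine uses, accumulating the same
#' rewards. Serves as an independent stochastic check of [run_cohort()]: the
#' estimates converge to the cohort totals as `n_patients` grows.
#'
#' @param spec a valid [model_spec()].
#' @param n_patients number of simulated patients.
#' @param seed RNG seed.
#' @return a list with `result` (a `strategy_result` of sample means),
#'   `se_cost` and `se_qaly` (Monte-Carlo standard errors), and `n`.
#' @export
microsim_oracle <- function(spec, n_patients = 10000L, seed = 1L) {
  stopifnot(n_patients >= 1L)
  cm <- compile_model(spec)
  H <- cm$horizon; S <- length(cm$state_names)
  set.seed(as.integer(seed))
  state <- rep.int(cm$initial, n_patients)
  cost <- rep.int(cm$upfront, n_patients)
  qaly <- numeric(n_patients)
  r <- cm$disc_rate
  for (t in seq_len(H) - 1L) {
    M <- cm$Ms[[t + 1L]]
    newstate <- state
    for (s in unique(state)) {
      if (cm$is_death[s]) next
      who <- which(state == s)
      newstate[who] <- sample.int(S, length(who), replace = TRUE, prob = M[s, ])
    }
    d_end <- (1 + r)^-(t + 1)
    if (cm$half_cycle) {
      uvec <- 0.5 * (cm$U[cbind(state, t + 1L)] + cm$U[cbind(newstate, t + 1L)])
      avec <- 0.5 * (cm$annual_cost[state] + cm$annual_cost[newstate])
      d <- (1 + r)^-(t + 0.5)
    } else if (cm$timing == "start") {
      uvec <- cm$U[cbind(state, t + 1L)]; avec <- cm$annual_cost[state]
      d <- (1 + r)^-t
    } else {
      uvec <- cm$U[cbind(newstate, t + 1L)]; avec <- cm$annual_cost[newstate]
      d <- d_end
    }
    qaly <- qaly + uvec * d
    moved <- newstate != state
    cost <- cost + avec * d
    if (any(moved))
      cost[moved] <- cost[moved] + cm$entry_cost[newstate[moved]] * d_end
    state <- newstate
  }
  res <- strategy_result(
    strategy = cm$strategy,
    total_cost = mean(cost), total_qaly = mean(qaly),
    os_15y = mean(!cm$is_death[state]),
    bc_mortality_15y = mean(cm$category[state] == "breast_cancer" & cm$is_death[state]),
    tox_mortality_15y = mean(cm$category[state] == "toxicity" & cm$is_death[state]))
  list(result = res,
       se_cost = stats::sd(cost) / sqrt(n_patients),
       se_qaly = stats::sd(qaly) / sqrt(n_patients),
       n = n_patients)
}

#' Apply an annual/period-cumulative interpretation assignment
#'
#' @param spec a [model_spec()].
#' @param assignment named character vector mapping ambiguous transition ids to
#'   `"annual"` or `"period_cumulative"`.
#' @return the modified spec.
#' @export
apply_interpretation <- function(spec, assignment) {
  for (i in seq_along(spec$transitions)) {
    id <- spec$transitions[[i]]$id
    if (id %in% names(assignment))
      spec$transitions[[i]]$interpretation <-
        match.arg(assignment[[id]], c("annual", "period_cumulative"))
  }
  if (!is.null(spec$meta$interpretations))
    spec$meta$interpretations[names(assignment)] <- as.list(assignment)
  spec
}

#' Calibrate ambiguous probability-row interpretations
#'
#' Several probability rows of the source tables can be read either as annual
#' probabilities or as cumulative probabilities over their multi-year period.
#' This harness exhaustively evaluates all `2^k` annual/period-cumulative
#' assignments over the `k` transitions flagged `ambiguous` in the spec,
#' scores each assignment by the normalized L2 distance of the model's
#' (cost, QALY, OS, BC mortality) quadruple to the supplied targets, and
#' returns the full score table plus the argmin. Deterministic.
#'
#' @param spec a [model_spec()] (normally the SOC fixture).
#' @param targets named list with elements `cost`, `qaly`, `os`, `bc_mort`;
#'   defaults to the bundled external benchmarks.
#' @return a list with `best` (named character vector, the winning
#'   assignment), `best_score`, and `table` (one row per assignment with the
#'   four model outputs and the score).
#' @export
calibrate_interpretation <- function(spec, targets = NULL) {
  if (is.null(targets)) {
    bm <- wbrt_benchmarks()
    soc <- bm$totals[bm$totals$strategy == "SOC", ]
    targets <- list(cost = soc$cost, qaly = soc$qaly,
                    os = bm$os_15y, bc_mort = bm$bc_mortality_15y)
  }
  ids <- unique(vapply(Filter(function(tr) tr$ambiguous, spec$transitions),
                       `[[`, "", "id"))
  k <- length(ids)
  choices <- rep(list(c("annual", "period_cumulative")), k)
  names(choices) <- ids
  grid <- expand.grid(choices, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    assignment <- unlist(grid[i, , drop = FALSE])
    res <- run_cohort(apply_interpretation(spec, assignment))$result
    x <- c(cost = res$total_cost, qaly = res$total_qaly,
           os = res$os_15y, bc_mort = res$bc_mortality_15y)
    tgt <- unlist(targets)[names(x)]
    score <- sqrt(mean(((x - tgt) / tgt)^2))
    rows[[i]] <- data.frame(grid[i, , drop = FALSE], t(x), score = score,
                            row.names = NULL)
  }
  tab <- do.call(rbind, rows)
  best_i <- which.min(tab$score)
  list(best = unlist(grid[best_i, , drop = FALSE]),
       best_score = tab$score[best_i], table = tab)
}
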