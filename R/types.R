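#' Uncertain scalar parameter
#'
#' A scalar model input together with its uncertainty description: a base
#' (point) value, an optional plausible range, an optional standard deviation,
#' and the distribution family used for probabilistic sensitivity analysis.
#'
#' @param base point estimate used in baseline runs.
#' @param low,high plausible range; `low <= base <= high`. `NA` if unknown.
#' @param sd standard deviation (used by the gamma family). `NA` if unknown.
#' @param family one of `"beta"`, `"gamma"`, `"fixed"`. Beta parameters must
#'   live in `[0, 1]`; gamma parameters must be positive.
#' @return an object of class `uparam`.
#' @export
uparam <- function(base, low = NA_real_, high = NA_real_, sd = NA_real_,
                   family = c("fixed", "beta", "gamma")) {
  family <- match.arg(family)
  stopifnot(is.numeric(base), length(base) == 1L)
  x <- list(base = as.numeric(base), low = as.numeric(low),
            high = as.numeric(high), sd = as.numeric(sd), family = family)
  class(x) <- "uparam"
  x
}

#' Piecewise-constant schedule over model cycles
#'
#' Intervals are half-open `[start, end)` in cycle units (0-based), so a
#' 15-cycle horizon is fully covered by pieces whose ends chain from 0 to 15.
#'
#' @param start,end integer cycle bounds of each piece.
#' @param value value on each piece.
#' @return a `data.frame` with columns `start`, `end`, `value`.
#' @export
piecewise <- function(start, end, value) {
  stopifnot(length(start) == length(end), length(end) == length(value))
  data.frame(start = as.integer(start), end = as.integer(end),
             value = as.numeric(value))
}

#' Evaluate a piecewise schedule at given cycles
#'
#' @param pw a [piecewise()] data frame.
#' @param cycles integer vector of cycles.
#' @param default value returned for cycles no piece covers.
#' @return numeric vector of the same length as `cycles`.
#' @export
pw_value <- function(pw, cycles, default = 0) {
  out <- rep(default, length(cycles))
  if (is.null(pw) || nrow(pw) == 0L) return(out)
  for (i in seq_len(nrow(pw))) {
    hit <- cycles >= pw$start[i] & cycles < pw$end[i]
    out[hit] <- pw$value[i]
  }
  out
}

#' Health state of the cohort model
#'
#' @param name state identifier.
#' @param utility a [piecewise()] schedule of utilities in `[0, 1]`; death
#'   states may pass `NULL` (utility 0).
#' @param entry_cost cost applied once, on entry into the state.
#' @param annual_cost cost applied for every cycle of occupancy.
#' @param is_death absorbing death state flag.
#' @param death_category one of `"breast_cancer"`, `"other_cause"`,
#'   `"toxicity"`, `"none"`.
#' @param earliest_entry_cycle first cycle (0-based) at which the state can be
#'   entered; transitions into it are gated to zero before this cycle.
#' @param is_initial whether the whole cohort starts here.
#' @param utility_unc,entry_cost_unc optional [uparam()] descriptions of the
#'   utility / entry-cost uncertainty, used by sensitivity analyses.
#' @return an object of class `health_state`.
#' @export
health_state <- function(name, utility = NULL, entry_cost = 0, annual_cost = 0,
                         is_death = FALSE,
                         death_category = c("none", "breast_cancer",
                                            "other_cause", "toxicity"),
                         earliest_entry_cycle = 0L, is_initial = FALSE,
                         utility_unc = NULL, entry_cost_unc = NULL) {
  death_category <- match.arg(death_category)
  x <- list(name = as.character(name), utility = utility,
            entry_cost = as.numeric(entry_cost),
            annual_cost = as.numeric(annual_cost),
            is_death = isTRUE(is_death), death_category = death_category,
            earliest_entry_cycle = as.integer(earliest_entry_cycle),
            is_initial = isTRUE(is_initial),
            utility_unc = utility_unc, entry_cost_unc = entry_cost_unc)
  class(x) <- "health_state"
  x
}

#' Transition schedule between two states
#'
#' Either a literal probability schedule (`prob`) or a reference to one of the
#' technique profile's side-effect probabilities (`param_ref`), in which case
#' the annual probability is the technique's base value gated by the target
#' state's `earliest_entry_cycle`.
#'
#' @param from,to state names.
#' @param prob a [piecewise()] probability schedule, or `NULL` with `param_ref`.
#' @param interpretation `"annual"` (value is a per-cycle probability) or
#'   `"period_cumulative"` (value is the cumulative probability over the whole
#'   piece, converted to a constant annual probability
#'   `1 - (1 - P)^(1/L)` for a piece of length `L`).
#' @param param_ref `"cardiac"`, `"cl_breast"` or `"lung"`, or `NULL`.
#' @param id optional stable identifier (used by the calibration harness).
#' @param ambiguous whether the annual-vs-cumulative reading of this row is
#'   ambiguous in the source tables (flag used by [calibrate_interpretation()]).
#' @return an object of class `transition`.
#' @export
transition <- function(from, to, prob = NULL,
                       interpretation = c("annual", "period_cumulative"),
                       param_ref = NULL, id = NULL, ambiguous = FALSE) {
  interpretation <- match.arg(interpretation)
  x <- list(from = as.character(from), to = as.character(to), prob = prob,
            interpretation = interpretation, param_ref = param_ref,
            id = if (is.null(id)) paste0(from, "->", to) else id,
            ambiguous = isTRUE(ambiguous))
  class(x) <- "transition"
  x
}

#' Radiotherapy technique profile
#'
#' @param name technique identifier (e.g. `"SOC"`, `"FIF"`, `"MA_VMAT"`).
#' @param upfront_cost one-time treatment cost, applied undiscounted at cycle 0.
#' @param side_effect_probs named list (`cardiac`, `cl_breast`, `lung`) of
#'   [uparam()] annual side-effect probabilities; may be empty for models that
#'   carry all probabilities in literal transition schedules.
#' @return an object of class `technique_profile`.
#' @export
technique_profile <- function(name, upfront_cost, side_effect_probs = list()) {
  x <- list(name = as.character(name), upfront_cost = as.numeric(upfront_cost),
            side_effect_probs = side_effect_probs)
  class(x) <- "technique_profile"
  x
}

#' Global model configuration
#'
#' @param start_age cohort age (years) at cycle 0.
#' @param horizon_cycles number of one-year cycles simulated.
#' @param cycle_length cycle length in years.
#' @param discount_rate annual discount rate for costs and QALYs.
#' @param reference_strategy name of the comparator strategy.
#' @param wtp_thresholds willingness-to-pay thresholds ($/QALY).
#' @param half_cycle_correction if `TRUE`, occupancy rewards use the mean of
#'   the pre- and post-transition occupancy and a mid-cycle discount exponent.
#' @param reward_timing `"end"` (rewards accrue on post-transition occupancy,
#'   discount exponent `t + 1`) or `"start"` (pre-transition occupancy,
#'   exponent `t`).
#' @param recurrence_progresses whether local-recurrence occupants keep facing
#'   the distant-metastasis schedule.
#' @param recurrence_bc_death whether local-recurrence occupants face the
#'   breast-cancer death schedule directly.
#' @param beta_range_semantics how a `(low, high)` range is read when moment
#'   matching a beta distribution: `"ci95"` (range = 95% interval, sd =
#'   range/3.92) or `"minmax"` (sd = range/4).
#' @return an object of class `model_config`.
#' @export
model_config <- function(start_age = 65, horizon_cycles = 15L, cycle_length = 1,
                         discount_rate = 0.03, reference_strategy = "SOC",
                         wtp_thresholds = c(50000, 100000),
                         half_cycle_correction = FALSE,
                         reward_timing = c("end", "start"),
                         recurrence_progresses = TRUE,
                         recurrence_bc_death = TRUE,
                         beta_range_semantics = c("ci95", "minmax")) {
  reward_timing <- match.arg(reward_timing)
  beta_range_semantics <- match.arg(beta_range_semantics)
  x <- list(start_age = as.numeric(start_age),
            horizon_cycles = as.integer(horizon_cycles),
            cycle_length = as.numeric(cycle_length),
            discount_rate = as.numeric(discount_rate),
            reference_strategy = as.character(reference_strategy),
            wtp_thresholds = as.numeric(wtp_thresholds),
            half_cycle_correction = isTRUE(half_cycle_correction),
            reward_timing = reward_timing,
            recurrence_progresses = isTRUE(recurrence_progresses),
            recurrence_bc_death = isTRUE(recurrence_bc_death),
            beta_range_semantics = beta_range_semantics)
  class(x) <- "model_config"
  x
}

#' Complete model specification for one strategy
#'
#' @param config a [model_config()].
#' @param states list of [health_state()] objects.
#' @param transitions list of [transition()] objects.
#' @param technique a [technique_profile()].
#' @param other_cause_mortality optional [piecewise()] schedule (indexed by
#'   cycle) of background mortality applied from every alive state to the
#'   `other_cause` death state.
#' @param meta optional named list of free-form metadata.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(config, states, transitions, technique,
                       other_cause_mortality = NULL, meta = list()) {
  names(states) <- vapply(states, `[[`, "", "name")
  x <- list(config = config, states = states, transitions = transitions,
            technique = technique,
            other_cause_mortality = other_cause_mortality, meta = meta)
  class(x) <- "model_spec"
  x
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> strategy:", x$technique$name,
      "| states:", length(x$states),
      "| transitions:", length(x$transitions),
      "| horizon:", x$config$horizon_cycles, "cycles\n")
  invisible(x)
}

state_names <- function(spec) vapply(spec$states, `[[`, "", "name")

# ---- validation ------------------------------------------------------------

violation <- function(field, rule, detail) {
  data.frame(field = field, rule = rule, detail = detail,
             stringsAsFactors = FALSE)
}

check_pw <- function(pw, field, horizon, lo = 0, hi = 1, cover = TRUE) {
  v <- list()
  if (is.null(pw) || nrow(pw) == 0L) {
    if (cover)
      v[[length(v) + 1L]] <- violation(field, "coverage",
                                       "schedule is empty but must cover the horizon")
    return(do.call(rbind, v))
  }
  if (any(pw$end <= pw$start))
    v[[length(v) + 1L]] <- violation(field, "interval_order",
                                     "piece with end <= start")
  o <- pw[order(pw$start), , drop = FALSE]
  if (nrow(o) > 1L && any(o$start[-1L] < o$end[-nrow(o)]))
    v[[length(v) + 1L]] <- violation(field, "interval_overlap",
                                     "cycle intervals overlap")
  if (cover) {
    covered <- pw_value(pw, seq_len(horizon) - 1L, default = NA_real_)
    if (anyNA(covered))
      v[[length(v) + 1L]] <- violation(field, "coverage",
                                       "schedule does not cover every cycle in [0, horizon)")
  }
  if (any(pw$value < lo | pw$value > hi))
    v[[length(v) + 1L]] <- violation(
      field, "range", sprintf("value outside [%g, %g]", lo, hi))
  do.call(rbind, v)
}

check_uparam <- function(p, field) {
  v <- list()
  if (is.null(p)) return(NULL)
  if (!is.na(p$low) && !is.na(p$high) &&
      !(p$low <= p$base && p$base <= p$high))
    v[[length(v) + 1L]] <- violation(field, "uparam_order",
                                     "low <= base <= high violated")
  if (p$family == "beta") {
    vals <- c(p$base, p$low, p$high)
    if (any(!is.na(vals) & (vals < 0 | vals > 1)))
      v[[length(v) + 1L]] <- violation(field, "beta_domain",
                                       "beta family requires values in [0, 1]")
  }
  if (p$family == "gamma" && p$base <= 0)
    v[[length(v) + 1L]] <- violation(field, "gamma_domain",
                                     "gamma family requires base > 0")
  do.call(rbind, v)
}

#' Validate a model specification
#'
#' Checks every structural invariant of the model and returns the violations
#' found, rather than raising conditions: utilities in `[0, 1]` with full
#' horizon coverage for non-death states; death states inert (utility 0, zero
#' costs); probability schedules in `[0, 1]` with disjoint intervals;
#' transition endpoints declared; exactly one initial state; positive upfront
#' cost; well-ordered uncertainty ranges.
#'
#' @param spec a [model_spec()].
#' @return a `data.frame` with columns `field`, `rule`, `detail`; zero rows
#'   if and only if the specification is valid.
#' @export
validate_spec <- function(spec) {
  H <- spec$config$horizon_cycles
  v <- list()
  add <- function(x) if (!is.null(x)) v[[length(v) + 1L]] <<- x

  if (H < 1L) add(violation("config.horizon_cycles", "range", "horizon_cycles >= 1"))
  if (spec$config$discount_rate < 0 || spec$config$discount_rate >= 1)
    add(violation("config.discount_rate", "range", "discount rate in [0, 1)"))
  if (!is.finite(spec$technique$upfront_cost) || spec$technique$upfront_cost <= 0)
    add(violation("technique.upfront_cost", "range", "upfront_cost > 0"))

  nm <- state_names(spec)
  if (anyDuplicated(nm))
    add(violation("states", "unique_names", "duplicate state names"))
  n_init <- sum(vapply(spec$states, `[[`, TRUE, "is_initial"))
  if (n_init != 1L)
    add(violation("states", "single_initial",
                  sprintf("exactly one initial state required, found %d", n_init)))

  for (s in spec$states) {
    f <- paste0("states.", s$name)
    if (s$is_death) {
      if (s$is_initial)
        add(violation(f, "initial_death", "initial state cannot be a death state"))
      uvals <- if (is.null(s$utility)) numeric() else s$utility$value
      if (any(uvals != 0))
        add(violation(paste0(f, ".utility"), "death_utility", "death states have utility 0"))
      if (s$entry_cost != 0 || s$annual_cost != 0)
        add(violation(paste0(f, ".costs"), "death_costs", "death states have zero costs"))
    } else {
      add(check_pw(s$utility, paste0(f, ".utility"), H, 0, 1, cover = TRUE))
    }
    if (s$entry_cost < 0 || s$annual_cost < 0)
      add(violation(paste0(f, ".costs"), "nonnegative", "costs must be >= 0"))
    if (s$earliest_entry_cycle < 0L)
      add(violation(paste0(f, ".earliest_entry_cycle"), "range", "must be >= 0"))
    add(check_uparam(s$utility_unc, paste0(f, ".utility_unc")))
    add(check_uparam(s$entry_cost_unc, paste0(f, ".entry_cost_unc")))
  }

  for (tr in spec$transitions) {
    f <- paste0("transitions.", tr$id)
    if (!(tr$from %in% nm))
      add(violation(f, "undeclared_state",
                    sprintf("from-state '%s' is not declared", tr$from)))
    if (!(tr$to %in% nm))
      add(violation(f, "undeclared_state",
                    sprintf("to-state '%s' is not declared", tr$to)))
    if (is.null(tr$param_ref)) {
      add(check_pw(tr$prob, paste0(f, ".prob"), H, 0, 1, cover = FALSE))
    } else {
      if (!tr$param_ref %in% names(spec$technique$side_effect_probs))
        add(violation(f, "missing_param_ref",
                      sprintf("technique has no side-effect parameter '%s'", tr$param_ref)))
    }
  }

  for (k in names(spec$technique$side_effect_probs))
    add(check_uparam(spec$technique$side_effect_probs[[k]],
                     paste0("technique.side_effect_probs.", k)))

  if (!is.null(spec$other_cause_mortality))
    add(check_pw(spec$other_cause_mortality, "other_cause_mortality", H, 0, 1,
                 cover = FALSE))

  out <- do.call(rbind, v)
  if (is.null(out))
    out <- data.frame(field = character(), rule = character(),
                      detail = character(), stringsAsFactors = FALSE)
  out
}
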