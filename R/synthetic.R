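# Random generation of valid Markov CEA model specifications, emulating the
# structure of the bundled WBRT model: a layered chain of transient states
# with forward transitions plus death sinks, piecewise-constant probability
# schedules, bounded utilities, and positive costs with uncertainty. Used for
# property testing of the engine and sensitivity machinery.

#' Generator configuration
#'
#' @param n_transient integer range `c(min, max)` of transient-state counts.
#' @param n_death number of death states (categories assigned round-robin
#'   over other-cause, breast-cancer and toxicity).
#' @param horizon number of cycles.
#' @param probability_scale maximum total annual exit probability per state;
#'   must lie in `(0, 1)`.
#' @param discount_rate annual discount rate.
#' @param seed RNG seed; generation is deterministic given the config.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_transient = c(2L, 5L), n_death = 2L,
                             horizon = 10L, probability_scale = 0.3,
                             discount_rate = 0.03, seed = 1L) {
  if (!(probability_scale > 0 && probability_scale < 1))
    stop("probability_scale must be in (0, 1)")
  if (min(n_transient) < 1L) stop("need at least one transient state")
  if (n_death < 1L) stop("need at least one death state")
  x <- list(n_transient = as.integer(n_transient),
            n_death = as.integer(n_death), horizon = as.integer(horizon),
            probability_scale = probability_scale,
            discount_rate = discount_rate, seed = as.integer(seed))
  class(x) <- "generator_config"
  x
}

# random piecewise schedule covering [0, H) with 1..3 pieces
random_pw <- function(H, lo, hi) {
  k <- sample.int(min(3L, H), 1L)
  breaks <- sort(c(0L, if (k > 1L) sample(seq_len(H - 1L), k - 1L), H))
  piecewise(breaks[-length(breaks)], breaks[-1L],
            stats::runif(k, lo, hi))
}

#' Generate a random valid model specification
#'
#' Topology is a layered DAG: transient states are ordered and transition only
#' forward (plus into death sinks), mirroring the disease-progression shape of
#' the bundled model. Exit probabilities per state sum below
#' `probability_scale` at every cycle; utilities are drawn in (0, 1); costs
#' are positive with plausible standard deviations. The result always passes
#' [validate_spec()] and is identical for identical configs.
#'
#' @param cfg a [generator_config()].
#' @return a valid [model_spec()].
#' @export
generate_model <- function(cfg = generator_config()) {
  set.seed(cfg$seed)
  H <- cfg$horizon
  nT <- if (length(cfg$n_transient) > 1L)
    sample(seq(cfg$n_transient[1L], cfg$n_transient[2L]), 1L)
  else cfg$n_transient[1L]
  t_names <- paste0("S", seq_len(nT))
  cats <- rep(c("other_cause", "breast_cancer", "toxicity"),
              length.out = cfg$n_death)
  d_names <- paste0("D", seq_len(cfg$n_death), "_", cats)

  states <- vector("list", nT + cfg$n_death)
  for (i in seq_len(nT)) {
    entry <- if (i == 1L) 0 else stats::runif(1, 0, 30000)
    states[[i]] <- health_state(
      t_names[i], utility = random_pw(H, 0.05, 0.95),
      entry_cost = entry,
      annual_cost = stats::runif(1, 0, 5000),
      is_initial = (i == 1L),
      entry_cost_unc = if (entry > 0)
        uparam(entry, sd = entry * stats::runif(1, 0.05, 0.3),
               family = "gamma"))
  }
  for (j in seq_len(cfg$n_death))
    states[[nT + j]] <- health_state(d_names[j], is_death = TRUE,
                                     death_category = cats[j])

  transitions <- list()
  for (i in seq_len(nT)) {
    targets <- c(if (i < nT) t_names[(i + 1L):nT], d_names)
    k <- sample.int(length(targets), sample.int(min(3L, length(targets)), 1L))
    chosen <- targets[k]
    cap <- cfg$probability_scale / length(chosen)
    for (to in chosen) {
      pw <- random_pw(H, 0, cap)
      transitions[[length(transitions) + 1L]] <- transition(
        t_names[i], to, prob = pw,
        interpretation = sample(c("annual", "period_cumulative"), 1L))
    }
  }

  spec <- model_spec(
    config = model_config(horizon_cycles = H,
                          discount_rate = cfg$discount_rate,
                          reference_strategy = "GEN"),
    states = states, transitions = transitions,
    technique = technique_profile("GEN",
                                  upfront_cost = stats::runif(1, 1000, 20000)),
    meta = list(schema_version = 1L, generator_seed = cfg$seed))
  spec
}

#' Randomly perturb a model specification
#'
#' Multiplies numeric model inputs by independent factors in
#' `[1 - step, 1 + step]` and clips the results back into their invariant
#' domains (probabilities and utilities to `[0, 1]`, costs to non-negative),
#' so the perturbed spec remains valid.
#'
#' @param spec a [model_spec()].
#' @param relative_step perturbation half-width, in `(0, 1)`.
#' @param seed RNG seed.
#' @param fields which input groups to perturb: any of `"probs"`,
#'   `"utilities"`, `"costs"`.
#' @return the perturbed, still-valid [model_spec()].
#' @export
perturb_model <- function(spec, relative_step = 0.1, seed = 1L,
                          fields = c("probs", "utilities", "costs")) {
  stopifnot(relative_step > 0, relative_step < 1)
  fields <- match.arg(fields, several.ok = TRUE)
  set.seed(as.integer(seed))
  fac <- function(n = 1L) stats::runif(n, 1 - relative_step, 1 + relative_step)
  clip01 <- function(x) pmin(1, pmax(0, x))

  if ("probs" %in% fields) {
    for (i in seq_along(spec$transitions)) {
      tr <- spec$transitions[[i]]
      if (!is.null(tr$prob))
        spec$transitions[[i]]$prob$value <-
          clip01(tr$prob$value * fac(nrow(tr$prob)))
    }
    for (k in names(spec$technique$side_effect_probs)) {
      p <- spec$technique$side_effect_probs[[k]]
      f <- fac()
      p$base <- clip01(p$base * f)
      if (!is.na(p$low)) p$low <- clip01(min(p$low * f, p$base))
      if (!is.na(p$high)) p$high <- clip01(max(p$high * f, p$base))
      spec$technique$side_effect_probs[[k]] <- p
    }
    if (!is.null(spec$other_cause_mortality))
      spec$other_cause_mortality$value <-
        clip01(spec$other_cause_mortality$value *
                 fac(nrow(spec$other_cause_mortality)))
  }
  if ("utilities" %in% fields) {
    for (nm in names(spec$states)) {
      s <- spec$states[[nm]]
      if (s$is_death || is.null(s$utility)) next
      f <- fac()
      spec$states[[nm]]$utility$value <- clip01(s$utility$value * f)
      if (!is.null(s$utility_unc)) {
        u <- s$utility_unc
        u$base <- clip01(u$base * f)
        if (!is.na(u$low)) u$low <- clip01(min(u$low * f, u$base))
        if (!is.na(u$high)) u$high <- clip01(max(u$high * f, u$base))
        spec$states[[nm]]$utility_unc <- u
      }
    }
  }
  if ("costs" %in% fields) {
    for (nm in names(spec$states)) {
      s <- spec$states[[nm]]
      if (s$is_death) next
      f <- fac()
      spec$states[[nm]]$entry_cost <- max(0, s$entry_cost * f)
      spec$states[[nm]]$annual_cost <- max(0, s$annual_cost * fac())
      if (!is.null(s$entry_cost_unc)) {
        cu <- s$entry_cost_unc
        cu$base <- max(0, cu$base * f)
        spec$states[[nm]]$entry_cost_unc <- cu
      }
    }
    spec$technique$upfront_cost <- max(1e-6, spec$technique$upfront_cost * fac())
  }
  spec
}
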