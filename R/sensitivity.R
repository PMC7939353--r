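# One-way (tornado) and probabilistic sensitivity analysis over the
# side-effect parameters: annual probabilities (per technique), state
# utilities, and episode treatment costs.

#' Method-of-moments beta distribution for a probability or utility
#'
#' The `(low, high)` range is read as a 95% interval (`sd = range/3.92`) or as
#' a min/max range (`sd = range/4`), and the beta shape parameters are derived
#' by moment matching: `alpha = m (m(1-m)/s^2 - 1)`, `beta = (1-m) (...)`. If
#' the implied shapes are not positive the min/max fallback is tried; a
#' degenerate range yields a point-mass (`fixed`) distribution with a warning.
#'
#' @param p an [uparam()] with `family = "beta"` and `0 < base < 1`.
#' @param range_semantics `"ci95"` or `"minmax"`.
#' @return a list of class `distribution_spec` with `family`, `param1`
#'   (alpha), `param2` (beta), `mean`, `sd`.
#' @export
moment_match_beta <- function(p, range_semantics = c("ci95", "minmax")) {
  range_semantics <- match.arg(range_semantics)
  m <- p$base
  if (!(m > 0 && m < 1)) stop("beta moment matching requires base in (0, 1)")
  if (is.na(p$low) || is.na(p$high) || p$high == p$low) {
    warning("degenerate or missing range for beta parameter; using point mass")
    return(dist_spec("fixed", m, NA_real_, m, 0))
  }
  mk <- function(s) {
    nu <- m * (1 - m) / s^2 - 1
    c(alpha = m * nu, beta = (1 - m) * nu)
  }
  s <- (p$high - p$low) / if (range_semantics == "ci95") 3.92 else 4
  ab <- mk(s)
  if (any(ab <= 0)) {
    s <- (p$high - p$low) / 4
    ab <- mk(s)
  }
  if (any(ab <= 0))
    stop("range too wide for a valid beta distribution at mean ", m)
  dist_spec("beta", ab[["alpha"]], ab[["beta"]], m, s)
}

#' Method-of-moments gamma distribution for a cost
#'
#' Shape `k = (base/sd)^2` and scale `theta = sd^2/base`, so the distribution
#' mean and standard deviation equal `base` and `sd` exactly.
#'
#' @param p an [uparam()] with `family = "gamma"`, `base > 0` and a positive
#'   `sd`; a missing `sd` yields a point-mass distribution with a warning.
#' @return a `distribution_spec`.
#' @export
moment_match_gamma <- function(p) {
  if (p$base <= 0) stop("gamma moment matching requires base > 0")
  if (is.na(p$sd) || p$sd <= 0) {
    warning("missing sd for gamma parameter; using point mass")
    return(dist_spec("fixed", p$base, NA_real_, p$base, 0))
  }
  dist_spec("gamma", (p$base / p$sd)^2, p$sd^2 / p$base, p$base, p$sd)
}

dist_spec <- function(family, param1, param2, mean, sd) {
  x <- list(family = family, param1 = param1, param2 = param2,
            mean = mean, sd = sd)
  class(x) <- "distribution_spec"
  x
}

#' Draw from a matched distribution
#'
#' @param d a `distribution_spec`.
#' @param n number of draws.
#' @return numeric vector of draws (`base` repeated for `fixed`).
#' @export
draw_dist <- function(d, n = 1L) {
  switch(d$family,
         beta = stats::rbeta(n, d$param1, d$param2),
         gamma = stats::rgamma(n, shape = d$param1, scale = d$param2),
         fixed = rep.int(d$mean, n),
         stop("unknown distribution family '", d$family, "'"))
}

# map side-effect keys to the state they enter, via the param_ref transitions
side_effect_states <- function(spec) {
  out <- character()
  for (tr in spec$transitions)
    if (!is.null(tr$param_ref)) out[tr$param_ref] <- tr$to
  out
}

#' Enumerate the varied sensitivity parameters of a spec
#'
#' The varied set is exactly the side-effect inputs: annual onset
#' probabilities (beta), state utilities (beta), and episode treatment costs
#' (gamma). Disease progression schedules, baseline utilities and treatment
#' charges stay fixed.
#'
#' @param spec a [model_spec()].
#' @return a `data.frame` with columns `param` (e.g. `"prob.cardiac"`),
#'   `base`, `low`, `high`, `sd`, `family`.
#' @export
sa_parameters <- function(spec) {
  ses <- side_effect_states(spec)
  rows <- list()
  for (key in names(ses)) {
    p <- spec$technique$side_effect_probs[[key]]
    if (!is.null(p))
      rows[[paste0("prob.", key)]] <- c(p$base, p$low, p$high, p$sd)
    st <- spec$states[[ses[[key]]]]
    if (!is.null(st$utility_unc)) {
      u <- st$utility_unc
      rows[[paste0("utility.", key)]] <- c(u$base, u$low, u$high, u$sd)
    }
    if (!is.null(st$entry_cost_unc)) {
      cst <- st$entry_cost_unc
      rows[[paste0("cost.", key)]] <- c(cst$base, cst$low, cst$high, cst$sd)
    }
  }
  if (!length(rows))
    return(data.frame(param = character(), base = numeric(), low = numeric(),
                      high = numeric(), sd = numeric(), family = character()))
  m <- do.call(rbind, rows)
  data.frame(param = names(rows), base = m[, 1], low = m[, 2], high = m[, 3],
             sd = m[, 4],
             family = ifelse(startsWith(names(rows), "cost."), "gamma", "beta"),
             row.names = NULL)
}

#' Set one sensitivity parameter in a spec
#'
#' @param spec a [model_spec()].
#' @param param parameter name as in [sa_parameters()] (`"prob.X"`,
#'   `"utility.X"`, `"cost.X"` with `X` a side-effect key).
#' @param value new value; probability/utility values are applied flat over
#'   the state's active window.
#' @return the modified spec.
#' @export
spec_set_param <- function(spec, param, value) {
  parts <- strsplit(param, ".", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) stop("unknown parameter '", param, "'")
  kind <- parts[1L]; key <- parts[2L]
  ses <- side_effect_states(spec)
  if (!key %in% names(ses)) stop("unknown side-effect key '", key, "'")
  if (kind == "prob") {
    spec$technique$side_effect_probs[[key]]$base <- value
  } else if (kind == "utility") {
    st <- ses[[key]]
    spec$states[[st]]$utility$value[] <- value
    if (!is.null(spec$states[[st]]$utility_unc))
      spec$states[[st]]$utility_unc$base <- value
  } else if (kind == "cost") {
    st <- ses[[key]]
    spec$states[[st]]$entry_cost <- value
    if (!is.null(spec$states[[st]]$entry_cost_unc))
      spec$states[[st]]$entry_cost_unc$base <- value
  } else stop("unknown parameter kind '", kind, "'")
  spec
}

# Compile once, evaluate many times with side-effect overrides. Assumes each
# side-effect onset cell of the transition matrix is fed by a single
# param_ref transition (true for the fixture and generated models).
make_evaluator <- function(spec) {
  cm <- compile_model(spec)
  onset <- list()
  for (tr in spec$transitions) {
    if (is.null(tr$param_ref) || !transition_active(tr, spec)) next
    onset[[tr$param_ref]] <- list(
      from = cm$idx[[tr$from]], to = cm$idx[[tr$to]],
      gate = spec$states[[tr$to]]$earliest_entry_cycle)
  }
  H <- cm$horizon
  S <- length(cm$state_names)
  init <- cm$initial
  d_end <- cm$disc_end
  d_start <- c(1, d_end[-H])
  d_half <- (1 + cm$disc_rate)^-(seq_len(H) - 0.5)
  ac <- cm$annual_cost
  alive <- !cm$is_death
  bc <- cm$is_death & cm$category == "breast_cancer"

  function(probs = NULL, utils = NULL, costs = NULL) {
    Ms <- cm$Ms
    if (length(probs)) {
      for (t in seq_len(H)) {
        M <- Ms[[t]]
        rows <- integer()
        for (key in names(probs)) {
          o <- onset[[key]]
          if (is.null(o) || t <= o$gate) next
          M[o$from, o$to] <- probs[[key]]
          rows <- c(rows, o$from)
        }
        if (length(rows)) {
          for (fr in unique(rows)) {
            ex <- M[fr, ]; ex[fr] <- 0
            s <- sum(ex)
            if (s > 1) { ex <- ex / s; s <- 1 }
            ex[fr] <- 1 - s
            M[fr, ] <- ex
          }
          Ms[[t]] <- M
        }
      }
    }
    U <- cm$U
    ec <- cm$entry_cost
    for (key in names(utils)) {
      o <- onset[[key]]
      if (!is.null(o)) U[o$to, ] <- utils[[key]]
    }
    for (key in names(costs)) {
      o <- onset[[key]]
      if (!is.null(o)) ec[o$to] <- costs[[key]]
    }
    occ <- numeric(S); occ[init] <- 1
    qaly <- 0; cost <- cm$upfront
    for (t in seq_len(H)) {
      M <- Ms[[t]]
      newocc <- drop(occ %*% M)
      entries <- newocc - occ * diag(M)
      if (cm$half_cycle) {
        basis <- 0.5 * (occ + newocc); d <- d_half[t]
      } else if (cm$timing == "start") {
        basis <- occ; d <- d_start[t]
      } else {
        basis <- newocc; d <- d_end[t]
      }
      qaly <- qaly + sum(basis * U[, t]) * d
      cost <- cost + sum(basis * ac) * d + sum(entries * ec) * d_end[t]
      occ <- newocc
    }
    strategy_result(strategy = cm$strategy, total_cost = cost,
                    total_qaly = qaly, os_15y = sum(occ[alive]),
                    bc_mortality_15y = sum(occ[bc]),
                    tox_mortality_15y = NA_real_)
  }
}

split_overrides <- function(values) {
  # named vector with names "kind.key" -> list(probs=, utils=, costs=)
  kinds <- sub("\\..*$", "", names(values))
  keys <- sub("^[^.]*\\.", "", names(values))
  list(probs = as.list(stats::setNames(values[kinds == "prob"], keys[kinds == "prob"])),
       utils = as.list(stats::setNames(values[kinds == "utility"], keys[kinds == "utility"])),
       costs = as.list(stats::setNames(values[kinds == "cost"], keys[kinds == "cost"])))
}

#' One-way (tornado) sensitivity analysis of the pairwise ICER
#'
#' Each parameter in turn is set to its low and then its high bound — in both
#' arms for the shared utility/cost parameters, in the owning arm only for the
#' technique-specific onset probabilities — with everything else at base, and
#' the alt-versus-ref ICER is recomputed. Entries are sorted by descending
#' swing `|icer_high - icer_low|`, ties broken lexicographically by parameter
#' name. Parameters without a finite range are skipped with a warning.
#'
#' @param ref_spec,alt_spec [model_spec()] objects for the reference and
#'   comparison strategy.
#' @return a `data.frame` with columns `parameter`, `low`, `high`,
#'   `icer_low`, `icer_high`, `swing`, plus attribute `baseline_icer`.
#' @export
tornado <- function(ref_spec, alt_spec) {
  ev_ref <- make_evaluator(ref_spec)
  ev_alt <- make_evaluator(alt_spec)
  base_icer <- compute_icer(ev_ref(), ev_alt())$icer

  params <- list()
  add_param <- function(name, arm, key, kind, low, high) {
    if (is.na(low) || is.na(high)) {
      warning("parameter ", name, " has no range; skipped")
      return()
    }
    params[[name]] <<- list(arm = arm, key = key, kind = kind,
                            low = low, high = high)
  }
  for (spec_arm in list(list(spec = ref_spec, arm = "ref"),
                        list(spec = alt_spec, arm = "alt"))) {
    tech <- spec_arm$spec$technique
    for (key in names(tech$side_effect_probs)) {
      p <- tech$side_effect_probs[[key]]
      add_param(paste0("P_", key, "_", tech$name), spec_arm$arm, key, "prob",
                p$low, p$high)
    }
  }
  ses <- side_effect_states(ref_spec)
  for (key in names(ses)) {
    st <- ref_spec$states[[ses[[key]]]]
    if (!is.null(st$utility_unc))
      add_param(paste0("Utility_", key), "both", key, "utility",
                st$utility_unc$low, st$utility_unc$high)
    if (!is.null(st$entry_cost_unc)) {
      cu <- st$entry_cost_unc
      add_param(paste0("Cost_", key), "both", key, "cost",
                if (is.na(cu$low)) cu$base - cu$sd else cu$low,
                if (is.na(cu$high)) cu$base + cu$sd else cu$high)
    }
  }

  eval_at <- function(p, value) {
    ov <- split_overrides(stats::setNames(value, paste0(p$kind, ".", p$key)))
    ref_res <- if (p$arm %in% c("ref", "both"))
      ev_ref(ov$probs, ov$utils, ov$costs) else ev_ref()
    alt_res <- if (p$arm %in% c("alt", "both"))
      ev_alt(ov$probs, ov$utils, ov$costs) else ev_alt()
    compute_icer(ref_res, alt_res)$icer
  }
  rows <- lapply(names(params), function(nmp) {
    p <- params[[nmp]]
    il <- eval_at(p, p$low); ih <- eval_at(p, p$high)
    data.frame(parameter = nmp, low = p$low, high = p$high,
               icer_low = il, icer_high = ih,
               swing = abs(ih - il), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing, out$parameter), ]
  rownames(out) <- NULL
  attr(out, "baseline_icer") <- base_icer
  out
}

# --- probabilistic sensitivity analysis -------------------------------------

# deterministic substream seed: one seed per (root, iteration, parameter key),
# so adding a parameter does not perturb the draws of the others
param_key_hash <- function(key) {
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 131 + cc) %% 2147483629
  h
}

substream_seed <- function(root, iteration, key_hash) {
  as.integer((root %% 2147483629 + iteration * 48271 + key_hash * 16807) %%
               2147483629)
}

#' Probabilistic sensitivity analysis over all strategies
#'
#' Per iteration, one joint draw of the varied parameters: the side-effect
#' utilities (beta) and episode costs (gamma) are drawn once and shared by
#' every strategy; each strategy's three side-effect onset probabilities are
#' drawn from that technique's own beta distributions. All strategies are then
#' evaluated on the shared draw. Draws are independent across iterations and
#' bit-reproducible under a fixed seed (each parameter has its own
#' deterministic substream).
#'
#' @param specs named list of [model_spec()] objects (one per strategy).
#' @param n_iterations number of Monte-Carlo iterations.
#' @param seed root RNG seed.
#' @param vary_reference_probs if `FALSE`, the reference strategy's own onset
#'   probabilities stay at base instead of being drawn.
#' @return an object of class `psa_samples`: list with `samples` (data frame
#'   `iteration`, `strategy`, `cost`, `qaly`), `n`, `seed`, `strategies`.
#' @export
run_psa <- function(specs, n_iterations = 1000L, seed = 20210308L,
                    vary_reference_probs = TRUE) {
  stopifnot(n_iterations >= 1L)
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, function(s) s$technique$name, "")
  ref_name <- specs[[1L]]$config$reference_strategy
  semantics <- specs[[1L]]$config$beta_range_semantics

  # shared utility/cost distributions from the first spec that carries them
  shared <- list()
  ses <- side_effect_states(specs[[1L]])
  for (key in names(ses)) {
    st <- specs[[1L]]$states[[ses[[key]]]]
    if (!is.null(st$utility_unc))
      shared[[paste0("utility.", key)]] <-
        moment_match_beta(st$utility_unc, semantics)
    if (!is.null(st$entry_cost_unc))
      shared[[paste0("cost.", key)]] <- moment_match_gamma(st$entry_cost_unc)
  }
  # per-strategy onset probability distributions and evaluators
  strat <- lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    dists <- list()
    if (!(nm == ref_name && !vary_reference_probs)) {
      for (key in names(sp$technique$side_effect_probs)) {
        p <- sp$technique$side_effect_probs[[key]]
        if (!is.null(p) && p$family == "beta")
          dists[[paste0("prob.", key)]] <- moment_match_beta(p, semantics)
      }
    }
    list(name = nm, eval = make_evaluator(sp), dists = dists,
         hashes = vapply(paste0(nm, ":", names(dists)), param_key_hash, 0))
  })
  names(strat) <- names(specs)
  shared_hashes <- vapply(names(shared), param_key_hash, 0)

  root <- as.integer(seed)
  nS <- length(specs)
  n <- as.integer(n_iterations)
  cost <- matrix(NA_real_, n, nS, dimnames = list(NULL, names(specs)))
  qaly <- matrix(NA_real_, n, nS, dimnames = list(NULL, names(specs)))
  for (i in seq_len(n)) {
    sh <- numeric(length(shared))
    names(sh) <- names(shared)
    for (j in seq_along(shared)) {
      set.seed(substream_seed(root, i, shared_hashes[j]))
      sh[j] <- draw_dist(shared[[j]])
    }
    ov <- split_overrides(sh)
    for (s in strat) {
      pv <- numeric(length(s$dists))
      names(pv) <- sub("^prob\\.", "", names(s$dists))
      for (j in seq_along(s$dists)) {
        set.seed(substream_seed(root, i, s$hashes[j]))
        pv[j] <- draw_dist(s$dists[[j]])
      }
      res <- s$eval(probs = as.list(pv), utils = ov$utils, costs = ov$costs)
      cost[i, s$name] <- res$total_cost
      qaly[i, s$name] <- res$total_qaly
    }
  }
  samples <- data.frame(
    iteration = rep(seq_len(n), times = nS),
    strategy = rep(names(specs), each = n),
    cost = as.vector(cost), qaly = as.vector(qaly))
  out <- list(samples = samples, n = n, seed = root, strategies = names(specs),
              reference = ref_name)
  class(out) <- "psa_samples"
  out
}

#' @export
print.psa_samples <- function(x, ...) {
  cat("<psa_samples>", x$n, "iterations x", length(x$strategies),
      "strategies (seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Cost-effectiveness acceptability curve (pairwise)
#'
#' At each willingness-to-pay threshold, the probability that `alt` is
#' cost-effective against `ref` is the fraction of PSA iterations in which
#' `alt` has the higher net monetary benefit; exact NMB ties count 0.5, so the
#' two strategies' probabilities sum to one at every threshold.
#'
#' @param psa a `psa_samples` object from [run_psa()].
#' @param ref,alt strategy names.
#' @param wtp_grid willingness-to-pay thresholds ($/QALY).
#' @return a `data.frame` with columns `wtp`, `probability_alt`,
#'   `probability_ref`.
#' @export
ceac <- function(psa, ref, alt, wtp_grid = seq(0, 150000, by = 5000)) {
  s <- psa$samples
  if (!all(c(ref, alt) %in% s$strategy))
    stop("unknown strategy name; have: ",
         paste(unique(s$strategy), collapse = ", "))
  rs <- s[s$strategy == ref, ]; as <- s[s$strategy == alt, ]
  rs <- rs[order(rs$iteration), ]; as <- as[order(as$iteration), ]
  probs <- vapply(wtp_grid, function(l) {
    diff <- (l * as$qaly - as$cost) - (l * rs$qaly - rs$cost)
    mean(diff > 0) + 0.5 * mean(diff == 0)
  }, 0)
  data.frame(wtp = wtp_grid, probability_alt = probs,
             probability_ref = 1 - probs)
}
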