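# YAML model-config serialization. One document per strategy; keys mirror the
# model_spec fields and the schema is versioned via `schema_version`.

pw_to_list <- function(pw) {
  if (is.null(pw)) return(NULL)
  lapply(seq_len(nrow(pw)), function(i)
    list(start = pw$start[i], end = pw$end[i], value = pw$value[i]))
}

list_to_pw <- function(x, field) {
  if (is.null(x) || !length(x)) return(NULL)
  bad <- !vapply(x, function(p) all(c("start", "end", "value") %in% names(p)), TRUE)
  if (any(bad))
    stop("field '", field, "': schedule pieces need start, end, value")
  piecewise(vapply(x, `[[`, 0, "start"), vapply(x, `[[`, 0, "end"),
            vapply(x, `[[`, 0, "value"))
}

uparam_to_list <- function(p) if (is.null(p)) NULL else unclass(p)

list_to_uparam <- function(x, field) {
  if (is.null(x)) return(NULL)
  if (is.null(x$base)) stop("field '", field, "': uncertain parameter needs 'base'")
  na_or <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  uparam(x$base, na_or(x$low), na_or(x$high), na_or(x$sd),
         family = if (is.null(x$family)) "fixed" else x$family)
}

spec_to_list <- function(spec) {
  list(
    schema_version = 1L,
    config = unclass(spec$config),
    technique = list(
      name = spec$technique$name,
      upfront_cost = spec$technique$upfront_cost,
      side_effect_probs = lapply(spec$technique$side_effect_probs,
                                 uparam_to_list)),
    states = lapply(unname(spec$states), function(s) list(
      name = s$name, is_initial = s$is_initial,
      utility = pw_to_list(s$utility),
      entry_cost = s$entry_cost, annual_cost = s$annual_cost,
      is_death = s$is_death, death_category = s$death_category,
      earliest_entry_cycle = s$earliest_entry_cycle,
      utility_unc = uparam_to_list(s$utility_unc),
      entry_cost_unc = uparam_to_list(s$entry_cost_unc))),
    transitions = lapply(spec$transitions, function(tr) list(
      from = tr$from, to = tr$to, id = tr$id,
      interpretation = tr$interpretation, ambiguous = tr$ambiguous,
      prob = pw_to_list(tr$prob), param_ref = tr$param_ref)),
    other_cause_mortality = pw_to_list(spec$other_cause_mortality),
    meta = spec$meta)
}

list_to_spec <- function(x, path = "<config>") {
  need <- function(obj, key, where) {
    if (is.null(obj[[key]]))
      stop(path, ": missing required field '", where, "'")
    obj[[key]]
  }
  if (is.null(x$schema_version))
    stop(path, ": missing required field 'schema_version'")
  cfg_in <- if (is.null(x$config)) list() else x$config
  cfg <- do.call(model_config,
                 cfg_in[intersect(names(cfg_in), names(formals(model_config)))])
  te <- need(x, "technique", "technique")
  tech <- technique_profile(
    need(te, "name", "technique.name"),
    need(te, "upfront_cost", "technique.upfront_cost"),
    side_effect_probs = lapply(
      stats::setNames(nm = names(te$side_effect_probs)),
      function(k) list_to_uparam(te$side_effect_probs[[k]],
                                 paste0("technique.side_effect_probs.", k))))
  states <- lapply(need(x, "states", "states"), function(s) {
    nm <- need(s, "name", "states[].name")
    health_state(
      name = nm,
      utility = list_to_pw(s$utility, paste0("states.", nm, ".utility")),
      entry_cost = if (is.null(s$entry_cost)) 0 else s$entry_cost,
      annual_cost = if (is.null(s$annual_cost)) 0 else s$annual_cost,
      is_death = isTRUE(s$is_death),
      death_category = if (is.null(s$death_category)) "none" else s$death_category,
      earliest_entry_cycle = if (is.null(s$earliest_entry_cycle)) 0L
                             else s$earliest_entry_cycle,
      is_initial = isTRUE(s$is_initial),
      utility_unc = list_to_uparam(s$utility_unc,
                                   paste0("states.", nm, ".utility_unc")),
      entry_cost_unc = list_to_uparam(s$entry_cost_unc,
                                      paste0("states.", nm, ".entry_cost_unc")))
  })
  transitions <- lapply(need(x, "transitions", "transitions"), function(tr) {
    transition(
      from = need(tr, "from", "transitions[].from"),
      to = need(tr, "to", "transitions[].to"),
      prob = list_to_pw(tr$prob, paste0("transitions.", tr$from, "->", tr$to, ".prob")),
      interpretation = if (is.null(tr$interpretation)) "annual" else tr$interpretation,
      param_ref = tr$param_ref, id = tr$id, ambiguous = isTRUE(tr$ambiguous))
  })
  model_spec(config = cfg, states = states, transitions = transitions,
             technique = tech,
             other_cause_mortality = list_to_pw(x$other_cause_mortality,
                                                "other_cause_mortality"),
             meta = if (is.null(x$meta)) list() else x$meta)
}

#' Write a model specification to a YAML config file
#'
#' @param spec a [model_spec()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(spec, path) {
  txt <- yaml::as.yaml(spec_to_list(spec), precision = 15L)
  writeLines(txt, path)
  invisible(path)
}

#' Read a model specification from a YAML config file
#'
#' The document is parsed, converted, and validated; any schema or invariant
#' violation raises an error naming the offending field. `read_model()` after
#' [write_model()] reproduces the spec field for field.
#'
#' @param path config file path.
#' @return a valid [model_spec()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  spec <- list_to_spec(yaml::read_yaml(path), path = path)
  viol <- validate_spec(spec)
  if (nrow(viol) > 0L)
    stop(path, ": invalid model spec:\n",
         paste0("  - ", viol$field, " [", viol$rule, "]: ", viol$detail,
                collapse = "\n"))
  spec
}
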