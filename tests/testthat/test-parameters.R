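test_that("fixture transcribes every published parameter cell", {
  soc <- get_fixture("SOC")

  # transition probability schedules (values as fractions of the printed %)
  tr <- function(spec, id, from = NULL) {
    hit <- Filter(function(x) x$id == id &&
                    (is.null(from) || x$from == from), spec$transitions)
    expect_length(hit, 1L)
    hit[[1L]]
  }
  expect_equal(tr(soc, "recurrence")$prob$value, c(0.0146, 0.0054, 0.0006))
  expect_equal(tr(soc, "metastasis")$prob$value, c(0.1225, 0.0775, 0.0775))
  expect_equal(tr(soc, "progression")$prob$value, c(0.1225, 0.0775, 0.0775))
  md <- tr(soc, "met_death", from = "Metastasis")
  expect_equal(md$prob$value, c(0.232, 0.140))
  expect_equal(md$prob$start, c(0L, 5L))
  expect_equal(md$prob$end, c(5L, 15L))
  expect_equal(soc$other_cause_mortality$value, c(0.0146, 0.0171, 0.0353))
  expect_equal(tr(soc, "cardiac_death")$prob,
               piecewise(10, 15, 0.0053))
  expect_equal(tr(soc, "cl_breast_death")$prob,
               piecewise(5, 15, 0.0212))
  expect_equal(tr(soc, "lung_death")$prob,
               piecewise(10, 15, 0.00078))

  # utilities
  u <- function(name) soc$states[[name]]$utility$value
  expect_equal(u("NED"), c(0.734, 0.716, 0.675))
  expect_equal(u("Recurrence"), c(0.66, 0.65, 0.61))
  expect_equal(u("Metastasis"), c(0.44, 0.43, 0.41))
  uu <- function(name) unlist(soc$states[[name]]$utility_unc[c("base", "low", "high")])
  expect_equal(unname(uu("Cardiac")), c(0.57, 0.54, 0.61))
  expect_equal(unname(uu("CLBreast")), c(0.54, 0.48, 0.55))
  expect_equal(unname(uu("Lung")), c(0.50, 0.39, 0.56))

  # side-effect onset windows
  expect_equal(soc$states$CLBreast$earliest_entry_cycle, 5L)
  expect_equal(soc$states$Cardiac$earliest_entry_cycle, 10L)
  expect_equal(soc$states$Lung$earliest_entry_cycle, 10L)

  # treatment and episode costs
  expect_equal(soc$states$Recurrence$entry_cost, 20879)
  expect_equal(soc$states$Metastasis$entry_cost, 13627)
  ec <- function(name) c(soc$states[[name]]$entry_cost,
                         soc$states[[name]]$entry_cost_unc$sd)
  expect_equal(ec("Cardiac"), c(11570, 3405))
  expect_equal(ec("CLBreast"), c(14494, 1199))
  expect_equal(ec("Lung"), c(20577, 2740))

  upfronts <- c(SOC = 12140, FIF = 12140, HybridIMRT = 15293, IMRT = 17438,
                STD_VMAT = 17438, NC_VMAT = 17438, MA_VMAT = 17438)
  # per-technique annual side-effect probabilities with ranges;
  # the degenerate printed IMRT cl_breast low bound is excluded (substituted
  # value, see fixture meta)
  probs <- list(
    SOC = list(cardiac = c(0.0124, 0.0080, 0.0203),
               cl_breast = c(0.0038, 0.0013, 0.0139),
               lung = c(0.0022, 0.0018, 0.0028)),
    FIF = list(cardiac = c(0.0115, 0.0080, 0.0197),
               cl_breast = c(0.0038, 0.0018, 0.0071),
               lung = c(0.0022, 0.0018, 0.0031)),
    HybridIMRT = list(cardiac = c(0.0116, 0.0077, 0.0188),
                      cl_breast = c(0.0035, 0.0012, 0.0133),
                      lung = c(0.0020, 0.0016, 0.0027)),
    IMRT = list(cardiac = c(0.0114, 0.0074, 0.0178),
                cl_breast = c(0.0032, NA, 0.0071),
                lung = c(0.0020, 0.0014, 0.0027)),
    STD_VMAT = list(cardiac = c(0.0116, 0.0069, 0.0177),
                    cl_breast = c(0.0027, 0.0017, 0.0054),
                    lung = c(0.0020, 0.0018, 0.0029)),
    NC_VMAT = list(cardiac = c(0.0105, 0.0065, 0.0151),
                   cl_breast = c(0.0027, 0.0017, 0.0078),
                   lung = c(0.0018, 0.0013, 0.0025)),
    MA_VMAT = list(cardiac = c(0.0103, 0.0065, 0.0152),
                   cl_breast = c(0.0026, 0.0015, 0.0039),
                   lung = c(0.0017, 0.0010, 0.0024)))
  for (tech in wbrt_techniques()) {
    spec <- get_fixture(tech)
    expect_equal(spec$technique$upfront_cost, unname(upfronts[tech]))
    for (key in c("cardiac", "cl_breast", "lung")) {
      p <- spec$technique$side_effect_probs[[key]]
      exp <- probs[[tech]][[key]]
      expect_equal(p$base, exp[1], info = paste(tech, key))
      if (!is.na(exp[2])) expect_equal(p$low, exp[2], info = paste(tech, key))
      expect_equal(p$high, exp[3], info = paste(tech, key))
      expect_equal(p$family, "beta")
    }
  }
})

test_that("techniques differ from SOC only in upfront cost and side-effect probabilities", {
  soc <- get_fixture("SOC")
  for (tech in setdiff(wbrt_techniques(), "SOC")) {
    spec <- get_fixture(tech)
    expect_equal(spec$states, soc$states)
    expect_equal(spec$transitions, soc$transitions)
    expect_equal(spec$other_cause_mortality, soc$other_cause_mortality)
    expect_equal(spec$config, soc$config)
  }
  # in particular FIF shares the recurrence/metastasis schedules exactly
  expect_equal(get_fixture("FIF")$transitions, soc$transitions)
})

test_that("unknown technique name raises an explicit error", {
  expect_error(wbrt_fixture("PROTON"), "unknown technique")
})

test_that("validate_spec accepts the fixture and reports invariant violations", {
  expect_identical(nrow(validate_spec(get_fixture("SOC"))), 0L)

  bad <- get_fixture("SOC")
  bad$states$NED$utility <- piecewise(c(0, 3), c(5, 15), c(0.7, 0.7))
  v <- validate_spec(bad)
  expect_true(any(v$rule == "interval_overlap" & grepl("NED", v$field)))

  bad <- get_fixture("SOC")
  bad$states$Recurrence$is_initial <- TRUE
  v <- validate_spec(bad)
  expect_true(any(v$rule == "single_initial"))

  bad <- get_fixture("SOC")
  bad$states$NED$utility$value[1] <- 1.2
  v <- validate_spec(bad)
  expect_true(any(v$rule == "range" & grepl("NED.utility", v$field)))

  bad <- get_fixture("SOC")
  bad$states$Death_BC$entry_cost <- 100
  expect_true(any(validate_spec(bad)$rule == "death_costs"))

  bad <- get_fixture("SOC")
  bad$technique$side_effect_probs$cardiac$low <- 0.5  # low > base
  expect_true(any(validate_spec(bad)$rule == "uparam_order"))

  bad <- get_fixture("SOC")
  bad$states <- bad$states[names(bad$states) != "Lung"]
  v <- validate_spec(bad)
  expect_true(any(v$rule == "undeclared_state" & grepl("Lung", v$detail)))
})

test_that("model configs round-trip through YAML field for field", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  soc <- get_fixture("SOC")
  write_model(soc, tmp)
  expect_spec_equal(read_model(tmp), soc)

  for (seed in 1:100) {
    spec <- generate_model(generator_config(seed = seed))
    write_model(spec, tmp)
    expect_spec_equal(read_model(tmp), spec)
  }
})

test_that("packaged per-technique config files equal the in-code fixture", {
  for (tech in wbrt_techniques()) {
    path <- system.file("extdata", paste0(tolower(tech), ".yaml"),
                        package = "wbrtcea")
    expect_true(nzchar(path))
    expect_spec_equal(read_model(path), get_fixture(tech))
  }
})

test_that("reading an invalid config names the offending field", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  soc <- get_fixture("SOC")

  bad <- soc
  bad$states$NED$utility$value[1] <- 1.2
  write_model(bad, tmp)
  expect_error(read_model(tmp), "NED.utility")

  bad <- soc
  bad$states <- bad$states[names(bad$states) != "CLBreast"]
  write_model(bad, tmp)
  expect_error(read_model(tmp), "CLBreast")

  x <- wbrtcea:::spec_to_list(soc)
  x$schema_version <- NULL
  writeLines(yaml::as.yaml(x), tmp)
  expect_error(read_model(tmp), "schema_version")
})
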