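# Standardized ODE system: interface, units, variable access, gates, ranges.

test_that("initial right-hand sides match independent hand-coded oracles", {
  m <- cached_model("hodgkin_huxley")
  y <- initial_state(m)
  d <- eval_rhs(m, 0, y)
  want <- align_oracle(hh_oracle_rhs(0, y), m)
  expect_equal(as.numeric(d), as.numeric(want), tolerance = 1e-12)

  lr <- cached_model("luo_rudy_1991")
  ylr <- initial_state(lr)
  dlr <- eval_rhs(lr, 0, ylr)
  wantlr <- align_oracle(lr91_oracle_rhs(0, ylr), lr)
  # mixed absolute/relative comparison: the resting dV/dt is a small
  # difference of O(1) currents, so a pure relative bound would amplify
  # benign evaluation-order float noise in the Nernst constants
  expect_lt(max(abs(dlr - wantlr) / (1 + abs(wantlr))), 1e-12)
})

test_that("oracle agreement holds across random states and stimulus values", {
  m <- cached_model("luo_rudy_1991")
  y0 <- initial_state(m)
  set.seed(11)
  for (k in 1:25) {
    y <- y0 * (1 + 0.3 * stats::runif(length(y0), -1, 1))
    y[[m$interface$v]] <- stats::runif(1, -95, 45)
    istim <- stats::runif(1, -30, 0)
    d <- eval_rhs(m, 0, y, i_stim = istim)
    want <- align_oracle(lr91_oracle_rhs(0, y, istim), m)
    expect_equal(as.numeric(d), as.numeric(want), tolerance = 1e-10)
  }
})

test_that("interface binds by annotation and by name heuristics identically", {
  m <- cached_model("hodgkin_huxley")
  expect_equal(m$interface$v, "V")
  expect_equal(m$interface$cm, "Cm")
  expect_equal(m$interface$stim, "i_Stim")
  expect_setequal(m$interface$currents, c("i_Na", "i_K", "i_L"))

  # strip the RDF block: binding must fall back to the common-name list
  doc <- make_hodgkin_huxley()
  stripped <- sub("<RDF.*</RDF>", "", doc)
  res <- convert_cellml(stripped)
  expect_equal(res$report$status, "ok")
  expect_equal(res$model$interface$v, "V")
  expect_equal(res$model$interface$stim, "i_Stim")
  expect_setequal(res$model$interface$currents, c("i_Na", "i_K", "i_L"))
})

test_that("self-excitatory models bind no stimulus slot and need none", {
  m <- cached_model("self_excitatory")
  expect_null(m$interface$stim)
  expect_true(m$interface$self_excitatory)
  expect_error(default_stimulus(m), "self-excitatory")
})

test_that("a dV/dt equation that is not a current balance is rejected", {
  doc <- make_toy_gate()
  # corrupt the V equation: double the current sum without adjusting currents
  bad <- sub("<apply><eq/><apply><diff/><bvar><ci>time</ci></bvar><ci>V</ci></apply>",
             paste0("<apply><eq/><apply><diff/><bvar><ci>time</ci></bvar><ci>V</ci></apply>",
                    '<apply><times/><cn units="dimensionless">2</cn>'),
             doc, fixed = TRUE)
  bad <- sub("</apply>\n    <apply><eq/><apply><diff/><bvar><ci>time</ci></bvar><ci>m</ci></apply>",
             "</apply></apply>\n    <apply><eq/><apply><diff/><bvar><ci>time</ci></bvar><ci>m</ci></apply>",
             bad, fixed = TRUE)
  res <- convert_cellml(bad)
  expect_equal(res$report$status, "failed")
  msgs <- vapply(res$report$failures, function(f) f$message, "")
  expect_true(any(grepl("dV/dt", msgs)))
})

test_that("units standardization maps a seconds/volts twin onto the ms/mV model", {
  # the toy gate re-authored in seconds and volts, same physics
  doc <- make_toy_gate()
  twin <- doc
  twin <- gsub('units="mV"', 'units="volt"', twin, fixed = TRUE)
  twin <- gsub('units="ms"', 'units="second"', twin, fixed = TRUE)
  twin <- gsub('units="per_ms"', 'units="per_s"', twin, fixed = TRUE)
  twin <- gsub('units="per_mV"', 'units="per_V"', twin, fixed = TRUE)
  twin <- sub('<units name="ms">', '<units name="per_s"><unit units="second" exponent="-1"/></units><units name="unused_ms">',
              twin, fixed = TRUE)
  twin <- sub('<units name="per_V">', '<units name="per_V"><unit units="volt" exponent="-1"/></units><units name="unused_pV">',
              twin, fixed = TRUE)
  # rescale the numeric values to the new declared units
  rescale <- function(txt, pattern, factor) {
    m <- gregexpr(pattern, txt)
    regmatches(txt, m) <- lapply(regmatches(txt, m), function(vals) {
      vapply(vals, function(v) {
        num <- as.numeric(sub('.*>([-0-9.eE+]+)<.*', '\\1', v))
        sub('>([-0-9.eE+]+)<', sprintf('>%.17g<', num * factor), v)
      }, "")
    })
    txt
  }
  twin <- rescale(twin, '<cn units="volt">[-0-9.eE+]+</cn>', 1e-3)
  twin <- rescale(twin, '<cn units="per_s">[-0-9.eE+]+</cn>', 1e3)
  twin <- sub('name="V" units="volt" initial_value="-60"',
              'name="V" units="volt" initial_value="-0.06"', twin, fixed = TRUE)
  twin <- sub('name="E_L" units="volt" initial_value="-70"',
              'name="E_L" units="volt" initial_value="-0.07"', twin, fixed = TRUE)
  twin <- sub('name="stim_duration" units="second" initial_value="1"',
              'name="stim_duration" units="second" initial_value="0.001"', twin, fixed = TRUE)
  twin <- sub('name="stim_period" units="second" initial_value="50"',
              'name="stim_period" units="second" initial_value="0.05"', twin, fixed = TRUE)
  twin <- sub('name="stim_start" units="second" initial_value="5"',
              'name="stim_start" units="second" initial_value="0.005"', twin, fixed = TRUE)
  res <- convert_cellml(twin)
  expect_equal(res$report$status, "ok")
  m_ms <- convert_cellml(doc)$model
  m_tw <- res$model
  expect_equal(initial_state(m_tw), initial_state(m_ms), tolerance = 1e-12)
  # identical standardized dynamics: same trace
  stim <- default_stimulus(m_ms)
  stim_tw <- default_stimulus(m_tw)
  expect_equal(unclass(stim_tw), unclass(stim), tolerance = 1e-12)
  tr1 <- solve_fixed(m_ms, solver_config("RK4", dt = 0.05), stim, c(0, 20))
  tr2 <- solve_fixed(m_tw, solver_config("RK4", dt = 0.05), stim_tw, c(0, 20))
  expect_equal(tr2$states, tr1$states, tolerance = 1e-10)
})

test_that("units standardization is idempotent", {
  raw <- parse_document(make_toy_gate())
  flat <- flatten(raw)
  ann <- read_annotations(raw, flat)
  once <- convert_units(flat, ann)
  twice <- convert_units(once, ann)
  expect_equal(vapply(twice$variables, function(v) v$initial_value, 1),
               vapply(once$variables, function(v) v$initial_value, 1))
  expect_equal(lapply(twice$odes, function(o) deparse1(o$rhs)),
               lapply(once$odes, function(o) deparse1(o$rhs)))
})

test_that("absolute-unit currents convert to densities via the capacitance pair", {
  # toy model in nA with annotated total and specific capacitance:
  # C_m = 50 pF, C_spec = 1 uF/cm^2 -> area = 5e-5 cm^2,
  # so 1 nA = 1e-3 uA over 5e-5 cm^2 = 20 uA/cm^2.
  variables <- c(list(
    myocyte:::fx_var("time", "ms"),
    myocyte:::fx_var("V", "mV", -60),
    myocyte:::fx_var("Cm_total", "picoF", 50),
    myocyte:::fx_var("Cspec", "uF_per_cm2", 1),
    myocyte:::fx_var("i_leak", "nanoA")
  ), myocyte:::fx_stim_vars(-8, 1, 50, 5))
  assignments <- list(
    list(var = "i_leak", rhs = quote(cn_(0.05, "nanoS") * (V - cn_(-70, "mV")))),
    list(var = "i_Stim", rhs = myocyte:::fx_stim_expr())
  )
  odes <- list(list(state = "V",
                    rhs = quote(-(i_leak) / Cm_total - i_Stim / Cspec)))
  ann <- list(terms = c(list(V = myocyte:::TERM_V,
                             Cm_total = myocyte:::TERM_CM,
                             Cspec = myocyte:::TERM_CM_SPECIFIC,
                             i_leak = "membrane_leakage_current"),
                        myocyte:::fx_stim_terms()))
  doc <- myocyte:::fx_doc("absolute_current", variables, assignments, odes, ann)
  doc <- sub("<component", paste0(
    '<units name="picoF"><unit units="farad" prefix="pico"/></units>',
    '<units name="nanoA"><unit units="ampere" prefix="nano"/></units>',
    '<units name="nanoS"><unit units="siemens" prefix="nano"/></units>',
    "<component"), doc, fixed = TRUE)
  res <- convert_cellml(doc)
  expect_equal(res$report$status, "ok")
  m <- res$model
  # hand dimensional analysis: i_leak(V=-60) = 0.05 nS * 10 mV = 0.5 pA
  # = 5e-7 uA; x (Cspec/Cm) = 1/(50e-6 uF) per cm^2 -> 0.01 uA/cm^2
  v <- get_any_variable(m, initial_state(m), 0, "membrane_leakage_current")
  expect_equal(v, 0.01, tolerance = 1e-12)
  expect_equal(m$parameters[["Cm_total"]], 1)  # rebound to Cspec, uF/cm^2
})

test_that("any variable is readable by term or raw name, with near-miss hints", {
  m <- cached_model("luo_rudy_1991")
  y <- initial_state(m)
  expect_equal(get_any_variable(m, y, 0, "membrane_voltage"), y[["V"]])
  # calcium is a state here
  expect_equal(get_any_variable(m, y, 0, "cytosolic_calcium_concentration"),
               y[["Cai"]])
  # derived quantity evaluated from state: E_si = 7.7 - 13.0287 log(Cai)
  expect_equal(get_any_variable(m, y, 0, "E_si"),
               7.7 - 13.0287 * log(y[["Cai"]]), tolerance = 1e-12)
  # a model where calcium is a parameter reads through the same term
  msing <- cached_model("singularity")
  expect_equal(get_any_variable(msing, initial_state(msing), 0,
                                "cytosolic_calcium_concentration"),
               initial_state(msing)[["c"]])
  expect_error(get_any_variable(m, y, 0, "membrane_voltagee"), "did you mean")
})

test_that("set_any_variable updates states and parameters but not derived", {
  m <- cached_model("hodgkin_huxley")
  y <- initial_state(m)
  # halving a conductance halves that current at fixed state
  i0 <- get_any_variable(m, y, 0, "i_Na")
  upd <- set_any_variable(m, y, "membrane_fast_sodium_current_conductance",
                          m$parameters[["g_Na"]] * 0.5)
  i1 <- get_any_variable(upd$model, y, 0, "i_Na")
  expect_equal(i1, i0 / 2, tolerance = 1e-12)
  # and the full RHS reflects it
  d0 <- eval_rhs(m, 0, y)
  d1 <- eval_rhs(upd$model, 0, y)
  expect_equal(d1[["V"]] - d0[["V"]], (i0 - i1) / m$parameters[["Cm"]],
               tolerance = 1e-10)
  # setting V touches only the V slot
  upd2 <- set_any_variable(m, y, "membrane_voltage", -50)
  expect_equal(upd2$state[["V"]], -50)
  expect_equal(upd2$state[names(y) != "V"], y[names(y) != "V"])
  expect_error(set_any_variable(m, y, "i_Na", 1), "not settable")
})

test_that("gate detection is invariant to algebraic form of the gate equation", {
  m <- cached_model("hodgkin_huxley")
  det <- detect_gates(m)
  expect_setequal(names(det$gates), c("m", "h", "n"))
  expect_setequal(det$non_gates, "V")
  # rewrite dm/dt from alpha(1-m)-beta*m to (m_inf - m)/tau form
  doc2 <- sub(
    "<apply><eq/><apply><diff/><bvar><ci>time</ci></bvar><ci>m</ci></apply><apply><minus/><apply><times/><ci>alpha_m</ci><apply><minus/><cn units=\"dimensionless\">1</cn><ci>m</ci></apply></apply><apply><times/><ci>beta_m</ci><ci>m</ci></apply></apply></apply>",
    "<apply><eq/><apply><diff/><bvar><ci>time</ci></bvar><ci>m</ci></apply><apply><times/><apply><plus/><ci>alpha_m</ci><ci>beta_m</ci></apply><apply><minus/><apply><divide/><ci>alpha_m</ci><apply><plus/><ci>alpha_m</ci><ci>beta_m</ci></apply></apply><ci>m</ci></apply></apply></apply>",
    make_hodgkin_huxley(), fixed = TRUE)
  expect_false(identical(doc2, make_hodgkin_huxley()))
  m2 <- convert_cellml(doc2)$model
  det2 <- detect_gates(m2)
  expect_true("m" %in% names(det2$gates))
  # identical tau and g_inf at a probe voltage
  env <- list2env(list(V = -55, piecewise_ = piecewise_))
  for (p in names(m$parameters)) assign(p, m$parameters[[p]], envir = env)
  y0 <- initial_state(m)
  for (s in names(y0)) if (s != "V") assign(s, y0[[s]], envir = env)
  assign("i_Stim", 0, envir = env)
  assign("time", 0, envir = env)
  inline <- function(model, what) {
    # evaluate gate expressions through the assignment chain
    e <- new.env(parent = env)
    for (a in model$assignments) assign(a$var, eval(a$rhs, e), envir = e)
    eval(what, e)
  }
  expect_equal(inline(m2, det2$gates$m$tau), inline(m, det$gates$m$tau),
               tolerance = 1e-12)
  expect_equal(inline(m2, det2$gates$m$g_inf), inline(m, det$gates$m$g_inf),
               tolerance = 1e-12)
})

test_that("nonlinear states are excluded from the gate set", {
  lr <- cached_model("luo_rudy_1991")
  det <- detect_gates(lr)
  expect_setequal(names(det$gates), c("m", "h", "j", "d", "f", "X"))
  expect_true("Cai" %in% det$non_gates)  # depends on i_si, not affine via gates
  # du/dt = -u^2 is not a gate
  sing <- cached_model("self_excitatory")
  det2 <- detect_gates(sing)
  expect_false("V" %in% names(det2$gates))
})

test_that("range checks report violations with variable, value and bound", {
  m <- cached_model("hodgkin_huxley")
  y <- initial_state(m)
  expect_length(check_ranges(m, y), 0L)
  y[["m"]] <- 1.2
  v <- check_ranges(m, y)
  expect_length(v, 1L)
  expect_equal(v[[1]]$variable, "m")
  expect_equal(v[[1]]$bound, 1)
  y[["m"]] <- -0.1
  expect_equal(check_ranges(m, y)[[1]]$side, "lower")
})

test_that("the default stimulus comes from the model's annotated parameters", {
  m <- cached_model("luo_rudy_1991")
  stim <- default_stimulus(m)
  expect_equal(stim$amplitude, -25.5)
  expect_equal(stim$duration, 2)
  expect_equal(stim$period, 1000)
  expect_equal(stim$start, 100)
  # a model without stimulus annotations demands an explicit stimulus
  doc <- make_toy_gate()
  doc2 <- gsub('resource="https://example.org/cardiac/metadata#membrane_stimulus_current_amplitude"',
               'resource="https://example.org/cardiac/metadata#something_else"',
               doc, fixed = TRUE)
  m2 <- convert_cellml(doc2)$model
  expect_error(default_stimulus(m2), "explicit")
})
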