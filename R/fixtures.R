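# In-repo model zoo.
#
# Every fixture is emitted as a CellML-subset document so the whole pipeline
# (parse -> flatten -> annotate -> standardize -> simulate) is exercised with
# no downloads.  Hodgkin-Huxley (1952, squid axon, modern sign convention)
# and Luo-Rudy (1991, guinea-pig ventricle) are transcribed from the original
# publications; the remaining models are synthetic stress fixtures.

fx_var <- function(name, units, init = NA_real_, id = name) {
  list(name = name, units = units, initial_value = init, ids = id)
}

fx_units_common <- function() {
  list(
    ms = list(list(units = "second", prefix = "milli")),
    mV = list(list(units = "volt", prefix = "milli")),
    per_ms = list(list(units = "second", prefix = "milli", exponent = "-1")),
    per_mV = list(list(units = "volt", prefix = "milli", exponent = "-1")),
    per_mV_ms = list(list(units = "volt", prefix = "milli", exponent = "-1"),
                     list(units = "second", prefix = "milli", exponent = "-1")),
    uA_per_cm2 = list(list(units = "ampere", prefix = "micro"),
                      list(units = "metre", prefix = "centi", exponent = "-2")),
    uF_per_cm2 = list(list(units = "farad", prefix = "micro"),
                      list(units = "metre", prefix = "centi", exponent = "-2")),
    mS_per_cm2 = list(list(units = "siemens", prefix = "milli"),
                      list(units = "metre", prefix = "centi", exponent = "-2")),
    mM = list(list(units = "molar", prefix = "milli")),
    mM_per_ms = list(list(units = "molar", prefix = "milli"),
                     list(units = "second", prefix = "milli", exponent = "-1")),
    mM_cm2_per_uA_ms = list(list(units = "molar", prefix = "milli"),
                            list(units = "metre", prefix = "centi", exponent = "2"),
                            list(units = "ampere", prefix = "micro", exponent = "-1"),
                            list(units = "second", prefix = "milli", exponent = "-1")),
    J_per_mol_K = list(list(units = "joule"),
                       list(units = "mole", exponent = "-1"),
                       list(units = "kelvin", exponent = "-1")),
    C_per_mol = list(list(units = "coulomb"), list(units = "mole", exponent = "-1"))
  )
}

# square-wave stimulus expression from the annotated parameter variables
fx_stim_expr <- function() {
  quote(piecewise_(
    (time >= stim_start) &
      (time - stim_start - stim_period * floor((time - stim_start) / stim_period) <
         stim_duration),
    stim_amplitude,
    cn_(0, "uA_per_cm2")))
}

fx_stim_vars <- function(amplitude, duration, period, start) {
  list(fx_var("i_Stim", "uA_per_cm2"),
       fx_var("stim_amplitude", "uA_per_cm2", amplitude),
       fx_var("stim_duration", "ms", duration),
       fx_var("stim_period", "ms", period),
       fx_var("stim_start", "ms", start))
}

fx_stim_terms <- function() {
  list(i_Stim = TERM_STIM,
       stim_amplitude = TERM_STIM_AMPL,
       stim_duration = TERM_STIM_DUR,
       stim_period = TERM_STIM_PERIOD,
       stim_start = TERM_STIM_OFFSET)
}

fx_doc <- function(name, variables, assignments, odes, annotations) {
  vars <- stats::setNames(variables, vapply(variables, function(v) v$name, ""))
  flat <- list(variables = vars, assignments = assignments, odes = odes,
               time_var = "time")
  write_document(flat, annotations, name = name,
                 unit_definitions = fx_units_common())
}

#' Minimal two-state fixture: leak current gated by one Hodgkin-Huxley gate
#'
#' dV/dt = -(g_L * m * (V - E_L) + I_stim)/C_m with a single gate whose
#' opening/closing rates are simple exponentials of V, so m(t) at fixed V has
#' a closed form for tests.
#'
#' @return document text.
#' @export
make_toy_gate <- function() {
  variables <- c(list(
    fx_var("time", "ms"),
    fx_var("V", "mV", -60),
    fx_var("m", "dimensionless", 0.1),
    fx_var("Cm", "uF_per_cm2", 1),
    fx_var("g_L", "mS_per_cm2", 0.5),
    fx_var("E_L", "mV", -70),
    fx_var("alpha_m", "per_ms"),
    fx_var("beta_m", "per_ms"),
    fx_var("i_L", "uA_per_cm2")
  ), fx_stim_vars(-8, 1, 50, 5))
  assignments <- list(
    list(var = "alpha_m", rhs = quote(cn_(0.2, "per_ms") * exp(V / cn_(25, "mV")))),
    list(var = "beta_m", rhs = quote(cn_(0.4, "per_ms") * exp(-V / cn_(25, "mV")))),
    list(var = "i_L", rhs = quote(g_L * m * (V - E_L))),
    list(var = "i_Stim", rhs = fx_stim_expr())
  )
  odes <- list(
    list(state = "V", rhs = quote(-(i_L + i_Stim) / Cm)),
    list(state = "m", rhs = quote(alpha_m * (1 - m) - beta_m * m))
  )
  ann <- list(
    terms = c(list(V = TERM_V, Cm = TERM_CM,
                   g_L = "membrane_leakage_current_conductance",
                   i_L = "membrane_leakage_current"),
              fx_stim_terms()),
    modifiable = c("g_L"),
    derived = c("i_L"),
    ranges = list(m = c(0, 1))
  )
  fx_doc("toy_gate", variables, assignments, odes, ann)
}

#' Hodgkin-Huxley (1952) squid-axon model, modern sign convention
#'
#' Four states (V, m, h, n), three currents (fast sodium, delayed-rectifier
#' potassium, leak).  Fully annotated: voltage, capacitance, stimulus
#' parameters, per-current conductances, gate ranges.  The default stimulus
#' (-20 uA/cm^2, 0.5 ms, 1 Hz, first pulse at 10 ms) elicits one action
#' potential per pace.
#'
#' @return document text.
#' @export
make_hodgkin_huxley <- function() {
  variables <- c(list(
    fx_var("time", "ms"),
    fx_var("V", "mV", -75),
    fx_var("m", "dimensionless", 0.05),
    fx_var("h", "dimensionless", 0.6),
    fx_var("n", "dimensionless", 0.325),
    fx_var("Cm", "uF_per_cm2", 1),
    fx_var("g_Na", "mS_per_cm2", 120),
    fx_var("g_K", "mS_per_cm2", 36),
    fx_var("g_L", "mS_per_cm2", 0.3),
    fx_var("E_Na", "mV", 40),
    fx_var("E_K", "mV", -87),
    fx_var("E_L", "mV", -64.387),
    fx_var("alpha_m", "per_ms"), fx_var("beta_m", "per_ms"),
    fx_var("alpha_h", "per_ms"), fx_var("beta_h", "per_ms"),
    fx_var("alpha_n", "per_ms"), fx_var("beta_n", "per_ms"),
    fx_var("i_Na", "uA_per_cm2"), fx_var("i_K", "uA_per_cm2"),
    fx_var("i_L", "uA_per_cm2")
  ), fx_stim_vars(-20, 0.5, 1000, 10))
  assignments <- list(
    list(var = "alpha_m", rhs = quote(
      cn_(-0.1, "per_mV_ms") * (V + cn_(50, "mV")) /
        (exp(-(V + cn_(50, "mV")) / cn_(10, "mV")) - 1))),
    list(var = "beta_m", rhs = quote(
      cn_(4, "per_ms") * exp(-(V + cn_(75, "mV")) / cn_(18, "mV")))),
    list(var = "alpha_h", rhs = quote(
      cn_(0.07, "per_ms") * exp(-(V + cn_(75, "mV")) / cn_(20, "mV")))),
    list(var = "beta_h", rhs = quote(
      cn_(1, "per_ms") / (exp(-(V + cn_(45, "mV")) / cn_(10, "mV")) + 1))),
    list(var = "alpha_n", rhs = quote(
      cn_(-0.01, "per_mV_ms") * (V + cn_(65, "mV")) /
        (exp(-(V + cn_(65, "mV")) / cn_(10, "mV")) - 1))),
    list(var = "beta_n", rhs = quote(
      cn_(0.125, "per_ms") * exp((V + cn_(75, "mV")) / cn_(80, "mV")))),
    list(var = "i_Na", rhs = quote(g_Na * m^3 * h * (V - E_Na))),
    list(var = "i_K", rhs = quote(g_K * n^4 * (V - E_K))),
    list(var = "i_L", rhs = quote(g_L * (V - E_L))),
    list(var = "i_Stim", rhs = fx_stim_expr())
  )
  odes <- list(
    list(state = "V", rhs = quote(-(i_Na + i_K + i_L + i_Stim) / Cm)),
    list(state = "m", rhs = quote(alpha_m * (1 - m) - beta_m * m)),
    list(state = "h", rhs = quote(alpha_h * (1 - h) - beta_h * h)),
    list(state = "n", rhs = quote(alpha_n * (1 - n) - beta_n * n))
  )
  ann <- list(
    terms = c(list(V = TERM_V, Cm = TERM_CM,
                   g_Na = "membrane_fast_sodium_current_conductance",
                   g_K = "membrane_potassium_current_conductance",
                   g_L = "membrane_leakage_current_conductance",
                   i_Na = "membrane_fast_sodium_current",
                   i_K = "membrane_potassium_current",
                   i_L = "membrane_leakage_current"),
              fx_stim_terms()),
    modifiable = c("g_Na", "g_K", "g_L"),
    derived = c("i_Na", "i_K", "i_L"),
    ranges = list(m = c(0, 1), h = c(0, 1), n = c(0, 1))
  )
  fx_doc("hodgkin_huxley_1952", variables, assignments, odes, ann)
}

#' Luo-Rudy (1991) guinea-pig ventricular model
#'
#' Eight states (V, six gates m/h/j/d/f/X, intracellular calcium Cai); six
#' currents (fast sodium, slow inward calcium, time-dependent and
#' time-independent potassium, plateau potassium, background).  Nernst
#' potentials are authored in volts from R, T, F so units standardization is
#' exercised.  Default stimulus: -25.5 uA/cm^2 for 2 ms at 1 Hz, first pulse
#' at 100 ms.
#'
#' @return document text.
#' @export
make_luo_rudy_1991 <- function() {
  variables <- c(list(
    fx_var("time", "ms"),
    fx_var("V", "mV", -84.3801107371),
    fx_var("m", "dimensionless", 0.00171338077730188),
    fx_var("h", "dimensionless", 0.982660523699656),
    fx_var("j", "dimensionless", 0.989108212766685),
    fx_var("d", "dimensionless", 0.00302126301779861),
    fx_var("f", "dimensionless", 0.999967936476325),
    fx_var("X", "dimensionless", 0.0417603108167287),
    fx_var("Cai", "mM", 0.00017948816388306),
    fx_var("Cm", "uF_per_cm2", 1),
    fx_var("R_const", "J_per_mol_K", 8.314),
    fx_var("T_const", "kelvin", 310),
    fx_var("F_const", "C_per_mol", 96484.6),
    fx_var("Nao", "mM", 140), fx_var("Nai", "mM", 18),
    fx_var("Ko", "mM", 5.4), fx_var("Ki", "mM", 145),
    fx_var("PR_NaK", "dimensionless", 0.01833),
    fx_var("g_Na", "mS_per_cm2", 23),
    fx_var("g_si", "mS_per_cm2", 0.09),
    fx_var("E_Na", "volt"), fx_var("E_K", "volt"), fx_var("E_K1", "volt"),
    fx_var("E_si", "mV"),
    fx_var("g_K_calc", "mS_per_cm2"), fx_var("g_K1_calc", "mS_per_cm2"),
    fx_var("alpha_m", "per_ms"), fx_var("beta_m", "per_ms"),
    fx_var("alpha_h", "per_ms"), fx_var("beta_h", "per_ms"),
    fx_var("alpha_j", "per_ms"), fx_var("beta_j", "per_ms"),
    fx_var("alpha_d", "per_ms"), fx_var("beta_d", "per_ms"),
    fx_var("alpha_f", "per_ms"), fx_var("beta_f", "per_ms"),
    fx_var("alpha_X", "per_ms"), fx_var("beta_X", "per_ms"),
    fx_var("Xi_factor", "dimensionless"),
    fx_var("alpha_K1", "per_ms"), fx_var("beta_K1", "per_ms"),
    fx_var("K1_inf", "dimensionless"), fx_var("Kp_factor", "dimensionless"),
    fx_var("i_Na", "uA_per_cm2"), fx_var("i_si", "uA_per_cm2"),
    fx_var("i_K", "uA_per_cm2"), fx_var("i_K1", "uA_per_cm2"),
    fx_var("i_Kp", "uA_per_cm2"), fx_var("i_b", "uA_per_cm2")
  ), fx_stim_vars(-25.5, 2, 1000, 100))
  assignments <- list(
    list(var = "E_Na", rhs = quote(R_const * T_const / F_const * log(Nao / Nai))),
    list(var = "E_K", rhs = quote(R_const * T_const / F_const *
                                    log((Ko + PR_NaK * Nao) / (Ki + PR_NaK * Nai)))),
    list(var = "E_K1", rhs = quote(R_const * T_const / F_const * log(Ko / Ki))),
    list(var = "E_si", rhs = quote(cn_(7.7, "mV") -
                                     cn_(13.0287, "mV") * log(Cai / cn_(1, "mM")))),
    list(var = "g_K_calc", rhs = quote(cn_(0.282, "mS_per_cm2") *
                                         sqrt(Ko / cn_(5.4, "mM")))),
    list(var = "g_K1_calc", rhs = quote(cn_(0.6047, "mS_per_cm2") *
                                          sqrt(Ko / cn_(5.4, "mM")))),
    list(var = "alpha_m", rhs = quote(
      cn_(0.32, "per_mV_ms") * (V + cn_(47.13, "mV")) /
        (1 - exp(cn_(-0.1, "per_mV") * (V + cn_(47.13, "mV")))))),
    list(var = "beta_m", rhs = quote(cn_(0.08, "per_ms") * exp(-V / cn_(11, "mV")))),
    list(var = "alpha_h", rhs = quote(piecewise_(
      V < cn_(-40, "mV"),
      cn_(0.135, "per_ms") * exp((cn_(80, "mV") + V) / cn_(-6.8, "mV")),
      cn_(0, "per_ms")))),
    list(var = "beta_h", rhs = quote(piecewise_(
      V < cn_(-40, "mV"),
      cn_(3.56, "per_ms") * exp(cn_(0.079, "per_mV") * V) +
        cn_(310000, "per_ms") * exp(cn_(0.35, "per_mV") * V),
      cn_(1, "per_ms") /
        (cn_(0.13, "dimensionless") * (1 + exp((V + cn_(10.66, "mV")) / cn_(-11.1, "mV"))))))),
    list(var = "alpha_j", rhs = quote(piecewise_(
      V < cn_(-40, "mV"),
      (cn_(-127140, "per_mV_ms") * exp(cn_(0.2444, "per_mV") * V) -
         cn_(3.474e-05, "per_mV_ms") * exp(cn_(-0.04391, "per_mV") * V)) *
        (V + cn_(37.78, "mV")) /
        (1 + exp(cn_(0.311, "per_mV") * (V + cn_(79.23, "mV")))),
      cn_(0, "per_ms")))),
    list(var = "beta_j", rhs = quote(piecewise_(
      V < cn_(-40, "mV"),
      cn_(0.1212, "per_ms") * exp(cn_(-0.01052, "per_mV") * V) /
        (1 + exp(cn_(-0.1378, "per_mV") * (V + cn_(40.14, "mV")))),
      cn_(0.3, "per_ms") * exp(cn_(-2.535e-07, "per_mV") * V) /
        (1 + exp(cn_(-0.1, "per_mV") * (V + cn_(32, "mV"))))))),
    list(var = "alpha_d", rhs = quote(
      cn_(0.095, "per_ms") * exp(cn_(-0.01, "per_mV") * (V - cn_(5, "mV"))) /
        (1 + exp(cn_(-0.072, "per_mV") * (V - cn_(5, "mV")))))),
    list(var = "beta_d", rhs = quote(
      cn_(0.07, "per_ms") * exp(cn_(-0.017, "per_mV") * (V + cn_(44, "mV"))) /
        (1 + exp(cn_(0.05, "per_mV") * (V + cn_(44, "mV")))))),
    list(var = "alpha_f", rhs = quote(
      cn_(0.012, "per_ms") * exp(cn_(-0.008, "per_mV") * (V + cn_(28, "mV"))) /
        (1 + exp(cn_(0.15, "per_mV") * (V + cn_(28, "mV")))))),
    list(var = "beta_f", rhs = quote(
      cn_(0.0065, "per_ms") * exp(cn_(-0.02, "per_mV") * (V + cn_(30, "mV"))) /
        (1 + exp(cn_(-0.2, "per_mV") * (V + cn_(30, "mV")))))),
    list(var = "alpha_X", rhs = quote(
      cn_(0.0005, "per_ms") * exp(cn_(0.083, "per_mV") * (V + cn_(50, "mV"))) /
        (1 + exp(cn_(0.057, "per_mV") * (V + cn_(50, "mV")))))),
    list(var = "beta_X", rhs = quote(
      cn_(0.0013, "per_ms") * exp(cn_(-0.06, "per_mV") * (V + cn_(20, "mV"))) /
        (1 + exp(cn_(-0.04, "per_mV") * (V + cn_(20, "mV")))))),
    list(var = "Xi_factor", rhs = quote(piecewise_(
      V > cn_(-100, "mV"),
      cn_(2.837, "mV") * (exp(cn_(0.04, "per_mV") * (V + cn_(77, "mV"))) - 1) /
        ((V + cn_(77, "mV")) * exp(cn_(0.04, "per_mV") * (V + cn_(35, "mV")))),
      cn_(1, "dimensionless")))),
    list(var = "alpha_K1", rhs = quote(
      cn_(1.02, "per_ms") /
        (1 + exp(cn_(0.2385, "per_mV") * (V - E_K1 - cn_(59.215, "mV")))))),
    list(var = "beta_K1", rhs = quote(
      (cn_(0.49124, "per_ms") * exp(cn_(0.08032, "per_mV") * (V - E_K1 + cn_(5.476, "mV"))) +
         cn_(1, "per_ms") * exp(cn_(0.06175, "per_mV") * (V - E_K1 - cn_(594.31, "mV")))) /
        (1 + exp(cn_(-0.5143, "per_mV") * (V - E_K1 + cn_(4.753, "mV")))))),
    list(var = "K1_inf", rhs = quote(alpha_K1 / (alpha_K1 + beta_K1))),
    list(var = "Kp_factor", rhs = quote(
      1 / (1 + exp((cn_(7.488, "mV") - V) / cn_(5.98, "mV"))))),
    list(var = "i_Na", rhs = quote(g_Na * m^3 * h * j * (V - E_Na))),
    list(var = "i_si", rhs = quote(g_si * d * f * (V - E_si))),
    list(var = "i_K", rhs = quote(g_K_calc * X * Xi_factor * (V - E_K))),
    list(var = "i_K1", rhs = quote(g_K1_calc * K1_inf * (V - E_K1))),
    list(var = "i_Kp", rhs = quote(cn_(0.0183, "mS_per_cm2") * Kp_factor * (V - E_K1))),
    list(var = "i_b", rhs = quote(cn_(0.03921, "mS_per_cm2") * (V + cn_(59.87, "mV")))),
    list(var = "i_Stim", rhs = fx_stim_expr())
  )
  odes <- list(
    list(state = "V", rhs = quote(-(i_Na + i_si + i_K + i_K1 + i_Kp + i_b + i_Stim) / Cm)),
    list(state = "m", rhs = quote(alpha_m * (1 - m) - beta_m * m)),
    list(state = "h", rhs = quote(alpha_h * (1 - h) - beta_h * h)),
    list(state = "j", rhs = quote(alpha_j * (1 - j) - beta_j * j)),
    list(state = "d", rhs = quote(alpha_d * (1 - d) - beta_d * d)),
    list(state = "f", rhs = quote(alpha_f * (1 - f) - beta_f * f)),
    list(state = "X", rhs = quote(alpha_X * (1 - X) - beta_X * X)),
    list(state = "Cai", rhs = quote(
      cn_(-0.0001, "mM_cm2_per_uA_ms") * i_si +
        cn_(0.07, "per_ms") * (cn_(0.0001, "mM") - Cai)))
  )
  ann <- list(
    terms = c(list(V = TERM_V, Cm = TERM_CM,
                   Cai = "cytosolic_calcium_concentration",
                   g_Na = "membrane_fast_sodium_current_conductance",
                   g_si = "membrane_L_type_calcium_current_conductance",
                   i_Na = "membrane_fast_sodium_current",
                   i_si = "membrane_slow_inward_current",
                   i_K = "membrane_delayed_rectifier_potassium_current",
                   i_K1 = "membrane_inward_rectifier_potassium_current",
                   i_Kp = "membrane_plateau_potassium_current",
                   i_b = "membrane_background_current"),
              fx_stim_terms()),
    modifiable = c("g_Na", "g_si"),
    derived = c("i_Na", "i_si", "i_K", "i_K1", "i_Kp", "i_b"),
    ranges = list(m = c(0, 1), h = c(0, 1), j = c(0, 1), d = c(0, 1),
                  f = c(0, 1), X = c(0, 1), Cai = c(0, Inf))
  )
  fx_doc("luo_rudy_1991", variables, assignments, odes, ann)
}

#' Self-excitatory two-state oscillator dressed as a cell model
#'
#' A damped-free voltage oscillator with one recovery current; flagged
#' self-excitatory, so no stimulus current is present or expected.
#'
#' @return document text.
#' @export
make_self_excitatory <- function() {
  variables <- list(
    fx_var("time", "ms"),
    fx_var("V", "mV", -30),
    fx_var("w", "dimensionless", 0),
    fx_var("Cm", "uF_per_cm2", 1),
    fx_var("i_w", "uA_per_cm2")
  )
  assignments <- list(
    list(var = "i_w", rhs = quote(cn_(1, "uA_per_cm2") * w))
  )
  odes <- list(
    list(state = "V", rhs = quote(-(i_w) / Cm)),
    list(state = "w", rhs = quote(cn_(0.01, "per_mV_ms") * (V - cn_(-50, "mV"))))
  )
  ann <- list(
    terms = list(V = TERM_V, Cm = TERM_CM, i_w = "membrane_recovery_current"),
    derived = c("i_w"),
    self_excitatory = TRUE
  )
  fx_doc("self_excitatory_oscillator", variables, assignments, odes, ann)
}

#' Synthetic stiff gate model with prescribed timescale spread
#'
#' One fast gate with time constant ~1/stiffness_ratio ms, slower gates
#' around 100 ms, all mildly voltage dependent so the gate updates are not
#' trivially exact.  Reproducible from the seed.
#'
#' @param stiffness_ratio ratio of slowest to fastest rate (>= 1).
#' @param n_states total number of states including V (>= 2).
#' @param seed RNG seed.
#' @return document text.
#' @export
make_synthetic_stiff <- function(stiffness_ratio = 1000, n_states = 4, seed = 1) {
  stopifnot(stiffness_ratio >= 1, n_states >= 2)
  set.seed(seed)
  ngate <- n_states - 1L
  rate <- c(stiffness_ratio / 2,
            if (ngate > 1L) stats::runif(ngate - 1L, 0.005, 0.02))  # per ms
  vh <- round(stats::runif(ngate, -60, -20), 2)
  erev <- round(stats::runif(ngate, -90, 30), 2)
  gbar <- round(stats::runif(ngate, 0.1, 0.5), 3)
  variables <- c(list(
    fx_var("time", "ms"),
    fx_var("V", "mV", -70),
    fx_var("Cm", "uF_per_cm2", 1)
  ), fx_stim_vars(-10, 1, 100, 5))
  assignments <- list(list(var = "i_Stim", rhs = fx_stim_expr()))
  odes <- list()
  isum <- NULL
  ranges <- list()
  for (k in seq_len(ngate)) {
    g <- sprintf("g%d", k)
    a <- sprintf("alpha%d", k); b <- sprintf("beta%d", k); i <- sprintf("i%d", k)
    variables <- c(variables, list(
      fx_var(g, "dimensionless", 0.1),
      fx_var(a, "per_ms"), fx_var(b, "per_ms"), fx_var(i, "uA_per_cm2")))
    sig <- bquote(1 / (1 + exp(-(V - cn_(.(vh[k]), "mV")) / cn_(10, "mV"))))
    assignments <- c(assignments, list(
      list(var = a, rhs = bquote(cn_(.(rate[k]), "per_ms") * .(sig))),
      list(var = b, rhs = bquote(cn_(.(rate[k]), "per_ms") * (1 - .(sig)))),
      list(var = i, rhs = bquote(cn_(.(gbar[k]), "mS_per_cm2") * .(as.symbol(g)) *
                                   (V - cn_(.(erev[k]), "mV"))))))
    odes <- c(odes, list(list(state = g, rhs = bquote(
      .(as.symbol(a)) * (1 - .(as.symbol(g))) - .(as.symbol(b)) * .(as.symbol(g))))))
    isum <- if (is.null(isum)) as.symbol(i) else call("+", isum, as.symbol(i))
    ranges[[g]] <- c(0, 1)
  }
  odes <- c(list(list(state = "V",
                      rhs = bquote(-(.(isum) + i_Stim) / Cm))), odes)
  ann <- list(terms = c(list(V = TERM_V, Cm = TERM_CM), fx_stim_terms()),
              ranges = ranges)
  fx_doc(sprintf("synthetic_stiff_r%g_n%d_s%d", stiffness_ratio, n_states, seed),
         variables, assignments, odes, ann)
}

#' Fixture with a removable rate singularity and an overflow-prone sigmoid
#'
#' Contains (a) a sodium-style activation rate with a removable 0/0
#' singularity at the round value V = 40 mV, and (b) a calcium-dependent
#' steady state 1/(1 + exp((c - 4e-4)/2.5e-5)) whose exponent overflows
#' double precision within the annotated calcium range, so its analytic
#' Jacobian entries are hazardous while plain RHS evaluation is safe under
#' IEEE rules.
#'
#' @return document text.
#' @export
make_singularity_model <- function() {
  variables <- c(list(
    fx_var("time", "ms"),
    fx_var("V", "mV", -80),
    fx_var("g", "dimensionless", 0.01),
    fx_var("c", "mM", 0.0002),
    fx_var("Cm", "uF_per_cm2", 1),
    fx_var("alpha_g", "per_ms"), fx_var("beta_g", "per_ms"),
    fx_var("r_inf", "dimensionless"),
    fx_var("i_g", "uA_per_cm2")
  ), fx_stim_vars(-15, 1, 200, 10))
  assignments <- list(
    list(var = "alpha_g", rhs = quote(
      cn_(0.1, "per_mV_ms") * (V - cn_(40, "mV")) /
        (1 - exp(cn_(-0.25, "per_mV") * (V - cn_(40, "mV")))))),
    list(var = "beta_g", rhs = quote(cn_(0.15, "per_ms") * exp(-V / cn_(30, "mV")))),
    list(var = "r_inf", rhs = quote(
      1 / (1 + exp((c - cn_(0.0004, "mM")) / cn_(2.5e-05, "mM"))))),
    list(var = "i_g", rhs = quote(cn_(2, "mS_per_cm2") * g * (V - cn_(60, "mV")))),
    list(var = "i_Stim", rhs = fx_stim_expr())
  )
  odes <- list(
    list(state = "V", rhs = quote(-(i_g + i_Stim) / Cm)),
    list(state = "g", rhs = quote(alpha_g * (1 - g) - beta_g * g)),
    list(state = "c", rhs = quote(
      cn_(0.001, "per_ms") * (cn_(0.0002, "mM") + cn_(0.0006, "mM") * r_inf - c)))
  )
  ann <- list(
    terms = c(list(V = TERM_V, Cm = TERM_CM,
                   c = "cytosolic_calcium_concentration",
                   i_g = "membrane_test_current"),
              fx_stim_terms()),
    derived = c("i_g"),
    ranges = list(g = c(0, 1), c = c(0, 0.05), V = c(-100, 80))
  )
  fx_doc("singularity_overflow", variables, assignments, odes, ann)
}

#' Deliberately broken fixtures, one per conversion-failure category
#'
#' @param category one of "missing-parameter", "over-constrained",
#'   "invalid-units", "unsupported-construct", "cn-no-units".
#' @return document text that fails conversion with exactly that category.
#' @export
make_broken_fixture <- function(category = c("missing-parameter",
                                             "over-constrained",
                                             "invalid-units",
                                             "unsupported-construct",
                                             "cn-no-units")) {
  category <- match.arg(category)
  doc <- make_toy_gate()
  switch(category,
    "missing-parameter" = {
      # drop the conductance's value
      sub(' name="g_L" units="mS_per_cm2" initial_value="0.5"',
          ' name="g_L" units="mS_per_cm2"', doc, fixed = TRUE)
    },
    "over-constrained" = {
      # second defining equation for the gate m
      sub("</math>",
          "<apply><eq/><ci>m</ci><cn units=\"dimensionless\">0.5</cn></apply></math>",
          doc, fixed = TRUE)
    },
    "invalid-units" = {
      # voltage declared in ms: dV/dt equation becomes dimensionally absurd
      sub(' name="V" units="mV"', ' name="V" units="ms"', doc, fixed = TRUE)
    },
    "unsupported-construct" = {
      sub("</component>", "<reaction/></component>", doc, fixed = TRUE)
    },
    "cn-no-units" = {
      sub('<cn units="uA_per_cm2">0</cn>', "<cn>0</cn>", doc, fixed = TRUE)
    }
  )
}

#' Names of the working fixtures in the zoo
#' @return character vector accepted by [fixture_document()].
#' @export
fixture_names <- function() {
  c("toy_gate", "hodgkin_huxley", "luo_rudy_1991", "self_excitatory",
    "synthetic_stiff", "singularity")
}

#' Fetch a fixture document by name
#' @param name one of [fixture_names()].
#' @param ... passed to the underlying generator (e.g. seed for
#'   `synthetic_stiff`).
#' @return document text.
#' @export
fixture_document <- function(name, ...) {
  switch(name,
    toy_gate = make_toy_gate(),
    hodgkin_huxley = make_hodgkin_huxley(),
    luo_rudy_1991 = make_luo_rudy_1991(),
    self_excitatory = make_self_excitatory(),
    synthetic_stiff = make_synthetic_stiff(...),
    singularity = make_singularity_model(),
    stop("unknown fixture '", name, "'; available: ",
         paste(fixture_names(), collapse = ", "), call. = FALSE)
  )
}

#' Convert a fixture straight to a model, asserting clean conversion
#' @inheritParams fixture_document
#' @return an `ode_system`.
#' @export
fixture_model <- function(name, ...) {
  res <- convert_cellml(fixture_document(name, ...))
  if (res$report$status != "ok") {
    stop("fixture '", name, "' failed conversion:\n",
         paste(vapply(res$report$failures, function(f)
           sprintf("[%s] %s: %s", f$category, f$location, f$message), ""),
           collapse = "\n"), call. = FALSE)
  }
  res$model
}
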