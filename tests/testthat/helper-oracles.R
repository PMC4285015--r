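# Independent oracles, hand-coded in plain R arithmetic (no package
# machinery), used to cross-check the parse -> flatten -> standardize ->
# compile pipeline and the integrators.

# Hodgkin-Huxley (1952) right-hand side, modern sign convention, all in
# ms/mV/uA/cm^2.  Transcribed directly; kept deliberately separate from the
# fixture document builder.
hh_oracle_rhs <- function(t, y, i_stim = 0) {
  V <- y[["V"]]; m <- y[["m"]]; h <- y[["h"]]; n <- y[["n"]]
  am <- -0.1 * (V + 50) / (exp(-(V + 50) / 10) - 1)
  bm <- 4 * exp(-(V + 75) / 18)
  ah <- 0.07 * exp(-(V + 75) / 20)
  bh <- 1 / (exp(-(V + 45) / 10) + 1)
  an <- -0.01 * (V + 65) / (exp(-(V + 65) / 10) - 1)
  bn <- 0.125 * exp((V + 75) / 80)
  i_na <- 120 * m^3 * h * (V - 40)
  i_k <- 36 * n^4 * (V + 87)
  i_l <- 0.3 * (V + 64.387)
  c(V = -(i_na + i_k + i_l + i_stim) / 1,
    m = am * (1 - m) - bm * m,
    h = ah * (1 - h) - bh * h,
    n = an * (1 - n) - bn * n)
}

# Luo-Rudy (1991) right-hand side, same independence rationale.
lr91_oracle_rhs <- function(t, y, i_stim = 0) {
  V <- y[["V"]]; m <- y[["m"]]; h <- y[["h"]]; j <- y[["j"]]
  d <- y[["d"]]; f <- y[["f"]]; X <- y[["X"]]; Cai <- y[["Cai"]]
  RTF <- 8.314 * 310 / 96484.6 * 1000  # mV
  E_Na <- RTF * log(140 / 18)
  E_K <- RTF * log((5.4 + 0.01833 * 140) / (145 + 0.01833 * 18))
  E_K1 <- RTF * log(5.4 / 145)
  am <- 0.32 * (V + 47.13) / (1 - exp(-0.1 * (V + 47.13)))
  bm <- 0.08 * exp(-V / 11)
  if (V < -40) {
    ah <- 0.135 * exp((80 + V) / -6.8)
    bh <- 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V)
    aj <- (-1.2714e5 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
      (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
    bj <- 0.1212 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
  } else {
    ah <- 0
    bh <- 1 / (0.13 * (1 + exp((V + 10.66) / -11.1)))
    aj <- 0
    bj <- 0.3 * exp(-2.535e-7 * V) / (1 + exp(-0.1 * (V + 32)))
  }
  ad <- 0.095 * exp(-0.01 * (V - 5)) / (1 + exp(-0.072 * (V - 5)))
  bd <- 0.07 * exp(-0.017 * (V + 44)) / (1 + exp(0.05 * (V + 44)))
  af <- 0.012 * exp(-0.008 * (V + 28)) / (1 + exp(0.15 * (V + 28)))
  bf <- 0.0065 * exp(-0.02 * (V + 30)) / (1 + exp(-0.2 * (V + 30)))
  aX <- 0.0005 * exp(0.083 * (V + 50)) / (1 + exp(0.057 * (V + 50)))
  bX <- 0.0013 * exp(-0.06 * (V + 20)) / (1 + exp(-0.04 * (V + 20)))
  E_si <- 7.7 - 13.0287 * log(Cai)
  i_na <- 23 * m^3 * h * j * (V - E_Na)
  i_si <- 0.09 * d * f * (V - E_si)
  Xi <- if (V > -100) {
    2.837 * (exp(0.04 * (V + 77)) - 1) / ((V + 77) * exp(0.04 * (V + 35)))
  } else 1
  i_k <- 0.282 * sqrt(5.4 / 5.4) * X * Xi * (V - E_K)
  aK1 <- 1.02 / (1 + exp(0.2385 * (V - E_K1 - 59.215)))
  bK1 <- (0.49124 * exp(0.08032 * (V - E_K1 + 5.476)) +
            exp(0.06175 * (V - E_K1 - 594.31))) /
    (1 + exp(-0.5143 * (V - E_K1 + 4.753)))
  i_k1 <- 0.6047 * sqrt(5.4 / 5.4) * (aK1 / (aK1 + bK1)) * (V - E_K1)
  i_kp <- 0.0183 * (1 / (1 + exp((7.488 - V) / 5.98))) * (V - E_K1)
  i_b <- 0.03921 * (V + 59.87)
  c(V = -(i_na + i_si + i_k + i_k1 + i_kp + i_b + i_stim) / 1,
    m = am * (1 - m) - bm * m,
    h = ah * (1 - h) - bh * h,
    j = aj * (1 - j) - bj * j,
    d = ad * (1 - d) - bd * d,
    f = af * (1 - f) - bf * f,
    X = aX * (1 - X) - bX * X,
    Cai = -1e-4 * i_si + 0.07 * (1e-4 - Cai))
}

# reorder an oracle derivative vector into a model's state layout
align_oracle <- function(d, model) d[model$state_names]

# empirical convergence order: least-squares slope of log2(error) against
# log2(dt) over halved steps
convergence_slope <- function(errs, dts) {
  keep <- is.finite(errs) & errs > 0
  stats::coef(stats::lm(log2(errs[keep]) ~ log2(dts[keep])))[[2]]
}

# logistic test problem du/dt = u(1-u) with exact solution
logistic_exact <- function(t, u0 = 0.5) 1 / (1 + (1 / u0 - 1) * exp(-t))

# fixture models are expensive to convert; share them across tests
fixture_cache <- new.env(parent = emptyenv())
cached_model <- function(name, ...) {
  key <- paste(name, ..., sep = "_")
  if (is.null(fixture_cache[[key]])) {
    fixture_cache[[key]] <- fixture_model(name, ...)
  }
  fixture_cache[[key]]
}

# one-gate linear-relaxation document used by the pacing contraction test:
# dV/dt = -(g*(V - E) + I_stim)/Cm relaxes toward E with rate g/Cm per ms,
# so the pace-to-pace map is a contraction with known factor exp(-g*P/Cm).
make_linear_relax_doc <- function(g = log(2) / 50, period = 50, v0 = -40,
                                  E = -70, drift = FALSE) {
  variables <- c(list(
    myocyte:::fx_var("time", "ms"),
    myocyte:::fx_var("V", "mV", v0),
    myocyte:::fx_var("Cm", "uF_per_cm2", 1),
    myocyte:::fx_var("g_leak", "mS_per_cm2", g),
    myocyte:::fx_var("E_leak", "mV", E),
    myocyte:::fx_var("i_leak", "uA_per_cm2")
  ), myocyte:::fx_stim_vars(0, 1, period, 0))
  leak <- if (drift) {
    quote(cn_(0.02, "uA_per_cm2") + g_leak * (V - E_leak) * cn_(0, "dimensionless"))
  } else {
    quote(g_leak * (V - E_leak))
  }
  assignments <- list(
    list(var = "i_leak", rhs = leak),
    list(var = "i_Stim", rhs = myocyte:::fx_stim_expr())
  )
  odes <- list(list(state = "V", rhs = quote(-(i_leak + i_Stim) / Cm)))
  ann <- list(terms = c(list(V = myocyte:::TERM_V, Cm = myocyte:::TERM_CM,
                             i_leak = "membrane_leakage_current"),
                        myocyte:::fx_stim_terms()),
              derived = "i_leak")
  myocyte:::fx_doc("linear_relax", variables, assignments, odes, ann)
}
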