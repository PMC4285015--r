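# Time integration for cell models.
#
# Fixed-step methods: forward Euler (FE), midpoint (RK2), classical RK4,
# Rush-Larsen (RL: exact exponential gate updates, FE elsewhere),
# generalized Rush-Larsen of order 1 and 2 (GRL1/GRL2: per-variable
# exponential updates from a diagonal linearization), and backward Euler
# (BE: explicit V, implicit-linear gates, Newton with the analytic
# sub-Jacobian for the rest).  Adaptive stiff solving is delegated to
# deSolve's lsoda under the wrapper contract (max step clamped to the
# stimulus duration, optional analytic Jacobian, V-as-parameter mode for
# tissue with no reinitialization between calls).

SOLVER_METHODS <- c("FE", "RK2", "RK4", "BE", "RL", "GRL1", "GRL2", "ADAPTIVE")

#' Solver configuration
#'
#' @param method one of FE, RK2, RK4, BE, RL, GRL1, GRL2, ADAPTIVE.
#' @param dt fixed timestep (ms); required for fixed-step methods.
#' @param reltol,abstol adaptive tolerances (defaults 1e-5, 1e-7).
#' @param max_dt maximum internal adaptive step (ms); further clamped to the
#'   stimulus duration so square-wave stimuli are never skipped.
#' @param sampling_dt output sampling interval (ms).
#' @param v_mode "state" (single cell) or "parameter" (tissue: V is an input,
#'   not a solved state).
#' @param use_analytic_jacobian supply the analytic Jacobian to the stiff
#'   solver when it is free of overflow hazards.
#' @param reset_policy "never", "on_failure" or "every_call" - whether the
#'   adaptive solver may carry internal stepping state across calls.
#' @return object of class `solver_config`.
#' @export
solver_config <- function(method = "ADAPTIVE", dt = NULL, reltol = 1e-5,
                          abstol = 1e-7, max_dt = 1, sampling_dt = 0.1,
                          v_mode = c("state", "parameter"),
                          use_analytic_jacobian = FALSE,
                          reset_policy = c("on_failure", "never", "every_call")) {
  method <- match.arg(method, SOLVER_METHODS)
  v_mode <- match.arg(v_mode)
  reset_policy <- match.arg(reset_policy)
  if (method != "ADAPTIVE") {
    stopifnot(!is.null(dt), dt > 0)
    if (sampling_dt < dt) sampling_dt <- dt
    ratio <- sampling_dt / dt
    if (abs(ratio - round(ratio)) > 1e-12 * ratio) {
      stop("dt must divide sampling_dt", call. = FALSE)
    }
  }
  structure(list(method = method, dt = dt, reltol = reltol, abstol = abstol,
                 max_dt = max_dt, sampling_dt = sampling_dt, v_mode = v_mode,
                 use_analytic_jacobian = use_analytic_jacobian,
                 reset_policy = reset_policy),
            class = "solver_config")
}

divergence_signal <- function(time, detail = "non-finite state") {
  structure(class = c("myo_divergence", "error", "condition"),
            list(message = sprintf("solver diverged at t = %g ms (%s)",
                                   time, detail),
                 time = time, detail = detail, call = NULL))
}

#' Square-wave stimulus current at a time point
#'
#' Active (returning the amplitude) on the half-open window
#' [start + k*period, start + k*period + duration) for integer k >= 0,
#' provided t does not exceed the optional end time.
#'
#' @param stim a [regular_stimulus()] or NULL (always 0).
#' @param t time or vector of times (ms).
#' @return stimulus current (uA/cm^2).
#' @export
stimulus_current <- function(stim, t) {
  if (is.null(stim)) return(rep(0, length(t)))
  rel <- t - stim$start
  phase <- rel - stim$period * floor(rel / stim$period)
  on <- rel >= 0 & phase < stim$duration
  if (!is.null(stim$end)) on <- on & t <= stim$end
  ifelse(on, stim$amplitude, 0)
}

# ---------------------------------------------------------------------------
# Single steps

check_finite <- function(y, t) {
  if (!all(is.finite(y))) stop(divergence_signal(t))
  y
}

#' One explicit step (FE, midpoint RK2, classical RK4)
#'
#' @param method "FE", "RK2" or "RK4".
#' @param rhs function(t, y) returning dy/dt.
#' @param t,y current time and state.
#' @param dt step (ms).
#' @return the advanced state; a non-finite stage raises a divergence
#'   condition carrying the time.
#' @export
step_explicit <- function(method, rhs, t, y, dt) {
  if (method == "FE") {
    k1 <- check_finite(rhs(t, y), t)
    return(check_finite(y + dt * k1, t))
  }
  if (method == "RK2") {
    k1 <- check_finite(rhs(t, y), t)
    k2 <- check_finite(rhs(t + dt / 2, y + dt / 2 * k1), t)
    return(check_finite(y + dt * k2, t))
  }
  if (method == "RK4") {
    k1 <- check_finite(rhs(t, y), t)
    k2 <- check_finite(rhs(t + dt / 2, y + dt / 2 * k1), t)
    k3 <- check_finite(rhs(t + dt / 2, y + dt / 2 * k2), t)
    k4 <- check_finite(rhs(t + dt, y + dt * k3), t)
    return(check_finite(y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), t))
  }
  stop("unknown explicit method '", method, "'", call. = FALSE)
}

#' One Rush-Larsen step
#'
#' Gates advance by the exact solution of their frozen-coefficient linear
#' ODE, g' = g_inf + (g - g_inf) exp(-dt/tau); the remaining states by
#' forward Euler.  When g_inf lies in [0, 1] the update maps [0, 1] into
#' itself for any dt.
#'
#' @param parts an `rl_parts` from [rearrange_rush_larsen()].
#' @param t,y current time and state.
#' @param dt step (ms).
#' @param i_stim stimulus current at time t.
#' @param v_override optional fixed V (tissue mode).
#' @return advanced state.
#' @export
step_rush_larsen <- function(parts, t, y, dt, i_stim = 0, v_override = NULL) {
  p <- parts$fn(t, y, i_stim, v_override)
  out <- y
  gn <- parts$gate_names
  if (length(gn) > 0L) {
    g <- y[gn]
    out[gn] <- p$g_inf + (g - p$g_inf) * exp(-dt / p$tau)
  }
  nn <- parts$non_gate_names
  if (length(nn) > 0L) out[nn] <- y[nn] + dt * p$dnon
  check_finite(out, t)
}

grl_update <- function(y, b, a, dt, eps = 1e-8) {
  out <- ifelse(abs(a) < eps, y + b * dt, y + b / a * expm1(a * dt))
  names(out) <- names(y)
  out
}

#' One first-order generalized Rush-Larsen step
#'
#' Each state is advanced by the exact solution of its scalar linearization
#' about the current state (others frozen, Jacobi style):
#' u' = u + (b/a)(exp(a dt) - 1) with a the diagonal partial and b the
#' current derivative; the |a| < 1e-8 limit uses u + b dt.
#'
#' @param parts a `grl_parts` from [grl_linearize()].
#' @inheritParams step_rush_larsen
#' @return advanced state.
#' @export
step_grl1 <- function(parts, t, y, dt, i_stim = 0, v_override = NULL) {
  p <- parts$fn(t, y, i_stim, v_override)
  check_finite(grl_update(y, p$b, p$a, dt), t)
}

#' One second-order generalized Rush-Larsen step
#'
#' A GRL1 half-step to t + dt/2, re-linearization of every equation about
#' the half-step state (f_i(y) ~ f_i(y*) + a_i (y_i - y*_i) with a_i the
#' diagonal partial at y*), then a full-step exact solution of the
#' linearized equations from the original state.  Second order on smooth
#' coupled systems; exact on decoupled linear ones.
#'
#' @inheritParams step_grl1
#' @param i_stim_half stimulus current at t + dt/2.
#' @return advanced state.
#' @export
step_grl2 <- function(parts, t, y, dt, i_stim = 0, v_override = NULL,
                      i_stim_half = i_stim) {
  p <- parts$fn(t, y, i_stim, v_override)
  half <- grl_update(y, p$b, p$a, dt / 2)
  p2 <- parts$fn(t + dt / 2, half, i_stim_half, v_override)
  b_eff <- p2$b - p2$a * (half - y)
  check_finite(grl_update(y, b_eff, p2$a, dt), t)
}

# ---------------------------------------------------------------------------
# Backward Euler

be_parts <- function(model) {
  if (!is.null(model$cache$be_parts)) return(model$cache$be_parts)
  rl <- rearrange_rush_larsen(model)
  v <- model$interface$v
  others <- setdiff(rl$non_gate_names, v)
  jac <- if (length(others) > 0L) model_jacobian(model) else NULL
  idx_others <- match(others, model$state_names)
  parts <- list(rl = rl, v = v, others = others, jac = jac,
                idx_others = idx_others,
                cmp = compile_rhs(model, partial_eval = TRUE))
  model$cache$be_parts <- parts
  parts
}

#' One backward Euler step
#'
#' V advances explicitly; gates by the unconditionally stable implicit
#' linear closed form g' = (g + dt g_inf/tau)/(1 + dt/tau) with coefficients
#' frozen at the updated V; any remaining states by Newton iteration on the
#' implicit residual using the analytic sub-Jacobian (convergence when the
#' infinity norm of the update drops below 1e-10, at most 15 iterations).
#'
#' @param parts from the internal BE partition of the model.
#' @inheritParams step_rush_larsen
#' @param i_stim_new stimulus current at t + dt (used for the implicit
#'   stages).
#' @return advanced state.
#' @export
step_backward_euler <- function(parts, t, y, dt, i_stim = 0, i_stim_new = i_stim,
                                v_override = NULL) {
  rl <- parts$rl
  ynew <- y
  # explicit V update (single-cell mode); in tissue mode V is a parameter
  if (is.null(v_override)) {
    d0 <- parts$cmp$fn(t, y, i_stim, NULL)
    vi <- match(parts$v, parts$cmp$state_names)
    ynew[parts$v] <- y[[parts$v]] + dt * d0[[vi]]
  }
  # gates at the new V, old other states
  p <- rl$fn(t + dt, ynew, i_stim_new, v_override)
  gn <- rl$gate_names
  if (length(gn) > 0L) {
    g <- y[gn]
    ynew[gn] <- (g + dt * p$g_inf / p$tau) / (1 + dt / p$tau)
  }
  # Newton for the remaining non-gate states
  others <- parts$others
  if (length(others) > 0L) {
    idx <- parts$idx_others
    u <- y[others]
    for (iter in seq_len(15L)) {
      ynew[others] <- u
      f <- parts$cmp$fn(t + dt, ynew, i_stim_new, v_override)
      r <- u - y[others] - dt * f[idx]
      J <- parts$jac$fn(t + dt, ynew, i_stim_new, v_override)
      A <- diag(length(others)) - dt * J[idx, idx, drop = FALSE]
      du <- tryCatch(solve(A, r), error = function(e) NULL)
      if (is.null(du) || !all(is.finite(du))) {
        stop(divergence_signal(t, "singular Newton system in backward Euler"))
      }
      u <- u - du
      if (max(abs(du)) < 1e-10) break
      if (iter == 15L) {
        stop(divergence_signal(t, sprintf(
          "Newton failed to converge in 15 iterations (last update %g)",
          max(abs(du)))))
      }
    }
    ynew[others] <- u
  }
  check_finite(ynew, t)
}

# ---------------------------------------------------------------------------
# Trace container

new_trace <- function(times, states, stimulus = NULL, metadata = list()) {
  structure(list(times = times, states = states, stimulus = stimulus,
                 metadata = metadata),
            class = "myo_trace")
}

#' @export
print.myo_trace <- function(x, ...) {
  cat(sprintf("Trace: %d samples over [%g, %g] ms, %d states (%s)\n",
              length(x$times), min(x$times), max(x$times), ncol(x$states),
              paste(utils::head(colnames(x$states), 6), collapse = ", ")))
  invisible(x)
}

#' Extract the voltage column of a trace
#' @param trace a trace from [solve_fixed()] or [solve_adaptive()].
#' @return numeric vector of V samples (mV).
#' @export
trace_voltage <- function(trace) {
  v <- trace$metadata$v_name %||% colnames(trace$states)[1]
  trace$states[, v]
}

#' @export
as.data.frame.myo_trace <- function(x, ...) {
  df <- data.frame(time = x$times, x$states, check.names = FALSE)
  if (!is.null(x$stimulus)) df$i_stim <- x$stimulus
  df
}

# ---------------------------------------------------------------------------
# Fixed-step driver

#' Fixed-step simulation
#'
#' Repeated stepping with the stimulus injected into the model's stimulus
#' slot, sampling the state at multiples of `sampling_dt`.  Range checks run
#' per the policy; instability raises a structured divergence condition
#' (never a silent NaN trace).
#'
#' @param model an `ode_system`.
#' @param config a [solver_config()] with a fixed-step method.
#' @param stimulus a [regular_stimulus()] or NULL.
#' @param t_span c(t0, t1) in ms.
#' @param range_check "warn", "strict" or "off".
#' @return a trace object.
#' @export
solve_fixed <- function(model, config, stimulus = NULL, t_span = c(0, 1000),
                        range_check = c("warn", "strict", "off")) {
  range_check <- match.arg(range_check)
  stopifnot(inherits(config, "solver_config"), config$method != "ADAPTIVE")
  dt <- config$dt
  nsub <- max(1L, as.integer(round(config$sampling_dt / dt)))
  n_samples <- floor((t_span[2] - t_span[1]) / (dt * nsub) + 1e-9)
  y <- initial_state(model)
  method <- config$method

  stepper <- make_stepper(model, method)
  times <- numeric(n_samples + 1L)
  states <- matrix(NA_real_, n_samples + 1L, length(y),
                   dimnames = list(NULL, names(y)))
  times[1L] <- t_span[1]
  states[1L, ] <- y
  k <- 0L
  for (samp in seq_len(n_samples)) {
    for (sub in seq_len(nsub)) {
      t <- t_span[1] + k * dt
      y <- stepper(t, y, dt, stimulus)
      k <- k + 1L
    }
    times[samp + 1L] <- t_span[1] + k * dt
    states[samp + 1L, ] <- y
    if (range_check != "off") {
      viol <- check_ranges(model, y)
      if (length(viol) > 0L) {
        msg <- paste(vapply(viol, function(v)
          sprintf("%s = %.6g outside %s bound %g", v$variable, v$value,
                  v$side, v$bound), ""), collapse = "; ")
        if (range_check == "strict") {
          stop("range check failed at t = ", times[samp + 1L], " ms: ", msg,
               call. = FALSE)
        }
        warning("range check at t = ", times[samp + 1L], " ms: ", msg,
                call. = FALSE)
      }
    }
  }
  new_trace(times, states,
            stimulus = stimulus_current(stimulus, times),
            metadata = list(model = model$name, method = method, dt = dt,
                            sampling_dt = dt * nsub,
                            v_name = model$interface$v))
}

make_stepper <- function(model, method) {
  if (method %in% c("FE", "RK2", "RK4")) {
    cmp <- compile_rhs(model, partial_eval = TRUE)
    fn <- cmp$fn
    function(t, y, dt, stimulus) {
      rhs <- function(tt, yy) fn(tt, yy, stimulus_current(stimulus, tt), NULL)
      step_explicit(method, rhs, t, y, dt)
    }
  } else if (method == "RL") {
    parts <- rearrange_rush_larsen(model)
    function(t, y, dt, stimulus) {
      step_rush_larsen(parts, t, y, dt, stimulus_current(stimulus, t), NULL)
    }
  } else if (method == "GRL1") {
    parts <- grl_linearize(model)
    function(t, y, dt, stimulus) {
      step_grl1(parts, t, y, dt, stimulus_current(stimulus, t), NULL)
    }
  } else if (method == "GRL2") {
    parts <- grl_linearize(model)
    function(t, y, dt, stimulus) {
      step_grl2(parts, t, y, dt, stimulus_current(stimulus, t), NULL,
                i_stim_half = stimulus_current(stimulus, t + dt / 2))
    }
  } else if (method == "BE") {
    parts <- be_parts(model)
    function(t, y, dt, stimulus) {
      step_backward_euler(parts, t, y, dt,
                          stimulus_current(stimulus, t),
                          stimulus_current(stimulus, t + dt), NULL)
    }
  } else {
    stop("unknown method '", method, "'", call. = FALSE)
  }
}

# ---------------------------------------------------------------------------
# Adaptive driver (deSolve::lsoda)

#' Adaptive stiff simulation
#'
#' Wraps the host stiff initial-value integrator (deSolve's lsoda).  The
#' maximum internal step is clamped to min(max_dt, stimulus duration) so a
#' square-wave stimulus can never fall between steps; the analytic Jacobian
#' is supplied when enabled and free of overflow hazards.  In
#' `v_mode = "parameter"` the voltage is an input (fixed over the call), the
#' stepping state (last internal step size) is carried across calls unless
#' the reset policy says otherwise, and an integration failure triggers one
#' reset-and-retry before a divergence condition is raised.
#'
#' @inheritParams solve_fixed
#' @param y0 initial state (defaults to the model's initial conditions).
#' @param v_value fixed voltage for `v_mode = "parameter"`.
#' @param carry internal stepping state from a previous call (as returned in
#'   the trace metadata under `carry`).
#' @return a trace object; `metadata$carry` holds the stepping state for
#'   continuation calls.
#' @export
solve_adaptive <- function(model, config = solver_config("ADAPTIVE"),
                           stimulus = NULL, t_span = c(0, 1000), y0 = NULL,
                           v_value = NULL, carry = NULL) {
  stopifnot(inherits(config, "solver_config"))
  y <- y0 %||% initial_state(model)
  v_param <- identical(config$v_mode, "parameter")
  vi <- match(model$interface$v, model$state_names)
  tape <- vm_rhs_tape(model)
  use_jac <- FALSE
  if (isTRUE(config$use_analytic_jacobian)) {
    jac <- model_jacobian(model)
    haz <- detect_jacobian_hazards(jac, model)
    use_jac <- !haz$recommend_numeric
  }
  jt <- if (use_jac) vm_jac_tape(model) else NULL
  stim_vec <- if (is.null(stimulus)) NULL else {
    as.numeric(c(stimulus$amplitude, stimulus$duration, stimulus$period,
                 stimulus$start, stimulus$end))
  }
  vmode_vec <- if (v_param) {
    as.numeric(c(vi - 1L, v_value %||% y[[model$interface$v]]))
  } else {
    NULL
  }
  tape_list <- list(tape$ops, tape$consts, tape$nreg, tape$out_idx)
  jt_list <- if (use_jac) list(jt$ops, jt$consts, jt$nreg, jt$out_idx)
  hmax <- config$max_dt
  if (!is.null(stimulus)) hmax <- min(hmax, stimulus$duration)
  times <- seq(t_span[1], t_span[2], by = config$sampling_dt)
  if (abs(times[length(times)] - t_span[2]) > 1e-9) times <- c(times, t_span[2])
  hini <- 0
  if (!is.null(carry) && config$reset_policy != "every_call") {
    hini <- min(carry$hlast %||% 0, hmax)
  }
  run <- function(hini) {
    # install the active tapes for the native derivative/Jacobian routines
    .Call(myo_vm_set_model, tape_list, jt_list, stim_vec, vmode_vec)
    withCallingHandlers(
      suppressWarnings(deSolve::lsoda(
        y = y, times = times, func = "myo_vm_derivs", parms = NULL,
        dllname = "myocyte", initfunc = NULL, nout = 0,
        rtol = config$reltol, atol = config$abstol, hmax = hmax, hini = hini,
        jacfunc = if (use_jac) "myo_vm_jac",
        jactype = if (use_jac) "fullusr" else "fullint",
        maxsteps = 500000L)),
      error = function(e) e)
  }
  out <- tryCatch(run(hini), error = function(e) e)
  bad <- inherits(out, "error") || nrow(out) < length(times) ||
    !all(is.finite(out[nrow(out), ]))
  if (bad && config$reset_policy %in% c("on_failure", "every_call")) {
    out <- tryCatch(run(0), error = function(e) e)
    bad <- inherits(out, "error") || nrow(out) < length(times) ||
      !all(is.finite(out[nrow(out), ]))
  }
  if (bad) {
    t_fail <- if (inherits(out, "error")) t_span[1] else out[nrow(out), 1]
    stop(divergence_signal(t_fail, "adaptive integrator failed"))
  }
  states <- out[, -1L, drop = FALSE]
  colnames(states) <- names(y)
  rstate <- attr(out, "rstate")
  new_trace(out[, 1L], states,
            stimulus = stimulus_current(stimulus, out[, 1L]),
            metadata = list(model = model$name, method = "ADAPTIVE",
                            reltol = config$reltol, abstol = config$abstol,
                            hmax = hmax, v_name = model$interface$v,
                            analytic_jacobian = use_jac,
                            carry = list(hlast = if (!is.null(rstate)) rstate[1] else 0)))
}

#' Simulate with any configured solver
#'
#' Dispatches to [solve_fixed()] or [solve_adaptive()].
#'
#' @inheritParams solve_fixed
#' @return a trace object.
#' @export
simulate_cell <- function(model, config, stimulus = NULL, t_span = c(0, 1000),
                          range_check = "warn") {
  if (config$method == "ADAPTIVE") {
    solve_adaptive(model, config, stimulus, t_span)
  } else {
    solve_fixed(model, config, stimulus, t_span, range_check = range_check)
  }
}
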