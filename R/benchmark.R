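# Accuracy benchmarking: the MRMS voltage-trace metric, reference solutions,
# the timestep/tolerance refinement protocol, action potential biomarkers,
# and a wall-clock timing harness (timing numbers are hardware-dependent and
# are reported, never asserted).

#' Mixed root mean square error between two voltage traces
#'
#' e = sqrt(mean(((Vhat - V)/(1 + |Vhat|))^2)) over the shared samples,
#' where Vhat is the reference.  The metric blends absolute error (around
#' 0 mV) and relative error (at large |V|); it is not symmetric in its
#' arguments because the reference alone enters the denominator.  When the
#' test trace is sampled at different times it is resampled onto the
#' reference times by linear interpolation.
#'
#' @param reference reference trace (or numeric vector of V samples).
#' @param test test trace (or numeric vector).
#' @param ref_times,test_times sample times when passing bare vectors.
#' @return object of class `mrms_result`: `e_mrms`, `n`, `aligned`.
#' @export
mrms <- function(reference, test, ref_times = NULL, test_times = NULL) {
  if (inherits(reference, "myo_trace")) {
    ref_times <- reference$times
    reference <- trace_voltage(reference)
  }
  if (inherits(test, "myo_trace")) {
    test_times <- test$times
    test <- trace_voltage(test)
  }
  aligned <- TRUE
  if (!is.null(ref_times) && !is.null(test_times) &&
      !(length(ref_times) == length(test_times) &&
        all(abs(ref_times - test_times) < 1e-9))) {
    keep <- ref_times >= min(test_times) - 1e-9 & ref_times <= max(test_times) + 1e-9
    if (!any(keep)) stop("traces have no overlapping time samples", call. = FALSE)
    reference <- reference[keep]
    test <- stats::approx(test_times, test, xout = ref_times[keep])$y
    aligned <- FALSE
  }
  if (length(reference) != length(test)) {
    stop("traces have different lengths and no sample times were supplied",
         call. = FALSE)
  }
  if (length(reference) == 0L) stop("empty traces", call. = FALSE)
  e <- sqrt(mean(((reference - test) / (1 + abs(reference)))^2))
  structure(list(e_mrms = e, n = length(reference), aligned = aligned),
            class = "mrms_result")
}

#' @export
print.mrms_result <- function(x, ...) {
  cat(sprintf("MRMS error: %.6g over %d samples%s\n", x$e_mrms, x$n,
              if (!x$aligned) " (test resampled)" else ""))
  invisible(x)
}

#' Converged reference solution
#'
#' Adaptive solve at reltol 1e-7 / abstol 1e-9 with the analytic Jacobian
#' when it is free of overflow hazards, sampled every 0.1 ms.  The duration
#' is paces x stimulus period for paced models and 1000 ms for
#' self-excitatory ones.
#'
#' @param model an `ode_system`.
#' @param stimulus a [regular_stimulus()]; defaults to the model's own
#'   annotated stimulus; ignored for self-excitatory models.
#' @param paces number of paces to simulate.
#' @param y0 optional initial state.
#' @return a trace object.
#' @export
reference_solution <- function(model, stimulus = NULL, paces = 2, y0 = NULL) {
  self_exc <- isTRUE(model$interface$self_excitatory)
  if (is.null(stimulus) && !self_exc) stimulus <- default_stimulus(model)
  t_end <- if (self_exc) 1000 else paces * stimulus$period
  cfg <- solver_config("ADAPTIVE", reltol = 1e-7, abstol = 1e-9,
                       max_dt = 1, sampling_dt = 0.1,
                       use_analytic_jacobian = TRUE)
  solve_adaptive(model, cfg, stimulus, c(0, t_end), y0 = y0)
}

#' Timestep/tolerance refinement to a target accuracy
#'
#' Level 0 is dt = 0.1 ms for fixed-step methods and reltol 1e-3 /
#' abstol 1e-5 for the adaptive solver.  After a divergence or an MRMS error
#' above the threshold the level advances (dt halved; tolerances tightened
#' ten-fold), stopping at the first acceptance or after 12 refinements.
#'
#' @param model an `ode_system`.
#' @param method solver name (see [solver_config()]).
#' @param threshold acceptable MRMS error (default 0.05).
#' @param stimulus pacing stimulus (default: the model's own).
#' @param paces simulated paces per trial.
#' @param reference precomputed [reference_solution()] (recomputed if NULL).
#' @param max_level refinement cap.
#' @return object of class `refinement_outcome`: `solver`, `n` (accepted
#'   level, 0-based; NA when never accepted), `dt` or `reltol`/`abstol`,
#'   `e_mrms`, `history` of (level, status, e_mrms).
#' @export
find_required_refinement <- function(model, method, threshold = 0.05,
                                     stimulus = NULL, paces = 2,
                                     reference = NULL, max_level = 12L) {
  self_exc <- isTRUE(model$interface$self_excitatory)
  if (is.null(stimulus) && !self_exc) stimulus <- default_stimulus(model)
  if (is.null(reference)) reference <- reference_solution(model, stimulus, paces)
  t_end <- if (self_exc) 1000 else paces * stimulus$period
  history <- list()
  for (level in 0:max_level) {
    cfg <- if (method == "ADAPTIVE") {
      solver_config("ADAPTIVE", reltol = 1e-3 * 10^-level,
                    abstol = 1e-5 * 10^-level, max_dt = 1, sampling_dt = 0.1)
    } else {
      solver_config(method, dt = 0.1 / 2^level, sampling_dt = 0.1)
    }
    trial <- tryCatch(
      simulate_cell(model, cfg, stimulus, c(0, t_end), range_check = "off"),
      myo_divergence = function(c) c
    )
    if (inherits(trial, "myo_divergence")) {
      history[[length(history) + 1L]] <-
        list(level = level, status = "diverged", e_mrms = NA_real_)
      next
    }
    e <- mrms(reference, trial)$e_mrms
    if (is.finite(e) && e <= threshold) {
      history[[length(history) + 1L]] <-
        list(level = level, status = "accepted", e_mrms = e)
      return(structure(list(
        solver = method, n = level,
        dt = cfg$dt, reltol = cfg$reltol, abstol = cfg$abstol,
        e_mrms = e, history = history), class = "refinement_outcome"))
    }
    history[[length(history) + 1L]] <-
      list(level = level, status = "too-inaccurate", e_mrms = e)
  }
  structure(list(solver = method, n = NA_integer_, dt = NULL,
                 reltol = NULL, abstol = NULL, e_mrms = NA_real_,
                 history = history),
            class = "refinement_outcome")
}

#' @export
print.refinement_outcome <- function(x, ...) {
  if (is.na(x$n)) {
    cat(sprintf("%s: not accepted within %d refinements\n", x$solver,
                length(x$history) - 1L))
  } else if (x$solver == "ADAPTIVE") {
    cat(sprintf("%s: accepted at level %d (reltol %g / abstol %g), MRMS %.4g\n",
                x$solver, x$n, x$reltol, x$abstol, x$e_mrms))
  } else {
    cat(sprintf("%s: accepted at level %d (dt %g ms), MRMS %.4g\n",
                x$solver, x$n, x$dt, x$e_mrms))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Biomarkers

#' Action potential biomarkers from a voltage trace
#'
#' Conventions: the resting potential is V just before the stimulus onset of
#' the analysed pace; the upstroke time is the sample of maximum
#' forward-difference dV/dt; peak V is the maximum over the pace; APD_p runs
#' from the upstroke time until V first falls below
#' peak - (p/100)(peak - rest), located by linear interpolation.
#'
#' @param trace a trace object.
#' @param stimulus the pacing stimulus (used to locate pace onsets); when
#'   NULL the whole trace is treated as one pace starting at its first
#'   sample.
#' @param pace which pace to analyse (default: the last complete one).
#' @return object of class `ap_biomarkers`: apd30/apd50/apd90 (ms), peak_v,
#'   resting_v (mV), dvdt_max (mV/ms).
#' @export
biomarkers <- function(trace, stimulus = NULL, pace = NULL) {
  tt <- trace$times
  vv <- trace_voltage(trace)
  if (!is.null(stimulus)) {
    onsets <- seq(stimulus$start, max(tt), by = stimulus$period)
    onsets <- onsets[onsets < max(tt)]
    if (length(onsets) == 0L) onsets <- tt[1]
    if (is.null(pace)) pace <- length(onsets)
    t0 <- onsets[pace]
    t1 <- if (pace < length(onsets)) onsets[pace + 1L] else max(tt)
  } else {
    t0 <- tt[1]
    t1 <- max(tt)
  }
  pre <- which(tt <= t0)
  resting_v <- if (length(pre) > 0L) vv[max(pre)] else vv[1]
  win <- tt >= t0 & tt <= t1
  tw <- tt[win]; vw <- vv[win]
  if (length(tw) < 3L) stop("no action potential: window too short", call. = FALSE)
  dv <- diff(vw) / diff(tw)
  dvdt_max <- max(dv)
  peak_v <- max(vw)
  amplitude <- peak_v - resting_v
  if (!is.finite(amplitude) || amplitude < 10 || dvdt_max <= 0) {
    stop("no action potential detected in the trace", call. = FALSE)
  }
  i_up <- which.max(dv)
  t_up <- tw[i_up + 1L]
  i_peak <- which.max(vw)
  apd <- function(p) {
    v_thresh <- peak_v - (p / 100) * amplitude
    cand <- which(seq_along(vw) > i_peak & vw < v_thresh)
    if (length(cand) == 0L) return(NA_real_)
    i <- cand[1]
    # linear interpolation of the downward crossing
    tcross <- if (i > 1L && vw[i - 1L] >= v_thresh) {
      tw[i - 1L] + (v_thresh - vw[i - 1L]) /
        (vw[i] - vw[i - 1L]) * (tw[i] - tw[i - 1L])
    } else {
      tw[i]
    }
    tcross - t_up
  }
  structure(list(apd30 = apd(30), apd50 = apd(50), apd90 = apd(90),
                 peak_v = peak_v, resting_v = resting_v, dvdt_max = dvdt_max),
            class = "ap_biomarkers")
}

#' @export
print.ap_biomarkers <- function(x, ...) {
  cat(sprintf(
    "AP biomarkers: APD30/50/90 = %.2f/%.2f/%.2f ms, peak %.2f mV, rest %.2f mV, max dV/dt %.1f mV/ms\n",
    x$apd30, x$apd50, x$apd90, x$peak_v, x$resting_v, x$dvdt_max))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Timing harness

#' Wall-clock timing of a solver (excluded from accuracy acceptance)
#'
#' Runs the configured solver for the given number of paces three times in
#' quick succession and reports the fastest run, normalized to wall seconds
#' per simulated second.
#'
#' @param model an `ode_system`.
#' @param config a [solver_config()].
#' @param stimulus pacing stimulus (default: the model's own).
#' @param paces paces per run.
#' @param repeats repetitions (fastest wins).
#' @return list with `seconds_per_simulated_second`, `all_runs`, `spread`.
#' @export
time_solver <- function(model, config, stimulus = NULL, paces = 2, repeats = 3) {
  if (is.null(stimulus)) stimulus <- default_stimulus(model)
  t_end <- paces * stimulus$period
  runs <- numeric(repeats)
  for (r in seq_len(repeats)) {
    runs[r] <- system.time(
      simulate_cell(model, config, stimulus, c(0, t_end)))[["elapsed"]]
  }
  list(seconds_per_simulated_second = min(runs) / (t_end / 1000),
       all_runs = runs, spread = diff(range(runs)))
}
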