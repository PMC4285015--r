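# Steady-state (limit cycle) pacing.
#
# A model paced with a regular stimulus settles onto a periodic orbit; we
# declare "steady state" when the L2 norm of the state change across one
# pace drops below a tolerance (1e-6 by default).  Regular alternans - a
# period-2 orbit - is detected from the two-pace state change passing the
# tolerance while the one-pace change repeatedly fails it.

#' Pace a model to its limit cycle
#'
#' Simulates pace by pace with the adaptive solver (stepping state carried
#' across paces), computing the L2 norm of the state change after each pace.
#' Convergence is declared when the one-pace norm drops below `norm_tol`;
#' alternans when the two-pace norm passes while the one-pace norm has
#' failed for at least 10 consecutive paces.  Hitting `max_paces` emits a
#' warning and returns the unconverged state.
#'
#' @param model an `ode_system`.
#' @param stimulus pacing stimulus (default: the model's own).
#' @param norm_tol L2 convergence tolerance on the per-pace state change.
#' @param max_paces pace budget.
#' @param config adaptive solver configuration.
#' @param y0 optional starting state.
#' @return object of class `pacing_result`: `state` (final state vector),
#'   `paces_run`, `converged`, `alternans`, `norm_history`,
#'   `norm2_history` (two-pace norms), `normalized_norm_history`
#'   (diagnostic: norms scaled per-variable by 1 + |value|).
#' @export
run_to_steady_state <- function(model, stimulus = NULL, norm_tol = 1e-6,
                                max_paces = 10000L,
                                config = solver_config("ADAPTIVE"),
                                y0 = NULL) {
  if (is.null(stimulus)) stimulus <- default_stimulus(model)
  period <- stimulus$period
  y <- y0 %||% initial_state(model)
  prev <- y
  prev2 <- NULL
  carry <- NULL
  norms <- numeric(0)
  norms2 <- numeric(0)
  norms_scaled <- numeric(0)
  fail_streak <- 0L
  converged <- FALSE
  alternans <- FALSE
  paces <- 0L
  for (k in seq_len(max_paces)) {
    tr <- solve_adaptive(model, config, stimulus,
                         t_span = c((k - 1) * period, k * period),
                         y0 = y, carry = carry)
    carry <- tr$metadata$carry
    y <- tr$states[nrow(tr$states), ]
    paces <- k
    d1 <- sqrt(sum((y - prev)^2))
    norms <- c(norms, d1)
    norms_scaled <- c(norms_scaled, sqrt(sum(((y - prev) / (1 + abs(y)))^2)))
    if (!is.null(prev2)) norms2 <- c(norms2, sqrt(sum((y - prev2)^2)))
    if (d1 < norm_tol) {
      converged <- TRUE
      break
    }
    fail_streak <- fail_streak + 1L
    if (fail_streak >= 10L && length(norms2) > 0L &&
        norms2[length(norms2)] < norm_tol) {
      alternans <- TRUE
      converged <- TRUE
      break
    }
    prev2 <- prev
    prev <- y
  }
  if (!converged) {
    warning(sprintf(
      "steady state not reached within %d paces (last one-pace norm %.3g); ",
      max_paces, norms[length(norms)]),
      "the model may not conserve ions", call. = FALSE)
  }
  structure(list(state = y, paces_run = paces, converged = converged,
                 alternans = alternans, norm_history = norms,
                 norm2_history = norms2,
                 normalized_norm_history = norms_scaled,
                 stimulus = stimulus, norm_tol = norm_tol),
            class = "pacing_result")
}

#' @export
print.pacing_result <- function(x, ...) {
  cat(sprintf("Pacing: %s after %d paces%s (last one-pace L2 norm %.3g)\n",
              if (x$converged) "converged" else "NOT converged", x$paces_run,
              if (x$alternans) " with alternans" else "",
              x$norm_history[length(x$norm_history)]))
  invisible(x)
}

#' Serialize / restore a pacing state (checkpoint style)
#'
#' @param result a `pacing_result` (or any named state vector).
#' @param path JSON file to write.
#' @return for `save_state`, the path invisibly; for `load_state`, a named
#'   state vector usable as `y0`.
#' @export
save_state <- function(result, path) {
  state <- if (inherits(result, "pacing_result")) result$state else result
  jsonlite::write_json(as.list(state), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) {
  unlist(jsonlite::fromJSON(path))
}

#' Continue pacing for a fixed number of paces
#'
#' One continuous adaptive solve sampled at pace boundaries (the integrator
#' is never reinitialized), returning the state after `paces` paces.
#'
#' @param model an `ode_system`.
#' @param stimulus pacing stimulus.
#' @param paces number of paces.
#' @param config adaptive solver configuration.
#' @param y0 starting state.
#' @param chunk paces per integrator call (memory control; stepping state is
#'   carried between chunks).
#' @return named state vector after the final pace.
#' @export
run_paces <- function(model, stimulus, paces,
                      config = solver_config("ADAPTIVE"), y0 = NULL,
                      chunk = 100L) {
  y <- y0 %||% initial_state(model)
  period <- stimulus$period
  done <- 0L
  carry <- NULL
  while (done < paces) {
    n <- min(chunk, paces - done)
    cfg <- config
    cfg$sampling_dt <- period * n  # endpoints only
    tr <- solve_adaptive(model, cfg, stimulus,
                         t_span = c(done * period, (done + n) * period),
                         y0 = y, carry = carry)
    carry <- tr$metadata$carry
    y <- tr$states[nrow(tr$states), ]
    done <- done + n
  }
  y
}

#' APD90 of one pace started from a given state
#'
#' Simulates a single pace at reference tolerances and extracts APD90.
#'
#' @param model an `ode_system`.
#' @param state starting state (e.g. a detected steady state).
#' @param stimulus pacing stimulus.
#' @return APD90 in ms.
#' @export
apd90_from_state <- function(model, state, stimulus) {
  cfg <- solver_config("ADAPTIVE", reltol = 1e-7, abstol = 1e-9,
                       sampling_dt = 0.1, use_analytic_jacobian = TRUE)
  tr <- solve_adaptive(model, cfg, stimulus, c(0, stimulus$period), y0 = state)
  biomarkers(tr, stimulus, pace = 1)$apd90
}

#' Compare the detected steady state against a long pacing run
#'
#' Measures |APD90 at the detected limit cycle - APD90 after `long_paces`
#' paces|, both from single reference-quality paces.
#'
#' @param model an `ode_system`.
#' @param stimulus pacing stimulus (default: the model's own).
#' @param long_paces length of the long run.
#' @param norm_tol steady-state detection tolerance.
#' @param config adaptive solver configuration used for pacing.
#' @return list with `apd90_steady`, `apd90_long`, `difference` (ms),
#'   `paces_to_converge`.
#' @export
compare_to_long_run <- function(model, stimulus = NULL, long_paces = 10000L,
                                norm_tol = 1e-6,
                                config = solver_config("ADAPTIVE")) {
  if (is.null(stimulus)) stimulus <- default_stimulus(model)
  ss <- run_to_steady_state(model, stimulus, norm_tol = norm_tol,
                            max_paces = long_paces, config = config)
  apd_ss <- apd90_from_state(model, ss$state, stimulus)
  remaining <- long_paces - ss$paces_run
  y_long <- if (remaining > 0L) {
    run_paces(model, stimulus, remaining, config = config, y0 = ss$state)
  } else {
    ss$state
  }
  apd_long <- apd90_from_state(model, y_long, stimulus)
  list(apd90_steady = apd_ss, apd90_long = apd_long,
       difference = abs(apd_ss - apd_long),
       paces_to_converge = ss$paces_run)
}
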