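# 1D monodomain strand simulation by Godunov operator splitting.
#
# chi (Cm dV/dt + I_ion(u, V)) = d/dx (sigma dV/dx) + I_stim_vol
# du/dt = f(u, V) per node, V treated as a fixed parameter.
#
# Space: linear finite elements on a uniform interval mesh with lumped mass
# and no-flux boundaries.  Time: per PDE step the cell ODEs advance with V
# frozen, the new total ionic current is evaluated from Eq (1)'s right-hand
# side, then V advances by one implicit (backward Euler) solve with I_ion
# frozen.

#' Uniform 1D interval mesh
#'
#' @param length_cm strand length (cm).
#' @param h inter-node spacing (cm).
#' @return object of class `mesh1d` with node `positions` (cm).
#' @export
mesh1d <- function(length_cm = 1, h = 0.01) {
  n <- round(length_cm / h) + 1L
  positions <- seq(0, length_cm, length.out = n)
  stopifnot(max(abs(diff(positions) - h)) < 1e-12)
  structure(list(positions = positions, h = h, n_nodes = n), class = "mesh1d")
}

#' Assemble the discrete diffusion operators
#'
#' Linear finite elements on the interval: tridiagonal stiffness
#' K = (sigma/h) tridiag(-1, 2, -1) with no-flux ends (rows sum to zero) and
#' the lumped mass vector M = h * (1/2, 1, ..., 1, 1/2).
#'
#' @param mesh a [mesh1d()].
#' @param sigma conductivity (mS/cm).
#' @return list with `K` (dense matrix, mS/cm.../cm), `M` (lumped mass
#'   diagonal, cm).
#' @export
assemble_operators <- function(mesh, sigma) {
  n <- mesh$n_nodes
  h <- mesh$h
  K <- matrix(0, n, n)
  off <- -sigma / h
  for (i in seq_len(n - 1L)) {
    K[i, i] <- K[i, i] + sigma / h
    K[i + 1L, i + 1L] <- K[i + 1L, i + 1L] + sigma / h
    K[i, i + 1L] <- off
    K[i + 1L, i] <- off
  }
  M <- rep(h, n)
  M[1] <- h / 2
  M[n] <- h / 2
  list(K = K, M = M)
}

#' Define a 1D monodomain problem
#'
#' Defaults follow the strand benchmark configuration: a 1 cm fibre at
#' 0.01 cm spacing, conductivity 1.75 mS/cm, surface-to-volume ratio
#' 1400 /cm, specific capacitance 1 uF/cm^2, and a volume stimulus of
#' -30000 uA/cm^3 on x in [0, 0.1] cm for t in [1, 5] ms.
#'
#' @param model cell model (`ode_system`) used at every node.
#' @param mesh a [mesh1d()].
#' @param sigma conductivity (mS/cm).
#' @param chi membrane surface area per unit volume (1/cm).
#' @param cm specific membrane capacitance (uF/cm^2).
#' @param stim_amplitude volume stimulus (uA/cm^3; negative depolarizes).
#' @param stim_x c(lo, hi) stimulated interval (cm).
#' @param stim_t c(on, off) stimulation window (ms).
#' @param pde_dt PDE timestep (ms).
#' @param ode_solver "RL" (vectorized Rush-Larsen at the PDE timestep),
#'   "FE", or "ADAPTIVE" (per-node stiff solving in V-as-parameter mode).
#' @param ode_config optional [solver_config()] for the adaptive cell solver.
#' @param duration total simulated time (ms).
#' @param sampling_dt output sampling interval (ms).
#' @return object of class `monodomain_problem`.
#' @export
monodomain_problem <- function(model, mesh = mesh1d(1, 0.01), sigma = 1.75,
                               chi = 1400, cm = 1,
                               stim_amplitude = -30000,
                               stim_x = c(0, 0.1), stim_t = c(1, 5),
                               pde_dt = 0.01,
                               ode_solver = c("RL", "FE", "ADAPTIVE"),
                               ode_config = NULL,
                               duration = 500, sampling_dt = 1) {
  ode_solver <- match.arg(ode_solver)
  stopifnot(pde_dt > 0, duration > 0, sampling_dt >= pde_dt)
  structure(list(model = model, mesh = mesh, sigma = sigma, chi = chi,
                 cm = cm, stim_amplitude = stim_amplitude, stim_x = stim_x,
                 stim_t = stim_t, pde_dt = pde_dt, ode_solver = ode_solver,
                 ode_config = ode_config, duration = duration,
                 sampling_dt = sampling_dt),
            class = "monodomain_problem")
}

# Vectorized Rush-Larsen cell updater across nodes: states held as a list of
# per-state vectors (length n_nodes); V is always overridden by the PDE
# solution.
make_tissue_rl <- function(model) {
  dec <- gate_decomposition(model)
  gate_names <- names(dec$gates)
  non_gates <- setdiff(dec$non_gates, model$interface$v)
  stmts <- c(unpack_state_stmts(model), assignment_stmts(model))
  outs <- list()
  for (g in gate_names) {
    outs[[length(outs) + 1L]] <- call("<-", as.symbol(sprintf(".gi_%s", g)),
                                      dec$gates[[g]]$g_inf)
    outs[[length(outs) + 1L]] <- call("<-", as.symbol(sprintf(".ta_%s", g)),
                                      dec$gates[[g]]$tau)
  }
  for (s in non_gates) {
    outs[[length(outs) + 1L]] <- call("<-", as.symbol(sprintf(".dn_%s", s)),
                                      model$rhs[[s]])
  }
  ret <- as.call(c(as.symbol("list"),
                   stats::setNames(
                     lapply(c(sprintf(".gi_%s", gate_names),
                              sprintf(".ta_%s", gate_names),
                              sprintf(".dn_%s", non_gates)), as.symbol),
                     c(sprintf("gi_%s", gate_names),
                       sprintf("ta_%s", gate_names),
                       sprintf("dn_%s", non_gates)))))
  fn <- compiler::cmpfun(make_eval_fn(model, c(stmts, outs, list(ret))))
  list(fn = fn, gate_names = gate_names, non_gates = non_gates)
}

#' Solve a 1D monodomain problem
#'
#' @param problem a [monodomain_problem()].
#' @param y0 optional per-node initial states (matrix n_states x n_nodes);
#'   defaults to the cell model's initial conditions at every node.
#' @return object of class `monodomain_solution`: `times` (ms), `positions`
#'   (cm), `V` (matrix: rows = sample times, cols = nodes), `final_states`
#'   (n_states x n_nodes).
#' @export
solve_monodomain <- function(problem, y0 = NULL) {
  model <- problem$model
  mesh <- problem$mesh
  n <- mesh$n_nodes
  sn <- model$state_names
  vname <- model$interface$v
  vi <- match(vname, sn)
  ops <- assemble_operators(mesh, problem$sigma)
  dt <- problem$pde_dt
  coef <- problem$chi * problem$cm / dt
  A <- diag(coef * ops$M) + ops$K
  Ainv <- solve(A)  # constant operator: factor once

  states <- y0 %||% matrix(initial_state(model), nrow = length(sn), ncol = n,
                           dimnames = list(sn, NULL))
  V <- states[vi, ]
  stim_nodes <- mesh$positions >= problem$stim_x[1] - 1e-12 &
    mesh$positions <= problem$stim_x[2] + 1e-12
  state_list <- lapply(seq_along(sn), function(i) states[i, ])

  cmp_vec <- compile_rhs(model, partial_eval = TRUE, vectorized = TRUE)
  use_adaptive <- identical(problem$ode_solver, "ADAPTIVE")
  rl <- if (!use_adaptive) make_tissue_rl(model)
  ode_cfg <- problem$ode_config %||%
    solver_config("ADAPTIVE", v_mode = "parameter", reset_policy = "on_failure")
  node_carry <- vector("list", n)

  nsub <- max(1L, as.integer(round(problem$sampling_dt / dt)))
  n_steps <- ceiling(problem$duration / dt - 1e-9)
  n_samp <- floor(n_steps / nsub)
  times <- numeric(n_samp + 1L)
  Vout <- matrix(NA_real_, n_samp + 1L, n)
  Vout[1L, ] <- V
  samp <- 1L

  gi_names <- if (!use_adaptive) sprintf("gi_%s", rl$gate_names)
  ta_names <- if (!use_adaptive) sprintf("ta_%s", rl$gate_names)
  gidx <- if (!use_adaptive) match(rl$gate_names, sn)
  nidx <- if (!use_adaptive) match(rl$non_gates, sn)

  for (step in seq_len(n_steps)) {
    t <- (step - 1L) * dt
    state_list[[vi]] <- V
    if (use_adaptive) {
      for (node in seq_len(n)) {
        y <- vapply(state_list, function(s) s[[node]], 1)
        names(y) <- sn
        tr <- tryCatch(
          solve_adaptive(model, ode_cfg, stimulus = NULL,
                         t_span = c(t, t + dt), y0 = y, v_value = V[[node]],
                         carry = node_carry[[node]]),
          myo_divergence = function(c) {
            stop(divergence_signal(c$time, sprintf("node %d: %s", node, c$detail)))
          })
        node_carry[[node]] <- tr$metadata$carry
        yn <- tr$states[nrow(tr$states), ]
        for (i in seq_along(sn)) state_list[[i]][[node]] <- yn[[i]]
      }
      state_list[[vi]] <- V
    } else if (identical(problem$ode_solver, "FE")) {
      d <- cmp_vec$fn(t, state_list, 0, V)
      for (i in setdiff(seq_along(sn), vi)) {
        state_list[[i]] <- state_list[[i]] + dt * d[[i]]
      }
    } else {
      p <- rl$fn(t, state_list, 0, V)
      for (k in seq_along(gidx)) {
        gi <- p[[gi_names[k]]]
        ta <- p[[ta_names[k]]]
        g <- state_list[[gidx[k]]]
        state_list[[gidx[k]]] <- gi + (g - gi) * exp(-dt / ta)
      }
      for (k in seq_along(nidx)) {
        state_list[[nidx[k]]] <- state_list[[nidx[k]]] + dt * p[[sprintf("dn_%s", rl$non_gates[k])]]
      }
    }
    if (!all(vapply(state_list, function(s) all(is.finite(s)), TRUE))) {
      bad <- which(!is.finite(Reduce(`+`, state_list)))[1]
      stop(divergence_signal(t, sprintf("cell state non-finite at node %d", bad)))
    }
    i_ion <- cmp_vec$i_ion(t + dt, state_list, V)
    stim <- if (t + dt > problem$stim_t[1] && t + dt <= problem$stim_t[2]) {
      ifelse(stim_nodes, problem$stim_amplitude, 0)
    } else {
      rep(0, n)
    }
    # the volume stimulus enters alongside the ionic current, so (as for the
    # single-cell Eq 1) a negative amplitude depolarizes
    b <- ops$M * (coef * V - problem$chi * i_ion - stim)
    V <- as.numeric(Ainv %*% b)
    if (!all(is.finite(V))) {
      stop(divergence_signal(t + dt, "PDE solve produced non-finite voltage"))
    }
    if (step %% nsub == 0L) {
      samp <- samp + 1L
      times[samp] <- step * dt
      Vout[samp, ] <- V
    }
  }
  state_list[[vi]] <- V
  final <- do.call(rbind, state_list)
  rownames(final) <- sn
  structure(list(times = times[seq_len(samp)], positions = mesh$positions,
                 V = Vout[seq_len(samp), , drop = FALSE], final_states = final,
                 problem = problem),
            class = "monodomain_solution")
}

#' @export
print.monodomain_solution <- function(x, ...) {
  cat(sprintf("Monodomain solution: %d nodes, %d samples over [0, %g] ms\n",
              length(x$positions), length(x$times), max(x$times)))
  invisible(x)
}

#' Voltage trace at one node, as a trace object
#' @param sol a `monodomain_solution`.
#' @param node node index (default: the last node).
#' @return a trace object with a single V column.
#' @export
node_trace <- function(sol, node = length(sol$positions)) {
  states <- matrix(sol$V[, node], ncol = 1, dimnames = list(NULL, "V"))
  new_trace(sol$times, states,
            metadata = list(model = sol$problem$model$name, v_name = "V",
                            node = node))
}

#' Per-node activation times and conduction velocity
#'
#' Activation is the first upward crossing of the threshold, located by
#' linear interpolation; conduction velocity is the least-squares slope of
#' position against activation time over the activated interior nodes.
#'
#' @param sol a `monodomain_solution`.
#' @param threshold activation threshold (mV).
#' @return list with `activation_times` (ms; NA where a node never
#'   activates) and `cv` (cm/ms; NA when fewer than 3 interior nodes
#'   activate).
#' @export
activation_times <- function(sol, threshold = 0) {
  tt <- sol$times
  n <- ncol(sol$V)
  act <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    v <- sol$V[, j]
    i <- which(v[-1] >= threshold & v[-length(v)] < threshold)
    if (length(i) > 0L) {
      i <- i[1]
      act[j] <- tt[i] + (threshold - v[i]) / (v[i + 1] - v[i]) * (tt[i + 1] - tt[i])
    } else if (v[1] >= threshold) {
      act[j] <- tt[1]
    }
  }
  interior <- seq(2L, n - 1L)
  ok <- interior[is.finite(act[interior])]
  cv <- if (length(ok) >= 3L) {
    stats::coef(stats::lm(sol$positions[ok] ~ act[ok]))[[2]]
  } else {
    NA_real_
  }
  list(activation_times = act, cv = cv)
}

#' @rdname activation_times
#' @param ... passed to `activation_times`.
#' @return `conduction_velocity`: the CV alone (cm/ms).
#' @export
conduction_velocity <- function(sol, ...) {
  activation_times(sol, ...)$cv
}

#' Write the space-time voltage matrix as CSV (+ JSON metadata)
#'
#' @param sol a `monodomain_solution`.
#' @param path CSV output path (rows = times, cols = nodes; first column is
#'   time in ms).  Metadata is written alongside as `<path>.json`.
#' @return path, invisibly.
#' @export
write_monodomain_csv <- function(sol, path) {
  df <- data.frame(time = sol$times, sol$V)
  names(df) <- c("time_ms", sprintf("x_%g", sol$positions))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(model = sol$problem$model$name, sigma = sol$problem$sigma,
               chi = sol$problem$chi, cm = sol$problem$cm,
               pde_dt = sol$problem$pde_dt,
               ode_solver = sol$problem$ode_solver,
               h = sol$problem$mesh$h, n_nodes = length(sol$positions))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
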