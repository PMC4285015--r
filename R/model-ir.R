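# The standardized annotated ODE system.
#
# A cell model is the capacitor equation dV/dt = -(sum_j I_j + I_stim)/C_m
# together with dU/dt = f(U, V) for the remaining states (channel gates and
# concentrations).  Documents are flattened, dimension-checked, rescaled to
# the standard units convention (ms, mV, uA/cm^2, uF/cm^2, mM, mS/cm^2) and
# bound to a standard interface (V, C_m, stimulus slot, ionic currents).

#' Interface name heuristics
#'
#' Fallback variable names used to bind the core concepts when a document
#' carries no annotations.  The shipped defaults live in
#' `inst/extdata/interface-names.json` and can be edited or overridden.
#'
#' @param path optional path to a JSON config overriding the shipped file.
#' @return list with `v_names`, `cm_names`, `stim_names`, `time_names`.
#' @export
interface_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "interface-names.json", package = "myocyte")
  }
  if (nzchar(path) && file.exists(path)) {
    return(jsonlite::fromJSON(path, simplifyVector = TRUE))
  }
  list(v_names = c("V", "E", "membrane_voltage", "Vm", "v", "V_m"),
       cm_names = c("Cm", "C_m", "C_sc", "C", "C_memb", "Cap"),
       stim_names = c("i_Stim", "I_st", "i_stim", "I_stim", "i_st", "IStim",
                      "i_pulse", "i_app"),
       time_names = c("time", "t", "T"))
}

# Standard ontology term names used throughout.
TERM_V <- "membrane_voltage"
TERM_CM <- "membrane_capacitance"
TERM_CM_SPECIFIC <- "membrane_specific_capacitance"
TERM_STIM <- "membrane_stimulus_current"
TERM_STIM_AMPL <- "membrane_stimulus_current_amplitude"
TERM_STIM_DUR <- "membrane_stimulus_current_duration"
TERM_STIM_PERIOD <- "membrane_stimulus_current_period"
TERM_STIM_OFFSET <- "membrane_stimulus_current_offset"
TERM_STIM_END <- "membrane_stimulus_current_end"

# ---------------------------------------------------------------------------
# Dimension checking

# Returns unit (for quantities), the string "bool" (for conditions), or
# raises a conversion failure on inconsistency.
expr_dims <- function(e, flat, where) {
  fail <- function(msg) {
    stop(conversion_failure("invalid-units", where,
                            paste0(msg, " in: ", deparse1(e))))
  }
  dimless <- unit_new(1)
  if (is_const(e)) return(dimless)
  if (is.symbol(e)) {
    v <- flat$variables[[as.character(e)]]
    if (is.null(v)) return(dimless)
    return(v$unit)
  }
  fn <- as.character(e[[1L]])
  if (fn == "cn_") {
    u <- tryCatch(resolve_unit(e[[3L]], flat$unit_table),
                  error = function(err) fail(conditionMessage(err)))
    return(u)
  }
  args <- lapply(as.list(e)[-1L], expr_dims, flat = flat, where = where)
  same <- function(a, b) unit_same_dim(a, b)
  switch(fn,
    "(" = args[[1L]],
    "+" = , "-" = {
      if (length(args) == 2L && !same(args[[1L]], args[[2L]])) {
        fail("operands of +/- have different dimensions")
      }
      args[[1L]]
    },
    "*" = unit_mul(args[[1L]], args[[2L]]),
    "/" = unit_mul(args[[1L]], unit_pow(args[[2L]], -1)),
    "^" = {
      p <- e[[3L]]
      if (!is_const(p)) {
        if (!unit_dimensionless(args[[1L]])) fail("non-constant exponent on dimensioned base")
        return(unit_new(1))
      }
      unit_pow(args[[1L]], p)
    },
    "sqrt" = unit_pow(args[[1L]], 0.5),
    "exp" = , "log" = , "log10" = , "tanh" = {
      if (!unit_dimensionless(args[[1L]])) {
        fail(sprintf("argument of %s() must be dimensionless", fn))
      }
      dimless
    },
    "abs" = , "floor" = , "ceiling" = args[[1L]],
    "<" = , ">" = , "<=" = , ">=" = , "==" = , "!=" = {
      if (!same(args[[1L]], args[[2L]])) fail("comparison of different dimensions")
      dimless
    },
    "&" = , "|" = , "!" = dimless,
    "piecewise_" = {
      n <- length(args)
      vals <- args[seq_len(n) %% 2L == 0L]
      if (n %% 2L == 1L) vals <- c(vals, args[n])
      for (v in vals[-1L]) {
        if (!same(vals[[1L]], v)) fail("piecewise branches have different dimensions")
      }
      vals[[1L]]
    },
    fail(sprintf("unsupported operator '%s'", fn))
  )
}

check_dimensions <- function(flat) {
  failures <- list()
  note <- function(expr_fn) {
    tryCatch({ expr_fn(); NULL },
             myo_conversion_failure = function(c) {
               failures[[length(failures) + 1L]] <<-
                 fail_record(c$category, c$location, c$detail)
             })
  }
  for (a in flat$assignments) {
    note(function() {
      u <- expr_dims(a$rhs, flat, sprintf("equation for '%s'", a$var))
      tu <- flat$variables[[a$var]]$unit
      if (!is.null(tu) && !unit_same_dim(u, tu)) {
        stop(conversion_failure("invalid-units", sprintf("equation for '%s'", a$var),
                                "right-hand side dimensions do not match the variable"))
      }
    })
  }
  tu_time <- if (!is.na(flat$time_var)) flat$variables[[flat$time_var]]$unit else NULL
  for (o in flat$odes) {
    note(function() {
      u <- expr_dims(o$rhs, flat, sprintf("rate equation for '%s'", o$state))
      su <- flat$variables[[o$state]]$unit
      if (!is.null(su) && !is.null(tu_time)) {
        want <- unit_mul(su, unit_pow(tu_time, -1))
        if (!unit_same_dim(u, want)) {
          stop(conversion_failure("invalid-units",
                                  sprintf("rate equation for '%s'", o$state),
                                  "right-hand side is not state-units per time-units"))
        }
      }
    })
  }
  failures
}

# ---------------------------------------------------------------------------
# Units standardization

# The standard convention is generated by a rescaled SI basis:
# length cm, time ms, current uA, amount umol, mass 1e-14 kg, temperature K.
# Under this basis every derived convention lands on its target: voltage mV,
# current density uA/cm^2, capacitance (density) uF(/cm^2), conductance
# density mS/cm^2, concentration mM.
.std_base_mult <- c(m = 1e-2, kg = 1e-14, s = 1e-3, A = 1e-6, mol = 1e-6, K = 1)

std_factor <- function(u) {
  u$multiplier / prod(.std_base_mult^u$dims)
}

std_unit_of <- function(u) unit_new(prod(.std_base_mult^u$dims), u$dims)

std_unit_label <- function(u) {
  conv <- standard_conventions()
  labels <- c(time = "ms", voltage = "mV", current_density = "uA/cm^2",
              capacitance_density = "uF/cm^2", capacitance = "uF",
              current = "uA", concentration = "mM",
              conductance_density = "mS/cm^2", rate = "per_ms",
              concentration_rate = "mM/ms", voltage_rate = "mV/ms")
  for (nm in names(conv)) {
    if (unit_same_dim(u, conv[[nm]])) return(labels[[nm]])
  }
  if (unit_dimensionless(u)) return("dimensionless")
  "standardized"
}

find_term_var <- function(ann, term) {
  for (v in names(ann$terms)) {
    if (term %in% ann$terms[[v]]) return(v)
  }
  NULL
}

current_like_vars <- function(flat, ann) {
  out <- character(0)
  for (v in names(ann$terms)) {
    if (any(grepl("^membrane_.*current$", ann$terms[[v]]))) out <- c(out, v)
  }
  out
}

#' Rescale a flattened model to the standard units convention
#'
#' Every variable and numeric constant is rescaled so that time is in ms,
#' voltage in mV, current densities in uA/cm^2, capacitance in uF/cm^2,
#' concentrations in mM and conductances in mS/cm^2; rate equations pick up
#' the time rescale by the chain rule.  Idempotent.  Currents declared in
#' absolute units (e.g. nA) and annotated as transmembrane currents are
#' converted to densities via the annotated membrane capacitance and specific
#' capacitance; if those are absent the conversion fails rather than assume a
#' cell size.
#'
#' @param flat flattened model from [flatten()].
#' @param ann annotations from [read_annotations()].
#' @return the rescaled flat model.
#' @export
convert_units <- function(flat, ann = NULL) {
  if (is.null(ann)) ann <- list(terms = list())
  current_dims <- unit_new(1, c(A = 1))$dims
  needs_area <- character(0)
  for (v in current_like_vars(flat, ann)) {
    u <- flat$variables[[v]]$unit
    if (!is.null(u) && all(abs(u$dims - current_dims) < 1e-9)) {
      needs_area <- c(needs_area, v)
    }
  }
  area_factor <- 1
  if (length(needs_area) > 0L) {
    cm_var <- find_term_var(ann, TERM_CM)
    cs_var <- find_term_var(ann, TERM_CM_SPECIFIC)
    if (is.null(cm_var) || is.null(cs_var)) {
      stop(conversion_failure("invalid-units", "interface",
        paste("model declares currents in absolute units; converting to",
              "current density requires annotated membrane_capacitance and",
              "membrane_specific_capacitance")))
    }
    cm_val <- flat$variables[[cm_var]]$initial_value *
      std_factor(flat$variables[[cm_var]]$unit)
    cs_val <- flat$variables[[cs_var]]$initial_value *
      std_factor(flat$variables[[cs_var]]$unit)
    area_factor <- cs_val / cm_val  # 1/cm^2 in standard units
  }

  # Quantity semantics: the dimension check has established each equation as
  # a physical-quantity identity, so expressing every variable and constant
  # in one consistent basis preserves each identity with no extra factors
  # (the time rescale of each rate equation arrives via its rate constants).
  s <- stats::setNames(numeric(length(flat$variables)), names(flat$variables))
  for (nm in names(flat$variables)) {
    s[[nm]] <- std_factor(flat$variables[[nm]]$unit)
  }

  convert_cns <- function(e) {
    if (is.call(e)) {
      if (is_call_to(e, "cn_")) {
        u <- resolve_unit(e[[3L]], flat$unit_table)
        return(e[[2L]] * std_factor(u))
      }
      for (i in seq_along(e)[-1L]) e[[i]] <- convert_cns(e[[i]])
    }
    e
  }

  for (i in seq_along(flat$assignments)) {
    a <- flat$assignments[[i]]
    rhs <- expr_fold(convert_cns(a$rhs))
    if (a$var %in% needs_area) rhs <- expr_fold(call("*", area_factor, rhs))
    flat$assignments[[i]]$rhs <- rhs
  }
  for (i in seq_along(flat$odes)) {
    flat$odes[[i]]$rhs <- expr_fold(convert_cns(flat$odes[[i]]$rhs))
  }
  for (nm in names(flat$variables)) {
    v <- flat$variables[[nm]]
    if (!is.na(v$initial_value)) {
      flat$variables[[nm]]$initial_value <- v$initial_value * s[[nm]]
      if (nm %in% needs_area) {
        flat$variables[[nm]]$initial_value <-
          flat$variables[[nm]]$initial_value * area_factor
      }
    }
    u_new <- std_unit_of(v$unit)
    if (nm %in% needs_area) {
      u_new <- unit_mul(u_new, unit_new(1, c(m = -2)))
      u_new <- unit_new(prod(.std_base_mult^u_new$dims), u_new$dims)
    }
    flat$variables[[nm]]$unit <- u_new
    flat$variables[[nm]]$units <- std_unit_label(u_new)
  }
  # currents converted from absolute to density: the membrane capacitance
  # binding becomes the specific capacitance so Eq (1) stays consistent
  if (length(needs_area) > 0L) {
    cm_var <- find_term_var(ann, TERM_CM)
    flat$variables[[cm_var]]$initial_value <- cs_val
    flat$variables[[cm_var]]$unit <- standard_conventions()$capacitance_density
    flat$variables[[cm_var]]$units <- "uF/cm^2"
  }
  flat$standardized <- TRUE
  flat
}

# ---------------------------------------------------------------------------
# Interface identification

#' Identify the standard interface of a flattened model
#'
#' Binds the transmembrane potential V, membrane capacitance C_m and the
#' stimulus-current slot, by annotation first and by a configurable
#' common-name heuristic second, then verifies that the dV/dt equation is an
#' algebraic variant of -(sum of ionic currents + I_stim)/C_m and enumerates
#' the ionic currents.  Self-excitatory models bind no stimulus slot.
#'
#' @param flat flattened (preferably standardized) model.
#' @param ann annotations from [read_annotations()].
#' @param config name-heuristic configuration, see [interface_config()].
#' @return list with `v`, `cm`, `stim`, `currents`, `time`,
#'   `self_excitatory`.
#' @export
identify_interface <- function(flat, ann, config = interface_config()) {
  states <- vapply(flat$odes, function(o) o$state, "")
  assigned <- vapply(flat$assignments, function(a) a$var, "")
  pick <- function(term, fallbacks, among = names(flat$variables)) {
    v <- find_term_var(ann, term)
    if (!is.null(v)) return(v)
    hit <- intersect(fallbacks, among)
    if (length(hit) > 0L) return(hit[[1L]])
    NULL
  }
  v_var <- pick(TERM_V, config$v_names, states)
  if (is.null(v_var)) {
    stop(conversion_failure("under-constrained", "interface",
                            "cannot identify the transmembrane potential V"))
  }
  cm_var <- pick(TERM_CM, config$cm_names)
  stim_var <- if (isTRUE(ann$self_excitatory)) NULL
              else pick(TERM_STIM, config$stim_names)

  # ionic currents: current-density variables the dV/dt equation depends on
  ode_v <- NULL
  for (o in flat$odes) if (o$state == v_var) ode_v <- o
  if (is.null(ode_v)) {
    stop(conversion_failure("under-constrained", "interface",
                            "V is not defined by a differential equation"))
  }
  cdens <- standard_conventions()$current_density
  is_current <- function(nm) {
    u <- flat$variables[[nm]]$unit
    !is.null(u) && unit_same_dim(u, cdens)
  }
  adef <- stats::setNames(lapply(flat$assignments, function(a) a$rhs), assigned)
  seen <- character(0)
  frontier <- setdiff(expr_free_vars(ode_v$rhs), c(flat$time_var, v_var))
  currents <- character(0)
  while (length(frontier) > 0L) {
    nm <- frontier[[1L]]; frontier <- frontier[-1L]
    if (nm %in% seen) next
    seen <- c(seen, nm)
    if (is_current(nm) && !identical(nm, stim_var)) {
      def <- adef[[nm]]
      subs <- if (!is.null(def)) expr_free_vars(def) else character(0)
      # a pure aggregate of other currents is expanded, a leaf current kept
      sub_cur <- subs[vapply(subs, is_current, TRUE)]
      if (!is.null(def) && length(sub_cur) > 0L &&
          setequal(subs, sub_cur)) {
        frontier <- c(frontier, sub_cur)
      } else {
        currents <- c(currents, nm)
      }
    } else if (nm %in% assigned) {
      next  # do not descend into non-current intermediates
    }
  }
  currents <- sort(unique(currents))
  list(v = v_var, cm = cm_var, stim = stim_var, currents = currents,
       time = flat$time_var, self_excitatory = isTRUE(ann$self_excitatory))
}

# Numeric verification that dV/dt matches -(sum I_j + I_stim)/C_m, allowing
# distributed and negated algebraic variants.
verify_v_equation <- function(flat, iface, n_probe = 3L, tol = 1e-6) {
  ode_v <- NULL
  for (o in flat$odes) if (o$state == iface$v) ode_v <- o
  env0 <- flat_eval_env(flat)
  cm_val <- function(env) {
    if (is.null(iface$cm)) 1 else get(iface$cm, envir = env)
  }
  set.seed(171717)
  for (k in seq_len(n_probe)) {
    env <- flat_eval_env(flat, jitter = if (k == 1L) 0 else 0.01)
    if (!is.null(iface$stim)) assign(iface$stim, 0.0, envir = env)
    eval_assignments(flat, env)
    lhs <- eval(ode_v$rhs, env)
    isum <- sum(vapply(iface$currents, function(nm) get(nm, envir = env), 1))
    rhs <- -isum / cm_val(env)
    if (!is.finite(lhs) || abs(lhs - rhs) > tol * (1 + abs(rhs))) {
      stop(conversion_failure(
        "unsupported-construct", "interface",
        sprintf("dV/dt equation does not match -(sum(I_j) + I_stim)/C_m (got %.6g, expected %.6g): %s",
                lhs, rhs, deparse1(ode_v$rhs))))
    }
  }
  invisible(TRUE)
}

flat_eval_env <- function(flat, jitter = 0) {
  env <- new.env(parent = baseenv())
  assign("piecewise_", piecewise_, envir = env)
  for (nm in names(flat$variables)) {
    v <- flat$variables[[nm]]
    if (!is.na(v$initial_value)) {
      val <- v$initial_value
      if (jitter > 0) val <- val * (1 + jitter * stats::runif(1, -1, 1))
      assign(nm, val, envir = env)
    }
  }
  if (!is.na(flat$time_var)) assign(flat$time_var, 0.0, envir = env)
  env
}

eval_assignments <- function(flat, env) {
  for (a in flat$assignments) {
    assign(a$var, eval(a$rhs, env), envir = env)
  }
  invisible(env)
}

# ---------------------------------------------------------------------------
# The compiled system object

#' Convert a CellML-subset document into an annotated ODE system
#'
#' Full pipeline: parse, flatten, dimension-check, rescale to the standard
#' units convention, bind the standard interface, and package the result as
#' an `ode_system`.  Conversion problems are collected into the returned
#' [conversion_report()] rather than thrown.
#'
#' @param xml_text document text, an `xml_document`, or a file path.
#' @param config interface name heuristics, see [interface_config()].
#' @return list with `model` (an `ode_system`, or NULL on failure) and
#'   `report` (a `conversion_report`).
#' @export
convert_cellml <- function(xml_text, config = interface_config()) {
  failures <- list()
  result <- tryCatch({
    if (is.character(xml_text) && length(xml_text) == 1L &&
        !grepl("<", xml_text, fixed = TRUE) && file.exists(xml_text)) {
      xml_text <- paste(readLines(xml_text, warn = FALSE), collapse = "\n")
    }
    raw <- parse_document(xml_text)
    flat <- flatten(raw)
    failures <- c(failures, flat$report$failures)
    if (length(failures) > 0L) return(list(model = NULL,
                                           report = conversion_report(failures)))
    ann <- read_annotations(raw, flat)
    failures <- c(failures, check_dimensions(flat))
    if (length(failures) > 0L) return(list(model = NULL,
                                           report = conversion_report(failures)))
    flat <- convert_units(flat, ann)
    iface <- identify_interface(flat, ann, config)
    verify_v_equation(flat, iface)
    model <- build_ode_system(flat, ann, iface, name = raw$name)
    list(model = model, report = conversion_report())
  },
  myo_conversion_failure = function(c) {
    failures <- c(failures, list(fail_record(c$category, c$location, c$detail)))
    list(model = NULL, report = conversion_report(failures))
  },
  error = function(e) {
    failures <- c(failures,
                  list(fail_record("unsupported-construct", "document",
                                   conditionMessage(e))))
    list(model = NULL, report = conversion_report(failures))
  })
  result
}

build_ode_system <- function(flat, ann, iface, name = "model") {
  states <- vapply(flat$odes, function(o) o$state, "")
  assigned <- vapply(flat$assignments, function(a) a$var, "")
  par_names <- setdiff(names(flat$variables), c(states, assigned, flat$time_var))
  # drop the stimulus defining equation: the slot is bound at solve time
  assignments <- flat$assignments
  if (!is.null(iface$stim)) {
    if (iface$stim %in% assigned) {
      assignments <- assignments[assigned != iface$stim]
      assigned <- setdiff(assigned, iface$stim)
    }
    par_names <- setdiff(par_names, iface$stim)
  }
  rhs <- stats::setNames(lapply(flat$odes, function(o) o$rhs), states)

  model <- structure(list(
    name = name,
    time_var = flat$time_var,
    state_names = states,        # reordered below
    state_units = vapply(states, function(s) flat$variables[[s]]$units, ""),
    initial_values = vapply(states, function(s) flat$variables[[s]]$initial_value, 1),
    parameters = vapply(par_names, function(p) flat$variables[[p]]$initial_value, 1),
    parameter_units = vapply(par_names, function(p) flat$variables[[p]]$units, ""),
    assignments = assignments,
    rhs = rhs,
    interface = iface,
    annotations = ann,
    variables = flat$variables,
    cache = new.env(parent = emptyenv())
  ), class = "ode_system")

  gates <- tryCatch(detect_gates(model)$gates, error = function(e) list())
  gate_names <- names(gates)
  ord <- c(iface$v, sort(intersect(gate_names, setdiff(states, iface$v))),
           sort(setdiff(states, c(iface$v, gate_names))))
  model$state_names <- ord
  model$state_units <- model$state_units[ord]
  model$initial_values <- model$initial_values[ord]
  model$rhs <- model$rhs[ord]
  model$cache <- new.env(parent = emptyenv())
  model
}

#' @export
print.ode_system <- function(x, ...) {
  cat(sprintf("Annotated ODE system '%s': %d states, %d parameters, %d derived\n",
              x$name, length(x$state_names), length(x$parameters),
              length(x$assignments)))
  cat("  states:", paste(x$state_names, collapse = ", "), "\n")
  cat(sprintf("  interface: V=%s, Cm=%s, stim=%s, currents={%s}\n",
              x$interface$v, x$interface$cm %||% "<none>",
              x$interface$stim %||% "<none>",
              paste(x$interface$currents, collapse = ", ")))
  invisible(x)
}

#' Initial state vector of a model
#' @param model an `ode_system`.
#' @return named numeric vector aligned with the model state layout.
#' @export
initial_state <- function(model) {
  stats::setNames(as.numeric(model$initial_values), model$state_names)
}

# Evaluation environment with parameters and helpers; reused across calls.
model_base_env <- function(model) {
  if (!is.null(model$cache$base_env)) return(model$cache$base_env)
  env <- new.env(parent = baseenv())
  assign("piecewise_", piecewise_, envir = env)
  for (nm in names(model$parameters)) assign(nm, model$parameters[[nm]], envir = env)
  model$cache$base_env <- env
  env
}

# Naive reference evaluator for the right-hand side: evaluates the ordered
# assignment chain then each state derivative.  Used as the oracle against
# which compiled evaluators are checked.
#' Evaluate the model right-hand side
#'
#' @param model an `ode_system`.
#' @param t time (ms).
#' @param state named or ordered state vector.
#' @param i_stim stimulus current value (uA/cm^2).
#' @param v_override when not NULL, V is treated as a parameter with this
#'   value (tissue mode) and the returned derivative for V is 0.
#' @return named derivative vector.
#' @export
eval_rhs <- function(model, t, state, i_stim = 0, v_override = NULL) {
  env <- new.env(parent = model_base_env(model))
  sn <- model$state_names
  for (i in seq_along(sn)) assign(sn[[i]], state[[i]], envir = env)
  if (!is.null(v_override)) assign(model$interface$v, v_override, envir = env)
  if (!is.na(model$time_var)) assign(model$time_var, t, envir = env)
  if (!is.null(model$interface$stim)) assign(model$interface$stim, i_stim, envir = env)
  for (a in model$assignments) assign(a$var, eval(a$rhs, env), envir = env)
  d <- vapply(sn, function(s) eval(model$rhs[[s]], env), 1)
  if (!is.null(v_override)) d[[model$interface$v]] <- 0
  d
}

# Total ionic current (excluding stimulus) at a state, per Eq (1)'s RHS.
eval_i_ion <- function(model, t, state, v_override = NULL) {
  env <- new.env(parent = model_base_env(model))
  sn <- model$state_names
  for (i in seq_along(sn)) assign(sn[[i]], state[[i]], envir = env)
  if (!is.null(v_override)) assign(model$interface$v, v_override, envir = env)
  if (!is.na(model$time_var)) assign(model$time_var, t, envir = env)
  if (!is.null(model$interface$stim)) assign(model$interface$stim, 0.0, envir = env)
  for (a in model$assignments) assign(a$var, eval(a$rhs, env), envir = env)
  sum(vapply(model$interface$currents, function(nm) get(nm, envir = env), 1))
}

# ---------------------------------------------------------------------------
# Inlined right-hand sides (assignments substituted), used by symbolic
# transforms.  Memoized per model.

model_rhs_inlined <- function(model) {
  if (!is.null(model$cache$rhs_inlined)) return(model$cache$rhs_inlined)
  mapping <- list()
  for (a in model$assignments) {
    mapping[[a$var]] <- expr_subst(a$rhs, mapping)
  }
  out <- lapply(model$rhs, function(e) expr_fold(expr_subst(e, mapping)))
  model$cache$rhs_inlined <- out
  out
}

# ---------------------------------------------------------------------------
# Variable access

resolve_any_name <- function(model, name) {
  # annotation term?
  for (v in names(model$annotations$terms)) {
    if (name %in% model$annotations$terms[[v]]) return(v)
  }
  known <- c(model$state_names, names(model$parameters),
             vapply(model$assignments, function(a) a$var, ""))
  if (name %in% known) return(name)
  terms <- unique(unlist(model$annotations$terms, use.names = FALSE))
  cand <- c(known, terms)
  near <- cand[utils::adist(name, cand) <= 3]
  stop("unknown variable '", name, "'",
       if (length(near) > 0L) paste0("; did you mean: ",
                                     paste(utils::head(near, 5), collapse = ", "), "?"),
       call. = FALSE)
}

#' Read any model quantity by name or annotation term
#'
#' Works uniformly whether the quantity is a state variable, a constant
#' parameter, or a derived quantity (evaluated from the current state).
#'
#' @param model an `ode_system`.
#' @param state state vector.
#' @param t time (ms).
#' @param name raw variable name or ontology term.
#' @return the current value.
#' @export
get_any_variable <- function(model, state, t, name) {
  var <- resolve_any_name(model, name)
  if (var %in% model$state_names) return(state[[var]])
  if (var %in% names(model$parameters)) return(model$parameters[[var]])
  env <- new.env(parent = model_base_env(model))
  sn <- model$state_names
  for (i in seq_along(sn)) assign(sn[[i]], state[[i]], envir = env)
  if (!is.na(model$time_var)) assign(model$time_var, t, envir = env)
  if (!is.null(model$interface$stim)) assign(model$interface$stim, 0.0, envir = env)
  for (a in model$assignments) {
    assign(a$var, eval(a$rhs, env), envir = env)
    if (a$var == var) return(get(var, envir = env))
  }
  stop("internal: '", var, "' not evaluated")  # nocov
}

#' Set a state variable or modifiable parameter by name or annotation term
#'
#' Derived quantities are computed from other variables and are rejected.
#'
#' @inheritParams get_any_variable
#' @param value new value.
#' @return list with updated `state` and `model`.
#' @export
set_any_variable <- function(model, state, name, value) {
  var <- resolve_any_name(model, name)
  if (var %in% vapply(model$assignments, function(a) a$var, "")) {
    stop("'", name, "' is a derived quantity and is not settable", call. = FALSE)
  }
  if (var %in% model$state_names) {
    state[[var]] <- value
    return(list(state = state, model = model))
  }
  model$parameters[[var]] <- value
  model$cache <- new.env(parent = emptyenv())  # invalidate memoized evaluators
  list(state = state, model = model)
}

# ---------------------------------------------------------------------------
# Gate detection

#' Detect gating variables
#'
#' A state g is a gate when its derivative is affine in g with coefficients
#' free of g (at fixed V): dg/dt = a*g + b.  Returns tau = -1/a and
#' g_inf = -b/a as expressions of the remaining variables; algebraically
#' equivalent authorings (alpha*(1-g) - beta*g vs (g_inf - g)/tau) yield
#' identical decompositions.
#'
#' @param model an `ode_system`.
#' @return list with `gates` (per gate: `a`, `b`, `tau`, `g_inf`
#'   expressions) and `non_gates` (character vector).
#' @export
detect_gates <- function(model) {
  inl <- model_rhs_inlined(model)
  gates <- list()
  non_gates <- character(0)
  for (s in model$state_names) {
    if (identical(s, model$interface$v)) { non_gates <- c(non_gates, s); next }
    e <- inl[[s]]
    a <- tryCatch(expr_fold(expr_diff(e, s)), error = function(err) NULL)
    if (is.null(a) || s %in% expr_free_vars(a)) {
      non_gates <- c(non_gates, s)
      next
    }
    b <- expr_fold(expr_subst(e, stats::setNames(list(0), s)))
    tau <- expr_fold(call("/", -1, a))
    g_inf <- expr_fold(call("-", call("/", b, a)))
    gates[[s]] <- list(a = a, b = b, tau = tau, g_inf = g_inf)
  }
  list(gates = gates, non_gates = non_gates)
}

# ---------------------------------------------------------------------------
# Range checks

#' Check annotated variable ranges
#'
#' @param model an `ode_system`.
#' @param state state vector.
#' @return list of violations, each naming the variable, value and bound;
#'   empty when all annotated variables are within bounds.
#' @export
check_ranges <- function(model, state) {
  out <- list()
  for (var in names(model$annotations$ranges)) {
    if (!var %in% model$state_names) next
    r <- model$annotations$ranges[[var]]
    v <- state[[var]]
    if (is.finite(r[1]) && v < r[1]) {
      out[[length(out) + 1L]] <- list(variable = var, value = v, bound = r[1],
                                      side = "lower")
    }
    if (is.finite(r[2]) && v > r[2]) {
      out[[length(out) + 1L]] <- list(variable = var, value = v, bound = r[2],
                                      side = "upper")
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Stimulus

#' Square-wave pacing stimulus
#'
#' @param amplitude stimulus amplitude (uA/cm^2; depolarizing stimuli are
#'   negative by convention).
#' @param duration pulse width (ms), 0 < duration < period.
#' @param period pacing period (ms).
#' @param start time of the first pulse (ms).
#' @param end optional last time at which the stimulus may fire (ms).
#' @return object of class `regular_stimulus`.
#' @export
regular_stimulus <- function(amplitude, duration, period, start = 0, end = NULL) {
  stopifnot(duration > 0, duration < period, is.null(end) || end >= start)
  structure(list(amplitude = amplitude, duration = duration, period = period,
                 start = start, end = end),
            class = "regular_stimulus")
}

#' @export
print.regular_stimulus <- function(x, ...) {
  cat(sprintf("RegularStimulus: %g uA/cm^2 for %g ms every %g ms from t=%g%s\n",
              x$amplitude, x$duration, x$period, x$start,
              if (!is.null(x$end)) sprintf(" until t=%g", x$end) else ""))
  invisible(x)
}

#' Build the model's own annotated default stimulus
#'
#' Uses the amplitude/duration/period/offset (and optional end) stimulus
#' parameter annotations, after units standardization.
#'
#' @param model an `ode_system`.
#' @return a [regular_stimulus()].
#' @export
default_stimulus <- function(model) {
  if (isTRUE(model$interface$self_excitatory)) {
    stop("model is marked self-excitatory and defines no stimulus; ",
         "it does not need one (supply a stimulus explicitly to override)",
         call. = FALSE)
  }
  grab <- function(term) {
    v <- find_term_var(model$annotations, term)
    if (is.null(v)) return(NULL)
    if (v %in% names(model$parameters)) return(model$parameters[[v]])
    if (v %in% model$state_names) return(initial_state(model)[[v]])
    NULL
  }
  ampl <- grab(TERM_STIM_AMPL); dur <- grab(TERM_STIM_DUR)
  per <- grab(TERM_STIM_PERIOD); off <- grab(TERM_STIM_OFFSET)
  if (is.null(ampl) || is.null(dur) || is.null(per)) {
    stop("model has no annotated square-wave stimulus parameters; ",
         "supply a regular_stimulus() explicitly", call. = FALSE)
  }
  regular_stimulus(ampl, dur, per, start = off %||% 0, end = grab(TERM_STIM_END))
}

# ---------------------------------------------------------------------------
# Summaries / export

#' Export a model summary as JSON
#' @param model an `ode_system`.
#' @param path optional file to write.
#' @return JSON string (invisibly when written to file).
#' @export
model_summary_json <- function(model, path = NULL) {
  s <- list(
    name = model$name,
    states = data.frame(name = model$state_names,
                        units = unname(model$state_units),
                        initial = unname(model$initial_values)),
    parameters = data.frame(name = names(model$parameters),
                            units = unname(model$parameter_units),
                            value = unname(model$parameters)),
    derived = vapply(model$assignments, function(a) a$var, ""),
    interface = model$interface[c("v", "cm", "stim", "currents", "time")],
    annotations = model$annotations$terms,
    self_excitatory = isTRUE(model$interface$self_excitatory)
  )
  js <- jsonlite::toJSON(s, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
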