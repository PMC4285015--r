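# Symbolic transforms on the model IR and compilation to fast evaluators.
#
# All transforms are exact except lookup tables (linear interpolation with a
# documented error bound).  Compiled evaluators are straight-line R closures
# generated from the expression trees and byte-compiled; piecewise
# expressions become if/else statements in scalar mode and vectorized
# selection in vector mode (for tissue simulation across nodes).

# ---------------------------------------------------------------------------
# Partial evaluation

#' Partially evaluate a model
#'
#' Folds constant subexpressions (non-modifiable parameters are substituted
#' by value, so shared thermodynamic constants like F/(R*T) collapse to one
#' precomputed number) and hoists repeated non-constant subexpressions into
#' shared temporaries.  Evaluation is preserved exactly; no approximation is
#' introduced.  Modifiable parameters remain symbolic so they can still be
#' changed afterwards.
#'
#' @param model an `ode_system`.
#' @return the transformed model, with `pe_temps` recording the count of new
#'   temporaries.
#' @export
partial_evaluate <- function(model) {
  fixed <- setdiff(names(model$parameters), model$annotations$modifiable)
  pmap <- as.list(model$parameters[fixed])
  spec <- function(e) expr_fold(expr_subst(e, pmap))
  assigns <- lapply(model$assignments, function(a) {
    list(var = a$var, rhs = spec(a$rhs))
  })
  rhs <- lapply(model$rhs, spec)

  all_exprs <- c(lapply(assigns, function(a) a$rhs), rhs)
  cse <- expr_cse(all_exprs, prefix = ".pe")
  na <- length(assigns)
  new_assigns <- list()
  emitted <- character(0)
  temp_deps <- lapply(cse$temps, expr_free_vars)
  emit_temps_for <- function(e, out) {
    emit_one <- function(tn, out) {
      if (tn %in% emitted) return(out)
      emitted <<- c(emitted, tn)  # mark first: deps cannot be cyclic
      for (dep in intersect(temp_deps[[tn]], names(cse$temps))) {
        out <- emit_one(dep, out)
      }
      out[[length(out) + 1L]] <- list(var = tn, rhs = cse$temps[[tn]])
      out
    }
    for (tn in intersect(expr_free_vars(e), names(cse$temps))) {
      out <- emit_one(tn, out)
    }
    out
  }
  for (i in seq_len(na)) {
    new_assigns <- emit_temps_for(cse$exprs[[i]], new_assigns)
    new_assigns[[length(new_assigns) + 1L]] <-
      list(var = assigns[[i]]$var, rhs = cse$exprs[[i]])
  }
  new_rhs <- model$rhs
  for (k in seq_along(rhs)) {
    new_assigns <- emit_temps_for(cse$exprs[[na + k]], new_assigns)
    new_rhs[[k]] <- cse$exprs[[na + k]]
  }
  model$assignments <- new_assigns
  model$rhs <- new_rhs
  model$parameters <- model$parameters[setdiff(names(model$parameters), fixed)]
  model$parameter_units <- model$parameter_units[names(model$parameters)]
  model$pe_temps <- length(cse$temps)
  model$pe_folded <- pmap
  model$cache <- new.env(parent = emptyenv())
  model
}

# ---------------------------------------------------------------------------
# Analytic Jacobian

#' Analytic Jacobian of the full ODE system
#'
#' Exact symbolic partials J[i, j] = d f_i / d v_j over the full state vector
#' v (V included), with common subexpressions across entries extracted into
#' shared temporaries.  Piecewise right-hand sides are differentiated
#' branch-wise.  Non-differentiable constructs (floor/ceiling) raise an error
#' naming the offending expression.
#'
#' @param model an `ode_system`.
#' @return object of class `jacobian_spec`: `vars`, `entries` (n x n list
#'   matrix of expressions), `temps`, `n_temps`, `naive_size` (total node
#'   count of the un-CSE'd entries), and `fn(t, state, i_stim, v_override)`
#'   returning the numeric Jacobian.
#' @export
model_jacobian <- function(model) {
  if (!is.null(model$cache$jacobian)) return(model$cache$jacobian)
  inl <- model_rhs_inlined(model)
  pmap <- as.list(model$parameters)
  vars <- model$state_names
  n <- length(vars)
  raw <- matrix(list(), n, n, dimnames = list(vars, vars))
  for (i in seq_len(n)) {
    fi <- expr_fold(expr_subst(inl[[vars[[i]]]], pmap))
    for (j in seq_len(n)) {
      raw[[i, j]] <- expr_fold(expr_diff(fi, vars[[j]]))
    }
  }
  naive_size <- sum(vapply(raw, expr_size, 1L))
  cse <- expr_cse(as.list(raw), prefix = ".j")
  entries <- matrix(cse$exprs, n, n, dimnames = list(vars, vars))
  fn <- compile_jacobian_fn(model, cse$temps, entries)
  spec <- structure(list(vars = vars, entries = entries, entries_raw = raw,
                         temps = cse$temps, n_temps = length(cse$temps),
                         naive_size = naive_size, fn = fn),
                    class = "jacobian_spec")
  model$cache$jacobian <- spec
  spec
}

expr_size <- function(e) {
  if (!is.call(e)) return(1L)
  1L + sum(vapply(as.list(e)[-1L], expr_size, 1L))
}

compile_jacobian_fn <- function(model, temps, entries) {
  n <- nrow(entries)
  stmts <- list()
  for (tn in names(temps)) {
    stmts[[length(stmts) + 1L]] <- call("<-", as.symbol(tn), temps[[tn]])
  }
  fill <- list()
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      e <- entries[[i, j]]
      if (is_const(e) && e == 0) next
      fill[[length(fill) + 1L]] <-
        call("<-", call("[", as.symbol(".J"), i, j), e)
    }
  }
  body_stmts <- c(
    unpack_state_stmts(model),
    stmts,
    list(call("<-", as.symbol(".J"),
              bquote(matrix(0, .(n), .(n))))),
    fill,
    list(as.symbol(".J")))
  f <- make_eval_fn(model, body_stmts)
  compiler::cmpfun(f)
}

# common preamble: unpack state entries, bind time/stimulus symbols
unpack_state_stmts <- function(model) {
  sn <- model$state_names
  stmts <- list()
  for (i in seq_along(sn)) {
    stmts[[length(stmts) + 1L]] <-
      call("<-", as.symbol(sn[[i]]), call("[[", as.symbol("state"), i))
  }
  v <- model$interface$v
  stmts[[length(stmts) + 1L]] <-
    bquote(if (!is.null(v_override)) .(as.symbol(v)) <- v_override)
  if (!is.na(model$time_var)) {
    stmts[[length(stmts) + 1L]] <- call("<-", as.symbol(model$time_var),
                                        as.symbol("t"))
  }
  if (!is.null(model$interface$stim)) {
    stmts[[length(stmts) + 1L]] <- call("<-", as.symbol(model$interface$stim),
                                        as.symbol("i_stim"))
  }
  stmts
}

make_eval_fn <- function(model, body_stmts, extra_env = list()) {
  env <- new.env(parent = asNamespace("myocyte"))
  for (nm in names(model$parameters)) assign(nm, model$parameters[[nm]], envir = env)
  for (nm in names(extra_env)) assign(nm, extra_env[[nm]], envir = env)
  f <- eval(call("function",
                 as.pairlist(alist(t = , state = , i_stim = 0, v_override = NULL)),
                 as.call(c(as.symbol("{"), body_stmts))),
            env)
  f
}

# ---------------------------------------------------------------------------
# Jacobian overflow hazards

#' Detect overflow hazards in an analytic Jacobian
#'
#' Interval-evaluates every exp() exponent appearing in each Jacobian entry
#' over the annotated variable ranges (the membrane potential defaults to
#' [-100, 80] mV when unannotated; detected gates to [0, 1]).  An entry is
#' flagged when an exponent can exceed the double-precision overflow
#' threshold log(.Machine$double.xmax) ~ 709.8, in which case the entry
#' evaluates to Inf even though the right-hand side itself remains finite
#' under IEEE rules; the report recommends a numeric-Jacobian fallback.
#'
#' @param jac a `jacobian_spec` from [model_jacobian()].
#' @param model the owning `ode_system` (for range annotations).
#' @param extra_bounds named list of c(lo, hi) overriding/extending bounds.
#' @return list with `hazardous` (logical n x n matrix), `details` (per
#'   flagged entry: i, j, exponent expression, interval), and
#'   `recommend_numeric` flag.
#' @export
detect_jacobian_hazards <- function(jac, model, extra_bounds = list()) {
  bounds <- model$annotations$ranges
  v <- model$interface$v
  if (is.null(bounds[[v]]) || !all(is.finite(bounds[[v]]))) {
    bounds[[v]] <- c(-100, 80)
  }
  gates <- tryCatch(names(detect_gates(model)$gates), error = function(e) character(0))
  for (g in gates) if (is.null(bounds[[g]])) bounds[[g]] <- c(0, 1)
  for (nm in names(extra_bounds)) bounds[[nm]] <- extra_bounds[[nm]]
  # cap infinite annotated bounds (e.g. concentrations [0, Inf)) at a finite
  # but generous magnitude so interval arithmetic stays informative
  thresh <- log(.Machine$double.xmax)
  n <- length(jac$vars)
  hazardous <- matrix(FALSE, n, n, dimnames = dimnames(jac$entries))
  details <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (arg in collect_exp_args(jac$entries_raw[[i, j]])) {
        iv <- expr_interval(arg, bounds)
        if (max(abs(iv)) > thresh) {
          hazardous[i, j] <- TRUE
          details[[length(details) + 1L]] <-
            list(i = i, j = j, exponent = arg, interval = iv)
        }
      }
    }
  }
  list(hazardous = hazardous, details = details,
       recommend_numeric = any(hazardous))
}

# ---------------------------------------------------------------------------
# Rush-Larsen rearrangement

# For gate states, prefer the raw (un-inlined) RHS for differentiation when
# no reachable assignment depends on the gate itself; coefficients then stay
# in terms of the cheap assignment variables.
gate_decomposition <- function(model) {
  det <- detect_gates(model)
  assigns <- model$assignments
  anames <- vapply(assigns, function(a) a$var, "")
  # transitive free variables of each assignment
  closure <- list()
  for (a in assigns) {
    fv <- expr_free_vars(a$rhs)
    fv <- unique(c(fv, unlist(closure[intersect(fv, names(closure))])))
    closure[[a$var]] <- fv
  }
  out <- list()
  for (g in names(det$gates)) {
    raw <- model$rhs[[g]]
    fv <- expr_free_vars(raw)
    reach <- unique(c(fv, unlist(closure[intersect(fv, anames)])))
    use_raw <- !any(vapply(intersect(fv, anames),
                           function(a) g %in% closure[[a]], TRUE))
    if (use_raw) {
      a_e <- expr_fold(expr_diff(raw, g))
      b_e <- expr_fold(expr_subst(raw, stats::setNames(list(0), g)))
      out[[g]] <- list(a = a_e, b = b_e,
                       tau = expr_fold(call("/", -1, a_e)),
                       g_inf = expr_fold(call("-", call("/", b_e, a_e))))
    } else {
      out[[g]] <- det$gates[[g]]
    }
  }
  list(gates = out, non_gates = det$non_gates)
}

#' Rush-Larsen rearrangement
#'
#' Splits the states into gates and non-gates and expresses each gate update
#' in the exponential closed form g' = g_inf + (g - g_inf) exp(-dt/tau),
#' with g_inf and tau functions of the frozen voltage and remaining states;
#' non-gates keep their plain right-hand side.  Models with zero gates
#' degrade to forward Euler.
#'
#' @param model an `ode_system`.
#' @return object of class `rl_parts`: `gate_names`, `non_gate_names`,
#'   `gates` (per-gate g_inf/tau expressions) and a compiled
#'   `fn(t, state, i_stim, v_override)` returning
#'   `list(g_inf =, tau =, dnon =)` (aligned to gate/non-gate order).
#' @export
rearrange_rush_larsen <- function(model) {
  if (!is.null(model$cache$rl_parts)) return(model$cache$rl_parts)
  dec <- gate_decomposition(model)
  gate_names <- names(dec$gates)
  non_gates <- dec$non_gates
  stmts <- assignment_stmts(model)
  ginf_v <- lapply(dec$gates, function(g) g$g_inf)
  tau_v <- lapply(dec$gates, function(g) g$tau)
  dnon_v <- lapply(model$rhs[non_gates], identity)
  mkvec <- function(name, exprs) {
    call("<-", as.symbol(name), as.call(c(as.symbol("c"), unname(exprs))))
  }
  body_stmts <- c(
    unpack_state_stmts(model),
    stmts,
    list(if (length(gate_names) > 0L) mkvec(".ginf", ginf_v) else
           quote(.ginf <- numeric(0)),
         if (length(gate_names) > 0L) mkvec(".tau", tau_v) else
           quote(.tau <- numeric(0)),
         if (length(non_gates) > 0L) mkvec(".dnon", dnon_v) else
           quote(.dnon <- numeric(0)),
         quote(list(g_inf = .ginf, tau = .tau, dnon = .dnon))))
  fn <- compiler::cmpfun(make_eval_fn(model, body_stmts))
  parts <- structure(list(gate_names = gate_names, non_gate_names = non_gates,
                          gates = dec$gates, fn = fn, model = model),
                     class = "rl_parts")
  model$cache$rl_parts <- parts
  parts
}

assignment_stmts <- function(model) {
  lapply(model$assignments, function(a) call("<-", as.symbol(a$var), a$rhs))
}

# ---------------------------------------------------------------------------
# Generalized Rush-Larsen linearization

#' Per-variable linearization for the generalized Rush-Larsen schemes
#'
#' For each state u_i computes b_i = f_i(current state) and the diagonal
#' partial a_i = d f_i / d u_i with the other variables frozen.  The scalar
#' update u_i' = u_i + (b_i/a_i)(exp(a_i dt) - 1) is exact on decoupled
#' linear systems; the |a_i| < 1e-8 limit uses u_i + b_i dt to avoid
#' catastrophic cancellation.
#'
#' @param model an `ode_system`.
#' @return object of class `grl_parts` with compiled
#'   `fn(t, state, i_stim, v_override)` returning `list(b =, a =)` aligned
#'   to the state order.
#' @export
grl_linearize <- function(model) {
  if (!is.null(model$cache$grl_parts)) return(model$cache$grl_parts)
  inl <- model_rhs_inlined(model)
  pmap <- as.list(model$parameters)
  diag_exprs <- lapply(model$state_names, function(s) {
    expr_fold(expr_diff(expr_fold(expr_subst(inl[[s]], pmap)), s))
  })
  stmts <- assignment_stmts(model)
  mkvec <- function(name, exprs) {
    call("<-", as.symbol(name), as.call(c(as.symbol("c"), unname(exprs))))
  }
  body_stmts <- c(
    unpack_state_stmts(model),
    stmts,
    list(mkvec(".b", model$rhs),
         mkvec(".a", diag_exprs),
         quote(list(b = .b, a = .a))))
  fn <- compiler::cmpfun(make_eval_fn(model, body_stmts))
  parts <- structure(list(fn = fn, model = model, diag = diag_exprs),
                     class = "grl_parts")
  model$cache$grl_parts <- parts
  parts
}

# ---------------------------------------------------------------------------
# Lookup tables

.expensive_fns <- c("exp", "log", "log10", "tanh")

has_expensive <- function(e) {
  if (!is.call(e)) return(FALSE)
  fn <- as.character(e[[1L]])
  if (fn %in% .expensive_fns) return(TRUE)
  if (fn == "^" && !(is_const(e[[3L]]) && e[[3L]] == round(e[[3L]]))) return(TRUE)
  any(vapply(as.list(e)[-1L], has_expensive, TRUE))
}

#' Default lookup-table specification for the membrane potential
#'
#' V in [-100, 80] mV with 0.01 mV steps; nodes offset from round values by
#' 1e-4 of a step so typical singular points (whole-number voltages) are
#' never sampled exactly.
#'
#' @param term keying annotation term.
#' @param lo,hi,step table range and spacing (keying units).
#' @param offset node offset as a fraction of a step.
#' @return a one-element list of table specs for [build_lookup_tables()].
#' @export
lookup_table_spec <- function(term = "membrane_voltage", lo = -100, hi = 80,
                              step = 0.01, offset = 1e-4) {
  list(list(term = term, lo = lo, hi = hi, step = step, offset = offset))
}

#' Extract lookup tables from a model
#'
#' Replaces every maximal subexpression that depends only on one keying
#' variable (and constants) and contains an expensive function (exp, ln,
#' log, tanh, non-integer power) with linear interpolation into a
#' precomputed node array.  Evaluating with the keying variable outside
#' [lo, hi] is an error naming the variable and value.
#'
#' @param model an `ode_system`.
#' @param specs list of table specs, see [lookup_table_spec()].
#' @return object of class `lookup_table_set`: per-key `spec`, `exprs`
#'   (tabulated expressions), `nodes` (keying positions), `values` (list of
#'   per-expression node values), plus `model` rewritten to call the tables.
#' @export
build_lookup_tables <- function(model, specs = lookup_table_spec()) {
  pmap <- as.list(model$parameters[setdiff(names(model$parameters),
                                           model$annotations$modifiable)])
  keys <- list()
  for (s in specs) {
    var <- find_term_var(model$annotations, s$term)
    if (is.null(var)) {
      stop("no variable annotated '", s$term, "' to key a lookup table",
           call. = FALSE)
    }
    keys[[var]] <- s
  }
  tab_exprs <- stats::setNames(vector("list", length(keys)), names(keys))
  counter <- new.env(parent = emptyenv()); counter$n <- 0L

  admissible <- function(e, key) {
    fv <- setdiff(expr_free_vars(e), names(pmap))
    length(fv) > 0L && all(fv == key) && has_expensive(e)
  }
  rewrite <- function(e) {
    if (!is.call(e)) return(e)
    efold <- expr_fold(expr_subst(e, pmap))
    for (key in names(keys)) {
      if (admissible(efold, key)) {
        kid <- deparse1(efold)
        hit <- match(kid, vapply(tab_exprs[[key]], function(x) x$id, ""))
        if (is.na(hit)) {
          tab_exprs[[key]][[length(tab_exprs[[key]]) + 1L]] <<-
            list(id = kid, expr = efold)
          hit <- length(tab_exprs[[key]])
        }
        return(call(".lut", key, hit, as.symbol(key)))
      }
    }
    for (i in seq_along(e)[-1L]) e[[i]] <- rewrite(e[[i]])
    e
  }
  new_assigns <- lapply(model$assignments, function(a) {
    list(var = a$var, rhs = rewrite(a$rhs))
  })
  new_rhs <- lapply(model$rhs, rewrite)

  tables <- list()
  for (key in names(keys)) {
    s <- keys[[key]]
    k <- seq.int(-1L, ceiling((s$hi - s$lo) / s$step) + 1L)
    nodes <- s$lo + (k + s$offset) * s$step
    values <- lapply(tab_exprs[[key]], function(te) {
      env <- new.env(parent = baseenv())
      assign("piecewise_", piecewise_, envir = env)
      assign(key, nodes, envir = env)
      as.numeric(eval(te$expr, env))
    })
    tables[[key]] <- list(variable = key, term = s$term, lo = s$lo, hi = s$hi,
                          step = s$step, offset = s$offset, nodes = nodes,
                          exprs = lapply(tab_exprs[[key]], function(te) te$expr),
                          values = values)
  }
  model$assignments <- new_assigns
  model$rhs <- new_rhs
  model$lookup_tables <- tables
  model$cache <- new.env(parent = emptyenv())
  structure(list(tables = tables, model = model,
                 n_expressions = sum(vapply(tables, function(t)
                   length(t$values), 1L))),
            class = "lookup_table_set")
}

# runtime interpolation; installed into compiled-evaluator environments
make_lut_fn <- function(tables) {
  function(key, idx, x) {
    tb <- tables[[key]]
    if (any(x < tb$lo | x > tb$hi)) {
      bad <- x[x < tb$lo | x > tb$hi][1]
      stop(structure(class = c("myo_lookup_range_error", "error", "condition"),
                     list(message = sprintf(
                       "lookup table keying variable '%s' = %g outside [%g, %g]",
                       tb$variable, bad, tb$lo, tb$hi),
                       variable = tb$variable, value = bad, call = NULL)))
    }
    pos <- (x - tb$nodes[1]) / tb$step
    i0 <- pmin(pmax(floor(pos), 0), length(tb$nodes) - 2L)
    w <- pos - i0
    v <- tb$values[[idx]]
    v[i0 + 1L] * (1 - w) + v[i0 + 2L] * w
  }
}

#' Export a lookup-table set as JSON
#' @param lts a `lookup_table_set`.
#' @param path optional output file.
#' @return JSON text (invisibly when written).
#' @export
lookup_tables_json <- function(lts, path = NULL) {
  out <- lapply(lts$tables, function(tb) {
    list(variable = tb$variable, term = tb$term, lo = tb$lo, hi = tb$hi,
         step = tb$step, offset = tb$offset,
         expressions = vapply(tb$exprs, deparse1, ""),
         values = tb$values)
  })
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

# ---------------------------------------------------------------------------
# Compilation

# Hoist piecewise_ (scalar mode: if/else chains) and, under overflow_safe,
# 0/0-guarded divisions, into statement position.  Returns list(stmts, expr).
hoist_special <- function(e, state_vars, counter, scalar = TRUE,
                          overflow_safe = FALSE) {
  stmts <- list()
  walk <- function(e) {
    if (!is.call(e)) return(e)
    fn <- as.character(e[[1L]])
    for (i in seq_along(e)[-1L]) e[[i]] <- walk(e[[i]])
    if (fn == "piecewise_" && scalar) {
      counter$n <- counter$n + 1L
      nm <- as.symbol(sprintf(".pw%d", counter$n))
      args <- as.list(e)[-1L]
      n <- length(args)
      chain <- if (n %% 2L == 1L) args[[n]] else NaN
      npair <- n %/% 2L
      for (k in rev(seq_len(npair))) {
        chain <- call("if", args[[2L * k - 1L]], args[[2L * k]], chain)
      }
      stmts[[length(stmts) + 1L]] <<- call("<-", nm, chain)
      return(nm)
    }
    if (fn == "/" && overflow_safe) {
      num <- e[[2L]]; den <- e[[3L]]
      # a shared single symbol (state or hoisted temporary of one) makes the
      # 0/0 limit computable by L'Hopital with respect to that symbol
      shared <- intersect(expr_free_vars(num), expr_free_vars(den))
      if (length(shared) == 1L && is.call(den)) {
        dnum <- tryCatch(expr_diff(num, shared), error = function(err) NULL)
        dden <- tryCatch(expr_diff(den, shared), error = function(err) NULL)
        if (!is.null(dnum) && !is.null(dden)) {
          counter$n <- counter$n + 1L
          nm <- as.symbol(sprintf(".sd%d", counter$n))
          stmts[[length(stmts) + 1L]] <<- call("<-", nm, e)
          guard <- if (scalar) {
            bquote(if (is.nan(.(nm))) .(nm) <- .(dnum) / .(dden))
          } else {
            bquote({
              .bad <- is.nan(.(nm))
              if (any(.bad)) .(nm)[.bad] <- ((.(dnum)) / (.(dden)))[.bad]
            })
          }
          stmts[[length(stmts) + 1L]] <<- guard
          return(nm)
        }
      }
    }
    e
  }
  out <- walk(e)
  list(stmts = stmts, expr = out)
}

#' Compile a model to a fast right-hand-side evaluator
#'
#' Generates a straight-line, byte-compiled closure from the (optionally
#' transformed) expression trees.  With all options off the evaluator agrees
#' with the naive tree-walking evaluator to within a few ulp; lookup tables
#' introduce the documented interpolation error.  Floating overflow never
#' raises: Inf propagates by IEEE rules (so 1/(1 + exp(huge)) evaluates to
#' 0), and with `overflow_safe` removable 0/0 singularities are patched with
#' their L'Hopital limit at evaluation time.
#'
#' @param model an `ode_system`.
#' @param partial_eval apply [partial_evaluate()] first.
#' @param lookup_tables NULL, or table specs for [build_lookup_tables()].
#' @param overflow_safe guard single-variable 0/0 divisions with their
#'   analytic limit.
#' @param vectorized generate a vector evaluator (states as same-length
#'   vectors across tissue nodes; piecewise via elementwise selection).
#' @return object of class `compiled_rhs`: `fn(t, state, i_stim,
#'   v_override)` returning the derivative vector, `i_ion(t, state,
#'   v_override)` returning the total ionic current, plus flags and the
#'   temporaries count.
#' @export
compile_rhs <- function(model, partial_eval = TRUE, lookup_tables = NULL,
                        overflow_safe = FALSE, vectorized = FALSE) {
  m <- model
  if (partial_eval) m <- partial_evaluate(m)
  tables <- NULL
  if (!is.null(lookup_tables)) {
    lts <- build_lookup_tables(m, lookup_tables)
    m <- lts$model
    tables <- lts$tables
  }
  counter <- new.env(parent = emptyenv()); counter$n <- 0L
  scalar <- !vectorized
  stmts <- list()
  emit <- function(var, e) {
    h <- hoist_special(e, m$state_names, counter, scalar = scalar,
                       overflow_safe = overflow_safe)
    stmts[c(length(stmts) + seq_along(h$stmts))] <<- h$stmts
    stmts[[length(stmts) + 1L]] <<- call("<-", as.symbol(var), h$expr)
  }
  for (a in m$assignments) emit(a$var, a$rhs)
  rhs_syms <- character(0)
  for (s in m$state_names) {
    nm <- sprintf(".d_%s", s)
    emit(nm, m$rhs[[s]])
    rhs_syms <- c(rhs_syms, nm)
  }
  v <- m$interface$v
  vi <- match(v, m$state_names)
  out_expr <- if (vectorized) {
    as.call(c(as.symbol("list"), lapply(rhs_syms, as.symbol)))
  } else {
    as.call(c(as.symbol("c"), lapply(rhs_syms, as.symbol)))
  }
  zero_v <- if (vectorized) {
    bquote(if (!is.null(v_override)) .out[[.(vi)]] <- 0 * .out[[.(vi)]])
  } else {
    bquote(if (!is.null(v_override)) .out[.(vi)] <- 0)
  }
  body_stmts <- c(
    unpack_state_stmts(m),
    stmts,
    list(call("<-", as.symbol(".out"), out_expr), zero_v, quote(.out)))
  extra <- list()
  if (!is.null(tables)) extra$.lut <- make_lut_fn(tables)
  fn <- compiler::cmpfun(make_eval_fn(m, body_stmts, extra_env = extra))

  # total ionic current evaluator (stimulus forced to zero)
  cur <- m$interface$currents
  stmts2 <- list()
  stmts2_emit <- function(var, e) {
    h <- hoist_special(e, m$state_names, counter, scalar = scalar,
                       overflow_safe = overflow_safe)
    stmts2[c(length(stmts2) + seq_along(h$stmts))] <<- h$stmts
    stmts2[[length(stmts2) + 1L]] <<- call("<-", as.symbol(var), h$expr)
  }
  for (a in m$assignments) stmts2_emit(a$var, a$rhs)
  isum <- if (length(cur) == 0L) 0 else
    Reduce(function(x, y) call("+", x, y), lapply(cur, as.symbol))
  body2 <- c(unpack_state_stmts(m), stmts2, list(isum))
  i_ion_fn <- compiler::cmpfun(make_eval_fn(m, body2, extra_env = extra))
  i_ion <- function(t, state, v_override = NULL) {
    i_ion_fn(t, state, i_stim = 0, v_override = v_override)
  }

  structure(list(fn = fn, i_ion = i_ion, model = m,
                 state_names = m$state_names,
                 uses_lookup_tables = !is.null(tables),
                 overflow_safe = overflow_safe,
                 vectorized = vectorized,
                 n_temps = counter$n + (m$pe_temps %||% 0L)),
            class = "compiled_rhs")
}

#' @export
print.compiled_rhs <- function(x, ...) {
  cat(sprintf("CompiledRhs for '%s': %d states, %d temporaries%s%s%s\n",
              x$model$name, length(x$state_names), x$n_temps,
              if (x$uses_lookup_tables) ", lookup tables" else "",
              if (x$overflow_safe) ", overflow-safe" else "",
              if (x$vectorized) ", vectorized" else ""))
  invisible(x)
}
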