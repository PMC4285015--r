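# Symbolic expression core.
#
# Model mathematics is represented as base R language objects (calls, symbols,
# numerics).  Piecewise expressions use the n-ary call
# `piecewise_(cond1, val1, cond2, val2, ..., otherwise)` evaluated by
# `piecewise_()` below.  All transforms (differentiation, substitution,
# constant folding, common-subexpression extraction) operate on these trees.

#' Piecewise expression evaluator
#'
#' Evaluates condition/value pairs in order and returns the value of the first
#' satisfied condition, or the trailing default when no condition holds.
#' Scalar and vector arguments are both supported; for vectors the selection
#' is elementwise.
#'
#' @param ... alternating condition, value arguments, with an optional final
#'   unpaired default value.
#' @return the selected value(s).
#' @export
piecewise_ <- function(...) {
  args <- list(...)
  n <- length(args)
  has_default <- n %% 2L == 1L
  npair <- n %/% 2L
  lens <- vapply(args, length, 1L)
  if (max(lens) == 1L) {
    for (k in seq_len(npair)) {
      if (isTRUE(args[[2L * k - 1L]])) return(args[[2L * k]])
    }
    if (has_default) return(args[[n]])
    return(NaN)
  }
  m <- max(lens)
  out <- rep(if (has_default) NaN else NaN, m)
  chosen <- rep(FALSE, m)
  for (k in seq_len(npair)) {
    cond <- rep_len(as.logical(args[[2L * k - 1L]]), m)
    val <- rep_len(args[[2L * k]], m)
    sel <- cond & !chosen
    out[sel] <- val[sel]
    chosen <- chosen | cond
  }
  if (has_default) {
    dflt <- rep_len(args[[n]], m)
    out[!chosen] <- dflt[!chosen]
  }
  out
}

is_const <- function(e) is.numeric(e) || is.logical(e)

is_call_to <- function(e, name) is.call(e) && identical(as.character(e[[1L]]), name)

#' @noRd
expr_free_vars <- function(e) {
  if (is.symbol(e)) return(as.character(e))
  if (is.call(e)) {
    args <- as.list(e)[-1L]
    return(unique(unlist(lapply(args, expr_free_vars), use.names = FALSE)))
  }
  character(0)
}

# Substitute symbols by expressions/values given as a named list.
expr_subst <- function(e, mapping) {
  if (is.symbol(e)) {
    nm <- as.character(e)
    if (nm %in% names(mapping)) {
      v <- mapping[[nm]]
      if (is.numeric(v) || is.language(v)) return(v)
      stop("substitution value for '", nm, "' must be numeric or a language object")
    }
    return(e)
  }
  if (is.call(e)) {
    for (i in seq_along(e)[-1L]) e[[i]] <- expr_subst(e[[i]], mapping)
    return(e)
  }
  e
}

# Pure numeric functions safe to fold at transform time.
.foldable_fns <- c("+", "-", "*", "/", "^", "exp", "log", "log10", "log2",
                   "sqrt", "abs", "tanh", "sign", "floor", "ceiling",
                   "(", "<", ">", "<=", ">=", "==", "!=", "&", "|", "!")

#' @noRd
expr_fold <- function(e) {
  if (!is.call(e)) return(e)
  fn <- as.character(e[[1L]])
  for (i in seq_along(e)[-1L]) e[[i]] <- expr_fold(e[[i]])
  args <- as.list(e)[-1L]
  if (fn %in% .foldable_fns && length(args) > 0L && all(vapply(args, is_const, TRUE))) {
    v <- suppressWarnings(eval(e, baseenv()))
    if (is.numeric(v) && length(v) == 1L && is.finite(v)) return(v)
    return(e)
  }
  if (fn == "(") return(e[[2L]])
  if (fn == "piecewise_") {
    n <- length(args)
    vals <- args[seq_len(n) %% 2L == 0L]
    if (n %% 2L == 1L) vals <- c(vals, args[n])
    if (length(vals) > 0L && all(vapply(vals, is_const, TRUE)) &&
        length(unique(unlist(vals))) == 1L) {
      return(vals[[1L]])
    }
    return(e)
  }
  simplify_node(e)
}

# Local algebraic identities; operates on a single call whose children are
# already folded.
simplify_node <- function(e) {
  fn <- as.character(e[[1L]])
  a <- if (length(e) >= 2L) e[[2L]] else NULL
  b <- if (length(e) >= 3L) e[[3L]] else NULL
  num0 <- function(x) is_const(x) && length(x) == 1L && x == 0
  num1 <- function(x) is_const(x) && length(x) == 1L && x == 1
  if (fn == "+" && length(e) == 3L) {
    if (num0(a)) return(b)
    if (num0(b)) return(a)
  } else if (fn == "-" && length(e) == 3L) {
    if (num0(b)) return(a)
    if (num0(a)) return(call("-", b))
  } else if (fn == "*" && length(e) == 3L) {
    if (num0(a) || num0(b)) return(0)
    if (num1(a)) return(b)
    if (num1(b)) return(a)
  } else if (fn == "/" && length(e) == 3L) {
    if (num0(a)) return(0)
    if (num1(b)) return(a)
  } else if (fn == "^" && length(e) == 3L) {
    if (num1(b)) return(a)
    if (num0(b)) return(1)
    if (num1(a)) return(1)
  } else if (fn == "-" && length(e) == 2L) {
    if (is_const(a)) return(-a)
  }
  e
}

mk <- function(fn, ...) expr_fold(as.call(c(as.symbol(fn), list(...))))

#' Symbolic derivative
#'
#' Differentiates an expression tree with respect to one variable.  Supported
#' operators: arithmetic, `^`, `exp`, `log`, `log10`, `sqrt`, `abs`, `tanh`
#' and `piecewise_` (differentiated branch-wise; at a boundary the convention
#' of the first satisfied branch applies).  `floor`/`ceiling` are rejected as
#' non-differentiable.
#'
#' @param e expression (language object or numeric).
#' @param var variable name (character).
#' @return the derivative expression, constant-folded.
#' @export
expr_diff <- function(e, var) {
  if (is_const(e)) return(0)
  if (is.symbol(e)) return(if (identical(as.character(e), var)) 1 else 0)
  stopifnot(is.call(e))
  fn <- as.character(e[[1L]])
  d <- function(x) expr_diff(x, var)
  if (fn == "(") return(d(e[[2L]]))
  if (fn == "+" && length(e) == 3L) return(mk("+", d(e[[2L]]), d(e[[3L]])))
  if (fn == "+" && length(e) == 2L) return(d(e[[2L]]))
  if (fn == "-" && length(e) == 3L) return(mk("-", d(e[[2L]]), d(e[[3L]])))
  if (fn == "-" && length(e) == 2L) return(mk("-", d(e[[2L]])))
  if (fn == "*") {
    u <- e[[2L]]; v <- e[[3L]]
    return(mk("+", mk("*", d(u), v), mk("*", u, d(v))))
  }
  if (fn == "/") {
    u <- e[[2L]]; v <- e[[3L]]
    return(mk("-", mk("/", d(u), v), mk("/", mk("*", u, d(v)), mk("^", v, 2))))
  }
  if (fn == "^") {
    u <- e[[2L]]; v <- e[[3L]]
    if (is_const(v)) {
      return(mk("*", mk("*", v, mk("^", u, v - 1)), d(u)))
    }
    # general power: u^v * (dv*log(u) + v*du/u)
    return(mk("*", e, mk("+", mk("*", d(v), mk("log", u)),
                         mk("/", mk("*", v, d(u)), u))))
  }
  if (fn == "exp") return(mk("*", e, d(e[[2L]])))
  if (fn == "log" && length(e) == 2L) return(mk("/", d(e[[2L]]), e[[2L]]))
  if (fn == "log10") return(mk("/", d(e[[2L]]), mk("*", e[[2L]], log(10))))
  if (fn == "sqrt") return(mk("/", d(e[[2L]]), mk("*", 2, e)))
  if (fn == "abs") return(mk("*", mk("sign", e[[2L]]), d(e[[2L]])))
  if (fn == "tanh") return(mk("*", mk("-", 1, mk("^", e, 2)), d(e[[2L]])))
  if (fn == "piecewise_") {
    args <- as.list(e)[-1L]
    n <- length(args)
    out <- vector("list", n)
    npair <- n %/% 2L
    for (k in seq_len(npair)) {
      out[[2L * k - 1L]] <- args[[2L * k - 1L]]
      out[[2L * k]] <- d(args[[2L * k]])
    }
    if (n %% 2L == 1L) out[[n]] <- d(args[[n]])
    return(as.call(c(as.symbol("piecewise_"), out)))
  }
  if (fn %in% c("floor", "ceiling")) {
    stop("cannot differentiate non-smooth expression: ", deparse1(e), call. = FALSE)
  }
  stop("cannot differentiate unsupported operator '", fn, "' in: ", deparse1(e),
       call. = FALSE)
}

# Canonical ordering of commutative operands (by deparsed text) so that
# syntactic CSE is reproducible and insensitive to authoring order.
expr_canonicalize <- function(e) {
  if (!is.call(e)) return(e)
  for (i in seq_along(e)[-1L]) e[[i]] <- expr_canonicalize(e[[i]])
  fn <- as.character(e[[1L]])
  if (fn %in% c("+", "*") && length(e) == 3L) {
    ka <- deparse1(e[[2L]]); kb <- deparse1(e[[3L]])
    if (kb < ka) {
      tmp <- e[[2L]]; e[[2L]] <- e[[3L]]; e[[3L]] <- tmp
    }
  }
  e
}

#' Common-subexpression extraction
#'
#' Hash-consing of syntactic subtrees (after canonical ordering of commutative
#' operands).  Any non-trivial subtree occurring at least twice across the
#' input expressions is hoisted into a shared temporary.
#'
#' @param exprs named list of expressions.
#' @param prefix name prefix for generated temporaries.
#' @return list with `temps` (named list of temporary definitions, in
#'   evaluation order) and `exprs` (the rewritten input expressions).
#' @export
expr_cse <- function(exprs, prefix = "tmp_") {
  exprs <- lapply(exprs, expr_canonicalize)
  counts <- new.env(parent = emptyenv())
  tally <- function(e) {
    if (!is.call(e)) return(invisible())
    key <- deparse1(e)
    n <- if (is.null(counts[[key]])) 0L else counts[[key]]
    counts[[key]] <- n + 1L
    # count children once per distinct occurrence of the parent
    for (i in seq_along(e)[-1L]) tally(e[[i]])
    invisible()
  }
  for (e in exprs) tally(e)
  temp_map <- new.env(parent = emptyenv())  # key -> temp symbol
  temps <- list()
  idx <- 0L
  rewrite <- function(e) {
    if (!is.call(e)) return(e)
    key <- deparse1(e)
    if (!is.null(temp_map[[key]])) return(temp_map[[key]])
    for (i in seq_along(e)[-1L]) e[[i]] <- rewrite(e[[i]])
    cnt <- counts[[key]]
    worth <- !is.null(cnt) && cnt >= 2L &&
      !identical(as.character(e[[1L]]), "(")
    if (worth) {
      idx <<- idx + 1L
      nm <- paste0(prefix, idx)
      temps[[nm]] <<- e
      sym <- as.symbol(nm)
      temp_map[[key]] <- sym
      return(sym)
    }
    e
  }
  out <- lapply(exprs, rewrite)
  list(temps = temps, exprs = out)
}

# Interval arithmetic over expression trees; intervals as c(lo, hi).
# Used by the Jacobian overflow-hazard detector.  Unknown symbols map to the
# supplied default interval.
expr_interval <- function(e, bounds, default = c(-Inf, Inf)) {
  iv <- function(lo, hi) c(min(lo, hi), max(lo, hi))
  if (is_const(e)) return(c(e, e))
  if (is.symbol(e)) {
    nm <- as.character(e)
    if (nm %in% names(bounds)) return(as.numeric(bounds[[nm]]))
    return(default)
  }
  fn <- as.character(e[[1L]])
  a <- if (length(e) >= 2L) expr_interval(e[[2L]], bounds, default)
  b <- if (length(e) >= 3L) expr_interval(e[[3L]], bounds, default)
  switch(fn,
    "(" = a,
    "+" = if (length(e) == 2L) a else c(a[1] + b[1], a[2] + b[2]),
    "-" = if (length(e) == 2L) iv(-a[2], -a[1]) else c(a[1] - b[2], a[2] - b[1]),
    "*" = {
      p <- c(a[1] * b[1], a[1] * b[2], a[2] * b[1], a[2] * b[2])
      p[is.nan(p)] <- 0
      range(p)
    },
    "/" = {
      if (b[1] <= 0 && b[2] >= 0) return(c(-Inf, Inf))
      p <- c(a[1] / b[1], a[1] / b[2], a[2] / b[1], a[2] / b[2])
      p[is.nan(p)] <- 0
      range(p)
    },
    "^" = {
      if (is_const(e[[3L]]) && e[[3L]] == round(e[[3L]]) && e[[3L]] >= 0) {
        p <- c(a[1]^e[[3L]], a[2]^e[[3L]])
        if (e[[3L]] %% 2 == 0 && a[1] < 0 && a[2] > 0) p <- c(0, p)
        range(p)
      } else c(-Inf, Inf)
    },
    "exp" = exp(a),
    "log" = if (a[1] <= 0) c(-Inf, log(max(a[2], 0))) else log(a),
    "sqrt" = sqrt(pmax(a, 0)),
    "abs" = if (a[1] <= 0 && a[2] >= 0) c(0, max(abs(a))) else range(abs(a)),
    "tanh" = tanh(a),
    "piecewise_" = {
      args <- as.list(e)[-1L]
      n <- length(args)
      vals <- args[seq_along(args) %% 2L == 0L]
      if (n %% 2L == 1L) vals <- c(vals, args[n])
      ivs <- lapply(vals, expr_interval, bounds = bounds, default = default)
      range(unlist(ivs))
    },
    c(-Inf, Inf)
  )
}

# Collect all exp() argument subexpressions in a tree.
collect_exp_args <- function(e) {
  out <- list()
  walk <- function(x) {
    if (!is.call(x)) return(invisible())
    if (identical(as.character(x[[1L]]), "exp")) out[[length(out) + 1L]] <<- x[[2L]]
    for (i in seq_along(x)[-1L]) walk(x[[i]])
    invisible()
  }
  walk(e)
  out
}
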