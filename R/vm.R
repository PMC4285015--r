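# Assembler for the compiled-evaluator virtual machine (src/vm.c).
#
# The partially evaluated model is flattened into a linear instruction tape
# over a register file: registers 0..(n_states-1) hold the state, then time
# and the stimulus current, then one register per instruction result.  The
# adaptive solver drives its right-hand-side (and analytic Jacobian)
# evaluations through this tape, avoiding interpreted-R cost in the hot
# loop.  Agreement with the naive tree-walking evaluator is part of the test
# suite.

.vm_ops <- c(CONST = 1L, ADD = 2L, SUB = 3L, MUL = 4L, DIV = 5L, NEG = 6L,
             POW = 7L, EXP = 8L, LOG = 9L, LOG10 = 10L, SQRT = 11L,
             ABS = 12L, TANH = 13L, FLOOR = 14L, CEIL = 15L, SIGN = 16L,
             LT = 17L, GT = 18L, LE = 19L, GE = 20L, EQ = 21L, NE = 22L,
             AND = 23L, OR = 24L, NOT = 25L, SEL = 26L)

.vm_fnmap <- c("+" = "ADD", "-" = "SUB", "*" = "MUL", "/" = "DIV",
               "^" = "POW", exp = "EXP", log = "LOG", log10 = "LOG10",
               sqrt = "SQRT", abs = "ABS", tanh = "TANH", floor = "FLOOR",
               ceiling = "CEIL", sign = "SIGN",
               "<" = "LT", ">" = "GT", "<=" = "LE", ">=" = "GE",
               "==" = "EQ", "!=" = "NE", "&" = "AND", "|" = "OR", "!" = "NOT")

# Tape for the model right-hand side: inputs are the state vector, time and
# the stimulus current; every parameter is folded (the tape is specialized
# to the current parameter values and rebuilt if they change).
vm_rhs_tape <- function(model) {
  if (!is.null(model$cache$vm_rhs)) return(model$cache$vm_rhs)
  sn <- model$state_names
  inputs <- as.list(stats::setNames(seq_along(sn) - 1L, sn))
  ipos <- length(sn)
  if (!is.na(model$time_var)) {
    inputs[[model$time_var]] <- ipos
  }
  ipos <- ipos + 1L
  if (!is.null(model$interface$stim)) {
    inputs[[model$interface$stim]] <- ipos
  }
  n_in <- length(sn) + 2L  # state..., time, i_stim (slots always reserved)
  pmap <- as.list(model$parameters)
  statements <- lapply(model$assignments, function(a) {
    list(var = a$var, rhs = expr_fold(expr_subst(a$rhs, pmap)))
  })
  outputs <- lapply(model$rhs, function(e) expr_fold(expr_subst(e, pmap)))
  tape <- vm_assemble(statements, outputs, inputs, n_in)
  model$cache$vm_rhs <- tape
  tape
}

vm_assemble <- function(statements, outputs, inputs, n_in) {
  # assemble statements + outputs into a tape; `inputs` maps symbol -> 0-based
  # register; n_in reserves the input register block
  tape <- local({
    consts <- numeric(0)
    const_map <- new.env(parent = emptyenv())
    rows <- list()
    nreg <- n_in
    defined <- inputs
    const_reg <- function(v) {
      key <- sprintf("%.17g", v)
      if (!is.null(const_map[[key]])) return(const_map[[key]])
      consts[[length(consts) + 1L]] <<- v
      r <- nreg; nreg <<- nreg + 1L
      rows[[length(rows) + 1L]] <<-
        c(.vm_ops[["CONST"]], length(consts) - 1L, 0L, 0L, r)
      const_map[[key]] <- r
      r
    }
    emit <- function(opname, a, b = 0L, c = 0L) {
      r <- nreg; nreg <<- nreg + 1L
      rows[[length(rows) + 1L]] <<- c(.vm_ops[[opname]], a, b, c, r)
      r
    }
    compile_expr <- function(e) {
      if (is_const(e)) return(const_reg(as.numeric(e)))
      if (is.symbol(e)) {
        nm <- as.character(e)
        r <- defined[[nm]]
        if (is.null(r)) stop("VM assembler: unbound symbol '", nm, "'", call. = FALSE)
        return(r)
      }
      stopifnot(is.call(e))
      fn <- as.character(e[[1L]])
      if (fn == "(") return(compile_expr(e[[2L]]))
      if (fn == "piecewise_") {
        args <- as.list(e)[-1L]
        n <- length(args)
        npair <- n %/% 2L
        acc <- if (n %% 2L == 1L) compile_expr(args[[n]]) else const_reg(NaN)
        for (k in rev(seq_len(npair))) {
          cond <- compile_expr(args[[2L * k - 1L]])
          val <- compile_expr(args[[2L * k]])
          acc <- emit("SEL", val, acc, cond)
        }
        return(acc)
      }
      if (fn == "-" && length(e) == 2L) return(emit("NEG", compile_expr(e[[2L]])))
      if (fn == "+" && length(e) == 2L) return(compile_expr(e[[2L]]))
      if (!fn %in% names(.vm_fnmap)) {
        stop("VM assembler: unsupported operator '", fn, "'", call. = FALSE)
      }
      a <- compile_expr(e[[2L]])
      if (length(e) == 2L) return(emit(.vm_fnmap[[fn]], a))
      b <- compile_expr(e[[3L]])
      emit(.vm_fnmap[[fn]], a, b)
    }
    for (st in statements) defined[[st$var]] <- compile_expr(st$rhs)
    out_idx <- vapply(outputs, compile_expr, 0L)
    ops <- do.call(rbind, rows)
    storage.mode(ops) <- "integer"
    list(ops = ops, consts = as.numeric(consts), nreg = as.integer(nreg),
         out_idx = as.integer(out_idx), n_inputs = n_in)
  })
  tape
}

# Evaluate a tape (thin wrapper; hot paths inline the .Call).
vm_eval <- function(tape, inputs) {
  .Call(myo_vm_eval, tape$ops, tape$consts, as.numeric(inputs), tape$nreg,
        tape$out_idx)
}

# Tape for the analytic Jacobian: outputs are the n^2 entries (column-major).
vm_jac_tape <- function(model) {
  if (!is.null(model$cache$vm_jac)) return(model$cache$vm_jac)
  jac <- model_jacobian(model)
  sn <- model$state_names
  n <- length(sn)
  inputs <- as.list(stats::setNames(seq_along(sn) - 1L, sn))
  if (!is.na(model$time_var)) inputs[[model$time_var]] <- length(sn)
  if (!is.null(model$interface$stim)) inputs[[model$interface$stim]] <- length(sn) + 1L
  statements <- lapply(names(jac$temps), function(nm) {
    list(var = nm, rhs = jac$temps[[nm]])
  })
  outputs <- as.list(jac$entries)  # column-major
  tape <- vm_assemble(statements, outputs, inputs, n + 2L)
  tape$n <- n
  model$cache$vm_jac <- tape
  tape
}
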