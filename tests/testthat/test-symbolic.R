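# Symbolic transforms: partial evaluation, Jacobians, hazards, RL/GRL
# rearrangements, lookup tables, compilation.

test_that("partial evaluation preserves the right-hand side exactly", {
  m <- cached_model("luo_rudy_1991")
  pe <- partial_evaluate(m)
  y0 <- initial_state(m)
  set.seed(5)
  for (k in 1:50) {
    y <- y0 * (1 + 0.3 * stats::runif(length(y0), -1, 1))
    y[[1]] <- stats::runif(1, -90, 40)
    a <- eval_rhs(pe, 0, y, i_stim = -5)
    b <- eval_rhs(m, 0, y, i_stim = -5)
    expect_lt(max(abs(a - b) / (1 + abs(b))), 1e-10)
  }
  # shared subexpressions were hoisted
  expect_gt(pe$pe_temps, 0)
})

test_that("thermodynamic constants fold to a single precomputed number", {
  # R*T/F appears three times across the Nernst potentials; after partial
  # evaluation no reference to the gas constant survives
  m <- cached_model("luo_rudy_1991")
  pe <- partial_evaluate(m)
  all_text <- paste(vapply(pe$assignments, function(a) deparse1(a$rhs), ""),
                    collapse = " ")
  expect_false(grepl("R_const|T_const|F_const", all_text))
  # the folded Nernst prefactor appears as a plain number
  e_na <- pe$assignments[[which(vapply(pe$assignments, function(a) a$var, "") == "E_Na")]]
  expect_true(is_call_to(e_na$rhs, "*") || is.numeric(e_na$rhs))
})

test_that("a model with no shared terms gains no temporaries", {
  doc <- make_linear_relax_doc()
  m <- convert_cellml(doc)$model
  pe <- partial_evaluate(m)
  expect_equal(pe$pe_temps, 0L)
  y <- initial_state(m)
  expect_equal(eval_rhs(pe, 0, y), eval_rhs(m, 0, y))
})

test_that("the analytic Jacobian matches central finite differences", {
  for (nm in c("hodgkin_huxley", "luo_rudy_1991")) {
    m <- cached_model(nm)
    jac <- model_jacobian(m)
    y0 <- initial_state(m)
    ns <- length(y0)
    set.seed(23)
    worst <- 0
    for (k in 1:100) {
      y <- y0 * (1 + 0.2 * stats::runif(ns, -1, 1))
      y[[1]] <- stats::runif(1, -85, 30)
      # keep away from the piecewise boundary at V = -40 (one-sided
      # derivatives differ by convention) and from the removable
      # singularity at V = -77 (the FD oracle itself breaks down there)
      if (nm == "luo_rudy_1991" && abs(y[[1]] + 40) < 1) y[[1]] <- -50
      if (nm == "luo_rudy_1991" && abs(y[[1]] + 77) < 1.5) y[[1]] <- -60
      J <- jac$fn(0, y, 0, NULL)
      Jfd <- matrix(0, ns, ns)
      for (j in seq_len(ns)) {
        # step scaled to the component (Cai lives at ~2e-4 mM)
        h <- max(1e-6 * abs(y[[j]]), 1e-9)
        yp <- y; ym <- y
        yp[[j]] <- yp[[j]] + h
        ym[[j]] <- ym[[j]] - h
        Jfd[, j] <- (eval_rhs(m, 0, yp) - eval_rhs(m, 0, ym)) / (2 * h)
      }
      worst <- max(worst, max(abs(J - Jfd) / (1 + abs(Jfd))))
    }
    expect_lt(worst, 1e-6)
    # CSE pays: shared temporaries shrink the total expression size
    expect_lt(jac$n_temps, jac$naive_size)
    expect_gt(jac$n_temps, 0)
  }
})

test_that("a linear system's Jacobian is its coefficient matrix", {
  doc <- make_linear_relax_doc(g = 0.25)
  m <- convert_cellml(doc)$model
  jac <- model_jacobian(m)
  J <- jac$fn(0, initial_state(m), 0, NULL)
  expect_equal(J, matrix(-0.25, 1, 1), tolerance = 1e-12)
})

test_that("non-differentiable right-hand sides are rejected with the expression named", {
  doc <- make_linear_relax_doc()
  doc2 <- sub("<apply><minus/><ci>V</ci><ci>E_leak</ci></apply>",
              "<apply><minus/><apply><floor/><ci>V</ci></apply><ci>E_leak</ci></apply>",
              doc, fixed = TRUE)
  expect_false(identical(doc2, doc))
  m <- convert_cellml(doc2)$model
  expect_error(model_jacobian(m), "floor")
})

test_that("overflow hazards are flagged for steep exponents and nowhere else", {
  ms <- cached_model("singularity")
  hz <- detect_jacobian_hazards(model_jacobian(ms), ms)
  expect_true(hz$recommend_numeric)
  # the hazardous entries involve the calcium-driven sigmoid
  expect_true(any(vapply(hz$details, function(d)
    "c" %in% expr_free_vars(d$exponent), TRUE)))

  mh <- cached_model("hodgkin_huxley")
  hz2 <- detect_jacobian_hazards(model_jacobian(mh), mh)
  expect_false(hz2$recommend_numeric)

  # constant Jacobian: nothing to flag
  ml <- convert_cellml(make_linear_relax_doc())$model
  hz3 <- detect_jacobian_hazards(model_jacobian(ml), ml)
  expect_false(hz3$recommend_numeric)
})

test_that("Rush-Larsen rearrangement reproduces the textbook decomposition", {
  m <- cached_model("hodgkin_huxley")
  parts <- rearrange_rush_larsen(m)
  expect_setequal(parts$gate_names, c("m", "h", "n"))
  y <- initial_state(m)
  p <- parts$fn(0, y, 0, NULL)
  # dg/dt = alpha (1-g) - beta g <=> g_inf = alpha/(alpha+beta),
  # tau = 1/(alpha+beta); check against directly evaluated rates
  V <- y[["V"]]
  am <- -0.1 * (V + 50) / (exp(-(V + 50) / 10) - 1)
  bm <- 4 * exp(-(V + 75) / 18)
  i <- match("m", parts$gate_names)
  expect_equal(p$g_inf[i], am / (am + bm), tolerance = 1e-12)
  expect_equal(p$tau[i], 1 / (am + bm), tolerance = 1e-12)
})

test_that("GRL linearization is exact on linear problems and O(dt^2) on logistic", {
  # du/dt = -u: one GRL1 step of any size is exact
  doc <- make_linear_relax_doc(g = 1, E = 0, v0 = 1)
  m <- convert_cellml(doc)$model
  parts <- grl_linearize(m)
  for (dt in c(0.1, 1, 7)) {
    y1 <- step_grl1(parts, 0, initial_state(m), dt)
    expect_equal(y1[["V"]], exp(-dt), tolerance = 1e-12)
  }
  # du/dt = c (a = 0 limit): u' = u0 + c dt
  doc0 <- make_linear_relax_doc(drift = TRUE)
  m0 <- convert_cellml(doc0)$model
  p0 <- grl_linearize(m0)
  y1 <- step_grl1(p0, 0, initial_state(m0), 2)
  expect_equal(y1[["V"]], initial_state(m0)[["V"]] - 0.02 * 2, tolerance = 1e-12)
})

test_that("lookup tables honour the interpolation error bound for exp(V)", {
  spec <- lookup_table_spec(lo = -100, hi = 80, step = 0.05)
  s <- spec[[1]]
  k <- seq.int(-1L, ceiling((s$hi - s$lo) / s$step) + 1L)
  nodes <- s$lo + (k + s$offset) * s$step
  vals <- exp(nodes)
  probe <- seq(-100, 80, length.out = 20001)
  pos <- (probe - nodes[1]) / s$step
  i0 <- pmin(pmax(floor(pos), 0), length(nodes) - 2L)
  w <- pos - i0
  approxv <- vals[i0 + 1L] * (1 - w) + vals[i0 + 2L] * w
  # linear interpolation error <= step^2 * max|f''| / 8 on each interval
  bound <- s$step^2 * exp(pmax(nodes[i0 + 2L], probe)) / 8
  expect_true(all(abs(approxv - exp(probe)) <= bound * (1 + 1e-9)))
})

test_that("lookup-table extraction tabulates only single-variable expensive terms", {
  m <- cached_model("hodgkin_huxley")
  lts <- build_lookup_tables(m, lookup_table_spec(step = 0.01))
  expect_gt(lts$n_expressions, 0)
  # every tabulated expression depends on V alone
  for (e in lts$tables$V$exprs) {
    expect_equal(expr_free_vars(e), "V")
  }
  # node positions are never integral voltages (offset property)
  expect_true(all(abs(lts$tables$V$nodes - round(lts$tables$V$nodes)) > 1e-9))
  # i_Na = g m^3 h (V - E) depends on V and gates jointly: never tabulated
  rewritten <- paste(vapply(lts$model$assignments, function(a) deparse1(a$rhs), ""),
                     collapse = " ")
  ina <- lts$model$assignments[[which(vapply(lts$model$assignments,
                                             function(a) a$var, "") == "i_Na")]]
  expect_false(grepl(".lut", deparse1(ina$rhs), fixed = TRUE))
})

test_that("compiled evaluators with tables stay within the table error bound", {
  m <- cached_model("hodgkin_huxley")
  cmp <- compile_rhs(m, lookup_tables = lookup_table_spec(step = 0.01))
  expect_true(cmp$uses_lookup_tables)
  y0 <- initial_state(m)
  set.seed(3)
  for (k in 1:50) {
    y <- y0
    y[["V"]] <- stats::runif(1, -99, 79)
    a <- cmp$fn(0, y, 0, NULL)
    b <- eval_rhs(m, 0, y)
    expect_lt(max(abs(a - b)), 1e-3)
  }
  # out of range: error names the variable and offending value
  ybad <- y0; ybad[["V"]] <- 100
  err <- tryCatch(cmp$fn(0, ybad, 0, NULL), error = function(e) e)
  expect_s3_class(err, "myo_lookup_range_error")
  expect_match(conditionMessage(err), "'V' = 100")
})

test_that("lookup tables export to JSON and re-import identically", {
  m <- cached_model("toy_gate")
  lts <- build_lookup_tables(m, lookup_table_spec(lo = -90, hi = 60, step = 0.5))
  path <- tempfile(fileext = ".json")
  lookup_tables_json(lts, path)
  back <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(back$V$lo, -90)
  expect_equal(unlist(back$V$values[[1]]), lts$tables$V$values[[1]],
               tolerance = 1e-12)
})

test_that("compilation is deterministic and option-transparent", {
  m <- cached_model("luo_rudy_1991")
  y0 <- initial_state(m)
  c1 <- compile_rhs(m, partial_eval = TRUE)
  c2 <- compile_rhs(m, partial_eval = TRUE)
  set.seed(9)
  for (k in 1:20) {
    y <- y0 * (1 + 0.25 * stats::runif(length(y0), -1, 1))
    expect_identical(c1$fn(3, y, -7, NULL), c2$fn(3, y, -7, NULL))
  }
  # options off vs on (no tables): ulp-level agreement with the naive path
  c0 <- compile_rhs(m, partial_eval = FALSE)
  for (k in 1:20) {
    y <- y0 * (1 + 0.25 * stats::runif(length(y0), -1, 1))
    a <- c0$fn(0, y, 0, NULL)
    b <- c1$fn(0, y, 0, NULL)
    expect_lt(max(abs(a - b) / (1 + abs(b))), 1e-10)
  }
})

test_that("IEEE overflow propagates benignly: 1/(1 + exp(huge)) is 0", {
  ms <- cached_model("singularity")
  cmp <- compile_rhs(ms)
  y <- initial_state(ms)
  y[["c"]] <- 0.049  # exponent ~ 1940: exp overflows to Inf
  d <- cmp$fn(0, y, 0, NULL)
  expect_true(all(is.finite(d)))
  # r_inf itself evaluated to exactly 0
  expect_equal(get_any_variable(ms, y, 0, "r_inf"), 0)
})

test_that("overflow-safe compilation patches removable 0/0 singularities", {
  ms <- cached_model("singularity")
  y40 <- initial_state(ms)
  y40[["V"]] <- 40  # alpha_g hits 0/0 exactly
  unsafe <- compile_rhs(ms, overflow_safe = FALSE)
  expect_true(any(is.nan(unsafe$fn(0, y40, 0, NULL))))
  safe <- compile_rhs(ms, overflow_safe = TRUE)
  d <- safe$fn(0, y40, 0, NULL)
  expect_true(all(is.finite(d)))
  # the patched value is the analytic limit: alpha_g -> 0.1/0.25
  dg <- d[[match("g", safe$state_names)]]
  g0 <- y40[["g"]]
  beta <- 0.15 * exp(-40 / 30)
  expect_equal(dg, 0.4 * (1 - g0) - beta * g0, tolerance = 1e-10)
})

test_that("the VM tape agrees with the naive evaluator everywhere", {
  for (nm in c("hodgkin_huxley", "luo_rudy_1991", "singularity")) {
    m <- cached_model(nm)
    tape <- myocyte:::vm_rhs_tape(m)
    y0 <- initial_state(m)
    set.seed(31)
    for (k in 1:60) {
      y <- y0 * (1 + 0.3 * stats::runif(length(y0), -1, 1))
      y[[1]] <- stats::runif(1, -95, 45)
      t <- stats::runif(1, 0, 500)
      a <- myocyte:::vm_eval(tape, c(y, t, -4))
      b <- eval_rhs(m, t, y, i_stim = -4)
      expect_lt(max(abs(a - b) / (1 + abs(b))), 1e-12)
    }
    jt <- myocyte:::vm_jac_tape(m)
    n <- length(y0)
    Jvm <- matrix(myocyte:::vm_eval(jt, c(y0, 0, 0)), n, n)
    Jr <- model_jacobian(m)$fn(0, y0, 0, NULL)
    expect_equal(Jvm, Jr, tolerance = 1e-14)
  }
})
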