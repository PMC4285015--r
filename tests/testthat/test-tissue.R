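# 1D monodomain strand: operators, splitting, activation analysis.

test_that("the stiffness operator conserves current and kills constants", {
  mesh <- mesh1d(0.02, 0.01)   # 3 nodes
  ops <- assemble_operators(mesh, sigma = 1.75)
  expect_equal(rowSums(ops$K), rep(0, 3), tolerance = 1e-14)
  v <- rep(-83.4, 3)
  expect_equal(as.numeric(ops$K %*% v), rep(0, 3), tolerance = 1e-12)
  expect_equal(sum(ops$M), 0.02, tolerance = 1e-14)
})

test_that("K/M approximates sigma V'' to second order on a quadratic field", {
  sigma <- 1.75
  for (h in c(0.02, 0.01, 0.005)) {
    mesh <- mesh1d(1, h)
    ops <- assemble_operators(mesh, sigma)
    x <- mesh$positions
    v <- 3 * x^2 - x          # V'' = 6
    lap <- -as.numeric(ops$K %*% v) / ops$M
    interior <- seq(2, length(x) - 1)
    expect_lt(max(abs(lap[interior] - sigma * 6)), 10 * h^2 + 1e-9)
  }
})

test_that("an uncoupled resting strand stays at rest (no spurious excitation)", {
  m <- cached_model("luo_rudy_1991")
  prob <- monodomain_problem(m, mesh = mesh1d(0.1, 0.01), sigma = 0,
                             stim_amplitude = 0, duration = 50,
                             pde_dt = 0.01, sampling_dt = 5)
  sol <- solve_monodomain(prob)
  expect_lt(max(abs(sol$V - sol$V[1, 1])), 1)
})

test_that("with sigma = 0 every node reproduces the single-cell clamp solution", {
  m <- cached_model("luo_rudy_1991")
  # all nodes stimulated identically, no coupling: each node is an
  # independent cell driven through the PDE's V update
  prob <- monodomain_problem(m, mesh = mesh1d(0.04, 0.01), sigma = 0,
                             stim_amplitude = -35000, stim_x = c(0, 1),
                             stim_t = c(1, 3), duration = 400,
                             pde_dt = 0.01, sampling_dt = 0.1,
                             ode_solver = "RL")
  sol <- solve_monodomain(prob)
  # single-cell comparison: same per-area stimulus (-35000/chi uA/cm^2)
  stim_cell <- regular_stimulus(prob$stim_amplitude / prob$chi, 2, 1000, 1)
  ref <- solve_adaptive(m, solver_config("ADAPTIVE", reltol = 1e-7,
                                         abstol = 1e-9, sampling_dt = 0.1),
                        stim_cell, c(0, 400))
  for (node in c(1, 3, 5)) {
    e <- mrms(ref, node_trace(sol, node))$e_mrms
    expect_lt(e, 0.05)
  }
})

test_that("halving the PDE timestep monotonically reduces the splitting error", {
  m <- cached_model("luo_rudy_1991")
  run <- function(pde_dt) {
    prob <- monodomain_problem(m, mesh = mesh1d(0.2, 0.01), duration = 40,
                               pde_dt = pde_dt, sampling_dt = 0.5,
                               stim_x = c(0, 0.05), stim_t = c(1, 3))
    node_trace(solve_monodomain(prob))
  }
  fine <- run(0.0025)
  errs <- vapply(c(0.02, 0.01, 0.005), function(dt) mrms(fine, run(dt))$e_mrms, 1)
  expect_true(all(diff(errs) < 0))
})

test_that("per-node adaptive cell solving agrees with RL and reset policy is immaterial", {
  m <- cached_model("luo_rudy_1991")
  base <- function(ode_solver, reset) {
    prob <- monodomain_problem(
      m, mesh = mesh1d(0.1, 0.01), duration = 30, pde_dt = 0.1,
      sampling_dt = 0.5, stim_x = c(0, 0.03), stim_t = c(1, 3),
      ode_solver = ode_solver,
      ode_config = solver_config("ADAPTIVE", v_mode = "parameter",
                                 reset_policy = reset))
    node_trace(solve_monodomain(prob))
  }
  no_reset <- base("ADAPTIVE", "never")
  every <- base("ADAPTIVE", "every_call")
  expect_lt(mrms(no_reset, every)$e_mrms, 0.05)
  rl <- base("RL", "never")
  expect_lt(mrms(no_reset, rl)$e_mrms, 0.05)
})

test_that("activation analysis recovers a synthetic traveling wave exactly", {
  # V(x, t) = H(t - x/c) scaled to -80/+20 mV with c = 0.05 cm/ms
  mesh <- mesh1d(1, 0.01)
  times <- seq(0, 30, by = 0.1)
  V <- outer(times, mesh$positions, function(t, x)
    ifelse(t - x / 0.05 >= 0, 20, -80))
  sol <- structure(list(times = times, positions = mesh$positions, V = V,
                        problem = list(model = list(name = "synthetic"))),
                   class = "monodomain_solution")
  at <- activation_times(sol, threshold = 0)
  expect_equal(conduction_velocity(sol), 0.05, tolerance = 0.02)
  # a quiescent run has no activations
  V0 <- matrix(-80, length(times), mesh$n_nodes)
  sol0 <- structure(list(times = times, positions = mesh$positions, V = V0,
                         problem = list(model = list(name = "synthetic"))),
                    class = "monodomain_solution")
  at0 <- activation_times(sol0)
  expect_true(all(is.na(at0$activation_times)))
  expect_true(is.na(at0$cv))
})

test_that("the space-time voltage export round-trips through CSV", {
  m <- cached_model("toy_gate")
  prob <- monodomain_problem(m, mesh = mesh1d(0.05, 0.01), duration = 5,
                             pde_dt = 0.05, sampling_dt = 1,
                             stim_t = c(1, 2), stim_amplitude = -5000)
  sol <- solve_monodomain(prob)
  path <- tempfile(fileext = ".csv")
  write_monodomain_csv(sol, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), length(sol$times))
  expect_equal(unname(as.matrix(back[, -1])), unname(sol$V), tolerance = 1e-10)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(meta$n_nodes, 6)
})
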