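test_that("rate tables reproduce the direct formulas to < 0.1%", {
  ws <- list(tables = build_rate_tables(0.005))
  set.seed(1)
  v <- runif(10000, -119, 79)
  tabs <- interp_tables(ws, v)
  r <- cmc_rates(v)
  direct_yinf <- cbind(r$alpha_m / (r$alpha_m + r$beta_m),
                       r$alpha_h / (r$alpha_h + r$beta_h),
                       r$alpha_j / (r$alpha_j + r$beta_j),
                       r$alpha_d / (r$alpha_d + r$beta_d),
                       r$alpha_f / (r$alpha_f + r$beta_f),
                       r$alpha_x / (r$alpha_x + r$beta_x))
  rel <- abs(tabs[, 1:6] - direct_yinf) / pmax(abs(direct_yinf), 1e-8)
  expect_lt(max(rel), 1e-3)
  # tabulated MFB current against the closed form
  relm <- abs(tabs[, 16] - mfb_current(v)) / pmax(abs(mfb_current(v)), 1e-6)
  expect_lt(max(relm), 1e-3)
})

test_that("two-node Crank-Nicolson step matches the closed-form decay factor", {
  g <- 50; c1 <- 20; c2 <- 10; dt <- 0.005
  net <- toy_network(c(c1, c2),
                     tibble::tibble(node_a = 1L, node_b = 2L, g = g,
                                    kind = "junctional_lateral",
                                    cell_a = 1L, cell_b = 2L))
  ws <- assemble_cn(net, dt, mfb = null_mfb())
  st <- toy_state(ws, v = c(1, -1), n = 2)
  st1 <- sim_run(st, ws, dt)
  lambda <- g * (1 / c1 + 1 / c2) # difference-mode eigenvalue (1/ms)
  factor <- (1 - dt * lambda / 2) / (1 + dt * lambda / 2)
  # mode amplitudes: weighted mean conserved, difference decays by `factor`
  expect_equal(diff(st1$v) / diff(st$v), factor, tolerance = 1e-12)
  expect_equal(sum(ws$c_pf * st1$v), sum(ws$c_pf * st$v), tolerance = 1e-12)
})

test_that("diffusion conserves total charge and fixes uniform potentials", {
  tess <- tessellate_strand(c(300, 40), spec_cmc(), 12)
  net <- build_network(assign_endogenous(tess, 0.25, 12))
  ws <- assemble_cn(net, 0.005, mfb = null_mfb())
  set.seed(2)
  v <- rnorm(ws$n, -70, 10)
  # independent route: the assembled operators via the Matrix solver
  v1 <- as.numeric(Matrix::solve(ws$m1, ws$m2 %*% v))
  expect_equal(sum(ws$c_pf * v1), sum(ws$c_pf * v), tolerance = 1e-8)
  # uniform potential is a fixed point of the diffusion step
  u <- rep(-63.2, ws$n)
  expect_equal(as.numeric(Matrix::solve(ws$m1, ws$m2 %*% u)), u, tolerance = 1e-10)
  # the compiled triangular-solve path agrees with the Matrix solver
  st <- toy_state(ws, v, ws$n)
  st$model <- rep(1L, ws$n) # null membrane: pure diffusion
  st1 <- sim_run(st, ws, 0.005)
  expect_equal(st1$v, v1, tolerance = 1e-10)
})

test_that("a disconnected passive node is untouched by diffusion", {
  net <- toy_network(c(10, 10), tibble::tibble(node_a = integer(),
                                               node_b = integer(),
                                               g = numeric(),
                                               kind = character(),
                                               cell_a = integer(),
                                               cell_b = integer()))
  ws <- assemble_cn(net, 0.005, mfb = null_mfb())
  st <- toy_state(ws, v = c(-20, 40), n = 2)
  st1 <- sim_run(st, ws, 1)
  expect_equal(st1$v, st$v, tolerance = 1e-12)
})

test_that("single passive node relaxes with the analytic RC time constant", {
  g_l <- 0.2 # ms^-1 leak rate
  net <- toy_network(15, tibble::tibble(node_a = integer(), node_b = integer(),
                                        g = numeric(), kind = character(),
                                        cell_a = integer(), cell_b = integer()))
  ws <- assemble_cn(net, 0.005, mfb = leak_mfb(g_l, v0 = -80))
  st <- toy_state(ws, v = -70, n = 1) # displaced by 10 mV
  st1 <- sim_run(st, ws, 10)
  # first-order splitting: per-step factor (1 - g dt) vs exp(-g dt) leaves a
  # relative error of about n (g dt)^2 / 2 = 1e-3 over these 2000 steps
  expect_equal(st1$v + 80, 10 * exp(-10 * g_l), tolerance = 3e-3)
})

test_that("tissue engine reproduces the plain-R single-cell integrator", {
  # a one-cell network is spatially uniform: its trajectory must match the
  # independent R reference integrator from the same displaced state
  lay <- two_rect_layout()
  lay$cells <- lay$cells[1, ]
  lay$contacts <- lay$contacts[0, ]
  net <- build_network(lay)
  ws <- assemble_cn(net, 0.005)
  st <- init_state(net, ws)
  st$v[] <- -60 # suprathreshold displacement -> full AP
  st1 <- sim_run(st, ws, 30, probes = 1L, probe_stride = 1L)
  ref_state <- cmc_steady_state(find_rmp("CMC"))
  ref_state$v <- -60
  ref <- integrate_cell(30, dt = 0.005, state = ref_state)
  # both fire: same activation time and peak; trace-wide agreement limited
  # only by the table interpolation of the rates
  m1 <- measure_trace(st1$trace$t, st1$trace$node_1)
  m2 <- measure_trace(ref$t, ref$v)
  expect_equal(m1$act_time, m2$act_time, tolerance = 0.05)
  expect_lt(abs(max(st1$trace$node_1) - max(ref$v)), 0.5)
  expect_lt(max(abs(st1$trace$node_1 - ref$v)), 2)
  expect_lt(abs(m1$dvdt_max - m2$dvdt_max) / m2$dvdt_max, 0.05)
})

test_that("uniform resting tissue is a fixed point of the full step", {
  lay <- control_strand_small()
  net <- build_network(lay)
  ws <- assemble_cn(net, 0.005)
  st <- init_state(net, ws)
  st1 <- sim_run(st, ws, 100)
  expect_lt(max(abs(st1$v - st$v)), 0.1)
  expect_true(all(is.na(st1$act_time)))
})

test_that("integration is deterministic and reuses one factorization", {
  lay <- control_strand_small()
  sim1 <- strand_sim(assign_endogenous(tessellate_strand(c(300, 40), spec_cmc(), 3), 0.3, 3))
  sim2 <- strand_sim(assign_endogenous(tessellate_strand(c(300, 40), spec_cmc(), 3), 0.3, 3))
  a <- sim_run(sim1$state, sim1$ws[["0.005"]], 5)
  b <- sim_run(sim2$state, sim2$ws[["0.005"]], 5)
  expect_identical(a$v, b$v) # bit-identical trajectories
  # one factorization per workspace, reused across chunks
  expect_equal(sim1$ws[["0.005"]]$n_factorizations, 1L)
  sim1 <- equilibrate(sim1, max_duration = 100, min_duration = 50)
  expect_equal(length(sim1$ws), 1) # no re-assembly for the same dt
})

test_that("halving the time step changes conduction velocity by < 1%", {
  lay <- control_strand_small()
  cv_at <- function(dt) {
    sim <- strand_sim(lay, dt = dt)
    m <- stimulate_and_measure(lay, sim = sim, post_window = 6,
                               equil = list(max_duration = 10, min_duration = 0,
                                            check_interval = 10, settle = 0))
    m$cv
  }
  cv1 <- cv_at(0.005)
  cv2 <- cv_at(0.0025)
  expect_lt(abs(cv1 - cv2) / cv1, 0.01)
})

test_that("potentials outside the table range are clamped with a warning", {
  net <- toy_network(10, tibble::tibble(node_a = integer(), node_b = integer(),
                                        g = numeric(), kind = character(),
                                        cell_a = integer(), cell_b = integer()))
  ws <- assemble_cn(net, 0.005, mfb = leak_mfb(0.1, -80))
  st <- toy_state(ws, v = -170, n = 1) # below the table range
  expect_warning(sim_run(st, ws, 0.05), "clamped")
})

test_that("non-finite potentials abort with a diagnostic", {
  net <- toy_network(10, tibble::tibble(node_a = integer(), node_b = integer(),
                                        g = numeric(), kind = character(),
                                        cell_a = integer(), cell_b = integer()))
  ws <- assemble_cn(net, 0.005, mfb = null_mfb())
  st <- toy_state(ws, v = NaN, n = 1)
  expect_error(suppressWarnings(sim_run(st, ws, 1)), "non-finite")
})
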