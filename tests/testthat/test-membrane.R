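test_that("Korhonen inward rectifier matches its closed form", {
  p <- cmc_params()
  # independent re-derivation of the formula at a probe potential
  v <- -60; ko <- 5.4; ek <- p$e_k
  dv <- v - ek - 6.1373
  oracle <- 0.0515 * (ko / (ko + 0.210)) * dv / (0.1653 + exp(0.0319 * dv))
  expect_equal(ik1_korhonen(v, ko, ek), oracle, tolerance = 1e-12)
  # zero exactly at E_K + 6.1373, inward below, outward above
  expect_equal(ik1_korhonen(ek + 6.1373, ko, ek), 0, tolerance = 1e-12)
  expect_lt(ik1_korhonen(ek, ko, ek), 0)
  expect_gt(ik1_korhonen(ek + 20, ko, ek), 0)
})

test_that("modified Ca2+ gate rates are the 30x-shifted / 2x LR1 rates", {
  v <- seq(-80, 40, by = 7)
  r <- ical_rates(v)
  alpha_d_lr1 <- function(u) 0.095 * exp(-0.01 * (u - 5)) / (1 + exp(-0.072 * (u - 5)))
  alpha_f_lr1 <- function(u) 0.012 * exp(-0.008 * (u + 28)) / (1 + exp(0.15 * (u + 28)))
  beta_f_lr1 <- function(u) 0.0065 * exp(-0.02 * (u + 30)) / (1 + exp(-0.2 * (u + 30)))
  expect_equal(r$alpha_d / alpha_d_lr1(v - 6), rep(30, length(v)), tolerance = 1e-12)
  expect_equal(r$alpha_f / alpha_f_lr1(v), rep(2, length(v)), tolerance = 1e-12)
  expect_equal(r$beta_f / beta_f_lr1(v), rep(2, length(v)), tolerance = 1e-12)
})

test_that("gate rates and steady states are well behaved over the table range", {
  v <- seq(-120, 80, by = 0.5)
  r <- cmc_rates(v)
  for (nm in names(r)) {
    expect_true(all(is.finite(r[[nm]])), info = nm)
    expect_true(all(r[[nm]] >= 0), info = nm)
  }
  ss <- cmc_steady_state(v)
  for (g in c("m", "h", "j", "d", "f", "x")) {
    expect_true(all(ss[[g]] >= 0 & ss[[g]] <= 1), info = g)
  }
})

test_that("CMC model rests near -79 mV with a stable, current-free rest", {
  rmp <- find_rmp("CMC")
  expect_gt(rmp, -80); expect_lt(rmp, -78)
  st <- cmc_steady_state(rmp)
  expect_lt(abs(cmc_total_current(st)$i_ion), 1e-3)
  # stability: positive slope of the steady-state I-V at the rest point
  iv <- steady_state_iv("CMC", rmp + c(-0.5, 0.5))
  expect_gt(diff(iv$i), 0)
})

test_that("MFB model rests at -36.1 mV with calibrated exponential slope", {
  p <- mfb_params()
  # slope calibration oracle: exp(27.9 / k) = 12.5 - 0.033 * 36.1
  k_oracle <- 27.9 / log(12.5 - 0.033 * 36.1)
  expect_equal(p$k, k_oracle, tolerance = 1e-6)
  expect_equal(mfb_current(-36.1, p), 0, tolerance = 1e-9)
  expect_equal(find_rmp("MFB"), -36.1, tolerance = 1e-6)
  # passivity: a single zero in [-100, 0], positive slope there, convex
  # increase at depolarized potentials
  v <- seq(-100, 0, by = 0.1)
  i <- mfb_current(v, p)
  expect_equal(sum(diff(sign(i)) != 0), 1)
  expect_gt(mfb_current(-36, p), 0)
  expect_gt(diff(mfb_current(c(19, 20), p)), diff(mfb_current(c(-1, 0), p)))
})

test_that("find_rmp recovers the rest of an artificial linear membrane", {
  lin <- leak_mfb(g_l = 1, v0 = -55.5)
  expect_equal(find_rmp("MFB", lin), -55.5, tolerance = 1e-6)
  # no positive-slope zero -> error
  no_rest <- mfb_params(a0 = 5, a1 = 0, a2 = 0, k = 1, c_norm = 1)
  expect_error(find_rmp("MFB", no_rest), "no stable rest")
})

test_that("accelerated L-type current peaks about 1 ms after a voltage step", {
  hold <- cmc_steady_state(-80)
  tr <- integrate_cell(6, dt = 0.001, state = hold,
                       v_clamp = function(t) if (t < 1) -80 else 0)
  post <- dplyr::filter(tr, t >= 1)
  # reconstruct the slow inward current, including the Ca2+-dependent
  # reversal (Ca2+ accumulation curtails the driving force early)
  i_si <- 0.18 * post$d * post$f * (post$v - (7.7 - 13.0287 * log(post$ca)))
  t_peak <- post$t[which.min(i_si)] - 1
  expect_gt(t_peak, 0.3); expect_lt(t_peak, 3) # milliseconds, not tens
  # the 30x gate acceleration is what makes it fast: an unaccelerated d
  # gate (tau 30x longer) would peak an order of magnitude later
  r0 <- ical_rates(0)
  tau_fast <- 1 / (r0$alpha_d + r0$beta_d)
  expect_lt(tau_fast, 1)            # activation time constant ~0.9 ms
  expect_gt(30 * tau_fast, 10 * t_peak) # unaccelerated tau alone exceeds 10x the peak time
})

test_that("Na+ availability falls about 30% for a 6 mV depolarization", {
  hj <- function(v) with(cmc_steady_state(v), h * j)
  rmp <- find_rmp("CMC")
  red <- 1 - hj(rmp + 6) / hj(rmp)
  expect_gt(red, 0.2); expect_lt(red, 0.4)
  # availability decreases monotonically over the depolarization range
  av <- vapply(seq(-80, -60, by = 2), hj, 0)
  expect_true(all(diff(av) < 0))
})

test_that("the +6 mV d-gate shift suppresses the destabilizing window current", {
  # reconstruct the steady-state I-V with the unshifted activation gate: the
  # window Ca2+ current then drags the curve down near rest, leaving at most
  # a marginal outward reserve, and carves a several-fold deeper inward dip
  p <- cmc_params()
  v <- seq(-100, -30, by = 0.25)
  st <- cmc_steady_state(v, p)
  r_unshift <- ical_rates(v + 6) # undoes the shift for d only
  st$d <- r_unshift$alpha_d / (r_unshift$alpha_d + r_unshift$beta_d)
  i_unshift <- cmc_total_current(st, p)$i_ion
  i_shift <- cmc_total_current(cmc_steady_state(v, p), p)$i_ion
  sel <- v >= -75 & v <= -55
  expect_lt(max(i_unshift[sel]), 0.05)  # quiescence at best marginal
  expect_gt(max(i_shift[sel]), 0.15)    # robust outward reserve with shift
  dip <- v >= -70 & v <= -30
  expect_lt(min(i_unshift[dip]), 3 * min(i_shift[dip])) # deeper window dip
  expect_silent(find_rmp("CMC", p))     # shifted model rests stably
})

test_that("steady-state I-V has the expected structure", {
  iv <- steady_state_iv("CMC", seq(-100, -95, by = 1))
  expect_true(all(iv$i < 0)) # dominated by the inward I_K1 limb
  # within the depolarized-rest corridor the current is small (sub-uA/uF),
  # consistent with an experimental envelope of that scale
  mid <- steady_state_iv("CMC", seq(-80, -60, by = 1))
  expect_true(all(abs(mid$i) < 1))
})

test_that("Rush-Larsen is exact for constant rates and matches tiny-step Euler", {
  a <- 0.3; b <- 0.1; y0 <- 0.2; dt <- 0.005
  yinf <- a / (a + b); tau <- 1 / (a + b)
  expect_equal(rush_larsen(y0, a, b, dt), yinf + (y0 - yinf) * exp(-dt / tau),
               tolerance = 1e-15)
  expect_equal(rush_larsen(yinf, a, b, 5), yinf, tolerance = 1e-15)
  expect_equal(rush_larsen(y0, 0, 0, dt), y0)
  # forward-Euler oracle at 1000x finer steps
  y_euler <- y0
  for (i in 1:1000) y_euler <- y_euler + (dt / 1000) * (a * (1 - y_euler) - b * y_euler)
  expect_equal(rush_larsen(y0, a, b, dt), y_euler, tolerance = 1e-6)
})
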