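#' Cardiomyocyte membrane parameters
#'
#' Constants of the modified Luo-Rudy I (LR1) ventricular ionic model used for
#' cultured neonatal cardiomyocytes (CMCs). Relative to the original LR1
#' model: the inward rectifier \eqn{I_{K1}} is replaced by the Korhonen
#' neonatal-rat formulation, the background current is removed
#' (\eqn{g_b = 0}), the maximal slow-inward conductance is doubled
#' (\eqn{g_{si} = 0.18} mS/uF), its d-gate rates are accelerated 30-fold and
#' shifted +6 mV, the f-gate rates are doubled, the delayed rectifier maximal
#' conductance is raised to 0.5 mS/uF, and the fast sodium conductance is set
#' to 8.1 mS/uF so that a control strand conducts at 41.4 cm/s.
#'
#' All current densities are in uA/uF (equal to mV/ms for
#' \eqn{C_m = 1} uF/cm^2), potentials in mV, time in ms, concentrations in mM.
#'
#' @param g_na Maximal fast Na+ conductance (mS/uF).
#' @param g_si Maximal slow inward (L-type Ca2+) conductance (mS/uF).
#' @param g_k Maximal delayed-rectifier K+ conductance (mS/uF).
#' @param g_kp Plateau K+ conductance (mS/uF), unmodified LR1 value.
#' @param g_b Background conductance; 0 in this model.
#' @param ko,ki Extra-/intracellular K+ (mM).
#' @param temp_celsius Temperature used for the Nernst potential of K+.
#' @param ca_rest Resting intracellular Ca2+ (mM), LR1 resting value.
#' @return A list of class `cmc_params`.
#' @export
cmc_params <- function(g_na = 8.1, g_si = 0.18, g_k = 0.5, g_kp = 0.0183,
                       g_b = 0, ko = 5.4, ki = 145, temp_celsius = 35,
                       ca_rest = 2e-4) {
  rtf <- 8.314462 * (273.15 + temp_celsius) / 96485.33 * 1000 # mV
  p <- list(
    g_na = g_na, e_na = 54.4,
    g_si = g_si,
    g_k = g_k, e_k_ik = -77,      # LR1 printed reversal for I_K (K/Na permeability)
    g_kp = g_kp, e_kp = -87.26,   # LR1 printed E_Kp (= their E_K1)
    g_b = g_b,
    ko = ko, ki = ki,
    e_k = rtf * log(ko / ki),     # Nernst E_K entering the Korhonen I_K1
    ca_rest = ca_rest
  )
  class(p) <- "cmc_params"
  p
}

#' Myofibroblast membrane parameters
#'
#' The myofibroblast (MFB) membrane is passive; its whole-cell
#' current-voltage relation was fitted to voltage-clamp data as
#' \eqn{I = a_0 + a_1 V + a_2 e^{(V + v_{off})/k}} (picoamperes). The
#' current density entering the tissue model is this fit divided by the
#' reference capacitance `c_norm` of the patched cells
#' (pA/pF = uA/uF).
#'
#' Two constants are calibrated rather than transcribed:
#' * the exponential slope `k` is root-found at construction so that the
#'   isolated MFB rests at exactly -36.1 mV, the reported resting potential
#'   of the fitted model (the printed denominator is typographically
#'   corrupted in the source);
#' * `c_norm` (default 31.2 pF) is set so that a strand with 30% endogenous
#'   MFBs depolarizes the cardiomyocyte resting potential by the reported
#'   ~6 mV (to about -73 mV). The reported -69 mV at 40% density then
#'   follows without further adjustment.
#'
#' @param a0 Constant term (pA).
#' @param a1 Linear slope (pA per mV).
#' @param v_off Offset of the exponential term (mV).
#' @param a2 Amplitude of the exponential term; 1 for the fitted model. Set
#'   to 0 to obtain a purely linear passive membrane (useful for testing).
#' @param k Exponential slope (mV); `NULL` (default) calibrates it to the
#'   -36.1 mV resting constraint.
#' @param v_rest Resting potential (mV) enforced by the calibration.
#' @param c_norm Reference capacitance (pF) converting the whole-cell fit
#'   into a density.
#' @return A list of class `mfb_params`.
#' @export
mfb_params <- function(a0 = -12.5, a1 = -0.033, v_off = 64, a2 = 1,
                       k = NULL, v_rest = -36.1, c_norm = 31.2) {
  if (is.null(k) && a2 != 0) {
    f <- function(kk) a0 + a1 * v_rest + a2 * exp((v_rest + v_off) / kk)
    k <- stats::uniroot(f, c(0.5, 200), tol = 1e-12)$root
  } else if (is.null(k)) {
    k <- 1
  }
  p <- list(a0 = a0, a1 = a1, a2 = a2, v_off = v_off, k = k, c_norm = c_norm)
  class(p) <- "mfb_params"
  p
}

#' Korhonen inward-rectifier K+ current
#'
#' Neonatal-rat \eqn{I_{K1}} replacing the LR1 inward rectifier:
#' \deqn{I_{K1} = 0.0515 \frac{[K]_o}{[K]_o + 0.210}
#'   \frac{V - E_K - 6.1373}{0.1653 + e^{0.0319 (V - E_K - 6.1373)}}}
#'
#' @param v Membrane potential (mV), vectorized.
#' @param ko Extracellular K+ (mM).
#' @param ek K+ Nernst potential (mV).
#' @return Current density (uA/uF).
#' @export
ik1_korhonen <- function(v, ko = 5.4, ek = cmc_params()$e_k) {
  stopifnot(ko > 0)
  dv <- v - ek - 6.1373
  0.0515 * (ko / (ko + 0.210)) * dv / (0.1653 + exp(0.0319 * dv))
}

#' Myofibroblast membrane current
#'
#' @param v Membrane potential (mV), vectorized.
#' @param params [mfb_params()].
#' @return Current density (uA/uF); positive = outward.
#' @export
mfb_current <- function(v, params = mfb_params()) {
  (params$a0 + params$a1 * v + params$a2 * exp((v + params$v_off) / params$k)) /
    params$c_norm
}

# LR1 rate constants with the model's modifications. Singular points of the
# alpha_m and Xi expressions are handled by their analytic limits.
safe_ratio <- function(num, den, limit) ifelse(abs(den) < 1e-10, limit, num / den)

alpha_m_lr1 <- function(v) {
  u <- v + 47.13
  safe_ratio(0.32 * u, 1 - exp(-0.1 * u), 3.2)
}
beta_m_lr1 <- function(v) 0.08 * exp(-v / 11)

alpha_h_lr1 <- function(v) ifelse(v < -40, 0.135 * exp((80 + v) / -6.8), 0)
beta_h_lr1 <- function(v) {
  ifelse(v < -40,
         3.56 * exp(0.079 * v) + 3.1e5 * exp(0.35 * v),
         1 / (0.13 * (1 + exp((v + 10.66) / -11.1))))
}

alpha_j_lr1 <- function(v) {
  ifelse(v < -40,
         (-1.2714e5 * exp(0.2444 * v) - 3.474e-5 * exp(-0.04391 * v)) *
           (v + 37.78) / (1 + exp(0.311 * (v + 79.23))),
         0)
}
beta_j_lr1 <- function(v) {
  ifelse(v < -40,
         0.1212 * exp(-0.01052 * v) / (1 + exp(-0.1378 * (v + 40.14))),
         0.3 * exp(-2.535e-7 * v) / (1 + exp(-0.1 * (v + 32))))
}

alpha_x_lr1 <- function(v) 0.0005 * exp(0.083 * (v + 50)) / (1 + exp(0.057 * (v + 50)))
beta_x_lr1 <- function(v) 0.0013 * exp(-0.06 * (v + 20)) / (1 + exp(-0.04 * (v + 20)))

#' Modified L-type Ca2+ gate rate constants
#'
#' Rates of the activation gate `d` (30-fold accelerated, shifted +6 mV) and
#' inactivation gate `f` (2-fold accelerated) of the slow inward current.
#' The acceleration yields a time to peak of about 1 ms; the +6 mV shift of
#' the d-gate removes the steady-state window current that would otherwise
#' destabilize the resting potential of quiescent monolayers.
#'
#' @param v Membrane potential (mV), vectorized.
#' @return A list with components `alpha_d`, `beta_d`, `alpha_f`, `beta_f`
#'   (ms^-1).
#' @export
ical_rates <- function(v) {
  vs <- v - 6 # +6 mV shift of the d-gate activation curve
  list(
    alpha_d = 30 * 0.095 * exp(-0.01 * (vs - 5)) / (1 + exp(-0.072 * (vs - 5))),
    beta_d  = 30 * 0.07 * exp(-0.017 * (vs + 44)) / (1 + exp(0.05 * (vs + 44))),
    alpha_f = 2 * 0.012 * exp(-0.008 * (v + 28)) / (1 + exp(0.15 * (v + 28))),
    beta_f  = 2 * 0.0065 * exp(-0.02 * (v + 30)) / (1 + exp(-0.2 * (v + 30)))
  )
}

#' All gate rate constants of the modified LR1 model
#'
#' @param v Membrane potential (mV), vectorized.
#' @return A list of `alpha_*`/`beta_*` vectors (ms^-1) for gates
#'   m, h, j, d, f, X.
#' @export
cmc_rates <- function(v) {
  c(list(
    alpha_m = alpha_m_lr1(v), beta_m = beta_m_lr1(v),
    alpha_h = alpha_h_lr1(v), beta_h = beta_h_lr1(v),
    alpha_j = alpha_j_lr1(v), beta_j = beta_j_lr1(v)
  ),
  ical_rates(v),
  list(alpha_x = alpha_x_lr1(v), beta_x = beta_x_lr1(v)))
}

# Time-independent rectification factor of I_K (LR1 "Xi").
xi_lr1 <- function(v) {
  u <- v + 77
  ifelse(v > -100,
         safe_ratio(2.837 * (exp(0.04 * u) - 1), u * exp(0.04 * (v + 35)),
                    2.837 * 0.04 / exp(0.04 * (-77 + 35))),
         1)
}

kp_lr1 <- function(v) 1 / (1 + exp((7.488 - v) / 5.98))

e_si <- function(ca) 7.7 - 13.0287 * log(ca)

gate_inf <- function(a, b) a / (a + b)

#' Resting gate state of the CMC model
#'
#' Gates at their voltage-dependent steady state, Ca2+ at the LR1 resting
#' value.
#'
#' @param v Membrane potential (mV).
#' @param params [cmc_params()].
#' @return A list with `v`, `m`, `h`, `j`, `d`, `f`, `x`, `ca`.
#' @export
cmc_steady_state <- function(v, params = cmc_params()) {
  r <- cmc_rates(v)
  list(v = v,
       m = gate_inf(r$alpha_m, r$beta_m),
       h = gate_inf(r$alpha_h, r$beta_h),
       j = gate_inf(r$alpha_j, r$beta_j),
       d = gate_inf(r$alpha_d, r$beta_d),
       f = gate_inf(r$alpha_f, r$beta_f),
       x = gate_inf(r$alpha_x, r$beta_x),
       ca = params$ca_rest)
}

#' Total ionic current of the modified LR1 CMC model
#'
#' Computes the instantaneous total current density, all gate rate constants
#' and the Ca2+ balance for a given dynamic state.
#'
#' @param state List with components `v`, `m`, `h`, `j`, `d`, `f`, `x`, `ca`
#'   (vectors of equal length are accepted).
#' @param params [cmc_params()].
#' @return A list with `i_ion` (uA/uF), the component currents, `rates`
#'   (as [cmc_rates()]) and `dca_dt` (mM/ms).
#' @export
cmc_total_current <- function(state, params = cmc_params()) {
  v <- state$v
  i_na <- params$g_na * state$m^3 * state$h * state$j * (v - params$e_na)
  i_si <- params$g_si * state$d * state$f * (v - e_si(state$ca))
  i_k  <- params$g_k * state$x * xi_lr1(v) * (v - params$e_k_ik)
  i_k1 <- ik1_korhonen(v, params$ko, params$e_k)
  i_kp <- params$g_kp * kp_lr1(v) * (v - params$e_kp)
  i_ion <- i_na + i_si + i_k + i_k1 + i_kp # I_b = 0 in this model
  list(i_ion = i_ion,
       i_na = i_na, i_si = i_si, i_k = i_k, i_k1 = i_k1, i_kp = i_kp,
       rates = cmc_rates(v),
       dca_dt = -1e-4 * i_si + 0.07 * (1e-4 - state$ca))
}

#' Steady-state current-voltage relation
#'
#' Total membrane current with every gate at its voltage-dependent steady
#' state; for the CMC model the intracellular Ca2+ is clamped at its resting
#' value. This is the curve whose positive-slope zero defines the resting
#' membrane potential.
#'
#' @param model `"CMC"` or `"MFB"`.
#' @param v_grid Membrane potentials (mV) at which to evaluate.
#' @param params Model parameters ([cmc_params()] or [mfb_params()]).
#' @return A tibble with columns `v` (mV) and `i` (uA/uF).
#' @export
steady_state_iv <- function(model = c("CMC", "MFB"),
                            v_grid = seq(-100, 20, by = 0.5),
                            params = NULL) {
  model <- match.arg(model)
  i <- if (model == "CMC") {
    params <- params %||% cmc_params()
    cmc_total_current(cmc_steady_state(v_grid, params), params)$i_ion
  } else {
    params <- params %||% mfb_params()
    mfb_current(v_grid, params)
  }
  tibble::tibble(v = v_grid, i = i)
}

#' Resting membrane potential of a membrane model
#'
#' Finds the zero crossing with positive slope of the steady-state
#' current-voltage relation within a search window, i.e. the stable resting
#' potential. The modified CMC model rests near -79 mV; the isolated MFB
#' model rests at -36.1 mV.
#'
#' @inheritParams steady_state_iv
#' @param interval Search window (mV).
#' @return Resting potential (mV).
#' @export
find_rmp <- function(model = c("CMC", "MFB"), params = NULL,
                     interval = c(-100, -20)) {
  model <- match.arg(model)
  f <- function(v) steady_state_iv(model, v, params)$i
  grid <- seq(interval[1], interval[2], by = 0.25)
  fg <- f(grid)
  up <- which(fg[-length(fg)] < 0 & fg[-1] >= 0) # "-" to "+": positive slope
  if (length(up) == 0) stop("no stable rest: no positive-slope zero in range")
  stats::uniroot(f, c(grid[up[1]], grid[up[1] + 1]), tol = 1e-10)$root
}

#' Exact-exponential (Rush-Larsen) gate update
#'
#' \eqn{y' = y_\infty + (y - y_\infty) e^{-\Delta t / \tau}} with
#' \eqn{y_\infty = \alpha/(\alpha+\beta)}, \eqn{\tau = 1/(\alpha+\beta)};
#' exact for rate constants frozen over the step.
#'
#' @param y Gate value(s) in `[0, 1]`.
#' @param alpha,beta Opening/closing rates (ms^-1), `>= 0`.
#' @param dt Time step (ms).
#' @return Updated gate value(s).
#' @export
rush_larsen <- function(y, alpha, beta, dt) {
  s <- alpha + beta
  ifelse(s <= 0, y, alpha / pmax(s, 1e-300) + (y - alpha / pmax(s, 1e-300)) * exp(-dt * s))
}

#' Integrate an isolated CMC (reference implementation)
#'
#' Plain-R single-cell integrator (Rush-Larsen gates, forward-Euler Ca2+)
#' used as an independent oracle for the compiled tissue engine and for
#' voltage-clamp style checks.
#'
#' @param duration Duration (ms).
#' @param dt Time step (ms).
#' @param params [cmc_params()].
#' @param state Initial state; default resting state at the model RMP.
#' @param i_stim Function of time (ms) returning stimulus current density
#'   (uA/uF, inward negative), or `NULL`.
#' @param v_clamp Function of time returning a clamped potential (mV), or
#'   `NULL` for free running.
#' @return A tibble with columns `t`, `v`, `i_ion`, the gates and `ca`.
#' @export
integrate_cell <- function(duration, dt = 0.005, params = cmc_params(),
                           state = NULL, i_stim = NULL, v_clamp = NULL) {
  if (is.null(state)) state <- cmc_steady_state(find_rmp("CMC", params), params)
  n <- ceiling(duration / dt)
  out <- matrix(NA_real_, n + 1, 10,
                dimnames = list(NULL, c("t", "v", "i_ion", "m", "h", "j", "d", "f", "x", "ca")))
  for (step in 0:n) {
    t <- step * dt
    if (!is.null(v_clamp)) state$v <- v_clamp(t)
    cur <- cmc_total_current(state, params)
    out[step + 1, ] <- c(t, state$v, cur$i_ion, state$m, state$h, state$j,
                         state$d, state$f, state$x, state$ca)
    if (step == n) break
    r <- cur$rates
    state$m <- rush_larsen(state$m, r$alpha_m, r$beta_m, dt)
    state$h <- rush_larsen(state$h, r$alpha_h, r$beta_h, dt)
    state$j <- rush_larsen(state$j, r$alpha_j, r$beta_j, dt)
    state$d <- rush_larsen(state$d, r$alpha_d, r$beta_d, dt)
    state$f <- rush_larsen(state$f, r$alpha_f, r$beta_f, dt)
    state$x <- rush_larsen(state$x, r$alpha_x, r$beta_x, dt)
    state$ca <- state$ca + dt * cur$dca_dt
    if (is.null(v_clamp)) {
      stim <- if (is.null(i_stim)) 0 else i_stim(t)
      state$v <- state$v - dt * (cur$i_ion + stim)
    }
  }
  tibble::as_tibble(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
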