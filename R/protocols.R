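#' Stimulus specification
#'
#' Rectangular current pulse injected into all base-layer nodes at one
#' extremity of the strand. The default (1 ms, 300 uA/uF, x < 100 um) is
#' strongly suprathreshold in every configuration studied, including fully
#' polarized two-layer tissue whose capacitive load roughly doubles the
#' diastolic threshold; measurements exclude the proximal quarter of the
#' strand, so the stimulus details do not affect them. For pacing, `period`
#' and `count` define a train.
#'
#' @param amplitude Current density (uA/uF), applied as depolarizing
#'   (inward) current.
#' @param duration Pulse duration (ms).
#' @param x_max Nodes with x below this (um) are stimulated (base layer).
#' @param period Pacing interval (ms); `NA` for a single pulse.
#' @param count Number of pulses.
#' @return A list of class `stimulus_spec`.
#' @export
stimulus_spec <- function(amplitude = 300, duration = 1, x_max = 100,
                          period = NA, count = 1L) {
  stopifnot(amplitude > 0, duration > 0)
  structure(list(amplitude = amplitude, duration = duration, x_max = x_max,
                 period = period, count = as.integer(count)),
            class = "stimulus_spec")
}

#' Set up a strand simulation
#'
#' Builds the weighted network and the Crank-Nicolson workspace for a
#' layout and initializes every node at its membrane model's resting state.
#'
#' @param layout A `tissue_layout`.
#' @param grid [grid_params()].
#' @param params [electrical_params()].
#' @param cmc,mfb Membrane parameter sets.
#' @param dt Protocol time step (ms).
#' @param excitable_mfb Replace the MFB membrane with the full CMC model
#'   (perturbation analysis) at unchanged coupling.
#' @return A list of class `strand_sim` with the network, workspace cache
#'   and state.
#' @export
strand_sim <- function(layout, grid = grid_params(), params = electrical_params(),
                       cmc = cmc_params(), mfb = mfb_params(), dt = 0.005,
                       excitable_mfb = FALSE) {
  net <- build_network(layout, grid, params)
  ws <- assemble_cn(net, dt, cmc, mfb)
  sim <- structure(list(layout = layout, net = net, ws = list(), dt = dt,
                        cmc = cmc, mfb = mfb, excitable_mfb = excitable_mfb,
                        spontaneous = FALSE, state = NULL), class = "strand_sim")
  sim$ws[[format(dt)]] <- ws
  sim$state <- init_state(net, ws, excitable_mfb)
  sim
}

ws_for <- function(sim, dt) {
  key <- format(dt)
  if (is.null(sim$ws[[key]])) {
    sim$ws[[key]] <- assemble_cn(sim$net, dt, sim$cmc, sim$mfb)
  }
  sim
}

#' Equilibrate a strand without stimulation
#'
#' Integrates the unstimulated tissue until the potential drift over a
#' check interval falls below `drift_tol` (or `max_duration` is reached) and
#' flags spontaneous activity (any node crossing -35 mV upward without a
#' stimulus). Because cardiomyocyte and myofibroblast nodes start from their
#' respective single-cell rests, the first moments of a mixed tissue can
#' fire one transient beat that is an artifact of the initial condition;
#' crossings within the initial `grace` window are therefore not classified
#' as spontaneous activity. The protocol reference is at least 2 s of
#' quiescent equilibration; a coarser equilibration-only time step may be
#' supplied to shorten wall time, in which case a settling window at the
#' protocol step follows.
#'
#' @param sim A [strand_sim()].
#' @param max_duration Maximum equilibration time (ms).
#' @param drift_tol Max per-node |dV| over `check_interval` to accept
#'   steady state (mV).
#' @param check_interval Drift check interval (ms).
#' @param equil_dt Optional coarser step (ms) for the drift phase.
#' @param settle Settling time (ms) at the protocol step after a coarse
#'   drift phase.
#' @param min_duration Minimum equilibration time (ms).
#' @param grace Initial window (ms) whose threshold crossings are treated as
#'   initial-condition transients, not spontaneous activity.
#' @param stop_on_spontaneous Stop early once spontaneous activity is
#'   detected (such tissues are excluded from conduction analysis).
#' @return The updated `strand_sim` (fields `spontaneous`,
#'   `equil_duration`).
#' @export
equilibrate <- function(sim, max_duration = 2000, drift_tol = 0.1,
                        check_interval = 50, equil_dt = NULL, settle = 50,
                        min_duration = 100, grace = 400,
                        stop_on_spontaneous = TRUE) {
  dt_eq <- equil_dt %||% sim$dt
  sim <- ws_for(sim, dt_eq)
  ws <- sim$ws[[format(dt_eq)]]
  st <- sim$state
  t_begin <- st$t
  past_grace <- FALSE
  repeat {
    vprev <- st$v
    st <- sim_run(st, ws, check_interval)
    elapsed <- st$t - t_begin
    drift <- max(abs(st$v - vprev))
    if (!past_grace && elapsed >= grace) {
      st <- reset_measurements(st) # discard initial-condition transients
      past_grace <- TRUE
    }
    if (past_grace && stop_on_spontaneous && any(!is.na(st$act_time))) break
    min_stop <- max(min_duration, min(grace, max_duration))
    if ((drift < drift_tol && elapsed >= min_stop) || elapsed >= max_duration) break
  }
  if (dt_eq != sim$dt) {
    st <- sim_run(st, sim$ws[[format(sim$dt)]], settle)
  }
  sim$spontaneous <- sim$spontaneous ||
    (past_grace && any(!is.na(st$act_time)))
  sim$equil_duration <- st$t - t_begin
  sim$state <- st
  sim
}

#' Diastolic threshold by bisection
#'
#' Finds the minimal stimulus amplitude (to within a relative tolerance)
#' that elicits a propagated response at `x_probe`, using short trial
#' integrations from the current (equilibrated) state.
#'
#' @param sim An equilibrated [strand_sim()].
#' @param stim [stimulus_spec()] providing duration and stimulated region.
#' @param bounds Search interval for the amplitude (uA/uF).
#' @param x_probe Propagation success is an activation beyond this x (um).
#' @param window Trial integration window (ms).
#' @param tol Relative amplitude tolerance.
#' @return Threshold amplitude (uA/uF).
#' @export
find_threshold <- function(sim, stim = stimulus_spec(), bounds = c(2, 400),
                           x_probe = NULL, window = 25, tol = 0.1) {
  x_probe <- x_probe %||% (0.3 * sim$layout$domain[1])
  ws <- sim$ws[[format(sim$dt)]]
  nodes <- sim$net$nodes
  stim_nodes <- nodes$node[nodes$x < stim$x_max & nodes$layer == 0]
  fires <- function(amp) {
    st <- reset_measurements(sim$state)
    st <- sim_run(st, ws, window,
                  stim = list(nodes = stim_nodes, amp = amp,
                              starts = st$t, duration = stim$duration))
    any(!is.na(st$act_time[nodes$x > x_probe]))
  }
  lo <- bounds[1]; hi <- bounds[2]
  if (fires(lo)) return(lo)
  if (!fires(hi)) stop("no activation at upper amplitude bound")
  while (hi / lo > 1 + tol) {
    mid <- sqrt(lo * hi)
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Per-trace activation metrics
#'
#' Resting potential (first sample), activation time (first upward crossing
#' of the threshold, linearly interpolated) and maximal rate of rise from
#' finite differences of consecutive samples, for a single sampled voltage
#' trace.
#'
#' @param t Sample times (ms).
#' @param v Sampled membrane potential (mV).
#' @param threshold Activation threshold (mV).
#' @return A list with `rmp` (mV), `act_time` (ms, `NA` if never crossing)
#'   and `dvdt_max` (V/s).
#' @export
measure_trace <- function(t, v, threshold = -35) {
  stopifnot(length(t) == length(v), length(t) >= 2)
  dv <- diff(v) / diff(t)
  up <- which(v[-length(v)] < threshold & v[-1] >= threshold)
  act <- if (length(up) == 0) NA_real_ else {
    i <- up[1]
    t[i] + (threshold - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
  }
  list(rmp = v[1], act_time = act, dvdt_max = max(dv))
}

#' Conduction velocity from an activation map
#'
#' Ordinary least squares fit of the earliest activation time per
#' x-coordinate against x, restricted to a central window of the strand
#' (default 25-75% of its length, excluding stimulation artifacts and
#' sealed-end effects); CV is the inverse slope.
#'
#' @param act A tibble/data frame with columns `x` (um) and `act_time`
#'   (ms); typically CMC-layer nodes.
#' @param strand_length Strand length (um).
#' @param window Fractional window of x used for the fit.
#' @return A list with `cv` (cm/s, `NA` if blocked), `slope` (ms/um),
#'   `r_squared`, `n_columns` and `blocked`.
#' @export
conduction_velocity <- function(act, strand_length, window = c(0.25, 0.75)) {
  act <- dplyr::filter(act, !is.na(.data$act_time),
                       .data$x >= window[1] * strand_length,
                       .data$x <= window[2] * strand_length)
  cols <- if (nrow(act) == 0) act[0, c("x", "act_time")] else {
    act |>
      dplyr::group_by(.data$x) |>
      dplyr::summarise(t = min(.data$act_time), .groups = "drop")
  }
  if (nrow(cols) < 2) {
    return(list(cv = NA_real_, slope = NA_real_, r_squared = NA_real_,
                n_columns = nrow(cols), blocked = TRUE))
  }
  fit <- stats::lm(t ~ x, cols)
  slope <- stats::coef(fit)[["x"]]
  ss_tot <- sum((cols$t - mean(cols$t))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  list(cv = 0.1 / slope, # um/ms -> cm/s
       slope = slope,
       r_squared = r2,
       n_columns = nrow(cols),
       blocked = FALSE)
}

#' Conduction delay across a myofibroblast insert
#'
#' Linear fits of earliest activation time vs x in the proximal and distal
#' CMC segments (excluding a 0.2 mm buffer on each side of the insert and
#' the outer strand margins), both extrapolated to the insert center; the
#' delay is their difference at that point.
#'
#' @param act A tibble with columns `x` and `act_time` (CMC nodes only).
#' @param gap `c(x_start, x_end)` of the insert (um).
#' @param strand_length Strand length (um).
#' @param buffer Excluded margin next to the insert (um).
#' @param edge_margin Excluded margin at the strand extremities, as a
#'   fraction of segment length.
#' @return A list with `delay` (ms), the two fits' slopes, and `blocked`.
#' @export
insert_delay <- function(act, gap, strand_length, buffer = 200,
                         edge_margin = 0.1) {
  center <- mean(gap)
  act <- dplyr::filter(act, !is.na(.data$act_time))
  cols <- if (nrow(act) == 0) {
    tibble::tibble(x = numeric(), t = numeric())
  } else {
    act |>
      dplyr::group_by(.data$x) |>
      dplyr::summarise(t = min(.data$act_time), .groups = "drop")
  }
  prox <- dplyr::filter(cols, .data$x < gap[1] - buffer,
                        .data$x > edge_margin * gap[1])
  dist <- dplyr::filter(cols, .data$x > gap[2] + buffer,
                        .data$x < strand_length - edge_margin * (strand_length - gap[2]))
  if (nrow(prox) < 2 || nrow(dist) < 2) {
    return(list(delay = NA_real_, blocked = TRUE,
                slope_prox = NA_real_, slope_dist = NA_real_))
  }
  fp <- stats::lm(t ~ x, prox)
  fd <- stats::lm(t ~ x, dist)
  pred <- function(f) sum(stats::coef(f) * c(1, center))
  list(delay = pred(fd) - pred(fp), blocked = FALSE,
       slope_prox = stats::coef(fp)[["x"]], slope_dist = stats::coef(fd)[["x"]])
}

#' Run the full stimulation protocol on a layout
#'
#' Composite driver: equilibrate (with spontaneous-activity detection),
#' stimulate at one extremity (optionally a pacing train whose last beat is
#' the measured one), integrate, and extract the per-node RMP (membrane
#' potential at the time of the measured stimulus), activation-time and
#' dV/dt_max maps together with CV and, for insert configurations, the
#' conduction delay.
#'
#' @param layout A `tissue_layout`.
#' @param stim [stimulus_spec()].
#' @param post_window Integration time after the measured stimulus (ms).
#' @param equil Arguments passed to [equilibrate()] (list).
#' @param window Central fraction of the strand for CV and mean metrics.
#' @param sim Optionally a pre-built [strand_sim()] (skips construction).
#' @param ... Passed to [strand_sim()].
#' @return A `strand_measurement` object; see [glance.strand_measurement()].
#' @export
stimulate_and_measure <- function(layout, stim = stimulus_spec(),
                                  post_window = 50, equil = list(),
                                  window = c(0.25, 0.75), sim = NULL, ...) {
  sim <- sim %||% strand_sim(layout, ...)
  sim <- do.call(equilibrate, c(list(sim), equil))
  ws <- sim$ws[[format(sim$dt)]]
  nodes <- sim$net$nodes
  st <- reset_measurements(sim$state)
  stim_nodes <- nodes$node[nodes$x < stim$x_max & nodes$layer == 0]
  n_beats <- stim$count
  if (n_beats > 1) {
    stopifnot(!is.na(stim$period))
    starts <- st$t + (seq_len(n_beats - 1) - 1) * stim$period
    st <- sim_run(st, ws, (n_beats - 1) * stim$period,
                  stim = list(nodes = stim_nodes, amp = stim$amplitude,
                              starts = starts, duration = stim$duration))
    st <- reset_measurements(st)
  }
  rmp <- st$v # membrane potential at the time of the measured stimulation
  st <- sim_run(st, ws, post_window,
                stim = list(nodes = stim_nodes, amp = stim$amplitude,
                            starts = st$t, duration = stim$duration))
  res <- tibble::tibble(
    node = nodes$node, x = nodes$x, y = nodes$y, layer = nodes$layer,
    cell_id = nodes$cell_id, phenotype = nodes$phenotype,
    rmp = rmp, act_time = st$act_time - (st$t - post_window),
    dvdt_max = st$dvdt_max)
  cmc_base <- dplyr::filter(res, .data$phenotype == "CMC", .data$layer == 0)
  cv <- conduction_velocity(cmc_base, layout$domain[1], window)
  delay <- if (!is.null(layout$insert_gap)) {
    insert_delay(cmc_base, layout$insert_gap, layout$domain[1])
  }
  central <- dplyr::filter(cmc_base,
                           .data$x >= window[1] * layout$domain[1],
                           .data$x <= window[2] * layout$domain[1])
  structure(list(
    nodes = res,
    configuration = layout$configuration,
    domain = layout$domain,
    mfb_density = mfb_density(layout),
    cv = cv$cv, cv_fit = cv,
    mean_rmp = mean(central$rmp),
    mean_dvdt_max = mean(central$dvdt_max[!is.na(central$act_time)]),
    spontaneous = sim$spontaneous,
    blocked = cv$blocked || (!is.null(delay) && delay$blocked),
    delay = if (is.null(delay)) NA_real_ else delay$delay,
    equil_duration = sim$equil_duration
  ), class = "strand_measurement")
}

#' @export
print.strand_measurement <- function(x, ...) {
  cat("<strand_measurement>", x$configuration,
      sprintf("(%%MFB %.1f)\n", 100 * x$mfb_density))
  cat(sprintf("  CV %.1f cm/s | mean RMP %.1f mV | mean dV/dt_max %.1f V/s\n",
              x$cv, x$mean_rmp, x$mean_dvdt_max))
  if (x$spontaneous) cat("  spontaneous activity during equilibration\n")
  if (x$blocked) cat("  conduction blocked\n")
  if (!is.na(x$delay)) cat(sprintf("  insert delay %.1f ms\n", x$delay))
  invisible(x)
}

#' @export
tidy.strand_measurement <- function(x, ...) x$nodes

#' One-row summary of a strand measurement
#'
#' @param x A `strand_measurement`.
#' @param ... Unused.
#' @return A one-row tibble with configuration, MFB density, CV, mean RMP,
#'   mean dV/dt_max, spontaneous/blocked flags and insert delay.
#' @export
glance.strand_measurement <- function(x, ...) {
  tibble::tibble(configuration = x$configuration,
                 mfb_density = x$mfb_density,
                 cv = x$cv, mean_rmp = x$mean_rmp,
                 mean_dvdt_max = x$mean_dvdt_max,
                 spontaneous = x$spontaneous, blocked = x$blocked,
                 delay = x$delay)
}

#' @export
autoplot.strand_measurement <- function(object, map = c("act_time", "rmp", "dvdt_max"),
                                        ...) {
  map <- match.arg(map)
  df <- dplyr::filter(object$nodes, .data$layer == 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data[[map]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", fill = map)
}
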