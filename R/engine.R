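#' Rate and current lookup tables
#'
#' Tabulates, on a uniform potential grid, the Rush-Larsen coefficients
#' (steady-state value and exponential decay factor for the given time step)
#' of all six gates, together with the purely voltage-dependent current
#' terms (inward rectifier, delayed-rectifier rectification factor, plateau
#' current, passive MFB current). Linear interpolation between the 0.01 mV
#' bins keeps the error in any rate below 0.1%.
#'
#' @param dt Time step (ms) folded into the decay factors.
#' @param v_range Table range (mV); potentials outside are clamped.
#' @param dv Bin width (mV).
#' @param cmc [cmc_params()].
#' @param mfb [mfb_params()].
#' @return A list with `vmin`, `dv` and the table matrix.
#' @export
build_rate_tables <- function(dt, v_range = c(-150, 150), dv = 0.01,
                              cmc = cmc_params(), mfb = mfb_params()) {
  v <- seq(v_range[1], v_range[2], by = dv)
  r <- cmc_rates(v)
  tab <- matrix(0, length(v), 16)
  gg <- list(c("alpha_m", "beta_m"), c("alpha_h", "beta_h"),
             c("alpha_j", "beta_j"), c("alpha_d", "beta_d"),
             c("alpha_f", "beta_f"), c("alpha_x", "beta_x"))
  for (g in seq_along(gg)) {
    a <- r[[gg[[g]][1]]]; b <- r[[gg[[g]][2]]]
    s <- a + b
    tab[, g] <- ifelse(s > 0, a / pmax(s, 1e-300), 0)
    tab[, g + 6] <- exp(-dt * s)
  }
  tab[, 13] <- ik1_korhonen(v, cmc$ko, cmc$e_k)
  tab[, 14] <- cmc$g_k * xi_lr1(v) * (v - cmc$e_k_ik)
  tab[, 15] <- cmc$g_kp * kp_lr1(v) * (v - cmc$e_kp)
  tab[, 16] <- mfb_current(v, mfb)
  list(vmin = v_range[1], dv = dv, tab = tab)
}

#' Assemble the Crank-Nicolson solver workspace
#'
#' Builds the weighted graph Laplacian of the resistor network and the
#' capacitance-scaled symmetric Crank-Nicolson pencil
#' \deqn{(\mathrm{diag}(C) + \tfrac{\Delta t}{2} L)\, v^{+} =
#'       (\mathrm{diag}(C) - \tfrac{\Delta t}{2} L)\, v,}
#' factorizes the (symmetric positive definite) left operator once with a
#' fill-reducing sparse Cholesky decomposition, and tabulates the rate
#' lookup tables. Every subsequent time step performs exactly two
#' triangular solves against the stored factor.
#'
#' @param net A fully weighted [build_network()] result.
#' @param dt Time step (ms); the protocol value is 0.005 ms.
#' @param cmc,mfb Membrane parameter sets baked into the rate tables.
#' @return A list of class `solver_workspace`.
#' @export
assemble_cn <- function(net, dt = 0.005, cmc = cmc_params(), mfb = mfb_params()) {
  stopifnot(!any(is.na(net$edges$g)), !is.null(net$nodes$c_pf))
  n <- nrow(net$nodes)
  w <- Matrix::sparseMatrix(i = c(net$edges$node_a, net$edges$node_b),
                            j = c(net$edges$node_b, net$edges$node_a),
                            x = c(net$edges$g, net$edges$g), dims = c(n, n))
  lap <- Matrix::Diagonal(n, Matrix::rowSums(w)) - w
  cvec <- net$nodes$c_pf
  m1 <- Matrix::forceSymmetric(Matrix::Diagonal(n, cvec) + (dt / 2) * lap)
  m2 <- methods::as(Matrix::Diagonal(n, cvec) - (dt / 2) * lap, "CsparseMatrix")
  ch <- tryCatch(Matrix::Cholesky(m1, LDL = FALSE, perm = TRUE, super = FALSE),
                 error = function(e) stop("left operator is not SPD: ", conditionMessage(e)))
  ex <- Matrix::expand(ch)
  L <- methods::as(ex$L, "CsparseMatrix")
  # each factor column must start with its diagonal for the triangular solves
  stopifnot(all(L@i[L@p[seq_len(n)] + 1L] == seq_len(n) - 1L))
  structure(list(
    n = n, dt = dt,
    Lp = L@p, Li = L@i, Lx = L@x,
    perm0 = ex$P@perm - 1L,
    M2p = m2@p, M2i = m2@i, M2x = m2@x,
    c_pf = cvec, m1 = m1, m2 = m2,
    tables = build_rate_tables(dt, cmc = cmc, mfb = mfb),
    cmc = cmc, mfb = mfb,
    n_factorizations = 1L
  ), class = "solver_workspace")
}

#' Exact-exponential update agreement with the tables
#'
#' Evaluates the tabulated Rush-Larsen coefficients at arbitrary potentials
#' by the same linear interpolation the compiled engine uses (for table
#' accuracy checks).
#'
#' @param ws A [assemble_cn()] workspace.
#' @param v Potentials (mV).
#' @return A matrix with the interpolated table rows.
#' @export
interp_tables <- function(ws, v) {
  tb <- ws$tables
  pos <- pmin(pmax((v - tb$vmin) / tb$dv, 0), nrow(tb$tab) - 1.000001)
  i0 <- floor(pos)
  f <- pos - i0
  tb$tab[i0 + 1, , drop = FALSE] * (1 - f) + tb$tab[i0 + 2, , drop = FALSE] * f
}

#' Initial simulation state
#'
#' Every node starts at the resting state of its membrane model: CMC nodes
#' at the CMC resting potential with gates at steady state and Ca2+ at the
#' LR1 resting value, MFB nodes at -36.1 mV. The `excitable_mfb`
#' perturbation replaces the MFB membrane by the full CMC model at
#' unchanged coupling.
#'
#' @param net A weighted network.
#' @param ws Solver workspace (for the membrane parameters).
#' @param excitable_mfb Logical; use the CMC ionic model at every node.
#' @return A list of class `sim_state`.
#' @export
init_state <- function(net, ws, excitable_mfb = FALSE) {
  n <- nrow(net$nodes)
  model <- ifelse(net$nodes$phenotype == "MFB" & !excitable_mfb, 1L, 0L)
  v_cmc <- find_rmp("CMC", ws$cmc)
  v_mfb <- find_rmp("MFB", ws$mfb)
  v <- ifelse(model == 0L, v_cmc, v_mfb)
  ss <- cmc_steady_state(v_cmc, ws$cmc)
  gates <- matrix(0, n, 6)
  gates[model == 0L, ] <- matrix(rep(unlist(ss[c("m", "h", "j", "d", "f", "x")]),
                                     each = sum(model == 0L)), ncol = 6)
  structure(list(t = 0, v = v, gates = gates,
                 ca = rep(ws$cmc$ca_rest, n), model = model,
                 act_time = rep(NA_real_, n), dvdt_max = rep(0, n)),
            class = "sim_state")
}

#' Reset per-upstroke measurements
#'
#' Clears activation times and maximal upstroke velocities (used between
#' paced beats) without touching the dynamic state.
#'
#' @param state A `sim_state`.
#' @return The state with cleared measurement registers.
#' @export
reset_measurements <- function(state) {
  state$act_time[] <- NA_real_
  state$dvdt_max[] <- 0
  state
}

#' Advance the simulation
#'
#' Runs the compiled operator-split integrator: explicit membrane reaction
#' (tabulated Rush-Larsen gates, forward-Euler Ca2+, stimulus current) then
#' the Crank-Nicolson diffusion solve against the stored Cholesky factor.
#' Activation times (upward crossing of the -35 mV threshold), maximal
#' dV/dt and optional probe-node traces are recorded on the fly.
#'
#' @param state A [init_state()] state.
#' @param ws Matching [assemble_cn()] workspace.
#' @param duration Time to advance (ms).
#' @param stim `NULL` or a list with `nodes` (1-based node ids), `amp`
#'   (uA/uF, applied as depolarizing inward current), `starts` (onset times,
#'   ms, absolute), `duration` (ms).
#' @param probes Optional 1-based node ids whose V is recorded.
#' @param probe_stride Record every this many steps.
#' @param act_threshold Activation threshold (mV).
#' @return The updated state; probe traces in `$trace` (tibble). A warning
#'   is raised when any potential fell outside the rate-table range (it is
#'   clamped to the table ends).
#' @export
sim_run <- function(state, ws, duration, stim = NULL, probes = integer(0),
                    probe_stride = 10L, act_threshold = -35) {
  n_steps <- max(1L, round(duration / ws$dt))
  if (is.null(stim)) {
    stim <- list(nodes = integer(0), amp = 0, starts = numeric(0), duration = 0)
  }
  res <- .run_chunk(n_steps, ws$dt, state$t,
                    ws$Lp, ws$Li, ws$Lx, ws$perm0,
                    ws$M2p, ws$M2i, ws$M2x,
                    state$v, state$gates, state$ca, state$model,
                    ws$tables$vmin, ws$tables$dv, ws$tables$tab,
                    c(ws$cmc$g_na, ws$cmc$e_na, ws$cmc$g_si),
                    as.integer(stim$nodes) - 1L, -abs(stim$amp),
                    stim$starts, stim$duration,
                    state$act_time, state$dvdt_max,
                    as.integer(probes) - 1L, probe_stride, act_threshold)
  state$v <- res$v
  state$gates <- res$gates
  state$ca <- res$ca
  state$t <- res$t
  state$act_time <- res$act_time
  state$dvdt_max <- res$dvdt_max
  if (res$clamped > 0) {
    warning("membrane potential outside rate-table range at ", res$clamped,
            " node-step(s); clamped to table ends")
  }
  if (length(probes) > 0) {
    tr <- res$traces
    colnames(tr) <- paste0("node_", probes)
    state$trace <- dplyr::bind_cols(tibble::tibble(t = res$trace_t),
                                    tibble::as_tibble(tr))
  }
  state
}
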