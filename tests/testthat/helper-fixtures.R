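# Shared fixtures and a cross-test cache so expensive simulations are run
# once per suite.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A hand-built two-rectangle layout (two 60x20 um cells abutting end to end)
# for exact-geometry checks.
two_rect_layout <- function(side_by_side = FALSE, phenos = c("CMC", "CMC")) {
  if (side_by_side) {
    domain <- c(60, 40)
    v1 <- cbind(c(0, 60, 60, 0), c(0, 0, 20, 20))
    v2 <- cbind(c(0, 60, 60, 0), c(20, 20, 40, 40))
    l1 <- c(0L, 0L, 2L, 0L) # edge to cell 2 is the top edge
    l2 <- c(1L, 0L, 0L, 0L) # edge to cell 1 is the bottom edge
  } else {
    domain <- c(120, 20)
    v1 <- cbind(c(0, 60, 60, 0), c(0, 0, 20, 20))
    v2 <- cbind(c(60, 120, 120, 60), c(0, 0, 20, 20))
    l1 <- c(0L, 2L, 0L, 0L)
    l2 <- c(0L, 0L, 0L, 1L)
  }
  cells <- tibble::tibble(
    cell_id = 1:2, layer = 0L, phenotype = phenos, tess_id = 1:2,
    x_lo = -Inf, x_hi = Inf,
    area = c(1200, 1200), perimeter = c(160, 160),
    bbox_l = c(60, 60), bbox_w = c(20, 20), thickness = 3,
    vertices = list(v1, v2), edge_labels = list(l1, l2))
  fibrostrand:::new_tissue_layout(cells, domain, "control",
                                  layer_meta = list(`0` = list(spacing = c(60, 20))))
}

# A passive membrane producing I = g_l * (V - v0) uA/uF (for analytic RC
# checks); a2 = 0 removes the exponential term.
leak_mfb <- function(g_l, v0) {
  mfb_params(a0 = -g_l * v0, a1 = g_l, a2 = 0, k = 1, c_norm = 1)
}

# Zero-current membrane: pure diffusion.
null_mfb <- function() mfb_params(a0 = 0, a1 = 0, a2 = 0, k = 1, c_norm = 1)

# Minimal hand-built discrete network (for operator-level solver tests).
toy_network <- function(c_pf, edges) {
  n <- length(c_pf)
  nodes <- tibble::tibble(node = seq_len(n), i = seq_len(n) - 1L, j = 0L,
                          layer = 0L, cell_id = seq_len(n),
                          phenotype = "MFB",
                          x = (seq_len(n) - 0.5) * 2.5, y = 1.25,
                          c_pf = c_pf)
  structure(list(nodes = nodes, edges = edges, grid = grid_params(),
                 layout = NULL, nxe = n, nye = 1L),
            class = "discrete_network")
}

toy_state <- function(ws, v, n) {
  structure(list(t = 0, v = v, gates = matrix(0, n, 6),
                 ca = rep(2e-4, n), model = rep(1L, n),
                 act_time = rep(NA_real_, n), dvdt_max = rep(0, n)),
            class = "sim_state")
}

# Small control strand measurement shared between protocol tests.
control_strand_small <- function() {
  cached("control_small", {
    tess <- tessellate_strand(c(800, 40), spec_cmc(), 101)
    assign_endogenous(tess, 0, 101)
  })
}

# Quiescence of an unstimulated control strand over the full 2 s protocol
# (at the protocol time step).
quiescence_run <- function() {
  cached("quiescence", {
    lay <- assign_endogenous(tessellate_strand(c(240, 40), spec_cmc(), 21), 0, 21)
    sim <- strand_sim(lay)
    equilibrate(sim, max_duration = 2000, min_duration = 2000, drift_tol = 0)
  })
}

# Spontaneous-activity probe of a fully coated strand (50% MFB density).
spontaneity_run <- function() {
  cached("spontaneity", {
    tess <- tessellate_strand(c(300, 40), spec_cmc(), 22)
    lay <- add_coating(assign_endogenous(tess, 0, 22), 1, spec_mfb_large(), 22)
    sim <- strand_sim(lay)
    equilibrate(sim, max_duration = 2000, equil_dt = 0.05)
  })
}

run_condition <- function(domain, arch, level, seed, post_window = 30,
                          perturbation = "none", stim = stimulus_spec(),
                          equil = list(equil_dt = 0.05, max_duration = 1000)) {
  key <- paste("cond", paste(domain, collapse = "x"), arch, level, seed,
               perturbation, stim$count, post_window,
               paste(unlist(equil), collapse = "-"), sep = "_")
  cached(key, {
    cfg <- scenario_config(arch, levels = level, domain = domain,
                           seeds = seed, perturbation = perturbation,
                           stim = stim, equil = equil,
                           post_window = post_window)
    run_scenario(cfg)
  })
}
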