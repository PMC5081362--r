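#' Scenario configuration
#'
#' Describes a family of simulations: one tissue architecture, a grid of
#' MFB densities / coverages / insert lengths, a number of independent
#' tissue realizations per condition and an optional mechanism-dissection
#' perturbation. Defaults follow the published study design (densities
#' 0-50% in steps of 5% for endogenous MFBs, coverages 0-100% in steps of
#' 10%, insert lengths 240-2880 um, 5 realizations per condition).
#'
#' @param architecture One of `"control"`, `"endogenous"`,
#'   `"coating_large"`, `"coating_small"`, `"insert_coated"`,
#'   `"insert_only"`.
#' @param levels Density grid (endogenous), coverage grid (coating) or
#'   insert-length grid in um (inserts); `NULL` gives the architecture's
#'   published default.
#' @param domain Strand dimensions (um).
#' @param n_realizations Independent tissue realizations per condition.
#' @param perturbation `"none"`, `"strong_coupling"`, `"excitable_mfb"` or
#'   `"strong_coupling+excitable_mfb"`.
#' @param seeds Base seeds, one per realization (default `1:n`).
#' @param stim [stimulus_spec()]; inserts default to a 2 Hz train.
#' @param equil Arguments for [equilibrate()].
#' @param post_window Integration window after the measured stimulus (ms).
#' @param grid,params,cmc,mfb,dt Model settings, see [strand_sim()].
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(architecture = c("endogenous", "control",
                                             "coating_large", "coating_small",
                                             "insert_coated", "insert_only"),
                            levels = NULL, domain = NULL, n_realizations = 5,
                            perturbation = c("none", "strong_coupling",
                                             "excitable_mfb",
                                             "strong_coupling+excitable_mfb"),
                            seeds = NULL, stim = NULL, equil = NULL,
                            post_window = 50,
                            grid = grid_params(), params = electrical_params(),
                            cmc = cmc_params(), mfb = mfb_params(), dt = 0.005) {
  architecture <- match.arg(architecture)
  perturbation <- match.arg(perturbation)
  insert <- architecture %in% c("insert_coated", "insert_only")
  levels <- levels %||% switch(architecture,
    control = 0,
    endogenous = seq(0, 0.5, by = 0.05),
    coating_large = , coating_small = seq(0, 1, by = 0.1),
    insert_coated = , insert_only = seq(240, 2880, by = 240))
  domain <- domain %||% if (insert) c(6000, 80) else c(3000, 80)
  # Insert strands are paced and measured on the last beat of a train. In
  # this implementation the action potential of fully coated strands is long
  # enough that 2 Hz pacing shows 2:1 capture (every second stimulus falls
  # into the refractory plateau); the default train therefore uses the
  # captured rhythm (1 s interval).
  stim <- stim %||% if (insert) {
    stimulus_spec(period = 1000, count = 3L)
  } else {
    stimulus_spec()
  }
  # fully coated insert strands have no stable rest (complete coverage is
  # spontaneously active); they get a fixed-length conditioning phase (the
  # initial transient beat plays the role of the first paced beat) instead
  # of a drift-terminated quiescent run
  equil <- equil %||% if (architecture == "insert_coated") {
    list(equil_dt = 0.1, max_duration = 950, min_duration = 950, settle = 50,
         stop_on_spontaneous = FALSE)
  } else {
    list(equil_dt = 0.05)
  }
  seeds <- seeds %||% seq_len(n_realizations)
  structure(list(architecture = architecture, levels = levels, domain = domain,
                 seeds = seeds, perturbation = perturbation, stim = stim,
                 equil = equil, post_window = post_window, grid = grid,
                 params = params, cmc = cmc, mfb = mfb, dt = dt),
            class = "scenario_config")
}

#' Apply a mechanism-dissection perturbation
#'
#' `strong_coupling` raises the MFB-involving junctional conductivities
#' (lateral gamma and vertical g_z) to the CMC-CMC values, isolating the
#' contribution of the different ionic repertoires. `excitable_mfb` swaps
#' the MFB membrane for the full CMC ionic model (including the fast Na+
#' current) at unchanged coupling, isolating the resistive contribution of
#' the MFBs. The combination applies both.
#'
#' @param params [electrical_params()].
#' @param perturbation Perturbation name (see [scenario_config()]).
#' @return A list with `params` (possibly modified) and `excitable_mfb`
#'   (logical).
#' @export
apply_perturbation <- function(params, perturbation = "none") {
  strong <- grepl("strong_coupling", perturbation, fixed = TRUE)
  excitable <- grepl("excitable_mfb", perturbation, fixed = TRUE)
  if (strong) {
    params$gamma_cmc_mfb <- params$gamma_cmc_cmc
    params$gamma_mfb_mfb <- params$gamma_cmc_cmc
    params$gz_cmc_mfb <- params$gz_cmc_cmc
    params$gz_mfb_mfb <- params$gz_cmc_cmc
  }
  list(params = params, excitable_mfb = excitable)
}

build_scenario_layout <- function(cfg, level, seed) {
  switch(cfg$architecture,
    control = assign_endogenous(tessellate_strand(cfg$domain, spec_cmc(), seed), 0, seed),
    endogenous = assign_endogenous(tessellate_strand(cfg$domain, spec_cmc(), seed),
                                   level, seed),
    coating_large = add_coating(
      assign_endogenous(tessellate_strand(cfg$domain, spec_cmc(), seed), 0, seed),
      level, spec_mfb_large(), seed),
    coating_small = add_coating(
      assign_endogenous(tessellate_strand(cfg$domain, spec_cmc(), seed), 0, seed),
      level, spec_mfb_cmc_sized(), seed),
    insert_coated = build_insert(cfg$domain, level, coated = TRUE, rng_seed = seed),
    insert_only = build_insert(cfg$domain, level, coated = FALSE, rng_seed = seed))
}

#' Run a scenario
#'
#' Loops over the condition grid and the tissue realizations, runs the full
#' measurement protocol for each and returns a tidy results table (one row
#' per realization x condition). Spontaneously active realizations are kept
#' in the table, flagged, and excluded from the aggregated summary
#' (`summarize_scenario()`), mirroring the exclusion rule of the study.
#' Individual failures are recorded and the run continues.
#'
#' @param cfg A [scenario_config()].
#' @param out Optional directory; results are written as CSV.
#' @param verbose Print one line per realization.
#' @return A tibble with per-realization metrics.
#' @export
run_scenario <- function(cfg, out = NULL, verbose = FALSE) {
  pert <- apply_perturbation(cfg$params, cfg$perturbation)
  grid_df <- tidyr::expand_grid(level = cfg$levels, seed = cfg$seeds)
  res <- purrr::pmap_dfr(grid_df, function(level, seed) {
    row <- tibble::tibble(architecture = cfg$architecture,
                          perturbation = cfg$perturbation,
                          level = level, seed = seed)
    meas <- tryCatch({
      layout <- build_scenario_layout(cfg, level, seed)
      sim <- strand_sim(layout, cfg$grid, pert$params, cfg$cmc, cfg$mfb,
                        cfg$dt, excitable_mfb = pert$excitable_mfb)
      stimulate_and_measure(layout, stim = cfg$stim, sim = sim,
                            post_window = cfg$post_window, equil = cfg$equil)
    }, error = function(e) e)
    if (inherits(meas, "error")) {
      row$error <- conditionMessage(meas)
      if (verbose) message("level ", level, " seed ", seed, " failed: ", row$error)
      return(row)
    }
    out_row <- dplyr::bind_cols(row, glance(meas)[-1])
    out_row$error <- NA_character_
    if (verbose) {
      message(sprintf("level %g seed %d: CV %.1f cm/s RMP %.1f mV%s",
                      level, seed, out_row$cv, out_row$mean_rmp,
                      if (isTRUE(out_row$spontaneous)) " [spontaneous]" else ""))
    }
    out_row
  })
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res, file.path(out, paste0(
      "scenario_", cfg$architecture, "_", cfg$perturbation, ".csv")),
      row.names = FALSE)
  }
  res
}

#' Aggregate scenario results
#'
#' Mean and SD of CV, RMP, dV/dt_max and insert delay per condition,
#' excluding spontaneously active or failed realizations from the
#' conduction statistics.
#'
#' @param res A [run_scenario()] table.
#' @return A tibble with one row per condition level.
#' @export
summarize_scenario <- function(res) {
  res |>
    dplyr::filter(is.na(.data$error),
                  # spontaneous tissues are excluded from the density-sweep
                  # statistics; paced insert strands are kept (pacing
                  # overdrives their slow intrinsic activity)
                  !.data$spontaneous | grepl("insert", .data$architecture)) |>
    dplyr::group_by(.data$architecture, .data$perturbation, .data$level) |>
    dplyr::summarise(
      n = dplyr::n(),
      mfb_density = mean(.data$mfb_density),
      cv_mean = mean(.data$cv[!.data$blocked]),
      cv_sd = stats::sd(.data$cv[!.data$blocked]),
      rmp_mean = mean(.data$mean_rmp),
      dvdt_mean = mean(.data$mean_dvdt_max),
      delay_mean = mean(.data$delay[!.data$blocked]),
      n_blocked = sum(.data$blocked),
      .groups = "drop")
}

#' Attribute conduction slowing to coupling vs phenotype
#'
#' For matched-seed runs under control parameters, strong coupling and
#' excitable MFBs, computes per condition the CV differences
#' \eqn{\Delta CV_{coupling} = CV_{strong} - CV_{control}} (the slowing
#' attributable to the moderate MFB coupling) and
#' \eqn{\Delta CV_{phenotype} = CV_{excitable} - CV_{control}} (the slowing
#' attributable to the unexcitable, depolarized MFB phenotype).
#'
#' @param res_control,res_strong,res_excitable [run_scenario()] tables with
#'   identical architecture, levels and seeds.
#' @return A tibble per level with mean control CV and the two paired mean
#'   differences.
#' @export
decompose_cv <- function(res_control, res_strong, res_excitable) {
  key <- c("architecture", "level", "seed")
  if (!identical(res_control[key], res_strong[key]) ||
      !identical(res_control[key], res_excitable[key])) {
    stop("runs are not matched (architecture/level/seed)")
  }
  paired <- dplyr::bind_rows(res_control, res_strong, res_excitable) |>
    dplyr::filter(is.na(.data$error), !.data$spontaneous, !.data$blocked) |>
    dplyr::select(dplyr::all_of(c(key, "perturbation", "cv"))) |>
    tidyr::pivot_wider(names_from = "perturbation", values_from = "cv") |>
    tidyr::drop_na()
  paired |>
    dplyr::group_by(.data$architecture, .data$level) |>
    dplyr::summarise(
      n = dplyr::n(),
      cv_control = mean(.data$none),
      dcv_coupling = mean(.data$strong_coupling - .data$none),
      dcv_phenotype = mean(.data$excitable_mfb - .data$none),
      .groups = "drop")
}
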