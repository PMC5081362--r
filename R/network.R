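#' Discretization grid parameters
#'
#' Square in-plane lattice step and inter-layer (z) spacing. Defaults follow
#' the tissue model: 2.5 um in-plane, 3 um (one cell thickness) between the
#' base and coating layers.
#'
#' @param dx,dy In-plane element size (um).
#' @param dz Inter-layer spacing (um), informational.
#' @return A list of class `grid_params`.
#' @export
grid_params <- function(dx = 2.5, dy = 2.5, dz = 3) {
  stopifnot(dx > 0, dy > 0, dz > 0)
  structure(list(dx = dx, dy = dy, dz = dz), class = "grid_params")
}

#' Passive electrical parameters
#'
#' Cytoplasmic resistivity, specific membrane capacitance, the intercellular
#' junctional conductivities gamma (conductance per um of contact length;
#' CMC-MFB and MFB-MFB are 5x smaller than CMC-CMC) and the inter-layer
#' conductances per discrete 2.5 x 2.5 um element (g_z, which already
#' include the cytoplasmic z-resistance in series).
#'
#' @param rho_cyto Cytoplasmic resistivity (Ohm cm), isotropic, identical
#'   for both cell types.
#' @param c_m Specific membrane capacitance (uF/cm^2).
#' @param gamma_cmc_cmc,gamma_cmc_mfb,gamma_mfb_mfb Lateral junctional
#'   conductivity (nS/um).
#' @param gz_cmc_cmc,gz_cmc_mfb,gz_mfb_mfb Vertical conductance per discrete
#'   element (nS).
#' @return A list of class `electrical_params`.
#' @export
electrical_params <- function(rho_cyto = 124, c_m = 1,
                              gamma_cmc_cmc = 77.4, gamma_cmc_mfb = 15.5,
                              gamma_mfb_mfb = 15.5,
                              gz_cmc_cmc = 2.94, gz_cmc_mfb = 0.59,
                              gz_mfb_mfb = 0.59) {
  p <- as.list(environment())
  stopifnot(all(unlist(p) > 0))
  structure(p, class = "electrical_params")
}

gamma_for <- function(params, pheno_a, pheno_b) {
  both_cmc <- pheno_a == "CMC" & pheno_b == "CMC"
  both_mfb <- pheno_a == "MFB" & pheno_b == "MFB"
  ifelse(both_cmc, params$gamma_cmc_cmc,
         ifelse(both_mfb, params$gamma_mfb_mfb, params$gamma_cmc_mfb))
}

gz_for <- function(params, pheno_a, pheno_b) {
  both_cmc <- pheno_a == "CMC" & pheno_b == "CMC"
  both_mfb <- pheno_a == "MFB" & pheno_b == "MFB"
  ifelse(both_cmc, params$gz_cmc_cmc,
         ifelse(both_mfb, params$gz_mfb_mfb, params$gz_cmc_mfb))
}

#' Discretize a tissue layout onto the regular grid
#'
#' Every grid element whose center falls inside a cell polygon becomes a
#' node of that cell (ties on exact boundaries go to the lower cell id).
#' Element pairs sharing a grid face within one cell form cytoplasmic edges;
#' across two cells of one layer, junctional-lateral edges tagged with their
#' parent contact; vertically overlapping base/coating elements form
#' vertical edges. Elements over empty coating regions or inside an
#' uncovered insert gap carry no node.
#'
#' @param layout A `tissue_layout`.
#' @param grid [grid_params()].
#' @return A list of class `discrete_network` with `nodes` and `edges`
#'   tibbles (topology only; see [lateral_conductances()],
#'   [vertical_conductances()], [capacitances()]).
#' @export
discretize <- function(layout, grid = grid_params()) {
  nxe <- round(layout$domain[1] / grid$dx)
  nye <- round(layout$domain[2] / grid$dy)
  layers <- sort(unique(layout$cells$layer))
  rasters <- list()
  for (lay in layers) {
    cells <- layout$cells[layout$cells$layer == lay, , drop = FALSE]
    cells <- cells[order(cells$cell_id), , drop = FALSE]
    nv <- vapply(cells$vertices, nrow, 0L)
    rasters[[as.character(lay)]] <- .raster_assign(
      nxe, nye, grid$dx, grid$dy,
      unlist(lapply(cells$vertices, function(v) v[, 1])),
      unlist(lapply(cells$vertices, function(v) v[, 2])),
      c(0L, cumsum(nv)), cells$cell_id)
  }
  # nodes
  node_tbls <- lapply(layers, function(lay) {
    M <- rasters[[as.character(lay)]]
    occ <- which(M > 0L, arr.ind = TRUE)
    tibble::tibble(i = occ[, 1] - 1L, j = occ[, 2] - 1L, layer = lay,
                   cell_id = M[occ])
  })
  nodes <- dplyr::bind_rows(node_tbls) |>
    dplyr::arrange(.data$layer, .data$i, .data$j) |>
    dplyr::mutate(node = dplyr::row_number(), .before = 1)
  pheno <- layout$cells$phenotype[match(nodes$cell_id, layout$cells$cell_id)]
  nodes$phenotype <- pheno
  nodes$x <- (nodes$i + 0.5) * grid$dx
  nodes$y <- (nodes$j + 0.5) * grid$dy
  missing_cells <- setdiff(layout$cells$cell_id, unique(nodes$cell_id))
  if (length(missing_cells) > 0) {
    warning(length(missing_cells),
            " cell(s) thinner than one grid element vanished from the grid")
  }
  # node-id lookup per layer
  idx <- list()
  for (lay in layers) {
    m <- matrix(0L, nxe, nye)
    sel <- nodes$layer == lay
    m[cbind(nodes$i[sel] + 1L, nodes$j[sel] + 1L)] <- nodes$node[sel]
    idx[[as.character(lay)]] <- m
  }
  edge_list <- list()
  for (lay in layers) {
    M <- rasters[[as.character(lay)]]
    id <- idx[[as.character(lay)]]
    # x-direction faces
    a <- id[-nxe, , drop = FALSE]; b <- id[-1, , drop = FALSE]
    ca <- M[-nxe, , drop = FALSE]; cb <- M[-1, , drop = FALSE]
    sel <- a > 0L & b > 0L
    ex <- tibble::tibble(node_a = a[sel], node_b = b[sel],
                         cell_a = ca[sel], cell_b = cb[sel])
    # y-direction faces
    a <- id[, -nye, drop = FALSE]; b <- id[, -1, drop = FALSE]
    ca <- M[, -nye, drop = FALSE]; cb <- M[, -1, drop = FALSE]
    sel <- a > 0L & b > 0L
    ey <- tibble::tibble(node_a = a[sel], node_b = b[sel],
                         cell_a = ca[sel], cell_b = cb[sel])
    e <- dplyr::bind_rows(ex, ey)
    e$kind <- ifelse(e$cell_a == e$cell_b, "cytoplasmic", "junctional_lateral")
    edge_list[[length(edge_list) + 1]] <- e
  }
  if (length(layers) == 2) {
    id0 <- idx[["0"]]; id1 <- idx[["1"]]
    sel <- id0 > 0L & id1 > 0L
    M0 <- rasters[["0"]]; M1 <- rasters[["1"]]
    edge_list[[length(edge_list) + 1]] <- tibble::tibble(
      node_a = id0[sel], node_b = id1[sel],
      cell_a = M0[sel], cell_b = M1[sel], kind = "vertical")
  }
  edges <- dplyr::bind_rows(edge_list)
  edges$g <- NA_real_
  structure(list(nodes = nodes, edges = edges, grid = grid, layout = layout,
                 nxe = nxe, nye = nye, rasters = rasters),
            class = "discrete_network")
}

#' @export
print.discrete_network <- function(x, ...) {
  cat("<discrete_network>", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat("  grid:", x$nxe, "x", x$nye, "elements at", x$grid$dx, "um\n")
  invisible(x)
}

#' Lateral conductances (cytoplasmic and junctional)
#'
#' Cytoplasmic edges get \eqn{g = (1/\rho_{cyto}) T \Delta y / \Delta x}
#' (and symmetrically in y). Each lateral contact's total junctional
#' conductance is \eqn{G = \gamma_{ab} L_c}, redistributed uniformly over
#' its N discretized staircase faces (\eqn{g = G/N}), so the per-contact
#' total is independent of the grid step.
#'
#' @param net A [discretize()]d network.
#' @param params [electrical_params()].
#' @return The network with lateral edge weights (nS) filled in.
#' @export
lateral_conductances <- function(net, params = electrical_params()) {
  edges <- net$edges
  cells <- net$layout$cells
  thick <- cells$thickness[match(edges$cell_a, cells$cell_id)]
  # square lattice: dy/dx = 1, so one value serves both orientations
  g_cyto <- 1e9 * (thick * 1e-4 * net$grid$dy * 1e-4) /
    (params$rho_cyto * net$grid$dx * 1e-4) # nS
  cyto <- edges$kind == "cytoplasmic"
  edges$g[cyto] <- g_cyto[cyto]
  jl <- which(edges$kind == "junctional_lateral")
  if (length(jl) > 0) {
    key <- paste(pmin(edges$cell_a[jl], edges$cell_b[jl]),
                 pmax(edges$cell_a[jl], edges$cell_b[jl]))
    n_seg <- table(key)
    ct <- net$layout$contacts[net$layout$contacts$orientation == "lateral", ]
    ckey <- paste(pmin(ct$cell_a, ct$cell_b), pmax(ct$cell_a, ct$cell_b))
    lc <- ct$length[match(key, ckey)]
    # contacts present on the grid but absent from the polygon arrangement
    # (corner-only touches) get zero conductance and are dropped
    lc[is.na(lc)] <- 0
    pa <- cells$phenotype[match(edges$cell_a[jl], cells$cell_id)]
    pb <- cells$phenotype[match(edges$cell_b[jl], cells$cell_id)]
    edges$g[jl] <- gamma_for(params, pa, pb) * lc / as.numeric(n_seg[key])
    # a contact clearly wider than one grid step between two cells that both
    # survived rasterization must produce >= 1 face; narrow slivers and
    # contacts of vanished cells are dropped silently
    present <- unique(net$nodes$cell_id)
    wide <- ct$length > 2 * max(net$grid$dx, net$grid$dy) &
      ct$cell_a %in% present & ct$cell_b %in% present
    if (any(!(ckey[wide] %in% key))) {
      stop("contact(s) with no discretized face: geometry/topology mismatch")
    }
  }
  net$edges <- dplyr::filter(edges, .data$kind == "vertical" | .data$g > 0)
  net
}

#' Vertical (inter-layer) conductances
#'
#' Every overlapping base/coating element pair receives the per-element
#' conductance g_z of its phenotype pair (CMC-MFB by default 0.59 nS; the
#' CMC-CMC value 2.94 nS applies in the strongly-coupled perturbation).
#'
#' @inheritParams lateral_conductances
#' @return The network with vertical edge weights (nS) filled in.
#' @export
vertical_conductances <- function(net, params = electrical_params()) {
  vert <- which(net$edges$kind == "vertical")
  if (length(vert) > 0) {
    cells <- net$layout$cells
    pa <- cells$phenotype[match(net$edges$cell_a[vert], cells$cell_id)]
    pb <- cells$phenotype[match(net$edges$cell_b[vert], cells$cell_id)]
    net$edges$g[vert] <- gz_for(params, pa, pb)
  }
  net
}

#' Node membrane capacitances
#'
#' Each cell's capacitance is \eqn{C = C_m (2A + T P)} with the footprint
#' area A and perimeter P of its continuous polygon (surfaces above and
#' below plus the lateral surface; both cells contribute lateral membrane at
#' a shared boundary). The cell total is distributed over its nodes
#' proportionally to the membrane area attributed to each node:
#' \eqn{2 \Delta x \Delta y} for every node plus \eqn{T \Delta} for each
#' grid face on the cell border, so summation over nodes recovers the cell
#' total exactly.
#'
#' @inheritParams lateral_conductances
#' @return The network with a `c_pf` column (pF) added to `nodes`.
#' @export
capacitances <- function(net, params = electrical_params()) {
  cells <- net$layout$cells
  c_cell <- params$c_m * 0.01 * (2 * cells$area + cells$thickness * cells$perimeter) # pF
  # border faces per node: 4 minus the number of same-cell lateral neighbours
  lat <- net$edges[net$edges$kind == "cytoplasmic", ]
  ncyt <- tabulate(c(lat$node_a, lat$node_b), nbins = nrow(net$nodes))
  thick <- cells$thickness[match(net$nodes$cell_id, cells$cell_id)]
  w <- 2 * net$grid$dx * net$grid$dy + thick * net$grid$dx * (4 - ncyt)
  wsum <- tapply(w, net$nodes$cell_id, sum)
  cc <- c_cell[match(net$nodes$cell_id, cells$cell_id)]
  net$nodes$c_pf <- cc * w / as.numeric(wsum[as.character(net$nodes$cell_id)])
  net
}

#' Build a fully weighted network from a layout
#'
#' Convenience wrapper: [discretize()] then [lateral_conductances()],
#' [vertical_conductances()] and [capacitances()].
#'
#' @param layout A `tissue_layout`.
#' @param grid [grid_params()].
#' @param params [electrical_params()].
#' @return A weighted `discrete_network`.
#' @export
build_network <- function(layout, grid = grid_params(),
                          params = electrical_params()) {
  discretize(layout, grid) |>
    lateral_conductances(params) |>
    vertical_conductances(params) |>
    capacitances(params)
}

#' @export
tidy.discrete_network <- function(x, ...) x$nodes
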