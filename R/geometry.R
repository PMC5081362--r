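#' Cell type specification
#'
#' Nominal dimensions of a cell population. Cultured cardiomyocytes (CMCs)
#' and endogenous myofibroblasts (MFBs) measure 60 x 20 x 3 um; large coating
#' MFBs measure 120 x 40 x 3 um. Tessellated cells are seeded at a density of
#' one cell per elliptical footprint pi*L*W/4, which reproduces the measured
#' mean single-cell capacitances under the geometric capacitance rule.
#'
#' @param phenotype `"CMC"` or `"MFB"`.
#' @param length,width,thickness Nominal cell dimensions (um).
#' @return A list of class `cell_spec`.
#' @export
cell_spec <- function(phenotype = c("CMC", "MFB"), length = 60, width = 20,
                      thickness = 3) {
  phenotype <- match.arg(phenotype)
  stopifnot(length > 0, width > 0, thickness > 0)
  structure(list(phenotype = phenotype, length = length, width = width,
                 thickness = thickness), class = "cell_spec")
}

#' @rdname cell_spec
#' @export
spec_cmc <- function() cell_spec("CMC", 60, 20, 3)

#' @rdname cell_spec
#' @export
spec_mfb_cmc_sized <- function() cell_spec("MFB", 60, 20, 3)

#' @rdname cell_spec
#' @export
spec_mfb_large <- function() cell_spec("MFB", 120, 40, 3)

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

shoelace_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

polygon_perimeter <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

# Clip a convex polygon (CCW, edge e_i = v_i -> v_{i+1} labelled labels[i])
# by the half-plane {p : nrm . (p - mid) <= 0}; the newly created edge gets
# label `lab`. Returns NULL when the polygon is fully removed.
clip_halfplane <- function(verts, labels, nrm, mid, lab, eps = 1e-9) {
  d <- (verts[, 1] - mid[1]) * nrm[1] + (verts[, 2] - mid[2]) * nrm[2]
  inside <- d <= eps
  if (all(inside)) return(list(verts = verts, labels = labels))
  if (!any(inside)) return(NULL)
  n <- nrow(verts)
  vx <- numeric(0); vy <- numeric(0); lb <- integer(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) {
      vx <- c(vx, verts[i, 1]); vy <- c(vy, verts[i, 2])
      if (inside[j]) {
        lb <- c(lb, labels[i])
      } else {
        t <- d[i] / (d[i] - d[j])
        vx <- c(vx, verts[i, 1] + t * (verts[j, 1] - verts[i, 1]))
        vy <- c(vy, verts[i, 2] + t * (verts[j, 2] - verts[i, 2]))
        lb <- c(lb, labels[i], lab)
      }
    } else if (inside[j]) {
      t <- d[i] / (d[i] - d[j])
      vx <- c(vx, verts[i, 1] + t * (verts[j, 1] - verts[i, 1]))
      vy <- c(vy, verts[i, 2] + t * (verts[j, 2] - verts[i, 2]))
      lb <- c(lb, labels[i])
    }
  }
  # drop vertices whose outgoing edge is degenerate (keeps labels aligned:
  # edge t lives and dies with vertex t)
  m <- length(vx)
  nxt <- c(seq_len(m)[-1], 1L)
  keep <- sqrt((vx[nxt] - vx)^2 + (vy[nxt] - vy)^2) > 1e-9
  if (sum(keep) < 3) return(NULL)
  list(verts = cbind(vx, vy)[keep, , drop = FALSE], labels = lb[keep])
}

# Anisotropic Voronoi tessellation of a rectangle from a jittered grid of
# seeds. Returns a list with per-cell polygons (vertices + per-edge neighbour
# labels), the seeds and the grid spacing. Edge label 0 = domain boundary,
# k > 0 = bisector with seed k.
voronoi_tessellation <- function(domain, spec, rng_seed, jitter = 0.35) {
  len <- domain[1]; wid <- domain[2]
  if (len < spec$length || wid < spec$width) stop("domain too small")
  # rows of nominal cell width; columns chosen so the seed density is
  # 1/(pi*L*W/4), i.e. one cell per mean elliptical footprint
  n_target <- len * wid / (pi * spec$length * spec$width / 4)
  ny <- max(1L, round(wid / spec$width))
  nx <- max(1L, round(n_target / ny))
  sx <- len / nx; sy <- wid / ny
  seeds <- with_seed(rng_seed, {
    gx <- rep(seq_len(nx) - 0.5, times = ny) * sx
    gy <- rep(seq_len(ny) - 0.5, each = nx) * sy
    cbind(gx + stats::runif(nx * ny, -jitter, jitter) * sx,
          gy + stats::runif(nx * ny, -jitter, jitter) * sy)
  })
  n <- nx * ny
  rect <- cbind(c(0, len, len, 0), c(0, 0, wid, wid))
  rect_lab <- c(0L, 0L, 0L, 0L)
  cells <- vector("list", n)
  ix <- (seq_len(n) - 1L) %% nx
  iy <- (seq_len(n) - 1L) %/% nx
  for (k in seq_len(n)) {
    # candidate neighbours within a 7x7 index window, nearest first
    sel <- which(abs(ix - ix[k]) <= 3L & abs(iy - iy[k]) <= 3L)
    sel <- sel[sel != k]
    du <- (seeds[sel, 1] - seeds[k, 1]) / sx
    dv <- (seeds[sel, 2] - seeds[k, 2]) / sy
    dist2 <- du^2 + dv^2
    ord <- order(dist2)
    verts <- rect; labels <- rect_lab
    for (q in ord) {
      # prune: a bisector at scaled distance >= polygon radius cannot cut
      ru <- (verts[, 1] - seeds[k, 1]) / sx
      rv <- (verts[, 2] - seeds[k, 2]) / sy
      if (dist2[q] >= 4 * max(ru^2 + rv^2)) break
      j <- sel[q]
      nrm <- c((seeds[j, 1] - seeds[k, 1]) / sx^2,
               (seeds[j, 2] - seeds[k, 2]) / sy^2)
      mid <- (seeds[j, ] + seeds[k, ]) / 2
      res <- clip_halfplane(verts, labels, nrm, mid, j)
      if (is.null(res)) stop("degenerate tessellation: empty cell")
      verts <- res$verts; labels <- res$labels
    }
    cells[[k]] <- list(verts = verts, labels = labels)
  }
  list(cells = cells, seeds = seeds, spacing = c(sx, sy), domain = domain)
}

cells_to_tibble <- function(tess, spec, layer = 0L) {
  n <- length(tess$cells)
  tibble::tibble(
    cell_id = seq_len(n),
    layer = layer,
    phenotype = spec$phenotype,
    tess_id = seq_len(n),
    x_lo = -Inf, x_hi = Inf,
    area = vapply(tess$cells, function(c) shoelace_area(c$verts), 0),
    perimeter = vapply(tess$cells, function(c) polygon_perimeter(c$verts), 0),
    bbox_l = vapply(tess$cells, function(c) diff(range(c$verts[, 1])), 0),
    bbox_w = vapply(tess$cells, function(c) diff(range(c$verts[, 2])), 0),
    thickness = spec$thickness,
    vertices = lapply(tess$cells, `[[`, "verts"),
    edge_labels = lapply(tess$cells, `[[`, "labels")
  )
}

#' Tessellate a strand domain into cell polygons
#'
#' Partitions a rectangular strand into convex polygons mimicking the
#' irregular brick-like layout of cultured cells. Seeds are placed on a
#' jittered anisotropic grid (jitter uniform within +/-35% of the spacing)
#' and the Voronoi diagram is computed in coordinates scaled by the grid
#' spacing, so cells are elongated along the strand with a length/width
#' ratio of about 3 for CMCs. The tessellation tiles the domain exactly and
#' is deterministic for a fixed seed.
#'
#' @param domain `c(length_x, width_y)` in um.
#' @param spec [cell_spec()] of the tessellated population.
#' @param rng_seed Integer seed.
#' @param jitter Seed jitter as a fraction of the grid spacing.
#' @return A tibble of cells (class `strand_tessellation`) with polygon
#'   vertices, footprint areas, perimeters and bounding boxes; the domain,
#'   spacing and seed are kept as attributes.
#' @export
tessellate_strand <- function(domain, spec = spec_cmc(), rng_seed = 1L,
                              jitter = 0.35) {
  tess <- voronoi_tessellation(domain, spec, rng_seed, jitter)
  out <- cells_to_tibble(tess, spec)
  attr(out, "domain") <- domain
  attr(out, "spacing") <- tess$spacing
  attr(out, "rng_seed") <- rng_seed
  class(out) <- c("strand_tessellation", class(out))
  out
}

# Lateral contacts from polygon edge labels. Sub-cells produced by vertical
# cuts share a tess_id and are disambiguated by their x-interval; edges
# labelled -1 are cut faces whose neighbour is the sibling sub-cell.
compute_lateral_contacts <- function(cells) {
  tess_key <- paste(cells$layer, cells$tess_id)
  by_tess <- split(seq_len(nrow(cells)), tess_key)
  res <- list()
  for (a in seq_len(nrow(cells))) {
    v <- cells$vertices[[a]]
    lab <- cells$edge_labels[[a]]
    n <- nrow(v)
    nxt <- c(seq_len(n)[-1], 1L)
    mx <- (v[, 1] + v[nxt, 1]) / 2
    my <- (v[, 2] + v[nxt, 2]) / 2
    elen <- sqrt((v[nxt, 1] - v[, 1])^2 + (v[nxt, 2] - v[, 2])^2)
    for (e in seq_len(n)) {
      if (elen[e] < 1e-9) next
      q <- lab[e]
      b <- NA_integer_
      if (q > 0L) {
        cand <- by_tess[[paste(cells$layer[a], q)]]
        if (is.null(cand)) next
        hit <- cand[cells$x_lo[cand] - 1e-6 <= mx[e] & mx[e] <= cells$x_hi[cand] + 1e-6]
        if (length(hit) == 0) next
        b <- hit[1]
      } else if (q == -1L) {
        sib <- setdiff(by_tess[[tess_key[a]]], a)
        # sibling on the other side of the cut containing this edge midpoint y
        hit <- sib[abs(pmin(pmax(mx[e], cells$x_lo[sib]), cells$x_hi[sib]) - mx[e]) < 1e-6]
        if (length(hit) == 0) next # sealed cut (gap side removed)
        b <- hit[1]
      } else {
        next # domain boundary
      }
      if (b > a) res[[length(res) + 1]] <- c(a, b, elen[e])
    }
  }
  if (length(res) == 0) {
    return(tibble::tibble(cell_a = integer(), cell_b = integer(),
                          length = numeric(), orientation = character(),
                          area = numeric()))
  }
  m <- do.call(rbind, res)
  tibble::tibble(cell_a = cells$cell_id[m[, 1]], cell_b = cells$cell_id[m[, 2]],
                 length = m[, 3]) |>
    dplyr::group_by(.data$cell_a, .data$cell_b) |>
    dplyr::summarise(length = sum(.data$length), .groups = "drop") |>
    dplyr::filter(.data$length > 1e-6) |>
    dplyr::mutate(orientation = "lateral", area = NA_real_)
}

# Area of intersection of two convex polygons (Sutherland-Hodgman).
convex_intersection_area <- function(pa, pb) {
  verts <- pa; labels <- integer(nrow(pa))
  nb <- nrow(pb)
  for (e in seq_len(nb)) {
    j <- if (e == nb) 1L else e + 1L
    edge <- pb[j, ] - pb[e, ]
    nrm <- c(edge[2], -edge[1]) # outward normal for CCW polygon
    res <- clip_halfplane(verts, labels, nrm, pb[e, ], 0L)
    if (is.null(res)) return(0)
    verts <- res$verts; labels <- res$labels
  }
  if (nrow(verts) < 3) return(0)
  shoelace_area(verts)
}

# Vertical (inter-layer) contacts: overlap areas between base and coating
# polygons, with a bounding-box prefilter.
compute_vertical_contacts <- function(cells) {
  base <- which(cells$layer == 0L)
  coat <- which(cells$layer == 1L)
  if (length(coat) == 0) {
    return(tibble::tibble(cell_a = integer(), cell_b = integer(),
                          length = numeric(), orientation = character(),
                          area = numeric()))
  }
  bb <- function(i) {
    v <- cells$vertices[[i]]
    c(range(v[, 1]), range(v[, 2]))
  }
  bbase <- vapply(base, bb, numeric(4))
  bcoat <- vapply(coat, bb, numeric(4))
  res <- list()
  for (ci in seq_along(coat)) {
    cand <- base[bbase[1, ] < bcoat[2, ci] & bbase[2, ] > bcoat[1, ci] &
                   bbase[3, ] < bcoat[4, ci] & bbase[4, ] > bcoat[3, ci]]
    for (b in cand) {
      a <- convex_intersection_area(cells$vertices[[b]], cells$vertices[[coat[ci]]])
      if (a > 1e-6) {
        res[[length(res) + 1]] <- c(cells$cell_id[b], cells$cell_id[coat[ci]], a)
      }
    }
  }
  if (length(res) == 0) {
    return(tibble::tibble(cell_a = integer(), cell_b = integer(),
                          length = numeric(), orientation = character(),
                          area = numeric()))
  }
  m <- do.call(rbind, res)
  tibble::tibble(cell_a = m[, 1], cell_b = m[, 2], length = NA_real_,
                 orientation = "vertical", area = m[, 3])
}

new_tissue_layout <- function(cells, domain, configuration, layer_meta,
                              coverage = NA_real_, insert_gap = NULL,
                              rng_seed = NA_integer_) {
  contacts <- dplyr::bind_rows(compute_lateral_contacts(cells),
                               compute_vertical_contacts(cells))
  structure(list(domain = domain, configuration = configuration,
                 cells = cells, contacts = contacts, layers = layer_meta,
                 coverage = coverage, insert_gap = insert_gap,
                 rng_seed = rng_seed),
            class = "tissue_layout")
}

#' @export
print.tissue_layout <- function(x, ...) {
  cat("<tissue_layout>", x$configuration, "\n")
  cat("  domain:", x$domain[1], "x", x$domain[2], "um\n")
  cat("  cells:", nrow(x$cells), " (", sum(x$cells$phenotype == "MFB"), "MFB )\n")
  cat("  contacts:", nrow(x$contacts), "\n")
  cat("  %MFB:", round(100 * mfb_density(x), 1), "\n")
  invisible(x)
}

#' Myofibroblast density of a layout
#'
#' Area-weighted MFB fraction: total MFB footprint area over total cell
#' footprint area (all layers). For a coating configuration with coverage
#' ratio c this equals c/(1+c).
#'
#' @param layout A [tissue_layout][assign_endogenous()].
#' @return Fraction in `[0, 1]`.
#' @export
mfb_density <- function(layout) {
  sum(layout$cells$area[layout$cells$phenotype == "MFB"]) / sum(layout$cells$area)
}

#' Assign endogenous myofibroblasts to a tessellation
#'
#' Relabels a uniformly random subset of cells as MFBs so that the realized
#' area fraction is the closest achievable to the requested density (cells
#' are relabelled in random order with no spatial correlation; clusters arise
#' purely by chance).
#'
#' @param tess A [tessellate_strand()] result (all-CMC).
#' @param density Target MFB area fraction in `[0, 1]`.
#' @param rng_seed Integer seed for the phenotype assignment.
#' @return A `tissue_layout`.
#' @export
assign_endogenous <- function(tess, density, rng_seed = 1L) {
  stopifnot(density >= 0, density <= 1)
  cells <- tibble::as_tibble(tess)
  n <- nrow(cells)
  ord <- with_seed(rng_seed, sample.int(n))
  cum <- c(0, cumsum(cells$area[ord])) / sum(cells$area)
  k <- which.min(abs(cum - density)) - 1L
  if (k > 0) cells$phenotype[ord[seq_len(k)]] <- "MFB"
  new_tissue_layout(cells, attr(tess, "domain"),
                    if (density == 0) "control" else "endogenous",
                    layer_meta = list(`0` = list(spacing = attr(tess, "spacing"))),
                    rng_seed = rng_seed)
}

#' Add a coating myofibroblast layer
#'
#' Generates an independent tessellation for the coating layer (uncorrelated
#' cell boundaries with respect to the base layer) and retains a uniformly
#' random subset of its polygons until the target coverage is first met or
#' exceeded. Dropped polygons leave the coating layer empty (no cell, no
#' membrane). Vertical contacts record the overlap area between each base
#' cell and each retained coating cell.
#'
#' @param base A `tissue_layout` whose cells are all CMCs.
#' @param coverage Target coating coverage ratio c in `[0, 1]`; the MFB
#'   density of the resulting layout is c/(1+c).
#' @param mfb_spec [cell_spec()] for the coating MFBs.
#' @param rng_seed Integer seed (coating tessellation and subset choice).
#' @return A `tissue_layout` with `configuration` `"coating_large"` or
#'   `"coating_small"` and the realized coverage in `$coverage`.
#' @export
add_coating <- function(base, coverage, mfb_spec = spec_mfb_large(),
                        rng_seed = 1L) {
  if (any(base$cells$phenotype != "CMC")) stop("base layout must be all-CMC")
  stopifnot(coverage >= 0, coverage <= 1)
  configuration <- if (mfb_spec$length >= 1.5 * 60) "coating_large" else "coating_small"
  if (coverage == 0) {
    out <- base
    out$configuration <- configuration
    out$coverage <- 0
    return(out)
  }
  tess <- voronoi_tessellation(base$domain, mfb_spec, rng_seed)
  coat <- cells_to_tibble(tess, mfb_spec, layer = 1L)
  domain_area <- prod(base$domain)
  ord <- with_seed(rng_seed + 1L, sample.int(nrow(coat)))
  cum <- cumsum(coat$area[ord]) / domain_area
  k <- if (coverage >= max(cum)) length(ord) else which(cum >= coverage)[1]
  keep <- sort(ord[seq_len(k)])
  coat <- coat[keep, , drop = FALSE]
  coat$cell_id <- max(base$cells$cell_id) + seq_len(nrow(coat))
  cells <- dplyr::bind_rows(base$cells, coat)
  layer_meta <- base$layers
  layer_meta$`1` <- list(spacing = tess$spacing)
  new_tissue_layout(cells, base$domain, configuration, layer_meta,
                    coverage = sum(coat$area) / domain_area,
                    rng_seed = rng_seed)
}

# Split cells of a tessellation tibble at a vertical line x = xc. The piece
# satisfying keep_side ("left"/"right"/"both") survives; "both" keeps both
# pieces as separate cells. Cut faces are labelled -1.
cut_cells_at <- function(cells, xc, keep_side = "both") {
  out <- list()
  for (i in seq_len(nrow(cells))) {
    v <- cells$vertices[[i]]
    if (all(v[, 1] <= xc + 1e-9)) {
      if (keep_side != "right") out[[length(out) + 1]] <- cells[i, ]
      next
    }
    if (all(v[, 1] >= xc - 1e-9)) {
      if (keep_side != "left") out[[length(out) + 1]] <- cells[i, ]
      next
    }
    lab <- cells$edge_labels[[i]]
    left <- clip_halfplane(v, lab, c(1, 0), c(xc, 0), -1L)
    right <- clip_halfplane(v, lab, c(-1, 0), c(xc, 0), -1L)
    for (side in list(c("left", 1), c("right", 2))) {
      if (keep_side == setdiff(c("left", "right"), side[1])) next
      piece <- if (side[1] == "left") left else right
      if (is.null(piece) || nrow(piece$verts) < 3) next
      a <- shoelace_area(piece$verts)
      if (a < 1e-6) next
      row <- cells[i, ]
      row$vertices <- list(piece$verts)
      row$edge_labels <- list(piece$labels)
      row$area <- a
      row$perimeter <- polygon_perimeter(piece$verts)
      row$bbox_l <- diff(range(piece$verts[, 1]))
      row$bbox_w <- diff(range(piece$verts[, 2]))
      row$x_lo <- max(row$x_lo, if (side[1] == "right") xc else -Inf)
      row$x_hi <- min(row$x_hi, if (side[1] == "left") xc else Inf)
      out[[length(out) + 1]] <- row
    }
  }
  res <- dplyr::bind_rows(out)
  res$cell_id <- seq_len(nrow(res))
  res
}

#' Build a strand with a myofibroblast insert
#'
#' A CMC strand interrupted in the center by a gap of predefined length.
#' With `coated = TRUE` (the in-vitro architecture) the two CMC segments and
#' the gap are covered by a full-coverage coating MFB layer; the MFBs over
#' the gap bridge the segments electrotonically. With `coated = FALSE` the
#' strand is a single layer whose gap is filled by CMC-sized MFBs, split
#' from the base tessellation at straight vertical cuts.
#'
#' @param strand_domain `c(length_x, width_y)` in um (paper default
#'   6000 x 80).
#' @param gap_length Insert length (um), centered; 0 gives a plain strand.
#' @param coated Logical, see above.
#' @param rng_seed Integer seed.
#' @param mfb_spec Coating MFB spec when `coated = TRUE` (default large
#'   MFBs); the uncoated insert uses CMC-sized MFBs.
#' @return A `tissue_layout` with `configuration` `"insert_coated"` or
#'   `"insert_only"` and the gap bounds in `$insert_gap`.
#' @export
build_insert <- function(strand_domain = c(6000, 80), gap_length, coated = TRUE,
                         rng_seed = 1L, mfb_spec = spec_mfb_large()) {
  stopifnot(gap_length >= 0, gap_length < strand_domain[1])
  tess <- voronoi_tessellation(strand_domain, spec_cmc(), rng_seed)
  cells <- cells_to_tibble(tess, spec_cmc())
  gap <- (strand_domain[1] + c(-1, 1) * gap_length) / 2
  if (gap_length > 0) {
    cells <- cut_cells_at(cells, gap[1], "both")
    cells <- cut_cells_at(cells, gap[2], "both")
    in_gap <- cells$x_lo >= gap[1] - 1e-9 & cells$x_hi <= gap[2] + 1e-9
    # pieces wholly inside (by interval or by geometry)
    mid_in <- vapply(cells$vertices, function(v) {
      m <- mean(range(v[, 1])); m > gap[1] - 1e-9 && m < gap[2] + 1e-9
    }, TRUE) & vapply(cells$vertices, function(v) {
      min(v[, 1]) >= gap[1] - 1e-6 && max(v[, 1]) <= gap[2] + 1e-6
    }, TRUE)
    in_gap <- in_gap | mid_in
    if (coated) {
      cells <- cells[!in_gap, , drop = FALSE]
      cells$cell_id <- seq_len(nrow(cells))
    } else {
      cells$phenotype[in_gap] <- "MFB"
    }
  }
  layer_meta <- list(`0` = list(spacing = tess$spacing))
  if (coated) {
    base <- new_tissue_layout(cells, strand_domain, "insert_coated", layer_meta,
                              insert_gap = if (gap_length > 0) gap else NULL,
                              rng_seed = rng_seed)
    out <- add_coating(base, 1, mfb_spec, rng_seed + 1000L)
    out$configuration <- "insert_coated"
    out$insert_gap <- if (gap_length > 0) gap else NULL
    return(out)
  }
  new_tissue_layout(cells, strand_domain, "insert_only", layer_meta,
                    insert_gap = if (gap_length > 0) gap else NULL,
                    rng_seed = rng_seed)
}

#' Inter-cell contacts of a layout
#'
#' Lateral contacts carry the shared-boundary length L_c computed from the
#' continuous polygons before discretization (the quantity the junctional
#' conductance G = gamma * L_c is based on); vertical contacts carry the
#' base/coating overlap area.
#'
#' @param layout A `tissue_layout`.
#' @return A tibble with columns `cell_a`, `cell_b`, `length` (um; NA for
#'   vertical), `orientation`, `area` (um^2; NA for lateral).
#' @export
contact_lengths <- function(layout) layout$contacts

#' @export
tidy.tissue_layout <- function(x, ...) {
  dplyr::select(x$cells, "cell_id", "layer", "phenotype", "area",
                "perimeter", "bbox_l", "bbox_w", "thickness")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.tissue_layout <- function(object, ...) {
  cells <- object$cells
  df <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    v <- cells$vertices[[i]]
    tibble::tibble(x = v[, 1], y = v[, 2], cell_id = cells$cell_id[i],
                   layer = cells$layer[i], phenotype = cells$phenotype[i])
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   group = .data$cell_id,
                                   fill = .data$phenotype)) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.1) +
    ggplot2::facet_wrap(~layer, ncol = 1,
                        labeller = ggplot2::as_labeller(c(`0` = "base layer",
                                                          `1` = "coating layer"))) +
    ggplot2::scale_fill_manual(values = c(CMC = "#f4a6b8", MFB = "#74c476")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)")
}
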