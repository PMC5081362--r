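test_that("tessellation tiles the domain exactly and is seed-deterministic", {
  tess <- tessellate_strand(c(3000, 80), spec_cmc(), 42)
  expect_equal(sum(tess$area), 3000 * 80, tolerance = 1e-9)
  expect_true(all(tess$area > 0))
  # polygons are simple and convex by construction: shoelace area positive
  expect_true(all(vapply(tess$vertices, fibrostrand:::shoelace_area, 0) > 0))
  tess2 <- tessellate_strand(c(3000, 80), spec_cmc(), 42)
  expect_identical(tess$vertices, tess2$vertices)
  tess3 <- tessellate_strand(c(3000, 80), spec_cmc(), 43)
  expect_false(identical(tess$vertices, tess3$vertices))
  expect_error(tessellate_strand(c(40, 10), spec_cmc(), 1), "domain too small")
})

test_that("generator calibration: realized cell dimensions match the nominal specs", {
  # Monte-Carlo over independent realizations; CMC cells should average
  # about 60 x 20 um bounding boxes (aspect ratio ~3) with mean footprint
  # near the elliptical area pi*L*W/4
  stats <- vapply(1:100, function(s) {
    te <- tessellate_strand(c(1500, 80), spec_cmc(), s)
    c(mean(te$bbox_l), mean(te$bbox_w), mean(te$area))
  }, numeric(3))
  expect_gt(mean(stats[1, ]), 50); expect_lt(mean(stats[1, ]), 70)
  expect_gt(mean(stats[2, ]), 16); expect_lt(mean(stats[2, ]), 24)
  expect_equal(mean(stats[3, ]), pi * 60 * 20 / 4, tolerance = 0.05)
  expect_equal(mean(stats[1, ]) / mean(stats[2, ]), 3, tolerance = 0.2)
})

test_that("contact lengths agree with an independent boundary audit", {
  # sum of all pairwise contact lengths must equal the total interior
  # boundary length, computed independently from perimeters:
  # (sum of perimeters - domain boundary) / 2
  for (seed in 1:5) {
    tess <- tessellate_strand(c(1000, 80), spec_cmc(), seed)
    lay <- assign_endogenous(tess, 0.3, seed)
    ct <- contact_lengths(lay)
    interior <- (sum(tess$perimeter) - 2 * (1000 + 80)) / 2
    expect_equal(sum(ct$length), interior, tolerance = 1e-6)
    expect_true(all(ct$length > 0))
    # each unordered pair appears exactly once
    expect_false(any(duplicated(paste(ct$cell_a, ct$cell_b))))
  }
})

test_that("abutting rectangles give the exact contact lengths", {
  end_to_end <- two_rect_layout(side_by_side = FALSE)
  expect_equal(nrow(end_to_end$contacts), 1)
  expect_equal(end_to_end$contacts$length, 20)
  side <- two_rect_layout(side_by_side = TRUE)
  expect_equal(side$contacts$length, 60)
})

test_that("endogenous MFB assignment hits the target density", {
  tess <- tessellate_strand(c(1500, 80), spec_cmc(), 7)
  lay0 <- assign_endogenous(tess, 0, 7)
  expect_equal(mfb_density(lay0), 0)
  expect_true(all(lay0$cells$phenotype == "CMC"))
  lay1 <- assign_endogenous(tess, 1, 7)
  expect_equal(mfb_density(lay1), 1)
  lay <- assign_endogenous(tess, 0.3, 7)
  max_cell_frac <- max(tess$area) / sum(tess$area)
  expect_lt(abs(mfb_density(lay) - 0.3), max_cell_frac)
  # assignment is by relabelling only: geometry untouched
  expect_identical(lay$cells$vertices, tess$vertices)
})

test_that("coating layer coverage and density bookkeeping", {
  tess <- tessellate_strand(c(1500, 80), spec_cmc(), 3)
  base <- assign_endogenous(tess, 0, 3)
  lay0 <- add_coating(base, 0, spec_mfb_large(), 3)
  expect_equal(nrow(lay0$cells), nrow(base$cells))
  lay <- add_coating(base, 0.3, spec_mfb_large(), 3)
  # coverage met or first exceeded; %MFB = c/(1+c)
  expect_gte(lay$coverage, 0.3)
  expect_lt(lay$coverage, 0.3 + max(lay$cells$area[lay$cells$layer == 1]) / (1500 * 80))
  expect_equal(mfb_density(lay), lay$coverage / (1 + lay$coverage), tolerance = 1e-9)
  # realized density within one coating cell of the c/(1+c) target
  expect_lt(abs(mfb_density(lay) - 0.3 / 1.3),
            max(lay$cells$area[lay$cells$layer == 1]) / (1500 * 80))
  full <- add_coating(base, 1, spec_mfb_large(), 3)
  expect_equal(full$coverage, 1, tolerance = 1e-9)
  expect_equal(mfb_density(full), 0.5, tolerance = 1e-9)
  # vertical contacts cover every overlap: their area sums to coverage*domain
  vc <- dplyr::filter(contact_lengths(full), orientation == "vertical")
  expect_equal(sum(vc$area), 1500 * 80, tolerance = 1e-6)
  expect_error(add_coating(assign_endogenous(tess, 0.2, 1), 0.3),
               "all-CMC")
})

test_that("insert construction: gap bounds, phenotypes and connectivity", {
  plain <- build_insert(c(1200, 80), 0, coated = FALSE, rng_seed = 5)
  expect_true(all(plain$cells$phenotype == "CMC"))
  expect_null(plain$insert_gap)

  lay <- build_insert(c(1200, 80), 240, coated = TRUE, rng_seed = 5)
  expect_equal(lay$insert_gap, c(480, 720))
  base <- lay$cells[lay$cells$layer == 0, ]
  coat <- lay$cells[lay$cells$layer == 1, ]
  # no base cell inside the gap; coating covers the whole strand
  base_x <- vapply(base$vertices, function(v) mean(range(v[, 1])), 0)
  expect_true(all(base_x < 480 + 1e-6 | base_x > 720 - 1e-6))
  expect_equal(sum(coat$area), 1200 * 80, tolerance = 1e-6)
  expect_true(all(coat$phenotype == "MFB"))
  # base area equals the domain minus the gap
  expect_equal(sum(base$area), 1200 * 80 - 240 * 80, tolerance = 1e-6)

  solo <- build_insert(c(1200, 80), 240, coated = FALSE, rng_seed = 5)
  expect_equal(unique(solo$cells$layer), 0L)
  expect_equal(sum(solo$cells$area), 1200 * 80, tolerance = 1e-6)
  in_gap <- solo$cells$phenotype == "MFB"
  gx <- vapply(solo$cells$vertices[in_gap], function(v) range(v[, 1]), numeric(2))
  expect_true(all(gx[1, ] >= 480 - 1e-6 & gx[2, ] <= 720 + 1e-6))
  # MFB area equals the gap area (straight cuts)
  expect_equal(sum(solo$cells$area[in_gap]), 240 * 80, tolerance = 1e-6)
  # cut creates CMC-MFB contacts bridging the gap edges
  ct <- contact_lengths(solo)
  ph <- solo$cells$phenotype[match(ct$cell_a, solo$cells$cell_id)] !=
    solo$cells$phenotype[match(ct$cell_b, solo$cells$cell_id)]
  # total about 2 x 80 um of cut faces (tiny dropped slivers tolerated)
  expect_gte(sum(ct$length[ph]), 150)
})
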