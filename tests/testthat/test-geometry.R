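# Tip-geometry validation and rasterization.

test_that("geometry invariants are enforced", {
  expect_s3_class(toy_tip_design("single"), "tip_geometry")
  # overlapping dual holes rejected
  expect_error(tip_geometry(holes = list(
    side_hole(length = 3e-3, tip_distance = 16.5e-3),
    side_hole(length = 3e-3, tip_distance = 18e-3))), "overlap")
  # hole outside the inserted wall rejected
  expect_error(tip_geometry(insertion_length = 10e-3,
                            holes = list(side_hole())), "outside")
  # more than two holes rejected
  expect_error(tip_geometry(holes = list(side_hole(), side_hole(),
                                         side_hole())), "two side-holes")
  # dual design orders holes proximal-first
  g2 <- toy_tip_design("dual_linear")
  expect_equal(g2$arrangement, "dual_linear")
  expect_lt(g2$hole_spans[[1]][2], g2$hole_spans[[2]][1])
})

test_that("rasterization resolves features or rejects with the feature named", {
  g <- toy_tip_design("single")
  expect_error(rasterize_geometry(g, 1e-3), "under-resolves")
  expect_error(rasterize_geometry(g, 1e-3), "wall thickness|lumen")

  d <- rasterize_geometry(g, 0.25e-3)
  # wall strips span the right number of cell rows
  expect_equal(sum(!d$mask[1, ]), 2 * round(g$wall_thickness / d$hy))
  expect_equal(length(d$lumen_rows), round(g$lumen_height / d$hy))
  # no-hole geometry: wall contiguous along the insertion except tip cut
  g0 <- toy_tip_design("no_hole")
  d0 <- rasterize_geometry(g0, 0.25e-3)
  j_up <- which(!d0$mask[1, ])
  j_up <- j_up[j_up > max(d0$lumen_rows)]
  i_wall_end <- round((g0$insertion_length - g0$tip_opening_length) / d0$hx)
  expect_true(all(!d0$mask[1:i_wall_end, j_up]))
  expect_true(all(d0$mask[(i_wall_end + 1):d0$nx, j_up]))
  expect_length(d0$hole_cols, 0)
})

test_that("achieved hole length converges to the requested length", {
  g <- tip_geometry(holes = list(side_hole(length = 2.9e-3)))
  errs <- sapply(c(0.5e-3, 0.25e-3, 0.125e-3), function(h) {
    d <- rasterize_geometry(g, h)
    abs(d$achieved_hole_lengths[1] - 2.9e-3)
  })
  # rasterization error is bounded by one cell and shrinks with spacing
  expect_lt(errs[1], 0.5e-3 + 1e-12)
  expect_lt(errs[2], 0.25e-3 + 1e-12)
  expect_lt(errs[3], 0.125e-3 + 1e-12)
})

test_that("chamfered holes produce a stair-step matching the angle", {
  g <- tip_geometry(holes = list(side_hole("angled_cut", length = 3e-3,
                                           chamfer_angle = 45)))
  d <- rasterize_geometry(g, 0.25e-3)
  # the opening at the outer surface is wider than at the inner surface by
  # ~2 * wall_thickness / tan(45) = 2 * wt
  j_up <- which(!d$mask[1, ]); j_up <- j_up[j_up > max(d$lumen_rows)]
  open_inner <- sum(d$mask[, min(j_up)] &
                      seq_len(d$nx) %in% which(d$xc < g$insertion_length))
  inner_row <- min(j_up); outer_row <- max(j_up)
  w_inner <- sum(d$mask[d$hole_cols[[1]][1]:d$nx, inner_row] &
                   d$xc[d$hole_cols[[1]][1]:d$nx] < 10e-3)
  n_in <- length(intersect(which(d$mask[, inner_row]),
                           which(d$xc > 3e-3 & d$xc < 11e-3)))
  n_out <- length(intersect(which(d$mask[, outer_row]),
                            which(d$xc > 3e-3 & d$xc < 11e-3)))
  expected_extra <- round(2 * g$wall_thickness / d$hx)
  expect_equal(n_out - n_in, expected_extra, tolerance = 1)
})
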