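rect_contour <- function() {
  # 2 x 1 axis-aligned rectangle with apex mid-top and base mid-bottom:
  # vertices CCW starting at the base-right corner region
  pts <- rbind(c(0.5, 0), c(0.5, 2), c(0, 2), c(-0.5, 2),
               c(-0.5, 0), c(0, 0))
  leaf_contour(pts, base_left = 5, base_right = 1, apex = 3, id = "rect")
}

test_that("blade measures are exact on a rectangle and flag convexity", {
  bm <- blade_measures(rect_contour())
  expect_equal(bm$length_um, 2)
  expect_equal(bm$width_um, 1)
  expect_equal(bm$aspect_ratio, 2)
  expect_equal(bm$area_um2, 2)
  expect_equal(bm$dissection_index, 1, tolerance = 1e-9)

  # any convex contour has DI = 1
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  ell <- cbind(3 * cos(th), 5 * sin(th))
  lc <- leaf_contour(ell, base_left = 34, base_right = 32, apex = 17,
                     id = "ellipse")
  expect_equal(blade_measures(lc)$dissection_index, 1, tolerance = 1e-9)
})

test_that("measures are rigid-invariant and scale correctly", {
  cfg <- quick_config(seed = 2)
  ct <- synthesize_leaf_contour(120, rank = 2, config = cfg)
  bm <- blade_measures(ct)
  # rotate + translate
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  moved <- ct
  moved$points <- sweep(ct$points %*% t(R), 2, c(500, -300), `+`)
  bm2 <- blade_measures(moved)
  expect_equal(bm2$length_um, bm$length_um, tolerance = 1e-9)
  expect_equal(bm2$width_um, bm$width_um, tolerance = 1e-9)
  expect_equal(bm2$area_um2, bm$area_um2, tolerance = 1e-9)
  expect_equal(bm2$dissection_index, bm$dissection_index, tolerance = 1e-9)
  # uniform scaling: lengths linear, areas quadratic
  scaled <- ct
  scaled$points <- ct$points * 3
  bm3 <- blade_measures(scaled)
  expect_equal(bm3$length_um, 3 * bm$length_um, tolerance = 1e-9)
  expect_equal(bm3$area_um2, 9 * bm$area_um2, tolerance = 1e-9)
  expect_equal(bm3$dissection_index, bm$dissection_index, tolerance = 1e-9)
})

test_that("tooth measures read the landmark geometry", {
  pts <- rbind(c(2, 0), c(2, 2), c(1.5, 3), c(1, 2.5), c(0.5, 3.5),
               c(0, 5), c(-2, 2), c(-2, 0))
  teeth <- data.frame(side = "right", sinus_prev = 3L, tip = 5L,
                      sinus_next = 6L)
  # direct triangle example: sinuses (0,0),(2,0), tip (1,1)
  tri <- leaf_contour(rbind(c(1, -2), c(2, 0), c(1, 1), c(0, 0), c(-1, -2)),
                      base_left = 5, base_right = 1, apex = 3,
                      teeth = data.frame(side = "right", sinus_prev = 4L,
                                         tip = 3L, sinus_next = 2L),
                      id = "tri")
  tm <- tooth_measures(tri, 1)
  expect_equal(tm$width_um, 2)
  expect_equal(tm$height_um, 1)
  expect_equal(tm$aspect_ratio, 0.5)

  # tip on the chord: zero height, zero aspect
  flatc <- leaf_contour(rbind(c(1, -2), c(2, 0), c(1, 0), c(0, 0), c(-1, -2)),
                        base_left = 5, base_right = 1, apex = 3,
                        teeth = data.frame(side = "right", sinus_prev = 4L,
                                           tip = 3L, sinus_next = 2L),
                        id = "flat")
  tm0 <- tooth_measures(flatc, 1)
  expect_equal(tm0$height_um, 0)
  expect_equal(tm0$aspect_ratio, 0)
})

test_that("synthetic contours round-trip their generating geometry", {
  cfg <- quick_config(seed = 6, n_contour_points = 512L)
  ts <- cfg$tooth_schedule
  ct <- synthesize_leaf_contour(300, rank = 3, config = cfg)
  bm <- blade_measures(ct)
  hp <- cfg$hill_by_rank[["3"]]
  L <- hill_eval(hp, 300)
  expect_lt(abs(bm$length_um - L) / L, 0.01)
  # width round-trips on a toothless blade (tooth tips protrude by design)
  young <- synthesize_leaf_contour(55, rank = 3, config = cfg)
  bmy <- blade_measures(young)
  Ly <- hill_eval(hp, 55)
  expect_lt(abs(bmy$length_um - Ly) / Ly, 0.01)
  expect_lt(abs(bmy$width_um - Ly / cfg$aspect_ratio(55)) /
              (Ly / cfg$aspect_ratio(55)), 0.01)
  expect_equal(bmy$dissection_index, 1, tolerance = 1e-6)
  expect_equal(count_teeth(young)$left, 0L)

  # per-tooth width/height within 2% of the generating Hill values
  tau <- 300 - ts$offsets_h
  present <- which(tau > 0)
  expect_equal(count_teeth(ct)$right, length(present))
  expect_equal(count_teeth(ct, pooled = TRUE)$pooled,
               rep(length(present), 2))
  for (side in c("left", "right")) {
    idx <- which(ct$teeth$side == side)
    for (r in seq_along(idx)) {       # base-to-apex order = tooth rank
      tm <- tooth_measures(ct, idx[r], bm)
      w_true <- hill_eval(ts$width, tau[present[r]])
      h_true <- hill_eval(ts$height, tau[present[r]])
      expect_lt(abs(tm$width_um - w_true) / w_true, 0.02)
      expect_lt(abs(tm$height_um - h_true) / h_true, 0.02)
    }
  }

  # dissection index rises with tooth height at fixed blade
  taller <- quick_config(seed = 6, n_contour_points = 512L,
                         tooth_schedule = list(
                           offsets_h = ts$offsets_h,
                           width = ts$width,
                           height = hill_params(2 * ts$height$l_max,
                                                ts$height$t_half,
                                                ts$height$n)))
  ct_tall <- synthesize_leaf_contour(300, rank = 3, config = taller)
  expect_gt(blade_measures(ct_tall)$dissection_index, bm$dissection_index)
  expect_gt(bm$dissection_index, 1)
})

test_that("tooth counts never decrease along an age series", {
  cfg <- quick_config(seed = 3)
  ages <- seq(40, 400, by = 40)
  counts <- vapply(ages, function(a)
    count_teeth(synthesize_leaf_contour(a, 2, cfg))$right, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("normalization preserves shape, registers rigidly, and is idempotent", {
  # resampling a circular arc margin keeps vertices on the circle
  th <- seq(-pi / 2 + 0.3, -pi / 2 - 0.3 + 2 * pi, length.out = 97)
  circ <- cbind(100 * cos(th), 100 * sin(th) + 100)
  lc <- leaf_contour(circ, base_left = 97, base_right = 1, apex = 49,
                     id = "circle")
  nc <- normalize_contour(lc, 80)
  # circumcentre of three well-separated resampled vertices = circle centre
  circumcentre <- function(p1, p2, p3) {
    d <- 2 * (p1[1] * (p2[2] - p3[2]) + p2[1] * (p3[2] - p1[2]) +
                p3[1] * (p1[2] - p2[2]))
    ux <- (sum(p1^2) * (p2[2] - p3[2]) + sum(p2^2) * (p3[2] - p1[2]) +
             sum(p3^2) * (p1[2] - p2[2])) / d
    uy <- (sum(p1^2) * (p3[1] - p2[1]) + sum(p2^2) * (p1[1] - p3[1]) +
             sum(p3^2) * (p2[1] - p1[1])) / d
    c(ux, uy)
  }
  ctr <- circumcentre(nc$points[20, ], nc$points[81, ], nc$points[140, ])
  radii <- sqrt(rowSums(sweep(nc$points, 2, ctr)^2))
  expect_true(all(abs(radii - 100) < 1e-3 * 100 + 0.2))

  cfg <- quick_config(seed = 8)
  ct <- synthesize_leaf_contour(250, 3, cfg)
  n1 <- normalize_contour(ct, 200)
  expect_equal(nrow(n1$points), 401L)
  expect_equal(n1$landmarks$base_right, 1L)
  expect_equal(n1$landmarks$apex, 201L)
  expect_equal(n1$landmarks$base_left, 401L)
  # registration: base midpoint at origin, apex on +y
  expect_equal(as.numeric((n1$points[1, ] + n1$points[401, ]) / 2), c(0, 0),
               tolerance = 1e-9)
  expect_lt(abs(n1$points[201, 1]), 1e-9)
  expect_gt(n1$points[201, 2], 0)
  # idempotent
  n2 <- normalize_contour(n1, 200)
  expect_lt(max(abs(n1$points - n2$points)), 1e-6)
  # measures survive resampling
  bm_raw <- blade_measures(ct)
  bm_n <- blade_measures(n1)
  expect_lt(abs(bm_n$length_um - bm_raw$length_um) / bm_raw$length_um, 0.005)
  expect_lt(abs(bm_n$area_um2 - bm_raw$area_um2) / bm_raw$area_um2, 0.005)
})
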