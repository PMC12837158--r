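test_that("slicing an analytic cylinder recovers its cross-sections", {
  ct <- slice_mesh(fix_cyl, c(0, 0, 10), c(0, 0, 1))
  r <- sqrt(rowSums(sweep(ct$points, 2, ct$centroid)^2))
  expect_lt(max(abs(r - 10)), 0.01)
  # contour length ~ 2 pi r at typical mesh density
  per <- sum(sqrt(rowSums((ct$points -
                             ct$points[c(2:nrow(ct$points), 1), ])^2)))
  expect_lt(abs(per - 2 * pi * 10) / (2 * pi * 10), 0.005)

  # 45-degree oblique section is an ellipse with semi-axes r and r/cos(45)
  ct45 <- slice_mesh(fix_cyl, c(0, 0, 10), c(0, 1, 1) / sqrt(2))
  pd <- polar_discretize(ct45, n_angles = 200)
  expect_equal(min(pd$radius), 10, tolerance = 1e-3)
  expect_equal(max(pd$radius), 10 / cos(pi / 4), tolerance = 1e-3)

  expect_error(slice_mesh(fix_cyl, c(0, 0, 50), c(0, 0, 1)),
               "plane outside mesh")
})

test_that("polar discretization matches ray-circle closed forms", {
  ct <- slice_mesh(fix_cyl, c(0, 0, 10), c(0, 0, 1))
  pd <- polar_discretize(ct, n_angles = 200)
  expect_length(pd$radius, 200)
  expect_true(all(abs(pd$radius - 10) < 0.01))
  expect_true(all(diff(pd$angle) > 0))

  # center offset 2 mm: ray toward the far side sees 12, near side 8
  pd2 <- polar_discretize(ct, center = c(-2, 0, 10), n_angles = 8)
  expect_equal(pd2$radius[1], 12, tolerance = 1e-2)
  expect_equal(pd2$radius[5], 8, tolerance = 1e-2)

  expect_error(polar_discretize(ct, center = c(15, 0, 10)),
               "center outside")
  expect_error(polar_discretize(ct, n_angles = 4), "n_angles")
})

test_that("polar discretization preserves convex contour area at n = 200", {
  ct <- slice_mesh(fix_cyl, c(0, 0, 7.3), c(0, 0, 1))
  pd <- polar_discretize(ct, n_angles = 200)
  r <- pd$radius
  area <- 0.5 * sum(r * c(r[-1], r[1]) * sin(2 * pi / 200))
  expect_lt(abs(area - ct$area) / ct$area, 0.01)
})

test_that("radii are invariant to a joint rigid-body transform", {
  ct <- slice_mesh(fix_cyl, c(0, 0, 10), c(0, 0, 1))
  pd <- polar_discretize(ct, n_angles = 100)
  R <- rotation3(c(1, 2, 3) / sqrt(14), 0.7)
  tr <- c(5, -3, 2)
  m2 <- transform_mesh(fix_cyl, R, tr)
  ct2 <- slice_mesh(m2, as.vector(R %*% c(0, 0, 10)) + tr,
                    as.vector(R %*% c(0, 0, 1)))
  pd2 <- polar_discretize(ct2, n_angles = 100)
  expect_lt(max(abs(sort(pd2$radius) - sort(pd$radius))), 1e-3)
})

test_that("centerline resampling is arclength-uniform with preserved ends", {
  p <- rbind(c(0, 0, 0), c(0, 0, 20))
  path <- resample_centerline(p, 0.5)
  expect_equal(nrow(path$points), 41L)
  expect_equal(path$points[1, ], c(0, 0, 0))
  expect_equal(path$points[41, ], c(0, 0, 20))
  expect_true(all(abs(path$tangents %*% c(0, 0, 1) - 1) < 1e-12))

  # quarter circle: recovered arclength within 1% at spacing R/100
  R <- 7
  th <- seq(0, pi / 2, length.out = 200)
  qc <- cbind(R * cos(th), R * sin(th), 0)
  path2 <- resample_centerline(qc, R / 100)
  expect_lt(abs(max(path2$s) - pi * R / 2) / (pi * R / 2), 0.01)

  expect_error(resample_centerline(rbind(c(1, 1, 1)), 0.5), "2")
  expect_warning(resample_centerline(rbind(c(0, 0, 0), c(0, 0, 0),
                                           c(0, 0, 5)), 0.5),
                 "duplicate")
})

test_that("centroid centerline tracks the tube axis and flags non-tubes", {
  cl <- centroid_centerline(fix_cyl, c(0, 0, 1), spacing = 1)
  expect_lt(max(abs(cl$points[, 1:2])), 1e-9)

  # bent tube: end-tangent change matches the declared bend within 2 degrees
  spec <- synthetic_case(r_prox = 11, r_dist = 11, angulation = 25)
  bent <- generate_aorta(spec)$mesh
  cl2 <- centroid_centerline(bent, c(0, 0, 1), spacing = 0.5)
  n <- nrow(cl2$tangents)
  ang <- acos(min(1, sum(cl2$tangents[1, ] * cl2$tangents[n, ]))) * 180 / pi
  expect_lt(abs(ang - 25), 2)

  # sphere: cross-section area varies wildly -> degenerate-path warning
  expect_warning(centroid_centerline(sphere_mesh(5), c(0, 0, 1),
                                     spacing = 0.5),
                 "degenerate")

  # two parallel tubes: branching slice error
  two <- surface_mesh(rbind(fix_cyl$vertices,
                            sweep(fix_cyl$vertices, 2, c(30, 0, 0), "+")),
                      rbind(fix_cyl$faces,
                            fix_cyl$faces + nrow(fix_cyl$vertices)))
  expect_error(centroid_centerline(two, c(0, 0, 1), spacing = 1),
               "branching")
})
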