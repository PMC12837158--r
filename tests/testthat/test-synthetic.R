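test_that("generated surfaces honour their declared geometry", {
  # equal radii, no bend: all slice radii equal within mesh tolerance
  cylspec <- synthetic_case(r_prox = 11, r_dist = 11)
  ag <- generate_aorta(cylspec)
  expect_true(is_watertight(ag$mesh))
  for (s in c(3, 10.25, 17)) {
    at <- centerline_at(ag$path, s)
    ct <- slice_mesh(ag$mesh, at$points[1, ], at$tangents[1, ])
    r <- polar_discretize(ct, n_angles = 64)$radius
    expect_lt(max(abs(r - 11)), 0.02)
  }

  # 12 -> 10 mm linear taper over 20 mm: mid-neck radius ~ 11 mm
  tap <- generate_aorta(synthetic_case(r_prox = 12, r_dist = 10))
  at <- centerline_at(tap$path, 10)
  ct <- slice_mesh(tap$mesh, at$points[1, ], at$tangents[1, ])
  expect_equal(mean(polar_discretize(ct, n_angles = 64)$radius), 11,
               tolerance = 0.005)

  expect_error(synthetic_case(r_prox = 12, sac_radius = 5),
               "self-intersecting")
})

test_that("mesh generation is deterministic (byte-identical files)", {
  spec <- synthetic_case(r_prox = 11.3, r_dist = 10.2, angulation = 15,
                         ovalization = 0.1,
                         defects = data.frame(start = 4, extent = 6,
                                              span_deg = 80, depth = 1.5,
                                              angle_deg = 120))
  f1 <- tempfile(fileext = ".stl")
  f2 <- tempfile(fileext = ".stl")
  write_mesh(generate_aorta(spec)$mesh, f1)
  write_mesh(generate_aorta(spec)$mesh, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("deployed graft apposes the wall except inside declared defects", {
  # no defects, zero ovalization: perfect apposition
  spec0 <- synthetic_case(r_prox = 11, r_dist = 11)
  ag0 <- generate_aorta(spec0)
  g0 <- generate_deployed_graft(spec0)
  expect_true(is_watertight(g0))
  f0 <- radial_sampling(ag0$mesh, g0, ag0$path)
  expect_lt(max(abs(f0$gap)), 0.05)

  # one defect depth 2 mm, span 90 deg, extent 5 mm: max sampled gap ~ 2 mm
  specd <- synthetic_case(r_prox = 11, r_dist = 11,
                          defects = data.frame(start = 5, extent = 5,
                                               span_deg = 90, depth = 2,
                                               angle_deg = 0))
  agd <- generate_aorta(specd)
  gd <- generate_deployed_graft(specd)
  fd <- radial_sampling(agd$mesh, gd, agd$path)
  expect_equal(max(fd$gap), 2, tolerance = 0.06)
  # argmax inside the declared footprint (s in [5,10], angle within +-45 deg)
  w <- which(fd$gap == max(fd$gap), arr.ind = TRUE)[1, ]
  expect_true(fd$s[w[1]] >= 5 && fd$s[w[1]] <= 10)
  a <- fd$angles[w[2]] * 180 / pi
  expect_true(min(a, 360 - a) <= 45)

  # ovalization 2/11: per-slice (rG,max - rG,min)/rG,max ~ 0.1818
  speco <- synthetic_case(r_prox = 11, r_dist = 11, ovalization = 2 / 11)
  ago <- generate_aorta(speco)
  go <- generate_deployed_graft(speco)
  fo <- radial_sampling(ago$mesh, go, ago$path)
  dev <- (fo$rG_max - fo$rG_min) / fo$rG_max
  expect_equal(mean(dev), 2 / 11, tolerance = 0.005)

  expect_error(generate_deployed_graft(
    synthetic_case(r_prox = 5, r_dist = 5,
                   defects = data.frame(start = 5, extent = 5, span_deg = 90,
                                        depth = 6, angle_deg = 0))),
    "gap depth")
})

test_that("analytic features match the mesh-measured route", {
  spec <- synthetic_case(r_prox = 12, r_dist = 10, ovalization = 0.12,
                         defects = data.frame(start = 6, extent = 7,
                                              span_deg = 100, depth = 1.8,
                                              angle_deg = 200))
  ag <- generate_aorta(spec)
  g <- generate_deployed_graft(spec)
  meas <- risk_features(radial_sampling(ag$mesh, g, ag$path))
  an <- analytic_features(spec)
  expect_equal(meas$ac, an$ac, tolerance = 0.01)
  expect_equal(meas$sgs2, an$sgs2, tolerance = 0.01)
  expect_equal(meas$sgm2, an$sgm2, tolerance = 1e-9)
})

test_that("cohort generation is reproducible with declared label structure", {
  c1 <- generate_cohort(100, leak_fraction = 0.3, seed = 5)
  c2 <- generate_cohort(100, leak_fraction = 0.3, seed = 5)
  expect_identical(c1$label, c2$label)
  expect_identical(c1$ac, c2$ac)
  expect_true(all(c1$label %in% 0:1))
  expect_length(attr(c1, "specs"), 100)

  # without gap defects or strong taper, the pre-noise rule labels negative
  rule <- attr(c1, "generating_rule")
  no_risk <- vapply(attr(c1, "specs"), function(sp) {
    deep <- !is.null(sp$defects) && any(sp$defects$depth > rule$depth_threshold_mm)
    !deep
  }, TRUE)
  shallow_ac <- c1$ac <= rule$conicity_threshold
  expect_true(all(c1$label_true[no_risk & shallow_ac] == 0))

  expect_error(generate_cohort(5), "n >= 10")
  expect_error(generate_cohort(50, leak_fraction = 1.2), "leak_fraction")
})

test_that("null confounding gives balanced pre-matching covariates", {
  co <- generate_cohort(1000, confounding = 0, seed = 2)
  covs <- c("age", "bmi", "neck_angle", "neck_length", "neck_diameter")
  smds <- vapply(covs, function(cv)
    abs(smd(co[[cv]][co$group == 1], co[[cv]][co$group == 0])), 1)
  expect_lt(mean(smds), 0.1)
  expect_lt(max(smds), 0.25)
})

test_that("feature monotonicity: deeper/longer defects and stronger taper", {
  region <- analysis_region()
  # SGM2 non-decreasing in depth and extent (analytic route over a grid)
  for (extent in c(6, 10, 14)) {
    sg <- vapply(c(0.5, 1.2, 2, 3), function(d)
      analytic_features(synthetic_case(
        defects = data.frame(start = 3, extent = extent, span_deg = 90,
                             depth = d, angle_deg = 0)), region)$sgm2, 1)
    expect_true(all(diff(sg) >= 0))
  }
  for (depth in c(1.5, 2.5)) {
    sg <- vapply(c(4, 8, 12, 16), function(e)
      analytic_features(synthetic_case(
        defects = data.frame(start = 2, extent = e, span_deg = 90,
                             depth = depth, angle_deg = 0)), region)$sgm2, 1)
    expect_true(all(diff(sg) >= 0))
  }
  # AC non-decreasing in taper
  acs <- vapply(c(0, 0.5, 1, 2, 3), function(dr)
    analytic_features(synthetic_case(r_prox = 11, r_dist = 11 - dr),
                      region)$ac, 1)
  expect_true(all(diff(acs) >= 0))
})
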