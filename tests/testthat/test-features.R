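test_that("conicity matches hand arithmetic and is taper/widen symmetric", {
  cyl <- make_field(matrix(10, 40, 8), matrix(10, 40, 8))
  expect_equal(aortic_conicity(cyl), 0)

  taper <- make_field(matrix(seq(12, 10, length.out = 40), 40, 8),
                      matrix(10, 40, 8))
  expect_equal(aortic_conicity(taper), 2 / 12)
  widen <- make_field(matrix(seq(10, 12, length.out = 40), 40, 8),
                      matrix(10, 40, 8))
  expect_equal(aortic_conicity(widen), 2 / 12)

  one_slice <- make_field(matrix(10, 1, 8), matrix(10, 1, 8))
  expect_error(aortic_conicity(one_slice), "2 slices")
})

test_that("shape score averages per-slice ellipse deviations", {
  # circular graft everywhere
  f0 <- make_field(matrix(11, 40, 8), matrix(11, 40, 8))
  expect_equal(graft_shape_score(f0), 0)

  # ellipse 11/9 at all slices: (11-9)/11
  ell <- matrix(rep(c(11, 9), each = 4 * 40), 40, 8)
  fe <- make_field(matrix(11, 40, 8), ell)
  expect_equal(graft_shape_score(fe), 2 / 11)

  # ellipse on 1 of 40 slices: mean = (2/11)/40
  mix <- matrix(11, 40, 8)
  mix[17, 1:4] <- 9
  fm <- make_field(matrix(11, 40, 8), mix)
  expect_equal(graft_shape_score(fm), (2 / 11) / 40)
  expect_equal(graft_shape_score(fm, method = "sum"), 2 / 11)
})

test_that("malapposition extent equals the exhaustive run-length oracle", {
  n_s <- 40
  n_a <- 16
  rA <- matrix(12, n_s, n_a)

  # gap-free field
  f0 <- make_field(rA, rA)
  expect_equal(malapposition_extent(f0, 0.1), 0)

  # constructed defect: gap 1.5 over slices 11..20 (5 mm) at two angles
  rG <- rA
  rG[11:20, 3:4] <- 12 - 1.5
  fd <- make_field(rA, rG)
  expect_equal(malapposition_extent(fd, 0.1), 5 / 20)
  expect_equal(malapposition_extent(fd, 0.1), sgm2_bruteforce(fd, 0.1))

  # gap everywhere: full run
  fall <- make_field(rA, rA - 1)
  expect_equal(malapposition_extent(fall, 0.1), 1)

  # randomized fields agree with the brute-force oracle exactly
  set.seed(11)
  for (rep in 1:5) {
    rG <- rA - matrix(rexp(n_s * n_a, rate = 8), n_s, n_a)
    fr <- make_field(rA, rG)
    expect_identical(malapposition_extent(fr, 0.1),
                     sgm2_bruteforce(fr, 0.1))
  }

  expect_error(malapposition_extent(f0, epsilon = 0), "epsilon")
})

test_that("feature bundle stays in range and records its threshold", {
  spec <- synthetic_case(r_prox = 12, r_dist = 10, ovalization = 0.15,
                         defects = data.frame(start = 5, extent = 8,
                                              span_deg = 120, depth = 2.2,
                                              angle_deg = 90))
  ag <- generate_aorta(spec)
  g <- generate_deployed_graft(spec)
  f <- risk_features(radial_sampling(ag$mesh, g, ag$path), epsilon = 0.1)
  expect_true(all(c(f$ac, f$sgs2, f$sgm2) >= 0 &
                    c(f$ac, f$sgs2, f$sgm2) <= 1))
  expect_equal(f$epsilon, 0.1)
  expect_gt(f$max_gap_mm, 2)
})

test_that("features tolerate mesh refinement within 2%", {
  mk <- function(msize) {
    spec <- synthetic_case(r_prox = 11.5, r_dist = 10, ovalization = 0.1,
                           mesh_size = msize,
                           defects = data.frame(start = 5, extent = 8,
                                                span_deg = 120, depth = 2,
                                                angle_deg = 0))
    ag <- generate_aorta(spec)
    risk_features(radial_sampling(ag$mesh, generate_deployed_graft(spec),
                                  ag$path))
  }
  coarse <- mk(0.9)
  fine <- mk(0.5)
  expect_equal(coarse$ac, fine$ac, tolerance = 0.02)
  expect_equal(coarse$sgs2, fine$sgs2, tolerance = 0.02)
  expect_equal(coarse$sgm2, fine$sgm2, tolerance = 0.03)
})
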