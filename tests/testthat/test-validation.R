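test_that("voxelization recovers analytic volumes", {
  vc <- voxelize(fix_cube, spacing = 0.25)
  expect_lt(abs(mask_volume(vc) - 1), 0.05)

  sp <- sphere_mesh(5)
  vs <- voxelize(sp, spacing = 0.25)
  expect_lt(abs(mask_volume(vs) - 4 / 3 * pi * 125) / (4 / 3 * pi * 125),
            0.02)

  # bounds far away from the mesh: empty mask
  far <- voxelize(fix_cube, spacing = 0.25,
                  bounds = rbind(c(10, 10, 10), c(12, 12, 12)))
  expect_equal(sum(far$occ), 0L)

  open_mesh <- surface_mesh(fix_cube$vertices, fix_cube$faces[-1, ])
  expect_error(voxelize(open_mesh), "watertight")
})

test_that("Dice behaves as an overlap metric", {
  va <- voxelize(fix_cube, spacing = 0.1)
  expect_equal(dice_coefficient(va, va), 1)

  bounds <- rbind(c(-1, -1, -1), c(3, 3, 3))
  a <- voxelize(fix_cube, 0.05, bounds)
  shifted <- transform_mesh(fix_cube, diag(3), c(0.5, 0, 0))
  b <- voxelize(shifted, 0.05, bounds)
  expect_equal(dice_coefficient(a, b), 0.5, tolerance = 0.02)
  expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))

  disj <- voxelize(transform_mesh(fix_cube, diag(3), c(2, 0, 0)), 0.05,
                   bounds)
  expect_equal(dice_coefficient(a, disj), 0)
  expect_error(dice_coefficient(a, voxelize(fix_cube, 0.1)), "same grid")
})

test_that("Hausdorff distance matches analytic offsets", {
  s1 <- sphere_mesh(10, n_rings = 61, n_seg = 72)
  expect_equal(hausdorff_distance(s1, s1, samples = 1000), 0)

  s2 <- sphere_mesh(10.3, n_rings = 61, n_seg = 72)
  expect_equal(hausdorff_distance(s1, s2, samples = 1000), 0.3,
               tolerance = 0.02)

  s3 <- transform_mesh(s1, diag(3), c(5, 0, 0))
  expect_equal(hausdorff_distance(s1, s3, samples = 1000), 5,
               tolerance = 0.05)
  # symmetry
  expect_equal(hausdorff_distance(s1, s2, samples = 1000),
               hausdorff_distance(s2, s1, samples = 1000),
               tolerance = 1e-9)

  degen <- surface_mesh(matrix(0, 3, 3), matrix(c(1L, 2L, 3L), 1))
  expect_error(hausdorff_distance(degen, s1), "degenerate")
})

test_that("sampled Hausdorff estimates satisfy the triangle inequality", {
  a <- sphere_mesh(10, n_rings = 41, n_seg = 48)
  b <- sphere_mesh(10.4, n_rings = 41, n_seg = 48)
  c_ <- transform_mesh(a, diag(3), c(1, 0, 0))
  hab <- hausdorff_distance(a, b, samples = 1000)
  hbc <- hausdorff_distance(b, c_, samples = 1000)
  hac <- hausdorff_distance(a, c_, samples = 1000)
  expect_lte(hac, hab + hbc + 0.01)
})

test_that("pipeline reconstruction passes the geometric-fidelity gates", {
  spec <- synthetic_case(r_prox = 11.5, r_dist = 10.2, angulation = 18,
                         ovalization = 0.08)
  ag <- generate_aorta(spec)
  rec <- reconstruct_surface(ag$mesh, ag$path)
  expect_true(is_watertight(rec))
  bb <- apply(ag$mesh$vertices, 2, range)
  bb[1, ] <- bb[1, ] - 1
  bb[2, ] <- bb[2, ] + 1
  dice <- dice_coefficient(voxelize(ag$mesh, 0.25, bb),
                           voxelize(rec, 0.25, bb))
  expect_gt(dice, 0.95)
  expect_lt(hausdorff_distance(ag$mesh, rec, samples = 2000), 0.5)
})
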