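# Shared fixtures, built once per test run.

# analytic cylinder, radius 10, length 20, axis z
fix_cyl <- cylinder_mesh(radius = 10, length = 20)

# unit cube [0,1]^3
fix_cube <- local({
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
             c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
             c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  surface_mesh(v, f)
})

# sphere built as a tube of circular rings (watertight by construction)
sphere_mesh <- function(R = 5, n_rings = 81, n_seg = 96) {
  z <- seq(-R, R, length.out = n_rings)
  r <- sqrt(pmax(R^2 - z^2, 1e-6))
  tg <- matrix(rep(c(0, 0, 1), each = n_rings), ncol = 3)
  fr <- eritwin:::transport_frames(tg)
  eritwin:::build_tube(cbind(0, 0, z), fr$e1, fr$e2,
                       matrix(r, n_rings, n_seg))
}

# apposition field built directly from given radius matrices (feature oracles)
make_field <- function(rA, rG, spacing = 0.5, n_angles = ncol(rA)) {
  region <- analysis_region(length = nrow(rA) * spacing, spacing = spacing,
                            n_angles = n_angles)
  structure(list(s = (seq_len(nrow(rA)) - 0.5) * spacing,
                 angles = 2 * pi * (seq_len(n_angles) - 1) / n_angles,
                 rA = rA, rG = rG, gap = rA - rG,
                 rG_min = apply(rG, 1, min), rG_max = apply(rG, 1, max),
                 R_G0 = mean(rG[1, ]), region = region, centers = "shared",
                 n_measurements = 2L * nrow(rA) * n_angles,
                 n_negative_gap = sum(rA - rG < 0)),
            class = "apposition_field")
}

rotation3 <- function(axis, angle) eritwin:::rotation_about(axis, angle)

# exhaustive run-length oracle for the malapposition extent, straight off the
# long-format export
sgm2_bruteforce <- function(field, epsilon) {
  df <- as.data.frame(field)
  best <- 0L
  for (a in unique(df$angle)) {
    sub <- df[df$angle == a, ]
    sub <- sub[order(sub$s), ]
    run <- 0L
    for (m in pmax(sub$gap, 0) > epsilon) {
      run <- if (m) run + 1L else 0L
      best <- max(best, run)
    }
  }
  min(best * field$region$spacing / field$region$length, 1)
}

# exhaustive pairwise AUC oracle for a binary prediction
auc_bruteforce <- function(tp, fp, tn, fn) {
  pred <- c(rep(1, tp), rep(0, fn), rep(1, fp), rep(0, tn))
  y <- c(rep(1, tp + fn), rep(0, fp + tn))
  pos <- pred[y == 1]
  neg <- pred[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}
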