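#' Parametric specification of a synthetic deployed case
#'
#' Describes an idealized aortic neck (optionally tapered, angulated, and
#' continuing into an aneurysm sac bulge) together with a stent-graft surface
#' deployed inside it. The deployed graft is apposed to the wall everywhere
#' except inside declared gap defects — smooth, cosine-tapered radial
#' depressions of the graft surface — and its cross-sections may be ovalized.
#' Ovalization is a property of the shared cross-section shape (a non-circular
#' neck to which the graft conforms), so it changes the graft shape without by
#' itself opening a gap. Every generated surface is watertight and fully
#' determined by the specification, so downstream stages are testable without
#' patient data.
#'
#' @param r_prox proximal neck radius (mm).
#' @param r_dist distal neck radius (mm); unequal radii create a conical neck.
#' @param neck_length neck (sealing zone) length (mm).
#' @param angulation centerline bend over the neck, degrees.
#' @param sac_radius maximum aneurysm sac radius (mm), or `NA` for a neck-only
#'   tube. Must be at least `r_dist`.
#' @param sac_length longitudinal extent of the sac bulge (mm).
#' @param graft_nominal_radius nominal (pre-deployment) graft radius (mm);
#'   recorded for oversizing bookkeeping.
#' @param ovalization cross-section ovalization amplitude,
#'   `(r_max - r_min)/r_max`, in \[0, 1).
#' @param defects `NULL` or a data.frame with one gap defect per row:
#'   `start` (arclength of the defect's proximal edge, mm), `extent`
#'   (longitudinal size, mm), `span_deg` (angular span, degrees), `depth`
#'   (maximum radial gap, mm), `angle_deg` (circumferential position of the
#'   defect center, degrees).
#' @param mesh_size target triangle edge length (mm).
#' @param seed random seed recorded with the case.
#' @return an object of class `synthetic_case`.
#' @examples
#' spec <- synthetic_case(r_prox = 12, r_dist = 10,
#'                        defects = data.frame(start = 5, extent = 5,
#'                                             span_deg = 90, depth = 2,
#'                                             angle_deg = 0))
#' geom <- generate_aorta(spec)
#' graft <- generate_deployed_graft(spec)
#' @export
synthetic_case <- function(r_prox = 10.6, r_dist = 10.6, neck_length = 20,
                           angulation = 0, sac_radius = NA,
                           sac_length = 25,
                           graft_nominal_radius = 1.15 * r_prox,
                           ovalization = 0, defects = NULL,
                           mesh_size = 0.7, seed = 1L) {
  if (r_prox <= 0 || r_dist <= 0) stop("neck radii must be positive")
  if (neck_length <= 0) stop("neck length must be positive")
  if (ovalization < 0 || ovalization >= 1)
    stop("ovalization must lie in [0, 1)")
  if (!is.na(sac_radius) && sac_radius < r_dist)
    stop("self-intersecting parameters: sac radius below distal neck radius")
  if (!is.null(defects)) {
    defects <- as.data.frame(defects)
    need <- c("start", "extent", "span_deg", "depth", "angle_deg")
    if (!all(need %in% names(defects)))
      stop("defects need columns: ", paste(need, collapse = ", "))
    if (any(defects$start < 0 |
            defects$start + defects$extent > neck_length + 1e-9))
      stop("gap defect extents must lie within the neck length")
    if (any(defects$depth < 0) || any(defects$extent <= 0) ||
        any(defects$span_deg <= 0))
      stop("gap defect sizes must be positive")
  }
  structure(list(r_prox = r_prox, r_dist = r_dist, neck_length = neck_length,
                 angulation = angulation, sac_radius = sac_radius,
                 sac_length = sac_length,
                 graft_nominal_radius = graft_nominal_radius,
                 ovalization = ovalization, defects = defects,
                 mesh_size = mesh_size, seed = as.integer(seed)),
            class = "synthetic_case")
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf(
    "synthetic_case: neck %.1f->%.1f mm radius over %.0f mm, %g deg bend\n",
    x$r_prox, x$r_dist, x$neck_length, x$angulation))
  cat(sprintf("  ovalization %.3f, %d gap defect(s), seed %d\n",
              x$ovalization,
              if (is.null(x$defects)) 0L else nrow(x$defects), x$seed))
  invisible(x)
}

# Neck/sac radius profile (circular-equivalent major radius) at arclength s.
case_radius_profile <- function(spec, s) {
  r <- spec$r_prox + (spec$r_dist - spec$r_prox) *
    pmin(pmax(s / spec$neck_length, 0), 1)
  if (!is.na(spec$sac_radius)) {
    u <- (s - spec$neck_length) / spec$sac_length
    bulge <- u > 0 & u < 1
    r[bulge] <- spec$r_dist +
      (spec$sac_radius - spec$r_dist) * sin(pi * u[bulge])^2
  }
  r
}

# Cosine-tapered defect depth field: total graft radial reduction at (s, phi).
# phi in radians in the ring frame.
case_defect_depth <- function(spec, s, phi) {
  depth <- numeric(length(s) * length(phi))
  dim(depth) <- c(length(s), length(phi))
  if (is.null(spec$defects)) return(depth)
  for (j in seq_len(nrow(spec$defects))) {
    d <- spec$defects[j, ]
    ctr_s <- d$start + d$extent / 2
    u <- 2 * (s - ctr_s) / d$extent
    wl <- ifelse(abs(u) <= 1, cos(pi * u / 2)^2, 0)
    dphi <- (phi - d$angle_deg * pi / 180 + pi) %% (2 * pi) - pi
    v <- 2 * dphi / (d$span_deg * pi / 180)
    wa <- ifelse(abs(v) <= 1, cos(pi * v / 2)^2, 0)
    depth <- depth + d$depth * outer(wl, wa)
  }
  depth
}

# Centerline, ring frames and per-ring scale for a synthetic case: the bend
# ramps over the middle half of the tube so both ends stay straight.
.case_skeleton <- function(spec, length_out, ring_spacing) {
  L <- length_out
  fine <- seq(0, L, by = min(0.1, ring_spacing / 4))
  alpha <- spec$angulation * pi / 180
  ramp <- pmin(pmax((fine / L - 0.3) / 0.4, 0), 1)
  theta <- alpha * ramp
  # integrate the unit tangent (sin theta, 0, cos theta) over arclength
  ds <- diff(fine)
  tx <- sin(theta)
  tz <- cos(theta)
  px <- c(0, cumsum((tx[-1] + tx[-length(tx)]) / 2 * ds))
  pz <- c(0, cumsum((tz[-1] + tz[-length(tz)]) / 2 * ds))
  pts <- cbind(px, 0, pz)
  path <- centerline_path(pts)
  s_ring <- seq(0, L, by = ring_spacing)
  if (s_ring[length(s_ring)] < L - 1e-9) s_ring <- c(s_ring, L)
  # chordal integration undershoots the parameter length slightly; rescale
  at <- centerline_at(path, s_ring * (max(path$s) / L))
  fr <- transport_frames(at$tangents)
  list(path = path, s = s_ring, centers = at$points,
       tangents = at$tangents, e1 = fr$e1, e2 = fr$e2)
}

# Polar radius of the ovalized cross-section (ellipse with major radius a
# along e1 and minor radius (1 - ovalization) * a) at ring angles phi.
.oval_radius <- function(a, ovalization, phi) {
  b <- (1 - ovalization) * a
  (a * b) / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
}

#' Generate a synthetic aortic surface
#'
#' Builds the watertight tubular lumen surface described by a
#' [synthetic_case()]: cross-section radius interpolating the proximal and
#' distal neck radii, an optional fusiform sac bulge, centerline angulation,
#' and shared cross-section ovalization.
#'
#' @param spec a [synthetic_case()].
#' @return list with `mesh` (a [surface_mesh()]) and `path` (the analytic
#'   [centerline_path()]).
#' @export
generate_aorta <- function(spec) {
  L <- spec$neck_length + if (is.na(spec$sac_radius)) 0 else spec$sac_length
  ring_spacing <- min(spec$mesh_size, 0.5)
  sk <- .case_skeleton(spec, L, ring_spacing)
  rmax <- max(case_radius_profile(spec, sk$s))
  n_seg <- max(48L, as.integer(ceiling(2 * pi * rmax / spec$mesh_size)))
  phi <- 2 * pi * (seq_len(n_seg) - 1) / n_seg
  a <- case_radius_profile(spec, sk$s)
  radii <- t(vapply(seq_along(sk$s),
                    function(i) .oval_radius(a[i], spec$ovalization, phi),
                    numeric(n_seg)))
  mesh <- build_tube(sk$centers, sk$e1, sk$e2, radii)
  list(mesh = mesh, path = sk$path)
}

#' Generate the deployed stent-graft surface for a case
#'
#' The graft conforms to the (possibly ovalized) aortic cross-section over the
#' neck, except inside the declared gap defects where its radius is reduced by
#' a cosine-tapered depth profile peaking at the stated maximum gap.
#'
#' @param spec a [synthetic_case()].
#' @param aorta optional output of [generate_aorta()] for the same spec; only
#'   used for consistency checks.
#' @return a [surface_mesh()] covering the neck region.
#' @export
generate_deployed_graft <- function(spec, aorta = NULL) {
  ring_spacing <- min(spec$mesh_size, 0.5)
  sk <- .case_skeleton(spec,
                       spec$neck_length +
                         if (is.na(spec$sac_radius)) 0 else spec$sac_length,
                       ring_spacing)
  keep <- sk$s <= spec$neck_length + 1e-9
  s <- sk$s[keep]
  a <- case_radius_profile(spec, s)
  n_seg <- max(48L,
               as.integer(ceiling(2 * pi * max(a) / spec$mesh_size)))
  phi <- 2 * pi * (seq_len(n_seg) - 1) / n_seg
  depth <- case_defect_depth(spec, s, phi)
  radii <- matrix(0, length(s), n_seg)
  for (i in seq_along(s)) {
    wall <- .oval_radius(a[i], spec$ovalization, phi)
    g <- wall - depth[i, ]
    if (any(g <= 0))
      stop(sprintf("gap depth >= local radius at s = %.2f mm", s[i]))
    radii[i, ] <- g
  }
  build_tube(sk$centers[keep, , drop = FALSE],
             sk$e1[keep, , drop = FALSE], sk$e2[keep, , drop = FALSE],
             radii)
}

#' Closed-form feature values for a synthetic case
#'
#' The generator knows its own geometry, so the three apposition features can
#' be evaluated on the continuous surface description without any meshing:
#' conicity from the radius profile at the first and last slice positions,
#' and the shape score and malapposition extent from the exact per-slice
#' wall/graft radius functions (ovalized cross-section minus the
#' cosine-tapered defect field) sampled on the same slice/angle grid the
#' measurement pipeline uses. Ground truth for cohort generation and an
#' independent check on the mesh-based route.
#'
#' @param spec a [synthetic_case()].
#' @param region an [analysis_region()].
#' @param epsilon malapposition gap threshold (mm).
#' @return list with `ac`, `sgs2`, `sgm2`.
#' @export
analytic_features <- function(spec, region = analysis_region(),
                              epsilon = 0.1) {
  s_i <- region$s0 + (seq_len(region$n_slices) - 0.5) * region$spacing
  r1 <- case_radius_profile(spec, s_i[1])
  r2 <- case_radius_profile(spec, s_i[length(s_i)])
  ac <- abs(r1 - r2) / max(r1, r2)
  phi <- 2 * pi * (seq_len(region$n_angles) - 1) / region$n_angles
  depth <- case_defect_depth(spec, s_i, phi)       # the gap field, exactly
  a <- case_radius_profile(spec, s_i)
  dev <- numeric(length(s_i))
  for (i in seq_along(s_i)) {
    rg <- .oval_radius(a[i], spec$ovalization, phi) - depth[i, ]
    dev[i] <- (max(rg) - min(rg)) / max(rg)
  }
  mal <- depth > epsilon
  max_run <- 0L
  for (k in seq_len(ncol(mal))) {
    r <- rle(mal[, k])
    runs <- r$lengths[r$values]
    if (length(runs)) max_run <- max(max_run, max(runs))
  }
  list(ac = ac, sgs2 = mean(dev),
       sgm2 = min(max_run * region$spacing / region$length, 1))
}

#' Generate a labeled synthetic cohort
#'
#' Draws `n` cases with clinical covariates (age, gender, BMI, comorbidity
#' flags, neck geometry), a per-case [synthetic_case()], closed-form
#' apposition features, a planning-group flag, and a ground-truth endoleak
#' label. The label follows a declared generative rule: a case leaks when its
#' maximum gap depth exceeds 1 mm persisting for at least 5 mm longitudinally,
#' or when its aortic conicity exceeds 0.25; labels are then flipped at the
#' stated noise rate. A `leak_fraction` share of cases is drawn from
#' leak-prone geometry (three quarters via deep, long gap defects; one quarter
#' via strong conicity), so the malapposition extent is declared the dominant
#' generating feature, conicity second, and the shape score carries no
#' generating weight.
#'
#' The group flag (digital-twin vs conventional planning) is assigned with a
#' probability that depends on age, smoking, hostile neck and neck angle
#' scaled by `confounding`; at `confounding = 0` the two groups have identical
#' covariate distributions.
#'
#' @param n number of cases (>= 10).
#' @param leak_fraction target fraction of leak-prone geometry, in (0, 1).
#' @param confounding strength of the covariate-group association (0 = none).
#' @param seed random seed; the draw is fully reproducible.
#' @param noise_rate label-flip probability.
#' @return data.frame with one row per case (covariates, geometry summaries,
#'   features `ac`/`sgs2`/`sgm2`, `group`, `label`) and the per-case specs in
#'   `attr(, "specs")`.
#' @export
generate_cohort <- function(n, leak_fraction = 1 / 3, confounding = 0,
                            seed = 1L, noise_rate = 0.05) {
  if (n < 10) stop("cohort generation needs n >= 10")
  if (leak_fraction <= 0 || leak_fraction >= 1)
    stop("leak_fraction must lie in (0, 1)")
  set.seed(seed)
  age <- round(stats::rnorm(n, 75, 9))
  male <- stats::rbinom(n, 1, 0.8)
  bmi <- round(stats::rnorm(n, 23.7, 3.9), 1)
  htn <- stats::rbinom(n, 1, 0.74)
  dm <- stats::rbinom(n, 1, 0.21)
  cad <- stats::rbinom(n, 1, 0.19)
  copd <- stats::rbinom(n, 1, 0.06)
  ckd <- stats::rbinom(n, 1, 0.08)
  smoking <- stats::rbinom(n, 1, 0.43)
  hostile_neck <- stats::rbinom(n, 1, 0.31)
  neck_angle <- pmin(abs(stats::rnorm(n, 35, 20)), 120)
  neck_length_cov <- pmin(pmax(stats::rnorm(n, 33, 12), 15), 60)
  r_prox <- pmin(pmax(stats::rnorm(n, 10.6, 1.3), 7), 15)

  risky <- stats::runif(n) < leak_fraction
  conic_type <- risky & stats::runif(n) < 0.25
  defect_type <- risky & !conic_type

  conicity <- abs(stats::rnorm(n, 0, 0.05))
  conicity[conic_type] <- stats::runif(sum(conic_type), 0.28, 0.42)
  widen <- stats::runif(n) < 0.5
  r_dist <- ifelse(widen, r_prox * (1 + conicity), r_prox * (1 - conicity))

  ovalization <- stats::runif(n, 0, 0.2)

  has_benign <- !defect_type & stats::runif(n) < 0.5
  depth <- extent <- rep(NA_real_, n)
  depth[defect_type] <- stats::runif(sum(defect_type), 2.0, 3.5)
  extent[defect_type] <- stats::runif(sum(defect_type), 11, 17)
  depth[has_benign] <- stats::runif(sum(has_benign), 0.2, 0.9)
  extent[has_benign] <- stats::runif(sum(has_benign), 2, 6)
  has_def <- !is.na(depth)
  ctr <- rep(NA_real_, n)
  ctr[has_def] <- stats::runif(sum(has_def), extent[has_def] / 2,
                               20 - extent[has_def] / 2)
  span <- ifelse(has_def, stats::runif(n, 60, 120), NA)
  dangle <- ifelse(has_def, stats::runif(n, 0, 360), NA)

  specs <- vector("list", n)
  ac <- sgs2 <- sgm2 <- numeric(n)
  region <- analysis_region()
  for (i in seq_len(n)) {
    defs <- if (has_def[i])
      data.frame(start = ctr[i] - extent[i] / 2, extent = extent[i],
                 span_deg = span[i], depth = depth[i], angle_deg = dangle[i])
    else NULL
    specs[[i]] <- synthetic_case(r_prox = r_prox[i], r_dist = r_dist[i],
                                 neck_length = 20,
                                 angulation = neck_angle[i],
                                 ovalization = ovalization[i],
                                 defects = defs, seed = seed + i)
    f <- analytic_features(specs[[i]], region)
    ac[i] <- f$ac
    sgs2[i] <- f$sgs2
    sgm2[i] <- f$sgm2
  }

  # declared rule: gap > 1 mm persisting >= 5 mm, or conicity > 0.25
  persist <- rep(0, n)
  idx <- which(has_def & depth > 1)
  persist[idx] <- extent[idx] * (2 / pi) * acos(sqrt(1 / depth[idx]))
  label_true <- as.integer(persist >= 5 | ac > 0.25)
  flip <- stats::runif(n) < noise_rate
  label <- as.integer(xor(label_true == 1L, flip))

  # treated (digital-twin planning) is the minority group: a 15% base rate
  # keeps 1:3 matching without replacement feasible with caliper headroom
  lp <- confounding * (0.03 * (age - 75) + 0.8 * smoking +
                         0.6 * hostile_neck + 0.01 * (neck_angle - 35))
  group <- stats::rbinom(n, 1, stats::plogis(stats::qlogis(0.15) + lp))

  out <- data.frame(case_id = sprintf("case%04d", seq_len(n)),
                    age = age, male = male, bmi = bmi, htn = htn, dm = dm,
                    cad = cad, copd = copd, ckd = ckd, smoking = smoking,
                    hostile_neck = hostile_neck, neck_angle = neck_angle,
                    neck_length = neck_length_cov,
                    neck_diameter = 2 * r_prox,
                    ac = ac, sgs2 = sgs2, sgm2 = sgm2,
                    group = group, label_true = label_true, label = label)
  attr(out, "specs") <- specs
  attr(out, "generating_rule") <-
    list(depth_threshold_mm = 1, persistence_mm = 5,
         conicity_threshold = 0.25, noise_rate = noise_rate,
         feature_weight_order = c("sgm2", "ac", "sgs2"))
  out
}
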