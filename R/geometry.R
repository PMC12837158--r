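#' Arclength-parameterized centerline
#'
#' @param points ordered matrix of 3-D points (mm), proximal first.
#' @return An object of class `centerline_path`: list with `points`,
#'   cumulative arclength `s` (mm, starting at 0) and unit `tangents`.
#' @export
centerline_path <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("a centerline needs at least 2 points")
  d <- diff(points)
  seg <- sqrt(rowSums(d^2))
  if (any(seg == 0)) stop("duplicate consecutive centerline points")
  s <- c(0, cumsum(seg))
  n <- nrow(points)
  # central differences in arclength, one-sided at the ends
  tg <- matrix(0, n, 3)
  tg[1, ] <- d[1, ] / seg[1]
  tg[n, ] <- d[n - 1, ] / seg[n - 1]
  if (n > 2) {
    mid <- points[3:n, , drop = FALSE] - points[1:(n - 2), , drop = FALSE]
    tg[2:(n - 1), ] <- mid / sqrt(rowSums(mid^2))
  }
  structure(list(points = points, s = s, tangents = tg),
            class = "centerline_path")
}

#' @export
print.centerline_path <- function(x, ...) {
  cat(sprintf("centerline_path: %d points, arclength %.2f mm\n",
              nrow(x$points), max(x$s)))
  invisible(x)
}

#' Resample a polyline at uniform arclength spacing
#'
#' Duplicate consecutive points are collapsed (with a warning); the endpoints
#' are preserved exactly and tangents are smoothed central differences.
#'
#' @param points ordered matrix of 3-D points (mm).
#' @param spacing target spacing in mm (> 0).
#' @return a [centerline_path()].
#' @export
resample_centerline <- function(points, spacing) {
  points <- as.matrix(points)
  if (spacing <= 0) stop("spacing must be > 0")
  if (nrow(points) >= 2) {
    seg <- sqrt(rowSums(diff(points)^2))
    if (any(seg < 1e-12)) {
      warning("collapsing duplicate consecutive centerline points")
      points <- points[c(TRUE, seg >= 1e-12), , drop = FALSE]
    }
  }
  if (nrow(points) < 2) stop("fewer than 2 distinct centerline points")
  s <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  L <- max(s)
  n_out <- max(2L, as.integer(round(L / spacing)) + 1L)
  s_new <- seq(0, L, length.out = n_out)
  p_new <- cbind(stats::approx(s, points[, 1], xout = s_new)$y,
                 stats::approx(s, points[, 2], xout = s_new)$y,
                 stats::approx(s, points[, 3], xout = s_new)$y)
  centerline_path(p_new)
}

#' Evaluate a centerline at given arclength positions
#'
#' Linear interpolation of position and (renormalized) tangent.
#'
#' @param path a [centerline_path()].
#' @param s arclength positions (mm) within the path's range.
#' @return list with matrices `points` and `tangents`.
#' @export
centerline_at <- function(path, s) {
  if (any(s < min(path$s) - 1e-9 | s > max(path$s) + 1e-9))
    stop("arclength position outside centerline range")
  s <- pmin(pmax(s, min(path$s)), max(path$s))
  p <- cbind(stats::approx(path$s, path$points[, 1], xout = s)$y,
             stats::approx(path$s, path$points[, 2], xout = s)$y,
             stats::approx(path$s, path$points[, 3], xout = s)$y)
  tg <- cbind(stats::approx(path$s, path$tangents[, 1], xout = s)$y,
              stats::approx(path$s, path$tangents[, 2], xout = s)$y,
              stats::approx(path$s, path$tangents[, 3], xout = s)$y)
  tg <- tg / sqrt(rowSums(tg^2))
  list(points = p, tangents = tg)
}

# In-plane orthonormal basis for a unit normal; e1 x e2 = normal so that
# angles measured CCW in (e1, e2) are CCW about the normal.
plane_basis <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Intersect a surface mesh with a plane
#'
#' Computes the closed intersection contour of a watertight surface with the
#' plane through `origin` with unit `normal`. When the plane cuts the surface
#' in several closed loops (e.g. through a bent tube twice), the loop whose
#' centroid is nearest `origin` is returned. The boundary is ordered
#' counter-clockwise about the normal.
#'
#' @param mesh a [surface_mesh()].
#' @param origin point on the plane (mm).
#' @param normal plane normal (normalized internally).
#' @param basis optional in-plane basis (list `e1`, `e2`) to make contour
#'   angles comparable across slices; defaults to [plane_basis()].
#' @return An object of class `planar_contour`: list with `points` (k x 3),
#'   `points2d` (k x 2, in the `e1`/`e2` basis about `origin`), `origin`,
#'   `normal`, `basis`, area-weighted `centroid` / `centroid2d`, and `area`
#'   (mm^2).
#' @export
slice_mesh <- function(mesh, origin, normal, basis = NULL) {
  n <- normal / sqrt(sum(normal^2))
  v <- mesh$vertices
  f <- mesh$faces
  d <- (v[, 1] - origin[1]) * n[1] + (v[, 2] - origin[2]) * n[2] +
    (v[, 3] - origin[3]) * n[3]
  # nudge vertices lying exactly on the plane to keep crossings transversal
  eps <- 1e-9 * max(1, max(abs(d)))
  d[d == 0] <- eps
  dsign <- d > 0
  tri_d <- matrix(dsign[f], ncol = 3)
  cross <- rowSums(tri_d) %in% c(1L, 2L)
  if (!any(cross)) stop("plane outside mesh: no intersection")
  fc <- f[cross, , drop = FALSE]
  # for each crossing triangle find its two crossing edges
  segs <- matrix(NA_real_, nrow = sum(cross), ncol = 6)
  edge_pairs <- list(c(1, 2), c(2, 3), c(3, 1))
  pts_for <- function(i1, i2, sel) {
    di <- d[i1]
    dj <- d[i2]
    t <- di / (di - dj)
    v[i1, , drop = FALSE] + t * (v[i2, , drop = FALSE] - v[i1, , drop = FALSE])
  }
  hit <- matrix(FALSE, nrow(fc), 3)
  for (k in 1:3) {
    i1 <- fc[, edge_pairs[[k]][1]]
    i2 <- fc[, edge_pairs[[k]][2]]
    hit[, k] <- (d[i1] > 0) != (d[i2] > 0)
  }
  pos <- t(apply(hit, 1, which))        # 2 crossing edges per triangle
  for (k in 1:2) {
    i1 <- fc[cbind(seq_len(nrow(fc)),
                   vapply(pos[, k], function(e) edge_pairs[[e]][1], 1))]
    i2 <- fc[cbind(seq_len(nrow(fc)),
                   vapply(pos[, k], function(e) edge_pairs[[e]][2], 1))]
    t <- d[i1] / (d[i1] - d[i2])
    segs[, (3 * k - 2):(3 * k)] <-
      v[i1, , drop = FALSE] + t * (v[i2, , drop = FALSE] -
                                     v[i1, , drop = FALSE])
  }
  loops <- .chain_segments(segs)
  if (length(loops) == 0) stop("non-watertight slice: open intersection")
  bas <- if (is.null(basis)) plane_basis(n) else basis
  loop_ctr_d <- vapply(loops, function(lp) sum((colMeans(lp) - origin)^2), 1)
  loop_areas <- vapply(loops, function(lp) {
    b2 <- cbind((lp[, 1] - origin[1]) * bas$e1[1] +
                  (lp[, 2] - origin[2]) * bas$e1[2] +
                  (lp[, 3] - origin[3]) * bas$e1[3],
                (lp[, 1] - origin[1]) * bas$e2[1] +
                  (lp[, 2] - origin[2]) * bas$e2[2] +
                  (lp[, 3] - origin[3]) * bas$e2[3])
    abs(.polygon_area2d(b2))
  }, 1)
  best <- loops[[which.min(loop_ctr_d)]]
  # drop duplicate consecutive points (plane through a mesh vertex/ring)
  nb <- nrow(best)
  dup <- rowSums((best - best[c(2:nb, 1), , drop = FALSE])^2) < (1e-7)^2
  if (any(dup)) best <- best[!dup, , drop = FALSE]
  if (nrow(best) < 3) stop("degenerate slice contour")
  p2 <- cbind((best[, 1] - origin[1]) * bas$e1[1] +
                (best[, 2] - origin[2]) * bas$e1[2] +
                (best[, 3] - origin[3]) * bas$e1[3],
              (best[, 1] - origin[1]) * bas$e2[1] +
                (best[, 2] - origin[2]) * bas$e2[2] +
                (best[, 3] - origin[3]) * bas$e2[3])
  # signed polygon area; reverse to enforce CCW about the normal
  a2 <- .polygon_area2d(p2)
  if (a2 < 0) {
    best <- best[nrow(best):1, , drop = FALSE]
    p2 <- p2[nrow(p2):1, , drop = FALSE]
    a2 <- -a2
  }
  c2 <- .polygon_centroid2d(p2)
  centroid <- origin + c2[1] * bas$e1 + c2[2] * bas$e2
  structure(list(points = best, points2d = p2, origin = origin, normal = n,
                 basis = bas, centroid = centroid, centroid2d = c2,
                 area = a2, n_loops = length(loops), loop_areas = loop_areas),
            class = "planar_contour")
}

#' @export
print.planar_contour <- function(x, ...) {
  cat(sprintf("planar_contour: %d points, area %.2f mm^2\n",
              nrow(x$points), x$area))
  invisible(x)
}

# Chain unordered segments (x1 y1 z1 x2 y2 z2 rows) into closed loops by
# matching endpoints on a rounded-coordinate key. Open chains are dropped.
.chain_segments <- function(segs) {
  p1 <- segs[, 1:3, drop = FALSE]
  p2 <- segs[, 4:6, drop = FALSE]
  scale <- max(abs(segs), 1)
  tol <- 1e-7 * scale
  keyify <- function(p) paste(round(p[, 1] / tol), round(p[, 2] / tol),
                              round(p[, 3] / tol))
  k1 <- keyify(p1)
  k2 <- keyify(p2)
  nseg <- nrow(segs)
  used <- rep(FALSE, nseg)
  # adjacency: for each endpoint key the segments touching it
  allk <- c(k1, k2)
  seg_of <- c(seq_len(nseg), seq_len(nseg))
  adj <- split(seg_of, allk)
  loops <- list()
  for (start in seq_len(nseg)) {
    if (used[start]) next
    used[start] <- TRUE
    pts <- list(p1[start, ], p2[start, ])
    cur_key <- k2[start]
    start_key <- k1[start]
    repeat {
      cand <- adj[[cur_key]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      nxt <- cand[1]
      used[nxt] <- TRUE
      if (k1[nxt] == cur_key) {
        pts[[length(pts) + 1]] <- p2[nxt, ]
        cur_key <- k2[nxt]
      } else {
        pts[[length(pts) + 1]] <- p1[nxt, ]
        cur_key <- k1[nxt]
      }
      if (cur_key == start_key) break
    }
    if (cur_key == start_key && length(pts) >= 4) {
      loop <- do.call(rbind, pts)
      loops[[length(loops) + 1]] <- loop[-nrow(loop), , drop = FALSE]
    }
  }
  loops
}

.polygon_area2d <- function(p) {
  x <- p[, 1]
  y <- p[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

.polygon_centroid2d <- function(p) {
  x <- p[, 1]
  y <- p[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

.point_in_polygon <- function(pt, poly) {
  # even-odd rule
  x <- poly[, 1]
  y <- poly[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  crosses <- ((y > pt[2]) != (yn > pt[2])) &
    (pt[1] < (xn - x) * (pt[2] - y) / (yn - y) + x)
  sum(crosses) %% 2 == 1
}

#' Radial discretization of a planar contour
#'
#' Casts `n_angles` uniformly spaced rays from `center` in the contour plane
#' and records the distance to the first outward boundary crossing — the
#' "dots per circumference" of the apposition sampling scheme. Taking the
#' first crossing means a folded boundary is measured at its lumen-facing
#' surface.
#'
#' @param contour a `planar_contour` from [slice_mesh()].
#' @param center 3-D point inside the contour; defaults to its centroid.
#' @param n_angles number of rays (>= 8), default 200.
#' @return data.frame with `angle` (radians, CCW about the contour normal,
#'   starting at the in-plane `e1` axis) and `radius` (mm).
#' @export
polar_discretize <- function(contour, center = NULL, n_angles = 200) {
  if (n_angles < 8) stop("n_angles must be >= 8")
  if (is.null(center)) {
    c2 <- contour$centroid2d
  } else {
    rel <- center - contour$origin
    off <- sum(rel * contour$normal)
    if (abs(off) > 1e-6 * max(1, sqrt(sum(rel^2))) + 1e-9)
      warning("center projected onto the contour plane")
    c2 <- c(sum(rel * contour$basis$e1), sum(rel * contour$basis$e2))
  }
  poly <- contour$points2d
  if (!.point_in_polygon(c2, poly)) stop("center outside contour polygon")
  px <- poly[, 1] - c2[1]
  py <- poly[, 2] - c2[2]
  qx <- c(px[-1], px[1])
  qy <- c(py[-1], py[1])
  ex <- qx - px
  ey <- qy - py
  phi <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  radii <- numeric(n_angles)
  for (k in seq_len(n_angles)) {
    dx <- cos(phi[k])
    dy <- sin(phi[k])
    denom <- dx * ey - dy * ex
    ok <- abs(denom) > 1e-14
    u <- (dy * px - dx * py) / denom         # param along edge: p + u e
    t <- if (abs(dx) > abs(dy)) (px + u * ex) / dx else (py + u * ey) / dy
    # half-open edge window with slack so a ray through a polygon vertex is
    # counted exactly once
    valid <- ok & u >= -1e-9 & u < 1 - 1e-9 & t > 1e-9
    if (!any(valid)) stop("no boundary crossing found along ray")
    radii[k] <- min(t[valid])
  }
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop("degenerate polygon: invalid radius")
  data.frame(angle = phi, radius = radii)
}

#' Centroid-based centerline of a tubular mesh
#'
#' Fallback when no centerline is supplied: slices the mesh perpendicular to
#' `axis_hint` at uniform spacing and connects the slice-contour centroids,
#' ordered proximal to distal along the hint axis.
#'
#' @param mesh a tubular [surface_mesh()].
#' @param axis_hint approximate tube axis (unit vector).
#' @param spacing slice spacing in mm.
#' @return a [centerline_path()].
#' @export
centroid_centerline <- function(mesh, axis_hint = c(0, 0, 1), spacing = 1) {
  a <- axis_hint / sqrt(sum(axis_hint^2))
  proj <- mesh$vertices %*% a
  lo <- min(proj)
  hi <- max(proj)
  if (hi - lo < 2 * spacing) stop("mesh is not tubular along axis_hint")
  probe <- function(origin, normal, pos_label) {
    cont <- tryCatch(slice_mesh(mesh, origin, normal),
                     error = function(e) NULL)
    if (is.null(cont)) return(NULL)
    if (cont$n_loops > 1 &&
        sort(cont$loop_areas, decreasing = TRUE)[2] >
          0.25 * max(cont$loop_areas))
      stop(sprintf("branching slice at axis position %.2f mm: %d contours",
                   pos_label, cont$n_loops))
    cont
  }
  # pass 1: slices normal to the hint axis (biased near tilted end caps)
  positions <- seq(lo + 0.51 * spacing, hi - 0.51 * spacing, by = spacing)
  ctr1 <- matrix(NA_real_, length(positions), 3)
  areas1 <- numeric(length(positions))
  for (i in seq_along(positions)) {
    cont <- probe(positions[i] * a, a, positions[i])
    if (is.null(cont))
      stop(sprintf("no closed contour at axis position %.2f mm",
                   positions[i]))
    ctr1[i, ] <- cont$centroid
    areas1[i] <- cont$area
  }
  path1 <- centerline_path(ctr1)
  n1 <- nrow(ctr1)
  # trim the zone where hint-normal planes cross a tilted end cap
  # (extent 2 r sin(tilt)), estimating the tilt away from the ends
  r_typ <- sqrt(stats::median(areas1) / pi)
  tilt_at <- function(idx) acos(min(abs(sum(path1$tangents[idx, ] * a)), 1))
  m_lo <- 2 * r_typ * sin(tilt_at(max(1, round(0.25 * n1)))) + spacing
  m_hi <- 2 * r_typ * sin(tilt_at(min(n1, round(0.75 * n1)))) + spacing
  keep <- which(positions >= lo + m_lo & positions <= hi - m_hi)
  if (length(keep) < 2) keep <- seq_len(n1)
  # pass 2: re-slice normal to the local pass-1 tangent (removes the
  # obliquity bias of pass 1 inside bends)
  pts <- list()
  areas <- c()
  for (i in keep) {
    cont <- probe(ctr1[i, ], path1$tangents[i, ], positions[i])
    if (is.null(cont)) next
    pts[[length(pts) + 1]] <- cont$centroid
    areas <- c(areas, cont$area)
  }
  if (length(pts) < 2) stop("mesh is not tubular along axis_hint")
  # march outward from both ends along the local tangent to recover the
  # straight end segments that the trim removed
  march <- function(pts, areas) {
    a_ref <- stats::median(areas)
    reason <- "limit"
    repeat {
      n <- length(pts)
      if (n < 2) break
      tdir <- pts[[n]] - pts[[n - 1]]
      tdir <- tdir / sqrt(sum(tdir^2))
      origin <- pts[[n]] + spacing * tdir
      cont <- tryCatch(probe(origin, tdir, NA), error = function(e) NULL)
      if (is.null(cont)) {
        reason <- "end"
        break
      }
      if (cont$area < 0.5 * a_ref ||
          sum((cont$centroid - pts[[n]])^2) > (2 * spacing)^2) {
        reason <- "collapse"
        break
      }
      pts[[n + 1]] <- cont$centroid
      areas <- c(areas, cont$area)
      if (length(pts) > n1 + 200) break
    }
    list(pts = pts, areas = areas, reason = reason)
  }
  fwd <- march(pts, areas)
  bwd <- march(lapply(rev(seq_along(fwd$pts)), function(i) fwd$pts[[i]]),
               rev(fwd$areas))
  ctr <- do.call(rbind, rev(bwd$pts))
  areas <- rev(bwd$areas)
  # a tubular mesh ends at its caps (the probe plane leaves the mesh); a
  # rounded closed shape instead collapses in cross-section at both ends
  if ((fwd$reason == "collapse" && bwd$reason == "collapse") ||
      max(areas) > 8 * max(min(areas), 1e-9))
    warning("degenerate path: mesh may not be tubular along axis_hint")
  centerline_path(ctr)
}
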