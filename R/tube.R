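# Tube-surface construction shared by the synthetic generators and the
# slice-based surface reconstruction.

# Parallel-transported in-plane frames along a polyline: keeps the angular
# origin consistent from slice to slice so that an angle index means the same
# circumferential position on every cross-section.
transport_frames <- function(tangents, e1_init = NULL) {
  n <- nrow(tangents)
  e1 <- matrix(0, n, 3)
  e2 <- matrix(0, n, 3)
  t1 <- tangents[1, ]
  if (is.null(e1_init)) {
    b <- plane_basis(t1)
    e1[1, ] <- b$e1
    e2[1, ] <- b$e2
  } else {
    v <- e1_init - sum(e1_init * t1) * t1
    if (sqrt(sum(v^2)) < 1e-9)
      stop("frame reference direction is parallel to the tangent")
    v <- v / sqrt(sum(v^2))
    e1[1, ] <- v
    e2[1, ] <- c(t1[2] * v[3] - t1[3] * v[2],
                 t1[3] * v[1] - t1[1] * v[3],
                 t1[1] * v[2] - t1[2] * v[1])
  }
  for (i in seq_len(n - 1) + 1) {
    t_i <- tangents[i, ]
    v <- e1[i - 1, ] - sum(e1[i - 1, ] * t_i) * t_i
    v <- v / sqrt(sum(v^2))
    e1[i, ] <- v
    e2[i, ] <- c(t_i[2] * v[3] - t_i[3] * v[2],
                 t_i[3] * v[1] - t_i[1] * v[3],
                 t_i[1] * v[2] - t_i[2] * v[1])
  }
  list(e1 = e1, e2 = e2)
}

# Build a capped tube from per-ring centers, frames and per-angle radii.
# radii: n_rings x n_seg matrix; angle k is 2*pi*(k-1)/n_seg in the (e1,e2)
# frame of each ring. Returns a watertight surface_mesh.
build_tube <- function(centers, e1, e2, radii) {
  n_ring <- nrow(centers)
  n_seg <- ncol(radii)
  phi <- 2 * pi * (seq_len(n_seg) - 1) / n_seg
  cp <- cos(phi)
  sp <- sin(phi)
  verts <- matrix(0, n_ring * n_seg + 2, 3)
  for (i in seq_len(n_ring)) {
    dir <- outer(cp, e1[i, ]) + outer(sp, e2[i, ])
    ring <- sweep(radii[i, ] * dir, 2, centers[i, ], "+")
    verts[(i - 1) * n_seg + seq_len(n_seg), ] <- ring
  }
  apex1 <- n_ring * n_seg + 1L   # proximal cap center
  apex2 <- n_ring * n_seg + 2L   # distal cap center
  verts[apex1, ] <- colMeans(verts[seq_len(n_seg), , drop = FALSE])
  verts[apex2, ] <- colMeans(verts[(n_ring - 1) * n_seg + seq_len(n_seg), ,
                                   drop = FALSE])
  idx <- function(i, k) (i - 1L) * n_seg + ((k - 1L) %% n_seg) + 1L
  k <- seq_len(n_seg)
  faces <- vector("list", n_ring + 1)
  for (i in seq_len(n_ring - 1)) {
    a <- idx(i, k)
    b <- idx(i, k + 1L)
    c_ <- idx(i + 1L, k + 1L)
    d <- idx(i + 1L, k)
    faces[[i]] <- rbind(cbind(a, b, c_), cbind(a, c_, d))
  }
  faces[[n_ring]] <- cbind(idx(1L, k + 1L), idx(1L, k),
                           rep(apex1, n_seg))
  faces[[n_ring + 1]] <- cbind(idx(n_ring, k), idx(n_ring, k + 1L),
                               rep(apex2, n_seg))
  surface_mesh(verts, do.call(rbind, faces), validate = FALSE)
}

#' Analytic cylinder mesh
#'
#' Right circular cylinder along the z axis starting at the origin; a
#' convenient analytic fixture for the slicing and sampling operations.
#'
#' @param radius cylinder radius (mm).
#' @param length cylinder length (mm).
#' @param n_seg circumferential segments.
#' @param ring_spacing longitudinal ring spacing (mm).
#' @return a watertight [surface_mesh()].
#' @export
cylinder_mesh <- function(radius = 10, length = 20, n_seg = 96,
                          ring_spacing = 0.5) {
  z <- seq(0, length, by = ring_spacing)
  if (z[length(z)] < length) z <- c(z, length)
  centers <- cbind(0, 0, z)
  tangents <- matrix(rep(c(0, 0, 1), each = length(z)), ncol = 3)
  fr <- transport_frames(tangents)
  radii <- matrix(radius, length(z), n_seg)
  build_tube(centers, fr$e1, fr$e2, radii)
}
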