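#' Triangulated surface mesh
#'
#' Container for a triangulated surface in millimetre coordinates, the common
#' currency of the geometry layer: the reconstructed aortic lumen, the deployed
#' stent-graft, and every synthetic phantom are `surface_mesh` objects.
#'
#' @param vertices numeric matrix, one 3-D point (mm) per row.
#' @param faces integer matrix, one triangle per row, 1-based vertex indices.
#' @param validate check index ranges and degenerate triangles.
#' @return An object of class `surface_mesh`: a list with `vertices`, `faces`
#'   and a lazily computed `watertight` flag (see [is_watertight()]).
#' @examples
#' m <- cylinder_mesh(radius = 10, length = 20)
#' m
#' is_watertight(m)
#' @export
surface_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (validate) {
    if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
      stop("face indices out of range")
    if (anyNA(vertices)) stop("vertices contain NA")
  }
  structure(list(vertices = vertices, faces = faces, watertight = NA),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bounds [mm]: x %.2f..%.2f  y %.2f..%.2f  z %.2f..%.2f\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# Canonical edge key table: each row one undirected edge occurrence.
.mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Check that a mesh is watertight
#'
#' A closed (watertight) surface has every undirected edge shared by exactly
#' two triangles. Vertex-soup inputs (e.g. STL) are fused with
#' [merge_vertices()] before the topological test.
#'
#' @param mesh a [surface_mesh()].
#' @param tol vertex-fusing tolerance in mm.
#' @return logical scalar.
#' @export
is_watertight <- function(mesh, tol = 1e-6) {
  mesh <- merge_vertices(mesh, tol = tol)
  if (nrow(mesh$faces) == 0) return(FALSE)
  e <- .mesh_edges(mesh)
  key <- paste(e[, 1], e[, 2])
  all(table(key) == 2L)
}

#' Fuse coincident vertices
#'
#' Collapses vertices closer than `tol` (grid-rounding), remapping faces and
#' dropping degenerate triangles. Needed after reading STL, which stores an
#' unindexed triangle soup.
#'
#' @inheritParams is_watertight
#' @return a [surface_mesh()] with unique vertices.
#' @export
merge_vertices <- function(mesh, tol = 1e-6) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  idx <- match(key, key)                 # first occurrence index per vertex
  keep <- sort(unique(idx))
  remap <- integer(nrow(v))
  remap[keep] <- seq_along(keep)
  f <- matrix(remap[idx[mesh$faces]], ncol = 3)
  degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  surface_mesh(v[keep, , drop = FALSE], f[!degen, , drop = FALSE],
               validate = FALSE)
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedra to the
#' origin); the absolute value is returned so orientation does not matter.
#'
#' @param mesh a watertight [surface_mesh()].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  abs(sum(det6)) / 6
}

#' Total surface area of a mesh
#' @param mesh a [surface_mesh()].
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) {
  sum(.triangle_areas(mesh))
}

.triangle_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Apply a rigid-body transform to a mesh
#'
#' @param mesh a [surface_mesh()].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 offset in mm.
#' @return the transformed [surface_mesh()].
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  out <- mesh
  out$vertices <- v
  out
}

# Rotation matrix about a unit axis by angle (radians), Rodrigues form.
rotation_about <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
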