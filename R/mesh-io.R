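#' Read a surface mesh from STL, PLY or VTK polydata
#'
#' Format is inferred from the file extension (`.stl`, `.ply`, `.vtk`).
#' STL may be binary or ASCII (auto-detected); PLY and VTK legacy polydata are
#' supported in their ASCII forms. STL triangle soups are fused into an
#' indexed mesh on read.
#'
#' @param path file path.
#' @return a [surface_mesh()].
#' @export
read_mesh <- function(path) {
  switch(tolower(tools::file_ext(path)),
         stl = read_stl(path),
         ply = read_ply(path),
         vtk = read_vtk_polydata(path),
         stop("unsupported mesh format: ", path))
}

#' Write a surface mesh to STL, PLY or VTK polydata
#'
#' @param mesh a [surface_mesh()].
#' @param path output path; extension selects the format.
#' @param binary for STL only: write the 50-byte-per-facet binary layout
#'   (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = TRUE) {
  switch(tolower(tools::file_ext(path)),
         stl = write_stl(mesh, path, binary = binary),
         ply = write_ply(mesh, path),
         vtk = write_vtk_polydata(mesh, path),
         stop("unsupported mesh format: ", path))
  invisible(path)
}

#' @rdname read_mesh
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  head <- readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  fsize <- file.size(path)
  close(con)
  is_binary <- length(ntri) == 1 && !is.na(ntri) &&
    fsize == 84 + 50 * as.numeric(ntri)
  if (is_binary) .read_stl_binary(path, ntri) else .read_stl_ascii(path)
}

.read_stl_binary <- function(path, ntri) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 84)
  rec <- readBin(con, "raw", 50 * ntri)
  # each facet: 12 floats (normal + 3 vertices) + uint16 attribute
  m <- matrix(rec, nrow = 50)
  fl <- readBin(as.vector(m[1:48, ]), "numeric", size = 4, n = 12 * ntri,
                endian = "little")
  fl <- matrix(fl, nrow = 12)             # cols = triangles
  v <- t(matrix(as.vector(fl[4:12, ]), nrow = 3))  # 3*ntri x 3 vertices
  faces <- matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE)
  merge_vertices(surface_mesh(v, faces, validate = FALSE))
}

.read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", txt, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("malformed ASCII STL: ", path)
  nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                   function(x) as.numeric(x[2:4]), numeric(3)))
  faces <- matrix(seq_len(nrow(nums)), ncol = 3, byrow = TRUE)
  merge_vertices(surface_mesh(nums, faces, validate = FALSE))
}

#' @rdname write_mesh
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- .face_normals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(n[i, ], t(v[f[i, ], ]))), con, size = 4,
               endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    out <- c("solid mesh",
             unlist(lapply(seq_len(nrow(f)), function(i) {
               tv <- v[f[i, ], , drop = FALSE]
               c(sprintf(" facet normal %.9g %.9g %.9g",
                         n[i, 1], n[i, 2], n[i, 3]),
                 "  outer loop",
                 sprintf("   vertex %.9g %.9g %.9g",
                         tv[, 1], tv[, 2], tv[, 3]),
                 "  endloop", " endfacet")
             })),
             "endsolid mesh")
    writeLines(out, path)
  }
  invisible(path)
}

.face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' @rdname read_mesh
#' @export
read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (!startsWith(txt[1], "ply")) stop("not a PLY file: ", path)
  hdr_end <- which(trimws(txt) == "end_header")[1]
  hdr <- txt[seq_len(hdr_end)]
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", hdr, value = TRUE)[1]))
  body <- txt[(hdr_end + 1):length(txt)]
  vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  v <- t(vapply(vparts, function(x) as.numeric(x[1:3]), numeric(3)))
  fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  f <- t(vapply(fparts, function(x) as.integer(x[2:4]) + 1L, integer(3)))
  surface_mesh(v, f)
}

#' @rdname write_mesh
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(c(hdr,
               sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)),
             path)
  invisible(path)
}

#' @rdname read_mesh
#' @export
read_vtk_polydata <- function(path) {
  txt <- readLines(path, warn = FALSE)
  ip <- grep("^POINTS", txt)[1]
  np <- as.integer(strsplit(txt[ip], "\\s+")[[1]][2])
  nums <- as.numeric(scan(text = paste(txt[(ip + 1):length(txt)][
    seq_len(grep("^(POLYGONS|LINES)", txt[(ip + 1):length(txt)])[1] - 1)],
    collapse = " "), what = numeric(), quiet = TRUE))
  v <- matrix(nums[seq_len(3 * np)], ncol = 3, byrow = TRUE)
  ig <- grep("^POLYGONS", txt)[1]
  if (is.na(ig)) stop("VTK file has no POLYGONS section: ", path)
  nf <- as.integer(strsplit(txt[ig], "\\s+")[[1]][2])
  fb <- scan(text = paste(txt[(ig + 1):length(txt)], collapse = " "),
             what = integer(), n = 4 * nf, quiet = TRUE)
  fb <- matrix(fb, ncol = 4, byrow = TRUE)
  if (any(fb[, 1] != 3L)) stop("non-triangular polygons in ", path)
  surface_mesh(v, fb[, 2:4] + 1L)
}

#' @rdname write_mesh
#' @export
write_vtk_polydata <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  writeLines(c("# vtk DataFile Version 3.0", "surface", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(v)),
               sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("POLYGONS %d %d", nrow(f), 4 * nrow(f)),
               sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)),
             path)
  invisible(path)
}

#' Read or write a centerline as a 3-column CSV
#'
#' Points are ordered proximal to distal, one `x,y,z` row (mm) per point.
#'
#' @param path CSV file path.
#' @return `read_centerline_csv()`: a numeric matrix of points.
#' @export
read_centerline_csv <- function(path) {
  d <- utils::read.csv(path)
  as.matrix(d[, 1:3])
}

#' @rdname read_centerline_csv
#' @param points numeric matrix of 3-D points.
#' @export
write_centerline_csv <- function(points, path) {
  utils::write.csv(data.frame(x = points[, 1], y = points[, 2],
                              z = points[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}
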