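#' Triangulated cell-surface mesh
#'
#' A `tri_mesh` is a closed, watertight triangulated surface with outward
#' per-vertex unit normals, used as the plasma-membrane boundary of a
#' simulated cell. All coordinates are in micrometres.
#'
#' @param vertices numeric matrix (n x 3) of vertex positions (um).
#' @param faces integer matrix (m x 3) of 1-based triangle vertex indices.
#' @param normals optional numeric matrix (n x 3) of outward unit vertex
#'   normals; recomputed from face geometry when absent.
#' @param attributes optional named list of per-vertex scalar/tensor
#'   attributes (each a vector or matrix with n rows).
#' @param validate check closedness and normal orientation (default TRUE).
#'
#' @return An object of class `tri_mesh` with elements `vertices`, `faces`,
#'   `normals`, `attributes`.
#' @export
tri_mesh <- function(vertices, faces, normals = NULL, attributes = list(),
                     validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (min(faces) < 1 || max(faces) > nrow(vertices))
    stop("face indices out of range")
  if (is.null(normals)) {
    normals <- compute_vertex_normals(vertices, faces)
  } else {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    nn <- sqrt(rowSums(normals^2))
    if (any(nn < 1e-12)) stop("zero-length vertex normal")
    normals <- normals / nn
  }
  m <- structure(
    list(vertices = vertices, faces = faces, normals = normals,
         attributes = attributes),
    class = "tri_mesh", index_env = new.env(parent = emptyenv()))
  if (validate) {
    if (!is_watertight(m)) stop("mesh is not closed (non-manifold edges)")
    ctr <- colMeans(vertices)
    outward <- rowSums(normals * sweep(vertices, 2, ctr)) > 0
    if (mean(outward) < 0.5) stop("vertex normals are not outward-oriented")
    if (surface_area(m) <= 0) stop("degenerate mesh: zero surface area")
  }
  m
}

#' @export
print.tri_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("tri_mesh: %d vertices, %d faces, area %.2f um^2\n",
              nrow(x$vertices), nrow(x$faces), surface_area(x)))
  cat(sprintf("  bounding box: [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] um\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

# area-weighted vertex normals, flipped to point away from the centroid
compute_vertex_normals <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  fn <- cross3(b - a, c_ - a) # length = 2 * triangle area
  n <- matrix(0, nrow(vertices), 3)
  for (j in 1:3) {
    for (k in 1:3) {
      acc <- tapply(fn[, k], faces[, j], sum)
      idx <- as.integer(names(acc))
      n[idx, k] <- n[idx, k] + acc
    }
  }
  ctr <- colMeans(vertices)
  sgn <- sign(rowSums(n * sweep(vertices, 2, ctr)))
  sgn[sgn == 0] <- 1
  n <- n * sgn
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Check that every mesh edge is shared by exactly two faces
#' @param mesh a [tri_mesh()]
#' @return logical
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Total surface area of a mesh
#' @param mesh a [tri_mesh()]
#' @return area in um^2
#' @export
surface_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  fn <- cross3(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
               v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])
  sum(sqrt(rowSums(fn^2))) / 2
}

# lazily built C++ nearest-point index, cached on the mesh object
mesh_index <- function(mesh) {
  env <- attr(mesh, "index_env")
  if (is.null(env$ptr)) {
    env$ptr <- mesh_index_build(mesh$vertices, mesh$faces, mesh$normals)
  }
  env$ptr
}

# ---------------------------------------------------------------------------
# Shape generation
# ---------------------------------------------------------------------------

# welded subdivided box surface: 6 faces, grid spacing <= resolution
subdivided_box <- function(dims, resolution) {
  h <- dims / 2
  verts <- list()
  faces <- list()
  nv <- 0L
  for (axis in 1:3) {
    uv <- setdiff(1:3, axis)
    n1 <- max(2L, ceiling(dims[uv[1]] / resolution))
    n2 <- max(2L, ceiling(dims[uv[2]] / resolution))
    s1 <- seq(-h[uv[1]], h[uv[1]], length.out = n1 + 1)
    s2 <- seq(-h[uv[2]], h[uv[2]], length.out = n2 + 1)
    for (side in c(-1, 1)) {
      g <- as.matrix(expand.grid(s1 = s1, s2 = s2))
      v <- matrix(0, nrow(g), 3)
      v[, uv[1]] <- g[, 1]
      v[, uv[2]] <- g[, 2]
      v[, axis] <- side * h[axis]
      id <- function(i, j) nv + (j - 1L) * (n1 + 1L) + i
      i <- rep(seq_len(n1), n2)
      j <- rep(seq_len(n2), each = n1)
      q00 <- id(i, j); q10 <- id(i + 1L, j)
      q01 <- id(i, j + 1L); q11 <- id(i + 1L, j + 1L)
      if (side > 0) {
        fc <- rbind(cbind(q00, q10, q11), cbind(q00, q11, q01))
      } else {
        fc <- rbind(cbind(q00, q11, q10), cbind(q00, q01, q11))
      }
      verts[[length(verts) + 1]] <- v
      faces[[length(faces) + 1]] <- fc
      nv <- nv + nrow(v)
    }
  }
  v <- do.call(rbind, verts)
  f <- do.call(rbind, faces)
  # weld duplicated vertices along box edges
  key <- apply(round(v, 9), 1, paste, collapse = "/")
  first <- !duplicated(key)
  map <- match(key, key[first])  # original vertex -> welded vertex index
  f <- matrix(map[f], ncol = 3)
  list(vertices = v[first, , drop = FALSE], faces = f)
}

#' Build a rounded-box cell mesh
#'
#' The surface is the Minkowski sum of a shrunken box (dimensions
#' `dims - 2 * corner_radius`) and a sphere of radius `corner_radius`, so the
#' minimal radius of curvature equals `corner_radius` by construction. Vertex
#' normals are analytic.
#'
#' @param dims numeric length 3: full box extents (um).
#' @param corner_radius rounding radius (um); must not exceed half of the
#'   smallest dimension.
#' @param resolution target mesh edge length (um). Default 0.4 um keeps at
#'   least ten triangles per smallest curvature radius used in practice.
#' @return a [tri_mesh()]
#' @export
build_rounded_box <- function(dims, corner_radius, resolution = 0.4) {
  dims <- as.numeric(dims)
  stopifnot(length(dims) == 3)
  if (any(dims <= 0)) stop("invalid shape: dimensions must be positive")
  if (corner_radius <= 0) stop("invalid shape: corner_radius must be > 0")
  if (corner_radius > min(dims) / 2 + 1e-12)
    stop("invalid shape: corner_radius exceeds half of the smallest dimension")
  box <- subdivided_box(dims, resolution)
  inner <- pmax(dims / 2 - corner_radius, 0)
  cl <- pmin(pmax(box$vertices, rep(-inner, each = nrow(box$vertices))),
             rep(inner, each = nrow(box$vertices)))
  d <- box$vertices - cl
  dn <- sqrt(rowSums(d^2))
  dn[dn < 1e-12] <- 1
  nrm <- d / dn
  v <- cl + corner_radius * nrm
  tri_mesh(v, box$faces, nrm)
}

#' Build an ellipsoid cell mesh
#'
#' An ellipsoid of revolution (two of the three axes equal), triangulated from
#' a subdivided cube projected to the unit sphere (no pole degeneracy) and
#' scaled by the semi-axes. Normals are analytic.
#'
#' @param axes numeric length 3: full axis lengths (um); exactly two must be
#'   equal (all three equal gives a sphere).
#' @param resolution target mesh edge length (um).
#' @return a [tri_mesh()]
#' @export
build_ellipsoid <- function(axes, resolution = 0.4) {
  axes <- as.numeric(axes)
  stopifnot(length(axes) == 3)
  if (any(axes <= 0)) stop("invalid shape: axes must be positive")
  eq <- c(isTRUE(all.equal(axes[1], axes[2])),
          isTRUE(all.equal(axes[2], axes[3])),
          isTRUE(all.equal(axes[1], axes[3])))
  if (!any(eq))
    stop("invalid shape: an ellipsoid of revolution needs two equal axes")
  a <- axes / 2
  # chord length on the sphere scaled by the largest semi-axis
  n <- max(8L, ceiling(pi * max(a) / (2 * resolution)))
  box <- subdivided_box(c(2, 2, 2), 2 / n)
  u <- box$vertices / sqrt(rowSums(box$vertices^2))
  v <- sweep(u, 2, a, `*`)
  nrm <- sweep(v, 2, a^2, `/`)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  tri_mesh(v, box$faces, nrm)
}

#' Named cell shapes
#'
#' Registry of the standard simulated cell shapes: cube (8.8 um side),
#' "square" (9 x 9 x 4.7 um), "long" (4.8 x 4.8 x 15.6 um), each in a sharp
#' (1.3 um corner radius) and a smooth variant (4.7 um, clamped to half the
#' smallest dimension where necessary), plus the ellipsoid of revolution
#' (10.3 um short, 16.8 um long axis; long axis along z) used for
#' directional-cue studies.
#'
#' @param name one of `"sharp_cube"`, `"smooth_cube"`, `"sharp_square"`,
#'   `"smooth_square"`, `"sharp_long"`, `"smooth_long"`, `"ellipsoid"`.
#' @param resolution target mesh edge length (um).
#' @return a [tri_mesh()]
#' @export
make_cell_shape <- function(name, resolution = 0.4) {
  dims <- list(cube = c(8.8, 8.8, 8.8), square = c(9, 9, 4.7),
               long = c(4.8, 4.8, 15.6))
  if (name == "ellipsoid")
    return(build_ellipsoid(c(10.3, 10.3, 16.8), resolution))
  parts <- strsplit(name, "_", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !parts[1] %in% c("sharp", "smooth") ||
      !parts[2] %in% names(dims))
    stop("unknown shape name: ", name)
  d <- dims[[parts[2]]]
  r <- if (parts[1] == "sharp") 1.3 else min(4.7, min(d) / 2)
  build_rounded_box(d, r, resolution)
}

#' Names of the registered cell shapes
#' @return character vector
#' @export
cell_shape_names <- function() {
  c("sharp_cube", "smooth_cube", "sharp_square", "smooth_square",
    "sharp_long", "smooth_long", "ellipsoid")
}

# ---------------------------------------------------------------------------
# Surface queries
# ---------------------------------------------------------------------------

#' Nearest point on the cell surface
#'
#' For each query point, returns the nearest point on the mesh, the outward
#' unit normal there (barycentric interpolation of vertex normals), the
#' unsigned distance, and a containment flag. Containment is decided by the
#' sign of `(query - nearest) . normal`, with magnitudes below 1e-9 um
#' treated as on-surface (inside).
#'
#' @param mesh a [tri_mesh()]
#' @param points numeric length-3 vector or (n x 3) matrix (um).
#' @return for a single point, a `surface_probe` list with `nearest_point`,
#'   `normal`, `distance`, `inside`; for a matrix, a list of the same fields
#'   vectorised (matrices / vectors with one row or element per query).
#' @export
nearest_surface <- function(mesh, points) {
  single <- is.null(dim(points))
  p <- if (single) matrix(points, 1, 3) else as.matrix(points)
  if (!all(is.finite(p))) stop("query points must be finite")
  res <- mesh_index_nearest(mesh_index(mesh), p)
  if (single) {
    structure(list(nearest_point = res$nearest[1, ], normal = res$normal[1, ],
                   distance = res$distance[1], inside = res$inside[1]),
              class = "surface_probe")
  } else {
    res
  }
}

#' Tangent plane at a surface probe
#' @param probe result of [nearest_surface()] for a single point
#' @return list with `point` and unit `normal`
#' @export
tangent_plane <- function(probe) {
  list(point = probe$nearest_point, normal = probe$normal)
}

#' Uniform random points on the cell surface
#'
#' Area-weighted triangle choice followed by uniform barycentric sampling
#' within the triangle; normals are interpolated from vertex normals. Uses
#' the R random number generator, so [set.seed()] gives reproducible draws.
#'
#' @param mesh a [tri_mesh()]
#' @param n number of samples
#' @return list with `points` (n x 3), `normals` (n x 3), `triangle` (index)
#' @export
sample_surface_point <- function(mesh, n = 1) {
  v <- mesh$vertices
  f <- mesh$faces
  fn <- cross3(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
               v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])
  areas <- sqrt(rowSums(fn^2)) / 2
  cum <- cumsum(areas)
  tri <- findInterval(stats::runif(n) * cum[length(cum)], cum) + 1L
  tri <- pmin(tri, length(areas))
  s <- sqrt(stats::runif(n))
  t <- stats::runif(n)
  w <- cbind(1 - s, s * (1 - t), s * t)
  pts <- w[, 1] * v[f[tri, 1], , drop = FALSE] +
    w[, 2] * v[f[tri, 2], , drop = FALSE] +
    w[, 3] * v[f[tri, 3], , drop = FALSE]
  nm <- mesh$normals
  nrm <- w[, 1] * nm[f[tri, 1], , drop = FALSE] +
    w[, 2] * nm[f[tri, 2], , drop = FALSE] +
    w[, 3] * nm[f[tri, 3], , drop = FALSE]
  nrm <- nrm / sqrt(rowSums(nrm^2))
  list(points = pts, normals = nrm, triangle = tri)
}

# ---------------------------------------------------------------------------
# Mesh I/O: ASCII OBJ and PLY with per-vertex normals
# ---------------------------------------------------------------------------

#' Write a mesh to OBJ or PLY (ASCII)
#' @param mesh a [tri_mesh()]
#' @param path output file; format chosen by extension (`.obj` or `.ply`)
#' @return invisibly, `path`
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; n <- mesh$normals; f <- mesh$faces
  if (ext == "obj") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("vn %.9g %.9g %.9g", n[, 1], n[, 2], n[, 3]), con)
    writeLines(sprintf("f %d//%d %d//%d %d//%d",
                       f[, 1], f[, 1], f[, 2], f[, 2], f[, 3], f[, 3]), con)
  } else if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property double x", "property double y", "property double z",
                 "property double nx", "property double ny",
                 "property double nz",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g %.9g %.9g %.9g",
                       v[, 1], v[, 2], v[, 3], n[, 1], n[, 2], n[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
               con)
  } else {
    stop("unsupported mesh format: ", ext)
  }
  invisible(path)
}

#' Read a mesh from OBJ or PLY (ASCII)
#'
#' Per-vertex normals are read when present and recomputed otherwise.
#' @param path input file (`.obj` or `.ply`)
#' @return a [tri_mesh()]
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "obj") {
    vl <- grep("^v ", lines, value = TRUE)
    nl <- grep("^vn ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x)
      as.numeric(x[2:4])))
    n <- if (length(nl)) do.call(rbind, lapply(strsplit(nl, "\\s+"),
      function(x) as.numeric(x[2:4]))) else NULL
    f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(x)
      as.integer(sub("/.*", "", x[2:4]))))
    tri_mesh(v, f, n)
  } else if (ext == "ply") {
    hend <- which(lines == "end_header")[1]
    if (is.na(hend)) stop("malformed PLY: no end_header")
    header <- lines[1:hend]
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", header, value = TRUE)))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", header, value = TRUE)))
    props <- sub("^property \\S+ ", "",
                 grep("^property (float|double)", header, value = TRUE))
    vdat <- do.call(rbind, lapply(strsplit(trimws(
      lines[(hend + 1):(hend + nv)]), "\\s+"), as.numeric))
    colnames(vdat) <- props[seq_len(ncol(vdat))]
    fdat <- do.call(rbind, lapply(strsplit(trimws(
      lines[(hend + nv + 1):(hend + nv + nf)]), "\\s+"), as.integer))
    if (any(fdat[, 1] != 3L)) stop("only triangular PLY faces are supported")
    v <- vdat[, c("x", "y", "z"), drop = FALSE]
    n <- if (all(c("nx", "ny", "nz") %in% colnames(vdat)))
      vdat[, c("nx", "ny", "nz"), drop = FALSE] else NULL
    tri_mesh(v, fdat[, 2:4, drop = FALSE] + 1L, n)
  } else {
    stop("unsupported mesh format: ", ext)
  }
}
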