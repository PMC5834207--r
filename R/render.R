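#' Rendering specification for confocal-like stacks
#'
#' Voxel grid resolution and blur weight. The axial (z) voxel extent is
#' typically about ten times the lateral one, mimicking the anisotropic
#' resolution of a confocal microscope; with the default lateral voxel of
#' ~0.1 um and axial of ~1 um this holds for the standard cell sizes.
#'
#' @param resolution integer length 3: voxel counts (rx, ry, rz)
#' @param neighbor_weight intensity added to neighbouring voxels (default
#'   0.3; the hit voxel gets 1.0)
#' @param neighborhood `6` (face-adjacent, default) or `26` (full cube)
#' @return an object of class `render_spec`
#' @export
render_spec <- function(resolution = c(128, 128, 16), neighbor_weight = 0.3,
                        neighborhood = 6) {
  resolution <- as.integer(resolution)
  stopifnot(length(resolution) == 3, all(resolution >= 1),
            neighbor_weight >= 0, neighborhood %in% c(6, 26))
  structure(list(resolution = resolution, neighbor_weight = neighbor_weight,
                 neighborhood = neighborhood), class = "render_spec")
}

#' Voxelize a snapshot into an intensity stack
#'
#' Each segment endpoint adds 1.0 to the voxel containing it and
#' `neighbor_weight` to each neighbouring voxel (face-adjacent by default),
#' yielding a blurred confocal-like signal. Endpoints outside `bounds` are
#' clipped with a warning.
#'
#' @param snapshot a `cortisim_snapshot`
#' @param spec a [render_spec()]
#' @param bounds 2 x 3 matrix (rows: min, max) of the rendered volume (um);
#'   defaults to the snapshot bounding box
#' @return 3D numeric array of dimensions `spec$resolution` with attributes
#'   `bounds` and `voxel_size_um`
#' @export
voxelize <- function(snapshot, spec = render_spec(), bounds = NULL) {
  res <- spec$resolution
  stack_dim <- res
  p <- as.matrix(snapshot[, c("x_um", "y_um", "z_um")])
  if (is.null(bounds)) {
    bounds <- apply(p, 2, range)
    if (nrow(p) == 0) bounds <- matrix(c(0, 1, 0, 1, 0, 1), 2, 3)
  }
  bounds <- as.matrix(bounds)
  out <- array(0, dim = stack_dim)
  if (nrow(p) > 0) {
    w <- bounds[2, ] - bounds[1, ]
    w[w <= 0] <- 1
    outside <- rep(FALSE, nrow(p))
    for (j in 1:3)
      outside <- outside | p[, j] < bounds[1, j] | p[, j] > bounds[2, j]
    if (any(outside))
      warning(sum(outside),
              " segment endpoint(s) outside the render bounds were clipped")
    ijk <- sapply(1:3, function(j)
      pmin(res[j], pmax(1L, floor((p[, j] - bounds[1, j]) / w[j] * res[j])
                        + 1L)))
    ijk <- matrix(as.integer(ijk), ncol = 3)
    nvox <- prod(res)
    lin <- ijk[, 1] + (ijk[, 2] - 1L) * res[1] +
      (ijk[, 3] - 1L) * res[1] * res[2]
    out <- out + array(tabulate(lin, nvox), dim = res)
    offsets <- if (spec$neighborhood == 6) {
      rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
            c(0, 0, 1), c(0, 0, -1))
    } else {
      g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
      g[rowSums(abs(g)) > 0, , drop = FALSE]
    }
    for (r in seq_len(nrow(offsets))) {
      nb <- sweep(ijk, 2, as.integer(offsets[r, ]), `+`)
      keep <- nb[, 1] >= 1 & nb[, 1] <= res[1] &
              nb[, 2] >= 1 & nb[, 2] <= res[2] &
              nb[, 3] >= 1 & nb[, 3] <= res[3]
      if (!any(keep)) next
      nbl <- nb[keep, 1] + (nb[keep, 2] - 1L) * res[1] +
        (nb[keep, 3] - 1L) * res[1] * res[2]
      out <- out + spec$neighbor_weight * array(tabulate(nbl, nvox),
                                                dim = res)
    }
  }
  attr(out, "bounds") <- bounds
  attr(out, "voxel_size_um") <- (bounds[2, ] - bounds[1, ]) / res
  out
}

#' Sum-projection along the optical axis
#'
#' Elementwise sum of the stack along z; total intensity is conserved
#' exactly.
#'
#' @param stack 3D array from [voxelize()]
#' @return 2D matrix (x, y)
#' @export
z_project <- function(stack) {
  stopifnot(length(dim(stack)) == 3)
  rowSums(stack, dims = 2)
}

#' Write an intensity stack as a multi-page TIFF (32-bit float)
#'
#' Intensities are scaled to [0, 1] by the stack maximum (the scale factor
#' is returned) since TIFF stores normalised floats.
#'
#' @param stack 3D array
#' @param path output TIFF
#' @return invisibly, the scale factor applied
#' @export
write_stack_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("writing TIFF stacks requires the 'tiff' package")
  mx <- max(stack, 1e-300)
  pages <- lapply(seq_len(dim(stack)[3]), function(k) t(stack[, , k]) / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(mx)
}

#' Write a z-projection as PNG (and optionally TIFF)
#' @param image 2D matrix from [z_project()]
#' @param path output file; format chosen by extension (`.png` or `.tif`)
#' @return invisibly, the scale factor applied
#' @export
write_projection <- function(image, path) {
  mx <- max(image, 1e-300)
  img <- t(image) / mx
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("writing PNG requires the 'png' package")
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("writing TIFF requires the 'tiff' package")
    tiff::writeTIFF(img, path, bits.per.sample = 32L)
  } else {
    stop("unsupported image format: ", ext)
  }
  invisible(mx)
}
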