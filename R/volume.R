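#' Labeled voxel volumes
#'
#' A `labeled_volume` couples a 3D integer label array (0 = background)
#' with the physical voxel size (micrometres per voxel along x, y, z) and
#' a world-coordinate origin. Voxel sampling is typically anisotropic:
#' serial-section reconstructions have much coarser sampling along the
#' cutting axis than in-plane.
#'
#' World coordinates: the centre of voxel `(i, j, k)` (1-based R indices)
#' is at `origin + (c(i, j, k) - 0.5) * voxel_size`.
#'
#' @param labels 3D integer array, non-negative, 0 = background.
#' @param voxel_size Numeric length-3, micrometres, strictly positive.
#' @param origin Numeric length-3, micrometres. Default `c(0, 0, 0)`.
#' @return A `labeled_volume` object.
#' @export
#' @examples
#' a <- array(0L, c(8, 8, 4)); a[4, 4, 2] <- 1L
#' labeled_volume(a, voxel_size = c(2, 2, 10))
labeled_volume <- function(labels, voxel_size, origin = c(0, 0, 0)) {
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3D array", call. = FALSE)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be 3 strictly positive numbers", call. = FALSE)
  if (min(labels) < 0) stop("labels must be >= 0", call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("labeled volume %d x %d x %d, voxel %g x %g x %g um, %d labels\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

#' Convert voxel linear indices to world coordinates
#'
#' @param idx Integer vector of linear indices into the label array.
#' @param vol A [labeled_volume()] (or any list with `labels` dims,
#'   `voxel_size`, `origin`).
#' @return n x 3 matrix of world coordinates (micrometres) of voxel centres.
#' @export
vox_to_world <- function(idx, vol) {
  ijk <- arrayInd(idx, dim(vol$labels))
  sweep(sweep(ijk - 0.5, 2, vol$voxel_size, "*"), 2, vol$origin, "+")
}

#' Convert world coordinates to voxel linear indices
#'
#' Points outside the volume map to `NA`.
#'
#' @param pts n x 3 matrix of world coordinates (micrometres).
#' @inheritParams vox_to_world
#' @return Integer vector of linear indices (NA where out of bounds).
#' @export
world_to_vox <- function(pts, vol) {
  pts <- rbind(pts)
  d <- dim(vol$labels)
  ijk <- floor(sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$voxel_size, "/")) + 1
  bad <- ijk[, 1] < 1 | ijk[, 1] > d[1] | ijk[, 2] < 1 | ijk[, 2] > d[2] |
    ijk[, 3] < 1 | ijk[, 3] > d[3]
  out <- rep(NA_integer_, nrow(ijk))
  if (any(!bad)) {
    g <- ijk[!bad, , drop = FALSE]
    out[!bad] <- as.integer(g[, 1] + d[1] * (g[, 2] - 1) +
                              d[1] * d[2] * (g[, 3] - 1))
  }
  out
}

#' Read / write labeled volumes as multipage TIFF with a JSON sidecar
#'
#' The TIFF stores one 16-bit page per z-slice; the sidecar JSON records
#' `voxel_size_um` and `origin_um` (pixel grids carry no physical units
#' of their own).
#'
#' @param vol A [labeled_volume()].
#' @param path TIFF file path; the sidecar is written at `sidecar` (default
#'   `<path>.json`).
#' @param sidecar Sidecar JSON path.
#' @return `write_volume` returns `path` invisibly; `read_volume` the volume.
#' @export
write_volume <- function(vol, path, sidecar = paste0(path, ".json")) {
  mx <- max(vol$labels)
  if (mx > 65535L) stop("label values exceed 16-bit TIFF range", call. = FALSE)
  pages <- lapply(seq_len(dim(vol$labels)[3]),
                  function(k) vol$labels[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(voxel_size_um = vol$voxel_size,
                            origin_um = vol$origin),
                       sidecar, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, sidecar = paste0(path, ".json")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  labels <- array(0L, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages))
    labels[, , k] <- as.integer(round(pages[[k]] * 65535))
  labeled_volume(labels, meta$voxel_size_um, meta$origin_um)
}
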