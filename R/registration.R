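#' Serial-section images
#'
#' One 2D gray-value section of a serial stack. Pixel `(row, col)` has
#' in-plane coordinates `(col - 0.5, row - 0.5) * pixel_size_um`; the
#' axial position of section `i` (0-based) is `i * thickness_um`.
#'
#' @param pixels Numeric matrix of gray values.
#' @param pixel_size_um In-plane sampling (um/px), > 0.
#' @param section_index 0-based position in the stack.
#' @param thickness_um Physical section thickness (um), > 0.
#' @return A `section_image` object.
#' @export
section_image <- function(pixels, pixel_size_um = 1, section_index = 0L,
                          thickness_um = 2) {
  stopifnot(is.matrix(pixels), pixel_size_um > 0, thickness_um > 0)
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 section_index = as.integer(section_index),
                 thickness_um = thickness_um),
            class = "section_image")
}

#' Rigid in-plane transforms
#'
#' Translation in micrometres plus rotation (degrees, counter-clockwise
#' about the image centre). Applying `t` to an image moves its content:
#' `out(q) = img(R(-theta) (q - c - t) + c)`.
#'
#' @param tx_um,ty_um Translation components (um).
#' @param theta_deg Rotation (degrees).
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(tx_um = 0, ty_um = 0, theta_deg = 0) {
  structure(list(tx_um = tx_um, ty_um = ty_um, theta_deg = theta_deg),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid transform: t = (%.3f, %.3f) um, theta = %.3f deg\n",
              x$tx_um, x$ty_um, x$theta_deg))
  invisible(x)
}

#' @rdname rigid_transform
#' @param a,b Transforms; `compose_transform(a, b)` applies `b` first,
#'   then `a`.
#' @export
compose_transform <- function(a, b) {
  th <- a$theta_deg * pi / 180
  rigid_transform(cos(th) * b$tx_um - sin(th) * b$ty_um + a$tx_um,
                  sin(th) * b$tx_um + cos(th) * b$ty_um + a$ty_um,
                  a$theta_deg + b$theta_deg)
}

#' @rdname rigid_transform
#' @param x Transform to invert.
#' @export
invert_transform <- function(x) {
  th <- -x$theta_deg * pi / 180
  rigid_transform(-(cos(th) * x$tx_um - sin(th) * x$ty_um),
                  -(sin(th) * x$tx_um + cos(th) * x$ty_um),
                  -x$theta_deg)
}

#' Warp an image by a rigid transform
#'
#' Bilinear interpolation; pixels whose source falls outside the frame
#' become `NA`.
#'
#' @param img A [section_image()] or matrix (then `pixel_size_um = 1`).
#' @param transform A [rigid_transform()].
#' @return Matrix of warped gray values with `NA` outside the overlap.
#' @export
warp_image <- function(img, transform) {
  px <- if (inherits(img, "section_image")) img$pixels else img
  psz <- if (inherits(img, "section_image")) img$pixel_size_um else 1
  nr <- nrow(px); nc <- ncol(px)
  cx <- nc / 2; cy <- nr / 2
  tx <- transform$tx_um / psz; ty <- transform$ty_um / psz
  th <- -transform$theta_deg * pi / 180 # inverse map
  xq <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc) - cx - tx
  yq <- matrix(rep(seq_len(nr) - 0.5, nc), nr, nc) - cy - ty
  xs <- cos(th) * xq - sin(th) * yq + cx
  ys <- sin(th) * xq + cos(th) * yq + cy
  ## bilinear sample at (xs, ys) in pixel-centre coordinates
  xi <- xs - 0.5; yi <- ys - 0.5 # 0-based continuous indices
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0; fy <- yi - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= nc - 2 & y0 <= nr - 2
  out <- matrix(NA_real_, nr, nc)
  if (any(ok)) {
    i00 <- (y0[ok] + 1) + nr * x0[ok]
    v <- (1 - fx[ok]) * (1 - fy[ok]) * px[i00] +
      (1 - fx[ok]) * fy[ok] * px[i00 + 1] +
      fx[ok] * (1 - fy[ok]) * px[i00 + nr] +
      fx[ok] * fy[ok] * px[i00 + nr + 1]
    out[ok] <- v
  }
  out
}

#' Search configuration for pairwise alignment
#'
#' @param theta_range Coarse rotation search bounds (degrees).
#' @param theta_step Coarse rotation step (degrees).
#' @param max_shift_px Translation search window half-width (px).
#' @param refine_steps Pattern-search step sizes (px and degrees),
#'   coarsest to finest.
#' @param min_overlap Minimum admissible overlap fraction.
#' @return A `search_config` list.
#' @export
search_config <- function(theta_range = c(-10, 10), theta_step = 1,
                          max_shift_px = 15,
                          refine_steps = c(0.5, 0.25),
                          min_overlap = 0.5) {
  list(theta_range = theta_range, theta_step = theta_step,
       max_shift_px = max_shift_px, refine_steps = refine_steps,
       min_overlap = min_overlap)
}

## mean squared gray difference over the overlap region (Inf when the
## overlap fraction falls below the configured minimum)
ssd_at <- function(fpx, mov, psz, tx_px, ty_px, theta, min_overlap) {
  w <- warp_image(mov, rigid_transform(tx_px * psz, ty_px * psz, theta))
  ok <- !is.na(w)
  if (mean(ok) < min_overlap) return(Inf)
  mean((fpx[ok] - w[ok])^2)
}

## integer-shift candidates by FFT cross-correlation of zero-mean images
cc_shift_candidates <- function(fz, mz, max_shift, n_cand = 3L) {
  nr <- nrow(fz); nc <- ncol(fz)
  cc <- Re(stats::fft(stats::fft(fz) * Conj(stats::fft(mz)), inverse = TRUE))
  sy <- c(0:(nr - 1)); sy[sy > nr / 2] <- sy[sy > nr / 2] - nr
  sx <- c(0:(nc - 1)); sx[sx > nc / 2] <- sx[sx > nc / 2] - nc
  allow <- outer(abs(sy) <= max_shift, abs(sx) <= max_shift)
  cc[!allow] <- -Inf
  ord <- order(cc, decreasing = TRUE)[seq_len(n_cand)]
  ij <- arrayInd(ord, dim(cc))
  cbind(tx = sx[ij[, 2]], ty = sy[ij[, 1]])
}

## greedy pattern search over (tx, ty, theta); SSD is non-increasing by
## construction (moves accepted only when they improve)
refine_pattern <- function(fpx, mov, psz, start, steps, min_overlap,
                           max_iter = 40L) {
  cur <- start
  best <- ssd_at(fpx, mov, psz, cur[1], cur[2], cur[3], min_overlap)
  for (st in steps) {
    for (iter in seq_len(max_iter)) {
      improved <- FALSE
      for (dim in 1:3) for (sgn in c(-1, 1)) {
        cand <- cur
        cand[dim] <- cand[dim] + sgn * st
        v <- ssd_at(fpx, mov, psz, cand[1], cand[2], cand[3], min_overlap)
        if (v < best) { best <- v; cur <- cand; improved <- TRUE }
      }
      if (!improved) break
    }
  }
  list(par = cur, ssd = best)
}

#' Rigid pairwise alignment of two sections
#'
#' Finds the rigid transform of `moving` minimising the sum of squared
#' gray-value differences against `fixed`, normalised per overlapping
#' pixel. Coarse stage: rotation grid with per-rotation translation
#' candidates from FFT cross-correlation; then pattern-search refinement
#' at sub-pixel / sub-degree steps.
#'
#' @param fixed,moving [section_image()]s with equal pixel size.
#' @param search A [search_config()].
#' @return List with `transform` (a [rigid_transform()]) and `ssd` (the
#'   attained minimum mean squared gray difference over the overlap).
#'   Constant (degenerate) images yield the identity with a warning.
#' @export
align_pair <- function(fixed, moving, search = search_config()) {
  if (!isTRUE(all.equal(fixed$pixel_size_um, moving$pixel_size_um)))
    stop("images must share a pixel size", call. = FALSE)
  fpx <- fixed$pixels
  psz <- fixed$pixel_size_um
  if (sd(fpx) == 0 || sd(moving$pixels) == 0) {
    warning("degenerate (constant) image: flat SSD objective, returning identity")
    return(list(transform = rigid_transform(),
                ssd = mean((fpx - moving$pixels)^2)))
  }
  fz <- fpx - mean(fpx)
  thetas <- seq(search$theta_range[1], search$theta_range[2],
                by = search$theta_step)
  best <- list(par = c(0, 0, 0),
               ssd = ssd_at(fpx, moving, psz, 0, 0, 0, search$min_overlap))
  for (th in thetas) {
    rot <- warp_image(moving, rigid_transform(0, 0, th))
    rz <- rot - mean(rot, na.rm = TRUE)
    rz[is.na(rz)] <- 0
    cand <- cc_shift_candidates(fz, rz, search$max_shift_px)
    for (r in seq_len(nrow(cand))) {
      v <- ssd_at(fpx, moving, psz, cand[r, 1], cand[r, 2], th,
                  search$min_overlap)
      if (v < best$ssd) best <- list(par = c(cand[r, 1], cand[r, 2], th),
                                     ssd = v)
    }
  }
  res <- refine_pattern(fpx, moving, psz, best$par,
                        c(search$refine_steps), search$min_overlap)
  list(transform = rigid_transform(res$par[1] * psz, res$par[2] * psz,
                                   res$par[3]),
       ssd = res$ssd)
}

#' Flag a pair against the difference profile of nearby matches
#'
#' A first-pass alignment occasionally produces a poor match; it is
#' detected by comparing its residual against a profile of expected
#' differences from nearby pairs: flagged when the residual exceeds the
#' rolling mean by more than `k` rolling standard deviations (window of
#' `window` pairs either side, the pair itself excluded). With fewer
#' pairs than the window, global statistics are used.
#'
#' @param residuals Numeric vector of per-pair SSD residuals (>= 0).
#' @param pair_index Index of the pair to test (1-based).
#' @param k Threshold multiplier (default 3).
#' @param window Half-width of the rolling window (default 5).
#' @return TRUE iff the pair is an outlier.
#' @export
detect_misalignment <- function(residuals, pair_index, k = 3, window = 5) {
  stopifnot(all(residuals >= 0), pair_index >= 1,
            pair_index <= length(residuals))
  nb <- setdiff(seq(max(1, pair_index - window),
                    min(length(residuals), pair_index + window)),
                pair_index)
  if (length(nb) < window) nb <- setdiff(seq_along(residuals), pair_index)
  if (length(nb) == 0) return(FALSE)
  m <- mean(residuals[nb])
  s <- if (length(nb) > 1) sd(residuals[nb]) else 0
  residuals[pair_index] > m + k * s
}

#' Broad-search rescue of a flagged pair
#'
#' Re-runs the alignment with a broader search space and random start
#' points: a full-window cross-correlation stage plus `restarts` random
#' (tx, ty, theta) starts, each refined by pattern search; the
#' best-of-restarts transform is returned. Deterministic for a given
#' seed.
#'
#' @param fixed,moving [section_image()]s.
#' @param restarts Number of random restarts.
#' @param seed RNG seed.
#' @param max_shift_px Broadened translation window (px); default is half
#'   the image size.
#' @param theta_range Broadened rotation bounds (degrees).
#' @return As [align_pair()]: list of `transform` and `ssd`.
#' @export
rescue_alignment <- function(fixed, moving, restarts = 15L, seed = 1L,
                             max_shift_px = NULL, theta_range = c(-10, 10)) {
  if (is.null(max_shift_px))
    max_shift_px <- floor(min(dim(fixed$pixels)) / 2) - 2
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  broad <- search_config(theta_range = theta_range, theta_step = 2,
                         max_shift_px = max_shift_px, min_overlap = 0.25)
  best <- align_pair(fixed, moving, broad)
  fpx <- fixed$pixels; psz <- fixed$pixel_size_um
  for (r in seq_len(restarts)) {
    start <- c(runif(1, -max_shift_px, max_shift_px),
               runif(1, -max_shift_px, max_shift_px),
               runif(1, theta_range[1], theta_range[2]))
    res <- refine_pattern(fpx, moving, psz, start, c(2, 1, 0.5, 0.25), 0.25)
    if (res$ssd < best$ssd)
      best <- list(transform = rigid_transform(res$par[1] * psz,
                                               res$par[2] * psz, res$par[3]),
                   ssd = res$ssd)
  }
  best
}

#' Compose pairwise transforms into a stack alignment
#'
#' Cumulative transforms place every section in the frame of section 0;
#' the axial coordinate of section `i` (0-based) is `i * thickness`, and
#' the stack's axial extent is `n_sections * thickness`.
#'
#' @param sections List of [section_image()] (length n).
#' @param pairwise List of n-1 [rigid_transform()]s, element `i` aligning
#'   section `i` (0-based `i`) to section `i - 1`.
#' @return An `aligned_stack`: `sections`, `cumulative` transforms,
#'   `z_um` per section, `axial_extent_um`.
#' @export
compose_stack <- function(sections, pairwise) {
  n <- length(sections)
  if (length(pairwise) != n - 1) {
    gap <- if (length(pairwise) < n - 1) length(pairwise) + 1 else n
    stop(sprintf("need %d pairwise transforms for %d sections (missing pair %d)",
                 n - 1, n, gap), call. = FALSE)
  }
  thickness <- sections[[1]]$thickness_um
  cumulative <- vector("list", n)
  cumulative[[1]] <- rigid_transform()
  for (i in seq_len(n - 1))
    cumulative[[i + 1]] <- compose_transform(cumulative[[i]], pairwise[[i]])
  structure(list(sections = sections, cumulative = cumulative,
                 z_um = (seq_len(n) - 1) * thickness,
                 axial_extent_um = n * thickness),
            class = "aligned_stack")
}

#' @export
print.aligned_stack <- function(x, ...) {
  cat(sprintf("aligned stack: %d sections, axial extent %g um\n",
              length(x$sections), x$axial_extent_um))
  invisible(x)
}

#' Align a full serial stack
#'
#' Pairwise SSD alignment of adjacent sections, difference-profile
#' outlier detection, broad-search rescue of flagged pairs, and removal
#' of unrescuable sections (the stack is re-linked across the gap by
#' keeping the best-effort transform and marking the section removed).
#'
#' @param sections List of [section_image()].
#' @param search A [search_config()].
#' @param seed Seed for rescue restarts.
#' @param k,window Outlier-rule constants (see [detect_misalignment()]).
#' @return List: `stack` (an `aligned_stack`), `table` (data frame of
#'   index, tx_um, ty_um, theta_deg, ssd, flagged, removed).
#' @export
align_stack <- function(sections, search = search_config(), seed = 1L,
                        k = 3, window = 5) {
  n <- length(sections)
  stopifnot(n >= 2)
  pair <- vector("list", n - 1)
  ssd <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    a <- align_pair(sections[[i]], sections[[i + 1]], search)
    pair[[i]] <- a$transform
    ssd[i] <- a$ssd
  }
  flagged <- vapply(seq_len(n - 1),
                    function(i) detect_misalignment(ssd, i, k, window),
                    logical(1))
  removed <- logical(n)
  for (i in which(flagged)) {
    r <- rescue_alignment(sections[[i]], sections[[i + 1]],
                          seed = seed + i)
    if (r$ssd < ssd[i]) { pair[[i]] <- r$transform; ssd[i] <- r$ssd }
    if (detect_misalignment(ssd, i, k, window)) removed[i + 1] <- TRUE
  }
  stack <- compose_stack(sections, pair)
  tab <- data.frame(
    index = seq_len(n) - 1L,
    tx_um = vapply(stack$cumulative, function(t) t$tx_um, numeric(1)),
    ty_um = vapply(stack$cumulative, function(t) t$ty_um, numeric(1)),
    theta_deg = vapply(stack$cumulative, function(t) t$theta_deg, numeric(1)),
    ssd = c(NA, ssd), flagged = c(FALSE, flagged), removed = removed)
  list(stack = stack, table = tab)
}
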