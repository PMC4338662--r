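#' Channel domains
#'
#' A channel domain is one connected advective conduit (blood capillary,
#' epithelial crypt/duct lumen, or a unicellular conduit) extracted from a
#' labeled volume: a set of voxels connected under 26-adjacency, carrying
#' an anatomy-term annotation.
#'
#' @param channel_id Identifier string.
#' @param voxels Sorted integer vector of linear voxel indices.
#' @param kind `"endothelial"`, `"epithelial"` or `"unicellular"`.
#' @param anatomy_term [ontology_term()] or id string.
#' @param label Original label value in the source volume.
#' @return A `channel_domain` object.
#' @export
channel_domain <- function(channel_id, voxels,
                           kind = c("endothelial", "epithelial", "unicellular"),
                           anatomy_term = NULL, label = NA_integer_) {
  kind <- match.arg(kind)
  structure(list(channel_id = channel_id,
                 voxels = sort(unique(as.integer(voxels))),
                 kind = kind,
                 anatomy_term = if (is.null(anatomy_term)) NULL
                                else term_id(anatomy_term),
                 label = label),
            class = "channel_domain")
}

#' @export
print.channel_domain <- function(x, ...) {
  cat(sprintf("channel %s (%s, label %s): %d voxels, term %s\n",
              x$channel_id, x$kind, x$label, length(x$voxels),
              if (is.null(x$anatomy_term)) "<none>" else x$anatomy_term))
  invisible(x)
}

#' Extract connected channel domains from a labeled volume
#'
#' Splits every non-zero label value into its 26-connected components,
#' one [channel_domain()] per component. Diagonal voxel contact counts as
#' connected.
#'
#' @param vol A [labeled_volume()].
#' @param kind Channel kind recorded on every extracted domain.
#' @param term_map Optional named list/character mapping label value (as
#'   character) to an anatomy term for the extracted channels.
#' @return List of [channel_domain()], ordered by (label, component).
#' @export
extract_channels <- function(vol, kind = "endothelial", term_map = NULL) {
  d <- dim(vol$labels)
  comp <- cpp_label26(as.vector(vol$labels), d)
  if (all(comp == 0L)) return(list())
  idx <- which(comp != 0L)
  parts <- split(idx, comp[idx])
  out <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    vox <- parts[[i]]
    lab <- vol$labels[vox[1]]
    term <- if (!is.null(term_map)) term_map[[as.character(lab)]] else NULL
    out[[i]] <- channel_domain(sprintf("ch%03d", i), vox, kind = kind,
                               anatomy_term = term, label = lab)
  }
  ## stable order: by label value then first voxel
  ord <- order(vapply(out, function(ch) ch$label, integer(1)),
               vapply(out, function(ch) ch$voxels[1], integer(1)))
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]$channel_id <- sprintf("ch%03d", i)
  out
}

#' True-Euclidean anisotropic dilation of a channel
#'
#' Returns exactly the voxels whose centre lies within `radius_um` (world
#' Euclidean distance, inclusive) of the nearest channel-voxel centre.
#' Computed by thresholding an exact anisotropic Euclidean distance
#' transform, which is equivalent to morphological dilation with a sphere
#' structuring element scaled to the voxel sampling, but exact: iterated
#' unit-ball dilation on an anisotropic grid would not give the true
#' Euclidean distance.
#'
#' @param domain A [channel_domain()] (or integer voxel index vector).
#' @param vol The [labeled_volume()] supplying grid shape and voxel size.
#' @param radius_um Dilation radius in micrometres (>= 0); default 40, the
#'   pFTU template value (half the 80 um diffusive-field diameter).
#' @return Sorted integer vector of linear voxel indices (a superset of
#'   the channel's own voxels).
#' @export
euclidean_dilate <- function(domain, vol,
                             radius_um = PFTU_DILATION_RADIUS_UM) {
  if (!is.numeric(radius_um) || length(radius_um) != 1 || is.na(radius_um) ||
      radius_um < 0)
    stop("radius_um must be a single non-negative number", call. = FALSE)
  vox <- if (inherits(domain, "channel_domain")) domain$voxels
         else as.integer(domain)
  d <- dim(vol$labels)
  mask <- logical(prod(d))
  mask[vox] <- TRUE
  d2 <- cpp_edt_sq(mask, d, vol$voxel_size)
  which(d2 <= radius_um * radius_um)
}

#' Extract an ordered centerline from a tube-like channel
#'
#' Finds the two geodesically most distant voxels of the channel (double
#' breadth-first sweep), joins them with a depth-weighted shortest path
#' that prefers voxels far from the channel surface, recentres each path
#' point to the centroid of the channel voxels in its perpendicular slab,
#' and smooths. The caller declares the channel tube-like; if parts of
#' the channel lie far from the resulting path (side branches), a warning
#' is emitted and the longest path is used.
#'
#' @param channel A [channel_domain()].
#' @param vol The source [labeled_volume()].
#' @param smooth Half-width (points) of the moving-average smoother.
#' @return A `centerline` object: `points` (n x 3 world um), `arclength`
#'   (cumulative, starting at 0), `tangent` (n x 3 unit vectors).
#' @export
centerline_of <- function(channel, vol, smooth = 2L) {
  vox <- channel$voxels
  if (length(vox) < 2L) {
    pts <- rbind(vox_to_world(vox, vol))
    return(structure(list(points = pts, arclength = 0,
                          tangent = matrix(NA_real_, 1, 3)),
                     class = "centerline"))
  }
  d <- dim(vol$labels)
  ijk <- arrayInd(vox, d)

  ## adjacency among channel voxels (26-neighbourhood), world-distance weights
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  ## depth: distance to background, used to pull the path onto the axis
  mask <- logical(prod(d)); mask[vox] <- TRUE
  depth <- sqrt(cpp_edt_sq(!mask, d, vol$voxel_size))[vox]
  maxdep <- max(depth, min(vol$voxel_size) / 2)

  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    nb <- ijk
    nb[, 1] <- nb[, 1] + o[1]; nb[, 2] <- nb[, 2] + o[2]; nb[, 3] <- nb[, 3] + o[3]
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1) + d[1] * d[2] * (nb[ok, 3] - 1)
    hit <- match(lin, vox)
    keep <- !is.na(hit)
    if (!any(keep)) next
    a <- which(ok)[keep]; b <- hit[keep]
    step <- sqrt(sum((o * vol$voxel_size)^2))
    ## penalise shallow voxels so the geodesic hugs the medial axis
    pen <- 1 + 4 * (1 - (depth[a] + depth[b]) / (2 * maxdep))
    from <- c(from, a); to <- c(to, b); w <- c(w, step * pen)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w),
    directed = FALSE, vertices = data.frame(name = seq_along(vox)))
  ## double sweep for geodesic endpoints
  d1 <- igraph::distances(g, v = 1)[1, ]
  e1 <- which.max(ifelse(is.finite(d1), d1, -Inf))
  d2 <- igraph::distances(g, v = e1)[1, ]
  e2 <- which.max(ifelse(is.finite(d2), d2, -Inf))
  path <- as.integer(igraph::shortest_paths(g, from = e1, to = e2,
                                            output = "vpath")$vpath[[1]])
  world <- vox_to_world(vox, vol)
  pts <- world[path, , drop = FALSE]

  ## branch heuristic: channel voxels much farther from the path than the
  ## tube half-thickness indicate an unvisited side branch
  nearp <- cpp_nearest_point(world, pts)
  doff <- sqrt(rowSums((world - pts[nearp, , drop = FALSE])^2))
  if (any(doff > 2.5 * maxdep + max(vol$voxel_size)))
    warning("channel appears branched; using longest path as centerline")

  ## recentre: replace each path point with the centroid of channel voxels
  ## whose nearest path point is this one (perpendicular slab centroid)
  if (nrow(pts) >= 3) {
    nearest <- cpp_nearest_point(world, pts)
    for (i in seq_len(nrow(pts))) {
      m <- nearest == i
      if (sum(m) > 0) pts[i, ] <- colMeans(world[m, , drop = FALSE])
    }
  }
  ## moving-average smoothing (ends kept)
  if (smooth > 0 && nrow(pts) > 2 * smooth + 1) {
    sm <- pts
    for (i in seq_len(nrow(pts))) {
      a <- max(1, i - smooth); b <- min(nrow(pts), i + smooth)
      sm[i, ] <- colMeans(pts[a:b, , drop = FALSE])
    }
    pts <- sm
  }
  ## drop consecutive duplicates, cumulative arclength, tangents
  seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                            pts[-nrow(pts), , drop = FALSE])^2))
  keep <- c(TRUE, seglen > 1e-9)
  pts <- pts[keep, , drop = FALSE]
  seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                            pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seglen))
  n <- nrow(pts)
  tang <- matrix(0, n, 3)
  if (n >= 2) {
    tang[1, ] <- pts[2, ] - pts[1, ]
    tang[n, ] <- pts[n, ] - pts[n - 1, ]
    if (n > 2) tang[2:(n - 1), ] <- pts[3:n, , drop = FALSE] -
        pts[1:(n - 2), , drop = FALSE]
    tang <- tang / sqrt(rowSums(tang^2))
  }
  structure(list(points = pts, arclength = s, tangent = tang),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("centerline: %d points, arclength %.1f um\n",
              nrow(x$points), max(x$arclength)))
  invisible(x)
}

#' A polyline given as world coordinates, bypassing skeletonization
#'
#' Channels delineated manually come with their own axis; this wraps an
#' explicit n x 3 point matrix (or CSV with columns x_um, y_um, z_um)
#' as a `centerline`.
#'
#' @param pts n x 3 matrix of world coordinates (um), or a CSV path.
#' @param spacing_um Resampling step (um): the polyline is densified so
#'   nearest-point queries against it resolve positions along the axis,
#'   not just its vertices.
#' @return A `centerline` object.
#' @export
centerline_from_points <- function(pts, spacing_um = 1) {
  if (is.character(pts)) {
    df <- read.csv(pts)
    pts <- as.matrix(df[, c("x_um", "y_um", "z_um")])
  }
  pts <- rbind(pts)
  seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                            pts[-nrow(pts), , drop = FALSE])^2))
  if (any(seglen <= 0)) stop("polyline has repeated points", call. = FALSE)
  pts <- densify_polyline(pts, spacing_um)
  seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                            pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seglen))
  n <- nrow(pts)
  tang <- matrix(0, n, 3)
  tang[1, ] <- pts[2, ] - pts[1, ]
  tang[n, ] <- pts[n, ] - pts[n - 1, ]
  if (n > 2) tang[2:(n - 1), ] <- pts[3:n, , drop = FALSE] -
      pts[1:(n - 2), , drop = FALSE]
  tang <- tang / sqrt(rowSums(tang^2))
  structure(list(points = pts, arclength = s, tangent = tang),
            class = "centerline")
}

#' pFTU domains
#'
#' One primary functional tissue unit: the diffusive-field voxels cuffing
#' a single channel segment of nominal 60 um length (80 um diameter,
#' 40 um dilation radius), annotated with an anatomy term.
#'
#' @param pftu_id,channel_id Identifiers.
#' @param segment_index 0-based index of the segment along the channel.
#' @param voxels Sorted linear voxel indices of the diffusive field.
#' @param anatomy_term Term inherited from the channel.
#' @param partial TRUE if the segment is a sub-length remainder.
#' @param seg_length_um Nominal segment length (um).
#' @return A `pftu_domain` object.
#' @export
pftu_domain <- function(pftu_id, channel_id, segment_index, voxels,
                        anatomy_term = NULL, partial = FALSE,
                        seg_length_um = PFTU_SEGMENT_LENGTH_UM) {
  structure(list(pftu_id = pftu_id, channel_id = channel_id,
                 segment_index = as.integer(segment_index),
                 voxels = sort(unique(as.integer(voxels))),
                 anatomy_term = if (is.null(anatomy_term)) NULL
                                else term_id(anatomy_term),
                 partial = isTRUE(partial),
                 seg_length_um = seg_length_um,
                 diameter_um = PFTU_DIAMETER_UM,
                 dilation_radius_um = PFTU_DILATION_RADIUS_UM),
            class = "pftu_domain")
}

#' @export
print.pftu_domain <- function(x, ...) {
  cat(sprintf("pFTU %s (channel %s, segment %d%s): %d voxels, term %s\n",
              x$pftu_id, x$channel_id, x$segment_index,
              if (x$partial) ", partial" else "", length(x$voxels),
              if (is.null(x$anatomy_term)) "<none>" else x$anatomy_term))
  invisible(x)
}

#' Cut a dilated channel domain into pFTU segments
#'
#' Every dilated voxel is assigned to the arclength bin
#' `[k*L, (k+1)*L)` of its nearest centerline point; the bin boundaries
#' realise cutting planes perpendicular to the tubule at each end of the
#' nominal 60 um length. The segments partition the dilated domain. A
#' final remainder shorter than `seg_length_um` is retained and flagged
#' `partial`.
#'
#' @param dilated Integer vector of dilated voxel indices
#'   (from [euclidean_dilate()]).
#' @param centerline A `centerline` for the channel.
#' @param vol The [labeled_volume()].
#' @param seg_length_um Segment length in micrometres (> 0); default 60.
#' @param channel_id,anatomy_term Propagated onto the pFTUs.
#' @return List of [pftu_domain()] in segment order.
#' @export
cut_segments <- function(dilated, centerline, vol,
                         seg_length_um = PFTU_SEGMENT_LENGTH_UM,
                         channel_id = "ch", anatomy_term = NULL) {
  if (!is.numeric(seg_length_um) || seg_length_um <= 0)
    stop("seg_length_um must be > 0", call. = FALSE)
  total <- max(centerline$arclength)
  if (!isTRUE(total > 0))
    stop("centerline has zero arclength; cannot cut segments", call. = FALSE)
  world <- vox_to_world(as.integer(dilated), vol)
  nearest <- cpp_nearest_point(world, centerline$points)
  s <- centerline$arclength[nearest]
  bin <- pmin(floor(s / seg_length_um), ceiling(total / seg_length_um) - 1)
  nseg <- ceiling(total / seg_length_um)
  partial_last <- (total %% seg_length_um) > 1e-9
  out <- vector("list", nseg)
  for (k in seq_len(nseg) - 1L) {
    vox <- as.integer(dilated)[bin == k]
    out[[k + 1L]] <- pftu_domain(
      pftu_id = sprintf("%s_pftu%03d", channel_id, k),
      channel_id = channel_id, segment_index = k, voxels = vox,
      anatomy_term = anatomy_term,
      partial = (k == nseg - 1L) && partial_last,
      seg_length_um = seg_length_um)
  }
  out
}

#' Spatial overlap between two pFTU domains
#'
#' Neighbouring diffusive fields overlap; the shared-voxel count and Dice
#' coefficient quantify the degree of overlap.
#'
#' @param a,b [pftu_domain()] objects (or voxel index vectors) on the
#'   same volume grid.
#' @param dims Optional grid dims used to verify both sets fit one grid.
#' @return List with `shared` (voxel count) and `dice`
#'   (`2|A.B| / (|A|+|B|)`; 0 when both empty).
#' @export
pftu_overlap <- function(a, b, dims = NULL) {
  va <- if (inherits(a, "pftu_domain")) a$voxels else as.integer(a)
  vb <- if (inherits(b, "pftu_domain")) b$voxels else as.integer(b)
  if (!is.null(dims)) {
    n <- prod(dims)
    if (length(va) && max(va) > n || length(vb) && max(vb) > n)
      stop("voxel indices exceed the stated grid", call. = FALSE)
  }
  shared <- length(intersect(va, vb))
  denom <- length(va) + length(vb)
  list(shared = shared, dice = if (denom == 0) 0 else 2 * shared / denom)
}

#' Parcellate a labeled volume into pFTUs
#'
#' Convenience pipeline: extract channels, dilate each by the template
#' radius, extract (or accept) centerlines, cut into segments.
#'
#' @param vol A [labeled_volume()].
#' @param radius_um Dilation radius (um), default 40.
#' @param seg_length_um Segment length (um), default 60.
#' @param kind Channel kind.
#' @param term_map Label value -> anatomy term mapping.
#' @param centerlines Optional named list (by channel id) of `centerline`
#'   objects to bypass skeleton extraction.
#' @return List with `channels`, `pftus` (flat list), `dilated` (named
#'   list of voxel sets per channel).
#' @export
parcellate <- function(vol, radius_um = PFTU_DILATION_RADIUS_UM,
                       seg_length_um = PFTU_SEGMENT_LENGTH_UM,
                       kind = "endothelial", term_map = NULL,
                       centerlines = NULL) {
  channels <- extract_channels(vol, kind = kind, term_map = term_map)
  pftus <- list()
  dilated <- list()
  for (ch in channels) {
    dil <- euclidean_dilate(ch, vol, radius_um)
    dilated[[ch$channel_id]] <- dil
    cl <- if (!is.null(centerlines) && !is.null(centerlines[[ch$channel_id]]))
      centerlines[[ch$channel_id]] else centerline_of(ch, vol)
    if (max(cl$arclength) <= 0) next
    pftus <- c(pftus, cut_segments(dil, cl, vol, seg_length_um,
                                   channel_id = ch$channel_id,
                                   anatomy_term = ch$anatomy_term))
  }
  list(channels = channels, pftus = pftus, dilated = dilated)
}

#' Write a pFTU parcellation to disk
#'
#' Writes one labeled volume (one label per pFTU, in list order) plus a
#' JSON manifest (id, channel, segment index, term, voxel count, partial
#' flag).
#'
#' @param pftus List of [pftu_domain()].
#' @param vol Source [labeled_volume()] (grid reference).
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_pftus <- function(pftus, vol, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lab <- array(0L, dim(vol$labels))
  for (i in seq_along(pftus)) lab[pftus[[i]]$voxels] <- i
  write_volume(labeled_volume(lab, vol$voxel_size, vol$origin),
               file.path(dir, "pftus.tif"))
  manifest <- lapply(pftus, function(p)
    list(pftu_id = p$pftu_id, channel = p$channel_id,
         segment_index = p$segment_index,
         anatomy_term = if (is.null(p$anatomy_term)) NA else p$anatomy_term,
         voxel_count = length(p$voxels), partial = p$partial))
  path <- file.path(dir, "pftus.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
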