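## Seeded generators emulating the inputs of each pipeline stage: labeled
## channel volumes with typed nuclei, misaligned serial stacks, and
## bifurcating vascular trees. All generators restore the caller's RNG
## state, so fixtures are reproducible and side-effect free.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

## densify a polyline (n x 3) to spacing <= step
densify_polyline <- function(pts, step) {
  pts <- rbind(pts)
  if (nrow(pts) == 1) return(pts)
  out <- list()
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    nseg <- max(1L, ceiling(len / step))
    f <- seq(0, 1, length.out = nseg + 1)
    seg <- cbind(a[1] + f * (b[1] - a[1]), a[2] + f * (b[2] - a[2]),
                 a[3] + f * (b[3] - a[3]))
    out[[i]] <- if (i < nrow(pts) - 1) seg[-nrow(seg), , drop = FALSE] else seg
  }
  do.call(rbind, out)
}

#' Generate a labeled tube volume with typed nuclei
#'
#' Rasterises tube-shaped channel domains (voxels whose centre lies
#' within the tube radius of the axis polyline) into an anisotropic
#' voxel grid and scatters cell nuclei in distance bands around the tube
#' walls (epithelial cells hug the wall, endothelium lines the lumen,
#' etc.). Ground truth voxel sets are returned for oracle testing.
#'
#' @param dims Grid size `c(nx, ny, nz)`.
#' @param voxel_size_um Voxel size `c(dx, dy, dz)` (um).
#' @param tubes List of tubes: each a list with `polyline` (n x 3 world
#'   um; or `start`/`end` points), `radius_um`, `label` (positive int).
#' @param nuclei List of groups: each a list with `ct_term`, `n`, `band`
#'   (`c(min, max)` distance from the tube *wall* in um; negative =
#'   inside the lumen) and optional `label` restricting to one tube.
#' @param seed RNG seed.
#' @param origin World origin (um).
#' @param allow_overlap Error on overlapping tube labels unless TRUE.
#' @return List: `volume` (a [labeled_volume()]), `channels` (ground
#'   truth voxel sets per tube, list of integer vectors), `marks`
#'   (a [cell_marks()] data frame).
#' @export
make_tube_volume <- function(dims, voxel_size_um, tubes, nuclei = list(),
                             seed = 1L, origin = c(0, 0, 0),
                             allow_overlap = FALSE) {
  vol <- labeled_volume(array(0L, dims), voxel_size_um, origin)
  centers <- vox_to_world(seq_len(prod(dims)), vol)
  labels <- integer(prod(dims))
  truth <- list()
  axes <- list()
  for (tb in tubes) {
    poly <- if (!is.null(tb$polyline)) tb$polyline else rbind(tb$start, tb$end)
    dense <- densify_polyline(poly, min(voxel_size_um) / 4)
    nearest <- cpp_nearest_point(centers, dense)
    d <- sqrt(rowSums((centers - dense[nearest, , drop = FALSE])^2))
    vox <- which(d <= tb$radius_um)
    if (!allow_overlap && any(labels[vox] != 0L & labels[vox] != tb$label))
      stop("tubes with different labels overlap", call. = FALSE)
    labels[vox] <- tb$label
    truth[[as.character(tb$label)]] <- sort(vox)
    axes[[as.character(tb$label)]] <- dense
  }
  vol$labels <- array(as.integer(labels), dims)
  marks <- NULL
  if (length(nuclei)) {
    lo <- origin
    hi <- origin + dims * voxel_size_um
    marks <- with_seed(seed, {
      rows <- list()
      for (g in nuclei) {
        ref_labels <- if (!is.null(g$label)) as.character(g$label)
                      else names(axes)
        radius_of <- vapply(tubes, function(tb) tb$radius_um, numeric(1))
        names(radius_of) <- vapply(tubes, function(tb)
          as.character(tb$label), character(1))
        got <- 0L
        tries <- 0L
        pts <- matrix(numeric(0), 0, 3)
        while (got < g$n && tries < 200 * g$n) {
          cand <- cbind(runif(g$n, lo[1], hi[1]), runif(g$n, lo[2], hi[2]),
                        runif(g$n, lo[3], hi[3]))
          ## distance from the wall of the nearest selected tube
          dwall <- rep(Inf, nrow(cand))
          for (lb in ref_labels) {
            nn <- cpp_nearest_point(cand, axes[[lb]])
            dax <- sqrt(rowSums((cand - axes[[lb]][nn, , drop = FALSE])^2))
            dwall <- pmin(dwall, dax - radius_of[[lb]])
          }
          ok <- dwall >= g$band[1] & dwall <= g$band[2]
          pts <- rbind(pts, cand[ok, , drop = FALSE])
          got <- nrow(pts)
          tries <- tries + g$n
        }
        if (got < g$n)
          stop("could not place ", g$n, " nuclei for ", g$ct_term,
               " in the requested band", call. = FALSE)
        pts <- pts[seq_len(g$n), , drop = FALSE]
        rows[[length(rows) + 1]] <- data.frame(
          x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3],
          ct_term = g$ct_term)
      }
      do.call(rbind, rows)
    })
    marks <- cell_marks(marks$x_um, marks$y_um, marks$z_um, marks$ct_term)
  }
  list(volume = vol, channels = truth, marks = marks)
}

#' Smooth random test texture
#'
#' Band-limited random field (white noise low-pass filtered in Fourier
#' space), suitable as registerable section content.
#'
#' @param n Image side (px).
#' @param seed RNG seed.
#' @param cutoff Low-pass cutoff as a fraction of Nyquist.
#' @return An n x n numeric matrix, zero mean, unit variance.
#' @export
texture_image <- function(n = 64, seed = 1L, cutoff = 0.2) {
  with_seed(seed, {
    z <- matrix(rnorm(n * n), n, n)
    f <- stats::fft(z)
    k <- c(0:(n - 1)); k[k > n / 2] <- k[k > n / 2] - n
    keep <- outer(abs(k) <= cutoff * n / 2, abs(k) <= cutoff * n / 2)
    img <- Re(stats::fft(f * keep, inverse = TRUE)) / (n * n)
    (img - mean(img)) / sd(img)
  })
}

#' Generate a misaligned serial-section stack with known ground truth
#'
#' Each section is the base image under the cumulative composition of
#' per-pair rigid perturbations drawn uniformly from the given ranges
#' (plus optional gray noise); the applied pairwise transforms are
#' returned as ground truth, so registration output can be scored as
#' `recovered o applied ~ identity`.
#'
#' @param image Base image matrix (e.g. [texture_image()]).
#' @param n_sections Number of sections.
#' @param shift_range_px Max |tx|, |ty| per pair (px).
#' @param theta_range_deg Max |theta| per pair (degrees).
#' @param seed RNG seed.
#' @param noise_sd Additive gray noise sd.
#' @param pixel_size_um,thickness_um Physical metadata.
#' @return List: `sections` (list of [section_image()]),
#'   `true_pairwise` (list of n-1 [rigid_transform()]s applied between
#'   adjacent sections).
#' @export
make_misaligned_stack <- function(image, n_sections, shift_range_px = 5,
                                  theta_range_deg = 3, seed = 1L,
                                  noise_sd = 0, pixel_size_um = 1,
                                  thickness_um = 2) {
  with_seed(seed, {
    truth <- vector("list", max(n_sections - 1, 0))
    cum <- rigid_transform()
    sections <- vector("list", n_sections)
    for (i in seq_len(n_sections)) {
      if (i > 1) {
        tr <- rigid_transform(
          runif(1, -shift_range_px, shift_range_px) * pixel_size_um,
          runif(1, -shift_range_px, shift_range_px) * pixel_size_um,
          runif(1, -theta_range_deg, theta_range_deg))
        truth[[i - 1]] <- tr
        cum <- compose_transform(cum, tr)
      }
      px <- warp_image(section_image(image, pixel_size_um), cum)
      px[is.na(px)] <- 0
      if (noise_sd > 0) px <- px + rnorm(length(px), sd = noise_sd)
      sections[[i]] <- section_image(px, pixel_size_um, i - 1L, thickness_um)
    }
    list(sections = sections, true_pairwise = truth)
  })
}

#' Generate a bifurcating vascular tree with microcirculations
#'
#' Builds a symmetric arterial binary tree of the given depth (depth 1 =
#' a single root artery), mirrors it on the venous side, joins each
#' arterial leaf to its venous twin through a microcirculation component
#' (arteriole, capillary, venule aggregates) and records supplies/drains
#' relations and branch order. Radii follow Murray-type scaling
#' (`r_child = r_parent * 2^(-1/3)`), lengths shrink geometrically, and
#' bed/segment parameters take physiological orders of magnitude (not
#' calibrated to any specific organism). The returned network passes
#' [validate_network()].
#'
#' @param depth Tree depth (>= 1); `2^(depth - 1)` leaves and
#'   microcirculations.
#' @param seed RNG seed (used when `asymmetry > 0`).
#' @param root_radius_m Root artery radius (m).
#' @param root_length_m Root artery length (m).
#' @param asymmetry Fractional jitter applied to child lengths.
#' @param wave_speed Target pulse-wave speed (m/s) setting the wall
#'   stiffness.
#' @param n_grid Cells per segment for the flow model.
#' @return List: `network` (a [vascular_network()] including the
#'   microcirculation triplet segments), `flow` (a [flow_model()] with
#'   the large vessels and one RCR bed per leaf), `terms` (fixture term
#'   store).
#' @export
make_vascular_tree <- function(depth, seed = 1L, root_radius_m = 2e-3,
                               root_length_m = 0.05, asymmetry = 0,
                               wave_speed = 8, n_grid = 12L) {
  stopifnot(depth >= 1)
  with_seed(seed, {
    rho <- 1050
    segs <- list()
    branches <- data.frame(parent = character(), child = character(),
                           origin_fraction = numeric())
    mics <- list()
    rels <- data.frame(subject = character(), predicate = character(),
                       object = character())
    fsegs <- list()
    beds <- list()
    terms <- list()
    props_of <- function(r, L) {
      A0 <- pi * r^2
      beta <- 2 * rho * wave_speed^2 / sqrt(A0)
      segment_properties(A0, beta, L, n_grid = n_grid)
    }
    add_term <- function(id, voc = "anatomy") {
      terms[[id]] <<- ontology_term(id, vocabulary = voc)
      id
    }
    ## recursive build: arterial node -> children or leaf microcirculation
    leaf_counter <- 0L
    build <- function(name, level, r, L, node_in) {
      aid <- paste0("art_", name)
      node_out <- paste0("na_", name)
      segs[[aid]] <<- vessel_segment(aid, "artery",
                                     add_term(paste0("FMA:artery-", name)),
                                     L, r, node_in, node_out)
      fsegs[[aid]] <<- list(from = node_in, to = node_out, props = props_of(r, L))
      if (level == depth) { # leaf: microcirculation + venous twin
        leaf_counter <<- leaf_counter + 1L
        k <- name
        region <- add_term(paste0("FMA:region-", k))
        trip <- list(a = paste0("mc_a_", k), c = paste0("mc_c_", k),
                     v = paste0("mc_v_", k))
        nmid1 <- paste0("nm1_", k); nmid2 <- paste0("nm2_", k)
        nven <- paste0("nv_", k)
        segs[[trip$a]] <<- vessel_segment(trip$a, "arteriole_aggregate",
                                          add_term(paste0("FMA:arterioles-", k)),
                                          2e-3, 3e-5, node_out, nmid1)
        segs[[trip$c]] <<- vessel_segment(trip$c, "capillary_aggregate",
                                          add_term(paste0("FMA:capillaries-", k)),
                                          1e-3, 4e-6, nmid1, nmid2)
        segs[[trip$v]] <<- vessel_segment(trip$v, "venule_aggregate",
                                          add_term(paste0("FMA:venules-", k)),
                                          2e-3, 4e-5, nmid2, nven)
        cid <- paste0("micro_", k)
        mics[[cid]] <<- microcirculation(cid, region, trip$a, trip$c, trip$v)
        rels <<- rbind(rels,
                       data.frame(subject = aid, predicate = "supplies",
                                  object = cid),
                       data.frame(subject = cid, predicate = "drains",
                                  object = paste0("vein_", name)))
        ## flow model: RCR bed bridging arterial leaf node to venous start
        beds[[length(beds) + 1]] <<- list(
          bed = lumped_bed(R_prox = 2e8 * 2^(depth - 1),
                           R_dist = 1e9 * 2^(depth - 1),
                           C = 1e-10 / 2^(depth - 1), region_term = region),
          from = node_out, to = nven)
        vid <- paste0("vein_", name)
        vnode_out <- paste0("nvv_", name)
        segs[[vid]] <<- vessel_segment(vid, "vein",
                                       add_term(paste0("FMA:vein-", name)),
                                       L, r * 1.3, nven, vnode_out)
        fsegs[[vid]] <<- list(from = nven, to = vnode_out,
                              props = props_of(r * 1.3, L))
        return(vnode_out)
      }
      rc <- r * 2^(-1 / 3)
      jit <- if (asymmetry > 0) runif(2, 1 - asymmetry, 1 + asymmetry)
             else c(1, 1)
      Lc <- L * 0.75 * jit
      vouts <- character(2)
      for (ci in 1:2) {
        child <- paste0(name, ci)
        branches <<- rbind(branches, data.frame(
          parent = aid, child = paste0("art_", child), origin_fraction = 1))
        rels <<- rbind(rels, data.frame(
          subject = aid, predicate = "has_branch",
          object = paste0("art_", child)))
        vouts[ci] <- build(child, level + 1, rc, Lc[ci], node_out)
      }
      ## venous confluence mirroring this bifurcation
      vid <- paste0("vein_", name)
      vnode_out <- paste0("nvv_", name)
      vnode_in <- paste0("nvj_", name)
      segs[[vid]] <<- vessel_segment(vid, "vein",
                                     add_term(paste0("FMA:vein-", name)),
                                     L, r * 1.3, vnode_in, vnode_out)
      fsegs[[vid]] <<- list(from = vnode_in, to = vnode_out,
                            props = props_of(r * 1.3, L))
      ## re-point the child veins' outlets into this confluence node
      for (ci in 1:2) {
        cvid <- paste0("vein_", name, ci)
        segs[[cvid]]$downstream <<- vnode_in
        fsegs[[cvid]]$to <<- vnode_in
      }
      vnode_out
    }
    build("1", 1, root_radius_m, root_length_m, "inlet")
    network <- vascular_network(unname(segs), unname(mics), branches, rels)
    flow <- flow_model(fsegs, beds, inlet = "inlet", p_out = 0)
    list(network = network, flow = flow,
         terms = term_store(unname(terms)))
  })
}
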