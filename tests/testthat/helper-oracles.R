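## Independent oracles and shared fixtures for the test suite.

## Brute-force all-pairs Euclidean dilation: every voxel whose centre is
## within `radius` of the nearest channel-voxel centre.  Chunked matrix
## arithmetic; independent of the distance-transform implementation.
brute_dilate <- function(vox, vol, radius) {
  d <- dim(vol$labels)
  n <- prod(d)
  ctr <- vox_to_world(seq_len(n), vol)
  ref <- vox_to_world(vox, vol)
  best <- rep(Inf, n)
  chunk <- 20000L
  for (lo in seq(1, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    q <- ctr[lo:hi, , drop = FALSE]
    d2 <- outer(rowSums(q^2), rep(1, nrow(ref))) -
      2 * q %*% t(ref) +
      outer(rep(1, nrow(q)), rowSums(ref^2))
    best[lo:hi] <- apply(d2, 1, min)
  }
  ## recompute exactly (coordinate-wise) for near-threshold voxels so the
  ## oracle's arithmetic matches plain per-axis differences
  cand <- which(abs(best - radius^2) < 1)
  for (i in cand) {
    dd <- (ctr[i, 1] - ref[, 1])^2 + (ctr[i, 2] - ref[, 2])^2 +
      (ctr[i, 3] - ref[, 3])^2
    best[i] <- min(dd)
  }
  which(best <= radius^2)
}

## Exhaustive DFS enumeration of simple directed paths between segment
## sets, on the VKB's shared-junction adjacency.  Independent of igraph.
dfs_paths <- function(net, from_segs, to_segs) {
  ids <- names(net$segments)
  dn <- vapply(net$segments, function(s) s$downstream, character(1))
  up <- vapply(net$segments, function(s) s$upstream, character(1))
  succ <- lapply(ids, function(a) ids[up == dn[[a]]])
  names(succ) <- ids
  out <- list()
  walk <- function(path, target_set) {
    cur <- path[length(path)]
    if (cur %in% target_set && length(path) >= 1) {
      out[[length(out) + 1L]] <<- path
    }
    for (nxt in succ[[cur]]) {
      if (!(nxt %in% path)) walk(c(path, nxt), target_set)
    }
  }
  for (f in from_segs) walk(f, to_segs)
  out
}

## Toy circulatory fixture: heart -> aorta -> renal artery -> kidney
## microcirculation -> renal vein -> vena cava; optionally a second
## (accessory) renal artery in parallel.
toy_kidney_network <- function(parallel_artery = FALSE) {
  seg <- function(id, kind, term, from, to, L = 0.05, r = 2e-3)
    vessel_segment(id, kind, term, L, r, from, to)
  segs <- list(
    seg("heart", "artery", "FMA:heart", "n0", "n1", L = 0.08),
    seg("aorta", "artery", "FMA:aorta", "n1", "n2", L = 0.2),
    seg("renal_art", "artery", "FMA:renal-artery", "n2", "n3", L = 0.04),
    seg("arterioles", "arteriole_aggregate", "FMA:kidney-arterioles",
        "n3", "n4", L = 2e-3, r = 3e-5),
    seg("capillaries", "capillary_aggregate", "FMA:kidney-capillaries",
        "n4", "n5", L = 1e-3, r = 4e-6),
    seg("venules", "venule_aggregate", "FMA:kidney-venules",
        "n5", "n6", L = 2e-3, r = 4e-5),
    seg("renal_vein", "vein", "FMA:renal-vein", "n6", "n7", L = 0.04),
    seg("vena_cava", "vein", "FMA:vena-cava", "n7", "n8", L = 0.2))
  if (parallel_artery)
    segs <- c(segs, list(seg("renal_art2", "artery", "FMA:renal-artery-acc",
                             "n2", "n3", L = 0.06)))
  mic <- microcirculation("kidney_bed", "FMA:kidney", "arterioles",
                          "capillaries", "venules")
  rel <- data.frame(
    subject = c("renal_art", "kidney_bed"),
    predicate = c("supplies", "drains"),
    object = c("kidney_bed", "renal_vein"))
  br <- data.frame(parent = "aorta", child = "renal_art",
                   origin_fraction = 0.6)
  vascular_network(segs, list(mic), br, rel)
}

## Straight-tube labeled volume with the pFTU-scale geometry; voxel
## sizes are quarter-micrometre multiples (exact squared-distance
## arithmetic).
straight_tube_volume <- function(length_um = 540, radius_um = 8,
                                 voxel = c(4, 4, 8), margin_um = 30,
                                 seed = 1L, nuclei = list()) {
  nx <- ceiling((length_um + 2 * margin_um) / voxel[1])
  ny <- ceiling((6 * radius_um + 80) / voxel[2])
  nz <- ceiling((6 * radius_um + 80) / voxel[3])
  cy <- ny * voxel[2] / 2
  cz <- nz * voxel[3] / 2
  axis <- rbind(c(margin_um, cy, cz), c(margin_um + length_um, cy, cz))
  fix <- make_tube_volume(c(nx, ny, nz), voxel,
                          tubes = list(list(polyline = axis,
                                            radius_um = radius_um,
                                            label = 1L)),
                          nuclei = nuclei, seed = seed)
  fix$axis <- axis
  fix
}

## random quarter-um-multiple voxel sizes in a realistic microscopy range
random_voxel_size <- function() {
  c(sample(seq(1, 4, by = 0.25), 1),
    sample(seq(1, 4, by = 0.25), 1),
    sample(seq(2, 10, by = 0.25), 1))
}
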