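test_that("channel extraction follows 26-connectivity per label", {
  a <- array(0L, c(10, 10, 4))
  a[2:4, 2, 1] <- 1L          # tube piece 1
  a[7:9, 8, 3] <- 1L          # disjoint piece, same label
  vol <- labeled_volume(a, c(2, 2, 4))
  ch <- extract_channels(vol)
  expect_length(ch, 2)
  expect_setequal(lengths(lapply(ch, `[[`, "voxels")), c(3L, 3L))

  ## single voxel: one channel of size 1
  b <- array(0L, c(4, 4, 4)); b[2, 2, 2] <- 5L
  expect_equal(lengths(lapply(extract_channels(labeled_volume(b, c(1, 1, 1))),
                              `[[`, "voxels")), 1L)

  ## touching only diagonally (all three axes differ): still one channel
  d <- array(0L, c(4, 4, 4)); d[1, 1, 1] <- 1L; d[2, 2, 2] <- 1L
  expect_length(extract_channels(labeled_volume(d, c(1, 1, 1))), 1)

  ## empty volume: no channels
  expect_length(extract_channels(labeled_volume(array(0L, c(3, 3, 3)),
                                                c(1, 1, 1))), 0)
})

test_that("dilation is exact: lattice offsets, anisotropy, radius zero", {
  ## single voxel, isotropic 10 um: exactly offsets with i^2+j^2+k^2 <= 16
  dims <- c(15, 15, 15)
  vol <- labeled_volume(array(0L, dims), c(10, 10, 10))
  centre <- cbind(8, 8, 8)
  cvox <- centre[1] + dims[1] * (centre[2] - 1) +
    dims[1] * dims[2] * (centre[3] - 1)
  dil <- euclidean_dilate(cvox, vol, 40)
  ijk <- arrayInd(dil, dims) - 8
  expect_true(all(rowSums(ijk^2) <= 16))
  expect_equal(length(dil), sum(apply(as.matrix(expand.grid(-4:4, -4:4, -4:4)),
                                      1, function(o) sum(o^2) <= 16)))

  ## anisotropic (10, 10, 20): i^2 + j^2 + 4 k^2 <= 16, fewer in z
  vola <- labeled_volume(array(0L, dims), c(10, 10, 20))
  dila <- euclidean_dilate(cvox, vola, 40)
  ijka <- arrayInd(dila, dims) - 8
  expect_true(all(ijka[, 1]^2 + ijka[, 2]^2 + 4 * ijka[, 3]^2 <= 16))
  expect_lt(max(abs(ijka[, 3])), max(abs(ijk[, 3])))
  expect_lt(length(dila), length(dil))

  ## radius zero: output == input; negative radius errors
  expect_equal(euclidean_dilate(cvox, vol, 0), as.integer(cvox))
  expect_error(euclidean_dilate(cvox, vol, -1), "non-negative")
})

test_that("dilation agrees exactly with brute force on random anisotropic volumes", {
  set.seed(33)
  for (trial in 1:4) {
    dims <- c(24, 20, 16)
    vs <- random_voxel_size()
    vol <- labeled_volume(array(0L, dims), vs)
    vox <- sample(prod(dims), 8)
    r <- sample(c(10, 25, 40), 1)
    expect_identical(euclidean_dilate(vox, vol, r),
                     as.integer(brute_dilate(vox, vol, r)))
  }
})

test_that("dilation is monotone in radius", {
  set.seed(4)
  dims <- c(20, 20, 12)
  vol <- labeled_volume(array(0L, dims), c(2, 2.5, 5))
  vox <- sample(prod(dims), 4)
  radii <- c(0, 5, 12, 20, 40)
  doms <- lapply(radii, function(r) euclidean_dilate(vox, vol, r))
  for (i in seq_along(radii)[-1])
    expect_true(all(doms[[i - 1]] %in% doms[[i]]))
})

test_that("centerlines of straight and bent tubes have correct geometry", {
  ## straight tube: centerline along the axis, axial unit tangents
  fix <- straight_tube_volume(length_um = 300, radius_um = 8,
                              voxel = c(4, 4, 8))
  vol <- fix$volume
  ch <- extract_channels(vol)[[1]]
  cl <- expect_silent(centerline_of(ch, vol))
  expect_gt(max(cl$arclength), 280)
  expect_lt(max(cl$arclength), 320)
  mid <- cl$points[10:(nrow(cl$points) - 10), ]
  expect_lt(max(abs(mid[, 2] - fix$axis[1, 2])), 4) # on-axis within a voxel
  tg <- cl$tangent[10:(nrow(cl$tangent) - 10), ]
  expect_gt(min(abs(tg[, 1])), 0.98) # tangents essentially +-x
  ## arclength strictly increasing; tangents unit norm
  expect_true(all(diff(cl$arclength) > 0))
  expect_equal(rowSums(cl$tangent^2), rep(1, nrow(cl$tangent)),
               tolerance = 1e-9)

  ## L-shaped tube: arclength ~ sum of leg lengths
  dims <- c(60, 60, 8); vs <- c(4, 4, 8)
  leg1 <- rbind(c(20, 20, 32), c(200, 20, 32))
  leg2 <- rbind(c(200, 20, 32), c(200, 200, 32))
  fixL <- make_tube_volume(dims, vs,
                           tubes = list(list(polyline = rbind(leg1, leg2[2, ]),
                                             radius_um = 8, label = 1L)))
  chL <- extract_channels(fixL$volume)[[1]]
  clL <- centerline_of(chL, fixL$volume)
  expect_equal(max(clL$arclength), 360, tolerance = 0.12) # corner cut allowed

  ## single-voxel channel: degenerate centerline, cutting refuses
  b <- array(0L, c(6, 6, 6)); b[3, 3, 3] <- 1L
  volb <- labeled_volume(b, c(1, 1, 1))
  chb <- extract_channels(volb)[[1]]
  clb <- centerline_of(chb, volb)
  expect_equal(nrow(clb$points), 1)
  expect_error(cut_segments(chb$voxels, clb, volb), "zero arclength")
})

test_that("segment cutting partitions the dilated domain into 60-um bins", {
  fix <- straight_tube_volume(length_um = 540, radius_um = 8)
  vol <- fix$volume
  ch <- extract_channels(vol)[[1]]
  dil <- euclidean_dilate(ch, vol, 40)
  cl <- centerline_from_points(fix$axis)
  expect_equal(max(cl$arclength), 540)

  segs <- cut_segments(dil, cl, vol, 60, channel_id = "t1",
                       anatomy_term = "FMA:tubule")
  expect_length(segs, 9) # 540 / 60
  expect_false(any(vapply(segs, `[[`, logical(1), "partial")))
  ## partition: disjoint, union equals the dilated set
  all_vox <- unlist(lapply(segs, `[[`, "voxels"))
  expect_equal(length(all_vox), length(dil))
  expect_equal(sort(all_vox), sort(dil))
  ## every segment contains its own channel voxels (cuff property)
  expect_true(all(ch$voxels %in% all_vox))

  ## 60-um centerline: a single segment
  cl60 <- centerline_from_points(rbind(fix$axis[1, ],
                                       fix$axis[1, ] + c(60, 0, 0)))
  segs60 <- cut_segments(dil, cl60, vol, 60)
  expect_length(segs60, 1)

  ## 150 um: 2 full + 1 partial (30 um) remainder
  cl150 <- centerline_from_points(rbind(fix$axis[1, ],
                                        fix$axis[1, ] + c(150, 0, 0)))
  segs150 <- cut_segments(dil, cl150, vol, 60)
  expect_length(segs150, 3)
  expect_equal(vapply(segs150, `[[`, logical(1), "partial"),
               c(FALSE, FALSE, TRUE))

  expect_error(cut_segments(dil, cl, vol, 0), "seg_length_um")
})

test_that("overlap metrics: identity, disjoint, and the two-tube oracle", {
  p1 <- pftu_domain("a", "ch", 0, c(1, 2, 3, 10))
  expect_equal(pftu_overlap(p1, p1), list(shared = 4L, dice = 1))
  p2 <- pftu_domain("b", "ch", 1, c(20, 30))
  expect_equal(pftu_overlap(p1, p2), list(shared = 0L, dice = 0))

  ## two parallel tubes 60 um apart (axis to axis), 40-um dilation:
  ## shared voxels equal the brute-force intersection
  dims <- c(40, 40, 20); vs <- c(4, 4, 8)
  a1 <- rbind(c(20, 50, 80), c(140, 50, 80))
  a2 <- rbind(c(20, 110, 80), c(140, 110, 80))
  fix <- make_tube_volume(dims, vs,
                          tubes = list(list(polyline = a1, radius_um = 8,
                                            label = 1L),
                                       list(polyline = a2, radius_um = 8,
                                            label = 2L)))
  vol <- fix$volume
  d1 <- euclidean_dilate(fix$channels[["1"]], vol, 40)
  d2 <- euclidean_dilate(fix$channels[["2"]], vol, 40)
  b1 <- brute_dilate(fix$channels[["1"]], vol, 40)
  b2 <- brute_dilate(fix$channels[["2"]], vol, 40)
  ov <- pftu_overlap(d1, d2)
  expect_gt(ov$shared, 0)
  expect_equal(ov$shared, length(intersect(b1, b2)))
})

test_that("volumes round-trip through TIFF + sidecar JSON", {
  fix <- straight_tube_volume(length_um = 120, radius_um = 8,
                              voxel = c(4, 4, 8))
  f <- withr::local_tempfile(fileext = ".tif")
  write_volume(fix$volume, f)
  vol2 <- read_volume(f)
  expect_equal(vol2, fix$volume)
})
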