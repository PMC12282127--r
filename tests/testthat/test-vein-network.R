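test_that("a straight bar yields one segment and no branch points", {
  net <- skeletonize_and_segment(bar_mask())
  expect_equal(nrow(net$segments), 1)
  expect_equal(net$n_branch_points, 0)
  expect_equal(dim(net$adjacency), c(1L, 1L))
  expect_equal(as.numeric(net$adjacency), 0)
})

test_that("a Y skeleton yields three mutually adjacent segments and one junction", {
  net <- skeletonize_and_segment(y_mask())
  expect_equal(nrow(net$segments), 3)
  expect_equal(net$n_branch_points, 1)
  A <- as.matrix(net$adjacency)
  expect_equal(A, matrix(1, 3, 3) - diag(3), ignore_attr = TRUE)
  expect_equal(connectivity(net), 1 / 3)
})

test_that("star masks give connectivity 1/k", {
  for (k in c(3, 4, 5, 8)) {
    net <- skeletonize_and_segment(star_mask(k))
    expect_equal(nrow(net$segments), k)
    expect_equal(net$n_branch_points, 1)
    expect_equal(connectivity(net), 1 / k)
  }
})

test_that("3x3 grid raster matches the hand-annotated reference", {
  # hand annotation of the rendered 3x3 grid graph: the four corner nodes are
  # pass-through (degree 2), so the 12 grid edges merge pairwise at corners
  # into 8 segments; the 4 mid-edge nodes (degree 3) and the centre (degree 4)
  # are the 5 branch points; the 4 cells are areoles.
  mask <- grid_mask(3)
  net <- skeletonize_and_segment(mask)
  expect_equal(nrow(net$segments), 8)
  expect_equal(net$n_branch_points, 5)
  feats <- vein_features(mask, net)
  expect_equal(feats$n_areoles, 4)
})

test_that("H skeleton adjacency matches the hand-drawn edge list", {
  net <- skeletonize_and_segment(h_mask())
  expect_equal(nrow(net$segments), 5)
  expect_equal(net$n_branch_points, 2)
  # identify segments by geometry: the crossbar spans the middle columns
  centroid <- t(vapply(net$pixels, colMeans, numeric(2)))
  nc <- net$dim[2]
  crossbar <- which(vapply(seq_len(5), function(i) {
    all(net$pixels[[i]][, 1] == net$pixels[[i]][1, 1])  # horizontal run
  }, logical(1)))
  expect_length(crossbar, 1)
  A <- as.matrix(net$adjacency)
  # crossbar touches all four half-bars
  expect_equal(sum(A[crossbar, ]), 4)
  # each half-bar touches the crossbar and its same-side partner
  verticals <- setdiff(1:5, crossbar)
  expect_true(all(rowSums(A)[verticals] == 2))
  left <- verticals[centroid[verticals, 2] < nc / 2]
  right <- setdiff(verticals, left)
  expect_equal(A[left[1], left[2]], 1)
  expect_equal(A[right[1], right[2]], 1)
  expect_equal(A[left[1], right[1]], 0)
})

test_that("degenerate and invalid masks are handled", {
  expect_error(vein_mask(matrix(FALSE, 4, 4)), "foreground")
  m <- matrix(FALSE, 7, 7); m[4, 4] <- TRUE
  expect_warning(net <- skeletonize_and_segment(vein_mask(m)), "degenerate")
  expect_equal(nrow(net$segments), 1)
})

test_that("thickness matches its definition on forced fixtures", {
  # one-pixel line: distance 1 at the centre, thickness 2
  net <- skeletonize_and_segment(bar_mask(width = 1))
  expect_equal(net$segments$thickness, 2)
  # 7-pixel bar: twice the centre distance from the brute-force search
  mask <- bar_mask(nr = 15, width = 7, row = 5)
  net <- skeletonize_and_segment(mask)
  ref <- brute_force_edt(unclass(mask))
  expect_equal(net$segments$thickness,
               2 * max(ref[net$pixels[[1]]]))
  expect_equal(net$segments$thickness, 2 * 4)  # centre row is 4 px from background
})

test_that("disk thickness approaches the diameter and matches brute force", {
  prev <- -Inf
  for (r in c(3, 5, 10)) {
    mask <- disk_mask(r)
    skel <- skeletonize(mask)
    dt <- distance_transform(mask)
    ref <- brute_force_edt(unclass(mask))
    expect_equal(dt, ref, tolerance = 1e-12, ignore_attr = TRUE)
    th <- 2 * max(dt[skel])
    expect_gt(th, prev)
    expect_lte(th, 2 * r + 1)
    expect_gte(th, 2 * (r - 1))
    prev <- th
  }
})

test_that("distance transform equals exhaustive search on random masks", {
  set.seed(7)
  for (rep in 1:3) {
    m <- matrix(runif(40 * 40) < 0.4, 40, 40)
    m[20, 20] <- TRUE
    expect_equal(distance_transform(vein_mask(m)), brute_force_edt(m),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("skeleton pixels partition into segments and junction clusters", {
  for (mask in list(y_mask(), h_mask(), grid_mask(3))) {
    net <- skeletonize_and_segment(mask, min_segment_px = 1)
    skel_px <- which(net$skeleton)
    seg_px <- unlist(lapply(net$pixels, function(p)
      (p[, 2] - 1) * nrow(net$skeleton) + p[, 1]))
    junc_px <- unlist(lapply(net$junctions, function(p)
      (p[, 2] - 1) * nrow(net$skeleton) + p[, 1]))
    expect_setequal(c(seg_px, junc_px), skel_px)
    expect_equal(anyDuplicated(c(seg_px, junc_px)), 0L)
  }
})

test_that("adjacency is symmetric with a zero diagonal on all fixtures", {
  for (mask in list(y_mask(), h_mask(), grid_mask(3), star_mask(5))) {
    A <- as.matrix(skeletonize_and_segment(mask)$adjacency)
    expect_equal(A, t(A))
    expect_true(all(diag(A) == 0))
    expect_true(all(A %in% c(0, 1)))
  }
})

test_that("connectivity is invariant to translation and rotation", {
  base <- grid_mask(3)
  c0 <- connectivity(skeletonize_and_segment(base))
  # translate by padding
  pad <- matrix(FALSE, nrow(base) + 6, ncol(base) + 6)
  pad[4:(nrow(base) + 3), 6:(ncol(base) + 5)] <- base
  expect_equal(connectivity(skeletonize_and_segment(vein_mask(pad))), c0)
  # rotate 90 degrees
  rot <- t(unclass(h_mask()))[rev(seq_len(ncol(h_mask()))), ]
  expect_equal(connectivity(skeletonize_and_segment(vein_mask(rot))),
               connectivity(skeletonize_and_segment(h_mask())))
})

test_that("vein features behave on simple masks", {
  line <- bar_mask()
  netl <- skeletonize_and_segment(line)
  expect_equal(vein_features(line, netl)$areoles_per_area, 0)
  # single closed loop: one areole
  m <- matrix(FALSE, 12, 12)
  m[3, 3:10] <- TRUE; m[10, 3:10] <- TRUE; m[3:10, 3] <- TRUE; m[3:10, 10] <- TRUE
  loop <- vein_mask(m)
  netc <- skeletonize_and_segment(loop)
  expect_equal(vein_features(loop, netc)$n_areoles, 1)
  # vein density is skeleton length over area
  f <- vein_features(line, netl)
  expect_equal(f$vein_density, sum(netl$skeleton) / (11 * 21))
})

test_that("measure_thickness errors on an empty segment", {
  expect_error(measure_thickness(bar_mask(), matrix(nrow = 0, ncol = 2)),
               "no pixels")
})

test_that("mask IO round-trips through PNG", {
  mask <- grid_mask(3)
  tmp <- tempfile(fileext = ".png")
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), tmp)
  back <- read_vein_mask(tmp)
  expect_equal(unclass(back), unclass(mask), ignore_attr = TRUE)
})
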