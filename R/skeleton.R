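#' Topological thinning of a binary mask
#'
#' Zhang-Suen thinning, producing a one-pixel-wide, 8-connected medial
#' skeleton of the vein mask.  The skeleton is the substrate on which vein
#' segments, branching points and thickness are defined.
#'
#' @param mask a [vein_mask()] or logical matrix.
#' @return Logical matrix of the same shape; TRUE = skeleton pixel.
#' @export
skeletonize <- function(mask) {
  px <- mask != 0
  nr <- nrow(px); nc <- ncol(px)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- px
  shift <- function(p, dr, dc) p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours P2..P9 clockwise from north
      P2 <- shift(pad, -1, 0);  P3 <- shift(pad, -1, 1)
      P4 <- shift(pad, 0, 1);   P5 <- shift(pad, 1, 1)
      P6 <- shift(pad, 1, 0);   P7 <- shift(pad, 1, -1)
      P8 <- shift(pad, 0, -1);  P9 <- shift(pad, -1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
           (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      cur <- shift(pad, 0, 0)
      if (step == 1) {
        cond <- cur & B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        cond <- cur & B >= 2 & B <= 6 & A == 1 &
          !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      if (any(cond)) {
        changed <- TRUE
        inner <- pad[2:(nr + 1L), 2:(nc + 1L)]
        inner[cond] <- FALSE
        pad[2:(nr + 1L), 2:(nc + 1L)] <- inner
      }
    }
    if (!changed) break
  }
  prune_redundant(pad[2:(nr + 1L), 2:(nc + 1L)])
}

# Remove skeleton pixels that are 8-redundant: a non-terminal pixel whose
# skeleton neighbours form a single 8-connected component can be deleted
# without breaking connectivity (e.g. the apex pixel of a pure L-corner,
# whose arms also touch diagonally).  Straight lines, diagonal staircases and
# true junctions are untouched.
prune_redundant <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  repeat {
    removed <- FALSE
    idx <- which(sk)
    for (p in idx) {
      r <- ((p - 1L) %% nr) + 1L
      c <- ((p - 1L) %/% nr) + 1L
      nb <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && sk[r2, c2])
          nb <- rbind(nb, c(r2, c2))
      }
      if (is.null(nb) || nrow(nb) < 2) next
      if (neighbourhood_components(nb) == 1) {
        sk[r, c] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  sk
}

# number of 8-connected components among a small set of pixel coordinates
neighbourhood_components <- function(nb) {
  n <- nrow(nb)
  comp <- seq_len(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (max(abs(nb[i, ] - nb[j, ])) <= 1) {
      old <- comp[j]; comp[comp == old] <- comp[i]
    }
  }
  length(unique(comp))
}

#' Extract the vein-segment graph from a binarized vein mask
#'
#' The mask is thinned to a one-pixel skeleton; skeleton pixels with three or
#' more 8-connected skeleton neighbours are branching points, and touching
#' branching pixels are merged into a single junction cluster.  A vein segment
#' is a connected run of skeleton pixels between two junctions, or between a
#' junction and an ending point.  Per-segment thickness is twice the maximum
#' exact Euclidean distance-transform value over the segment's medial-axis
#' pixels.  Segments shorter than `min_segment_px` that touch a junction are
#' merged into their longest neighbouring segment (thinning can emit tiny
#' spurs near junctions).
#'
#' @param mask a [vein_mask()].
#' @param min_segment_px minimum segment length in pixels (default 3);
#'   shorter segments are merged into their longest neighbour.
#' @return A `vein_network` object: list with elements `segments` (data frame
#'   `id`, `n_pixels`, `thickness`, `degree`), `pixels` (list of (row, col)
#'   coordinate matrices), `endpoints` (list of 0-2 terminal coordinates),
#'   `junctions` (list of junction-cluster coordinate matrices),
#'   `seg_junctions` (list of junction ids touched by each segment),
#'   `adjacency` (sparse symmetric 0/1 Matrix), `n_branch_points`,
#'   `skeleton` (logical matrix), `dim`, `pixel_scale`.
#' @examples
#' m <- matrix(FALSE, 9, 9)
#' m[5, 2:8] <- TRUE; m[1:4, 5] <- TRUE   # a "T" junction
#' net <- skeletonize_and_segment(vein_mask(m))
#' net$segments
#' @export
skeletonize_and_segment <- function(mask, min_segment_px = 3) {
  if (!inherits(mask, "vein_mask")) mask <- vein_mask(mask)
  skel <- skeletonize(mask)
  if (!any(skel)) stop("skeleton is empty")
  nn <- neighbour_count8(skel)
  if (sum(skel) == 1L) {
    warning("skeleton is a single isolated pixel; returning one degenerate segment")
  }

  branch <- skel & nn >= 3L
  jlab <- label_components8(branch)
  njunc <- max(jlab)

  segpx <- skel & !branch
  slab <- label_components8(segpx)
  nseg <- max(slab)

  if (nseg == 0L) {
    # skeleton is a single junction blob: treat the whole skeleton as one
    # degenerate segment with no junctions
    slab <- label_components8(skel)
    nseg <- max(slab)
    jlab[] <- 0L
    njunc <- 0L
  }

  seg_pixels <- lapply(seq_len(nseg), function(s) which_coords(slab == s))

  # junction ids adjacent (8-neighbourhood) to each segment
  jcoords <- lapply(seq_len(njunc), function(j) which_coords(jlab == j))
  seg_junc <- lapply(seq_len(nseg), function(s) {
    pc <- seg_pixels[[s]]
    js <- integer(0)
    for (j in seq_len(njunc)) {
      if (coords_adjacent(pc, jcoords[[j]])) js <- c(js, j)
    }
    js
  })

  # merge too-short segments into their longest neighbour
  res <- merge_short_segments(seg_pixels, seg_junc, min_segment_px)
  seg_pixels <- res$pixels
  seg_junc <- res$junctions
  nseg <- length(seg_pixels)

  dt <- distance_transform(mask)
  thickness <- vapply(seg_pixels, function(pc) {
    2 * max(dt[pc])
  }, numeric(1))
  thickness <- pmax(thickness, 2)  # a vein is at least one pixel wide

  endpoints <- lapply(seg_pixels, function(pc) {
    if (nrow(pc) == 1L) return(pc)
    # terminal pixels: <= 1 neighbour within the segment
    deg <- within_degree(pc)
    pc[deg <= 1L, , drop = FALSE]
  })

  adjacency <- adjacency_from_junctions(seg_junc, nseg)

  net <- structure(list(
    segments = data.frame(id = seq_len(nseg),
                          n_pixels = vapply(seg_pixels, nrow, integer(1)),
                          thickness = thickness,
                          degree = Matrix::rowSums(adjacency)),
    pixels = seg_pixels,
    endpoints = endpoints,
    junctions = jcoords,
    seg_junctions = seg_junc,
    adjacency = adjacency,
    n_branch_points = njunc,
    skeleton = skel,
    dim = dim(mask),
    pixel_scale = attr(mask, "pixel_scale")
  ), class = "vein_network")
  net
}

# TRUE if any pixel of a is within the 8-neighbourhood of any pixel of b
coords_adjacent <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(FALSE)
  for (k in seq_len(nrow(b))) {
    if (any(abs(a[, 1] - b[k, 1]) <= 1 & abs(a[, 2] - b[k, 2]) <= 1))
      return(TRUE)
  }
  FALSE
}

# 8-neighbour degree of each pixel within a coordinate set
within_degree <- function(pc) {
  n <- nrow(pc)
  deg <- integer(n)
  for (i in seq_len(n)) {
    deg[i] <- sum(abs(pc[, 1] - pc[i, 1]) <= 1 & abs(pc[, 2] - pc[i, 2]) <= 1) - 1L
  }
  deg
}

merge_short_segments <- function(seg_pixels, seg_junc, min_segment_px) {
  repeat {
    sizes <- vapply(seg_pixels, nrow, integer(1))
    nseg <- length(seg_pixels)
    adj <- adjacency_from_junctions(seg_junc, nseg)
    short <- which(sizes < min_segment_px)
    merged <- FALSE
    for (s in short) {
      nb <- which(adj[s, ] > 0)
      if (!length(nb)) next
      tgt <- nb[which.max(sizes[nb])]
      seg_pixels[[tgt]] <- rbind(seg_pixels[[tgt]], seg_pixels[[s]])
      seg_junc[[tgt]] <- sort(unique(c(seg_junc[[tgt]], seg_junc[[s]])))
      seg_pixels[[s]] <- NULL
      seg_junc[[s]] <- NULL
      merged <- TRUE
      break  # indices shifted; restart scan
    }
    if (!merged) break
  }
  list(pixels = seg_pixels, junctions = seg_junc)
}

#' Adjacency matrix of a segmented vein network
#'
#' Two vein segments are neighbours (e_ij = 1) iff they touch a common
#' junction cluster.  The result is symmetric with a zero diagonal.
#'
#' @param seg_junctions list giving, per segment, the ids of the junction
#'   clusters it touches (as produced by [skeletonize_and_segment()]).
#' @param n number of segments.
#' @return Sparse symmetric 0/1 `Matrix` of dimension n x n.
#' @export
adjacency_from_junctions <- function(seg_junctions, n = length(seg_junctions)) {
  A <- Matrix::Matrix(0, n, n, sparse = TRUE)
  if (n >= 2) {
    all_j <- unique(unlist(seg_junctions))
    for (j in all_j) {
      segs <- which(vapply(seg_junctions, function(js) j %in% js, logical(1)))
      if (length(segs) >= 2) {
        pr <- utils::combn(segs, 2)
        for (k in seq_len(ncol(pr))) {
          A[pr[1, k], pr[2, k]] <- 1
          A[pr[2, k], pr[1, k]] <- 1
        }
      }
    }
  }
  methods::as(A, "generalMatrix")
}

#' Exact Euclidean distance transform of a vein mask
#'
#' For every foreground pixel, the Euclidean distance (in pixel units, between
#' pixel centres) to the nearest background pixel; 0 on background.
#'
#' @param mask a [vein_mask()] or logical matrix.
#' @return Numeric matrix of distances.
#' @export
distance_transform <- function(mask) {
  px <- mask != 0
  dt <- EBImage::distmap(matrix(as.numeric(px), nrow(px), ncol(px)),
                         metric = "euclidean")
  matrix(EBImage::imageData(dt), nrow(px), ncol(px))
}

#' Thickness of one vein segment
#'
#' Twice the maximum distance-transform value over the segment's medial-axis
#' (skeleton) pixels, i.e. twice the largest inscribed-circle radius along the
#' segment.  A single-pixel-wide vein with background on both sides has
#' distance 1 at its centre and thickness 2 by this definition.
#'
#' @param mask the full [vein_mask()] the segment was extracted from.
#' @param pixel_coords (row, col) matrix of the segment's skeleton pixels.
#' @return Thickness in pixels (scalar).
#' @export
measure_thickness <- function(mask, pixel_coords) {
  if (is.null(pixel_coords) || !nrow(pixel_coords))
    stop("segment has no pixels")
  dt <- distance_transform(mask)
  2 * max(dt[pixel_coords])
}

#' @export
print.vein_network <- function(x, ...) {
  cat(sprintf("vein network: %d segments, %d branching points, connectivity %.3f\n",
              nrow(x$segments), x$n_branch_points, connectivity(x)))
  cat(sprintf("  thickness (px): median %.1f, range [%.1f, %.1f]\n",
              median(x$segments$thickness), min(x$segments$thickness),
              max(x$segments$thickness)))
  invisible(x)
}

#' Degree of connectivity of a venation network
#'
#' The ratio of the number of branching points to the number of vein
#' segments, a standard summary of how connected a transport network is.
#'
#' @param network a `vein_network`.
#' @return Dimensionless ratio.
#' @seealso [connectivity_ratio()] for computing the ratio from counts alone.
#' @export
connectivity <- function(network) {
  connectivity_ratio(network$n_branch_points, nrow(network$segments))
}

#' Connectivity from branching-point and segment counts
#'
#' @param n_branch_points number (or mean number) of branching points.
#' @param n_segments number (or mean number) of vein segments.
#' @return `n_branch_points / n_segments`, vectorized.
#' @examples
#' connectivity_ratio(122.43, 244.14)  # a species-mean ratio
#' @export
connectivity_ratio <- function(n_branch_points, n_segments) {
  if (any(n_segments <= 0)) stop("n_segments must be positive")
  n_branch_points / n_segments
}

#' Venation features of a mask/network pair
#'
#' @param mask the [vein_mask()] the network was extracted from.
#' @param network the matching `vein_network`.
#' @return List with `connectivity` (branching points per segment),
#'   `vein_density` (skeleton length per image area, in 1/length units of
#'   `pixel_scale`), `areoles_per_area` (count of background regions fully
#'   enclosed by vein, per image area) and the raw `n_areoles`.
#' @export
vein_features <- function(mask, network) {
  if (!inherits(mask, "vein_mask")) mask <- vein_mask(mask)
  ps <- attr(mask, "pixel_scale")
  area <- nrow(mask) * ncol(mask) * ps^2
  skel_len <- sum(network$skeleton) * ps
  # areoles: background components (4-connected, the complement of an
  # 8-connected foreground) that do not touch the image border
  bg <- EBImage::imageData(EBImage::bwlabel(
    matrix(as.numeric(!(mask != 0)), nrow(mask), ncol(mask))))
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  n_areoles <- length(setdiff(unique(as.vector(bg)), c(0, border_labels)))
  list(connectivity = connectivity(network),
       vein_density = skel_len / area,
       areoles_per_area = n_areoles / area,
       n_areoles = n_areoles)
}
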