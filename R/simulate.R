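#' Simulate a vein-segment network
#'
#' Two generators for the spatial substrate of the survival models:
#' \describe{
#'   \item{lattice}{segments are the edges of a k x k grid of junctions
#'     (2k(k-1) segments); when an exact segment count `m` is requested the
#'     smallest sufficient lattice is built and random segments are pruned
#'     (keeping the segment graph connected) until `m` remain.  Thickness is
#'     lognormal.}
#'   \item{hierarchical}{recursive bifurcation: each branching adds child
#'     segments whose thickness tapers relative to the parent (parent always
#'     thicker), mimicking vein-order hierarchy; optional cross-links between
#'     same-depth segments emulate reticulation and raise connectivity.}
#' }
#'
#' @param m target number of segments (exact); alternatively give `k` for an
#'   unpruned k x k lattice.
#' @param kind "lattice" or "hierarchical".
#' @param k lattice side (junction count per side), overrides `m`.
#' @param cross_link_prob probability of a reticulating cross-link per
#'   same-depth segment pair (hierarchical mode; default 0.05).
#' @param thickness_base median thickness in pixels (default 6).
#' @param taper per-level thickness multiplier in hierarchical mode
#'   (default 0.7).
#' @param seed integer seed.
#' @return A `vein_network` object (graph-level: `segments`, `adjacency`,
#'   `n_branch_points`; lattice networks also carry `lattice` geometry for
#'   [rasterize_network()]).
#' @examples
#' net <- sim_vein_network(m = 40, kind = "lattice", seed = 1)
#' connectivity(net)
#' @export
sim_vein_network <- function(m = NULL, kind = c("lattice", "hierarchical"),
                             k = NULL, cross_link_prob = 0.05,
                             thickness_base = 6, taper = 0.7, seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "lattice") sim_lattice_network(m, k, thickness_base)
  else sim_hierarchical_network(m, cross_link_prob, thickness_base, taper)
}

sim_lattice_network <- function(m, k, thickness_base) {
  if (is.null(k)) {
    if (is.null(m)) stop("give `m` or `k`")
    if (m < 4) stop("lattice networks need at least 4 segments")
    k <- 2
    while (2 * k * (k - 1) < m) k <- k + 1
  }
  # nodes (junctions) on a k x k grid; segments are lattice edges
  node_id <- function(i, j) (j - 1L) * k + i
  edges <- NULL
  for (j in seq_len(k)) for (i in seq_len(k)) {
    if (i < k) edges <- rbind(edges, c(node_id(i, j), node_id(i + 1, j)))
    if (j < k) edges <- rbind(edges, c(node_id(i, j), node_id(i, j + 1)))
  }
  m0 <- nrow(edges)
  if (!is.null(m) && m0 < m) stop("lattice of side ", k, " has only ", m0, " segments")
  # prune random segments, keeping the segment (line) graph connected
  if (!is.null(m) && m0 > m) {
    for (drop in seq_len(m0 - m)) {
      ok <- FALSE
      for (try in seq_len(200)) {
        cand <- sample.int(nrow(edges), 1)
        trial <- edges[-cand, , drop = FALSE]
        if (segment_graph_connected(trial)) { edges <- trial; ok <- TRUE; break }
      }
      if (!ok) stop("could not prune lattice to ", m, " segments while staying connected")
    }
  }
  finish_node_network(edges, k,
                      thickness = pmax(stats::rlnorm(nrow(edges),
                                                     log(thickness_base), 0.3), 2))
}

# edges share a junction -> segment adjacency; connected?
segment_graph_connected <- function(edges) {
  A <- segment_adjacency_from_edges(edges)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::components(g)$no == 1
}

segment_adjacency_from_edges <- function(edges) {
  n <- nrow(edges)
  A <- Matrix::Matrix(0, n, n, sparse = TRUE)
  for (node in unique(as.vector(edges))) {
    segs <- which(edges[, 1] == node | edges[, 2] == node)
    if (length(segs) >= 2) {
      pr <- utils::combn(segs, 2)
      for (q in seq_len(ncol(pr))) {
        A[pr[1, q], pr[2, q]] <- 1
        A[pr[2, q], pr[1, q]] <- 1
      }
    }
  }
  methods::as(A, "generalMatrix")
}

finish_node_network <- function(edges, k, thickness) {
  n <- nrow(edges)
  A <- segment_adjacency_from_edges(edges)
  # branching points: junctions where >= 3 segments meet
  node_deg <- table(factor(as.vector(edges), levels = seq_len(k * k)))
  nb <- sum(node_deg >= 3)
  structure(list(
    segments = data.frame(id = seq_len(n), n_pixels = NA_integer_,
                          thickness = thickness,
                          degree = Matrix::rowSums(A)),
    pixels = NULL, endpoints = NULL, junctions = NULL, seg_junctions = NULL,
    adjacency = A, n_branch_points = nb, skeleton = NULL,
    dim = NULL, pixel_scale = 1,
    lattice = list(k = k, edges = edges)
  ), class = "vein_network")
}

sim_hierarchical_network <- function(m, cross_link_prob, thickness_base, taper) {
  if (is.null(m) || m < 2) stop("hierarchical networks need `m` >= 2")
  depth <- c(0)
  thickness <- c(thickness_base)
  parent <- c(NA_integer_)
  edge_list <- NULL        # adjacency pairs between segments
  n_branch <- 0L
  tips <- c(1L)
  while (length(depth) < m) {
    tip <- tips[1]; tips <- tips[-1]
    n_child <- min(2L, m - length(depth))
    ids <- length(depth) + seq_len(n_child)
    for (cid in ids) {
      depth <- c(depth, depth[tip] + 1L)
      thickness <- c(thickness,
                     thickness[tip] * taper * exp(runif(1, -0.1, 0.1)))
      parent <- c(parent, tip)
      edge_list <- rbind(edge_list, c(tip, cid))
    }
    if (n_child == 2L) edge_list <- rbind(edge_list, c(ids[1], ids[2]))
    n_branch <- n_branch + 1L
    tips <- c(tips, ids)
    if (!length(tips)) break
  }
  n <- length(depth)
  # reticulating cross-links between same-depth, not-yet-adjacent segments
  for (d in unique(depth)) {
    at <- which(depth == d)
    if (length(at) >= 2) {
      pr <- utils::combn(at, 2)
      for (q in seq_len(ncol(pr))) {
        i <- pr[1, q]; j <- pr[2, q]
        if (parent[i] %in% c(parent[j]) ||
            any(edge_list[, 1] == i & edge_list[, 2] == j)) next
        if (runif(1) < cross_link_prob) {
          edge_list <- rbind(edge_list, c(i, j))
          n_branch <- n_branch + 1L
        }
      }
    }
  }
  A <- Matrix::Matrix(0, n, n, sparse = TRUE)
  for (q in seq_len(nrow(edge_list))) {
    A[edge_list[q, 1], edge_list[q, 2]] <- 1
    A[edge_list[q, 2], edge_list[q, 1]] <- 1
  }
  A <- methods::as(A, "generalMatrix")
  structure(list(
    segments = data.frame(id = seq_len(n), n_pixels = NA_integer_,
                          thickness = pmax(thickness, 2),
                          degree = Matrix::rowSums(A), depth = depth,
                          parent = parent),
    pixels = NULL, endpoints = NULL, junctions = NULL, seg_junctions = NULL,
    adjacency = A, n_branch_points = n_branch, skeleton = NULL,
    dim = NULL, pixel_scale = 1
  ), class = "vein_network")
}

#' Rasterize a simulated lattice network to a vein mask
#'
#' Draws each lattice segment as a one-pixel-wide line between its junction
#' pixels, giving a mask whose skeleton is the drawing itself.  Useful for
#' exercising the image pipeline on networks with known structure.
#'
#' @param network a lattice network from [sim_vein_network()].
#' @param spacing junction spacing in pixels (default 12).
#' @param margin border margin in pixels (default 3).
#' @return A [vein_mask()].
#' @export
rasterize_network <- function(network, spacing = 12, margin = 3) {
  lat <- network$lattice
  if (is.null(lat)) stop("rasterization is implemented for lattice networks")
  k <- lat$k
  size <- margin * 2 + (k - 1) * spacing + 1
  px <- matrix(FALSE, size, size)
  node_rc <- function(id) {
    i <- ((id - 1L) %% k) + 1L
    j <- ((id - 1L) %/% k) + 1L
    c(margin + 1 + (i - 1) * spacing, margin + 1 + (j - 1) * spacing)
  }
  for (q in seq_len(nrow(lat$edges))) {
    a <- node_rc(lat$edges[q, 1]); b <- node_rc(lat$edges[q, 2])
    if (a[1] == b[1]) px[a[1], a[2]:b[2]] <- TRUE
    else px[a[1]:b[1], a[2]] <- TRUE
  }
  vein_mask(px)
}

#' Simulate frailty fields with IID or ICAR covariance
#'
#' IID: independent N(0, tau2).  ICAR: a zero-mean Gaussian field with
#' covariance `tau2 * pseudoinverse(L)` (L the graph Laplacian), drawn per
#' connected component and summing to zero within each component by
#' construction.
#'
#' @param network a `vein_network` or adjacency matrix.
#' @param tau2 variance parameter (> 0).
#' @param kind "iid" or "icar".
#' @param seed integer seed.
#' @return Numeric frailty vector of length m.
#' @export
sim_frailties <- function(network, tau2, kind = c("iid", "icar"), seed = 1) {
  kind <- match.arg(kind)
  if (tau2 <= 0) stop("`tau2` must be positive")
  A <- as_adjacency(network)
  m <- nrow(A)
  set.seed(seed)
  if (kind == "iid") return(rnorm(m, 0, sqrt(tau2)))
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)$membership
  v <- numeric(m)
  for (c0 in unique(comp)) {
    sel <- which(comp == c0)
    if (length(sel) == 1) { v[sel] <- 0; next }
    Ac <- as.matrix(A[sel, sel])
    L <- diag(rowSums(Ac)) - Ac
    ed <- eigen(L, symmetric = TRUE)
    nz <- ed$values > max(ed$values) * 1e-10
    z <- rnorm(sum(nz))
    v[sel] <- ed$vectors[, nz, drop = FALSE] %*% (z * sqrt(tau2 / ed$values[nz]))
  }
  v
}

# closed-form inverse of the proportional-odds Weibull survival function:
# solve S_i(t) = u for t
po_weibull_quantile <- function(u, eta, theta1, theta2) {
  eta <- pmin(pmax(eta, -30), 30)
  a <- exp(-eta)
  S0 <- u / (a - (a - 1) * u)
  pmax((-log(S0) / exp(theta1))^(1 / theta2), 1e-12)
}

draw_event_table <- function(eta, theta1, theta2, censor_time,
                             segment = seq_along(eta)) {
  u <- runif(length(eta))
  t <- po_weibull_quantile(u, eta, theta1, theta2)
  delta <- as.integer(t <= censor_time)
  event_table(delta, ifelse(delta == 1L, t, censor_time), segment = segment)
}

#' Simulate right-censored embolism events from the survival model
#'
#' Event times are drawn by inverting the proportional-odds Weibull survival
#' function in closed form (one uniform draw per segment); segments whose
#' latent time exceeds `censor_time` are administratively right-censored at
#' it.
#'
#' @param network a `vein_network` (used for segment count, ids and default
#'   thickness).
#' @param frailty per-segment frailty vector (e.g. from [sim_frailties()]).
#' @param theta1,theta2 Weibull base parameters.
#' @param beta thickness coefficient (default 0: no thickness effect).
#' @param thickness covariate; defaults to `network$segments$thickness`.
#' @param standardize_thickness z-score the thickness before applying `beta`
#'   (default TRUE, matching [veinfrail()]).
#' @param censor_time end-of-observation |Psi| (MPa, > 0).
#' @param seed integer seed.
#' @return An [event_table()].
#' @export
sim_events <- function(network, frailty, theta1, theta2, beta = 0,
                       thickness = NULL, standardize_thickness = TRUE,
                       censor_time, seed = 1) {
  if (censor_time <= 0) stop("`censor_time` must be positive")
  m <- nrow(network$segments)
  if (length(frailty) != m) stop("`frailty` length must match the network")
  x <- numeric(m)
  if (beta != 0) {
    x <- if (is.null(thickness)) network$segments$thickness else thickness
    if (standardize_thickness) x <- (x - mean(x)) / sd(x)
  }
  set.seed(seed)
  draw_event_table(frailty + beta * x, theta1, theta2, censor_time,
                   segment = network$segments$id)
}

#' Render simulated events as an embolism frame stack
#'
#' Builds, from an image-derived network and an event table over it, a frame
#' stack with one frame per distinct event time (|Psi| descending as frames
#' advance) plus a final, possibly empty, frame at the censoring time.  Each
#' segment is rendered with its skeleton pixels that are unambiguously its
#' own (outside every other segment's dilation radius), so that
#' [map_events()] with the spillover filter off reproduces the event table
#' exactly.
#'
#' @param events an [event_table()] aligned with `network`.
#' @param network a `vein_network` with pixel coordinates (i.e. extracted
#'   from a mask via [skeletonize_and_segment()]).
#' @return A [frame_stack()].
#' @export
render_frames <- function(events, network) {
  if (is.null(network$pixels))
    stop("`network` must carry pixel coordinates (extracted from a mask)")
  m <- nrow(network$segments)
  radius <- ceiling(network$segments$thickness / 2)
  own_px <- lapply(seq_len(m), function(i) {
    pc <- network$pixels[[i]]
    keep <- rep(TRUE, nrow(pc))
    for (j in seq_len(m)) {
      if (j == i) next
      d2 <- cross_dist2(pc, network$pixels[[j]])
      keep <- keep & apply(d2 > radius[j]^2, 1, all)
    }
    pc[keep, , drop = FALSE]
  })
  if (any(vapply(own_px, nrow, integer(1)) == 0))
    stop("some segments have no pixels exclusively their own; cannot render")
  ev_times <- sort(unique(events$time[events$delta == 1]))
  censor <- attr(events, "censor_time")
  frame_times <- unique(c(ev_times, censor))
  frames <- lapply(frame_times, function(tt) {
    f <- matrix(FALSE, network$dim[1], network$dim[2])
    for (i in which(events$delta == 1 & events$time == tt)) f[own_px[[i]]] <- TRUE
    f
  })
  frame_stack(frames, -frame_times)
}
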