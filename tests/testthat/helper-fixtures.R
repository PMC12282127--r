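# Raster fixtures built in code.

# straight horizontal bar, `width` pixels thick
bar_mask <- function(nr = 11, nc = 21, width = 1, row = ceiling(nr / 2)) {
  m <- matrix(FALSE, nr, nc)
  m[row:(row + width - 1), 2:(nc - 1)] <- TRUE
  vein_mask(m)
}

# three one-pixel arms meeting at a single central pixel
y_mask <- function(arm = 6) {
  n <- 2 * arm + 3
  c0 <- ceiling(n / 2)
  m <- matrix(FALSE, n, n)
  m[(c0 - arm):c0, c0] <- TRUE                       # north arm
  for (k in 1:arm) {                                 # two diagonal arms
    m[c0 + k, c0 - k] <- TRUE
    m[c0 + k, c0 + k] <- TRUE
  }
  m[c0, c0] <- TRUE
  vein_mask(m)
}

# "H": two vertical bars joined by a crossbar; 2 junctions, 5 segments
h_mask <- function(arm = 6, gap = 8) {
  nr <- 2 * arm + 3
  nc <- gap + 5
  m <- matrix(FALSE, nr, nc)
  mid <- arm + 2
  m[2:(nr - 1), 2] <- TRUE
  m[2:(nr - 1), nc - 1] <- TRUE
  m[mid, 2:(nc - 1)] <- TRUE
  vein_mask(m)
}

# star with k one-pixel arms radiating from the centre (k in 3..8)
star_mask <- function(k, arm = 6) {
  n <- 2 * arm + 5
  c0 <- ceiling(n / 2)
  dirs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))[seq_len(k), , drop = FALSE]
  m <- matrix(FALSE, n, n)
  m[c0, c0] <- TRUE
  for (d in seq_len(k)) for (s in 1:arm)
    m[c0 + s * dirs[d, 1], c0 + s * dirs[d, 2]] <- TRUE
  vein_mask(m)
}

# 3x3 grid of junctions joined by one-pixel lines (grid-graph raster)
grid_mask <- function(k = 3, spacing = 8, margin = 3) {
  size <- 2 * margin + (k - 1) * spacing + 1
  m <- matrix(FALSE, size, size)
  at <- margin + 1 + (seq_len(k) - 1) * spacing
  for (a in at) {
    m[a, at[1]:at[k]] <- TRUE
    m[at[1]:at[k], a] <- TRUE
  }
  vein_mask(m)
}

# filled disk of radius r (pixel-centre metric)
disk_mask <- function(r, pad = 3) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  m <- outer(seq_len(n), seq_len(n),
             function(i, j) (i - c0)^2 + (j - c0)^2 <= r^2)
  vein_mask(m)
}

# quick fit on simulated lattice data, reused by several tests
quick_fit <- function(m = 60, model = "spatial-dependent", tau2 = 1,
                      prior_kind = "icar", beta = 0, theta1 = 0, theta2 = 1.5,
                      censor_time = 3, seed = 1, iter = 1500, burnin = 750,
                      thin = 2, ...) {
  net <- sim_vein_network(m = m, kind = "lattice", seed = seed)
  fr <- sim_frailties(net, tau2 = tau2, kind = prior_kind, seed = seed + 1)
  ev <- sim_events(net, fr, theta1 = theta1, theta2 = theta2, beta = beta,
                   censor_time = censor_time, seed = seed + 2)
  fit <- suppressWarnings(veinfrail(ev, net, model = model, iter = iter,
                                    burnin = burnin, thin = thin,
                                    seed = seed, ...))
  list(net = net, frailty = fr, events = ev, fit = fit)
}

# administrative censoring of a fully observed event table at the q-th
# quantile of its latent times (used for stated-censoring experiments)
censor_at_quantile <- function(latent, q) {
  cens <- unname(quantile(latent$time, q, type = 1))
  event_table(as.integer(latent$time <= cens),
              ifelse(latent$time <= cens, latent$time, cens),
              segment = latent$segment)
}

# contract degree-2 junctions of a lattice segment graph: merge the two edge
# segments meeting at each corner node into one vertex of the reference graph
contract_corner_segments <- function(net) {
  edges <- net$lattice$edges
  k <- net$lattice$k
  node_deg <- table(factor(as.vector(edges), levels = seq_len(k * k)))
  corner_nodes <- as.integer(names(node_deg)[node_deg == 2])
  g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
  member <- seq_len(nrow(edges))
  for (cn in corner_nodes) {
    segs <- which(edges[, 1] == cn | edges[, 2] == cn)
    member[member == member[segs[2]]] <- member[segs[1]]
  }
  # remove the edge between merged pairs, then contract
  cg <- igraph::contract(g, match(member, unique(member)))
  igraph::simplify(cg)
}
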