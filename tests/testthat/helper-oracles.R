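# Independent oracles used across the suite.  These are deliberately written
# as naive brute-force / closed-form computations, sharing no code with the
# package internals they check.

# exhaustive nearest-background Euclidean distance for every foreground pixel
brute_force_edt <- function(px) {
  bg <- which(!px, arr.ind = TRUE)
  fg <- which(px, arr.ind = TRUE)
  out <- matrix(0, nrow(px), ncol(px))
  for (k in seq_len(nrow(fg))) {
    r <- fg[k, 1]; c <- fg[k, 2]
    d <- sqrt((bg[, 1] - r)^2 + (bg[, 2] - c)^2)
    out[r, c] <- min(d)
  }
  out
}

# naive product-limit estimator (no confidence band)
brute_force_km <- function(time, delta) {
  ut <- sort(unique(time[delta == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (k in seq_along(ut)) {
    n_risk <- sum(time >= ut[k])
    n_event <- sum(time == ut[k] & delta == 1)
    s <- s * (1 - n_event / n_risk)
    surv[k] <- s
  }
  data.frame(time = ut, surv = surv)
}

# log-density of the constrained ICAR field: zero-mean Gaussian with
# covariance tau2 * pseudoinverse(Laplacian), via explicit pseudo-inverse
dense_icar_oracle <- function(v, tau2, A) {
  A <- as.matrix(A)
  L <- diag(rowSums(A)) - A
  ed <- eigen(L, symmetric = TRUE)
  nz <- ed$values > max(ed$values) * 1e-10
  rank <- sum(nz)
  # project v onto the span of the non-null eigenvectors
  z <- t(ed$vectors[, nz, drop = FALSE]) %*% v
  sum(dnorm(z, 0, sqrt(tau2 / ed$values[nz]), log = TRUE))
}

# exhaustive pairwise concordance count
brute_force_cindex <- function(scores, time, delta) {
  num <- den <- 0
  n <- length(scores)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (delta[i] == 1 && time[i] < time[j]) {
      den <- den + 1
      if (scores[i] > scores[j]) num <- num + 1
    }
  }
  num / den
}

# a small family of connected graphs up to n nodes, as adjacency matrices
graph_family <- function(max_n = 12, seed = 42) {
  set.seed(seed)
  gs <- list()
  add <- function(g) gs[[length(gs) + 1]] <<- as.matrix(igraph::as_adjacency_matrix(g))
  for (n in c(2, 3, 5, 8, 12)) add(igraph::make_ring(n))
  for (n in c(2, 4, 7, 12)) add(igraph::make_lattice(c(n, 1)))  # paths
  for (n in c(4, 6, 10)) add(igraph::make_star(n, mode = "undirected"))
  add(igraph::make_full_graph(5))
  add(igraph::make_lattice(c(3, 4)))
  for (n in c(6, 9, 12)) {
    repeat {
      g <- igraph::sample_gnp(n, 0.4)
      if (igraph::is_connected(g)) { add(g); break }
    }
  }
  gs
}
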