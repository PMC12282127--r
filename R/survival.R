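#' Weibull base survival function
#'
#' The leaf-level temporal backbone of the embolism survival models:
#' `S0(t) = exp(-exp(theta1) * t^theta2)`, where t is the magnitude of water
#' potential |Psi| in MPa.  `theta1` sets the scale (more negative = slower
#' progression and more spread), `theta2` the shape (positive values mean
#' segments become more likely to embolize as desiccation progresses).
#'
#' @param t non-negative time(s), |Psi| in MPa.
#' @param theta1 log-scale parameter (unconstrained real).
#' @param theta2 shape parameter (> 0 for a proper survival law).
#' @return Survival probability in (0, 1]; equals 1 at t = 0.
#' @examples
#' base_survival(log(2), 0, 1)  # exponential special case: 0.5
#' @export
base_survival <- function(t, theta1, theta2) {
  if (any(t < 0)) stop("`t` must be non-negative")
  exp(-exp(theta1) * t^theta2)
}

#' Proportional-odds segment survival function
#'
#' Per-segment survival under the frailty model: the frailty (plus optional
#' thickness effect) multiplies the odds of survival uniformly over time,
#' \deqn{S_i(t) = \frac{e^{-\eta_i} S_0(t)}{1 + (e^{-\eta_i} - 1) S_0(t)},}
#' with linear predictor `eta = v_i` or `eta = v_i + beta * x_i`.  Larger
#' `eta` (higher frailty) means earlier embolism; `eta = 0` recovers the base
#' survival.
#'
#' @inheritParams base_survival
#' @param eta linear predictor (frailty, plus thickness term if used);
#'   recycled against `t`.
#' @return Survival probability; a valid non-increasing survival function of
#'   `t` for every fixed `eta`.
#' @export
segment_survival <- function(t, eta, theta1, theta2) {
  S0 <- base_survival(t, theta1, theta2)
  eta <- pmin(pmax(eta, -30), 30)
  a <- exp(-eta)
  a * S0 / (1 + (a - 1) * S0)
}

#' Event density of the proportional-odds segment survival model
#'
#' The closed-form density `f_i(t) = -dS_i/dt`:
#' \deqn{f_i(t) = \frac{e^{-\eta_i} f_0(t)}{(1 + (e^{-\eta_i}-1) S_0(t))^2},}
#' where `f0` is the Weibull base density.
#'
#' @inheritParams segment_survival
#' @return Density value(s), non-negative.
#' @export
segment_density <- function(t, eta, theta1, theta2) {
  if (any(t < 0)) stop("`t` must be non-negative")
  S0 <- base_survival(t, theta1, theta2)
  f0 <- exp(theta1) * theta2 * t^(theta2 - 1) * S0
  eta <- pmin(pmax(eta, -30), 30)
  a <- exp(-eta)
  a * f0 / (1 + (a - 1) * S0)^2
}

#' Censored-data log-likelihood of the frailty survival model
#'
#' Sum over segments of `delta_i * log f_i(t_i) + (1 - delta_i) * log
#' S_i(t_i)`; both observed and right-censored segments contribute.  Returns
#' `-Inf` (never an error) when the likelihood underflows.
#'
#' @param events an [event_table()] (or data.frame with `delta`, `time`).
#' @param frailty per-segment frailty vector v.
#' @param theta1,theta2 Weibull base parameters.
#' @param beta thickness regression coefficient (default 0).
#' @param thickness per-segment thickness covariate x (required if `beta`
#'   is nonzero).
#' @return Scalar log-likelihood.
#' @export
loglik_embolism <- function(events, frailty, theta1, theta2, beta = 0,
                            thickness = NULL) {
  m <- nrow(events)
  if (length(frailty) != m) stop("`frailty` length must match `events`")
  x <- if (is.null(thickness)) numeric(m) else thickness
  if (beta != 0 && is.null(thickness)) stop("`thickness` required when beta != 0")
  eta <- frailty + beta * x
  lf <- log(segment_density(events$time, eta, theta1, theta2))
  ls <- log(segment_survival(events$time, eta, theta1, theta2))
  ll <- sum(ifelse(events$delta == 1, lf, ls))
  if (!is.finite(ll)) -Inf else ll
}

#' IID Gaussian log-prior for frailties
#'
#' Independent zero-mean Gaussian frailties with variance `tau2` (the
#' spatial-independent model's prior).
#'
#' @param v frailty vector.
#' @param tau2 variance (> 0); its inverse is the spatial dependence
#'   parameter reported by the models.
#' @return Scalar log-density.
#' @export
iid_log_prior <- function(v, tau2) {
  if (!is.numeric(tau2) || length(tau2) != 1 || tau2 <= 0)
    stop("`tau2` must be a single positive number")
  sum(dnorm(v, 0, sqrt(tau2), log = TRUE))
}

#' ICAR log-prior for frailties on the vein adjacency graph
#'
#' The intrinsic conditionally autoregressive prior: conditionally, each
#' frailty is Gaussian around the mean of its neighbours with variance
#' `tau2 / e_i+`.  The joint (improper) density has the pairwise-difference
#' form `-(1/(2 tau2)) * sum_(edges) (v_i - v_j)^2`; the value returned here
#' is the proper density of the constrained field on the per-component
#' sum-to-zero subspace, i.e. the zero-mean Gaussian with covariance
#' `tau2 * pseudoinverse(L)` where L is the graph Laplacian.
#'
#' @param v frailty vector (should sum to ~0 within each connected
#'   component; the density is evaluated at the projection regardless).
#' @param tau2 conditional variance parameter (> 0).
#' @param adjacency symmetric 0/1 adjacency matrix (dense or sparse).
#' @return Scalar log-density.
#' @export
icar_log_prior <- function(v, tau2, adjacency) {
  if (!is.numeric(tau2) || length(tau2) != 1 || tau2 <= 0)
    stop("`tau2` must be a single positive number")
  A <- as.matrix(adjacency)
  m <- length(v)
  if (!all(dim(A) == m)) stop("adjacency dimension does not match `v`")
  deg <- rowSums(A)
  if (any(deg == 0))
    stop("ICAR prior undefined for isolated segments (degree 0)")
  L <- diag(deg) - A
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  nz <- ev[ev > max(ev) * 1e-10]
  rank <- length(nz)
  q <- as.numeric(crossprod(v, L %*% v))
  -0.5 * rank * log(2 * pi * tau2) + 0.5 * sum(log(nz)) - q / (2 * tau2)
}
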