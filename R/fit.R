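#' Prior settings for the embolism survival models
#'
#' Hyperpriors: `theta1 ~ N(0, 10^2)`, `log theta2 ~ N(0, 1.5^2)`,
#' `beta ~ N(0, 10^2)` and the precision `tau^-2 ~ Gamma(shape 1, rate
#' 0.01)` — weakly informative on the scale of |Psi| in MPa.
#'
#' @param theta1_mean,theta1_sd Gaussian prior on the Weibull log-scale.
#' @param log_theta2_mean,log_theta2_sd Gaussian prior on log shape.
#' @param beta_mean,beta_sd Gaussian prior on the thickness coefficient.
#' @param prec_shape,prec_rate Gamma prior on the frailty precision tau^-2.
#' @return Named list of hyperparameters.
#' @export
veinfrail_priors <- function(theta1_mean = 0, theta1_sd = 10,
                             log_theta2_mean = 0, log_theta2_sd = 1.5,
                             beta_mean = 0, beta_sd = 10,
                             prec_shape = 1, prec_rate = 0.01) {
  list(theta1_mean = theta1_mean, theta1_sd = theta1_sd,
       log_theta2_mean = log_theta2_mean, log_theta2_sd = log_theta2_sd,
       beta_mean = beta_mean, beta_sd = beta_sd,
       prec_shape = prec_shape, prec_rate = prec_rate)
}

# normalize a network argument to a sparse symmetric adjacency matrix
as_adjacency <- function(network, m = NULL) {
  A <- if (inherits(network, "vein_network")) network$adjacency
       else if (inherits(network, "igraph")) igraph::as_adjacency_matrix(network)
       else network
  if (is.null(A)) {
    if (is.null(m)) stop("a network (or adjacency matrix) is required")
    return(Matrix::Matrix(0, m, m, sparse = TRUE))
  }
  A <- methods::as(Matrix::Matrix(A, sparse = TRUE), "generalMatrix")
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (!Matrix::isSymmetric(A)) stop("adjacency must be symmetric")
  if (any(Matrix::diag(A) != 0)) stop("adjacency must have a zero diagonal")
  A
}

#' Fit a Bayesian proportional-odds spatial survival model for embolism
#'
#' Fits, by Metropolis-within-Gibbs MCMC, the frailty survival model in which
#' each vein segment's odds of remaining water-filled are the Weibull base
#' odds scaled by `exp(-eta_i)`, with `eta_i = v_i` (spatial-independent and
#' spatial-dependent models) or `eta_i = v_i + beta * x_i` (spatial-thickness
#' model).  The frailty prior is IID Gaussian for the spatial-independent
#' model and ICAR on the vein adjacency graph for the other two; under ICAR
#' the frailties are recentred to sum to zero within each connected component
#' every sweep.  Both observed and right-censored segments enter the
#' likelihood.
#'
#' @param events an [event_table()] (or data.frame with `delta`, `time`);
#'   must contain at least one observed event.
#' @param network a `vein_network`, igraph graph, or adjacency matrix.
#'   Required for the ICAR variants; ignored (beyond segment count checks)
#'   for the spatial-independent model.
#' @param model `"spatial-independent"` (IID frailty prior),
#'   `"spatial-dependent"` (ICAR prior) or `"spatial-thickness"` (ICAR prior
#'   plus vein-thickness covariate).  Short forms `"independent"`,
#'   `"dependent"`, `"thickness"` are accepted.
#' @param thickness per-segment thickness covariate; taken from
#'   `network$segments$thickness` when NULL and the model needs it.
#' @param standardize_thickness z-score the thickness within the leaf before
#'   it enters the linear predictor (default TRUE), making `beta` comparable
#'   across leaves and species.
#' @param chains number of MCMC chains (default 2; at least 2 needed for
#'   split-Rhat).
#' @param iter total iterations per chain (default 10000).
#' @param burnin discarded initial iterations (default `iter / 2`).
#' @param thin thinning interval (default 5).
#' @param seed integer seed; fits are deterministic given (data, model,
#'   seed, chains, iter).
#' @param priors hyperparameters, see [veinfrail_priors()].
#' @param rhat_threshold flag non-convergence when any split-Rhat exceeds
#'   this (default 1.05); a warning flag is recorded, never an error.
#' @return Object of class `veinfrail` with components `draws` (data frame:
#'   chain, iter, theta1, theta2, beta, tau2, loglik), `v` (draws x segments
#'   frailty matrix), `model`, `data`, `diagnostics` (Rhat, ESS, acceptance
#'   rates, `converged`), `priors`, `seed`.
#' @examples
#' net <- sim_vein_network(40, kind = "lattice", seed = 1)
#' fr  <- sim_frailties(net, tau2 = 0.5, kind = "icar", seed = 2)
#' ev  <- sim_events(net, fr, theta1 = 0, theta2 = 1.5, censor_time = 3, seed = 3)
#' fit <- veinfrail(ev, net, model = "spatial-dependent",
#'                  iter = 400, burnin = 200, thin = 2, seed = 4)
#' coef(fit)
#' @export
veinfrail <- function(events, network = NULL,
                      model = c("spatial-independent", "spatial-dependent",
                                "spatial-thickness"),
                      thickness = NULL, standardize_thickness = TRUE,
                      chains = 2, iter = 10000, burnin = iter / 2, thin = 5,
                      seed = 1, priors = veinfrail_priors(),
                      rhat_threshold = 1.05) {
  model <- match_model(model)
  if (!inherits(events, "data.frame") || !all(c("delta", "time") %in% names(events)))
    stop("`events` must be an event_table (columns delta, time)")
  m <- nrow(events)
  if (sum(events$delta) < 1) stop("at least one observed event is required")
  if (any(events$time <= 0)) stop("event times must be positive")
  icar <- model != "spatial-independent"
  use_beta <- model == "spatial-thickness"

  A <- as_adjacency(network, m = m)
  if (nrow(A) != m) stop("network has ", nrow(A), " segments but events have ", m)
  deg <- Matrix::rowSums(A)
  if (icar && any(deg == 0))
    stop("ICAR models require every segment to have at least one neighbour")

  x <- numeric(m)
  if (use_beta) {
    if (is.null(thickness) && inherits(network, "vein_network"))
      thickness <- network$segments$thickness
    if (is.null(thickness)) stop("`thickness` required for the spatial-thickness model")
    if (length(thickness) != m) stop("`thickness` length must match `events`")
    x <- as.numeric(thickness)
    if (standardize_thickness) {
      if (sd(x) == 0) stop("thickness has zero variance; cannot standardize")
      x <- (x - mean(x)) / sd(x)
    }
  }

  # CSR neighbour lists and connected components
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)$membership - 1L
  ncomp <- max(comp) + 1L
  nbrs <- lapply(seq_len(m), function(i) which(A[i, ] != 0) - 1L)
  adj_ptr <- c(0L, cumsum(lengths(nbrs)))
  adj_idx <- as.integer(unlist(nbrs))

  burnin <- as.integer(burnin); iter <- as.integer(iter); thin <- as.integer(thin)
  if (burnin >= iter) stop("`burnin` must be smaller than `iter`")

  set.seed(seed)
  chain_res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    v0 <- rnorm(m, 0, 0.2)
    if (icar) for (c0 in unique(comp)) {
      sel <- comp == c0; v0[sel] <- v0[sel] - mean(v0[sel])
    }
    init <- c(rnorm(1, 0, 0.5), rnorm(1, 0, 0.3),
              if (use_beta) rnorm(1, 0, 0.5) else 0,
              1, v0)
    chain_res[[ch]] <- mcmc_chain(
      as.integer(events$delta), as.numeric(events$time), x, use_beta,
      adj_ptr, adj_idx, icar, as.integer(comp), as.integer(ncomp),
      priors, iter, burnin, thin, init)
  }

  nkeep <- length(chain_res[[1]]$theta1)
  draws <- do.call(rbind, lapply(seq_len(chains), function(ch) {
    r <- chain_res[[ch]]
    data.frame(chain = ch, iter = seq_len(nkeep), theta1 = r$theta1,
               theta2 = r$theta2, beta = r$beta, tau2 = r$tau2,
               loglik = r$loglik)
  }))
  v <- do.call(rbind, lapply(chain_res, `[[`, "v"))

  pars <- c("theta1", "theta2", "tau2", if (use_beta) "beta")
  diag_tab <- diagnose_chains(draws, pars, chains)
  converged <- all(is.finite(diag_tab$rhat)) && all(diag_tab$rhat < rhat_threshold)
  if (!converged)
    warning("MCMC convergence flag: max split-Rhat ",
            sprintf("%.3f", max(diag_tab$rhat, na.rm = TRUE)),
            " exceeds ", rhat_threshold)

  structure(list(
    draws = draws, v = v, model = model,
    data = list(events = events, adjacency = A, thickness = x,
                use_thickness = use_beta,
                thickness_raw = if (use_beta) thickness else NULL),
    diagnostics = list(
      table = diag_tab, converged = converged,
      accept_frailty = mean(vapply(chain_res, `[[`, numeric(1), "accept_frailty")),
      accept_global = mean(vapply(chain_res, `[[`, numeric(1), "accept_global"))),
    chains = chains, iter = iter, burnin = burnin, thin = thin,
    priors = priors, seed = seed
  ), class = "veinfrail")
}

match_model <- function(model) {
  model <- model[1]
  full <- c(independent = "spatial-independent",
            dependent = "spatial-dependent",
            thickness = "spatial-thickness")
  if (model %in% full) return(model)
  if (model %in% names(full)) return(full[[model]])
  stop("unknown model: ", model,
       " (use spatial-independent / spatial-dependent / spatial-thickness)")
}

# split-Rhat and effective sample size per scalar parameter
diagnose_chains <- function(draws, pars, chains) {
  out <- data.frame(parameter = pars, rhat = NA_real_, ess = NA_real_)
  for (k in seq_along(pars)) {
    xs <- lapply(seq_len(chains), function(ch) draws[[pars[k]]][draws$chain == ch])
    out$rhat[k] <- split_rhat(xs)
    out$ess[k] <- sum(vapply(xs, function(x) {
      as.numeric(coda::effectiveSize(coda::mcmc(x)))
    }, numeric(1)))
  }
  out
}

split_rhat <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(x) {
    n <- length(x) %/% 2
    list(x[seq_len(n)], x[(length(x) - n + 1):length(x)])
  }), recursive = FALSE)
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.veinfrail <- function(x, ...) {
  cat(sprintf("Proportional-odds spatial survival model (%s)\n", x$model))
  cat(sprintf("  %d vein segments, %d events, %d chains x %d kept draws\n",
              nrow(x$data$events), sum(x$data$events$delta), x$chains,
              sum(x$draws$chain == 1)))
  cm <- coef(x)
  cat("  posterior means: ",
      paste(sprintf("%s = %.3f", names(cm), cm), collapse = ", "), "\n")
  if (!x$diagnostics$converged)
    cat("  WARNING: convergence flag raised (split-Rhat above threshold)\n")
  invisible(x)
}

#' @export
summary.veinfrail <- function(object, level = 0.95, ...) {
  a <- (1 - level) / 2
  pars <- c("theta1", "theta2", "tau2", if (object$data$use_thickness) "beta")
  tab <- do.call(rbind, lapply(pars, function(p) {
    d <- object$draws[[p]]
    data.frame(parameter = p, mean = mean(d), sd = sd(d),
               lower = quantile(d, a), upper = quantile(d, 1 - a))
  }))
  # report the spatial dependence parameter (precision) alongside tau2
  prec <- 1 / object$draws$tau2
  tab <- rbind(tab, data.frame(parameter = "precision", mean = mean(prec),
                               sd = sd(prec), lower = quantile(prec, a),
                               upper = quantile(prec, 1 - a)))
  rownames(tab) <- NULL
  tab <- merge(tab, object$diagnostics$table, by = "parameter",
               all.x = TRUE, sort = FALSE)
  out <- list(model = object$model, table = tab,
              accept = c(frailty = object$diagnostics$accept_frailty,
                         global = object$diagnostics$accept_global),
              converged = object$diagnostics$converged)
  class(out) <- "summary.veinfrail"
  out
}

#' @export
print.summary.veinfrail <- function(x, ...) {
  cat(sprintf("Model: %s\n", x$model))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) round(v, 3))
  print(tab, row.names = FALSE)
  cat(sprintf("acceptance rates: frailty %.2f, global %.2f; converged: %s\n",
              x$accept["frailty"], x$accept["global"], x$converged))
  invisible(x)
}

#' @export
coef.veinfrail <- function(object, ...) {
  out <- c(theta1 = mean(object$draws$theta1),
           theta2 = mean(object$draws$theta2),
           tau2 = mean(object$draws$tau2))
  if (object$data$use_thickness)
    out <- c(out, beta = mean(object$draws$beta))
  out
}

#' Posterior frailty summaries for mapping back onto the leaf
#'
#' Posterior means and credible intervals of the per-segment frailties v_i
#' (log-odds scale), and, for the thickness model, of the full linear
#' predictor `v_i + beta * x_i` (the quantity rendered as a frailty map and
#' used as the concordance risk score).
#'
#' @param fit a [veinfrail()] fit.
#' @param level credible level (default 0.95).
#' @return data.frame with columns `segment`, `frailty_mean`, `frailty_sd`,
#'   `frailty_lower`, `frailty_upper` and, when applicable, `linpred_mean`.
#' @export
frailties <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "veinfrail"))
  a <- (1 - level) / 2
  qs <- apply(fit$v, 2, quantile, probs = c(a, 1 - a))
  out <- data.frame(segment = fit$data$events$segment,
                    frailty_mean = colMeans(fit$v),
                    frailty_sd = apply(fit$v, 2, sd),
                    frailty_lower = qs[1, ], frailty_upper = qs[2, ])
  if (fit$data$use_thickness) {
    lin <- fit$v + outer(fit$draws$beta, fit$data$thickness)
    out$linpred_mean <- colMeans(lin)
  }
  out
}

#' Predict survival from a fitted embolism model
#'
#' @param object a [veinfrail()] fit.
#' @param times evaluation grid of |Psi| values; defaults to 200 points over
#'   (0, max observed time].
#' @param type `"population"` for the leaf-level segment-averaged survival
#'   curve with a pointwise credible band, or `"segment"` for the posterior
#'   mean survival of every segment at each time.
#' @param level credible level for the population band.
#' @param ... unused.
#' @return For `"population"`, a [survival_curve()]; for `"segment"`, a
#'   times x segments matrix.
#' @export
predict.veinfrail <- function(object, times = NULL,
                              type = c("population", "segment"),
                              level = 0.95, ...) {
  type <- match.arg(type)
  if (is.null(times))
    times <- seq(1e-6, max(object$data$events$time), length.out = 200)
  if (any(times < 0)) stop("`times` must be non-negative")
  d <- object$draws
  if (type == "population") {
    cur <- population_curves(d$theta1, d$theta2, d$beta, object$v,
                             object$data$thickness, times)
    a <- (1 - level) / 2
    qs <- apply(cur, 2, quantile, probs = c(a, 1 - a))
    survival_curve(times, colMeans(cur), qs[1, ], qs[2, ])
  } else {
    eta <- object$v + outer(d$beta, object$data$thickness)
    nd <- nrow(eta)
    out <- matrix(0, length(times), ncol(eta))
    for (k in seq_len(nd)) {
      S0 <- base_survival(times, d$theta1[k], d$theta2[k])
      a <- exp(-pmin(pmax(eta[k, ], -30), 30))
      out <- out + outer(S0, a, function(s, aa) aa * s / (1 + (aa - 1) * s))
    }
    out / nd
  }
}

#' Plot the population survival curve of a fitted model
#'
#' @param x a [veinfrail()] fit.
#' @param km optional [km_estimator()] curve to overlay.
#' @param ... passed to `plot.survival_curve`.
#' @export
plot.veinfrail <- function(x, km = NULL, ...) {
  pc <- predict(x, type = "population")
  plot(pc, ...)
  if (!is.null(km)) {
    lines(km$time, km$surv, type = "s", col = "grey30", lty = 2)
    legend("topright", legend = c(x$model, "KM"), lty = c(1, 2),
           col = c("steelblue", "grey30"), bty = "n")
  }
  invisible(x)
}

#' Simulate event tables from the posterior of a fitted model
#'
#' For each requested replicate, one retained posterior draw of
#' `(theta, beta, v)` is selected and a new right-censored event table is
#' generated from the proportional-odds survival law at the original
#' censoring time.
#'
#' @param object a [veinfrail()] fit.
#' @param nsim number of replicate tables.
#' @param seed integer seed.
#' @param ... unused.
#' @return List of [event_table()] objects (a single table if `nsim = 1`).
#' @export
simulate.veinfrail <- function(object, nsim = 1, seed = 1, ...) {
  set.seed(seed)
  censor <- attr(object$data$events, "censor_time")
  if (is.null(censor)) censor <- max(object$data$events$time)
  d <- object$draws
  picks <- sample.int(nrow(d), nsim, replace = TRUE)
  out <- lapply(picks, function(k) {
    eta <- object$v[k, ] + d$beta[k] * object$data$thickness
    draw_event_table(eta, d$theta1[k], d$theta2[k], censor,
                     segment = object$data$events$segment)
  })
  if (nsim == 1) out[[1]] else out
}

#' Deviance information criterion of a fitted model
#'
#' Conditional DIC with focus on `(theta, beta, v)`: `DIC = Dbar + pD`, where
#' `D = -2 log L`, `Dbar` is the posterior mean deviance over retained draws
#' and `pD = Dbar - D(posterior means)`.  Lower is better.  Non-finite
#' deviance draws are excluded with a warning.
#'
#' @param fit a [veinfrail()] fit.
#' @return List with `dic`, `dbar`, `dhat`, `pd`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "veinfrail"))
  D <- -2 * fit$draws$loglik
  ok <- is.finite(D)
  if (!all(ok)) {
    warning(sum(!ok), " non-finite deviance draws excluded from DIC")
    D <- D[ok]
  }
  dbar <- mean(D)
  ev <- fit$data$events
  dhat <- -2 * loglik_state(as.integer(ev$delta), as.numeric(ev$time),
                            fit$data$thickness, colMeans(fit$v),
                            mean(fit$draws$beta), mean(fit$draws$theta1),
                            mean(fit$draws$theta2))
  pd <- dbar - dhat
  list(dic = dbar + pd, dbar = dbar, dhat = dhat, pd = pd)
}
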