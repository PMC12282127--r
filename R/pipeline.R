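#' Write a vein network to a directory of delimited files
#'
#' `segments.csv` (id, n_pixels, thickness, endpoints as `row:col`
#' 0-based, `;`-separated), `edges.csv` (i, j; each undirected edge once)
#' and `features.json` (connectivity, branch/segment counts, plus vein
#' density and areoles when a mask is supplied).
#'
#' @param network a `vein_network`.
#' @param dir output directory (created if needed).
#' @param mask optional matching [vein_mask()] for density/areole features.
#' @return The directory path, invisibly.
#' @export
write_network <- function(network, dir, mask = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  segs <- network$segments
  ep <- if (is.null(network$endpoints)) rep("", nrow(segs)) else
    vapply(network$endpoints, function(e) {
      if (is.null(e) || !nrow(e)) "" else
        paste(sprintf("%d:%d", e[, 1] - 1L, e[, 2] - 1L), collapse = ";")
    }, character(1))
  write.csv(data.frame(id = segs$id, n_pixels = segs$n_pixels,
                       thickness = segs$thickness, endpoints = ep),
            file.path(dir, "segments.csv"), row.names = FALSE)
  A <- network$adjacency
  idx <- Matrix::which(A != 0, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  write.csv(data.frame(i = idx[, 1], j = idx[, 2]),
            file.path(dir, "edges.csv"), row.names = FALSE)
  feats <- if (!is.null(mask)) vein_features(mask, network) else
    list(connectivity = connectivity(network))
  feats$n_segments <- nrow(segs)
  feats$n_branch_points <- network$n_branch_points
  jsonlite::write_json(feats, file.path(dir, "features.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a vein network from delimited files
#'
#' Rebuilds a graph-level `vein_network` from a `segments.csv` /
#' `edges.csv` pair as written by [write_network()] (pixel-level fields are
#' not recoverable from the tables and are left NULL).
#'
#' @param dir directory containing `segments.csv` and `edges.csv`.
#' @return A `vein_network`.
#' @export
read_network <- function(dir) {
  segs <- read.csv(file.path(dir, "segments.csv"))
  edges <- read.csv(file.path(dir, "edges.csv"))
  n <- nrow(segs)
  A <- Matrix::Matrix(0, n, n, sparse = TRUE)
  if (nrow(edges)) {
    for (q in seq_len(nrow(edges))) {
      A[edges$i[q], edges$j[q]] <- 1
      A[edges$j[q], edges$i[q]] <- 1
    }
  }
  nb <- NA_integer_
  fj <- file.path(dir, "features.json")
  if (file.exists(fj)) nb <- jsonlite::read_json(fj)$n_branch_points
  structure(list(
    segments = data.frame(id = segs$id, n_pixels = segs$n_pixels,
                          thickness = segs$thickness,
                          degree = Matrix::rowSums(A)),
    pixels = NULL, endpoints = NULL, junctions = NULL, seg_junctions = NULL,
    adjacency = methods::as(A, "generalMatrix"), n_branch_points = nb,
    skeleton = NULL, dim = NULL, pixel_scale = 1
  ), class = "vein_network")
}

#' Write posterior draws and a fit summary
#'
#' `draws.csv` holds the scalar parameters in long format (chain, iter,
#' parameter, value); `summary.json` the posterior means, credible
#' intervals, split-Rhat and effective sample sizes.
#'
#' @param fit a [veinfrail()] fit.
#' @param dir output directory.
#' @return The directory path, invisibly.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pars <- c("theta1", "theta2", "tau2", if (fit$data$use_thickness) "beta")
  long <- do.call(rbind, lapply(pars, function(p)
    data.frame(chain = fit$draws$chain, iter = fit$draws$iter,
               parameter = p, value = fit$draws[[p]])))
  write.csv(long, file.path(dir, "draws.csv"), row.names = FALSE)
  sm <- summary(fit)
  jsonlite::write_json(
    list(model = fit$model, seed = fit$seed, chains = fit$chains,
         iter = fit$iter, burnin = fit$burnin, thin = fit$thin,
         converged = sm$converged, parameters = sm$table),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(dir)
}

#' Run the simulation-fit-evaluation pipeline from a config
#'
#' Executes the requested stages in order on a single configuration:
#' `simulate` (network, frailties, events), `fit` (one or more model
#' variants) and `evaluate` (KM baseline, band-area change, DIC, temporal
#' split C-index, P50).  A resolved copy of the configuration, a log and a
#' checksum manifest of every file written are placed in the output
#' directory.
#'
#' @param config named list (or path to a JSON/YAML file) with elements
#'   `out_dir`, `seed`, optional `stages` (default all), `simulate` (m,
#'   kind, tau2, prior_kind, theta1, theta2, beta, censor_time), `fit`
#'   (models, iter, burnin, thin, chains), `evaluate` (split fraction).
#' @return Invisibly, the manifest data frame (path, md5).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  defaults <- list(
    seed = 1, stages = c("simulate", "fit", "evaluate"),
    simulate = list(m = 100, kind = "lattice", tau2 = 1, prior_kind = "icar",
                    theta1 = 0, theta2 = 1.5, beta = 0, censor_time = 3),
    fit = list(models = "spatial-dependent", iter = 2000, burnin = 1000,
               thin = 2, chains = 2),
    evaluate = list(fraction = 0.8))
  config <- modifyList(defaults, config)
  if (is.null(config$out_dir)) stop("config must name an `out_dir`")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  logline <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                               "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  logline("veinfrail ", as.character(utils::packageVersion("veinfrail")),
          ", seed ", config$seed)
  jsonlite::write_json(config, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  sim <- config$simulate
  net <- events <- NULL
  fits <- list()
  if ("simulate" %in% config$stages) {
    t0 <- proc.time()[3]
    net <- sim_vein_network(m = sim$m, kind = sim$kind, seed = config$seed)
    fr <- sim_frailties(net, tau2 = sim$tau2, kind = sim$prior_kind,
                        seed = config$seed + 1)
    events <- sim_events(net, fr, theta1 = sim$theta1, theta2 = sim$theta2,
                         beta = sim$beta, censor_time = sim$censor_time,
                         seed = config$seed + 2)
    write_network(net, file.path(config$out_dir, "network"))
    write_event_table(events, file.path(config$out_dir, "events.csv"))
    logline("simulate: m=", nrow(net$segments), ", events=",
            sum(events$delta), " (", round(proc.time()[3] - t0, 1), "s)")
  } else {
    if (!is.null(config$events_csv)) {
      if (!file.exists(config$events_csv))
        stop("missing input: ", config$events_csv)
      events <- read_event_table(config$events_csv)
    }
    if (!is.null(config$network_dir)) net <- read_network(config$network_dir)
  }

  if ("fit" %in% config$stages) {
    for (mv in config$fit$models) {
      t0 <- proc.time()[3]
      fit <- veinfrail(events, net, model = mv,
                       chains = config$fit$chains, iter = config$fit$iter,
                       burnin = config$fit$burnin, thin = config$fit$thin,
                       seed = config$seed)
      fits[[mv]] <- fit
      write_fit(fit, file.path(config$out_dir, paste0("fit-", mv)))
      logline("fit ", mv, ": DIC=", round(dic(fit)$dic, 1),
              " (", round(proc.time()[3] - t0, 1), "s)")
    }
  }

  if ("evaluate" %in% config$stages && length(fits)) {
    km <- km_estimator(events)
    report <- list()
    for (mv in names(fits)) {
      mc <- model_survival_curve(fits[[mv]])
      ci <- tryCatch(
        evaluate_c_index(events, net, model = mv,
                         fraction = config$evaluate$fraction,
                         chains = config$fit$chains, iter = config$fit$iter,
                         burnin = config$fit$burnin, thin = config$fit$thin,
                         seed = config$seed)$c_index,
        error = function(e) NA_real_)
      report[[mv]] <- list(
        dic = dic(fits[[mv]])$dic,
        band_area_relative_change = band_area_relative_change(mc, km),
        c_index = ci,
        p50 = vulnerability_from_survival(mc)$p50)
      utils::write.csv(as.data.frame(mc),
                       file.path(config$out_dir, paste0("curve-", mv, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(report, file.path(config$out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
    logline("evaluate: done")
  }

  files <- setdiff(list.files(config$out_dir, recursive = TRUE,
                              full.names = TRUE), logf)
  manifest <- data.frame(path = files, md5 = unname(tools::md5sum(files)))
  write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
            row.names = FALSE)
  invisible(manifest)
}

read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
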