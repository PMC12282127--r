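#' Survival curve with pointwise 95% band
#'
#' @param time increasing positive grid (|Psi|, MPa).
#' @param surv point estimate, non-increasing in `time`.
#' @param lower,upper pointwise band limits, `0 <= lower <= surv <= upper <= 1`.
#' @return data.frame of class `survival_curve`.
#' @export
survival_curve <- function(time, surv, lower = surv, upper = surv) {
  if (is.unsorted(time, strictly = FALSE)) stop("`time` must be increasing")
  if (any(time < 0)) stop("`time` must be non-negative")
  eps <- 1e-8
  if (any(surv > pmin(upper + eps, 1 + eps)) || any(surv < pmax(lower - eps, -eps)))
    stop("band must bracket the point estimate within [0, 1]")
  structure(data.frame(time = time, surv = surv, lower = pmax(lower, 0),
                       upper = pmin(upper, 1)),
            class = c("survival_curve", "data.frame"))
}

#' @export
plot.survival_curve <- function(x, col = "steelblue", band = TRUE,
                                xlab = "|Psi| (MPa)",
                                ylab = "Survival probability", ...) {
  plot(x$time, x$surv, type = "l", col = col, ylim = c(0, 1),
       xlab = xlab, ylab = ylab, ...)
  if (band)
    polygon(c(x$time, rev(x$time)), c(x$lower, rev(x$upper)),
            col = adjustcolor(col, 0.2), border = NA)
  invisible(x)
}

#' Kaplan-Meier estimator with Greenwood 95% band
#'
#' The spatially agnostic baseline: product-limit survival estimate with a
#' log-log transformed Greenwood confidence band.  Censored segments enter
#' the risk sets.  Where the transform is undefined (estimate at 1 or 0) the
#' band collapses onto the point estimate.
#'
#' @param events an [event_table()].
#' @param level confidence level (default 0.95).
#' @return A [survival_curve()] evaluated at the observed event times
#'   (step-function values; use step interpolation between them).
#' @export
km_estimator <- function(events, level = 0.95) {
  if (sum(events$delta) == 0) {
    warning("all segments censored: flat KM curve at 1 with degenerate band")
    tmax <- max(events$time)
    return(survival_curve(c(0, tmax), c(1, 1)))
  }
  sf <- survival::survfit(survival::Surv(events$time, events$delta) ~ 1,
                          conf.type = "log-log", conf.int = level)
  lo <- ifelse(is.na(sf$lower), sf$surv, sf$lower)
  hi <- ifelse(is.na(sf$upper), sf$surv, sf$upper)
  survival_curve(sf$time, sf$surv, lo, hi)
}

#' Population survival curve of a fitted model
#'
#' For each retained posterior draw the leaf-level curve is the
#' segment-averaged survival `(1/m) sum_i S_i(t)`; the point estimate is the
#' posterior mean and the band the pointwise 2.5/97.5% posterior quantiles.
#'
#' @param fit a [veinfrail()] fit.
#' @param grid evaluation grid (default: 200 points over (0, max observed
#'   time]).
#' @param level credible level (default 0.95).
#' @return A [survival_curve()].
#' @export
model_survival_curve <- function(fit, grid = NULL, level = 0.95) {
  predict(fit, times = grid, type = "population", level = level)
}

#' Relative change in 95% band area versus a baseline curve
#'
#' Integrates the pointwise band width of each curve over a common grid
#' (trapezoidal rule; the model curve is linearly interpolated, the KM curve
#' step-interpolated) and returns `(area_model - area_km) / area_km`.
#' Negative values mean the model reduced uncertainty relative to the
#' baseline.
#'
#' @param model_curve a [survival_curve()] from [model_survival_curve()].
#' @param km_curve the [km_estimator()] baseline.
#' @return Signed fraction.
#' @export
band_area_relative_change <- function(model_curve, km_curve) {
  grid <- sort(unique(c(model_curve$time, km_curve$time)))
  grid <- grid[grid >= max(min(model_curve$time), min(km_curve$time)) &
               grid <= min(max(model_curve$time), max(km_curve$time))]
  if (length(grid) < 2) stop("curves do not share a usable time range")
  wm <- curve_width(model_curve, grid, method = "linear")
  wk <- curve_width(km_curve, grid, method = "constant")
  area_m <- trapezoid(grid, wm)
  area_k <- trapezoid(grid, wk)
  if (area_k == 0) stop("KM band area is zero; relative change undefined")
  (area_m - area_k) / area_k
}

curve_width <- function(curve, grid, method) {
  lo <- approx(curve$time, curve$lower, grid, method = method, rule = 2)$y
  hi <- approx(curve$time, curve$upper, grid, method = method, rule = 2)$y
  hi - lo
}

trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' Temporal 80/20 split of an event table
#'
#' The threshold is the `fraction` quantile of the observed event times (the
#' `ceiling(fraction * n)`-th smallest event time; ties at the threshold go
#' to the training set).  Training data keep events at or before the
#' threshold and administratively censor every other segment at the
#' threshold; the test set holds the uncensored events after the threshold
#' with their true times.
#'
#' @param events an [event_table()] with at least 5 observed events.
#' @param fraction training fraction in (0, 1), default 0.8.
#' @return List of class `split_data`: `train` (event_table over all
#'   segments), `test` (event_table of the test segments), `test_index`
#'   (row indices of test segments), `threshold`.
#' @export
temporal_split <- function(events, fraction = 0.8) {
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1)")
  ev_times <- events$time[events$delta == 1]
  n <- length(ev_times)
  if (n < 5) stop("need at least 5 observed events to split")
  threshold <- sort(ev_times)[ceiling(fraction * n)]
  is_test <- events$delta == 1 & events$time > threshold
  if (!any(is_test))
    stop("test set is empty (all events at or before the threshold)")
  train <- event_table(ifelse(events$delta == 1 & events$time <= threshold, 1L, 0L),
                       ifelse(events$delta == 1 & events$time <= threshold,
                              events$time, threshold),
                       segment = events$segment)
  test <- event_table(events$delta[is_test], events$time[is_test],
                      segment = events$segment[is_test])
  structure(list(train = train, test = test, test_index = which(is_test),
                 threshold = threshold),
            class = "split_data")
}

#' Concordance index of risk scores against event times
#'
#' The probability that, of two comparable segments (the earlier one
#' uncensored), the earlier-embolizing one has the strictly higher risk
#' score: `C = sum_ij 1{v_i > v_j} 1{t_i < t_j} delta_i / sum_ij 1{t_i <
#' t_j} delta_i`.  Ties in the scores contribute zero.  Chance level is 0.5.
#'
#' @param scores per-segment risk scores (e.g. posterior-mean frailties,
#'   plus the thickness term for the thickness model).
#' @param events the matching [event_table()] (typically the test set from
#'   [temporal_split()]).
#' @return C-index in [0, 1].
#' @export
c_index <- function(scores, events) {
  if (length(scores) != nrow(events)) stop("`scores` length must match `events`")
  ti <- events$time; di <- events$delta
  comparable <- outer(ti, ti, `<`) & (di == 1)   # rows i with delta_i = 1
  n_comp <- sum(comparable)
  if (n_comp == 0) stop("no comparable pairs (need an uncensored earlier event)")
  concordant <- comparable & outer(scores, scores, `>`)
  sum(concordant) / n_comp
}

#' Vulnerability curve and P50 from a survival curve
#'
#' Percent embolized is `100 * (1 - S(t))`; P50 is the water potential (as a
#' negative MPa value) at which the survival estimate crosses 0.5, by linear
#' interpolation, or NA when the curve never reaches 0.5.
#'
#' @param curve a [survival_curve()].
#' @return List with `curve` (data.frame: time, psi = -time,
#'   percent_embolized and band limits) and `p50` (negative MPa or NA).
#' @export
vulnerability_from_survival <- function(curve) {
  vc <- data.frame(time = curve$time, psi = -curve$time,
                   percent_embolized = 100 * (1 - curve$surv),
                   lower = 100 * (1 - curve$upper),
                   upper = 100 * (1 - curve$lower))
  p50 <- NA_real_
  below <- which(curve$surv <= 0.5)
  if (length(below)) {
    k <- below[1]
    if (curve$surv[k] == 0.5 || k == 1) {
      p50 <- -curve$time[k]
    } else {
      s1 <- curve$surv[k - 1]; s2 <- curve$surv[k]
      t1 <- curve$time[k - 1]; t2 <- curve$time[k]
      p50 <- -(t1 + (s1 - 0.5) / (s1 - s2) * (t2 - t1))
    }
  }
  list(curve = vc, p50 = p50)
}

#' Between-species Pearson correlation of parameter and feature means
#'
#' Correlates per-species mean model parameters with per-species mean
#' venation features (or mean P50) across species, the between-species
#' component of the correlation decomposition for species-clustered samples.
#'
#' @param summaries data.frame with one row per species.
#' @param param column name of the parameter mean.
#' @param feature column name of the feature (or P50) mean.
#' @return Pearson r, or NA (with a warning) when fewer than 3 species or
#'   zero variance.
#' @export
between_species_correlation <- function(summaries, param, feature) {
  x <- summaries[[param]]; y <- summaries[[feature]]
  if (is.null(x) || is.null(y)) stop("missing column: ", param, " or ", feature)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 species")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  cor(x[ok], y[ok])
}

#' Per-leaf correlation between vein thickness and event water potential
#'
#' Pearson r between segment thickness and the water potential magnitude
#' |Psi| at which the embolism event occurred, over uncensored segments
#' only.  Negative r means thicker veins embolize at smaller |Psi| (less
#' negative Psi), i.e. earlier in desiccation — the thicker-to-thinner
#' propagation pattern.
#'
#' @param events an [event_table()].
#' @param thickness per-segment thickness, aligned with `events`.
#' @return Pearson r, or NA when fewer than 3 events or zero variance.
#' @export
thickness_time_correlation <- function(events, thickness) {
  if (length(thickness) != nrow(events))
    stop("`thickness` length must match `events`")
  sel <- events$delta == 1
  if (sum(sel) < 3) return(NA_real_)
  x <- thickness[sel]
  tt <- events$time[sel]
  if (sd(x) == 0 || sd(tt) == 0) return(NA_real_)
  cor(x, tt)
}

#' Temporal-split concordance evaluation of a model variant
#'
#' Convenience wrapper mirroring the standard evaluation loop: split the
#' events at the `fraction` quantile of event times, refit the model on the
#' training data (test segments censored at the threshold), and score the
#' test segments' true ordering with the posterior-mean frailty (plus the
#' thickness term for the thickness model) as risk score.
#'
#' @param events full [event_table()].
#' @param network the `vein_network` (or adjacency).
#' @param model,thickness,... passed to [veinfrail()].
#' @param fraction training fraction (default 0.8).
#' @return List with `c_index`, `split`, `fit`.
#' @export
evaluate_c_index <- function(events, network, model, thickness = NULL,
                             fraction = 0.8, ...) {
  sp <- temporal_split(events, fraction)
  fit <- veinfrail(sp$train, network, model = model, thickness = thickness, ...)
  fr <- frailties(fit)
  scores <- if (fit$data$use_thickness) fr$linpred_mean else fr$frailty_mean
  list(c_index = c_index(scores[sp$test_index], sp$test),
       split = sp, fit = fit)
}
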