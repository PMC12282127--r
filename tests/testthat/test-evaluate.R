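test_that("KM estimator matches hand product-limit computations", {
  # three distinct uncensored times: steps 2/3, 1/3, 0
  km <- km_estimator(event_table(c(1, 1, 1), c(1, 2, 3)))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # {1, 2+, 3}: S(1) = 2/3, S(3) = 0
  km2 <- km_estimator(event_table(c(1, 0, 1), c(1, 2, 3)))
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)
  # all censored: flat with a warning
  expect_warning(km3 <- km_estimator(event_table(c(0, 0), c(2, 2))), "censored")
  expect_true(all(km3$surv == 1))
})

test_that("KM estimator agrees with the naive product-limit oracle on random data", {
  set.seed(21)
  for (rep in 1:50) {
    n <- sample(10:60, 1)
    cens <- runif(1, 1, 4)
    latent <- rweibull(n, shape = runif(1, 0.8, 2.5), scale = runif(1, 0.5, 3))
    delta <- as.integer(latent <= cens)
    if (!any(delta == 1)) next
    ev <- event_table(delta, ifelse(delta == 1, latent, cens))
    km <- km_estimator(ev)
    ref <- brute_force_km(ev$time, ev$delta)
    expect_equal(km$surv[match(ref$time, km$time)], ref$surv,
                 tolerance = 1e-12)
  }
})

test_that("band area relative change matches hand integrations", {
  grid <- seq(0.1, 2, length.out = 40)
  s <- seq(0.75, 0.25, length.out = 40)
  km <- survival_curve(grid, s, s - 0.2, s + 0.2)
  expect_equal(band_area_relative_change(km, km), 0)
  half <- survival_curve(grid, s, s - 0.1, s + 0.1)
  expect_equal(band_area_relative_change(half, km), -0.5, tolerance = 1e-10)
  # piecewise fixture integrated by hand: model width 0.2 on [0,1] and 0.4 on
  # (1,2] against constant baseline width 0.2 -> areas 0.6 vs 0.4 -> +0.5
  t3 <- c(0, 1, 1 + 1e-9, 2)
  s3 <- rep(0.6, 4)
  a <- survival_curve(t3, s3, s3 - c(0.1, 0.1, 0.2, 0.2),
                      s3 + c(0.1, 0.1, 0.2, 0.2))
  b <- survival_curve(t3, s3, s3 - 0.1, s3 + 0.1)
  expect_equal(band_area_relative_change(a, b), 0.5, tolerance = 1e-6)
  zero <- survival_curve(grid, s, s, s)
  expect_error(band_area_relative_change(half, zero), "zero")
})

test_that("degenerate posteriors give zero-width bands and pD = 0", {
  r <- quick_fit(m = 16, seed = 23, iter = 400, burnin = 200)
  fit <- r$fit
  # collapse the posterior onto a single draw
  fit$draws <- fit$draws[rep(1, 50), ]
  fit$v <- fit$v[rep(1, 50), ]
  pc <- predict(fit, times = c(0.5, 1, 1.5))
  expect_equal(pc$lower, pc$upper)
  d <- dic(fit)
  expect_equal(d$pd, 0, tolerance = 1e-8)
  expect_equal(d$dic, d$dbar)
})

test_that("DIC penalty is non-negative on well-behaved fits", {
  for (seed in c(25, 26)) {
    r <- quick_fit(m = 40, seed = seed, iter = 1000, burnin = 500)
    expect_gte(dic(r$fit)$pd, 0)
  }
})

test_that("temporal split follows the 80th-percentile tie rule", {
  # 10 distinct event times: 8 train, 2 test
  ev <- event_table(rep(1, 10), seq(0.5, 5, by = 0.5))
  sp <- temporal_split(ev)
  expect_equal(sum(sp$train$delta), 8)
  expect_equal(nrow(sp$test), 2)
  expect_equal(sp$threshold, 4)
  expect_true(all(sp$train$time[sp$train$delta == 0] == sp$threshold))
  # ties at the threshold go to train
  ev2 <- event_table(rep(1, 10), c(1, 2, 3, 4, 5, 6, 7, 8, 8, 9))
  sp2 <- temporal_split(ev2)
  expect_equal(sp2$threshold, 8)
  expect_equal(sum(sp2$train$delta), 9)
  expect_equal(sp2$test$time, 9)
  # all tied: empty test set is an error
  expect_error(temporal_split(event_table(rep(1, 6), rep(2, 6))), "empty")
  expect_error(temporal_split(ev, fraction = 1.2), "0, 1")
  expect_error(temporal_split(event_table(c(1, 1, 0), c(1, 2, 3))), "at least 5")
})

test_that("C-index matches Eq-style pair counting", {
  ev <- event_table(rep(1, 6), c(0.3, 0.7, 1.1, 1.6, 2.2, 2.9))
  expect_equal(c_index(-ev$time, ev), 1)        # perfect ordering
  expect_equal(c_index(ev$time, ev), 0)         # fully reversed
  # 4-segment fixture with one censored, against exhaustive enumeration
  ev4 <- event_table(c(1, 1, 0, 1), c(1, 2, 3, 2.5))
  sc <- c(0.9, -0.3, 0.2, 0.1)
  expect_equal(c_index(sc, ev4), brute_force_cindex(sc, ev4$time, ev4$delta))
  # rank invariance
  set.seed(27)
  for (k in 1:10) {
    n <- 15
    delta <- rbinom(n, 1, 0.8)
    evr <- event_table(delta, ifelse(delta == 1, runif(n, 0.1, 3), 3.5))
    s <- rnorm(n)
    expect_equal(c_index(s, evr), c_index(rank(s), evr))
    expect_equal(c_index(s, evr), brute_force_cindex(s, evr$time, evr$delta))
  }
  expect_error(c_index(c(1, 2), event_table(c(0, 0), c(2, 2))), "comparable")
})

test_that("ties in risk scores count as discordant", {
  ev <- event_table(c(1, 1), c(1, 2))
  expect_equal(c_index(c(0.5, 0.5), ev), 0)
})

test_that("vulnerability conversion and P50 extraction", {
  # flat survival: no crossing, P50 missing
  flat <- survival_curve(c(0.5, 1, 2), c(1, 1, 1))
  vf <- vulnerability_from_survival(flat)
  expect_true(is.na(vf$p50))
  expect_true(all(vf$curve$percent_embolized == 0))
  # exponential decay with rate log 2 per MPa: P50 at -1 MPa
  tt <- seq(0.01, 4, length.out = 500)
  expc <- survival_curve(tt, exp(-log(2) * tt))
  expect_equal(vulnerability_from_survival(expc)$p50, -1, tolerance = 1e-3)
  # step fixture interpolated by hand: crossing between (1, 0.8) and (2, 0.2)
  # at t = 1.5
  st <- survival_curve(c(1, 2), c(0.8, 0.2))
  expect_equal(vulnerability_from_survival(st)$p50, -1.5)
})

test_that("between-species correlation reproduces the textbook formula", {
  tab <- data.frame(species = letters[1:5],
                    beta = c(0.2, 0.5, 0.9, 1.1, 1.4),
                    connectivity = c(0.50, 0.55, 0.58, 0.61, 0.62),
                    p50 = c(-1.8, -2.2, -2.0, -2.9, -2.4))
  # hand Pearson computation, frozen
  x <- tab$beta; y <- tab$connectivity
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(between_species_correlation(tab, "beta", "connectivity"), hand)
  # collinear and anti-collinear extremes
  tab$lin <- 2 * tab$beta + 1
  expect_equal(between_species_correlation(tab, "beta", "lin"), 1)
  tab$neg <- -tab$lin
  expect_equal(between_species_correlation(tab, "beta", "neg"), -1)
  expect_error(between_species_correlation(tab[1:2, ], "beta", "p50"), "3 species")
  tab$const <- 1
  expect_warning(r <- between_species_correlation(tab, "beta", "const"), "variance")
  expect_true(is.na(r))
})

test_that("thickness-time correlation has the documented sign convention", {
  # thickness strictly decreasing in |Psi| of the event: thicker = earlier,
  # so r is -1 on a linear fixture
  ev <- event_table(rep(1, 5), c(0.5, 1, 1.5, 2, 2.5))
  th <- c(10, 8, 6, 4, 2)
  expect_equal(thickness_time_correlation(ev, th), -1)
  expect_equal(thickness_time_correlation(ev, rev(th)), 1)
  expect_true(is.na(thickness_time_correlation(ev, rep(5, 5))))
  ev2 <- event_table(c(1, 1, 0, 0, 0), c(1, 2, 3, 3, 3))
  expect_true(is.na(thickness_time_correlation(ev2, th)))
})

test_that("the temporal-split concordance wrapper runs end to end", {
  r <- quick_fit(m = 60, model = "spatial-thickness", beta = 1.5, tau2 = 0.3,
                 seed = 29, iter = 1000, burnin = 500)
  res <- suppressWarnings(
    evaluate_c_index(r$events, r$net, model = "spatial-thickness",
                     iter = 1000, burnin = 500, thin = 2, seed = 29))
  expect_true(res$c_index >= 0 && res$c_index <= 1)
  expect_s3_class(res$split, "split_data")
  # every test segment appears censored at the threshold in training data
  expect_true(all(res$split$train$delta[res$split$test_index] == 0))
  expect_true(all(res$split$train$time[res$split$test_index] ==
                    res$split$threshold))
})
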