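# helper: brute-force spillover filtering, enumerating every sequential
# removal order and requiring them to agree (used on fixtures where the fixed
# point is order-invariant)
enumerate_spillover <- function(candidates, network, spill_radius, spill_frac) {
  removable <- function(k, cands) {
    if (cands[[k]]$coverage >= spill_frac) return(FALSE)
    for (o in seq_along(cands)) {
      if (o == k || cands[[o]]$frame != cands[[k]]$frame ||
          cands[[o]]$segment == cands[[k]]$segment) next
    d2 <- outer(cands[[k]]$pixels[, 1], network$pixels[[cands[[o]]$segment]][, 1], `-`)^2 +
          outer(cands[[k]]$pixels[, 2], network$pixels[[cands[[o]]$segment]][, 2], `-`)^2
      if (min(d2) <= spill_radius^2) return(TRUE)
    }
    FALSE
  }
  results <- list()
  recurse <- function(cands) {
    rem <- which(vapply(seq_along(cands), removable, logical(1), cands = cands))
    if (!length(rem)) {
      results[[length(results) + 1]] <<- sort(vapply(cands, `[[`, numeric(1), "segment"))
      return()
    }
    for (k in rem) recurse(cands[-k])
  }
  recurse(candidates)
  uniq <- unique(results)
  expect_length(uniq, 1)
  uniq[[1]]
}

test_that("a frame touching a single segment yields one event, rest censored", {
  net <- skeletonize_and_segment(y_mask(arm = 8))
  target <- 2
  px <- net$pixels[[target]]
  f1 <- matrix(FALSE, net$dim[1], net$dim[2])
  f1[px[3, 1], px[3, 2]] <- TRUE
  f2 <- matrix(FALSE, net$dim[1], net$dim[2])
  stack <- frame_stack(list(f1, f2), c(-1.5, -2.5))
  ev <- map_events(stack, net)
  expect_equal(ev$delta[target], 1L)
  expect_equal(ev$time[target], 1.5)
  expect_equal(ev$delta[-target], rep(0L, 2))
  expect_equal(ev$time[-target], rep(2.5, 2))
})

test_that("an all-empty stack censors every segment at the final |Psi|", {
  net <- skeletonize_and_segment(y_mask())
  empty <- matrix(FALSE, net$dim[1], net$dim[2])
  stack <- frame_stack(list(empty, empty, empty), c(-0.5, -1.2, -3.1))
  ev <- map_events(stack, net)
  expect_equal(ev$delta, rep(0L, 3))
  expect_equal(ev$time, rep(3.1, 3))
})

test_that("stack validation errors are raised", {
  net <- skeletonize_and_segment(y_mask())
  expect_error(frame_stack(list(), numeric(0)), "zero frames")
  f <- matrix(FALSE, 5, 5)
  expect_error(map_events(frame_stack(list(f), -1), net), "does not match")
  expect_error(frame_stack(list(f, f), c(-2, -1)), "non-increasing")
})

test_that("tied water potentials collapse by pixel union", {
  a <- matrix(FALSE, 4, 4); a[1, 1] <- TRUE
  b <- matrix(FALSE, 4, 4); b[4, 4] <- TRUE
  st <- frame_stack(list(a, b), c(-1, -1))
  expect_length(st$frames, 1)
  expect_equal(sum(st$frames[[1]]), 2)
})

test_that("spillover conditions behave as specified on edge cases", {
  net <- skeletonize_and_segment(h_mask(arm = 12))
  crossbar <- which(vapply(net$pixels, function(p) all(p[, 1] == p[1, 1]),
                           logical(1)))
  other <- setdiff(seq_len(5), crossbar)[1]
  full_cov <- list(segment = crossbar, frame = 1, time = 1,
                   pixels = net$pixels[[crossbar]], coverage = 1)
  # full coverage is never removed, whatever its surroundings
  expect_length(remove_spillover(list(full_cov), net), 1)
  # a 1-pixel candidate adjacent to a same-frame event is removed
  touch <- net$pixels[[other]][which.min(
    apply(veinfrail:::cross_dist2(net$pixels[[other]], net$pixels[[crossbar]]),
          1, min)), , drop = FALSE]
  tiny <- list(segment = other, frame = 1, time = 1, pixels = touch,
               coverage = 1 / nrow(net$pixels[[other]]))
  kept <- remove_spillover(list(full_cov, tiny), net, spill_radius = 3,
                           spill_frac = 0.1)
  expect_equal(vapply(kept, `[[`, numeric(1), "segment"), crossbar)
  # but survives when it is in a different frame
  tiny2 <- tiny; tiny2$frame <- 2
  expect_length(remove_spillover(list(full_cov, tiny2), net,
                                 spill_radius = 3), 2)
})

test_that("spillover fixed point matches exhaustive removal-order enumeration", {
  net <- skeletonize_and_segment(grid_mask(3, spacing = 10))
  A <- as.matrix(net$adjacency)
  # anchor event on segment a; two weak candidates whose pixels are close to
  # the anchor (all removal orders agree on the fixed point)
  a <- 1
  nbs <- which(A[a, ] > 0)[1:2]
  near_a <- function(s) {
    d <- apply(veinfrail:::cross_dist2(net$pixels[[s]], net$pixels[[a]]), 1, min)
    net$pixels[[s]][which.min(d), , drop = FALSE]
  }
  cands <- list(
    list(segment = a, frame = 1, time = 1, pixels = net$pixels[[a]], coverage = 1),
    list(segment = nbs[1], frame = 1, time = 1, pixels = near_a(nbs[1]),
         coverage = 0.05),
    list(segment = nbs[2], frame = 1, time = 1, pixels = near_a(nbs[2]),
         coverage = 0.05))
  kept <- remove_spillover(cands, net, spill_radius = 3, spill_frac = 0.1)
  got <- sort(vapply(kept, `[[`, numeric(1), "segment"))
  want <- enumerate_spillover(cands, net, spill_radius = 3, spill_frac = 0.1)
  expect_equal(got, want)
  expect_equal(got, a)
})

test_that("spillover filtering is idempotent", {
  net <- skeletonize_and_segment(grid_mask(3, spacing = 10))
  set.seed(11)
  cands <- lapply(seq_len(nrow(net$segments)), function(s) {
    px <- net$pixels[[s]]
    take <- sample(nrow(px), max(1, rbinom(1, nrow(px), 0.3)))
    list(segment = s, frame = sample(2, 1), time = 1,
         pixels = px[take, , drop = FALSE], coverage = length(take) / nrow(px))
  })
  once <- remove_spillover(cands, net)
  twice <- remove_spillover(once, net)
  expect_identical(once, twice)
})

test_that("parameter validation for the spillover rule", {
  net <- skeletonize_and_segment(y_mask())
  expect_error(remove_spillover(list(), net, spill_radius = -1), "non-negative")
  expect_error(remove_spillover(list(), net, spill_frac = 1.5), "0, 1")
})

test_that("event times take only |Psi| frame values; censored rows share the end time", {
  net <- skeletonize_and_segment(grid_mask(3))
  set.seed(5)
  psis <- c(-0.8, -1.4, -2.2, -3.0)
  frames <- lapply(psis, function(p) {
    f <- matrix(FALSE, net$dim[1], net$dim[2])
    f[sample(length(f), 30)] <- TRUE
    f
  })
  ev <- map_events(frame_stack(frames, psis), net, filter_spillover = FALSE)
  expect_true(all(ev$time[ev$delta == 1] %in% abs(psis)))
  expect_true(all(ev$time[ev$delta == 0] == 3.0))
})

test_that("adding embolized pixels never delays an observed event", {
  net <- skeletonize_and_segment(grid_mask(3))
  set.seed(9)
  psis <- c(-1, -2, -3)
  base_frames <- lapply(psis, function(p) {
    f <- matrix(FALSE, net$dim[1], net$dim[2])
    f[sample(length(f), 20)] <- TRUE
    f
  })
  more_frames <- lapply(base_frames, function(f) {
    f[sample(length(f), 20)] <- TRUE
    f
  })
  ev1 <- map_events(frame_stack(base_frames, psis), net, filter_spillover = FALSE)
  ev2 <- map_events(frame_stack(more_frames, psis), net, filter_spillover = FALSE)
  both <- ev1$delta == 1 & ev2$delta == 1
  expect_true(all(ev2$time[both] <= ev1$time[both]))
  expect_true(all(ev2$delta >= ev1$delta))
})

test_that("rendered frames round-trip through map_events without spillover filtering", {
  net <- skeletonize_and_segment(rasterize_network(
    sim_vein_network(k = 3, kind = "lattice", seed = 2), spacing = 12))
  m <- nrow(net$segments)
  fr <- sim_frailties(net, tau2 = 0.5, kind = "icar", seed = 3)
  ev <- sim_events(net, fr, theta1 = 0, theta2 = 1.5, censor_time = 2, seed = 4)
  stack <- render_frames(ev, net)
  back <- map_events(stack, net, filter_spillover = FALSE)
  expect_equal(back$delta, ev$delta)
  expect_equal(back$time, ev$time)
})

test_that("event tables round-trip through CSV", {
  ev <- event_table(c(1, 0, 1), c(1.2, 3, 2.1))
  tmp <- tempfile(fileext = ".csv")
  write_event_table(ev, tmp)
  back <- read_event_table(tmp)
  expect_equal(back$delta, ev$delta)
  expect_equal(back$time, ev$time)
  expect_equal(attr(back, "censor_time"), 3)
})
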