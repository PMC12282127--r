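#' Frame stack of embolized pixels
#'
#' An ordered sequence of boolean rasters marking newly embolized pixels, one
#' water potential (MPa, non-positive and non-increasing over frames) per
#' frame.  Frames with tied water potentials are collapsed by taking the
#' union of their pixels.
#'
#' @param frames list of logical matrices, all of the same shape.
#' @param water_potentials numeric vector, one Psi (MPa) per frame,
#'   non-increasing.
#' @return Object of class `frame_stack`.
#' @export
frame_stack <- function(frames, water_potentials) {
  if (!length(frames)) stop("frame stack has zero frames")
  if (length(frames) != length(water_potentials))
    stop("need one water potential per frame")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share the same raster shape")
  if (is.unsorted(rev(water_potentials)))
    stop("water potentials must be non-increasing over frames")
  frames <- lapply(frames, function(f) f != 0)
  # collapse ties by pixel union
  if (anyDuplicated(water_potentials)) {
    grp <- match(water_potentials, unique(water_potentials))
    frames <- lapply(split(frames, grp), function(fs) Reduce(`|`, fs))
    water_potentials <- unique(water_potentials)
  }
  structure(list(frames = frames, water_potentials = water_potentials),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("frame stack: %d frames, Psi from %.3g to %.3g MPa, %d embolized pixels total\n",
              length(x$frames), x$water_potentials[1],
              x$water_potentials[length(x$frames)],
              sum(vapply(x$frames, sum, numeric(1)))))
  invisible(x)
}

#' Read a frame stack from PNG files plus a water-potential table
#'
#' @param paths character vector of raster paths, in frame order.
#' @param psi_csv CSV with columns `frame` (1-based index into `paths`) and
#'   `water_potential_MPa`; alternatively pass `water_potentials` directly.
#' @param water_potentials numeric vector used instead of `psi_csv`.
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(paths, psi_csv = NULL, water_potentials = NULL) {
  frames <- lapply(paths, function(p) read_raster(p) != 0)
  if (is.null(water_potentials)) {
    tab <- read.csv(psi_csv)
    water_potentials <- tab$water_potential_MPa[order(tab$frame)]
  }
  frame_stack(frames, water_potentials)
}

#' Right-censored event table
#'
#' Per-segment embolism event data: indicator `delta` (1 = embolism observed)
#' and `time`, the magnitude of water potential |Psi| (MPa) at the event, or
#' at the end of observation for censored segments.
#'
#' @param delta 0/1 vector.
#' @param time positive times, |Psi| in MPa.
#' @param segment optional segment ids (default 1..m).
#' @return data.frame of class `event_table` with columns `segment`, `delta`,
#'   `time` and a `censor_time` attribute (end-of-observation |Psi|).
#' @export
event_table <- function(delta, time, segment = seq_along(delta)) {
  delta <- as.integer(delta)
  if (!all(delta %in% c(0L, 1L))) stop("`delta` must be 0/1")
  if (length(time) != length(delta)) stop("`delta` and `time` lengths differ")
  if (any(time <= 0)) stop("event times must be positive (|Psi| in MPa)")
  censor_time <- if (any(delta == 0L)) unique(time[delta == 0L]) else max(time)
  if (length(censor_time) > 1)
    stop("all censored segments must share the end-of-observation time")
  structure(data.frame(segment = segment, delta = delta, time = time),
            censor_time = censor_time,
            class = c("event_table", "data.frame"))
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("event table: %d segments, %d events (%.0f%%), censoring at |Psi| = %.3g MPa\n",
              nrow(x), sum(x$delta), 100 * mean(x$delta),
              attr(x, "censor_time")))
  invisible(NextMethod())
}

#' Candidate embolism events for each vein segment
#'
#' A segment's candidate event is the first frame whose embolized pixels fall
#' within the segment's dilated skeleton (dilation radius = thickness / 2,
#' rounded up).  `coverage` is the fraction of the segment's skeleton pixels
#' that have an embolized pixel of that frame within the dilation radius.
#'
#' @param stack a [frame_stack()].
#' @param network a `vein_network` extracted from the matching mask.
#' @return List of candidates, each a list with `segment`, `frame`, `time`
#'   (|Psi| of the frame), `pixels` (coordinates of the embolized pixels
#'   assigned to the segment) and `coverage`.
#' @export
event_candidates <- function(stack, network) {
  if (!inherits(stack, "frame_stack")) stop("`stack` must be a frame_stack")
  fd <- dim(stack$frames[[1]])
  if (!all(fd == network$dim))
    stop("frame shape (", fd[1], "x", fd[2],
         ") does not match the mask (", network$dim[1], "x", network$dim[2], ")")
  m <- nrow(network$segments)
  radius <- ceiling(network$segments$thickness / 2)
  cands <- list()
  for (i in seq_len(m)) {
    skel <- network$pixels[[i]]
    r <- radius[i]
    for (f in seq_along(stack$frames)) {
      emb <- which_coords(stack$frames[[f]])
      if (!nrow(emb)) next
      d2 <- cross_dist2(skel, emb)
      near <- d2 <= r^2
      if (any(near)) {
        cands[[length(cands) + 1L]] <- list(
          segment = i, frame = f,
          time = abs(stack$water_potentials[f]),
          pixels = emb[apply(near, 2, any), , drop = FALSE],
          coverage = mean(apply(near, 1, any)))
        break
      }
    }
  }
  cands
}

# squared Euclidean distances between two (row, col) coordinate sets
cross_dist2 <- function(a, b) {
  outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2
}

#' Iterative spillover filtering of candidate events
#'
#' Optical embolism signals can bleed a few pixels across a junction, creating
#' spurious candidates on neighbouring segments.  A candidate is treated as
#' spillover and removed when (a) its embolized pixels lie within
#' `spill_radius` pixels of the skeleton of another segment holding an
#' accepted event in the same frame, and (b) they cover less than
#' `spill_frac` of the candidate segment's skeleton.  Rounds of simultaneous
#' removal are applied until a fixed point is reached (removal is monotone,
#' so the iteration always terminates, and re-applying the filter to its own
#' output changes nothing).
#'
#' @param candidates list as produced by [event_candidates()].
#' @param network the matching `vein_network`.
#' @param spill_radius pixel distance for condition (a); default 2.
#' @param spill_frac skeleton-coverage threshold for condition (b); default
#'   0.10.
#' @return The filtered candidate list.
#' @export
remove_spillover <- function(candidates, network, spill_radius = 2,
                             spill_frac = 0.10) {
  if (spill_radius < 0) stop("`spill_radius` must be non-negative")
  if (spill_frac < 0 || spill_frac > 1) stop("`spill_frac` must be in [0, 1]")
  repeat {
    if (length(candidates) <= 1) break
    frames <- vapply(candidates, `[[`, numeric(1), "frame")
    segs <- vapply(candidates, `[[`, numeric(1), "segment")
    cov <- vapply(candidates, `[[`, numeric(1), "coverage")
    drop <- logical(length(candidates))
    for (k in seq_along(candidates)) {
      if (cov[k] >= spill_frac) next           # substantial event: keep
      same_frame <- which(frames == frames[k] & segs != segs[k])
      for (o in same_frame) {
        d2 <- cross_dist2(candidates[[k]]$pixels,
                          network$pixels[[segs[o]]])
        if (min(d2) <= spill_radius^2) { drop[k] <- TRUE; break }
      }
    }
    if (!any(drop)) break
    candidates <- candidates[!drop]
  }
  candidates
}

#' Map a frame stack onto vein segments as right-censored event data
#'
#' Builds per-segment candidate events ([event_candidates()]), optionally
#' applies the spillover filter ([remove_spillover()]), and emits an
#' [event_table()]: delta_i = 1 with t_i = |Psi| of the candidate frame for
#' segments with an accepted event, else delta_i = 0 with t_i = |Psi| of the
#' final frame.
#'
#' @inheritParams event_candidates
#' @inheritParams remove_spillover
#' @param filter_spillover apply the spillover filter (default TRUE).
#' @return An [event_table()] with one row per segment of `network`.
#' @export
map_events <- function(stack, network, filter_spillover = TRUE,
                       spill_radius = 2, spill_frac = 0.10) {
  cands <- event_candidates(stack, network)
  if (filter_spillover)
    cands <- remove_spillover(cands, network, spill_radius, spill_frac)
  m <- nrow(network$segments)
  end_time <- abs(stack$water_potentials[length(stack$water_potentials)])
  delta <- integer(m)
  time <- rep(end_time, m)
  for (cd in cands) {
    delta[cd$segment] <- 1L
    time[cd$segment] <- cd$time
  }
  event_table(delta, time, segment = network$segments$id)
}

#' Write / read an event table as CSV
#'
#' Columns: `segment_id`, `delta`, `time_MPa`.
#' @param events an [event_table()].
#' @param path CSV path.
#' @export
write_event_table <- function(events, path) {
  write.csv(data.frame(segment_id = events$segment, delta = events$delta,
                       time_MPa = events$time),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  tab <- read.csv(path)
  need <- c("segment_id", "delta", "time_MPa")
  if (!all(need %in% names(tab)))
    stop("event CSV must have columns: ", paste(need, collapse = ", "))
  event_table(tab$delta, tab$time_MPa, segment = tab$segment_id)
}
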