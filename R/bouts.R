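#' Estimate the movement-detection noise floor of a track
#'
#' The camera/segmentation noise scale is estimated from the per-step
#' displacement during the first seconds of the record, when the animal is
#' still in post-contact immobility and any apparent displacement is
#' measurement noise. Isotropic centroid noise makes still-frame step lengths
#' Rayleigh distributed, so the noise scale sigma is estimated robustly as
#' `median / 1.177` (few steps fall in the window at coarse sampling, which
#' rules out empirical tail quantiles), and the detection threshold is set a
#' guard band of `factor` sigma above it: at the default 10 sigma a
#' false-positive moving frame is vanishingly rare over a full record even
#' allowing for the sampling error of sigma, while genuine steps remain an
#' order of magnitude larger on every substrate.
#'
#' @param track a (typically coarse-grained) [pci_track()].
#' @param pci_window seconds of the initial record assumed still.
#' @param factor guard band in units of the Rayleigh noise scale.
#' @return threshold displacement (mm) per step.
#' @export
estimate_move_threshold <- function(track, pci_window = 10, factor = 10) {
  stopifnot(inherits(track, "pci_track"))
  d <- step_lengths(track)
  sel <- track$t[-length(track$t)] < track$t0 + pci_window
  if (!any(sel)) sel[1] <- TRUE
  sigma <- stats::median(d[sel]) / 1.177
  factor * sigma
}

# per-step displacement (mm); step i spans [t_i, t_{i+1}]
step_lengths <- function(track) {
  sqrt(diff(track$x)^2 + diff(track$y)^2)
}

#' Segment a track into alternating immobility and movement bouts
#'
#' A frame-to-frame step is "moving" if its displacement exceeds
#' `move_threshold`. A movement bout terminates only after at least
#' `still_gap` seconds of consecutive non-moving steps ("no movement for more
#' than a couple of seconds"); shorter still gaps inside a movement bout are
#' bridged, while the terminal gap itself belongs to the following immobility
#' bout. Immobility bouts fill the complement, and the bout list starts with
#' the immobility period containing the first timestamp (the PCI).
#'
#' @param track a coarse-grained [pci_track()].
#' @param move_threshold displacement threshold (mm) per step, or `"auto"` to
#'   use [estimate_move_threshold()].
#' @param still_gap seconds of stillness that terminate a movement bout;
#'   must be at least the sampling interval.
#' @return data.frame of class `bout_events` with columns `kind`
#'   (`"immobility"`/`"movement"`), `start`, `end` (s) and
#'   `sequential_number` (1-based within kind).
#' @export
segment_bouts <- function(track, move_threshold = "auto", still_gap = 3.2) {
  stopifnot(inherits(track, "pci_track"))
  if (length(track$t) < 2) stop("track too short to segment")
  if (identical(move_threshold, "auto"))
    move_threshold <- estimate_move_threshold(track)
  stopifnot(move_threshold >= 0)  # 0 = any positive step counts as moving
  if (still_gap < track$dt - 1e-9)
    stop("still_gap must be at least the sampling interval")

  t <- track$t
  moving <- step_lengths(track) > move_threshold
  n <- length(moving)

  if (!any(moving)) {
    ev <- data.frame(kind = "immobility", start = t[1], end = t[n + 1],
                     sequential_number = 1L)
    class(ev) <- c("bout_events", "data.frame")
    return(ev)
  }

  # run-length encode the moving indicator over steps
  r <- rle(moving)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  # a still run is bridged into movement when it is interior (movement on
  # both sides) and shorter than still_gap
  state <- r$values
  for (j in seq_along(state)) {
    if (!r$values[j] && j > 1L && j < length(state)) {
      gap <- t[run_end[j] + 1L] - t[run_start[j]]
      if (gap < still_gap - 1e-9) state[j] <- TRUE
    }
  }
  # merge consecutive equal states
  step_state <- inverse.rle(list(lengths = r$lengths, values = state))
  r2 <- rle(step_state)
  e2 <- cumsum(r2$lengths)
  s2 <- e2 - r2$lengths + 1L
  ev <- data.frame(
    kind = ifelse(r2$values, "movement", "immobility"),
    start = t[s2], end = t[e2 + 1L]
  )
  ev$sequential_number <- stats::ave(seq_len(nrow(ev)), ev$kind,
                                     FUN = seq_along)
  class(ev) <- c("bout_events", "data.frame")
  ev
}

#' Time of first arrival at the arena wall
#'
#' @param track a [pci_track()].
#' @param wall_margin distance (mm) from an arena edge counting as arrival
#'   (about one body length).
#' @return arrival time (s), or `NA` if the wall is never reached.
#' @export
wall_arrival_time <- function(track, wall_margin = 5) {
  d <- pmin(track$x, ARENA_SIDE_MM - track$x,
            track$y, ARENA_SIDE_MM - track$y)
  i <- which(d <= wall_margin)
  if (!length(i)) return(NA_real_)
  track$t[i[1]]
}

#' Truncate a track at a time point
#'
#' Keeps the samples up to and including `t_end`, mirroring a record that
#' stops when the animal reaches the arena wall.
#'
#' @param track a [pci_track()].
#' @param t_end last time (s) to keep.
#' @return a shortened `pci_track`.
#' @export
truncate_track <- function(track, t_end) {
  stopifnot(inherits(track, "pci_track"))
  keep <- track$t <= t_end + 1e-9
  if (sum(keep) < 2) stop("truncation leaves fewer than 2 samples")
  out <- pci_track(track$individual_id, track$treatment, track$t[keep],
                   track$x[keep], track$y[keep], level = track$level)
  out$out_of_arena <- track$out_of_arena
  out
}

#' Clip a bout sequence at a time point
#'
#' Drops the bouts after `t_end` and truncates the bout in progress there,
#' mirroring a record that ends when the animal reaches the arena wall.
#'
#' @param bouts a [bout_sequence()].
#' @param t_end clipping time (s, absolute).
#' @return a shortened `bout_sequence` with `reached_wall` set.
#' @export
clip_bout_sequence <- function(bouts, t_end) {
  stopifnot(inherits(bouts, "bout_sequence"))
  imm <- numeric(0); mov <- numeric(0)
  tcur <- bouts$arrival_time
  if (t_end <= tcur) stop("clip time precedes the arrival time")
  for (k in seq_along(bouts$immobility)) {
    dk <- bouts$immobility[k]
    if (tcur + dk >= t_end) {
      if (t_end > tcur) imm <- c(imm, t_end - tcur)
      tcur <- t_end; break
    }
    imm <- c(imm, dk); tcur <- tcur + dk
    if (k > length(bouts$movement)) break
    dm <- bouts$movement[k]
    if (tcur + dm >= t_end) {
      mov <- c(mov, t_end - tcur); tcur <- t_end; break
    }
    mov <- c(mov, dm); tcur <- tcur + dm
  }
  bout_sequence(bouts$individual_id, bouts$treatment, imm, mov,
                arrival_time = bouts$arrival_time, reached_wall = TRUE)
}

#' Extract a bout sequence from segmented events
#'
#' Truncates segmented bout events to at most 16 immobility and 16 movement
#' periods and, optionally, at the individual's arrival at the arena wall
#' (events after the arrival are dropped and the event containing it is
#' clipped there).
#'
#' @param events a `bout_events` data.frame from [segment_bouts()].
#' @param max_pairs maximum periods of each kind to retain.
#' @param track the source track; required when `wall_rule` is `TRUE`.
#' @param wall_rule stop the sequence at wall arrival.
#' @param wall_margin see [wall_arrival_time()].
#' @param window observation window (s) passed to [bout_sequence()].
#' @return a [bout_sequence()].
#' @export
extract_sequence <- function(events, max_pairs = MAX_BOUT_PAIRS,
                             track = NULL, wall_rule = FALSE,
                             wall_margin = 5, window = OBS_WINDOW_S) {
  stopifnot(inherits(events, "data.frame"), nrow(events) >= 1)
  if (is.null(track))
    stop("extract_sequence needs the source track for metadata")
  reached_wall <- FALSE
  if (wall_rule) {
    wt <- wall_arrival_time(track, wall_margin)
    if (!is.na(wt)) {
      reached_wall <- TRUE
      keep <- events$start < wt
      events <- events[keep, , drop = FALSE]
      if (nrow(events) == 0) stop("wall reached before any bout completed")
      events$end[nrow(events)] <- min(events$end[nrow(events)], wt)
    }
  }
  imm <- events[events$kind == "immobility", , drop = FALSE]
  mov <- events[events$kind == "movement", , drop = FALSE]
  if (nrow(imm) == 0 || events$kind[1] != "immobility")
    stop("bout sequence must start with an immobility period (PCI)")
  imm <- imm[seq_len(min(nrow(imm), max_pairs)), , drop = FALSE]
  mov <- mov[seq_len(min(nrow(mov), max_pairs)), , drop = FALSE]
  # keep the alternation consistent after truncation: the last retained
  # movement cannot precede the last retained immobility by more than one
  if (nrow(mov) > nrow(imm)) mov <- mov[seq_len(nrow(imm)), , drop = FALSE]
  if (nrow(imm) > nrow(mov) + 1L)
    imm <- imm[seq_len(nrow(mov) + 1L), , drop = FALSE]
  di <- imm$end - imm$start
  dm <- mov$end - mov$start
  bout_sequence(track$individual_id, track$treatment,
                immobility = di, movement = if (nrow(mov)) dm else numeric(0),
                arrival_time = track$t0, reached_wall = reached_wall,
                window = window)
}
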