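#' Recursive pairwise coarse-graining of a track
#'
#' Replaces every two successive values of time, x and y by their average,
#' recursively, halving the series at each level. A trailing odd sample is
#' dropped. Four levels on a 10 fps track give an effective sampling
#' interval of 1.6 s.
#'
#' @param track a [pci_track()].
#' @param levels number of halvings (>= 0).
#' @return a coarse-grained `pci_track` with `level` incremented by `levels`
#'   and `dt` multiplied by `2^levels`.
#' @export
coarse_grain <- function(track, levels = 4L) {
  stopifnot(inherits(track, "pci_track"), levels >= 0)
  t <- track$t; x <- track$x; y <- track$y
  for (l in seq_len(levels)) {
    n2 <- length(t) %/% 2L
    if (n2 < 1L) stop("track too short for ", levels, " coarse-graining levels")
    o <- 2L * seq_len(n2) - 1L
    t <- (t[o] + t[o + 1L]) / 2
    x <- (x[o] + x[o + 1L]) / 2
    y <- (y[o] + y[o + 1L]) / 2
  }
  if (length(t) < 2L) stop("track too short for ", levels,
                           " coarse-graining levels")
  out <- pci_track(track$individual_id, track$treatment, t, x, y,
                   level = track$level + as.integer(levels))
  out$out_of_arena <- track$out_of_arena
  out
}

#' Running-average smoothing of a track
#'
#' Centred moving average of the coordinates with an odd window; near the
#' edges the window shrinks symmetrically, so a window of 1 is the identity.
#' Timestamps are unchanged. Used to damp centroid-resolution noise on sand
#' substrates, where the movement length scale approaches the measurement
#' error.
#'
#' @param track a [pci_track()].
#' @param window odd integer window length (samples).
#' @return a smoothed `pci_track`.
#' @export
smooth_track <- function(track, window = 3L) {
  stopifnot(inherits(track, "pci_track"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("smoothing window must be an odd integer >= 1")
  run_mean <- function(v) {
    n <- length(v)
    h <- (window - 1L) %/% 2L
    vapply(seq_len(n), function(i) {
      hi <- min(h, i - 1L, n - i)
      mean(v[(i - hi):(i + hi)])
    }, 0)
  }
  out <- pci_track(track$individual_id, track$treatment, track$t,
                   run_mean(track$x), run_mean(track$y),
                   level = track$level)
  out$out_of_arena <- track$out_of_arena
  out
}
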