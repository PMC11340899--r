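#' Geometric (log-spaced) time bins
#'
#' Divides the observation window into `n_bins` intervals of equal width on a
#' log scale; each bin's midpoint is the geometric mean of its edges.
#'
#' @param n_bins number of intervals.
#' @param t_min lower edge (s); defaults to the effective sampling interval
#'   of the 4x coarse-grained data.
#' @param t_max upper edge (s); defaults to the 90 min observation window.
#' @return data.frame with columns `bin`, `lower`, `upper`, `midpoint`.
#' @export
log_bins <- function(n_bins = 14L, t_min = 1.6, t_max = OBS_WINDOW_S) {
  stopifnot(n_bins >= 2, t_min > 0, t_max > t_min)
  edges <- exp(seq(log(t_min), log(t_max), length.out = n_bins + 1L))
  data.frame(bin = seq_len(n_bins), lower = edges[-length(edges)],
             upper = edges[-1], midpoint = sqrt(edges[-length(edges)] *
                                                  edges[-1]))
}

# shared machinery: per-individual per-bin means of `values` observed at
# times-since-PCI `tau`, averaged across the individuals that (a) have a
# sample in the bin and (b) moved at or before the bin's upper edge
profile_engine <- function(per_indiv, bins, kind) {
  n_bins <- nrow(bins)
  acc <- matrix(NA_real_, length(per_indiv), n_bins)
  for (i in seq_along(per_indiv)) {
    p <- per_indiv[[i]]
    idx <- findInterval(p$tau, c(bins$lower[1], bins$upper),
                        left.open = TRUE, rightmost.closed = FALSE)
    ok <- idx >= 1 & idx <= n_bins & p$tau > bins$lower[1] - 1e-12
    idx[!ok] <- NA
    if (!any(ok)) next
    m <- tapply(p$value[ok], idx[ok], mean)
    bs <- as.integer(names(m))
    contributes <- !is.na(p$first_move) & p$first_move <= bins$upper[bs]
    acc[i, bs[contributes]] <- m[contributes]
  }
  n_ind <- colSums(!is.na(acc))
  mu <- ifelse(n_ind > 0, colMeans(acc, na.rm = TRUE), NA_real_)
  sdv <- apply(acc, 2, stats::sd, na.rm = TRUE)
  upper <- ifelse(n_ind >= 2,
                  mu + stats::qt(0.975, pmax(n_ind - 1, 1)) *
                    sdv / sqrt(pmax(n_ind, 1)),
                  NA_real_)
  out <- data.frame(bin = bins$bin, midpoint = bins$midpoint, mean = mu,
                    upper_ci = upper, n_individuals = n_ind)
  structure(list(kind = kind, profile = out, bins = bins),
            class = "dispersal_profile")
}

#' @export
print.dispersal_profile <- function(x, ...) {
  cat(sprintf("<dispersal_profile> %s over %d log-time bins\n", x$kind,
              nrow(x$profile)))
  print(x$profile, digits = 4)
  invisible(x)
}

# Build per-individual tau/value records for the two profile kinds. The time
# axis is re-zeroed at each individual's PCI end and the reference position
# is the position at (the first sample at or after) that time.
profile_records <- function(tracks, pci_ends, kind, move_threshold) {
  lapply(tracks, function(tr) {
    pe <- pci_ends[[tr$individual_id]]
    if (is.null(pe) || is.na(pe)) return(NULL)
    ref_i <- which(tr$t >= pe - 1e-9)[1]
    if (is.na(ref_i) || ref_i >= length(tr$t)) return(NULL)
    thr <- if (identical(move_threshold, "auto"))
      estimate_move_threshold(tr) else move_threshold
    steps <- step_lengths(tr)
    move_t <- tr$t[-length(tr$t)][steps >= thr] - tr$t[ref_i]
    first_move <- if (length(move_t[move_t >= -1e-9]))
      min(move_t[move_t >= -1e-9]) else NA_real_
    if (kind == "MSD") {
      tau <- tr$t[ref_i:length(tr$t)] - tr$t[ref_i]
      value <- (tr$x[ref_i:length(tr$t)] - tr$x[ref_i])^2 +
        (tr$y[ref_i:length(tr$t)] - tr$y[ref_i])^2
    } else {
      i <- ref_i:(length(tr$t) - 1L)
      tau <- tr$t[i] - tr$t[ref_i]
      value <- steps[i] / tr$dt
    }
    list(tau = tau, value = value, first_move = first_move)
  })
}

#' Log-binned mean squared displacement profile
#'
#' For each individual, the squared displacement from its position at the
#' end of PCI is averaged within each log-time bin (time re-zeroed at the
#' PCI end); the profile is the across-individual mean per bin, over the
#' individuals that have samples in the bin and have moved by the bin's
#' upper edge, with the upper 95% t-confidence limit. Bins with fewer than
#' two contributing individuals carry no confidence limit.
#'
#' @param tracks list of coarse-grained [pci_track()]s (or a [pci_cohort()]).
#' @param pci_ends named numeric vector/list of PCI end times (s, absolute)
#'   per individual id.
#' @param move_threshold step displacement (mm) counting as movement, used
#'   by the "has moved" contribution rule; `"auto"` estimates the noise
#'   floor per track via [estimate_move_threshold()].
#' @param n_bins,t_min,t_max binning, see [log_bins()].
#' @return a `dispersal_profile` (MSD in mm^2).
#' @export
msd_profile <- function(tracks, pci_ends, move_threshold = "auto",
                        n_bins = 14L, t_min = 1.6, t_max = OBS_WINDOW_S) {
  if (inherits(tracks, "pci_cohort")) tracks <- tracks$tracks
  bins <- log_bins(n_bins, t_min, t_max)
  recs <- Filter(Negate(is.null),
                 profile_records(tracks, as.list(pci_ends), "MSD",
                                 move_threshold))
  profile_engine(recs, bins, "MSD")
}

#' Log-binned mean instantaneous speed profile
#'
#' As [msd_profile()], with the per-step displacement divided by the
#' sampling interval as the per-sample value.
#'
#' @inheritParams msd_profile
#' @return a `dispersal_profile` (MIS in mm/s).
#' @export
mis_profile <- function(tracks, pci_ends, move_threshold = "auto",
                        n_bins = 14L, t_min = 1.6, t_max = OBS_WINDOW_S) {
  if (inherits(tracks, "pci_cohort")) tracks <- tracks$tracks
  bins <- log_bins(n_bins, t_min, t_max)
  recs <- Filter(Negate(is.null),
                 profile_records(tracks, as.list(pci_ends), "MIS",
                                 move_threshold))
  profile_engine(recs, bins, "MIS")
}

## ---- segmented regression ----------------------------------------------------

# Davies-type supremum test for the existence of one breakpoint:
# H0 linear, H1 one breakpoint. The score statistic for an added hinge
# (x - c)+ is evaluated on a grid of interior candidates; the p-value uses
# Davies' (1987) upper bound for the supremum of |t| over the grid.
davies_test <- function(x, y, grid = NULL) {
  n <- length(x)
  if (is.null(grid)) grid <- sort(unique(x))[2:(length(unique(x)) - 1L)]
  tstat <- vapply(grid, function(c0) {
    u <- pmax(x - c0, 0)
    f <- stats::lm(y ~ x + u)
    s <- summary(f)$coefficients
    if (nrow(s) < 3 || is.na(s[3, 3])) 0 else s[3, 3]
  }, 0)
  M <- max(abs(tstat))
  V <- sum(abs(diff(tstat)))
  p <- 2 * stats::pnorm(-M) + V * exp(-M^2 / 2) / sqrt(8 * pi)
  list(statistic = M, p = min(1, p), grid = grid, tstat = tstat)
}

#' One-breakpoint segmented (broken-stick) regression
#'
#' Continuous piecewise-linear least squares with a single estimated
#' breakpoint, fitted by iterative linearisation: at each iteration the
#' working model `y ~ x + (x - psi)+ + I(x > psi)` is refitted and the
#' breakpoint updated by `psi <- psi + gamma / beta2`. The existence of the
#' breakpoint is tested first (Davies-type supremum score test over the
#' interior design points); when the null of no breakpoint is not rejected
#' at `alpha`, the simple linear regression is returned instead with both
#' slopes equal.
#'
#' @param x,y numeric vectors (at least 6 points); rows with missing values
#'   are dropped.
#' @param psi starting breakpoint (defaults to the median of `x`).
#' @param alpha level of the breakpoint-existence test.
#' @param max_iter,tol iteration control; non-convergence is an error
#'   reporting the last breakpoint.
#' @param force `"auto"` (Davies test decides), `"segmented"` or `"linear"`.
#' @return an object of class `segmented_fit` with elements `model`
#'   (`"segmented"` or `"linear"`), `slope1`, `slope2` (estimates with
#'   95% CIs), `psi` (estimate with 95% CI; `NA` for a linear fit),
#'   `davies_p`, `r2adj` and `n`.
#' @export
segmented_fit <- function(x, y, psi = NULL, alpha = 0.05, max_iter = 50L,
                          tol = 1e-8, force = c("auto", "segmented",
                                                "linear")) {
  force <- match.arg(force)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 6) stop("segmented regression needs at least 6 points")
  dv <- davies_test(x, y)

  linear_out <- function() {
    f <- stats::lm(y ~ x)
    s <- summary(f)
    ci <- stats::confint(f)["x", ]
    sl <- c(estimate = unname(coef(f)["x"]), lower = ci[[1]],
            upper = ci[[2]])
    structure(list(model = "linear", slope1 = sl, slope2 = sl,
                   psi = c(estimate = NA_real_, lower = NA_real_,
                           upper = NA_real_),
                   davies_p = dv$p, r2adj = s$adj.r.squared, n = n,
                   fit = f),
              class = "segmented_fit")
  }
  if (force == "linear" || (force == "auto" && dv$p >= alpha))
    return(linear_out())

  if (is.null(psi)) psi <- stats::median(x)
  rng <- range(x)
  ssr_at <- function(p) {
    f <- stats::lm(y ~ x + pmax(x - p, 0))
    sum(stats::resid(f)^2)
  }
  last_psi <- psi
  ssr <- ssr_at(psi)
  fit <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    u <- pmax(x - psi, 0)
    v <- -(x > psi)
    fit <- stats::lm(y ~ x + u + v)
    b <- coef(fit)
    if (any(is.na(b[c("u", "v")]))) break
    if (abs(b[["v"]]) < 1e-10) { converged <- TRUE; break }
    step <- b[["v"]] / b[["u"]]
    # damp the update (halve the step) until the residual sum of squares of
    # the hinge model no longer worsens, which prevents oscillation
    psi_new <- psi; ssr_new <- ssr
    for (h in 0:10) {
      cand <- min(max(psi + step / 2^h, rng[1] + 1e-8), rng[2] - 1e-8)
      sc <- ssr_at(cand)
      if (sc <= ssr + 1e-12) { psi_new <- cand; ssr_new <- sc; break }
    }
    if (abs(psi_new - psi) < tol * max(1, diff(rng))) {
      psi <- psi_new; converged <- TRUE; break
    }
    last_psi <- psi <- psi_new
    ssr <- ssr_new
  }
  if (!converged) {
    # rescue: profile the residual sum of squares of the hinge model over a
    # fine deterministic grid of candidate breakpoints and take the minimum
    grid <- seq(rng[1] + 0.02 * diff(rng), rng[2] - 0.02 * diff(rng),
                length.out = 201L)
    ssr_grid <- vapply(grid, ssr_at, 0)
    if (all(!is.finite(ssr_grid)))
      stop("breakpoint iteration did not converge after ", max_iter,
           " iterations; last psi = ", signif(last_psi, 6))
    psi <- grid[which.min(ssr_grid)]
  }
  if (is.null(fit) || any(is.na(coef(fit)[c("u")])))
    stop("segmented fit failed; last psi = ", signif(last_psi, 6))

  # final working model at the converged psi for inference
  u <- pmax(x - psi, 0)
  v <- -(x > psi)
  wfit <- stats::lm(y ~ x + u + v)
  b <- coef(wfit)
  V <- stats::vcov(wfit)
  dof <- wfit$df.residual
  tq <- stats::qt(0.975, dof)
  s1 <- b[["x"]]
  s1_se <- sqrt(V["x", "x"])
  s2 <- b[["x"]] + b[["u"]]
  s2_se <- sqrt(V["x", "x"] + V["u", "u"] + 2 * V["x", "u"])
  psi_se <- sqrt(V["v", "v"]) / abs(b[["u"]])
  # refit without the working term for R2
  ffit <- stats::lm(y ~ x + u)
  structure(list(
    model = "segmented",
    slope1 = c(estimate = s1, lower = s1 - tq * s1_se,
               upper = s1 + tq * s1_se),
    slope2 = c(estimate = s2, lower = s2 - tq * s2_se,
               upper = s2 + tq * s2_se),
    psi = c(estimate = psi, lower = psi - tq * psi_se,
            upper = psi + tq * psi_se),
    davies_p = dv$p, r2adj = summary(ffit)$adj.r.squared, n = n,
    fit = ffit, converged = converged, iterations = it
  ), class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  if (x$model == "linear") {
    cat(sprintf(
      "<segmented_fit> linear (no breakpoint, Davies p = %.3g): slope %.3f [%.3f, %.3f], R2adj = %.1f%%\n",
      x$davies_p, x$slope1[["estimate"]], x$slope1[["lower"]],
      x$slope1[["upper"]], 100 * x$r2adj))
  } else {
    cat(sprintf(
      "<segmented_fit> breakpoint %.3f [%.3f, %.3f] (Davies p = %.3g), slopes %.3f / %.3f, R2adj = %.1f%%\n",
      x$psi[["estimate"]], x$psi[["lower"]], x$psi[["upper"]], x$davies_p,
      x$slope1[["estimate"]], x$slope2[["estimate"]], 100 * x$r2adj))
  }
  invisible(x)
}

#' Fit a dispersal profile on log or linear axes
#'
#' Convenience wrapper: regresses the profile's per-bin means against the
#' log10 bin midpoints, on log10 means for MSD (log-log) and linear means
#' for MIS (semi-log), dropping bins with fewer than two contributing
#' individuals.
#'
#' @param profile a `dispersal_profile`.
#' @param log_y take log10 of the bin means (default `TRUE` for MSD).
#' @param ... passed to [segmented_fit()].
#' @return a `segmented_fit`.
#' @export
fit_dispersal_profile <- function(profile, log_y = profile$kind == "MSD",
                                  ...) {
  stopifnot(inherits(profile, "dispersal_profile"))
  p <- profile$profile
  keep <- p$n_individuals >= 2 & is.finite(p$mean)
  if (log_y) keep <- keep & p$mean > 0
  x <- log10(p$midpoint[keep])
  y <- if (log_y) log10(p$mean[keep]) else p$mean[keep]
  segmented_fit(x, y, ...)
}

#' Classify the diffusion regime of a log-log MSD fit
#'
#' On log-log axes a slope of 1 is ordinary diffusion. The designated slope
#' is the segment covering the most bins (the single slope for a linear
#' fit); its 95% CI entirely below 1 is sub-diffusive, entirely above is
#' super-diffusive, straddling 1 is diffusive.
#'
#' @param fit a `segmented_fit` of log10 MSD against log10 time.
#' @param x values (log10 time) used in the fit, to count bins per segment;
#'   optional when the fit is linear.
#' @return one of `"sub_diffusive"`, `"diffusive"`, `"super_diffusive"`.
#' @export
classify_diffusion <- function(fit, x = NULL) {
  stopifnot(inherits(fit, "segmented_fit"))
  sl <- if (fit$model == "linear") fit$slope1 else {
    if (is.null(x)) x <- stats::model.frame(fit$fit)$x
    n_left <- sum(x <= fit$psi[["estimate"]])
    if (n_left >= length(x) - n_left) fit$slope1 else fit$slope2
  }
  if (sl[["upper"]] < 1) "sub_diffusive"
  else if (sl[["lower"]] > 1) "super_diffusive"
  else "diffusive"
}

#' Start-to-finish displacement
#'
#' Euclidean distance (mm) between the drop point and the final position.
#'
#' @param track a [pci_track()], or a length-2 numeric start position.
#' @param finish final position, required when `track` is a position.
#' @param wall_rule when `TRUE` and the track reaches the wall, the final
#'   position is the position at wall arrival.
#' @param wall_margin see [wall_arrival_time()].
#' @return displacement (mm).
#' @export
start_finish_displacement <- function(track, finish = NULL,
                                      wall_rule = FALSE, wall_margin = 5) {
  if (inherits(track, "pci_track")) {
    start <- c(track$x[1], track$y[1])
    end_i <- length(track$t)
    if (wall_rule) {
      wt <- wall_arrival_time(track, wall_margin)
      if (!is.na(wt)) end_i <- which(track$t >= wt)[1]
    }
    finish <- c(track$x[end_i], track$y[end_i])
  } else {
    start <- as.numeric(track)
    stopifnot(length(start) == 2, length(finish) == 2)
  }
  sqrt(sum((finish - start)^2))
}

#' Per-individual start-to-finish displacements for a cohort of tracks
#'
#' @param cohort a [pci_cohort()] with tracks.
#' @param ... passed to [start_finish_displacement()].
#' @return data.frame with `individual_id`, `treatment`, `displacement` (mm)
#'   and `at_ceiling` (within 1 mm of the 159 mm half-diagonal ceiling).
#' @export
cohort_displacements <- function(cohort, ...) {
  stopifnot(inherits(cohort, "pci_cohort"))
  rows <- lapply(cohort$tracks, function(tr) {
    d <- start_finish_displacement(tr, ...)
    data.frame(individual_id = tr$individual_id, treatment = tr$treatment,
               displacement = d,
               at_ceiling = d >= ARENA_HALF_DIAGONAL_MM - 1)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
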