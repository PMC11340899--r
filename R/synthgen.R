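## Synthetic cohorts with the statistical structure the analysis assumes:
## per-individual alternating bout sequences whose log10 durations trend
## linearly in log10 event index with random intercepts/slopes, and 2-D
## tracks rendering immobility as stillness (plus centroid jitter at the
## camera-noise scale) and movement as a correlated random walk in the
## 225 x 225 mm arena.

#' Scenario specification for the synthetic generator
#'
#' Defaults parameterise the three study substrates. Trend slopes are the
#' reported substrate estimates (immobility -1.18 / -1.00 / -0.36 and
#' movement +1.16 / +0.38 / +0.01 for paper / shallow sand / deep sand);
#' sample sizes are 22 / 8 / 8 individuals; intercepts put PCI at the
#' several-hundred-second scale and the first movement at the one-second
#' scale on paper; per-substrate speeds and turning noise are calibrated so
#' that start-to-finish displacements reproduce the reported medians
#' (about 114.5 / 12.4 / 4.1 mm) with speed increasing over successive
#' movement bouts on paper and decaying on sand.
#'
#' @param treatment `"paper"`, `"shallow_sand"` or `"deep_sand"`; selects
#'   the per-substrate defaults, all of which can be overridden.
#' @param n_individuals cohort size.
#' @param imm_intercept,imm_slope log10-duration intercept (at event 1) and
#'   log10-log10 slope of the immobility trend.
#' @param mov_intercept,mov_slope same for movement durations.
#' @param sd_intercept,sd_slope,sd_resid random-effect and residual SDs on
#'   the log10 scale.
#' @param base_speed movement speed (mm/s) during the first movement bout.
#' @param speed_trend multiplicative speed factor per successive movement
#'   bout (> 1 accelerates, < 1 decelerates).
#' @param turn_sd SD (radians) of the wrapped-normal turning angle per raw
#'   frame of the correlated random walk (larger = more tortuous).
#' @param jitter_sd centroid jitter SD (mm) during immobility, emulating
#'   camera noise.
#' @param imm_law marginal law used by [sample_durations()] draws for this
#'   scenario (`list(family =, ...)`); not used by the trend generator.
#' @param window observation window (s).
#' @param max_pairs bout pairs cap.
#' @param fps raw track sampling rate (frames/s).
#' @return a list of class `scenario_spec`.
#' @export
scenario_spec <- function(treatment = c("paper", "shallow_sand",
                                        "deep_sand"),
                          n_individuals = NULL,
                          imm_intercept = 2.45, imm_slope = NULL,
                          mov_intercept = NULL, mov_slope = NULL,
                          sd_intercept = 0.35, sd_slope = 0.15,
                          sd_resid = 0.45,
                          base_speed = NULL, speed_trend = NULL,
                          turn_sd = NULL, jitter_sd = 0.05,
                          imm_law = list(family = "lognormal", mu = 4.5,
                                         sigma = 1.4),
                          window = OBS_WINDOW_S,
                          max_pairs = MAX_BOUT_PAIRS, fps = 10) {
  treatment <- match.arg(treatment)
  defaults <- list(
    paper = list(n = 22L, imm_slope = -1.18, mov_intercept = 0.0,
                 mov_slope = 1.16, base_speed = 2.0, speed_trend = 1.10,
                 turn_sd = 0.08),
    shallow_sand = list(n = 8L, imm_slope = -1.00, mov_intercept = 0.30,
                        mov_slope = 0.38, base_speed = 0.75,
                        speed_trend = 0.90, turn_sd = 0.2),
    deep_sand = list(n = 8L, imm_slope = -0.36, mov_intercept = 0.30,
                     mov_slope = 0.01, base_speed = 0.80,
                     speed_trend = 0.80, turn_sd = 0.4)
  )[[treatment]]
  spec <- list(
    treatment = treatment,
    n_individuals = if (is.null(n_individuals)) defaults$n
                    else as.integer(n_individuals),
    imm_intercept = imm_intercept,
    imm_slope = if (is.null(imm_slope)) defaults$imm_slope else imm_slope,
    mov_intercept = if (is.null(mov_intercept)) defaults$mov_intercept
                    else mov_intercept,
    mov_slope = if (is.null(mov_slope)) defaults$mov_slope else mov_slope,
    sd_intercept = sd_intercept, sd_slope = sd_slope, sd_resid = sd_resid,
    base_speed = if (is.null(base_speed)) defaults$base_speed
                 else base_speed,
    speed_trend = if (is.null(speed_trend)) defaults$speed_trend
                  else speed_trend,
    turn_sd = if (is.null(turn_sd)) defaults$turn_sd else turn_sd,
    jitter_sd = jitter_sd, imm_law = imm_law,
    window = window, max_pairs = as.integer(max_pairs), fps = fps
  )
  stopifnot(spec$n_individuals >= 2, spec$sd_resid >= 0,
            spec$base_speed >= 0, spec$jitter_sd >= 0)
  class(spec) <- "scenario_spec"
  spec
}

#' Draw i.i.d. durations from a parametric law
#'
#' Inverse-CDF sampling from the continuous exponential, log-normal or
#' power-law model, reproducible under a fixed seed.
#'
#' @param law list with `family` (`"exponential"`, `"lognormal"`,
#'   `"powerlaw"`) and its parameters: `lambda` (1/s); `mu`, `sigma` (of the
#'   natural-log duration); `alpha` (> 1) and `xmin` (s).
#' @param n number of draws.
#' @param seed optional integer seed (set locally).
#' @return numeric vector of durations (s).
#' @export
sample_durations <- function(law, n, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  u <- stats::runif(n)
  switch(law$family,
    exponential = {
      stopifnot(law$lambda > 0)
      -log(1 - u) / law$lambda
    },
    lognormal = {
      stopifnot(law$sigma >= 0)
      exp(law$mu + law$sigma * stats::qnorm(u))
    },
    powerlaw = {
      stopifnot(law$alpha > 1, law$xmin > 0)
      law$xmin * (1 - u)^(-1 / (law$alpha - 1))
    },
    stop("unknown law family: ", law$family))
}

#' Generate a synthetic bout cohort
#'
#' Per individual, a random intercept and slope deviation are drawn, and the
#' duration of bout `k` is `10^(a_i + b_i * log10(k) + eps)` with i.i.d.
#' normal residuals on the log10 scale, separately for immobility and
#' movement. The sequence is truncated so that the cumulative time stays
#' within the observation window and at most `max_pairs` pairs are kept.
#'
#' @param spec a [scenario_spec()].
#' @param seed integer root seed; per-individual streams are derived from it
#'   so individuals are reproducible independently.
#' @param ids optional character vector of individual ids (length
#'   `n_individuals`); lets the same animal appear under several treatments,
#'   as in the repeated study design.
#' @return a [pci_cohort()] of bout sequences (with synthetic weights).
#' @export
gen_bout_cohort <- function(spec, seed = 1L, ids = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(ids))
    ids <- sprintf("%s_%02d", spec$treatment, seq_len(spec$n_individuals))
  stopifnot(length(ids) == spec$n_individuals)
  bouts <- vector("list", spec$n_individuals)
  weights <- numeric(0)
  for (i in seq_len(spec$n_individuals)) {
    id <- ids[i]
    set.seed((as.numeric(seed) * 1000 + i) %% 2147483647)
    a_imm <- spec$imm_intercept + stats::rnorm(1, 0, spec$sd_intercept)
    b_imm <- spec$imm_slope + stats::rnorm(1, 0, spec$sd_slope)
    a_mov <- spec$mov_intercept + stats::rnorm(1, 0, spec$sd_intercept)
    b_mov <- spec$mov_slope + stats::rnorm(1, 0, spec$sd_slope)
    arr <- stats::runif(1, 30, 90)
    imm <- numeric(0); mov <- numeric(0)
    tcur <- arr
    for (k in seq_len(spec$max_pairs)) {
      ik <- 10^(a_imm + b_imm * log10(k) + stats::rnorm(1, 0,
                                                        spec$sd_resid))
      if (tcur + ik > spec$window) break
      imm <- c(imm, ik); tcur <- tcur + ik
      mk <- 10^(a_mov + b_mov * log10(k) + stats::rnorm(1, 0,
                                                        spec$sd_resid))
      if (tcur + mk > spec$window) break
      mov <- c(mov, mk); tcur <- tcur + mk
    }
    if (!length(imm)) {
      # PCI alone outlasted the window: record the censored PCI
      imm <- spec$window - arr
    }
    bouts[[i]] <- bout_sequence(id, spec$treatment, imm, mov,
                                arrival_time = arr,
                                window = spec$window)
    weights[id] <- round(stats::rlnorm(1, log(0.036), 0.7), 4)
  }
  pci_cohort(bouts = bouts, weights = weights)
}

#' Render a bout sequence as a raw 2-D track
#'
#' Generates a raw track at `spec$fps` samples per second starting at the
#' drop point in the arena centre. Immobility bouts are stationary apart
#' from isotropic Gaussian centroid jitter at the camera-noise scale;
#' during movement bout `k` the animal performs a correlated random walk at
#' speed `base_speed * speed_trend^(k-1)` with wrapped-normal turning
#' angles, reflected at the arena walls. Once the animal reaches the wall
#' (within `wall_margin` mm) it stops for the remainder of the record,
#' mirroring the observed behaviour on the hard substrate.
#'
#' @param bouts a [bout_sequence()].
#' @param spec a [scenario_spec()].
#' @param seed integer seed.
#' @param wall_margin wall-arrival distance (mm); `Inf` disables stopping.
#' @return a raw [pci_track()] (level 0).
#' @export
gen_track <- function(bouts, spec, seed = 1L, wall_margin = 5) {
  stopifnot(inherits(bouts, "bout_sequence"),
            inherits(spec, "scenario_spec"))
  set.seed(as.numeric(seed) %% 2147483647)
  dt <- 1 / spec$fps
  t_end <- spec$window
  n <- floor((t_end - bouts$arrival_time) / dt) + 1L
  t <- bouts$arrival_time + dt * (seq_len(n) - 1L)
  x <- numeric(n); y <- numeric(n)
  x[1] <- ARENA_HALF_WIDTH_MM; y[1] <- ARENA_HALF_WIDTH_MM

  # per-frame state: movement bout index (0 = immobile)
  state <- integer(n)
  tcur <- bouts$arrival_time
  for (k in seq_along(bouts$immobility)) {
    tcur <- tcur + bouts$immobility[k]
    if (k <= length(bouts$movement)) {
      sel <- t >= tcur & t < tcur + bouts$movement[k]
      state[sel] <- k
      tcur <- tcur + bouts$movement[k]
    }
  }

  heading <- stats::runif(1, 0, 2 * pi)
  stopped <- FALSE
  for (i in 2:n) {
    if (!stopped && state[i - 1L] > 0L) {
      k <- state[i - 1L]
      sp <- spec$base_speed * spec$speed_trend^(k - 1L)
      heading <- heading + stats::rnorm(1, 0, spec$turn_sd)
      nx <- x[i - 1L] + sp * dt * cos(heading)
      ny <- y[i - 1L] + sp * dt * sin(heading)
      # reflective walls
      if (nx < 0) { nx <- -nx; heading <- pi - heading }
      if (nx > ARENA_SIDE_MM) { nx <- 2 * ARENA_SIDE_MM - nx
                                heading <- pi - heading }
      if (ny < 0) { ny <- -ny; heading <- -heading }
      if (ny > ARENA_SIDE_MM) { ny <- 2 * ARENA_SIDE_MM - ny
                                heading <- -heading }
      x[i] <- nx; y[i] <- ny
      if (is.finite(wall_margin) &&
          min(nx, ARENA_SIDE_MM - nx, ny, ARENA_SIDE_MM - ny) <=
            wall_margin) stopped <- TRUE
    } else {
      x[i] <- x[i - 1L]; y[i] <- y[i - 1L]
    }
  }
  if (spec$jitter_sd > 0) {
    # centroid-detection noise affects every frame
    x <- pmin(pmax(x + stats::rnorm(n, 0, spec$jitter_sd), 0),
              ARENA_SIDE_MM)
    y <- pmin(pmax(y + stats::rnorm(n, 0, spec$jitter_sd), 0),
              ARENA_SIDE_MM)
  }
  pci_track(bouts$individual_id, bouts$treatment, t, x, y, level = 0L)
}

#' Generate the full synthetic study
#'
#' The three-substrate study at its design sample sizes (22 paper, 8 shallow
#' sand, 8 deep sand) with the repeated design: every sand-tested animal is
#' also tested on paper (ids AL01-AL08 on shallow sand, AL09-AL16 on deep
#' sand, AL01-AL22 on paper). Bout sequences come from the trend generator
#' and, if requested, a raw track is rendered for every individual.
#'
#' @param seed integer root seed.
#' @param tracks also render tracks (slower).
#' @param specs optional named list of [scenario_spec()]s to override the
#'   per-substrate defaults.
#' @return a named list of [pci_cohort()]s (`paper`, `shallow_sand`,
#'   `deep_sand`), each holding bouts (and tracks).
#' @export
simulate_study <- function(seed = 1L, tracks = TRUE, specs = NULL) {
  if (is.null(specs))
    specs <- lapply(stats::setNames(TREATMENTS, TREATMENTS), scenario_spec)
  id_pool <- function(tr, n) {
    start <- switch(tr, paper = 1L, shallow_sand = 1L, deep_sand = 9L, 1L)
    sprintf("AL%02d", seq.int(start, length.out = n))
  }
  out <- list()
  for (tr in names(specs)) {
    spec <- specs[[tr]]
    cohort <- gen_bout_cohort(spec, seed = seed + match(tr, TREATMENTS),
                              ids = id_pool(tr, spec$n_individuals))
    if (tracks) {
      cohort$tracks <- lapply(seq_along(cohort$bouts), function(i) {
        gen_track(cohort$bouts[[i]], spec,
                  seed = (as.numeric(seed) + match(tr, TREATMENTS)) *
                    10000 + i)
      })
      # data collection ends at wall arrival: clip the bout record there,
      # as in the field protocol (only ever reached on the hard substrate)
      for (i in seq_along(cohort$tracks)) {
        wt <- wall_arrival_time(cohort$tracks[[i]])
        if (!is.na(wt) && wt > pci_end(cohort$bouts[[i]]))
          cohort$bouts[[i]] <- clip_bout_sequence(cohort$bouts[[i]], wt)
      }
    }
    out[[tr]] <- cohort
  }
  out
}
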