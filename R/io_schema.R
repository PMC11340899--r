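#' Normalise substrate treatment labels
#'
#' Field data sheets label the three substrates `Paper`, `2.3sand` and
#' `4.6sand`; internally the package uses `paper`, `shallow_sand` and
#' `deep_sand`.
#'
#' @param x character vector of labels in either convention.
#' @return character vector of normalised labels.
#' @export
normalize_treatment <- function(x) {
  map <- c(
    "Paper" = "paper", "paper" = "paper",
    "2.3sand" = "shallow_sand", "shallow_sand" = "shallow_sand",
    "Shallow sand" = "shallow_sand",
    "4.6sand" = "deep_sand", "deep_sand" = "deep_sand",
    "Deep sand" = "deep_sand"
  )
  out <- unname(map[as.character(x)])
  if (anyNA(out)) {
    stop("unknown treatment label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

#' Sheet-style label for a normalised treatment
#' @param x normalised treatment labels.
#' @return character vector of sheet labels (`Paper`, `2.3sand`, `4.6sand`).
#' @export
treatment_label <- function(x) {
  map <- c(paper = "Paper", shallow_sand = "2.3sand", deep_sand = "4.6sand")
  out <- unname(map[as.character(x)])
  if (anyNA(out)) stop("unknown normalised treatment: ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

TREATMENTS <- c("paper", "shallow_sand", "deep_sand")

#' Construct a centroid track
#'
#' A track is the time-ordered 2-D centroid position of one individual at a
#' fixed sampling interval, with the arena geometry attached. Coordinates are
#' in mm with the origin at the arena's lower-left corner; the drop point is
#' the arena centre (112.5, 112.5).
#'
#' @param individual_id identifier, coerced to character.
#' @param treatment substrate label (any convention accepted by
#'   [normalize_treatment()]).
#' @param t numeric vector of timestamps (s), strictly increasing with
#'   constant spacing.
#' @param x,y numeric coordinate vectors (mm), same length as `t`.
#' @param level coarse-graining level already applied (0 = raw).
#' @param tol relative tolerance on spacing regularity.
#' @return an object of class `pci_track`.
#' @export
pci_track <- function(individual_id, treatment, t, x, y, level = 0L,
                      tol = 1e-6) {
  stopifnot(length(t) >= 2, length(x) == length(t), length(y) == length(t))
  dts <- diff(t)
  dt <- stats::median(dts)
  if (dt <= 0 || any(dts <= 0)) stop("timestamps must be strictly increasing")
  if (max(abs(dts - dt)) > tol * dt + 1e-12) {
    stop("irregular sampling: spacing varies by more than tolerance (dt = ",
         signif(dt, 6), ")")
  }
  out_of_arena <- any(x < 0 | x > ARENA_SIDE_MM | y < 0 | y > ARENA_SIDE_MM)
  if (out_of_arena) {
    warning("track ", individual_id,
            " has positions outside the 225 mm arena; kept and flagged")
  }
  structure(
    list(
      individual_id = as.character(individual_id),
      treatment = normalize_treatment(treatment),
      t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
      dt = dt, t0 = t[1], level = as.integer(level),
      arena_half_width = ARENA_HALF_WIDTH_MM,
      arena_half_diagonal = ARENA_HALF_DIAGONAL_MM,
      out_of_arena = out_of_arena
    ),
    class = "pci_track"
  )
}

#' @export
print.pci_track <- function(x, ...) {
  cat(sprintf(
    "<pci_track> %s on %s: %d samples, dt = %g s, t = [%g, %g] s, level %d\n",
    x$individual_id, x$treatment, length(x$t), x$dt, x$t[1],
    x$t[length(x$t)], x$level))
  invisible(x)
}

#' @export
as.data.frame.pci_track <- function(x, ...) {
  data.frame(time = x$t, x = x$x, y = x$y)
}

#' Construct an alternating bout sequence
#'
#' Alternating immobility/movement durations for one individual.
#' `immobility[1]` is the post-contact immobility (PCI) itself. A sequence
#' holds `kI` immobility and `kM` movement durations with
#' `kM %in% c(kI - 1, kI)`: the record either ends during (or right after)
#' a movement period or during an immobility period.
#'
#' @param individual_id identifier.
#' @param treatment substrate label.
#' @param immobility,movement positive duration vectors (s).
#' @param arrival_time time (s) the animal landed on the substrate.
#' @param reached_wall logical, whether the individual reached the arena wall.
#' @param window observation window (s) that must contain all bouts.
#' @return an object of class `bout_sequence`.
#' @export
bout_sequence <- function(individual_id, treatment, immobility, movement,
                          arrival_time = 0, reached_wall = FALSE,
                          window = OBS_WINDOW_S) {
  kI <- length(immobility); kM <- length(movement)
  if (kI < 1) stop("at least one immobility period (the PCI) is required")
  if (!(kM %in% c(kI - 1L, kI)))
    stop("movement count must equal immobility count or be one less (",
         individual_id, ": kI = ", kI, ", kM = ", kM, ")")
  if (kI > MAX_BOUT_PAIRS || kM > MAX_BOUT_PAIRS)
    stop("at most ", MAX_BOUT_PAIRS, " periods of each kind are retained")
  if (any(immobility <= 0) || any(c(movement, 1) <= 0))
    stop("all bout durations must be positive (", individual_id, ")")
  total <- sum(immobility) + sum(movement)
  if (arrival_time + total > window + 1e-6)
    stop("bouts exceed the ", window, " s observation window (",
         individual_id, ")")
  structure(
    list(
      individual_id = as.character(individual_id),
      treatment = normalize_treatment(treatment),
      immobility = as.numeric(immobility),
      movement = as.numeric(movement),
      arrival_time = as.numeric(arrival_time),
      reached_wall = isTRUE(reached_wall)
    ),
    class = "bout_sequence"
  )
}

#' @export
print.bout_sequence <- function(x, ...) {
  cat(sprintf(
    "<bout_sequence> %s on %s: %d immobility / %d movement periods, PCI = %g s%s\n",
    x$individual_id, x$treatment, length(x$immobility), length(x$movement),
    x$immobility[1], if (x$reached_wall) ", reached wall" else ""))
  invisible(x)
}

#' End of PCI for a bout sequence
#'
#' Absolute time (s) at which the first immobility period ends, i.e. the
#' start of the first movement.
#' @param bouts a `bout_sequence`.
#' @return numeric time (s).
#' @export
pci_end <- function(bouts) {
  stopifnot(inherits(bouts, "bout_sequence"))
  bouts$arrival_time + bouts$immobility[1]
}

#' Construct a cohort
#'
#' A cohort bundles bout sequences and/or tracks for a set of individuals,
#' together with their body weights. Individual ids must be unique within a
#' treatment (the same animal may appear under two treatments, mirroring the
#' repeated design).
#'
#' @param bouts list of `bout_sequence` objects.
#' @param tracks list of `pci_track` objects.
#' @param weights named numeric vector of body weights (g), names are
#'   individual ids. Optional.
#' @return an object of class `pci_cohort`.
#' @export
pci_cohort <- function(bouts = list(), tracks = list(), weights = NULL) {
  stopifnot(all(vapply(bouts, inherits, TRUE, "bout_sequence")),
            all(vapply(tracks, inherits, TRUE, "pci_track")))
  key <- function(z) paste(z$treatment, z$individual_id)
  for (lst in list(bouts, tracks)) {
    if (length(lst)) {
      k <- vapply(lst, key, "")
      if (anyDuplicated(k))
        stop("duplicate individual within a treatment: ",
             k[duplicated(k)][1])
    }
  }
  if (!is.null(weights)) {
    if (is.null(names(weights)) || any(weights <= 0))
      stop("weights must be a named vector of positive grams")
  }
  structure(list(bouts = bouts, tracks = tracks, weights = weights),
            class = "pci_cohort")
}

#' @export
print.pci_cohort <- function(x, ...) {
  tr <- table(vapply(x$bouts, function(b) b$treatment, ""))
  cat(sprintf("<pci_cohort> %d bout sequences, %d tracks\n",
              length(x$bouts), length(x$tracks)))
  if (length(tr)) print(tr)
  invisible(x)
}

#' Long data frame of bout durations in a cohort
#'
#' @param cohort a `pci_cohort`.
#' @param response `"immobility"` or `"movement"`.
#' @return data.frame with columns `individual_id`, `treatment`, `k`
#'   (1-based sequential number within kind) and `duration` (s).
#' @export
cohort_durations <- function(cohort,
                             response = c("immobility", "movement")) {
  response <- match.arg(response)
  rows <- lapply(cohort$bouts, function(b) {
    d <- b[[response]]
    if (!length(d)) return(NULL)
    data.frame(individual_id = b$individual_id, treatment = b$treatment,
               k = seq_along(d), duration = d)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ---- S1-style bout tables ---------------------------------------------------

# Column names of the manual bout sheet: per period k, start and end time of
# movement k plus the stored immobility/movement durations.
s1_period_cols <- function(k) {
  c(sprintf("StTM%d_s", k), sprintf("I%ddur_s", k),
    sprintf("EnTM%d_s", k), sprintf("M%ddur_s", k))
}

#' Read a manual bout table
#'
#' Reads a bout sheet in the manual-scoring schema: one row per individual
#' with columns `ALid`, `Weight_g`, `Treat`, `ArrT_s` and, for each period
#' `k` in 1..16, `StTMk_s` (movement start), `EnTMk_s` (movement end),
#' `Ikdur_s` and `Mkdur_s` (stored durations). Durations are recomputed from
#' the start/end times wherever both are present and must agree with the
#' stored columns to within 1 s (the manual-scoring precision); any larger
#' discrepancy is an error naming the offending cell.
#'
#' @param path CSV file (or `.xlsx` if the readxl package is installed).
#' @param tol agreement tolerance (s) between stored and recomputed
#'   durations.
#' @return a [pci_cohort()] of bout sequences with weights attached.
#' @export
read_bout_table <- function(path, tol = 1) {
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading .xlsx requires the readxl package; export to CSV instead")
    df <- as.data.frame(readxl::read_excel(path))
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
  }
  required <- c("ALid", "Weight_g", "Treat", "ArrT_s")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("bout table is missing required column(s): ",
         paste(missing, collapse = ", "))

  bouts <- list(); weights <- numeric(0); problems <- character(0)
  for (r in seq_len(nrow(df))) {
    row <- df[r, ]
    id <- as.character(row$ALid)
    arr <- as.numeric(row$ArrT_s)
    imm <- numeric(0); mov <- numeric(0)
    prev_end <- arr
    for (k in seq_len(MAX_BOUT_PAIRS)) {
      cols <- s1_period_cols(k)
      st <- if (cols[1] %in% names(df)) as.numeric(row[[cols[1]]]) else NA
      idur <- if (cols[2] %in% names(df)) as.numeric(row[[cols[2]]]) else NA
      en <- if (cols[3] %in% names(df)) as.numeric(row[[cols[3]]]) else NA
      mdur <- if (cols[4] %in% names(df)) as.numeric(row[[cols[4]]]) else NA
      if (all(is.na(c(st, idur, en, mdur)))) break
      # immobility k runs from the end of movement k-1 (or arrival) to StTMk
      i_rec <- if (!is.na(st) && !is.na(prev_end)) st - prev_end else NA
      if (!is.na(i_rec) && !is.na(idur) && abs(i_rec - idur) > tol + 1e-9) {
        problems <- c(problems, sprintf(
          "ALid %s, I%ddur_s: stored %g s vs recomputed %g s", id, k,
          idur, i_rec))
      }
      ik <- if (!is.na(idur)) idur else i_rec
      if (is.na(ik)) break
      imm <- c(imm, ik)
      m_rec <- if (!is.na(st) && !is.na(en)) en - st else NA
      if (!is.na(m_rec) && !is.na(mdur) && abs(m_rec - mdur) > tol + 1e-9) {
        problems <- c(problems, sprintf(
          "ALid %s, M%ddur_s: stored %g s vs recomputed %g s", id, k,
          mdur, m_rec))
      }
      mk <- if (!is.na(mdur)) mdur else m_rec
      if (is.na(mk)) break  # record ends during immobility k: kM = kI - 1
      mov <- c(mov, mk)
      prev_end <- if (!is.na(en)) en else prev_end + ik + mk
    }
    if (length(problems)) next
    if (!length(imm)) {
      warning("ALid ", id, ": no usable periods; record dropped")
      next
    }
    if (any(c(imm, mov) <= 0)) {
      warning("ALid ", id,
              ": non-positive duration encountered; record dropped")
      next
    }
    bs <- bout_sequence(id, as.character(row$Treat), imm, mov,
                        arrival_time = arr)
    bouts[[length(bouts) + 1L]] <- bs
    w <- as.numeric(row$Weight_g)
    if (!is.na(w)) weights[id] <- w
  }
  if (length(problems))
    stop("duration/timestamp discrepancies exceed ", tol, " s:\n  ",
         paste(problems, collapse = "\n  "))
  pci_cohort(bouts = bouts, weights = if (length(weights)) weights else NULL)
}

#' Write a cohort's bout sequences as a manual-schema bout table
#'
#' Inverse of [read_bout_table()]: start/end times are reconstructed from the
#' arrival time and the cumulative durations, and the stored duration columns
#' are written verbatim so that a write/read round-trip preserves durations
#' exactly.
#'
#' @param cohort a `pci_cohort` with bout sequences.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_bout_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "pci_cohort"), length(cohort$bouts) > 0)
  kmax <- max(vapply(cohort$bouts, function(b) length(b$immobility), 0L))
  cols <- c("ALid", "Weight_g", "Treat", "ArrT_s",
            as.vector(vapply(seq_len(kmax), s1_period_cols,
                             character(4))))
  rows <- lapply(cohort$bouts, function(b) {
    row <- as.list(setNames(rep(NA_real_, length(cols)), cols))
    row$ALid <- b$individual_id
    row$Weight_g <- if (!is.null(cohort$weights) &&
                        b$individual_id %in% names(cohort$weights))
      cohort$weights[[b$individual_id]] else NA_real_
    row$Treat <- treatment_label(b$treatment)
    row$ArrT_s <- b$arrival_time
    tcur <- b$arrival_time
    for (k in seq_along(b$immobility)) {
      st <- tcur + b$immobility[k]
      row[[sprintf("I%ddur_s", k)]] <- b$immobility[k]
      row[[sprintf("StTM%d_s", k)]] <- st
      if (k <= length(b$movement)) {
        en <- st + b$movement[k]
        row[[sprintf("EnTM%d_s", k)]] <- en
        row[[sprintf("M%ddur_s", k)]] <- b$movement[k]
        tcur <- en
      }
    }
    as.data.frame(row, check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

## ---- track files ------------------------------------------------------------

#' Read a centroid track from CSV
#'
#' Expects columns `time`, `x`, `y`. The sampling interval is inferred from
#' the median spacing; irregular spacing is an error. Out-of-arena
#' coordinates are kept but flagged with a warning.
#'
#' @param path CSV file.
#' @param individual_id,treatment metadata attached to the track (defaults
#'   are taken from optional `individual_id`/`treatment` columns or the file
#'   name).
#' @return a [pci_track()].
#' @export
read_track <- function(path, individual_id = NULL, treatment = "paper") {
  df <- utils::read.csv(path)
  need <- c("time", "x", "y")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("track file is missing column(s): ", paste(missing, collapse = ", "))
  if (is.null(individual_id)) {
    individual_id <- if ("individual_id" %in% names(df))
      df$individual_id[1] else sub("\\.csv$", "", basename(path))
  }
  if ("treatment" %in% names(df)) treatment <- df$treatment[1]
  pci_track(individual_id, treatment, df$time, df$x, df$y)
}

#' Write a centroid track to CSV
#' @param track a `pci_track`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "pci_track"))
  df <- data.frame(time = track$t, x = track$x, y = track$y,
                   individual_id = track$individual_id,
                   treatment = track$treatment)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
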