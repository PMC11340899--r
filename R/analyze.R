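#' Run the full post-PCI analysis pipeline on a study
#'
#' End-to-end driver: pools the three substrate cohorts, fits the
#' bout-duration trend models with slope contrasts, compares the tail models
#' of the pooled per-substrate duration distributions, and — when tracks are
#' present — coarse-grains and (on sand) smooths the tracks, computes the
#' log-binned MSD and MIS profiles with their regressions, classifies the
#' diffusion regime per substrate, and fits the start-to-finish displacement
#' model.
#'
#' @param study named list of [pci_cohort()]s per treatment, as returned by
#'   [simulate_study()] (bout sequences required, tracks optional).
#' @param levels coarse-graining levels applied to raw tracks.
#' @param smooth_window running-average window applied to sand tracks.
#' @param move_threshold step threshold (mm) used by the dispersal
#'   profiles, or `"auto"` for the per-track noise floor.
#' @param wall_rule truncate paper tracks/displacements at wall arrival.
#' @return a list of class `pci_study_analysis` with elements
#'   `trend_immobility`, `trend_movement` (each a fit plus `contrasts`),
#'   `tails` (per substrate x response [compare_all()] results),
#'   `dispersal` (per substrate MSD/MIS profiles, fits and diffusion class)
#'   and `displacement` (per-individual table plus the mixed model), the
#'   latter two `NULL` without tracks.
#' @export
analyze_study <- function(study, levels = 4L, smooth_window = 3L,
                          move_threshold = "auto", wall_rule = TRUE) {
  stopifnot(is.list(study), length(study) >= 1)
  all_bouts <- unlist(lapply(study, function(co) co$bouts),
                      recursive = FALSE)
  weights <- do.call(c, unname(lapply(study, function(co) co$weights)))
  pooled <- pci_cohort(bouts = all_bouts,
                       weights = weights[!duplicated(names(weights))])

  trend_imm <- fit_duration_trend(pooled, "immobility")
  trend_mov <- fit_duration_trend(pooled, "movement")
  out <- list(
    trend_immobility = list(fit = trend_imm,
                            contrasts = contrast_slopes(trend_imm)),
    trend_movement = list(fit = trend_mov,
                          contrasts = contrast_slopes(trend_mov))
  )

  out$tails <- lapply(study, function(co) {
    cc <- pci_cohort(bouts = co$bouts)
    list(immobility = compare_all(cohort_durations(cc, "immobility")$duration),
         movement = compare_all(cohort_durations(cc, "movement")$duration))
  })

  have_tracks <- all(vapply(study, function(co) length(co$tracks) > 0, TRUE))
  if (have_tracks) {
    disp_rows <- list(); dispersal <- list()
    for (tr in names(study)) {
      co <- study[[tr]]
      prepped <- lapply(co$tracks, function(trk) {
        g <- coarse_grain(trk, levels)
        if (tr != "paper" && smooth_window > 1L)
          g <- smooth_track(g, smooth_window)
        if (wall_rule && tr == "paper") {
          wt <- wall_arrival_time(g)
          if (!is.na(wt) && wt > g$t0 + 2 * g$dt) g <- truncate_track(g, wt)
        }
        g
      })
      ends <- stats::setNames(
        vapply(co$bouts, pci_end, 0),
        vapply(co$bouts, function(b) b$individual_id, ""))
      msd <- msd_profile(prepped, ends, move_threshold)
      mis <- mis_profile(prepped, ends, move_threshold)
      msd_fit <- tryCatch(fit_dispersal_profile(msd),
                          error = function(e) e)
      mis_fit <- tryCatch(fit_dispersal_profile(mis, force = "linear"),
                          error = function(e) e)
      dispersal[[tr]] <- list(
        msd = msd, mis = mis, msd_fit = msd_fit, mis_fit = mis_fit,
        diffusion = if (inherits(msd_fit, "segmented_fit"))
          classify_diffusion(msd_fit) else NA_character_)
      disp_rows[[tr]] <- cohort_displacements(
        pci_cohort(tracks = prepped), wall_rule = wall_rule && tr == "paper")
    }
    out$dispersal <- dispersal
    disp <- do.call(rbind, disp_rows)
    out$displacement <- list(table = disp,
                             fit = fit_displacement_model(disp))
  }
  class(out) <- "pci_study_analysis"
  out
}

#' @export
print.pci_study_analysis <- function(x, ...) {
  cat("== Immobility duration trend ==\n")
  print(x$trend_immobility$fit)
  print(x$trend_immobility$contrasts, digits = 4)
  cat("\n== Movement duration trend ==\n")
  print(x$trend_movement$fit)
  print(x$trend_movement$contrasts, digits = 4)
  cat("\n== Duration distribution comparisons ==\n")
  for (tr in names(x$tails)) {
    cat("--", tr, "immobility:\n")
    print(x$tails[[tr]]$immobility)
  }
  if (!is.null(x$dispersal)) {
    cat("\n== Dispersal ==\n")
    for (tr in names(x$dispersal)) {
      d <- x$dispersal[[tr]]
      cat(sprintf("-- %s: %s", tr, d$diffusion))
      if (inherits(d$msd_fit, "segmented_fit"))
        cat(sprintf(" (MSD R2adj = %.1f%%)", 100 * d$msd_fit$r2adj))
      cat("\n")
    }
    cat("\nDisplacement medians (mm):\n")
    print(round(x$displacement$fit$medians, 1))
  }
  invisible(x)
}

#' Slope-contrast report table
#'
#' The post-hoc slope-comparison layout of the duration-trend analyses:
#' compared slopes, estimated difference, SE, Z and adjusted P.
#'
#' @param analysis a `pci_study_analysis`.
#' @param response `"immobility"` or `"movement"`.
#' @return data.frame.
#' @export
trend_table <- function(analysis,
                        response = c("immobility", "movement")) {
  response <- match.arg(response)
  el <- if (response == "immobility") analysis$trend_immobility
        else analysis$trend_movement
  ct <- el$contrasts
  data.frame(`Compared slopes` = ct$pair,
             `Estimated difference` = round(ct$estimate, 4),
             SE = round(ct$se, 4), Z = round(ct$z, 3),
             P = signif(ct$p, 3), check.names = FALSE)
}

#' Tail-comparison report table
#'
#' Per-substrate Vuong statistics and p-values for the three model pairs,
#' in the layout of the goodness-of-fit tables.
#'
#' @param analysis a `pci_study_analysis`.
#' @param response `"immobility"` or `"movement"`.
#' @return data.frame with one row per substrate.
#' @export
tail_table <- function(analysis, response = c("immobility", "movement")) {
  response <- match.arg(response)
  rows <- lapply(names(analysis$tails), function(tr) {
    tc <- analysis$tails[[tr]][[response]]
    cmp <- tc$comparisons
    fmt <- function(i) sprintf("%.3f, %.3g%s", cmp$statistic[i], cmp$p[i],
                               if (cmp$significant[i]) " *" else "")
    data.frame(Substrate = tr, N = tc$n,
               `EXP vs LN` = fmt(1), `EXP vs PL` = fmt(2),
               `LN vs PL` = fmt(3), check.names = FALSE)
  })
  do.call(rbind, rows)
}

#' Export a dispersal profile as a plain data frame
#'
#' Per-bin midpoints, means and upper confidence limits, ready for CSV
#' export or plotting.
#'
#' @param profile a `dispersal_profile`.
#' @return data.frame.
#' @export
profile_table <- function(profile) {
  stopifnot(inherits(profile, "dispersal_profile"))
  cbind(kind = profile$kind, profile$profile)
}
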