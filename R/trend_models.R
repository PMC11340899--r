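#' Fit the log-log bout-duration trend model
#'
#' Linear mixed-effects model of `log10(duration)` against
#' `log10(sequential number)` with a separate intercept and slope per
#' substrate and a random individual effect, reflecting the repeated design
#' (the same animal is tested on paper and on one sand depth). The random
#' structure defaults to intercept-and-slope for immobility durations and
#' intercept-only for movement durations; a singular random-slope fit falls
#' back to intercept-only with a warning. Slope t-tests use Satterthwaite
#' degrees of freedom (REML).
#'
#' @param cohort a [pci_cohort()] with bout sequences, or a long data.frame
#'   as returned by [cohort_durations()].
#' @param response `"immobility"` or `"movement"`.
#' @param random_structure `"auto"` (default rule above),
#'   `"intercept_and_slope"` or `"intercept_only"`.
#' @param REML logical, restricted maximum likelihood (default `TRUE`).
#' @return an object of class `pci_trend_fit` with elements `model` (the
#'   lmerTest fit), `slopes` (per-treatment estimate, SE, Satterthwaite df,
#'   t, p), `intercepts`, `response`, `random_structure`, `logLik` and
#'   `lrt_random` (likelihood-ratio test of the random factor against a
#'   fixed-effects-only fit).
#' @export
fit_duration_trend <- function(cohort,
                               response = c("immobility", "movement"),
                               random_structure = c("auto",
                                                    "intercept_and_slope",
                                                    "intercept_only"),
                               REML = TRUE) {
  response <- match.arg(response)
  random_structure <- match.arg(random_structure)
  df <- if (inherits(cohort, "pci_cohort"))
    cohort_durations(cohort, response) else as.data.frame(cohort)
  stopifnot(all(c("individual_id", "treatment", "k", "duration") %in%
                  names(df)))
  if (any(df$duration <= 0)) stop("durations must be positive")
  df$treatment <- factor(df$treatment,
                         levels = intersect(TREATMENTS, df$treatment))
  n_per <- tapply(df$individual_id, df$treatment,
                  function(z) length(unique(z)))
  if (any(n_per < 2)) stop("need >= 2 individuals per treatment")
  df$log_dur <- log10(df$duration)
  df$log_k <- log10(df$k)

  if (random_structure == "auto")
    random_structure <- if (response == "immobility")
      "intercept_and_slope" else "intercept_only"

  fit_with <- function(struct) {
    re <- if (struct == "intercept_and_slope")
      "(1 + log_k | individual_id)" else "(1 | individual_id)"
    fml <- stats::as.formula(paste(
      "log_dur ~ 0 + treatment + treatment:log_k +", re))
    lmerTest::lmer(fml, data = df, REML = REML)
  }
  model <- fit_with(random_structure)
  if (random_structure == "intercept_and_slope" &&
      lme4::isSingular(model, tol = 1e-4)) {
    warning("singular random intercept+slope fit; ",
            "falling back to a random intercept only")
    random_structure <- "intercept_only"
    model <- fit_with(random_structure)
  }

  sm <- summary(model)$coefficients
  lev <- levels(df$treatment)
  slope_rows <- paste0("treatment", lev, ":log_k")
  int_rows <- paste0("treatment", lev)
  slopes <- data.frame(
    treatment = lev,
    estimate = sm[slope_rows, "Estimate"],
    se = sm[slope_rows, "Std. Error"],
    df = sm[slope_rows, "df"],
    t = sm[slope_rows, "t value"],
    p = sm[slope_rows, "Pr(>|t|)"],
    row.names = NULL
  )
  intercepts <- stats::setNames(sm[int_rows, "Estimate"], lev)

  # value of the random factor: LRT against the fixed-effects-only model
  fit_ml <- lme4::refitML(model)
  lm0 <- stats::lm(log_dur ~ 0 + treatment + treatment:log_k, data = df)
  lrt_stat <- max(0, 2 * (as.numeric(stats::logLik(fit_ml)) -
                            as.numeric(stats::logLik(lm0))))
  lrt_df <- if (random_structure == "intercept_and_slope") 3L else 1L
  lrt <- c(statistic = lrt_stat, df = lrt_df,
           p = stats::pchisq(lrt_stat, lrt_df, lower.tail = FALSE))

  structure(
    list(model = model, data = df, response = response,
         slopes = slopes, intercepts = intercepts,
         random_structure = random_structure,
         slope_terms = stats::setNames(slope_rows, lev),
         logLik = as.numeric(stats::logLik(model)), lrt_random = lrt),
    class = "pci_trend_fit"
  )
}

#' @export
print.pci_trend_fit <- function(x, ...) {
  cat(sprintf(
    "<pci_trend_fit> log10(%s duration) ~ log10(event number), random %s\n",
    x$response, x$random_structure))
  print(x$slopes, digits = 4)
  invisible(x)
}

# single-step max-|Z| adjusted p-values for a set of normal contrasts with
# correlation matrix R (the adjustment used by standard post-hoc machinery)
single_step_p <- function(z, R) {
  vapply(seq_along(z), function(i) {
    if (!is.finite(z[i])) return(NA_real_)
    a <- abs(z[i])
    if (a == 0) return(1)
    p <- 1 - mvtnorm::pmvnorm(lower = rep(-a, nrow(R)),
                              upper = rep(a, nrow(R)), corr = R,
                              abseps = 1e-6)
    min(max(as.numeric(p), 0), 1)
  }, 0)
}

# generic contrast engine over a fitted model's coefficients
contrast_engine <- function(est, V, terms, labels,
                            adjust = c("single-step", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  pairs <- utils::combn(seq_along(terms), 2)
  K <- matrix(0, ncol(pairs), length(est),
              dimnames = list(NULL, names(est)))
  pair_lab <- character(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    K[j, terms[a]] <- 1
    K[j, terms[b]] <- -1
    pair_lab[j] <- paste(labels[a], "-", labels[b])
  }
  d <- as.numeric(K %*% est)
  Vk <- K %*% V %*% t(K)
  se <- sqrt(diag(Vk))
  z <- d / se
  p0 <- 2 * stats::pnorm(-abs(z))
  p <- switch(adjust,
    "single-step" = single_step_p(z, stats::cov2cor(Vk)),
    "bonferroni" = pmin(1, p0 * length(z)),
    "none" = p0)
  data.frame(pair = pair_lab, estimate = d, se = se, z = z, p = p)
}

#' Pairwise post-hoc contrasts between treatment slopes
#'
#' All pairwise differences between the per-treatment slopes of a fitted
#' duration-trend model, with `Z = difference / SE` on the fixed-effects
#' covariance and a multiplicity adjustment over the three comparisons
#' (single-step max-|Z| joint-normal by default, Bonferroni as fallback).
#'
#' @param fit a `pci_trend_fit` from [fit_duration_trend()].
#' @param adjust `"single-step"`, `"bonferroni"` or `"none"`.
#' @return data.frame with columns `pair`, `estimate`, `se`, `z`, `p`.
#' @export
contrast_slopes <- function(fit,
                            adjust = c("single-step", "bonferroni", "none")) {
  stopifnot(inherits(fit, "pci_trend_fit"))
  est <- lme4::fixef(fit$model)
  V <- as.matrix(stats::vcov(fit$model))
  contrast_engine(est, V, fit$slope_terms, names(fit$slope_terms),
                  match.arg(adjust))
}

#' Mixed model for start-to-finish displacement
#'
#' Fits `log10(displacement)` against substrate with a random individual
#' effect (the repeated design), floors zero displacements at the
#' measurement resolution before the log, and reports per-treatment medians
#' alongside all pairwise treatment contrasts.
#'
#' @param displacements data.frame with columns `individual_id`, `treatment`
#'   and `displacement` (mm), one row per individual per treatment.
#' @param floor_mm measurement resolution used to floor zero displacement.
#' @param adjust multiplicity adjustment for the contrasts.
#' @return an object of class `pci_displacement_fit` with elements `model`,
#'   `means` (per-treatment fitted log10 means), `medians` (mm),
#'   `contrasts` and `lrt_random`.
#' @export
fit_displacement_model <- function(displacements, floor_mm = 0.1,
                                   adjust = c("single-step", "bonferroni",
                                              "none")) {
  adjust <- match.arg(adjust)
  df <- as.data.frame(displacements)
  stopifnot(all(c("individual_id", "treatment", "displacement") %in%
                  names(df)))
  if (any(df$displacement < floor_mm)) {
    message(sum(df$displacement < floor_mm),
            " displacement(s) floored at the ", floor_mm, " mm resolution")
    df$displacement <- pmax(df$displacement, floor_mm)
  }
  df$treatment <- factor(df$treatment,
                         levels = intersect(TREATMENTS, df$treatment))
  df$log_d <- log10(df$displacement)
  model <- suppressMessages(lmerTest::lmer(
    log_d ~ 0 + treatment + (1 | individual_id), data = df, REML = TRUE))
  est <- lme4::fixef(model)
  V <- as.matrix(stats::vcov(model))
  lev <- levels(df$treatment)
  terms <- stats::setNames(paste0("treatment", lev), lev)
  contrasts <- contrast_engine(est, V, terms, lev, adjust)
  medians <- tapply(df$displacement, df$treatment, stats::median)
  fit_ml <- lme4::refitML(model)
  lm0 <- stats::lm(log_d ~ 0 + treatment, data = df)
  lrt_stat <- max(0, 2 * (as.numeric(stats::logLik(fit_ml)) -
                            as.numeric(stats::logLik(lm0))))
  lrt <- c(statistic = lrt_stat, df = 1,
           p = stats::pchisq(lrt_stat, 1, lower.tail = FALSE))
  structure(
    list(model = model, means = stats::setNames(as.numeric(est[terms]), lev),
         medians = as.numeric(medians[lev]) |> stats::setNames(lev),
         contrasts = contrasts, lrt_random = lrt, data = df),
    class = "pci_displacement_fit"
  )
}

#' @export
print.pci_displacement_fit <- function(x, ...) {
  cat("<pci_displacement_fit> log10(start-to-finish displacement) ~ substrate\n")
  cat("medians (mm):\n"); print(round(x$medians, 1))
  print(x$contrasts, digits = 4)
  invisible(x)
}
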