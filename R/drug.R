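#' Slope of the linear portion of a kinetic fluorescence trace
#'
#' Enzyme activity is read off a kinetic assay as the slope of the
#' linear phase of the fluorescence trace. The slope is estimated by
#' ordinary least squares over the contiguous window of `window_points`
#' readings that maximizes R-squared (ties go to the earliest window),
#' which locates the linear portion even when the trace later saturates.
#'
#' @param time_s Timestamps in seconds, strictly increasing (or a data
#'   frame with columns `time_s` and `rfu`).
#' @param rfu Fluorescence readings (relative units).
#' @param window_points Window length (default 10, minimum 3).
#' @return List with `slope` (fluorescence units per minute),
#'   `r_squared`, `window` (first and last index used), `degenerate`
#'   (`TRUE` when the trace is flat and the slope is defined as 0).
#' @export
kinetic_slope <- function(time_s, rfu = NULL, window_points = 10L) {
  if (is.data.frame(time_s)) {
    rfu <- time_s$rfu
    time_s <- time_s$time_s
  }
  if (is.null(rfu)) stop("fluorescence readings required")
  n <- length(time_s)
  if (n != length(rfu)) stop("time and fluorescence lengths differ")
  if (any(diff(time_s) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  if (window_points < 3L) stop("window_points must be at least 3")
  if (window_points > n) {
    stop(sprintf("window_points = %d exceeds trace length (%d)",
                 window_points, n))
  }
  starts <- seq_len(n - window_points + 1L)
  best <- list(r2 = -Inf, slope = NA_real_, start = NA_integer_)
  for (s in starts) {
    idx <- s:(s + window_points - 1L)
    x <- time_s[idx]; y <- rfu[idx]
    vx <- stats::var(x); vy <- stats::var(y)
    if (vy == 0) next                    # flat window: no information
    slope <- stats::cov(x, y) / vx
    r2 <- stats::cor(x, y)^2
    if (r2 > best$r2) best <- list(r2 = r2, slope = slope, start = s)
  }
  if (!is.finite(best$r2)) {
    return(list(slope = 0, r_squared = NA_real_,
                window = c(1L, window_points), degenerate = TRUE))
  }
  list(slope = best$slope * 60,          # per-second OLS slope -> per minute
       r_squared = best$r2,
       window = c(best$start, best$start + window_points - 1L),
       degenerate = FALSE)
}

#' Inhibitor activity score from kinetic slopes
#'
#' `score = (RFI_DI - RFI_u) / (RFI_u - RFI_Zn) * 100`, where `RFI_u`
#' is the slope of the untreated reaction, `RFI_DI` of the
#' inhibitor-treated reaction and `RFI_Zn` of the zinc-blocked negative
#' control. The signed score is 0 for no inhibition and -100 at the
#' level of the full block; because inhibition yields negative scores,
#' the magnitude is also reported as `inhibition_percent`.
#'
#' @param rfi_di,rfi_u,rfi_zn Slopes (fluorescence/min) of the
#'   inhibitor-treated, untreated and zinc-blocked reactions.
#' @return List with `score` (signed percent) and `inhibition_percent`
#'   (its negation).
#' @export
#' @examples
#' activity_score(40, 100, 10)  # -66.7% signed, 66.7% inhibition
activity_score <- function(rfi_di, rfi_u, rfi_zn) {
  vals <- c(rfi_di, rfi_u, rfi_zn)
  if (any(!is.finite(vals))) stop("slopes must be finite")
  if (rfi_u == rfi_zn) {
    stop("no dynamic range: untreated and zinc-blocked slopes are equal")
  }
  score <- (rfi_di - rfi_u) / (rfi_u - rfi_zn) * 100
  list(score = score, inhibition_percent = -score)
}

#' Enzyme activity assay from three kinetic traces
#'
#' Convenience wrapper extracting the three slopes with
#' [kinetic_slope()] and scoring them with [activity_score()].
#'
#' @param trace_untreated,trace_inhibitor,trace_zinc Data frames with
#'   columns `time_s` and `rfu`.
#' @param window_points Passed to [kinetic_slope()].
#' @return List with `rfi_u`, `rfi_di`, `rfi_zn`, `score`,
#'   `inhibition_percent`.
#' @export
enzyme_activity <- function(trace_untreated, trace_inhibitor, trace_zinc,
                            window_points = 10L) {
  rfi_u <- kinetic_slope(trace_untreated, window_points = window_points)
  rfi_di <- kinetic_slope(trace_inhibitor, window_points = window_points)
  rfi_zn <- kinetic_slope(trace_zinc, window_points = window_points)
  sc <- activity_score(rfi_di$slope, rfi_u$slope, rfi_zn$slope)
  list(rfi_u = rfi_u$slope, rfi_di = rfi_di$slope, rfi_zn = rfi_zn$slope,
       score = sc$score, inhibition_percent = sc$inhibition_percent)
}

#' Fit the median-effect equation to a dose-response curve
#'
#' The median-effect model `fa / (1 - fa) = (D / Dm)^m` linearizes to a
#' regression of `log(fa / (1 - fa))` on `log(D)`: the slope is the
#' sigmoidicity `m` and `Dm = exp(-intercept / m)` is the median-effect
#' dose (the dose producing 50% effect). Points with `fa` at exactly 0
#' or 1 carry no information on the log-odds scale and are excluded with
#' a warning; at least 3 usable points are required.
#'
#' @param doses Positive doses.
#' @param fa Fractions affected in `[0, 1]`.
#' @param drug Optional drug name carried through to results.
#' @return An object of class `kinsig_mefit`: list with `drug`, `m`,
#'   `dm`, `r2` of the log-linear fit, `n` points used, and `valid`
#'   (`m > 0 && dm > 0`).
#' @export
median_effect_fit <- function(doses, fa, drug = NULL) {
  if (length(doses) != length(fa)) stop("doses and fa lengths differ")
  if (any(doses <= 0)) stop("doses must be positive")
  if (any(fa < 0 | fa > 1)) stop("fa must lie in [0, 1]")
  usable <- fa > 0 & fa < 1
  if (any(!usable)) {
    warning(sprintf("excluding %d point(s) with fa at 0 or 1",
                    sum(!usable)))
  }
  if (sum(usable) < 3L) {
    stop("need at least 3 dose points with fa strictly inside (0, 1)")
  }
  d <- doses[usable]; f <- fa[usable]
  y <- log(f / (1 - f))
  fit <- stats::lm(y ~ log(d))
  m <- unname(stats::coef(fit)[[2L]])
  dm <- exp(-unname(stats::coef(fit)[[1L]]) / m)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(
    list(drug = drug, m = m, dm = dm,
         r2 = r2, n = sum(usable),
         valid = is.finite(m) && is.finite(dm) && m > 0 && dm > 0),
    class = "kinsig_mefit"
  )
}

#' @export
print.kinsig_mefit <- function(x, ...) {
  cat(sprintf("<kinsig_mefit> %s: m = %.4g, Dm = %.4g (r2 = %.4f, n = %d)%s\n",
              x$drug %||% "drug", x$m, x$dm, x$r2, x$n,
              if (x$valid) "" else " [invalid]"))
  invisible(x)
}

#' Dose producing a given effect under a median-effect fit
#'
#' `Dx = Dm * (fa / (1 - fa))^(1/m)`.
#'
#' @param fit A `kinsig_mefit`.
#' @param fa Fraction affected, strictly inside (0, 1).
#' @return Dose(s).
#' @export
median_effect_dose <- function(fit, fa) {
  stopifnot(inherits(fit, "kinsig_mefit"))
  if (any(fa <= 0 | fa >= 1)) stop("fa must lie strictly inside (0, 1)")
  fit$dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Chou-Talalay combination index
#'
#' Non-constant-ratio, mutually-exclusive-effects form:
#' `CI = d1 / Dx1(fa) + d2 / Dx2(fa)`, where `Dx_i(fa)` is the dose of
#' drug i alone producing the observed combined effect `fa` under its
#' median-effect fit. `CI < 1` indicates synergy, `CI = 1` Loewe
#' additivity, `CI > 1` antagonism; see [ci_classify()] for labels.
#'
#' @param d1,d2 Doses of the two drugs in the combination (vectorized).
#' @param fa Observed fraction affected of the combination, strictly
#'   inside (0, 1).
#' @param fit1,fit2 `kinsig_mefit` objects for the two single agents.
#' @return Numeric combination index per point.
#' @export
combination_index <- function(d1, d2, fa, fit1, fit2) {
  stopifnot(inherits(fit1, "kinsig_mefit"), inherits(fit2, "kinsig_mefit"))
  if (any(fa <= 0 | fa >= 1)) stop("fa must lie strictly inside (0, 1)")
  if (any(d1 < 0) || any(d2 < 0)) stop("doses must be non-negative")
  d1 / median_effect_dose(fit1, fa) + d2 / median_effect_dose(fit2, fa)
}

#' Label combination indices
#'
#' @param ci Combination indices.
#' @param tolerance Half-width of the additivity band around 1
#'   (default 0.05).
#' @return Character vector: `"synergy"`, `"additive"`, `"antagonism"`.
#' @export
ci_classify <- function(ci, tolerance = 0.05) {
  ifelse(ci < 1 - tolerance, "synergy",
         ifelse(ci > 1 + tolerance, "antagonism", "additive"))
}
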