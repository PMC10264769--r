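#' Construct a pressure-volume curve
#'
#' An ordered (mass, water potential) series from progressive bench
#' dehydration of one organ, plus its oven-dry mass. Points must be sorted
#' in drying order (masses non-increasing); water potentials are negative
#' MPa.
#'
#' @param masses Fresh masses, g, non-increasing.
#' @param psis Bulk water potentials, MPa, all < 0.
#' @param dry_mass Oven-dry mass, g.
#' @return An object of class `pv_curve`.
#' @export
pv_curve <- function(masses, psis, dry_mass) {
  n <- length(masses)
  if (n < 6L) stop("at least 6 PV points are required", call. = FALSE)
  if (length(psis) != n)
    stop("masses and psis must have equal length", call. = FALSE)
  if (any(psis >= 0)) stop("all water potentials must be < 0 MPa",
                           call. = FALSE)
  if (dry_mass <= 0 || any(masses <= dry_mass))
    stop("masses must exceed dry_mass > 0", call. = FALSE)
  if (any(diff(masses) > 1e-12))
    stop("masses must be non-increasing (drying order)", call. = FALSE)
  structure(list(masses = as.numeric(masses), psis = as.numeric(psis),
                 dry_mass = dry_mass),
            class = "pv_curve")
}

#' @export
print.pv_curve <- function(x, ...) {
  cat("Pressure-volume curve:", length(x$masses), "points, dry mass",
      x$dry_mass, "g\n")
  cat("  mass", round(max(x$masses), 4), "->", round(min(x$masses), 4),
      "g;  psi", round(max(x$psis), 3), "->", round(min(x$psis), 3), "MPa\n")
  invisible(x)
}

#' Saturated mass of a PV sample
#'
#' By default the maximum observed mass. With `correct = TRUE` the initial
#' linear region of mass vs water potential is extrapolated to zero water
#' potential: leading points sitting above that line (an oversaturation
#' plateau from excess surface or intercellular water) are dropped from the
#' fit, and the extrapolated intercept is used as the saturated mass.
#'
#' @param curve A [pv_curve()] object.
#' @param correct Apply the plateau/extrapolation correction?
#' @param r2_target Leading points are dropped (up to `max_drop`) until the
#'   initial-region fit reaches this r^2.
#' @param max_drop Maximum number of leading points considered plateau.
#' @return List with `sat_mass` (g), `corrected` flag, and `n_plateau`
#'   (points excluded as plateau).
#' @export
saturated_mass <- function(curve, correct = FALSE, r2_target = 0.995,
                           max_drop = 3L) {
  stopifnot(inherits(curve, "pv_curve"))
  m_max <- max(curve$masses)
  if (!correct)
    return(list(sat_mass = m_max, corrected = FALSE, n_plateau = 0L))
  n <- length(curve$masses)
  # initial region: the hydrated half of the curve (at least 4 points)
  m_init <- max(4L, ceiling(n / 2))
  fit_region <- function(drop) {
    idx <- seq(drop + 1L, m_init)
    f <- .ols_line(curve$psis[idx], curve$masses[idx])
    list(intercept = f$a, r2 = f$r2, drop = drop)
  }
  max_drop <- min(max_drop, m_init - 3L)
  if (max_drop < 0L) {
    warning("fewer than 3 points in the initial region; using max(masses)")
    return(list(sat_mass = m_max, corrected = FALSE, n_plateau = 0L))
  }
  best <- NULL
  for (d in 0:max_drop) {
    cand <- fit_region(d)
    if (is.null(best) || cand$r2 > best$r2) best <- cand
    if (cand$r2 >= r2_target) { best <- cand; break }
  }
  plateau <- best$drop > 0L
  use_intercept <- plateau || best$intercept > m_max
  list(sat_mass = if (use_intercept) best$intercept else m_max,
       corrected = use_intercept, n_plateau = best$drop)
}

#' Saturated water content
#'
#' Water mass at full hydration per unit dry mass:
#' `(sat_mass - dry_mass) / dry_mass`, g g^-1.
#'
#' @param curve A [pv_curve()] object.
#' @param sat_mass Saturated mass, g; defaults to [saturated_mass()]
#'   without correction.
#' @return SWC in g g^-1.
#' @export
swc <- function(curve, sat_mass = NULL) {
  stopifnot(inherits(curve, "pv_curve"))
  if (is.null(sat_mass)) sat_mass <- saturated_mass(curve)$sat_mass
  if (sat_mass <= curve$dry_mass)
    stop("sat_mass must exceed dry_mass", call. = FALSE)
  (sat_mass - curve$dry_mass) / curve$dry_mass
}

# molar mass of water, g mol^-1
.MW_WATER <- 18.015

# plain OLS of y on x without lm() overhead; r2 = 1 for an exact fit on
# degenerate (zero-variance) y
.ols_line <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(list(a = NA_real_, b = NA_real_, r2 = 0))
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  sst <- sum((y - mean(y))^2)
  sse <- sum((y - a - b * x)^2)
  r2 <- if (sst == 0) 1 else 1 - sse / sst
  list(a = a, b = b, r2 = r2)
}

#' Fit pressure-volume parameters
#'
#' Tyree-Hammel-style analysis of a PV curve on a dry-mass basis. The
#' cumulative water deficit (saturated mass minus observed mass) is computed
#' per point; the turgor-loss breakpoint is chosen by exhaustive search as
#' the split maximising the r^2 of the post-breakpoint linear fit of
#' `-1/psi` against deficit (at least `min_seg` points per segment, ties
#' broken toward the more hydrated breakpoint). Then:
#' osmotic potential at full turgor `psi_sft = -1/intercept`; turgor loss
#' point `psi_tlp` from the fitted line evaluated midway between the last
#' pre-breakpoint and first post-breakpoint deficits (midpoint estimator,
#' chosen to halve discretisation bias); absolute capacitance `c_t` as the
#' slope of water content (mol per kg dry mass) against psi over the
#' pre-breakpoint segment, reported positive. A post-turgor-loss
#' capacitance is reported as a secondary field.
#'
#' If the whole series is already linear in `-1/psi` (r^2 >= 0.999) the
#' curve is treated as purely osmotic: the breakpoint is flagged at the
#' first point and capacitance is taken over the whole series.
#'
#' @param curve A [pv_curve()] object spanning both sides of turgor loss.
#' @param sat_mass Optional saturated mass, g; default [saturated_mass()]
#'   with `correct = plateau_correct`.
#' @param plateau_correct Apply the plateau correction when deriving the
#'   saturated mass internally.
#' @param min_seg Minimum points per segment (default 3).
#' @return List of class `pv_parameters`: `swc` (g g^-1), `psi_sft`,
#'   `psi_tlp` (MPa), `c_t`, `c_t_post` (mol kg^-1 MPa^-1), `tlp_index`,
#'   `sat_mass`, `corrected`, `r2_post`, `apoplastic_frac_est`,
#'   `no_turgor`.
#' @export
fit_pv <- function(curve, sat_mass = NULL, plateau_correct = FALSE,
                   min_seg = 3L) {
  stopifnot(inherits(curve, "pv_curve"))
  corrected <- FALSE
  if (is.null(sat_mass)) {
    sm <- saturated_mass(curve, correct = plateau_correct)
    sat_mass <- sm$sat_mass
    corrected <- sm$corrected
  }
  n <- length(curve$masses)
  deficit <- sat_mass - curve$masses            # g water lost from saturation
  y <- -1 / curve$psis                          # positive, declines while drying
  line_fit <- function(idx) .ols_line(deficit[idx], y[idx])
  full <- line_fit(seq_len(n))
  min_seg <- max(3L, as.integer(min_seg))
  ks <- seq(min_seg + 1L, n - min_seg + 1L)
  if (length(ks) < 1L)
    stop("too few points to place a breakpoint with ", min_seg,
         " points per segment", call. = FALSE)
  fits <- lapply(ks, function(k) line_fit(k:n))
  r2s <- vapply(fits, `[[`, numeric(1), "r2")
  # purely osmotic curve: -1/psi linear in deficit throughout, so no split
  # can improve on the whole-series fit
  no_turgor <- full$r2 >= 1 - 1e-9 && full$r2 >= max(r2s) - 1e-9
  if (no_turgor) {
    k <- 1L
    post <- full
  } else {
    # residual variance per split; the best split estimates the measurement
    # noise, then the most hydrated split whose residual variance is
    # consistent with that noise (5% F-criterion) is chosen, so the post
    # segment is as long as the data allow. A bare argmax of r2 would favour
    # short, lucky segments near the dry end.
    sig2 <- vapply(seq_along(ks), function(i) {
      idx <- ks[i]:n
      yy <- y[idx]
      f <- fits[[i]]
      sum((yy - f$a - f$b * deficit[idx])^2) / (length(idx) - 2L)
    }, numeric(1))
    sig2_best <- min(sig2)
    tol <- 1e-12 * stats::var(y)
    admissible <- vapply(seq_along(ks), function(i) {
      dfk <- length(ks[i]:n) - 2L
      crit <- sig2_best * stats::qf(0.95, dfk, n - ks[which.min(sig2)] + 1L - 2L)
      sig2[i] <= crit + tol
    }, logical(1))
    best <- which(admissible)[1]
    k <- ks[best]
    post <- fits[[best]]
  }
  if (!is.finite(post$a) || post$a <= 0)
    stop("PV fit failed: -1/psi intercept at zero deficit is not positive ",
         "(no admissible osmotic line); r2_post = ", signif(post$r2, 4),
         call. = FALSE)
  psi_sft <- -1 / post$a
  d_break <- if (k > 1L) (deficit[k - 1L] + deficit[k]) / 2 else deficit[1L]
  y_break <- post$a + post$b * d_break
  if (y_break <= 0)
    stop("PV fit failed: fitted -1/psi non-positive at the breakpoint",
         call. = FALSE)
  psi_tlp <- -1 / y_break
  psi_tlp <- min(psi_tlp, psi_sft)   # guard against tiny numerical excess
  # capacitance: water content in mol per kg dry mass vs psi
  wc <- (curve$masses - curve$dry_mass) * 1000 / (.MW_WATER * curve$dry_mass)
  ct_slope <- function(idx) {
    if (length(idx) < 2L) return(NA_real_)
    unname(stats::coef(stats::lm(wc[idx] ~ curve$psis[idx]))[2])
  }
  pre_idx <- if (no_turgor) seq_len(n) else seq_len(k - 1L)
  c_t <- ct_slope(pre_idx)
  c_t_post <- ct_slope(k:n)
  if (is.finite(c_t) && c_t < 0)
    warning("pre-turgor-loss capacitance fitted negative; check the curve")
  # deficit at which the osmotic line predicts symplastic water exhausted
  apo <- NA_real_
  if (post$b < 0) {
    d_zero <- -post$a / post$b
    apo <- 1 - d_zero / (sat_mass - curve$dry_mass)
  }
  structure(list(swc = swc(curve, sat_mass), psi_sft = psi_sft,
                 psi_tlp = psi_tlp, c_t = c_t, c_t_post = c_t_post,
                 tlp_index = k, sat_mass = sat_mass, corrected = corrected,
                 r2_post = post$r2, apoplastic_frac_est = apo,
                 no_turgor = no_turgor),
            class = "pv_parameters")
}

#' @export
print.pv_parameters <- function(x, ...) {
  cat("Pressure-volume parameters (dry-mass basis)\n")
  cat("  SWC:    ", signif(x$swc, 4), "g g^-1\n")
  cat("  psi_sft:", signif(x$psi_sft, 4), "MPa\n")
  cat("  psi_tlp:", signif(x$psi_tlp, 4), "MPa",
      if (x$no_turgor) " (no turgor region detected)" else "", "\n")
  cat("  C_T:    ", signif(x$c_t, 4), "mol kg^-1 MPa^-1  (post-TLP:",
      signif(x$c_t_post, 4), ")\n")
  cat("  breakpoint index:", x$tlp_index, " r2 (post):",
      round(x$r2_post, 4), "\n")
  invisible(x)
}
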