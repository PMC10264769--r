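#' Construct a bench drying curve
#'
#' A timed series of whole-organ masses weighed under recorded air
#' temperature and relative humidity, used to estimate minimum diffusive
#' conductance after stomatal closure.
#'
#' @param times Weighing times, seconds, strictly increasing.
#' @param masses Organ masses, g.
#' @param temps Air temperature at each weighing, degrees C.
#' @param rhs Relative humidity at each weighing, percent (0-100, open).
#' @param projected_area Single-sided projected organ area, m^2.
#' @param dry_mass Oven-dry mass, g.
#' @param p_atm Atmospheric pressure, kPa.
#' @return An object of class `drying_curve`.
#' @export
drying_curve <- function(times, masses, temps, rhs, projected_area,
                         dry_mass, p_atm = 101.3) {
  n <- length(times)
  if (n < 3L) stop("at least 3 weighings are required", call. = FALSE)
  if (length(masses) != n || length(temps) != n || length(rhs) != n)
    stop("times, masses, temps and rhs must have equal length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(rhs <= 0) || any(rhs >= 100))
    stop("relative humidity must lie strictly between 0 and 100 %",
         call. = FALSE)
  if (dry_mass <= 0 || any(masses < dry_mass))
    stop("masses must be >= dry_mass > 0", call. = FALSE)
  if (projected_area <= 0) stop("projected_area must be > 0", call. = FALSE)
  if (p_atm <= 0) stop("p_atm must be > 0", call. = FALSE)
  structure(list(times = as.numeric(times), masses = as.numeric(masses),
                 temps = as.numeric(temps), rhs = as.numeric(rhs),
                 projected_area = projected_area, dry_mass = dry_mass,
                 p_atm = p_atm),
            class = "drying_curve")
}

#' @export
print.drying_curve <- function(x, ...) {
  cat("Drying curve:", length(x$times), "weighings over",
      round(diff(range(x$times)) / 60, 1), "min\n")
  cat("  mass", round(x$masses[1], 4), "->", round(x$masses[length(x$masses)], 4),
      "g; dry mass", x$dry_mass, "g; area", x$projected_area, "m^2\n")
  invisible(x)
}

#' Vapour pressure deficit (Arden Buck equation)
#'
#' `VPD = (1 - RH/100) * 0.61121 * exp(17.502 T / (240.97 + T))` with T in
#' degrees C, giving the saturation deficit in kPa.
#'
#' @param temp Air temperature, degrees C (between -40 and 60).
#' @param rh Relative humidity, percent (0-100).
#' @return VPD in kPa (vectorised).
#' @export
vpd <- function(temp, rh) {
  if (any(rh < 0 | rh > 100))
    stop("relative humidity must be within [0, 100] %", call. = FALSE)
  if (any(temp <= -40 | temp >= 60))
    stop("temperature outside the valid range (-40, 60) degrees C",
         call. = FALSE)
  e_sat <- 0.61121 * exp(17.502 * temp / (240.97 + temp))
  (1 - rh / 100) * e_sat
}

#' Water loss rate from a drying curve
#'
#' Ordinary least-squares slope of mass (g) on time (s), reported as a
#' positive loss rate. `window = "full"` fits the whole series;
#' `window = "auto"` searches every contiguous window of at least
#' `min_window` points and keeps the one maximising r^2, for organs whose
#' initial (stomatal) phase is not linear.
#'
#' @param curve A [drying_curve()] object.
#' @param window `"full"` (default) or `"auto"`.
#' @param min_window Minimum window length for `"auto"` (default 5).
#' @return List with `wl_slope` (g s^-1, positive for mass loss),
#'   `fit_window` (integer index range), `r2`, and `increasing` flag set
#'   when mass increases over the fitted window.
#' @export
water_loss_rate <- function(curve, window = c("full", "auto"),
                            min_window = 5L) {
  stopifnot(inherits(curve, "drying_curve"))
  window <- match.arg(window)
  n <- length(curve$times)
  fit_ls <- function(idx) {
    f <- .ols_line(curve$times[idx], curve$masses[idx])
    list(slope = f$b, r2 = f$r2, idx = idx)
  }
  if (window == "full") {
    best <- fit_ls(seq_len(n))
  } else {
    min_window <- max(3L, as.integer(min_window))
    if (n < min_window) stop("too few points for the requested window",
                             call. = FALSE)
    best <- NULL
    for (i in seq_len(n - min_window + 1L)) {
      for (j in seq(i + min_window - 1L, n)) {
        cand <- fit_ls(i:j)
        # prefer higher r2; at (near-)equal r2 keep the longer window
        if (is.null(best) || cand$r2 > best$r2 + 1e-12 ||
            (abs(cand$r2 - best$r2) <= 1e-12 &&
             length(cand$idx) > length(best$idx)))
          best <- cand
      }
    }
  }
  slope <- best$slope
  if (is.na(slope)) slope <- 0
  increasing <- slope > 0
  if (increasing)
    warning("mass increases over the fitted window; water loss rate <= 0")
  list(wl_slope = -slope, fit_window = range(best$idx), r2 = best$r2,
       increasing = increasing)
}

#' Minimum diffusive conductance from a drying curve
#'
#' `g_min = WL * P_atm / VPD`, where WL is the mass-loss slope converted to
#' mmol s^-1 (molar mass of water 18.015 g mol^-1) and normalised by the
#' projected area (for `g_min_area`) or dry mass (for `g_min_mass`), and
#' VPD is the mean of per-weighing Arden Buck deficits over the fitted
#' window.
#'
#' @param curve A [drying_curve()] object.
#' @param window Passed to [water_loss_rate()].
#' @return List of class `gmin_result` with `g_min_area`
#'   (mmol m^-2 s^-1), `g_min_mass` (mmol g^-1 s^-1), `wl_slope` (g s^-1),
#'   `fit_window`, `r2`, `vpd_mean` (kPa).
#' @export
gmin <- function(curve, window = c("full", "auto")) {
  stopifnot(inherits(curve, "drying_curve"))
  wl <- water_loss_rate(curve, window = window)
  idx <- seq(wl$fit_window[1], wl$fit_window[2])
  vpd_mean <- mean(vpd(curve$temps[idx], curve$rhs[idx]))
  if (vpd_mean < 1e-6)
    stop("air saturated over the fit window (VPD ~ 0); conductance undefined",
         call. = FALSE)
  wl_mmol <- wl$wl_slope / 18.015 * 1000          # g s^-1 -> mmol s^-1
  g_area <- wl_mmol / curve$projected_area * curve$p_atm / vpd_mean
  g_mass <- wl_mmol / curve$dry_mass * curve$p_atm / vpd_mean
  structure(list(g_min_area = g_area, g_min_mass = g_mass,
                 wl_slope = wl$wl_slope, fit_window = wl$fit_window,
                 r2 = wl$r2, vpd_mean = vpd_mean,
                 increasing = wl$increasing),
            class = "gmin_result")
}

#' @export
print.gmin_result <- function(x, ...) {
  cat("Minimum diffusive conductance\n")
  cat("  g_min,area:", signif(x$g_min_area, 4), "mmol m^-2 s^-1\n")
  cat("  g_min,mass:", signif(x$g_min_mass, 4), "mmol g^-1 s^-1\n")
  cat("  WL slope:", signif(x$wl_slope, 4), "g s^-1 (r2 =",
      round(x$r2, 4), "), mean VPD:", round(x$vpd_mean, 3), "kPa\n")
  invisible(x)
}
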