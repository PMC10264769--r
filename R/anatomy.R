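#' Construct a vessel cross-section record
#'
#' Bundles the measurements taken from one xylem cross-section image:
#' equivalent circular lumen diameters of all vessels in the field, sampled
#' double-wall thicknesses, and the image area over which vessels were
#' counted.
#'
#' @param vessel_diameters Numeric vector of equivalent circular lumen
#'   diameters, in micrometres. Use [equivalent_diameter()] to convert
#'   long/short axis pairs measured on elliptical lumina.
#' @param wall_thickness_pairs Numeric vector of double-wall thicknesses
#'   (T_w, micrometres) measured on pairs of connected vessels. May be empty.
#' @param image_area Image area in mm^2 (e.g. 0.22 for a 20x field of view).
#' @return An object of class `vessel_section`.
#' @export
vessel_section <- function(vessel_diameters, wall_thickness_pairs = numeric(),
                           image_area) {
  vessel_diameters <- as.numeric(vessel_diameters)
  if (length(vessel_diameters) < 1L)
    stop("at least one vessel diameter is required", call. = FALSE)
  if (any(!is.finite(vessel_diameters)) || any(vessel_diameters <= 0))
    stop("all vessel diameters must be finite and > 0", call. = FALSE)
  if (!is.numeric(image_area) || length(image_area) != 1L ||
      !is.finite(image_area) || image_area <= 0)
    stop("image_area must be a single positive number (mm^2)", call. = FALSE)
  wall_thickness_pairs <- as.numeric(wall_thickness_pairs)
  if (any(wall_thickness_pairs <= 0))
    stop("wall thicknesses must be > 0", call. = FALSE)
  structure(list(vessel_diameters = vessel_diameters,
                 wall_thickness_pairs = wall_thickness_pairs,
                 image_area = image_area),
            class = "vessel_section")
}

#' @export
print.vessel_section <- function(x, ...) {
  cat("Vessel cross-section:", length(x$vessel_diameters), "vessels over",
      x$image_area, "mm^2\n")
  cat("  lumen diameter (um): mean", round(mean(x$vessel_diameters), 2),
      " range", round(min(x$vessel_diameters), 2), "-",
      round(max(x$vessel_diameters), 2), "\n")
  if (length(x$wall_thickness_pairs))
    cat("  double wall thickness T_w (um): mean",
        round(mean(x$wall_thickness_pairs), 2), "\n")
  invisible(x)
}

#' Equivalent circular diameter of an elliptical vessel lumen
#'
#' Area-preserving conversion: an ellipse with axes `d_long`, `d_short` has
#' the same area as a circle of diameter `sqrt(d_long * d_short)`.
#'
#' @param d_long,d_short Long and short lumen axes, micrometres.
#' @return Equivalent circular diameter, micrometres (vectorised).
#' @export
equivalent_diameter <- function(d_long, d_short) {
  if (any(d_long < d_short))
    stop("d_long must be >= d_short", call. = FALSE)
  if (any(d_short <= 0)) stop("diameters must be > 0", call. = FALSE)
  sqrt(d_long * d_short)
}

#' Physical constants for Hagen-Poiseuille conductivity
#'
#' @param rho Fluid density, kg m^-3 (water at 20 degrees C by default).
#' @param eta Dynamic viscosity, MPa s (water at 20 degrees C by default).
#' @return A list of class `physical_constants`.
#' @export
physical_constants <- function(rho = 998.2, eta = 1.002e-9) {
  if (rho <= 0 || eta <= 0) stop("rho and eta must be > 0", call. = FALSE)
  structure(list(rho = rho, eta = eta), class = "physical_constants")
}

#' Hydraulically weighted vessel diameter
#'
#' The fourth-power mean of vessel lumen diameters,
#' `D_h = (sum(D^4)/N)^0.25`, which weights vessels by their
#' Hagen-Poiseuille conductance contribution.
#'
#' @param section A [vessel_section()] object, or a numeric vector of
#'   diameters (micrometres).
#' @return D_h in the units of the input diameters.
#' @export
hydraulic_diameter <- function(section) {
  d <- if (inherits(section, "vessel_section")) section$vessel_diameters
       else as.numeric(section)
  if (length(d) < 1L) stop("at least one vessel diameter is required",
                           call. = FALSE)
  if (any(d <= 0)) stop("diameters must be > 0", call. = FALSE)
  (mean(d^4))^0.25
}

#' Vessel frequency
#'
#' Number of vessels divided by the image area.
#'
#' @param section A [vessel_section()] object.
#' @return VF in vessels mm^-2.
#' @export
vessel_frequency <- function(section) {
  stopifnot(inherits(section, "vessel_section"))
  length(section$vessel_diameters) / section$image_area
}

#' Theoretical hydraulic conductivity (Hagen-Poiseuille)
#'
#' `K_th = (pi * rho / (128 * eta)) * VF * D_h^4`, with VF converted from
#' mm^-2 to m^-2 and D_h from micrometres to metres internally, so the
#' result is in kg m^-1 MPa^-1 s^-1.
#'
#' @param vf Vessel frequency, vessels mm^-2.
#' @param d_h Hydraulically weighted vessel diameter, micrometres.
#' @param constants A [physical_constants()] object.
#' @return K_th in kg m^-1 MPa^-1 s^-1.
#' @export
theoretical_conductivity <- function(vf, d_h,
                                     constants = physical_constants()) {
  if (!is.finite(d_h) || d_h <= 0) stop("d_h must be > 0", call. = FALSE)
  if (!is.finite(vf) || vf < 0) stop("vf must be >= 0", call. = FALSE)
  vf_si <- vf * 1e6          # mm^-2 -> m^-2
  dh_si <- d_h * 1e-6        # um -> m
  (pi * constants$rho / (128 * constants$eta)) * vf_si * dh_si^4
}

#' Construct an intervessel pit morphology record
#'
#' Per-pit membrane and aperture long/short diameters and areas, plus pit
#' counts per known wall area for pit density.
#'
#' @param d_pml,d_pms Pit membrane longest/shortest diameters, micrometres
#'   (vectors, one value per pit).
#' @param d_pal,d_pas Pit aperture longest/shortest diameters, micrometres.
#' @param a_pit,a_pa Pit membrane and aperture surface areas, um^2.
#' @param pit_counts Data frame with columns `n_pits` and `wall_area`
#'   (um^2), one row per imaged wall; used for pit density.
#' @return An object of class `pit_morphology`.
#' @export
pit_morphology <- function(d_pml, d_pms, d_pal, d_pas, a_pit, a_pa,
                           pit_counts = NULL) {
  n <- length(d_pml)
  if (n < 1L) stop("at least one pit is required", call. = FALSE)
  lens <- list(d_pml, d_pms, d_pal, d_pas, a_pit, a_pa)
  if (any(vapply(lens, length, 1L) != n))
    stop("all per-pit vectors must have the same length", call. = FALSE)
  if (any(d_pms <= 0) || any(d_pas <= 0) || any(a_pit <= 0) || any(a_pa <= 0))
    stop("pit diameters and areas must be > 0", call. = FALSE)
  if (any(d_pml < d_pms) || any(d_pal < d_pas))
    stop("long diameters must be >= short diameters", call. = FALSE)
  if (any(a_pa > a_pit))
    stop("aperture area cannot exceed pit membrane area", call. = FALSE)
  if (!is.null(pit_counts)) {
    pit_counts <- as.data.frame(pit_counts)
    if (!all(c("n_pits", "wall_area") %in% names(pit_counts)))
      stop("pit_counts needs columns n_pits and wall_area", call. = FALSE)
    if (any(pit_counts$wall_area <= 0) || any(pit_counts$n_pits < 0))
      stop("wall areas must be > 0 and counts >= 0", call. = FALSE)
  }
  structure(list(d_pml = d_pml, d_pms = d_pms, d_pal = d_pal, d_pas = d_pas,
                 a_pit = a_pit, a_pa = a_pa, pit_counts = pit_counts),
            class = "pit_morphology")
}

#' Summarise intervessel pit traits
#'
#' Mean membrane/aperture diameters and areas, shape ratios R_pa =
#' D_pal/D_pas and R_pit = D_pml/D_pms, and pit density D_p. Shape ratios
#' are computed per pit and then averaged by default (`ratio_mode =
#' "per_pit"`); `"of_means"` computes them from the mean diameters instead.
#' D_p pools counts across walls: `sum(n_pits) / sum(wall_area)`, weighting
#' by observed wall area.
#'
#' @param pits A [pit_morphology()] object.
#' @param ratio_mode `"per_pit"` (mean of per-pit ratios, default) or
#'   `"of_means"` (ratio of mean diameters).
#' @return Named list: `d_pml`, `d_pms`, `d_pal`, `d_pas` (um), `a_pit`,
#'   `a_pa` (um^2), `r_pa`, `r_pit` (dimensionless, >= 1), `d_p`
#'   (no. um^-2; `NA` if no pit counts supplied).
#' @export
pit_summary <- function(pits, ratio_mode = c("per_pit", "of_means")) {
  stopifnot(inherits(pits, "pit_morphology"))
  ratio_mode <- match.arg(ratio_mode)
  r_pa <- switch(ratio_mode,
                 per_pit = mean(pits$d_pal / pits$d_pas),
                 of_means = mean(pits$d_pal) / mean(pits$d_pas))
  r_pit <- switch(ratio_mode,
                  per_pit = mean(pits$d_pml / pits$d_pms),
                  of_means = mean(pits$d_pml) / mean(pits$d_pms))
  d_p <- if (is.null(pits$pit_counts) || nrow(pits$pit_counts) == 0) NA_real_
         else sum(pits$pit_counts$n_pits) / sum(pits$pit_counts$wall_area)
  list(d_pml = mean(pits$d_pml), d_pms = mean(pits$d_pms),
       d_pal = mean(pits$d_pal), d_pas = mean(pits$d_pas),
       a_pit = mean(pits$a_pit), a_pa = mean(pits$a_pa),
       r_pa = r_pa, r_pit = r_pit, d_p = d_p)
}

#' Pit packing position relative to the full-coverage limit
#'
#' The product `D_p * A_pit` is the fraction of intervessel wall area
#' occupied by pit membranes; 1 corresponds to complete coverage, the
#' geometric packing limit used to position taxa along the packing axis.
#'
#' @param a_pit Mean pit membrane area, um^2.
#' @param d_p Pit density, no. um^-2.
#' @return Wall coverage fraction (dimensionless).
#' @export
packing_position <- function(a_pit, d_p) {
  if (any(!is.finite(a_pit)) || any(!is.finite(d_p)) ||
      any(a_pit <= 0) || any(d_p <= 0))
    stop("a_pit and d_p must be positive", call. = FALSE)
  a_pit * d_p
}

#' Construct a stomatal count field
#'
#' One photomicrograph field with stomatal centroid positions and (optional)
#' guard-cell pair outline areas.
#'
#' @param centroids Two-column matrix or data frame of (x, y) centroid
#'   positions, micrometres, within `[0, width] x [0, height]`.
#' @param stomatal_areas Optional numeric vector of stomatal areas, um^2.
#' @param field_width,field_height Field dimensions, micrometres.
#' @return An object of class `stomatal_field`.
#' @export
stomatal_field <- function(centroids, stomatal_areas = numeric(),
                           field_width, field_height) {
  if (field_width <= 0 || field_height <= 0)
    stop("field dimensions must be > 0", call. = FALSE)
  centroids <- as.matrix(centroids)
  if (length(centroids) == 0) centroids <- matrix(numeric(), ncol = 2)
  if (ncol(centroids) != 2)
    stop("centroids must have two columns (x, y)", call. = FALSE)
  if (nrow(centroids) > 0 &&
      (any(centroids[, 1] < 0) || any(centroids[, 1] > field_width) ||
       any(centroids[, 2] < 0) || any(centroids[, 2] > field_height)))
    stop("centroids must lie within the field", call. = FALSE)
  structure(list(centroids = centroids,
                 stomatal_areas = as.numeric(stomatal_areas),
                 field_width = field_width, field_height = field_height),
            class = "stomatal_field")
}

#' Stomatal density and size under the border-counting rule
#'
#' Stomata visible along the top and left borders of the field are counted;
#' those along the bottom and right borders are discarded, so each stoma is
#' counted exactly once across tiled fields. "Along a border" means the
#' centroid lies within `border_tol` of that edge. The y axis points up:
#' the top border is `y = field_height`, the bottom `y = 0`.
#'
#' @param field A [stomatal_field()] object.
#' @param border_tol Distance (micrometres) within which a centroid counts
#'   as on a border; supply the pixel size of the source image.
#' @return List with `d_s` (stomata mm^-2) and `s_s` (mean stomatal area,
#'   um^2; `NA` with a flag when no areas were measured), plus the retained
#'   count `n`.
#' @export
stomatal_traits <- function(field, border_tol = 0) {
  stopifnot(inherits(field, "stomatal_field"))
  xy <- field$centroids
  if (nrow(xy) == 0) {
    n_keep <- 0L
  } else {
    on_left   <- xy[, 1] <= border_tol
    on_right  <- xy[, 1] >= field$field_width - border_tol
    on_top    <- xy[, 2] >= field$field_height - border_tol
    on_bottom <- xy[, 2] <= border_tol
    # discard bottom/right-border stomata unless they also touch top/left
    keep <- !((on_right | on_bottom) & !(on_left | on_top))
    n_keep <- sum(keep)
  }
  area_mm2 <- field$field_width * field$field_height / 1e6  # um^2 -> mm^2
  s_s <- if (length(field$stomatal_areas)) mean(field$stomatal_areas)
         else NA_real_
  list(d_s = n_keep / area_mm2, s_s = s_s, n = n_keep,
       s_s_defined = length(field$stomatal_areas) > 0)
}
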