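#' Default synthetic study design
#'
#' Describes the simulated study: 10 species, two organs (flower, leaf), and
#' a 23-trait panel with per-organ medians chosen as realistic values for
#' subtropical woody angiosperms (flowers leakier, with higher capacitance
#' and water content and less negative water potentials than leaves; pit and
#' vessel dimensions slightly smaller in peduncles than petioles). Trait
#' medians are illustrative, not measurements. Cross-trait correlation is
#' induced by a two-factor model (a xylem/pit size axis and a water-economy
#' axis), which guarantees a positive semidefinite correlation matrix.
#'
#' @param n_species Number of species (default 10).
#' @param cv Among-species coefficient of variation of each trait
#'   (default 0.3); converted to a log-scale Brownian-motion spread.
#' @param noise_log Organ-level measurement noise, sd on the log scale
#'   (default 0.1).
#' @return List of class `study_design` with `n_species`, `organs`,
#'   `traits` (data frame: trait, leaf and flower medians, sign, factor
#'   loadings f1 and f2), `cv`, `noise_log`, and the implied trait
#'   correlation matrix `R`.
#' @export
study_design <- function(n_species = 10, cv = 0.3, noise_log = 0.1) {
  if (n_species < 2) stop("n_species must be >= 2", call. = FALSE)
  if (cv < 0 || noise_log < 0) stop("cv and noise_log must be >= 0",
                                    call. = FALSE)
  tr <- data.frame(
    trait = c("g_min_area", "g_min_mass", "c_t", "swc", "psi_sft", "psi_tlp",
              "d_pml", "d_pms", "d_pal", "d_pas", "a_pit", "a_pa",
              "r_pa", "r_pit", "d_p", "s_s", "d_s", "d_v", "thickness",
              "d_h", "t_w", "vf", "k_th"),
    leaf   = c(4, 0.08, 2, 1.5, -1.8, -2.2,
               5.0, 4.2, 2.6, 1.6, 13.29, 2.5,
               1.6, 1.2, 0.045, 500, 250, 6, 0.25,
               18, 2.5, 120, 0.30),
    flower = c(16, 0.40, 8, 4.0, -1.0, -1.2,
               4.2, 3.6, 2.2, 1.4, 9.38, 2.2,
               1.6, 1.2, 0.052, 600, 15, 2, 0.35,
               16, 2.2, 100, 0.16),
    f1 = c(0, 0, 0, 0, 0, 0,
           0.8, 0.8, 0.7, 0.7, 0.85, 0.75,
           0, 0, -0.8, 0, 0, 0, 0,
           0.6, 0.5, -0.4, 0.7),
    f2 = c(0.6, 0.7, 0.7, 0.8, -0.6, -0.6,
           0, 0, 0, 0, 0, 0,
           0.2, 0.2, 0, 0.2, -0.3, -0.3, 0.5,
           0, 0, 0, 0),
    stringsAsFactors = FALSE)
  tr$sign <- ifelse(tr$leaf < 0, -1, 1)
  L <- as.matrix(tr[, c("f1", "f2")])
  R <- L %*% t(L)
  diag(R) <- 1
  dimnames(R) <- list(tr$trait, tr$trait)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("trait correlation matrix is not PSD",
                            call. = FALSE)
  structure(list(n_species = n_species, organs = c("flower", "leaf"),
                 traits = tr, cv = cv, noise_log = noise_log, R = R),
            class = "study_design")
}

#' Simulate an ultrametric phylogeny
#'
#' Coalescent tree (via `ape::rcoal`) rescaled to unit depth, with tip
#' labels `sp01 ... spNN`. Reproducible under a fixed seed.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Optional integer seed.
#' @return An ultrametric `phylo` object of depth 1.
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  if (n_tips < 2) stop("n_tips must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  labs <- sprintf("sp%02d", seq_len(n_tips))
  tree <- ape::rcoal(n_tips, tip.label = labs)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree
}

# correlated Brownian motion on a tree: one standardised (unit tip variance
# on a unit-depth tree) deviate per tip and trait, with cross-trait
# correlation R at every instant
sim_correlated_bm <- function(tree, R) {
  k <- nrow(R)
  Lc <- t(chol(R + diag(1e-10, k)))
  n_tip <- length(tree$tip.label)
  ord <- ape::reorder.phylo(tree, "postorder")
  # preorder: reverse postorder edge list
  edges <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]
  lens <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]
  states <- matrix(0, n_tip + tree$Nnode, k)
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1]; ch <- edges[e, 2]
    states[ch, ] <- states[par, ] +
      sqrt(lens[e]) * as.numeric(Lc %*% stats::rnorm(k))
  }
  out <- states[seq_len(n_tip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  colnames(out) <- colnames(R)
  out
}

#' Simulate a species-by-organ trait table
#'
#' Traits evolve on the tree under correlated Brownian motion on the log
#' scale (so positivity-constrained traits stay positive; water potentials
#' are negated lognormals). The species-level deviation is shared between
#' organs of a species (inducing correlated trait evolution between flowers
#' and leaves), organ identity enters as a fixed offset (the difference of
#' the log medians), and independent lognormal measurement noise is added
#' per species-by-organ cell.
#'
#' @param design A [study_design()] object.
#' @param tree A `phylo` object whose tips are the species (defaults to a
#'   fresh [simulate_tree()]).
#' @param seed Optional integer seed.
#' @return Wide trait table: data frame with `species`, `organ` and one
#'   column per trait; attribute `truth` holds the design, tree and the
#'   latent species deviations.
#' @export
simulate_traits <- function(design = study_design(), tree = NULL,
                            seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tree)) tree <- simulate_tree(design$n_species)
  species <- tree$tip.label
  tr <- design$traits
  k <- nrow(tr)
  sd_log <- sqrt(log(1 + design$cv^2))
  z <- sim_correlated_bm(tree, design$R)   # species x trait, ~N(0,1) tips
  rows <- list()
  for (org in design$organs) {
    med <- tr[[org]]
    vals <- matrix(NA_real_, length(species), k)
    for (j in seq_len(k)) {
      eps <- stats::rnorm(length(species), 0, design$noise_log)
      vals[, j] <- tr$sign[j] * abs(med[j]) *
        exp(sd_log * z[species, j] + eps)
    }
    df <- data.frame(species = species, organ = org, vals,
                     stringsAsFactors = FALSE)
    names(df)[-(1:2)] <- tr$trait
    rows[[org]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(design = design, tree = tree, z = z,
                             sd_log = sd_log)
  out
}

#' Simulate a bench drying curve with known conductance
#'
#' Inverts the minimum-conductance equation: an organ with area-normalised
#' conductance `g_area_true` (mmol m^-2 s^-1) under constant temperature
#' and humidity loses mass at `WL = g_area_true * area * VPD / P_atm`
#' (converted to g s^-1), sampled at fixed intervals with Gaussian weighing
#' noise.
#'
#' @param g_area_true True area-normalised conductance, mmol m^-2 s^-1.
#' @param area Projected area, m^2.
#' @param dry_mass Oven-dry mass, g.
#' @param temp,rh Air temperature (degrees C) and relative humidity (%),
#'   scalars or vectors of length `n_points`.
#' @param n_points Number of weighings (default 10).
#' @param interval Seconds between weighings (default 600 = 10 min).
#' @param noise_sd Weighing noise sd, g (default 1e-4, a 0.1 mg balance).
#' @param p_atm Atmospheric pressure, kPa.
#' @param initial_water Initial water content, g; default twice the total
#'   simulated loss (plus 10 mg) so the series stays above dry mass.
#' @param seed Optional integer seed.
#' @return A [drying_curve()] with attribute `truth` (the generating
#'   parameters, including the implied true `wl_slope`).
#' @export
simulate_drying_curve <- function(g_area_true, area, dry_mass, temp = 25,
                                  rh = 50, n_points = 10, interval = 600,
                                  noise_sd = 1e-4, p_atm = 101.3,
                                  initial_water = NULL, seed = NULL) {
  if (g_area_true <= 0) stop("g_area_true must be > 0", call. = FALSE)
  if (any(rh >= 100)) stop("rh must be < 100 %", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  times <- interval * (seq_len(n_points) - 1)
  temps <- rep_len(temp, n_points)
  rhs <- rep_len(rh, n_points)
  vpds <- vpd(temps, rhs)
  # mmol s^-1 -> g s^-1 via molar mass; loss integrated stepwise so a
  # varying T/RH schedule is honoured
  wl_inst <- g_area_true * area * vpds / p_atm * .MW_WATER / 1000
  loss <- c(0, cumsum(0.5 * (wl_inst[-n_points] + wl_inst[-1]) *
                        diff(times)))
  if (is.null(initial_water)) initial_water <- 2 * max(loss) + 0.01
  masses <- dry_mass + initial_water - loss +
    stats::rnorm(n_points, 0, noise_sd)
  keep <- masses > dry_mass
  if (!all(keep)) {
    warning("organ dried below its dry mass; series truncated to ",
            sum(keep), " points")
    times <- times[keep]; masses <- masses[keep]
    temps <- temps[keep]; rhs <- rhs[keep]
  }
  out <- drying_curve(times, masses, temps, rhs, projected_area = area,
                      dry_mass = dry_mass, p_atm = p_atm)
  attr(out, "truth") <- list(g_area = g_area_true,
                             g_mass = g_area_true * area / dry_mass,
                             wl_slope = mean(wl_inst))
  out
}

#' Simulate a pressure-volume curve with known parameters
#'
#' Standard PV generating model on a dry-mass basis. With symplastic
#' relative water content `R_s`, the osmotic component is
#' `psi_s = psi_sft / R_s` and the turgor component declines from
#' `-psi_sft` at full hydration (`R_s = 1`, so the total starts at 0) to
#' zero at the turgor loss point `R_s = r_tlp`, shaped by
#' `((R_s - r_tlp) / (1 - r_tlp))^elastic_exponent`. Below the turgor loss
#' point the curve is purely osmotic, making `-1/psi` exactly linear in the
#' water deficit there with intercept `-1/psi_sft`. The implied true turgor
#' loss point is `psi_sft / r_tlp`. Masses follow from the total relative
#' water content (symplastic plus apoplastic) and the saturated water
#' content; Gaussian noise is added to the water potentials.
#'
#' An oversaturation plateau can be prepended: `plateau_points` extra
#' leading observations carrying `plateau_excess` of surface water above
#' the true saturated mass, at slightly negative water potentials.
#'
#' @param psi_sft Osmotic potential at full turgor, MPa (< 0).
#' @param swc_true Saturated water content, g g^-1.
#' @param apoplastic_frac Apoplastic fraction of saturated water (0 to <1).
#' @param elastic_exponent Shape of the turgor decline (1 = linear in R_s).
#' @param r_tlp Symplastic relative water content at turgor loss
#'   (default 0.85).
#' @param n_points Number of observations (default 12).
#' @param noise_sd Water-potential noise sd, MPa (default 0.02).
#' @param dry_mass Dry mass, g (default 1).
#' @param span How far below `r_tlp` the sampling extends, in R_s units
#'   (default 0.25).
#' @param plateau_points,plateau_excess Oversaturation plateau: number of
#'   leading points and their excess water as a fraction of saturated mass.
#' @param seed Optional integer seed.
#' @return A [pv_curve()] with attribute `truth` (generating parameters,
#'   including `psi_tlp` and `sat_mass`).
#' @export
simulate_pv_curve <- function(psi_sft = -1.5, swc_true = 1.5,
                              apoplastic_frac = 0.2, elastic_exponent = 1,
                              r_tlp = 0.85, n_points = 12, noise_sd = 0.02,
                              dry_mass = 1, span = 0.25,
                              plateau_points = 0, plateau_excess = 0.01,
                              seed = NULL) {
  if (psi_sft >= 0) stop("psi_sft must be < 0", call. = FALSE)
  if (apoplastic_frac < 0 || apoplastic_frac >= 1)
    stop("apoplastic_frac must be in [0, 1)", call. = FALSE)
  if (r_tlp <= 0 || r_tlp >= 1) stop("r_tlp must be in (0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rs <- seq(0.99, r_tlp - span, length.out = n_points)
  if (min(rs) <= 0) stop("sampling span reaches non-physical R_s <= 0",
                         call. = FALSE)
  psi_s <- psi_sft / rs
  turgor <- ifelse(rs > r_tlp,
                   -psi_sft * ((rs - r_tlp) / (1 - r_tlp))^elastic_exponent,
                   0)
  psi <- psi_s + turgor
  sat_mass <- dry_mass * (1 + swc_true)
  r_total <- apoplastic_frac + (1 - apoplastic_frac) * rs
  masses <- dry_mass * (1 + swc_true * r_total)
  psi_obs <- pmin(psi + stats::rnorm(n_points, 0, noise_sd), -0.01)
  if (plateau_points > 0) {
    excess <- plateau_excess * sat_mass * seq(1, 0.5,
                                              length.out = plateau_points)
    plat_psi <- pmin(seq(-0.02, -0.05, length.out = plateau_points) +
                       stats::rnorm(plateau_points, 0, noise_sd / 2), -0.01)
    masses <- c(sat_mass + excess, masses)
    psi_obs <- c(plat_psi, psi_obs)
  }
  out <- pv_curve(masses, psi_obs, dry_mass)
  attr(out, "truth") <- list(psi_sft = psi_sft, psi_tlp = psi_sft / r_tlp,
                             swc = swc_true, sat_mass = sat_mass,
                             apoplastic_frac = apoplastic_frac,
                             r_tlp = r_tlp)
  out
}

#' Simulate a complete synthetic study
#'
#' Generates every input the pipeline consumes, with known ground truth: an
#' ultrametric tree, a species-by-organ trait table evolved on it, one
#' drying curve and one PV curve per species and organ (their generating
#' parameters taken from that species' trait-table values, so curve-level
#' estimates and table-level statistics are mutually consistent).
#'
#' @param seed Integer seed driving the whole study.
#' @param design A [study_design()] object.
#' @param dir Optional output directory; when given, writes `tree.nwk`,
#'   `traits.csv` (long format), `curves.csv` + `curves_meta.csv`,
#'   `pv.csv` + `pv_meta.csv` and `truth.json`.
#' @param drying_noise_sd,pv_noise_sd Measurement noise for the curve
#'   generators.
#' @return List of class `synthetic_study`: `tree`, `traits` (wide),
#'   `drying` and `pv` (named lists of curves), `meta` (per-sample data
#'   frame), `truth`.
#' @export
simulate_study <- function(seed = 1, design = study_design(), dir = NULL,
                           drying_noise_sd = 1e-4, pv_noise_sd = 0.02) {
  set.seed(seed)
  tree <- simulate_tree(design$n_species)
  traits <- simulate_traits(design, tree)
  areas <- c(flower = 4e-3, leaf = 3e-3)        # m^2
  dry_masses <- c(flower = 0.5, leaf = 0.3)     # g
  drying <- list(); pv <- list(); meta <- list()
  for (i in seq_len(nrow(traits))) {
    sp <- traits$species[i]; org <- traits$organ[i]
    id <- paste(sp, org, sep = "_")
    drying[[id]] <- simulate_drying_curve(
      g_area_true = traits$g_min_area[i], area = areas[[org]],
      dry_mass = dry_masses[[org]], noise_sd = drying_noise_sd)
    r_tlp <- traits$psi_sft[i] / traits$psi_tlp[i]
    pv[[id]] <- simulate_pv_curve(
      psi_sft = traits$psi_sft[i], swc_true = traits$swc[i],
      apoplastic_frac = 0.2, r_tlp = min(max(r_tlp, 0.5), 0.95),
      noise_sd = pv_noise_sd, dry_mass = dry_masses[[org]])
    meta[[id]] <- data.frame(sample_id = id, species = sp, organ = org,
                             area_m2 = areas[[org]],
                             dry_mass_g = dry_masses[[org]],
                             p_atm_kpa = 101.3, stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL
  study <- structure(list(tree = tree, traits = traits, drying = drying,
                          pv = pv, meta = meta,
                          truth = list(seed = seed,
                                       design_traits = design$traits,
                                       sd_log = attr(traits, "truth")$sd_log)),
                     class = "synthetic_study")
  if (!is.null(dir)) write_study(study, dir)
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic study:", length(x$tree$tip.label), "species x",
      length(unique(x$traits$organ)), "organs,",
      ncol(x$traits) - 2, "traits;", length(x$drying), "drying curves,",
      length(x$pv), "PV curves\n")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_phylogeny(study$tree, file.path(dir, "tree.nwk"))
  write_trait_table(study$traits, file.path(dir, "traits.csv"))
  cv <- do.call(rbind, lapply(names(study$drying), function(id) {
    cu <- study$drying[[id]]
    data.frame(sample_id = id, time_s = cu$times, mass_g = cu$masses,
               temp_c = cu$temps, rh_pct = cu$rhs)
  }))
  utils::write.csv(cv, file.path(dir, "curves.csv"), row.names = FALSE)
  utils::write.csv(study$meta, file.path(dir, "curves_meta.csv"),
                   row.names = FALSE)
  pvd <- do.call(rbind, lapply(names(study$pv), function(id) {
    cu <- study$pv[[id]]
    data.frame(sample_id = id, step = seq_along(cu$masses),
               mass_g = cu$masses, psi_mpa = cu$psis)
  }))
  utils::write.csv(pvd, file.path(dir, "pv.csv"), row.names = FALSE)
  utils::write.csv(study$meta[, c("sample_id", "species", "organ",
                                  "dry_mass_g")],
                   file.path(dir, "pv_meta.csv"), row.names = FALSE)
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
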