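#' Read a trait table from CSV
#'
#' Accepts either the long schema (`species, organ, trait, mean[, se, n]`)
#' or a wide table (`species, organ`, one column per trait). Long input is
#' pivoted to wide using the `mean` column.
#'
#' @param path CSV path.
#' @return Wide trait table data frame (`species`, `organ`, trait columns).
#' @export
read_trait_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "organ") %in% names(df)))
    stop("trait table needs species and organ columns", call. = FALSE)
  if (all(c("trait", "mean") %in% names(df))) {
    wide <- stats::reshape(df[, c("species", "organ", "trait", "mean")],
                           idvar = c("species", "organ"),
                           timevar = "trait", direction = "wide")
    names(wide) <- sub("^mean\\.", "", names(wide))
    rownames(wide) <- NULL
    attr(wide, "reshapeWide") <- NULL
    return(wide)
  }
  df
}

#' Write a trait table to CSV (long schema)
#'
#' @param table Wide trait table.
#' @param path Output CSV path.
#' @param se,n Optional matching data frames/values for the long schema's
#'   standard-error and sample-size columns (defaults NA).
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path, se = NA_real_, n = NA_integer_) {
  traits <- setdiff(names(table), c("species", "organ"))
  long <- do.call(rbind, lapply(traits, function(tr) {
    data.frame(species = table$species, organ = table$organ, trait = tr,
               mean = table[[tr]], se = se, n = n,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read drying curves from long-format CSV
#'
#' `curves` has one row per weighing (`sample_id, time_s, mass_g, temp_c,
#' rh_pct`); `meta` one row per sample (`sample_id, species, organ,
#' area_m2, dry_mass_g[, p_atm_kpa]`).
#'
#' @param curves_path,meta_path CSV paths.
#' @return List with `curves` (named list of [drying_curve()]) and `meta`.
#' @export
read_drying_curves <- function(curves_path, meta_path) {
  cv <- utils::read.csv(curves_path, stringsAsFactors = FALSE)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_s", "mass_g", "temp_c", "rh_pct")
  if (!all(need %in% names(cv)))
    stop("curves CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(c("sample_id", "area_m2", "dry_mass_g") %in% names(meta)))
    stop("curves metadata needs sample_id, area_m2, dry_mass_g",
         call. = FALSE)
  if (is.null(meta$p_atm_kpa)) meta$p_atm_kpa <- 101.3
  curves <- lapply(split(cv, cv$sample_id), function(d) {
    d <- d[order(d$time_s), ]
    m <- meta[meta$sample_id == d$sample_id[1], ]
    if (nrow(m) != 1)
      stop("no unique metadata row for sample ", d$sample_id[1],
           call. = FALSE)
    drying_curve(d$time_s, d$mass_g, d$temp_c, d$rh_pct,
                 projected_area = m$area_m2, dry_mass = m$dry_mass_g,
                 p_atm = m$p_atm_kpa)
  })
  list(curves = curves, meta = meta)
}

#' Read pressure-volume curves from long-format CSV
#'
#' `pv` has one row per observation (`sample_id, step, mass_g, psi_mpa`);
#' `meta` one row per sample (`sample_id, species, organ, dry_mass_g`).
#'
#' @param pv_path,meta_path CSV paths.
#' @return List with `curves` (named list of [pv_curve()]) and `meta`.
#' @export
read_pv_curves <- function(pv_path, meta_path) {
  pvd <- utils::read.csv(pv_path, stringsAsFactors = FALSE)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "step", "mass_g", "psi_mpa")
  if (!all(need %in% names(pvd)))
    stop("PV CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(c("sample_id", "dry_mass_g") %in% names(meta)))
    stop("PV metadata needs sample_id and dry_mass_g", call. = FALSE)
  curves <- lapply(split(pvd, pvd$sample_id), function(d) {
    d <- d[order(d$step), ]
    m <- meta[meta$sample_id == d$sample_id[1], ]
    if (nrow(m) != 1)
      stop("no unique metadata row for sample ", d$sample_id[1],
           call. = FALSE)
    pv_curve(d$mass_g, d$psi_mpa, dry_mass = m$dry_mass_g)
  })
  list(curves = curves, meta = meta)
}
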