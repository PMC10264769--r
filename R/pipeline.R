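#' Run the full comparative hydraulics pipeline
#'
#' Orchestrates the whole analysis from input files (or in-memory objects):
#' estimates minimum diffusive conductance from drying curves and
#' pressure-volume parameters from PV curves, assembles the species-by-organ
#' trait table, and computes (i) per-organ trait means with standard errors,
#' (ii) the flower-vs-leaf paired-t table, (iii) OLS and SMA fits for all
#' configured trait pairs within each organ, (iv) phylogenetic independent
#' contrast correlations within each organ and between organs per trait, and
#' (v) a PCA of the trait table with the convex-hull overlap of the two
#' organs in PC1-PC2 space. Results are returned as a report object and,
#' when `out_dir` is set, written as TSV tables plus a machine-readable
#' JSON report (floats at 6 significant digits) and a run log recording the
#' seed and package version.
#'
#' @param config A named list or the path of a YAML file with entries:
#'   `traits` (CSV path or data frame, long or wide), `tree` (newick path
#'   or `phylo`), `curves`/`curves_meta` and `pv`/`pv_meta` (CSV paths),
#'   `analyses` (subset of `"gmin"`, `"pv"`, `"means"`, `"ttest"`,
#'   `"regression"`, `"pic"`, `"pca"`; default all that the inputs allow),
#'   `alpha` (default 0.05), `window` (`"full"`/`"auto"` for drying fits),
#'   `plateau_correct` (PV saturated-mass correction), `trait_pairs`
#'   (two-column data frame of trait pairs; default all pairs),
#'   `pca_traits`, `seed`, `out_dir`.
#' @return A list of class `hydrotrait_report`, invisibly when written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  alpha <- config$alpha %||% 0.05
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  window <- config$window %||% "full"
  notices <- character()
  failures <- character()

  table <- NULL
  if (!is.null(config$traits)) {
    table <- if (is.data.frame(config$traits)) config$traits
             else read_trait_table(config$traits)
  }

  sample_stats <- NULL
  # stage: g_min from drying curves
  gmin_tab <- NULL
  if (!is.null(config$curves)) {
    dc <- read_drying_curves(config$curves, config$curves_meta)
    est <- lapply(names(dc$curves), function(id) {
      g <- tryCatch(gmin(dc$curves[[id]], window = window),
                    error = function(e) {
                      failures <<- c(failures, paste0("gmin[", id, "]: ",
                                                      conditionMessage(e)))
                      NULL
                    })
      if (is.null(g)) return(NULL)
      m <- dc$meta[dc$meta$sample_id == id, ]
      data.frame(species = m$species, organ = m$organ,
                 g_min_area = g$g_min_area, g_min_mass = g$g_min_mass)
    })
    est <- do.call(rbind, est)
    if (!is.null(est))
      gmin_tab <- stats::aggregate(cbind(g_min_area, g_min_mass) ~
                                     species + organ, est, mean)
  }
  # stage: PV parameters
  pv_tab <- NULL
  if (!is.null(config$pv)) {
    pc <- read_pv_curves(config$pv, config$pv_meta)
    est <- lapply(names(pc$curves), function(id) {
      f <- tryCatch(fit_pv(pc$curves[[id]],
                           plateau_correct = isTRUE(config$plateau_correct)),
                    error = function(e) {
                      failures <<- c(failures, paste0("pv[", id, "]: ",
                                                      conditionMessage(e)))
                      NULL
                    })
      if (is.null(f)) return(NULL)
      m <- pc$meta[pc$meta$sample_id == id, ]
      data.frame(species = m$species, organ = m$organ, swc = f$swc,
                 psi_sft = f$psi_sft, psi_tlp = f$psi_tlp, c_t = f$c_t)
    })
    est <- do.call(rbind, est)
    if (!is.null(est))
      pv_tab <- stats::aggregate(cbind(swc, psi_sft, psi_tlp, c_t) ~
                                   species + organ, est, mean)
  }
  merge_stage <- function(tab, stage) {
    if (is.null(stage)) return(tab)
    if (is.null(tab)) return(stage)
    tab <- tab[, setdiff(names(tab),
                         setdiff(names(stage), c("species", "organ"))),
               drop = FALSE]
    merge(tab, stage, by = c("species", "organ"), all.x = TRUE)
  }
  table <- merge_stage(table, gmin_tab)
  table <- merge_stage(table, pv_tab)
  if (is.null(table))
    stop("no trait table: supply `traits` or curve inputs", call. = FALSE)
  traits <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                    c("species", "organ"))
  organs <- unique(table$organ)
  paired_possible <- all(c("flower", "leaf") %in% organs)
  if (!paired_possible)
    notices <- c(notices, paste0("only organ(s) ",
                                 paste(organs, collapse = ", "),
                                 " present: paired analyses skipped"))

  tree <- NULL
  if (!is.null(config$tree)) {
    tree <- if (inherits(config$tree, "phylo")) validate_phylogeny(config$tree)
            else read_phylogeny(file = config$tree)
    offenders <- c(setdiff(tree$tip.label, table$species),
                   setdiff(table$species, tree$tip.label))
    if (length(offenders))
      stop("species mismatch between tree and trait table: ",
           paste(unique(offenders), collapse = ", "), call. = FALSE)
  }

  analyses <- config$analyses %||%
    c("means", if (paired_possible) "ttest", "regression",
      if (!is.null(tree)) "pic", "pca")
  report <- list(schema_version = "1.0",
                 seed = config$seed %||% NA_integer_,
                 alpha = alpha)

  if ("means" %in% analyses) {
    rows <- list()
    for (tr in traits) for (org in organs) {
      v <- table[[tr]][table$organ == org]
      v <- v[is.finite(v)]
      rows[[paste(tr, org)]] <- data.frame(
        trait = tr, organ = org, mean = mean(v),
        se = stats::sd(v) / sqrt(length(v)), n = length(v))
    }
    report$organ_means <- do.call(rbind, rows)
    rownames(report$organ_means) <- NULL
  }

  if ("ttest" %in% analyses && paired_possible) {
    rows <- lapply(traits, function(tr) {
      res <- tryCatch(paired_t(table, tr), error = function(e) NULL)
      if (is.null(res)) return(NULL)
      data.frame(trait = tr, t = res$t, p = res$p, n = res$n,
                 mean_diff = res$mean_diff,
                 significant = res$p < alpha)
    })
    report$paired_tests <- do.call(rbind, rows)
  }

  pairs <- config$trait_pairs
  if (is.null(pairs)) {
    cmb <- utils::combn(traits, 2)
    pairs <- data.frame(x = cmb[1, ], y = cmb[2, ], stringsAsFactors = FALSE)
  } else pairs <- as.data.frame(pairs)

  if ("regression" %in% analyses) {
    rows <- list()
    for (org in organs) {
      sub <- table[table$organ == org, ]
      for (i in seq_len(nrow(pairs))) {
        x <- sub[[pairs$x[i]]]; y <- sub[[pairs$y[i]]]
        o <- tryCatch(suppressWarnings(ols(x, y)), error = function(e) NULL)
        s <- tryCatch(suppressWarnings(sma(x, y)), error = function(e) NULL)
        if (is.null(o) || is.null(s)) next
        rows[[length(rows) + 1L]] <- data.frame(
          organ = org, x = pairs$x[i], y = pairs$y[i],
          ols_slope = o$slope, ols_r2 = o$r2, ols_p = o$p,
          sma_slope = s$slope, sma_r2 = s$r2, sma_p = s$p, n = o$n)
      }
    }
    report$regressions <- do.call(rbind, rows)
  }

  if ("pic" %in% analyses && !is.null(tree)) {
    trait_vec <- function(org, tr) {
      sub <- table[table$organ == org, ]
      stats::setNames(sub[[tr]], sub$species)
    }
    rows <- list()
    for (org in organs) {
      for (i in seq_len(nrow(pairs))) {
        vx <- trait_vec(org, pairs$x[i]); vy <- trait_vec(org, pairs$y[i])
        ok <- is.finite(vx) & is.finite(vy)
        if (sum(ok) < length(tree$tip.label)) next
        res <- tryCatch(
          suppressWarnings(pic_correlation(tree, vx, vy)),
          error = function(e) NULL)
        if (is.null(res)) next
        rows[[length(rows) + 1L]] <- data.frame(
          organ = org, x = pairs$x[i], y = pairs$y[i],
          r2 = res$r2, p = res$p, slope = res$slope, n = res$n)
      }
    }
    report$pic_within <- do.call(rbind, rows)
    if (paired_possible) {
      rows <- lapply(traits, function(tr) {
        vf <- trait_vec("flower", tr); vl <- trait_vec("leaf", tr)
        if (!all(is.finite(vf)) || !all(is.finite(vl))) return(NULL)
        res <- tryCatch(suppressWarnings(pic_correlation(tree, vf, vl)),
                        error = function(e) NULL)
        if (is.null(res)) return(NULL)
        data.frame(trait = tr, r2 = res$r2, p = res$p, slope = res$slope,
                   n = res$n)
      })
      report$pic_between <- do.call(rbind, rows)
    }
  }

  if ("pca" %in% analyses) {
    pca_traits <- config$pca_traits %||% traits
    pca <- tryCatch(trait_pca(table, pca_traits), error = function(e) {
      failures <<- c(failures, paste0("pca: ", conditionMessage(e)))
      NULL
    })
    if (!is.null(pca)) {
      report$pca <- list(var_frac = pca$var_frac,
                         loadings = as.data.frame(pca$loadings),
                         scores = pca$scores,
                         dropped = pca$dropped)
      if (paired_possible &&
          all(table(pca$scores$organ) >= 3)) {
        hv <- hull_overlap(pca$scores[, c("PC1", "PC2")], pca$scores$organ)
        report$pca$hull_overlap <- hv$overlap
        report$pca$hull_degenerate <- hv$degenerate
      }
    }
  }

  report$trait_table <- table
  report$notices <- notices
  report$failures <- failures
  class(report) <- "hydrotrait_report"

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline report bundle
#'
#' Writes each result table as TSV, the full report as JSON (floats at 6
#' significant digits, no timestamps so reruns are byte-identical), and a
#' plain-text log with the package version and seed.
#'
#' @param report A `hydrotrait_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "hydrotrait_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(x, name) {
    if (!is.null(x))
      utils::write.table(x, file.path(dir, paste0(name, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  tsv(report$organ_means, "organ_means")
  tsv(report$paired_tests, "paired_tests")
  tsv(report$regressions, "regressions")
  tsv(report$pic_within, "pic_within")
  tsv(report$pic_between, "pic_between")
  tsv(report$trait_table, "trait_table")
  if (!is.null(report$pca)) {
    tsv(cbind(trait = rownames(report$pca$loadings), report$pca$loadings),
        "pca_loadings")
    tsv(report$pca$scores, "pca_scores")
  }
  out <- unclass(report)
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = I(6), na = "null",
                       dataframe = "columns")
  writeLines(c(paste("hydrotrait version:",
                     as.character(utils::packageVersion("hydrotrait"))),
               paste("R version:", R.version.string),
               paste("seed:", report$seed),
               paste("alpha:", report$alpha),
               if (length(report$notices))
                 paste("notice:", report$notices),
               if (length(report$failures))
                 paste("failure:", report$failures)),
             file.path(dir, "log.txt"))
  invisible(dir)
}

#' @export
print.hydrotrait_report <- function(x, ...) {
  cat("hydrotrait pipeline report\n")
  if (!is.null(x$paired_tests))
    cat("  paired flower-vs-leaf tests:", nrow(x$paired_tests), "traits,",
        sum(x$paired_tests$significant), "significant at alpha =",
        x$alpha, "\n")
  if (!is.null(x$regressions))
    cat("  trait-pair regressions:", nrow(x$regressions), "\n")
  if (!is.null(x$pic_within))
    cat("  PIC correlations (within organ):", nrow(x$pic_within), "\n")
  if (!is.null(x$pca))
    cat("  PCA: PC1", round(100 * x$pca$var_frac[1], 2), "%, PC2",
        round(100 * x$pca$var_frac[2], 2), "%; hull overlap",
        if (!is.null(x$pca$hull_overlap)) round(x$pca$hull_overlap, 3)
        else NA, "\n")
  for (nt in x$notices) cat("  notice:", nt, "\n")
  for (fl in x$failures) cat("  failure:", fl, "\n")
  invisible(x)
}
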