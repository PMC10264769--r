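#' Paired t-test between organs for one trait
#'
#' Pairs flower and leaf values by species and tests the mean difference
#' (flower minus leaf) with a two-sided paired t-test.
#'
#' @param table Wide trait table: data frame with `species`, `organ`
#'   (`"flower"`/`"leaf"`) and one column per trait.
#' @param trait Trait column name.
#' @return List with `t`, `p`, `n` (complete pairs), `df`, `mean_diff`.
#' @export
paired_t <- function(table, trait) {
  stopifnot(is.data.frame(table), trait %in% names(table))
  fl <- table[table$organ == "flower", c("species", trait)]
  lf <- table[table$organ == "leaf", c("species", trait)]
  merged <- merge(fl, lf, by = "species", suffixes = c("_f", "_l"))
  xf <- merged[[paste0(trait, "_f")]]
  xl <- merged[[paste0(trait, "_l")]]
  ok <- is.finite(xf) & is.finite(xl)
  if (sum(ok) < 2L)
    stop("need at least 2 species with both organs measured for ", trait,
         call. = FALSE)
  d <- xf[ok] - xl[ok]
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, n = length(d),
                                 df = length(d) - 1L, mean_diff = 0))
    stop("zero-variance differences; t undefined", call. = FALSE)
  }
  ht <- stats::t.test(xf[ok], xl[ok], paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, n = length(d),
       df = unname(ht$parameter), mean_diff = unname(ht$estimate))
}

#' One-way ANOVA with LSD post hoc letters
#'
#' One-way ANOVA across groups followed by Fisher's least significant
#' difference pairwise tests on the pooled mean square error, summarised as
#' a compact letter display: groups sharing a letter do not differ at
#' `alpha`. By default the LSD step is protected (only run when the ANOVA
#' itself is significant); otherwise all groups share one letter.
#'
#' @param groups Named list of numeric vectors (one per group), each with
#'   at least 2 values.
#' @param alpha Significance level (default 0.05).
#' @param protected Run LSD only when ANOVA p < alpha (default TRUE).
#' @return List with `F`, `p`, `df`, `letters` (named character vector),
#'   `means`, `lsd_p` (matrix of pairwise p-values, NA diagonal).
#' @export
anova_lsd <- function(groups, alpha = 0.05, protected = TRUE) {
  if (!is.list(groups) || length(groups) < 2L || is.null(names(groups)))
    stop("groups must be a named list with >= 2 groups", call. = FALSE)
  sizes <- vapply(groups, length, 1L)
  if (any(sizes < 2L))
    stop("every group needs at least 2 values", call. = FALSE)
  g <- factor(rep(names(groups), sizes), levels = names(groups))
  y <- unlist(groups, use.names = FALSE)
  fit <- stats::lm(y ~ g)
  an <- stats::anova(fit)
  Fval <- an$`F value`[1]
  pval <- an$`Pr(>F)`[1]
  df_res <- an$Df[2]
  mse <- an$`Mean Sq`[2]
  k <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  lsd_p <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    se <- sqrt(mse * (1 / sizes[i] + 1 / sizes[j]))
    tij <- (means[i] - means[j]) / se
    lsd_p[i, j] <- lsd_p[j, i] <- 2 * stats::pt(-abs(tij), df_res)
  }
  sig <- lsd_p < alpha
  if (protected && !(is.finite(pval) && pval < alpha)) sig[] <- FALSE
  letters_out <- cld_letters(sig, order(means, decreasing = TRUE))
  list(F = Fval, p = pval, df = c(k - 1L, df_res), letters = letters_out,
       means = means, lsd_p = lsd_p)
}

# Compact letter display by insert-and-absorb: start from one set holding
# all groups; for every significantly different pair split each set that
# contains both; drop sets that are subsets of others; letter the sets in
# the order the groups are ranked.
cld_letters <- function(sig, rank_order) {
  k <- nrow(sig)
  nms <- rownames(sig)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    if (!isTRUE(sig[i, j])) next
    new_sets <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb subsets
    keep <- rep(TRUE, length(new_sets))
    for (a in seq_along(new_sets)) for (b in seq_along(new_sets)) {
      if (a != b && keep[a] && keep[b] &&
          all(new_sets[[a]] %in% new_sets[[b]]) &&
          !(all(new_sets[[b]] %in% new_sets[[a]]) && a < b))
        keep[a] <- FALSE
    }
    sets <- unique(new_sets[keep])
  }
  # order sets by the best-ranked member so "a" goes to the top group
  first_rank <- vapply(sets, function(s) min(match(s, rank_order)), numeric(1))
  sets <- sets[order(first_rank)]
  out <- character(k)
  for (si in seq_along(sets))
    for (m in sets[[si]]) out[m] <- paste0(out[m], letters[si])
  names(out) <- nms
  out
}

#' Ordinary least-squares regression
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped.
#' @return List with `slope`, `intercept`, `r2`, `p` (two-sided slope
#'   test), `n`.
#' @export
ols <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero variance in x", call. = FALSE)
  f <- stats::lm(y ~ x)
  s <- summary(f)
  list(slope = unname(stats::coef(f)[2]),
       intercept = unname(stats::coef(f)[1]),
       r2 = s$r.squared,
       p = s$coefficients[2, 4],
       n = length(x))
}

#' Standardized major axis (SMA) regression
#'
#' Symmetric line fit for allometric scaling: `slope = sign(r) * sd(y) /
#' sd(x)`, `intercept = mean(y) - slope * mean(x)`; significance is the
#' test of the correlation (t on n - 2 df), since an SMA slope differs from
#' zero exactly when the correlation does.
#'
#' @param x,y Numeric vectors; incomplete pairs are dropped.
#' @return List of class `sma_fit`: `slope`, `intercept`, `r2`, `p`, `n`.
#' @export
sma <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0)
    stop("zero variance in x or y; SMA undefined", call. = FALSE)
  r <- stats::cor(x, y)
  slope <- (if (r < 0) -1 else 1) * sy / sx
  ct <- stats::cor.test(x, y)
  structure(list(slope = slope,
                 intercept = mean(y) - slope * mean(x),
                 r2 = r^2, p = ct$p.value, n = length(x)),
            class = "sma_fit")
}

#' @export
print.sma_fit <- function(x, ...) {
  cat("SMA fit: slope", signif(x$slope, 4), " intercept",
      signif(x$intercept, 4), " r2", round(x$r2, 4), " p",
      signif(x$p, 3), " n", x$n, "\n")
  invisible(x)
}

#' Principal component analysis of a trait table
#'
#' PCA of the species-by-organ trait matrix on centred (and by default
#' scaled) data, i.e. an eigendecomposition of the correlation matrix. Rows
#' with missing values in the selected traits are dropped and reported.
#' Sign convention: within each PC the loading with the largest absolute
#' value is made positive, so results are reproducible across platforms.
#'
#' @param table Wide trait table with `species`, `organ` and trait columns.
#' @param traits Character vector of trait columns (default: all numeric
#'   trait columns).
#' @param scale Scale traits to unit variance (default TRUE).
#' @return List of class `pca_result`: `loadings` (traits x PCs), `scores`
#'   (data frame with species, organ, PC columns), `var_frac`, `dropped`
#'   (row labels removed as incomplete).
#' @export
trait_pca <- function(table, traits = NULL, scale = TRUE) {
  stopifnot(is.data.frame(table))
  if (is.null(traits))
    traits <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                      c("species", "organ"))
  miss <- setdiff(traits, names(table))
  if (length(miss)) stop("traits not in table: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  m <- as.matrix(table[, traits, drop = FALSE])
  complete <- stats::complete.cases(m)
  dropped <- paste(table$species[!complete], table$organ[!complete])
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 3L) stop("fewer than 3 complete rows", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("constant trait column(s): ",
         paste(traits[sds == 0], collapse = ", "), call. = FALSE)
  pr <- stats::prcomp(m, center = TRUE, scale. = scale)
  flip <- apply(pr$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pr$rotation <- sweep(pr$rotation, 2, flip, `*`)
  pr$x <- sweep(pr$x, 2, flip, `*`)
  scores <- data.frame(species = table$species[complete],
                       organ = table$organ[complete],
                       pr$x, check.names = FALSE)
  structure(list(loadings = pr$rotation, scores = scores,
                 var_frac = pr$sdev^2 / sum(pr$sdev^2),
                 sdev = pr$sdev, center = pr$center,
                 scale = if (scale) pr$scale else rep(1, ncol(m)),
                 dropped = dropped),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA of", nrow(x$loadings), "traits,", nrow(x$scores), "rows\n")
  vf <- round(100 * x$var_frac[seq_len(min(4, length(x$var_frac)))], 2)
  cat("  variance explained (%):", paste(vf, collapse = ", "), "...\n")
  if (length(x$dropped))
    cat("  dropped incomplete rows:", paste(x$dropped, collapse = "; "), "\n")
  invisible(x)
}

#' Convex-hull overlap of two groups in a 2-D score space
#'
#' Intersection-over-union of the convex hulls of two groups of points
#' (typically PC1-PC2 scores): `area(intersection) / area(union)`.
#' Degenerate (collinear) groups have zero-area hulls and are flagged.
#'
#' @param scores Two-column numeric matrix or data frame of coordinates.
#' @param groups Vector of group labels (exactly 2 distinct values), one
#'   per row, each group with at least 3 points.
#' @return List with `overlap` (IoU in 0..1), `area` (named, per group),
#'   `area_intersection`, `degenerate` flag.
#' @export
hull_overlap <- function(scores, groups) {
  scores <- as.matrix(scores[, 1:2])
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("exactly two groups are required", call. = FALSE)
  pts <- split.data.frame(scores, groups)
  if (any(vapply(pts, nrow, 1L) < 3L))
    stop("each group needs at least 3 points", call. = FALSE)
  hulls <- lapply(pts, function(p) {
    h <- grDevices::chull(p)
    poly_ccw(p[h, , drop = FALSE])
  })
  areas <- vapply(hulls, poly_area, numeric(1))
  if (any(areas <= 1e-12)) {
    return(list(overlap = 0, area = areas, area_intersection = 0,
                degenerate = TRUE))
  }
  inter <- clip_convex(hulls[[1]], hulls[[2]])
  ai <- if (is.null(inter) || nrow(inter) < 3L) 0 else poly_area(inter)
  list(overlap = ai / (sum(areas) - ai), area = areas,
       area_intersection = ai, degenerate = FALSE)
}

# signed (shoelace) area; positive for counter-clockwise vertex order
poly_signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

poly_area <- function(p) abs(poly_signed_area(p))

poly_ccw <- function(p) if (poly_signed_area(p) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p

# Sutherland-Hodgman clipping of convex polygon `subject` by convex `clip`
# (both CCW); returns the intersection polygon or NULL when empty
clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0) return(NULL)
    a <- clip[e, ]; b <- clip[if (e == nc) 1 else e + 1, ]
    inside <- function(p) (b[1] - a[1]) * (p[2] - a[2]) -
                          (b[2] - a[2]) * (p[1] - a[1]) >= -1e-12
    isect <- function(p, q) {
      dc <- c(a[1] - b[1], a[2] - b[2])
      dp <- c(p[1] - q[1], p[2] - q[2])
      n1 <- a[1] * b[2] - a[2] * b[1]
      n2 <- p[1] * q[2] - p[2] * q[1]
      den <- dc[1] * dp[2] - dc[2] * dp[1]
      c((n1 * dp[1] - n2 * dc[1]) / den, (n1 * dp[2] - n2 * dc[2]) / den)
    }
    inp <- out
    out <- matrix(numeric(), ncol = 2)
    n <- nrow(inp)
    for (i in seq_len(n)) {
      p <- inp[i, ]; q <- inp[if (i == n) 1 else i + 1, ]
      pin <- inside(p); qin <- inside(q)
      if (pin) {
        out <- rbind(out, p)
        if (!qin) out <- rbind(out, isect(p, q))
      } else if (qin) {
        out <- rbind(out, isect(p, q))
      }
    }
  }
  if (nrow(out) == 0) NULL else out
}
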