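make_table <- function(fl, lf, trait = "x", species = NULL) {
  if (is.null(species)) species <- sprintf("sp%02d", seq_along(fl))
  out <- data.frame(species = rep(species, 2),
                    organ = rep(c("flower", "leaf"), each = length(fl)),
                    v = c(fl, lf))
  names(out)[3] <- trait
  out
}

test_that("paired t pairs by species and matches the one-sample identity", {
  lf <- c(2, 5, 3)
  expect_equal(paired_t(make_table(lf, lf), "x"),
               list(t = 0, p = 1, n = 3L, df = 2L, mean_diff = 0))
  # differences (1, 2, 0): t = sqrt(3), df = 2 (hand computation)
  tab <- make_table(lf + c(1, 2, 0), lf)
  res <- paired_t(tab, "x")
  expect_equal(res$t, sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2L)
  # identity with one-sample t on the differences
  one <- stats::t.test(c(1, 2, 0))
  expect_equal(res$t, unname(one$statistic))
  expect_equal(res$p, one$p.value)
  # antisymmetric under swapping organ roles
  tab_sw <- tab
  tab_sw$organ <- ifelse(tab$organ == "flower", "leaf", "flower")
  expect_equal(paired_t(tab_sw, "x")$t, -res$t)
  # pairing is by species, not row order
  tab_perm <- tab[c(4, 1, 6, 3, 2, 5), ]
  expect_equal(paired_t(tab_perm, "x")$t, res$t)
  expect_error(paired_t(make_table(c(3, 4, 5), c(1, 2, 3)), "x"),
               "zero-variance")
})

test_that("one-way ANOVA with LSD letters", {
  # clearly separated groups get distinct letters
  res <- anova_lsd(list(low = c(10, 11, 12), high = c(100, 101, 102)))
  expect_lt(res$p, 0.001)
  expect_equal(unname(res$letters["high"]), "a")
  expect_equal(unname(res$letters["low"]), "b")
  # explicit two-sample t: F = t^2 for 2 groups
  tt <- stats::t.test(c(10, 11, 12), c(100, 101, 102), var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  # identical groups share one letter
  same <- anova_lsd(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_true(all(same$letters == "a"))
  # letter display invariant to input order up to relabeling
  g <- list(g1 = c(1, 2, 2), g2 = c(9, 10, 11), g3 = c(9.5, 10.5, 10))
  r1 <- anova_lsd(g)
  r2 <- anova_lsd(g[c(3, 1, 2)])
  shares <- function(r, a, b)
    length(intersect(strsplit(r$letters[[a]], "")[[1]],
                     strsplit(r$letters[[b]], "")[[1]])) > 0
  for (pair in list(c("g1", "g2"), c("g1", "g3"), c("g2", "g3")))
    expect_equal(shares(r1, pair[1], pair[2]), shares(r2, pair[1], pair[2]))
  expect_error(anova_lsd(list(a = 1, b = c(1, 2))), "at least 2 values")
  # protected LSD: non-significant ANOVA -> one shared letter
  set.seed(8)
  g0 <- list(a = rnorm(5), b = rnorm(5), c = rnorm(5))
  expect_true(all(anova_lsd(g0)$letters == "a"))
})

test_that("OLS wrapper", {
  x <- c(1, 2, 3, 4, 5)
  res <- suppressWarnings(ols(x, 3 * x + 1))
  expect_equal(res$slope, 3, tolerance = 1e-12)
  expect_equal(res$intercept, 1, tolerance = 1e-12)
  expect_equal(res$r2, 1)
  set.seed(19)
  x <- rnorm(50); y <- rnorm(50)
  expect_equal(ols(x, y)$r2, ols(y, x)$r2, tolerance = 1e-12)
  # consistency on noisy line
  set.seed(23)
  x <- rnorm(1000); y <- 2 * x + rnorm(1000)
  sl <- ols(x, y)$slope
  expect_gt(sl, 1.9); expect_lt(sl, 2.1)
  expect_error(ols(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("SMA closed form and identities", {
  x <- c(1, 2, 3, 4)
  res <- sma(x, 2 * x)
  expect_equal(res$slope, 2, tolerance = 1e-12)
  expect_equal(res$intercept, 0, tolerance = 1e-12)
  expect_equal(res$r2, 1)
  # negative correlation with sd ratio 3
  set.seed(4)
  x <- rnorm(30, sd = 1)
  y <- -3 * x + 0  # sd_y = 3 sd_x, r = -1
  expect_equal(sma(x, y)$slope, -3, tolerance = 1e-12)
  # identities on random data: |slope| = sd_y/sd_x; reciprocity;
  # SMA = OLS / |r|
  for (i in 1:100) {
    x <- rnorm(sample(5:30, 1)); y <- rnorm(length(x), sd = runif(1, .2, 5))
    s <- sma(x, y)
    expect_equal(abs(s$slope), sd(y) / sd(x), tolerance = 1e-10)
    expect_equal(s$slope * sma(y, x)$slope, 1, tolerance = 1e-10)
    expect_equal(s$slope, ols(x, y)$slope / abs(cor(x, y)),
                 tolerance = 1e-10)
    expect_equal(sign(s$slope), sign(cor(x, y)))
  }
  expect_error(sma(rep(2, 5), rnorm(5)), "zero variance")
})

test_that("PCA on centred, scaled traits", {
  # two perfectly correlated traits -> PC1 carries everything
  set.seed(6)
  v <- rnorm(8)
  tab <- data.frame(species = sprintf("sp%d", 1:8), organ = "leaf",
                    a = v, b = 3 * v + 2)
  p <- trait_pca(tab)
  expect_equal(p$var_frac[1], 1, tolerance = 1e-12)
  expect_equal(sum(p$var_frac), 1, tolerance = 1e-12)
  # reconstruction with all PCs retained
  tab2 <- data.frame(species = sprintf("sp%d", 1:20), organ = "leaf",
                     a = rnorm(20), b = rnorm(20), c = rnorm(20))
  p2 <- trait_pca(tab2)
  z <- scale(as.matrix(tab2[, c("a", "b", "c")]))
  recon <- as.matrix(p2$scores[, c("PC1", "PC2", "PC3")]) %*% t(p2$loadings)
  expect_lt(max(abs(recon - z)), 1e-10)
  # isotropic Gaussian: fractions near 1/3
  set.seed(41)
  tab3 <- data.frame(species = sprintf("sp%d", 1:3000), organ = "leaf",
                     a = rnorm(3000), b = rnorm(3000), c = rnorm(3000))
  expect_true(all(abs(trait_pca(tab3)$var_frac - 1 / 3) < 0.05))
  # constant column named in the error; incomplete rows dropped and logged
  tabc <- tab2; tabc$b <- 5
  expect_error(trait_pca(tabc), "constant trait column.*b")
  tabm <- tab2; tabm$a[3] <- NA
  pm <- trait_pca(tabm)
  expect_equal(nrow(pm$scores), 19)
  expect_equal(pm$dropped, "sp3 leaf")
  # deterministic sign convention: largest loading positive per PC
  for (j in seq_len(ncol(p2$loadings))) {
    l <- p2$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
})

test_that("convex hull overlap in score space", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  # identical point sets
  res <- hull_overlap(rbind(sq, sq), rep(c("a", "b"), each = 4))
  expect_equal(res$overlap, 1, tolerance = 1e-12)
  # far separated
  res0 <- hull_overlap(rbind(sq, sq + 10), rep(c("a", "b"), each = 4))
  expect_equal(res0$overlap, 0)
  # unit squares offset by half their width: IoU = 1/3 (analytic)
  sq2 <- cbind(sq[, 1] + 0.5, sq[, 2])
  res3 <- hull_overlap(rbind(sq, sq2), rep(c("a", "b"), each = 4))
  expect_equal(res3$overlap, 1 / 3, tolerance = 1e-12)
  # collinear group flagged degenerate
  line <- cbind(1:4, 2 * (1:4))
  resd <- hull_overlap(rbind(sq, line), rep(c("a", "b"), each = 4))
  expect_true(resd$degenerate)
  expect_equal(resd$overlap, 0)
  expect_error(hull_overlap(sq, c("a", "a", "b", "b")), "at least 3")
})
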