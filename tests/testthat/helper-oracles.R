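# Independent oracles used across the suite.

# Brute-force Brownian-motion covariance: C[i, j] = shared path length from
# the root to the most recent common ancestor of tips i and j, computed by
# walking the edge list (independent of ape::vcv and of the pruning code).
brute_vcv <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  # path of (node, edge length) from root to each tip
  parent_of <- stats::setNames(tree$edge[, 1], tree$edge[, 2])
  len_of <- stats::setNames(tree$edge.length, tree$edge[, 2])
  path_nodes <- function(tip) {
    nodes <- integer(); node <- tip
    while (node != root) {
      nodes <- c(node, nodes)
      node <- parent_of[[as.character(node)]]
    }
    nodes
  }
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(n), path_nodes)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- intersect(paths[[i]], paths[[j]])
    C[i, j] <- sum(len_of[as.character(shared)])
  }
  C
}

# Contrast coefficient matrix: exploit linearity of the contrast operator by
# applying it to unit vectors; rows must satisfy A C A' = I under Brownian
# motion for correctly variance-standardised contrasts.
contrast_matrix <- function(tree) {
  n <- length(tree$tip.label)
  cols <- lapply(seq_len(n), function(i) {
    v <- stats::setNames(numeric(n), tree$tip.label)
    v[i] <- 1
    as.numeric(pic_contrasts(tree, v))
  })
  matrix(unlist(cols), nrow = n - 1L, ncol = n)
}

# Exhaustive reimplementation of the PV breakpoint rule, written as a plain
# double loop so it can guard the production code against future
# optimisations: for every admissible split, fit the post line by textbook
# formulas; estimate noise from the best split; return the most hydrated
# split whose residual variance passes the 5% F-criterion.
brute_force_breakpoint <- function(deficit, y, min_seg = 3L) {
  n <- length(y)
  ks <- seq(min_seg + 1L, n - min_seg + 1L)
  stats_for <- function(k) {
    d <- deficit[k:n]; yy <- y[k:n]
    b <- sum((d - mean(d)) * (yy - mean(yy))) / sum((d - mean(d))^2)
    a <- mean(yy) - b * mean(d)
    sse <- sum((yy - a - b * d)^2)
    list(sig2 = sse / (length(d) - 2L), df = length(d) - 2L)
  }
  all_stats <- lapply(ks, stats_for)
  sig2 <- vapply(all_stats, `[[`, numeric(1), "sig2")
  best <- which.min(sig2)
  tol <- 1e-12 * stats::var(y)
  for (i in seq_along(ks)) {
    crit <- sig2[best] * stats::qf(0.95, all_stats[[i]]$df,
                                   all_stats[[best]]$df)
    if (sig2[i] <= crit + tol) return(ks[i])
  }
  ks[best]
}

# fixture trees (all <= 6 tips) for contrast oracle checks
fixture_trees <- function() {
  list(
    read_phylogeny("(A:1,B:1);"),
    read_phylogeny("((A:1,B:1):0.5,C:1.5);"),
    read_phylogeny("((A:1,B:2):0.5,(C:1.5,D:0.7):0.8);"),
    read_phylogeny("(((A:0.3,B:0.4):0.2,C:1):0.5,(D:0.6,E:0.9):0.4);"),
    read_phylogeny(paste0("((A:0.2,(B:0.5,C:0.1):0.4):0.3,",
                          "((D:0.7,E:0.2):0.1,F:0.8):0.6);"))
  )
}
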