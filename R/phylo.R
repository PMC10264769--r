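#' Read and validate a phylogeny from newick
#'
#' Parses a newick string or file (via ape) and validates the requirements
#' of the comparative analyses: unique tip labels, at least two tips, and a
#' branch length on every edge. Polytomies are accepted but flagged with a
#' warning, since megatree-derived study trees often contain them.
#'
#' @param text Newick string (ignored when `file` is given).
#' @param file Path to a newick file.
#' @return An `ape` `phylo` object.
#' @export
read_phylogeny <- function(text = NULL, file = NULL) {
  tree <- if (!is.null(file)) ape::read.tree(file)
          else ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse newick input", call. = FALSE)
  validate_phylogeny(tree)
}

#' @rdname read_phylogeny
#' @param tree A `phylo` object.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (length(tree$tip.label) < 2L)
    stop("a phylogeny needs at least 2 tips", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("tip labels must be unique", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("parse error: tree has no branch lengths", call. = FALSE)
  bad <- which(!is.finite(tree$edge.length) | tree$edge.length <= 0)
  if (length(bad)) {
    nodes <- tree$edge[bad, 2]
    labs <- ifelse(nodes <= length(tree$tip.label),
                   tree$tip.label[nodes], paste0("node#", nodes))
    stop("parse error: missing or non-positive branch length leading to: ",
         paste(labs, collapse = ", "), call. = FALSE)
  }
  if (!ape::is.binary(tree))
    warning("tree contains polytomies; they will be resolved arbitrarily ",
            "with zero-length branches for contrast calculations")
  tree
}

#' Write a phylogeny to newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when `NULL` the newick string is returned.
#' @return Newick string (invisibly when written to file).
#' @export
write_phylogeny <- function(tree, file = NULL) {
  if (is.null(file)) ape::write.tree(tree)
  else { ape::write.tree(tree, file = file); invisible(ape::write.tree(tree)) }
}

#' Phylogenetic independent contrasts (Felsenstein pruning)
#'
#' Computes one standardised contrast per internal node by post-order
#' pruning: at each node the contrast is the difference between the two
#' daughter values divided by the square root of the summed daughter branch
#' lengths, the ancestral value is the variance-weighted mean of the
#' daughters, and the ancestral branch is inflated by
#' `v1 * v2 / (v1 + v2)`. Under Brownian motion the contrasts are iid
#' normal. Polytomies are resolved arbitrarily into bifurcations with
#' zero-length branches (with a warning from validation).
#'
#' @param tree A `phylo` object with branch lengths.
#' @param trait Named numeric vector; names must cover all tip labels.
#' @return Numeric vector of `n_tips - 1` contrasts (for a bifurcating
#'   tree), named by internal node number, with attribute `node_order`.
#' @export
pic_contrasts <- function(tree, trait) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  tips <- tree$tip.label
  if (is.null(names(trait)))
    stop("trait vector must be named by tip label", call. = FALSE)
  missing_tips <- setdiff(tips, names(trait))
  if (length(missing_tips))
    stop("missing trait values for tips: ",
         paste(missing_tips, collapse = ", "), call. = FALSE)
  x_tip <- trait[tips]
  if (any(!is.finite(x_tip)))
    stop("non-finite trait values for tips: ",
         paste(tips[!is.finite(x_tip)], collapse = ", "), call. = FALSE)
  n_tip <- length(tips)
  n_node <- tree$Nnode
  ord <- ape::reorder.phylo(tree, "postorder")
  # working vectors over all nodes (1..n_tip tips, then internals)
  xval <- c(as.numeric(x_tip), rep(NA_real_, n_node))
  vlen <- numeric(n_tip + n_node)
  vlen[ord$edge[, 2]] <- ord$edge.length
  contrasts <- rep(NA_real_, n_node)
  # postorder edges come in daughter pairs for a bifurcating tree
  parents <- unique(ord$edge[, 1])
  for (p in parents) {
    ch <- ord$edge[ord$edge[, 1] == p, 2]
    i <- ch[1]; j <- ch[2]
    vi <- vlen[i]; vj <- vlen[j]
    contrasts[p - n_tip] <- (xval[i] - xval[j]) / sqrt(vi + vj)
    xval[p] <- (xval[i] / vi + xval[j] / vj) / (1 / vi + 1 / vj)
    if (!is.finite(xval[p]))  # both daughter branches zero length
      xval[p] <- mean(c(xval[i], xval[j]))
    vlen[p] <- vlen[p] + vi * vj / (vi + vj)
  }
  names(contrasts) <- seq_len(n_node) + n_tip
  structure(contrasts, node_order = parents)
}

#' Correlation between two traits on phylogenetic independent contrasts
#'
#' Regresses the contrasts of `trait_y` on those of `trait_x` through the
#' origin (the field standard: contrast signs are arbitrary, so the fit
#' must be invariant to sign flips, which a through-origin fit is). r^2 is
#' the through-origin coefficient of determination and the p-value comes
#' from the t statistic of the slope on `n_contrasts - 1` degrees of
#' freedom. An intercept mode is available for sensitivity analysis.
#'
#' @param tree A `phylo` object.
#' @param trait_x,trait_y Named numeric vectors over the tips.
#' @param intercept Fit with an intercept instead (non-standard).
#' @return List with `r2`, `p`, `slope`, `n` (number of contrasts).
#' @export
pic_correlation <- function(tree, trait_x, trait_y, intercept = FALSE) {
  cx <- as.numeric(pic_contrasts(tree, trait_x))
  cy <- as.numeric(pic_contrasts(tree, trait_y))
  m <- length(cx)
  if (m < 3L)
    stop("fewer than 3 contrasts; correlation statistics undefined",
         call. = FALSE)
  if (intercept) {
    f <- stats::lm(cy ~ cx)
    s <- summary(f)
    return(list(r2 = s$r.squared, p = s$coefficients[2, 4],
                slope = unname(stats::coef(f)[2]), n = m))
  }
  sxx <- sum(cx^2)
  if (sxx == 0) stop("x contrasts are all zero", call. = FALSE)
  slope <- sum(cx * cy) / sxx
  rss <- sum((cy - slope * cx)^2)
  tss <- sum(cy^2)
  r2 <- if (tss == 0) NA_real_ else 1 - rss / tss
  df <- m - 1L
  se <- sqrt(rss / df / sxx)
  if (se == 0) {
    p <- if (slope == 0) 1 else 0
  } else {
    tval <- slope / se
    p <- 2 * stats::pt(-abs(tval), df)
  }
  list(r2 = r2, p = p, slope = slope, n = m)
}
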