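#' Genetic PCA via the genomic relationship matrix
#'
#' Standardizes genotype dosages per locus, `z = (x - 2p) / sqrt(2p(1-p))`
#' with `p` the alternate-allele frequency among non-missing calls (missing
#' calls become 0 after centering, i.e. mean imputation), forms the GRM
#' `Z Z' / M` over the `M` polymorphic loci, and eigendecomposes it.
#' Sample coordinates are eigenvectors scaled by the square root of their
#' eigenvalues; each component's variance fraction is its eigenvalue over
#' the total positive eigenvalue mass.
#'
#' @param gm A [genotype_matrix()].
#' @param n_comp Number of components to keep (default 10, capped at n).
#' @return A `grm_pca`: list with `scores` (tibble `sample`, `PC1`, ...),
#'   `var_frac`, `values`, `grm`.
#' @export
pca_grm <- function(gm, n_comp = 10L) {
  if (n_samples(gm) < 2L) abort("PCA needs at least two samples")
  g <- gm$geno
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) abort("all loci are monomorphic; PCA undefined")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(g, 2L, 2 * p, "-")
  z <- sweep(z, 2L, sqrt(2 * p * (1 - p)), "/")
  z[is.na(z)] <- 0
  grm <- tcrossprod(z) / ncol(z)
  eig <- eigen(grm, symmetric = TRUE)
  pos <- pmax(eig$values, 0)
  n_comp <- min(n_comp, length(eig$values))
  coords <- eig$vectors[, seq_len(n_comp), drop = FALSE] %*%
    diag(sqrt(pos[seq_len(n_comp)]), n_comp)
  colnames(coords) <- paste0("PC", seq_len(n_comp))
  structure(
    list(
      scores = bind_cols(tibble(sample = gm$samples), as_tibble(coords)),
      var_frac = eig$values / sum(pos),
      values = eig$values,
      grm = grm
    ),
    class = "grm_pca"
  )
}

#' @export
print.grm_pca <- function(x, ...) {
  cat(sprintf(
    "<grm_pca> %d samples; PC1 %.2f%%, PC2 %.2f%% of variance\n",
    nrow(x$scores), 100 * x$var_frac[1], 100 * x$var_frac[2]
  ))
  invisible(x)
}

#' Sample coordinates of a genetic PCA
#' @param x A `grm_pca`.
#' @param ... Unused.
#' @return The scores tibble.
#' @method tidy grm_pca
#' @export
tidy.grm_pca <- function(x, ...) x$scores

#' Variance fractions of a genetic PCA
#' @param x A `grm_pca`.
#' @param ... Unused.
#' @return Tibble: `component`, `var_frac`.
#' @method glance grm_pca
#' @export
glance.grm_pca <- function(x, ...) {
  tibble(
    component = seq_along(x$var_frac),
    var_frac = x$var_frac
  )
}

#' PC1-PC2 scatter of a genetic PCA
#' @param object A `grm_pca`.
#' @param varieties Optional sample-to-cultivar map for coloring.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot grm_pca
#' @export
autoplot.grm_pca <- function(object, varieties = NULL, ...) {
  d <- object$scores
  if (!is.null(varieties)) {
    d <- left_join(d, variety_assignment(varieties), by = "sample")
    p <- ggplot2::ggplot(d, ggplot2::aes(
      x = .data$PC1, y = .data$PC2, colour = .data$variety
    ))
  } else {
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.2f%%)", 100 * object$var_frac[1]),
      y = sprintf("PC2 (%.2f%%)", 100 * object$var_frac[2])
    ) +
    ggplot2::theme_minimal()
}
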