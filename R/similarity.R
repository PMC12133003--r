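#' Pairwise sample similarity (consistent typing / common SNPs)
#'
#' For each pair of samples: `common` = loci where both calls are
#' non-missing, `consistent` = common loci with identical genotype codes
#' (heterozygotes match only heterozygotes), similarity =
#' `consistent / common`. Pairs with no common locus are undefined (`NA`).
#'
#' @param gm A [genotype_matrix()].
#' @param loci Optional locus subset (ids, logical or integer index);
#'   default all loci. An empty subset is an error.
#' @return A `similarity_matrix`: list with `similarity` (n x n, diagonal 1
#'   where defined), `common` (pairwise common-SNP counts), `samples`.
#' @export
pairwise_similarity <- function(gm, loci = NULL) {
  if (!is.null(loci)) gm <- subset_loci(gm, loci)
  if (n_loci(gm) == 0L) abort("similarity needs at least one locus")
  g <- gm$geno
  obs <- !is.na(g)
  storage.mode(obs) <- "double"
  common <- obs %*% t(obs)
  matches <- matrix(0, nrow(g), nrow(g))
  for (code in 0:2) {
    ind <- (!is.na(g) & g == code)
    storage.mode(ind) <- "double"
    matches <- matches + ind %*% t(ind)
  }
  sim <- ifelse(common > 0, matches / common, NA_real_)
  dimnames(sim) <- list(gm$samples, gm$samples)
  dimnames(common) <- dimnames(sim)
  structure(
    list(similarity = sim, common = common, samples = gm$samples),
    class = "similarity_matrix"
  )
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d samples\n", length(x$samples)))
  invisible(x)
}

#' Unordered off-diagonal pairs of a similarity matrix
#' @param x A `similarity_matrix`.
#' @param ... Unused.
#' @return Tibble: `sample_i`, `sample_j`, `similarity`, `common`.
#' @method tidy similarity_matrix
#' @export
tidy.similarity_matrix <- function(x, ...) {
  n <- length(x$samples)
  idx <- which(upper.tri(x$similarity), arr.ind = TRUE)
  tibble(
    sample_i = x$samples[idx[, 1]],
    sample_j = x$samples[idx[, 2]],
    similarity = x$similarity[idx],
    common = x$common[idx]
  )
}

#' Core-versus-total similarity correlation
#'
#' Panel validation: over all unordered sample pairs (diagonal excluded;
#' pairs undefined in either matrix dropped), ordinary least squares of the
#' core-panel similarity on the total-SNP similarity, with the Pearson
#' correlation and its two-sided t-test p-value.
#'
#' @param total_sim,core_sim `similarity_matrix` objects over the same
#'   samples in the same order.
#' @return A `similarity_correlation`: list with `r`, `p_value`, `slope`,
#'   `intercept`, `n_pairs`, and the pair tibble in `data`.
#' @export
similarity_correlation <- function(total_sim, core_sim) {
  if (!identical(total_sim$samples, core_sim$samples)) {
    abort("similarity matrices must share samples in the same order")
  }
  pairs <- tidy(total_sim) |>
    rename(total = "similarity", common_total = "common") |>
    mutate(
      core = tidy(core_sim)$similarity,
      common_core = tidy(core_sim)$common
    ) |>
    filter(!is.na(.data$total), !is.na(.data$core))
  if (nrow(pairs) < 3L) abort("need at least 3 defined pairs")
  if (stats::sd(pairs$total) == 0 || stats::sd(pairs$core) == 0) {
    abort("zero variance in a similarity vector; correlation undefined")
  }
  fit <- lm(core ~ total, data = pairs)
  ct <- cor.test(pairs$total, pairs$core, method = "pearson")
  structure(
    list(
      r = unname(ct$estimate), p_value = ct$p.value,
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      n_pairs = nrow(pairs), data = pairs
    ),
    class = "similarity_correlation"
  )
}

#' @export
print.similarity_correlation <- function(x, ...) {
  cat(sprintf(
    "<similarity_correlation> r = %.4f (p = %.3g) over %d pairs\n  core = %.3f + %.3f * total\n",
    x$r, x$p_value, x$n_pairs, x$intercept, x$slope
  ))
  invisible(x)
}

#' @method tidy similarity_correlation
#' @export
tidy.similarity_correlation <- function(x, ...) {
  tibble(
    term = c("intercept", "total"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @method glance similarity_correlation
#' @export
glance.similarity_correlation <- function(x, ...) {
  tibble(
    r = x$r, r_squared = x$r^2, p_value = x$p_value,
    slope = x$slope, intercept = x$intercept, n_pairs = x$n_pairs
  )
}

#' Scatter plot of core versus total similarity
#' @param object A `similarity_correlation`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot similarity_correlation
#' @export
autoplot.similarity_correlation <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$total, y = .data$core)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(
      slope = object$slope, intercept = object$intercept, colour = "red"
    ) +
    ggplot2::labs(
      x = "similarity (total SNPs)", y = "similarity (core SNPs)",
      title = sprintf("r = %.3f, p = %.2g (%d pairs)",
        object$r, object$p_value, object$n_pairs)
    ) +
    ggplot2::theme_minimal()
}
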