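#' Botstein polymorphic information content
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`. For a biallelic locus
#' with alternate-allele frequency `p` this is the closed form
#' `1 - (p^2 + q^2) - 2 p^2 q^2`.
#'
#' @param freqs Numeric vector of allele frequencies summing to 1.
#' @return PIC value in `[0, 1)`.
#' @export
#' @examples
#' pic(c(0.5, 0.5))   # 0.375
#' pic(c(0.125, 0.875))
pic <- function(freqs) {
  stopifnot(all(freqs >= 0), abs(sum(freqs) - 1) < 1e-8)
  sq <- freqs^2
  cross <- outer(sq, sq)
  1 - sum(sq) - sum(cross[upper.tri(cross)]) * 2
}

# Vectorised biallelic closed form over alt-allele frequencies.
pic_biallelic <- function(p) {
  q <- 1 - p
  1 - (p^2 + q^2) - 2 * p^2 * q^2
}

#' Per-locus population-genetic summary statistics
#'
#' For each locus of a genotype or consensus matrix: alternate-allele
#' frequency `p` among non-missing calls, minor-allele frequency
#' `maf = min(p, 1 - p)`, observed heterozygosity `ho` (heterozygous calls /
#' non-missing calls), expected heterozygosity (genetic diversity)
#' `he = 2 p (1 - p)`, unbiased per-site nucleotide diversity
#' `pi = he * n / (n - 1)` with `n` the number of non-missing alleles, and
#' Botstein `pic`. Loci with no non-missing call get `NA` throughout.
#'
#' @param x A [genotype_matrix()] or `consensus_matrix`.
#' @return Tibble: `id`, `chrom`, `pos`, `n_obs` (non-missing genotypes),
#'   `p_alt`, `maf`, `ho`, `he`, `pi`, `pic`.
#' @export
locus_stats <- function(x) {
  g <- x$geno
  n_obs <- unname(colSums(!is.na(g)))
  n_het <- unname(colSums(g == 1L, na.rm = TRUE))
  p <- ifelse(n_obs > 0L, unname(colSums(g, na.rm = TRUE)) / (2 * n_obs), NA_real_)
  he <- 2 * p * (1 - p)
  n_alleles <- 2 * n_obs
  tibble(
    id = x$loci$id, chrom = x$loci$chrom, pos = x$loci$pos,
    n_obs = n_obs, p_alt = p,
    maf = pmin(p, 1 - p),
    ho = ifelse(n_obs > 0L, n_het / n_obs, NA_real_),
    he = he,
    pi = ifelse(n_alleles > 1L, he * n_alleles / (n_alleles - 1L), NA_real_),
    pic = pic_biallelic(p)
  )
}

#' Mean and range of panel statistics
#'
#' @param stats A [locus_stats()] tibble (or any tibble of per-locus
#'   numeric statistics).
#' @param digits Decimals for half-up rounding in the report (default 3;
#'   `NULL` for unrounded).
#' @return Tibble: `statistic`, `mean`, `min`, `max` over loci, missing
#'   values excluded.
#' @export
summarize_panel <- function(stats, digits = 3) {
  num <- stats[vapply(stats, is.numeric, logical(1))]
  num <- num[setdiff(names(num), c("pos", "n_obs"))]
  if (nrow(num) == 0L) abort("no loci to summarize")
  out <- tibble(
    statistic = names(num),
    mean = vapply(num, function(v) mean(v, na.rm = TRUE), numeric(1),
      USE.NAMES = FALSE),
    min = vapply(num, function(v) suppressWarnings(min(v, na.rm = TRUE)),
      numeric(1), USE.NAMES = FALSE),
    max = vapply(num, function(v) suppressWarnings(max(v, na.rm = TRUE)),
      numeric(1), USE.NAMES = FALSE)
  )
  if (!is.null(digits)) {
    out <- mutate(out, dplyr::across(c("mean", "min", "max"),
      ~ round_half_up(.x, digits)))
  }
  out
}

#' SNP density in sliding windows
#'
#' Counts loci per half-open window `[k * step, k * step + window)` along
#' each chromosome (1-based positions; with `step == window` the windows
#' tile the chromosome and counts sum to the locus count). Windows with no
#' loci are reported with zero counts up to the chromosome length (given or
#' inferred from the last locus).
#'
#' @param loci Locus tibble (`chrom`, `pos`) or a [genotype_matrix()].
#' @param window,step Window and step sizes in bp (default 500000 each).
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return Tibble: `chrom`, `start`, `end` (half-open bounds), `n_snps`.
#' @export
snp_density <- function(loci, window = 5e5, step = 5e5, chrom_lengths = NULL) {
  if (inherits(loci, "genotype_matrix")) loci <- loci$loci
  stopifnot(window > 0, step > 0)
  out <- list()
  for (chr in unique(loci$chrom)) {
    pos <- loci$pos[loci$chrom == chr]
    len <- if (!is.null(chrom_lengths) && chr %in% names(chrom_lengths)) {
      chrom_lengths[[chr]]
    } else {
      max(pos)
    }
    starts <- seq(0, max(0, len - 1), by = step)
    counts <- vapply(starts, function(s) {
      sum(pos >= s & pos < s + window)
    }, numeric(1))
    out[[chr]] <- tibble(
      chrom = chr, start = starts, end = starts + window, n_snps = counts
    )
  }
  bind_rows(out)
}

#' Weir-Cockerham Fst over predefined populations
#'
#' Multi-locus ratio-of-sums estimator from the per-locus a (among
#' population), b (among individuals within population) and c (within
#' individual) variance components, computed from genotype counts. Used to
#' calibrate the Balding-Nichols simulator against its configured drift
#' parameter.
#'
#' @param gm A [genotype_matrix()].
#' @param varieties Sample-to-cultivar map.
#' @return List: `fst` (ratio-of-sums estimate), `per_locus` tibble.
#' @export
wc_fst <- function(gm, varieties) {
  vlab <- match_varieties(gm, varieties)
  vlev <- unique(vlab)
  r <- length(vlev)
  if (r < 2L) abort("Fst needs at least two populations")
  m <- n_loci(gm)
  n_i <- matrix(0, r, m) # genotyped individuals per pop x locus
  p_i <- matrix(0, r, m) # alt freq per pop x locus
  h_i <- matrix(0, r, m) # observed het fraction per pop x locus
  for (k in seq_len(r)) {
    sub <- gm$geno[vlab == vlev[k], , drop = FALSE]
    n_obs <- colSums(!is.na(sub))
    n_i[k, ] <- n_obs
    p_i[k, ] <- ifelse(n_obs > 0, colSums(sub, na.rm = TRUE) / (2 * n_obs), 0)
    h_i[k, ] <- ifelse(n_obs > 0, colSums(sub == 1L, na.rm = TRUE) / n_obs, 0)
  }
  n_tot <- colSums(n_i)
  n_bar <- n_tot / r
  nc <- (n_tot - colSums(n_i^2) / n_tot) / (r - 1)
  p_bar <- colSums(n_i * p_i) / n_tot
  s2 <- colSums(n_i * (p_i - rep(p_bar, each = r))^2) / ((r - 1) * n_bar)
  h_bar <- colSums(n_i * h_i) / n_tot
  a <- n_bar / nc *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- n_bar / (n_bar - 1) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
      (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  c_comp <- h_bar / 2
  usable <- n_tot > 0 & n_bar > 1 & is.finite(a + b + c_comp)
  fst <- sum(a[usable]) / sum((a + b + c_comp)[usable])
  list(
    fst = fst,
    per_locus = tibble(
      id = gm$loci$id, a = a, b = b, c = c_comp,
      fst = ifelse(a + b + c_comp > 0, a / (a + b + c_comp), NA_real_)
    )
  )
}
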