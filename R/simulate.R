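#' Simulation configuration for a multi-cultivar GBS-like genotype panel
#'
#' Defines the study design the package's analyses assume: a handful of
#' differentiated cultivar populations, each a set of diploid individuals
#' genotyped at biallelic SNPs scattered over many chromosomes, with
#' Poisson per-call depth and missing-completely-at-random dropouts.
#' Population allele frequencies follow the Balding-Nichols model: at each
#' locus an ancestral frequency `p` is drawn and each population's frequency
#' is Beta-distributed with mean `p` and variance `Fst * p * (1 - p)`.
#'
#' @param n_varieties Number of cultivar populations (default 4).
#' @param n_per_variety Diploid individuals per cultivar (default 10).
#' @param n_loci Number of biallelic SNP loci (default 40000, a desk-scale
#'   stand-in for a GBS call set of hundreds of thousands of sites, large
#'   enough that a few thousand loci survive the selection cascade).
#' @param n_chrom Number of chromosomes (default 31).
#' @param chrom_length Length of each chromosome in bp (scalar or vector of
#'   length `n_chrom`; default 1e7).
#' @param fst Balding-Nichols drift parameter in (0, 1) (default 0.2).
#' @param maf_range Range of the Uniform law for the ancestral minor-allele
#'   frequency (default `c(0.05, 0.5)`); the minor allele is assigned to the
#'   reference or alternate allele at random.
#' @param missing_rate MCAR probability that a call is dropped (default 0.05).
#' @param mean_depth Mean of the Poisson per-call depth (default 11.6,
#'   matching a typical mid-depth GBS run).
#' @param admixture_noise Fraction of each individual's ancestry drawn from
#'   the other cultivars (default 0: pure populations, genotypes in exact
#'   Hardy-Weinberg proportions within each cultivar).
#' @param n_ld_blocks Number of duplicated-genotype LD blocks to inject
#'   (default 0). Each block copies one anchor locus's genotypes into the
#'   next `ld_block_size - 1` loci with per-call flip probability
#'   `ld_flip_rate`, creating near-r2-1 pairs for pruning tests.
#' @param ld_block_size,ld_flip_rate Block geometry and copy noise.
#' @param seed RNG seed (integer).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_varieties = 4L, n_per_variety = 10L, n_loci = 40000L,
                       n_chrom = 31L, chrom_length = 1e7, fst = 0.2,
                       maf_range = c(0.05, 0.5), missing_rate = 0.05,
                       mean_depth = 11.6, admixture_noise = 0,
                       n_ld_blocks = 0L, ld_block_size = 5L,
                       ld_flip_rate = 0.02, seed = 1L) {
  cfg <- list(
    n_varieties = as.integer(n_varieties),
    n_per_variety = as.integer(n_per_variety),
    n_loci = as.integer(n_loci), n_chrom = as.integer(n_chrom),
    chrom_length = rep_len(as.numeric(chrom_length), as.integer(n_chrom)),
    fst = fst, maf_range = maf_range, missing_rate = missing_rate,
    mean_depth = mean_depth, admixture_noise = admixture_noise,
    n_ld_blocks = as.integer(n_ld_blocks),
    ld_block_size = as.integer(ld_block_size), ld_flip_rate = ld_flip_rate,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_varieties >= 1L, cfg$n_per_variety >= 1L, cfg$n_loci >= 0L,
    cfg$n_chrom >= 1L, cfg$fst > 0, cfg$fst < 1,
    cfg$missing_rate >= 0, cfg$missing_rate < 1, cfg$mean_depth > 0,
    cfg$admixture_noise >= 0, cfg$admixture_noise < 1
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Draw ancestral and per-population allele frequencies
#'
#' Balding-Nichols: per-population alternate-allele frequency at a locus is
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` around the ancestral `p`
#' (variance `F p (1 - p)`). For `F` below 1e-9 the Beta collapses to `p`.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_truth` list: `loci` (tibble chrom/pos/id/ref/alt),
#'   `p_anc` (ancestral alt-allele frequency per locus), `pop_freq`
#'   (`n_varieties` x `n_loci` matrix), `varieties` (population labels),
#'   `sample_variety` (per-sample population label), `samples`.
#' @export
simulate_frequencies <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "frequencies"))
  m <- cfg$n_loci
  k <- cfg$n_varieties
  maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  to_alt <- runif(m) < 0.5
  p_anc <- ifelse(to_alt, maf, 1 - maf)
  f <- cfg$fst
  if (f < 1e-9) {
    pop_freq <- matrix(rep(p_anc, each = k), k, m)
  } else {
    a <- p_anc * (1 - f) / f
    b <- (1 - p_anc) * (1 - f) / f
    pop_freq <- matrix(
      rbeta(k * m, rep(a, each = k), rep(b, each = k)), k, m
    )
  }
  # locus placement: chromosomes drawn uniformly, unique sorted positions
  chrom_idx <- sort(sample.int(cfg$n_chrom, m, replace = TRUE))
  chroms <- sprintf("chr%02d", seq_len(cfg$n_chrom))
  pos <- integer(m)
  for (c_i in seq_len(cfg$n_chrom)) {
    sel <- chrom_idx == c_i
    if (!any(sel)) next
    pos[sel] <- sort(sample.int(cfg$chrom_length[c_i], sum(sel)))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  loci <- tibble(
    chrom = chroms[chrom_idx], pos = pos,
    id = paste0(chroms[chrom_idx], ":", pos),
    ref = ref, alt = unname(alt)
  )
  loci$id <- make.unique(loci$id)
  varieties <- paste0("V", seq_len(k))
  samples <- paste0(
    rep(varieties, each = cfg$n_per_variety), "_",
    sprintf("%02d", rep(seq_len(cfg$n_per_variety), k))
  )
  structure(
    list(
      loci = loci, p_anc = p_anc, pop_freq = pop_freq,
      varieties = varieties,
      sample_variety = rep(varieties, each = cfg$n_per_variety),
      samples = samples
    ),
    class = "sim_truth"
  )
}

#' Simulate genotypes, depths and missingness from frequency truth
#'
#' Each genotype is Binomial(2, population alternate-allele frequency) —
#' Hardy-Weinberg proportions within each cultivar (when
#' `admixture_noise > 0` the frequency is the individual's ancestry-weighted
#' mixture). Depth is Poisson(`mean_depth`); a call is missing when an MCAR
#' draw falls below `missing_rate` or its simulated depth is at most 4.
#'
#' @param truth A `sim_truth` from [simulate_frequencies()].
#' @param cfg The matching [sim_config()].
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(truth, cfg) {
  set.seed(derive_seed(cfg$seed, "genotypes"))
  n <- length(truth$samples)
  m <- nrow(truth$loci)
  k <- cfg$n_varieties
  pop_of <- match(truth$sample_variety, truth$varieties)
  if (cfg$admixture_noise > 0 && k > 1L) {
    q <- matrix(cfg$admixture_noise / (k - 1L), n, k)
    q[cbind(seq_len(n), pop_of)] <- 1 - cfg$admixture_noise
    p_ind <- q %*% truth$pop_freq
  } else {
    p_ind <- truth$pop_freq[pop_of, , drop = FALSE]
  }
  geno <- matrix(rbinom(n * m, 2L, as.vector(p_ind)), n, m)
  depth <- matrix(rpois(n * m, cfg$mean_depth), n, m)
  drop <- matrix(runif(n * m) < cfg$missing_rate, n, m) | depth <= 4L
  geno[drop] <- NA_integer_
  if (cfg$n_ld_blocks > 0L && m >= cfg$ld_block_size) {
    geno <- inject_ld_blocks(geno, truth$loci, cfg)
  }
  genotype_matrix(geno, truth$loci, samples = truth$samples, depth = depth)
}

# Copy anchor-locus genotype columns over the following loci of each block
# (same chromosome), flipping each call to a random genotype with small
# probability, to create near-duplicate high-r2 marker runs.
inject_ld_blocks <- function(geno, loci, cfg) {
  m <- nrow(loci)
  size <- cfg$ld_block_size
  anchors <- integer(0)
  candidates <- which(vapply(
    seq_len(m - size + 1L),
    function(i) loci$chrom[i] == loci$chrom[i + size - 1L], logical(1)
  ))
  if (length(candidates)) {
    anchors <- sort(sample(candidates, min(cfg$n_ld_blocks, length(candidates))))
  }
  for (a in anchors) {
    for (j in seq.int(a + 1L, a + size - 1L)) {
      col <- geno[, a]
      flip <- runif(length(col)) < cfg$ld_flip_rate
      col[flip] <- sample(0:2, sum(flip), replace = TRUE)
      geno[, j] <- col
    }
  }
  attr(geno, "ld_anchors") <- anchors
  geno
}

#' Simulate a full dataset (frequencies + genotypes + cultivar map)
#'
#' @param cfg A [sim_config()].
#' @return List with `gm` (a [genotype_matrix()]), `varieties` (sample map
#'   tibble), and `truth` (the `sim_truth`).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  truth <- simulate_frequencies(cfg)
  gm <- simulate_genotypes(truth, cfg)
  list(
    gm = gm,
    varieties = tibble(sample = truth$samples, variety = truth$sample_variety),
    truth = truth
  )
}

#' Write a simulated dataset to disk as VCF + TSV + truth JSON
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default "sim").
#' @return Named list of the three file paths, invisibly; the dataset is
#'   returned in the `dataset` attribute.
#' @export
write_fixture <- function(cfg = sim_config(), dir = ".", prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_dataset(cfg)
  paths <- list(
    vcf = file.path(dir, paste0(prefix, ".vcf")),
    varieties = file.path(dir, paste0(prefix, "_varieties.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.json"))
  )
  write_vcf(ds$gm, paths$vcf)
  write_variety_map(ds$varieties, paths$varieties)
  jsonlite::write_json(
    list(
      config = unclass(cfg),
      samples = ds$truth$samples,
      sample_variety = ds$truth$sample_variety,
      p_anc = ds$truth$p_anc,
      pop_freq = ds$truth$pop_freq,
      loci = ds$truth$loci
    ),
    paths$truth,
    digits = NA
  )
  structure(paths, dataset = ds)
}
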