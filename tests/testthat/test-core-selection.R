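test_that("depth threshold is strictly exclusive and multi-allelics are removed", {
  codes <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  depth <- matrix(c(5L, 4L, 10L, 10L), 2, 2)
  gm <- toy_gm(codes, depth = depth)
  out <- filter_depth_biallelic(gm)
  expect_equal(unname(out$gm$geno[, 1]), c(0L, NA)) # depth 4 masked
  expect_equal(unname(out$gm$geno[, 2]), c(2L, 1L)) # depth > 4 kept
  expect_equal(out$n_masked, 1L)

  # tri-allelic and non-SNP alt loci are dropped and audited
  gm2 <- toy_gm(matrix(0L, 2, 3), depth = matrix(10L, 2, 3))
  gm2$loci$alt <- c("G", "G,T", "*")
  out2 <- filter_depth_biallelic(gm2)
  expect_equal(n_loci(out2$gm), 1L)
  expect_equal(nrow(out2$removed), 2L)
  expect_setequal(out2$removed$reason, "not_biallelic_snp")

  # all depths above threshold, biallelic -> unchanged
  gm3 <- toy_gm(matrix(1L, 2, 2), depth = matrix(5L, 2, 2))
  expect_identical(filter_depth_biallelic(gm3)$gm$geno, gm3$geno)
})

test_that("consensus rule boundaries: 7/10 consensus kept, 6/10 missing", {
  codes <- rbind(
    matrix(0L, 7, 2),
    matrix(1L, 3, 2)
  )
  codes[7, 2] <- 1L # second locus: 6 x code0, 4 x code1
  gm <- toy_gm(codes, depth = matrix(10L, 10, 2))
  vm <- tibble::tibble(sample = gm$samples, variety = "V1")
  cm <- consensus_genotypes(gm, vm)
  expect_equal(unname(cm$geno[1, 1]), 0L)        # 7/10 = 70% >= 70%
  expect_true(is.na(cm$geno[1, 2]))              # 60% < 70%

  # all code 2 -> consensus 2; all missing -> missing
  codes2 <- matrix(2L, 10, 2)
  codes2[, 2] <- NA_integer_
  cm2 <- consensus_genotypes(
    toy_gm(codes2, depth = matrix(10L, 10, 2)), vm
  )
  expect_equal(unname(cm2$geno[1, ]), c(2L, NA))
})

test_that("consensus denominators ignore missing calls", {
  # 7 of 10 calls missing; 3 non-missing agree -> consensus (3/3 = 100%)
  codes <- matrix(NA_integer_, 10, 1)
  codes[1:3, 1] <- 2L
  vmg <- toy_gm(codes, depth = matrix(10L, 10, 1))
  vm <- tibble::tibble(sample = vmg$samples, variety = "V1")
  expect_equal(unname(consensus_genotypes(vmg, vm)$geno[1, 1]), 2L)
})

test_that("consensus is invariant to sample order and cultivar relabeling", {
  ds <- simulate_dataset(sim_config(n_loci = 200L, seed = 12L))
  cm <- consensus_genotypes(ds$gm, ds$varieties)

  perm <- sample(seq_len(n_samples(ds$gm)))
  gm_p <- genotype_matrix(
    ds$gm$geno[perm, ], ds$gm$loci,
    samples = ds$gm$samples[perm], depth = ds$gm$depth[perm, ]
  )
  cm_p <- consensus_genotypes(gm_p, ds$varieties)
  expect_identical(cm$geno[cm$varieties, ], cm_p$geno[cm$varieties, ])

  relab <- ds$varieties
  relab$variety <- paste0("X_", relab$variety)
  cm_r <- consensus_genotypes(ds$gm, relab)
  expect_identical(unname(cm$geno), unname(cm_r$geno))
})

test_that("polymorphism screen removes all-identical consensus rows, missing ignored", {
  loci <- toy_gm(matrix(0L, 2, 5))$loci
  cons <- matrix(c(
    0L, 0L, 0L, 0L,   # locus 1: monomorphic
    0L, 0L, NA, 0L,   # locus 2: non-missing identical -> monomorphic
    NA, NA, NA, NA,   # locus 3: all missing -> monomorphic
    0L, 0L, 2L, 2L,   # locus 4: polymorphic
    1L, 1L, 2L, NA    # locus 5: polymorphic
  ), 4, 5)
  cm <- structure(
    list(geno = cons, varieties = paste0("V", 1:4), loci = loci),
    class = "consensus_matrix"
  )
  # pair with a sample matrix in exact HWE so only polymorphism acts
  sample_codes <- matrix(rep(c(0L, 1L, 1L, 2L), 5), 4, 5)
  gm_s <- toy_gm(sample_codes, depth = matrix(10L, 4, 5))
  out <- polymorphism_hwe_filter(cm, gm_s)
  expect_setequal(out$removed$id[out$removed$reason == "monomorphic"],
    loci$id[1:3])
  expect_equal(ncol(out$cm$geno), 2L)
})

test_that("HWE screen removes loci with extreme pooled heterozygote deficit", {
  # 20/0/20 pooled counts: p << 1e-5 -> removed; 10/20/10 in HWE -> kept
  bad <- c(rep(0L, 20), rep(2L, 20))
  good <- c(rep(0L, 10), rep(1L, 20), rep(2L, 10))
  gm <- toy_gm(cbind(bad, good), depth = matrix(10L, 40, 2))
  vm <- block_varieties(gm, 4L)
  cm <- consensus_genotypes(gm, vm)
  # make consensus polymorphic at both loci so only HWE differentiates
  cm$geno <- rbind(c(0L, 0L), c(0L, 1L), c(2L, 1L), c(2L, 2L))
  out <- polymorphism_hwe_filter(cm, gm)
  expect_equal(out$removed$reason, "hwe_fail")
  expect_equal(out$removed$id, gm$loci$id[1])
  expect_lt(out$hwe_p[1], 1e-5)
  expect_gt(out$hwe_p[2], 1e-5)
})

test_that("missingness/MAF screen applies the >30% and <0.01 boundaries at n = 4", {
  loci <- toy_gm(matrix(0L, 2, 4))$loci
  cm <- structure(
    list(geno = matrix(c(
      0L, 0L, NA, NA,   # locus 1: 2/4 missing -> removed
      0L, 0L, NA, 0L,   # locus 2: 1/4 missing (25% <= 30%) but MAF 0 -> removed
      0L, 2L, 1L, 1L,   # locus 3: kept (maf 0.5)
      0L, 0L, 1L, 2L    # locus 4: kept (maf 3/8)
    ), 4, 4), varieties = paste0("V", 1:4), loci = loci),
    class = "consensus_matrix"
  )
  out <- missing_maf_filter(cm)
  expect_equal(ncol(out$cm$geno), 2L)
  expect_equal(
    out$removed$reason[match(loci$id[1:2], out$removed$id)],
    c("missingness", "low_maf")
  )
  # consensus (0,0,0,1): MAF 1/8 = 0.125 -> kept
  cm2 <- structure(
    list(geno = matrix(c(0L, 0L, 0L, 1L), 4, 1),
      varieties = paste0("V", 1:4), loci = loci[1, ]),
    class = "consensus_matrix"
  )
  expect_equal(ncol(missing_maf_filter(cm2)$cm$geno), 1L)
})

test_that("PIC screen keeps the minimum attainable polymorphic consensus and drops maf 0", {
  loci <- toy_gm(matrix(0L, 2, 3))$loci
  cm <- structure(
    list(geno = matrix(c(
      0L, 0L, 0L, 1L,  # maf 0.125 -> PIC 0.195 kept
      0L, 1L, 1L, 2L,  # maf 0.5   -> PIC 0.375 kept
      0L, 0L, 0L, 0L   # maf 0     -> PIC 0 removed
    ), 4, 3), varieties = paste0("V", 1:4), loci = loci),
    class = "consensus_matrix"
  )
  out <- pic_filter(cm)
  expect_equal(ncol(out$cm$geno), 2L)
  expect_equal(out$removed$id, loci$id[3])
  expect_equal(round_half_up(out$pic[1], 3), 0.195)
  expect_equal(round_half_up(out$pic[2], 3), 0.375)
})

test_that("LD pruning removes exactly one of two identical columns and keeps independent loci", {
  set.seed(13)
  base <- sample(0:2, 40, replace = TRUE)
  other <- sample(0:2, 40, replace = TRUE)
  gm <- toy_gm(cbind(base, base, other), depth = matrix(10L, 40, 3))
  out <- ld_prune(gm)
  expect_equal(n_loci(out$gm), 2L)
  expect_equal(nrow(out$removed), 1L)

  # all pairwise r2 below threshold -> all kept
  set.seed(14)
  indep <- matrix(sample(0:2, 40 * 5, replace = TRUE), 40, 5)
  gm2 <- toy_gm(indep, depth = matrix(10L, 40, 5))
  expect_equal(n_loci(ld_prune(gm2)$gm), 5L)
})

test_that("LD pruning matches the brute-force window oracle on block-copy fixtures", {
  params <- filter_params(ld_window = 20L, ld_step = 5L, ld_r2 = 0.8)
  for (seed in c(21L, 22L)) {
    ds <- simulate_dataset(sim_config(
      n_loci = 180L, n_chrom = 2L, n_ld_blocks = 8L, ld_block_size = 4L,
      ld_flip_rate = 0.05, seed = seed
    ))
    got <- ld_prune(ds$gm, params)
    expect_identical(got$kept, oracle_ld_prune(ds$gm, params))

    # post-condition: no surviving pair within any evaluated window above r2
    gm_kept <- got$gm
    for (chr in unique(gm_kept$loci$chrom)) {
      idx <- which(gm_kept$loci$chrom == chr)
      for (s in seq(1, length(idx), by = params$ld_step)) {
        win <- idx[s:min(s + params$ld_window - 1, length(idx))]
        if (length(win) < 2) next
        r2 <- suppressWarnings(
          cor(gm_kept$geno[, win], use = "pairwise.complete.obs")^2
        )
        r2[!upper.tri(r2)] <- NA
        expect_false(any(r2 > params$ld_r2, na.rm = TRUE))
      }
    }
  }
})

test_that("cascade report arithmetic is exact and stages chain", {
  ds <- simulate_dataset(sim_config(n_loci = 3000L, seed = 15L))
  panel <- select_core(ds$gm, ds$varieties)
  rep <- panel$report
  expect_equal(rep$n_removed, rep$n_in - rep$n_out)
  expect_equal(rep$n_in[-1], rep$n_out[-nrow(rep)])
  expect_true(all(diff(rep$n_out) <= 0))
  expect_equal(n_loci(panel$core), rep$n_out[nrow(rep)])
  # removal audit covers every lost locus exactly once
  expect_equal(nrow(panel$removed), rep$n_in[1] - rep$n_out[nrow(rep)])
})

test_that("every surviving core locus satisfies all consensus thresholds", {
  ds <- simulate_dataset(sim_config(n_loci = 3000L, seed = 16L))
  params <- filter_params()
  panel <- select_core(ds$gm, ds$varieties, params)
  fr <- corepanel:::consensus_freq(panel$consensus)
  expect_true(all(fr$maf >= params$min_maf))
  expect_true(all(fr$missing_frac <= params$max_missing))
  expect_true(all(corepanel:::pic_biallelic(fr$p_alt) >= params$min_pic))
  hwe_core <- panel$hwe_p[match(
    panel$core$loci$id, panel$stage_ids$depth_biallelic
  )]
  expect_true(all(hwe_core >= params$hwe_alpha))
})

test_that("degenerate settings produce a valid empty panel with a complete report", {
  ds <- simulate_dataset(sim_config(n_loci = 300L, seed = 17L))
  panel <- suppressWarnings(
    select_core(ds$gm, ds$varieties, filter_params(min_pic = 1.0))
  )
  expect_equal(n_loci(panel$core), 0L)
  expect_equal(panel$report$n_out[nrow(panel$report)], 0L)
  expect_equal(panel$report$n_removed[panel$report$stage == "pic"],
    panel$report$n_in[panel$report$stage == "pic"])

  # monomorphic input dies at the polymorphism stage
  gm_mono <- toy_gm(matrix(0L, 8, 5), depth = matrix(10L, 8, 5))
  vm <- block_varieties(gm_mono, 4L)
  p2 <- suppressWarnings(select_core(gm_mono, vm))
  expect_equal(n_loci(p2$core), 0L)
  expect_equal(
    p2$report$n_out[p2$report$stage == "polymorphism_hwe"], 0L
  )
})
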