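# Shared fixture builders. Everything is generated in code; no binary data.

# Tiny genotype matrix from an explicit code matrix (samples x loci).
toy_gm <- function(codes, depth = NULL, chrom = "chr01", ref = "A", alt = "G") {
  codes <- as.matrix(codes)
  m <- ncol(codes)
  loci <- tibble::tibble(
    chrom = rep_len(chrom, m),
    pos = seq_len(m) * 100L,
    id = paste0(rep_len(chrom, m), ":", seq_len(m) * 100L),
    ref = rep_len(ref, m),
    alt = rep_len(alt, m)
  )
  genotype_matrix(
    codes, loci,
    samples = paste0("s", seq_len(nrow(codes))),
    depth = depth
  )
}

# Block-structured variety map: first n/k samples -> V1, etc.
block_varieties <- function(gm, k) {
  n <- n_samples(gm)
  per <- ceiling(n / k)
  tibble::tibble(
    sample = gm$samples,
    variety = paste0("V", rep(seq_len(k), each = per)[seq_len(n)])
  )
}

# Hand-written 3-record, 2-sample VCF used by the parser tests.
write_toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr01>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", "sampleA", "sampleB"), collapse = "\t"),
    "chr01\t100\t.\tA\tG\t.\t.\t.\tGT:DP\t0/0:3\t0/1:9",
    "chr01\t200\t.\tC\tT\t.\t.\t.\tGT\t1/1\t./.",
    "chr01\t300\t.\tG\tA\t.\t.\t.\tGT:DP\t0|1:7\t1|0:8"
  ), path)
  path
}

# Independent enumeration oracle for the exact HWE test: direct
# log-factorial Levene probabilities, no recurrence.
oracle_hwe <- function(a, b, c) {
  n <- a + b + c
  if (n == 0) return(1)
  n_ref <- 2 * a + b
  n_alt <- 2 * c + b
  hs <- seq(n_ref %% 2, min(n_ref, n_alt), by = 2)
  logp <- vapply(hs, function(h) {
    naa <- (n_ref - h) / 2
    nbb <- (n_alt - h) / 2
    lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
      h * log(2) + lfactorial(n_ref) + lfactorial(n_alt) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp)
  p_obs <- p[hs == b]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

# Brute-force LD pruning oracle: literal re-application of the window rule
# with explicit pairwise-complete r^2 loops (no shared code with ld_prune).
oracle_ld_prune <- function(gm, params) {
  r2_pair <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2) return(NA_real_)
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
    cor(x[ok], y[ok])^2
  }
  p <- colMeans(gm$geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.na(maf)] <- 0
  alive <- rep(TRUE, n_loci(gm))
  for (chr in unique(gm$loci$chrom)) {
    idx <- which(gm$loci$chrom == chr)
    for (s in seq(1, length(idx), by = params$ld_step)) {
      win <- idx[s:min(s + params$ld_window - 1, length(idx))]
      repeat {
        cur <- win[alive[win]]
        if (length(cur) < 2) break
        removed_one <- FALSE
        for (ii in seq_len(length(cur) - 1)) {
          for (jj in seq(ii + 1, length(cur))) {
            r2 <- r2_pair(gm$geno[, cur[ii]], gm$geno[, cur[jj]])
            if (!is.na(r2) && r2 > params$ld_r2) {
              drop <- if (maf[cur[ii]] < maf[cur[jj]]) cur[ii] else cur[jj]
              alive[drop] <- FALSE
              removed_one <- TRUE
              break
            }
          }
          if (removed_one) break
        }
        if (!removed_one) break
      }
    }
  }
  gm$loci$id[alive]
}

# All 24 permutations of 1:4 (cluster-label matching).
perms4 <- function() {
  out <- NULL
  for (a in 1:4) for (b in setdiff(1:4, a)) for (c in setdiff(1:4, c(a, b))) {
    out <- rbind(out, c(a, b, c, setdiff(1:4, c(a, b, c))))
  }
  out
}

# Small, well-separated 4-population dataset reused by the structure tests.
structure_fixture <- function(n_loci = 2000L, fst = 0.25, seed = 31L, ...) {
  simulate_dataset(sim_config(n_loci = n_loci, fst = fst, seed = seed, ...))
}
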