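#' Filtering parameters for core-SNP selection
#'
#' Thresholds of the six-stage screening cascade. All boundaries follow the
#' workflow's literal inequalities: depth strictly greater than `min_depth`
#' is kept; gene identity at least `identity_threshold` defines a consensus;
#' loci with exact HWE p strictly below `hwe_alpha`, consensus missingness
#' strictly above `max_missing`, MAF strictly below `min_maf`, or PIC
#' strictly below `min_pic` are removed; pairwise r2 strictly above `ld_r2`
#' triggers pruning.
#'
#' @param min_depth Per-call depth floor (exclusive; default 4).
#' @param identity_threshold Gene identity rate for a cultivar consensus
#'   (inclusive; default 0.70).
#' @param hwe_alpha Exact HWE p-value floor (default 1e-5).
#' @param max_missing Maximum consensus missingness fraction (default 0.30).
#' @param min_maf Minimum consensus minor-allele frequency (default 0.01).
#' @param min_pic Minimum polymorphic information content (default 0.10).
#' @param ld_window,ld_step Sliding window size and step in SNP counts for
#'   LD pruning (defaults 50 and 10, the PLINK `--indep-pairwise 50 10`
#'   geometry).
#' @param ld_r2 Squared-correlation threshold for pruning (default 0.99).
#' @param hwe_level Matrix on which genotype counts for the HWE test are
#'   taken: `"samples"` (default; pooled individual genotypes) or
#'   `"consensus"` (cultivar consensus calls; note that with only a few
#'   cultivars the exact test cannot reach small p-values).
#' @return A `filter_params` list.
#' @export
filter_params <- function(min_depth = 4L, identity_threshold = 0.70,
                          hwe_alpha = 1e-5, max_missing = 0.30,
                          min_maf = 0.01, min_pic = 0.10,
                          ld_window = 50L, ld_step = 10L, ld_r2 = 0.99,
                          hwe_level = c("samples", "consensus")) {
  hwe_level <- match.arg(hwe_level)
  p <- list(
    min_depth = as.integer(min_depth),
    identity_threshold = identity_threshold, hwe_alpha = hwe_alpha,
    max_missing = max_missing, min_maf = min_maf, min_pic = min_pic,
    ld_window = as.integer(ld_window), ld_step = as.integer(ld_step),
    ld_r2 = ld_r2, hwe_level = hwe_level
  )
  stopifnot(
    p$min_depth >= 0L, p$identity_threshold > 0, p$identity_threshold <= 1,
    p$hwe_alpha >= 0, p$hwe_alpha <= 1, p$max_missing >= 0, p$max_missing <= 1,
    p$min_maf >= 0, p$min_maf <= 0.5, p$min_pic >= 0,
    p$ld_window >= 2L, p$ld_step >= 1L, p$ld_step <= p$ld_window,
    p$ld_r2 > 0, p$ld_r2 <= 1
  )
  class(p) <- "filter_params"
  p
}

#' Depth masking and biallelic-SNP retention
#'
#' Calls with depth at or below `min_depth` are set missing; loci that are
#' not biallelic single-base SNPs (more than one alternate allele, or any
#' non-ACGT allele such as a spanning deletion) are removed.
#'
#' @param gm A [genotype_matrix()].
#' @param params A [filter_params()].
#' @return List: `gm` (the filtered matrix), `removed` (tibble `id`,
#'   `reason` for dropped loci), `n_masked` (calls newly set missing).
#' @export
filter_depth_biallelic <- function(gm, params = filter_params()) {
  mask <- gm$depth <= params$min_depth & !is.na(gm$geno)
  geno <- gm$geno
  geno[mask] <- NA_integer_
  keep <- is_biallelic_snp(gm$loci)
  removed <- tibble(id = gm$loci$id[!keep], reason = "not_biallelic_snp")
  out <- genotype_matrix(
    geno[, keep, drop = FALSE], gm$loci[keep, ],
    samples = gm$samples, depth = gm$depth[, keep, drop = FALSE]
  )
  list(gm = out, removed = removed, n_masked = sum(mask))
}

#' Cultivar consensus genotypes under the gene-identity rule
#'
#' For each cultivar and locus, the consensus is the modal genotype among
#' the cultivar's non-missing calls provided its share (the gene identity
#' rate) is at least `identity_threshold`; otherwise, and when every call is
#' missing, the cultivar's genotype at that locus is missing.
#'
#' @param gm A [genotype_matrix()].
#' @param varieties Sample-to-cultivar map (tibble `sample`, `variety`).
#' @param params A [filter_params()].
#' @return A `consensus_matrix`: list with `geno`
#'   (`n_varieties` x `n_loci` codes), `varieties`, `loci`.
#' @export
consensus_genotypes <- function(gm, varieties, params = filter_params()) {
  vlab <- match_varieties(gm, varieties)
  vlev <- unique(vlab)
  m <- n_loci(gm)
  cons <- matrix(NA_integer_, length(vlev), m,
    dimnames = list(vlev, gm$loci$id)
  )
  for (v_i in seq_along(vlev)) {
    sub <- gm$geno[vlab == vlev[v_i], , drop = FALSE]
    n0 <- colSums(sub == 0L, na.rm = TRUE)
    n1 <- colSums(sub == 1L, na.rm = TRUE)
    n2 <- colSums(sub == 2L, na.rm = TRUE)
    tot <- n0 + n1 + n2
    counts <- cbind(n0, n1, n2)
    modal <- max.col(counts, ties.method = "first") - 1L
    modal_n <- pmax(n0, pmax(n1, n2))
    ok <- tot >= 1L & modal_n / pmax(tot, 1L) >= params$identity_threshold
    cons[v_i, ok] <- modal[ok]
  }
  structure(
    list(geno = cons, varieties = vlev, loci = gm$loci),
    class = "consensus_matrix"
  )
}

#' @export
print.consensus_matrix <- function(x, ...) {
  cat(sprintf(
    "<consensus_matrix> %d cultivars x %d loci\n",
    length(x$varieties), nrow(x$loci)
  ))
  invisible(x)
}

subset_consensus <- function(cm, keep) {
  if (is.logical(keep)) keep <- which(keep)
  structure(
    list(
      geno = cm$geno[, keep, drop = FALSE], varieties = cm$varieties,
      loci = cm$loci[keep, ]
    ),
    class = "consensus_matrix"
  )
}

# Consensus-level alternate-allele frequency and missingness per locus.
consensus_freq <- function(cm) {
  n_obs <- colSums(!is.na(cm$geno))
  alt <- colSums(cm$geno, na.rm = TRUE)
  p <- ifelse(n_obs > 0L, alt / (2 * n_obs), NA_real_)
  tibble(
    id = cm$loci$id, n_obs = n_obs, p_alt = p,
    maf = pmin(p, 1 - p),
    missing_frac = 1 - n_obs / length(cm$varieties)
  )
}

#' Polymorphism and Hardy-Weinberg screen
#'
#' Removes loci whose non-missing consensus genotypes are all identical
#' (no polymorphism among cultivars; all-missing loci count as
#' non-polymorphic) and loci whose exact HWE p-value falls below
#' `hwe_alpha`. Genotype counts for the HWE test are taken at the level
#' named by `params$hwe_level` — by default the pooled sample genotypes,
#' where the exact test has enough resolution for p-values below 1e-5.
#'
#' @param cm A `consensus_matrix` from [consensus_genotypes()].
#' @param gm The [genotype_matrix()] the consensus was built from (same
#'   loci).
#' @param params A [filter_params()].
#' @return List: `cm`, `gm` (both restricted to kept loci), `removed`
#'   tibble, `hwe_p` (p-value per input locus).
#' @export
polymorphism_hwe_filter <- function(cm, gm, params = filter_params()) {
  stopifnot(identical(cm$loci$id, gm$loci$id))
  g <- cm$geno
  n_obs <- colSums(!is.na(g))
  mins <- suppressWarnings(apply(g, 2L, min, na.rm = TRUE))
  maxs <- suppressWarnings(apply(g, 2L, max, na.rm = TRUE))
  polymorphic <- n_obs > 0L & mins != maxs
  counts <- if (params$hwe_level == "samples") {
    genotype_counts(gm)
  } else {
    cbind(
      colSums(g == 0L, na.rm = TRUE), colSums(g == 1L, na.rm = TRUE),
      colSums(g == 2L, na.rm = TRUE)
    )
  }
  hwe_p <- hwe_exact_vec(counts)
  hwe_ok <- hwe_p >= params$hwe_alpha
  keep <- polymorphic & hwe_ok
  removed <- tibble(
    id = cm$loci$id[!keep],
    reason = as.character(ifelse(!polymorphic[!keep], "monomorphic", "hwe_fail"))
  )
  list(
    cm = subset_consensus(cm, keep), gm = subset_loci(gm, keep),
    removed = removed, hwe_p = hwe_p
  )
}

#' Consensus missingness and minor-allele-frequency screen
#'
#' A locus is removed when the fraction of cultivars with a missing
#' consensus exceeds `max_missing`, or when the consensus-level MAF
#' (two alleles per non-missing cultivar) falls below `min_maf`.
#'
#' @inheritParams polymorphism_hwe_filter
#' @return List: `cm` (restricted), `removed` tibble, `stats` (per-locus
#'   consensus frequency table).
#' @export
missing_maf_filter <- function(cm, params = filter_params()) {
  fr <- consensus_freq(cm)
  too_missing <- fr$missing_frac > params$max_missing
  low_maf <- is.na(fr$maf) | fr$maf < params$min_maf
  keep <- !too_missing & !low_maf
  removed <- tibble(
    id = fr$id[!keep],
    reason = as.character(ifelse(too_missing[!keep], "missingness", "low_maf"))
  )
  list(cm = subset_consensus(cm, keep), removed = removed, stats = fr)
}

#' Polymorphic information content screen
#'
#' Removes loci whose Botstein PIC, computed from consensus allele
#' frequencies, falls below `min_pic`.
#'
#' @inheritParams polymorphism_hwe_filter
#' @return List: `cm` (restricted), `removed` tibble, `pic` per input locus.
#' @export
pic_filter <- function(cm, params = filter_params()) {
  fr <- consensus_freq(cm)
  pic_vals <- pic_biallelic(fr$p_alt)
  keep <- !is.na(pic_vals) & pic_vals >= params$min_pic
  removed <- tibble(id = fr$id[!keep], reason = "low_pic")
  list(cm = subset_consensus(cm, keep), removed = removed, pic = pic_vals)
}

#' Sliding-window LD pruning of near-duplicate markers
#'
#' PLINK-style `--indep-pairwise` pruning on genotype dosages: per
#' chromosome a window of `ld_window` SNPs advances by `ld_step` SNPs;
#' within each window, while any retained pair has squared Pearson
#' correlation above `ld_r2` (computed over samples non-missing at both
#' loci), the member with the lower sample-level MAF is removed (tie: the
#' later locus).
#'
#' @param gm A [genotype_matrix()] holding the loci still alive at this
#'   stage.
#' @param params A [filter_params()].
#' @return List: `gm` (pruned), `removed` tibble, `kept` locus ids.
#' @export
ld_prune <- function(gm, params = filter_params()) {
  m <- n_loci(gm)
  if (m == 0L) {
    return(list(gm = gm, removed = tibble(id = character(), reason = character()),
      kept = character()))
  }
  p_alt <- colMeans(gm$geno, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  maf[is.na(maf)] <- 0
  alive <- rep(TRUE, m)
  for (chr in unique(gm$loci$chrom)) {
    idx <- which(gm$loci$chrom == chr)
    mc <- length(idx)
    starts <- seq.int(1L, mc, by = params$ld_step)
    for (s in starts) {
      win <- idx[s:min(s + params$ld_window - 1L, mc)]
      win <- win[alive[win]]
      if (length(win) < 2L) next
      repeat {
        r2 <- suppressWarnings(
          cor(gm$geno[, win, drop = FALSE],
            use = "pairwise.complete.obs"
          )^2
        )
        r2[!upper.tri(r2)] <- NA
        hit <- which(!is.na(r2) & r2 > params$ld_r2, arr.ind = TRUE)
        if (nrow(hit) == 0L) break
        i <- win[hit[1L, 1L]]
        j <- win[hit[1L, 2L]]
        drop_locus <- if (maf[i] < maf[j]) i else j # tie -> later locus j
        alive[drop_locus] <- FALSE
        win <- win[win != drop_locus]
        if (length(win) < 2L) break
      }
    }
  }
  removed <- tibble(id = gm$loci$id[!alive], reason = "ld_prune")
  list(gm = subset_loci(gm, alive), removed = removed,
    kept = gm$loci$id[alive])
}

#' Run the full six-stage core-SNP selection cascade
#'
#' Stages, in order: (1) depth masking and biallelic retention;
#' (2) cultivar consensus genotyping (gene identity rate >=
#' `identity_threshold`); (3) removal of non-polymorphic loci and exact-HWE
#' failures; (4) consensus missingness / MAF screen; (5) PIC screen;
#' (6) sliding-window LD pruning on sample-level genotypes. Every stage is
#' audited in a filter report whose arithmetic is exact
#' (`n_out = n_in - n_removed`, chained).
#'
#' @param gm A [genotype_matrix()].
#' @param varieties Sample-to-cultivar map.
#' @param params A [filter_params()].
#' @return A `core_panel` object: list with `core` (the pruned
#'   [genotype_matrix()] of core SNPs), `consensus` (consensus matrix on the
#'   core loci), `filtered` (the post-depth/biallelic sample matrix, i.e.
#'   the "total SNPs"), `stage_ids` (locus ids surviving each stage),
#'   `report` (tibble `stage`, `n_in`, `n_removed`, `n_out`), `removed`
#'   (per-locus reasons), `hwe_p`, `params`.
#' @export
select_core <- function(gm, varieties, params = filter_params()) {
  stages <- list()
  removed_all <- list()
  note <- function(stage, n_in, n_out) {
    tibble(stage = stage, n_in = n_in, n_removed = n_in - n_out, n_out = n_out)
  }

  s1 <- filter_depth_biallelic(gm, params)
  stages$depth_biallelic <- note("depth_biallelic", n_loci(gm), n_loci(s1$gm))
  removed_all$depth <- s1$removed

  cm <- consensus_genotypes(s1$gm, varieties, params)
  stages$consensus <- note("consensus", n_loci(s1$gm), n_loci(s1$gm))

  s3 <- polymorphism_hwe_filter(cm, s1$gm, params)
  stages$polymorphism_hwe <- note(
    "polymorphism_hwe", ncol(cm$geno), ncol(s3$cm$geno)
  )
  removed_all$poly <- s3$removed

  s4 <- missing_maf_filter(s3$cm, params)
  stages$missing_maf <- note("missing_maf", ncol(s3$cm$geno), ncol(s4$cm$geno))
  removed_all$missing <- s4$removed

  s5 <- pic_filter(s4$cm, params)
  stages$pic <- note("pic", ncol(s4$cm$geno), ncol(s5$cm$geno))
  removed_all$pic <- s5$removed

  gm5 <- subset_loci(s3$gm, match(s5$cm$loci$id, s3$gm$loci$id))
  s6 <- ld_prune(gm5, params)
  stages$ld_prune <- note("ld_prune", n_loci(gm5), n_loci(s6$gm))
  removed_all$ld <- s6$removed

  if (n_loci(s6$gm) == 0L) {
    warn("no loci survived the selection cascade; returning an empty panel")
  }
  structure(
    list(
      core = s6$gm,
      consensus = subset_consensus(
        s5$cm, match(s6$gm$loci$id, s5$cm$loci$id)
      ),
      filtered = s1$gm,
      stage_ids = list(
        depth_biallelic = s1$gm$loci$id,
        polymorphism_hwe = s3$cm$loci$id,
        missing_maf = s4$cm$loci$id,
        pic = s5$cm$loci$id,
        ld_prune = s6$gm$loci$id
      ),
      report = bind_rows(stages),
      removed = bind_rows(removed_all),
      hwe_p = s3$hwe_p,
      params = params
    ),
    class = "core_panel"
  )
}

#' @export
print.core_panel <- function(x, ...) {
  cat(sprintf(
    "<core_panel> %d core SNPs from %d input loci\n",
    n_loci(x$core), x$report$n_in[1]
  ))
  print(x$report)
  invisible(x)
}

#' Tidy the filter report of a core panel
#' @param x A `core_panel` from [select_core()].
#' @param ... Unused.
#' @return The stage-by-stage filter report tibble.
#' @method tidy core_panel
#' @export
tidy.core_panel <- function(x, ...) x$report

#' One-row summary of a core panel
#' @param x A `core_panel`.
#' @param ... Unused.
#' @return Tibble with input/core locus counts and masked-call totals.
#' @method glance core_panel
#' @export
glance.core_panel <- function(x, ...) {
  tibble(
    n_input = x$report$n_in[1],
    n_core = n_loci(x$core),
    n_stages = nrow(x$report),
    n_removed = x$report$n_in[1] - n_loci(x$core)
  )
}
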