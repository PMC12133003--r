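#' Run the full screening and validation pipeline
#'
#' Orchestrates simulate/load -> core-SNP selection -> panel statistics ->
#' similarity validation -> population structure, writing every module
#' output plus a JSON run report into `outdir`. A single global seed fans
#' out to per-stage derived seeds so each stage is independently
#' reproducible.
#'
#' @param gm A [genotype_matrix()], or `NULL` to simulate from `sim_cfg`.
#' @param varieties Sample-to-cultivar map (ignored when simulating).
#' @param sim_cfg A [sim_config()] used when `gm` is `NULL`.
#' @param params A [filter_params()].
#' @param outdir Output directory (created).
#' @param k_range K values for admixture CV; empty vector skips the
#'   structure stage.
#' @param folds CV folds (default 5).
#' @param bootstrap_B NJ bootstrap replicates (default 100 at pipeline
#'   scale; 0 skips supports).
#' @param n_restarts EM restarts (default 8).
#' @param seed Global seed.
#' @return A `run_report` list: config echo, filter report, panel
#'   summaries, correlation, `k_best`, file manifest, wall-clock seconds
#'   per stage.
#' @export
run_pipeline <- function(gm = NULL, varieties = NULL, sim_cfg = sim_config(),
                         params = filter_params(), outdir = tempfile("run"),
                         k_range = 1:7, folds = 5L, bootstrap_B = 100L,
                         n_restarts = 8L, seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  timing <- list()
  clock <- function(stage, expr) {
    t0 <- Sys.time()
    out <- force(expr)
    timing[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }
  emit <- function(obj, name, writer) {
    path <- file.path(outdir, name)
    writer(obj, path)
    manifest <<- c(manifest, path)
    path
  }

  if (is.null(gm)) {
    sim_cfg$seed <- derive_seed(seed, "simulate")
    ds <- clock("simulate", simulate_dataset(sim_cfg))
    gm <- ds$gm
    varieties <- ds$varieties
    emit(gm, "input.vcf", write_vcf)
    emit(varieties, "varieties.tsv", write_variety_map)
  } else if (is.null(varieties)) {
    abort("varieties map required when genotypes are supplied")
  }
  varieties <- variety_assignment(varieties)

  panel <- clock("select", select_core(gm, varieties, params))
  emit(panel$core, "core.vcf", write_vcf)
  emit(panel$report, "filter_report.tsv",
    function(x, p) readr::write_tsv(x, p, progress = FALSE))
  emit(panel$report, "filter_report.json",
    function(x, p) jsonlite::write_json(x, p, digits = NA))
  emit(consensus_tibble(panel$consensus), "consensus.tsv",
    function(x, p) readr::write_tsv(x, p, progress = FALSE))

  stats_out <- clock("stats", {
    total_stats <- locus_stats(panel$filtered)
    core_stats <- locus_stats(panel$consensus)
    list(
      total = total_stats, core = core_stats,
      total_summary = summarize_panel(total_stats),
      core_summary = summarize_panel(core_stats),
      density_total = snp_density(panel$filtered),
      density_core = snp_density(panel$core)
    )
  })
  for (nm in names(stats_out)) {
    emit(stats_out[[nm]], paste0(nm, ".tsv"),
      function(x, p) readr::write_tsv(x, p, progress = FALSE))
  }

  validate_out <- clock("validate", {
    total_sim <- pairwise_similarity(panel$filtered)
    core_sim <- pairwise_similarity(panel$core)
    corr <- similarity_correlation(total_sim, core_sim)
    list(total_sim = total_sim, core_sim = core_sim, corr = corr)
  })
  emit(tidy(validate_out$total_sim) |>
    mutate(core_similarity = tidy(validate_out$core_sim)$similarity),
  "similarity_pairs.tsv",
  function(x, p) readr::write_tsv(x, p, progress = FALSE))
  emit(glance(validate_out$corr), "correlation.json",
    function(x, p) jsonlite::write_json(as.list(x), p, auto_unbox = TRUE,
      digits = NA))

  k_best <- NA_integer_
  structure_skipped <- length(k_range) == 0L
  if (!structure_skipped && n_loci(panel$core) > 0L) {
    struct_out <- clock("structure", {
      pca <- pca_grm(panel$core)
      boot <- bootstrap_support(panel$core,
        B = bootstrap_B, seed = derive_seed(seed, "boot"))
      cv <- cv_choose_k(panel$core,
        k_range = k_range, folds = folds,
        seed = derive_seed(seed, "cv"), n_restarts = n_restarts
      )
      fit <- admixture_em(panel$core, cv$k_best,
        seed = derive_seed(seed, "fit"), n_restarts = n_restarts)
      list(pca = pca, boot = boot, cv = cv, fit = fit)
    })
    emit(struct_out$pca$scores, "pca.tsv",
      function(x, p) readr::write_tsv(x, p, progress = FALSE))
    emit(struct_out$boot$tree, "nj_tree.nwk", function(x, p) write_newick(x, p))
    emit(struct_out$cv$cv_mean, "cv_errors.tsv",
      function(x, p) readr::write_tsv(x, p, progress = FALSE))
    emit(tidy(struct_out$fit), "admixture_q.tsv",
      function(x, p) readr::write_tsv(x, p, progress = FALSE))
    k_best <- struct_out$cv$k_best
  }

  emit(heatmap_export(panel$core), "heatmap_matrix.tsv",
    function(x, p) readr::write_tsv(x, p, progress = FALSE))

  report <- list(
    package_version = as.character(utils::packageVersion("corepanel")),
    seed = seed,
    params = unclass(params),
    filter_report = panel$report,
    core_loci = n_loci(panel$core),
    correlation = glance(validate_out$corr),
    k_best = k_best,
    structure_skipped = structure_skipped,
    manifest = manifest,
    seconds_per_stage = timing
  )
  jsonlite::write_json(
    report, file.path(outdir, "run_report.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE
  )
  report$manifest <- c(report$manifest, file.path(outdir, "run_report.json"))
  class(report) <- "run_report"
  report
}

consensus_tibble <- function(cm) {
  out <- as_tibble(t(cm$geno), .name_repair = "minimal")
  names(out) <- cm$varieties
  bind_cols(cm$loci[c("chrom", "pos", "id", "ref", "alt")], out)
}

#' Export the genotype character matrix behind a panel heatmap
#'
#' Loci in rows, samples in columns. Homozygous calls are doubled bases
#' ("AA", "CC", ...), heterozygous calls are the ref+alt base pair ("AG"),
#' missing calls are empty strings.
#'
#' @param x A [genotype_matrix()] or `consensus_matrix` with at least one
#'   locus.
#' @return Tibble: `chrom`, `pos`, `id`, then one character column per
#'   sample.
#' @export
heatmap_export <- function(x) {
  if (nrow(x$loci) == 0L) abort("empty panel; nothing to export")
  labels <- x$samples %||% x$varieties
  ref <- x$loci$ref
  alt <- substr(x$loci$alt, 1, 1)
  lookup <- cbind(paste0(ref, ref), paste0(ref, alt), paste0(alt, alt))
  chars <- matrix("", nrow(x$loci), length(labels))
  for (code in 0:2) {
    sel <- t(!is.na(x$geno) & x$geno == code)
    chars[sel] <- matrix(rep(lookup[, code + 1L], length(labels)),
      nrow(x$loci))[sel]
  }
  colnames(chars) <- labels
  bind_cols(x$loci[c("chrom", "pos", "id")], as_tibble(chars))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(
    "<run_report> %d core SNPs; r = %.4f; K* = %s; %d files\n",
    x$core_loci, x$correlation$r,
    ifelse(is.na(x$k_best), "skipped", x$k_best), length(x$manifest)
  ))
  invisible(x)
}

#' Tile plot of SNP density along chromosomes
#' @param density A [snp_density()] tibble.
#' @return A ggplot.
#' @export
plot_snp_density <- function(density) {
  ggplot2::ggplot(density, ggplot2::aes(
    x = (.data$start + .data$end) / 2e6, y = .data$chrom,
    fill = .data$n_snps
  )) +
    ggplot2::geom_tile(ggplot2::aes(width = (.data$end - .data$start) / 1e6)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "position (Mb)", y = NULL, fill = "SNPs") +
    ggplot2::theme_minimal()
}
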