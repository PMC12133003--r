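#' Genotype matrix container
#'
#' The central in-memory object of the package: diploid genotype codes for
#' `n` samples at `m` biallelic (or flagged multi-allelic) loci, together
#' with per-call sequencing depth and per-locus metadata.
#'
#' Genotype codes are `0` (homozygous reference), `1` (heterozygous),
#' `2` (homozygous alternate) and `NA` (missing). Missing is a distinguished
#' sentinel and is never conflated with code 0. Depth is a non-negative
#' integer per call (0 when the source VCF carried no DP).
#'
#' @param geno Integer matrix, samples in rows, loci in columns, entries in
#'   `{0, 1, 2, NA}`.
#' @param depth Integer matrix of the same shape; non-negative. Defaults to
#'   all zeros.
#' @param samples Character vector of unique sample labels (row order).
#' @param loci Tibble with columns `chrom`, `pos` (1-based), `id`, `ref`,
#'   `alt` (comma-separated when multi-allelic), one row per column of
#'   `geno`, sorted by chromosome then position.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, loci, samples = rownames(geno), depth = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(samples)) abort("sample labels are required")
  samples <- as.character(samples)
  if (anyDuplicated(samples)) abort("duplicate sample names")
  if (length(samples) != nrow(geno)) abort("samples do not match genotype rows")
  loci <- validate_loci(loci)
  if (nrow(loci) != ncol(geno)) abort("loci do not match genotype columns")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    abort("genotype codes must be 0, 1, 2 or NA")
  }
  if (is.null(depth)) {
    depth <- matrix(0L, nrow(geno), ncol(geno))
  }
  depth <- as.matrix(depth)
  storage.mode(depth) <- "integer"
  if (!all(dim(depth) == dim(geno))) abort("depth shape must match genotypes")
  if (any(depth < 0L, na.rm = TRUE)) abort("depth must be non-negative")
  depth[is.na(depth)] <- 0L
  rownames(geno) <- samples
  rownames(depth) <- samples
  colnames(geno) <- loci$id
  colnames(depth) <- loci$id
  structure(
    list(geno = geno, depth = depth, samples = samples, loci = loci),
    class = "genotype_matrix"
  )
}

validate_loci <- function(loci) {
  loci <- tibble::as_tibble(loci)
  needed <- c("chrom", "pos", "ref", "alt")
  if (!all(needed %in% names(loci))) {
    abort(paste("loci must have columns:", paste(needed, collapse = ", ")))
  }
  loci$chrom <- as.character(loci$chrom)
  loci$pos <- as.integer(loci$pos)
  if (nrow(loci) && any(loci$pos < 1L)) abort("positions must be >= 1")
  if (is.null(loci[["id"]]) || anyNA(loci[["id"]])) {
    loci$id <- paste0(loci$chrom, ":", loci$pos)
  }
  loci$id <- as.character(loci$id)
  # sorted by (chrom, pos) within chromosome blocks
  ord <- order(match(loci$chrom, unique(loci$chrom)), loci$pos)
  if (nrow(loci) && !identical(ord, seq_len(nrow(loci)))) {
    abort("loci must be sorted by chromosome then position")
  }
  loci[c("chrom", "pos", "id", "ref", "alt")]
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- if (length(x$geno)) mean(is.na(x$geno)) else 0
  cat(sprintf(
    "<genotype_matrix> %d samples x %d loci (%.1f%% missing calls)\n",
    length(x$samples), nrow(x$loci), 100 * miss
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$samples), nrow(x$loci))

#' Number of samples / loci in a genotype matrix
#' @param gm A [genotype_matrix()].
#' @return Integer count.
#' @export
n_samples <- function(gm) length(gm$samples)

#' @rdname n_samples
#' @export
n_loci <- function(gm) nrow(gm$loci)

#' Subset a genotype matrix by loci
#'
#' @param gm A [genotype_matrix()].
#' @param keep Logical, integer, or character (locus id) index of loci to keep.
#' @return A `genotype_matrix` restricted to the selected loci, in their
#'   original order.
#' @export
subset_loci <- function(gm, keep) {
  if (is.character(keep)) keep <- match(keep, gm$loci$id)
  if (is.logical(keep)) keep <- which(keep)
  keep <- sort(unique(as.integer(keep)))
  genotype_matrix(
    gm$geno[, keep, drop = FALSE],
    gm$loci[keep, ],
    samples = gm$samples,
    depth = gm$depth[, keep, drop = FALSE]
  )
}

#' Identify biallelic single-base SNP loci
#'
#' A locus qualifies when it has exactly one alternate allele and both
#' alleles are single A/C/G/T bases; spanning-deletion (`*`) or symbolic
#' alleles fail the test and are removed by the biallelic filter.
#'
#' @param loci Locus tibble (`ref`, `alt`).
#' @return Logical vector over loci.
#' @export
is_biallelic_snp <- function(loci) {
  one_alt <- !grepl(",", loci$alt, fixed = TRUE)
  snp <- loci$ref %in% c("A", "C", "G", "T") & loci$alt %in% c("A", "C", "G", "T")
  one_alt & snp & loci$ref != loci$alt
}

#' Convert a genotype matrix to a long tibble
#'
#' @param x A [genotype_matrix()].
#' @param ... Unused.
#' @return Tibble with one row per sample-locus call: `sample`, `chrom`,
#'   `pos`, `id`, `genotype`, `depth`.
#' @method as_tibble genotype_matrix
#' @export
as_tibble.genotype_matrix <- function(x, ...) {
  tibble(
    sample = rep(x$samples, times = nrow(x$loci)),
    chrom = rep(x$loci$chrom, each = length(x$samples)),
    pos = rep(x$loci$pos, each = length(x$samples)),
    id = rep(x$loci$id, each = length(x$samples)),
    genotype = as.integer(x$geno),
    depth = as.integer(x$depth)
  )
}

#' Cultivar assignment table
#'
#' Reads or validates the two-column sample-to-cultivar map used for
#' consensus genotyping and structure truth.
#'
#' @param x A data frame (or tibble) with columns `sample` and `variety`, or
#'   a two-column data frame in that order.
#' @return Tibble with columns `sample`, `variety`.
#' @export
variety_assignment <- function(x) {
  x <- tibble::as_tibble(x)
  if (!all(c("sample", "variety") %in% names(x))) {
    if (ncol(x) < 2) abort("variety map needs two columns: sample, variety")
    names(x)[1:2] <- c("sample", "variety")
  }
  x <- distinct(x[c("sample", "variety")])
  conf <- x |> count(.data$sample) |> filter(.data$n > 1L)
  if (nrow(conf)) {
    abort(paste0(
      "samples assigned to more than one cultivar: ",
      paste(conf$sample, collapse = ", ")
    ))
  }
  x$sample <- as.character(x$sample)
  x$variety <- as.character(x$variety)
  x
}

# Align a variety map to a genotype matrix; every sample must be assigned.
match_varieties <- function(gm, varieties) {
  varieties <- variety_assignment(varieties)
  idx <- match(gm$samples, varieties$sample)
  if (anyNA(idx)) {
    abort(paste0(
      "samples missing from variety map: ",
      paste(gm$samples[is.na(idx)], collapse = ", ")
    ))
  }
  varieties$variety[idx]
}
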