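# VCF and table I/O. Reading goes through vcfR; writing emits plain-text
# VCF 4.2 so that fixtures and outputs stay grep-able and round-trip exactly.

#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses GT (required) and per-call DP (optional, 0 when absent) from a
#' VCF 4.x file. `0/0 -> 0`, `0/1`/`1/0 -> 1`, `1/1 -> 2`; phased separators
#' (`|`) are accepted; half-missing calls (`./1`) and any call involving an
#' allele index above 1 become missing. Multi-allelic records are kept and
#' flagged in the locus table (their `alt` holds a comma-separated list) so
#' that the biallelic filter, not the parser, removes and counts them.
#'
#' @param path Path to an uncompressed or gzipped VCF file.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE, checkFile = TRUE)
  samples <- colnames(vcf@gt)[-1]
  if (anyDuplicated(samples)) abort("duplicate sample names in VCF header")
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(vcf@fix) == 0L) {
    loci <- tibble(
      chrom = character(), pos = integer(), id = character(),
      ref = character(), alt = character()
    )
    geno <- matrix(NA_integer_, length(samples), 0L)
    return(genotype_matrix(geno, loci, samples = samples))
  }
  if (!all(grepl("(^|:)GT(:|$)", vcf@gt[, "FORMAT"]))) {
    abort("VCF FORMAT lacks GT on one or more records; genotypes unusable")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  geno <- t(gt_to_code(gt))
  if (is.null(dp)) {
    depth <- matrix(0L, nrow(geno), ncol(geno))
  } else {
    dp[is.na(dp)] <- 0
    depth <- t(matrix(as.integer(dp), nrow(gt), ncol(gt)))
  }
  loci <- tibble(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
      paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"]
    ),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"])
  )
  loci$id <- make.unique(loci$id)
  ord <- order(match(loci$chrom, unique(loci$chrom)), loci$pos)
  genotype_matrix(
    geno[, ord, drop = FALSE],
    loci[ord, ],
    samples = samples,
    depth = depth[, ord, drop = FALSE]
  )
}

# GT string matrix (loci x samples) -> integer codes; strand/phase agnostic.
gt_to_code <- function(gt) {
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  g <- gsub("|", "/", gt, fixed = TRUE)
  code[g %in% c("0/0")] <- 0L
  code[g %in% c("0/1", "1/0")] <- 1L
  code[g %in% c("1/1")] <- 2L
  code
}

code_to_gt <- function(code) {
  out <- rep("./.", length(code))
  out[!is.na(code) & code == 0L] <- "0/0"
  out[!is.na(code) & code == 1L] <- "0/1"
  out[!is.na(code) & code == 2L] <- "1/1"
  out
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Emits VCF 4.2 with GT:DP per call. Re-reading the file with [read_vcf()]
#' reproduces genotype codes, depths, loci and sample order exactly.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=corepanel",
    paste0("##contig=<ID=", unique(gm$loci$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
      gm$samples
    ), collapse = "\t")
  )
  writeLines(header, con)
  m <- nrow(gm$loci)
  if (m > 0L) {
    calls <- matrix(
      paste0(code_to_gt(t(gm$geno)), ":", as.integer(t(gm$depth))),
      nrow = m
    )
    body <- paste(
      gm$loci$chrom, gm$loci$pos, gm$loci$id, gm$loci$ref, gm$loci$alt,
      ".", ".", ".", "GT:DP",
      apply(calls, 1L, paste, collapse = "\t"),
      sep = "\t"
    )
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a sample-to-cultivar map
#'
#' Two-column TSV (`sample`, `variety`/cultivar), header row optional.
#' A sample repeated with conflicting cultivars is an error.
#'
#' @param path TSV file path.
#' @return Tibble with columns `sample`, `variety`.
#' @export
read_variety_map <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = FALSE, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(x) < 2) abort("variety map must have two columns")
  if (nrow(x) && tolower(x[[1]][1]) %in% c("sample", "sample_id", "id")) {
    x <- x[-1, ]
  }
  variety_assignment(setNames(x[1:2], c("sample", "variety")))
}

#' Write a sample-to-cultivar map
#' @param varieties Tibble with columns `sample`, `variety`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_variety_map <- function(varieties, path) {
  readr::write_tsv(variety_assignment(varieties), path, progress = FALSE)
  invisible(path)
}
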