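# Fingerprint strings and p-distance. The fingerprint alphabet per locus:
# homozygous reference -> the reference base, homozygous alternate -> the
# alternate base, heterozygous -> the IUPAC ambiguity code of the two bases
# (R/Y/S/W/K/M), missing -> "-". The mapping is a bijection on non-missing
# codes given locus metadata.

iupac_het <- c(
  AG = "R", GA = "R", CT = "Y", TC = "Y", CG = "S", GC = "S",
  AT = "W", TA = "W", GT = "K", TG = "K", AC = "M", CA = "M"
)

#' Per-sample fingerprint strings
#'
#' Assembles each sample's (or cultivar's) genotypes head to tail into a
#' character string, one character per locus, with missing sites written as
#' `-`.
#'
#' @param x A [genotype_matrix()] or `consensus_matrix`.
#' @return Named character vector of equal-length strings.
#' @export
fingerprint_strings <- function(x) {
  labels <- x$samples %||% x$varieties
  m <- nrow(x$loci)
  if (m == 0L) return(setNames(rep("", length(labels)), labels))
  alphabet <- fingerprint_alphabet(x$loci)
  chars <- matrix("-", nrow(x$geno), m)
  for (code in 0:2) {
    sel <- !is.na(x$geno) & x$geno == code
    chars[sel] <- rep(alphabet[, code + 1L], each = nrow(x$geno))[sel]
  }
  setNames(apply(chars, 1L, paste, collapse = ""), labels)
}

# Per-locus 3-character alphabet: columns code 0, 1, 2.
fingerprint_alphabet <- function(loci) {
  het <- iupac_het[paste0(loci$ref, substr(loci$alt, 1, 1))]
  het[is.na(het)] <- "N" # degenerate/multi-allelic loci have no het code
  cbind(loci$ref, unname(het), substr(loci$alt, 1, 1))
}

#' Decode fingerprint strings back to genotype codes
#'
#' Inverse of [fingerprint_strings()] given the locus table.
#'
#' @param strings Character vector of fingerprints.
#' @param loci The locus tibble the strings were encoded against.
#' @return Integer matrix of genotype codes (`NA` for `-`).
#' @export
fingerprint_codes <- function(strings, loci) {
  alphabet <- fingerprint_alphabet(loci)
  chars <- do.call(rbind, strsplit(strings, ""))
  codes <- matrix(NA_integer_, nrow(chars), ncol(chars))
  for (code in 0:2) {
    codes[chars == rep(alphabet[, code + 1L], each = nrow(chars))] <- code
  }
  rownames(codes) <- names(strings)
  codes
}

#' Pairwise p-distance
#'
#' Fraction of compared positions that differ between two samples;
#' positions missing in either member are excluded. On the same loci and
#' missing-handling, `p_distance = 1 - pairwise_similarity`.
#'
#' @param x A [genotype_matrix()], `consensus_matrix`, or character vector
#'   of fingerprint strings (with `-` as missing).
#' @return Symmetric distance matrix with zero diagonal. A pair with no
#'   compared positions is an error.
#' @export
p_distance <- function(x) {
  if (is.character(x)) {
    codes <- do.call(rbind, strsplit(x, ""))
    codes[codes == "-"] <- NA
    labels <- names(x) %||% paste0("s", seq_along(x))
    num <- matrix(match(codes, sort(unique(as.vector(codes[!is.na(codes)])))),
      nrow(codes), ncol(codes))
    g <- num
  } else {
    g <- x$geno
    labels <- x$samples %||% x$varieties
  }
  if (nrow(g) < 2L) abort("p-distance needs at least two samples")
  obs <- !is.na(g)
  storage.mode(obs) <- "double"
  common <- obs %*% t(obs)
  matches <- matrix(0, nrow(g), nrow(g))
  for (v in sort(unique(as.vector(g[!is.na(g)])))) {
    ind <- (!is.na(g) & g == v)
    storage.mode(ind) <- "double"
    matches <- matches + ind %*% t(ind)
  }
  if (any(common[upper.tri(common)] == 0)) {
    abort("a sample pair shares no compared positions")
  }
  d <- (common - matches) / common
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  d
}
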