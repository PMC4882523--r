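#' Genotype matrix container
#'
#' A light container for diploid SNP-array genotypes: an integer dosage
#' matrix (samples in rows, variants in columns, entries 0/1/2 = copies of
#' the alternate allele, `NA` = missing call) together with a variant table
#' and the ordered sample IDs.
#'
#' @param dosage integer matrix, samples x variants; entries in
#'   \{0, 1, 2, NA\}.
#' @param variants tibble with columns `chrom`, `pos` (1-based bp), `vid`,
#'   `ref`, `alt`, sorted by (`chrom`, `pos`).
#' @param samples character vector of sample IDs, one per dosage row.
#'
#' @return An object of class `geno_mat`.
#' @export
geno_mat <- function(dosage, variants, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  variants <- tibble::as_tibble(variants)
  stopifnot(
    nrow(dosage) == length(samples),
    ncol(dosage) == nrow(variants),
    all(c("chrom", "pos", "vid", "ref", "alt") %in% names(variants))
  )
  if (anyDuplicated(samples)) {
    stop("duplicated sample ID: ", samples[duplicated(samples)][1])
  }
  if (any(variants$pos < 1)) stop("variant positions must be >= 1")
  ord <- order(variants$chrom, variants$pos)
  if (!identical(ord, seq_len(nrow(variants)))) {
    variants <- variants[ord, ]
    dosage <- dosage[, ord, drop = FALSE]
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  dimnames(dosage) <- list(samples, variants$vid)
  structure(list(dosage = dosage, variants = variants, samples = samples),
            class = "geno_mat")
}

#' @export
print.geno_mat <- function(x, ...) {
  cat(sprintf("<geno_mat> %d samples x %d variants (%d chromosome%s)\n",
              length(x$samples), nrow(x$variants),
              dplyr::n_distinct(x$variants$chrom),
              if (dplyr::n_distinct(x$variants$chrom) == 1) "" else "s"))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_mat <- function(x) dim(x$dosage)

#' Phased haplotype container
#'
#' Phased binary haplotypes for one population group: a 0/1 matrix with one
#' row per chromosome copy (two consecutive rows per diploid sample) and one
#' column per variant. No missing alleles are allowed; phased input is a
#' contract of the haplotype-based statistics.
#'
#' @param haplo binary matrix, haplotypes x variants.
#' @param variants variant tibble as in [geno_mat()].
#' @param samples sample IDs; row `2i - 1` and `2i` are the two chromosome
#'   copies of sample `i`.
#'
#' @return An object of class `hap_set`.
#' @export
hap_set <- function(haplo, variants, samples) {
  haplo <- as.matrix(haplo)
  storage.mode(haplo) <- "integer"
  variants <- tibble::as_tibble(variants)
  stopifnot(
    ncol(haplo) == nrow(variants),
    nrow(haplo) == 2L * length(samples)
  )
  if (anyNA(haplo)) stop("phased haplotypes must not contain missing alleles")
  if (!all(haplo %in% c(0L, 1L))) stop("haplotype alleles must be 0 or 1")
  structure(list(haplo = haplo, variants = variants, samples = samples),
            class = "hap_set")
}

#' @export
print.hap_set <- function(x, ...) {
  cat(sprintf("<hap_set> %d haplotypes (%d samples) x %d variants\n",
              nrow(x$haplo), length(x$samples), nrow(x$variants)))
  invisible(x)
}

#' @export
dim.hap_set <- function(x) dim(x$haplo)

#' Collapse a haplotype set to genotype dosages
#'
#' @param h a [hap_set()].
#' @return A [geno_mat()] with dosage = sum of the two chromosome copies.
#' @export
hap_to_geno <- function(h) {
  stopifnot(inherits(h, "hap_set"))
  n <- length(h$samples)
  dos <- h$haplo[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    h$haplo[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  geno_mat(dos, h$variants, h$samples)
}
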