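#' QC configuration
#'
#' Thresholds for per-SNP quality control. The defaults mirror common
#' SNP-array practice for between-breed scans: minor allele frequency
#' strictly above 0.01, per-SNP missing rate strictly below 0.05, and the X
#' chromosome excluded.
#'
#' @param maf_min minimum minor allele frequency (strict `>`).
#' @param missing_max maximum per-SNP missing rate (strict `<`).
#' @param exclude_chroms chromosome labels to drop entirely.
#'
#' @return A `qc_config` list.
#' @export
qc_config <- function(maf_min = 0.01, missing_max = 0.05,
                      exclude_chroms = "X") {
  stopifnot(maf_min >= 0, maf_min <= 0.5, missing_max >= 0, missing_max <= 1)
  structure(list(maf_min = maf_min, missing_max = missing_max,
                 exclude_chroms = as.character(exclude_chroms)),
            class = "qc_config")
}

split_ws <- function(lines) strsplit(trimws(lines), "[ \t]+")

#' Read PLINK text genotypes (PED/MAP)
#'
#' Whitespace-delimited PLINK 1.x text format: the MAP file has four columns
#' (chromosome, variant ID, genetic distance, bp position); the PED file has
#' six leading columns (family ID, individual ID, paternal and maternal IDs,
#' sex, phenotype) followed by two allele columns per variant. The missing
#' genotype code is `0 0`. The sample key is the family and individual ID
#' joined by `_`, except that a family ID of `0` (or equal to the individual
#' ID) leaves the individual ID unchanged.
#'
#' When `alleles` is supplied, dosages count its `alt` allele at each
#' variant; otherwise each variant is oriented to its minor allele computed
#' over all samples in the file (ties broken to the alphabetically later
#' allele), so the same orientation is used for every downstream group.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @param alleles optional tibble with columns `vid`, `ref`, `alt` fixing
#'   the dosage orientation.
#'
#' @return A [geno_mat()].
#' @export
read_plink <- function(ped_path, map_path, alleles = NULL) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)

  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines)) & !startsWith(map_lines, "#")]
  map_tok <- split_ws(map_lines)
  bad <- which(lengths(map_tok) != 4L)
  if (length(bad)) {
    stop("malformed MAP line ", bad[1], ": expected 4 fields, got ",
         lengths(map_tok)[bad[1]])
  }
  map_mat <- do.call(rbind, map_tok)
  variants <- tibble::tibble(
    chrom = map_mat[, 1], vid = map_mat[, 2],
    pos = as.integer(map_mat[, 4])
  )
  m <- nrow(variants)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines)) & !startsWith(ped_lines, "#")]
  ped_tok <- split_ws(ped_lines)
  bad <- which(lengths(ped_tok) != 6L + 2L * m)
  if (length(bad)) {
    stop("malformed PED line ", bad[1], ": expected ", 6L + 2L * m,
         " fields, got ", lengths(ped_tok)[bad[1]])
  }
  ped_mat <- do.call(rbind, ped_tok)
  fid <- ped_mat[, 1]
  iid <- ped_mat[, 2]
  samples <- ifelse(fid == "0" | fid == iid, iid, paste(fid, iid, sep = "_"))
  if (anyDuplicated(samples)) {
    stop("duplicated sample ID in PED: ", samples[duplicated(samples)][1])
  }

  a1 <- ped_mat[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- ped_mat[, 6L + 2L * seq_len(m), drop = FALSE]
  miss <- a1 == "0" | a2 == "0"
  a1[miss] <- NA_character_
  a2[miss] <- NA_character_

  ref <- character(m)
  alt <- character(m)
  dosage <- matrix(NA_integer_, nrow(ped_mat), m)
  if (!is.null(alleles)) {
    alleles <- tibble::as_tibble(alleles)
    idx <- match(variants$vid, alleles$vid)
    if (anyNA(idx)) {
      stop("allele table missing variant: ", variants$vid[which(is.na(idx))[1]])
    }
    ref <- alleles$ref[idx]
    alt <- alleles$alt[idx]
  }
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    if (is.null(alleles)) {
      tab <- sort(table(obs), decreasing = TRUE)
      lv <- names(tab)
      if (length(lv) > 2L) {
        stop("variant ", variants$vid[j], " has >2 alleles in PED")
      }
      # minor = least frequent; tie broken to the alphabetically later allele
      if (length(lv) == 2L && tab[1] == tab[2]) lv <- sort(lv)
      if (length(lv) == 0L) lv <- c("A", "B")
      if (length(lv) == 1L) lv <- c(lv, if (lv == "A") "B" else "A")
      ref[j] <- lv[1]
      alt[j] <- lv[2]
    }
    dosage[, j] <- (a1[, j] == alt[j]) + (a2[, j] == alt[j])
  }
  geno_mat(dosage,
           dplyr::mutate(variants, ref = ref, alt = alt),
           samples)
}

#' Write PLINK text genotypes (PED/MAP)
#'
#' @param g a [geno_mat()].
#' @param ped_path,map_path output paths.
#' @param fid family IDs, recycled; the default `"0"` keeps sample keys
#'   unchanged on re-read.
#' @return Invisibly, the two paths.
#' @export
write_plink <- function(g, ped_path, map_path, fid = "0") {
  stopifnot(inherits(g, "geno_mat"))
  v <- g$variants
  writeLines(paste(v$chrom, v$vid, 0, v$pos, sep = "\t"), map_path)
  n <- length(g$samples)
  fid <- rep_len(fid, n)
  gt <- matrix("0\t0", n, nrow(v))
  for (j in seq_len(nrow(v))) {
    d <- g$dosage[, j]
    gt[, j] <- dplyr::case_when(
      is.na(d) ~ "0\t0",
      d == 0L ~ paste(v$ref[j], v$ref[j], sep = "\t"),
      d == 1L ~ paste(v$ref[j], v$alt[j], sep = "\t"),
      TRUE ~ paste(v$alt[j], v$alt[j], sep = "\t")
    )
  }
  lead <- paste(fid, g$samples, 0, 0, 0, -9, sep = "\t")
  writeLines(paste(lead, apply(gt, 1, paste, collapse = "\t"), sep = "\t"),
             ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a VCF into genotypes or phased haplotypes
#'
#' Only biallelic records are used; multiallelic rows are skipped with a
#' message reporting the count. With `require_phased = TRUE` every genotype
#' must use the `|` separator and the result is a [hap_set()] preserving the
#' within-sample chromosome order; otherwise a [geno_mat()] of alt-allele
#' dosages is returned.
#'
#' @param vcf_path path to a VCF (plain or bgzipped).
#' @param require_phased logical; demand fully phased GT fields.
#' @return A [geno_mat()] or, with `require_phased = TRUE`, a [hap_set()].
#' @export
read_vcf <- function(vcf_path, require_phased = FALSE) {
  if (!file.exists(vcf_path)) stop("VCF file not found: ", vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  bi <- vcfR::is.biallelic(vcf)
  if (any(!bi)) {
    message("skipped ", sum(!bi), " multiallelic record(s)")
    vcf <- vcf[bi, ]
  }
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = 7,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  variants <- tibble::tibble(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    vid = fix[, "ID"], ref = fix[, "REF"], alt = fix[, "ALT"]
  )
  gt <- vcfR::extract.gt(vcf, element = "GT")  # variants x samples
  samples <- colnames(gt)
  core <- sub(":.*$", "", gt)

  if (require_phased) {
    unph <- !is.na(core) & !grepl("|", core, fixed = TRUE)
    miss <- is.na(core) | grepl("\\.", core)
    if (any(unph)) {
      idx <- which(unph, arr.ind = TRUE)[1, ]
      stop("unphased genotype at ", variants$chrom[idx[1]], ":",
           variants$pos[idx[1]], " sample ", samples[idx[2]],
           " under require_phased")
    }
    if (any(miss)) {
      idx <- which(miss, arr.ind = TRUE)[1, ]
      stop("missing genotype at ", variants$chrom[idx[1]], ":",
           variants$pos[idx[1]], " sample ", samples[idx[2]],
           " in phased input")
    }
    h1 <- as.integer(substr(core, 1, 1))
    h2 <- as.integer(substr(core, 3, 3))
    n <- length(samples)
    haplo <- matrix(0L, 2L * n, nrow(variants))
    haplo[seq(1, 2 * n, 2), ] <- t(matrix(h1, nrow(variants), n))
    haplo[seq(2, 2 * n, 2), ] <- t(matrix(h2, nrow(variants), n))
    return(hap_set(haplo, variants, samples))
  }

  miss <- is.na(core) | grepl("\\.", core)
  d1 <- suppressWarnings(as.integer(substr(core, 1, 1)))
  d2 <- suppressWarnings(as.integer(substr(core, 3, 3)))
  dos <- matrix(d1 + d2, nrow(variants), length(samples))
  dos[matrix(miss, nrow(variants), length(samples))] <- NA_integer_
  geno_mat(t(dos), variants, samples)
}

#' Write genotypes or haplotypes as VCF
#'
#' @param x a [geno_mat()] (unphased `/` genotypes, `./.` for missing) or a
#'   [hap_set()] (phased `|` genotypes).
#' @param path output path (plain text).
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(x, path) {
  v <- x$variants
  contigs <- vapply(unique(v$chrom), function(ch) {
    sprintf("##contig=<ID=%s,length=%d>", ch,
            max(v$pos[v$chrom == ch]) + 1L)
  }, "")
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           contigs,
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$samples), collapse = "\t"))
  if (inherits(x, "hap_set")) {
    n <- length(x$samples)
    h1 <- x$haplo[seq(1, 2 * n, 2), , drop = FALSE]
    h2 <- x$haplo[seq(2, 2 * n, 2), , drop = FALSE]
    gt <- matrix(paste(h1, h2, sep = "|"), n, nrow(v))
  } else if (inherits(x, "geno_mat")) {
    d <- x$dosage
    gt <- matrix("./.", nrow(d), ncol(d))
    gt[!is.na(d) & d == 0L] <- "0/0"
    gt[!is.na(d) & d == 1L] <- "0/1"
    gt[!is.na(d) & d == 2L] <- "1/1"
  } else {
    stop("x must be a geno_mat or hap_set")
  }
  body <- paste(v$chrom, v$pos, v$vid, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write a population map
#'
#' Three tab-separated columns: sample, breed, group (e.g. `G1` for the
#' highland group, `G2` for the lowland group). Lines starting with `#` are
#' comments.
#'
#' @param path file path.
#' @return `read_pop_map()` returns a tibble with columns `sample`, `breed`,
#'   `group`.
#' @export
read_pop_map <- function(path) {
  pm <- readr::read_tsv(path, comment = "#",
                        col_names = c("sample", "breed", "group"),
                        col_types = "ccc", progress = FALSE)
  if (anyDuplicated(pm$sample)) {
    stop("duplicated sample in population map: ",
         pm$sample[duplicated(pm$sample)][1])
  }
  pm
}

#' @rdname read_pop_map
#' @param pm population-map tibble.
#' @export
write_pop_map <- function(pm, path) {
  writeLines(c("#sample\tbreed\tgroup",
               paste(pm$sample, pm$breed, pm$group, sep = "\t")), path)
  invisible(path)
}

col_missing_rate <- function(dosage) unname(colMeans(is.na(dosage)))

col_alt_freq <- function(dosage) {
  n2 <- 2 * colSums(!is.na(dosage))
  cnt <- colSums(dosage, na.rm = TRUE)
  unname(ifelse(n2 == 0, NA_real_, cnt / n2))
}

#' Apply per-SNP quality control
#'
#' Retains SNPs with minor allele frequency strictly above `maf_min`
#' (computed over all samples), missing rate strictly below `missing_max`,
#' and chromosome outside `exclude_chroms`. Each removed SNP is attributed
#' to its first failing criterion in the order MAF, missingness, chromosome.
#'
#' @param g a [geno_mat()].
#' @param cfg a [qc_config()].
#' @return A list of class `qc_result` with elements `genotypes` (filtered
#'   [geno_mat()]) and `report` (tibble of per-criterion removal counts).
#' @export
apply_qc <- function(g, cfg = qc_config()) {
  stopifnot(inherits(g, "geno_mat"), inherits(cfg, "qc_config"))
  if (ncol(g$dosage) == 0L) stop("empty genotype matrix")
  p <- col_alt_freq(g$dosage)
  maf <- pmin(p, 1 - p)
  fail_maf <- is.na(maf) | maf <= cfg$maf_min
  fail_miss <- col_missing_rate(g$dosage) >= cfg$missing_max
  fail_chrom <- g$variants$chrom %in% cfg$exclude_chroms

  first_fail <- dplyr::case_when(
    fail_maf ~ "maf",
    fail_miss ~ "missingness",
    fail_chrom ~ "chromosome",
    TRUE ~ "retained"
  )
  keep <- first_fail == "retained"
  if (!any(keep)) stop("QC removed every SNP; check thresholds and input")

  report <- tibble::tibble(
    criterion = c("input", "maf", "missingness", "chromosome", "retained"),
    n = c(length(keep), sum(first_fail == "maf"),
          sum(first_fail == "missingness"),
          sum(first_fail == "chromosome"), sum(keep))
  )
  out <- geno_mat(g$dosage[, keep, drop = FALSE], g$variants[keep, ],
                  g$samples)
  structure(list(genotypes = out, report = report), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result>\n")
  print(x$report)
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param qc a `qc_result` from [apply_qc()].
#' @param path output path.
#' @export
write_qc_report <- function(qc, path) {
  writeLines(c("#criterion\tn",
               paste(qc$report$criterion, qc$report$n, sep = "\t")), path)
  invisible(path)
}

#' Per-breed or per-group allele frequencies
#'
#' Alt-allele frequency per analysis unit: alt allele count over twice the
#' non-missing sample count. A unit with zero non-missing calls at a SNP
#' gets `NA`, never 0.
#'
#' @param g a [geno_mat()].
#' @param pm population map tibble (`sample`, `breed`, `group`).
#' @param by `"group"` or `"breed"`.
#' @return A tibble with one row per (variant, unit): `vid`, `chrom`, `pos`,
#'   `unit`, `n` (non-missing samples), `p_alt`.
#' @export
allele_frequencies <- function(g, pm, by = c("group", "breed")) {
  by <- match.arg(by)
  stopifnot(inherits(g, "geno_mat"))
  missing_pm <- setdiff(g$samples, pm$sample)
  if (length(missing_pm)) {
    stop("samples absent from population map: ",
         paste(head(missing_pm, 3), collapse = ", "))
  }
  unit <- pm[[by]][match(g$samples, pm$sample)]
  purrr::map_dfr(sort(unique(unit)), function(u) {
    d <- g$dosage[unit == u, , drop = FALSE]
    tibble::tibble(
      vid = g$variants$vid, chrom = g$variants$chrom, pos = g$variants$pos,
      unit = u, n = unname(colSums(!is.na(d))), p_alt = col_alt_freq(d)
    )
  })
}
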