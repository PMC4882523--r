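#' Selection-scan configuration
#'
#' @param fst_quantile upper-tail fraction for the F_ST scan (default top
#'   1\%).
#' @param xpehh_quantile upper-tail fraction for the XP-EHH scan (default
#'   top 5\%).
#' @param ehh_cutoff EHH level at which haplotype extension stops and the
#'   integration is truncated.
#' @param max_extension_bp maximum one-sided extension from the core (bp).
#' @param max_gap_bp inter-SNP gap that truncates the extension (bp).
#' @param gene_flank_bp flank added to gene intervals when annotating
#'   candidate SNPs (bp).
#' @return A `scan_config` list.
#' @export
scan_config <- function(fst_quantile = 0.01, xpehh_quantile = 0.05,
                        ehh_cutoff = 0.05, max_extension_bp = 1e6,
                        max_gap_bp = 2e5, gene_flank_bp = 25000) {
  stopifnot(fst_quantile > 0, fst_quantile < 0.5,
            xpehh_quantile > 0, xpehh_quantile < 0.5,
            ehh_cutoff > 0, ehh_cutoff < 1,
            max_extension_bp > 0, max_gap_bp > 0, gene_flank_bp >= 0)
  structure(list(fst_quantile = fst_quantile,
                 xpehh_quantile = xpehh_quantile,
                 ehh_cutoff = ehh_cutoff,
                 max_extension_bp = max_extension_bp,
                 max_gap_bp = max_gap_bp,
                 gene_flank_bp = gene_flank_bp),
            class = "scan_config")
}

# per-locus n (non-missing diploids), alt frequency and observed
# heterozygote proportion for one population's dosage submatrix
locus_summaries <- function(dosage) {
  n <- unname(colSums(!is.na(dosage)))
  p <- col_alt_freq(dosage)
  h <- ifelse(n == 0, NA_real_,
              unname(colSums(dosage == 1L, na.rm = TRUE)) / n)
  list(n = n, p = p, h = h)
}

#' Weir-Cockerham variance components for two populations
#'
#' Single-locus variance components for r = 2 populations: `a` (among
#' populations), `b` (among individuals within populations) and `c` (within
#' individuals), with theta = a/(a + b + c). All arguments are vectorized
#' over loci.
#'
#' The intermediates are the weighted mean sample size `n_bar`, the
#' size-variance correction `n_c`, the weighted mean allele frequency
#' `p_bar`, the among-population frequency variance `s2`, and the weighted
#' mean observed heterozygosity `h_bar`.
#'
#' @param n1,n2 diploid sample sizes with non-missing calls.
#' @param p1,p2 alt-allele frequencies.
#' @param h1,h2 observed heterozygote proportions.
#' @return Tibble: `a`, `b`, `c`, `theta`, `defined`. Loci where the total
#'   variance a + b + c is zero (e.g. monomorphic) or a sample size is below
#'   2 are flagged `defined = FALSE` with `theta = NA`.
#' @export
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  n_bar <- (n1 + n2) / r
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)

  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) *
       (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2

  ok_n <- !is.na(n1) & !is.na(n2) & n1 >= 2 & n2 >= 2 &
    !is.na(p1) & !is.na(p2) & !is.na(h1) & !is.na(h2)
  denom <- a + b + cc
  defined <- ok_n & !is.na(denom) & denom != 0
  theta <- ifelse(defined, a / denom, NA_real_)
  tibble::tibble(a = ifelse(ok_n, a, NA_real_),
                 b = ifelse(ok_n, b, NA_real_),
                 c = ifelse(ok_n, cc, NA_real_),
                 theta = theta, defined = defined)
}

#' Per-SNP F_ST scan between two groups
#'
#' Computes Weir-Cockerham components per SNP between the G1 (highland,
#' observed) and G2 (lowland, reference) groups, using non-missing genotypes
#' only.
#'
#' @param g a [geno_mat()] (after QC).
#' @param pm population map tibble with a `group` column containing `"G1"`
#'   and `"G2"`.
#' @return Tibble: variant columns plus `n1`, `p1`, `n2`, `p2`, `a`, `b`,
#'   `c`, `theta`, `defined`.
#' @export
fst_scan <- function(g, pm) {
  stopifnot(inherits(g, "geno_mat"))
  grp <- pm$group[match(g$samples, pm$sample)]
  if (!any(grp == "G1", na.rm = TRUE) || !any(grp == "G2", na.rm = TRUE)) {
    stop("both groups G1 and G2 must be non-empty")
  }
  s1 <- locus_summaries(g$dosage[which(grp == "G1"), , drop = FALSE])
  s2 <- locus_summaries(g$dosage[which(grp == "G2"), , drop = FALSE])
  comp <- wc_components(s1$n, s1$p, s1$h, s2$n, s2$p, s2$h)
  dplyr::bind_cols(g$variants,
                   tibble::tibble(n1 = s1$n, p1 = s1$p, n2 = s2$n,
                                  p2 = s2$p),
                   comp)
}

chrom_bounds <- function(variants) {
  idx <- seq_len(nrow(variants))
  lo <- stats::ave(idx, variants$chrom, FUN = min)
  hi <- stats::ave(idx, variants$chrom, FUN = max)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

#' Extended haplotype homozygosity decay from a core SNP
#'
#' All haplotypes are pooled at the core (the cross-population convention):
#' at each successive SNP outward, haplotypes are partitioned by identity of
#' the extended segment from the core to that SNP, and EHH is the
#' probability that two randomly chosen haplotypes are identical over the
#' segment. The curve starts at (0, 1) and is truncated when it drops below
#' `ehh_cutoff` (point kept, reason `"cutoff"`), when the extension exceeds
#' `max_extension_bp` (`"max_extension"`), when an inter-SNP gap exceeds
#' `max_gap_bp` (`"gap"`), or at the chromosome end (`"end"`).
#'
#' @param h a [hap_set()].
#' @param core_index variant column index of the core SNP.
#' @param side `"left"`, `"right"` or `"both"`.
#' @param cfg a [scan_config()].
#' @return A tibble of class `ehh_curve`: `side`, `dist` (bp from core),
#'   `ehh`, with truncation reasons in the `"reason"` attribute and the core
#'   index in `"core_index"`.
#' @export
ehh <- function(h, core_index, side = c("both", "left", "right"),
                cfg = scan_config()) {
  side <- match.arg(side)
  stopifnot(inherits(h, "hap_set"))
  m <- nrow(h$variants)
  if (core_index < 1 || core_index > m) {
    stop("core_index out of range: ", core_index)
  }
  if (nrow(h$haplo) < 2) stop("need at least 2 haplotypes")
  bounds <- chrom_bounds(h$variants)
  pos <- as.numeric(h$variants$pos)
  sides <- if (side == "both") c("left", "right") else side
  reasons <- character(0)
  out <- purrr::map_dfr(sides, function(s) {
    dir <- if (s == "left") -1L else 1L
    res <- .ehh_side_cpp(h$haplo, core_index, dir, pos,
                         bounds$lo[core_index], bounds$hi[core_index],
                         cfg$ehh_cutoff, cfg$max_extension_bp,
                         cfg$max_gap_bp)
    reasons[[s]] <<- res$reason
    tibble::tibble(side = s, dist = res$dist, ehh = res$ehh)
  })
  structure(out, reason = reasons, core_index = core_index,
            class = c("ehh_curve", class(out)))
}

trapezoid_above_cutoff <- function(dist, ehh_vals, cutoff) {
  v <- pmax(ehh_vals - cutoff, 0)
  if (length(v) < 2) return(0)
  sum(diff(dist) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' Integrated EHH (iHH)
#'
#' Trapezoidal integral of (EHH - cutoff), clipped at zero, over physical
#' distance, summed over the left and right sides of the decay curve. The
#' result is flagged undefined when either side was truncated before
#' decaying below the cutoff (by span, gap or chromosome end), matching the
#' "null" cross-population scores of array-edge or unresolved cores.
#'
#' @param curve an `ehh_curve` from [ehh()] with both sides.
#' @param cfg the [scan_config()] used to build the curve.
#' @return A single area in bp units with attribute `"defined"`.
#' @export
ihh <- function(curve, cfg = scan_config()) {
  stopifnot(inherits(curve, "ehh_curve"))
  reasons <- attr(curve, "reason")
  defined <- all(c("left", "right") %in% names(reasons)) &&
    all(reasons == "cutoff")
  area <- sum(vapply(unique(curve$side), function(s) {
    sel <- curve$side == s
    trapezoid_above_cutoff(curve$dist[sel], curve$ehh[sel], cfg$ehh_cutoff)
  }, 0))
  structure(if (defined) area else 0, defined = defined,
            reason = reasons)
}

# fast path used by xpehh_scan: both sides for one core, plain numerics
ihh_at_core <- function(haplo, pos, core, lo, hi, cfg) {
  l <- .ehh_side_cpp(haplo, core, -1L, pos, lo, hi, cfg$ehh_cutoff,
                     cfg$max_extension_bp, cfg$max_gap_bp)
  r <- .ehh_side_cpp(haplo, core, 1L, pos, lo, hi, cfg$ehh_cutoff,
                     cfg$max_extension_bp, cfg$max_gap_bp)
  if (l$reason != "cutoff" || r$reason != "cutoff") {
    return(c(0, 0))
  }
  c(trapezoid_above_cutoff(l$dist, l$ehh, cfg$ehh_cutoff) +
      trapezoid_above_cutoff(r$dist, r$ehh, cfg$ehh_cutoff), 1)
}

#' Cross-population EHH (XP-EHH) scan
#'
#' For each core SNP, EHH decay is computed on all haplotypes of the
#' observed (highland, G1) and reference (lowland, G2) populations
#' separately; the raw score is `ln(iHH_obs / iHH_ref)` and standardized
#' scores are (raw - mean)/sd over all defined raw scores genome-wide.
#' Positive scores indicate long-range haplotype homozygosity (selection) in
#' the observed population; negative scores point to the reference
#' population. Cores where either iHH is undefined or zero carry
#' `defined = FALSE` ("null" scores) with a reason code.
#'
#' @param h_obs,h_ref [hap_set()]s sharing an identical variant list.
#' @param cfg a [scan_config()].
#' @return Tibble: variant columns plus `ihh_obs`, `ihh_ref`, `raw`, `std`,
#'   `defined`, `reason`.
#' @export
xpehh_scan <- function(h_obs, h_ref, cfg = scan_config()) {
  stopifnot(inherits(h_obs, "hap_set"), inherits(h_ref, "hap_set"))
  if (!identical(h_obs$variants[c("chrom", "pos", "vid")],
                 h_ref$variants[c("chrom", "pos", "vid")])) {
    stop("observed and reference haplotype sets must share the variant list")
  }
  v <- h_obs$variants
  m <- nrow(v)
  bounds <- chrom_bounds(v)
  pos <- as.numeric(v$pos)

  ihh_obs <- numeric(m)
  ihh_ref <- numeric(m)
  def_obs <- logical(m)
  def_ref <- logical(m)
  for (i in seq_len(m)) {
    o <- ihh_at_core(h_obs$haplo, pos, i, bounds$lo[i], bounds$hi[i], cfg)
    r <- ihh_at_core(h_ref$haplo, pos, i, bounds$lo[i], bounds$hi[i], cfg)
    ihh_obs[i] <- o[1]; def_obs[i] <- o[2] == 1
    ihh_ref[i] <- r[1]; def_ref[i] <- r[2] == 1
  }
  reason <- dplyr::case_when(
    !def_obs | !def_ref ~ "undecayed",
    ihh_obs == 0 | ihh_ref == 0 ~ "zero_ihh",
    TRUE ~ "ok"
  )
  defined <- reason == "ok"
  raw <- ifelse(defined, log(ihh_obs / ihh_ref), NA_real_)
  mu <- mean(raw[defined])
  sdev <- stats::sd(raw[defined])
  std <- if (isTRUE(sdev > 0)) (raw - mu) / sdev else raw * NA_real_
  dplyr::bind_cols(v, tibble::tibble(ihh_obs = ihh_obs, ihh_ref = ihh_ref,
                                     raw = raw, std = std,
                                     defined = defined, reason = reason))
}

#' Upper-tail quantile selection with boundary ties
#'
#' Selects the `ceiling(q * M)` largest defined values (M = number of
#' defined values); ties at the boundary are all included, so the selected
#' set can exceed `ceiling(q * M)`. The reported threshold is the smallest
#' selected value.
#'
#' @param values numeric vector; `NA` marks undefined entries unless
#'   `defined` is given.
#' @param q upper-tail fraction, in (0, 0.5).
#' @param defined optional logical vector of defined flags.
#' @return List: `indices` (into `values`), `threshold`, `n_target`
#'   (ceiling count before ties), `n_selected`.
#' @export
top_quantile <- function(values, q, defined = !is.na(values)) {
  if (q <= 0 || q >= 0.5) stop("q must be in (0, 0.5)")
  vals <- values[defined]
  M <- length(vals)
  if (M < 1) stop("no defined values")
  k <- ceiling(q * M)
  threshold <- sort(vals, decreasing = TRUE)[k]
  idx <- which(defined & values >= threshold)
  list(indices = idx, threshold = threshold, n_target = k,
       n_selected = length(idx))
}

#' Combine F_ST and XP-EHH tails into a candidate set
#'
#' Candidates are the intersection of the two upper tails plus a rescue set:
#' SNPs in the F_ST tail whose XP-EHH score is undefined ("null"). The two
#' sets are disjoint by construction and their union is the candidate list.
#'
#' @param fst_sel integer indices in the F_ST upper tail.
#' @param xpehh_sel integer indices in the XP-EHH upper tail.
#' @param xpehh_defined logical vector over the SNP universe.
#' @return List of class `candidate_set`: `intersect_snps`, `rescue_snps`,
#'   `union`.
#' @export
build_candidates <- function(fst_sel, xpehh_sel, xpehh_defined) {
  intersect_snps <- sort(intersect(fst_sel, xpehh_sel))
  rescue_snps <- sort(fst_sel[!xpehh_defined[fst_sel]])
  stopifnot(length(intersect(intersect_snps, rescue_snps)) == 0)
  structure(list(intersect_snps = intersect_snps,
                 rescue_snps = rescue_snps,
                 union = sort(union(intersect_snps, rescue_snps))),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf(
    "<candidate_set> %d intersection + %d rescue = %d candidate SNPs\n",
    length(x$intersect_snps), length(x$rescue_snps), length(x$union)))
  invisible(x)
}

#' Read gene intervals from GFF3 or BED
#'
#' GFF3 is parsed with \pkg{rtracklayer} and filtered to `gene` features;
#' the symbol is taken from the `Name` attribute, falling back to `gene_id`
#' then `ID`. BED input must have at least 6 columns (chrom, start, end,
#' name, score, strand); BED starts are converted to 1-based inclusive.
#'
#' @param path annotation path ending in `.gff3`/`.gff` or `.bed`.
#' @return Tibble: `chrom`, `start`, `end`, `strand`, `gene` (1-based
#'   inclusive coordinates).
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    tok <- split_ws(lines)
    bad <- which(lengths(tok) < 6L)
    if (length(bad)) {
      stop("malformed BED line ", bad[1], ": expected >= 6 fields")
    }
    bm <- do.call(rbind, tok)
    return(tibble::tibble(chrom = bm[, 1],
                          start = as.integer(bm[, 2]) + 1L,
                          end = as.integer(bm[, 3]),
                          strand = bm[, 6], gene = bm[, 4]))
  }
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("GFF3 parse error in ", path, ": ",
                                          conditionMessage(e)))
  gr <- gr[gr$type == "gene"]
  meta <- as.data.frame(gr)
  sym <- meta$Name
  if (is.null(sym)) sym <- meta$gene_id
  if (is.null(sym)) sym <- meta$ID
  sym[is.na(sym)] <- meta$ID[is.na(sym)]
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start = GenomicRanges::start(gr),
                 end = GenomicRanges::end(gr),
                 strand = as.character(GenomicRanges::strand(gr)),
                 gene = as.character(sym))
}

#' Annotate candidate SNPs with overlapping genes
#'
#' A gene is reported when any candidate SNP lies within
#' `[start - flank_bp, end + flank_bp]` (1-based inclusive); genes are
#' deduplicated by symbol and list their supporting SNPs.
#'
#' @param snps tibble with `chrom`, `pos`, `vid` (candidate SNPs).
#' @param genes tibble as from [read_gene_annotation()].
#' @param flank_bp symmetric flank in bp.
#' @return Tibble: `gene`, `chrom`, `start`, `end`, `strand`, `n_snps`,
#'   `snps` (comma-separated supporting variant IDs).
#' @export
annotate_genes <- function(snps, genes, flank_bp = 25000) {
  snps <- tibble::as_tibble(snps)
  genes <- tibble::as_tibble(genes)
  if (nrow(snps) == 0 || nrow(genes) == 0) {
    return(tibble::tibble(gene = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), n_snps = integer(),
                          snps = character()))
  }
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos, snps$pos))
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(genes$start - flank_bp, 1L),
                     genes$end + flank_bp))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  if (length(hits) == 0) {
    return(annotate_genes(snps[0, ], genes, flank_bp))
  }
  tibble::tibble(
    gene = genes$gene[S4Vectors::subjectHits(hits)],
    vid = snps$vid[S4Vectors::queryHits(hits)],
    chrom = genes$chrom[S4Vectors::subjectHits(hits)],
    start = genes$start[S4Vectors::subjectHits(hits)],
    end = genes$end[S4Vectors::subjectHits(hits)],
    strand = genes$strand[S4Vectors::subjectHits(hits)]
  ) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(chrom = dplyr::first(.data$chrom),
                     start = min(.data$start), end = max(.data$end),
                     strand = dplyr::first(.data$strand),
                     n_snps = dplyr::n_distinct(.data$vid),
                     snps = paste(unique(.data$vid), collapse = ","),
                     .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$start)
}
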