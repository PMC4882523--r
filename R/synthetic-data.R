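#' Simulation configuration
#'
#' Parameters for the two-group synthetic study that stands in for the
#' undeposited SNP-array genotypes: a highland group (G1) and a lowland
#' group (G2) of diploid samples, SNPs placed on a few chromosomes,
#' Balding-Nichols background differentiation, an optional localized
#' selective sweep in G1 (a shared long haplotype driven to high frequency),
#' and phenotypes with additive genotype and sex effects.
#'
#' Defaults are the package's reference study conditions: 2 x 40 diploids,
#' 10,000 SNPs on three 50-Mb chromosomes (~15 kb spacing), background
#' F = 0.08, and a sweep to frequency 0.9 over a 1-Mb span centred on
#' chromosome 1.
#'
#' @param n_g1,n_g2 diploid sample counts per group.
#' @param n_snps total SNP count.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param fst_background Balding-Nichols differentiation parameter F in
#'   (0, 1).
#' @param sweep `NULL` for a null simulation, or a list with `chrom`, `pos`
#'   (bp), `freq` (final G1 frequency of the swept haplotype) and `span_bp`
#'   (length of the shared haplotype).
#' @param rho latent first-order copying coefficient controlling baseline
#'   LD between adjacent SNPs.
#' @param missing_rate genotype missingness applied to the dosage matrix
#'   only (haplotypes stay complete, as phased input requires).
#' @param phenotype_effect per-alt-copy shift of the causal traits (RBC,
#'   MCV, MCH), in trait units.
#' @param sex_effect additive shift for males, all traits.
#' @param noise_sd residual standard deviation, all traits.
#' @param seed integer; fully determines every generated object.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_g1 = 40, n_g2 = 40, n_snps = 10000,
                       chrom_lengths = c(chr1 = 5e7, chr2 = 5e7,
                                         chr3 = 5e7),
                       fst_background = 0.08,
                       sweep = list(chrom = "chr1", pos = 2.5e7,
                                    freq = 0.9, span_bp = 1e6),
                       rho = 0.3, missing_rate = 0.01,
                       phenotype_effect = 1, sex_effect = 0.5,
                       noise_sd = 1, seed = 1) {
  stopifnot(n_g1 > 0, n_g2 > 0, n_snps > 0, all(chrom_lengths > 0),
            fst_background > 0, fst_background < 1,
            rho >= 0, rho < 1, missing_rate >= 0, missing_rate < 1,
            noise_sd >= 0)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  if (!is.null(sweep)) {
    stopifnot(sweep$chrom %in% names(chrom_lengths),
              sweep$freq > 0, sweep$freq <= 1, sweep$span_bp > 0)
    if (sweep$pos - sweep$span_bp / 2 < 1 ||
        sweep$pos + sweep$span_bp / 2 > chrom_lengths[[sweep$chrom]]) {
      stop("sweep span exceeds the chromosome")
    }
  }
  structure(list(n_g1 = as.integer(n_g1), n_g2 = as.integer(n_g2),
                 n_snps = as.integer(n_snps),
                 chrom_lengths = chrom_lengths,
                 fst_background = fst_background, sweep = sweep,
                 rho = rho, missing_rate = missing_rate,
                 phenotype_effect = phenotype_effect,
                 sex_effect = sex_effect, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate per-SNP ancestral and group allele frequencies
#'
#' Ancestral frequencies are Uniform(0.05, 0.95); each group's frequency is
#' drawn independently from Beta(p(1-F)/F, (1-p)(1-F)/F) (the
#' Balding-Nichols model), so the expected Weir-Cockerham differentiation
#' between the groups is close to F. The SNP nearest the sweep position has
#' its G1 frequency overridden to the sweep frequency.
#'
#' @param cfg a [sim_config()].
#' @return Tibble: `chrom`, `pos`, `vid`, `ref`, `alt`, `p_anc`, `p_g1`,
#'   `p_g2`, `is_sweep`. Called inside [simulate_study()]'s seed scope; call
#'   via `withr::with_seed()` for standalone determinism.
#' @export
simulate_frequencies <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lens <- cfg$chrom_lengths
  n_per <- pmax(1L, round(cfg$n_snps * lens / sum(lens)))
  # fix rounding drift on the first chromosome
  n_per[1] <- n_per[1] + cfg$n_snps - sum(n_per)
  variants <- purrr::map_dfr(seq_along(lens), function(k) {
    tibble::tibble(chrom = names(lens)[k],
                   pos = sort(sample.int(lens[[k]], n_per[k])))
  })
  m <- nrow(variants)
  variants$vid <- sprintf("snp%05d", seq_len(m))
  variants$ref <- "A"
  variants$alt <- "G"

  f <- cfg$fst_background
  p_anc <- stats::runif(m, 0.05, 0.95)
  shp <- (1 - f) / f
  p_g1 <- stats::rbeta(m, p_anc * shp, (1 - p_anc) * shp)
  p_g2 <- stats::rbeta(m, p_anc * shp, (1 - p_anc) * shp)
  is_sweep <- rep(FALSE, m)
  if (!is.null(cfg$sweep)) {
    on_chr <- which(variants$chrom == cfg$sweep$chrom)
    core <- on_chr[which.min(abs(variants$pos[on_chr] - cfg$sweep$pos))]
    is_sweep[core] <- TRUE
    p_g1[core] <- cfg$sweep$freq
  }
  dplyr::bind_cols(variants,
                   tibble::tibble(p_anc = p_anc, p_g1 = p_g1, p_g2 = p_g2,
                                  is_sweep = is_sweep))
}

# latent AR(1) copying process: one 0/1 haplotype matrix (H x m) with
# marginal column frequencies p and geometrically decaying LD; the latent
# chain restarts at chromosome boundaries
draw_haplotypes <- function(n_hap, p, chrom, rho) {
  m <- length(p)
  Z <- matrix(0, n_hap, m)
  Z[, 1] <- stats::rnorm(n_hap)
  if (m > 1) {
    new_chrom <- c(TRUE, chrom[-1] != chrom[-m])
    for (j in 2:m) {
      e <- stats::rnorm(n_hap)
      Z[, j] <- if (new_chrom[j]) e
                else rho * Z[, j - 1] + sqrt(1 - rho^2) * e
    }
  }
  H <- matrix(0L, n_hap, m)
  U <- stats::pnorm(Z)
  for (j in seq_len(m)) H[, j] <- as.integer(U[, j] < p[j])
  H
}

#' Simulate phased haplotypes and genotypes for both groups
#'
#' Background haplotypes are drawn SNP-wise from each group's frequencies
#' with a first-order latent copying process (coefficient `rho`) creating
#' baseline LD. The sweep is modelled mechanically: a fraction of G1
#' haplotypes equal to the sweep frequency is forced to carry one shared
#' donor haplotype across the sweep span, the donor carrying the alternate
#' allele at the core and non-carriers the reference allele, so the core
#' frequency is exact. Genotypes are formed by pairing consecutive
#' haplotypes; the missingness mask applies to the genotype matrix only.
#'
#' @param cfg a [sim_config()].
#' @param freqs output of [simulate_frequencies()].
#' @return List: `hap_g1`, `hap_g2` ([hap_set()]s), `genotypes`
#'   ([geno_mat()] over all samples), `pop_map` (tibble), `core_index`
#'   (sweep core column or `NA`).
#' @export
simulate_haplotypes <- function(cfg, freqs) {
  stopifnot(inherits(cfg, "sim_config"))
  m <- nrow(freqs)
  variants <- freqs[c("chrom", "pos", "vid", "ref", "alt")]
  h1 <- draw_haplotypes(2L * cfg$n_g1, freqs$p_g1, freqs$chrom, cfg$rho)
  h2 <- draw_haplotypes(2L * cfg$n_g2, freqs$p_g2, freqs$chrom, cfg$rho)

  core <- NA_integer_
  if (!is.null(cfg$sweep)) {
    core <- which(freqs$is_sweep)
    span <- which(freqs$chrom == cfg$sweep$chrom &
                    abs(freqs$pos - freqs$pos[core]) <= cfg$sweep$span_bp / 2)
    donor <- h1[1, span]
    donor[span == core] <- 1L
    n_carrier <- round(cfg$sweep$freq * nrow(h1))
    carriers <- sample.int(nrow(h1), n_carrier)
    h1[carriers, span] <- rep(donor, each = n_carrier)
    h1[setdiff(seq_len(nrow(h1)), carriers), core] <- 0L
  }

  samples_g1 <- sprintf("G1_%03d", seq_len(cfg$n_g1))
  samples_g2 <- sprintf("G2_%03d", seq_len(cfg$n_g2))
  hap_g1 <- hap_set(h1, variants, samples_g1)
  hap_g2 <- hap_set(h2, variants, samples_g2)

  dos <- rbind(hap_to_geno(hap_g1)$dosage, hap_to_geno(hap_g2)$dosage)
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(length(dos)) < cfg$missing_rate,
                   nrow(dos), ncol(dos))
    dos[mask] <- NA_integer_
  }
  genotypes <- geno_mat(dos, variants, c(samples_g1, samples_g2))

  breeds_g1 <- c("TIBQ", "TIBS", "TIBN")
  breeds_g2 <- c("HUS", "TON", "LTH", "LOP")
  pop_map <- tibble::tibble(
    sample = c(samples_g1, samples_g2),
    breed = c(rep_len(breeds_g1, cfg$n_g1), rep_len(breeds_g2, cfg$n_g2)),
    group = rep(c("G1", "G2"), c(cfg$n_g1, cfg$n_g2))
  )
  list(hap_g1 = hap_g1, hap_g2 = hap_g2, genotypes = genotypes,
       pop_map = pop_map, core_index = core)
}

#' Simulate haematological phenotypes
#'
#' Each trait is baseline + genotype effect (causal traits only) + sex
#' effect + Gaussian noise. Baselines are typical ovine haematology values;
#' the genotype effect (per alternate-allele copy at the causal SNP) is
#' applied to RBC, MCV and MCH. Sexes alternate male/female for balance.
#'
#' @param cfg a [sim_config()].
#' @param causal_dosage integer vector of alt-allele dosages at the causal
#'   SNP, one per sample (missing treated as 0 copies).
#' @param samples sample IDs.
#' @return Phenotype tibble: `sample`, `sex`, RBC, HGB, HCT, MCV, MCH,
#'   MCHC.
#' @export
simulate_phenotypes <- function(cfg, causal_dosage, samples) {
  stopifnot(inherits(cfg, "sim_config"),
            length(causal_dosage) == length(samples))
  n <- length(samples)
  sex <- rep_len(c("male", "female"), n)
  dos <- ifelse(is.na(causal_dosage), 0, causal_dosage)
  baselines <- c(RBC = 9.5, HGB = 110, HCT = 0.33, MCV = 34, MCH = 12,
                 MCHC = 355)
  causal <- c("RBC", "MCV", "MCH")
  out <- tibble::tibble(sample = samples, sex = sex)
  for (tr in names(baselines)) {
    eff <- if (tr %in% causal) cfg$phenotype_effect else 0
    out[[tr]] <- baselines[[tr]] + eff * dos +
      cfg$sex_effect * (sex == "male") +
      stats::rnorm(n, 0, cfg$noise_sd)
  }
  out
}

#' Simulate a complete two-group study
#'
#' Runs the frequency, haplotype/genotype and phenotype generators under the
#' configuration seed (via [withr::with_seed()]), plus a gene annotation
#' with genes tiled every 150 kb and one gene guaranteed to overlap the
#' sweep core. Identical configurations give identical output.
#'
#' @param cfg a [sim_config()].
#' @return List: `config`, `frequencies`, `hap_g1`, `hap_g2`, `genotypes`,
#'   `pop_map`, `core_index`, `phenotypes`, `genes`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    freqs <- simulate_frequencies(cfg)
    hg <- simulate_haplotypes(cfg, freqs)
    causal <- if (!is.na(hg$core_index)) hg$core_index
              else max(1L, nrow(freqs) %/% 2L)
    ph <- simulate_phenotypes(cfg, hg$genotypes$dosage[, causal],
                              hg$genotypes$samples)
    genes <- tile_genes(cfg, freqs, hg$core_index)
    c(list(config = cfg, frequencies = freqs), hg,
      list(phenotypes = ph, genes = genes))
  })
}

# genes of 40 kb tiled every 150 kb, plus one gene centred on the sweep core
tile_genes <- function(cfg, freqs, core_index) {
  lens <- cfg$chrom_lengths
  genes <- purrr::map_dfr(seq_along(lens), function(k) {
    starts <- seq(50000, lens[[k]] - 50000, by = 150000)
    tibble::tibble(chrom = names(lens)[k], start = as.integer(starts),
                   end = as.integer(starts + 40000), strand = "+",
                   gene = sprintf("%s_G%04d", toupper(names(lens)[k]),
                                  seq_along(starts)))
  })
  if (!is.null(core_index) && !is.na(core_index) && length(core_index)) {
    core_pos <- freqs$pos[core_index]
    genes <- dplyr::bind_rows(genes, tibble::tibble(
      chrom = freqs$chrom[core_index],
      start = as.integer(max(core_pos - 20000, 1)),
      end = as.integer(core_pos + 20000), strand = "+",
      gene = "SWEEP_CORE_GENE"))
  }
  dplyr::arrange(genes, .data$chrom, .data$start)
}

#' Write a gene annotation as GFF3
#'
#' @param genes tibble with `chrom`, `start`, `end`, `strand`, `gene`
#'   (1-based inclusive).
#' @param path output path.
#' @export
write_gene_annotation <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$ID <- genes$gene
  gr$Name <- genes$gene
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a complete fixture bundle
#'
#' Emits every file the pipeline stages consume: PED/MAP genotypes, an
#' allele-orientation table, one phased VCF per group, the population map,
#' a GFF3 gene annotation, the phenotype table, and (last, so that a partial
#' bundle is detectable by its absence) a `manifest.txt` recording the
#' configuration and seed as `key=value` lines.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_fixture_bundle <- function(cfg = sim_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_study(cfg)
  paths <- c(
    ped = file.path(out_dir, "genotypes.ped"),
    map = file.path(out_dir, "genotypes.map"),
    alleles = file.path(out_dir, "alleles.tsv"),
    vcf_g1 = file.path(out_dir, "phased_g1.vcf"),
    vcf_g2 = file.path(out_dir, "phased_g2.vcf"),
    pop_map = file.path(out_dir, "pop_map.tsv"),
    genes = file.path(out_dir, "genes.gff3"),
    phenotypes = file.path(out_dir, "phenotypes.tsv"),
    manifest = file.path(out_dir, "manifest.txt")
  )
  write_plink(sim$genotypes, paths[["ped"]], paths[["map"]])
  readr::write_tsv(sim$genotypes$variants[c("vid", "ref", "alt")],
                   paths[["alleles"]])
  write_vcf(sim$hap_g1, paths[["vcf_g1"]])
  write_vcf(sim$hap_g2, paths[["vcf_g2"]])
  write_pop_map(sim$pop_map, paths[["pop_map"]])
  write_gene_annotation(sim$genes, paths[["genes"]])
  write_phenotypes(sim$phenotypes, paths[["phenotypes"]])

  cfgv <- sim$config
  kv <- c(
    n_g1 = cfgv$n_g1, n_g2 = cfgv$n_g2, n_snps = cfgv$n_snps,
    chrom_lengths = paste(names(cfgv$chrom_lengths),
                          cfgv$chrom_lengths, sep = ":", collapse = ","),
    fst_background = cfgv$fst_background,
    sweep = if (is.null(cfgv$sweep)) "none"
            else paste(cfgv$sweep$chrom, cfgv$sweep$pos, cfgv$sweep$freq,
                       cfgv$sweep$span_bp, sep = ":"),
    rho = cfgv$rho, missing_rate = cfgv$missing_rate,
    phenotype_effect = cfgv$phenotype_effect,
    sex_effect = cfgv$sex_effect, noise_sd = cfgv$noise_sd,
    seed = cfgv$seed
  )
  writeLines(paste0(names(kv), "=", kv), paths[["manifest"]])
  invisible(paths)
}
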