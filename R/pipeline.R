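bundle_paths <- function(dir) {
  c(ped = file.path(dir, "genotypes.ped"),
    map = file.path(dir, "genotypes.map"),
    alleles = file.path(dir, "alleles.tsv"),
    vcf_g1 = file.path(dir, "phased_g1.vcf"),
    vcf_g2 = file.path(dir, "phased_g2.vcf"),
    pop_map = file.path(dir, "pop_map.tsv"),
    genes = file.path(dir, "genes.gff3"),
    phenotypes = file.path(dir, "phenotypes.tsv"))
}

read_bundle_genotypes <- function(dir) {
  p <- bundle_paths(dir)
  alleles <- if (file.exists(p[["alleles"]])) {
    readr::read_tsv(p[["alleles"]], col_types = "ccc", progress = FALSE)
  } else NULL
  read_plink(p[["ped"]], p[["map"]], alleles = alleles)
}

hap_subset <- function(h, keep_vids) {
  idx <- which(h$variants$vid %in% keep_vids)
  hap_set(h$haplo[, idx, drop = FALSE], h$variants[idx, ], h$samples)
}

#' Pipeline stage: simulate a fixture bundle
#'
#' @param out_dir output directory.
#' @param cfg a [sim_config()].
#' @return Invisibly, the bundle file paths.
#' @export
run_simulate <- function(out_dir, cfg = sim_config()) {
  paths <- write_fixture_bundle(cfg, out_dir)
  message("simulate: wrote bundle (", cfg$n_snps, " SNPs, ",
          cfg$n_g1 + cfg$n_g2, " samples) to ", out_dir)
  invisible(paths)
}

#' Pipeline stage: quality control
#'
#' Reads PLINK genotypes from `in_dir`, applies [apply_qc()], and writes the
#' filtered PED/MAP (plus allele table and a copy of the population map) and
#' a QC report to `out_dir`.
#'
#' @param in_dir directory holding a fixture bundle (or at least
#'   `genotypes.ped`/`genotypes.map`).
#' @param out_dir output directory.
#' @param cfg a [qc_config()].
#' @return Invisibly, the `qc_result`.
#' @export
run_qc <- function(in_dir, out_dir, cfg = qc_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- read_bundle_genotypes(in_dir)
  qc <- apply_qc(g, cfg)
  write_plink(qc$genotypes, file.path(out_dir, "genotypes.ped"),
              file.path(out_dir, "genotypes.map"))
  readr::write_tsv(qc$genotypes$variants[c("vid", "ref", "alt")],
                   file.path(out_dir, "alleles.tsv"))
  pmp <- bundle_paths(in_dir)[["pop_map"]]
  if (file.exists(pmp)) {
    file.copy(pmp, file.path(out_dir, "pop_map.tsv"), overwrite = TRUE)
  }
  write_qc_report(qc, file.path(out_dir, "qc_report.tsv"))
  message("qc: ", qc$report$n[qc$report$criterion == "retained"], " of ",
          qc$report$n[qc$report$criterion == "input"], " SNPs retained")
  invisible(qc)
}

#' Pipeline stage: population structure
#'
#' LD pruning, IBS distances, classical MDS, per-breed nucleotide diversity,
#' pairwise multi-locus F_ST between breeds and a neighbour-joining tree on
#' that matrix, written as TSV/Newick files.
#'
#' @param in_dir directory with (QC-filtered) `genotypes.ped`/`.map` and
#'   `pop_map.tsv`.
#' @param out_dir output directory.
#' @param prune_cfg a [prune_config()].
#' @param k MDS dimensions.
#' @return Invisibly, a list with the in-memory results.
#' @export
run_structure <- function(in_dir, out_dir, prune_cfg = prune_config(),
                          k = 2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- read_bundle_genotypes(in_dir)
  pm <- read_pop_map(bundle_paths(in_dir)[["pop_map"]])

  kept <- ld_prune(g, prune_cfg)
  writeLines(g$variants$vid[kept], file.path(out_dir, "pruned_variants.txt"))
  gp <- geno_mat(g$dosage[, kept, drop = FALSE], g$variants[kept, ],
                 g$samples)
  message("structure: ", length(kept), " of ", ncol(g$dosage),
          " SNPs retained after LD pruning")

  d <- ibs_distance(gp)
  write_distance_matrix(d, file.path(out_dir, "ibs_dist.tsv"))
  mds <- classical_mds(d, k = k)
  readr::write_tsv(mds, file.path(out_dir, "mds.tsv"))

  div <- nucleotide_diversity(g, pm)
  readr::write_tsv(div, file.path(out_dir, "diversity.tsv"))

  fstm <- pairwise_fst(g, pm)
  write_distance_matrix(fstm, file.path(out_dir, "fst_matrix.tsv"))
  tree <- nj_tree(fstm)
  write_newick(tree, file.path(out_dir, "tree.nwk"))
  invisible(list(pruned = kept, ibs = d, mds = mds, diversity = div,
                 fst_matrix = fstm, tree = tree))
}

#' Pipeline stage: selection scan
#'
#' Per-SNP Weir-Cockerham F_ST between G1 and G2 on the QC-passing SNPs,
#' XP-EHH from the phased per-group VCFs restricted to the same SNP
#' universe, upper-quantile thresholds, the intersection-plus-rescue
#' candidate rule, and gene annotation. Thresholds and tail/candidate counts
#' are logged.
#'
#' @param qc_dir directory with QC-filtered genotypes and `pop_map.tsv`.
#' @param bundle_dir directory with the phased VCFs and `genes.gff3`.
#' @param out_dir output directory.
#' @param cfg a [scan_config()].
#' @return Invisibly, a list with `scan` (tibble), `candidates`
#'   (`candidate_set`) and `genes` (tibble).
#' @export
run_scan <- function(qc_dir, bundle_dir, out_dir, cfg = scan_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- read_bundle_genotypes(qc_dir)
  pm <- read_pop_map(bundle_paths(qc_dir)[["pop_map"]])
  bp <- bundle_paths(bundle_dir)
  h_obs <- hap_subset(read_vcf(bp[["vcf_g1"]], require_phased = TRUE),
                      g$variants$vid)
  h_ref <- hap_subset(read_vcf(bp[["vcf_g2"]], require_phased = TRUE),
                      g$variants$vid)

  fst <- fst_scan(g, pm)
  xp <- xpehh_scan(h_obs, h_ref, cfg)
  stopifnot(identical(fst$vid, xp$vid))

  fst_top <- top_quantile(fst$theta, cfg$fst_quantile,
                          defined = fst$defined)
  xp_top <- top_quantile(xp$std, cfg$xpehh_quantile, defined = xp$defined)
  cand <- build_candidates(fst_top$indices, xp_top$indices, xp$defined)
  message(sprintf(
    paste0("scan: %d SNPs; top %.0f%% F_ST > %.3f: %d SNPs; ",
           "top %.0f%% XP-EHH > %.3f: %d SNPs (of %d defined); ",
           "intersection %d + rescue %d = %d candidates"),
    nrow(fst), 100 * cfg$fst_quantile, fst_top$threshold,
    fst_top$n_selected, 100 * cfg$xpehh_quantile, xp_top$threshold,
    xp_top$n_selected, sum(xp$defined), length(cand$intersect_snps),
    length(cand$rescue_snps), length(cand$union)))

  scan <- dplyr::bind_cols(
    fst,
    xp[c("ihh_obs", "ihh_ref", "raw", "std", "reason")]) |>
    dplyr::rename(xpehh_raw = "raw", xpehh_std = "std",
                  xpehh_reason = "reason") |>
    dplyr::mutate(
      fst_tail = dplyr::row_number() %in% fst_top$indices,
      xpehh_tail = dplyr::row_number() %in% xp_top$indices,
      candidate = dplyr::row_number() %in% cand$union,
      rescue = dplyr::row_number() %in% cand$rescue_snps)
  readr::write_tsv(scan, file.path(out_dir, "scan.tsv"))
  readr::write_tsv(scan[scan$candidate, ],
                   file.path(out_dir, "candidates.tsv"))

  genes_tbl <- tibble::tibble()
  if (file.exists(bp[["genes"]])) {
    ann <- read_gene_annotation(bp[["genes"]])
    genes_tbl <- annotate_genes(scan[scan$candidate,
                                     c("chrom", "pos", "vid")],
                                ann, cfg$gene_flank_bp)
    readr::write_tsv(genes_tbl, file.path(out_dir, "candidate_genes.tsv"))
    message("scan: ", nrow(genes_tbl), " candidate genes")
  }
  invisible(list(scan = scan, fst_top = fst_top, xpehh_top = xp_top,
                 candidates = cand, genes = genes_tbl))
}

#' Pipeline stage: genotype-phenotype association
#'
#' Between-group allele-frequency chi-squared tests at the tested variants,
#' then for each variant and haematological trait in the highland group: the
#' sex-adjusted general linear model, Fisher's LSD post hoc, and the
#' highland vs lowland Welch comparison per trait.
#'
#' @param bundle_dir directory with genotypes, `pop_map.tsv` and
#'   `phenotypes.tsv`.
#' @param out_dir output directory.
#' @param vids variant IDs to test; default: the SNP with the largest
#'   defined F_ST between groups.
#' @param traits trait columns to analyse.
#' @return Invisibly, a list of result tibbles.
#' @export
run_assoc <- function(bundle_dir, out_dir, vids = NULL,
                      traits = c("RBC", "HGB", "HCT", "MCV", "MCH",
                                 "MCHC")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- read_bundle_genotypes(bundle_dir)
  pm <- read_pop_map(bundle_paths(bundle_dir)[["pop_map"]])
  ph <- read_phenotypes(bundle_paths(bundle_dir)[["phenotypes"]])

  if (is.null(vids)) {
    fst <- fst_scan(g, pm)
    vids <- fst$vid[which.max(ifelse(fst$defined, fst$theta, -Inf))]
  }
  idx <- match(vids, g$variants$vid)
  if (anyNA(idx)) stop("variant not found: ", vids[which(is.na(idx))[1]])

  grp <- pm$group[match(g$samples, pm$sample)]
  chisq_tbl <- purrr::map_dfr(seq_along(vids), function(k) {
    d <- g$dosage[, idx[k]]
    cnt <- function(sel) {
      dd <- d[sel & !is.na(d)]
      c(2 * length(dd) - sum(dd), sum(dd))
    }
    dplyr::bind_cols(tibble::tibble(vid = vids[k]),
                     allele_chisq(cnt(grp == "G1"), cnt(grp == "G2")))
  })
  readr::write_tsv(chisq_tbl, file.path(out_dir, "allele_chisq.tsv"))

  high <- ph[ph$sample %in% pm$sample[pm$group == "G1"], ]
  low <- ph[ph$sample %in% pm$sample[pm$group == "G2"], ]
  cmp_tbl <- purrr::map_dfr(traits, function(tr) {
    dplyr::mutate(group_trait_compare(high, low, tr), trait = tr,
                  .before = 1)
  })
  readr::write_tsv(cmp_tbl, file.path(out_dir, "group_compare.tsv"))

  glm_tbl <- tibble::tibble()
  lsd_tbl <- tibble::tibble()
  for (k in seq_along(vids)) {
    v <- g$variants[idx[k], ]
    d <- g$dosage[, idx[k]]
    calls <- tibble::tibble(
      sample = g$samples,
      genotype = dplyr::case_when(
        is.na(d) ~ NA_character_,
        d == 0L ~ paste0(v$ref, v$ref),
        d == 1L ~ paste0(v$ref, v$alt),
        TRUE ~ paste0(v$alt, v$alt)))
    calls <- calls[calls$sample %in% high$sample, ]
    for (tr in traits) {
      fit <- tryCatch(glm_association(high, calls, tr),
                      error = function(e) NULL)
      if (is.null(fit)) next
      glm_tbl <- dplyr::bind_rows(
        glm_tbl, dplyr::mutate(glance(fit), vid = vids[k], .before = 1))
      lsd_tbl <- dplyr::bind_rows(
        lsd_tbl, dplyr::mutate(lsd_posthoc(fit), vid = vids[k],
                               trait = tr, .before = 1))
    }
  }
  readr::write_tsv(glm_tbl, file.path(out_dir, "glm_association.tsv"))
  readr::write_tsv(lsd_tbl, file.path(out_dir, "lsd_posthoc.tsv"))
  message("assoc: ", length(vids), " variant(s) x ", length(traits),
          " traits")
  invisible(list(chisq = chisq_tbl, group_compare = cmp_tbl,
                 glm = glm_tbl, lsd = lsd_tbl))
}

#' Run the full pipeline on a synthetic study
#'
#' simulate -> qc -> structure -> scan -> assoc, writing each stage under
#' `out_dir`. All randomness flows through `cfg$seed` (optionally overridden
#' by `seed`), so reruns with the same configuration are byte-identical.
#'
#' @param out_dir output directory; stages write to `sim/`, `qc/`,
#'   `structure/`, `scan/`, `assoc/` beneath it.
#' @param cfg a [sim_config()].
#' @param qc_cfg,prune_cfg,scan_cfg stage configurations.
#' @param seed optional seed overriding `cfg$seed`.
#' @return Invisibly, a list with each stage's in-memory result.
#' @export
run_all <- function(out_dir, cfg = sim_config(), qc_cfg = qc_config(),
                    prune_cfg = prune_config(), scan_cfg = scan_config(),
                    seed = NULL) {
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dirs <- file.path(out_dir, c("sim", "qc", "structure", "scan", "assoc"))
  names(dirs) <- c("sim", "qc", "structure", "scan", "assoc")
  run_simulate(dirs[["sim"]], cfg)
  qc <- run_qc(dirs[["sim"]], dirs[["qc"]], qc_cfg)
  st <- run_structure(dirs[["qc"]], dirs[["structure"]], prune_cfg)
  sc <- run_scan(dirs[["qc"]], dirs[["sim"]], dirs[["scan"]], scan_cfg)
  top_cand <- if (length(sc$candidates$union)) {
    scan <- sc$scan
    cand_rows <- scan[scan$candidate, ]
    cand_rows$vid[which.max(cand_rows$theta)]
  } else NULL
  as <- run_assoc(dirs[["sim"]], dirs[["assoc"]], vids = top_cand)
  invisible(list(dirs = dirs, qc = qc, structure = st, scan = sc,
                 assoc = as))
}

#' Read a pipeline run configuration (YAML)
#'
#' Sections `qc`, `prune`, `scan` and `sim` map onto [qc_config()],
#' [prune_config()], [scan_config()] and [sim_config()]; unknown sections or
#' keys are rejected.
#'
#' @param path YAML file path.
#' @return List with one config object per section (defaults where absent).
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read config files")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("qc", "prune", "scan", "sim")
  extra <- setdiff(names(raw), known)
  if (length(extra)) stop("unknown config section(s): ",
                          paste(extra, collapse = ", "))
  ctor <- list(qc = qc_config, prune = prune_config, scan = scan_config,
               sim = sim_config)
  out <- list()
  for (s in known) {
    args <- raw[[s]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), names(formals(ctor[[s]])))
    if (length(bad)) stop("unknown key(s) in section '", s, "': ",
                          paste(bad, collapse = ", "))
    if (s == "sim" && !is.null(args$chrom_lengths)) {
      args$chrom_lengths <- unlist(args$chrom_lengths)
    }
    out[[s]] <- do.call(ctor[[s]], args)
  }
  out
}
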