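#' LD pruning configuration
#'
#' Sliding-window pruning in the style of PLINK's `--indep-pairwise`: windows
#' of `window_snps` SNPs advanced by `step_snps`, removing SNPs until no
#' retained pair within any window has squared dosage correlation above
#' `r2_max`.
#'
#' @param window_snps window size in SNPs.
#' @param step_snps window shift in SNPs.
#' @param r2_max pairwise r-squared threshold.
#' @return A `prune_config` list.
#' @export
prune_config <- function(window_snps = 25, step_snps = 5, r2_max = 0.05) {
  if (window_snps < 2) stop("window_snps must be >= 2")
  stopifnot(step_snps >= 1, step_snps <= window_snps,
            r2_max > 0, r2_max < 1)
  structure(list(window_snps = as.integer(window_snps),
                 step_snps = as.integer(step_snps), r2_max = r2_max),
            class = "prune_config")
}

impute_mean <- function(dosage) {
  mu <- colMeans(dosage, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  na <- which(is.na(dosage), arr.ind = TRUE)
  if (nrow(na)) dosage[na] <- mu[na[, 2]]
  dosage
}

r2_pair <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Greedy sliding-window LD pruning
#'
#' Missing dosages are mean-imputed per SNP before computing squared Pearson
#' correlations, so the procedure is deterministic. Within each window, while
#' any retained pair exceeds `r2_max`, one member of the first offending pair
#' (in index order) is dropped: the SNP with more missing calls, ties going
#' to the later position. Windows never span chromosomes.
#'
#' @param g a [geno_mat()].
#' @param cfg a [prune_config()].
#' @return Sorted integer vector of retained variant indices (columns of
#'   `g$dosage`).
#' @export
ld_prune <- function(g, cfg = prune_config()) {
  stopifnot(inherits(g, "geno_mat"), inherits(cfg, "prune_config"))
  m <- ncol(g$dosage)
  n_miss <- colSums(is.na(g$dosage))
  X <- impute_mean(g$dosage)
  keep <- rep(TRUE, m)

  for (ch in unique(g$variants$chrom)) {
    idx <- which(g$variants$chrom == ch)
    mc <- length(idx)
    start <- 1L
    repeat {
      win <- idx[start:min(start + cfg$window_snps - 1L, mc)]
      active <- win[keep[win]]
      while (length(active) > 1L) {
        R2 <- suppressWarnings(stats::cor(X[, active, drop = FALSE]))^2
        R2[!is.finite(R2)] <- 0
        diag(R2) <- 0
        off <- which(R2 > cfg$r2_max, arr.ind = TRUE)
        if (!nrow(off)) break
        off <- off[off[, 1] < off[, 2], , drop = FALSE]
        pair <- off[order(off[, 1], off[, 2])[1], ]
        i <- active[pair[1]]
        j <- active[pair[2]]
        drop <- if (n_miss[i] > n_miss[j]) i
                else if (n_miss[j] > n_miss[i]) j
                else max(i, j)  # tie: later position (indices sorted by pos)
        keep[drop] <- FALSE
        active <- active[active != drop]
      }
      if (start + cfg$window_snps - 1L >= mc) break
      start <- start + cfg$step_snps
    }
  }
  which(keep)
}

#' Pairwise identity-by-state distances
#'
#' For samples i and j, over SNPs non-missing in both: IBS similarity is the
#' mean of (2 - |dosage_i - dosage_j|)/2, and the distance is 1 minus that.
#'
#' @param g a [geno_mat()].
#' @return A symmetric base matrix with sample IDs as dimnames, zero
#'   diagonal.
#' @export
ibs_distance <- function(g) {
  stopifnot(inherits(g, "geno_mat"))
  n <- length(g$samples)
  if (n < 2) stop("need at least 2 samples")
  X <- g$dosage
  D <- matrix(0, n, n, dimnames = list(g$samples, g$samples))
  for (i in seq_len(n - 1)) {
    xi <- X[i, ]
    for (j in (i + 1):n) {
      ok <- !is.na(xi) & !is.na(X[j, ])
      if (!any(ok)) {
        stop("samples ", g$samples[i], " and ", g$samples[j],
             " share no non-missing SNPs")
      }
      d <- mean(abs(xi[ok] - X[j, ok])) / 2
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  D
}

#' Classical (metric) multidimensional scaling
#'
#' Double-centres the squared distances and extracts coordinates from the
#' top-k non-negative eigenvalues (Torgerson MDS, as in PLINK's
#' `--mds-plot`). Axes are oriented so the first non-zero loading of each
#' component is positive. When fewer than `k` positive eigenvalues exist,
#' the remaining columns are zero-filled and a warning is recorded in the
#' `"mds_warning"` attribute.
#'
#' @param d symmetric distance matrix with labelled rows.
#' @param k number of components.
#' @return A tibble: `sample`, `C1` ... `Ck`, with eigenvalues in the
#'   `"eig"` attribute.
#' @export
classical_mds <- function(d, k = 2) {
  stopifnot(k >= 1, is.matrix(d), nrow(d) == ncol(d))
  fit <- suppressWarnings(stats::cmdscale(d, k = k, eig = TRUE))
  pts <- fit$points
  warn <- NULL
  # eigenvalues below numerical noise (relative to the largest) carry no
  # geometry; zero their columns rather than keep rounding artefacts
  tol <- max(fit$eig) * 1e-8
  keep_dim <- which(fit$eig[seq_len(ncol(pts))] > tol)
  if (length(keep_dim) < k) {
    warn <- sprintf(
      "only %d informative eigenvalue(s); columns %s zero-padded",
      length(keep_dim),
      paste(seq(length(keep_dim) + 1, k), collapse = ","))
    pts <- cbind(pts[, keep_dim, drop = FALSE],
                 matrix(0, nrow(d), k - length(keep_dim)))
  }
  for (j in seq_len(k)) {
    nz <- which(abs(pts[, j]) > 1e-12)
    if (length(nz) && pts[nz[1], j] < 0) pts[, j] <- -pts[, j]
  }
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("unit", seq_len(nrow(d)))
  out <- tibble::as_tibble(as.data.frame(pts), .name_repair = "minimal")
  names(out) <- paste0("C", seq_len(k))
  out <- dplyr::bind_cols(tibble::tibble(sample = labs), out)
  attr(out, "eig") <- fit$eig
  attr(out, "mds_warning") <- warn
  out
}

#' Per-breed nucleotide diversity
#'
#' Unbiased per-site heterozygosity summed over SNPs and divided by
#' `total_sites`: pi = sum over sites of 2 p (1 - p) n/(n - 1) over
#' `total_sites`, with n the number of non-missing allele calls at the site.
#' `total_sites` represents the surveyed sequence length; when only the SNP
#' panel is known it defaults to the SNP count, making pi a per-SNP
#' diversity.
#'
#' @param g a [geno_mat()].
#' @param pm population map tibble.
#' @param total_sites denominator; `NULL` means the number of SNPs.
#' @return Tibble: `breed`, `pi` (`NA` for breeds with fewer than 2
#'   samples), `n_sites`.
#' @export
nucleotide_diversity <- function(g, pm, total_sites = NULL) {
  stopifnot(inherits(g, "geno_mat"))
  if (is.null(total_sites)) total_sites <- ncol(g$dosage)
  if (total_sites < ncol(g$dosage)) {
    stop("total_sites must be at least the number of SNPs")
  }
  breed <- pm$breed[match(g$samples, pm$sample)]
  purrr::map_dfr(sort(unique(breed)), function(b) {
    d <- g$dosage[which(breed == b), , drop = FALSE]
    if (nrow(d) < 2) {
      return(tibble::tibble(breed = b, pi = NA_real_,
                            n_sites = as.integer(total_sites)))
    }
    n <- 2 * colSums(!is.na(d))
    p <- col_alt_freq(d)
    ok <- !is.na(p) & n >= 2
    contrib <- 2 * p[ok] * (1 - p[ok]) * n[ok] / (n[ok] - 1)
    tibble::tibble(breed = b, pi = sum(contrib) / total_sites,
                   n_sites = as.integer(total_sites))
  })
}

#' Multi-locus pairwise F_ST between breeds
#'
#' For each breed pair, Weir-Cockerham variance components are computed per
#' locus (see [wc_components()]) and combined as a ratio of sums:
#' theta = sum(a) / sum(a + b + c) over loci with defined components.
#' Negative multi-locus estimates are clipped to 0 for use as distances.
#'
#' @param g a [geno_mat()].
#' @param pm population map tibble.
#' @return A symmetric breed x breed matrix of clipped multi-locus theta,
#'   with unclipped values in the `"theta_raw"` attribute.
#' @export
pairwise_fst <- function(g, pm) {
  stopifnot(inherits(g, "geno_mat"))
  breed <- pm$breed[match(g$samples, pm$sample)]
  breeds <- sort(unique(breed))
  if (length(breeds) < 2) stop("need at least 2 breeds")
  nb <- length(breeds)
  Th <- matrix(0, nb, nb, dimnames = list(breeds, breeds))
  raw <- Th
  for (i in seq_len(nb - 1)) {
    for (j in (i + 1):nb) {
      gi <- g$dosage[which(breed == breeds[i]), , drop = FALSE]
      gj <- g$dosage[which(breed == breeds[j]), , drop = FALSE]
      si <- locus_summaries(gi)
      sj <- locus_summaries(gj)
      comp <- wc_components(si$n, si$p, si$h, sj$n, sj$p, sj$h)
      ok <- comp$defined
      if (!any(ok)) {
        stop("breeds ", breeds[i], " and ", breeds[j],
             " share no polymorphic loci")
      }
      th <- sum(comp$a[ok]) / sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
      raw[i, j] <- raw[j, i] <- th
      Th[i, j] <- Th[j, i] <- max(th, 0)
    }
  }
  attr(Th, "theta_raw") <- raw
  Th
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via \pkg{ape}), post-processed so that
#' negative branch lengths are clipped to zero with the residual transferred
#' to the adjacent sister edge, preserving path lengths between leaves where
#' possible.
#'
#' @param d symmetric distance matrix over units (e.g. breeds), labelled.
#' @return An [ape::nj()] `phylo` object.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) >= 3)
  if (any(!is.finite(d))) stop("non-finite distances")
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    child <- tr$edge[e, 2]
    parent <- tr$edge[e, 1]
    resid <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    sisters <- which(tr$edge[, 1] == parent & seq_along(tr$edge[, 2]) != e)
    if (length(sisters)) {
      s <- sisters[1]
      tr$edge.length[s] <- max(tr$edge.length[s] + resid, 0)
    }
  }
  tr
}

#' Write a tree in Newick format
#' @param tree a `phylo` object.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a distance matrix as square TSV
#' @param d labelled square matrix.
#' @param path output path.
#' @export
write_distance_matrix <- function(d, path) {
  lines <- c(paste(c("#unit", colnames(d)), collapse = "\t"),
             vapply(seq_len(nrow(d)), function(i) {
               paste(c(rownames(d)[i], format(d[i, ], digits = 10,
                                              scientific = FALSE,
                                              trim = TRUE)),
                     collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}
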