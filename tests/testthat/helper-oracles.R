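# Independent brute-force oracles and tiny fixture builders used across the
# test files. These deliberately re-derive each quantity by the most direct
# route (loops, pair enumeration, closed forms) rather than calling the
# package's vectorized implementations.

make_geno <- function(dosage, chrom = NULL, pos = NULL, samples = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(nrow(dosage)))
  geno_mat(dosage,
           tibble::tibble(chrom = chrom, pos = as.integer(pos),
                          vid = sprintf("v%03d", seq_len(m)),
                          ref = "A", alt = "G"),
           samples)
}

make_haps <- function(haplo, pos = NULL, chrom = NULL) {
  haplo <- as.matrix(haplo)
  m <- ncol(haplo)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(chrom)) chrom <- rep("chr1", m)
  stopifnot(nrow(haplo) %% 2 == 0)
  hap_set(haplo,
          tibble::tibble(chrom = chrom, pos = as.integer(pos),
                         vid = sprintf("v%03d", seq_len(m)),
                         ref = "A", alt = "G"),
          sprintf("s%02d", seq_len(nrow(haplo) / 2)))
}

# scalar Weir-Cockerham components for r = 2, one locus at a time
wc_scalar <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  ni <- c(n1, n2); pi <- c(p1, p2); hi <- c(h1, h2)
  nbar <- sum(ni) / r
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- sum(ni * pi) / (r * nbar)
  s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  list(a = a, b = b, c = cc,
       theta = if (denom != 0) a / denom else NA_real_)
}

# brute-force IBS distance: loop over SNPs shared by a sample pair
ibs_brute <- function(dosage) {
  n <- nrow(dosage)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      num <- 0; den <- 0
      for (k in seq_len(ncol(dosage))) {
        if (!is.na(dosage[i, k]) && !is.na(dosage[j, k])) {
          num <- num + (2 - abs(dosage[i, k] - dosage[j, k])) / 2
          den <- den + 1
        }
      }
      D[i, j] <- 1 - num / den
    }
  }
  D
}

# EHH decay by O(n^2) pair enumeration, re-implementing the truncation rules
# independently of the C++ partition algorithm
ehh_enum <- function(haplo, pos, core, dir, cutoff = 0.05, max_ext = 1e6,
                     max_gap = 2e5, lo = 1L, hi = ncol(haplo)) {
  n <- nrow(haplo)
  pairs <- utils::combn(n, 2)
  out_d <- 0
  out_e <- 1
  j <- core
  repeat {
    jn <- j + dir
    if (jn < lo || jn > hi) break
    if (abs(pos[jn] - pos[j]) > max_gap) break
    if (abs(pos[jn] - pos[core]) > max_ext) break
    j <- jn
    seg <- if (dir > 0) core:j else j:core
    same <- 0
    for (k in seq_len(ncol(pairs))) {
      if (all(haplo[pairs[1, k], seg] == haplo[pairs[2, k], seg])) {
        same <- same + 1
      }
    }
    e <- same / ncol(pairs)
    out_d <- c(out_d, abs(pos[j] - pos[core]))
    out_e <- c(out_e, e)
    if (e < cutoff) break
  }
  list(dist = out_d, ehh = out_e)
}

# chi-squared closed form for a 2x2 table: N(ad - bc)^2 / row/col products
chisq_closed <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# draw a diploid genotype matrix from fixed per-group allele frequencies
draw_group_geno <- function(n, p) {
  m <- length(p)
  matrix(stats::rbinom(n * m, 2, rep(p, each = n)), n, m)
}

small_sim <- function(seed = 1, ...) {
  sim_config(n_g1 = 12, n_g2 = 12, n_snps = 400,
             chrom_lengths = c(chr1 = 6e6, chr2 = 6e6),
             sweep = list(chrom = "chr1", pos = 3e6, freq = 0.9,
                          span_bp = 8e5),
             seed = seed, ...)
}
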