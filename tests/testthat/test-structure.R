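test_that("LD pruning removes correlated SNPs and passes an exhaustive check", {
  set.seed(21)
  base <- rbinom(30, 2, 0.5)
  g <- make_geno(cbind(base, base))           # r^2 = 1 pair
  expect_length(ld_prune(g, prune_config()), 1L)

  # independent SNPs all kept (many samples keep chance r^2 below 0.05)
  set.seed(22)
  gi <- make_geno(matrix(rbinom(400 * 10, 2, 0.5), 400, 10))
  R2 <- suppressWarnings(cor(gi$dosage))^2
  skip_if(any(R2[upper.tri(R2)] > 0.05))       # construction check only
  expect_length(ld_prune(gi, prune_config()), 10L)

  # planted correlation blocks, verified window-by-window afterwards
  set.seed(23)
  n <- 40
  cols <- list()
  k <- 1
  while (k <= 60) {
    block <- sample(2:4, 1)
    anchor <- rbinom(n, 2, runif(1, 0.2, 0.8))
    for (b in seq_len(min(block, 60 - k + 1))) {
      noisy <- anchor
      flip <- sample(n, 3)
      noisy[flip] <- rbinom(3, 2, 0.5)
      cols[[k]] <- noisy
      k <- k + 1
    }
  }
  g60 <- make_geno(do.call(cbind, cols))
  cfg <- prune_config()
  kept <- ld_prune(g60, cfg)
  X <- g60$dosage
  starts <- seq(1, 60, by = cfg$step_snps)
  for (s in starts) {
    win <- s:min(s + cfg$window_snps - 1, 60)
    act <- intersect(win, kept)
    if (length(act) < 2) next
    for (i in act) {
      for (j in act) {
        if (i < j) expect_lte(r2 <- suppressWarnings(cor(X[, i], X[, j]))^2,
                              cfg$r2_max)
      }
    }
  }
  expect_error(prune_config(window_snps = 1), "window_snps")
})

test_that("IBS distance matches brute force and its boundary cases", {
  g <- make_geno(rbind(c(0L, 1L, 2L), c(0L, 1L, 2L)))
  expect_equal(unname(ibs_distance(g)[1, 2]), 0)

  g2 <- make_geno(rbind(c(0L, 0L, 0L), c(2L, 2L, 2L)))
  expect_equal(unname(ibs_distance(g2)[1, 2]), 1)

  set.seed(31)
  dos <- matrix(rbinom(10 * 50, 2, 0.4), 10, 50)
  dos[sample(length(dos), 40)] <- NA_integer_
  g3 <- make_geno(dos)
  expect_equal(unname(ibs_distance(g3)), ibs_brute(dos), tolerance = 1e-12)

  g4 <- make_geno(rbind(c(0L, NA), c(NA, 0L)))
  expect_error(ibs_distance(g4), "s01 and s02")
})

test_that("classical MDS reconstructs Euclidean configurations", {
  # collinear points at 0, 1, 2: second component vanishes
  d <- rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0))
  rownames(d) <- colnames(d) <- c("a", "b", "c")
  mds <- classical_mds(d, k = 2)
  expect_lt(max(abs(mds$C2)), 1e-9)
  expect_false(is.null(attr(mds, "mds_warning")))

  set.seed(32)
  pts <- matrix(rnorm(14), 7, 2)
  d2 <- as.matrix(dist(pts))
  m2 <- classical_mds(d2, k = 2)
  rec <- as.matrix(dist(as.matrix(m2[, c("C1", "C2")])))
  expect_equal(unname(rec), unname(d2), tolerance = 1e-9)

  # sign convention: first nonzero loading of each axis is positive
  expect_gte(m2$C1[which(abs(m2$C1) > 1e-12)[1]], 0)
})

test_that("MDS component 1 separates simulated groups", {
  sim <- simulate_study(sim_config(n_g1 = 15, n_g2 = 15, n_snps = 1500,
                                   chrom_lengths = c(chr1 = 3e7),
                                   fst_background = 0.1, sweep = NULL,
                                   missing_rate = 0, seed = 8))
  d <- ibs_distance(sim$genotypes)
  mds <- classical_mds(d, k = 2)
  grp <- sim$pop_map$group[match(mds$sample, sim$pop_map$sample)]
  c1 <- split(mds$C1, grp)
  expect_true(max(c1$G1) < min(c1$G2) || max(c1$G2) < min(c1$G1))
})

test_that("nucleotide diversity follows the unbiased per-site formula", {
  g <- make_geno(matrix(0L, 4, 3))
  pm <- tibble::tibble(sample = g$samples, breed = "B", group = "G1")
  expect_equal(nucleotide_diversity(g, pm)$pi, 0)

  # one SNP, dosages 0 and 2: p = 0.5, n = 4 alleles, pi = 2*.25*(4/3)
  g1 <- make_geno(matrix(c(0L, 2L), ncol = 1))
  pm1 <- tibble::tibble(sample = g1$samples, breed = "B", group = "G1")
  expect_equal(nucleotide_diversity(g1, pm1, total_sites = 1)$pi, 2 / 3)

  # breed with < 2 samples is a sentinel
  pm2 <- tibble::tibble(sample = g1$samples, breed = c("B", "C"),
                        group = "G1")
  expect_true(all(is.na(nucleotide_diversity(g1, pm2)$pi)))

  # rank order tracks the simulated diversity level
  set.seed(33)
  hits <- 0
  for (r in 1:20) {
    p_hi <- runif(300, 0.3, 0.5)
    p_lo <- runif(300, 0.02, 0.08)
    dos <- rbind(draw_group_geno(10, p_hi), draw_group_geno(10, p_lo))
    gg <- make_geno(dos)
    pmr <- tibble::tibble(sample = gg$samples,
                          breed = rep(c("HI", "LO"), each = 10),
                          group = "G1")
    pi <- nucleotide_diversity(gg, pmr)
    if (pi$pi[pi$breed == "HI"] > pi$pi[pi$breed == "LO"]) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("pairwise multi-locus F_ST behaves at its extremes and recovers F", {
  set.seed(34)
  dos <- draw_group_geno(12, runif(200, 0.2, 0.8))
  g <- make_geno(rbind(dos, dos))
  pm <- tibble::tibble(sample = g$samples,
                       breed = rep(c("B1", "B2"), each = 12),
                       group = "G1")
  fm <- pairwise_fst(g, pm)
  expect_equal(unname(fm["B1", "B2"]), 0)            # clipped
  expect_lte(attr(fm, "theta_raw")["B1", "B2"], 0)   # <= 0 before clipping
  expect_equal(as.vector(fm), as.vector(t(fm)))

  # fixed difference at every locus: theta = 1
  gfix <- make_geno(rbind(matrix(0L, 5, 20), matrix(2L, 5, 20)))
  pmf <- tibble::tibble(sample = gfix$samples,
                        breed = rep(c("A", "B"), each = 5), group = "G1")
  expect_equal(unname(pairwise_fst(gfix, pmf)["A", "B"]), 1)

  # Balding-Nichols parameter recovery across replicates
  set.seed(35)
  for (r in 1:20) {
    p_anc <- runif(2000, 0.05, 0.95)
    shp <- (1 - 0.1) / 0.1
    pa <- rbeta(2000, p_anc * shp, (1 - p_anc) * shp)
    pb <- rbeta(2000, p_anc * shp, (1 - p_anc) * shp)
    gg <- make_geno(rbind(draw_group_geno(25, pa), draw_group_geno(25, pb)))
    pmr <- tibble::tibble(sample = gg$samples,
                          breed = rep(c("A", "B"), each = 25), group = "G1")
    th <- unname(pairwise_fst(gg, pmr)["A", "B"])
    expect_gte(th, 0.05)
    expect_lte(th, 0.15)
  }
})

test_that("neighbour joining recovers additive topologies and path lengths", {
  d4 <- matrix(6, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d4) <- 0
  d4["a", "b"] <- d4["b", "a"] <- 2
  d4["c", "d"] <- d4["d", "c"] <- 2
  tr <- nj_tree(d4)
  # additivity forces the ((a,b),(c,d)) split
  want <- ape::read.tree(text = "((a:1,b:1):1,c:1,d:1);")
  expect_equal(ape::dist.topo(ape::unroot(tr), want)[1], 0)
  expect_equal(unname(ape::cophenetic.phylo(tr)[rownames(d4), colnames(d4)]),
               unname(d4), tolerance = 1e-9)

  # 3 taxa: closed-form three-point branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(d3)
  expect_equal(unname(ape::cophenetic.phylo(t3)[rownames(d3), colnames(d3)]),
               unname(d3), tolerance = 1e-9)

  # random 7-leaf additive matrices: topology and distances recovered
  set.seed(36)
  for (r in 1:5) {
    gen <- ape::rtree(7)
    gen$edge.length <- runif(nrow(gen$edge), 0.5, 2)
    dm <- ape::cophenetic.phylo(gen)
    rec <- nj_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(gen), ape::unroot(rec))[1], 0)
    expect_equal(unname(ape::cophenetic.phylo(rec)[rownames(dm), colnames(dm)]),
                 unname(dm), tolerance = 1e-9)
  }

  d4na <- d4; d4na[1, 2] <- d4na[2, 1] <- Inf
  expect_error(nj_tree(d4na), "non-finite")
})
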