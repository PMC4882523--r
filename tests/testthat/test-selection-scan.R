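test_that("Weir-Cockerham components match hand evaluations and a scalar oracle", {
  # monomorphic locus: all components zero, theta undefined
  mono <- wc_components(10, 1, 0, 10, 1, 0)
  expect_equal(mono$a, 0)
  expect_equal(mono$b, 0)
  expect_equal(mono$c, 0)
  expect_false(mono$defined)
  expect_true(is.na(mono$theta))

  # fixed difference: a = 0.5, b = c = 0, theta = 1
  fx <- wc_components(10, 1, 0, 10, 0, 0)
  expect_equal(fx$a, 0.5)
  expect_equal(fx$b, 0)
  expect_equal(fx$c, 0)
  expect_equal(fx$theta, 1)

  # small samples are flagged, not raised
  expect_false(wc_components(1, 0.5, 0.5, 10, 0.2, 0.3)$defined)

  set.seed(41)
  n1 <- sample(5:60, 1000, TRUE)
  n2 <- sample(5:60, 1000, TRUE)
  p1 <- runif(1000)
  p2 <- runif(1000)
  h1 <- runif(1000) * 2 * pmin(p1, 1 - p1)
  h2 <- runif(1000) * 2 * pmin(p2, 1 - p2)
  vec <- wc_components(n1, p1, h1, n2, p2, h2)
  for (i in seq_len(1000)) {
    sc <- wc_scalar(n1[i], p1[i], h1[i], n2[i], p2[i], h2[i])
    expect_equal(vec$a[i], sc$a, tolerance = 1e-12)
    expect_equal(vec$theta[i], sc$theta, tolerance = 1e-12)
  }
  expect_true(all(vec$theta <= 1, na.rm = TRUE))
})

test_that("fst_scan matches locus-wise components and flags extremes", {
  set.seed(42)
  dos <- draw_group_geno(20, runif(300, 0.1, 0.9))
  g <- make_geno(rbind(dos, dos))
  pm <- tibble::tibble(sample = g$samples, breed = "B",
                       group = rep(c("G1", "G2"), each = 20))
  sc <- fst_scan(g, pm)
  expect_true(all(sc$theta <= 0, na.rm = TRUE))  # cloned groups

  set.seed(43)
  d1 <- draw_group_geno(40, rep(0.95, 1))
  d2 <- draw_group_geno(40, rep(0.10, 1))
  gs <- make_geno(rbind(d1, d2))
  pms <- tibble::tibble(sample = gs$samples, breed = "B",
                        group = rep(c("G1", "G2"), each = 40))
  expect_gt(fst_scan(gs, pms)$theta, 0.5)

  # scan equals per-locus scalar evaluation on a mixed fixture
  set.seed(44)
  dd <- rbind(draw_group_geno(15, runif(500, 0.05, 0.95)),
              draw_group_geno(18, runif(500, 0.05, 0.95)))
  dd[sample(length(dd), 200)] <- NA_integer_
  gm <- make_geno(dd)
  pmm <- tibble::tibble(sample = gm$samples, breed = "B",
                        group = rep(c("G1", "G2"), c(15, 18)))
  sc2 <- fst_scan(gm, pmm)
  for (j in sample(500, 50)) {
    x1 <- dd[1:15, j]; x1 <- x1[!is.na(x1)]
    x2 <- dd[16:33, j]; x2 <- x2[!is.na(x2)]
    sco <- wc_scalar(length(x1), sum(x1) / (2 * length(x1)),
                     mean(x1 == 1), length(x2), sum(x2) / (2 * length(x2)),
                     mean(x2 == 1))
    if (sc2$defined[j]) expect_equal(sc2$theta[j], sco$theta,
                                     tolerance = 1e-12)
  }
  expect_error(fst_scan(gm, dplyr::mutate(pmm, group = "G1")), "G2")
})

test_that("EHH equals pair enumeration and obeys its boundary cases", {
  # all haplotypes identical: EHH stays 1 over the whole span
  h <- make_haps(matrix(1L, 6, 10))
  cv <- ehh(h, 5)
  expect_true(all(cv$ehh == 1))

  # all haplotypes pairwise distinct at the first extension: EHH = 0 there
  hd <- make_haps(rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L)))
  cr <- ehh(hd, 1, side = "right")
  expect_equal(cr$ehh, c(1, 0))

  # two identical pairs at distance x: EHH = 2 / C(4,2) = 1/3
  hp <- make_haps(rbind(c(1L, 0L), c(1L, 0L), c(1L, 1L), c(1L, 1L)),
                  pos = c(1000L, 2000L))
  cp <- ehh(hp, 1, side = "right")
  expect_equal(cp$ehh[cp$dist == 1000], 1 / 3)

  expect_error(ehh(hp, 99), "out of range")

  # randomized haplotype sets against the O(n^2) enumeration oracle
  set.seed(45)
  cfg <- scan_config()
  for (r in 1:25) {
    n <- 2 * sample(2:8, 1)
    m <- sample(10:40, 1)
    H <- matrix(rbinom(n * m, 1, runif(1, 0.2, 0.8)), n, m)
    pos <- sort(sample.int(5e5, m))
    hs <- make_haps(H, pos = pos)
    core <- sample(m, 1)
    for (s in c("left", "right")) {
      got <- ehh(hs, core, side = s, cfg = cfg)
      dir <- if (s == "left") -1 else 1
      want <- ehh_enum(H, pos, core, dir, cfg$ehh_cutoff,
                       cfg$max_extension_bp, cfg$max_gap_bp)
      expect_equal(got$dist, want$dist)
      expect_equal(got$ehh, want$ehh, tolerance = 1e-12)
      # monotone non-increasing decay
      expect_true(all(diff(got$ehh) <= 1e-12))
    }
  }
})

test_that("iHH integrates the clipped decay curve", {
  mk_curve <- function(ld, le, rd, re, reasons) {
    structure(tibble::tibble(side = rep(c("left", "right"),
                                        c(length(ld), length(rd))),
                             dist = c(ld, rd), ehh = c(le, re)),
              reason = reasons, core_index = 1L,
              class = c("ehh_curve", "tbl_df", "tbl", "data.frame"))
  }
  cfg <- scan_config(ehh_cutoff = 0.05)

  # curve pinned at the cutoff everywhere integrates to zero
  flat <- mk_curve(c(0, 500), c(0.05, 0.05), c(0, 500), c(0.05, 0.05),
                   c(left = "cutoff", right = "cutoff"))
  expect_equal(as.numeric(ihh(flat, cfg)), 0)

  # single decaying side: trapezoid closed form 0.5 * 1000 * 0.95
  tri <- mk_curve(0, 1, c(0, 1000), c(1, 0.05),
                  c(left = "cutoff", right = "cutoff"))
  expect_equal(as.numeric(ihh(tri, cfg)), 475)

  # truncation by gap/span makes the area undefined
  und <- mk_curve(c(0, 1000), c(1, 0.04), c(0, 1000), c(1, 0.5),
                  c(left = "cutoff", right = "gap"))
  expect_false(attr(ihh(und, cfg), "defined"))

  # random decaying curves match a fine-grid Riemann sum
  set.seed(46)
  for (r in 1:20) {
    k <- sample(4:12, 1)
    d <- c(0, sort(sample.int(2e5, k - 1)))
    e <- c(1, sort(runif(k - 1, 0, 0.9), decreasing = TRUE))
    e[k] <- runif(1, 0, cfg$ehh_cutoff)   # ends below the cutoff
    cur <- mk_curve(d, e, 0, 1, c(left = "cutoff", right = "cutoff"))
    area <- as.numeric(ihh(cur, cfg))
    grid <- seq(0, max(d), length.out = 2e5)
    vals <- approx(d, pmax(e - cfg$ehh_cutoff, 0), xout = grid)$y
    fine <- sum(diff(grid) * (head(vals, -1) + tail(vals, -1)) / 2)
    expect_equal(area, fine, tolerance = 1e-6)
  }
})

test_that("XP-EHH is symmetric, antisymmetric and standardized", {
  sim <- simulate_study(small_sim(seed = 9))
  h1 <- sim$hap_g1
  h2 <- sim$hap_g2
  cfg <- scan_config()

  same <- xpehh_scan(h1, h1, cfg)
  expect_true(all(same$raw[same$defined] == 0))

  ab <- xpehh_scan(h1, h2, cfg)
  ba <- xpehh_scan(h2, h1, cfg)
  expect_equal(ab$raw, -ba$raw)
  expect_equal(mean(ab$std[ab$defined]), 0, tolerance = 1e-9)
  expect_equal(sd(ab$std[ab$defined]), 1, tolerance = 1e-9)

  h2x <- hap_set(h2$haplo[, -1], h2$variants[-1, ], h2$samples)
  expect_error(xpehh_scan(h1, h2x), "variant list")
})

test_that("top-quantile selection applies the ceiling-with-ties rule", {
  set.seed(47)
  v <- sample(seq_len(46355))   # distinct scores
  sel <- top_quantile(v, 0.01)
  expect_identical(sel$n_selected, 464L)
  expect_equal(sel$threshold, sort(v, decreasing = TRUE)[464])

  expect_identical(top_quantile(runif(100), 0.05)$n_selected, 5L)

  tied <- c(10, 8, 8, 8, 5, 4, 3, 2, 1.5, 1)   # k = 2, 3-way boundary tie
  s2 <- top_quantile(tied, 0.2)
  expect_identical(s2$n_selected, 4L)
  expect_setequal(s2$indices, c(1, 2, 3, 4))

  expect_error(top_quantile(v, 0.6), "q must be")
  expect_error(top_quantile(rep(NA_real_, 5), 0.1), "no defined")
})

test_that("candidate building intersects tails and rescues null XP-EHH", {
  def <- c(FALSE, rep(TRUE, 9))
  cs <- build_candidates(c(1, 2, 3), c(2, 3, 4), def)
  expect_identical(cs$intersect_snps, c(2, 3))
  expect_identical(cs$rescue_snps, 1)
  expect_identical(cs$union, c(1, 2, 3))
  expect_length(intersect(cs$intersect_snps, cs$rescue_snps), 0)

  cs2 <- build_candidates(c(5, 6), c(8, 9), rep(TRUE, 10))
  expect_length(cs2$intersect_snps, 0)
  expect_length(cs2$rescue_snps, 0)

  cs3 <- build_candidates(c(5, 6), c(4, 5, 6, 7), rep(TRUE, 10))
  expect_identical(cs3$intersect_snps, c(5, 6))
})

test_that("gene annotation honours flanks and matches an all-pairs check", {
  genes <- tibble::tibble(chrom = "chr1", start = 500L, end = 2000L,
                          strand = "+", gene = "GENE1")
  snp_in <- tibble::tibble(chrom = "chr1", pos = 1000L, vid = "v1")
  expect_identical(annotate_genes(snp_in, genes, 0)$gene, "GENE1")

  snp_up <- tibble::tibble(chrom = "chr1", pos = 500L - 30000L + 2000L,
                           vid = "v2")  # 28 kb upstream of start
  expect_identical(nrow(annotate_genes(snp_up, genes, 25000)), 0L)

  set.seed(48)
  genes10 <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 10, TRUE),
    start = as.integer(sample.int(9e5, 10)), strand = "+",
    gene = sprintf("G%02d", 1:10)) |>
    dplyr::mutate(end = start + 30000L)
  snps5 <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 5, TRUE),
                          pos = as.integer(sample.int(1e6, 5)),
                          vid = sprintf("v%d", 1:5))
  flank <- 25000
  got <- annotate_genes(snps5, genes10, flank)
  want <- character(0)
  for (i in seq_len(10)) {
    for (j in seq_len(5)) {
      if (genes10$chrom[i] == snps5$chrom[j] &&
          snps5$pos[j] >= genes10$start[i] - flank &&
          snps5$pos[j] <= genes10$end[i] + flank) {
        want <- union(want, genes10$gene[i])
      }
    }
  }
  expect_setequal(got$gene, want)
})

test_that("annotation files round-trip through GFF3 and parse from BED", {
  genes <- tibble::tibble(chrom = c("chr1", "chr2"),
                          start = c(1000L, 5000L), end = c(4000L, 9000L),
                          strand = c("+", "-"), gene = c("ALPHA", "BETA"))
  p <- withr::local_tempfile(fileext = ".gff3")
  write_gene_annotation(genes, p)
  back <- read_gene_annotation(p)
  expect_equal(dplyr::arrange(back, .data$gene),
               dplyr::arrange(genes, .data$gene)[names(back)])

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t4000\tALPHA\t0\t+",
               "chr2\t4999\t9000\tBETA\t0\t-"), bed)
  bb <- read_gene_annotation(bed)
  expect_equal(bb$start, c(1000L, 5000L))
  writeLines("chr1\t1\t2", bed)
  expect_error(read_gene_annotation(bed), "line 1")
})
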