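#' Allele-frequency chi-squared test between two groups
#'
#' Pearson chi-squared (no continuity correction) on the 2x2 table of
#' reference/alternate allele counts in two groups, 1 degree of freedom. A
#' zero allele column (an allele absent from both groups) makes the
#' statistic undefined and is flagged rather than raised.
#'
#' @param counts_g1,counts_g2 length-2 integer vectors `(ref, alt)` of
#'   allele counts.
#' @return Tibble: `chisq`, `df`, `p`, `defined`.
#' @export
allele_chisq <- function(counts_g1, counts_g2) {
  stopifnot(length(counts_g1) == 2, length(counts_g2) == 2,
            all(c(counts_g1, counts_g2) >= 0))
  tab <- rbind(g1 = counts_g1, g2 = counts_g2)
  if (any(rowSums(tab) == 0)) stop("both groups need at least one allele")
  if (any(colSums(tab) == 0)) {
    return(tibble::tibble(chisq = NA_real_, df = 1L, p = NA_real_,
                          defined = FALSE))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(chisq = unname(ct$statistic), df = 1L,
                 p = unname(ct$p.value), defined = TRUE)
}

#' Genotype-phenotype association with a sex covariate
#'
#' Ordinary least squares of one haematological trait on genotype (unordered
#' factor) plus sex (factor), mirroring a general linear model with sex as a
#' covariate. The overall genotype effect is the F-test comparing the full
#' model against the sex-only model; adjusted (least-squares) genotype means
#' are predictions averaged over a balanced sex grid.
#'
#' @param ph phenotype tibble with columns `sample`, `sex` and the trait.
#' @param calls tibble with columns `sample`, `genotype` (e.g. `"CC"`,
#'   `"CT"`, `"TT"`).
#' @param trait name of the trait column in `ph`.
#' @return An object of class `assoc_fit` with [tidy()] (adjusted means) and
#'   [glance()] (overall F-test) methods.
#' @export
glm_association <- function(ph, calls, trait) {
  dat <- dplyr::inner_join(tibble::as_tibble(ph), tibble::as_tibble(calls),
                           by = "sample")
  stopifnot(trait %in% names(dat), "sex" %in% names(dat))
  dat <- dat[stats::complete.cases(dat[, c(trait, "sex", "genotype")]), ]
  dat$genotype <- factor(dat$genotype)
  dat$sex <- factor(dat$sex)
  counts <- table(dat$genotype)
  if (length(counts) < 2) stop("need at least 2 genotype classes")
  if (any(counts < 2)) {
    stop("genotype class with fewer than 2 samples: ",
         names(counts)[counts < 2][1])
  }
  dat$.y <- dat[[trait]]
  use_sex <- nlevels(dat$sex) > 1
  full <- if (use_sex) stats::lm(.y ~ genotype + sex, data = dat)
          else stats::lm(.y ~ genotype, data = dat)
  if (anyNA(stats::coef(full))) {
    stop("singular design: genotype is confounded with sex (aliased: ",
         paste(names(stats::coef(full))[is.na(stats::coef(full))],
               collapse = ", "), ")")
  }
  reduced <- if (use_sex) stats::lm(.y ~ sex, data = dat)
             else stats::lm(.y ~ 1, data = dat)
  an <- stats::anova(reduced, full)

  # adjusted means: predictions averaged over a balanced sex grid
  grid <- expand.grid(genotype = levels(dat$genotype),
                      sex = levels(dat$sex))
  grid$.fit <- stats::predict(full, newdata = grid)
  adj <- tibble::as_tibble(grid) |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(adj_mean = mean(.data$.fit), .groups = "drop") |>
    dplyr::mutate(n = as.integer(counts[as.character(.data$genotype)]))

  structure(list(fit = full, trait = trait, data = dat,
                 adjusted_means = adj,
                 f = an$F[2], p = an$`Pr(>F)`[2],
                 df_genotype = an$Df[2], df_residual = full$df.residual,
                 sigma = summary(full)$sigma),
            class = "assoc_fit")
}

#' @export
print.assoc_fit <- function(x, ...) {
  cat(sprintf("<assoc_fit> %s ~ genotype + sex (n = %d)\n", x$trait,
              nrow(x$data)))
  cat(sprintf("  genotype F(%d, %d) = %.3f, p = %.4g\n", x$df_genotype,
              x$df_residual, x$f, x$p))
  print(x$adjusted_means)
  invisible(x)
}

#' @export
tidy.assoc_fit <- function(x, ...) {
  dplyr::mutate(x$adjusted_means, trait = x$trait, .before = 1)
}

#' @export
glance.assoc_fit <- function(x, ...) {
  tibble::tibble(trait = x$trait, statistic = x$f, p.value = x$p,
                 df = x$df_genotype, df.residual = x$df_residual,
                 sigma = x$sigma, nobs = nrow(x$data))
}

# balanced-grid contrast vector for one genotype level
lsmean_contrast <- function(fit, level, genotype_levels, sex_levels) {
  grid <- expand.grid(genotype = factor(level, levels = genotype_levels),
                      sex = factor(sex_levels, levels = sex_levels))
  X <- stats::model.matrix(stats::delete.response(stats::terms(fit)), grid)
  colMeans(X)
}

#' Fisher's LSD post-hoc comparisons of adjusted genotype means
#'
#' Unadjusted pairwise t-tests on the adjusted (least-squares) means, using
#' the fitted model's residual variance and degrees of freedom. No
#' multiplicity correction is applied (Fisher's least significant
#' difference).
#'
#' @param x an `assoc_fit` from [glm_association()].
#' @return Tibble: `contrast`, `estimate` (difference of adjusted means),
#'   `se`, `t`, `df`, `p`.
#' @export
lsd_posthoc <- function(x) {
  stopifnot(inherits(x, "assoc_fit"))
  glev <- levels(x$data$genotype)
  slev <- levels(x$data$sex)
  if (length(glev) < 2) stop("need at least 2 genotype classes")
  V <- stats::vcov(x$fit)
  L <- vapply(glev, lsmean_contrast, numeric(ncol(V)), fit = x$fit,
              genotype_levels = glev, sex_levels = slev)
  means <- drop(crossprod(L, stats::coef(x$fit)))
  pairs <- utils::combn(glev, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    cvec <- L[, pr[1]] - L[, pr[2]]
    est <- unname(means[pr[1]] - means[pr[2]])
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tval <- est / se
    tibble::tibble(contrast = paste(pr[1], "-", pr[2]), estimate = est,
                   se = se, t = tval, df = x$df_residual,
                   p = 2 * stats::pt(-abs(tval), x$df_residual))
  })
}

#' Highland vs lowland trait comparison
#'
#' Welch two-sample t-test of one trait between a highland and a lowland
#' phenotype table, overall and stratified by sex. Two groups with zero
#' variance and equal means give t = 0, p = 1 by convention.
#'
#' @param ph_high,ph_low phenotype tibbles (`sample`, `sex`, traits).
#' @param trait trait column name.
#' @return Tibble with rows `overall` and one per shared sex: `stratum`,
#'   `n_high`, `n_low`, `mean_high`, `mean_low`, `t`, `df`, `p`.
#' @export
group_trait_compare <- function(ph_high, ph_low, trait) {
  one <- function(xh, xl, label) {
    xh <- xh[!is.na(xh)]
    xl <- xl[!is.na(xl)]
    if (length(xh) < 2 || length(xl) < 2) {
      return(tibble::tibble(stratum = label, n_high = length(xh),
                            n_low = length(xl), mean_high = mean(xh),
                            mean_low = mean(xl), t = NA_real_,
                            df = NA_real_, p = NA_real_))
    }
    if (stats::sd(xh) == 0 && stats::sd(xl) == 0) {
      eq <- isTRUE(all.equal(mean(xh), mean(xl)))
      return(tibble::tibble(stratum = label, n_high = length(xh),
                            n_low = length(xl), mean_high = mean(xh),
                            mean_low = mean(xl),
                            t = if (eq) 0 else Inf, df = NA_real_,
                            p = if (eq) 1 else 0))
    }
    tt <- stats::t.test(xh, xl)
    tibble::tibble(stratum = label, n_high = length(xh),
                   n_low = length(xl), mean_high = mean(xh),
                   mean_low = mean(xl), t = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value)
  }
  out <- one(ph_high[[trait]], ph_low[[trait]], "overall")
  for (s in sort(intersect(unique(ph_high$sex), unique(ph_low$sex)))) {
    out <- dplyr::bind_rows(
      out, one(ph_high[[trait]][ph_high$sex == s],
               ph_low[[trait]][ph_low$sex == s], s))
  }
  out
}

#' Read / write a phenotype table
#'
#' Tab-separated: `sample`, `sex`, then the six haematological traits RBC
#' (10^12/L), HGB (g/L), HCT (fraction), MCV (fL), MCH (pg), MCHC (g/L).
#'
#' @param path file path.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  readr::read_tsv(path, comment = "#", col_types = readr::cols(
    sample = "c", sex = "c", .default = "d"), progress = FALSE)
}

#' @rdname read_phenotypes
#' @param ph phenotype tibble.
#' @export
write_phenotypes <- function(ph, path) {
  readr::write_tsv(ph, path)
  invisible(path)
}
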