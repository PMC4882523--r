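#' Manhattan-style plot of a selection scan
#'
#' F_ST (theta) and standardized XP-EHH along the genome, with candidate
#' SNPs highlighted.
#'
#' @param scan scan tibble from [run_scan()] (or [fst_scan()] output with
#'   optional `xpehh_std`/`candidate` columns).
#' @return A ggplot object.
#' @export
plot_selection_scan <- function(scan) {
  scan <- tibble::as_tibble(scan)
  long <- scan |>
    dplyr::mutate(candidate = if ("candidate" %in% names(scan)) {
      .data$candidate
    } else FALSE) |>
    tidyr::pivot_longer(
      dplyr::any_of(c("theta", "xpehh_std")),
      names_to = "statistic", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(.data$pos / 1e6, .data$value,
                                     colour = .data$candidate)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_grid(statistic ~ chrom, scales = "free",
                        space = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot MDS coordinates coloured by group
#'
#' @param mds tibble from [classical_mds()] (columns `sample`, `C1`, `C2`).
#' @param pm population map tibble.
#' @return A ggplot object.
#' @export
plot_mds <- function(mds, pm) {
  dat <- dplyr::left_join(mds, pm, by = "sample")
  ggplot2::ggplot(dat, ggplot2::aes(.data$C1, .data$C2,
                                    colour = .data$group,
                                    shape = .data$breed)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Component 1", y = "Component 2") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ehh_curve <- function(object, ...) {
  dat <- dplyr::mutate(object,
                       dist = ifelse(.data$side == "left", -.data$dist,
                                     .data$dist))
  ggplot2::ggplot(dat, ggplot2::aes(.data$dist / 1000, .data$ehh,
                                    group = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "distance from core (kb)", y = "EHH") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.assoc_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$genotype, .data$.y)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5, size = 1) +
    ggplot2::geom_point(data = object$adjusted_means,
                        ggplot2::aes(.data$genotype, .data$adj_mean),
                        colour = "red", size = 3, shape = 18) +
    ggplot2::labs(x = "genotype", y = object$trait,
                  subtitle = sprintf("genotype F = %.2f, p = %.3g",
                                     object$f, object$p)) +
    ggplot2::theme_minimal()
}
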