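#' Tidiers and plots for scan results
#'
#' `tidy()` returns the per-window / per-test table; `glance()` a one-row
#' summary; `autoplot()` a ggplot.
#'
#' @param x A `candidate_windows`, `wilcoxon_enrichment` or `ehh_curve`
#'   object.
#' @param ... Unused.
#' @name tropiscan-tidiers
NULL

#' @rdname tropiscan-tidiers
#' @export
tidy.candidate_windows <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' @rdname tropiscan-tidiers
#' @export
glance.candidate_windows <- function(x, ...) {
  tibble(
    n_windows = nrow(x),
    n_in_top = sum(x$in_top),
    n_retained = sum(x$retained),
    n_excluded_by_control = sum(x$excluded_by_control),
    n_merged = nrow(merge_intervals(x)),
    top_n = attr(x, "top_n"),
    alpha = attr(x, "alpha")
  )
}

#' @rdname tropiscan-tidiers
#' @param object A `candidate_windows` object.
#' @export
autoplot.candidate_windows <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = (start + end) / 2, y = max_rsb)) +
    ggplot2::geom_point(ggplot2::aes(colour = retained), size = 0.8) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "window midpoint (bp)", y = "max Rsb",
                  colour = "retained") +
    ggplot2::theme_minimal()
}

#' @rdname tropiscan-tidiers
#' @export
tidy.wilcoxon_enrichment <- function(x, ...) {
  tibble(
    statistic = x$statistic, z = x$z, p.value = x$p.value,
    alternative = x$alternative, method = x$method,
    mean_selected = x$mean_selected, mean_control = x$mean_control,
    n_selected = x$n_selected, n_control = x$n_control
  )
}

#' @rdname tropiscan-tidiers
#' @export
glance.wilcoxon_enrichment <- function(x, ...) tidy(x)

#' @rdname tropiscan-tidiers
#' @export
autoplot.wilcoxon_enrichment <- function(object, ...) {
  d <- bind_rows(
    tibble(group = "selected", donor_fraction = object$values_selected),
    tibble(group = "control", donor_fraction = object$values_control)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = group, y = donor_fraction)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "donor ancestry fraction") +
    ggplot2::theme_minimal()
}

#' @rdname tropiscan-tidiers
#' @export
autoplot.ehh_curve <- function(object, ...) {
  core_pos <- attr(object, "core_pos")
  d <- bind_rows(
    as_tibble(object),
    tibble(side = "core", site = attr(object, "core_site"),
           pos = core_pos, value = 1)
  ) %>% arrange(pos)
  ggplot2::ggplot(d, ggplot2::aes(x = pos, y = value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = core_pos, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "position (bp)",
                  y = attr(object, "statistic")) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of an Rsb scan
#'
#' @param scan A scan tibble from [rsb_scan()] (optionally with `perm_p`).
#' @param alpha Significance threshold used for colouring when `perm_p`
#'   is present.
#' @return A ggplot object.
#' @export
plot_scan <- function(scan, alpha = 0.05) {
  d <- scan %>% filter(!is.na(rsb))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = pos, y = rsb))
  if ("perm_p" %in% names(d)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = perm_p < alpha),
                                 size = 0.5) +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                              `TRUE` = "firebrick"))
  } else {
    p <- p + ggplot2::geom_point(size = 0.5, colour = "grey40")
  }
  p + ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "Rsb") +
    ggplot2::theme_minimal()
}
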