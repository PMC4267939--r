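#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a site frequency spectrum
#'
#' Bar plot of the SFS, optionally dropping the (usually dominant)
#' monomorphic classes.
#'
#' @param object An [new_sfs()] object.
#' @param polymorphic_only Drop classes 0 and n (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sfs
#' @export
autoplot.sfs <- function(object, polymorphic_only = TRUE, ...) {
  df <- tibble::as_tibble(object)
  n <- attr(object, "n")
  if (polymorphic_only) df <- df[df$i > 0 & df$i < n, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = sprintf("haplotypes carrying the %s-codon state", attr(object, "focal")),
      y = "sites"
    ) +
    ggplot2::theme_minimal()
}

#' Plot observed vs fitted site frequency spectrum
#'
#' @param object An `sfs_fit` from [fit_sfs_model()].
#' @param polymorphic_only Drop classes 0 and n (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sfs_fit
#' @export
autoplot.sfs_fit <- function(object, polymorphic_only = TRUE, ...) {
  n <- object$n
  p <- expected_sfs(object$params, n)
  df <- tibble::tibble(
    i = 0:n,
    observed = object$counts,
    fitted = p * sum(object$counts)
  )
  if (polymorphic_only) df <- df[df$i > 0 & df$i < n, ]
  df <- tidyr::pivot_longer(df, c("observed", "fitted"),
    names_to = "series", values_to = "sites"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$i, y = .data$sites,
    fill = .data$series
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "focal-state count", y = "sites") +
    ggplot2::theme_minimal()
}

#' Plot binned selection estimates with confidence intervals
#'
#' @param binned Output of [fit_binned()].
#' @return A ggplot object.
#' @export
plot_gamma_bins <- function(binned) {
  ggplot2::ggplot(binned, ggplot2::aes(x = factor(.data$bin), y = .data$gamma)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$gamma_lo, ymax = .data$gamma_hi),
      width = 0.2, na.rm = TRUE
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "bin", y = expression(hat(gamma))) +
    ggplot2::theme_minimal()
}
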