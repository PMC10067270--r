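#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a global epistasis fit
#'
#' One row per regression term, in the usual broom column layout.
#'
#' @param x A `ge_ols` object from [ols_fit()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.ge_ols <- function(x, ...) {
  if (x$degenerate) {
    return(tibble::tibble(term = c("(Intercept)", "F_B"),
                          estimate = NA_real_, std.error = NA_real_,
                          statistic = NA_real_, p.value = NA_real_))
  }
  stat <- if (x$slope_se == 0) {
    if (x$slope == 0) 0 else Inf * sign(x$slope)
  } else {
    x$slope / x$slope_se
  }
  tibble::tibble(
    term = c("(Intercept)", "F_B"),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, x$slope_se),
    statistic = c(NA_real_, stat),
    p.value = c(NA_real_, x$p_value)
  )
}

#' @rdname tidy.ge_ols
#' @export
glance.ge_ols <- function(x, ...) {
  tibble::tibble(focal = x$focal, n_points = x$n_points, slope = x$slope,
                 intercept = x$intercept, r_squared = x$r_squared,
                 p_value = x$p_value, mean_dF = x$mean_dF,
                 degenerate = x$degenerate)
}

#' @rdname tidy.ge_ols
#' @param object A `ge_ols` object.
#' @export
autoplot.ge_ols <- function(object, ...) {
  p <- ggplot2::ggplot(object$points,
                       ggplot2::aes(x = .data$F_B, y = .data$dF)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = expression(F[B]), y = expression(Delta * F),
      title = if (is.na(object$focal)) NULL else {
        paste("Global epistasis of", object$focal)
      }) +
    ggplot2::theme_minimal()
  if (!object$degenerate) {
    p <- p + ggplot2::geom_abline(slope = object$slope,
                                  intercept = object$intercept)
  }
  p
}

#' Tidy a slope decomposition
#'
#' `tidy()` returns the per-partner table; `glance()` the one-row summary
#' with the predicted slope and intercept.
#'
#' @param x A `slope_decomposition` from [decompose_slope()].
#' @param ... Unused.
#' @export
tidy.slope_decomposition <- function(x, ...) {
  dplyr::mutate(x$partners, focal = x$focal, .before = 1L)
}

#' @rdname tidy.slope_decomposition
#' @export
glance.slope_decomposition <- function(x, ...) {
  tibble::tibble(focal = x$focal, mode = x$mode,
                 n_partners = nrow(x$partners),
                 predicted_slope = x$predicted_slope,
                 predicted_intercept = x$predicted_intercept,
                 degenerate = x$degenerate)
}

#' @rdname tidy.slope_decomposition
#' @param object A `slope_decomposition` object.
#' @export
autoplot.slope_decomposition <- function(object, ...) {
  dat <- dplyr::filter(object$partners, !is.na(.data$product))
  ggplot2::ggplot(dat,
                  ggplot2::aes(x = .data$avg_epistasis, y = .data$avg_effect,
                               size = abs(.data$product),
                               colour = .data$avg_epistasis > 0)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_text(ggplot2::aes(label = .data$partner),
                       size = 3, vjust = -1.2, show.legend = FALSE) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#2e7d32", `FALSE` = "#c62828"),
      labels = c(`TRUE` = "positive", `FALSE` = "negative")) +
    ggplot2::labs(
      x = "average pairwise epistasis",
      y = "average background effect",
      size = "|contribution|", colour = "epistasis sign",
      title = paste("Slope decomposition for", object$focal)) +
    ggplot2::theme_minimal()
}

#' Faceted global epistasis plot of a landscape
#'
#' One panel per focal mutation: the `(F_B, dF)` scatter with its
#' least-squares line.
#'
#' @param landscape A [landscape][as_landscape].
#' @param focal Loci to plot (default all).
#' @param alpha Significance level forwarded to [ge_fit()].
#' @return A ggplot object.
#' @export
plot_global_epistasis <- function(landscape, focal = NULL, alpha = 0.05) {
  foci <- if (is.null(focal)) locus_names(landscape) else focal
  pts <- purrr::map_dfr(foci, function(lc) {
    dplyr::mutate(ge_scatter(landscape, lc), focal = lc)
  })
  fits <- dplyr::filter(ge_fit(landscape, alpha = alpha),
                        .data$focal %in% foci, !.data$degenerate)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$F_B, y = .data$dF)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_abline(
      data = fits,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept)) +
    ggplot2::facet_wrap(~focal) +
    ggplot2::labs(x = expression(F[B]), y = expression(Delta * F)) +
    ggplot2::theme_minimal()
}
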