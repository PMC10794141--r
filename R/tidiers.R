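#' Tidiers for fitted result objects
#'
#' broom-style `tidy()` and `glance()` methods for the package's result
#' classes, so results drop straight into dplyr pipelines.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name demic-tidiers
NULL

#' @rdname demic-tidiers
#' @export
tidy.founder_regression <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "distance_km"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname demic-tidiers
#' @export
glance.founder_regression <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, p.value = x$p_value, nobs = x$n)
}

#' @rdname demic-tidiers
#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(estimate = x$r, p.value = x$p,
                 n.perm = x$n_perm, conditioned.on = x$conditioned_on)
}

#' @rdname demic-tidiers
#' @export
glance.mantel_result <- function(x, ...) tidy.mantel_result(x, ...)

#' @rdname demic-tidiers
#' @export
tidy.fstat_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, pops = x$pops,
                 estimate = x$estimate, std.error = x$se, z = x$z)
}

#' @rdname demic-tidiers
#' @export
tidy.procrustes_fit <- function(x, ...) {
  tibble::tibble(correlation = x$correlation, scale = x$scale,
                 p.value = x$p, n.perm = x$n_perm)
}

#' @rdname demic-tidiers
#' @export
glance.procrustes_fit <- function(x, ...) tidy.procrustes_fit(x, ...)

#' @rdname demic-tidiers
#' @export
tidy.admixture_date <- function(x, ...) {
  tibble::tibble(estimate = x$t_hat, admixture.fraction = 1 - x$m_hat,
                 conf.low = x$ci_lo, conf.high = x$ci_hi,
                 n.tracts = x$n_tracts)
}

#' Plot a per-population statistic against distance from the origin
#'
#' Scatter of the statistic versus great-circle distance from the
#' origin with the OLS fit overlaid: the serial-founder diagnostic view.
#'
#' @param values Tibble with `population` and a statistic column.
#' @param manifest Sample manifest.
#' @param origin `(lat, lon)` origin.
#' @param stat Optional statistic column name.
#' @return A ggplot object.
#' @export
plot_diversity_decline <- function(values, manifest, origin, stat = NULL) {
  values <- tibble::as_tibble(values)
  if (is.null(stat)) stat <- setdiff(names(values), "population")[1]
  d <- dplyr::inner_join(values, distance_from_origin(manifest, origin),
                         by = "population")
  ggplot2::ggplot(d, ggplot2::aes(.data$distance_km, .data[[stat]])) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dashed") +
    ggplot2::labs(x = "distance from origin (km)", y = stat) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.genotype_pca <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point() +
    ggplot2::theme_minimal()
}
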