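#' Labelled symmetric distance matrix
#'
#' Shared container for genetic (`fst`), geographic (`geographic_km`)
#' and linguistic (`linguistic`) population distance matrices.
#'
#' @param values Symmetric numeric matrix with zero diagonal.
#' @param labels Population labels (defaults to `rownames(values)`).
#' @param kind One of `"fst"`, `"geographic_km"`, `"linguistic"`.
#' @return A `dist_matrix`.
#' @export
dist_matrix <- function(values, labels = rownames(values),
                        kind = c("fst", "geographic_km", "linguistic")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(labels)) stop("dist_matrix: labels required")
  if (nrow(values) != ncol(values) || nrow(values) != length(labels))
    stop("dist_matrix: values must be square with one row per label")
  if (max(abs(values - t(values)), na.rm = TRUE) > 1e-8)
    stop("dist_matrix: values not symmetric")
  dimnames(values) <- list(labels, labels)
  diag(values) <- 0
  structure(list(labels = as.character(labels), values = values, kind = kind),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("<dist_matrix> kind '", x$kind, "', ", length(x$labels),
      " populations\n", sep = "")
  print(round(x$values[seq_len(min(5, nrow(x$values))),
                       seq_len(min(5, ncol(x$values)))], 4))
  invisible(x)
}

#' Upper-triangle pair tibble of a distance matrix
#'
#' Pairs are emitted in column-major upper-triangle order (the order
#' `combn()` of the labels produces), the pair order shared by every
#' consumer in the package.
#'
#' @param x A [dist_matrix()].
#' @param ... Unused.
#' @return Tibble with `pop1`, `pop2`, `value`.
#' @export
as_tibble.dist_matrix <- function(x, ...) {
  p <- combn(x$labels, 2)
  tibble::tibble(pop1 = p[1, ], pop2 = p[2, ],
                 value = x$values[lower.tri(x$values)])
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

upper_vec <- function(x) x$values[lower.tri(x$values)]  # combn-ordered

align_dist <- function(x, template) {
  if (!setequal(x$labels, template$labels))
    stop("distance matrices carry different label sets")
  i <- match(template$labels, x$labels)
  dist_matrix(x$values[i, i], template$labels[seq_along(i)], x$kind)
}

#' Reorder / subset a distance matrix by labels
#'
#' @param x A [dist_matrix()].
#' @param labels Labels to keep, in the desired order.
#' @return A [dist_matrix()].
#' @export
subset_dist <- function(x, labels) {
  miss <- setdiff(labels, x$labels)
  if (length(miss)) stop("subset_dist: label(s) absent: ",
                         paste(miss, collapse = ", "))
  i <- match(labels, x$labels)
  dist_matrix(x$values[i, i, drop = FALSE], labels, x$kind)
}

#' Write / read a labelled distance matrix as TSV
#'
#' First row and first column hold the labels.
#'
#' @param x A [dist_matrix()].
#' @param path File path.
#' @param kind Matrix kind for [read_dist_matrix()].
#' @return `path` / a [dist_matrix()].
#' @export
write_dist_matrix <- function(x, path) {
  write.table(x$values, path, quote = FALSE, sep = "\t",
              row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @export
read_dist_matrix <- function(path, kind = "fst") {
  v <- as.matrix(read.table(path, header = TRUE, sep = "\t", row.names = 1,
                            check.names = FALSE))
  dist_matrix(v, rownames(v), kind)
}

#' @export
autoplot.dist_matrix <- function(object, ...) {
  d <- as_tibble(object)
  d <- dplyr::bind_rows(d, dplyr::rename(d, pop1 = "pop2", pop2 = "pop1"))
  ggplot2::ggplot(d, ggplot2::aes(.data$pop1, .data$pop2,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = object$kind) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
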