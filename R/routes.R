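#' Origin-anchored FST profile
#'
#' Extracts the origin population's row of a pairwise FST matrix, origin
#' excluded: the genetic distance of every other population from the
#' expansion source.
#'
#' @param fst A [dist_matrix()] of kind `"fst"`.
#' @param origin Origin population label.
#' @return Tibble with `population`, `fst`.
#' @export
origin_fst_profile <- function(fst, origin) {
  if (!origin %in% fst$labels)
    stop("origin_fst_profile: origin '", origin, "' absent from matrix")
  others <- setdiff(fst$labels, origin)
  tibble::tibble(population = others,
                 fst = unname(fst$values[origin, others]))
}

#' Trace expansion routes by nearest genetic distance
#'
#' Origin-seeded Prim accretion: starting from the origin population,
#' repeatedly attach the unattached population with the smallest FST to
#' any attached population, directing the edge outward.  Ties are broken
#' by smaller great-circle distance, then lexicographic label.  The
#' result is a spanning tree (equivalently the minimum spanning tree of
#' the FST graph) rooted at the origin.  Populations listed in `exclude`
#' are removed before tracing, which is how leave-one-out sensitivity
#' (does removing a hub rewire its children?) is run.
#'
#' @param fst A [dist_matrix()] of kind `"fst"`.
#' @param manifest Sample manifest with population coordinates.
#' @param origin Origin population label.
#' @param exclude Optional labels to drop before tracing.
#' @return A `route_graph`: list with `edges` (tibble: `parent`,
#'   `child`, `fst`, `km`, `step`), `nodes` (tibble with coordinates)
#'   and `root`.
#' @export
trace_routes <- function(fst, manifest, origin, exclude = NULL) {
  labels <- setdiff(fst$labels, exclude)
  if (!origin %in% labels)
    stop("trace_routes: origin '", origin, "' not among included labels")
  fst <- subset_dist(fst, labels)
  geo <- subset_dist(great_circle_matrix(
    manifest[manifest$population %in% labels, ]), labels)
  P <- length(labels)
  w <- fst$values
  if (anyNA(w)) {
    usable <- rowSums(is.na(w)) < P - 1
    if (!all(usable))
      stop("trace_routes: population(s) with no usable FST: ",
           paste(labels[!usable], collapse = ", "))
  }
  attached <- labels == origin
  edges <- list()
  for (step in seq_len(P - 1)) {
    cand <- expand.grid(from = which(attached), to = which(!attached))
    cand$fst <- w[cbind(cand$from, cand$to)]
    cand <- cand[!is.na(cand$fst), ]
    if (nrow(cand) == 0)
      stop("trace_routes: graph disconnected after NaN pruning")
    cand$km <- geo$values[cbind(cand$from, cand$to)]
    cand <- cand[order(cand$fst, cand$km, labels[cand$to],
                       labels[cand$from]), ]
    best <- cand[1, ]
    edges[[step]] <- tibble::tibble(
      parent = labels[best$from], child = labels[best$to],
      fst = best$fst, km = best$km, step = step)
    attached[best$to] <- TRUE
  }
  coords <- dplyr::distinct(manifest[manifest$population %in% labels, ],
                            .data$population, .data$latitude,
                            .data$longitude)
  structure(list(edges = dplyr::bind_rows(edges), nodes = coords,
                 root = origin),
            class = "route_graph")
}

#' @export
print.route_graph <- function(x, ...) {
  cat("<route_graph> rooted at '", x$root, "', ", nrow(x$edges),
      " edges over ", nrow(x$nodes), " populations\n", sep = "")
  invisible(x)
}

#' @export
autoplot.route_graph <- function(object, ...) {
  e <- object$edges |>
    dplyr::left_join(dplyr::rename(object$nodes, parent = "population",
                                   lat0 = "latitude", lon0 = "longitude"),
                     by = "parent") |>
    dplyr::left_join(dplyr::rename(object$nodes, child = "population",
                                   lat1 = "latitude", lon1 = "longitude"),
                     by = "child")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = e,
      ggplot2::aes(x = .data$lon0, y = .data$lat0, xend = .data$lon1,
                   yend = .data$lat1, colour = .data$fst),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_point(data = object$nodes,
                        ggplot2::aes(.data$longitude, .data$latitude)) +
    ggplot2::scale_colour_viridis_c(name = "FST") +
    ggplot2::labs(x = "longitude", y = "latitude") +
    ggplot2::theme_minimal()
}

#' Hexagonal FST-gradient surface
#'
#' Inverse-distance-weighted interpolation of an origin-anchored FST
#' profile onto the centres of a pointy-top hexagonal grid covering the
#' populations' bounding box, followed by a finite-difference gradient
#' estimate from each cell's six neighbours (exact for planar fields).
#' Cells with no population within `cutoff_deg` are flagged empty.
#'
#' @param fst_profile Tibble with `population`, `fst` (e.g. from
#'   [origin_fst_profile()]).
#' @param manifest Sample manifest with population coordinates.
#' @param hex_size Centre-to-centre hexagon spacing in degrees.
#' @param idw_power Inverse-distance weighting exponent (default 2).
#' @param cutoff_deg Interpolation support radius in degrees (default
#'   `Inf`: every cell is filled).
#' @return A `gradient_surface` tibble: `lat`, `lon`, `value`,
#'   `gradient` (per degree; `NA` on boundary cells), `empty`.
#' @export
gengrad_surface <- function(fst_profile, manifest, hex_size = 1,
                            idw_power = 2, cutoff_deg = Inf) {
  pts <- dplyr::distinct(
    manifest[manifest$population %in% fst_profile$population, ],
    .data$population, .data$latitude, .data$longitude) |>
    dplyr::inner_join(fst_profile, by = "population")
  if (nrow(pts) < 4) stop("gengrad_surface: need >= 4 populations")

  dx <- hex_size; dy <- hex_size * sqrt(3) / 2
  lon0 <- min(pts$longitude) - dx; lon1 <- max(pts$longitude) + dx
  lat0 <- min(pts$latitude) - dy; lat1 <- max(pts$latitude) + dy
  rows <- seq(lat0, lat1, by = dy)
  cells <- dplyr::bind_rows(lapply(seq_along(rows), function(ri) {
    off <- if (ri %% 2 == 0) dx / 2 else 0
    tibble::tibble(row = ri, lat = rows[ri],
                   lon = seq(lon0 + off, lon1, by = dx))
  }))

  interp <- function(lat, lon) {
    d <- sqrt((pts$latitude - lat)^2 + (pts$longitude - lon)^2)
    if (all(d > cutoff_deg)) return(NA_real_)
    use <- d <= cutoff_deg
    if (any(d[use] < 1e-9)) return(pts$fst[use][which.min(d[use])])
    w <- 1 / d[use]^idw_power
    sum(w * pts$fst[use]) / sum(w)
  }
  cells$value <- mapply(interp, cells$lat, cells$lon)
  cells$empty <- is.na(cells$value)

  # gradient from the six neighbour differences: for unit direction
  # vectors u_i of a hexagon, sum_i u_i u_i' = 3 I, so
  # grad = sum_i (v_i - v_0) u_i / (3 d) exactly for planar fields
  grad <- rep(NA_real_, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    if (cells$empty[i]) next
    # triangular-lattice neighbours: same row at 0/180 degrees, adjacent
    # rows at +-60/+-120
    ang <- (seq_len(6) - 1) * pi / 3
    nb_lon <- cells$lon[i] + hex_size * cos(ang)
    nb_lat <- cells$lat[i] + hex_size * sin(ang)
    gx <- 0; gy <- 0; complete <- TRUE
    for (q in seq_len(6)) {
      d2 <- (cells$lon - nb_lon[q])^2 + (cells$lat - nb_lat[q])^2
      j <- which.min(d2)
      if (d2[j] > (0.25 * hex_size)^2 || cells$empty[j]) {
        complete <- FALSE
        break
      }
      dv <- cells$value[j] - cells$value[i]
      gx <- gx + dv * cos(ang[q])
      gy <- gy + dv * sin(ang[q])
    }
    if (complete)
      grad[i] <- sqrt(gx^2 + gy^2) / (3 * hex_size)
  }
  cells$gradient <- grad
  out <- cells[, c("lat", "lon", "value", "gradient", "empty")]
  attr(out, "hex_size") <- hex_size
  attr(out, "idw_power") <- idw_power
  class(out) <- c("gradient_surface", class(out))
  out
}

#' @export
autoplot.gradient_surface <- function(object, ...) {
  ggplot2::ggplot(object[!object$empty, ],
                  ggplot2::aes(.data$lon, .data$lat)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$gradient), shape = 18,
                        size = 4) +
    ggplot2::scale_colour_viridis_c(name = "FST gradient") +
    ggplot2::labs(x = "longitude", y = "latitude") +
    ggplot2::theme_minimal()
}
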