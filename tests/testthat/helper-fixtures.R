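# Shared fixture builders, all programmatic.

make_panel <- function(haps, chrom = NULL, pos_bp = NULL, pos_cM = NULL,
                       ids = NULL) {
  haps <- as.matrix(haps)
  L <- ncol(haps)
  if (is.null(chrom)) chrom <- rep("1", L)
  if (is.null(pos_bp)) pos_bp <- stats::ave(seq_len(L), chrom,
                                            FUN = seq_along) * 100000L
  if (is.null(pos_cM)) pos_cM <- pos_bp / 1e6   # 1 cM/Mb
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(nrow(haps) / 2))
  genotype_panel(haps, data.frame(chrom = chrom, pos_bp = pos_bp,
                                  pos_cM = pos_cM), ids)
}

rand_panel <- function(n_samples, L, miss_rate = 0, n_chrom = 1) {
  h <- matrix(rbinom(2 * n_samples * L, 1, 0.5), nrow = 2 * n_samples)
  if (miss_rate > 0)
    h[runif(length(h)) < miss_rate] <- NA_integer_
  chrom <- as.character(rep(seq_len(n_chrom), each = ceiling(L / n_chrom))[
    seq_len(L)])
  make_panel(h, chrom = chrom)
}

make_manifest <- function(populations, n_each = 1, lat = NULL, lon = NULL,
                          group = "E-BSP", flags = "") {
  P <- length(populations)
  if (is.null(lat)) lat <- seq(0, -10, length.out = P)
  if (is.null(lon)) lon <- seq(10, 30, length.out = P)
  tibble::tibble(
    sample_id = as.vector(vapply(seq_len(P), function(i)
      sprintf("%s_%02d", populations[i], seq_len(n_each)),
      character(n_each))),
    population = rep(populations, each = n_each),
    country = "synthetic",
    linguistic_group = rep(group, length.out = P * n_each),
    latitude = rep(lat, each = n_each),
    longitude = rep(lon, each = n_each),
    qc_flags = rep(flags, length.out = P * n_each))
}

# manifest matching a panel one-sample-per-id, one population per sample
panel_manifest <- function(panel, populations) {
  n <- n_samples(panel)
  pops <- rep(populations, length.out = n)
  u <- unique(pops)
  lat <- seq(0, -10, length.out = length(u))[match(pops, u)]
  lon <- seq(10, 30, length.out = length(u))[match(pops, u)]
  tibble::tibble(sample_id = panel$sample_ids, population = pops,
                 country = "synthetic", linguistic_group = "E-BSP",
                 latitude = lat, longitude = lon, qc_flags = "")
}

# exhaustive minimum-spanning-tree weight via Prufer-sequence enumeration
prufer_decode <- function(seq, n) {
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, n - 1, 2)
  k <- 0
  for (s in seq) {
    leaf <- which(degree == 1L)[1]
    k <- k + 1
    edges[k, ] <- c(leaf, s)
    degree[leaf] <- degree[leaf] - 1L
    degree[s] <- degree[s] - 1L
  }
  rest <- which(degree == 1L)
  edges[n - 1, ] <- rest
  edges
}

exhaustive_mst_weight <- function(w) {
  n <- nrow(w)
  if (n == 2) return(w[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (i in seq_len(nrow(seqs))) {
    e <- prufer_decode(seqs[i, ], n)
    tw <- sum(w[e])
    if (tw < best) best <- tw
  }
  best
}

# expected distinct-haplotype count under hypergeometric subsampling
rarefied_expectation <- function(counts, g) {
  n <- sum(counts)
  sum(1 - choose(n - counts, g) / choose(n, g))
}

# pairwise graph distances (in edges) over a founding tree, labelled by cell
igraph_free_tree_dist <- function(truth) {
  e <- truth$founding_edges
  nodes <- sort(unique(c(truth$origin_cell, e$parent, e$child)))
  adj <- stats::setNames(vector("list", length(nodes)), as.character(nodes))
  for (i in seq_len(nrow(e))) {
    p <- as.character(e$parent[i]); ch <- as.character(e$child[i])
    adj[[p]] <- c(adj[[p]], ch)
    adj[[ch]] <- c(adj[[ch]], p)
  }
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(as.character(nodes),
                                         as.character(nodes)))
  for (s in as.character(nodes)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) {
        if (d[s, v] > d[s, u] + 1) {
          d[s, v] <- d[s, u] + 1
          queue <- c(queue, v)
        }
      }
    }
  }
  d
}
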