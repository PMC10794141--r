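#' Per-population allele frequencies
#'
#' Missing alleles are excluded per SNP per population, so each SNP has
#' its own effective haplotype count.
#'
#' @param panel A [genotype_panel()].
#' @param manifest Sample manifest.
#' @return List with `p` (populations x SNPs frequency matrix) and `n`
#'   (populations x SNPs haplotype counts).
#' @export
population_freqs <- function(panel, manifest) {
  pops <- haplotype_populations(panel, manifest)
  h <- panel$haplotypes
  ones <- rowsum(ifelse(is.na(h), 0L, h), pops)
  used <- rowsum((!is.na(h)) * 1L, pops)
  p <- ones / used
  p[used == 0] <- NA_real_
  list(p = p, n = used)
}

#' Hudson pairwise FST matrix
#'
#' Ratio-of-averages Hudson estimator: per SNP the numerator is
#' \eqn{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)} and the
#' denominator \eqn{p_1(1-p_2) + p_2(1-p_1)}, with `n` counted in
#' haplotypes; SNP-wise sums are taken before the ratio.  SNPs with
#' fewer than two usable haplotypes in either population are excluded
#' for that pair; a pair with a zero pooled denominator (no variation)
#' is `NaN` with a warning.
#'
#' @inheritParams population_freqs
#' @return A [dist_matrix()] of kind `"fst"`.
#' @export
hudson_fst_matrix <- function(panel, manifest) {
  fr <- population_freqs(panel, manifest)
  pops <- rownames(fr$p)
  P <- length(pops)
  if (P < 2) stop("hudson_fst_matrix: need >= 2 populations")
  v <- matrix(0, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1)) for (j in seq(i + 1, P)) {
    v[i, j] <- v[j, i] <- hudson_fst_pair(
      fr$p[i, ], fr$n[i, ], fr$p[j, ], fr$n[j, ])
  }
  if (any(is.nan(v)))
    warning("hudson_fst_matrix: pair(s) with no usable variation set to NaN")
  dist_matrix(v, pops, "fst")
}

hudson_fst_pair <- function(p1, n1, p2, n2) {
  ok <- !is.na(p1) & !is.na(p2) & n1 >= 2 & n2 >= 2
  if (!any(ok)) return(NaN)
  p1 <- p1[ok]; p2 <- p2[ok]; n1 <- n1[ok]; n2 <- n2[ok]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (sum(den) == 0) return(NaN)
  sum(num) / sum(den)
}

#' f3 and f4 statistics with block-jackknife errors
#'
#' `f3(C; A, B)` is the SNP-average of \eqn{(c-a)(c-b)}, minus the
#' target's finite-sample heterozygosity correction
#' \eqn{c(1-c)/(n_C-1)} unless `corrected = FALSE`; a significantly
#' negative f3 signals admixture in C from sources related to A and B.
#' `f4(A, B; C, D)` is the SNP-average of \eqn{(a-b)(c-d)}.  Standard
#' errors come from a leave-one-block-out jackknife over consecutive
#' SNP blocks.
#'
#' @inheritParams population_freqs
#' @param mode `"f3"` or `"f4"`.
#' @param pops Ordered population labels: `c(C, A, B)` for f3 (target
#'   first), `c(A, B, C, D)` for f4.
#' @param block_snps SNPs per jackknife block.
#' @param corrected Apply the f3 target correction (default `TRUE`).
#' @return An `fstat_result` one-row tibble: `statistic`, `pops`,
#'   `estimate`, `se`, `z`, `n_snps`, `n_blocks`.
#' @export
f_statistic <- function(panel, manifest, mode = c("f3", "f4"), pops,
                        block_snps = 50, corrected = TRUE) {
  mode <- match.arg(mode)
  need <- if (mode == "f3") 3L else 4L
  if (length(pops) != need)
    stop("f_statistic: ", mode, " needs ", need, " populations")
  fr <- population_freqs(panel, manifest)
  miss <- setdiff(pops, rownames(fr$p))
  if (length(miss)) stop("f_statistic: unknown population(s) ",
                         paste(miss, collapse = ", "))
  if (mode == "f3") {
    cfr <- fr$p[pops[1], ]; a <- fr$p[pops[2], ]; b <- fr$p[pops[3], ]
    nc <- fr$n[pops[1], ]
    per_snp <- (cfr - a) * (cfr - b)
    if (corrected) per_snp <- per_snp - cfr * (1 - cfr) / (nc - 1)
    ok <- !is.na(per_snp) & nc >= 2
  } else {
    a <- fr$p[pops[1], ]; b <- fr$p[pops[2], ]
    cfr <- fr$p[pops[3], ]; d <- fr$p[pops[4], ]
    per_snp <- (a - b) * (cfr - d)
    ok <- !is.na(per_snp)
  }
  per_snp <- per_snp[ok]
  n_snps <- length(per_snp)
  if (n_snps < 2 * block_snps)
    stop("f_statistic: need >= 2 jackknife blocks (",
         n_snps, " usable SNPs, block_snps = ", block_snps, ")")
  block <- ceiling(seq_len(n_snps) / block_snps)
  B <- max(block)
  est <- mean(per_snp)
  tot <- sum(per_snp)
  bsum <- rowsum(per_snp, block)[, 1]
  bn <- tabulate(block)
  loo <- (tot - bsum) / (n_snps - bn)
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  structure(tibble::tibble(
    statistic = mode, pops = paste(pops, collapse = ";"),
    estimate = est, se = se,
    z = if (se > 0) est / se else NA_real_,
    n_snps = n_snps, n_blocks = B),
    class = c("fstat_result", "tbl_df", "tbl", "data.frame"))
}

#' Great-circle distance matrix between populations
#'
#' Haversine distances on a sphere of radius 6,371.0088 km between the
#' manifest's population coordinates.
#'
#' @param manifest Sample manifest (one coordinate pair per population).
#' @return A [dist_matrix()] of kind `"geographic_km"`.
#' @export
great_circle_matrix <- function(manifest) {
  coords <- dplyr::distinct(manifest, .data$population, .data$latitude,
                            .data$longitude)
  if (anyNA(coords$latitude) || anyNA(coords$longitude))
    stop("great_circle_matrix: missing coordinates")
  km <- geosphere::distm(cbind(coords$longitude, coords$latitude),
                         fun = function(x, y)
                           geosphere::distHaversine(x, y, r = 6371008.8)) / 1000
  dist_matrix(km, coords$population, "geographic_km")
}

#' Great-circle distance of each population from an origin point
#'
#' @param manifest Sample manifest.
#' @param origin `(lat, lon)` of the origin.
#' @return Tibble with `population`, `distance_km`.
#' @export
distance_from_origin <- function(manifest, origin) {
  coords <- dplyr::distinct(manifest, .data$population, .data$latitude,
                            .data$longitude)
  km <- geosphere::distHaversine(cbind(coords$longitude, coords$latitude),
                                 c(origin[2], origin[1]), r = 6371008.8) / 1000
  tibble::tibble(population = coords$population, distance_km = km)
}

#' Linguistic distance from a multistate cognate matrix
#'
#' Rows are languages, columns meaning slots, entries integer cognate
#' classes with `NA`/`"?"` for missing.  The distance between two
#' languages is the proportion of mutually non-missing slots whose
#' states differ (Hamming proportion).
#'
#' @param cognates Matrix or data frame of cognate classes.
#' @param labels Language labels (defaults to rownames).
#' @return A [dist_matrix()] of kind `"linguistic"`.
#' @export
linguistic_distance_matrix <- function(cognates, labels = rownames(cognates)) {
  m <- as.matrix(cognates)
  m[m == "?"] <- NA
  if (is.null(labels)) stop("linguistic_distance_matrix: labels required")
  P <- nrow(m)
  v <- matrix(0, P, P)
  for (i in seq_len(P - 1)) for (j in seq(i + 1, P)) {
    ok <- !is.na(m[i, ]) & !is.na(m[j, ])
    v[i, j] <- v[j, i] <-
      if (!any(ok)) NaN else mean(m[i, ok] != m[j, ok])
  }
  if (any(is.nan(v)))
    warning("linguistic_distance_matrix: pair(s) share no scored slots")
  dist_matrix(v, labels, "linguistic")
}

#' Mantel and partial Mantel permutation tests
#'
#' `r` is the Pearson correlation over upper-triangle entries of the two
#' matrices; for the partial test the triangles of `x` and `y` are first
#' replaced by their OLS residuals on the triangle of `z`.  Significance
#' comes from simultaneous row/column permutation of one matrix, with a
#' two-sided p-value `(1 + #{|r_perm| >= |r_obs|}) / (1 + n_perm)`.
#'
#' @param x,y [dist_matrix()] objects with matching label sets.
#' @param z Optional third matrix to condition on (partial Mantel).
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed for the permutations.
#' @return A `mantel_result` one-row tibble: `r`, `p`, `n_perm`, `seed`,
#'   `conditioned_on`.
#' @export
mantel_test <- function(x, y, z = NULL, n_perm = 9999, seed = 1) {
  if (n_perm < 99) stop("mantel_test: n_perm must be >= 99")
  y <- align_dist(y, x)
  if (!is.null(z)) z <- align_dist(z, x)
  P <- length(x$labels)
  lower <- lower.tri(x$values)

  r_of <- function(xm, ym) {
    xv <- xm[lower]; yv <- ym[lower]
    if (!is.null(z)) {
      zv <- z$values[lower]
      xv <- stats::resid(lm(xv ~ zv))
      yv <- stats::resid(lm(yv ~ zv))
    }
    cor(xv, yv)
  }
  r_obs <- r_of(x$values, y$values)
  set.seed(as.integer(seed))
  r_perm <- replicate(n_perm, {
    i <- sample.int(P)
    r_of(x$values, y$values[i, i])
  })
  p <- (1 + sum(abs(r_perm) >= abs(r_obs))) / (1 + n_perm)
  structure(tibble::tibble(
    r = r_obs, p = p, n_perm = as.integer(n_perm), seed = as.integer(seed),
    conditioned_on = if (is.null(z)) NA_character_ else z$kind),
    class = c("mantel_result", "tbl_df", "tbl", "data.frame"))
}

#' PCA of a genotype panel
#'
#' Diploid dosages are mean-imputed per SNP, centred, and scaled by
#' \eqn{\sqrt{p(1-p)}} with `p` the sample allele frequency; the
#' coordinates are the top right-singular projections of the resulting
#' matrix.  All-missing or monomorphic SNPs are dropped with a warning.
#' Signs are fixed by making each component's largest-magnitude SNP
#' loading positive, so repeated runs are identical.
#'
#' @param panel A [genotype_panel()].
#' @param n_components Number of components to return.
#' @return A `genotype_pca` object: tibble of `sample_id`, `PC1..PCk`,
#'   with eigenvalues in `attr(, "eigenvalues")`.
#' @export
genotype_pca <- function(panel, n_components = 2) {
  g <- genotype_matrix(panel)
  if (nrow(g) < 3) stop("genotype_pca: need >= 3 samples")
  p <- colMeans(g, na.rm = TRUE) / 2
  drop <- !is.finite(p) | p <= 0 | p >= 1
  if (any(drop)) {
    warning("genotype_pca: dropping ", sum(drop),
            " all-missing or monomorphic SNP(s)")
    g <- g[, !drop, drop = FALSE]
    p <- p[!drop]
  }
  mu <- 2 * p
  for (j in seq_len(ncol(g))) {
    na <- is.na(g[, j])
    if (any(na)) g[na, j] <- mu[j]
  }
  x <- sweep(sweep(g, 2, mu), 2, sqrt(p * (1 - p)), "/")
  k <- min(n_components, nrow(x) - 1, ncol(x))
  sv <- svd(x, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(i) {
    l <- sv$v[, i]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(k)], k), 2, flip, "*")
  out <- tibble::as_tibble(as.data.frame(scores))
  names(out) <- paste0("PC", seq_len(k))
  out <- dplyr::bind_cols(tibble::tibble(sample_id = panel$sample_ids), out)
  attr(out, "eigenvalues") <- sv$d[seq_len(k)]^2 / (nrow(x) - 1)
  class(out) <- c("genotype_pca", class(out))
  out
}

#' Procrustes similarity fit of one 2-D configuration onto another
#'
#' Finds the translation, rigid rotation (with optional reflection) and
#' uniform scale minimizing the sum of squared distances from the
#' transformed `a` to `b`, via the singular-value solution.  The
#' Procrustes correlation is \eqn{\sqrt{1 - ss_{res}/ss_{tot}}} with
#' `ss_tot` the total sum of squares of centred `b`; significance is
#' assessed by permuting row labels of `a`.
#'
#' @param a,b Numeric matrices (rows matched, 2 columns) or data frames.
#' @param n_perm Label permutations for the p-value.
#' @param seed Integer seed.
#' @return A `procrustes_fit` list: `rotation`, `scale`, `translation`,
#'   `correlation`, `p`, `fitted`.
#' @export
procrustes_fit <- function(a, b, n_perm = 999, seed = 1) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("procrustes_fit: row mismatch")
  if (nrow(a) < 3) stop("procrustes_fit: need >= 3 points")

  fit1 <- function(a, b) {
    ca <- colMeans(a); cb <- colMeans(b)
    ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
    sv <- svd(crossprod(ac, bc))
    rot <- sv$u %*% t(sv$v)
    ssa <- sum(ac^2); ssb <- sum(bc^2)
    sc <- sum(sv$d) / ssa
    ss_res <- ssb - sum(sv$d)^2 / ssa
    corr <- sqrt(max(0, 1 - ss_res / ssb))
    list(rotation = rot, scale = sc,
         translation = cb - sc * as.vector(ca %*% rot), corr = corr,
         fitted = sweep(sc * ac %*% rot, 2, cb, "+"))
  }
  obs <- fit1(a, b)
  set.seed(as.integer(seed))
  perm <- replicate(n_perm, fit1(a[sample.int(nrow(a)), ], b)$corr)
  p <- (1 + sum(perm >= obs$corr)) / (1 + n_perm)
  structure(list(rotation = obs$rotation, scale = obs$scale,
                 translation = obs$translation, correlation = obs$corr,
                 p = p, fitted = obs$fitted, n_perm = n_perm),
            class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat("<procrustes_fit> correlation ", round(x$correlation, 4),
      ", scale ", round(x$scale, 4), ", p = ", x$p, "\n", sep = "")
  invisible(x)
}
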