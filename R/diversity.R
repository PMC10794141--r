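#' Window layout of a panel
#'
#' Consecutive non-overlapping blocks of `window_snps` SNPs within each
#' chromosome; a trailing remainder shorter than `window_snps` is
#' dropped.
#' @noRd
snp_windows <- function(variants, window_snps) {
  out <- list()
  for (ch in unique(variants$chrom)) {
    idx <- which(variants$chrom == ch)
    nwin <- length(idx) %/% window_snps
    if (nwin == 0) next
    for (w in seq_len(nwin)) {
      out[[length(out) + 1]] <- list(
        chrom = ch, snps = idx[seq((w - 1) * window_snps + 1,
                                   w * window_snps)])
    }
  }
  out
}

window_hap_strings <- function(haps, snps) {
  block <- haps[, snps, drop = FALSE]
  keep <- rowSums(is.na(block)) == 0
  if (!any(keep)) return(character(0))
  apply(block[keep, , drop = FALSE], 1, paste, collapse = "")
}

#' Rarefied haplotype richness per population
#'
#' In each window of `window_snps` consecutive SNPs, `g` haplotypes are
#' subsampled without replacement and the number of distinct window
#' haplotypes among them is counted; counts are averaged over `reps`
#' subsamples, then over a chromosome's windows, then across
#' chromosomes.  Haplotypes with a masked allele inside a window drop
#' out of that window's pool; windows whose pool falls below `g` are
#' skipped.
#'
#' @param panel A [genotype_panel()].
#' @param manifest Sample manifest.
#' @param window_snps SNPs per window (default 20).
#' @param g Rarefaction depth in haplotypes (default 20, i.e. 10
#'   diploids, the smallest population size the generators emit).
#' @param reps Monte-Carlo subsamples per window (default 10).
#' @param seed Integer seed.
#' @return Tibble with `population`, `haplotype_richness`, `n_used`
#'   (diploids).
#' @export
haplotype_richness <- function(panel, manifest, window_snps = 20, g = 20,
                               reps = 10, seed = 1) {
  pops <- haplotype_populations(panel, manifest)
  wins <- snp_windows(panel$variants, window_snps)
  if (length(wins) == 0) stop("haplotype_richness: no complete window")
  set.seed(as.integer(seed))
  res <- lapply(unique(pops), function(pp) {
    haps <- panel$haplotypes[pops == pp, , drop = FALSE]
    if (nrow(haps) < g)
      stop("haplotype_richness: population ", pp, " has ", nrow(haps),
           " haplotypes, fewer than rarefaction depth g = ", g)
    per_chrom <- list()
    for (w in wins) {
      hs <- window_hap_strings(haps, w$snps)
      if (length(hs) < g) next
      counts <- vapply(seq_len(reps), function(...) {
        length(unique(hs[sample.int(length(hs), g)]))
      }, numeric(1))
      per_chrom[[w$chrom]] <- c(per_chrom[[w$chrom]], mean(counts))
    }
    if (length(per_chrom) == 0)
      stop("haplotype_richness: population ", pp,
           " has no window with >= g complete haplotypes")
    tibble::tibble(population = pp,
                   haplotype_richness =
                     mean(vapply(per_chrom, mean, numeric(1))),
                   n_used = nrow(haps) / 2)
  })
  dplyr::bind_rows(res)
}

#' Unbiased haplotype heterozygosity per population
#'
#' Per window, \eqn{(n/(n-1)) (1 - \sum_h p_h^2)} over the window
#' haplotype frequencies among the `n` complete haplotypes; averaged
#' over a chromosome's windows and then across chromosomes.  Windows
#' with fewer than two complete haplotypes are skipped.
#'
#' @inheritParams haplotype_richness
#' @return Tibble with `population`, `haplotype_heterozygosity`,
#'   `n_used`.
#' @export
haplotype_heterozygosity <- function(panel, manifest, window_snps = 20) {
  pops <- haplotype_populations(panel, manifest)
  wins <- snp_windows(panel$variants, window_snps)
  if (length(wins) == 0) stop("haplotype_heterozygosity: no complete window")
  res <- lapply(unique(pops), function(pp) {
    haps <- panel$haplotypes[pops == pp, , drop = FALSE]
    if (nrow(haps) < 2)
      stop("haplotype_heterozygosity: population ", pp, " has < 2 haplotypes")
    per_chrom <- list()
    for (w in wins) {
      hs <- window_hap_strings(haps, w$snps)
      n <- length(hs)
      if (n < 2) next
      ph <- table(hs) / n
      per_chrom[[w$chrom]] <- c(per_chrom[[w$chrom]],
                                n / (n - 1) * (1 - sum(ph^2)))
    }
    if (length(per_chrom) == 0)
      stop("haplotype_heterozygosity: population ", pp,
           " has no usable window")
    tibble::tibble(population = pp,
                   haplotype_heterozygosity =
                     mean(vapply(per_chrom, mean, numeric(1))),
                   n_used = nrow(haps) / 2)
  })
  dplyr::bind_rows(res)
}

#' LD decay profile per population
#'
#' Squared Pearson correlation of haplotype allele indicators between
#' all same-chromosome SNP pairs at most `max_bp` apart, handled
#' pairwise-complete; pairs where either SNP is monomorphic among the
#' usable haplotypes are skipped.  Mean r-squared is reported per
#' physical-distance bin.
#'
#' @inheritParams haplotype_richness
#' @param max_bp Maximum pair distance in bp (default 500,000).
#' @param bins Bin edges in bp (default 10 equal bins up to `max_bp`).
#' @return Tibble with `population`, `bin_lo`, `bin_hi`, `mean_r2`,
#'   `n_pairs`.
#' @export
ld_decay <- function(panel, manifest, max_bp = 500000,
                     bins = seq(0, max_bp, length.out = 11)) {
  pops <- haplotype_populations(panel, manifest)
  v <- panel$variants
  res <- list()
  for (pp in unique(pops)) {
    haps <- panel$haplotypes[pops == pp, , drop = FALSE]
    if (nrow(haps) < 4) stop("ld_decay: population ", pp,
                             " has < 4 haplotypes")
    dist_all <- numeric(0); r2_all <- numeric(0)
    L <- ncol(haps)
    for (k in seq_len(L - 1)) {
      i <- seq_len(L - k); j <- i + k
      same <- v$chrom[i] == v$chrom[j]
      ok <- same & (v$pos_bp[j] - v$pos_bp[i]) <= max_bp
      if (!any(ok)) {
        # within a chromosome pair distance only grows with the offset
        if (!any(same)) break
        if (min((v$pos_bp[j] - v$pos_bp[i])[same]) > max_bp) break
        next
      }
      i <- i[ok]; j <- j[ok]
      A <- haps[, i, drop = FALSE]; B <- haps[, j, drop = FALSE]
      M <- (!is.na(A)) & (!is.na(B))
      A0 <- ifelse(M, A, 0L); B0 <- ifelse(M, B, 0L)
      n <- colSums(M)
      sA <- colSums(A0); sB <- colSums(B0); sAB <- colSums(A0 * B0)
      num <- n * sAB - sA * sB
      den <- (n * sA - sA^2) * (n * sB - sB^2)
      usable <- n >= 4 & den > 0
      if (!any(usable)) next
      r2 <- num[usable]^2 / den[usable]
      dist_all <- c(dist_all, (v$pos_bp[j] - v$pos_bp[i])[usable])
      r2_all <- c(r2_all, r2)
    }
    if (length(r2_all) == 0) next
    bin <- cut(dist_all, breaks = bins, include.lowest = TRUE)
    d <- tibble::tibble(population = pp, bin = bin, r2 = r2_all)
    res[[pp]] <- d |>
      dplyr::group_by(.data$population, .data$bin) |>
      dplyr::summarise(mean_r2 = mean(.data$r2),
                       n_pairs = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(bin_lo = bins[as.integer(.data$bin)],
                    bin_hi = bins[as.integer(.data$bin) + 1]) |>
      dplyr::select("population", "bin_lo", "bin_hi", "mean_r2", "n_pairs")
  }
  dplyr::bind_rows(res)
}

#' Call runs of homozygosity and summarize them
#'
#' Diploid genotypes are formed by pairing each sample's two haplotypes.
#' A run is a maximal stretch of calls containing at least `min_snps`
#' homozygous SNPs, at most `het_allowance` heterozygous calls, and
#' spanning at least `min_kb` kilobases; runs are trimmed to homozygous
#' endpoints and reported as 0-based half-open bp intervals.  Missing
#' genotypes neither break a run nor count toward `min_snps`.
#'
#' Per individual the five classic parameters are reported (mean ROH
#' size, total ROH length, sum of short runs < 1.6 Mb, sum of long runs
#' >= 1.6 Mb, and `F_ROH` = total length / mapped autosomal length)
#' together with six length-class sums (< 0.5, 0.5-1, 1-2, 2-4, 4-8,
#' > 8 Mb) that total the total length exactly.
#'
#' @param panel A [genotype_panel()] with bp positions.
#' @param min_snps Minimum homozygous SNPs per run (default 50).
#' @param min_kb Minimum run span in kb (default 500).
#' @param het_allowance Heterozygous calls tolerated per run (default 1).
#' @return List with `segments` (tibble: `sample_id`, `chrom`, `start`,
#'   `end`) and `summary` (tibble per individual: the five parameters
#'   and `class_*` sums, lengths in bp).
#' @export
call_roh <- function(panel, min_snps = 50, min_kb = 500, het_allowance = 1) {
  v <- panel$variants
  if (anyNA(v$pos_bp)) stop("call_roh: panel lacks bp positions")
  g <- genotype_matrix(panel)
  map_len <- sum(vapply(unique(v$chrom), function(ch) {
    p <- v$pos_bp[v$chrom == ch]
    max(p) + 1 - min(p)
  }, numeric(1)))
  class_breaks <- c(0, 0.5e6, 1e6, 2e6, 4e6, 8e6, Inf)
  class_names <- c("class_lt0.5Mb", "class_0.5_1Mb", "class_1_2Mb",
                   "class_2_4Mb", "class_4_8Mb", "class_gt8Mb")

  seg_rows <- list(); sum_rows <- list()
  for (si in seq_len(nrow(g))) {
    segs <- list()
    for (ch in unique(v$chrom)) {
      idx <- which(v$chrom == ch)
      loc <- roh_scan_chrom(g[si, idx], v$pos_bp[idx],
                            min_snps, min_kb * 1000, het_allowance)
      for (s in loc) segs[[length(segs) + 1]] <- c(idx[s[1]], idx[s[2]])
    }
    if (length(segs)) {
      sd <- do.call(rbind, segs)
      seg_rows[[si]] <- tibble::tibble(
        sample_id = rownames(g)[si],
        chrom = v$chrom[sd[, 1]], start = v$pos_bp[sd[, 1]],
        end = v$pos_bp[sd[, 2]] + 1L)
      len <- seg_rows[[si]]$end - seg_rows[[si]]$start
    } else len <- numeric(0)
    cls <- vapply(seq_len(6), function(k) {
      sum(len[len > class_breaks[k] & len <= class_breaks[k + 1]])
    }, numeric(1))
    names(cls) <- class_names
    sum_rows[[si]] <- tibble::tibble(
      sample_id = rownames(g)[si],
      n_segments = length(len),
      mean_roh_size = if (length(len)) mean(len) else 0,
      total_roh_length = sum(len),
      sum_short = sum(len[len < 1.6e6]),
      sum_long = sum(len[len >= 1.6e6]),
      f_roh = sum(len) / map_len,
      !!!as.list(cls))
  }
  list(segments = dplyr::bind_rows(seg_rows),
       summary = dplyr::bind_rows(sum_rows))
}

# Two-pointer scan of one chromosome of one individual.  Returns a list
# of c(start_snp, end_snp) pairs of indices into the chromosome's SNP
# vector; the caller translates them to panel-wide indices.
#' @noRd
roh_scan_chrom <- function(geno, pos, min_snps, min_bp, het_allowance) {
  het <- !is.na(geno) & geno == 1L
  hom <- !is.na(geno) & geno != 1L
  n <- length(geno)
  segs <- list()
  i <- 1
  while (i <= n) {
    # extend from i while het count stays within allowance
    hets <- 0; j <- i - 1
    while (j < n) {
      if (het[j + 1] && hets + 1 > het_allowance) break
      j <- j + 1
      if (het[j]) hets <- hets + 1
    }
    # trim to homozygous endpoints
    a <- i; b <- j
    while (a <= b && !hom[a]) a <- a + 1
    while (b >= a && !hom[b]) b <- b - 1
    if (a <= b && sum(hom[a:b]) >= min_snps &&
        (pos[b] + 1 - pos[a]) >= min_bp) {
      segs[[length(segs) + 1]] <- c(a, b)
      i <- b + 1
    } else {
      # restart just past the first het (or the end)
      nxt <- which(het[i:min(j + 1, n)])[1]
      i <- if (is.na(nxt)) j + 1 else i + nxt
    }
  }
  segs
}

#' Regression of a per-population statistic on distance from an origin
#'
#' Ordinary least squares of the statistic on great-circle distance (km)
#' from the origin, with a two-sided t-test on the slope.  A negative,
#' significant slope in diversity is the serial-founder signature; an
#' equilibrium isolation-by-distance population shows no such decline.
#'
#' @param values Tibble with `population` and one numeric statistic
#'   column (the first non-population column is used, or name it via
#'   `stat`).
#' @param manifest Sample manifest with population coordinates.
#' @param origin `(lat, lon)` of the putative origin.
#' @param stat Optional name of the statistic column.
#' @return A `founder_regression` one-row tibble: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`.
#' @export
diversity_distance_regression <- function(values, manifest, origin,
                                          stat = NULL) {
  values <- tibble::as_tibble(values)
  if (is.null(stat))
    stat <- setdiff(names(values), "population")[1]
  d <- dplyr::inner_join(values, distance_from_origin(manifest, origin),
                         by = "population")
  if (nrow(d) < 3)
    stop("diversity_distance_regression: need >= 3 populations")
  y <- d[[stat]]
  if (sd(y) < 1e-12) {
    # degenerate flat response: no trend by definition
    return(structure(tibble::tibble(
      statistic = stat, slope = 0, intercept = mean(y), r_squared = 0,
      p_value = 1, n = nrow(d)),
      class = c("founder_regression", "tbl_df", "tbl", "data.frame")))
  }
  fit <- lm(y ~ d$distance_km)
  sm <- summary(fit)
  slope_p <- if (nrow(sm$coefficients) > 1 && !is.nan(sm$coefficients[2, 2]))
    sm$coefficients[2, 4] else 1
  structure(tibble::tibble(
    statistic = stat,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = if (is.nan(sm$r.squared)) 0 else sm$r.squared,
    p_value = slope_p,
    n = nrow(d)),
    class = c("founder_regression", "tbl_df", "tbl", "data.frame"))
}

#' Per-population diversity table
#'
#' Convenience wrapper computing rarefied haplotype richness and
#' unbiased haplotype heterozygosity in one pass.
#'
#' @inheritParams haplotype_richness
#' @return Tibble with `population`, `n_used`, `haplotype_richness`,
#'   `haplotype_heterozygosity`.
#' @export
diversity_table <- function(panel, manifest, window_snps = 20, g = 20,
                            reps = 10, seed = 1) {
  r <- haplotype_richness(panel, manifest, window_snps, g, reps, seed)
  h <- haplotype_heterozygosity(panel, manifest, window_snps)
  dplyr::inner_join(r, dplyr::select(h, -"n_used"), by = "population") |>
    dplyr::select("population", "n_used", "haplotype_richness",
                  "haplotype_heterozygosity")
}
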