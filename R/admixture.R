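#' Local-ancestry tract sets
#'
#' A tract set is a tibble with one row per labelled genomic interval
#' per haplotype: `haplotype_id` (`"<sample_id>_1"` / `"<sample_id>_2"`,
#' matching panel haplotype-row order), `chrom`, `start_bp`, `end_bp`
#' (0-based half-open), `start_cM`, `end_cM`, and `ancestry` (one of
#' `WCA`, `wRHG`, `KhoeSan`, `AfroAsiatic`, `other`).  Within a
#' haplotype and chromosome, tracts must be sorted, non-overlapping and
#' tile the mapped span without gaps.
#'
#' @param tracts Data frame with the columns above.
#' @return A validated `ancestry_tracts` tibble.
#' @export
ancestry_tracts <- function(tracts) {
  tracts <- tibble::as_tibble(tracts)
  need <- c("haplotype_id", "chrom", "start_bp", "end_bp",
            "start_cM", "end_cM", "ancestry")
  miss <- setdiff(need, names(tracts))
  if (length(miss)) stop("ancestry_tracts: missing column(s) ",
                         paste(miss, collapse = ", "))
  labs <- c("WCA", "wRHG", "KhoeSan", "AfroAsiatic", "other")
  if (any(!tracts$ancestry %in% labs))
    stop("ancestry_tracts: ancestry must be one of ",
         paste(labs, collapse = ", "))
  tracts <- dplyr::arrange(tracts, .data$haplotype_id, .data$chrom,
                           .data$start_bp)
  by_hap <- split(tracts, paste(tracts$haplotype_id, tracts$chrom))
  for (g in by_hap) {
    if (any(g$end_bp <= g$start_bp))
      stop("ancestry_tracts: empty or inverted tract")
    if (nrow(g) > 1 && any(g$start_bp[-1] != g$end_bp[-nrow(g)]))
      stop("ancestry_tracts: tracts of ", g$haplotype_id[1], " chrom ",
           g$chrom[1], " overlap or leave gaps")
  }
  class(tracts) <- c("ancestry_tracts", class(tracts))
  tracts
}

#' @rdname ancestry_tracts
#' @param path TSV path (columns as above).
#' @export
read_tracts <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  colClasses = c("character", "character", "integer",
                                 "integer", "numeric", "numeric",
                                 "character"))
  ancestry_tracts(d)
}

#' @rdname ancestry_tracts
#' @export
write_tracts <- function(tracts, path) {
  write.table(tracts, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

panel_haplotype_ids <- function(panel) {
  as.vector(rbind(paste0(panel$sample_ids, "_1"),
                  paste0(panel$sample_ids, "_2")))
}

#' Mask a panel down to one ancestry
#'
#' Sets alleles falling inside tracts not labelled `target` to missing,
#' haplotype by haplotype, and reports the cM-weighted target-ancestry
#' share of each haplotype averaged per sample.  Masking is idempotent
#' and every variant of every panel haplotype must be covered by a
#' tract.
#'
#' @param panel A [genotype_panel()].
#' @param tracts An [ancestry_tracts()] set covering the panel.
#' @param target Ancestry label to keep (default `"WCA"`).
#' @return List with `panel` (masked) and `fractions` (tibble:
#'   `sample_id`, `ancestry_fraction`).
#' @export
mask_by_ancestry <- function(panel, tracts, target = "WCA") {
  tracts <- ancestry_tracts(tracts)
  hap_ids <- panel_haplotype_ids(panel)
  v <- panel$variants
  haps <- panel$haplotypes
  frac <- numeric(length(hap_ids))
  for (h in seq_along(hap_ids)) {
    tr <- tracts[tracts$haplotype_id == hap_ids[h], ]
    if (nrow(tr) == 0)
      stop("mask_by_ancestry: no tracts for haplotype ", hap_ids[h])
    covered <- rep(FALSE, nrow(v))
    inside_non_target <- rep(FALSE, nrow(v))
    for (ti in seq_len(nrow(tr))) {
      inb <- v$chrom == tr$chrom[ti] & v$pos_bp >= tr$start_bp[ti] &
        v$pos_bp < tr$end_bp[ti]
      covered <- covered | inb
      if (tr$ancestry[ti] != target)
        inside_non_target <- inside_non_target | inb
    }
    if (!all(covered))
      stop("mask_by_ancestry: variant position(s) outside tract coverage ",
           "for ", hap_ids[h], ": ",
           paste(head(v$pos_bp[!covered], 5), collapse = ", "))
    haps[h, inside_non_target] <- NA_integer_
    span <- sum(tr$end_cM - tr$start_cM)
    frac[h] <- sum((tr$end_cM - tr$start_cM)[tr$ancestry == target]) / span
  }
  fractions <- tibble::tibble(
    sample_id = panel$sample_ids,
    ancestry_fraction = (frac[seq(1, length(frac), 2)] +
                           frac[seq(2, length(frac), 2)]) / 2)
  list(panel = genotype_panel(haps, v, panel$sample_ids),
       fractions = fractions)
}

#' Filter and downsample a masked dataset
#'
#' Drops populations whose mean target-ancestry fraction falls below
#' `min_fraction` or with fewer than `min_n` samples, and randomly
#' downsamples larger populations to `max_n` individuals without
#' replacement.
#'
#' @param panel A [genotype_panel()] (typically masked).
#' @param fractions Per-sample ancestry fractions from
#'   [mask_by_ancestry()].
#' @param manifest Sample manifest.
#' @param min_fraction Minimum population mean ancestry fraction
#'   (default 0.70).
#' @param min_n,max_n Population size bounds (defaults 10 and 30).
#' @param seed Integer seed for downsampling.
#' @return List with the filtered `panel` and `manifest`.
#' @export
prepare_masked_dataset <- function(panel, fractions, manifest,
                                   min_fraction = 0.70, min_n = 10,
                                   max_n = 30, seed = 1) {
  i <- match(panel$sample_ids, fractions$sample_id)
  if (anyNA(i)) stop("prepare_masked_dataset: fractions missing for ",
                     "some panel samples")
  j <- match(panel$sample_ids, manifest$sample_id)
  if (anyNA(j)) stop("prepare_masked_dataset: manifest missing samples")
  d <- tibble::tibble(sample_id = panel$sample_ids,
                      fraction = fractions$ancestry_fraction[i],
                      population = manifest$population[j])
  keep_pops <- d |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(mf = mean(.data$fraction), n = dplyr::n()) |>
    dplyr::filter(.data$mf >= min_fraction, .data$n >= min_n)
  d <- d[d$population %in% keep_pops$population, ]
  if (nrow(d) == 0) stop("prepare_masked_dataset: no populations retained")
  set.seed(as.integer(seed))
  keep_ids <- d |>
    dplyr::group_by(.data$population) |>
    dplyr::group_modify(function(g, ...) {
      if (nrow(g) > max_n) g[sort(sample.int(nrow(g), max_n)), ] else g
    }) |>
    dplyr::ungroup() |>
    dplyr::pull("sample_id")
  list(panel = subset_samples(panel, keep_ids),
       manifest = manifest[manifest$sample_id %in% keep_ids, ])
}

#' Date admixture from ancestry tract lengths
#'
#' Non-target tract lengths are approximately exponential with rate
#' \eqn{(1-m)t} per Morgan after `t` generations of recombination, so
#' \eqn{\hat t = 1 / ((1-\hat m)\,\bar L)} with \eqn{\hat m} the mean
#' non-target cM fraction across haplotypes and \eqn{\bar L} the mean
#' non-target tract length in Morgans.  Tracts touching a chromosome
#' end are censored and excluded from \eqn{\bar L}.  The confidence
#' interval is a percentile bootstrap over haplotypes.
#'
#' @param tracts An [ancestry_tracts()] set (one population).
#' @param target Target ancestry label (default `"WCA"`).
#' @param min_tracts Minimum pooled uncensored non-target tracts
#'   (default 20).
#' @param n_boot Bootstrap replicates (default 200).
#' @param conf Interval coverage (default 0.95).
#' @param seed Integer seed.
#' @return An `admixture_date` one-row tibble: `t_hat`, `m_hat`,
#'   `mean_tract_morgans`, `n_tracts`, `ci_lo`, `ci_hi`.
#' @export
date_admixture_from_tracts <- function(tracts, target = "WCA",
                                       min_tracts = 20, n_boot = 200,
                                       conf = 0.95, seed = 1) {
  tracts <- ancestry_tracts(tracts)
  non <- tracts[tracts$ancestry != target, ]
  if (nrow(non) == 0)
    stop("date_admixture_from_tracts: no non-target tracts ",
         "(population appears unadmixed)")
  chrom_ends <- tracts |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(cm0 = min(.data$start_cM), cm1 = max(.data$end_cM))

  est <- function(tr_all, tr_non) {
    by_hap <- tr_all |>
      dplyr::group_by(.data$haplotype_id) |>
      dplyr::summarise(
        span = sum(.data$end_cM - .data$start_cM),
        non = sum((.data$end_cM - .data$start_cM)
                  [.data$ancestry != target]))
    m_hat <- mean(by_hap$non / by_hap$span)
    e <- dplyr::left_join(tr_non, chrom_ends, by = "chrom")
    interior <- e$start_cM > e$cm0 & e$end_cM < e$cm1
    lens <- (e$end_cM - e$start_cM)[interior] / 100
    c(m_hat = m_hat, L = mean(lens), n = length(lens))
  }
  e0 <- est(tracts, non)
  if (e0[["n"]] < min_tracts)
    stop("date_admixture_from_tracts: only ", e0[["n"]],
         " uncensored non-target tracts (need >= ", min_tracts, ")")
  t_hat <- 1 / ((1 - e0[["m_hat"]]) * e0[["L"]])

  haps <- unique(tracts$haplotype_id)
  set.seed(as.integer(seed))
  boots <- replicate(n_boot, {
    hb <- sample(haps, replace = TRUE)
    # haplotypes resampled with multiplicity
    pick <- unlist(lapply(hb, function(h) which(tracts$haplotype_id == h)))
    tb <- tracts[pick, ]
    nb <- tb[tb$ancestry != target, ]
    if (nrow(nb) == 0) return(NA_real_)
    eb <- est(tb, nb)
    if (!is.finite(eb[["L"]]) || eb[["n"]] == 0) return(NA_real_)
    1 / ((1 - eb[["m_hat"]]) * eb[["L"]])
  })
  qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                 na.rm = TRUE, names = FALSE)
  structure(tibble::tibble(
    t_hat = t_hat, m_hat = e0[["m_hat"]],
    mean_tract_morgans = e0[["L"]], n_tracts = as.integer(e0[["n"]]),
    ci_lo = qs[1], ci_hi = qs[2]),
    class = c("admixture_date", "tbl_df", "tbl", "data.frame"))
}

#' Regression of admixture dates on distance from the origin
#'
#' Delegates to [diversity_distance_regression()] with the dates as the
#' statistic.  The slope is reported signed: under an expansion with
#' admixture on arrival, generations-ago decreases away from the
#' homeland, i.e. the slope of date on distance is negative; the caller
#' interprets the sign.
#'
#' @param dates Tibble with `population` and `t_hat` columns (e.g. rows
#'   of [date_admixture_from_tracts()] results).
#' @inheritParams diversity_distance_regression
#' @return A `founder_regression` tibble.
#' @export
date_distance_regression <- function(dates, manifest, origin) {
  dates <- tibble::as_tibble(dates)
  if (!all(c("population", "t_hat") %in% names(dates)))
    stop("date_distance_regression: dates need population and t_hat")
  diversity_distance_regression(dates[, c("population", "t_hat")],
                                manifest, origin, stat = "t_hat")
}
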