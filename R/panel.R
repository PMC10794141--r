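#' Phased genotype panel
#'
#' A `genotype_panel` holds phased biallelic SNP haplotypes: an integer
#' matrix of 0/1/`NA` with two rows per diploid sample (rows `2i - 1` and
#' `2i` are the two haplotypes of sample `i`), plus a variant table with
#' physical (bp) and genetic (cM) positions.  `NA` encodes a masked or
#' missing allele and only appears after ancestry masking or on import.
#'
#' @param haplotypes Integer matrix of 0/1/`NA`, `2 * length(sample_ids)`
#'   rows, one column per variant.
#' @param variants Data frame with columns `chrom` (character), `pos_bp`
#'   (integer, strictly increasing within chromosome) and `pos_cM`
#'   (numeric, non-decreasing within chromosome).
#' @param sample_ids Character vector of unique sample identifiers, in
#'   haplotype-row order.
#'
#' @return An object of class `genotype_panel`.
#' @export
#' @examples
#' p <- genotype_panel(
#'   haplotypes = matrix(c(0L, 1L, 1L, 0L), nrow = 2),
#'   variants = data.frame(chrom = "1", pos_bp = c(100L, 200L),
#'                         pos_cM = c(0.1, 0.2)),
#'   sample_ids = "s1"
#' )
#' n_samples(p)
genotype_panel <- function(haplotypes, variants, sample_ids) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  variants <- tibble::as_tibble(variants)
  stopifnot(all(c("chrom", "pos_bp", "pos_cM") %in% names(variants)))
  variants$chrom <- as.character(variants$chrom)
  variants$pos_bp <- as.integer(variants$pos_bp)
  variants$pos_cM <- as.numeric(variants$pos_cM)
  sample_ids <- as.character(sample_ids)

  if (nrow(haplotypes) != 2L * length(sample_ids))
    stop("genotype_panel: need exactly 2 haplotype rows per sample (",
         nrow(haplotypes), " rows for ", length(sample_ids), " samples)")
  if (ncol(haplotypes) != nrow(variants))
    stop("genotype_panel: ", ncol(haplotypes), " haplotype columns but ",
         nrow(variants), " variants")
  if (anyDuplicated(sample_ids))
    stop("genotype_panel: duplicated sample ids")
  bad <- !(haplotypes %in% c(0L, 1L, NA_integer_))
  if (any(bad)) stop("genotype_panel: alleles must be 0, 1 or NA")
  for (ch in unique(variants$chrom)) {
    i <- variants$chrom == ch
    if (is.unsorted(variants$pos_bp[i], strictly = TRUE))
      stop("genotype_panel: pos_bp not strictly increasing on chrom ", ch)
    if (is.unsorted(variants$pos_cM[i]))
      stop("genotype_panel: pos_cM not non-decreasing on chrom ", ch)
  }

  structure(list(haplotypes = haplotypes, variants = variants,
                 sample_ids = sample_ids),
            class = "genotype_panel")
}

#' @rdname genotype_panel
#' @param x,panel A `genotype_panel`.
#' @export
n_samples <- function(panel) length(panel$sample_ids)

#' @rdname genotype_panel
#' @export
n_variants <- function(panel) nrow(panel$variants)

#' @rdname genotype_panel
#' @param ... Unused.
#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", n_samples(x), " samples (",
      nrow(x$haplotypes), " haplotypes) x ", n_variants(x),
      " variants on ", length(unique(x$variants$chrom)),
      " chromosome(s)\n", sep = "")
  miss <- mean(is.na(x$haplotypes))
  if (miss > 0) cat("  missing/masked alleles: ",
                    sprintf("%.1f%%", 100 * miss), "\n", sep = "")
  invisible(x)
}

#' Subset a panel to a set of samples
#'
#' @param panel A `genotype_panel`.
#' @param sample_ids Sample ids to keep; order is taken from the panel so
#'   surviving haplotype-row order is preserved.
#' @return A `genotype_panel`.
#' @export
subset_samples <- function(panel, sample_ids) {
  keep <- panel$sample_ids %in% sample_ids
  if (!any(keep)) stop("subset_samples: no samples left")
  rows <- rep(keep, each = 2L)
  genotype_panel(panel$haplotypes[rows, , drop = FALSE], panel$variants,
                 panel$sample_ids[keep])
}

#' Haplotype-row population labels for a panel
#'
#' Looks each panel sample up in the manifest and repeats its population
#' label for both haplotype rows.
#'
#' @param panel A `genotype_panel`.
#' @param manifest A sample manifest (see [read_manifest()]).
#' @return Character vector, one entry per haplotype row.
#' @export
haplotype_populations <- function(panel, manifest) {
  i <- match(panel$sample_ids, manifest$sample_id)
  if (anyNA(i))
    stop("panel sample(s) absent from manifest: ",
         paste(head(panel$sample_ids[is.na(i)], 5), collapse = ", "))
  rep(manifest$population[i], each = 2L)
}

#' Diploid genotype matrix from a phased panel
#'
#' Sums the two haplotypes of each sample into 0/1/2 dosages; any masked
#' allele makes the genotype `NA`.
#'
#' @param panel A `genotype_panel`.
#' @return Integer matrix, samples x variants.
#' @export
genotype_matrix <- function(panel) {
  h <- panel$haplotypes
  g <- h[seq(1, nrow(h), by = 2), , drop = FALSE] +
    h[seq(2, nrow(h), by = 2), , drop = FALSE]
  rownames(g) <- panel$sample_ids
  g
}
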