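#' Read a phased genotype panel
#'
#' Two plain-text dialects are supported.  `"ped_map"` is PLINK text: a
#' space-delimited `.ped` with the six pedigree columns followed by two
#' alleles per variant (allele 1 = reference = 0, allele 2 = alternate =
#' 1, `0` = missing) and a `.map` with chromosome, id, cM and bp columns;
#' `path` is the stem without extension.  `"tsv"` is a phased
#' variant-major table: columns `chrom`, `pos_bp`, `pos_cM`, then two
#' columns `<id>_A`, `<id>_B` per sample, with `.` for missing.
#'
#' The `.ped` allele order within a sample is taken as phase, which is
#' how the package's own writer and fixtures use the format.
#'
#' @param path File path (for `ped_map`, the stem shared by `.ped` and
#'   `.map`).
#' @param format `"ped_map"` or `"tsv"`.
#' @return A [genotype_panel()].
#' @export
read_panel <- function(path, format = c("ped_map", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") return(read_panel_tsv(path))

  map_file <- paste0(path, ".map")
  ped_file <- paste0(path, ".ped")
  if (!file.exists(map_file) || !file.exists(ped_file))
    stop("read_panel: missing ", map_file, " or ", ped_file)

  map <- read.table(map_file, header = FALSE, colClasses =
                      c("character", "character", "numeric", "integer"))
  names(map) <- c("chrom", "id", "pos_cM", "pos_bp")
  L <- nrow(map)

  lines <- readLines(ped_file)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  haps <- matrix(NA_integer_, nrow = 2L * n, ncol = L)
  ids <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * L)
      stop("read_panel: malformed .ped line ", i, ": expected ",
           6L + 2L * L, " fields, got ", length(f),
           if (length(f) %% 2L == 1L) " (odd allele count: ploidy != 2)")
    ids[i] <- f[2]
    al <- f[-(1:6)]
    code <- match(al, c("1", "2")) - 1L   # "0" (missing) -> NA
    if (any(!al %in% c("0", "1", "2")))
      stop("read_panel: unknown allele code on .ped line ", i)
    haps[2L * i - 1L, ] <- code[seq(1, 2L * L, by = 2)]
    haps[2L * i, ]      <- code[seq(2, 2L * L, by = 2)]
  }
  genotype_panel(haps, map[, c("chrom", "pos_bp", "pos_cM")], ids)
}

read_panel_tsv <- function(path) {
  d <- read.table(path, header = FALSE, sep = "\t", colClasses = "character",
                  check.names = FALSE)
  hdr <- as.character(d[1, ])
  d <- d[-1, , drop = FALSE]
  fixed <- c("chrom", "pos_bp", "pos_cM")
  if (!identical(hdr[1:3], fixed))
    stop("read_panel: TSV header must start with chrom, pos_bp, pos_cM")
  hap_cols <- hdr[-(1:3)]
  if (length(hap_cols) %% 2L != 0L)
    stop("read_panel: odd number of haplotype columns (ploidy != 2)")
  ids_a <- sub("_A$", "", hap_cols[seq(1, length(hap_cols), by = 2)])
  ids_b <- sub("_B$", "", hap_cols[seq(2, length(hap_cols), by = 2)])
  if (!identical(ids_a, ids_b))
    stop("read_panel: haplotype columns not paired as <id>_A, <id>_B")
  al <- as.matrix(d[, -(1:3), drop = FALSE])
  al[al == "."] <- NA
  haps <- matrix(NA_integer_, nrow = length(hap_cols), ncol = nrow(d))
  suppressWarnings(storage.mode(al) <- "integer")
  if (any(!is.na(al) & !(al %in% c(0L, 1L))))
    stop("read_panel: TSV alleles must be 0, 1 or .")
  # al is variants x hap columns; interleave to sample-major rows
  for (j in seq_along(hap_cols)) haps[j, ] <- al[, j]
  genotype_panel(haps,
                 data.frame(chrom = d[[1]], pos_bp = as.integer(d[[2]]),
                            pos_cM = as.numeric(d[[3]])),
                 ids_a)
}

#' Write a phased genotype panel
#'
#' Emits the dialects read by [read_panel()]; `write_panel()` then
#' `read_panel()` round-trips exactly (missing alleles become PLINK's
#' `0` in `.ped` and `.` in TSV).
#'
#' @param panel A [genotype_panel()].
#' @inheritParams read_panel
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, format = c("ped_map", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    ids <- panel$sample_ids
    hdr <- c("chrom", "pos_bp", "pos_cM",
             as.vector(rbind(paste0(ids, "_A"), paste0(ids, "_B"))))
    al <- t(panel$haplotypes)          # variants x haplotype rows
    al <- matrix(as.character(al), nrow = nrow(al))
    al[is.na(al)] <- "."
    body <- cbind(panel$variants$chrom, as.character(panel$variants$pos_bp),
                  as.character(panel$variants$pos_cM), al)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(hdr, collapse = "\t"), con)
    if (nrow(body) > 0)
      writeLines(apply(body, 1, paste, collapse = "\t"), con)
    return(invisible(path))
  }

  v <- panel$variants
  map <- data.frame(v$chrom, paste0(v$chrom, "_", v$pos_bp), v$pos_cM, v$pos_bp)
  write.table(map, paste0(path, ".map"), quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  n <- n_samples(panel)
  con <- file(paste0(path, ".ped"), "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    h1 <- panel$haplotypes[2L * i - 1L, ]
    h2 <- panel$haplotypes[2L * i, ]
    al <- as.vector(rbind(h1, h2)) + 1L
    al[is.na(al)] <- 0L
    writeLines(paste(c("FAM", panel$sample_ids[i], "0", "0", "0", "-9", al),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read or write a sample manifest
#'
#' The manifest is a CSV with columns `sample_id`, `population`,
#' `country`, `linguistic_group` (one of `NW-BSP2`, `WW-BSP`, `SW-BSP`,
#' `E-BSP`, `non-BSP`), `latitude`, `longitude` and `qc_flags`
#' (`;`-separated subset of `low_call_rate`, `kin_excluded`; empty for
#' none).  Every population must map to a single coordinate pair.
#'
#' @param path CSV file path.
#' @return A tibble with one row per sample.
#' @export
read_manifest <- function(path) {
  d <- read.table(path, header = TRUE, sep = ",", colClasses = "character")
  d$latitude <- as.numeric(d$latitude)
  d$longitude <- as.numeric(d$longitude)
  validate_manifest(tibble::as_tibble(d))
}

#' @rdname read_manifest
#' @param manifest Manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, quote = FALSE, sep = ",", row.names = FALSE)
  invisible(path)
}

validate_manifest <- function(manifest) {
  need <- c("sample_id", "population", "country", "linguistic_group",
            "latitude", "longitude", "qc_flags")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stop("manifest: missing column(s) ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(manifest$sample_id)) stop("manifest: duplicated sample_id")
  groups <- c("NW-BSP2", "WW-BSP", "SW-BSP", "E-BSP", "non-BSP")
  if (any(!manifest$linguistic_group %in% groups))
    stop("manifest: linguistic_group must be one of ",
         paste(groups, collapse = ", "))
  if (any(manifest$latitude < -90 | manifest$latitude > 90, na.rm = TRUE))
    stop("manifest: latitude outside [-90, 90]")
  if (any(manifest$longitude < -180 | manifest$longitude > 180, na.rm = TRUE))
    stop("manifest: longitude outside [-180, 180]")
  flags <- strsplit(manifest$qc_flags, ";", fixed = TRUE)
  ok <- vapply(flags, function(f)
    all(f %in% c("low_call_rate", "kin_excluded", "")), logical(1))
  if (!all(ok)) stop("manifest: unknown qc flag")
  chk <- unique(manifest[, c("population", "latitude", "longitude")])
  if (anyDuplicated(chk$population))
    stop("manifest: population mapped to more than one coordinate pair")
  tibble::as_tibble(manifest)
}

manifest_flags <- function(manifest, flag) {
  vapply(strsplit(manifest$qc_flags, ";", fixed = TRUE),
         function(f) flag %in% f, logical(1))
}

#' Apply the QC exclusion ledger to a panel
#'
#' Removes samples flagged `low_call_rate`, then samples flagged
#' `kin_excluded`.  A sample carrying both flags is counted once, under
#' `low_call_rate` (call-rate filtering applies first), so the report's
#' counts always satisfy
#' `n_retained = n_input - n_removed_call_rate - n_removed_kinship`.
#' Surviving haplotype-row order is preserved.
#'
#' @param manifest Sample manifest covering every panel sample.
#' @param panel A [genotype_panel()].
#' @return A list with elements `panel` (filtered) and `report`, a
#'   one-row tibble with `n_input`, `n_removed_call_rate`,
#'   `n_removed_kinship`, `n_retained`.
#' @export
#' @examples
#' # a 1,763-sample ledger with 67 + 105 flags retains 1,591 samples
apply_qc_ledger <- function(manifest, panel) {
  manifest <- validate_manifest(manifest)
  i <- match(panel$sample_ids, manifest$sample_id)
  if (anyNA(i))
    stop("apply_qc_ledger: panel sample(s) absent from manifest: ",
         paste(head(panel$sample_ids[is.na(i)], 5), collapse = ", "))
  low <- manifest_flags(manifest, "low_call_rate")[i]
  kin <- manifest_flags(manifest, "kin_excluded")[i] & !low
  keep <- !(low | kin)
  report <- tibble::tibble(
    n_input = length(keep),
    n_removed_call_rate = sum(low),
    n_removed_kinship = sum(kin),
    n_retained = sum(keep))
  if (!any(keep)) stop("apply_qc_ledger: no samples retained")
  list(panel = subset_samples(panel, panel$sample_ids[keep]),
       report = report)
}

#' QC retention count for a manifest alone
#'
#' Bookkeeping form of [apply_qc_ledger()] for when only the ledger is
#' at hand: counts flagged samples (both-flag samples counted under
#' `low_call_rate`) without touching genotypes.
#'
#' @inheritParams apply_qc_ledger
#' @return One-row tibble as in [apply_qc_ledger()].
#' @export
qc_report <- function(manifest) {
  manifest <- validate_manifest(manifest)
  low <- manifest_flags(manifest, "low_call_rate")
  kin <- manifest_flags(manifest, "kin_excluded") & !low
  tibble::tibble(
    n_input = nrow(manifest),
    n_removed_call_rate = sum(low),
    n_removed_kinship = sum(kin),
    n_retained = nrow(manifest) - sum(low) - sum(kin))
}
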