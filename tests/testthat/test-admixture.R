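# two-sample fixture: one chromosome of 100 cM, 10 SNPs every 10 cM,
# haplotype 1 of s1 carries a non-target tract over 40% of the map
masking_fixture <- function() {
  L <- 10
  pos_cM <- seq(5, 95, by = 10)
  pos_bp <- as.integer(pos_cM * 1e6)
  h <- matrix(1L, 4, L)
  p <- genotype_panel(h, data.frame(chrom = "1", pos_bp = pos_bp,
                                    pos_cM = pos_cM),
                      c("s1", "s2"))
  tr <- tibble::tibble(
    haplotype_id = c("s1_1", "s1_1", "s1_2", "s2_1", "s2_2"),
    chrom = "1",
    start_bp = as.integer(c(0, 40e6, 0, 0, 0)),
    end_bp = as.integer(c(40e6, 100e6, 100e6, 100e6, 100e6)),
    start_cM = c(0, 40, 0, 0, 0),
    end_cM = c(40, 100, 100, 100, 100),
    ancestry = c("WCA", "wRHG", "WCA", "WCA", "WCA"))
  list(panel = p, tracts = ancestry_tracts(tr))
}

test_that("masking blanks exactly the variants inside non-target tracts", {
  fx <- masking_fixture()
  out <- mask_by_ancestry(fx$panel, fx$tracts, "WCA")
  # haplotype s1_1: tract [40, 100) cM is non-target -> SNPs at 45..95
  masked <- is.na(out$panel$haplotypes[1, ])
  expect_identical(masked, fx$panel$variants$pos_cM >= 40)
  expect_false(anyNA(out$panel$haplotypes[-1, ]))
  # cM-weighted fraction: s1 = (0.4 + 1)/2, s2 = 1
  expect_equal(out$fractions$ancestry_fraction, c(0.7, 1))
})

test_that("masking is idempotent and the identity on all-target tracts", {
  fx <- masking_fixture()
  once <- mask_by_ancestry(fx$panel, fx$tracts, "WCA")
  twice <- mask_by_ancestry(once$panel, fx$tracts, "WCA")
  expect_identical(once$panel$haplotypes, twice$panel$haplotypes)

  all_target <- fx$tracts
  all_target$ancestry <- "WCA"
  id <- mask_by_ancestry(fx$panel, ancestry_tracts(all_target), "WCA")
  expect_identical(id$panel$haplotypes, fx$panel$haplotypes)
  expect_equal(id$fractions$ancestry_fraction, c(1, 1))
})

test_that("variants outside tract coverage are reported", {
  fx <- masking_fixture()
  short <- fx$tracts
  short$end_bp[3] <- as.integer(50e6)   # s1_2 now covers only half
  short$end_cM[3] <- 50
  expect_error(mask_by_ancestry(fx$panel, short, "WCA"), "coverage")
})

test_that("target and non-target cM fractions sum to one per haplotype", {
  set.seed(91)
  d <- generate_admixed_dataset(admixed_config(
    n_chrom = 1, L_snps = 100, t_admix = 5, N_admixed = 40,
    n_admixed = 10, n_source = 5), seed = 3)
  spans <- d$tracts |>
    dplyr::group_by(haplotype_id) |>
    dplyr::summarise(
      target = sum((end_cM - start_cM)[ancestry == "WCA"]),
      non = sum((end_cM - start_cM)[ancestry != "WCA"]),
      total = sum(end_cM - start_cM))
  expect_equal(spans$target + spans$non, spans$total, tolerance = 1e-9)
})

test_that("population filtering applies the ancestry and size thresholds", {
  set.seed(92)
  p <- rand_panel(75, 12)
  man <- panel_manifest(p, rep(c("low", "mid", "high"), times = c(15, 15, 45)))
  fr <- tibble::tibble(
    sample_id = p$sample_ids,
    ancestry_fraction = rep(c(0.65, 0.72, 0.95), times = c(15, 15, 45)))
  out <- prepare_masked_dataset(p, fr, man, min_fraction = 0.70,
                                min_n = 10, max_n = 30, seed = 1)
  kept <- table(out$manifest$population)
  expect_false("low" %in% names(kept))
  expect_equal(unname(kept[["mid"]]), 15)
  expect_equal(unname(kept[["high"]]), 30)  # downsampled from 45

  # identity when everything is within bounds
  man2 <- panel_manifest(p, rep(c("a", "b", "c"), times = c(15, 15, 45)))
  fr2 <- fr; fr2$ancestry_fraction <- 0.9
  out2 <- prepare_masked_dataset(p, fr2, man2, max_n = 50, seed = 1)
  expect_identical(out2$panel$sample_ids, p$sample_ids)
})

test_that("tract dating evaluates the closed form and scales correctly", {
  # 30 interior non-target tracts of 5 cM on a 50% admixed background:
  # m = 0.5, Lbar = 0.05 Morgan -> t = 1 / (0.5 * 0.05) = 40
  # layout per haplotype (cM): wRHG [0,20) | WCA [20,45) | wRHG [45,70)
  # | WCA [70,95) | wRHG [95,100): non-target fraction exactly 0.5; the
  # end tracts are censored, leaving one interior tract of 25 cM
  mk <- function(scale = 1) {
    starts <- c(0, 20, 45, 70, 95) * scale
    ends <- c(20, 45, 70, 95, 100) * scale
    anc <- c("wRHG", "WCA", "wRHG", "WCA", "wRHG")
    rows <- lapply(1:30, function(h) tibble::tibble(
      haplotype_id = sprintf("s%02d_%d", ceiling(h / 2), 2 - h %% 2),
      chrom = "1",
      start_bp = as.integer(starts * 1e6), end_bp = as.integer(ends * 1e6),
      start_cM = starts, end_cM = ends, ancestry = anc))
    ancestry_tracts(dplyr::bind_rows(rows))
  }
  tr <- mk(1)
  m_hat <- 0.5
  t_expect <- 1 / ((1 - m_hat) * 0.25)   # = 8 generations
  d1 <- date_admixture_from_tracts(tr, min_tracts = 10)
  expect_equal(d1$t_hat, t_expect, tolerance = 1e-9)
  expect_equal(d1$m_hat, m_hat, tolerance = 1e-9)

  d2 <- date_admixture_from_tracts(mk(2), min_tracts = 10)
  expect_equal(d2$t_hat, t_expect / 2, tolerance = 1e-9)

  unadm <- tr
  unadm$ancestry <- "WCA"
  expect_error(date_admixture_from_tracts(ancestry_tracts(unadm)),
               "unadmixed")
})

test_that("dating is monotone in the simulated admixture time", {
  ok <- 0
  for (s in 1:10) {
    t_hats <- vapply(c(10, 30, 100), function(tt) {
      d <- generate_admixed_dataset(admixed_config(
        n_chrom = 2, L_snps = 20, t_admix = tt, N_admixed = 80,
        n_admixed = 20, n_source = 4), seed = 1000 * s + tt)
      date_admixture_from_tracts(d$tracts, min_tracts = 10)$t_hat
    }, numeric(1))
    if (t_hats[1] < t_hats[2] && t_hats[2] < t_hats[3]) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("date-distance regression reuses the OLS machinery", {
  man <- make_manifest(sprintf("p%d", 1:5))
  origin <- c(man$latitude[1], man$longitude[1])
  km <- distance_from_origin(man, origin)
  dates <- tibble::tibble(population = km$population,
                          t_hat = 60 - 0.01 * km$distance_km)
  reg <- suppressWarnings(date_distance_regression(dates, man, origin))
  expect_equal(reg$slope, -0.01, tolerance = 1e-9)
  expect_equal(reg$r_squared, 1, tolerance = 1e-9)
  flat <- tibble::tibble(population = km$population, t_hat = 30)
  expect_equal(date_distance_regression(flat, man, origin)$slope, 0)
})
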