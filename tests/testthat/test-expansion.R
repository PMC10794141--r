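test_that("route scenarios enumerate exactly northern, southern, both", {
  sc <- route_scenarios(9, 6)
  expect_setequal(names(sc), c("northern", "southern", "both"))
  expect_error(scenario_spec("eastern"), "arg")
  expect_error(scenario_spec("southern", m = 0.3), "0.25")
  expect_error(scenario_spec("southern", founder_size = 3), "even")
})

test_that("habitability masks count out barrier and corridor cells", {
  sc_open <- scenario_spec("both")
  g <- build_landscape(10, 10, sc_open, K = 10)
  expect_true(all(g$cells$habitable))

  sc <- scenario_spec("southern", barrier_rows = 4:5,
                      corridors = cbind(row = c(4, 5), col = c(3, 3)),
                      r = 0.5)
  # wait: one 2-cell corridor through a 2-row band opens 2 cells
  g2 <- build_landscape(10, 10, sc, K = 10)
  expect_equal(sum(g2$cells$habitable), 100 - 20 + 2)

  sc4 <- scenario_spec("southern", barrier_rows = 4:5,
                       corridors = as.matrix(expand.grid(row = 4:5,
                                                         col = 3:4)))
  g3 <- build_landscape(10, 10, sc4, K = 10)
  expect_equal(sum(g3$cells$habitable), 100 - 20 + 4)
})

test_that("an origin inside a closed barrier is rejected", {
  sc <- scenario_spec("southern", barrier_rows = 1)
  expect_error(build_landscape(6, 6, sc, K = 10),
               "closed barrier")
})

test_that("mirrored corridor geometry gives mirror-identical masks", {
  w <- 9
  n <- scenario_spec("northern", barrier_rows = 3,
                     corridors = cbind(row = 3, col = 8))
  s <- scenario_spec("southern", barrier_rows = 3,
                     corridors = cbind(row = 3, col = w + 1 - 8))
  gn <- build_landscape(w, 5, n, K = 5)
  gs <- build_landscape(w, 5, s, K = 5)
  mn <- matrix(gn$cells$habitable, nrow = 5, ncol = w, byrow = TRUE)
  ms <- matrix(gs$cells$habitable, nrow = 5, ncol = w, byrow = TRUE)
  expect_identical(mn, ms[, w:1])
})

test_that("without migration or colonization only the origin is occupied", {
  sc <- scenario_spec("both", r = 0.5, m = 0, founder_size = 4,
                      colonization_threshold = 1.5)
  g <- build_landscape(4, 4, sc, K = 10)
  res <- simulate_expansion(g, sc, sim_genetics(1, 20, 50), 15, seed = 3)
  expect_equal(sum(!is.na(res$arrival$arrival)), 1)
  expect_equal(res$arrival$arrival[g$origin_cell], 0)
  expect_equal(nrow(res$founding_edges), 0)
})

test_that("arrival times increase strictly along a linear corridor", {
  sc <- scenario_spec("both", r = 1, m = 0.05, founder_size = 6,
                      colonization_threshold = 0.5,
                      barrier_rows = 2)
  g <- build_landscape(12, 2, sc, K = 10)   # habitable row 1 only
  gen <- sim_genetics(1, 30, 50)
  for (s in 1:20) {
    res <- simulate_expansion(g, sc, gen, 80, seed = 100 + s)
    arr <- res$arrival$arrival[1:12]
    expect_false(anyNA(arr))
    expect_true(all(diff(arr) > 0))
  }
})

test_that("founding edges form a tree rooted at the origin", {
  sc <- scenario_spec("southern", barrier_rows = 3,
                      corridors = cbind(row = 3, col = 2))
  g <- build_landscape(6, 5, sc, K = 10)
  res <- simulate_expansion(g, sc, sim_genetics(1, 30, 50), 60, seed = 5)
  e <- res$founding_edges
  colonized <- res$arrival$cell[!is.na(res$arrival$arrival)]
  expect_equal(sort(c(g$origin_cell, e$child)), sort(colonized))
  expect_equal(anyDuplicated(e$child), 0)      # exactly one founding edge
  expect_false(g$origin_cell %in% e$child)     # root has no parent
  # every parent was colonized no later than its child
  arr <- res$arrival$arrival
  expect_true(all(arr[e$parent] < e$generation | e$parent == g$origin_cell))
})

test_that("single-deme allele-frequency change matches WF binomial variance", {
  # same seed replays the first generation, so the two runs differ by
  # exactly one WF resampling step conditioned on the gen-1 frequency
  sc <- scenario_spec("both", r = 0.5, m = 0, founder_size = 2,
                      colonization_threshold = 2)
  g <- build_landscape(2, 2, sc, K = 50)
  gen <- sim_genetics(1, 1, 100, init_freqs = 0.5)
  step <- vapply(1:2000, function(s) {
    p1 <- mean(simulate_expansion(g, sc, gen, 1, seed = s)$haplotypes[, 1])
    p2 <- mean(simulate_expansion(g, sc, gen, 2, seed = s)$haplotypes[, 1])
    c(p1, p2 - p1)
  }, numeric(2))
  oracle <- mean(step[1, ] * (1 - step[1, ])) / (2 * 50)
  expect_lt(abs(var(step[2, ]) - oracle) / oracle, 0.10)
})

test_that("identical inputs and seed reproduce the run bitwise", {
  sc <- scenario_spec("both", r = 0.8, m = 0.1, founder_size = 6,
                      colonization_threshold = 0.4)
  g <- build_landscape(5, 4, sc, K = 8)
  gen <- sim_genetics(2, 25, 80)
  r1 <- simulate_expansion(g, sc, gen, 30, seed = 77)
  r2 <- simulate_expansion(g, sc, gen, 30, seed = 77)
  expect_identical(r1$haplotypes, r2$haplotypes)
  expect_identical(r1$arrival, r2$arrival)
  expect_identical(r1$founding_edges, r2$founding_edges)
})

test_that("census stays at carrying capacity under full occupancy", {
  # at capacity the logistic mean equals K, so Binomial(K, 1) = K for
  # every deme in every generation; migration must conserve this
  sc <- scenario_spec("both", r = 0.5, m = 0.2, founder_size = 2,
                      colonization_threshold = 0.5)
  g <- build_landscape(4, 3, sc, K = 7)
  res <- simulate_expansion(g, sc, sim_genetics(1, 10, 50), 25, seed = 2,
                            full_occupancy = TRUE)
  expect_true(all(res$census == 7))
  expect_equal(nrow(res$haplotypes), 2 * 7 * 12)
})

test_that("small founder groups depress downstream haplotype diversity", {
  # terminal-deme heterozygosity under F = 4 vs F = 2K on a corridor
  gen <- sim_genetics(1, 120, 100)
  worse <- 0
  for (s in 1:20) {
    het <- vapply(c(4, 100), function(F) {
      sc <- scenario_spec("both", r = 0.8, m = 0.02, founder_size = F,
                          colonization_threshold = 0.5, barrier_rows = 2)
      g <- build_landscape(8, 2, sc, K = 50)
      res <- simulate_expansion(g, sc, gen, 60, seed = 1000 * s + F)
      sp <- sample_panel(res, tibble::tibble(cell = 8, n = 20),
                         seed = s)
      haplotype_heterozygosity(sp$panel, sp$manifest,
                               window_snps = 20)$haplotype_heterozygosity
    }, numeric(1))
    if (het[1] < het[2]) worse <- worse + 1
  }
  expect_gte(worse, 18)
})

test_that("richness declines along a corridor under serial founding", {
  gen <- sim_genetics(1, 400, 100)
  sc <- scenario_spec("both", r = 0.8, m = 0.02, founder_size = 6,
                      colonization_threshold = 0.5, barrier_rows = 2)
  g <- build_landscape(15, 2, sc, K = 30)
  pts <- list()
  for (s in 1:10) {
    res <- simulate_expansion(g, sc, gen, 150, seed = 300 + s)
    expect_true(all(!is.na(res$arrival$arrival[1:15])))
    expect_gte(150 - max(res$arrival$arrival[1:15]), 60)
    sp <- sample_panel(res, tibble::tibble(cell = 1:15, n = 10), seed = s)
    r <- haplotype_richness(sp$panel, sp$manifest, seed = s)
    idx <- as.integer(sub("pop_c", "", r$population))
    pts[[s]] <- data.frame(index = idx, richness = r$haplotype_richness)
  }
  d <- do.call(rbind, pts)
  fit <- summary(lm(richness ~ index, data = d))
  expect_lt(fit$coefficients[2, 1], 0)
  expect_lt(fit$coefficients[2, 4], 0.01)
})

test_that("deme sampling is exhaustive, paired and reproducible", {
  sc <- scenario_spec("both", r = 0.6, m = 0.05, founder_size = 6,
                      colonization_threshold = 0.5)
  g <- build_landscape(3, 3, sc, K = 10)
  res <- simulate_expansion(g, sc, sim_genetics(1, 40, 60), 30, seed = 9)
  cell <- g$origin_cell
  n_avail <- res$census[cell]
  sp <- sample_panel(res, tibble::tibble(cell = cell, n = n_avail), seed = 1)
  expect_equal(nrow(sp$panel$haplotypes), 2 * n_avail)
  store <- res$haplotypes[res$deme_of == cell, , drop = FALSE]
  key <- function(m) sort(apply(m, 1, paste, collapse = ""))
  expect_identical(key(sp$panel$haplotypes), key(store))

  sp10 <- sample_panel(res, tibble::tibble(cell = cell, n = 5), seed = 2)
  expect_equal(nrow(sp10$panel$haplotypes), 10)
  sp10b <- sample_panel(res, tibble::tibble(cell = cell, n = 5), seed = 2)
  expect_identical(sp10$panel$haplotypes, sp10b$panel$haplotypes)
  expect_error(sample_panel(res, tibble::tibble(cell = cell, n = 99)),
               "holding")
  sc0 <- scenario_spec("both", r = 0.5, m = 0, founder_size = 2,
                       colonization_threshold = 2)
  res0 <- simulate_expansion(g, sc0, sim_genetics(1, 10, 60), 5, seed = 1)
  empty_cell <- setdiff(1:9, g$origin_cell)[1]
  expect_error(sample_panel(res0, tibble::tibble(cell = empty_cell, n = 2)),
               "uncolonized")
})
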