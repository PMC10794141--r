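test_that("Hudson FST hits the closed-form endpoints", {
  # alternate fixed differences at every SNP: numerator = denominator
  h <- rbind(matrix(0L, 20, 10), matrix(1L, 20, 10))
  p <- make_panel(h)
  man <- panel_manifest(p, rep(c("A", "B"), each = 10))
  fst <- hudson_fst_matrix(p, man)
  expect_equal(fst$values["A", "B"], 1)

  # two samples from one panmictic pool stay near zero
  set.seed(71)
  freqs <- runif(300, 0.2, 0.8)
  h2 <- t(vapply(seq_len(120), function(i) rbinom(300, 1, freqs),
                 numeric(300)))
  storage.mode(h2) <- "integer"
  p2 <- make_panel(h2)
  man2 <- panel_manifest(p2, rep(c("A", "B"), each = 30))
  fst2 <- hudson_fst_matrix(p2, man2)
  expect_lt(abs(fst2$values["A", "B"]), 0.02)
})

test_that("Hudson FST is invariant to allele-label flips", {
  set.seed(72)
  p <- rand_panel(20, 50)
  man <- panel_manifest(p, rep(c("A", "B"), each = 10))
  f1 <- hudson_fst_matrix(p, man)
  flip <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  h <- p$haplotypes
  h[, flip] <- 1L - h[, flip]
  f2 <- hudson_fst_matrix(make_panel(h), man)
  expect_equal(f1$values, f2$values, tolerance = 1e-12)
})

test_that("a pair with no usable variation is NaN with a warning", {
  h <- matrix(0L, 8, 5)
  p <- make_panel(h)
  man <- panel_manifest(p, rep(c("A", "B"), each = 2))
  expect_warning(fst <- hudson_fst_matrix(p, man), "NaN")
  expect_true(is.nan(fst$values["A", "B"]))
})

test_that("f4 with a repeated population is exactly zero and antisymmetric", {
  set.seed(73)
  p <- rand_panel(24, 200)
  man <- panel_manifest(p, rep(c("A", "B", "C", "D"), each = 6))
  z <- f_statistic(p, man, "f4", c("A", "A", "B", "C"), block_snps = 20)
  expect_identical(z$estimate, 0)
  f_abcd <- f_statistic(p, man, "f4", c("A", "B", "C", "D"), block_snps = 20)
  f_bacd <- f_statistic(p, man, "f4", c("B", "A", "C", "D"), block_snps = 20)
  f_abdc <- f_statistic(p, man, "f4", c("A", "B", "D", "C"), block_snps = 20)
  expect_equal(f_abcd$estimate, -f_bacd$estimate, tolerance = 1e-14)
  expect_equal(f_abcd$estimate, -f_abdc$estimate, tolerance = 1e-14)
  expect_equal(f_abcd$se, f_bacd$se, tolerance = 1e-14)
})

test_that("uncorrected f3 reproduces the hand-computed single-SNP value", {
  # a = 0, b = 1, c = 0.5 exactly: (c-a)(c-b) = -0.25 at every SNP
  hA <- matrix(0L, 20, 2)
  hB <- matrix(1L, 20, 2)
  hC <- rbind(matrix(0L, 10, 2), matrix(1L, 10, 2))
  p <- make_panel(rbind(hC, hA, hB))
  man <- panel_manifest(p, rep(c("C", "A", "B"), each = 10))
  f3 <- f_statistic(p, man, "f3", c("C", "A", "B"), block_snps = 1,
                    corrected = FALSE)
  expect_equal(f3$estimate, -0.25)
})

test_that("great-circle distances match the haversine closed form", {
  man <- make_manifest(c("o", "e", "anti"),
                       lat = c(0, 0, 0), lon = c(0, 1, 180))
  d <- great_circle_matrix(man)
  expect_equal(d$values["o", "o"], 0)
  expect_lt(abs(d$values["o", "e"] - 111.195), 0.01)
  expect_lt(abs(d$values["o", "anti"] - pi * 6371.0088), 0.1)
})

test_that("linguistic distances are Hamming proportions over shared slots", {
  m <- rbind(a = c(1, 1, 2, 3, 4, 5, 1, 2, 3, 4),
             b = c(1, 1, 2, 3, 4, 5, 1, 2, 3, 4),
             c = c(9, 1, 2, 8, 4, 5, 1, 7, 3, 4))
  d <- linguistic_distance_matrix(m)
  expect_equal(d$values["a", "b"], 0)
  expect_equal(d$values["a", "c"], 0.3)

  m2 <- m
  m2[1, 1:5] <- NA
  d2 <- linguistic_distance_matrix(m2)
  expect_equal(d2$values["a", "c"], mean(m[1, 6:10] != m[3, 6:10]))

  set.seed(74)
  for (i in 1:5) {
    mr <- matrix(sample(c(1:4, NA), 50, replace = TRUE), 5)
    rownames(mr) <- paste0("l", 1:5)
    dr <- suppressWarnings(linguistic_distance_matrix(mr))
    expect_equal(dr$values, t(dr$values))
  }
})

test_that("Mantel r equals the plain Pearson correlation of the triangles", {
  set.seed(75)
  rd <- function() {
    m <- matrix(runif(100), 10); m <- m + t(m); diag(m) <- 0
    dist_matrix(m, paste0("l", 1:10), "fst")
  }
  x <- rd(); y <- rd()
  mt <- mantel_test(x, y, n_perm = 99, seed = 1)
  expect_equal(mt$r, cor(x$values[upper.tri(x$values)],
                         y$values[upper.tri(y$values)]))
  # and against the independent reference implementation
  vg <- vegan::mantel(x$values, y$values, permutations = 99)
  expect_equal(mt$r, unname(vg$statistic), tolerance = 1e-12)

  self <- mantel_test(x, x, n_perm = 199, seed = 2)
  expect_equal(self$r, 1)
  expect_equal(self$p, 1 / 200)
})

test_that("partial Mantel conditions out a shared driver", {
  set.seed(76)
  base <- matrix(runif(400), 20); base <- base + t(base); diag(base) <- 0
  lab <- paste0("l", 1:20)
  noise <- function() {
    m <- matrix(runif(400, 0, 0.1), 20); m <- m + t(m); diag(m) <- 0; m
  }
  x <- dist_matrix(base + noise(), lab, "fst")
  y <- dist_matrix(base + noise(), lab, "linguistic")
  z <- dist_matrix(base, lab, "geographic_km")
  plain <- mantel_test(x, y, n_perm = 199, seed = 3)
  partial <- mantel_test(x, y, z, n_perm = 199, seed = 3)
  expect_gt(plain$r, 0.9)
  expect_lt(abs(partial$r), 0.5)
  expect_identical(partial$conditioned_on, "geographic_km")
})

test_that("label alignment is enforced and reordered transparently", {
  set.seed(77)
  m <- matrix(runif(25), 5); m <- m + t(m); diag(m) <- 0
  x <- dist_matrix(m, paste0("l", 1:5), "fst")
  y <- dist_matrix(m[5:1, 5:1], paste0("l", 5:1), "fst")
  expect_equal(mantel_test(x, y, n_perm = 99, seed = 1)$r, 1)
  z <- dist_matrix(m, paste0("other", 1:5), "fst")
  expect_error(mantel_test(x, z, n_perm = 99), "label")
})

test_that("PCA separates duplicated clusters and matches a dense eigensolve", {
  g1 <- rep(c(0L, 1L), length.out = 50)
  g2 <- rep(c(1L, 0L), length.out = 50)
  mk_ind <- function(hap) rbind(hap, hap)
  h <- do.call(rbind, c(replicate(5, mk_ind(g1), simplify = FALSE),
                        replicate(5, mk_ind(g2), simplify = FALSE)))
  p <- make_panel(h)
  pc <- genotype_pca(p, 2)
  expect_true(all(sign(pc$PC1[1:5]) != sign(pc$PC1[6:10])))
  expect_lt(diff(range(pc$PC1[1:5])), 1e-8)

  set.seed(78)
  p2 <- rand_panel(20, 50)
  pc2 <- genotype_pca(p2, 5)
  g <- genotype_matrix(p2)
  fr <- colMeans(g) / 2
  keep <- fr > 0 & fr < 1
  x <- sweep(sweep(g[, keep], 2, 2 * fr[keep]), 2,
             sqrt(fr[keep] * (1 - fr[keep])), "/")
  ev <- eigen(stats::cov(x))$values[1:5]
  expect_equal(unname(attr(pc2, "eigenvalues")), ev, tolerance = 1e-8)

  pc2b <- genotype_pca(p2, 5)
  expect_identical(pc2, pc2b)   # sign convention fixes repeated runs
})

test_that("Procrustes recovers an applied similarity transform", {
  set.seed(79)
  a <- matrix(rnorm(24), ncol = 2)
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  b <- sweep(0.649 * a %*% rot, 2, c(3, -2), "+")
  fit <- procrustes_fit(a, b, n_perm = 99, seed = 1)
  expect_equal(fit$correlation, 1, tolerance = 1e-9)
  expect_equal(fit$scale, 0.649, tolerance = 1e-9)
  expect_equal(fit$fitted, b, tolerance = 1e-9)
  expect_equal(fit$p, 1 / 100)
})

test_that("Procrustes agrees with a rotation-angle grid search and vegan", {
  set.seed(80)
  a <- matrix(rnorm(8), 4, 2)
  b <- matrix(rnorm(8), 4, 2)
  fit <- procrustes_fit(a, b, n_perm = 99, seed = 1)
  # grid-search oracle over rotation angle with closed-form scale
  ac <- scale(a, scale = FALSE); bc <- scale(b, scale = FALSE)
  best <- Inf
  for (th in seq(0, 2 * pi, length.out = 7201)) {
    for (refl in c(1, -1)) {
      r <- matrix(c(cos(th), sin(th) * refl, -sin(th),
                    cos(th) * refl), 2)
      sc <- sum(diag(crossprod(ac %*% r, bc))) / sum(ac^2)
      if (sc < 0) next
      ss <- sum((sc * ac %*% r - bc)^2)
      if (ss < best) best <- ss
    }
  }
  corr_oracle <- sqrt(1 - best / sum(bc^2))
  expect_equal(fit$correlation, corr_oracle, tolerance = 1e-4)

  vg <- vegan::protest(b, a, permutations = 99)
  expect_equal(fit$correlation, sqrt(1 - vg$ss), tolerance = 1e-8)
})
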