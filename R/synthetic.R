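#' Small-world pipeline configuration
#'
#' The default desk-scale study conditions used throughout the package's
#' tests: a 12 x 8 deme lattice, 18 sampled populations of 10-30
#' diploids, two chromosomes of 2,000 SNPs each on a uniform 1 cM/Mb
#' map, carrying capacity 30 diploids per deme, and the southern-route
#' scenario geometry.  Every field can be overridden.
#'
#' @param ... Overrides for any config entry.
#' @return Named list of generator settings.
#' @export
small_world_config <- function(...) {
  cfg <- list(width = 12, height = 8, K = 30, n_pops = 18,
              scenario = "southern", barrier_rows = 4,
              southern_col = 2, northern_col = 12,
              r = 0.6, m = 0.05, founder_size = 8,
              colonization_threshold = 0.5,
              n_chrom = 2, L_snps = 2000, cM_length = 100,
              generations = 120,
              min_n = 10, max_n = 30)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

config_scenario <- function(cfg) {
  route_scenarios(cfg$width, cfg$height, barrier_rows = cfg$barrier_rows,
                  southern_col = cfg$southern_col,
                  northern_col = cfg$northern_col,
                  r = cfg$r, m = cfg$m, founder_size = cfg$founder_size,
                  colonization_threshold =
                    cfg$colonization_threshold)[[cfg$scenario]]
}

# pick n_pops colonized demes spread along the expansion (arrival-time
# quantiles), origin deme always first
pick_sampled_demes <- function(result, n_pops) {
  arr <- result$arrival
  col <- arr[!is.na(arr$arrival), ]
  col <- col[order(col$arrival, col$cell), ]
  if (nrow(col) < n_pops)
    stop("generator: only ", nrow(col), " demes colonized; cannot place ",
         n_pops, " populations")
  idx <- unique(round(seq(1, nrow(col), length.out = n_pops)))
  col$cell[idx]
}

assign_groups <- function(arrivals) {
  q <- cut(rank(arrivals, ties.method = "first"), 4, labels = FALSE)
  c("NW-BSP2", "WW-BSP", "E-BSP", "SW-BSP")[q]
}

#' Generate a serial-founder dataset
#'
#' Runs the lattice expansion under the configured route scenario and
#' samples populations of `min_n`-`max_n` diploids spread along the
#' colonized lattice, with manifest coordinates taken from the deme
#' cells.  The returned truth records the founding tree, so downstream
#' checks can compare inferred routes and language trees against it.
#'
#' @param config A [small_world_config()] list.
#' @param seed Integer seed; the output is a pure function of
#'   `(config, seed)`.
#' @return List with `panel`, `manifest` and `truth` (generator name,
#'   parameters, founding tree, arrival times, sampling plan, seed).
#' @export
generate_serial_founder_dataset <- function(config = small_world_config(),
                                            seed = 1) {
  sc <- config_scenario(config)
  grid <- build_landscape(config$width, config$height, sc, K = config$K)
  set.seed(as.integer(seed))
  genetics <- sim_genetics(config$n_chrom, config$L_snps, config$cM_length)
  sim_seed <- sample.int(.Machine$integer.max, 1)
  res <- simulate_expansion(grid, sc, genetics, config$generations, sim_seed)
  cells <- pick_sampled_demes(res, config$n_pops)
  set.seed(sim_seed + 1)
  ns <- sample(seq(config$min_n, min(config$max_n, config$K)),
               length(cells), replace = TRUE)
  arr <- res$arrival$arrival[cells]
  sampling <- tibble::tibble(cell = cells, n = ns,
                             population = sprintf("pop%02d",
                                                  seq_along(cells)))
  sp <- sample_panel(res, sampling, seed = sim_seed + 2,
                     linguistic_group = assign_groups(arr))
  truth <- list(generator = "serial_founder",
                params = list(scenario = sc$name, r = sc$r, m = sc$m,
                              founder_size = sc$founder_size,
                              colonization_threshold =
                                sc$colonization_threshold),
                founding_edges = res$founding_edges,
                arrival = res$arrival, origin_cell = grid$origin_cell,
                grid = grid, sampling = sampling, seed = seed)
  list(panel = sp$panel, manifest = sp$manifest, truth = truth)
}

#' Generate an equilibrium stepping-stone dataset
#'
#' Every habitable deme starts at carrying capacity and the lattice is
#' run for a burn-in of `20 * K` generations (no expansion), producing
#' isolation by distance - differentiation grows with lattice
#' separation - without an origin-anchored diversity cline.  Defaults
#' shrink the deme size to keep the burn-in at desk scale.
#'
#' @inheritParams generate_serial_founder_dataset
#' @export
generate_stepping_stone_dataset <- function(
    config = small_world_config(K = 15, barrier_rows = integer(0)),
    seed = 1) {
  sc <- scenario_spec("both", barrier_rows = config$barrier_rows,
                      r = config$r, m = config$m,
                      founder_size = config$founder_size,
                      colonization_threshold = config$colonization_threshold)
  grid <- build_landscape(config$width, config$height, sc, K = config$K)
  set.seed(as.integer(seed))
  genetics <- sim_genetics(config$n_chrom, config$L_snps, config$cM_length)
  sim_seed <- sample.int(.Machine$integer.max, 1)
  burn_in <- 20 * config$K
  res <- simulate_expansion(grid, sc, genetics, burn_in, sim_seed,
                            full_occupancy = TRUE)
  occupied <- res$arrival$cell[!is.na(res$arrival$arrival)]
  set.seed(sim_seed + 1)
  cells <- sort(sample(occupied, config$n_pops))
  ns <- sample(seq(config$min_n, min(config$max_n, config$K)),
               length(cells), replace = TRUE)
  sampling <- tibble::tibble(cell = cells, n = ns,
                             population = sprintf("pop%02d",
                                                  seq_along(cells)))
  sp <- sample_panel(res, sampling, seed = sim_seed + 2,
                     linguistic_group = "E-BSP")
  truth <- list(generator = "stepping_stone",
                params = list(m = sc$m, K = config$K, burn_in = burn_in),
                founding_edges = res$founding_edges,
                arrival = res$arrival, origin_cell = grid$origin_cell,
                grid = grid, sampling = sampling, seed = seed)
  list(panel = sp$panel, manifest = sp$manifest, truth = truth)
}

drift_freqs <- function(p, n_dip, gens) {
  for (g in seq_len(gens)) p <- rbinom(length(p), 2 * n_dip, p) / (2 * n_dip)
  p
}

bernoulli_haps <- function(n_hap, p) {
  matrix(rbinom(n_hap * length(p), 1, rep(p, each = n_hap)),
         nrow = n_hap)
}

# tract bookkeeping on 3-column matrices (start, end, ancestry code)
cut_tracts <- function(tr, lo, hi) {
  keep <- tr[, 2] > lo & tr[, 1] < hi
  tr <- tr[keep, , drop = FALSE]
  if (nrow(tr)) {
    tr[, 1] <- pmax(tr[, 1], lo)
    tr[, 2] <- pmin(tr[, 2], hi)
  }
  tr
}

merge_tracts <- function(tr) {
  n <- nrow(tr)
  if (n <= 1) return(tr)
  same <- tr[-1, 3] == tr[-n, 3]
  if (!any(same)) return(tr)
  grp <- cumsum(c(1, !same))
  out <- matrix(0, max(grp), 3)
  out[, 1] <- tr[!duplicated(grp), 1]
  out[, 2] <- tr[rev(!duplicated(rev(grp))), 2]
  out[, 3] <- tr[!duplicated(grp), 3]
  out
}

#' Generate an admixed dataset with exact ancestry tracts
#'
#' Two source populations are produced by drifting one ancestral panel
#' in two isolated demes for `0.3 * 2 * N_source` generations (enough
#' divergence for admixture f3 tests to have power at desk-scale sample
#' sizes).  At `t_admix` generations before present a target population
#' of `N_admixed` diploids is founded with a fraction `m_admix` of its
#' haplotypes drawn from the non-target source, then mates randomly
#' with Poisson recombination; ancestry tracts are propagated exactly,
#' so non-target tract lengths are approximately exponential with rate
#' `(1 - m_admix) * t_admix` per Morgan.
#'
#' The panel holds three populations: `WCA_src`, `wRHG_src` (the
#' sources) and `admixed`; tracts are returned for the admixed samples.
#'
#' @param config List with `n_chrom`, `L_snps`, `cM_length`, `t_admix`,
#'   `m_admix`, `n_admixed`, `n_source`, `N_admixed`, `N_source` (see
#'   [admixed_config()]).
#' @param seed Integer seed.
#' @return List with `panel`, `tracts`, `manifest`, `truth`.
#' @export
generate_admixed_dataset <- function(config = admixed_config(), seed = 1) {
  if (config$t_admix <= 0) stop("generate_admixed_dataset: t_admix must be > 0")
  set.seed(as.integer(seed))
  genetics <- sim_genetics(config$n_chrom, config$L_snps, config$cM_length)
  v <- genetics$variants
  L <- nrow(v)
  chroms <- unique(v$chrom)
  cl <- config$cM_length

  p0 <- runif(L, 0.1, 0.9)
  d_gens <- round(0.3 * 2 * config$N_source)
  pA <- drift_freqs(p0, config$N_source, d_gens)
  pB <- drift_freqs(p0, config$N_source, d_gens)

  # admixed founding generation: whole-genome single-ancestry haplotypes
  N <- config$N_admixed
  anc0 <- ifelse(runif(2 * N) < config$m_admix, "wRHG", "WCA")
  haps <- matrix(0L, 2 * N, L)
  for (h in seq_len(2 * N)) {
    p <- if (anc0[h] == "WCA") pA else pB
    haps[h, ] <- rbinom(L, 1, p)
  }
  anc_levels <- c("WCA", "wRHG")
  tracts <- lapply(seq_len(2 * N), function(h) {
    lapply(chroms, function(ch)
      matrix(c(0, cl, match(anc0[h], anc_levels)), 1, 3))
  })

  snp_of_chrom <- lapply(chroms, function(ch) which(v$chrom == ch))
  pos_of_chrom <- lapply(seq_along(chroms),
                         function(ci) v$pos_cM[snp_of_chrom[[ci]]])

  gamete_tracked <- function(h1, h2, t1, t2) {
    al <- integer(L); tr <- vector("list", length(chroms))
    for (ci in seq_along(chroms)) {
      k <- rpois(1, cl / 100)
      start_first <- runif(1) < 0.5
      idx <- snp_of_chrom[[ci]]
      if (k == 0) {
        al[idx] <- if (start_first) h1[idx] else h2[idx]
        tr[[ci]] <- if (start_first) t1[[ci]] else t2[[ci]]
        next
      }
      br <- sort(runif(k, 0, cl))
      bounds <- c(0, br, cl)
      seg_of_snp <- findInterval(pos_of_chrom[[ci]], br)
      use_first <- (seg_of_snp %% 2 == 0) == start_first
      al[idx] <- ifelse(use_first, h1[idx], h2[idx])
      pieces <- lapply(seq_len(k + 1), function(s) {
        src <- if (((s - 1) %% 2 == 0) == start_first) t1[[ci]] else t2[[ci]]
        cut_tracts(src, bounds[s], bounds[s + 1])
      })
      tr[[ci]] <- merge_tracts(do.call(rbind, pieces))
    }
    list(al = al, tr = tr)
  }

  for (g in seq_len(config$t_admix)) {
    new_haps <- matrix(0L, 2 * N, L)
    new_tracts <- vector("list", 2 * N)
    for (i in seq_len(N)) {
      par <- sample.int(N, 2, replace = TRUE)
      for (q in 1:2) {
        a <- 2 * par[q] - 1
        gm <- gamete_tracked(haps[a, ], haps[a + 1, ],
                             tracts[[a]], tracts[[a + 1]])
        new_haps[2 * i - 2 + q, ] <- gm$al
        new_tracts[[2 * i - 2 + q]] <- gm$tr
      }
    }
    haps <- new_haps
    tracts <- new_tracts
  }

  pick <- sort(sample.int(N, config$n_admixed))
  adm_ids <- sprintf("adm_%03d", seq_along(pick))
  adm_rows <- as.vector(rbind(2 * pick - 1, 2 * pick))
  adm_haps <- haps[adm_rows, , drop = FALSE]

  tract_rows <- list()
  for (s in seq_along(pick)) for (q in 1:2) {
    hrow <- adm_rows[2 * s - 2 + q]
    for (ci in seq_along(chroms)) {
      tr <- tracts[[hrow]][[ci]]
      bp_start <- round(tr[, 1] * 1e6)
      bp_end <- round(tr[, 2] * 1e6)
      # keep the chromosome-terminal SNP inside the last half-open tract
      bp_end[nrow(tr)] <- bp_end[nrow(tr)] + 1
      tract_rows[[length(tract_rows) + 1]] <- tibble::tibble(
        haplotype_id = paste0(adm_ids[s], "_", q), chrom = chroms[ci],
        start_bp = as.integer(bp_start), end_bp = as.integer(bp_end),
        start_cM = tr[, 1], end_cM = tr[, 2],
        ancestry = anc_levels[tr[, 3]])
    }
  }
  tract_set <- ancestry_tracts(dplyr::bind_rows(tract_rows))

  src_haps <- rbind(bernoulli_haps(2 * config$n_source, pA),
                    bernoulli_haps(2 * config$n_source, pB))
  src_ids <- c(sprintf("wca_%03d", seq_len(config$n_source)),
               sprintf("rhg_%03d", seq_len(config$n_source)))
  panel <- genotype_panel(rbind(src_haps, adm_haps), v,
                          c(src_ids, adm_ids))
  manifest <- tibble::tibble(
    sample_id = c(src_ids, adm_ids),
    population = c(rep("WCA_src", config$n_source),
                   rep("wRHG_src", config$n_source),
                   rep("admixed", config$n_admixed)),
    country = "synthetic",
    linguistic_group = c(rep("non-BSP", 2 * config$n_source),
                         rep("E-BSP", config$n_admixed)),
    latitude = c(rep(0, config$n_source), rep(5, config$n_source),
                 rep(2.5, config$n_admixed)),
    longitude = c(rep(10, config$n_source), rep(12, config$n_source),
                  rep(15, config$n_admixed)),
    qc_flags = "")
  truth <- list(generator = "admixed",
                params = list(t_admix = config$t_admix,
                              m_admix = config$m_admix,
                              N_admixed = config$N_admixed,
                              divergence_gens = d_gens),
                seed = seed)
  list(panel = panel, tracts = tract_set, manifest = manifest,
       truth = truth)
}

#' @rdname generate_admixed_dataset
#' @param ... Overrides for any config entry.
#' @export
admixed_config <- function(...) {
  cfg <- list(n_chrom = 2, L_snps = 1000, cM_length = 100,
              t_admix = 30, m_admix = 0.2, n_admixed = 50,
              n_source = 30, N_admixed = 200, N_source = 50)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Generate a finite island-model dataset
#'
#' Per-SNP Wright-Fisher drift with a common migrant pool
#' (`p_i' = (1 - m) p_i + m * pbar` followed by binomial resampling in
#' each of `n_demes` demes of `N` diploids), run to equilibrium, then
#' diploid samples drawn from the final frequencies.  At equilibrium
#' mean pairwise FST is close to `1 / (1 + 4 N m)`.
#'
#' @param n_demes,N,m Island-model parameters.
#' @param gens Generations to run (default 200).
#' @param L Number of unlinked SNPs.
#' @param n_sample Diploids sampled per deme.
#' @param seed Integer seed.
#' @return List with `panel`, `manifest`.
#' @export
generate_island_dataset <- function(n_demes = 8, N = 50, m = 0.02,
                                    gens = 200, L = 1000, n_sample = 20,
                                    seed = 1) {
  set.seed(as.integer(seed))
  p0 <- runif(L, 0.2, 0.8)
  p <- matrix(rep(p0, each = n_demes), n_demes, L)
  for (g in seq_len(gens)) {
    pbar <- colMeans(p)
    pm <- sweep((1 - m) * p, 2, m * pbar, "+")
    p <- matrix(rbinom(n_demes * L, 2 * N, as.vector(pm)),
                n_demes, L) / (2 * N)
  }
  haps <- do.call(rbind, lapply(seq_len(n_demes), function(d)
    bernoulli_haps(2 * n_sample, p[d, ])))
  ids <- as.vector(vapply(seq_len(n_demes), function(d)
    sprintf("isl%02d_%03d", d, seq_len(n_sample)),
    character(n_sample)))
  variants <- tibble::tibble(chrom = rep("1", L),
                             pos_bp = as.integer(seq_len(L) * 1e6),
                             pos_cM = seq_len(L) * 1.0)
  panel <- genotype_panel(haps, variants, ids)
  manifest <- tibble::tibble(
    sample_id = ids,
    population = rep(sprintf("island%02d", seq_len(n_demes)),
                     each = n_sample),
    country = "synthetic", linguistic_group = "non-BSP",
    latitude = rep(seq_len(n_demes), each = n_sample),
    longitude = rep(seq_len(n_demes) * 2, each = n_sample),
    qc_flags = "")
  list(panel = panel, manifest = manifest)
}

#' Evolve a multistate cognate matrix on the founding tree
#'
#' Each meaning slot starts in one cognate class at the origin deme and
#' evolves along the founding-tree edges: with probability `sub_prob`
#' per edge a slot switches to a new, previously unused class
#' (infinite-alleles replacement, so cognate classes never revert).
#' Rows are the sampled populations, read off at their demes.
#'
#' @param truth Truth record of a lattice generator (needs
#'   `founding_edges`, `origin_cell`, `sampling`).
#' @param n_slots Number of meaning slots (default 200).
#' @param sub_prob Replacement probability per slot per tree edge.
#' @param seed Integer seed.
#' @return Integer matrix, populations x slots.
#' @export
generate_cognate_matrix <- function(truth, n_slots = 200, sub_prob = 0.1,
                                    seed = 1) {
  if (is.null(truth$founding_edges) || is.null(truth$sampling))
    stop("generate_cognate_matrix: truth lacks a founding tree/sampling")
  set.seed(as.integer(seed))
  edges <- truth$founding_edges
  states <- list()
  states[[as.character(truth$origin_cell)]] <- rep(1L, n_slots)
  counter <- 1L
  for (e in seq_len(nrow(edges))) {
    par <- as.character(edges$parent[e])
    chi <- as.character(edges$child[e])
    s <- states[[par]]
    if (is.null(s))
      stop("generate_cognate_matrix: founding edges out of order")
    sub <- runif(n_slots) < sub_prob
    if (any(sub)) {
      s[sub] <- counter + seq_len(sum(sub))
      counter <- counter + sum(sub)
    }
    states[[chi]] <- s
  }
  m <- t(vapply(truth$sampling$cell, function(cell) {
    s <- states[[as.character(cell)]]
    if (is.null(s)) stop("generate_cognate_matrix: sampled deme ", cell,
                         " not on the founding tree")
    s
  }, integer(n_slots)))
  rownames(m) <- truth$sampling$population
  colnames(m) <- sprintf("slot%03d", seq_len(n_slots))
  m
}
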