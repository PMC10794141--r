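#' Summary-statistic vector of a panel
#'
#' The per-simulation observable used for scenario comparison: the
#' pairwise Hudson FST vector over all population pairs, in the shared
#' upper-triangle order of [as_tibble.dist_matrix()].
#'
#' @param panel A [genotype_panel()].
#' @param manifest Sample manifest.
#' @return Tibble with `pop1`, `pop2`, `value` (FST per pair).
#' @export
compute_summary <- function(panel, manifest) {
  fst <- hudson_fst_matrix(panel, manifest)
  out <- as_tibble(fst)
  if (all(is.nan(out$value)))
    stop("compute_summary: all pairs monomorphic; no usable denominator")
  out
}

#' Support of one scenario against an observed summary vector
#'
#' Each simulated vector is scored by the squared Pearson correlation
#' (r-squared) with the observed vector; the scenario's support is the
#' maximum per-simulation r-squared, reported together with the mean
#' over the top decile of simulations and the best draw's parameters.
#'
#' @param observed Summary tibble from [compute_summary()].
#' @param sims List of simulations, each a list with elements `params`
#'   (named list/vector) and `summary` (a tibble sharing `observed`'s
#'   pair labels).
#' @param scenario Scenario name.
#' @return A `scenario_support` one-row tibble: `scenario`, `n_sims`,
#'   `r2_max`, `r2_top_decile_mean`, and `best_*` parameter columns.
#' @export
scenario_support <- function(observed, sims, scenario) {
  if (nrow(observed) < 3)
    stop("scenario_support: need >= 3 population pairs")
  obs_key <- paste(observed$pop1, observed$pop2)
  r2 <- vapply(sims, function(s) {
    if (nrow(s$summary) == 0) return(NA_real_)   # failed / uncolonized draw
    key <- paste(s$summary$pop1, s$summary$pop2)
    if (!identical(sort(key), sort(obs_key)))
      stop("scenario_support: simulation pair labels do not match observed")
    v <- s$summary$value[match(obs_key, key)]
    ok <- is.finite(v) & is.finite(observed$value)
    if (sum(ok) < 3) return(NA_real_)
    if (sd(v[ok]) == 0 || sd(observed$value[ok]) == 0) return(NA_real_)
    cor(observed$value[ok], v[ok])^2
  }, numeric(1))
  usable <- is.finite(r2)
  if (!any(usable))
    stop("scenario_support: no simulation produced a usable summary")
  r2u <- r2[usable]
  top <- sort(r2u, decreasing = TRUE)
  top <- top[seq_len(max(1, ceiling(length(top) / 10)))]
  best <- sims[usable][[which.max(r2u)]]$params
  out <- tibble::tibble(scenario = scenario, n_sims = length(sims),
                        r2_max = max(r2u), r2_top_decile_mean = mean(top))
  for (nm in names(best)) out[[paste0("best_", nm)]] <- best[[nm]]
  class(out) <- c("scenario_support", class(out))
  out
}

#' Rank scenarios by support
#'
#' Descending by `r2_max`, ties broken by `r2_top_decile_mean`, then by
#' name.
#'
#' @param supports List of [scenario_support()] rows (or a bound
#'   tibble).
#' @return Tibble of supports in rank order with a `rank` column.
#' @export
rank_scenarios <- function(supports) {
  if (inherits(supports, "data.frame")) d <- tibble::as_tibble(supports)
  else {
    if (length(supports) == 0) stop("rank_scenarios: empty support list")
    d <- dplyr::bind_rows(supports)
  }
  if (nrow(d) == 0) stop("rank_scenarios: empty support list")
  d <- d[order(-d$r2_max, -d$r2_top_decile_mean, d$scenario), ]
  d$rank <- seq_len(nrow(d))
  d
}

#' Uniform priors for scenario sweeps
#'
#' Defaults follow the sweep design: growth rate `r` uniform on
#' `[0.2, 1]`, migration `m` on `[0.01, 0.2]`, founder size `F` an even
#' count on `[2, 20]`, colonization threshold on `[0.25, 0.75]`.
#'
#' @param r,m,founder_size,colonization_threshold Length-2 ranges.
#' @return A `scenario_priors` list.
#' @export
scenario_priors <- function(r = c(0.2, 1.0), m = c(0.01, 0.2),
                            founder_size = c(2, 20),
                            colonization_threshold = c(0.25, 0.75)) {
  list(r = r, m = m, founder_size = founder_size,
       colonization_threshold = colonization_threshold)
}

draw_params <- function(priors) {
  f <- 2 * sample.int(priors$founder_size[2] %/% 2, 1)  # even 2..F_max
  f <- max(f, priors$founder_size[1])
  list(r = runif(1, priors$r[1], priors$r[2]),
       m = runif(1, priors$m[1], priors$m[2]),
       founder_size = f,
       colonization_threshold = runif(1, priors$colonization_threshold[1],
                                      priors$colonization_threshold[2]))
}

#' Sweep prior draws under each route scenario
#'
#' Runs `n_sims` simulations per scenario with parameters drawn from
#' uniform priors, samples the same demes as the observed design, and
#' computes the FST summary vector for each draw.  Draws under which a
#' sampled deme was never colonized yield no usable summary and carry
#' zero support.
#'
#' @param scenarios Named list of [scenario_spec()]s (see
#'   [route_scenarios()]).
#' @param grid_args List of arguments for [build_landscape()] (`width`,
#'   `height`, `K`, ...); the habitability mask is rebuilt per scenario.
#' @param genetics A [sim_genetics()] description.
#' @param sampling Sampling design tibble (`cell`, `n`, optional
#'   `population`) shared by every draw.
#' @param generations Generations per simulation.
#' @param n_sims Prior draws per scenario.
#' @param priors A [scenario_priors()] list.
#' @param seed Integer seed.
#' @return Named list (per scenario) of lists with `params` and
#'   `summary`, ready for [scenario_support()].
#' @export
scenario_sweep <- function(scenarios, grid_args, genetics, sampling,
                           generations, n_sims = 200,
                           priors = scenario_priors(), seed = 1) {
  set.seed(as.integer(seed))
  out <- list()
  for (sc_name in names(scenarios)) {
    sc <- scenarios[[sc_name]]
    sims <- vector("list", n_sims)
    for (k in seq_len(n_sims)) {
      par <- draw_params(priors)
      sck <- scenario_spec(sc$name, barrier_rows = sc$barrier_rows,
                           corridors = sc$corridors, r = par$r, m = par$m,
                           founder_size = par$founder_size,
                           colonization_threshold =
                             par$colonization_threshold)
      grid <- do.call(build_landscape,
                      c(grid_args, list(scenario = sck)))
      sim_seed <- sample.int(.Machine$integer.max, 1)
      res <- simulate_expansion(grid, sck, genetics, generations, sim_seed)
      summ <- tryCatch({
        sp <- sample_panel(res, sampling, seed = sim_seed)
        # extreme prior draws can leave pairs monomorphic (NaN); those
        # pairs simply drop out of the support correlation
        suppressWarnings(compute_summary(sp$panel, sp$manifest))
      }, error = function(e) NULL)
      sims[[k]] <- list(params = par,
                        summary = if (is.null(summ)) {
                          tibble::tibble(pop1 = character(0),
                                         pop2 = character(0),
                                         value = numeric(0))
                        } else summ)
    }
    out[[sc_name]] <- sims
  }
  out
}

#' Desk-scale route-inference design
#'
#' The toy geometry used for scenario recovery: a 9 x 6 lattice with the
#' origin in the north-west, a full-width barrier band on row 3, a
#' southern corridor through the barrier at column 2 and a northern
#' passage at the eastern edge (column 9), carrying capacity 10 diploids
#' per deme, one chromosome of 150 SNPs, and eight sampled populations
#' of 8 diploids placed on both sides of the barrier.
#'
#' @param n_sims Prior draws per scenario for [scenario_recovery()].
#' @return List with `scenarios`, `grid_args`, `genetics_args`,
#'   `sampling`, `generations`, `n_sims`.
#' @export
route_toy_design <- function(n_sims = 200) {
  list(scenarios = route_scenarios(9, 6, barrier_rows = 3,
                                   southern_col = 2, northern_col = 9),
       grid_args = list(width = 9, height = 6, K = 10),
       genetics_args = list(n_chrom = 1, L_snps = 150, cM_length = 100),
       sampling = tibble::tibble(cell = c(1, 5, 9, 14, 29, 41, 50, 54),
                                 n = 8,
                                 population = sprintf("p%d", 1:8)),
       generations = 60, n_sims = n_sims)
}

#' One scenario-recovery replicate
#'
#' Generates an "observed" dataset under `truth_scenario` with mid-range
#' parameters, sweeps `n_sims` prior draws under each candidate
#' scenario, and ranks the scenarios by support.
#'
#' @param design A [route_toy_design()] list.
#' @param truth_scenario Name of the data-generating scenario.
#' @param seed Integer seed covering observed generation and the sweep.
#' @return The ranked support tibble (see [rank_scenarios()]) with the
#'   truth scenario name in `attr(, "truth")`.
#' @export
scenario_recovery <- function(design = route_toy_design(),
                              truth_scenario = "southern", seed = 1) {
  sc <- design$scenarios[[truth_scenario]]
  genetics <- do.call(sim_genetics, design$genetics_args)
  grid <- do.call(build_landscape,
                  c(design$grid_args, list(scenario = sc)))
  res <- simulate_expansion(grid, sc, genetics, design$generations,
                            seed = seed)
  sp <- sample_panel(res, design$sampling, seed = seed + 1)
  observed <- compute_summary(sp$panel, sp$manifest)
  sweep <- scenario_sweep(design$scenarios, design$grid_args, genetics,
                          design$sampling, design$generations,
                          n_sims = design$n_sims, seed = seed + 2)
  supports <- lapply(names(sweep), function(nm)
    scenario_support(observed, sweep[[nm]], nm))
  out <- rank_scenarios(supports)
  attr(out, "truth") <- truth_scenario
  out
}
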