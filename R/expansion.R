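#' Expansion scenario specification
#'
#' A scenario fixes the demographic parameters of the lattice expansion
#' and the geometry of the uninhabitable barrier band (the "rainforest"
#' rows) with its open corridors.  The three canonical route scenarios
#' are `northern` (corridor at the eastern edge, around the barrier),
#' `southern` (corridor through the barrier in the west) and `both`.
#'
#' @param name One of `"northern"`, `"southern"`, `"both"`.
#' @param barrier_rows Integer vector of blocked grid rows (may be empty).
#' @param corridors Integer matrix with columns `row`, `col`: barrier
#'   cells left open.
#' @param r Logistic growth rate per generation (> 0).
#' @param m Migration rate per haplotype per neighbour per generation,
#'   in `[0, 0.25]` so that 4-neighbour exchange conserves haplotypes.
#' @param founder_size Number of founder haplotypes `F` seeding a new
#'   deme (even, `>= 2`).
#' @param colonization_threshold Fraction of carrying capacity a deme
#'   must exceed before budding into empty neighbours.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(name = c("southern", "northern", "both"),
                          barrier_rows = integer(0),
                          corridors = NULL,
                          r = 0.6, m = 0.05, founder_size = 8,
                          colonization_threshold = 0.5) {
  name <- match.arg(name)
  if (r <= 0) stop("scenario_spec: r must be > 0")
  if (m < 0 || m > 0.25) stop("scenario_spec: m must be in [0, 0.25]")
  founder_size <- as.integer(founder_size)
  if (founder_size < 2 || founder_size %% 2L != 0L)
    stop("scenario_spec: founder_size must be an even count >= 2")
  if (is.null(corridors)) corridors <- matrix(integer(0), ncol = 2)
  corridors <- matrix(as.integer(corridors), ncol = 2,
                      dimnames = list(NULL, c("row", "col")))
  structure(list(name = name, barrier_rows = as.integer(barrier_rows),
                 corridors = corridors, r = r, m = m,
                 founder_size = founder_size,
                 colonization_threshold = colonization_threshold),
            class = "scenario_spec")
}

#' The three canonical route scenarios on a toy grid
#'
#' Builds `northern`, `southern` and `both` scenario specs sharing one
#' barrier band across the grid: the northern route passes around the
#' barrier along the eastern edge, the southern route through a corridor
#' in the west.
#'
#' @param width,height Grid dimensions.
#' @param barrier_rows Rows occupied by the barrier band.
#' @param southern_col,northern_col Corridor columns for each route.
#' @param ... Demographic parameters passed to [scenario_spec()].
#' @return Named list of three `scenario_spec`s.
#' @export
route_scenarios <- function(width, height,
                            barrier_rows = round(height / 2),
                            southern_col = 2, northern_col = width, ...) {
  mk <- function(name, cols) {
    scenario_spec(name, barrier_rows = barrier_rows,
                  corridors = as.matrix(expand.grid(row = barrier_rows,
                                                    col = cols)), ...)
  }
  list(northern = mk("northern", northern_col),
       southern = mk("southern", southern_col),
       both = mk("both", c(southern_col, northern_col)))
}

#' Build a deme lattice for a scenario
#'
#' Cells are laid out on an equirectangular grid: row 1 is the most
#' northern latitude and columns increase eastward, `cell_deg` degrees
#' apart.  The barrier rows of the scenario are uninhabitable except at
#' its corridor cells.
#'
#' @param width,height Grid dimensions in cells (each >= 2).
#' @param scenario A [scenario_spec()].
#' @param origin `(lat, lon)` of the expansion origin; mapped to the
#'   nearest cell, which must be habitable.
#' @param K Carrying capacity in diploids per habitable cell.
#' @param lat0,lon0 Coordinates of the row-1, column-1 cell.
#' @param cell_deg Cell size in degrees.
#' @return A `deme_grid` list with `width`, `height`, `cells` (tibble of
#'   `cell`, `row`, `col`, `lat`, `lon`, `habitable`, `K`) and
#'   `origin_cell`.
#' @export
build_landscape <- function(width, height, scenario, origin = NULL,
                            K = 30, lat0 = 5, lon0 = 10, cell_deg = 2) {
  if (width < 2 || height < 2) stop("build_landscape: grid must be >= 2x2")
  row <- rep(seq_len(height), each = width)
  col <- rep(seq_len(width), times = height)
  lat <- lat0 - (row - 1) * cell_deg
  lon <- lon0 + (col - 1) * cell_deg
  habitable <- rep(TRUE, width * height)
  blocked <- row %in% scenario$barrier_rows
  if (nrow(scenario$corridors) > 0) {
    open <- paste(row, col) %in%
      paste(scenario$corridors[, "row"], scenario$corridors[, "col"])
    blocked <- blocked & !open
  }
  habitable[blocked] <- FALSE

  if (is.null(origin)) origin <- c(lat0, lon0)
  origin_cell <- which.min((lat - origin[1])^2 + (lon - origin[2])^2)
  if (!habitable[origin_cell])
    stop("build_landscape: origin falls inside a closed barrier")

  cells <- tibble::tibble(cell = seq_len(width * height), row = row,
                          col = col, lat = lat, lon = lon,
                          habitable = habitable,
                          K = ifelse(habitable, as.integer(K), 0L))
  structure(list(width = width, height = height, cells = cells,
                 origin_cell = origin_cell),
            class = "deme_grid")
}

#' @export
print.deme_grid <- function(x, ...) {
  cat("<deme_grid> ", x$width, "x", x$height, " cells, ",
      sum(x$cells$habitable), " habitable, origin at cell ",
      x$origin_cell, "\n", sep = "")
  invisible(x)
}

#' Default genetics of a simulated panel
#'
#' Chromosomes carry `L_snps` evenly spaced SNPs each; the genetic map
#' is uniform at 1 cM/Mb, so a chromosome of `cM_length` centimorgans
#' spans `cM_length` megabases.  Initial allele frequencies default to
#' standing variation drawn uniformly on `[0.1, 0.9]`.
#'
#' @param n_chrom Number of chromosomes.
#' @param L_snps SNPs per chromosome.
#' @param cM_length Genetic length per chromosome (cM).
#' @param init_freqs Optional vector of initial allele frequencies,
#'   length `n_chrom * L_snps`.
#' @return A `sim_genetics` list.
#' @export
sim_genetics <- function(n_chrom = 2, L_snps = 200, cM_length = 100,
                         init_freqs = NULL) {
  L <- n_chrom * L_snps
  if (is.null(init_freqs)) init_freqs <- runif(L, 0.1, 0.9)
  if (length(init_freqs) != L)
    stop("sim_genetics: init_freqs must have length n_chrom * L_snps")
  pos_cM <- rep(seq(0, cM_length, length.out = L_snps + 1)[-1], n_chrom)
  variants <- tibble::tibble(
    chrom = as.character(rep(seq_len(n_chrom), each = L_snps)),
    pos_bp = as.integer(round(pos_cM * 1e6)),  # 1 cM/Mb
    pos_cM = pos_cM)
  structure(list(n_chrom = n_chrom, L_snps = L_snps, cM_length = cM_length,
                 init_freqs = init_freqs, variants = variants),
            class = "sim_genetics")
}

#' Simulate a Wright-Fisher range expansion on a deme lattice
#'
#' Forward-in-time simulation.  Each generation, every occupied deme
#' grows stochastically toward carrying capacity (`N' ~ Binomial(K, mu/K)`
#' with logistic mean `mu = N + rN(1 - N/K)`, floored at 1), is replaced
#' by Wright-Fisher resampling of `2N'` haplotypes with per-chromosome
#' Poisson recombination on the cM map, exchanges a
#' `Binomial(min(2N_i, 2N_j), m)`-sized symmetric swap of haplotypes
#' with each occupied 4-neighbour, and buds `founder_size` founder
#' haplotypes into each empty habitable neighbour once its census
#' exceeds `colonization_threshold * K`.  Identical inputs and seed give
#' identical results.
#'
#' @param grid A [build_landscape()] lattice.
#' @param scenario A [scenario_spec()]; its demographic parameters drive
#'   the run (the grid already encodes its habitability mask).
#' @param genetics A [sim_genetics()] description.
#' @param generations Number of generations (> 0).
#' @param seed Integer seed.
#' @param full_occupancy Start with every habitable deme at carrying
#'   capacity (stepping-stone mode) instead of origin-only.
#' @return An `expansion_result` with `arrival` (tibble: cell,
#'   generation of colonization, NA if never), `founding_edges` (tibble:
#'   parent, child, generation), `haplotypes`/`deme_of`/`census` (the
#'   extant haplotype store), plus the inputs.
#' @export
simulate_expansion <- function(grid, scenario, genetics, generations,
                               seed, full_occupancy = FALSE) {
  if (generations <= 0) stop("simulate_expansion: generations must be > 0")
  cells <- grid$cells
  if (!full_occupancy &&
      sum(cells$habitable) <= 1L)
    warning("simulate_expansion: no habitable cell beyond the origin; ",
            "no expansion possible")
  set.seed(as.integer(seed))
  res <- sim_expansion_cpp(
    habitable = cells$habitable, K = cells$K,
    width = grid$width, height = grid$height, origin = grid$origin_cell,
    r = scenario$r, m = scenario$m, F = scenario$founder_size,
    thresh = scenario$colonization_threshold,
    pos_cM = genetics$variants$pos_cM,
    chrom_id = as.integer(genetics$variants$chrom),
    init_freqs = genetics$init_freqs,
    generations = as.integer(generations),
    full_occupancy = full_occupancy)

  arrival <- res$arrival
  arrival[arrival < 0] <- NA_integer_
  structure(list(
    arrival = tibble::tibble(cell = cells$cell, arrival = arrival),
    founding_edges = tibble::tibble(parent = res$edge_parent,
                                    child = res$edge_child,
                                    generation = res$edge_generation),
    haplotypes = res$haplotypes, deme_of = res$deme_of,
    census = res$census, grid = grid, scenario = scenario,
    genetics = genetics, generations = generations, rng_seed = seed),
    class = "expansion_result")
}

#' @export
print.expansion_result <- function(x, ...) {
  cat("<expansion_result> scenario '", x$scenario$name, "', ",
      sum(!is.na(x$arrival$arrival)), "/", nrow(x$arrival),
      " cells colonized after ", x$generations, " generations (seed ",
      x$rng_seed, ")\n", sep = "")
  invisible(x)
}

#' Sample a genotype panel from an expansion result
#'
#' Draws diploid individuals without replacement from the extant
#' haplotype store of chosen demes and builds a panel plus manifest with
#' the deme cell coordinates as population coordinates.
#'
#' @param result An [simulate_expansion()] result.
#' @param sampling Tibble/data frame with columns `cell` and `n`
#'   (diploids to draw), optionally `population` names.
#' @param seed Integer seed for the draw.
#' @param linguistic_group Either a single group label for all
#'   populations or one per sampled deme.
#' @return List with `panel` ([genotype_panel()]) and `manifest`.
#' @export
sample_panel <- function(result, sampling, seed = 1,
                         linguistic_group = "E-BSP") {
  sampling <- tibble::as_tibble(sampling)
  if (!"population" %in% names(sampling))
    sampling$population <- paste0("pop_c", sampling$cell)
  set.seed(as.integer(seed))
  cells <- result$grid$cells
  if (length(linguistic_group) == 1)
    linguistic_group <- rep(linguistic_group, nrow(sampling))

  hap_list <- list(); ids <- character(0); man <- list()
  for (i in seq_len(nrow(sampling))) {
    cell <- sampling$cell[i]; n <- sampling$n[i]
    rows <- which(result$deme_of == cell)
    if (length(rows) == 0)
      stop("sample_panel: deme ", cell, " is empty/uncolonized")
    n_avail <- length(rows) / 2
    if (n > n_avail)
      stop("sample_panel: requested ", n, " diploids from deme ", cell,
           " holding ", n_avail)
    ind <- sort(sample.int(n_avail, n))
    hap_rows <- as.vector(rbind(rows[2 * ind - 1], rows[2 * ind]))
    hap_list[[i]] <- result$haplotypes[hap_rows, , drop = FALSE]
    sid <- sprintf("%s_%03d", sampling$population[i], seq_len(n))
    ids <- c(ids, sid)
    man[[i]] <- tibble::tibble(
      sample_id = sid, population = sampling$population[i],
      country = "synthetic", linguistic_group = linguistic_group[i],
      latitude = cells$lat[cell], longitude = cells$lon[cell],
      qc_flags = "")
  }
  panel <- genotype_panel(do.call(rbind, hap_list),
                          result$genetics$variants, ids)
  list(panel = panel, manifest = dplyr::bind_rows(man))
}
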