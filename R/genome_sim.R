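#' Genome architecture for the linkage-block simulator
#'
#' The diploid genome is split into chromosomes, each a row of
#' non-recombining linkage blocks separated by recombination hotspots.
#' Defaults mirror a human-like architecture: 23 chromosomes of L = 100
#' blocks with exactly 2 crossovers per chromosome per meiosis.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param blocks_per_chromosome Blocks per chromosome, L >= 2.
#' @param crossovers_per_chromosome Crossovers per chromosome per meiosis
#'   (exact count, not a mean); must be <= L - 1.
#' @return An object of class `"vf_arch"`.
#' @export
genome_architecture <- function(n_chromosomes = 23,
                                blocks_per_chromosome = 100,
                                crossovers_per_chromosome = 2) {
  if (blocks_per_chromosome < 2) stop("'blocks_per_chromosome' must be >= 2")
  if (crossovers_per_chromosome > blocks_per_chromosome - 1)
    stop("'crossovers_per_chromosome' must be <= L - 1")
  if (n_chromosomes < 1) stop("'n_chromosomes' must be >= 1")
  structure(list(n_chromosomes = n_chromosomes,
                 blocks_per_chromosome = blocks_per_chromosome,
                 crossovers_per_chromosome = crossovers_per_chromosome),
            class = "vf_arch")
}

#' Simulation configuration
#'
#' @param N Diploid population size.
#' @param params A [model_params()] object supplying Ud, Ub and the DFEs
#'   (its `delta_env` plays no role inside the simulator).
#' @param architecture A [genome_architecture()].
#' @param generations Run length in generations (1 generation = N Moran
#'   birth-death events); default 100 * N.
#' @param burn_in_window Window (generations) for the variance-slope burn-in
#'   rule.
#' @param burn_in_slope Slope threshold; burn-in can end once the OLS slope
#'   of fitness variance over the last `burn_in_window` generations drops
#'   below this. Default 0.07 / N.
#' @param post_threshold_wait Extra generations appended after the slope
#'   criterion is first met.
#' @param ledger Track every non-neutral mutation to fixation or loss
#'   (needed for flux decomposition); adds overhead, intended for moderate N.
#' @param tracer Record the genealogy of one neutral tracer block for
#'   coalescent effective-size estimation.
#' @param tracer_chromosome,tracer_block Position of the tracer block
#'   (defaults: mid-genome).
#' @param seed Optional integer seed applied via `set.seed()` at run start.
#' @return An object of class `"vf_sim_config"`.
#' @export
sim_config <- function(N, params = model_params(),
                       architecture = genome_architecture(),
                       generations = 100 * N,
                       burn_in_window = 200,
                       burn_in_slope = 0.07 / N,
                       post_threshold_wait = 100,
                       ledger = FALSE, tracer = FALSE,
                       tracer_chromosome = NULL, tracer_block = NULL,
                       seed = NULL) {
  stopifnot(N >= 2, generations > 0)
  if (is.null(tracer_chromosome))
    tracer_chromosome <- max(1L, ceiling(architecture$n_chromosomes / 2))
  if (is.null(tracer_block))
    tracer_block <- max(1L, ceiling(architecture$blocks_per_chromosome / 2))
  structure(list(N = N, params = params, architecture = architecture,
                 generations = generations, burn_in_window = burn_in_window,
                 burn_in_slope = burn_in_slope,
                 post_threshold_wait = post_threshold_wait,
                 ledger = ledger, tracer = tracer,
                 tracer_chromosome = tracer_chromosome,
                 tracer_block = tracer_block, seed = seed),
            class = "vf_sim_config")
}

.new_sim_handle <- function(config) {
  a <- config$architecture
  p <- config$params
  tb0 <- (config$tracer_chromosome - 1L) * a$blocks_per_chromosome +
    (config$tracer_block - 1L)
  cpp_sim_new(as.integer(config$N), as.integer(a$n_chromosomes),
              as.integer(a$blocks_per_chromosome),
              as.integer(a$crossovers_per_chromosome),
              p$Ud, p$Ub, p$deleterious_dfe$shape, p$deleterious_dfe$scale,
              p$beneficial_dfe$mean, isTRUE(config$ledger),
              isTRUE(config$tracer), as.integer(tb0))
}

#' Initialise a clonal population
#'
#' All block loads start at 1, so every individual has fitness 1 and the
#' fitness variance is 0; the burn-in phase moves the population away from
#' this clonal state.
#'
#' @param config A [sim_config()].
#' @return A list with the simulator `handle` (external pointer), the
#'   `config`, and a `state` snapshot (`loads` matrix of 2*B rows by N
#'   columns, `fitness`, `generation`).
#' @export
init_population <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  h <- .new_sim_handle(config)
  list(handle = h, config = config, state = cpp_sim_state(h))
}

#' Form one recombined gamete from a diploid parent
#'
#' Per chromosome, the copying haplotype starts from a fair coin and switches
#' at exactly `crossovers_per_chromosome` hotspot positions drawn uniformly
#' without replacement from the L - 1 internal block boundaries; chromosomes
#' assort independently.
#'
#' @param parent_loads A (n_chr * L) x 2 matrix of block loads (columns are
#'   the two haplotypes).
#' @param architecture A [genome_architecture()].
#' @return List with `loads` (numeric vector of the gamete's block loads) and
#'   `source` (0/1 vector saying which parental haplotype each block came
#'   from).
#' @export
make_gamete <- function(parent_loads, architecture = genome_architecture()) {
  a <- architecture
  cpp_make_gamete(parent_loads, a$n_chromosomes, a$blocks_per_chromosome,
                  a$crossovers_per_chromosome)
}

#' Apply new mutations to an offspring genome
#'
#' Draws Poisson(Ud) deleterious and Poisson(Ub) beneficial mutation counts,
#' assigns each mutation to a uniformly random block copy among the 2 * n_chr
#' * L copies, and multiplies that block's load by (1 + s); a load with
#' 1 + s <= 0 is set to 0 (lethal).
#'
#' @param genome_loads A (n_chr * L) x 2 matrix of block loads.
#' @param params A [model_params()].
#' @return List with the mutated `loads` matrix and a `mutations` data.frame
#'   (hap, block, s, type with 0 = deleterious, 1 = beneficial).
#' @export
mutate_offspring <- function(genome_loads, params) {
  cpp_mutate_genome(genome_loads, params$Ud, params$Ub,
                    params$deleterious_dfe$shape,
                    params$deleterious_dfe$scale,
                    params$beneficial_dfe$mean)
}

#' Advance a simulation by whole generations
#'
#' Each generation is N Moran events: a uniformly chosen individual dies and
#' is replaced by the offspring of two fitness-proportionally sampled
#' hermaphroditic parents (sampled with replacement; selfing allowed).
#'
#' @param population A list with a `handle`, as returned by
#'   [init_population()].
#' @param generations Number of generations to advance.
#' @return The population list, invisibly; its trajectory grows internally.
#' @export
advance_generations <- function(population, generations) {
  cpp_sim_run(population$handle, generations)
  invisible(population)
}

#' Burn-in detection from the fitness-variance trajectory
#'
#' The burn-in ends `wait` generations after the first generation g at which
#' the OLS slope of the fitness variance over generations (g - window + 1)..g
#' falls strictly below `threshold`.
#'
#' @param var_series Per-generation fitness variance.
#' @param N Population size (used only for the default threshold).
#' @param window Regression window length (generations).
#' @param threshold Slope threshold; default 0.07 / N.
#' @param wait Generations appended after the criterion is met.
#' @return The burn-in end generation (index into the series), or `NA` with a
#'   warning if the criterion is never met.
#' @export
detect_burn_in <- function(var_series, N, window = 200, threshold = 0.07 / N,
                           wait = 100) {
  n <- length(var_series)
  if (n < window) stop(sprintf("need at least %d generations recorded", window))
  x <- seq_len(window)
  wts <- (x - mean(x)) / sum((x - mean(x))^2)
  # rolling OLS slope: slope_g = sum(wts * y[(g-window+1):g])
  sl <- stats::filter(var_series, rev(wts), method = "convolution", sides = 1)
  hit <- which(!is.na(sl) & sl < threshold)
  if (length(hit) == 0) {
    warning("burn-in criterion never met within the recorded trajectory")
    return(NA_integer_)
  }
  hit[1] + wait
}

#' Net-flux estimate from a fitness trajectory
#'
#' The OLS slope of log mean population fitness against generation index over
#' the post-burn-in generations. Uses ln of the mean fitness, not the mean of
#' ln fitness.
#'
#' @param trajectory Data frame with columns `generation` and `mean_fitness`.
#' @param burn_in_end Last burn-in generation; only later generations enter
#'   the regression.
#' @return The slope (per-generation change in log mean fitness).
#' @export
estimate_vnet <- function(trajectory, burn_in_end) {
  keep <- trajectory$generation > burn_in_end
  if (sum(keep) < 2) stop("need at least 2 post-burn-in generations")
  y <- trajectory$mean_fitness[keep]
  if (any(y <= 0)) stop("mean fitness reached 0: log flux undefined")
  g <- trajectory$generation[keep]
  unname(stats::coef(stats::lm.fit(cbind(1, g), log(y)))[2])
}

#' Run a full linkage-block Moran simulation
#'
#' Initialises a clonal population, advances `generations` generations,
#' detects the burn-in from the fitness-variance trajectory and estimates the
#' net fitness flux from the post-burn-in log mean fitness. With
#' `ledger = TRUE` the returned object carries all fixation events for flux
#' decomposition; with `tracer = TRUE` the handle supports coalescence-time
#' sampling via [tracer_pair_times()].
#'
#' @param config A [sim_config()].
#' @return An object of class `"vf_sim_run"`: list with `trajectory`
#'   (generation, mean_fitness, var_fitness), `burn_in_end`, `vnet`,
#'   `fixations` (if the ledger is on), `config` and the live `handle`.
#' @export
sim_run <- function(config) {
  pop <- init_population(config)
  advance_generations(pop, config$generations)
  tr <- cpp_sim_trajectory(pop$handle)
  trajectory <- data.frame(generation = seq_along(tr$mean_fitness),
                           mean_fitness = tr$mean_fitness,
                           var_fitness = tr$var_fitness)
  burn_in_end <- tryCatch(
    detect_burn_in(trajectory$var_fitness, config$N,
                   window = config$burn_in_window,
                   threshold = config$burn_in_slope,
                   wait = config$post_threshold_wait),
    error = function(e) NA_integer_)
  vnet <- if (!is.na(burn_in_end) &&
              burn_in_end < nrow(trajectory) - 1) {
    estimate_vnet(trajectory, burn_in_end)
  } else NA_real_
  structure(list(trajectory = trajectory, burn_in_end = burn_in_end,
                 vnet = vnet,
                 fixations = if (config$ledger)
                   cpp_sim_fixations(pop$handle) else NULL,
                 config = config, handle = pop$handle),
            class = "vf_sim_run")
}

#' @export
print.vf_sim_run <- function(x, ...) {
  cat(sprintf(
    "Moran linkage-block run: N = %d, %d generations, burn-in end = %s\n",
    x$config$N, nrow(x$trajectory),
    ifelse(is.na(x$burn_in_end), "not reached", x$burn_in_end)))
  cat(sprintf("  estimated vnet = %s\n",
              ifelse(is.na(x$vnet), "NA", format(x$vnet, digits = 4))))
  invisible(x)
}

#' Snapshot of the simulator state
#'
#' @param population_or_run A list holding a simulator `handle`.
#' @return List with the `loads` matrix (2*B x N), per-individual `fitness`,
#'   and the `generation` counter.
#' @export
population_state <- function(population_or_run) {
  cpp_sim_state(population_or_run$handle)
}

#' Inject a tracked marker mutation
#'
#' Places a single mutation of selection coefficient `s` on one uniformly
#' chosen block copy (or a specified one) and registers it in the fixation
#' ledger, so its carrier count among the 2N haplotypes is followed to
#' fixation or loss. A neutral marker (`s = 0`, the default) gives a direct
#' empirical check of the fixation probability 1/(2N).
#'
#' @param population A list with a ledger-enabled simulator `handle`.
#' @param s Selection coefficient of the marker.
#' @param type `"neutral"`, `"deleterious"` or `"beneficial"` (bookkeeping
#'   only; neutral markers are excluded from flux decompositions).
#' @return The integer marker id.
#' @export
inject_marker <- function(population, s = 0,
                          type = c("neutral", "deleterious", "beneficial")) {
  type <- match.arg(type)
  code <- c(neutral = 2L, deleterious = 0L, beneficial = 1L)[[type]]
  cpp_sim_inject(population$handle, s, code, -1L, -1L, -1L)
}

#' Track a marker to fixation or loss
#'
#' Advances the simulation one generation at a time until the marker either
#' fixes (all 2N copies carry it) or is lost, or `max_generations` elapse.
#'
#' @param population A list with a ledger-enabled simulator `handle`.
#' @param marker_id Id returned by [inject_marker()].
#' @param max_generations Cap on additional generations.
#' @return `"fixed"`, `"lost"` or `"segregating"`.
#' @export
run_until_marker_resolved <- function(population, marker_id,
                                      max_generations = 1e5) {
  status <- cpp_sim_run_until_resolved(population$handle,
                                       as.integer(marker_id),
                                       max_generations)
  c("lost", "segregating", "fixed")[status + 2L]
}

#' Replicate neutral-marker fixation trials
#'
#' Runs `n_runs` independent mini-simulations without selection, injecting a
#' single neutral marker into each and following it to absorption. The
#' fraction fixed estimates the neutral fixation probability, which under the
#' Moran model is exactly 1/(2N).
#'
#' @param n_runs Number of replicate mini-runs.
#' @param N Diploid population size.
#' @param architecture A [genome_architecture()].
#' @param max_generations Per-run cap (unresolved markers count as lost,
#'   with a warning).
#' @return Logical vector: `TRUE` where the marker fixed.
#' @export
neutral_fixation_trials <- function(n_runs, N = 20,
                                    architecture = genome_architecture(4, 25, 2),
                                    max_generations = 2000) {
  params0 <- model_params(Ud = 0, Ub = 0)
  fixed <- logical(n_runs)
  unresolved <- 0L
  for (i in seq_len(n_runs)) {
    cfg <- sim_config(N, params0, architecture, generations = 1,
                      ledger = TRUE)
    pop <- init_population(cfg)
    id <- inject_marker(pop, s = 0, type = "neutral")
    status <- run_until_marker_resolved(pop, id, max_generations)
    if (status == "segregating") unresolved <- unresolved + 1L
    fixed[i] <- status == "fixed"
  }
  if (unresolved > 0)
    warning(sprintf("%d of %d markers unresolved after %g generations",
                    unresolved, n_runs, max_generations))
  fixed
}
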