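#' Lower bound on the deleterious mutation rate from constraint arithmetic
#'
#' Multiplies the constrained fraction of the genome, the diploid genome
#' size, the fraction of mutations deleterious enough to be purged, and the
#' per-base-pair point mutation rate. With human values (0.55, 6e9, 0.057,
#' 1.16e-8) the product is about 2.18 deleterious mutations per diploid
#' genome per replication.
#'
#' @param fraction_non_te Fraction of the genome not dominated by dead
#'   transposable elements.
#' @param genome_size Diploid genome size in base pairs.
#' @param constraint Fraction of mutations in that portion purged by
#'   selection.
#' @param mu Point mutation rate per base pair per replication.
#' @return Deleterious mutations per diploid genome per generation.
#' @export
ud_lower_bound <- function(fraction_non_te = 0.55, genome_size = 6e9,
                           constraint = 0.057, mu = 1.16e-8) {
  args <- c(fraction_non_te, genome_size, constraint, mu)
  if (any(!is.finite(args)) || any(args < 0))
    stop("all inputs must be non-negative finite numbers")
  fraction_non_te * genome_size * constraint * mu
}

.vf_scenarios <- function() {
  base <- model_params(Ud = 2, Ub = 0.002,
                       deleterious_dfe = dfe_preset("human_nonsynonymous"),
                       beneficial_dfe = dfe_exponential(0.001))
  list(
    fig2 = list(
      scale = "desk",
      description = "Analytic Ncrit and drought:meltdown ratio, static and deteriorating environments",
      run = function(seed) {
        nc0 <- find_ncrit(base)
        r0 <- drought_meltdown_ratio(base, ncrit = nc0)
        p_env <- model_params(base$Ud, base$Ub, base$deleterious_dfe,
                              base$beneficial_dfe, delta_env = -1.5e-5)
        nc_env <- find_ncrit(p_env)
        r_env <- drought_meltdown_ratio(p_env, ncrit = nc_env)
        data.frame(delta_env = c(0, -1.5e-5),
                   ncrit = c(nc0, nc_env),
                   ratio = c(r0$ratio, r_env$ratio),
                   whitlock_ncrit = whitlock_ncrit(base))
      }),
    fig3 = list(
      scale = "desk",
      description = "Environmental-change threshold where drought overtakes meltdown, Ud/Ub in {1000, 100}",
      run = function(seed) {
        do.call(rbind, lapply(c(0.002, 0.02), function(ub) {
          p <- model_params(base$Ud, ub, base$deleterious_dfe,
                            base$beneficial_dfe)
          th <- env_threshold_analysis(p)
          data.frame(Ud_over_Ub = base$Ud / ub,
                     delta_env_star = th$delta_env_star,
                     generations_per_10pct = th$generations_per_10pct,
                     ncrit = th$ncrit, vd = th$vd,
                     flux_ratio = th$flux_ratio)
        }))
      }),
    fig4 = list(
      scale = "desk",
      description = "Ratio sweep over Ud/Ub, static environment",
      run = function(seed) {
        sw <- flux_sweep(Ud = 2, Ub = 2 / c(10, 30, 100, 300, 1000, 3000))
        sw$Ud_over_Ub <- sw$Ud / sw$Ub
        sw
      }),
    fig5 = list(
      scale = "desk",
      description = "Ratio sweep over Ub under fast and slow environmental change",
      run = function(seed) {
        sw <- flux_sweep(Ud = 2, Ub = 2 / c(10, 100, 1000),
                         delta_env = c(-1.5e-5, -1e-6))
        sw$Ud_over_Ub <- sw$Ud / sw$Ub
        sw
      }),
    desk_fig6 = list(
      scale = "desk",
      description = "Reduced-scale simulated vnet across N with Ud = 0.2, Ud/Ub = 1000",
      run = function(seed) {
        p <- model_params(Ud = 0.2, Ub = 0.0002,
                          deleterious_dfe = base$deleterious_dfe,
                          beneficial_dfe = base$beneficial_dfe)
        do.call(rbind, lapply(c(200, 400, 800), function(N) {
          run <- sim_run(sim_config(N, p, generations = 100 * N))
          data.frame(N = N, vnet_sim = run$vnet,
                     vnet_analytic = net_flux(p, N)$vnet,
                     burn_in_end = run$burn_in_end)
        }))
      }),
    fig6 = list(
      scale = "full",
      description = paste(
        "Full-scale LD estimate of Ncrit and the simulated ratio",
        "(Ud = 2, Ud/Ub = 1000; ~10 replicates near N = 4600 at 100N",
        "generations -- expect days of CPU time)"),
      run = function(seed) {
        p <- model_params(Ud = 2, Ub = 0.002)
        est <- estimate_ncrit(function(rep) sim_vnet_evaluator(p),
                              n_replicates = 10)
        flux_fun <- function(N) {
          d <- sim_flux_decomposition(as.integer(round(N)), p)
          c(d$vd, d$vb)
        }
        sr <- simulated_ratio(flux_fun, est$ncrit, eps = 150,
                              replicates = 10)
        data.frame(ncrit_sim = est$ncrit, ratio_sim = sr$ratio,
                   ratio_se = sr$ratio_se,
                   ncrit_analytic = find_ncrit(p),
                   ne = rescaled_ne(find_ncrit(p), est$ncrit, est$ncrit))
      }),
    intro_ud = list(
      scale = "desk",
      description = "Worked lower bound on the human deleterious mutation rate",
      run = function(seed) {
        data.frame(fraction_non_te = 0.55, genome_size = 6e9,
                   constraint = 0.057, mu = 1.16e-8,
                   ud_lower_bound = ud_lower_bound())
      })
  )
}

#' List available scenarios
#'
#' @return Data frame with scenario names, their compute scale ("desk"
#'   scenarios finish in minutes on one CPU; "full" carries an explicit
#'   compute warning) and a one-line description.
#' @export
list_scenarios <- function() {
  sc <- .vf_scenarios()
  data.frame(name = names(sc),
             scale = vapply(sc, `[[`, "", "scale"),
             description = vapply(sc, `[[`, "", "description"),
             row.names = NULL)
}

#' Run a named scenario
#'
#' Deterministic (analytic) scenarios are bit-reproducible; stochastic ones
#' are reproducible given the same seed. When `out_dir` is supplied the
#' result table is written as `result.csv` and a manifest (`manifest.json`:
#' package version, scenario, seed, runtime, parameters) alongside it.
#'
#' @param name Scenario name; see [list_scenarios()].
#' @param seed Integer seed for stochastic scenarios.
#' @param out_dir Optional output directory (created; must not already
#'   contain a manifest for another run).
#' @return The scenario's result data.frame, invisibly when writing to
#'   `out_dir`.
#' @export
run_scenario <- function(name, seed = 1, out_dir = NULL) {
  sc <- .vf_scenarios()
  if (!name %in% names(sc))
    stop(sprintf("unknown scenario '%s'; see list_scenarios()", name))
  if (sc[[name]]$scale == "full")
    message("full-scale scenario: this is a multi-day computation at published problem sizes")
  set.seed(seed)
  t0 <- proc.time()[["elapsed"]]
  result <- sc[[name]]$run(seed)
  elapsed <- proc.time()[["elapsed"]] - t0
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    manifest_path <- file.path(out_dir, "manifest.json")
    if (file.exists(manifest_path))
      stop(sprintf("output directory '%s' already holds a run manifest",
                   out_dir))
    utils::write.csv(result, file.path(out_dir, "result.csv"),
                     row.names = FALSE)
    manifest <- list(
      package = "vortexflux",
      version = as.character(utils::packageVersion("vortexflux")),
      scenario = name, seed = seed, runtime_seconds = elapsed,
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
    return(invisible(result))
  }
  result
}
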