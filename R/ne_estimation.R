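#' Coalescence times of the neutral tracer block
#'
#' Samples random pairs of the 2N haplotype copies of the tracer block at the
#' current state of a tracer-enabled run and returns the time (in
#' generations) since each pair's most recent common ancestor. Pairs whose
#' lineages do not coalesce within the recorded genealogy come back as `NA`.
#'
#' @param run A `"vf_sim_run"` (or any list with a tracer-enabled `handle`).
#' @param n_pairs Number of random pairs.
#' @return Numeric vector of pairwise coalescence times.
#' @export
tracer_pair_times <- function(run, n_pairs = 100) {
  cpp_sim_tracer_pairs(run$handle, as.integer(n_pairs))
}

#' Coalescent Ne/N ratio against a neutral control
#'
#' Runs the focal configuration and a matching neutral control (same N and
#' architecture, Ud = Ub = 0), each carrying a neutral tracer block, and
#' estimates \deqn{N_e/N = \bar{T}_2(\mathrm{focal}) /
#' \bar{T}_2(\mathrm{control}),} the ratio of mean pairwise coalescence
#' times. Taking the ratio to a same-size neutral control sidesteps the Moran
#' timescale constant. Background selection in the focal run shortens
#' coalescence times, giving a ratio below 1.
#'
#' @details
#' A single genealogy gives highly correlated pairwise times (every pair
#' shares the same tree), so each run is sampled at several checkpoints
#' spaced a multiple of N generations apart -- far enough for the tracer
#' tree to turn over -- after a warm-up of one third of the run. The
#' checkpoint means are the statistical units for the standard error.
#'
#' @param config Focal [sim_config()]; `tracer` is forced on.
#' @param control_config Optional control configuration; defaults to `config`
#'   with mutation rates zeroed. Must share N and architecture with `config`.
#' @param replicates Independent replicate runs per arm.
#' @param n_pairs Pairs sampled per checkpoint.
#' @param spacing Generations between checkpoints (default 2N).
#' @return An object of class `"vf_ne_report"`: list with `ratio`, `se`,
#'   mean coalescence times and the per-checkpoint means for both arms.
#' @export
coalescent_ne_ratio <- function(config, control_config = NULL,
                                replicates = 3, n_pairs = 100,
                                spacing = NULL) {
  if (is.null(control_config)) {
    control_config <- config
    p <- config$params
    control_config$params <- model_params(0, 0, p$deleterious_dfe,
                                          p$beneficial_dfe)
  }
  if (control_config$N != config$N)
    stop("focal and control configurations must share N")
  if (is.null(spacing)) spacing <- 2 * config$N
  arm <- function(cfg) {
    cfg$tracer <- TRUE
    warm <- ceiling(cfg$generations / 3)
    n_checks <- max(1L, floor((cfg$generations - warm) / spacing))
    check_means <- numeric(0)
    for (r in seq_len(replicates)) {
      pop <- init_population(cfg)
      advance_generations(pop, warm)
      for (k in seq_len(n_checks)) {
        advance_generations(pop, spacing)
        t2 <- cpp_sim_tracer_pairs(pop$handle, as.integer(n_pairs))
        obs <- t2[!is.na(t2)]
        if (length(obs) > 0) check_means <- c(check_means, mean(obs))
      }
    }
    if (length(check_means) < 2)
      stop("too few coalesced tracer samples; lengthen the run")
    check_means
  }
  t2_focal <- arm(config)
  t2_control <- arm(control_config)
  m_f <- mean(t2_focal); m_c <- mean(t2_control)
  ratio <- m_f / m_c
  # delta method over checkpoint means (adjacent checkpoints retain some
  # genealogical correlation, so this is a mild underestimate)
  se <- ratio * sqrt(stats::var(t2_focal) / (length(t2_focal) * m_f^2) +
                     stats::var(t2_control) / (length(t2_control) * m_c^2))
  structure(list(N = config$N, ratio = ratio, se = se,
                 t2_focal_mean = m_f, t2_control_mean = m_c,
                 t2_focal = t2_focal, t2_control = t2_control,
                 control = "Ud = Ub = 0 neutral"),
            class = "vf_ne_report")
}

#' @export
print.vf_ne_report <- function(x, ...) {
  cat(sprintf("Coalescent Ne/N at N = %d: %.3f (SE %.3f)\n", x$N, x$ratio,
              x$se))
  cat(sprintf("  mean T2 focal = %.1f gen, control = %.1f gen (%s control)\n",
              x$t2_focal_mean, x$t2_control_mean, x$control))
  invisible(x)
}

#' Effective size from matching the analytic deleterious flux
#'
#' Finds the population size N' at which the linkage-equilibrium deleterious
#' flux equals an observed (simulated) flux: since |vd| is strictly
#' decreasing in N, the root is unique when it exists.
#'
#' @param vd_sim Observed deleterious flux (must be negative).
#' @param params A [model_params()].
#' @param interval Search interval for N'.
#' @return The flux-matched effective population size.
#' @export
flux_matched_ne <- function(vd_sim, params, interval = c(10, 1e7)) {
  if (!is.finite(vd_sim) || vd_sim >= 0)
    stop("'vd_sim' must be negative: the analytic vd < 0 for all N")
  f <- function(N) deleterious_flux(params, N) - vd_sim
  flo <- f(interval[1]); fhi <- f(interval[2])
  if (flo * fhi > 0)
    stop(sprintf(
      "no N in [%g, %g] matches vd = %g (analytic range [%g, %g])",
      interval[1], interval[2], vd_sim, deleterious_flux(params, interval[1]),
      deleterious_flux(params, interval[2])))
  stats::uniroot(f, interval, f.lower = flo, f.upper = fhi,
                 tol = .Machine$double.eps^0.5)$root
}

#' Ne rescaling from analytic and simulated critical sizes
#'
#' Linkage disequilibrium raises the simulated critical size above the
#' linkage-equilibrium one; attributing the excess to a reduced effective
#' size gives \deqn{N_e = N \cdot N_{crit}^{analytic} / N_{crit}^{sim}.}
#'
#' @param analytic_ncrit Critical size from [find_ncrit()].
#' @param simulated_ncrit Critical size from [estimate_ncrit()].
#' @param N Census size to rescale.
#' @return Effective population size.
#' @export
rescaled_ne <- function(analytic_ncrit, simulated_ncrit, N) {
  stopifnot(analytic_ncrit > 0, simulated_ncrit > 0)
  N * analytic_ncrit / simulated_ncrit
}
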