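#' Decompose simulated net flux into deleterious and beneficial components
#'
#' Uses the fixation ledger of a simulation run: for mutations whose fixation
#' generation lies in `(burn_in_end, run_end]`,
#' \deqn{v_d = \sum_i 2 s_{d,i} / G^*, \qquad v_b = \sum_i 2 s_{b,i} / G^*,}
#' where \eqn{G^* = } `run_end - burn_in_end` is the number of post-burn-in
#' generations. Fixation tracking follows mean fitness only up to
#' polymorphism-driven fluctuations, so `vd + vb` matches the trajectory
#' slope statistically, not exactly.
#'
#' @param fixations Data frame with columns `s`, `type` (0 deleterious,
#'   1 beneficial, 2 neutral) and `fixation_gen`, as returned in
#'   `sim_run(...)$fixations`.
#' @param burn_in_end,run_end Window bounds in generations (`run_end >
#'   burn_in_end`).
#' @return An object of class `"vf_flux_decomposition"`: list with `vd`,
#'   `vb`, `G_star`, `nd`, `nb` and the filtered fixation table.
#' @export
flux_decompose <- function(fixations, burn_in_end, run_end) {
  G_star <- run_end - burn_in_end
  if (!is.finite(G_star) || G_star <= 0)
    stop("invalid decomposition window: run_end must exceed burn_in_end")
  if (is.null(fixations)) fixations <- data.frame(
    s = numeric(0), type = integer(0), fixation_gen = numeric(0))
  keep <- fixations$fixation_gen > burn_in_end &
    fixations$fixation_gen <= run_end
  fx <- fixations[keep, , drop = FALSE]
  del <- fx$type == 0
  ben <- fx$type == 1
  structure(list(vd = sum(2 * fx$s[del]) / G_star,
                 vb = sum(2 * fx$s[ben]) / G_star,
                 G_star = G_star, nd = sum(del), nb = sum(ben),
                 fixations = fx),
            class = "vf_flux_decomposition")
}

#' @export
print.vf_flux_decomposition <- function(x, ...) {
  cat(sprintf(
    "Flux decomposition over G* = %g generations: vd = %.4g (%d fixations), vb = %.4g (%d fixations)\n",
    x$G_star, x$vd, x$nd, x$vb, x$nb))
  invisible(x)
}

#' Run a ledger-enabled simulation and decompose its fluxes
#'
#' Convenience wrapper: runs [sim_run()] with the ledger on and returns the
#' [flux_decompose()] of the post-burn-in window.
#'
#' @param N Population size.
#' @param params A [model_params()].
#' @param architecture A [genome_architecture()].
#' @param generations Run length (default 100 * N).
#' @return A `"vf_flux_decomposition"`; the run itself is in attribute
#'   `"run"`.
#' @export
sim_flux_decomposition <- function(N, params,
                                   architecture = genome_architecture(),
                                   generations = 100 * N) {
  cfg <- sim_config(N, params, architecture, generations = generations,
                    ledger = TRUE)
  run <- sim_run(cfg)
  if (is.na(run$burn_in_end))
    stop(sprintf("burn-in never completed at N = %d", N))
  d <- flux_decompose(run$fixations, run$burn_in_end, nrow(run$trajectory))
  attr(d, "run") <- run
  d
}

#' Simulated flux derivatives and drought : meltdown ratio
#'
#' Central differences of the replicate-mean deleterious and beneficial
#' fluxes at `ncrit +/- eps`:
#' \deqn{dv/dN = \frac{v(N_{crit}+\varepsilon) - v(N_{crit}-\varepsilon)}
#' {2\varepsilon},}
#' with the population-size step a balance between noise reduction (larger
#' eps) and curvature bias (smaller eps). Replicate standard errors are
#' propagated to the ratio by the delta method.
#'
#' @param flux_fun Function `N -> c(vd, vb)` returning one (stochastic) flux
#'   decomposition; e.g. a wrapper around [sim_flux_decomposition()], or an
#'   analytic stub in tests.
#' @param ncrit Critical size around which to difference.
#' @param eps Population-size step (default 150 individuals; must satisfy
#'   `0 < eps < ncrit`).
#' @param replicates Replicates per side.
#' @return An object of class `"vf_sim_ratio"`: list with `ncrit`, `eps`,
#'   `dvd_dN`, `dvb_dN`, `ratio`, `ratio_se` and the per-side flux matrices.
#' @export
simulated_ratio <- function(flux_fun, ncrit, eps = 150, replicates = 10) {
  if (!is.finite(eps) || eps <= 0) stop("'eps' must be > 0")
  if (eps >= ncrit) stop("'eps' must be smaller than ncrit")
  run_side <- function(N) {
    t(vapply(seq_len(replicates), function(i) {
      v <- flux_fun(N)
      c(vd = unname(v[1]), vb = unname(v[2]))
    }, numeric(2)))
  }
  hi <- run_side(ncrit + eps)
  lo <- run_side(ncrit - eps)
  dvd <- (mean(hi[, "vd"]) - mean(lo[, "vd"])) / (2 * eps)
  dvb <- (mean(hi[, "vb"]) - mean(lo[, "vb"])) / (2 * eps)
  se_diff <- function(a, b) {
    sqrt(stats::var(a) / length(a) + stats::var(b) / length(b)) / (2 * eps)
  }
  se_dvd <- se_diff(hi[, "vd"], lo[, "vd"])
  se_dvb <- se_diff(hi[, "vb"], lo[, "vb"])
  ratio <- dvb / dvd
  ratio_se <- if (dvd != 0 && dvb != 0) {
    abs(ratio) * sqrt((se_dvb / dvb)^2 + (se_dvd / dvd)^2)
  } else NA_real_
  if (!is.finite(dvd) || dvd <= 0)
    warning("non-positive dvd/dN estimate: derivative is noise-dominated")
  structure(list(ncrit = ncrit, eps = eps, dvd_dN = dvd, dvb_dN = dvb,
                 ratio = ratio, ratio_se = ratio_se, upper = hi, lower = lo),
            class = "vf_sim_ratio")
}

#' @export
print.vf_sim_ratio <- function(x, ...) {
  cat(sprintf(
    "Simulated drought:meltdown ratio at Ncrit = %.5g (eps = %g): %.4g (SE %.2g)\n",
    x$ncrit, x$eps, x$ratio, x$ratio_se))
  invisible(x)
}
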