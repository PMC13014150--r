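#' Model parameters for the linkage-equilibrium flux model
#'
#' Bundles the genome-wide mutation rates, the two DFEs and the environmental
#' deterioration rate into a single object consumed by the flux functions.
#'
#' @param Ud Deleterious mutations per diploid genome per generation (>= 0).
#' @param Ub Beneficial mutations per diploid genome per generation (>= 0).
#' @param deleterious_dfe A [dfe_gamma()] object.
#' @param beneficial_dfe A [dfe_exponential()] object.
#' @param delta_env Constant per-generation change in log mean fitness from
#'   environmental deterioration (<= 0; 0 means a static environment).
#' @return An object of class `"vf_params"`.
#' @examples
#' p <- model_params(Ud = 2, Ub = 0.002)
#' find_ncrit(p)
#' @export
model_params <- function(Ud = 2, Ub = 0.002,
                         deleterious_dfe = dfe_preset("human_nonsynonymous"),
                         beneficial_dfe = dfe_exponential(0.001),
                         delta_env = 0) {
  if (!is.finite(Ud) || Ud < 0) stop("'Ud' must be >= 0")
  if (!is.finite(Ub) || Ub < 0) stop("'Ub' must be >= 0")
  if (!inherits(deleterious_dfe, "vf_dfe_gamma"))
    stop("'deleterious_dfe' must be a gamma deleterious DFE")
  if (!inherits(beneficial_dfe, "vf_dfe_exp"))
    stop("'beneficial_dfe' must be an exponential beneficial DFE")
  if (!is.finite(delta_env) || delta_env > 0)
    stop("'delta_env' must be <= 0")
  structure(list(Ud = Ud, Ub = Ub, deleterious_dfe = deleterious_dfe,
                 beneficial_dfe = beneficial_dfe, delta_env = delta_env),
            class = "vf_params")
}

#' @export
print.vf_params <- function(x, ...) {
  cat(sprintf("Flux model parameters: Ud = %g, Ub = %g, delta_env = %g\n",
              x$Ud, x$Ub, x$delta_env))
  print(x$deleterious_dfe)
  print(x$beneficial_dfe)
  invisible(x)
}

#' Exact Moran fixation probability
#'
#' Probability that a single new co-dominant mutation of selection coefficient
#' `s` fixes in a diploid population of size `N` under the Moran birth-death
#' process: \deqn{p_{fix}(s) = \frac{1 - e^{-s}}{1 - e^{-2Ns}},} with the
#' continuous limit \eqn{1/(2N)} at \eqn{s = 0}. Evaluation is overflow-safe
#' for arbitrarily large \eqn{|s|} and \eqn{N} (asymptotic log-space branches
#' for strongly deleterious mutations).
#'
#' @param s Selection coefficient(s), finite.
#' @param N Diploid population size (>= 1; treated as continuous).
#' @return Fixation probabilities in (0, 1), vectorised over `s`.
#' @export
pfix <- function(s, N) {
  stopifnot(all(is.finite(s)), length(N) == 1, is.finite(N), N >= 1)
  out <- numeric(length(s))
  zero <- s == 0
  out[zero] <- 1 / (2 * N)
  neg <- s < 0
  if (any(neg)) {
    # both numerator and denominator are expm1 of positive arguments;
    # work in logs to survive |s| or 2N|s| beyond exp overflow
    x <- -s[neg]
    out[neg] <- exp(.log_expm1(x) - .log_expm1(2 * N * x))
  }
  pos <- s > 0
  if (any(pos)) {
    out[pos] <- expm1(-s[pos]) / expm1(-2 * N * s[pos])
  }
  out
}

# log(expm1(x)) for x > 0 without overflow
.log_expm1 <- function(x) {
  ifelse(x > 37, x, log(expm1(x)))
}

# d/dN [N * pfix(s, N)] = pfix(s, N) * (1 - y / (e^y - 1)), y = 2Ns.
# The second factor is computed overflow-safely.
.dN_npfix_factor <- function(s, N) {
  y <- 2 * N * s
  h <- ifelse(y == 0, 1, ifelse(y > 700, 0, y / expm1(y)))
  1 - h
}

# piecewise adaptive quadrature on |s| in (0, Inf); the split points tame the
# integrable gamma singularity at 0 (shape < 1) and the scale change at large s
.flux_quadrature <- function(f, rel.tol = 1e-10) {
  splits <- c(0, 1e-6, 1e-4, 1e-2, 1, Inf)
  total <- 0
  for (k in seq_len(length(splits) - 1)) {
    r <- tryCatch(
      stats::integrate(f, splits[k], splits[k + 1], rel.tol = rel.tol,
                       abs.tol = 0, stop.on.error = TRUE),
      error = function(e) {
        stop(sprintf("flux quadrature failed on [%g, %g]: %s", splits[k],
                     splits[k + 1], conditionMessage(e)), call. = FALSE)
      })
    total <- total + r$value
  }
  total
}

#' Deleterious fitness flux
#'
#' Expected per-generation change in log mean fitness from fixations of new
#' deleterious mutations:
#' \deqn{v_d = U_d N \int_{-\infty}^{0} p_d(s)\, 2s\, p_{fix}(s, N)\, ds \le 0.}
#' Computed by adaptive quadrature on the \eqn{|s|} half-line.
#'
#' @param params A [model_params()] object.
#' @param N Diploid population size.
#' @return Non-positive fitness change per generation.
#' @export
deleterious_flux <- function(params, N) {
  stopifnot(inherits(params, "vf_params"), N >= 1)
  if (params$Ud == 0) return(0)
  d <- params$deleterious_dfe
  f <- function(x) {
    stats::dgamma(x, shape = d$shape, scale = d$scale) * (-2 * x) *
      pfix(-x, N)
  }
  params$Ud * N * .flux_quadrature(f)
}

#' Beneficial fitness flux
#'
#' Expected per-generation change in log mean fitness from fixations of new
#' beneficial mutations:
#' \deqn{v_b = U_b N \int_{0}^{\infty} p_b(s)\, 2s\, p_{fix}(s, N)\, ds \ge 0.}
#'
#' @inheritParams deleterious_flux
#' @return Non-negative fitness change per generation.
#' @export
beneficial_flux <- function(params, N) {
  stopifnot(inherits(params, "vf_params"), N >= 1)
  if (params$Ub == 0) return(0)
  b <- params$beneficial_dfe
  f <- function(x) {
    stats::dexp(x, rate = 1 / b$mean) * 2 * x * pfix(x, N)
  }
  params$Ub * N * .flux_quadrature(f)
}

#' Net fitness flux at a population size
#'
#' @inheritParams deleterious_flux
#' @return An object of class `"vf_flux"`: a list with `N`, `vd`, `vb` and
#'   `vnet = vd + vb + delta_env`.
#' @export
net_flux <- function(params, N) {
  vd <- deleterious_flux(params, N)
  vb <- beneficial_flux(params, N)
  structure(list(N = N, vd = vd, vb = vb,
                 vnet = vd + vb + params$delta_env),
            class = "vf_flux")
}

#' @export
print.vf_flux <- function(x, ...) {
  cat(sprintf("N = %.6g: vd = %.6g, vb = %.6g, vnet = %.6g\n", x$N, x$vd,
              x$vb, x$vnet))
  invisible(x)
}

#' Critical population size
#'
#' Solves \eqn{v_{net}(N) = v_b + v_d + \delta_{env} = 0} for continuous
#' \eqn{N} by bracketed root finding. Net flux is negative below the root
#' (extinction vortex) and positive above it; the root is the tipping point.
#' The initial bracket is expanded by factors of two, down to `N = 10` and up
#' to `N = 1e8`, before giving up.
#'
#' @param params A [model_params()] object.
#' @param interval Initial search interval for N.
#' @param tol Absolute tolerance on `vnet` at the returned root.
#' @return Critical population size (unrounded).
#' @export
find_ncrit <- function(params, interval = c(500, 1e5), tol = 1e-10) {
  f <- function(N) {
    v <- net_flux(params, N)
    v$vnet
  }
  lo <- interval[1]; hi <- interval[2]
  flo <- f(lo); fhi <- f(hi)
  while (flo * fhi > 0 && (lo > 10 || hi < 1e8)) {
    if (fhi < 0 && hi < 1e8) { hi <- min(hi * 2, 1e8); fhi <- f(hi) }
    else if (flo > 0 && lo > 10) { lo <- max(lo / 2, 10); flo <- f(lo) }
    else break
  }
  if (flo * fhi > 0)
    stop(sprintf(paste0(
      "no sign change in vnet on [%g, %g]: vnet(lo) = %.4g, vnet(hi) = %.4g",
      " (with Ub = 0 no Ncrit exists: vnet < 0 everywhere)"),
      lo, hi, flo, fhi))
  r <- stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                      tol = .Machine$double.eps^0.5)
  # polish until |vnet| below tol (uniroot's tol is on N, not f)
  if (abs(r$f.root) > tol) {
    r <- stats::uniroot(f, c(max(lo, r$root * 0.99), min(hi, r$root * 1.01)),
                        tol = .Machine$double.eps)
  }
  r$root
}

#' Derivative of a fitness flux with respect to population size
#'
#' Differentiates under the integral sign: since the flux is
#' \eqn{U N \int p(s) 2s\, p_{fix}(s, N) ds}, its derivative is
#' \eqn{U \int p(s) 2s\, \partial_N [N p_{fix}(s, N)] ds} with
#' \eqn{\partial_N [N p_{fix}] = p_{fix} (1 - 2Ns/(e^{2Ns} - 1))}.
#' Both derivatives are positive near the critical population size: the
#' deleterious flux becomes less negative, and the beneficial flux more
#' positive, as N grows.
#'
#' @inheritParams deleterious_flux
#' @param which `"deleterious"` or `"beneficial"`.
#' @return Per-individual flux change dv/dN.
#' @export
flux_derivative <- function(params, N, which = c("deleterious", "beneficial")) {
  which <- match.arg(which)
  stopifnot(inherits(params, "vf_params"), N >= 2)
  if (which == "deleterious") {
    if (params$Ud == 0) return(0)
    d <- params$deleterious_dfe
    f <- function(x) {
      stats::dgamma(x, shape = d$shape, scale = d$scale) * (-2 * x) *
        pfix(-x, N) * .dN_npfix_factor(-x, N)
    }
    params$Ud * .flux_quadrature(f)
  } else {
    if (params$Ub == 0) return(0)
    b <- params$beneficial_dfe
    f <- function(x) {
      stats::dexp(x, rate = 1 / b$mean) * 2 * x * pfix(x, N) *
        .dN_npfix_factor(x, N)
    }
    params$Ub * .flux_quadrature(f)
  }
}

#' Drought : meltdown ratio at the critical population size
#'
#' The ratio \eqn{(dv_b/dN) / (dv_d/dN)} evaluated at \eqn{N_{crit}}. A value
#' below 1 means a marginal change in population size has more impact through
#' the deleterious flux (mutational meltdown); above 1, through the shortage
#' of beneficial mutations (mutational drought).
#'
#' @param params A [model_params()] object.
#' @param ncrit Optionally, a precomputed critical population size; found via
#'   [find_ncrit()] when `NULL`.
#' @return An object of class `"vf_ratio"`: list with `ncrit`, `dvb_dN`,
#'   `dvd_dN` and `ratio`.
#' @export
drought_meltdown_ratio <- function(params, ncrit = NULL) {
  if (is.null(ncrit)) ncrit <- find_ncrit(params)
  dvd <- flux_derivative(params, ncrit, "deleterious")
  dvb <- flux_derivative(params, ncrit, "beneficial")
  structure(list(ncrit = ncrit, dvb_dN = dvb, dvd_dN = dvd,
                 ratio = dvb / dvd),
            class = "vf_ratio")
}

#' @export
print.vf_ratio <- function(x, ...) {
  cat(sprintf(
    "Ncrit = %.6g; dvb/dN = %.4g, dvd/dN = %.4g; drought:meltdown = %.4g\n",
    x$ncrit, x$dvb_dN, x$dvd_dN, x$ratio))
  invisible(x)
}

#' Closed-form critical population size (exponential-DFE approximation)
#'
#' The classical closed form for the critical size under exponential DFEs,
#' scaled by 2 for the Moran model:
#' \deqn{N_{crit} \approx 2 \left(\frac{U_d}{64\, \bar{s}_b^2\, |\bar{s}_d|\,
#' U_b}\right)^{1/3}.}
#' It underestimates the quadrature result when the deleterious DFE is
#' overdispersed relative to an exponential (cv > 1).
#'
#' @param params A [model_params()] object with positive rates and means.
#' @return Approximate critical population size.
#' @export
whitlock_ncrit <- function(params) {
  sb <- dfe_moments(params$beneficial_dfe)$mean
  sd_ <- abs(dfe_moments(params$deleterious_dfe)$mean)
  if (params$Ud <= 0 || params$Ub <= 0 || sb <= 0 || sd_ <= 0)
    stop("whitlock_ncrit() needs positive Ud, Ub and DFE means")
  2 * (params$Ud / (64 * sb^2 * sd_ * params$Ub))^(1 / 3)
}

#' Convert a fitness-decline horizon to an environmental change rate
#'
#' A deterioration rate is often easier to read as the number of generations
#' over which fitness declines by 10%: \eqn{\delta_{env} = -0.1 / g}.
#'
#' @param generations_per_10pct_decline Generations for a 10% fitness decline
#'   (> 0).
#' @return The (negative) per-generation rate `delta_env`.
#' @export
env_rate <- function(generations_per_10pct_decline) {
  g <- generations_per_10pct_decline
  if (!is.numeric(g) || any(!is.finite(g)) || any(g <= 0))
    stop("'generations_per_10pct_decline' must be positive")
  -0.1 / g
}

#' Environmental-change threshold for drought dominance
#'
#' Finds the deterioration rate \eqn{\delta_{env}^*} at which the
#' drought : meltdown ratio equals 1 (root finding over
#' \eqn{\delta_{env} \in [-10^{-3.5}, 0)}), then compares it with the
#' deleterious flux at the corresponding critical population size:
#' `flux_ratio` \eqn{= |\delta_{env}^*| / |v_d(N_{crit})|}. A flux ratio well
#' below 1 marks the environmental change as slow relative to mutational
#' degradation and yet already sufficient to make drought dominate.
#'
#' @param params A [model_params()] object; its `delta_env` is ignored (the
#'   rate is the unknown).
#' @param range Search range for `delta_env` (negative values).
#' @return List with `delta_env_star`, `generations_per_10pct`, `ncrit`,
#'   `vd`, and `flux_ratio`.
#' @export
env_threshold_analysis <- function(params, range = c(-10^-3.5, -1e-7)) {
  ratio_at <- function(denv) {
    p <- model_params(params$Ud, params$Ub, params$deleterious_dfe,
                      params$beneficial_dfe, delta_env = denv)
    drought_meltdown_ratio(p)$ratio
  }
  f <- function(denv) ratio_at(denv) - 1
  flo <- f(range[1]); fhi <- f(range[2])
  if (flo * fhi > 0) {
    side <- if (flo > 0) "above" else "below"
    stop(sprintf(
      "drought:meltdown ratio stays %s 1 over delta_env in [%g, %g]",
      side, range[1], range[2]))
  }
  star <- stats::uniroot(f, range, tol = 1e-12)$root
  p_star <- model_params(params$Ud, params$Ub, params$deleterious_dfe,
                         params$beneficial_dfe, delta_env = star)
  nc <- find_ncrit(p_star)
  vd <- deleterious_flux(p_star, nc)
  list(delta_env_star = star,
       generations_per_10pct = -0.1 / star,
       ncrit = nc,
       vd = vd,
       flux_ratio = abs(star) / abs(vd))
}

#' Parameter sweep over the analytic model
#'
#' Evaluates [find_ncrit()] and [drought_meltdown_ratio()] over the Cartesian
#' product of parameter vectors. Rows where no root exists are kept with an
#' explicit `status` flag rather than dropped.
#'
#' @param Ud,Ub,sb_mean,delta_env Numeric vectors swept over.
#' @param sd_mean Vector of (negative) deleterious DFE means, applied to
#'   `base_dfe` via [dfe_with_mean()]; `NA` entries keep the base DFE.
#' @param cv Vector of deleterious-DFE coefficients of variation, applied via
#'   [dfe_with_cv()]; `NA` entries keep the base DFE's cv.
#' @param base_dfe Deleterious DFE the sweep modifies.
#' @return A data.frame with one row per combination: the parameters plus
#'   `ncrit`, `ratio`, `vd`, `vb` and `status` ("ok" or the error message).
#' @export
flux_sweep <- function(Ud = 2, Ub = 0.002, sb_mean = 0.001,
                       sd_mean = NA_real_, cv = NA_real_, delta_env = 0,
                       base_dfe = dfe_preset("human_nonsynonymous")) {
  grid <- expand.grid(Ud = Ud, Ub = Ub, sb_mean = sb_mean, sd_mean = sd_mean,
                      cv = cv, delta_env = delta_env,
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  out <- cbind(grid, ncrit = NA_real_, ratio = NA_real_, vd = NA_real_,
               vb = NA_real_, status = rep("ok", n),
               stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    res <- tryCatch({
      d <- base_dfe
      if (!is.na(grid$sd_mean[i])) d <- dfe_with_mean(d, grid$sd_mean[i])
      if (!is.na(grid$cv[i])) d <- dfe_with_cv(d, grid$cv[i])
      p <- model_params(grid$Ud[i], grid$Ub[i], d,
                        dfe_exponential(grid$sb_mean[i]),
                        delta_env = grid$delta_env[i])
      nc <- find_ncrit(p)
      r <- drought_meltdown_ratio(p, ncrit = nc)
      fl <- net_flux(p, nc)
      list(ncrit = nc, ratio = r$ratio, vd = fl$vd, vb = fl$vb,
           status = "ok")
    }, error = function(e) {
      list(ncrit = NA_real_, ratio = NA_real_, vd = NA_real_, vb = NA_real_,
           status = conditionMessage(e))
    })
    out$ncrit[i] <- res$ncrit
    out$ratio[i] <- res$ratio
    out$vd[i] <- res$vd
    out$vb[i] <- res$vb
    out$status[i] <- res$status
  }
  out
}
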