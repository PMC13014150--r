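#' Distributions of fitness effects (DFEs)
#'
#' Three DFE flavours are used throughout the package:
#'
#' * `dfe_gamma()` — a gamma distribution of *deleterious* selection
#'   coefficients. The shape/scale parameters are stored on the magnitude
#'   (\eqn{|s|}) scale but the distribution has support on \eqn{s < 0}:
#'   densities, moments and samples are all reported with a negative sign.
#' * `dfe_pop_gamma()` — the same gamma distribution expressed on the
#'   population-scaled \eqn{2 N_e s} axis, as DFE-inference studies report it.
#'   Use [dfe_rescale()] to convert it to the per-copy scale.
#' * `dfe_exponential()` — an exponential distribution of *beneficial*
#'   selection coefficients with support on \eqn{s > 0}.
#'
#' Selection coefficients with \eqn{s \le -1} are retained: in the Moran model
#' they behave indistinguishably from lethal mutations and need no truncation.
#'
#' @param shape Gamma shape parameter (dimensionless, > 0).
#' @param scale Gamma scale parameter: on the \eqn{|s|} scale for
#'   `dfe_gamma()`, on the \eqn{2 N_e s} scale for `dfe_pop_gamma()`.
#' @param two_ne The scaling constant \eqn{2 N_e} (number of gene copies) used
#'   by the inference that produced the population-scaled parameters.
#' @param mean Mean beneficial selection coefficient \eqn{\bar{s}_b > 0}.
#' @return An object of class `"vf_dfe"` (subclass `"vf_dfe_gamma"`,
#'   `"vf_dfe_pop_gamma"` or `"vf_dfe_exp"`).
#' @examples
#' human <- dfe_rescale(dfe_pop_gamma(0.169, 1327.4, two_ne = 23646))
#' dfe_moments(human)
#' @name dfe
NULL

#' @rdname dfe
#' @export
dfe_gamma <- function(shape, scale) {
  stopifnot(is.numeric(shape), is.numeric(scale), length(shape) == 1,
            length(scale) == 1)
  if (!is.finite(shape) || shape <= 0) stop("'shape' must be > 0")
  if (!is.finite(scale) || scale <= 0) stop("'scale' must be > 0")
  structure(list(shape = shape, scale = scale),
            class = c("vf_dfe_gamma", "vf_dfe"))
}

#' @rdname dfe
#' @export
dfe_pop_gamma <- function(shape, scale, two_ne) {
  stopifnot(length(two_ne) == 1)
  if (!is.finite(two_ne) || two_ne <= 0) stop("'two_ne' must be > 0")
  if (!is.finite(shape) || shape <= 0) stop("'shape' must be > 0")
  if (!is.finite(scale) || scale <= 0) stop("'scale' must be > 0")
  structure(list(shape = shape, scale = scale, two_ne = two_ne),
            class = c("vf_dfe_pop_gamma", "vf_dfe"))
}

#' @rdname dfe
#' @export
dfe_exponential <- function(mean) {
  stopifnot(is.numeric(mean), length(mean) == 1)
  if (!is.finite(mean) || mean <= 0) stop("'mean' must be > 0")
  structure(list(mean = mean), class = c("vf_dfe_exp", "vf_dfe"))
}

#' Rescale a population-scaled gamma DFE to the selection-coefficient scale
#'
#' Divides the scale parameter by \eqn{2 N_e}, leaving the shape untouched,
#' which converts a DFE reported on the \eqn{2 N_e s} axis into one on the
#' per-copy \eqn{s} axis.
#'
#' @param dfe A [dfe_pop_gamma()] object.
#' @return A [dfe_gamma()] object.
#' @export
dfe_rescale <- function(dfe) {
  if (!inherits(dfe, "vf_dfe_pop_gamma"))
    stop("dfe_rescale() expects a population-scaled gamma DFE")
  dfe_gamma(dfe$shape, dfe$scale / dfe$two_ne)
}

#' Mean and coefficient of variation of a DFE
#'
#' @param dfe A DFE object.
#' @return A list with elements `mean` (signed selection coefficient) and
#'   `cv` (dimensionless). For the gamma deleterious DFE the mean is
#'   \eqn{-\alpha\beta} and the cv is \eqn{1/\sqrt{\alpha}}; an exponential
#'   DFE has cv exactly 1.
#' @export
dfe_moments <- function(dfe) UseMethod("dfe_moments")

#' @export
dfe_moments.vf_dfe_gamma <- function(dfe) {
  list(mean = -dfe$shape * dfe$scale, cv = 1 / sqrt(dfe$shape))
}

#' @export
dfe_moments.vf_dfe_pop_gamma <- function(dfe) {
  m <- dfe_moments(dfe_rescale(dfe))
  m
}

#' @export
dfe_moments.vf_dfe_exp <- function(dfe) list(mean = dfe$mean, cv = 1)

#' DFE density on the signed selection-coefficient axis
#'
#' @param dfe A DFE object.
#' @param s Vector of signed selection coefficients.
#' @return Density values; zero off the support (\eqn{s<0} for the gamma
#'   deleterious DFE, \eqn{s>0} for the exponential beneficial DFE).
#' @export
dfe_density <- function(dfe, s) UseMethod("dfe_density")

#' @export
dfe_density.vf_dfe_gamma <- function(dfe, s) {
  ifelse(s < 0, stats::dgamma(-s, shape = dfe$shape, scale = dfe$scale), 0)
}

#' @export
dfe_density.vf_dfe_exp <- function(dfe, s) {
  ifelse(s > 0, stats::dexp(s, rate = 1 / dfe$mean), 0)
}

#' Adjust the mean of a gamma deleterious DFE, keeping the shape fixed
#'
#' Only the scale parameter moves, so the coefficient of variation is
#' unchanged.
#'
#' @param dfe A [dfe_gamma()] object.
#' @param new_mean New (negative) mean selection coefficient.
#' @return A [dfe_gamma()] object with `moments(...)$mean == new_mean`.
#' @export
dfe_with_mean <- function(dfe, new_mean) {
  if (!inherits(dfe, "vf_dfe_gamma"))
    stop("dfe_with_mean() expects a gamma deleterious DFE")
  if (!is.finite(new_mean) || new_mean >= 0)
    stop("'new_mean' must be negative (deleterious)")
  dfe_gamma(dfe$shape, abs(new_mean) / dfe$shape)
}

#' Adjust the coefficient of variation of a gamma DFE at fixed mean
#'
#' Shape and scale move together (\eqn{\alpha = 1/\mathrm{cv}^2},
#' \eqn{\beta = |\bar{s}|\,\mathrm{cv}^2}) so the mean is preserved exactly.
#'
#' @param dfe A [dfe_gamma()] object.
#' @param new_cv New coefficient of variation (> 0).
#' @return A [dfe_gamma()] object.
#' @export
dfe_with_cv <- function(dfe, new_cv) {
  if (!inherits(dfe, "vf_dfe_gamma"))
    stop("dfe_with_cv() expects a gamma deleterious DFE")
  if (!is.finite(new_cv) || new_cv <= 0) stop("'new_cv' must be > 0")
  old_mean <- abs(dfe_moments(dfe)$mean)
  dfe_gamma(1 / new_cv^2, old_mean * new_cv^2)
}

#' Sample selection coefficients from a DFE
#'
#' @param dfe A DFE object.
#' @param n Number of draws (>= 0).
#' @return Numeric vector of signed selection coefficients.
#' @export
dfe_sample <- function(dfe, n) UseMethod("dfe_sample")

#' @export
dfe_sample.vf_dfe_gamma <- function(dfe, n) {
  stopifnot(n >= 0)
  -stats::rgamma(n, shape = dfe$shape, scale = dfe$scale)
}

#' @export
dfe_sample.vf_dfe_exp <- function(dfe, n) {
  stopifnot(n >= 0)
  stats::rexp(n, rate = 1 / dfe$mean)
}

#' @export
print.vf_dfe <- function(x, ...) {
  if (inherits(x, "vf_dfe_gamma")) {
    m <- dfe_moments(x)
    cat(sprintf(
      "Gamma deleterious DFE (s < 0): shape = %.4g, scale = %.4g\n", x$shape,
      x$scale))
    cat(sprintf("  mean s = %.4g, cv = %.3g\n", m$mean, m$cv))
  } else if (inherits(x, "vf_dfe_pop_gamma")) {
    cat(sprintf(
      "Population-scaled gamma DFE (2Ne*s): shape = %.4g, scale = %.4g, 2Ne = %g\n",
      x$shape, x$scale, x$two_ne))
  } else {
    cat(sprintf("Exponential beneficial DFE (s > 0): mean = %.4g\n", x$mean))
  }
  invisible(x)
}

#' Named DFE presets
#'
#' `"human_nonsynonymous"` is the gamma DFE inferred from the human
#' non-synonymous site frequency spectrum (shape 0.169, population-scaled
#' scale 1327.4, \eqn{2 N_e = 23646}); rescaling is done exactly
#' (scale = 1327.4 / 23646, not the rounded 0.056), giving a mean
#' selection coefficient of about -0.00949.
#'
#' @param name Preset name.
#' @param rescaled If `TRUE` (default) return the per-copy [dfe_gamma()];
#'   otherwise the raw [dfe_pop_gamma()].
#' @return A DFE object.
#' @export
dfe_preset <- function(name = "human_nonsynonymous", rescaled = TRUE) {
  presets <- list(
    human_nonsynonymous = dfe_pop_gamma(0.169, 1327.4, two_ne = 23646)
  )
  if (!name %in% names(presets))
    stop(sprintf("unknown DFE preset '%s'", name))
  p <- presets[[name]]
  if (rescaled) dfe_rescale(p) else p
}

#' Read a DFE from a YAML key-value file
#'
#' Recognised keys: `family` ("gamma", "pop_gamma" or "exponential"),
#' `shape`, `scale`, `mean`, `two_ne`.
#'
#' @param path Path to a YAML file.
#' @return A DFE object.
#' @export
read_dfe_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$family)) stop("DFE config needs a 'family' key")
  switch(cfg$family,
    gamma = dfe_gamma(cfg$shape, cfg$scale),
    pop_gamma = dfe_pop_gamma(cfg$shape, cfg$scale, cfg$two_ne),
    exponential = dfe_exponential(cfg$mean),
    stop(sprintf("unknown DFE family '%s'", cfg$family))
  )
}
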