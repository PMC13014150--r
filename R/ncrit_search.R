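#' Bracket the critical population size of a (possibly noisy) evaluator
#'
#' Evaluates `evaluator(N)` at the initial guesses (1500 and 6000 by default)
#' and keeps expanding outward by a factor of two (750, 12000, 375, 24000,
#' ...) until estimates of both signs have been seen.
#'
#' @param evaluator Function N -> net flux estimate.
#' @param init Two initial guesses.
#' @param expand_factor Outward expansion factor.
#' @param min_N,max_N Caps; crossing either raises a bracket-failure error.
#' @return A data.frame of all evaluated points (`N`, `vnet`), with the
#'   achieved bracket in attributes `lower` and `upper`.
#' @export
bracket_ncrit <- function(evaluator, init = c(1500, 6000), expand_factor = 2,
                          min_N = 50, max_N = 1e6) {
  pts <- data.frame(N = numeric(0), vnet = numeric(0))
  eval_at <- function(N) {
    v <- evaluator(N)
    pts[nrow(pts) + 1, ] <<- c(N, v)
    v
  }
  lo <- min(init); hi <- max(init)
  eval_at(lo); eval_at(hi)
  repeat {
    if (any(pts$vnet > 0) && any(pts$vnet < 0)) break
    lo <- lo / expand_factor; hi <- hi * expand_factor
    if (lo < min_N || hi > max_N)
      stop(sprintf(
        "failed to bracket a sign change in [%g, %g]: all estimates %s 0",
        min_N, max_N, if (all(pts$vnet < 0)) "below" else "above"))
    eval_at(lo)
    if (any(pts$vnet > 0) && any(pts$vnet < 0)) break
    eval_at(hi)
  }
  neg <- pts[pts$vnet < 0, ]; pos <- pts[pts$vnet > 0, ]
  attr(pts, "lower") <- neg$N[which.max(neg$N)]
  attr(pts, "upper") <- pos$N[which.min(pos$N)]
  pts
}

#' Secant iteration on a noisy net-flux evaluator
#'
#' Standard secant updates on (N, vnet) pairs, seeded with the last two
#' bracketing evaluations. Iteration stops when the magnitude of vnet changes
#' by less than `rel_change` between successive evaluations (the stall point
#' where noise dominates), or at `max_iter` iterations (flagged).
#'
#' @param evaluator Function N -> net flux estimate.
#' @param points Data frame of prior evaluations (e.g. from
#'   [bracket_ncrit()]); the last two rows seed the iteration.
#' @param rel_change Relative-change termination threshold (default 0.15).
#' @param max_iter Safety cap on iterations.
#' @param min_N Evaluations are clamped to be at least this large.
#' @return The augmented points data.frame; attribute `converged` is FALSE if
#'   the cap was hit, and `final_N` holds the last evaluated N.
#' @export
secant_search <- function(evaluator, points, rel_change = 0.15,
                          max_iter = 30, min_N = 10) {
  stopifnot(nrow(points) >= 2)
  pts <- points
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    n <- nrow(pts)
    N1 <- pts$N[n - 1]; N2 <- pts$N[n]
    v1 <- pts$vnet[n - 1]; v2 <- pts$vnet[n]
    if (v2 == v1) {
      # flat secant: perturb by 1% and continue
      N_new <- N2 * 1.01
    } else {
      N_new <- N2 - v2 * (N2 - N1) / (v2 - v1)
    }
    if (!is.finite(N_new) || N_new < min_N) N_new <- max(min_N, (N1 + N2) / 2)
    v_new <- evaluator(N_new)
    pts[nrow(pts) + 1, ] <- c(N_new, v_new)
    if (v_new == 0 || (v2 != 0 && abs(v_new - v2) / abs(v2) < rel_change)) {
      # an exact zero is a found root; otherwise stop once successive
      # estimates stall (the stochastic noise floor)
      converged <- TRUE
      break
    }
  }
  attr(pts, "converged") <- converged
  attr(pts, "final_N") <- pts$N[nrow(pts)]
  pts
}

#' Zero-intercept of a line fitted near the final evaluation
#'
#' Fits an OLS line vnet = a + b N through all evaluated points whose N lies
#' within a factor of `window_factor` of `final_N`, and returns the zero
#' intercept -a/b as the critical-size estimate.
#'
#' @param points Data frame with columns `N` and `vnet`.
#' @param final_N Centre of the inclusion window (usually the last secant
#'   evaluation).
#' @param window_factor Inclusion window is `[final_N / window_factor,
#'   final_N * window_factor]`.
#' @return The intercept estimate; attributes `slope`, `intercept`,
#'   `n_points` and `reliable` (FALSE when the fitted slope is not positive).
#' @export
fit_ncrit_intercept <- function(points, final_N, window_factor = 3) {
  keep <- points$N >= final_N / window_factor &
    points$N <= final_N * window_factor
  if (sum(keep) < 2)
    stop("fewer than 2 evaluated points within a factor of 3 of final N")
  fit <- stats::lm.fit(cbind(1, points$N[keep]), points$vnet[keep])
  a <- unname(fit$coefficients[1]); b <- unname(fit$coefficients[2])
  if (!is.finite(b) || b == 0) stop("degenerate line fit (zero slope)")
  est <- -a / b
  attr(est, "slope") <- b
  attr(est, "intercept") <- a
  attr(est, "n_points") <- sum(keep)
  attr(est, "reliable") <- is.finite(b) && b > 0
  est
}

#' Replicated stochastic search for the simulated critical population size
#'
#' Runs the bracket / secant / line-fit pipeline once per replicate with an
#' independent evaluator, and averages the per-replicate zero intercepts.
#'
#' @param make_evaluator Function `(replicate_index)` returning an evaluator
#'   `N -> vnet` (so each replicate gets independent stochasticity). Pass a
#'   plain evaluator function of one argument N to reuse it across
#'   replicates (useful for deterministic evaluators).
#' @param n_replicates Number of replicates (default 10).
#' @param rel_change,max_iter,window_factor Passed to the pipeline stages.
#' @param init,min_N,max_N Passed to [bracket_ncrit()].
#' @return An object of class `"vf_ncrit_estimate"`: list with `ncrit` (mean
#'   of intercepts), `intercepts`, `points` (per-replicate evaluation
#'   tables), and `failures` (error messages of failed replicates).
#' @export
estimate_ncrit <- function(make_evaluator, n_replicates = 10,
                           rel_change = 0.15, max_iter = 30,
                           window_factor = 3, init = c(1500, 6000),
                           min_N = 50, max_N = 1e6) {
  factory <- make_evaluator
  # allow passing a bare evaluator f(N)
  test_is_factory <- tryCatch({
    cand <- make_evaluator(1)
    is.function(cand)
  }, error = function(e) FALSE)
  if (!test_is_factory) factory <- function(rep) make_evaluator

  intercepts <- rep(NA_real_, n_replicates)
  all_points <- vector("list", n_replicates)
  failures <- character(0)
  for (r in seq_len(n_replicates)) {
    res <- tryCatch({
      ev <- factory(r)
      pts <- bracket_ncrit(ev, init = init, min_N = min_N, max_N = max_N)
      pts <- secant_search(ev, pts, rel_change = rel_change,
                           max_iter = max_iter, min_N = min_N)
      est <- fit_ncrit_intercept(pts, attr(pts, "final_N"),
                                 window_factor = window_factor)
      list(est = as.numeric(est), pts = pts)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, conditionMessage(res))
    } else {
      intercepts[r] <- res$est
      all_points[[r]] <- res$pts
    }
  }
  ok <- !is.na(intercepts)
  if (!any(ok)) stop("all replicates failed: ", failures[1])
  if (sum(ok) < n_replicates)
    warning(sprintf("%d of %d replicates failed; mean over %d",
                    n_replicates - sum(ok), n_replicates, sum(ok)))
  structure(list(ncrit = mean(intercepts[ok]), intercepts = intercepts,
                 points = all_points, failures = failures),
            class = "vf_ncrit_estimate")
}

#' @export
print.vf_ncrit_estimate <- function(x, ...) {
  ok <- sum(!is.na(x$intercepts))
  cat(sprintf("Simulated Ncrit = %.5g (mean of %d replicate intercepts)\n",
              x$ncrit, ok))
  invisible(x)
}

#' Net-flux evaluator backed by the linkage-block simulator
#'
#' Returns a closure suitable for [bracket_ncrit()] / [estimate_ncrit()]:
#' each call runs a fresh simulation at the requested N and returns its
#' post-burn-in net-flux slope.
#'
#' @param params A [model_params()].
#' @param architecture A [genome_architecture()].
#' @param generations_factor Run length as a multiple of N (default 100).
#' @return Function `N -> vnet` (N is rounded to an integer >= 3).
#' @export
sim_vnet_evaluator <- function(params, architecture = genome_architecture(),
                               generations_factor = 100) {
  function(N) {
    N <- max(3L, as.integer(round(N)))
    cfg <- sim_config(N, params, architecture,
                      generations = generations_factor * N)
    run <- sim_run(cfg)
    if (is.na(run$vnet)) stop(sprintf("run at N = %d yielded no vnet", N))
    run$vnet
  }
}
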