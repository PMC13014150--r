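# Independent oracles used across the test files.

# Exact fixation probability of a single copy in a birth-death Markov chain
# on 0..2N copies with per-copy success ratio e^s, found by solving the
# absorption linear system h_i = p_i h_{i+1} + q_i h_{i-1}; h_0 = 0,
# h_{2N} = 1. Independent of the closed-form expression used by pfix().
chain_fixation_prob <- function(s, N) {
  M <- 2 * N
  r <- exp(s)                      # birth : death odds at every interior state
  p <- r / (1 + r)
  q <- 1 - p
  # interior states 1..M-1
  n <- M - 1
  A <- diag(n)
  b <- numeric(n)
  for (i in seq_len(n)) {
    if (i > 1) A[i, i - 1] <- -q
    if (i < n) A[i, i + 1] <- -p
    if (i == n) b[i] <- p          # h_M = 1
  }
  solve(A, b)[1]
}

# Monte-Carlo flux estimate with standard error, as a quadrature cross-check
mc_flux <- function(params, N, which = "deleterious", n_draws = 1e6) {
  dfe <- if (which == "deleterious") params$deleterious_dfe else
    params$beneficial_dfe
  U <- if (which == "deleterious") params$Ud else params$Ub
  s <- dfe_sample(dfe, n_draws)
  vals <- 2 * s * pfix_vec(s, N)
  est <- U * N * mean(vals)
  se <- U * N * stats::sd(vals) / sqrt(n_draws)
  list(value = est, se = se)
}

# chunked vectorised pfix (keeps memory flat at large n_draws)
pfix_vec <- function(s, N, chunk = 2e6) {
  out <- numeric(length(s))
  i <- 1
  while (i <= length(s)) {
    j <- min(i + chunk - 1, length(s))
    out[i:j] <- pfix(s[i:j], N)
    i <- j + 1
  }
  out
}

# OLS slope computed the long way (hand oracle for rolling-slope code)
ols_slope <- function(y) {
  x <- seq_along(y)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

default_params <- function(delta_env = 0) {
  model_params(Ud = 2, Ub = 0.002,
               deleterious_dfe = dfe_preset("human_nonsynonymous"),
               beneficial_dfe = dfe_exponential(0.001),
               delta_env = delta_env)
}
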