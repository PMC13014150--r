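test_that("pfix matches its limits, frozen values, and stays in (0, 1)", {
  expect_identical(pfix(0, 1833), 1 / 3666)
  # high-precision evaluations of the closed form
  expect_equal(pfix(0.001, 3666), 1.00015e-3, tolerance = 1e-4)
  expect_equal(pfix(-0.001, 3666), 6.54e-7, tolerance = 1e-2)
  s <- c(-5, -1, -0.1, -1e-3, -1e-8, 1e-8, 1e-3, 0.1, 1, 5)
  for (N in c(2, 50, 3666, 1e6)) {
    v <- pfix(s, N)
    # strongly deleterious values underflow to 0 at large N; otherwise (0, 1)
    expect_true(all(is.finite(v) & v >= 0 & v < 1))
    expect_true(all(v[s > 0] > 0))
    expect_true(all(diff(v) >= 0))  # monotone non-decreasing in s
    keep <- v > 1e-300
    expect_true(all(diff(v[keep]) > 0))
  }
  # overflow-safe far beyond double exp range
  expect_equal(pfix(5, 1e7), 1 - exp(-5), tolerance = 1e-12)
  expect_true(pfix(-50, 1e7) >= 0)
  expect_false(is.nan(pfix(-50, 1e7)))
})

test_that("pfix equals the absorption probability of the Moran birth-death chain", {
  # brute-force linear solve for 2N <= 20, to 1e-12
  for (N in c(2, 5, 10)) {
    for (s in c(-0.5, -0.05, -0.001, 0.001, 0.05, 0.5)) {
      expect_equal(pfix(s, N), chain_fixation_prob(s, N), tolerance = 1e-12)
    }
    expect_equal(pfix(0, N), 1 / (2 * N), tolerance = 1e-12)
  }
})

test_that("quadrature fluxes agree with Monte-Carlo oracles", {
  set.seed(101)
  p <- default_params()
  # 1e7-draw check at the headline population size
  mc_d <- mc_flux(p, 3666, "deleterious", n_draws = 1e7)
  mc_b <- mc_flux(p, 3666, "beneficial", n_draws = 1e7)
  expect_lt(abs(deleterious_flux(p, 3666) - mc_d$value), 3 * mc_d$se)
  expect_lt(abs(beneficial_flux(p, 3666) - mc_b$value), 3 * mc_b$se)
  expect_lt(abs(deleterious_flux(p, 3666) / mc_d$value - 1), 0.005)
  expect_lt(abs(beneficial_flux(p, 3666) / mc_b$value - 1), 0.005)
  # grid of (N, params) combinations at 1e6 draws
  grid <- expand.grid(N = c(100, 1000, 10000),
                      Ud = c(0.2, 2), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    pg <- model_params(Ud = grid$Ud[i], Ub = 0.002)
    for (wh in c("deleterious", "beneficial")) {
      mc <- mc_flux(pg, grid$N[i], wh, n_draws = 1e6)
      ana <- if (wh == "deleterious") deleterious_flux(pg, grid$N[i]) else
        beneficial_flux(pg, grid$N[i])
      expect_lt(abs(ana - mc$value), 3 * mc$se)
    }
  }
})

test_that("flux signs, trivial rates and monotonicity in N", {
  p <- default_params()
  expect_identical(deleterious_flux(model_params(Ud = 0, Ub = 0.002), 500), 0)
  expect_identical(beneficial_flux(model_params(Ud = 2, Ub = 0), 500), 0)
  Ns <- c(100, 500, 2000, 10000, 1e5)
  vd <- vapply(Ns, function(N) deleterious_flux(p, N), 0)
  vb <- vapply(Ns, function(N) beneficial_flux(p, N), 0)
  expect_true(all(vd < 0) && all(vb > 0))
  expect_true(all(diff(abs(vd)) < 0))  # |vd| shrinks with N
  expect_true(all(diff(vb) > 0))       # vb grows with N
})

test_that("net flux composes exactly and changes sign across the root", {
  p <- default_params(delta_env = -1e-6)
  f <- net_flux(p, 1234)
  expect_identical(f$vnet, f$vd + f$vb + p$delta_env)
  p0 <- model_params(Ud = 0, Ub = 0, delta_env = -1e-6)
  expect_equal(net_flux(p0, 100)$vnet, -1e-6)
  pd <- default_params()
  expect_lt(net_flux(pd, 2000)$vnet, 0)
  expect_gt(net_flux(pd, 6000)$vnet, 0)
})

test_that("find_ncrit recovers a constructed root and rejects rootless models", {
  p <- default_params()
  # construct Ub so that vb exactly cancels vd at N = 5000
  vb_unit <- beneficial_flux(model_params(Ud = 2, Ub = 1), 5000)
  ub_star <- abs(deleterious_flux(p, 5000)) / vb_unit
  p_star <- model_params(2, ub_star)
  expect_equal(find_ncrit(p_star), 5000, tolerance = 1e-6)
  # vnet at the root is zero to tight tolerance
  nc <- find_ncrit(p)
  expect_lt(abs(net_flux(p, nc)$vnet), 1e-10)
  # tipping point: vnet strictly increasing around the root
  Ns <- seq(nc / 2, 2 * nc, length.out = 7)
  vn <- vapply(Ns, function(N) net_flux(p, N)$vnet, 0)
  expect_true(all(diff(vn) > 0))
  expect_error(find_ncrit(model_params(2, 0)), "no sign change")
})

test_that("flux derivatives match central differences and ignore delta_env", {
  p <- default_params()
  for (N in c(1000, 3664, 8000)) {
    for (wh in c("deleterious", "beneficial")) {
      ana <- flux_derivative(p, N, wh)
      fd <- if (wh == "deleterious") {
        (deleterious_flux(p, N + 1) - deleterious_flux(p, N - 1)) / 2
      } else {
        (beneficial_flux(p, N + 1) - beneficial_flux(p, N - 1)) / 2
      }
      expect_equal(ana, fd, tolerance = 1e-3)
      expect_gt(ana, 0)
    }
  }
  expect_identical(flux_derivative(model_params(Ud = 0, Ub = 0.002), 100,
                                   "deleterious"), 0)
  p_env <- default_params(delta_env = -1.5e-5)
  expect_identical(flux_derivative(p_env, 3000, "deleterious"),
                   flux_derivative(default_params(), 3000, "deleterious"))
})

test_that("drought:meltdown ratio is invariant to joint Ud, Ub scaling", {
  base <- drought_meltdown_ratio(default_params())
  for (f in c(0.5, 2, 5)) {
    r <- drought_meltdown_ratio(model_params(2 * f, 0.002 * f))
    expect_equal(r$ratio, base$ratio, tolerance = 1e-6)
  }
})

test_that("ratio responds to DFE changes in the expected directions", {
  base_dfe <- dfe_preset("human_nonsynonymous")
  ratio_for <- function(del = base_dfe, sb = 0.001) {
    drought_meltdown_ratio(model_params(2, 0.002, del,
                                        dfe_exponential(sb)))$ratio
  }
  # weaker beneficial effects: ratio decreases
  r_sb <- vapply(c(0.002, 0.001, 0.0005), function(sb) ratio_for(sb = sb), 0)
  expect_true(all(diff(r_sb) < 0))
  # stronger deleterious effects: ratio decreases
  m0 <- dfe_moments(base_dfe)$mean
  r_sd <- vapply(c(0.5, 1, 2), function(f)
    ratio_for(del = dfe_with_mean(base_dfe, f * m0)), 0)
  expect_true(all(diff(r_sd) < 0))
  # more overdispersed deleterious DFE at fixed mean: ratio increases
  r_cv <- vapply(c(1.5, 2.43, 3.5), function(cv)
    ratio_for(del = dfe_with_cv(base_dfe, cv)), 0)
  expect_true(all(diff(r_cv) > 0))
})

test_that("closed-form critical size obeys its algebraic structure", {
  # argument equal to 1 gives exactly 2
  p1 <- model_params(1, 1 / (64 * 1), dfe_with_mean(dfe_gamma(1, 1), -1),
                     dfe_exponential(1))
  expect_equal(whitlock_ncrit(p1), 2, tolerance = 1e-12)
  # cube-root homogeneity: scaling Ud by 8 doubles the result
  p <- default_params()
  p8 <- model_params(16, 0.002)
  expect_equal(whitlock_ncrit(p8), 2 * whitlock_ncrit(p), tolerance = 1e-12)
  expect_error(whitlock_ncrit(model_params(2, 0)), "positive")
})

test_that("environmental rate conversion round-trips", {
  expect_identical(env_rate(1e5), -1e-6)
  expect_equal(env_rate(10^2.5), -10^-3.5)
  d <- -1.5e-5
  expect_equal(env_rate(-0.1 / d), d)
  expect_error(env_rate(0), "positive")
  expect_error(env_rate(-10), "positive")
})

test_that("sweep rows match direct calls and flag rootless combinations", {
  sw <- flux_sweep(Ud = 2, Ub = 0.002)
  expect_equal(nrow(sw), 1)
  expect_equal(sw$ncrit, find_ncrit(default_params()), tolerance = 1e-8)
  expect_equal(sw$ratio, drought_meltdown_ratio(default_params())$ratio,
               tolerance = 1e-6)
  # rootless row carried with a status flag, not dropped
  sw0 <- flux_sweep(Ud = 2, Ub = c(0, 0.002))
  expect_equal(nrow(sw0), 2)
  expect_match(sw0$status[sw0$Ub == 0], "no sign change")
  expect_true(is.na(sw0$ncrit[sw0$Ub == 0]))
  # ratio saturates as beneficial mutations become scarce: successive gaps
  # shrink along the Ud/Ub grid and the curve is flat past Ud/Ub ~ 1000
  sw_r <- flux_sweep(Ud = 2, Ub = 2 / c(10, 100, 300, 1000, 3000))
  gaps <- abs(diff(sw_r$ratio[order(sw_r$Ud / sw_r$Ub)]))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[length(gaps)], 0.01)
  # critical size grows with the rate of environmental decline
  sw_e <- flux_sweep(delta_env = c(0, -5e-6, -1.5e-5))
  expect_true(all(diff(sw_e$ncrit[order(-sw_e$delta_env)]) > 0))
})
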