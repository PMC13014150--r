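test_that("densities integrate to 1 over their signed supports", {
  g <- dfe_preset("human_nonsynonymous")
  e <- dfe_exponential(0.001)
  # piecewise around the integrable gamma singularity at 0
  cuts <- c(0, 1e-6, 1e-4, 1e-2, 1, Inf)
  ig <- sum(vapply(seq_len(length(cuts) - 1), function(k) {
    integrate(function(x) dfe_density(g, -x), cuts[k], cuts[k + 1],
              rel.tol = 1e-9)$value
  }, 0))
  ie <- integrate(function(s) dfe_density(e, s), 0, Inf, rel.tol = 1e-10)
  expect_equal(ig, 1, tolerance = 1e-6)
  expect_equal(ie$value, 1, tolerance = 1e-6)
  # density vanishes off-support
  expect_identical(dfe_density(g, c(0, 0.01)), c(0, 0))
  expect_identical(dfe_density(e, c(0, -0.01)), c(0, 0))
})

test_that("population-scaled rescaling divides the scale by 2Ne exactly", {
  pop <- dfe_pop_gamma(0.169, 1327.4, two_ne = 23646)
  g <- dfe_rescale(pop)
  expect_equal(g$shape, 0.169)
  expect_equal(g$scale, 1327.4 / 23646)
  expect_equal(g$scale, 0.056, tolerance = 0.005)  # the conventional rounding
  # mean of the rescaled DFE: -alpha * beta / 2Ne, about -0.0095
  expect_equal(dfe_moments(g)$mean, -0.169 * 1327.4 / 23646, tolerance = 1e-12)
  expect_equal(dfe_moments(g)$mean, -0.009, tolerance = 0.06)
  # identity case
  id <- dfe_rescale(dfe_pop_gamma(1, 0.37, two_ne = 1))
  expect_equal(id$scale, 0.37)
  expect_error(dfe_pop_gamma(0.169, 1327.4, two_ne = 0), "two_ne")
  expect_error(dfe_pop_gamma(0.169, -1, two_ne = 10), "scale")
})

test_that("moments: gamma cv is 1/sqrt(shape), exponential cv is exactly 1", {
  m <- dfe_moments(dfe_preset("human_nonsynonymous"))
  expect_equal(m$cv, 1 / sqrt(0.169))
  expect_equal(m$cv, 2.4, tolerance = 0.02)   # overdispersed vs exponential
  expect_identical(dfe_moments(dfe_exponential(0.001))$cv, 1)
  # gamma with shape 1 is an exponential: cv 1, mean -scale
  m1 <- dfe_moments(dfe_gamma(1, 0.01))
  expect_equal(m1$mean, -0.01)
  expect_equal(m1$cv, 1)
})

test_that("with_mean moves only the scale and round-trips the mean exactly", {
  g <- dfe_gamma(0.169, 0.056)
  m0 <- dfe_moments(g)$mean
  same <- dfe_with_mean(g, m0)
  expect_equal(same$scale, g$scale)
  doubled <- dfe_with_mean(g, 2 * m0)
  expect_equal(doubled$shape, g$shape)
  expect_equal(doubled$scale, 0.112)
  expect_identical(dfe_moments(doubled)$mean, 2 * m0)
  expect_error(dfe_with_mean(g, 0.01), "negative")
  expect_error(dfe_with_mean(g, 0), "negative")
})

test_that("with_cv preserves the mean bit-for-bit and hits the target cv", {
  g <- dfe_gamma(0.169, 0.056)
  m0 <- dfe_moments(g)$mean
  fixed_point <- dfe_with_cv(g, 1 / sqrt(0.169))
  expect_equal(fixed_point$shape, g$shape, tolerance = 1e-12)
  expect_equal(fixed_point$scale, g$scale, tolerance = 1e-12)
  for (cv in c(0.5, 1, 2, 3.7)) {
    gg <- dfe_with_cv(g, cv)
    mm <- dfe_moments(gg)
    expect_identical(mm$mean, m0)
    expect_equal(mm$cv, cv, tolerance = 1e-12)
  }
  # cv 1 collapses to the exponential-like shape-1 gamma
  g1 <- dfe_with_cv(g, 1)
  expect_equal(g1$shape, 1)
  expect_equal(g1$scale, abs(m0))
  expect_error(dfe_with_cv(g, 0), "new_cv")
})

test_that("sampling has the right sign, mean and distribution", {
  set.seed(42)
  g <- dfe_preset("human_nonsynonymous")
  e <- dfe_exponential(0.001)
  expect_length(dfe_sample(g, 0), 0)
  sg <- dfe_sample(g, 1e6)
  expect_true(all(sg < 0))
  mg <- dfe_moments(g)
  se_g <- mg$cv * abs(mg$mean) / sqrt(1e6)
  expect_lt(abs(mean(sg) - mg$mean), 3 * se_g)
  se <- dfe_sample(e, 1e6)
  expect_true(all(se > 0))
  expect_lt(abs(mean(se) - 0.001), 3 * 0.001 / sqrt(1e6))
  # distributional agreement at n = 1e5
  # shape 0.169 puts enormous mass near 0, where doubles underflow and tie
  ks_g <- suppressWarnings(
    stats::ks.test(-dfe_sample(g, 1e5), stats::pgamma,
                   shape = g$shape, scale = g$scale))
  ks_e <- stats::ks.test(dfe_sample(e, 1e5), stats::pexp, rate = 1000)
  expect_gt(ks_g$p.value, 0.01)
  expect_gt(ks_e$p.value, 0.01)
})

test_that("DFE configs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("family: pop_gamma", "shape: 0.169", "scale: 1327.4",
               "two_ne: 23646"), path)
  d <- read_dfe_config(path)
  expect_s3_class(d, "vf_dfe_pop_gamma")
  expect_equal(dfe_rescale(d)$scale, 1327.4 / 23646)
  path2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("family: exponential", "mean: 0.001"), path2)
  expect_equal(read_dfe_config(path2)$mean, 0.001)
  path3 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("family: nope", path3)
  expect_error(read_dfe_config(path3), "unknown DFE family")
})

test_that("the shipped DFE config files load and match the preset", {
  f <- system.file("extdata", "human_nonsynonymous_dfe.yaml",
                   package = "vortexflux")
  d <- dfe_rescale(read_dfe_config(f))
  ref <- dfe_preset("human_nonsynonymous")
  expect_equal(d$shape, ref$shape)
  expect_equal(d$scale, ref$scale)
  fb <- system.file("extdata", "beneficial_dfe.yaml", package = "vortexflux")
  expect_equal(read_dfe_config(fb)$mean, 0.001)
})
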