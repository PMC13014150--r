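arch_small <- genome_architecture(4, 25, 2)

test_that("a fresh population is clonal with unit fitness", {
  set.seed(1)
  pop <- init_population(sim_config(10, model_params(), arch_small,
                                    generations = 10))
  expect_equal(pop$state$fitness, rep(1, 10))
  expect_equal(dim(pop$state$loads), c(2 * 4 * 25, 10))
  expect_true(all(pop$state$loads == 1))
  # default architecture: 2 x 23 x 100 block copies per individual
  pop2 <- init_population(sim_config(5, model_params(), generations = 10))
  expect_equal(nrow(pop2$state$loads), 2 * 23 * 100)
})

test_that("gametes recombine at exactly the configured number of hotspots", {
  set.seed(2)
  B <- 4 * 25
  # heterozygous at every block: haplotype identity is readable from loads
  parent <- cbind(rep(1, B), rep(2, B))
  g <- make_gamete(parent, arch_small)
  expect_equal(g$loads, ifelse(g$source == 0, 1, 2))
  # per chromosome: exactly 2 crossovers means exactly 2 switch points
  for (c_ in 1:4) {
    src <- g$source[((c_ - 1) * 25 + 1):(c_ * 25)]
    expect_equal(sum(diff(src) != 0), 2)
  }
  # zero crossovers: each chromosome is a single unrecombined haplotype
  arch0 <- genome_architecture(4, 25, 0)
  g0 <- make_gamete(parent, arch0)
  for (c_ in 1:4) {
    src <- g0$source[((c_ - 1) * 25 + 1):(c_ * 25)]
    expect_equal(length(unique(src)), 1)
  }
  # homozygous parent: gamete equals the haplotype regardless of crossovers
  hom <- cbind(seq_len(B), seq_len(B))
  expect_equal(make_gamete(hom, arch_small)$loads, as.numeric(seq_len(B)))
})

test_that("each block copy is inherited with frequency 1/2", {
  set.seed(3)
  B <- 4 * 25
  parent <- cbind(rep(1, B), rep(2, B))
  n <- 2e4
  counts <- numeric(B)
  for (i in seq_len(n)) {
    counts <- counts + (make_gamete(parent, arch_small)$source == 0)
  }
  freq <- counts / n
  se <- sqrt(0.25 / n)
  expect_true(all(abs(freq - 0.5) < 3 * se + 1e-9))
})

test_that("offspring mutation counts are Poisson with the configured means", {
  set.seed(4)
  p <- model_params(Ud = 2, Ub = 0.5)
  B <- 4 * 25
  genome <- cbind(rep(1, B), rep(1, B))
  n <- 2e4
  nd <- nb <- numeric(n)
  for (i in seq_len(n)) {
    m <- mutate_offspring(genome, p)$mutations
    nd[i] <- sum(m$type == 0)
    nb[i] <- sum(m$type == 1)
  }
  expect_lt(abs(mean(nd) - 2), 3 * sqrt(2 / n))
  expect_lt(abs(mean(nb) - 0.5), 3 * sqrt(0.5 / n))
  # no mutation pressure leaves the genome untouched
  m0 <- mutate_offspring(genome, model_params(Ud = 0, Ub = 0))
  expect_identical(m0$loads, genome)
  expect_equal(nrow(m0$mutations), 0)
})

test_that("mutations multiply block loads and lethals zero them", {
  set.seed(5)
  p <- model_params(Ud = 5, Ub = 1)
  B <- 4 * 25
  genome <- cbind(rep(1, B), rep(1, B))
  res <- mutate_offspring(genome, p)
  m <- res$mutations
  expected <- genome
  for (i in seq_len(nrow(m))) {
    b <- m$block[i] + 1; h <- m$hap[i] + 1
    f <- 1 + m$s[i]
    expected[b, h] <- if (f <= 0) 0 else expected[b, h] * f
  }
  expect_equal(res$loads, expected, tolerance = 1e-12)
})

test_that("an individual with a lethal load is never chosen as parent", {
  set.seed(6)
  cfg <- sim_config(2, model_params(Ud = 0, Ub = 0), arch_small,
                    generations = 25, ledger = TRUE)
  pop <- init_population(cfg)
  # drop a lethal (s = -1) onto one haplotype of individual 1
  vortexflux:::cpp_sim_inject(pop$handle, -1, 0L, 0L, 0L, 0L)
  st <- vortexflux:::cpp_sim_state(pop$handle)
  expect_equal(sort(st$fitness), c(0, 1))
  advance_generations(pop, 25)
  st2 <- vortexflux:::cpp_sim_state(pop$handle)
  # the lethal lineage cannot reproduce, so the population purges it
  expect_equal(st2$fitness, c(1, 1))
  expect_true(all(st2$loads == 1))
})

test_that("runs are reproducible from the seed and neutral runs are flat", {
  p0 <- model_params(Ud = 0.2, Ub = 0.0002)
  r1 <- sim_run(sim_config(40, p0, arch_small, generations = 400, seed = 99))
  r2 <- sim_run(sim_config(40, p0, arch_small, generations = 400, seed = 99))
  expect_identical(r1$vnet, r2$vnet)
  expect_identical(r1$trajectory, r2$trajectory)
  # no mutations: fitness stays exactly 1, vnet exactly 0
  r0 <- sim_run(sim_config(20, model_params(Ud = 0, Ub = 0), arch_small,
                           generations = 400, seed = 7))
  expect_true(all(r0$trajectory$mean_fitness == 1))
  expect_identical(r0$vnet, 0)
})

test_that("maintained fitness equals the product of block loads", {
  set.seed(8)
  run <- sim_run(sim_config(30, model_params(Ud = 1, Ub = 0.01), arch_small,
                            generations = 300))
  st <- population_state(run)
  recomputed <- apply(st$loads, 2, prod)
  expect_equal(recomputed, st$fitness, tolerance = 1e-9)
})

test_that("mean fitness only degrades without beneficial mutations", {
  set.seed(9)
  # one-sided trend on replicate means over a long horizon
  finals <- vapply(1:5, function(i) {
    r <- sim_run(sim_config(30, model_params(Ud = 0.5, Ub = 0), arch_small,
                            generations = 1500))
    mean(tail(r$trajectory$mean_fitness, 100))
  }, 0)
  starts <- 1  # clonal start
  expect_true(all(finals < starts))
})

test_that("burn-in detection applies the windowed slope rule", {
  N <- 100
  thr <- 0.07 / N
  # flat series: criterion met at the first eligible window
  flat <- rep(0.01, 400)
  expect_equal(detect_burn_in(flat, N), 200 + 100)
  # rising at twice the threshold: never met
  rising <- (1:400) * 2 * thr
  expect_warning(bi <- detect_burn_in(rising, N), "never met")
  expect_true(is.na(bi))
  # piecewise: steep for 300 generations, then nearly flat; the hand OLS
  # oracle locates the first window whose slope drops below threshold
  y <- c((1:300) * 0.2 / N, 300 * 0.2 / N + (1:300) * 0.01 / N)
  slopes <- vapply(200:600, function(g) ols_slope(y[(g - 199):g]), 0)
  first <- (200:600)[which(slopes < thr)[1]]
  expect_equal(detect_burn_in(y, N), first + 100)
  expect_gt(first, 300)  # only after the flat regime dominates the window
  expect_error(detect_burn_in(rep(0, 100), N), "at least")
})

test_that("vnet estimation is exact on a synthetic log-linear trajectory", {
  g <- 1:500
  traj <- data.frame(generation = g, mean_fitness = exp(0.2 - 3e-4 * g))
  expect_equal(estimate_vnet(traj, 100), -3e-4, tolerance = 1e-12)
  const <- data.frame(generation = g, mean_fitness = rep(0.5, 500))
  expect_equal(estimate_vnet(const, 100), 0)
  bad <- data.frame(generation = 1:10, mean_fitness = c(rep(1, 9), 0))
  expect_error(estimate_vnet(bad, 0), "log flux undefined")
  expect_error(estimate_vnet(traj, 499), "at least 2")
})

test_that("neutral markers fix at close to the injected frequency 1/(2N)", {
  set.seed(10)
  # fast pilot at modest replication; the full 1e4-replicate version runs in
  # the acceptance suite
  fx <- neutral_fixation_trials(600, N = 10, max_generations = 1500)
  bt <- stats::binom.test(sum(fx), length(fx), p = 1 / 20)
  expect_gt(bt$p.value, 1e-3)
})
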