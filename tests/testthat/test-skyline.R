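test_that("coalescent density matches the n = 2 closed form", {
  for (tt in c(200, 5000, 20000)) {
    for (N in c(1000, 8000)) {
      gen <- list(tree = ape::read.tree(
        text = sprintf("(a:%f,b:%f);", tt, tt)),
        tip_times = c(a = 0, b = 0))
      expect_equal(coalescent_loglik(gen, N), -tt / N - log(N),
                   tolerance = 1e-12)
    }
  }
})

test_that("coalescent density matches direct interval computation", {
  # 5 heterochronous tips; oracle enumerates intervals explicitly from
  # the sorted event list, independently of the package routine
  gen <- simulate_genealogy(demographic_scenario(
    sizes = 4000,
    samples = data.frame(time = c(0, 0, 0, 1500, 3000), n = 1)),
    seed = 19)
  theta <- c(3000, 9000)
  gs <- c(2L, 2L)
  ours <- coalescent_loglik(gen, theta, gs)
  tips <- sort(unname(gen$tip_times))
  coal <- sort(gen$node_times[6:9])
  events <- rbind(data.frame(t = tips, type = "s"),
                  data.frame(t = coal, type = "c"))
  events <- events[order(events$t, events$type, method = "radix",
                         decreasing = c(FALSE, TRUE)), ]
  k <- 0; tcur <- events$t[1]; ic <- 0; oracle <- 0
  for (r in seq_len(nrow(events))) {
    th <- theta[if (ic < 2) 1 else 2]
    oracle <- oracle - k * (k - 1) / 2 * (events$t[r] - tcur) / th
    tcur <- events$t[r]
    if (events$type[r] == "s") k <- k + 1
    else { oracle <- oracle - log(th); k <- k - 1; ic <- ic + 1 }
  }
  expect_equal(ours, oracle, tolerance = 1e-10)
})

test_that("doubling all population sizes obeys the closed-form shift", {
  gen <- simulate_genealogy(demographic_scenario(
    sizes = 5000, samples = data.frame(time = 0, n = 6)), seed = 23)
  N <- 4000
  l1 <- coalescent_loglik(gen, N)
  l2 <- coalescent_loglik(gen, 2 * N)
  # log f(2N) - log f(N) = -(n-1) log 2 + A/(2N), A = sum k(k-1)/2 dt
  ct <- sort(gen$node_times[7:11])
  times <- c(0, ct); A <- 0; k <- 6
  for (i in seq_len(5)) { A <- A + k * (k - 1) / 2 * (ct[i] - times[i])
    k <- k - 1 }
  expect_equal(l2 - l1, -5 * log(2) + A / (2 * N), tolerance = 1e-10)
})

test_that("a coalescence below a descendant tip date is an error", {
  # consistent branch lengths that still place the node below tip b
  tr <- ape::read.tree(text = "(a:1000,b:-1000);")
  gen <- list(tree = tr, tip_times = c(a = 0, b = 2000))
  expect_error(coalescent_loglik(gen, 1000), "descendant tip")
  # inconsistent branch lengths are caught too
  tr2 <- ape::read.tree(text = "(a:100,b:2100);")
  gen2 <- list(tree = tr2, tip_times = c(a = 0, b = 2000))
  expect_error(coalescent_loglik(gen2, 1000), "inconsistent")
})

test_that("identical seeds reproduce chains bit-identically", {
  scen <- demographic_scenario(sizes = 4000,
                               samples = data.frame(time = 0, n = 8))
  gen <- simulate_genealogy(scen, seed = 2)
  aln <- simulate_sequences(gen, 410, rate = 1e-6, kappa = 8, seed = 3)
  hs <- heterochronous_sample(aln)
  f1 <- run_mcmc(hs, chain_length = 2e4, thin = 100, seed = 11,
                 rate = 1e-6, ncat = 1, m_groups = 2)
  f2 <- run_mcmc(hs, chain_length = 2e4, thin = 100, seed = 11,
                 rate = 1e-6, ncat = 1, m_groups = 2)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$coal_times, f2$coal_times)
  expect_identical(f1$scalars, f2$scalars)
  f3 <- run_mcmc(hs, chain_length = 2e4, thin = 100, seed = 12,
                 rate = 1e-6, ncat = 1, m_groups = 2)
  expect_false(identical(f1$theta, f3$theta))
})

test_that("the sampler reproduces the analytic conjugate-style posterior", {
  # fixed genealogy, single group, no data: theta | genealogy is
  # inverse-gamma(n-1, A) under the 1/theta prior
  scen <- demographic_scenario(sizes = 5000,
                               samples = data.frame(time = 0, n = 8))
  gen <- simulate_genealogy(scen, seed = 3)
  aln <- simulate_sequences(gen, 410, rate = 3e-7, kappa = 10, seed = 2)
  hs <- heterochronous_sample(aln)
  fit <- run_mcmc(hs, chain_length = 4e5, thin = 100, m_groups = 1,
                  seed = 5, rate = 3e-7, ncat = 1, use_data = FALSE,
                  estimate_topology = FALSE, estimate_times = FALSE,
                  init_genealogy = gen, init = list(theta = 3000))
  th <- fit$theta[fit$keep, 1]
  ct <- sort(gen$node_times[9:15])
  times <- c(0, ct); A <- 0; k <- 8
  for (i in seq_len(7)) { A <- A + k * (k - 1) / 2 * (ct[i] - times[i])
    k <- k - 1 }
  expect_equal(mean(th), A / 6, tolerance = 0.05)
  expect_equal(unname(quantile(th, c(.25, .5, .75))),
               A / qgamma(c(.75, .5, .25), shape = 7), tolerance = 0.08)
})

test_that("prior sampling matches Kingman coalescent expectations", {
  scen <- demographic_scenario(sizes = 5000,
                               samples = data.frame(time = 0, n = 8))
  gen <- simulate_genealogy(scen, seed = 1)
  aln <- simulate_sequences(gen, 410, rate = 3e-7, kappa = 10, seed = 2)
  hs <- heterochronous_sample(aln)
  fit <- run_mcmc(hs, chain_length = 1e6, thin = 200, m_groups = 1,
                  seed = 17, rate = 3e-7, ncat = 1, use_data = FALSE,
                  priors = list(theta_lo = 4999.999, theta_hi = 5000.001),
                  init = list(theta = 5000))
  k <- fit$keep
  # E[first coalescence] = theta/(8*7/2); E[TMRCA] = 2 theta (1 - 1/8)
  expect_equal(mean(fit$coal_times[k, 1]), 5000 / 28, tolerance = 0.1)
  expect_equal(mean(fit$coal_times[k, 7]), 8750, tolerance = 0.1)
})

test_that("rate transfer carries the ancient posterior median across", {
  scen <- demographic_scenario(sizes = 5000, samples = data.frame(
    time = c(rep(0, 6), seq(2000, 12000, length.out = 6)), n = 1))
  gen <- simulate_genealogy(scen, seed = 31)
  aln <- simulate_sequences(gen, 410, rate = 1e-6, kappa = 8, seed = 32)
  hs <- heterochronous_sample(aln, tip_dates = gen$tip_times)
  fit <- run_mcmc(hs, chain_length = 1e5, thin = 100, seed = 41,
                  ncat = 1, m_groups = 1)
  tx <- transfer_rate(fit)
  expect_equal(tx$rate, median(fit$scalars$rate[fit$keep]))
  # a fixed-rate run has nothing to transfer
  fitf <- run_mcmc(hs, chain_length = 2e4, thin = 100, seed = 42,
                   ncat = 1, m_groups = 1, rate = 1e-6)
  expect_error(transfer_rate(fitf), "fixed rate")
  # contemporaneous data cannot estimate a rate at all
  aln0 <- aln; rownames(aln0) <- rownames(aln)
  hs0 <- heterochronous_sample(aln0)
  expect_error(run_mcmc(hs0, chain_length = 2e4, thin = 100, seed = 43,
                        ncat = 1), "distinct tip dates")
})

test_that("trajectory summaries honour degenerate posteriors and grids", {
  fake <- structure(list(
    theta = matrix(rep(c(1000, 5000), each = 200), 200, 2),
    coal_times = matrix(rep(seq(100, 700, length.out = 7), each = 200),
                        200, 7),
    keep = 1:200, group_sizes = c(4L, 3L)), class = "skyline_fit")
  traj <- summarize_trajectory(fake, grid = c(0, 200, 500, 650))
  expect_identical(traj$median, traj$lower95)
  expect_identical(traj$median, traj$upper95)
  # boundary between groups is the 4th coalescent time (400)
  expect_equal(traj$median, c(1000, 1000, 5000, 5000))
  expect_warning(summarize_trajectory(fake, grid = c(800, 900)),
                 "beyond")
  expect_error(summarize_trajectory(fake, grid = c(3, 2, 1)),
               "increasing")
})

test_that("a two-phase expansion is visible in the trajectory", {
  scen <- demographic_scenario(breakpoints = 650,
                               sizes = c(50000, 5000),
                               samples = data.frame(time = 0, n = 20))
  gen <- simulate_genealogy(scen, seed = 21)
  aln <- simulate_sequences(gen, 410, rate = 1e-6, kappa = 10, seed = 22)
  hs <- heterochronous_sample(aln)
  fit <- run_mcmc(hs, chain_length = 5e5, thin = 250, seed = 5,
                  m_groups = 3, rate = 1e-6, ncat = 1)
  traj <- summarize_trajectory(fit, grid = seq(0, 3000, by = 150))
  # the recent (expanded) end exceeds the ancient end
  expect_gt(traj$median[1], traj$median[nrow(traj)])
  # posterior of the fold change between endpoints covers the truth (10x)
  k <- fit$keep
  ratio <- fit$theta[k, 1] / fit$theta[k, 3]
  hpd <- hpd_interval(ratio)
  expect_true(hpd[1] <= 10 && 10 <= hpd[2])
})

test_that("HPD intervals are shortest intervals at the requested mass", {
  set.seed(77)
  x <- rexp(4000)
  h <- hpd_interval(x, 0.9)
  expect_equal(h[1], min(x), tolerance = 0.05)
  expect_lt(h[2], quantile(x, 0.97))
  expect_gte(mean(x >= h[1] & x <= h[2]), 0.9 - 1e-9)
})
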