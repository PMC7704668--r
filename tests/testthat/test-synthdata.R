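test_that("scenario validation rejects inconsistent inputs", {
  expect_error(demographic_scenario(breakpoints = c(10, 5),
                                    sizes = c(1, 2, 3)), "increasing")
  expect_error(demographic_scenario(sizes = c(1, 2)), "one size per")
  expect_error(demographic_scenario(sizes = -5), "positive")
  expect_error(demographic_scenario(
    sizes = 100, samples = data.frame(time = 0, n = 1)), "2 tips")
})

test_that("pairwise TMRCA matches the Kingman expectation", {
  scen <- demographic_scenario(sizes = 1000,
                               samples = data.frame(time = 0, n = 2))
  set.seed(101)
  tm <- vapply(1:10000, function(i) {
    g <- simulate_genealogy(scen)
    max(g$node_times)
  }, numeric(1))
  # Exp(mean 1000): se of the mean over 10k replicates
  se <- 1000 / sqrt(10000)
  expect_lt(abs(mean(tm) - 1000), 3 * se)
})

test_that("total branch length matches the closed form for n = 10", {
  scen <- demographic_scenario(sizes = 2000,
                               samples = data.frame(time = 0, n = 10))
  set.seed(102)
  tot <- vapply(1:1000, function(i) {
    g <- simulate_genealogy(scen)
    sum(g$tree$edge.length)
  }, numeric(1))
  expected <- 2 * 2000 * sum(1 / (1:9))
  se <- sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - expected), 3.5 * se)
})

test_that("serially sampled tips constrain the TMRCA", {
  scen <- demographic_scenario(sizes = 500, samples = data.frame(
    time = c(0, 500), n = 1))
  for (i in 1:50) {
    g <- simulate_genealogy(scen, seed = 500 + i)
    expect_gte(max(g$node_times), 500)
    expect_equal(sort(unname(g$tip_times)), c(0, 500))
  }
})

test_that("rate zero reproduces the root sequence at every tip", {
  scen <- demographic_scenario(sizes = 1000,
                               samples = data.frame(time = 0, n = 5))
  g <- simulate_genealogy(scen, seed = 9)
  aln <- simulate_sequences(g, 100, rate = 0, seed = 10)
  expect_equal(nrow(unique(aln)), 1L)
})

test_that("segregating sites match the Watterson expectation", {
  n <- 10; theta <- 3000; r <- 1e-6; L <- 410
  scen <- demographic_scenario(sizes = theta,
                               samples = data.frame(time = 0, n = n))
  set.seed(103)
  S <- vapply(1:1000, function(i) {
    g <- simulate_genealogy(scen)
    aln <- simulate_sequences(g, L, rate = r)
    sum(apply(aln, 2, function(col) length(unique(col)) > 1))
  }, numeric(1))
  expected <- 2 * theta * r * L * sum(1 / (1:(n - 1)))
  se <- sd(S) / sqrt(length(S))
  # finite-sites recurrent mutation slightly deflates S; allow 3 SD + 2%
  expect_lt(abs(mean(S) - expected), 3 * se + 0.02 * expected)
})

test_that("long simulations reach the HKY stationary composition", {
  pi <- c(.35, .25, .15, .25)
  tr <- ape::read.tree(text = "(a:0.5,b:0.5);")
  aln <- simulate_sequences(tr, 60000, rate = 1, kappa = 7, pi = pi,
                            seed = 104)
  obs <- table(factor(aln, levels = c("A", "C", "G", "T"))) /
    length(aln)
  expect_lt(max(abs(as.numeric(obs) - pi)), 0.01)
})

test_that("panel truth records drive exact downstream recovery", {
  spec <- list(motifs = data.frame(
    name = c("root", "S"), parent = c("-", "root"),
    variants = c("", "500,600,700")),
    leaves_per_clade = c(S = 8, root = 2), n_private = 0,
    positions = c(1000, 16000))
  pan <- simulate_panel(spec, seed = 71)
  # zero private mutations: clade leaves identical, collapse to one
  hap <- collapse_haplotypes(pan$profiles)
  expect_equal(max(hap$size), 8L)
  spec$n_private <- 2
  pan2 <- simulate_panel(spec, seed = 72)
  mat <- build_tree(pan2$profiles, outgroup = "root_1")
  clade <- grep("^S_", mat$tree$tip.label, value = TRUE)
  expect_identical(find_clade_motif(mat, clade), c("500", "600", "700"))
})

test_that("coding panels carry consistent truth and codon structure", {
  tr <- clock_test_tree()
  sim <- simulate_coding_panel(tr, rates = c(4e-9, 2e-9, 2e-8),
                               n_genes = 5, codons_per_gene = 100,
                               seed = 61)
  expect_equal(ncol(sim$partition$aln), 1500L)
  expect_equal(sim$partition$codon_pos[1:6], c(1, 2, 3, 1, 2, 3))
  expect_equal(sum(sim$partition$complemented), 300L)
  expect_equal(unname(sim$truth$ages[1]), 335000)
  # a zero-rate partition contributes no variable sites
  sim0 <- simulate_coding_panel(tr, rates = c(0, 2e-9, 2e-8),
                                n_genes = 3, codons_per_gene = 50,
                                seed = 62)
  p1 <- sim0$partition$aln[, sim0$partition$codon_pos == 1, drop = FALSE]
  expect_equal(nrow(unique(p1)), 1L)
  # third positions fastest: most variable sites at position 3
  p3 <- sim$partition$aln[, sim$partition$codon_pos == 3, drop = FALSE]
  var3 <- sum(apply(p3, 2, function(c) length(unique(c)) > 1))
  p2 <- sim$partition$aln[, sim$partition$codon_pos == 2, drop = FALSE]
  var2 <- sum(apply(p2, 2, function(c) length(unique(c)) > 1))
  expect_gt(var3, var2)
})

test_that("generators are seed-reproducible", {
  scen <- demographic_scenario(sizes = 1000,
                               samples = data.frame(time = 0, n = 6))
  g1 <- simulate_genealogy(scen, seed = 5)
  g2 <- simulate_genealogy(scen, seed = 5)
  expect_identical(g1$node_times, g2$node_times)
  a1 <- simulate_sequences(g1, 200, rate = 1e-6, seed = 6)
  a2 <- simulate_sequences(g2, 200, rate = 1e-6, seed = 6)
  expect_identical(a1, a2)
  p1 <- simulate_panel(list(motifs = data.frame(
    name = c("root", "A"), parent = c("-", "root"), variants = c("", "9")),
    leaves_per_clade = c(A = 3, root = 1)), seed = 7)
  p2 <- simulate_panel(list(motifs = data.frame(
    name = c("root", "A"), parent = c("-", "root"), variants = c("", "9")),
    leaves_per_clade = c(A = 3, root = 1)), seed = 7)
  expect_identical(lapply(p1$profiles, function(p) p$variants$label),
                   lapply(p2$profiles, function(p) p$variants$label))
})
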