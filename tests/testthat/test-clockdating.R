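test_that("partition building extracts, complements and maps genes", {
  # two genes: G1 on H (9 bp), G2 on L (6 bp)
  g1 <- "ATGAAACCC"; g2 <- "GGATTT"
  annot <- data.frame(gene = c("G1", "G2"), start = c(1, 10),
                      end = c(9, 15), strand = c("H", "L"))
  recs <- mito_records("r1", paste0(g1, g2))
  part <- build_partition(recs, annot, check_stops = FALSE)
  expect_equal(paste(part$aln[1, 1:9], collapse = ""), g1)
  expect_equal(paste(part$aln[1, 10:15], collapse = ""), revcomp(g2))
  expect_equal(part$codon_pos, c(rep(1:3, 3), rep(1:3, 2)))
  expect_identical(part$complemented, c(rep(FALSE, 9), rep(TRUE, 6)))

  expect_identical(revcomp(revcomp("ACGTRY")), "ACGTRY")

  bad <- data.frame(gene = "G1", start = 1, end = 8, strand = "H")
  expect_error(build_partition(recs, bad), "divisible by 3")
})

test_that("premature stop codons trigger a mis-annotation warning", {
  seqs <- paste(rep("TAA", 20), collapse = "")
  recs <- mito_records("r1", seqs)
  annot <- data.frame(gene = "G1", start = 1, end = 60, strand = "H")
  expect_warning(build_partition(recs, annot), "stop codons")
})

test_that("pruning likelihood matches the JC closed form", {
  # single site, two identical leaves, total path t
  for (t in c(0.05, 0.3, 1.2)) {
    tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", t / 2, t / 2))
    aln <- matrix(c("A", "A"), 2, 1, dimnames = list(c("a", "b"), NULL))
    ll <- pruning_loglik(aln, tr, "JC")
    expect_equal(ll, log((1 / 16) * (1 + 3 * exp(-4 * t / 3))),
                 tolerance = 1e-12)
  }
})

test_that("pruning equals brute-force enumeration over internal states", {
  brute <- function(aln, tree, kappa, pi, rates, rw) {
    tr <- ape::reorder.phylo(tree, "postorder")
    bases <- c("A", "C", "G", "T")
    m <- aln[tr$tip.label, , drop = FALSE]
    nn <- tr$Nnode
    root <- tr$edge[nrow(tr$edge), 1]
    total <- 0
    for (s in seq_len(ncol(m))) {
      states <- match(m[, s], bases)
      lik <- 0
      for (c in seq_along(rates)) {
        P <- lapply(seq_len(nrow(tr$edge)), function(e)
          mitohap:::hky_pmat(tr$edge.length[e] * rates[c], kappa, pi))
        grid <- as.matrix(expand.grid(rep(list(1:4), nn)))
        likc <- 0
        for (g in seq_len(nrow(grid))) {
          asg <- c(states, grid[g, ])
          pr <- pi[asg[root]]
          for (e in seq_len(nrow(tr$edge)))
            pr <- pr * P[[e]][asg[tr$edge[e, 1]], asg[tr$edge[e, 2]]]
          likc <- likc + pr
        }
        lik <- lik + rw[c] * likc
      }
      total <- total + log(lik)
    }
    total
  }
  set.seed(6)
  for (i in 1:4) {
    n <- sample(3:5, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- runif(nrow(tr$edge), 0.01, 0.5)
    pi <- c(.3, .25, .15, .3)
    aln <- simulate_sequences(tr, 12, rate = 1, kappa = 3, pi = pi,
                              seed = 700 + i)
    ll <- pruning_loglik(aln, tr, "HKY", kappa = 3, pi = pi)
    bb <- brute(aln, tr, 3, pi, 1, 1)
    expect_equal(ll, bb, tolerance = 1e-10)
    # with +G mixture as well
    mix <- mitohap:::rate_mixture(0, 0.7, 4)
    llg <- pruning_loglik(aln, tr, "HKY+G", kappa = 3, pi = pi,
                          alpha = 0.7)
    bbg <- brute(aln, tr, 3, pi, mix$rates, mix$weights)
    expect_equal(llg, bbg, tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to re-rooting (pulley principle)", {
  set.seed(14)
  tr <- ape::rtree(6)
  tr$edge.length <- runif(nrow(tr$edge), 0.02, 0.3)
  pi <- c(.28, .22, .22, .28)
  aln <- simulate_sequences(tr, 200, rate = 1, kappa = 5, pi = pi,
                            seed = 15)
  ll1 <- pruning_loglik(aln, tr, "HKY", kappa = 5, pi = pi)
  for (og in c("t1", "t3")) {
    tr2 <- ape::root(ape::unroot(tr), outgroup = og, resolve.root = TRUE)
    ll2 <- pruning_loglik(aln, tr2, "HKY", kappa = 5, pi = pi)
    expect_equal(ll1, ll2, tolerance = 1e-9)
  }
})

test_that("HKY transition matrices are valid and time-reversible", {
  pi <- c(.31, .24, .17, .28)
  for (t in c(0.01, 0.2, 2)) {
    P <- mitohap:::hky_pmat(t, kappa = 6, pi = pi)
    expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-12)
    expect_equal(pi * P, t(pi * P), tolerance = 1e-12)  # detailed balance
  }
  # C++ and R implementations agree (cross-check of both)
  aln <- matrix(c("A", "G"), 2, 1, dimnames = list(c("a", "b"), NULL))
  tr <- ape::read.tree(text = "(a:0.1,b:0.1);")
  ll <- pruning_loglik(aln, tr, "HKY", kappa = 6, pi = pi)
  P <- mitohap:::hky_pmat(0.2, 6, pi)
  expect_equal(ll, log(pi[1] * P[1, 3]), tolerance = 1e-12)
})

test_that("zero divergence dates an MRCA at (numerically) zero", {
  tr <- ape::read.tree(text =
    "((a:1000,b:1000):334000,(c:300000,d:300000):35000);")
  sim <- simulate_coding_panel(tr, rates = c(1e-8, 5e-9, 5e-8),
                               seed = 4, n_genes = 4,
                               codons_per_gene = 300)
  # overwrite a and b with identical sequences
  sim$partition$aln["b", ] <- sim$partition$aln["a", ]
  fit <- fit_global_clock(tr, sim$partition,
                          calibration = list(tips = c("a", "c"),
                                             age = 335000),
                          n_boot = 0, n_starts = 1, seed = 2)
  expect_lt(node_age(fit, c("a", "b"))$age, 0.01 * 335000)
})

test_that("no variable sites is a non-identifiability error", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:2,d:2):0);")
  aln <- matrix("A", 4, 30, dimnames = list(c("a", "b", "c", "d"), NULL))
  part <- structure(list(aln = aln, codon_pos = rep(1:3, 10),
                         gene = rep("G1", 30),
                         complemented = rep(FALSE, 30)),
                    class = "codon_partition_alignment")
  expect_error(fit_global_clock(tr, part,
                                calibration = list(tips = c("a", "c"),
                                                   age = 1000),
                                n_boot = 0, seed = 1),
               "identifiable")
})

test_that("dated trees are ultrametric and scale with the calibration", {
  tr <- clock_test_tree()
  sim <- simulate_coding_panel(tr, rates = c(8e-9, 4e-9, 4e-8),
                               kappa = 20, seed = 12)
  fit1 <- fit_global_clock(tr, sim$partition,
                           calibration = list(tips = c("i1", "p1"),
                                              age = 335000),
                           n_boot = 0, n_starts = 1, seed = 5)
  # ultrametric: root-to-tip path lengths all equal
  depths <- ape::node.depth.edgelength(fit1$tree)
  tipd <- depths[seq_along(fit1$tree$tip.label)]
  expect_lt(diff(range(tipd)) / max(tipd), 1e-6)

  fit2 <- fit_global_clock(tr, sim$partition,
                           calibration = list(tips = c("i1", "p1"),
                                              age = 2 * 335000),
                           n_boot = 0, n_starts = 1, seed = 5)
  expect_equal(unname(fit2$ages) / unname(fit1$ages),
               rep(2, length(fit1$ages)), tolerance = 1e-2)
  expect_equal(fit2$rates / fit1$rates, rep(0.5, 3), tolerance = 1e-2)
})

test_that("whole-codon and third-only dating agree on the same data", {
  tr <- clock_test_tree()
  sim <- simulate_coding_panel(tr, rates = c(8e-9, 4e-9, 4e-8),
                               kappa = 20, seed = 30)
  cal <- list(tips = c("i1", "p1"), age = 335000)
  fw <- fit_global_clock(tr, sim$partition, cal, mode = "whole",
                         n_boot = 25, n_starts = 1, seed = 6)
  ft <- fit_global_clock(tr, sim$partition, cal, mode = "third_only",
                         n_boot = 25, n_starts = 1, seed = 7)
  tab <- age_table(list(whole = fw, third = ft),
                   clades = list(P = c("p0", "p1", "p2"),
                                 P1a = c("p1", "p2"),
                                 taurus = c("t1", "t2", "p1")))
  expect_equal(nrow(tab), 3L)
  # two modes agree within a joint 2-SE band
  for (i in seq_len(nrow(tab))) {
    se <- sqrt(tab$whole_se[i]^2 + tab$third_se[i]^2)
    expect_lt(abs(tab$whole_age[i] - tab$third_age[i]), 2.5 * se + 1)
  }
})

test_that("dropping ancient tips removes them from the dated tree", {
  tr <- clock_test_tree()
  sim <- simulate_coding_panel(tr, rates = c(8e-9, 4e-9, 4e-8),
                               seed = 44)
  fit <- fit_global_clock(tr, sim$partition,
                          calibration = list(tips = c("i1", "p1"),
                                             age = 335000),
                          include_aurochs = FALSE,
                          ancient_ids = c("p0"),
                          n_boot = 0, n_starts = 1, seed = 8)
  expect_false("p0" %in% fit$tree$tip.label)
  expect_identical(fit$aurochs, "excluded")
})
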