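test_that("fitch_score counts differences on trivial trees", {
  p1 <- variant_profile("a", c("10", "20", "30"))
  p2 <- variant_profile("b", character())
  tr <- ape::read.tree(text = "(a,b);")
  expect_equal(fitch_score(tr, list(p1, p2)), 3)
  expect_error(fitch_score(ape::read.tree(text = "(a,zz);"),
                           list(p1, p2)), "zz")
})

test_that("homoplasy-free characters give the same length on any topology", {
  # private (singleton) variants are homoplasy-free on every topology
  profs <- list(variant_profile("a", c("1", "2")),
                variant_profile("b", c("3")),
                variant_profile("c", c("9")),
                variant_profile("d", character()))
  topos <- c("((a,b),(c,d));", "((a,c),(b,d));", "((a,d),(b,c));")
  scores <- vapply(topos, function(tx)
    fitch_score(ape::read.tree(text = tx), profs), numeric(1))
  expect_equal(unname(scores), rep(4, 3))
})

test_that("a planted recurrence costs exactly one extra step", {
  # same variant on two leaves that share nothing else
  profs <- list(variant_profile("a", c("1", "2", "99")),
                variant_profile("b", c("1", "2")),
                variant_profile("c", c("5", "99")),
                variant_profile("d", c("5")))
  ch <- mitohap:::profiles_to_characters(profs)
  res <- mitohap:::.exhaustive_parsimony(ch$states, rep(1, ncol(ch$states)))
  # distinct variants: 1,2,5,99 -> 4; the recurrence of 99 adds one step
  expect_equal(res$score, 5)
})

test_that("fitch_score agrees with phangorn on random instances", {
  skip_if_not_installed("phangorn")
  set.seed(5)
  for (i in 1:10) {
    profs <- random_profile_set(6, n_pool = 10, seed = 300 + i)
    tr <- ape::rtree(6, tip.label = paste0("s", 1:6))
    ours <- fitch_score(tr, profs)
    ch <- mitohap:::profiles_to_characters(profs)
    dat <- t(apply(ch$states, 1, function(r) c("0", "1")[r]))
    pd <- phangorn::phyDat(dat, type = "USER", levels = c("0", "1"))
    expect_equal(ours, phangorn::parsimony(tr, pd))
  }
})

test_that("branch-and-bound equals exhaustive search on random instances", {
  for (i in 1:15) {
    k <- sample(4:7, 1)
    profs <- random_profile_set(k, n_pool = 10, seed = 400 + i)
    ch <- mitohap:::profiles_to_characters(profs)
    w <- rep(1, ncol(ch$states))
    ex <- mitohap:::.exhaustive_parsimony(ch$states, w)
    bb <- mitohap:::.bb_parsimony(ch$states, w, Inf)
    expect_equal(bb$score, ex$score)
  }
})

test_that("build_tree's length equals the fitch score of its topology", {
  profs <- random_profile_set(7, n_pool = 14, seed = 77)
  mat <- build_tree(profs, outgroup = "s1")
  expect_equal(fitch_score(mat$tree_binary, profs), mat$length)
  expect_equal(sum(vapply(mat$branch_mutations, nrow, integer(1))),
               mat$length)
})

test_that("star phylogenies collapse to one node with private branches", {
  spec <- list(motifs = data.frame(name = "root", parent = "-",
                                   variants = ""),
               leaves_per_clade = c(root = 6), n_private = 3,
               positions = c(100, 16000))
  pan <- simulate_panel(spec, seed = 7)
  mat <- build_tree(pan$profiles, outgroup = "root_1")
  expect_equal(mat$tree$Nnode, 1L)
  for (l in mat$tree$tip.label) {
    e <- which(mat$tree$edge[, 2] == match(l, mat$tree$tip.label))
    expect_setequal(mat$branch_mutations[[e]]$label,
                    pan$truth$private[[l]])
  }
  expect_identical(find_clade_motif(mat, mat$tree$tip.label),
                   character(0))
})

test_that("a planted six-transition stem motif is recovered exactly", {
  spec <- list(motifs = data.frame(
    name = c("root", "P1a"), parent = c("-", "root"),
    variants = c("", "2171,5681,11468,12738,15714,16247")),
    leaves_per_clade = c(P1a = 10, root = 2), n_private = 2,
    positions = c(100, 16000))
  pan <- simulate_panel(spec, seed = 13)
  mat <- build_tree(pan$profiles, outgroup = "root_1")
  clade <- clade_leaves(mat, "P1a_")
  motif <- find_clade_motif(mat, clade)
  expect_identical(motif, c("2171", "5681", "11468", "12738", "15714",
                            "16247"))
})

test_that("non-monophyletic leaf sets are rejected with intruders named", {
  spec <- list(motifs = data.frame(
    name = c("root", "A", "B"), parent = c("-", "root", "root"),
    variants = c("", "10,20", "30,40")),
    leaves_per_clade = c(A = 3, B = 3, root = 1), n_private = 1,
    positions = c(100, 16000))
  pan <- simulate_panel(spec, seed = 3)
  mat <- build_tree(pan$profiles, outgroup = "root_1")
  a_leaves <- clade_leaves(mat, "A_")
  expect_error(find_clade_motif(mat, a_leaves), NA)
  b_leaves <- clade_leaves(mat, "B_")
  expect_error(find_clade_motif(mat, c(a_leaves, b_leaves[1])),
               "monophyletic")
})

test_that("relabelling leaves permutes output without changing length", {
  profs <- random_profile_set(6, n_pool = 10, seed = 21)
  mat1 <- build_tree(profs, outgroup = "s1")
  relab <- lapply(profs, function(p)
    variant_profile(paste0("z", p$sample_id), p$variants$label))
  mat2 <- build_tree(relab, outgroup = "zs1")
  expect_equal(mat1$length, mat2$length)
  t1 <- mat1$tree_binary; t2 <- mat2$tree_binary
  t2$tip.label <- sub("^z", "", t2$tip.label)
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
})

test_that("a reversion nested inside carriers is flagged as @ on its branch", {
  # the back-mutated leaf sits inside a subclade of carriers, so parsimony
  # is forced to reconstruct gain-then-loss rather than a different gain
  profs <- list(
    variant_profile("root_1", character()),
    variant_profile("C_1", c("100", "200", "300", "7001")),
    variant_profile("C_2", c("100", "200", "300", "7002")),
    variant_profile("C1_1", c("100", "200", "300", "400", "500", "7003")),
    variant_profile("C1_2", c("100", "200", "300", "400", "500", "7004")),
    variant_profile("C1_3", c("200", "300", "400", "500", "7005")))
  mat <- build_tree(profs, outgroup = "root_1")
  e <- which(mat$tree$edge[, 2] == match("C1_3", mat$tree$tip.label))
  df <- mat$branch_mutations[[e]]
  expect_true("@100" %in% df$label)
  expect_true(df$back[df$label == "@100"])
  # the gain of 100 lies on the path above the loss
  anc_labels <- character()
  node <- mat$tree$edge[e, 1]
  repeat {
    ee <- which(mat$tree$edge[, 2] == node)
    if (!length(ee)) break
    anc_labels <- c(anc_labels, mat$branch_mutations[[ee]]$label)
    node <- mat$tree$edge[ee, 1]
  }
  expect_true("100" %in% anc_labels)
})

test_that("injected panel back mutations still classify to the clade", {
  spec <- list(motifs = data.frame(
    name = c("root", "C"), parent = c("-", "root"),
    variants = c("", "100,200,300,400")),
    leaves_per_clade = c(C = 6, root = 2), n_private = 1,
    positions = c(1000, 16000), n_back = 1)
  pan <- simulate_panel(spec, seed = 31)
  cl <- classify(
    pan$profiles[[match(pan$truth$back[[1]]$leaf,
                        vapply(pan$profiles,
                               function(p) p$sample_id, ""))]],
    load_motifs(spec$motifs))
  expect_identical(cl$best_haplogroup, "C")
  expect_identical(cl$missing, pan$truth$back[[1]]$label)
})

test_that("model selection respects likelihood nesting and picks by BIC", {
  set.seed(9)
  tr <- ape::rtree(6)
  tr$edge.length <- tr$edge.length * 0.05
  aln <- simulate_sequences(tr, 2000, rate = 1, kappa = 4,
                            pi = c(.3, .2, .2, .3), seed = 91)
  ms <- select_model(aln, tr)
  tab <- ms$table
  ll <- function(m) tab$loglik[tab$model == m]
  for (vr in c("", "+I", "+G")) {
    expect_true(ll(paste0("K80", vr)) >= ll(paste0("JC", vr)) - 1e-6)
    expect_true(ll(paste0("HKY", vr)) >= ll(paste0("K80", vr)) - 1e-6)
  }
  # +I / +G approach their base model at the parameter-space boundary
  expect_true(ll("HKY+I") >= ll("HKY") - 0.1)
  expect_true(ll("HKY+G") >= ll("HKY") - 0.1)
  expect_identical(ms$best, tab$model[which.min(tab$BIC)])
  expect_error(select_model(aln[1, , drop = FALSE], tr), "2 sequences")
})

test_that("control-region trees use BRS coordinates and window checks", {
  # build window sequences from planted profiles
  refwin <- random_reference(410, seed = 55)
  mk <- function(id, labs_local) {
    p <- variant_profile(id, labs_local)
    mutate_sequence(refwin, p)
  }
  seqs <- c(BRS = refwin,
            a1 = mk("a1", c("100", "345")),
            a2 = mk("a2", c("100", "345")),
            b1 = mk("b1", c("200")))
  mat <- control_region_tree(seqs, ref_id = "BRS")
  all_labels <- unlist(lapply(mat$branch_mutations, function(d) d$label))
  # np 345 in the window is BRS np 345 + 15902
  expect_true("16247" %in% all_labels)
  expect_true("16002" %in% all_labels)
  short <- substr(seqs, 1, 400)
  expect_error(control_region_tree(short, ref_id = "BRS"),
               "window mismatch")
})
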