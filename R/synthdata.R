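# -- synthetic data generators ------------------------------------------------
#
# Every generator is seed-reproducible and returns a truth record rich
# enough that downstream recovery tests never re-derive expectations.

#' Define a piecewise-constant demographic scenario
#'
#' @param breakpoints epoch boundaries in YBP, strictly increasing (may be
#'   empty for a constant size).
#' @param sizes per-epoch population size (N_f x generation time, years);
#'   `length(sizes) == length(breakpoints) + 1`, most recent epoch first.
#' @param samples sampling schedule: data frame with columns `time` (YBP)
#'   and `n` (tips entering at that time), and optionally `id` when `n` is
#'   1 per row.
#' @return an object of class `demographic_scenario`.
#' @export
demographic_scenario <- function(breakpoints = numeric(), sizes,
                                 samples = data.frame(time = 0, n = 2)) {
  if (length(sizes) != length(breakpoints) + 1)
    stop("need one size per epoch: length(sizes) == length(breakpoints)+1")
  if (length(breakpoints) && any(diff(breakpoints) <= 0))
    stop("breakpoints must be strictly increasing")
  if (any(sizes <= 0)) stop("population sizes must be positive")
  if (!all(c("time", "n") %in% names(samples)))
    stop("samples needs columns time, n")
  if (sum(samples$n) < 2) stop("need at least 2 tips in total")
  if (any(samples$time < 0)) stop("sampling times must be >= 0")
  structure(list(breakpoints = breakpoints, sizes = sizes,
                 samples = samples),
            class = "demographic_scenario")
}

# N(t) lookup for a scenario (t in YBP)
scenario_size_at <- function(scenario, t) {
  idx <- findInterval(t, scenario$breakpoints) + 1
  scenario$sizes[idx]
}

#' Simulate a heterochronous coalescent genealogy
#'
#' Kingman coalescent with time-varying rate k(k-1)/(2 N(t)) under a
#' piecewise-constant N(t); tips enter the active set at their sampling
#' dates. For n = 2 contemporaneous tips and constant N the TMRCA is
#' Exponential with mean N.
#'
#' @param scenario a [demographic_scenario()].
#' @param seed integer seed.
#' @return an object of class `dated_genealogy`: `tree` (phylo with branch
#'   lengths in years), `tip_times` (named) and `node_times` (all nodes).
#' @export
simulate_genealogy <- function(scenario, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  smp <- scenario$samples[order(scenario$samples$time), , drop = FALSE]
  tip_times <- rep(smp$time, smp$n)
  ntip <- length(tip_times)
  tip_ids <- if (!is.null(smp$id) && all(smp$n == 1)) {
    rep(smp$id, smp$n)
  } else paste0("t", seq_len(ntip))
  # node bookkeeping: tips 1..ntip, internals ntip+1 .. 2*ntip-1
  node_time <- c(tip_times, rep(NA_real_, ntip - 1))
  kids <- matrix(NA_integer_, ntip - 1, 2)
  active <- integer(0)
  pend <- seq_len(ntip)                 # tips not yet sampled (sorted)
  nxt <- ntip + 1L
  t <- tip_times[1]
  while (length(pend) && tip_times[pend[1]] <= t) {
    active <- c(active, pend[1]); pend <- pend[-1]
  }
  bps <- scenario$breakpoints
  while (length(active) + length(pend) > 1) {
    k <- length(active)
    if (k < 2) {                        # wait for the next sampling event
      t <- tip_times[pend[1]]
      while (length(pend) && tip_times[pend[1]] <= t) {
        active <- c(active, pend[1]); pend <- pend[-1]
      }
      next
    }
    target <- rexp(1)                   # integrated-rate draw
    tnow <- t
    repeat {
      N <- scenario_size_at(scenario, tnow)
      bp_next <- bps[bps > tnow]
      t_epoch_end <- if (length(bp_next)) bp_next[1] else Inf
      t_sample <- if (length(pend)) tip_times[pend[1]] else Inf
      t_stop <- min(t_epoch_end, t_sample)
      rate <- k * (k - 1) / (2 * N)
      cap <- rate * (t_stop - tnow)
      if (target <= cap) { tnow <- tnow + target / rate; break }
      target <- target - cap
      tnow <- t_stop
      if (t_sample <= t_epoch_end) {    # absorb the sampling event
        t <- tnow
        while (length(pend) && tip_times[pend[1]] <= t) {
          active <- c(active, pend[1]); pend <- pend[-1]
        }
        k <- length(active)
        target <- rexp(1)               # memoryless restart
      }
    }
    t <- tnow
    pair <- sample(length(active), 2)
    node_time[nxt] <- t
    kids[nxt - ntip, ] <- active[pair]
    active <- c(active[-pair], nxt)
    nxt <- nxt + 1L
  }
  # assemble phylo: root is the last created internal node
  nint <- ntip - 1L
  edge <- matrix(0L, 2 * nint, 2)
  elen <- numeric(2 * nint)
  # ape numbering: tips 1..ntip; internal ape id = ntip + (ntip-1) - (i - ntip - 1)
  # so the root (our node 2*ntip-1) becomes ape ntip+1
  ape_id <- c(seq_len(ntip), rev(ntip + seq_len(nint)))
  r <- 1L
  for (i in seq_len(nint)) {
    me <- ntip + i
    for (ch in kids[i, ]) {
      edge[r, ] <- c(ape_id[me], ape_id[ch])
      elen[r] <- node_time[me] - node_time[ch]
      r <- r + 1L
    }
  }
  tree <- structure(list(edge = edge, edge.length = elen,
                         tip.label = tip_ids, Nnode = nint),
                    class = "phylo")
  tree <- ape::reorder.phylo(tree, "cladewise")
  nt_out <- c(node_time[seq_len(ntip)],
              node_time[ntip + rev(seq_len(nint))])
  structure(list(tree = tree, tip_times = setNames(tip_times, tip_ids),
                 node_times = nt_out),
            class = "dated_genealogy")
}

#' @export
print.dated_genealogy <- function(x, ...) {
  nt <- length(x$tree$tip.label)
  cat("dated_genealogy:", nt, "tips, TMRCA",
      round(max(x$node_times), 1), "YBP\n")
  invisible(x)
}

# R-side HKY transition probability matrix (mirrors the C++ closed form;
# also serves as its cross-check in the tests)
hky_pmat <- function(t, kappa = 1, pi = rep(0.25, 4)) {
  names(pi) <- c("A", "C", "G", "T")
  piR <- pi["A"] + pi["G"]; piY <- pi["C"] + pi["T"]
  beta <- 1 / (2 * kappa * (pi["A"] * pi["G"] + pi["C"] * pi["T"]) +
                 2 * piR * piY)
  e2 <- exp(-beta * t)
  P <- matrix(0, 4, 4, dimnames = list(names(pi), names(pi)))
  for (j in names(pi)) {
    Pi <- if (j %in% c("A", "G")) piR else piY
    e3 <- exp(-beta * t * (Pi * kappa + 1 - Pi))
    for (i in names(pi)) {
      P[i, j] <- if (i == j) {
        pi[j] + pi[j] * (1 / Pi - 1) * e2 + ((Pi - pi[j]) / Pi) * e3
      } else if ((i %in% c("A", "G")) == (j %in% c("A", "G"))) {
        pi[j] + pi[j] * (1 / Pi - 1) * e2 - (pi[j] / Pi) * e3
      } else pi[j] * (1 - e2)
    }
  }
  unname(P)
}

#' Simulate sequence evolution along a genealogy
#'
#' HKY (optionally +Gamma site rates) simulation: the root state is drawn
#' from the stationary frequencies and each branch applies its closed-form
#' transition matrix with branch length `rate * years [* site rate]`.
#'
#' @param genealogy a `dated_genealogy` or a `phylo` whose branch lengths
#'   are already in expected substitutions/site (then use `rate = 1`).
#' @param length number of sites.
#' @param rate clock rate in substitutions/site/year.
#' @param kappa,pi HKY parameters.
#' @param alpha optional gamma shape for among-site rate variation.
#' @param ncat gamma categories.
#' @param seed integer seed.
#' @return character matrix (tips x sites) with tip row names.
#' @export
simulate_sequences <- function(genealogy, length, rate, kappa = 1,
                               pi = rep(0.25, 4), alpha = NULL, ncat = 4,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length > 0, rate >= 0)
  tree <- if (inherits(genealogy, "dated_genealogy")) genealogy$tree
          else genealogy
  tr <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tr$tip.label)
  nn <- tr$Nnode
  bases <- c("A", "C", "G", "T")
  site_rate <- rep(1, length)
  if (!is.null(alpha)) {
    g <- discrete_gamma_rates(alpha, ncat)
    site_rate <- g[base::sample.int(ncat, length, replace = TRUE)]
  }
  states <- matrix(0L, nt + nn, length)
  root <- tr$edge[nrow(tr$edge), 1]
  states[root, ] <- base::sample.int(4, length, replace = TRUE, prob = pi)
  rates_u <- sort(unique(site_rate))
  for (e in rev(seq_len(nrow(tr$edge)))) {   # preorder: parent before child
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    bl <- tr$edge.length[e] * rate
    for (ru in rates_u) {
      idx <- which(site_rate == ru)
      P <- hky_pmat(bl * ru, kappa, pi)
      cum <- t(apply(P, 1, cumsum))
      u <- runif(length(idx))
      ps <- states[p, idx]
      for (s in 1:4) {
        sel <- which(ps == s)
        if (length(sel))
          states[ch, idx[sel]] <- findInterval(u[sel], cum[s, ],
                                               left.open = TRUE) + 1L
      }
    }
  }
  out <- matrix(bases[states[seq_len(nt), , drop = FALSE]], nt, length)
  rownames(out) <- tr$tip.label
  out
}

#' Generate a random reference-like mitogenome sequence
#' @param length sequence length.
#' @param pi base frequencies.
#' @param seed integer seed.
#' @export
random_reference <- function(length = 16338, pi = c(.33, .26, .13, .28),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(base::sample(c("A", "C", "G", "T"), length, replace = TRUE,
                     prob = pi), collapse = "")
}

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")

#' Plant a random variant set on a reference
#'
#' Draws non-interfering transitions, transversions, insertions and
#' deletions whose canonical (3'-justified) labels equal the planted labels
#' by construction: deletions are placed at the 3' end of their homopolymer
#' run and inserted bases are chosen to differ from the following base, so
#' no justification shift can occur. Used as the exact truth for
#' variant-calling round-trip tests.
#'
#' @param ref reference sequence string.
#' @param n_transitions,n_transversions,n_insertions,n_deletions counts.
#' @param seed integer seed.
#' @param min_gap minimum spacing between planted events.
#' @return a [variant_profile()] whose labels are the canonical truth.
#' @export
simulate_variant_set <- function(ref, n_transitions = 10,
                                 n_transversions = 2, n_insertions = 1,
                                 n_deletions = 1, seed = NULL,
                                 min_gap = 5) {
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(ref)
  rc <- strsplit(ref, "")[[1]]
  used <- logical(L)
  reserve <- function(p) {
    lo <- max(1, p - min_gap); hi <- min(L, p + min_gap)
    if (any(used[lo:hi])) return(FALSE)
    used[lo:hi] <<- TRUE
    TRUE
  }
  labels <- character()
  draw_pos <- function() base::sample.int(L - 2 * min_gap, 1) + min_gap
  n_try <- 0
  add <- function(need, fn) {
    got <- 0
    while (got < need) {
      n_try <<- n_try + 1
      if (n_try > 10000 * (need + 1)) stop("could not place variants")
      p <- draw_pos()
      lab <- fn(p)
      if (!is.null(lab)) got <- got + 1
    }
  }
  add(n_transitions, function(p) {
    if (!reserve(p)) return(NULL)
    labels <<- c(labels, as.character(p))
    p
  })
  add(n_transversions, function(p) {
    if (!reserve(p)) return(NULL)
    tv <- setdiff(c("A", "C", "G", "T"), c(rc[p], TRANSITION_OF[rc[p]]))
    labels <<- c(labels, paste0(p, base::sample(tv, 1)))
    p
  })
  add(n_deletions, function(p) {
    # 3' end of the homopolymer run containing p, and next base differs
    while (p < L && rc[p + 1] == rc[p]) p <- p + 1
    if (p >= L - min_gap || !reserve(p)) return(NULL)
    labels <<- c(labels, paste0(p, "d"))
    p
  })
  add(n_insertions, function(p) {
    b <- base::sample(setdiff(c("A", "C", "G", "T"),
                              c(rc[p], rc[p + 1])), 1)
    if (!reserve(p)) return(NULL)
    labels <<- c(labels, paste0(p, "+", b))
    p
  })
  variant_profile("planted", labels)
}

#' Apply a variant profile to a reference sequence
#'
#' Produces the mutated sample sequence implied by a profile (substitutions,
#' insertions, deletions; heteroplasmies are written as their IUPAC code if
#' `derived` is present, otherwise skipped).
#'
#' @param ref reference string.
#' @param profile a [variant_profile()].
#' @return the mutated sequence string.
#' @export
mutate_sequence <- function(ref, profile) {
  rc <- strsplit(ref, "")[[1]]
  v <- profile$variants
  v <- v[order(-v$position), , drop = FALSE]  # right-to-left keeps coords
  for (i in seq_len(nrow(v))) {
    p <- v$position[i]
    switch(v$vclass[i],
      transition = { rc[p] <- TRANSITION_OF[rc[p]] },
      transversion = { rc[p] <- v$derived[i] },
      insertion = {
        rc <- append(rc, strsplit(v$derived[i], "")[[1]], after = p)
      },
      deletion = {
        e <- if (is.na(v$end[i])) p else v$end[i]
        rc <- rc[-(p:e)]
      },
      heteroplasmy = {
        if (!is.na(v$derived[i])) rc[p] <- v$derived[i]
      })
  }
  paste(rc, collapse = "")
}

#' Simulate a motif-structured haplotype panel
#'
#' Generates variant profiles that realise a planted haplogroup motif tree
#' (each clade's stem carries its defining variants) plus per-leaf private
#' transitions, with optional injected recurrences (the same variant on two
#' unrelated leaves) and back mutations (a diagnostic variant removed from
#' one leaf). Placement avoids collisions, so parsimony truth is exact by
#' construction unless injections say otherwise.
#'
#' @param spec a list: `motifs` (data frame `name`,`parent`,`variants` or a
#'   `motif_tree`), `leaves_per_clade` (named integer; names are motif-tree
#'   leaves or internal nodes to sample under), `n_private` (mean private
#'   transitions per leaf, Poisson), `positions` (range to draw private
#'   positions from), `n_recurrent`, `n_back`.
#' @param seed integer seed.
#' @return list with `profiles` (list of [variant_profile()]) and `truth`
#'   (stem motifs per clade, private labels per leaf, injected recurrence /
#'   back-mutation records).
#' @export
simulate_panel <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  motifs <- if (inherits(spec$motifs, "motif_tree")) spec$motifs
            else load_motifs(spec$motifs)
  lpc <- spec$leaves_per_clade
  n_private <- if (is.null(spec$n_private)) 2 else spec$n_private
  pos_range <- if (is.null(spec$positions)) c(1, 16338) else spec$positions
  n_rec <- if (is.null(spec$n_recurrent)) 0 else spec$n_recurrent
  n_back <- if (is.null(spec$n_back)) 0 else spec$n_back
  used_pos <- unique(unlist(lapply(motifs$cumulative, function(l)
    if (length(l)) parse_variant(l)$position else integer())))
  draw_private <- function(n) {
    out <- integer(0)
    while (length(out) < n) {
      p <- base::sample(pos_range[1]:pos_range[2], 1)
      if (!p %in% used_pos) { used_pos <<- c(used_pos, p); out <- c(out, p) }
    }
    as.character(out)
  }
  profiles <- list()
  truth_private <- list()
  for (clade in names(lpc)) {
    if (!clade %in% names(motifs$cumulative))
      stop("unknown clade in spec: ", clade)
    stem <- motifs$cumulative[[clade]]
    for (i in seq_len(lpc[[clade]])) {
      id <- paste0(clade, "_", i)
      priv <- draw_private(rpois(1, n_private))
      profiles[[id]] <- variant_profile(id, c(stem, priv))
      truth_private[[id]] <- priv
    }
  }
  rec_records <- list()
  if (n_rec > 0) {
    donors <- names(truth_private)[lengths(truth_private) > 0]
    for (r in seq_len(n_rec)) {
      a <- base::sample(donors, 1)
      lab <- base::sample(truth_private[[a]], 1)
      others <- setdiff(names(profiles),
                        grep(paste0("^", sub("_[0-9]+$", "", a), "_"),
                             names(profiles), value = TRUE))
      if (!length(others)) next
      b <- base::sample(others, 1)
      profiles[[b]] <- variant_profile(
        b, c(profiles[[b]]$variants$label, lab))
      rec_records[[length(rec_records) + 1]] <- list(label = lab,
                                                     leaves = c(a, b))
    }
  }
  back_records <- list()
  if (n_back > 0) {
    carriers <- names(profiles)[vapply(names(profiles), function(id) {
      clade <- sub("_[0-9]+$", "", id)
      length(motifs$cumulative[[clade]]) > 0
    }, logical(1))]
    for (r in seq_len(min(n_back, length(carriers)))) {
      id <- base::sample(carriers, 1)
      carriers <- setdiff(carriers, id)
      clade <- sub("_[0-9]+$", "", id)
      lab <- base::sample(motifs$cumulative[[clade]], 1)
      keep <- setdiff(profiles[[id]]$variants$label, lab)
      profiles[[id]] <- variant_profile(id, keep)
      back_records[[length(back_records) + 1]] <- list(label = lab,
                                                       leaf = id)
    }
  }
  list(profiles = unname(profiles),
       truth = list(stem_motifs = motifs$cumulative,
                    branch_motifs = motifs$motif,
                    private = truth_private,
                    recurrent = rec_records, back = back_records))
}

#' Simulate a codon-partitioned coding panel with known node ages
#'
#' Evolves the three codon-position site classes with their own rates
#' (third positions fastest by default) along an ultrametric tree whose
#' branch lengths are in years, assembles the sites into a toy 13-gene
#' annotation (one L-strand gene whose genomic block is stored as the
#' complement, exercising the partition builder), and records truth.
#'
#' @param tree rooted binary ultrametric `phylo`, branch lengths in years.
#' @param rates per-codon-position rates (subs/site/year), length 3.
#' @param kappa,pi HKY parameters.
#' @param n_genes number of genes (one of them on the L strand).
#' @param codons_per_gene codons per gene.
#' @param seed integer seed.
#' @return list with `records` (a `mito_records`), `annotation`,
#'   `partition` (a ready `codon_partition_alignment`) and `truth`
#'   (node ages, rates).
#' @export
simulate_coding_panel <- function(tree, rates = c(4e-9, 2e-9, 2e-8),
                                  kappa = 20, pi = c(.33, .26, .13, .28),
                                  n_genes = 13, codons_per_gene = 292,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(rates) == 3, ape::is.rooted(tree))
  nt <- length(tree$tip.label)
  ncod_tot <- n_genes * codons_per_gene
  pos_seqs <- lapply(1:3, function(k)
    simulate_sequences(tree, ncod_tot, rates[k], kappa = kappa, pi = pi))
  # interleave codon positions
  coding <- matrix("", nt, 3 * ncod_tot)
  coding[, seq(1, 3 * ncod_tot, 3)] <- pos_seqs[[1]]
  coding[, seq(2, 3 * ncod_tot, 3)] <- pos_seqs[[2]]
  coding[, seq(3, 3 * ncod_tot, 3)] <- pos_seqs[[3]]
  rownames(coding) <- rownames(pos_seqs[[1]])
  glen <- 3 * codons_per_gene
  annotation <- data.frame(
    gene = c(paste0("G", seq_len(n_genes - 1)), "ND6L"),
    start = (seq_len(n_genes) - 1) * glen + 1,
    end = seq_len(n_genes) * glen,
    strand = c(rep("H", n_genes - 1), "L"),
    stringsAsFactors = FALSE)
  seqs <- apply(coding, 1, paste, collapse = "")
  # store the genomic (H-strand) representation of the L-strand gene
  lg <- n_genes
  for (i in seq_along(seqs)) {
    block <- substr(seqs[i], annotation$start[lg], annotation$end[lg])
    substr(seqs[i], annotation$start[lg], annotation$end[lg]) <-
      revcomp(block)
  }
  records <- mito_records(rownames(coding), unname(seqs))
  partition <- build_partition(records, annotation, check_stops = FALSE)
  # truth node ages from the tree (root-to-tip path must be ultrametric)
  depths <- ape::node.depth.edgelength(tree)
  ages <- max(depths) - depths
  names(ages) <- as.character(seq_along(ages))
  list(records = records, annotation = annotation, partition = partition,
       truth = list(ages = ages[(nt + 1):(nt + tree$Nnode)],
                    rates = rates, kappa = kappa))
}
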