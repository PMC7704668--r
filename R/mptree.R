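# -- mutation-annotated parsimony trees --------------------------------------

# Build binary presence/absence characters from variant profiles.
# States are bitmasks: 1 = absent, 2 = present, 3 = missing (used for
# heteroplasmic positions, which are not fixed states).
profiles_to_characters <- function(profiles) {
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample ids in profiles")
  all_v <- do.call(rbind, lapply(profiles, function(p) p$variants))
  char_labels <- sort(unique(
    all_v$label[all_v$vclass != "heteroplasmy"]))
  if (length(char_labels) == 0)
    return(list(states = matrix(integer(), length(ids), 0,
                                dimnames = list(ids, NULL)),
                labels = character()))
  char_pos <- parse_variant(char_labels)$position
  states <- matrix(1L, length(ids), length(char_labels),
                   dimnames = list(ids, char_labels))
  for (i in seq_along(profiles)) {
    v <- profiles[[i]]$variants
    states[i, v$label[v$vclass != "heteroplasmy"]] <- 2L
    het_pos <- v$position[v$vclass == "heteroplasmy"]
    if (length(het_pos))
      states[i, char_pos %in% het_pos] <- 3L
  }
  list(states = states, labels = char_labels)
}

#' Fitch parsimony length of a tree
#'
#' Counts the minimum number of state changes needed to explain the
#' presence/absence of every variant on the given topology (heteroplasmic
#' positions are treated as missing).
#'
#' @param tree a `phylo` whose tip labels match the profile sample ids.
#' @param profiles list of [variant_profile()]s.
#' @return the parsimony length (numeric).
#' @export
fitch_score <- function(tree, profiles) {
  ch <- profiles_to_characters(profiles)
  missing_tips <- setdiff(tree$tip.label, rownames(ch$states))
  if (length(missing_tips))
    stop("no profile for leaf: ", paste(missing_tips, collapse = ", "))
  st <- ch$states[tree$tip.label, , drop = FALSE]
  if (ncol(st) == 0) return(0)
  tr <- ape::reorder.phylo(tree, "postorder")
  .fitch_count(tr$edge, length(tr$tip.label), st,
               rep(1, ncol(st)))
}

# orient an undirected edge list (0-based, tips 0..ntax-1) into a phylo
adjacency_to_phylo <- function(eu, ev, ntax, tip_labels) {
  if (ntax == 2) {
    return(structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2,
                                        byrow = TRUE),
                          edge.length = NULL, tip.label = tip_labels,
                          Nnode = 1L), class = "phylo"))
  }
  nodes <- sort(unique(c(eu, ev)))
  internal <- nodes[nodes >= ntax]
  ape_id <- integer(max(nodes) + 1)
  ape_id[nodes[nodes < ntax] + 1] <- nodes[nodes < ntax] + 1L
  ape_id[internal + 1] <- ntax + seq_along(internal)
  adj <- vector("list", max(nodes) + 1)
  for (i in seq_along(eu)) {
    adj[[eu[i] + 1]] <- c(adj[[eu[i] + 1]], ev[i])
    adj[[ev[i] + 1]] <- c(adj[[ev[i] + 1]], eu[i])
  }
  start <- internal[1]
  parent <- rep(-2L, max(nodes) + 1)
  parent[start + 1] <- -1L
  stack <- start
  edges <- matrix(0L, length(eu), 2)
  r <- 0L
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (v in adj[[u + 1]]) {
      if (parent[u + 1] == v) next
      parent[v + 1] <- u
      r <- r + 1L
      edges[r, ] <- c(ape_id[u + 1], ape_id[v + 1])
      stack <- c(stack, v)
    }
  }
  tr <- structure(list(edge = edges, tip.label = tip_labels,
                       Nnode = length(internal)), class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

phylo_to_adjacency <- function(tree) {
  ntax <- length(tree$tip.label)
  # 0-based, tips 0..ntax-1; internal nodes keep ape order
  list(eu = tree$edge[, 1] - 1L, ev = tree$edge[, 2] - 1L, ntax = ntax)
}

score_adjacency <- function(eu, ev, ntax, tip_labels, states) {
  tr <- adjacency_to_phylo(eu, ev, ntax, tip_labels)
  trp <- ape::reorder.phylo(tr, "postorder")
  .fitch_count(trp$edge, ntax, states[trp$tip.label, , drop = FALSE],
               rep(1, ncol(states)))
}

# all NNI rearrangements of an undirected binary tree (0-based edge lists)
nni_moves <- function(eu, ev, ntax) {
  out <- list()
  for (i in seq_along(eu)) {
    u <- eu[i]; v <- ev[i]
    if (u < ntax || v < ntax) next
    at_u <- setdiff(c(ev[eu == u], eu[ev == u]), v)
    at_v <- setdiff(c(ev[eu == v], eu[ev == v]), u)
    b <- at_u[2]
    for (x in at_v) {
      eu2 <- eu; ev2 <- ev
      # replace edge (u,b) with (u,x) and edge (v,x) with (v,b)
      ib <- which((eu2 == u & ev2 == b) | (eu2 == b & ev2 == u))[1]
      ix <- which((eu2 == v & ev2 == x) | (eu2 == x & ev2 == v))[1]
      eu2[ib] <- u; ev2[ib] <- x
      eu2[ix] <- v; ev2[ix] <- b
      out[[length(out) + 1]] <- list(eu = eu2, ev = ev2)
    }
  }
  out
}

# random sequential-addition starting topology
random_addition_tree <- function(ntax) {
  ord <- base::sample.int(ntax) - 1L
  eu <- c(ord[1], ord[2], ord[3]); ev <- rep(ntax, 3)
  nxt <- ntax + 1L
  for (k in 4:ntax) {
    e <- base::sample.int(length(eu), 1)
    u <- eu[e]; v <- ev[e]
    eu[e] <- u; ev[e] <- nxt
    eu <- c(eu, nxt, nxt); ev <- c(ev, v, ord[k])
    nxt <- nxt + 1L
  }
  list(eu = eu, ev = ev)
}

#' Build a mutation-annotated parsimony tree
#'
#' Collapses samples into haplotypes, finds a minimum-length topology -
#' exactly by branch and bound for up to `exact_limit` haplotypes,
#' otherwise by NNI hill-climbing from a neighbour-joining start with
#' seeded random restarts - roots it on the outgroup, and assigns every
#' mutation to a branch by Fitch traceback. Recurrent mutations (gains on
#' two or more branches) and back mutations (prefix `@`) are flagged, as
#' are characters whose placement is ambiguous.
#'
#' @param profiles list of [variant_profile()]s.
#' @param outgroup sample id used to root the tree (e.g. the reference);
#'   defaults to the first haplotype.
#' @param search `"auto"` (exact up to `exact_limit`), `"exact"`,
#'   `"exhaustive"` (no pruning; mainly for validation) or `"heuristic"`.
#' @param exact_limit haplotype count up to which the exact search runs.
#' @param seed integer seed for heuristic restarts.
#' @param n_restarts random-addition restarts for the heuristic search.
#' @param collapse_unsupported collapse internal branches carrying no
#'   mutations into polytomies (star-like presentation); the fully binary
#'   search tree is kept in `$tree_binary`.
#' @return an object of class `mutation_annotated_tree`: rooted `tree`,
#'   `branch_mutations` (one data frame per edge: `label`, `recurrent`,
#'   `back`, `ambiguous`), `haplotypes` (leaf membership), `length`
#'   (parsimony length).
#' @export
build_tree <- function(profiles, outgroup = NULL,
                       search = c("auto", "exact", "exhaustive",
                                  "heuristic"),
                       exact_limit = 12, seed = 1, n_restarts = 3,
                       collapse_unsupported = TRUE) {
  search <- match.arg(search)
  hap <- collapse_haplotypes(profiles)
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  # leaf names: the sample id when unique, else the haplotype id
  leaf_name <- vapply(seq_len(nrow(hap)), function(i)
    if (hap$size[i] == 1) hap$members[[i]][1] else hap$haplotype[i],
    character(1))
  rep_profiles <- lapply(seq_len(nrow(hap)), function(i) {
    p <- profiles[[match(hap$members[[i]][1], ids)]]
    structure(list(sample_id = leaf_name[i], variants = p$variants),
              class = "variant_profile")
  })
  haplotypes <- setNames(hap$members, leaf_name)
  ntax <- length(rep_profiles)
  if (!is.null(outgroup)) {
    og_leaf <- leaf_name[vapply(hap$members, function(m)
      outgroup %in% m, logical(1))]
    if (length(og_leaf) != 1)
      stop("outgroup sample not found among profiles: ", outgroup)
  } else og_leaf <- leaf_name[1]

  if (ntax < 2) {
    return(structure(list(tree = NULL, branch_mutations = list(),
                          haplotypes = haplotypes, length = 0,
                          degenerate = TRUE),
                     class = "mutation_annotated_tree"))
  }
  ch <- profiles_to_characters(rep_profiles)
  states <- ch$states
  w <- rep(1, ncol(states))

  if (ntax == 2) {
    unrooted <- adjacency_to_phylo(c(0L), c(1L), 2L, leaf_name)
  } else if (search == "exhaustive" ||
             (search %in% c("auto", "exact") && ntax <= exact_limit)) {
    res <- if (search == "exhaustive") {
      .exhaustive_parsimony(states, w)
    } else {
      ub <- heuristic_search(states, leaf_name, seed, 1)$score
      .bb_parsimony(states, w, ub)
    }
    unrooted <- adjacency_to_phylo(res$edge_u, res$edge_v, ntax,
                                   leaf_name)
  } else if (search == "exact" && ntax > exact_limit) {
    stop("exact search limited to ", exact_limit, " haplotypes")
  } else {
    unrooted <- heuristic_search(states, leaf_name, seed,
                                 n_restarts)$tree
  }
  rooted <- if (ntax == 2) unrooted
            else ape::root(unrooted, outgroup = og_leaf,
                           resolve.root = TRUE)
  ann <- annotate_tree(rooted, states, ch$labels)
  out <- list(tree = rooted, branch_mutations = ann$branch_mutations,
              haplotypes = haplotypes, length = ann$length,
              tree_binary = rooted, degenerate = FALSE)
  if (collapse_unsupported && ntax > 2) {
    cl <- collapse_empty_branches(rooted, ann$branch_mutations)
    out$tree <- cl$tree
    out$branch_mutations <- cl$branch_mutations
  }
  structure(out, class = "mutation_annotated_tree")
}

# collapse internal branches carrying no mutations into polytomies,
# re-mapping the per-branch mutation tables by child clade
collapse_empty_branches <- function(tree, branch_mutations) {
  counts <- vapply(branch_mutations, nrow, integer(1))
  nt <- length(tree$tip.label)
  internal <- tree$edge[, 2] > nt
  if (!any(internal & counts == 0))
    return(list(tree = tree, branch_mutations = branch_mutations))
  t2 <- tree
  t2$edge.length <- ifelse(internal & counts == 0, 0, 1)
  t2 <- ape::di2multi(t2, tol = 0.5)
  t2$edge.length <- NULL
  clade_key <- function(tr, node)
    paste(sort(tips_under(tr, node)), collapse = "|")
  keys_old <- vapply(tree$edge[, 2], clade_key, character(1), tr = tree)
  keys_new <- vapply(t2$edge[, 2], clade_key, character(1), tr = t2)
  bm2 <- branch_mutations[match(keys_new, keys_old)]
  list(tree = t2, branch_mutations = bm2)
}

# NJ start + NNI hill climb with random-addition restarts
heuristic_search <- function(states, tip_labels, seed, n_restarts) {
  ntax <- nrow(states)
  set.seed(derive_seed(seed, "mptree-heuristic"))
  # pairwise Hamming distance, missing excluded pairwise
  d <- matrix(0, ntax, ntax, dimnames = list(tip_labels, tip_labels))
  for (i in seq_len(ntax - 1)) for (j in (i + 1):ntax) {
    ok <- states[i, ] != 3L & states[j, ] != 3L
    d[i, j] <- d[j, i] <- sum(states[i, ok] != states[j, ok])
  }
  starts <- list()
  nj <- tryCatch(ape::unroot(ape::nj(d)), error = function(e) NULL)
  if (!is.null(nj)) {
    nj$tip.label <- nj$tip.label  # keep labels
    adj <- phylo_to_adjacency_named(nj, tip_labels)
    starts[[1]] <- adj
  }
  while (length(starts) < n_restarts)
    starts[[length(starts) + 1]] <- random_addition_tree(ntax)
  best <- NULL
  for (st in starts) {
    cur <- st
    cur_score <- score_adjacency(cur$eu, cur$ev, ntax, tip_labels, states)
    repeat {
      improved <- FALSE
      for (mv in nni_moves(cur$eu, cur$ev, ntax)) {
        sc <- score_adjacency(mv$eu, mv$ev, ntax, tip_labels, states)
        if (sc < cur_score) {
          cur <- mv; cur_score <- sc; improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
    if (is.null(best) || cur_score < best$score)
      best <- list(score = cur_score,
                   tree = adjacency_to_phylo(cur$eu, cur$ev, ntax,
                                             tip_labels))
  }
  best
}

# phylo (with labels in arbitrary order) -> 0-based adjacency with tips
# renumbered to match `tip_labels`
phylo_to_adjacency_named <- function(tree, tip_labels) {
  ntax <- length(tip_labels)
  perm <- match(tree$tip.label, tip_labels)  # ape tip i -> our tip perm[i]-1
  map_node <- function(x)
    ifelse(x <= ntax, perm[x] - 1L, x - 1L)
  list(eu = map_node(tree$edge[, 1]), ev = map_node(tree$edge[, 2]),
       ntax = ntax)
}

# Fitch traceback on a rooted binary tree; returns per-edge mutation tables
annotate_tree <- function(tree, states, labels) {
  tr <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tr$tip.label)
  nn <- tr$Nnode
  nchar_ <- ncol(states)
  st <- states[tr$tip.label, , drop = FALSE]
  S <- matrix(0L, nt + nn, nchar_)
  S[seq_len(nt), ] <- st
  ambiguous <- rep(FALSE, nchar_)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    if (all(S[p, ] == 0L)) S[p, ] <- S[ch, ]
    else {
      inter <- bitwAnd(S[p, ], S[ch, ])
      un <- bitwOr(S[p, ], S[ch, ])
      take_union <- inter == 0L
      ambiguous <- ambiguous | take_union
      S[p, ] <- ifelse(take_union, un, inter)
    }
  }
  root <- tr$edge[nrow(tr$edge), 1]
  final <- matrix(0L, nt + nn, nchar_)
  # root prefers the ancestral (absent) state
  final[root, ] <- ifelse(bitwAnd(S[root, ], 1L) > 0L, 1L, 2L)
  for (e in rev(seq_len(nrow(tr$edge)))) {   # preorder
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    keep <- bitwAnd(S[ch, ], final[p, ]) > 0L
    other <- ifelse(bitwAnd(S[ch, ], 1L) > 0L, 1L, 2L)
    final[ch, ] <- ifelse(keep, final[p, ], other)
  }
  n_gain <- integer(nchar_)
  per_edge_gain <- vector("list", nrow(tr$edge))
  per_edge_loss <- vector("list", nrow(tr$edge))
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    gain <- which(final[p, ] == 1L & final[ch, ] == 2L)
    loss <- which(final[p, ] == 2L & final[ch, ] == 1L)
    per_edge_gain[[e]] <- gain
    per_edge_loss[[e]] <- loss
    n_gain[gain] <- n_gain[gain] + 1L
  }
  total <- 0
  branch_mutations <- vector("list", nrow(tree$edge))
  # map back to the input tree's edge order
  key_in <- paste(tree$edge[, 1], tree$edge[, 2])
  key_tr <- paste(tr$edge[, 1], tr$edge[, 2])
  ord <- match(key_in, key_tr)
  for (i in seq_along(branch_mutations)) {
    e <- ord[i]
    gain <- per_edge_gain[[e]]; loss <- per_edge_loss[[e]]
    back_labels <- if (length(loss)) paste0("@", labels[loss])
                   else character(0)
    df <- data.frame(
      label = c(labels[gain], back_labels),
      recurrent = c(n_gain[gain] > 1L, rep(FALSE, length(loss))),
      back = c(rep(FALSE, length(gain)), rep(TRUE, length(loss))),
      ambiguous = ambiguous[c(gain, loss)],
      stringsAsFactors = FALSE)
    if (nrow(df))
      df <- df[order(parse_variant(sub("^@", "", df$label))$position), ,
               drop = FALSE]
    rownames(df) <- NULL
    branch_mutations[[i]] <- df
    total <- total + nrow(df)
  }
  list(branch_mutations = branch_mutations, length = total)
}

#' @export
print.mutation_annotated_tree <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("mutation_annotated_tree: degenerate (", length(x$haplotypes),
        "haplotype )\n")
    return(invisible(x))
  }
  cat("mutation_annotated_tree:", length(x$tree$tip.label),
      "haplotypes, parsimony length", x$length, "\n")
  invisible(x)
}

#' Variants on the stem branch of a clade
#'
#' Returns the mutation labels assigned to the branch subtending the most
#' recent common ancestor of the given leaves, sorted by position - the
#' clade's diagnostic motif. The leaf set must be monophyletic.
#'
#' @param mat a `mutation_annotated_tree` from [build_tree()].
#' @param leaves leaf labels forming the clade.
#' @return character vector of labels (empty for the root clade).
#' @export
find_clade_motif <- function(mat, leaves) {
  tree <- mat$tree
  stopifnot(all(leaves %in% tree$tip.label))
  nt <- length(tree$tip.label)
  if (setequal(leaves, tree$tip.label)) return(character(0))
  node <- if (length(leaves) == 1) match(leaves, tree$tip.label)
          else ape::getMRCA(tree, leaves)
  desc <- tips_under(tree, node)
  intruders <- setdiff(desc, leaves)
  if (length(intruders))
    stop("leaf set is not monophyletic; intruding leaves: ",
         paste(intruders, collapse = ", "))
  e <- which(tree$edge[, 2] == node)
  if (length(e) == 0) return(character(0))     # clade is the root
  df <- mat$branch_mutations[[e]]
  labs <- df$label[!df$back]
  labs[order(parse_variant(labs)$position)]
}

tips_under <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) return(tree$tip.label[node])
  todo <- node; tips <- integer(0)
  while (length(todo)) {
    cur <- todo[1]; todo <- todo[-1]
    kids <- tree$edge[tree$edge[, 1] == cur, 2]
    tips <- c(tips, kids[kids <= nt])
    todo <- c(todo, kids[kids > nt])
  }
  tree$tip.label[tips]
}

#' Substitution model selection by BIC
#'
#' Fits {JC, K80, HKY} x {plain, +I, +G4} on a fixed topology by maximum
#' likelihood (branch lengths re-optimised per model, warm-started from the
#' nested simpler fit so the likelihood never decreases with model
#' complexity) and ranks models by BIC = -2 lnL + k ln(n_sites), counting
#' branch lengths in k.
#'
#' @param aln alignment (see [pruning_loglik()] for accepted forms).
#' @param topology a `phylo`; branch lengths, if any, are used as the
#'   starting point.
#' @return an object of class `model_selection`: data frame `model`,
#'   `loglik`, `k`, `BIC`, plus `best`.
#' @export
select_model <- function(aln, topology) {
  m <- as_char_matrix(aln)
  if (nrow(m) < 2) stop("model selection needs at least 2 sequences")
  cp <- compress_patterns(m, topology$tip.label)
  n_sites <- sum(cp$weights)
  tr <- ape::reorder.phylo(ape::unroot(topology), "postorder")
  nedge <- nrow(tr$edge)
  nt <- length(tr$tip.label)

  eval_ll <- function(bl, kappa, pi, pinv, alpha) {
    mix <- rate_mixture(pinv, alpha, 4)
    .pruning_loglik(tr$edge, bl, nt, cp$patterns, cp$weights, pi, kappa,
                    mix$rates, mix$weights)
  }
  softmax4 <- function(lg) { e <- exp(c(lg, 0)); e / sum(e) }
  base_models <- c("JC", "K80", "HKY")
  variants <- c("", "+I", "+G")
  bl0 <- rep(max(mean_pairwise_diff(cp) / nedge, 1e-4), nedge)
  results <- list()
  fits <- list()
  for (bm in base_models) {
    for (vr in variants) {
      name <- paste0(bm, vr)
      has_k <- bm != "JC"; has_i <- vr == "+I"; has_g <- vr == "+G"
      has_f <- bm == "HKY"   # base frequencies free (3 softmax logits)
      # warm start from the nested simpler model, so the likelihood can
      # only improve along the JC -> K80 -> HKY chain
      init <- if (vr != "" && !is.null(fits[[bm]])) fits[[bm]]
              else if (bm == "K80" && !is.null(fits[[paste0("JC", vr)]]))
                fits[[paste0("JC", vr)]]
              else if (bm == "HKY" && !is.null(fits[[paste0("K80", vr)]]))
                fits[[paste0("K80", vr)]]
              else NULL
      bl_init <- if (!is.null(init)) init$bl else bl0
      k_init <- if (!is.null(init) && has_k) max(init$kappa, 1.001) else 2
      par <- log(bl_init)
      lower <- rep(-20, nedge); upper <- rep(2, nedge)
      if (has_k) { par <- c(par, log(k_init))
        lower <- c(lower, log(0.2)); upper <- c(upper, log(100)) }
      if (has_f) {
        # start at the nested model's (uniform) frequencies
        f_init <- if (!is.null(init) && !is.null(init$pi_logits))
          init$pi_logits else rep(0, 3)
        par <- c(par, f_init)
        lower <- c(lower, rep(-8, 3)); upper <- c(upper, rep(8, 3))
      }
      if (has_i) { par <- c(par, stats::qlogis(0.05))
        lower <- c(lower, -8); upper <- c(upper, 8) }
      if (has_g) { par <- c(par, log(1))
        lower <- c(lower, log(0.02)); upper <- c(upper, log(50)) }
      obj <- function(p) {
        i <- nedge
        bl <- exp(p[seq_len(nedge)])
        kappa <- if (has_k) { i <- i + 1; exp(p[i]) } else 1
        pi <- if (has_f) { lg <- p[i + 1:3]; i <- i + 3; softmax4(lg) }
              else rep(0.25, 4)
        pinv <- if (has_i) { i <- i + 1; stats::plogis(p[i]) } else 0
        alpha <- if (has_g) { i <- i + 1; exp(p[i]) } else NULL
        -eval_ll(bl, kappa, pi, pinv, alpha)
      }
      o <- optim(par, obj, method = "L-BFGS-B", lower = lower,
                 upper = upper,
                 control = list(maxit = 300, factr = 1e5))
      ll <- -o$value
      i <- nedge
      fit <- list(bl = exp(o$par[seq_len(nedge)]))
      fit$kappa <- if (has_k) { i <- i + 1; exp(o$par[i]) } else 1
      if (has_f) { fit$pi_logits <- o$par[i + 1:3]; i <- i + 3 }
      fit$pinv <- if (has_i) { i <- i + 1; stats::plogis(o$par[i]) } else 0
      fit$alpha <- if (has_g) { i <- i + 1; exp(o$par[i]) } else NA
      fits[[name]] <- fit
      k <- nedge + has_k + has_i + has_g + has_f * 3
      results[[name]] <- data.frame(model = name, loglik = ll, k = k,
                                    BIC = -2 * ll + k * log(n_sites),
                                    stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, results)
  rownames(tab) <- NULL
  structure(list(table = tab[order(tab$BIC), ],
                 best = tab$model[which.min(tab$BIC)]),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("model selection by BIC; best:", x$best, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Shift a profile's coordinates (window projection)
#'
#' Adds `offset` to every variant position - used to express variants
#' called on a windowed alignment (e.g. the 410-bp control region starting
#' at np 15,903) in full-reference coordinates.
#'
#' @param profile a [variant_profile()].
#' @param offset integer added to all positions.
#' @export
shift_profile <- function(profile, offset) {
  v <- profile$variants
  v$position <- v$position + as.integer(offset)
  v$end <- v$end + as.integer(offset)
  v$label <- format_variant(v)
  variant_profile(profile$sample_id, v$label)
}

#' Mutation-annotated tree from control-region sequences
#'
#' Calls variants of each 410-bp control-region sequence (nps
#' 15,903-16,312) against the reference window, lifts the labels to BRS
#' coordinates and builds the parsimony tree with the same machinery as
#' [build_tree()]. All sequences must have exactly the window length.
#'
#' @param aln character matrix / named vector of window sequences
#'   (alignment-free; each is aligned to the reference window internally).
#' @param ref_id row/name of the reference window sequence.
#' @param outgroup sample id for rooting (defaults to `ref_id`).
#' @param window BRS window, 1-based inclusive.
#' @param ... passed to [build_tree()].
#' @export
control_region_tree <- function(aln, ref_id, outgroup = ref_id,
                                window = CR_WINDOW, ...) {
  m <- as_char_matrix(aln)
  want <- window[2] - window[1] + 1L
  if (ncol(m) != want)
    stop("window mismatch: sequences are ", ncol(m), " bp, expected ",
         want)
  if (!ref_id %in% rownames(m)) stop("reference id not in alignment")
  refseq <- paste(m[ref_id, ], collapse = "")
  profiles <- lapply(rownames(m), function(id) {
    if (id == ref_id) return(variant_profile(id))
    qry <- paste(m[id, ], collapse = "")
    p <- call_variants(align_to_reference(qry, refseq, band = 32),
                       sample_id = id)
    shift_profile(p, window[1] - 1L)
  })
  build_tree(profiles, outgroup = outgroup, ...)
}
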