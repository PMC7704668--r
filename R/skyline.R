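# -- Bayesian skyline plot machinery -----------------------------------------

#' Construct a heterochronous (serially sampled) alignment
#'
#' Bundles an alignment of equal-length control-region sequences with
#' per-tip sampling times in years before present (0 for modern samples).
#'
#' @param aln character matrix (tips x sites) with row names, or named
#'   character vector of sequences.
#' @param tip_dates named numeric vector of sampling times (YBP); names must
#'   cover the alignment rows. Missing entries default to 0 only when
#'   `default_modern = TRUE`.
#' @param tip_sd optional named numeric vector of C14 date uncertainties
#'   (recorded, not sampled).
#' @param default_modern treat unlisted tips as modern (date 0).
#' @return an object of class `heterochronous_sample`.
#' @export
heterochronous_sample <- function(aln, tip_dates = NULL, tip_sd = NULL,
                                  default_modern = TRUE) {
  m <- as_char_matrix(aln)
  if (is.null(rownames(m))) stop("alignment rows must be named")
  ids <- rownames(m)
  td <- setNames(rep(0, length(ids)), ids)
  if (!is.null(tip_dates)) {
    extra <- setdiff(names(tip_dates), ids)
    if (length(extra)) stop("tip date for unknown tip: ", extra[1])
    if (!default_modern && length(setdiff(ids, names(tip_dates))))
      stop("missing tip dates for: ",
           paste(setdiff(ids, names(tip_dates)), collapse = ", "))
    td[names(tip_dates)] <- tip_dates
  }
  if (any(td < 0)) stop("tip dates must be >= 0 (years before present)")
  sdv <- setNames(rep(NA_real_, length(ids)), ids)
  if (!is.null(tip_sd)) sdv[names(tip_sd)] <- tip_sd
  structure(list(aln = m, tip_dates = td, tip_sd = sdv),
            class = "heterochronous_sample")
}

#' @export
print.heterochronous_sample <- function(x, ...) {
  cat("heterochronous_sample:", nrow(x$aln), "tips x", ncol(x$aln),
      "sites;", sum(x$tip_dates > 0), "dated (ancient) tips\n")
  invisible(x)
}

# node times (YBP) of a tip-dated genealogy; gen is a `dated_genealogy`
# (from simulate_genealogy) or a list(tree, tip_times)
genealogy_times <- function(gen) {
  if (inherits(gen, "dated_genealogy"))
    return(list(tree = gen$tree, tip_times = gen$tip_times,
                node_times = gen$node_times))
  tree <- gen$tree
  tipt <- gen$tip_times[tree$tip.label]
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  times <- c(unname(tipt), rep(NA_real_, nn))
  tr <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    t_p <- times[ch] + tr$edge.length[e]
    if (is.na(times[p])) times[p] <- t_p
    else if (abs(times[p] - t_p) > 1e-6 * max(1, times[p]))
      stop("branch lengths inconsistent with tip dates")
  }
  list(tree = tree, tip_times = tipt, node_times = times)
}

#' Piecewise-constant heterochronous coalescent log-density
#'
#' Standard skyline coalescent density: within each inter-event interval the
#' coalescence rate is k(k-1)/(2 N) with k lineages and N the population
#' size (N_f x generation time, in years) of the group the next coalescence
#' belongs to; lineage counts step up at sampling events. For n = 2
#' contemporaneous tips and constant N this reduces to
#' `-t/N - log N` at coalescence time t.
#'
#' @param genealogy a `dated_genealogy` (see [simulate_genealogy()]) or a
#'   list with `tree` (phylo) and `tip_times` (named, YBP).
#' @param theta per-group population sizes (years), most recent first.
#' @param group_sizes number of coalescent intervals per group; defaults to
#'   a single group spanning all n-1 events when `theta` has length 1, or
#'   near-equal groups otherwise.
#' @return the log-density (a scalar).
#' @export
coalescent_loglik <- function(genealogy, theta, group_sizes = NULL) {
  g <- genealogy_times(genealogy)
  nt <- length(g$tree$tip.label)
  coal <- sort(g$node_times[(nt + 1):(nt + g$tree$Nnode)])
  tips <- sort(unname(g$tip_times))
  if (is.null(group_sizes)) group_sizes <- skyline_groups(nt, length(theta))
  if (sum(group_sizes) != nt - 1 || any(group_sizes < 1))
    stop("group sizes must be >= 1 and sum to n-1")
  if (length(theta) != length(group_sizes))
    stop("theta and group_sizes lengths differ")
  if (any(theta <= 0)) stop("population sizes must be positive")
  # validity: each coalescence must postdate its descendant tips
  tr <- ape::reorder.phylo(g$tree, "postorder")
  for (e in seq_len(nrow(tr$edge)))
    if (g$node_times[tr$edge[e, 1]] < g$node_times[tr$edge[e, 2]] - 1e-9)
      stop("coalescence before a descendant tip's date")
  gcum <- cumsum(group_sizes)
  logp <- 0
  is_ <- 1L; ic <- 1L; k <- 0L
  tcur <- tips[1]
  while (is_ <= length(tips) && tips[is_] <= tcur) { k <- k + 1L; is_ <- is_ + 1L }
  while (ic <= length(coal)) {
    th <- theta[which(ic <= gcum)[1]]
    tnext_s <- if (is_ <= length(tips)) tips[is_] else Inf
    tnext <- min(tnext_s, coal[ic])
    logp <- logp - 0.5 * k * (k - 1) * (tnext - tcur) / th
    tcur <- tnext
    if (tnext_s <= coal[ic]) { k <- k + 1L; is_ <- is_ + 1L }
    else { logp <- logp - log(th); k <- k - 1L; ic <- ic + 1L }
  }
  logp
}

# near-equal skyline group sizes over n-1 coalescent intervals
skyline_groups <- function(ntip, m) {
  m <- max(1L, min(m, ntip - 1L))
  sizes <- diff(floor(seq(0, ntip - 1, length.out = m + 1)))
  as.integer(sizes)
}

#' Run the Bayesian skyline MCMC
#'
#' Metropolis-Hastings over the tip-dated genealogy (node-time moves,
#' narrow exchange, Wilson-Balding subtree regraft, whole-tree scaling),
#' per-group population sizes, HKY kappa, gamma shape and - when the tips
#' carry at least two distinct dates - the clock rate. Priors: log-uniform
#' population sizes on \[1, 1e8\] years, uniform kappa on (0, 100],
#' Exponential(1) gamma shape, log-uniform rate. Identical seeds reproduce
#' chains bit-identically.
#'
#' @param sample a [heterochronous_sample()].
#' @param chain_length total MCMC steps (default 2e6, a desk-scale chain).
#' @param thin sampling interval (default 1000).
#' @param burnin_frac fraction of recorded samples discarded by downstream
#'   summaries (recorded in the result; default 0.1).
#' @param m_groups number of skyline groups (capped at n-1).
#' @param seed integer seed (required; drives the whole chain).
#' @param rate fixed clock rate (subs/site/year). If `NULL` the rate is
#'   estimated, which requires >= 2 distinct tip dates.
#' @param ncat gamma categories (4 = HKY+G, 1 = plain HKY).
#' @param use_data if `FALSE`, sample from the prior (no sequence
#'   likelihood); used for validation.
#' @param estimate_topology,estimate_times enable/disable genealogy moves
#'   (disabling both fixes the genealogy at `init_genealogy`).
#' @param estimate_kappa,estimate_alpha enable/disable those parameters.
#' @param init_genealogy optional `dated_genealogy` used as starting state.
#' @param priors optional overrides: `theta_lo`, `theta_hi`, `kappa_max`,
#'   `rate_lo`, `rate_hi`, `alpha_rate`.
#' @param init optional overrides: `theta`, `kappa`, `alpha`, `rate`.
#' @return an object of class `skyline_fit` with thinned posterior samples
#'   (`theta` matrix, sorted coalescent times, scalars), per-parameter ESS,
#'   per-move acceptance rates and the run configuration.
#' @export
run_mcmc <- function(sample, chain_length = 2e6, thin = 1000,
                     burnin_frac = 0.1, m_groups = 5, seed,
                     rate = NULL, ncat = 4, use_data = TRUE,
                     estimate_topology = TRUE, estimate_times = TRUE,
                     estimate_kappa = TRUE, estimate_alpha = TRUE,
                     init_genealogy = NULL, priors = list(),
                     init = list()) {
  stopifnot(inherits(sample, "heterochronous_sample"))
  ntip <- nrow(sample$aln)
  if (ntip < 3) stop("need at least 3 tips")
  if (chain_length < 100 * thin)
    stop("chain_length must be at least 100 * thin")
  if (missing(seed)) stop("an explicit integer seed is required")
  n_dates <- length(unique(sample$tip_dates))
  est_rate <- is.null(rate)
  if (est_rate && n_dates < 2)
    stop("clock rate is unidentifiable without >= 2 distinct tip dates; ",
         "supply a fixed `rate`")
  cp <- compress_patterns(sample$aln, rownames(sample$aln))
  n_var <- sum(apply(cp$patterns, 2, function(col)
    length(unique(col[col != 15L])) > 1))
  if (use_data && n_var == 0)
    warning("all sequences identical: the posterior is driven by the prior")

  pr <- utils::modifyList(list(theta_lo = 1, theta_hi = 1e8,
                               kappa_max = 100, rate_lo = 1e-12,
                               rate_hi = 1e-2, alpha_rate = 1), priors)
  gsizes <- skyline_groups(ntip, m_groups)
  m <- length(gsizes)

  set.seed(derive_seed(seed, "skyline-init"))
  theta0 <- init$theta
  if (is.null(theta0)) {
    # crude moment-based start: pairwise diversity / (2 * rate)
    r0 <- if (est_rate) 1e-7 else rate
    d <- mean_pairwise_diff(cp)
    theta0 <- max(d / (2 * r0), pr$theta_lo * 10, 100)
  }
  theta0 <- rep_len(theta0, m)
  kappa0 <- if (is.null(init$kappa)) 2 else init$kappa
  alpha0 <- if (is.null(init$alpha)) 0.5 else init$alpha
  rate0 <- if (est_rate) {
    if (is.null(init$rate)) 1e-7 else init$rate
  } else rate

  gen0 <- init_genealogy
  if (is.null(gen0)) {
    scen <- demographic_scenario(
      sizes = theta0[1],
      samples = data.frame(time = unname(sample$tip_dates), n = 1,
                           id = rownames(sample$aln),
                           stringsAsFactors = FALSE))
    gen0 <- simulate_genealogy(scen, seed = derive_seed(seed, "init-tree"))
  }
  g0 <- genealogy_times(gen0)
  arr <- phylo_to_arrays(g0$tree, g0$node_times, rownames(sample$aln))

  pi <- empirical_base_freq(sample$aln)
  mw <- c(node_time = if (estimate_times) 0.22 else 0,
          root = if (estimate_times) 0.05 else 0,
          narrow = if (estimate_topology) 0.08 else 0,
          wb = if (estimate_topology) 0.15 else 0,
          theta = 0.22,
          kappa = if (estimate_kappa && use_data) 0.05 else 0,
          alpha = if (estimate_alpha && use_data && ncat > 1) 0.05 else 0,
          rate = if (est_rate) 0.08 else 0,
          scale_all = if (estimate_times) 0.10 else 0,
          rate_times = if (est_rate && estimate_times) 0.10 else 0)
  if (sum(mw) == 0) stop("no free parameters to sample")

  set.seed(derive_seed(seed, "skyline-chain"))
  res <- .skyline_mcmc(cp$patterns, cp$weights, pi,
                       unname(sample$tip_dates[arr$tip_order]),
                       arr$parent, arr$left, arr$right, arr$time,
                       theta0, kappa0, alpha0, rate0,
                       gsizes, as.integer(ncat), pr, unname(mw),
                       chain_length, thin, use_data)

  nsamp <- nrow(res$theta)
  n_burn <- floor(burnin_frac * nsamp)
  keep <- if (n_burn > 0) (n_burn + 1):nsamp else seq_len(nsamp)
  scalars <- data.frame(kappa = res$kappa, alpha = res$alpha,
                        rate = res$rate, loglik = res$loglik,
                        logprior = res$logprior)
  ess <- c(theta = min(apply(res$theta[keep, , drop = FALSE], 2, ess_scalar)),
           kappa = if (mw["kappa"] > 0) ess_scalar(res$kappa[keep]) else NA,
           alpha = if (mw["alpha"] > 0) ess_scalar(res$alpha[keep]) else NA,
           rate = if (est_rate) ess_scalar(res$rate[keep]) else NA)
  structure(list(
    theta = res$theta, coal_times = res$coal_times, scalars = scalars,
    acceptance = setNames(res$acceptance, names(mw)),
    ess = ess, keep = keep, n_burnin = n_burn,
    group_sizes = gsizes, tip_dates = sample$tip_dates,
    config = list(chain_length = chain_length, thin = thin,
                  burnin_frac = burnin_frac, seed = seed, ncat = ncat,
                  rate_fixed = if (est_rate) NA_real_ else rate,
                  priors = pr, n_distinct_dates = n_dates)),
    class = "skyline_fit")
}

#' @export
print.skyline_fit <- function(x, ...) {
  cat("skyline_fit:", nrow(x$theta), "samples (",
      length(x$keep), "post burn-in ),", length(x$group_sizes),
      "groups\n")
  cat("  min theta ESS:", round(x$ess[["theta"]], 1), "\n")
  invisible(x)
}

# convert a rooted binary phylo + node times into the flat arrays the C++
# sampler uses (tips reordered to match `ids`)
phylo_to_arrays <- function(tree, node_times, ids) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  stopifnot(nn == nt - 1)
  ord <- match(ids, tree$tip.label)
  if (any(is.na(ord))) stop("genealogy tips do not match alignment ids")
  # map ape node number -> 0-based array index (tips in `ids` order first)
  idx <- integer(nt + nn)
  idx[ord] <- seq_len(nt) - 1L          # ape tip ord[i] -> i-1
  idx[(nt + 1):(nt + nn)] <- nt:(nt + nn - 1)
  parent <- rep(-1L, nt + nn)
  left <- rep(-1L, nt + nn); right <- rep(-1L, nt + nn)
  for (e in seq_len(nrow(tree$edge))) {
    p <- idx[tree$edge[e, 1]]; ch <- idx[tree$edge[e, 2]]
    parent[ch + 1] <- p
    if (left[p + 1] < 0) left[p + 1] <- ch else right[p + 1] <- ch
  }
  time <- numeric(nt + nn)
  time[idx + 1] <- node_times
  list(parent = parent, left = left, right = right, time = time,
       tip_order = ids)
}

# effective sample size via the ar() spectral estimate (coda-style)
ess_scalar <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10 || var(x) == 0) return(n)
  sp <- tryCatch({
    a <- ar(x, aic = TRUE, order.max = min(20, floor(n / 5)))
    a$var.pred / (1 - sum(a$ar))^2
  }, error = function(e) var(x))
  max(1, min(n, n * var(x) / sp))
}

#' Highest posterior density interval
#'
#' Shortest interval containing a given posterior mass (empirical, from
#' sorted samples).
#'
#' @param x numeric vector of posterior samples.
#' @param prob coverage probability.
#' @return `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) return(c(NA_real_, NA_real_))
  k <- max(1, ceiling(prob * n))
  if (k >= n) return(c(x[1], x[n]))
  w <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(w)
  c(x[i], x[i + k])
}

#' Transfer a clock rate from an ancient run to a modern run
#'
#' The mutation rate is identifiable only with date spread among the tips
#' (e.g. radiocarbon-dated aurochs); the rate estimated there is applied,
#' fixed, to the modern (contemporaneous) data set, with provenance
#' recorded.
#'
#' @param ancient_fit a `skyline_fit` whose run estimated the rate.
#' @return a list of class `rate_transfer` with `rate` (posterior median),
#'   `hpd` and provenance fields; pass `rate = transfer$rate` to
#'   [run_mcmc()] for the modern data.
#' @export
transfer_rate <- function(ancient_fit) {
  stopifnot(inherits(ancient_fit, "skyline_fit"))
  if (ancient_fit$config$n_distinct_dates < 2)
    stop("ancient run has no tip-date spread: rate unidentifiable")
  if (!is.na(ancient_fit$config$rate_fixed))
    stop("ancient run used a fixed rate; nothing to transfer")
  r <- ancient_fit$scalars$rate[ancient_fit$keep]
  structure(list(rate = median(r), hpd = hpd_interval(r),
                 n_samples = length(r),
                 source = "posterior median of tip-dated (ancient) run"),
            class = "rate_transfer")
}

#' Summarise a skyline posterior into a trajectory
#'
#' Evaluates every posterior sample's stepwise population-size function on a
#' time grid and reports the pointwise median and 95% HPD of
#' N_f x generation time (years).
#'
#' @param fit a `skyline_fit`.
#' @param grid time grid in YBP; defaults to 101 points from 0 to the
#'   posterior median root age.
#' @param prob HPD mass.
#' @return a data frame of class `skyline_trajectory`: `time_ybp`,
#'   `median`, `lower95`, `upper95`.
#' @export
summarize_trajectory <- function(fit, grid = NULL, prob = 0.95) {
  keep <- fit$keep
  if (length(keep) < 100)
    stop("need at least 100 post burn-in samples")
  roots <- fit$coal_times[keep, ncol(fit$coal_times)]
  if (is.null(grid))
    grid <- seq(0, stats::median(roots), length.out = 101)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (min(grid) > max(roots))
    warning("grid lies beyond all sampled root times; trajectory truncated")
  gcum <- cumsum(fit$group_sizes)
  m <- length(gcum)
  th <- fit$theta[keep, , drop = FALSE]
  ct <- fit$coal_times[keep, , drop = FALSE]
  vals <- matrix(NA_real_, length(keep), length(grid))
  for (i in seq_along(keep)) {
    bounds <- ct[i, gcum[-m]]           # group boundaries (times)
    gidx <- findInterval(grid, bounds) + 1L
    vals[i, ] <- th[i, gidx]
  }
  med <- apply(vals, 2, median)
  hpd <- apply(vals, 2, hpd_interval, prob = prob)
  out <- data.frame(time_ybp = grid, median = med,
                    lower95 = hpd[1, ], upper95 = hpd[2, ])
  class(out) <- c("skyline_trajectory", "data.frame")
  out
}

#' Write a trajectory to TSV
#' @param traj a `skyline_trajectory`.
#' @param path output path.
#' @export
write_trajectory <- function(traj, path) {
  write.table(traj, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
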