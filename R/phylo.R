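#' Time tree container
#'
#' A rooted topology with branch durations in Myr and tip ages in Ma
#' (0 = extant, > 0 = fossil tip terminating at its last appearance).
#'
#' @param phylo an `ape::phylo` object with branch lengths in Myr.
#' @param root_age age of the root in Ma.
#' @return object of class `time_tree` with `phylo`, `root_age`,
#'   `tip_ages` (named), `node_ages` (indexed by ape node number).
#' @export
time_tree <- function(phylo, root_age) {
  stopifnot(inherits(phylo, "phylo"), !is.null(phylo$edge.length))
  if (any(phylo$edge.length < 0)) stop("time_tree: negative branch duration")
  depth <- ape::node.depth.edgelength(phylo)
  ages <- root_age - depth
  if (any(ages < -1e-6)) stop("time_tree: tip older than root age implies")
  ntip <- length(phylo$tip.label)
  structure(list(phylo = phylo, root_age = root_age,
                 tip_ages = stats::setNames(ages[seq_len(ntip)], phylo$tip.label),
                 node_ages = ages),
            class = "time_tree")
}

#' @export
print.time_tree <- function(x, ...) {
  cat(sprintf("<time_tree> %d tips (%d extant), root age %.2f Ma\n",
              length(x$tip_ages), sum(x$tip_ages < 1e-8), x$root_age))
  invisible(x)
}

#' Prune a time tree to a subset of tips
#'
#' Drops the other tips while preserving every kept tip's age and the ages
#' of the retained internal nodes.
#'
#' @param tree a `time_tree`.
#' @param tips tip labels to keep (>= 2).
#' @return a `time_tree` on the subset.
#' @export
prune_time_tree <- function(tree, tips) {
  stopifnot(inherits(tree, "time_tree"), length(tips) >= 2L,
            all(tips %in% tree$phylo$tip.label))
  ph <- ape::keep.tip(tree$phylo, tips)
  d1 <- ape::node.depth.edgelength(ph)[1L]
  time_tree(ph, root_age = d1 + tree$tip_ages[[ph$tip.label[1L]]])
}

#' Estimate sampling and extinction rates from stratigraphic durations
#'
#' Constant-rates model: taxon durations are exponential with rate q (the
#' per-lineage-Myr extinction rate), observed at a finite stratigraphic
#' resolution, so durations shorter than one interval appear as
#' single-interval taxa. q is the maximum-likelihood estimate under
#' interval censoring; the per-lineage-Myr sampling rate r follows from
#' the singleton fraction, since with Poisson sampling at rate r the
#' probability that a sampled taxon is found in a single horizon is
#' q/(q + r). The speciation rate is set equal to the extinction rate.
#'
#' @param durations nonnegative stratigraphic durations in Myr.
#' @param interval_length stratigraphic resolution in Myr (default 1).
#' @return object of class `rate_estimates` with `sampling_rate`,
#'   `extinction_rate`, `speciation_rate` (all per lineage-Myr).
#' @export
estimate_rates <- function(durations, interval_length = 1) {
  d <- as.numeric(durations)
  if (length(d) < 3L) stop("estimate_rates: need at least 3 taxa")
  if (any(d < 0)) stop("estimate_rates: negative duration")
  if (all(d == 0))
    stop("estimate_rates: all durations zero (uninformative data)")
  dt <- interval_length
  single <- d < dt
  n1 <- sum(single)
  dl <- d[!single]
  if (length(dl) == 0L) {
    stop("estimate_rates: every duration below the interval resolution")
  } else if (n1 == 0L) {
    q <- 1 / mean(dl)
  } else {
    nll <- function(q) -(n1 * log1p(-exp(-q * dt)) +
                         length(dl) * log(q) - q * sum(dl))
    q <- stats::optimize(nll, c(1e-8, 1e4))$minimum
  }
  f1 <- (n1 + 0.5) / (length(d) + 1)   # continuity-corrected singleton fraction
  r <- q * (1 - f1) / f1
  structure(list(sampling_rate = r, extinction_rate = q, speciation_rate = q),
            class = "rate_estimates")
}

#' Time-calibrate a topology from fossil occurrence data
#'
#' Stochastic minimum-age calibration: tips terminate at their last
#' appearance; each node's age is the oldest constraint among its children
#' (child node ages and descendant first appearances) plus an
#' Exponential(sampling_rate) extension, applied tip-to-root. Higher
#' sampling rates imply shorter unsampled history, so extensions shrink
#' toward zero as the sampling rate grows. Every node is therefore at
#' least as old as the oldest first appearance among its descendants, and
#' no branch has zero length.
#'
#' @param topology a rooted `ape::phylo` (branch lengths ignored).
#' @param occurrences data.frame with columns `taxon`, `first_appearance`,
#'   `last_appearance` (Ma), one row per tip.
#' @param rates a `rate_estimates` object.
#' @param n_trees number of calibrated trees to draw.
#' @param seed integer seed; same seed reproduces the tree list exactly.
#' @return list of `time_tree` objects, length `n_trees`.
#' @export
time_calibrate <- function(topology, occurrences, rates, n_trees = 250L,
                           seed = 1L) {
  stopifnot(inherits(topology, "phylo"), inherits(rates, "rate_estimates"))
  tips <- topology$tip.label
  occ <- as.data.frame(occurrences)
  miss <- setdiff(tips, occ$taxon)
  if (length(miss))
    stop("time_calibrate: tips without occurrence records: ",
         paste(miss, collapse = ", "))
  o <- occ[match(tips, occ$taxon), ]
  if (any(o$first_appearance < o$last_appearance) || any(o$last_appearance < 0))
    stop("time_calibrate: occurrence records must satisfy first >= last >= 0")
  ntip <- length(tips)
  nnode <- topology$Nnode
  edge <- topology$edge
  # children-first order over internal nodes
  po <- unique(ape::reorder.phylo(topology, "postorder")$edge[, 1L])
  children <- split(edge[, 2L], edge[, 1L])
  set.seed(as.integer(seed))
  rate <- rates$sampling_rate
  lapply(seq_len(n_trees), function(tr) {
    ages <- numeric(ntip + nnode)
    ages[seq_len(ntip)] <- o$last_appearance
    for (nd in po) {
      ch <- children[[as.character(nd)]]
      cons <- max(ifelse(ch <= ntip, o$first_appearance[ch], ages[ch]))
      ages[nd] <- cons + stats::rexp(1L, rate)
    }
    ph <- topology
    ph$edge.length <- ages[edge[, 1L]] - ages[edge[, 2L]]
    time_tree(ph, root_age = ages[ntip + 1L])
  })
}

#' Average a sample of time trees sharing one topology
#'
#' Node ages are averaged arithmetically across the trees; the topology is
#' unchanged. This is the consensus used downstream for phylogenetic
#' signal and PGLS.
#'
#' @param trees list of `time_tree` objects on an identical topology.
#' @return a single consensus `time_tree`.
#' @export
consensus_tree <- function(trees) {
  stopifnot(length(trees) >= 1L,
            all(vapply(trees, inherits, TRUE, "time_tree")))
  ref <- trees[[1L]]$phylo
  for (t in trees[-1L]) {
    same <- identical(t$phylo$edge, ref$edge) &&
      identical(t$phylo$tip.label, ref$tip.label)
    if (!same) stop("consensus_tree: trees differ in topology")
  }
  ages <- Reduce(`+`, lapply(trees, `[[`, "node_ages")) / length(trees)
  ph <- ref
  ph$edge.length <- ages[ref$edge[, 1L]] - ages[ref$edge[, 2L]]
  time_tree(ph, root_age = ages[length(ref$tip.label) + 1L])
}

#' Brownian-motion covariance matrix of a time tree
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j;
#' the diagonal is root-to-tip depth. Computed with `ape::vcv.phylo`.
#'
#' @param tree a `time_tree`.
#' @return symmetric positive semi-definite matrix with tip-name dimnames.
#' @export
bm_covariance <- function(tree) {
  stopifnot(inherits(tree, "time_tree"))
  ape::vcv.phylo(tree$phylo)
}

# C^(-1/2) via symmetric eigendecomposition
inv_sqrt_spd <- function(C, tol = 1e-10) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < tol * max(e$values))
    stop("covariance matrix numerically singular; ",
         "consider a minimum branch-length floor")
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

k_mult_stat <- function(Y, Ci, Cihalf, denom_expect, n) {
  a <- colSums(Ci %*% Y) / sum(Ci)
  Yc <- sweep(Y, 2L, a)
  mse0 <- sum(Yc^2) / (n - 1)
  U <- Cihalf %*% Yc
  mse <- sum(U^2) / (n - 1)
  (mse0 / mse) / denom_expect
}

#' Multivariate Blomberg's K with a permutation test
#'
#' Generalization of Blomberg's K to multivariate data: the ratio of the
#' observed mean squared deviation from the phylogenetically weighted root
#' state (in the raw vs the phylogenetically whitened space, via traces
#' over the Brownian-motion covariance) to its expectation under Brownian
#' motion, for which K = 1. Significance is assessed by permuting tip
#' rows, with the add-one convention p = (b + 1)/(n_perm + 1).
#'
#' @param data n x d matrix, rows named by (or ordered as) the tree tips.
#' @param tree a `time_tree`.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return object of class `phylo_signal_result`: `K`, `p_value`,
#'   `n_permutations`.
#' @export
blomberg_k_mult <- function(data, tree, n_perm = 1000L, seed = 1L) {
  Y <- as.matrix(data)
  C <- bm_covariance(tree)
  n <- nrow(C)
  if (nrow(Y) != n) stop("blomberg_k_mult: rows must match tree tips")
  if (!is.null(rownames(Y))) {
    if (!setequal(rownames(Y), colnames(C)))
      stop("blomberg_k_mult: data row names do not match tip labels")
    Y <- Y[colnames(C), , drop = FALSE]
  }
  if (sum(scale(Y, scale = FALSE)^2) == 0)
    stop("blomberg_k_mult: zero variance in data")
  Ci <- solve(C)
  Cihalf <- inv_sqrt_spd(C)
  denom_expect <- (sum(diag(C)) - n / sum(Ci)) / (n - 1)
  k_obs <- k_mult_stat(Y, Ci, Cihalf, denom_expect, n)
  set.seed(as.integer(seed))
  k_perm <- vapply(seq_len(n_perm), function(b)
    k_mult_stat(Y[sample.int(n), , drop = FALSE], Ci, Cihalf,
                denom_expect, n), numeric(1))
  p <- (sum(k_perm >= k_obs) + 1) / (n_perm + 1)
  structure(list(K = k_obs, p_value = p, n_permutations = n_perm),
            class = "phylo_signal_result")
}

#' @export
print.phylo_signal_result <- function(x, ...) {
  cat(sprintf("Blomberg's K (multivariate): K = %.4f, p = %.4g (%d permutations)\n",
              x$K, x$p_value, x$n_permutations))
  invisible(x)
}

#' Maximum-likelihood Brownian-motion ancestral states
#'
#' Joint ML estimates of internal-node states under Brownian motion:
#' the branch-length-weighted harmonic interpolation that minimizes
#' sum over edges of (x_parent - x_child)^2 / length, solved as one
#' sparse linear system for all trait columns. The root estimate equals
#' the generalized-least-squares root state.
#'
#' @param data n x d matrix, rows named by (or ordered as) the tips.
#' @param tree a `time_tree`.
#' @return (number of internal nodes) x d matrix, rows named by ape node
#'   number (root first).
#' @export
ancestral_states_bm <- function(data, tree) {
  Y <- as.matrix(data)
  ph <- tree$phylo
  ntip <- length(ph$tip.label)
  nnode <- ph$Nnode
  if (nrow(Y) != ntip) stop("ancestral_states_bm: rows must match tips")
  if (!is.null(rownames(Y))) Y <- Y[ph$tip.label, , drop = FALSE]
  w <- 1 / pmax(ph$edge.length, 1e-12)
  A <- matrix(0, nnode, nnode)
  B <- matrix(0, nnode, ncol(Y))
  for (e in seq_len(nrow(ph$edge))) {
    p <- ph$edge[e, 1L] - ntip
    ch <- ph$edge[e, 2L]
    A[p, p] <- A[p, p] + w[e]
    if (ch <= ntip) {
      B[p, ] <- B[p, ] + w[e] * Y[ch, ]
    } else {
      q <- ch - ntip
      A[q, q] <- A[q, q] + w[e]
      A[p, q] <- A[p, q] - w[e]
      A[q, p] <- A[q, p] - w[e]
    }
  }
  est <- solve(A, B)
  rownames(est) <- as.character(ntip + seq_len(nnode))
  colnames(est) <- colnames(Y)
  est
}
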