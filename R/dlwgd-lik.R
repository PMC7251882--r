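#' Gene-family filters for the reconciliation-stage count matrix
#'
#' Two filters are applied in order. First, families absent from either
#' of the two clades stemming from the species-tree root are removed
#' (such families could have originated de novo inside an arbitrary
#' subtree and carry no information about the root process). Second, a
#' Poisson outlier criterion on the surviving families: under an
#' approximately Poisson total size `X`, the transform `Y = 2*sqrt(X)`
#' is approximately Normal(median(Y), 1), so families with
#' `Y > median(Y) + 3` are removed as outliers.
#'
#' @param counts families x species integer matrix (species names must
#'   match the tree's tips).
#' @param tree dated species tree.
#' @return list with `counts` (the retained matrix) and `report`: one
#'   row per input family with `X`, `Y`, the threshold, root-clade
#'   presence flags, `kept` and `reason` (`""`, `"root_clade"` or
#'   `"poisson_outlier"`).
#' @examples
#' tr <- as_dated_tree("((A:1,B:1):1,(C:1,D:1):1);")
#' m <- rbind(f1 = c(A = 1, B = 1, C = 1, D = 1), f2 = c(2, 0, 0, 0))
#' filter_families(m, tr)$report
#' @export
filter_families <- function(counts, tree) {
  tree <- as_dated_tree(tree)
  if (!all(tree$tip.label %in% colnames(counts)))
    stop("count matrix lacks species present in the tree")
  counts <- counts[, tree$tip.label, drop = FALSE]
  clades <- root_clades(tree)
  in1 <- rowSums(counts[, clades[[1]], drop = FALSE]) > 0
  in2 <- rowSums(counts[, clades[[2]], drop = FALSE]) > 0
  X <- rowSums(counts)
  Y <- 2 * sqrt(X)
  root_ok <- in1 & in2
  # the outlier threshold uses the median over the root-filter survivors
  medY <- stats::median(Y[root_ok])
  thr <- medY + 3
  outlier <- Y > thr
  kept <- root_ok & !outlier
  report <- data.frame(family = rownames(counts), X = X, Y = Y,
                       threshold = thr, in_clade1 = in1, in_clade2 = in2,
                       kept = kept,
                       reason = ifelse(!root_ok, "root_clade",
                                ifelse(outlier, "poisson_outlier", "")),
                       row.names = NULL, stringsAsFactors = FALSE)
  list(counts = counts[kept, , drop = FALSE], report = report)
}

#' Log-likelihood of gene-family counts under the DL+WGD model
#'
#' Pruning recursion over the species tree on count states `0..bound`:
#' along every branch the count distribution evolves by the linear
#' birth-death kernel (see [bd_transition_probability()]); at a
#' hypothesized WGD each gene independently adds a retained copy with
#' probability `q` (binomial thinning-doubling); the root count is
#' marginalized over the geometric prior on `{1, 2, ...}` with parameter
#' `eta`; and the likelihood is conditioned on the family-inclusion
#' event of [filter_families()] — at least one surviving gene in each
#' clade stemming from the root.
#'
#' @param counts a named integer vector (one family) or a families x
#'   species matrix.
#' @param tree dated species tree.
#' @param lambda,mu rates, scalar or named per branch (see
#'   [branch_ids()]).
#' @param eta geometric root-prior parameter.
#' @param wgds `NULL` or WGD hypotheses (see [wgd_hypothesis()]); `q`
#'   supplies their retention rates when the hypotheses carry none.
#' @param q optional vector of retention rates overriding `wgds$q`.
#' @param bound state-space truncation bound; defaults to
#'   `4 * max(counts) + 10` and must be at least twice the largest
#'   observed count. A probability-mass leak above `1e-6` in the
#'   reachable states raises an error.
#' @return log-likelihood (summed over families when `counts` is a
#'   matrix); per-family values are attached as `attr(, "per_family")`.
#' @export
family_loglikelihood <- function(counts, tree, lambda, mu, eta = 0.9,
                                 wgds = NULL, q = NULL, bound = NULL) {
  tree <- as_dated_tree(tree)
  if (is.null(dim(counts))) counts <- matrix(counts, 1L,
                                             dimnames = list("fam1", names(counts)))
  if (!all(tree$tip.label %in% colnames(counts)))
    stop("counts lack species present in the tree")
  counts <- counts[, tree$tip.label, drop = FALSE]
  ids <- branch_ids(tree)
  lam <- expand_branch_rates(lambda, ids, "lambda")
  mur <- expand_branch_rates(mu, ids, "mu")
  wgds <- resolve_wgds(wgds, tree)
  if (is.null(q)) q <- wgds$q
  if (nrow(wgds) && (length(q) != nrow(wgds) || anyNA(q)))
    stop("a retention rate is needed for every WGD hypothesis")
  maxc <- if (length(counts)) max(counts) else 0L
  if (is.null(bound)) bound <- 4L * maxc + 10L
  if (bound < 2L * maxc) stop("truncation bound must be >= 2 x max observed count")
  ll <- loglik_pruning(counts, tree, lam, mur, eta, wgds, q, bound)
  out <- sum(ll)
  attr(out, "per_family") <- ll
  out
}

# per-branch operator matrices, with the truncation-leak check over the
# states the observed counts can reach
build_branch_ops <- function(tree, lam, mur, wgds, q, N, max_count) {
  ntip <- length(tree$tip.label)
  nl <- node_labels(tree)
  wnode <- if (nrow(wgds)) branch_node(tree, wgds$branch) else integer(0)
  ops <- vector("list", ntip + tree$Nnode)
  reach <- min(N, max(2L, 2L * max_count))
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    sel <- wnode == child
    ops[[child]] <- branch_operator(N, tree$edge.length[e], lam[[nl[child]]],
                                    mur[[nl[child]]],
                                    if (any(sel)) wgds[sel, , drop = FALSE] else NULL,
                                    q[sel])
    leak <- 1 - rowSums(ops[[child]])[seq_len(reach + 1L)]
    if (any(leak > 1e-6))
      stop("truncation bound too small: probability-mass leak ",
           format(max(leak), digits = 3))
  }
  ops
}

# vectorized-over-families pruning; returns per-family log-likelihoods
loglik_pruning <- function(counts, tree, lam, mur, eta, wgds, q, N, ops = NULL) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nl <- node_labels(tree)
  Fn <- nrow(counts)
  wnode <- if (nrow(wgds)) branch_node(tree, wgds$branch) else integer(0)
  if (is.null(ops))
    ops <- build_branch_ops(tree, lam, mur, wgds, q, N, max(counts, 0L))

  # postorder partials, states x families, with per-family log scaling
  logscale <- if (Fn) rep(0, Fn) else numeric(0)
  partial <- vector("list", ntip + tree$Nnode)
  for (tip in seq_len(ntip)) {
    Pm <- matrix(0, N + 1L, Fn)
    cc <- pmin(counts[, tip], N)
    Pm[cbind(cc + 1L, seq_len(Fn))] <- 1
    partial[[tip]] <- Pm
  }
  nodes_post <- rev(unique(tree$edge[order(tree$edge[, 1], decreasing = FALSE), 1]))
  # ensure children before parents: process internal nodes in decreasing
  # height order via a simple postorder on edges
  po <- postorder_nodes(tree)
  for (v in po) {
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    Pm <- ops[[kids[1]]] %*% partial[[kids[1]]]
    for (k in kids[-1]) Pm <- Pm * (ops[[k]] %*% partial[[k]])
    if (Fn) {
      mx <- apply(Pm, 2, max)
      mx[mx <= 0] <- 1
      Pm <- sweep(Pm, 2, mx, "/")
      logscale <- logscale + log(mx)
    }
    partial[[v]] <- Pm
  }
  geomv <- c(0, eta * (1 - eta)^(0:(N - 1L)))
  lik <- as.numeric(geomv %*% partial[[root]])
  # conditioning on >= 1 survivor in each root clade
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  ext <- vapply(kids, function(k) subtree_extinction(k, tree, lam, mur, wgds, q, wnode),
                numeric(1))
  S <- function(x) if (x <= 0) 0 else eta * x / (1 - (1 - eta) * x)
  pinc <- 1 - S(ext[1]) - S(ext[2]) + S(ext[1] * ext[2])
  log(pmax(lik, 1e-300)) + logscale - log(pinc)
}

postorder_nodes <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  out <- integer(0)
  walk <- function(v) {
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    for (k in kids) if (k > ntip) walk(k)
    out <<- c(out, v)
  }
  walk(root)
  out
}

# probability that one gene at node `child`'s parent end of the branch
# leaves no observed descendants at the leaves below `child`
subtree_extinction <- function(child, tree, lam, mur, wgds, q, wnode) {
  ntip <- length(tree$tip.label)
  nl <- node_labels(tree)
  z <- if (child <= ntip) 0 else {
    kids <- tree$edge[tree$edge[, 1] == child, 2]
    prod(vapply(kids, function(k)
      subtree_extinction(k, tree, lam, mur, wgds, q, wnode), numeric(1)))
  }
  e <- match(child, tree$edge[, 2])
  sel <- wnode == child
  branch_extinction(z, tree$edge.length[e], lam[[nl[child]]], mur[[nl[child]]],
                    if (any(sel)) wgds[sel, , drop = FALSE] else NULL, q[sel])
}
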