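#' Rate models for the DL+WGD process
#'
#' Bundles the branch-wise duplication rate `lambda`, loss rate `mu`
#' (events/gene lineage/My), root-size parameter `eta`, per-WGD
#' retention rates `q`, and the prior structure:
#' \itemize{
#'   \item `constant` — one `lambda` and one `mu` for the whole tree;
#'     `lambda, mu ~ Exponential(mean 0.005)`, `eta ~ Beta(10, 2)`.
#'   \item `independent_rates` — branch-wise rates, iid log-normal:
#'     `log lambda_b ~ Normal(log m_lambda, sigma2)` (same for `mu_b`),
#'     with `m_lambda, m_mu ~ Exponential(mean 0.5)` and
#'     `sigma2 ~ InverseGamma(5, 1)`.
#'   \item `gbm` — geometric Brownian motion along the tree: a child
#'     branch's log-rate diffuses from its parent's with drift
#'     `-nu^2 t / 2` and variance `nu^2 t` (`nu = 0.1`, strong
#'     phylogenetic correlation); the two root-adjacent branches start
#'     from `log m` with `m ~ Exponential(mean 0.5)`.
#' }
#' Retention rates are uniform on `[0, 1]` in all structures.
#'
#' @param tree dated species tree.
#' @param structure `"constant"`, `"independent_rates"` or `"gbm"`.
#' @param lambda,mu scalar (constant) or per-branch named vectors.
#' @param eta root-prior parameter in `(0, 1]`.
#' @param q numeric vector of retention rates (one per WGD hypothesis).
#' @param hyper list of hyperparameters: `m_lambda`, `m_mu`, `sigma2`
#'   (independent_rates), `nu` (gbm, default 0.1).
#' @return object of class `rate_model`.
#' @export
rate_model <- function(tree, structure = c("constant", "independent_rates", "gbm"),
                       lambda = 0.002, mu = 0.002, eta = 0.8, q = numeric(0),
                       hyper = list()) {
  structure <- match.arg(structure)
  tree <- as_dated_tree(tree)
  ids <- branch_ids(tree)
  lam <- expand_branch_rates(lambda, ids, "lambda")
  mur <- expand_branch_rates(mu, ids, "mu")
  if (structure == "constant" &&
      (length(unique(lam)) > 1L || length(unique(mur)) > 1L))
    stop("constant structure requires equal rates on all branches")
  if (any(lam < 0) || any(mur < 0)) stop("rates must be non-negative")
  if (eta <= 0 || eta > 1) stop("eta must lie in (0, 1]")
  if (length(q) && (any(q < 0) || any(q > 1))) stop("q must lie in [0, 1]")
  defaults <- list(m_lambda = 0.5, m_mu = 0.5, sigma2 = 1, nu = 0.1)
  hyper <- utils::modifyList(defaults, hyper)
  base::structure(list(tree = tree, structure = structure, lambda = lam,
                       mu = mur, eta = eta, q = q, hyper = hyper),
                  class = "rate_model")
}

dinvgamma_log <- function(x, shape, rate) {
  if (x <= 0) return(-Inf)
  shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x
}

#' Log prior density of a rate model
#'
#' @param model a [rate_model()].
#' @return the log prior density; `-Inf` outside the support.
#' @export
prior_logdensity <- function(model) {
  stopifnot(inherits(model, "rate_model"))
  lam <- model$lambda; mur <- model$mu; eta <- model$eta; q <- model$q
  h <- model$hyper
  if (any(lam < 0) || any(mur < 0) || eta <= 0 || eta > 1 ||
      (length(q) && (any(q < 0) || any(q > 1)))) return(-Inf)
  lp <- stats::dbeta(eta, 10, 2, log = TRUE)
  lp <- lp + sum(stats::dunif(q, 0, 1, log = TRUE))
  if (model$structure == "constant") {
    lp <- lp + stats::dexp(lam[1], 1 / 0.005, log = TRUE) +
               stats::dexp(mur[1], 1 / 0.005, log = TRUE)
    return(as.numeric(lp))
  }
  if (h$m_lambda <= 0 || h$m_mu <= 0 || h$sigma2 <= 0) return(-Inf)
  lp <- lp + stats::dexp(h$m_lambda, 1 / 0.5, log = TRUE) +
             stats::dexp(h$m_mu, 1 / 0.5, log = TRUE)
  if (model$structure == "independent_rates") {
    lp <- lp + dinvgamma_log(h$sigma2, 5, 1)
    s <- sqrt(h$sigma2)
    lp <- lp + sum(stats::dlnorm(lam, log(h$m_lambda), s, log = TRUE)) +
               sum(stats::dlnorm(mur, log(h$m_mu), s, log = TRUE))
    return(as.numeric(lp))
  }
  # gbm: diffusion of log rates along the tree, drift-corrected so the
  # rate process is a martingale in expectation
  tree <- model$tree
  nu <- h$nu
  nl <- node_labels(tree)
  root <- length(tree$tip.label) + 1L
  for (rates in list(list(v = lam, m = h$m_lambda), list(v = mur, m = h$m_mu))) {
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      t <- tree$edge.length[e]
      parent_log <- if (parent == root) log(rates$m) else log(rates$v[[nl[parent]]])
      lp <- lp + stats::dnorm(log(rates$v[[nl[child]]]),
                              parent_log - nu^2 * t / 2, nu * sqrt(t), log = TRUE) -
            log(rates$v[[nl[child]]])  # Jacobian: density on the rate scale
    }
  }
  as.numeric(lp)
}
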