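#' Bayesian inference of duplication/loss rates and WGD retention
#'
#' Adaptive random-walk Metropolis sampling of the DL+WGD model
#' posterior from a filtered gene-family count matrix on a dated species
#' tree. Rates are proposed on the log scale and `eta` and the retention
#' rates on the logit scale, in blocks (rates, hyperparameters, `eta`,
#' each `q`); proposal scales adapt toward a 30% acceptance rate during
#' burn-in and are frozen afterwards. With `n_chains > 1`, independent
#' chains are run and convergence is summarized by the split-chain
#' statistic; pilot chains on random family subsets (the usual check
#' before committing to a full run) are available via `n_pilot_chains`.
#'
#' `dlwgd()` is the one-stop fitting function: it applies
#' [filter_families()] and then calls `run_mcmc()`.
#'
#' @param counts families x species count matrix (already filtered for
#'   `run_mcmc()`; `dlwgd()` filters internally). A matrix with zero
#'   rows yields prior-only sampling.
#' @param tree dated species tree.
#' @param wgds `NULL` or WGD hypotheses (see [wgd_hypothesis()]); their
#'   retention rates become free parameters.
#' @param structure prior structure, see [rate_model()].
#' @param n_iter,burnin chain length and burn-in (defaults 11000/1000,
#'   the full-data regime; reduce for pilot-scale work).
#' @param n_chains number of independent chains.
#' @param n_pilot_chains number of pilot chains on random subsets of
#'   `pilot_size` families (0 to skip).
#' @param pilot_size families per pilot subset.
#' @param eta_fixed fix `eta` at this value instead of sampling it (the
#'   usual practice after a constant-rates run).
#' @param constrain_root for branch-wise structures, constrain the two
#'   branches stemming from the root to share duplication and loss rates.
#' @param bound state-space truncation bound (see
#'   [family_loglikelihood()]).
#' @param seed integer seed.
#' @param thin keep every `thin`-th post-burn-in sample.
#' @return object of class `dlwgd` with posterior draws (`$trace`, a
#'   data.frame pooling all chains; `$chains` keeps them separate),
#'   acceptance rates, and diagnostics; see [summary.dlwgd()],
#'   [coef.dlwgd()], [summarize_wgd_support()].
#' @export
run_mcmc <- function(counts, tree, wgds = NULL,
                     structure = c("constant", "independent_rates", "gbm"),
                     n_iter = 11000, burnin = 1000, n_chains = 1,
                     n_pilot_chains = 0, pilot_size = 1000,
                     eta_fixed = NULL, constrain_root = FALSE,
                     bound = NULL, seed = NULL, thin = 1) {
  structure <- match.arg(structure)
  tree <- as_dated_tree(tree)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(counts)) counts <- matrix(0L, 0L, length(tree$tip.label),
                                        dimnames = list(NULL, tree$tip.label))
  if (nrow(counts)) counts <- counts[, tree$tip.label, drop = FALSE]
  wgds <- resolve_wgds(wgds, tree)
  maxc <- if (nrow(counts)) max(counts) else 0L
  if (is.null(bound)) bound <- 4L * maxc + 10L

  par <- mcmc_parameterization(tree, structure, wgds, eta_fixed, constrain_root)
  pilots <- list()
  if (n_pilot_chains > 0 && nrow(counts) > pilot_size) {
    for (p in seq_len(n_pilot_chains)) {
      sub <- counts[sample.int(nrow(counts), pilot_size), , drop = FALSE]
      pilots[[p]] <- mcmc_chain(sub, tree, wgds, structure, par,
                                n_iter = max(2000, n_iter %/% 4),
                                burnin = max(200, burnin %/% 4),
                                bound = bound, thin = thin)
    }
  }
  chains <- lapply(seq_len(n_chains), function(ch)
    mcmc_chain(counts, tree, wgds, structure, par, n_iter, burnin, bound, thin))
  trace <- do.call(rbind, lapply(chains, `[[`, "trace"))
  out <- base::structure(list(
    trace = trace, chains = chains, pilots = pilots,
    param_names = colnames(chains[[1]]$trace),
    accept = chains[[1]]$accept, structure = structure, tree = tree,
    wgds = wgds, n_families = nrow(counts), n_iter = n_iter, burnin = burnin,
    n_chains = n_chains, eta_fixed = eta_fixed, bound = bound, seed = seed),
    class = "dlwgd")
  out
}

#' @rdname run_mcmc
#' @param ... passed on to `run_mcmc()`.
#' @export
dlwgd <- function(counts, tree, wgds = NULL, structure = "constant", ...) {
  tree <- as_dated_tree(tree)
  flt <- filter_families(counts, tree)
  fit <- run_mcmc(flt$counts, tree, wgds = wgds, structure = structure, ...)
  fit$filter_report <- flt$report
  fit
}

# parameter bookkeeping: names, transforms, block structure
mcmc_parameterization <- function(tree, structure, wgds, eta_fixed, constrain_root) {
  ids <- branch_ids(tree)
  root <- length(tree$tip.label) + 1L
  root_kids <- node_labels(tree)[tree$edge[tree$edge[, 1] == root, 2]]
  rate_ids <- ids
  tie <- NULL
  if (constrain_root && structure != "constant") {
    rate_ids <- setdiff(ids, root_kids[2])
    tie <- c(root_kids[2], root_kids[1])  # second root branch copies the first
  }
  nm <- if (structure == "constant") c("lambda", "mu") else
    c(paste0("lambda_", rate_ids), paste0("mu_", rate_ids),
      "m_lambda", "m_mu", if (structure == "independent_rates") "sigma2")
  if (is.null(eta_fixed)) nm <- c(nm, "eta")
  if (nrow(wgds)) nm <- c(nm, paste0("q_", wgds$name))
  blocks <- list()
  if (structure == "constant") blocks$rates <- c("lambda", "mu")
  else {
    for (b in rate_ids) blocks[[paste0("rates_", b)]] <- paste0(c("lambda_", "mu_"), b)
    blocks$hyper <- intersect(c("m_lambda", "m_mu", "sigma2"), nm)
  }
  if (is.null(eta_fixed)) blocks$eta <- "eta"
  for (qn in grep("^q_", nm, value = TRUE)) blocks[[qn]] <- qn
  list(names = nm, blocks = blocks, rate_ids = rate_ids, tie = tie,
       eta_fixed = eta_fixed, structure = structure)
}

mcmc_unpack <- function(theta, par, tree, wgds) {
  ids <- branch_ids(tree)
  h <- list(m_lambda = 0.5, m_mu = 0.5, sigma2 = 1, nu = 0.1)
  if (par$structure == "constant") {
    lam <- stats::setNames(rep(exp(theta[["lambda"]]), length(ids)), ids)
    mur <- stats::setNames(rep(exp(theta[["mu"]]), length(ids)), ids)
  } else {
    lam <- stats::setNames(exp(theta[paste0("lambda_", par$rate_ids)])[match(ids, par$rate_ids)], ids)
    mur <- stats::setNames(exp(theta[paste0("mu_", par$rate_ids)])[match(ids, par$rate_ids)], ids)
    if (!is.null(par$tie)) {
      lam[par$tie[1]] <- lam[par$tie[2]]
      mur[par$tie[1]] <- mur[par$tie[2]]
    }
    h$m_lambda <- exp(theta[["m_lambda"]])
    h$m_mu <- exp(theta[["m_mu"]])
    if (par$structure == "independent_rates") h$sigma2 <- exp(theta[["sigma2"]])
  }
  eta <- if (is.null(par$eta_fixed)) stats::plogis(theta[["eta"]]) else par$eta_fixed
  q <- if (nrow(wgds)) stats::plogis(theta[grep("^q_", par$names, value = TRUE)]) else numeric(0)
  list(lambda = lam, mu = mur, eta = eta, q = unname(q), hyper = h)
}

# log posterior = log prior (+ transform Jacobians) + log likelihood;
# branch operators are cached across evaluations keyed on (rates, q)
mcmc_logpost <- function(theta, par, counts, tree, wgds, bound, cache = NULL) {
  st <- mcmc_unpack(theta, par, tree, wgds)
  model <- try(rate_model(tree, par$structure, st$lambda, st$mu, st$eta, st$q,
                          hyper = st$hyper), silent = TRUE)
  if (inherits(model, "try-error")) return(-Inf)
  lp <- prior_logdensity(model)
  if (!is.finite(lp)) return(-Inf)
  # Jacobians of the log transform on rates/hypers and logit on eta/q
  rate_par <- grep("^(lambda|mu|m_lambda|m_mu|sigma2)", par$names, value = TRUE)
  lp <- lp + sum(theta[rate_par])
  logit_par <- grep("^(eta$|q_)", par$names, value = TRUE)
  if (length(logit_par)) {
    pv <- stats::plogis(theta[logit_par])
    lp <- lp + sum(log(pv) + log1p(-pv))
  }
  if (nrow(counts)) {
    ops <- NULL
    key <- NULL
    if (!is.null(cache)) {
      key <- paste(c(st$lambda, st$mu, st$q), collapse = ",")
      ops <- cache$store[[key]]
    }
    if (is.null(ops)) {
      ops <- try(build_branch_ops(tree, st$lambda, st$mu, wgds, st$q, bound,
                                  max(counts, 0L)), silent = TRUE)
      if (inherits(ops, "try-error")) return(-Inf)
      if (!is.null(cache)) {
        cache$store[[key]] <- ops
        if (length(cache$store) > 3) cache$store[[1]] <- NULL
      }
    }
    ll <- try(loglik_pruning(counts, tree, st$lambda, st$mu, st$eta, wgds, st$q,
                             bound, ops = ops), silent = TRUE)
    if (inherits(ll, "try-error") || !all(is.finite(ll))) return(-Inf)
    lp <- lp + sum(ll)
  }
  lp
}

mcmc_chain <- function(counts, tree, wgds, structure, par, n_iter, burnin,
                       bound, thin) {
  nm <- par$names
  theta <- stats::setNames(numeric(length(nm)), nm)
  theta[grep("^(lambda|mu)", nm)] <- log(0.002)
  theta[grep("^(m_lambda|m_mu)", nm)] <- log(0.002)
  if ("sigma2" %in% nm) theta["sigma2"] <- log(0.2)
  if ("eta" %in% nm) theta["eta"] <- stats::qlogis(10 / 12)
  theta[grep("^q_", nm)] <- stats::qlogis(0.2)
  cache <- new.env(parent = emptyenv())
  cache$store <- list()
  lp <- mcmc_logpost(theta, par, counts, tree, wgds, bound, cache)
  if (!is.finite(lp)) stop("non-finite initial posterior density")

  scales <- stats::setNames(rep(0.3, length(par$blocks)), names(par$blocks))
  acc <- win <- stats::setNames(numeric(length(par$blocks)), names(par$blocks))
  keep <- floor((n_iter - burnin) / thin)
  trace <- matrix(NA_real_, keep, length(nm) + 1L,
                  dimnames = list(NULL, c(nm, "logpost")))
  k <- 0L
  for (it in seq_len(n_iter)) {
    for (bl in names(par$blocks)) {
      idx <- par$blocks[[bl]]
      prop <- theta
      prop[idx] <- prop[idx] + stats::rnorm(length(idx), 0, scales[[bl]])
      lp2 <- mcmc_logpost(prop, par, counts, tree, wgds, bound, cache)
      if (is.finite(lp2) && log(stats::runif(1)) < lp2 - lp) {
        theta <- prop; lp <- lp2
        acc[[bl]] <- acc[[bl]] + 1
      }
      win[[bl]] <- win[[bl]] + 1
      if (it <= burnin && win[[bl]] %% 25 == 0) {
        rate <- acc[[bl]] / win[[bl]]
        scales[[bl]] <- min(5, max(1e-3, scales[[bl]] * exp(rate - 0.3)))
      }
    }
    if (it > burnin && (it - burnin) %% thin == 0 && k < keep) {
      k <- k + 1L
      st <- mcmc_unpack(theta, par, tree, wgds)
      natural <- c(
        if (par$structure == "constant") c(st$lambda[1], st$mu[1]) else
          c(st$lambda[par$rate_ids], st$mu[par$rate_ids],
            st$hyper$m_lambda, st$hyper$m_mu,
            if (par$structure == "independent_rates") st$hyper$sigma2),
        if (is.null(par$eta_fixed)) st$eta,
        st$q)
      trace[k, ] <- c(natural, lp)
    }
  }
  list(trace = as.data.frame(trace[seq_len(k), , drop = FALSE]),
       accept = acc / pmax(win, 1), scales = scales)
}

#' @export
print.dlwgd <- function(x, ...) {
  cat("DL+WGD posterior fit (", x$structure, " rates)\n", sep = "")
  cat("  families:", x$n_families, "| chains:", x$n_chains,
      "| iterations:", x$n_iter, "(burn-in", paste0(x$burnin, ")"), "\n")
  if (nrow(x$wgds)) cat("  WGD hypotheses:", paste(x$wgds$name, collapse = ", "), "\n")
  s <- summary(x)
  print(s[, c("mean", "q2.5", "q97.5")], digits = 4)
  invisible(x)
}

#' Posterior summary of a DL+WGD fit
#'
#' @param object a [dlwgd] fit.
#' @param ... unused.
#' @return data.frame with posterior mean, 2.5/97.5% quantiles,
#'   effective sample size and (for multiple chains) the split-chain
#'   convergence statistic per parameter.
#' @export
summary.dlwgd <- function(object, ...) {
  tr <- object$trace
  pars <- setdiff(colnames(tr), "logpost")
  out <- data.frame(
    mean = vapply(tr[pars], mean, numeric(1)),
    q2.5 = vapply(tr[pars], stats::quantile, numeric(1), probs = 0.025),
    q97.5 = vapply(tr[pars], stats::quantile, numeric(1), probs = 0.975),
    ess = vapply(tr[pars], ess, numeric(1)),
    rhat = vapply(pars, function(p) split_rhat(
      lapply(object$chains, function(ch) ch$trace[[p]])), numeric(1)))
  rownames(out) <- pars
  out
}

#' @export
coef.dlwgd <- function(object, ...) {
  s <- summary(object)
  stats::setNames(s$mean, rownames(s))
}

#' @export
logLik.dlwgd <- function(object, ...) {
  ll <- mean(object$trace$logpost)
  base::structure(ll, df = length(object$param_names), class = "logLik")
}

#' @export
plot.dlwgd <- function(x, pars = NULL, ...) {
  pars <- pars %||% utils::head(setdiff(colnames(x$trace), "logpost"), 4)
  old <- graphics::par(mfrow = c(length(pars), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (p in pars)
    graphics::plot(x$trace[[p]], type = "l", ylab = p, xlab = "", ...)
  invisible(x)
}

# effective sample size from the initial positive autocorrelation sequence
ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  s <- if (length(pos)) sum(ac[seq_len(pos[1] - 1)]) else sum(ac)
  max(1, n / (1 + 2 * max(s, 0)))
}

# split-chain convergence statistic (each chain halved)
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    h <- length(x) %/% 2
    if (h < 2) return(NULL)
    list(x[seq_len(h)], x[(h + 1):(2 * h)])
  }), recursive = FALSE)
  if (length(halves) < 2) return(NA_real_)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars); B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Per-WGD support verdict from the posterior retention rates
#'
#' A hypothesized WGD is `supported` when the lower bound of the 95%
#' credible interval of its retention rate exceeds `floor` — a
#' decisively non-zero retention rate. A bimodal retention posterior
#' (a second density mode, e.g. near q = 0) is reported in the
#' `multimodal` column: with multiple modes the pooled interval should
#' be interpreted with caution.
#'
#' @param fit a [dlwgd] fit (or a data.frame trace with `q_*` columns).
#' @param floor minimal credible lower bound for support.
#' @return data.frame with one row per WGD: mean, interval, verdict,
#'   multimodality flag.
#' @export
summarize_wgd_support <- function(fit, floor = 0.01) {
  tr <- if (inherits(fit, "dlwgd")) fit$trace else fit
  qcols <- grep("^q_", colnames(tr), value = TRUE)
  if (!length(qcols)) stop("no retention-rate (q) samples in the trace")
  out <- do.call(rbind, lapply(qcols, function(p) {
    x <- tr[[p]]
    qs <- stats::quantile(x, c(0.025, 0.975))
    mm <- is_multimodal(x)
    data.frame(wgd = sub("^q_", "", p), mean = mean(x),
               q2.5 = unname(qs[1]), q97.5 = unname(qs[2]),
               verdict = if (qs[1] > floor) "supported" else "unsupported",
               multimodal = mm, stringsAsFactors = FALSE)
  }))
  if (any(out$multimodal))
    warning("multimodal retention-rate posterior for: ",
            paste(out$wgd[out$multimodal], collapse = ", "),
            " - pooled intervals may be misleading")
  rownames(out) <- NULL
  out
}

# two substantial density modes separated by a genuine valley
is_multimodal <- function(x, height = 0.2, valley = 0.5) {
  if (length(unique(x)) < 10) return(FALSE)
  d <- stats::density(x, n = 256)
  y <- d$y / max(d$y)
  peaks <- which(diff(sign(diff(y))) < 0) + 1L
  if (y[1] > y[2]) peaks <- c(1L, peaks)
  if (y[length(y)] > y[length(y) - 1]) peaks <- c(peaks, length(y))
  peaks <- peaks[y[peaks] >= height]
  if (length(peaks) < 2) return(FALSE)
  for (i in seq_len(length(peaks) - 1L)) {
    seg <- y[peaks[i]:peaks[i + 1L]]
    if (min(seg) < valley * min(y[peaks[i]], y[peaks[i + 1L]])) return(TRUE)
  }
  FALSE
}
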