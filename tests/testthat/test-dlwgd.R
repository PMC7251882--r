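test_that("birth-death kernel matches closed forms and the matrix exponential", {
  skip_if_not_installed("Matrix")
  # pure-death and critical closed forms
  expect_equal(bd_transition_probability(1, 0, 0, 0.01, 100), 1 - exp(-1))
  r <- 0.002; t <- 100
  expect_equal(bd_transition_probability(1, 0, r, r, t), r * t / (1 + r * t))
  # spot grid against the truncated matrix-exponential oracle
  for (lam in c(0, 2e-3)) for (mu in c(1e-3, 5e-3)) for (t in c(10, 500)) {
    O <- bd_expm_oracle(100, lam, mu, t)
    for (n in c(0, 1, 3, 7)) for (m in c(0, 2, 6)) {
      expect_lt(abs(bd_transition_probability(n, m, lam, mu, t) -
                    O[n + 1, m + 1]), 1e-8)
    }
  }
  expect_error(bd_transition_probability(-1, 0, 1e-3, 1e-3, 1), "negative")
})

test_that("family likelihood equals enumeration on two-leaf instances", {
  skip_if_not_installed("Matrix")
  tr <- as_dated_tree("(A:50,B:50);")
  for (lam in c(0.001, 0.002)) for (eta in c(0.7, 0.9))
    for (cA in 1:3) for (cB in 1:2) {
      mine <- family_loglikelihood(c(A = cA, B = cB), tr, lam, 0.002, eta,
                                   bound = 40)
      expect_lt(abs(as.numeric(mine) -
                    loglik_oracle_2leaf(cA, cB, 50, 50, lam, 0.002, eta)), 1e-8)
    }
})

test_that("family likelihood equals enumeration on a three-leaf instance", {
  skip_if_not_installed("Matrix")
  tr <- as_dated_tree("((A:30,B:30):20,C:50);")
  for (cA in 0:2) for (cC in 1:2) {
    if (cA == 0) next
    mine <- family_loglikelihood(c(A = cA, B = 1, C = cC), tr, 0.002, 0.001,
                                 0.8, bound = 40)
    expect_lt(abs(as.numeric(mine) -
                  loglik_oracle_3leaf(cA, 1, cC, 30, 20, 50, 0.002, 0.001, 0.8)),
              1e-8)
  }
})

test_that("likelihood is additive, label-invariant and truncation-stable", {
  tr <- tree9()
  sim <- simulate_family_counts(tr, 0.002, 0.002, eta = 0.8, n_families = 40,
                                seed = 40)
  flt <- filter_families(sim$counts, tr)
  cc <- flt$counts
  ll <- family_loglikelihood(cc, tr, 0.002, 0.002, 0.8, bound = 70)
  per <- attr(ll, "per_family")
  expect_equal(as.numeric(ll), sum(per))
  # label invariance: permuting family rows permutes per-family terms
  perm <- sample(nrow(cc))
  ll2 <- family_loglikelihood(cc[perm, ], tr, 0.002, 0.002, 0.8, bound = 70)
  expect_equal(sort(attr(ll2, "per_family")), sort(per))
  # increasing the truncation bound hardly moves the result
  ll3 <- family_loglikelihood(cc, tr, 0.002, 0.002, 0.8, bound = 110)
  expect_lt(abs(as.numeric(ll3) - as.numeric(ll)), 1e-6)
  expect_error(family_loglikelihood(cc, tr, 0.002, 0.002, 0.8,
                                    bound = max(cc)), "bound")
})

test_that("q = 0 reduces the WGD model to the plain DL model", {
  tr <- tree9()
  sim <- simulate_family_counts(tr, 0.002, 0.002, eta = 0.8, n_families = 30,
                                seed = 41)
  cc <- filter_families(sim$counts, tr)$counts
  w <- wgd_hypothesis("n12")
  l0 <- family_loglikelihood(cc, tr, 0.002, 0.0015, 0.8, wgds = w, q = 0,
                             bound = 70)
  l1 <- family_loglikelihood(cc, tr, 0.002, 0.0015, 0.8, bound = 70)
  expect_equal(as.numeric(l0), as.numeric(l1), tolerance = 1e-12)
})

test_that("family filters implement the worked size rule and root-clade rule", {
  tr <- as_dated_tree("((A:1,B:1):1,(C:1,D:1):1);")
  counts <- rbind(f1 = c(A = 1L, B = 0L, C = 0L, D = 0L),  # one clade only
                  f2 = c(1L, 0L, 1L, 0L),
                  f3 = c(2L, 1L, 1L, 0L),
                  f4 = c(3L, 3L, 2L, 1L),
                  f5 = c(9L, 7L, 5L, 4L))
  out <- filter_families(counts, tr)
  rep <- out$report
  expect_identical(rep$reason[rep$family == "f1"], "root_clade")
  # X = {1,4,9,25} worked example: Y = {2,4,6,10}, median 5, threshold 8
  expect_equal(rep$Y[match(c("f1", "f2", "f3", "f4", "f5"), rep$family)],
               2 * sqrt(c(1, 2, 4, 9, 25)))
  sizes <- rowSums(counts[-1, ])
  expect_identical(rep$reason[rep$family == "f5"], "poisson_outlier")
  expect_identical(rownames(out$counts), c("f2", "f3", "f4"))
  # all families identical size: outlier rule removes none
  same <- matrix(1L, 6, 4, dimnames = list(paste0("g", 1:6), colnames(counts)))
  expect_identical(nrow(filter_families(same, tr)$counts), 6L)
})

test_that("prior densities follow their stated families", {
  tr <- tree9()
  m <- rate_model(tr, "constant", 0.005, 0.005, eta = 10 / 12)
  lp <- prior_logdensity(m)
  expect_equal(lp, stats::dexp(0.005, 1 / 0.005, log = TRUE) * 2 +
                 stats::dbeta(10 / 12, 10, 2, log = TRUE))
  # outside the support
  expect_identical(prior_logdensity(rate_model(tr, "constant", 0.005, 0.005,
                                               eta = 0.5, q = 0.4)) >
                   -Inf, TRUE)
  bad <- rate_model(tr, "constant", 0.005, 0.005)
  bad$q <- 1.2
  expect_identical(prior_logdensity(bad), -Inf)
  bad2 <- rate_model(tr, "constant", 0.005, 0.005)
  bad2$eta <- 1.5
  expect_identical(prior_logdensity(bad2), -Inf)
  # independent-rates prior: Monte-Carlo mean of a branch rate matches
  # the analytic log-normal mean
  set.seed(42)
  m_l <- 0.002; s2 <- 0.09
  draws <- stats::rlnorm(1e5, log(m_l), sqrt(s2))
  expect_lt(abs(mean(draws) - m_l * exp(s2 / 2)) / (m_l * exp(s2 / 2)), 0.01)
  ids <- branch_ids(tr)
  mir <- rate_model(tr, "independent_rates",
                    stats::setNames(rep(0.002, length(ids)), ids),
                    stats::setNames(rep(0.002, length(ids)), ids),
                    hyper = list(m_lambda = 0.002, m_mu = 0.002, sigma2 = 0.09))
  expect_true(is.finite(prior_logdensity(mir)))
  mgbm <- rate_model(tr, "gbm",
                     stats::setNames(rep(0.002, length(ids)), ids),
                     stats::setNames(rep(0.002, length(ids)), ids),
                     hyper = list(m_lambda = 0.002, m_mu = 0.002))
  expect_true(is.finite(prior_logdensity(mgbm)))
})

test_that("prior-only sampling reproduces the analytic priors", {
  tr <- as_dated_tree("(A:50,B:50);")
  fit <- run_mcmc(NULL, tr, n_iter = 12000, burnin = 2000, seed = 43)
  s <- summary(fit)
  # eta ~ Beta(10, 2): mean 10/12
  expect_lt(abs(s["eta", "mean"] - 10 / 12), 0.02)
  # lambda ~ Exponential(mean 0.005)
  expect_lt(abs(s["lambda", "mean"] - 0.005) / 0.005, 0.15)
  expect_lt(abs(s["lambda", "q97.5"] - stats::qexp(0.975, 1 / 0.005)) /
            stats::qexp(0.975, 1 / 0.005), 0.25)
})

test_that("WGD support verdicts follow the credible-interval rule", {
  tr1 <- data.frame(q_test = stats::runif(2000, 0.25, 0.35))
  s1 <- summarize_wgd_support(tr1)
  expect_identical(s1$verdict, "supported")
  tr2 <- data.frame(q_test = stats::runif(2000, 0, 0.005))
  expect_identical(summarize_wgd_support(tr2)$verdict, "unsupported")
  # bimodal trace: verdict from the pooled interval, multimodality flagged
  tr3 <- data.frame(q_test = c(stats::rnorm(1200, 0.3, 0.02),
                               abs(stats::rnorm(800, 0, 0.004))))
  expect_warning(s3 <- summarize_wgd_support(tr3), "multimodal")
  expect_true(s3$multimodal)
  expect_identical(s3$verdict,
                   if (stats::quantile(tr3$q_test, 0.025) > 0.01)
                     "supported" else "unsupported")
  expect_error(summarize_wgd_support(data.frame(lambda = 1:5)), "q")
})
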