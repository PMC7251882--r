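test_that("family simulation honors its degenerate and forced regimes", {
  tr <- as_dated_tree("((A:100,B:100)ab:50,C:150);")
  # no events possible
  s0 <- simulate_family_counts(tr, 0, 0, eta = 1, n_families = 25, seed = 1)
  expect_true(all(s0$counts == 1L))
  expect_identical(nrow(s0$events), 0L)
  # forced retention doubles every leaf below the WGD branch
  s1 <- simulate_family_counts(tr, 0, 0, wgds = wgd_hypothesis("ab", 25, q = 1),
                               eta = 1, n_families = 25, seed = 2)
  expect_true(all(s1$counts[, c("A", "B")] == 2L))
  expect_true(all(s1$counts[, "C"] == 1L))
  expect_true(all(s1$events$type == "wgd_retention"))
})

test_that("event logs replay to the exact count matrix", {
  tr <- tree9()
  sim <- simulate_family_counts(tr, 0.004, 0.003,
                                wgds = wgd_hypothesis("n12", q = 0.4),
                                eta = 0.7, n_families = 120, seed = 3)
  expect_identical(replay_family_counts(sim), sim$counts)
})

test_that("branch mean matches the linear birth-death expectation", {
  # single 100 My branch: E[count] = exp((lambda - mu) t)
  tr <- as_dated_tree("(A:100,B:0.000001);")
  sim <- simulate_family_counts(tr, 0.002, 0.001, eta = 1,
                                n_families = 10000, seed = 4)
  x <- sim$counts[, "A"]
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - exp(0.1)), 3 * se)
})

test_that("geometric root prior has mean 1/eta", {
  tr <- as_dated_tree("(A:1,B:1);")
  sim <- simulate_family_counts(tr, 0, 0, eta = 0.4, n_families = 20000, seed = 5)
  rc <- sim$root_counts
  expect_lt(abs(mean(rc) - 1 / 0.4), 3 * stats::sd(rc) / sqrt(length(rc)))
})

test_that("leaf counts are stochastically increasing in lambda (mu = 0)", {
  tr <- as_dated_tree("(A:200,B:200);")
  lams <- c(0.001, 0.002, 0.004)
  means <- vapply(lams, function(l) {
    mean(simulate_family_counts(tr, l, 0, eta = 1, n_families = 3000,
                                seed = 6)$counts)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("paranome Ks simulator recovers its generating parameters", {
  # background-only: ML exponential fit recovers the loss hazard
  bg <- simulate_paranome_ks(1, 1.5, NULL, n_events = 20000, seed = 7)
  # MLE of a (0,5]-truncated exponential via optimize
  nll <- function(r) -sum(stats::dexp(bg$ks, r, log = TRUE) -
                          log(stats::pexp(5, r)))
  rhat <- stats::optimize(nll, c(0.1, 10))$minimum
  expect_lt(abs(rhat - 1.5) / 1.5, 0.10)
  # histogram counts non-increasing up to sampling noise (coarse bins)
  h <- build_ks_histogram(bg, bin_width = 0.5)
  expect_true(all(diff(h$counts) < 0.05 * h$total_weight))
  # pure pulse location
  p <- simulate_paranome_ks(0, 1, data.frame(mean = 0.8, sd = 0.1, size = 1),
                            n_events = 5000, seed = 8)
  expect_lt(abs(mean(p$ks) - 0.8), 0.01)
  # mixture proportion recovered by a two-component fit
  mx <- simulate_paranome_ks(0.8, 1.5, data.frame(mean = 0.8, sd = 0.1, size = 0.2),
                             n_events = 20000, seed = 9)
  nll2 <- function(par) {
    w <- stats::plogis(par[1]); r <- exp(par[2])
    -sum(log((1 - w) * stats::dexp(mx$ks, r) / stats::pexp(5, r) +
             w * stats::dnorm(mx$ks, 0.8, 0.1)))
  }
  fit <- stats::optim(c(0, 0), nll2)
  expect_lt(abs(stats::plogis(fit$par[1]) - 0.2), 0.05)
  expect_error(simulate_paranome_ks(0, 1, NULL, 10), "zero")
})

test_that("planted genome layouts satisfy their construction contract", {
  lay <- simulate_genome_layout(3, 30, data.frame(topology = "inter_scaffold",
                                                  n_anchors = 6, ks_mean = 0.8),
                                seed = 10)
  expect_identical(nrow(lay$pairs), 6L)
  g <- lay$genes
  expect_identical(length(unique(g$scaffold[match(c(lay$pairs$gene_a,
                                                    lay$pairs$gene_b),
                                                  g$gene_id)])), 2L)
  # palindrome: partner ranks order-reversed, inverted orientation
  pal <- simulate_genome_layout(2, 30, data.frame(topology = "palindrome",
                                                  n_anchors = 5, ks_mean = 0.1),
                                feature_gap = 5, seed = 11)
  rg <- rank_genes(pal$genes)
  ra <- rg$rank[match(pal$pairs$gene_a, rg$gene_id)]
  rb <- rg$rank[match(pal$pairs$gene_b, rg$gene_id)]
  expect_true(all(diff(ra[order(ra)]) > 0))
  expect_equal(order(ra), rev(order(rb)))
  strands <- rg$strand[match(pal$pairs$gene_b, rg$gene_id)]
  expect_true(all(strands == "-"))
  # gene intervals never overlap within a scaffold
  for (s in split(rg, rg$scaffold))
    expect_true(all(s$start[-1] > s$end[-nrow(s)]))
  expect_error(simulate_genome_layout(1, 5, data.frame(topology = "palindrome",
                                                       n_anchors = 10,
                                                       ks_mean = 1)),
               "infeasible")
})

test_that("coverage tracks honor depth, haplotigs and overdispersion", {
  trk0 <- simulate_coverage_track(c(s1 = 5000), 100, 0)
  expect_true(all(trk0$depths$s1 == 100L))
  trk <- simulate_coverage_track(c(s1 = 50000), 100, 0.05,
    data.frame(scaffold = "s1", start = 10001, end = 20000,
               depth_fraction = 0.5), seed = 12)
  expect_lt(abs(mean(trk$depths$s1[10001:20000]) - 50), 2)
  expect_lt(abs(mean(trk$depths$s1[-(10001:20000)]) - 100), 2)
  # overdispersed: variance exceeds the Poisson variance (= mean)
  bg <- trk$depths$s1[-(10001:20000)]
  expect_gt(stats::var(bg), 1.5 * mean(bg))
  expect_error(simulate_coverage_track(c(s1 = 100), 50, 0,
    data.frame(scaffold = "s1", start = 90, end = 120, depth_fraction = 0.5)),
    "bounds")
})
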