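test_that("Markov clustering partitions the graph as expected", {
  clique <- function(p, n) {
    g <- expand.grid(a = seq_len(n), b = seq_len(n))
    g <- g[g$a < g$b, ]
    data.frame(gene_a = paste0(p, g$a), gene_b = paste0(p, g$b), weight = 1)
  }
  # disconnected components can never merge
  fams <- cluster_paralogs_mcl(rbind(clique("x", 3), clique("y", 3)))
  expect_identical(lapply(fams, sort), list(c("x1", "x2", "x3"),
                                            c("y1", "y2", "y3")))
  expect_identical(cluster_paralogs_mcl(
    data.frame(gene_a = "a", gene_b = "b", weight = 1))[[1]], c("a", "b"))
  expect_error(cluster_paralogs_mcl(data.frame(gene_a = "a", gene_b = "b",
                                               weight = 1), inflation = 1),
               "inflation")
})

test_that("barbell graph splits into two clusters like a reference run", {
  clique <- function(p, n) {
    g <- expand.grid(a = seq_len(n), b = seq_len(n))
    g <- g[g$a < g$b, ]
    data.frame(gene_a = paste0(p, g$a), gene_b = paste0(p, g$b), weight = 1)
  }
  bb <- rbind(clique("u", 4), clique("v", 4),
              data.frame(gene_a = "u4", gene_b = "v1", weight = 0.3))
  got <- cluster_paralogs_mcl(bb, inflation = 2)
  ref <- ref_mcl(wgdsig:::as_adjacency(bb), inflation = 2)
  norm <- function(x) sort(unname(vapply(x, function(cl)
    paste(sort(cl), collapse = "+"), character(1))))
  expect_identical(norm(got), norm(ref))
})

test_that("clustering output is a partition over random graphs", {
  set.seed(13)
  for (rep in 1:5) {
    n <- 14
    g <- expand.grid(a = 1:n, b = 1:n)
    g <- g[g$a < g$b, ]
    g <- g[stats::runif(nrow(g)) < 0.25, ]
    edges <- data.frame(gene_a = paste0("g", g$a), gene_b = paste0("g", g$b),
                        weight = stats::runif(nrow(g), 0.5, 2))
    fams <- cluster_paralogs_mcl(edges)
    members <- unlist(fams)
    expect_false(anyDuplicated(members) > 0)
    all_v <- unique(c(edges$gene_a, edges$gene_b))
    expect_setequal(c(members, attr(fams, "singletons")), all_v)
    # clusters never span disconnected components
    gr <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
    comp <- igraph::components(gr)$membership
    for (cl in fams) expect_identical(length(unique(comp[cl])), 1L)
  }
})

test_that("codon backthreading maps columns and strips gaps", {
  aln <- c(s1 = "MK-V", s2 = "MKAV")
  cds <- c(s1 = "ATGAAAGTT", s2 = "ATGAAAGCTGTT")
  out <- backthread_codon_alignment(aln, cds)
  expect_identical(unname(nchar(out)), c(9L, 9L))
  expect_identical(out[["s1"]], "ATGAAAGTT")
  expect_identical(out[["s2"]], "ATGAAAGTT")
  # ungapped identical proteins pass through, trailing stop tolerated
  aln2 <- c(s1 = "MKV", s2 = "MKV")
  cds2 <- c(s1 = "ATGAAAGTTTAA", s2 = "ATGAAGGTA")
  out2 <- backthread_codon_alignment(aln2, cds2)
  expect_identical(out2[["s1"]], "ATGAAAGTT")
  expect_identical(out2[["s2"]], "ATGAAGGTA")
  # internal stop is an error
  expect_error(backthread_codon_alignment(c(s1 = "M*V"), c(s1 = "ATGTAAGTT")),
               "stop")
  expect_error(backthread_codon_alignment(c(s1 = "MKV"), c(s1 = "ATGAAA")),
               "mismatch")
})

test_that("GY94 pairwise estimates recover simulated distances", {
  # identical sequences: the MLE of the distance is exactly zero
  p <- simulate_gy94_pair(120, ks = 0.4, seed = 14)
  expect_identical(estimate_ks_pair(c(a = p[[1]], b = p[[1]]))$ks, 0)
  # recovery within 10% (averaged over replicates: single 1000-codon
  # draws carry ~9% sampling noise at intermediate Ks)
  for (ks in c(0.2, 0.5, 1.0)) {
    est <- vapply(1:3, function(s)
      estimate_ks_pair(simulate_gy94_pair(1000, ks = ks, seed = 100 * ks + s))$ks,
      numeric(1))
    expect_lt(abs(mean(est) - ks) / ks, 0.10)
  }
  # symmetric in its two sequences
  p2 <- simulate_gy94_pair(400, ks = 0.6, seed = 15)
  e1 <- estimate_ks_pair(p2)
  e2 <- estimate_ks_pair(rev(p2))
  expect_lt(abs(e1$ks - e2$ks), 1e-4)
  expect_error(estimate_ks_pair(simulate_gy94_pair(10, ks = 0.2, seed = 1)),
               "floor")
})

test_that("GY94 estimates are concordant with counting-method Ks", {
  skip_if_not_installed("seqinr")
  for (ks in c(0.2, 0.5)) {
    p <- simulate_gy94_pair(1000, ks = ks, seed = 200 + 10 * ks)
    est <- estimate_ks_pair(p)
    al <- structure(list(nb = 2L, nam = c("a", "b"),
                         seq = tolower(unname(p)), com = NA),
                    class = "alignment")
    ng <- seqinr::kaks(al)
    expect_lt(abs(as.numeric(ng$ks) - est$ks) / est$ks, 0.30)
  }
})

test_that("node weighting distributes pair Ks over duplication events", {
  # 2-member family: one event, weight 1
  ev2 <- weight_ks_by_node(c("a", "b"),
                           data.frame(gene_a = "a", gene_b = "b", ks = 0.4))
  expect_identical(ev2$weight, 1)
  expect_identical(ev2$consensus_ks, 0.4)
  # 3 members, ((a,b),c)
  ks <- data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
                   ks = c(0.2, 1.0, 1.1))
  ev3 <- weight_ks_by_node(c("a", "b", "c"), ks, "((a:1,b:1):1,c:2);")
  ab <- ev3[ev3$n_pairs == 1, ]
  expect_identical(ab$ks, 0.2)
  expect_identical(ab$weight, 1)
  root <- ev3[ev3$n_pairs == 2, ]
  expect_identical(root$weight, c(0.5, 0.5))
  expect_identical(unique(root$consensus_ks), mean(c(1.0, 1.1)))
  # per-node weights always sum to one
  agg <- tapply(ev3$weight, ev3$node, sum)
  expect_true(all(abs(agg - 1) < 1e-12))
})

test_that("node events match brute-force LCA grouping on random families", {
  set.seed(16)
  for (rep in 1:4) {
    n <- 8L
    tr <- ape::rtree(n, tip.label = paste0("g", 1:n))
    cmb <- utils::combn(paste0("g", 1:n), 2)
    kp <- data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
                     ks = stats::runif(ncol(cmb), 0.05, 3))
    ev <- weight_ks_by_node(paste0("g", 1:n), kp, tr)
    # total event weight equals the internal-node count
    expect_equal(sum(ev$weight), n - 1)
    expect_identical(length(unique(ev$node)), 7L)
    # brute force: group the 28 pairs by the deepest shared node of
    # their root-to-tip paths and compare the partitions
    rooted <- if (ape::is.rooted(tr)) tr else phangorn::midpoint(tr)
    rooted <- ape::multi2di(rooted)
    root <- n + 1L
    path_to <- function(tip) ape::nodepath(rooted, root, match(tip, rooted$tip.label))
    brute <- vapply(seq_len(ncol(cmb)), function(k) {
      shared <- intersect(path_to(cmb[1, k]), path_to(cmb[2, k]))
      shared[length(shared)]
    }, numeric(1))
    key <- paste(ev$gene_a, ev$gene_b)
    brute_of_row <- brute[match(key, paste(cmb[1, ], cmb[2, ]))]
    # same partition: implementation node labels refine brute groups 1:1
    expect_identical(length(unique(paste(ev$node, brute_of_row))),
                     length(unique(ev$node)))
    expect_identical(length(unique(brute_of_row)), length(unique(ev$node)))
    for (node in unique(ev$node)) {
      rows <- ev[ev$node == node, ]
      expect_equal(rows$weight, rep(1 / nrow(rows), nrow(rows)))
      expect_equal(unique(rows$consensus_ks), mean(rows$ks))
      expect_gte(unique(rows$consensus_ks), min(rows$ks))
      expect_lte(unique(rows$consensus_ks), max(rows$ks))
    }
  }
})

test_that("saturated pairs are excluded before node averaging by default", {
  ks <- data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
                   ks = c(0.2, 7.5, 1.1), saturated = c(FALSE, TRUE, FALSE))
  ev <- weight_ks_by_node(c("a", "b", "c"), ks, "((a:1,b:1):1,c:2);")
  # the saturated a-c pair contributes nothing; root consensus is b-c alone
  expect_false(any(ev$gene_a == "a" & ev$gene_b == "c"))
  expect_identical(ev$consensus_ks[ev$n_pairs == 1 & ev$gene_a == "b"], 1.1)
  # with "never", the saturated pair enters the consensus
  ev2 <- weight_ks_by_node(c("a", "b", "c"), ks, "((a:1,b:1):1,c:2);",
                           exclude_saturated = "never")
  expect_identical(sort(unique(ev2$n_pairs)), c(1L, 2L))
})

test_that("Ks event filter applies the (0, 5] retention window", {
  ev <- data.frame(ks = c(0, 0.3, 4.9, 5.2), weight = 1,
                   consensus_ks = c(0, 0.3, 4.9, 5.2))
  out <- filter_ks_events(ev)
  expect_identical(out$ks, c(0.3, 4.9))
  expect_identical(unname(attr(out, "removed")), c(1L, 1L))
  empty <- filter_ks_events(ev[0, ])
  expect_identical(nrow(empty), 0L)
  expect_warning(filter_ks_events(data.frame(ks = c(6, 7), weight = 1,
                                             consensus_ks = c(6, 7))),
                 "filtered out")
})
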