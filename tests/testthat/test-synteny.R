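toy_genes <- function(n_per = 20, scafs = c("s1", "s2")) {
  do.call(rbind, lapply(scafs, function(s) {
    data.frame(gene_id = sprintf("%s_g%02d", s, seq_len(n_per)), scaffold = s,
               start = (seq_len(n_per) - 1L) * 1000L + 1L,
               end = (seq_len(n_per) - 1L) * 1000L + 900L, strand = "+",
               stringsAsFactors = FALSE)
  }))
}

test_that("gene ranking orders by start with id tie-breaks per scaffold", {
  g <- data.frame(gene_id = c("b", "a", "c", "z", "y"),
                  scaffold = c("s1", "s1", "s1", "s2", "s2"),
                  start = c(100, 50, 200, 10, 10), end = c(150, 90, 260, 20, 30),
                  strand = "+")
  r <- rank_genes(g)
  expect_identical(r$rank[match(c("a", "b", "c"), r$gene_id)], c(0L, 1L, 2L))
  # tie on start: lexicographic id order, independent per scaffold
  expect_identical(r$rank[match(c("y", "z"), r$gene_id)], c(0L, 1L))
  expect_error(rank_genes(data.frame(gene_id = "x", scaffold = "s",
                                     start = 5, end = 2, strand = "+")),
               "start > end")
})

test_that("perfect diagonals chain into single blocks of the right orientation", {
  g <- toy_genes()
  diag5 <- data.frame(gene_a = sprintf("s1_g%02d", 1:5),
                      gene_b = sprintf("s2_g%02d", 3:7), evalue = 1e-30)
  bl <- chain_collinear_blocks(diag5, g, seed_size = 5, max_gap = 25)
  expect_identical(nrow(bl$blocks), 1L)
  expect_identical(bl$blocks$orientation, "parallel")
  expect_identical(bl$blocks$n_anchors, 5L)
  anti5 <- data.frame(gene_a = sprintf("s1_g%02d", 1:5),
                      gene_b = sprintf("s2_g%02d", 7:3), evalue = 1e-30)
  bl2 <- chain_collinear_blocks(anti5, g, seed_size = 5, max_gap = 25)
  expect_identical(bl2$blocks$orientation, "inverted")
  # below seed size: nothing emitted
  bl3 <- chain_collinear_blocks(diag5[1:3, ], g, seed_size = 5, max_gap = 25)
  expect_identical(nrow(bl3$blocks), 0L)
})

test_that("chaining equals exhaustive enumeration on random small grids", {
  set.seed(17)
  g <- toy_genes(10)
  for (rep in 1:40) {
    npts <- sample(4:8, 1)
    r1 <- sample(0:9, npts, replace = TRUE)
    r2 <- sample(0:9, npts, replace = TRUE)
    pts <- unique(data.frame(r1 = r1, r2 = r2))
    max_gap <- sample(c(6, 10, 18), 1)
    seed_size <- sample(2:3, 1)
    pairs <- data.frame(gene_a = sprintf("s1_g%02d", pts$r1 + 1L),
                        gene_b = sprintf("s2_g%02d", pts$r2 + 1L),
                        evalue = 1e-30)
    got <- chain_collinear_blocks(pairs, g, seed_size = seed_size,
                                  max_gap = max_gap)
    want <- oracle_chain_blocks(pts, seed_size, max_gap)
    expect_identical(nrow(got$blocks), length(want))
    if (length(want)) {
      got_sets <- lapply(split(got$anchors, got$anchors$block_id), function(a)
        sort(paste(a$rank_a, a$rank_b)))
      want_sets <- lapply(want, function(b)
        sort(paste(b$anchors$r1, b$anchors$r2)))
      expect_setequal(unname(got_sets), unname(want_sets))
      expect_setequal(got$blocks$score, vapply(want, `[[`, numeric(1), "score"))
    }
  }
})

test_that("relaxed settings never yield fewer anchors than stringent", {
  set.seed(18)
  for (rep in 1:12) {
    lay <- simulate_genome_layout(
      n_scaffolds = 6, genes_per_scaffold = 110,
      planted_blocks = data.frame(
        topology = sample(c("inter_scaffold", "palindrome", "tandem_array"),
                          3, replace = TRUE),
        n_anchors = sample(5:8, 3, replace = TRUE),
        ks_mean = stats::runif(3, 0.1, 1)),
      tandem_singletons = sample(0:3, 1), dispersed_pairs = sample(0:6, 1),
      seed = 1000 + rep)
    genes <- rank_genes(lay)
    strict <- chain_collinear_blocks(lay$pairs, genes, preset = "stringent")
    relaxed <- chain_collinear_blocks(lay$pairs, genes, preset = "relaxed")
    expect_gte(nrow(relaxed$anchors), nrow(strict$anchors))
  }
})

test_that("classification recovers the planted registry and is a partition", {
  set.seed(19)
  for (rep in 1:6) {
    lay <- simulate_genome_layout(
      n_scaffolds = 6, genes_per_scaffold = 120,
      planted_blocks = data.frame(
        topology = c("inter_scaffold", "palindrome", "tandem_array"),
        n_anchors = sample(5:7, 3, replace = TRUE),
        ks_mean = c(0.8, 0.15, 0.15)),
      tandem_singletons = 3, dispersed_pairs = 6, seed = 2000 + rep)
    genes <- rank_genes(lay)
    bl <- chain_collinear_blocks(lay$pairs, genes, preset = "stringent")
    cls <- classify_duplicates(lay$pairs, bl, genes)
    expect_identical(cls$classification, cls$true_class)
    expect_identical(sum(table(cls$classification)), nrow(lay$pairs))
    # topology recovery against the registry
    got_topo <- sort(bl$blocks$topology)
    expect_identical(got_topo, sort(lay$blocks$topology))
  }
})

test_that("block topology labels follow scaffold and orientation", {
  mk <- function(sa, sb, orient) data.frame(scaffold_a = sa, scaffold_b = sb,
                                            orientation = orient)
  expect_identical(classify_block_topology(mk("s1", "s2", "parallel")),
                   "inter_scaffold")
  expect_identical(classify_block_topology(mk("s1", "s1", "inverted")),
                   "palindrome")
  expect_identical(classify_block_topology(mk("s1", "s1", "parallel")),
                   "tandem_array")
})

test_that("anchors take precedence over tandem in classification", {
  g <- toy_genes(12, "s1")
  # adjacent run duplicated right after itself: anchors despite adjacency
  pairs <- data.frame(gene_a = sprintf("s1_g%02d", 1:5),
                      gene_b = sprintf("s1_g%02d", 6:10), evalue = 1e-30)
  bl <- chain_collinear_blocks(pairs, g, seed_size = 5, max_gap = 25)
  cls <- classify_duplicates(pairs, bl, g)
  expect_true(all(cls$classification == "segmental_anchor"))
  # same pairs without chaining: nearest pair would be tandem
  cls2 <- classify_duplicates(data.frame(gene_a = "s1_g01", gene_b = "s1_g02",
                                         evalue = 1), NULL, g)
  expect_identical(cls2$classification, "tandem")
})

test_that("reversing one scaffold flips inter-scaffold orientation only", {
  set.seed(20)
  lay <- simulate_genome_layout(
    n_scaffolds = 4, genes_per_scaffold = 110,
    planted_blocks = data.frame(
      topology = c("inter_scaffold", "palindrome", "tandem_array"),
      n_anchors = c(6, 5, 5), ks_mean = 0.5),
    seed = 21)
  genes <- rank_genes(lay)
  bl <- chain_collinear_blocks(lay$pairs, genes, preset = "stringent")
  # reverse the coordinate system of the first scaffold of the inter block
  target <- bl$blocks$scaffold_a[bl$blocks$topology == "inter_scaffold"][1]
  g2 <- lay$genes
  sel <- g2$scaffold == target
  L <- max(g2$end[sel]) + 1L
  ns <- L - g2$end[sel]
  ne <- L - g2$start[sel]
  g2$start[sel] <- ns
  g2$end[sel] <- ne
  bl2 <- chain_collinear_blocks(lay$pairs, rank_genes(g2), preset = "stringent")
  key <- function(b) {
    topo <- b$blocks[order(b$blocks$scaffold_a, b$blocks$scaffold_b), ]
    paste(topo$scaffold_a, topo$scaffold_b, topo$n_anchors)
  }
  expect_setequal(key(bl), key(bl2))   # membership preserved
  o1 <- bl$blocks$orientation[bl$blocks$topology == "inter_scaffold"]
  o2 <- bl2$blocks$orientation[bl2$blocks$topology == "inter_scaffold"]
  expect_false(identical(o1, o2))      # orientation flipped
  # intra-scaffold topologies are untouched
  expect_identical(sort(bl2$blocks$topology[bl2$blocks$scaffold_a ==
                                            bl2$blocks$scaffold_b]),
                   c("palindrome", "tandem_array"))
})

test_that("macrosynteny export is one deterministic row per pair", {
  lay <- simulate_genome_layout(3, 60,
    planted_blocks = data.frame(topology = "inter_scaffold", n_anchors = 5,
                                ks_mean = 0.8),
    dispersed_pairs = 4, seed = 22)
  genes <- rank_genes(lay)
  bl <- chain_collinear_blocks(lay$pairs, genes, preset = "stringent")
  dp <- macrosynteny_dotplot(lay$pairs, genes, bl)
  expect_identical(nrow(dp), nrow(lay$pairs))
  expect_identical(sum(dp$anchor), 5L)
  dp2 <- macrosynteny_dotplot(lay$pairs, genes, bl)
  expect_identical(dp, dp2)
})
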