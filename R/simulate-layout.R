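#' Simulate a genome layout with planted co-linear blocks
#'
#' Builds an artificial genome of `n_scaffolds` scaffolds carrying
#' `genes_per_scaffold` ordered genes each, and plants duplication
#' features with known ground truth: co-linear blocks of chosen topology
#' (`inter_scaffold`: the two copies on different scaffolds;
#' `tandem_array`: both copies adjacent on one scaffold in parallel
#' orientation; `palindrome`: both copies on one scaffold in inverted
#' orientation), adjacent tandem duplicate pairs, and dispersed duplicate
#' pairs. Every planted homolog pair is assigned a Ks value near the
#' requested block mean, so downstream classifiers and Ks analyses can be
#' checked against the registry.
#'
#' @param n_scaffolds,genes_per_scaffold genome dimensions.
#' @param planted_blocks `NULL` or data.frame with columns `topology`
#'   (one of `"inter_scaffold"`, `"tandem_array"`, `"palindrome"`),
#'   `n_anchors`, `ks_mean`.
#' @param tandem_singletons number of adjacent tandem duplicate pairs.
#' @param dispersed_pairs number of dispersed duplicate pairs.
#' @param ks_sd standard deviation of planted Ks values around their mean.
#' @param gene_length,intergenic gene span and spacing in bp.
#' @param feature_gap guard gap (in genes) between planted features;
#'   must exceed the largest chaining `max_gap` that will be applied so
#'   that distinct features cannot merge into one chain.
#' @param seed integer seed.
#' @return object of class `genome_layout`: list with `genes` (gene_id,
#'   scaffold, start, end, strand), `pairs` (gene_a, gene_b, evalue,
#'   bitscore, ks, true_class, block_id), `blocks` (registry: block_id,
#'   topology, n_anchors, ks_mean), `scaffold_lengths`.
#' @examples
#' lay <- simulate_genome_layout(2, 30,
#'   planted_blocks = data.frame(topology = "inter_scaffold",
#'                               n_anchors = 6, ks_mean = 0.8), seed = 1)
#' lay$blocks
#' @export
simulate_genome_layout <- function(n_scaffolds = 4, genes_per_scaffold = 50,
                                   planted_blocks = NULL, tandem_singletons = 0,
                                   dispersed_pairs = 0, ks_sd = 0.05,
                                   gene_length = 900, intergenic = 100,
                                   feature_gap = 45, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scafs <- sprintf("scf%02d", seq_len(n_scaffolds))
  span <- gene_length + intergenic
  genes <- do.call(rbind, lapply(seq_len(n_scaffolds), function(s) {
    i <- seq_len(genes_per_scaffold)
    data.frame(gene_id = sprintf("%sg%03d", scafs[s], i), scaffold = scafs[s],
               start = (i - 1L) * span + 1L, end = (i - 1L) * span + gene_length,
               strand = "+", stringsAsFactors = FALSE)
  }))
  scaffold_lengths <- stats::setNames(rep(genes_per_scaffold * span, n_scaffolds), scafs)

  # first-fit allocator with a guard gap between features larger than any
  # chaining gap in use, so distinct planted features can never merge into
  # one chain or look mutually adjacent
  free <- stats::setNames(rep(1L, n_scaffolds), scafs)
  gap <- as.integer(feature_gap)
  alloc <- function(len, exclude = NULL) {
    for (s in setdiff(scafs, exclude)) {
      if (free[[s]] + len - 1L <= genes_per_scaffold) {
        idx <- free[[s]] + seq_len(len) - 1L
        free[[s]] <<- free[[s]] + len + gap
        return(list(scaffold = s, idx = idx))
      }
    }
    stop("infeasible placement: requested features do not fit on the scaffolds")
  }
  gid <- function(s, i) sprintf("%sg%03d", s, i)

  pairs <- list(); registry <- list(); bid <- 0L
  if (!is.null(planted_blocks)) {
    for (b in seq_len(nrow(planted_blocks))) {
      topo <- match.arg(planted_blocks$topology[b],
                        c("inter_scaffold", "tandem_array", "palindrome"))
      k <- planted_blocks$n_anchors[b]
      km <- planted_blocks$ks_mean[b]
      bid <- bid + 1L
      if (topo == "inter_scaffold") {
        a <- alloc(k)
        b2 <- alloc(k, exclude = a$scaffold)
        ga <- gid(a$scaffold, a$idx); gb <- gid(b2$scaffold, b2$idx)
      } else {
        a <- alloc(2L * k)
        ga <- gid(a$scaffold, a$idx[seq_len(k)])
        second <- a$idx[k + seq_len(k)]
        if (topo == "palindrome") {
          gb <- gid(a$scaffold, rev(second))  # order-reversed partner ranks
          genes$strand[genes$gene_id %in% gid(a$scaffold, second)] <- "-"
        } else {
          gb <- gid(a$scaffold, second)
        }
      }
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene_a = ga, gene_b = gb, evalue = 1e-30,
        bitscore = round(stats::runif(k, 180, 260), 1),
        ks = rtrunc(k, function(n) stats::rnorm(n, km, ks_sd)),
        true_class = "segmental_anchor", block_id = sprintf("blk%02d", bid),
        stringsAsFactors = FALSE)
      registry[[length(registry) + 1L]] <- data.frame(
        block_id = sprintf("blk%02d", bid), topology = topo, n_anchors = k,
        ks_mean = km, stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(tandem_singletons)) {
    a <- alloc(2L)
    pairs[[length(pairs) + 1L]] <- data.frame(
      gene_a = gid(a$scaffold, a$idx[1]), gene_b = gid(a$scaffold, a$idx[2]),
      evalue = 1e-25, bitscore = round(stats::runif(1, 150, 240), 1),
      ks = rtrunc(1L, function(n) stats::rexp(n, 1.5)),
      true_class = "tandem", block_id = NA_character_, stringsAsFactors = FALSE)
  }
  # dispersed pairs are placed at random positions in the yet-unallocated
  # tail of the scaffolds, on different scaffolds where possible, so they
  # cannot line up into spurious co-linear runs or mimic tandem pairs
  rand_slot <- function(exclude = NULL) {
    ok <- setdiff(scafs[free[scafs] <= genes_per_scaffold], exclude)
    if (!length(ok)) ok <- scafs[free[scafs] <= genes_per_scaffold]
    if (!length(ok)) stop("infeasible placement: requested features do not fit on the scaffolds")
    s <- sample(ok, 1L)
    i <- sample(seq.int(free[[s]], genes_per_scaffold), 1L)
    # mark a neighborhood as consumed only if it was the next free slot
    if (i == free[[s]]) free[[s]] <<- free[[s]] + 1L + gap
    list(scaffold = s, idx = i)
  }
  for (i in seq_len(dispersed_pairs)) {
    a <- rand_slot()
    b2 <- rand_slot(exclude = a$scaffold)
    if (b2$scaffold == a$scaffold && abs(b2$idx - a$idx) <= 2L)
      b2$idx <- min(genes_per_scaffold, a$idx + 5L)
    pairs[[length(pairs) + 1L]] <- data.frame(
      gene_a = gid(a$scaffold, a$idx), gene_b = gid(b2$scaffold, b2$idx),
      evalue = 1e-20, bitscore = round(stats::runif(1, 120, 220), 1),
      ks = rtrunc(1L, function(n) stats::rexp(n, 1.5)),
      true_class = "dispersed", block_id = NA_character_, stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene_a = character(), gene_b = character(), evalue = numeric(),
               bitscore = numeric(), ks = numeric(), true_class = character(),
               block_id = character(), stringsAsFactors = FALSE)
  registry <- if (length(registry)) do.call(rbind, registry) else
    data.frame(block_id = character(), topology = character(),
               n_anchors = integer(), ks_mean = numeric(), stringsAsFactors = FALSE)
  structure(list(genes = genes, pairs = pairs, blocks = registry,
                 scaffold_lengths = scaffold_lengths, seed = seed),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("Synthetic genome layout:", length(x$scaffold_lengths), "scaffolds,",
      nrow(x$genes), "genes\n")
  cat("  planted blocks:", nrow(x$blocks), "| homolog pairs:", nrow(x$pairs), "\n")
  if (nrow(x$blocks)) print(table(x$blocks$topology))
  invisible(x)
}
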