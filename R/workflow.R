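#' Per-genome WGD-signature workflow
#'
#' Runs the per-genome stages in dependency order — gene ranking,
#' co-linear block chaining, duplicate classification, block topology,
#' paranome Ks histogram and peak detection, anchor-Ks overlay, the
#' optional haplotig coverage test — and applies the decision framework
#' ([assess_duplication_signature()]). Every configuration value used is
#' echoed into the returned run manifest, and all tabular artifacts can
#' be written to an output directory.
#'
#' @param config a list (or path to a YAML/JSON file read with
#'   [read_pipeline_config()]) with elements:
#'   \describe{
#'     \item{genes}{gene table, or a GFF3 path.}
#'     \item{pairs}{homolog pair table (`gene_a`, `gene_b`, `evalue`,
#'       optionally `ks`), or a 12-column tabular path.}
#'     \item{ks_events}{data.frame with `ks` and `weight` columns for the
#'       whole-paranome age distribution (e.g. node-weighted events from
#'       [weight_ks_by_node()]).}
#'     \item{pairs_ks}{optional pair-level Ks table (or TSV path) with
#'       `gene_a`, `gene_b`, `ks`, merged onto `pairs` for the anchor-Ks
#'       overlay.}
#'     \item{coverage}{optional coverage track or bedgraph path.}
#'     \item{params}{optional overrides: `preset`, `seed_size`,
#'       `max_gap`, `evalue_cutoff`, `bin_width`, `anchor_mass_frac`,
#'       `inter_frac`, `min_total_weight`, `n_random`, `tandem_rank_gap`.}
#'     \item{seed}{global seed.}
#'     \item{outdir}{optional output directory.}
#'   }
#' @return list of class `genome_report`: ranked genes, blocks,
#'   classified pairs, histogram, peaks, coverage verdicts, the
#'   [signature_verdict][assess_duplication_signature()], and `manifest`.
#' @export
run_genome_workflow <- function(config) {
  config <- as_pipeline_config(config)
  p <- config$params %||% list()
  defaults <- list(preset = "stringent", bin_width = 0.1,
                   anchor_mass_frac = 0.5, inter_frac = 0.5,
                   min_total_weight = 200, n_random = 1000,
                   tandem_rank_gap = 1, seed_size = NULL, max_gap = NULL,
                   evalue_cutoff = NULL)
  p <- utils::modifyList(defaults, p)
  if (!is.null(config$seed)) set.seed(config$seed)

  genes <- config$genes
  if (is.character(genes)) genes <- read_genes_gff3(genes)
  if (inherits(genes, "genome_layout")) genes <- genes$genes
  genes <- rank_genes(genes)
  pairs <- config$pairs
  if (is.character(pairs))
    pairs <- read_similarity_hits(pairs, p$evalue_cutoff %||% 1e-5)
  if (!is.null(config$pairs_ks)) {
    pk <- config$pairs_ks
    if (is.character(pk)) pk <- utils::read.delim(pk)
    pairs$ks <- pk$ks[match(pair_key(pairs$gene_a, pairs$gene_b),
                            pair_key(pk$gene_a, pk$gene_b))]
  }

  chain_args <- list(pairs = pairs, genes = genes, preset = p$preset)
  for (a in c("seed_size", "max_gap", "evalue_cutoff"))
    if (!is.null(p[[a]])) { chain_args[[a]] <- p[[a]]; chain_args$preset <- NULL }
  blocks <- do.call(chain_collinear_blocks, chain_args)
  pairs <- classify_duplicates(pairs, blocks, genes, p$tandem_rank_gap)

  ks_events <- config$ks_events
  hist <- peaks <- NULL
  if (!is.null(ks_events)) {
    ks_events <- filter_ks_events(ks_events, on = "pair")
    hist <- build_ks_histogram(ks_events, bin_width = p$bin_width)
    peaks <- try(detect_ks_peaks(ks_events,
                                 min_total_weight = p$min_total_weight),
                 silent = TRUE)
    if (inherits(peaks, "try-error")) peaks <- NULL
  }
  anchor_events <- anchor_ks_events(pairs, blocks)

  coverage <- NULL
  if (!is.null(config$coverage) && nrow(blocks$blocks)) {
    iv <- block_intervals(blocks, genes)
    iv$block_id <- paste(iv$block_id, iv$copy, sep = "_")
    coverage <- block_coverage_test(config$coverage, iv,
                                    n_random = p$n_random,
                                    seed = config$seed %||% 1L)
  }
  verdict <- assess_duplication_signature(peaks, anchor_events,
                                          blocks$blocks$topology,
                                          anchor_mass_frac = p$anchor_mass_frac,
                                          inter_frac = p$inter_frac)
  report <- base::structure(list(
    genes = genes, blocks = blocks, pairs = pairs, histogram = hist,
    peaks = peaks, anchor_events = anchor_events, coverage = coverage,
    verdict = verdict, dotplot = macrosynteny_dotplot(pairs, genes, blocks),
    manifest = list(params = p, seed = config$seed,
                    n_genes = nrow(genes), n_pairs = nrow(pairs),
                    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    class = "genome_report")
  if (!is.null(config$outdir)) write_genome_report(report, config$outdir)
  report
}

anchor_ks_events <- function(pairs, blocks) {
  if (is.null(pairs$ks) || !nrow(blocks$anchors))
    return(data.frame(ks = numeric(), weight = numeric()))
  key <- pair_key(pairs$gene_a, pairs$gene_b)
  sel <- key %in% pair_key(blocks$anchors$gene_a, blocks$anchors$gene_b)
  ks <- pairs$ks[sel]
  keep <- !is.na(ks) & ks > 0 & ks <= 5
  data.frame(ks = ks[keep], weight = rep(1, sum(keep)))
}

#' @export
print.genome_report <- function(x, ...) {
  cat("Per-genome duplication report\n")
  cat("  genes:", nrow(x$genes), "| homolog pairs:", nrow(x$pairs), "\n")
  cat("  blocks:", nrow(x$blocks$blocks), "| classification:",
      paste(names(table(x$pairs$classification)),
            table(x$pairs$classification), collapse = ", "), "\n")
  if (!is.null(x$peaks) && nrow(x$peaks))
    cat("  paranome peaks at Ks:",
        paste(round(x$peaks$location, 2), collapse = ", "), "\n")
  print(x$verdict)
  invisible(x)
}

write_genome_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.table(x, file.path(outdir, f), sep = "\t",
                                         quote = FALSE, row.names = FALSE)
  w(report$blocks$blocks, "blocks.tsv")
  w(report$blocks$anchors, "anchors.tsv")
  w(report$pairs, "pair_classification.tsv")
  w(report$dotplot, "dotplot.tsv")
  if (!is.null(report$histogram))
    w(data.frame(bin_lo = utils::head(report$histogram$edges, -1),
                 bin_hi = report$histogram$edges[-1],
                 weight = report$histogram$counts), "ks_histogram.tsv")
  if (!is.null(report$coverage)) w(report$coverage, "coverage_verdicts.tsv")
  jsonlite::write_json(
    list(label = report$verdict$label, evidence = report$verdict$evidence,
         manifest = report$manifest),
    file.path(outdir, "verdict.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Cross-genome phylogenomic workflow
#'
#' Applies the gene-family filters and runs the DL+WGD posterior
#' inference, returning the posterior summary, the per-branch rate table
#' and the per-WGD support verdicts.
#'
#' @param config list (or YAML/JSON path) with `counts` (matrix or TSV
#'   path), `tree` (phylo or newick path), optional `wgds` (list of
#'   [wgd_hypothesis()] or data.frame), `mcmc` (overrides passed to
#'   [run_mcmc()]), `seed`, `outdir`.
#' @return list of class `phylo_report`: `fit`, `summary`,
#'   `filter_report`, `branch_rates`, `wgd_support` (NULL without
#'   hypotheses), `manifest`.
#' @export
run_phylo_workflow <- function(config) {
  config <- as_pipeline_config(config)
  counts <- config$counts
  if (is.character(counts)) counts <- read_count_matrix(counts)
  tree <- as_dated_tree(config$tree)
  wgds <- config$wgds
  if (!is.null(wgds) && is.list(wgds) && !is.data.frame(wgds) &&
      !inherits(wgds, "wgd_hypothesis") && !is.null(wgds[[1]]$branch) &&
      !is.data.frame(wgds[[1]]))
    wgds <- lapply(wgds, function(w) do.call(wgd_hypothesis, w))
  args <- c(list(counts = counts, tree = tree, wgds = wgds,
                 seed = config$seed), config$mcmc %||% list())
  fit <- do.call(dlwgd, args)
  s <- summary(fit)
  branch_rates <- branch_rate_table(fit)
  support <- if (nrow(fit$wgds)) summarize_wgd_support(fit) else NULL
  report <- base::structure(list(
    fit = fit, summary = s, filter_report = fit$filter_report,
    branch_rates = branch_rates, wgd_support = support,
    manifest = list(mcmc = config$mcmc, seed = config$seed,
                    n_families = fit$n_families,
                    structure = fit$structure)),
    class = "phylo_report")
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(fit$trace, file.path(config$outdir, "trace.csv"),
                     row.names = FALSE)
    utils::write.table(cbind(param = rownames(s), s),
                       file.path(config$outdir, "posterior_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(branch_rates, file.path(config$outdir, "branch_rates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(support))
      utils::write.table(support, file.path(config$outdir, "wgd_support.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}

# per-branch posterior mean duplication/loss rates (constant structure
# repeats the shared rates on every branch)
branch_rate_table <- function(fit) {
  ids <- branch_ids(fit$tree)
  cf <- coef(fit)
  lam <- if (fit$structure == "constant") rep(cf[["lambda"]], length(ids)) else {
    v <- cf[paste0("lambda_", ids)]
    if (anyNA(v)) { # root constraint: copy the estimated twin branch
      miss <- ids[is.na(v)]
      root <- length(fit$tree$tip.label) + 1L
      twins <- node_labels(fit$tree)[fit$tree$edge[fit$tree$edge[, 1] == root, 2]]
      v[is.na(v)] <- cf[paste0("lambda_", setdiff(twins, miss))]
    }
    unname(v)
  }
  mur <- if (fit$structure == "constant") rep(cf[["mu"]], length(ids)) else {
    v <- cf[paste0("mu_", ids)]
    if (anyNA(v)) {
      miss <- ids[is.na(v)]
      root <- length(fit$tree$tip.label) + 1L
      twins <- node_labels(fit$tree)[fit$tree$edge[fit$tree$edge[, 1] == root, 2]]
      v[is.na(v)] <- cf[paste0("mu_", setdiff(twins, miss))]
    }
    unname(v)
  }
  data.frame(branch = ids, length_my = fit$tree$edge.length,
             lambda = lam, mu = mur, stringsAsFactors = FALSE)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path configuration file; format decided by extension.
#' @return the configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is needed for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
}

as_pipeline_config <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  known <- c("genes", "pairs", "pairs_ks", "ks_events", "coverage", "params",
             "seed", "outdir", "counts", "tree", "wgds", "mcmc")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  config
}

#' Materialize a named synthetic scenario bundle on disk
#'
#' Writes a complete per-genome input bundle — GFF3 gene coordinates,
#' 12-column homolog hits, a Ks-event TSV, a bedgraph coverage track —
#' for one of three archetypal scenarios: `wgd_like` (an old WGD: an
#' interior Ks peak at 0.8, anchors clustered in it, blocks on separate
#' scaffolds), `segmental_burst` (recent blocks, many within scaffolds
#' as palindromes/tandem arrays, no paranome peak) and `ssd_only`
#' (background duplication only).
#'
#' @param scenario one of `"wgd_like"`, `"segmental_burst"`, `"ssd_only"`.
#' @param dir output directory.
#' @param seed integer seed.
#' @param n_events number of paranome Ks events.
#' @return (invisibly) the list of written paths (GFF3 genes, tabular
#'   hits, a pair-level Ks table for the anchor overlay, paranome Ks
#'   events, bedgraph coverage) plus the in-memory layout, Ks events and
#'   coverage track.
#' @export
write_fixture_bundle <- function(scenario = c("wgd_like", "segmental_burst", "ssd_only"),
                                 dir, seed = 1, n_events = 3000) {
  scenario <- match.arg(scenario)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  sc <- fixture_scenario(scenario, seed, n_events)
  paths <- list(gff = file.path(dir, "genes.gff3"),
                hits = file.path(dir, "hits.tsv"),
                pair_ks = file.path(dir, "pair_ks.tsv"),
                ks = file.path(dir, "ks_events.tsv"),
                bedgraph = file.path(dir, "coverage.bedgraph"))
  write_genes_gff3(sc$layout$genes, paths$gff)
  write_similarity_hits(sc$layout$pairs, paths$hits)
  utils::write.table(sc$layout$pairs[, c("gene_a", "gene_b", "ks")],
                     paths$pair_ks, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sc$ks_events, paths$ks, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_bedgraph(sc$coverage, paths$bedgraph)
  invisible(c(paths, sc))
}

# in-memory scenario construction shared by fixtures and tests
fixture_scenario <- function(scenario, seed = 1, n_events = 3000) {
  set.seed(seed)
  if (scenario == "wgd_like") {
    layout <- simulate_genome_layout(
      n_scaffolds = 8, genes_per_scaffold = 120,
      planted_blocks = data.frame(topology = rep("inter_scaffold", 4),
                                  n_anchors = c(8, 7, 6, 6), ks_mean = 0.8),
      tandem_singletons = 4, dispersed_pairs = 10, seed = seed)
    ks <- simulate_paranome_ks(0.72, 1.5,
                               data.frame(mean = 0.8, sd = 0.1, size = 0.28),
                               n_events = n_events, seed = seed + 1)
  } else if (scenario == "segmental_burst") {
    layout <- simulate_genome_layout(
      n_scaffolds = 8, genes_per_scaffold = 120,
      planted_blocks = data.frame(
        topology = c("palindrome", "palindrome", "tandem_array", "inter_scaffold"),
        n_anchors = c(6, 6, 5, 5), ks_mean = 0.12),
      tandem_singletons = 4, dispersed_pairs = 10, seed = seed)
    ks <- simulate_paranome_ks(1, 1.5, NULL, n_events = n_events, seed = seed + 1)
  } else {
    layout <- simulate_genome_layout(n_scaffolds = 8, genes_per_scaffold = 120,
                                     tandem_singletons = 6, dispersed_pairs = 20,
                                     seed = seed)
    ks <- simulate_paranome_ks(1, 1.5, NULL, n_events = n_events, seed = seed + 1)
  }
  coverage <- simulate_coverage_track(layout$scaffold_lengths, base_depth = 100,
                                      overdispersion = 0.02, seed = seed + 2)
  list(layout = layout, ks_events = ks, coverage = coverage)
}
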