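#' Assign per-scaffold gene-order ranks
#'
#' @param genes data.frame with `gene_id`, `scaffold`, `start`, `end`,
#'   `strand` (e.g. from [read_genes_gff3()] or a
#'   [genome layout][simulate_genome_layout()]).
#' @return the table with a 0-based `rank` column, ordered by scaffold
#'   then start; ties on start are broken by gene id (lexicographic).
#' @export
rank_genes <- function(genes) {
  if (inherits(genes, "genome_layout")) genes <- genes$genes
  if (any(genes$start > genes$end)) stop("gene with start > end")
  key <- paste(genes$scaffold, genes$start, genes$gene_id)
  if (anyDuplicated(key)) stop("genes with identical scaffold, start and id")
  genes <- genes[order(genes$scaffold, genes$start, genes$gene_id), , drop = FALSE]
  genes$rank <- stats::ave(seq_len(nrow(genes)), genes$scaffold,
                           FUN = function(i) seq_along(i) - 1L)
  rownames(genes) <- NULL
  genes
}

#' Chain homolog hits into co-linear blocks
#'
#' Within-genome homolog pairs are placed in the gene-rank grid of every
#' scaffold pair (including a scaffold against itself, with the trivial
#' self diagonal masked) and chained by sparse dynamic programming:
#' every anchor contributes `match_reward`, consecutive anchors must
#' advance strictly in rank on both copies (increasing on the second copy
#' for parallel chains, decreasing for inverted ones) with a rank-space
#' Manhattan distance of at most `max_gap`, and each step costs
#' `gap_penalty` per unit of Manhattan distance. Chains are extracted
#' best-first (score, then anchor count, then first-anchor order);
#' extracted anchors cannot be reused, which resolves overlaps; chains
#' with at least `seed_size` anchors are emitted.
#'
#' Two named presets reproduce the stringent regime
#' (`seed_size = 5`, `max_gap = 25`, `evalue_cutoff = 1e-10`) and the
#' relaxed regime (`seed_size = 3`, `max_gap = 40`,
#' `evalue_cutoff = 1e-5`) of the co-linearity analysis.
#'
#' @param pairs data.frame of homolog pairs: `gene_a`, `gene_b`,
#'   `evalue` (optional), plus optional `ks`.
#' @param genes ranked gene table from [rank_genes()].
#' @param seed_size minimum number of anchors per emitted block.
#' @param max_gap maximal rank-space Manhattan distance between
#'   consecutive anchors.
#' @param evalue_cutoff hits above this E-value are ignored.
#' @param match_reward,gap_penalty chain scoring parameters.
#' @param preset `"stringent"`, `"relaxed"` or `NULL`; a preset
#'   overrides `seed_size`, `max_gap` and `evalue_cutoff`.
#' @return object of class `collinear_blocks`: list with `blocks`
#'   (block_id, scaffold_a, scaffold_b, orientation, topology, n_anchors,
#'   score, median_ks) and `anchors` (block_id, gene_a, gene_b, rank_a,
#'   rank_b).
#' @export
chain_collinear_blocks <- function(pairs, genes, seed_size = 5, max_gap = 25,
                                   evalue_cutoff = 1e-10, match_reward = 50,
                                   gap_penalty = 1, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("stringent", "relaxed"))
    if (preset == "stringent") { seed_size <- 5; max_gap <- 25; evalue_cutoff <- 1e-10 }
    else { seed_size <- 3; max_gap <- 40; evalue_cutoff <- 1e-5 }
  }
  if (!"rank" %in% names(genes)) genes <- rank_genes(genes)
  p <- pairs[pairs$gene_a != pairs$gene_b, , drop = FALSE]
  if (!is.null(p$evalue)) p <- p[p$evalue <= evalue_cutoff, , drop = FALSE]
  ia <- match(p$gene_a, genes$gene_id); ib <- match(p$gene_b, genes$gene_id)
  keep <- !is.na(ia) & !is.na(ib)
  p <- p[keep, , drop = FALSE]; ia <- ia[keep]; ib <- ib[keep]
  pts <- data.frame(gene_a = p$gene_a, gene_b = p$gene_b,
                    scf_a = genes$scaffold[ia], scf_b = genes$scaffold[ib],
                    r1 = genes$rank[ia], r2 = genes$rank[ib],
                    ks = if (!is.null(p$ks)) p$ks else NA_real_,
                    stringsAsFactors = FALSE)
  # canonical orientation of each point: scaffold_a <= scaffold_b, and for
  # self pairs rank1 < rank2 (each unordered pair appears once)
  swap <- pts$scf_a > pts$scf_b | (pts$scf_a == pts$scf_b & pts$r1 > pts$r2)
  pts[swap, c("gene_a", "gene_b", "scf_a", "scf_b", "r1", "r2")] <-
    pts[swap, c("gene_b", "gene_a", "scf_b", "scf_a", "r2", "r1")]
  pts <- pts[!(pts$scf_a == pts$scf_b & pts$r1 == pts$r2), , drop = FALSE]
  pts <- pts[!duplicated(paste(pts$gene_a, pts$gene_b)), , drop = FALSE]

  blocks <- list(); anchors <- list(); bid <- 0L
  for (grp in split(pts, paste(pts$scf_a, pts$scf_b))) {
    repeat {
      if (nrow(grp) < 2L) break
      best <- best_chain(grp, max_gap, match_reward, gap_penalty)
      if (is.null(best) || length(best$idx) < 2L) break
      chain <- grp[best$idx, , drop = FALSE]
      grp <- grp[-best$idx, , drop = FALSE]
      if (nrow(chain) < seed_size) next
      bid <- bid + 1L
      id <- sprintf("block%03d", bid)
      blocks[[bid]] <- data.frame(
        block_id = id, scaffold_a = chain$scf_a[1], scaffold_b = chain$scf_b[1],
        orientation = best$orientation, topology = NA_character_,
        n_anchors = nrow(chain), score = best$score,
        median_ks = stats::median(chain$ks), stringsAsFactors = FALSE)
      anchors[[bid]] <- data.frame(block_id = id, gene_a = chain$gene_a,
                                   gene_b = chain$gene_b, rank_a = chain$r1,
                                   rank_b = chain$r2, stringsAsFactors = FALSE)
    }
  }
  blocks <- Filter(Negate(is.null), blocks)
  anchors <- Filter(Negate(is.null), anchors)
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(block_id = character(), scaffold_a = character(),
               scaffold_b = character(), orientation = character(),
               topology = character(), n_anchors = integer(), score = numeric(),
               median_ks = numeric(), stringsAsFactors = FALSE)
  anchors <- if (length(anchors)) do.call(rbind, anchors) else
    data.frame(block_id = character(), gene_a = character(), gene_b = character(),
               rank_a = integer(), rank_b = integer(), stringsAsFactors = FALSE)
  if (nrow(blocks))
    blocks$topology <- vapply(seq_len(nrow(blocks)), function(i)
      classify_block_topology(blocks[i, ]), character(1))
  rownames(blocks) <- rownames(anchors) <- NULL
  structure(list(blocks = blocks, anchors = anchors,
                 params = list(seed_size = seed_size, max_gap = max_gap,
                               evalue_cutoff = evalue_cutoff,
                               match_reward = match_reward,
                               gap_penalty = gap_penalty)),
            class = "collinear_blocks")
}

# best chain in one rank grid over both orientations, by (score, length,
# point order); suffix dynamic programming with lexicographically minimal
# reconstruction so ties resolve deterministically
best_chain <- function(grp, max_gap, match_reward, gap_penalty) {
  o <- order(grp$r1, grp$r2)
  r1 <- grp$r1[o]; r2 <- grp$r2[o]
  n <- length(r1)
  overall <- NULL
  for (orient in c("parallel", "inverted")) {
    sgn <- if (orient == "parallel") 1 else -1
    sc <- rep(match_reward, n); ln <- rep(1L, n); nxt <- rep(NA_integer_, n)
    for (i in n:1) {
      for (j in seq_len(n)) {
        if (r1[j] <= r1[i]) next
        if (sgn * (r2[j] - r2[i]) <= 0) next
        d <- (r1[j] - r1[i]) + abs(r2[j] - r2[i])
        if (d > max_gap) next
        cand_sc <- match_reward + sc[j] - gap_penalty * d
        if (cand_sc > sc[i] || (cand_sc == sc[i] && ln[j] + 1L > ln[i]) ||
            (cand_sc == sc[i] && ln[j] + 1L == ln[i] &&
             (is.na(nxt[i]) || j < nxt[i]))) {
          sc[i] <- cand_sc; ln[i] <- ln[j] + 1L; nxt[i] <- j
        }
      }
    }
    st <- which(sc == max(sc))
    st <- st[which.max(ln[st])]
    chain <- integer(0); i <- st
    while (!is.na(i)) { chain <- c(chain, i); i <- nxt[i] }
    cand <- list(score = sc[st], len = ln[st], idx = o[chain],
                 orientation = orient, start = st)
    # exact (score, length) ties resolve to the parallel orientation
    if (is.null(overall) ||
        cand$score > overall$score ||
        (cand$score == overall$score && cand$len > overall$len))
      overall <- cand
  }
  if (is.null(overall) || overall$len < 2L) return(NULL)
  overall
}

#' Classify duplicate gene pairs by genomic context
#'
#' Anchor pairs inside co-linear blocks are `segmental_anchor`
#' (segmental/WGD-derived); non-anchor pairs on one scaffold within
#' `tandem_rank_gap` ranks are `tandem`; everything else is `dispersed`.
#' Precedence: segmental_anchor > tandem > dispersed.
#'
#' @param pairs homolog pair data.frame (`gene_a`, `gene_b`, ...).
#' @param blocks result of [chain_collinear_blocks()] (or `NULL`).
#' @param genes ranked gene table.
#' @param tandem_rank_gap maximal rank distance for the tandem label.
#' @return `pairs` with a `classification` column.
#' @export
classify_duplicates <- function(pairs, blocks, genes, tandem_rank_gap = 1) {
  if (!"rank" %in% names(genes)) genes <- rank_genes(genes)
  key <- pair_key(pairs$gene_a, pairs$gene_b)
  anchor_keys <- if (!is.null(blocks) && nrow(blocks$anchors))
    pair_key(blocks$anchors$gene_a, blocks$anchors$gene_b) else character(0)
  ia <- match(pairs$gene_a, genes$gene_id); ib <- match(pairs$gene_b, genes$gene_id)
  same <- genes$scaffold[ia] == genes$scaffold[ib]
  rd <- abs(genes$rank[ia] - genes$rank[ib])
  cls <- ifelse(key %in% anchor_keys, "segmental_anchor",
         ifelse(!is.na(same) & same & rd <= tandem_rank_gap, "tandem", "dispersed"))
  pairs$classification <- cls
  pairs
}

#' Topology of one co-linear block
#'
#' `inter_scaffold` when the two copies lie on different scaffolds;
#' intra-scaffold blocks are `palindrome` when inverted (the second copy
#' in order-reversed orientation) and `tandem_array` when parallel.
#'
#' @param block one-row data.frame with `scaffold_a`, `scaffold_b`,
#'   `orientation`.
#' @return one of `"inter_scaffold"`, `"palindrome"`, `"tandem_array"`.
#' @export
classify_block_topology <- function(block) {
  if (block$scaffold_a != block$scaffold_b) return("inter_scaffold")
  if (block$orientation == "inverted") "palindrome" else "tandem_array"
}

#' Macrosynteny scatter export of duplicate gene positions
#'
#' One row per homolog pair with genome-concatenated coordinates of both
#' genes (scaffolds laid end to end in deterministic order: decreasing
#' length, then id), anchors flagged — the data behind a within-genome
#' duplicate dot plot.
#'
#' @param pairs homolog pair data.frame.
#' @param genes ranked gene table.
#' @param blocks optional [chain_collinear_blocks()] result used to flag
#'   anchor pairs.
#' @param scaffold_lengths optional named lengths; inferred from gene
#'   extents when absent.
#' @return data.frame with `gene_a`, `gene_b`, `x`, `y` (bp in the
#'   concatenated coordinate system), `scaffold_a`, `scaffold_b`,
#'   `anchor` (logical).
#' @export
macrosynteny_dotplot <- function(pairs, genes, blocks = NULL,
                                 scaffold_lengths = NULL) {
  if (!"rank" %in% names(genes)) genes <- rank_genes(genes)
  if (is.null(scaffold_lengths)) {
    scaffold_lengths <- tapply(genes$end, genes$scaffold, max)
    scaffold_lengths <- stats::setNames(as.numeric(scaffold_lengths),
                                        names(scaffold_lengths))
  }
  ord <- names(scaffold_lengths)[order(-scaffold_lengths, names(scaffold_lengths))]
  offset <- stats::setNames(cumsum(c(0, scaffold_lengths[ord][-length(ord)])), ord)
  ia <- match(pairs$gene_a, genes$gene_id); ib <- match(pairs$gene_b, genes$gene_id)
  mid <- function(i) (genes$start[i] + genes$end[i]) / 2
  anchor_keys <- if (!is.null(blocks) && nrow(blocks$anchors))
    pair_key(blocks$anchors$gene_a, blocks$anchors$gene_b) else character(0)
  data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
             x = offset[genes$scaffold[ia]] + mid(ia),
             y = offset[genes$scaffold[ib]] + mid(ib),
             scaffold_a = genes$scaffold[ia], scaffold_b = genes$scaffold[ib],
             anchor = pair_key(pairs$gene_a, pairs$gene_b) %in% anchor_keys,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.collinear_blocks <- function(x, ...) {
  cat("Co-linear blocks:", nrow(x$blocks), "block(s),",
      nrow(x$anchors), "anchor pair(s)\n")
  if (nrow(x$blocks)) print(table(x$blocks$topology))
  invisible(x)
}
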