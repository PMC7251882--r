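#' File input and output for the standard formats the pipeline consumes
#'
#' The pipeline ingests the standard outputs of external tools: gene
#' coordinates as GFF3, all-vs-all within-proteome similarity hits in the
#' 12-column tabular format, per-base read coverage as bedgraph, gene
#' family count matrices as TSV and species trees as newick. GFF3 and
#' bedgraph go through `rtracklayer`.
#'
#' @name wgdsig-io
NULL

#' Read gene features from GFF3
#'
#' @param path GFF3 file.
#' @param feature feature type to keep (default `"gene"`).
#' @return data.frame with columns `gene_id`, `scaffold`, `start`, `end`,
#'   `strand` (1-based, closed coordinates).
#' @export
read_genes_gff3 <- function(path, feature = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == feature]
  id <- if (!is.null(gr$ID)) gr$ID else gr$Name
  data.frame(gene_id = as.character(id),
             scaffold = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write a gene table (e.g. from [simulate_genome_layout()]) as GFF3
#'
#' @param genes data.frame with `gene_id`, `scaffold`, `start`, `end`,
#'   `strand`.
#' @param path output file.
#' @export
write_genes_gff3 <- function(genes, path) {
  strand <- ifelse(genes$strand %in% c("+", "-"), genes$strand, "*")
  gr <- GenomicRanges::GRanges(genes$scaffold,
                               IRanges::IRanges(genes$start, genes$end),
                               strand = strand)
  gr$type <- "gene"
  gr$source <- "wgdsig"
  gr$ID <- genes$gene_id
  gr$Name <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read 12-column tabular similarity hits
#'
#' The conventional 12 columns of an all-vs-all protein similarity
#' search: query, subject, percent identity, alignment length,
#' mismatches, gap openings, query start/end, subject start/end, E-value,
#' bit score. Self hits are dropped; hits above `evalue_cutoff` are
#' removed; reciprocal duplicates are collapsed to one row per unordered
#' pair keeping the best (lowest E-value, then highest bit score) hit.
#'
#' @param path tab-separated file without header.
#' @param evalue_cutoff maximum E-value retained (1e-10 in the stringent
#'   regime, 1e-5 in the relaxed regime).
#' @return data.frame with columns `gene_a`, `gene_b`, `pident`,
#'   `length`, `evalue`, `bitscore`.
#' @export
read_similarity_hits <- function(path, evalue_cutoff = 1e-10) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- utils::read.table(path, sep = "\t", header = FALSE, col.names = cols,
                         stringsAsFactors = FALSE)
  dedupe_hits(data.frame(gene_a = x$qseqid, gene_b = x$sseqid, pident = x$pident,
                         length = x$length, evalue = x$evalue,
                         bitscore = x$bitscore, stringsAsFactors = FALSE),
              evalue_cutoff)
}

dedupe_hits <- function(hits, evalue_cutoff = Inf) {
  hits <- hits[hits$gene_a != hits$gene_b & hits$evalue <= evalue_cutoff, , drop = FALSE]
  a <- pmin(hits$gene_a, hits$gene_b)
  b <- pmax(hits$gene_a, hits$gene_b)
  hits$gene_a <- a; hits$gene_b <- b
  hits <- hits[order(a, b, hits$evalue, -hits$bitscore), , drop = FALSE]
  hits <- hits[!duplicated(paste(hits$gene_a, hits$gene_b)), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write homolog pairs in 12-column tabular format
#'
#' @param pairs data.frame with at least `gene_a`, `gene_b`, `evalue`,
#'   `bitscore`.
#' @param path output file.
#' @export
write_similarity_hits <- function(pairs, path) {
  n <- nrow(pairs)
  x <- data.frame(pairs$gene_a, pairs$gene_b, 90, 200, 10, 0, 1, 200, 1, 200,
                  format(pairs$evalue, scientific = TRUE), pairs$bitscore)
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write bedgraph coverage tracks
#'
#' Bedgraph intervals (0-based, half-open) are expanded to per-base depth
#' vectors; positions not covered by any interval get depth 0.
#'
#' @param path bedgraph file.
#' @param scaffold_lengths optional named vector; defaults to the largest
#'   end coordinate seen per scaffold.
#' @return named list of integer per-base depth vectors.
#' @export
read_bedgraph <- function(path, scaffold_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  scaf <- as.character(GenomicRanges::seqnames(gr))
  if (is.null(scaffold_lengths))
    scaffold_lengths <- tapply(GenomicRanges::end(gr), scaf, max)
  out <- lapply(names(scaffold_lengths), function(s) {
    d <- integer(scaffold_lengths[[s]])
    sel <- scaf == s
    st <- GenomicRanges::start(gr)[sel]; en <- GenomicRanges::end(gr)[sel]
    sc <- as.integer(gr$score[sel])
    for (i in seq_along(st)) d[st[i]:en[i]] <- sc[i]
    d
  })
  names(out) <- names(scaffold_lengths)
  out
}

#' @rdname read_bedgraph
#' @param track a [coverage_track][simulate_coverage_track()] or named
#'   list of per-base depths.
#' @export
write_bedgraph <- function(track, path) {
  depths <- as_depth_list(track)
  grl <- lapply(names(depths), function(s) {
    r <- S4Vectors::Rle(depths[[s]])
    en <- cumsum(S4Vectors::runLength(r))
    st <- en - S4Vectors::runLength(r) + 1L
    gr <- GenomicRanges::GRanges(s, IRanges::IRanges(st, en))
    gr$score <- as.numeric(S4Vectors::runValue(r))
    gr
  })
  gr <- suppressWarnings(do.call(c, grl))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read and write gene-family count matrices
#'
#' TSV with family ids in the first column and one column per species.
#'
#' @param path TSV file.
#' @return integer matrix, families x species.
#' @export
read_count_matrix <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_count_matrix
#' @param counts integer matrix, families x species.
#' @export
write_count_matrix <- function(counts, path) {
  utils::write.table(data.frame(family = rownames(counts), counts,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
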