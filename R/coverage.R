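#' Resampling coverage test for haplotig-like co-linear blocks
#'
#' A co-linear block whose two copies are really two haplotigs of the
#' same region shows a drop in read depth. For each block interval the
#' mean per-base depth is compared to the distribution of mean depths of
#' `n_random` randomly placed genome regions of the same length; the
#' block is flagged `haplotig_suspect` when its mean falls below the
#' lower bound of the background 95% interval.
#'
#' Two normal-assumption intervals over the resampled region means are
#' reported: the distributional interval `mean +/- 1.96 * sd` (used for
#' flagging, so that under the null a region fails at the nominal
#' one-sided 2.5% rate) and the standard-error interval of the background
#' mean `mean +/- 1.96 * sd/sqrt(n)`; empirical 2.5/97.5 percentiles are
#' reported alongside.
#'
#' @param track a [coverage_track][simulate_coverage_track()], or a named
#'   list of per-base depth vectors, or a path to a bedgraph file.
#' @param blocks data.frame with columns `block_id`, `scaffold`, `start`,
#'   `end` (1-based, closed), e.g. from [block_intervals()].
#' @param n_random number of random same-length regions (>= 100).
#' @param seed integer seed for the resampling.
#' @return data.frame of class `coverage_verdicts`: block id, block mean
#'   depth, background mean, distributional CI (`bg_lower`, `bg_upper`),
#'   standard-error CI (`sem_lower`, `sem_upper`), empirical percentiles
#'   (`emp_lower`, `emp_upper`) and `flag`.
#' @export
block_coverage_test <- function(track, blocks, n_random = 1000, seed = NULL) {
  depths <- as_depth_list(track)
  if (!length(depths) || sum(lengths(depths)) == 0) stop("empty coverage track")
  if (n_random < 100) stop("n_random must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  cums <- lapply(depths, function(d) cumsum(as.numeric(d)))
  lens <- lengths(depths)
  out <- lapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    L <- b$end - b$start + 1L
    if (is.null(depths[[b$scaffold]]) || b$start < 1 || b$end > lens[[b$scaffold]])
      stop("block interval outside track bounds: ", b$block_id)
    cs <- cums[[b$scaffold]]
    bm <- (cs[b$end] - if (b$start > 1) cs[b$start - 1] else 0) / L
    elig <- pmax(lens - L + 1L, 0L)
    if (sum(elig) == 0) stop("block longer than every scaffold: ", b$block_id)
    scf <- sample(names(depths), n_random, replace = TRUE, prob = elig)
    means <- vapply(seq_len(n_random), function(j) {
      s <- sample.int(elig[[scf[j]]], 1L)
      cs2 <- cums[[scf[j]]]
      (cs2[s + L - 1L] - if (s > 1) cs2[s - 1] else 0) / L
    }, numeric(1))
    m <- mean(means); sd_ <- stats::sd(means)
    data.frame(block_id = b$block_id, length = L, block_mean = bm,
               bg_mean = m,
               bg_lower = m - 1.96 * sd_, bg_upper = m + 1.96 * sd_,
               sem_lower = m - 1.96 * sd_ / sqrt(n_random),
               sem_upper = m + 1.96 * sd_ / sqrt(n_random),
               emp_lower = unname(stats::quantile(means, 0.025)),
               emp_upper = unname(stats::quantile(means, 0.975)),
               flag = if (bm < m - 1.96 * sd_) "haplotig_suspect" else "normal",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("coverage_verdicts", class(out))
  out
}

as_depth_list <- function(track) {
  if (inherits(track, "coverage_track")) return(track$depths)
  if (is.character(track)) return(read_bedgraph(track))
  if (is.list(track)) return(track)
  stop("unsupported coverage track representation")
}

#' Genomic intervals spanned by co-linear blocks
#'
#' Converts chained co-linear blocks to the genomic intervals their two
#' copies span (from the first to the last anchor gene on each side),
#' yielding the inputs of [block_coverage_test()].
#'
#' @param blocks result of [chain_collinear_blocks()].
#' @param genes ranked gene table (see [rank_genes()]).
#' @return data.frame with columns `block_id`, `copy` (`"a"`/`"b"`),
#'   `scaffold`, `start`, `end`.
#' @export
block_intervals <- function(blocks, genes) {
  anc <- blocks$anchors
  out <- lapply(split(anc, anc$block_id), function(a) {
    ga <- genes[match(a$gene_a, genes$gene_id), ]
    gb <- genes[match(a$gene_b, genes$gene_id), ]
    rbind(
      data.frame(block_id = a$block_id[1], copy = "a", scaffold = ga$scaffold[1],
                 start = min(ga$start), end = max(ga$end), stringsAsFactors = FALSE),
      data.frame(block_id = a$block_id[1], copy = "b", scaffold = gb$scaffold[1],
                 start = min(gb$start), end = max(gb$end), stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
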