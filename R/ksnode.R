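#' Node-weighted Ks events for one paralog family
#'
#' Every internal node of a family's (rooted) tree represents one
#' duplication event. The member pairs whose most recent common ancestor
#' is that node all date the same event, so each contributing pair
#' carries weight `1 / (number of pairs at the node)` and the node's
#' consensus Ks is the mean of its contributing pair estimates. Per node
#' the weights sum to one, so a histogram of the returned rows counts
#' duplication events, not duplicate pairs.
#'
#' @param family character vector of member gene ids (>= 2).
#' @param ks_pairs data.frame with columns `gene_a`, `gene_b`, `ks` and
#'   optionally a logical `saturated`; one row per unordered member pair.
#' @param family_tree the family tree as an [ape::phylo] object or a
#'   newick string (e.g. from an external approximate-ML program); may be
#'   unrooted, in which case it is midpoint-rooted. Not needed for
#'   2-member families. See [family_tree_nj()] for the built-in fallback.
#' @param family_id label recorded in the output.
#' @param exclude_saturated `"before"` drops saturated pairs before
#'   node-averaging (default), `"after"` keeps them for the consensus and
#'   lets [filter_ks_events()] act downstream, `"never"` keeps them.
#' @return data.frame with one row per contributing pair: `family`,
#'   `node`, `gene_a`, `gene_b`, `ks` (pair estimate), `weight`,
#'   `consensus_ks` (node mean), `n_pairs` (pairs at the node).
#' @examples
#' ks <- data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
#'                  ks = c(0.2, 1.0, 1.1))
#' weight_ks_by_node(c("a", "b", "c"), ks, "((a:1,b:1):1,c:2);")
#' @export
weight_ks_by_node <- function(family, ks_pairs, family_tree = NULL,
                              family_id = "fam1",
                              exclude_saturated = c("before", "after", "never")) {
  exclude_saturated <- match.arg(exclude_saturated)
  if (length(family) < 2) stop("Ks analysis needs families of >= 2 members")
  sat <- if (!is.null(ks_pairs$saturated)) ks_pairs$saturated else rep(FALSE, nrow(ks_pairs))
  if (exclude_saturated == "before") {
    ks_pairs <- ks_pairs[!sat, , drop = FALSE]
    sat <- rep(FALSE, nrow(ks_pairs))
  }
  if (length(family) == 2L) {
    if (nrow(ks_pairs) < 1) return(empty_ks_events())
    return(data.frame(family = family_id, node = "n1",
                      gene_a = ks_pairs$gene_a[1], gene_b = ks_pairs$gene_b[1],
                      ks = ks_pairs$ks[1], weight = 1,
                      consensus_ks = ks_pairs$ks[1], n_pairs = 1L,
                      stringsAsFactors = FALSE))
  }
  if (is.null(family_tree)) stop("families of > 2 members need a family tree")
  tr <- if (is.character(family_tree)) ape::read.tree(text = family_tree) else family_tree
  if (!all(family %in% tr$tip.label))
    stop("family tree does not cover all members")
  tr <- ape::keep.tip(tr, family)
  if (!ape::is.rooted(tr)) tr <- phangorn::midpoint(tr)
  tr <- ape::multi2di(tr)
  mr <- ape::mrca(tr)
  cmb <- utils::combn(family, 2)
  pk <- ks_lookup(ks_pairs)
  rows <- lapply(seq_len(ncol(cmb)), function(k) {
    a <- cmb[1, k]; b <- cmb[2, k]
    ks <- pk[[pair_key(a, b)]]
    if (is.null(ks)) return(NULL)
    data.frame(gene_a = a, gene_b = b, ks = ks,
               node = mr[a, b] - length(tr$tip.label),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || !nrow(rows)) return(empty_ks_events())
  out <- do.call(rbind, lapply(split(rows, rows$node), function(g) {
    g$weight <- 1 / nrow(g)
    g$consensus_ks <- mean(g$ks)
    g$n_pairs <- nrow(g)
    g
  }))
  out$family <- family_id
  out$node <- paste0("n", out$node)
  rownames(out) <- NULL
  out[, c("family", "node", "gene_a", "gene_b", "ks", "weight",
          "consensus_ks", "n_pairs")]
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

ks_lookup <- function(ks_pairs) {
  out <- as.list(ks_pairs$ks)
  names(out) <- pair_key(ks_pairs$gene_a, ks_pairs$gene_b)
  out
}

empty_ks_events <- function() {
  data.frame(family = character(), node = character(), gene_a = character(),
             gene_b = character(), ks = numeric(), weight = numeric(),
             consensus_ks = numeric(), n_pairs = integer(),
             stringsAsFactors = FALSE)
}

#' Neighbor-joining fallback family tree from a protein alignment
#'
#' Builds an approximate family tree by neighbor joining on protein
#' p-distances and midpoint-roots it. Only the LCA structure of the
#' topology matters for node weighting, so an approximate tree suffices
#' when no externally inferred tree is available.
#'
#' @param protein_alignment named character vector of aligned amino-acid
#'   strings.
#' @return a rooted [ape::phylo] object.
#' @export
family_tree_nj <- function(protein_alignment) {
  nm <- names(protein_alignment)
  mat <- do.call(rbind, strsplit(toupper(protein_alignment), ""))
  rownames(mat) <- nm
  n <- length(nm)
  d <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    d[i, j] <- d[j, i] <- if (any(ok)) mean(mat[i, ok] != mat[j, ok]) else 0.5
  }
  tr <- ape::nj(stats::as.dist(d))
  phangorn::midpoint(tr)
}

#' Filter Ks events to the informative range
#'
#' Removes duplication events whose Ks is exactly zero or exceeds
#' `max_ks` (saturated beyond reliability), the conventional `(0, 5]`
#' retention window for paranome age distributions.
#'
#' @param events data.frame of Ks events (see [weight_ks_by_node()]); the
#'   filter is applied to the `consensus_ks` column when present (an
#'   event-level filter), else to `ks`.
#' @param max_ks upper retention bound.
#' @param on filter on `"consensus"` or `"pair"` Ks values.
#' @return the retained rows; numbers of removed rows are reported via a
#'   message and attached as `attr(, "removed")`.
#' @export
filter_ks_events <- function(events, max_ks = 5, on = c("consensus", "pair")) {
  on <- match.arg(on)
  col <- if (on == "consensus" && !is.null(events$consensus_ks)) "consensus_ks" else "ks"
  if (!nrow(events)) return(events)
  keep <- events[[col]] > 0 & events[[col]] <= max_ks
  removed <- c(zero = sum(events[[col]] <= 0), high = sum(events[[col]] > max_ks))
  if (any(removed > 0))
    message("filter_ks_events: removed ", removed[["zero"]], " zero and ",
            removed[["high"]], " saturated (> ", max_ks, ") rows")
  out <- events[keep, , drop = FALSE]
  if (!nrow(out) && nrow(events)) warning("all Ks events were filtered out")
  attr(out, "removed") <- removed
  out
}
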