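#' Markov clustering of the within-genome similarity graph
#'
#' Delineates paralogous gene families from an undirected weighted
#' similarity graph by Markov clustering (MCL): the column-stochastic
#' transition matrix is alternately squared (expansion) and taken to an
#' entrywise power followed by column renormalization (inflation), with
#' near-zero entries pruned, until the matrix is (numerically) invariant.
#' Clusters are read off the attractors of the limit matrix. Self-loops
#' with the maximum incident edge weight are added to every vertex
#' before normalization, the usual regularization.
#'
#' @param graph either a data.frame of edges with columns `gene_a`,
#'   `gene_b` and a weight column (`bitscore` or `weight`), e.g. from
#'   [read_similarity_hits()], or a symmetric adjacency matrix.
#' @param inflation inflation factor (> 1); 2.0 is the conventional
#'   default for paranome construction.
#' @param prune entries below this value are set to zero each iteration.
#' @param max_iter maximum number of expansion/inflation rounds.
#' @param min_size smallest family size returned; singletons (size 1)
#'   are dropped by default since they carry no duplication signal.
#' @return list of character vectors (gene ids), largest family first;
#'   singletons that were discarded are attached as `attr(, "singletons")`.
#' @examples
#' edges <- data.frame(gene_a = c("a", "a", "b", "x"),
#'                     gene_b = c("b", "c", "c", "y"), weight = 1)
#' cluster_paralogs_mcl(edges)
#' @export
cluster_paralogs_mcl <- function(graph, inflation = 2, prune = 1e-5,
                                 max_iter = 100, min_size = 2) {
  if (inflation <= 1) stop("inflation must exceed 1")
  A <- as_adjacency(graph)
  if (!nrow(A)) stop("similarity graph is empty")
  # self-loops at the maximum incident weight
  diag(A) <- apply(A, 1, max)
  diag(A)[diag(A) == 0] <- 1
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M            # expansion
    M2 <- M2^inflation       # inflation
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, "/")
    if (max(abs(M2 - M)) < 1e-8) { M <- M2; break }
    M <- M2
    if (it == max_iter) stop("Markov clustering did not converge in ",
                             max_iter, " iterations")
  }
  # attractors = vertices with positive return probability; each cluster is
  # an attractor row's support, merged over attractors sharing support
  keep <- which(diag(M) > prune)
  members <- lapply(keep, function(i) which(M[i, ] > prune))
  clusters <- list()
  assigned <- rep(FALSE, nrow(A))
  for (m in members) {
    hit <- vapply(clusters, function(cl) any(m %in% cl), logical(1))
    if (any(hit)) {
      j <- which(hit)[1]
      clusters[[j]] <- sort(unique(c(clusters[[j]], m)))
    } else clusters[[length(clusters) + 1L]] <- sort(m)
    assigned[m] <- TRUE
  }
  # any vertex not in an attractor's support joins its strongest column
  for (v in which(!assigned)) {
    best <- which.max(M[, v])
    hit <- which(vapply(clusters, function(cl) best %in% cl, logical(1)))
    if (length(hit)) clusters[[hit[1]]] <- sort(c(clusters[[hit[1]]], v))
    else clusters[[length(clusters) + 1L]] <- v
  }
  fams <- lapply(clusters, function(cl) rownames(A)[cl])
  fams <- fams[order(-lengths(fams))]
  small <- lengths(fams) < min_size
  structure(fams[!small], singletons = unlist(fams[small], use.names = FALSE))
}

as_adjacency <- function(graph) {
  if (is.matrix(graph)) {
    if (!isSymmetric(unname(graph))) stop("adjacency matrix must be symmetric")
    diag(graph) <- 0
    return(graph)
  }
  stopifnot(is.data.frame(graph))
  graph <- graph[graph$gene_a != graph$gene_b, , drop = FALSE]
  w <- if (!is.null(graph$weight)) graph$weight else
       if (!is.null(graph$bitscore)) graph$bitscore else rep(1, nrow(graph))
  v <- sort(unique(c(graph$gene_a, graph$gene_b)))
  A <- matrix(0, length(v), length(v), dimnames = list(v, v))
  ia <- match(graph$gene_a, v); ib <- match(graph$gene_b, v)
  for (k in seq_along(ia)) {
    A[ia[k], ib[k]] <- max(A[ia[k], ib[k]], w[k])
    A[ib[k], ia[k]] <- A[ia[k], ib[k]]
  }
  A
}
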