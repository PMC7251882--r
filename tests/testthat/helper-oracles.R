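# Independent oracles used across the suite. These deliberately take
# different computational routes than the package code they check.

# --- truncated matrix exponential of the linear birth-death generator ---
bd_expm_oracle <- function(N, lam, mu, t) {
  Q <- matrix(0, N + 1, N + 1)
  for (n in 0:N) {
    if (n + 1 <= N) Q[n + 1, n + 2] <- n * lam
    if (n >= 1) Q[n + 1, n] <- n * mu
  }
  diag(Q) <- -rowSums(Q)
  as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
}

# --- exhaustive enumeration of the two-leaf family likelihood ---
loglik_oracle_2leaf <- function(cA, cB, t1, t2, lam, mu, eta, S = 80, N = 80) {
  P1 <- bd_expm_oracle(N, lam, mu, t1)
  P2 <- bd_expm_oracle(N, lam, mu, t2)
  geom <- eta * (1 - eta)^(0:(S - 1))
  num <- sum(sapply(1:S, function(s) geom[s] * P1[s + 1, cA + 1] * P2[s + 1, cB + 1]))
  eA <- P1[2, 1]; eB <- P2[2, 1]
  pinc <- sum(sapply(1:S, function(s) geom[s] * (1 - eA^s) * (1 - eB^s)))
  log(num) - log(pinc)
}

# --- exhaustive enumeration for ((A:t1,B:t1):t0, C:t2) ---
loglik_oracle_3leaf <- function(cA, cB, cC, t1, t0, t2, lam, mu, eta,
                                S = 60, N = 60) {
  P1 <- bd_expm_oracle(N, lam, mu, t1)
  P0 <- bd_expm_oracle(N, lam, mu, t0)
  P2 <- bd_expm_oracle(N, lam, mu, t2)
  geom <- eta * (1 - eta)^(0:(S - 1))
  num <- 0
  for (s in 1:S) {
    inner <- sum(sapply(0:N, function(v)
      P0[s + 1, v + 1] * P1[v + 1, cA + 1] * P1[v + 1, cB + 1]))
    num <- num + geom[s] * inner * P2[s + 1, cC + 1]
  }
  eAB <- sum(sapply(0:N, function(v) P0[2, v + 1] * ((P1[2, 1]^2)^v)))
  eC <- P2[2, 1]
  pinc <- sum(sapply(1:S, function(s) geom[s] * (1 - eAB^s) * (1 - eC^s)))
  log(num) - log(pinc)
}

# --- exhaustive chain enumeration mirroring the declared extraction
# semantics: best chain by (score, length, lexicographic point order),
# extracted repeatedly; emitted when >= seed_size anchors ---
oracle_best_chain <- function(r1, r2, max_gap, match_reward, gap_penalty) {
  o <- order(r1, r2)
  r1 <- r1[o]; r2 <- r2[o]
  n <- length(r1)
  best <- NULL
  # chains are enumerated in lexicographic order (parallel orientation
  # first, starts and successors in ascending point order), so keeping
  # the first chain that strictly improves (score, length) reproduces
  # the implementation's deterministic tie-breaking
  consider <- function(chain, score, orientation) {
    cand <- list(score = score, len = length(chain), idx = o[chain],
                 orientation = orientation, seq = chain)
    better <- is.null(best) || cand$score > best$score ||
      (cand$score == best$score && cand$len > best$len)
    if (better) best <<- cand
  }
  grow <- function(chain, score, sgn) {
    i <- chain[length(chain)]
    if (length(chain) >= 2) consider(chain, score, if (sgn > 0) "parallel" else "inverted")
    for (j in seq_len(n)) {
      if (r1[j] <= r1[i]) next
      if (sgn * (r2[j] - r2[i]) <= 0) next
      d <- (r1[j] - r1[i]) + abs(r2[j] - r2[i])
      if (d > max_gap) next
      grow(c(chain, j), score + match_reward - gap_penalty * d, sgn)
    }
  }
  for (sgn in c(1, -1)) for (i in seq_len(n)) grow(i, match_reward, sgn)
  best
}

oracle_chain_blocks <- function(pts, seed_size, max_gap, match_reward = 50,
                                gap_penalty = 1) {
  blocks <- list()
  repeat {
    if (nrow(pts) < 2) break
    best <- oracle_best_chain(pts$r1, pts$r2, max_gap, match_reward, gap_penalty)
    if (is.null(best)) break
    chain <- pts[best$idx, , drop = FALSE]
    pts <- pts[-best$idx, , drop = FALSE]
    if (nrow(chain) >= seed_size)
      blocks[[length(blocks) + 1L]] <- list(anchors = chain, score = best$score,
                                            orientation = best$orientation)
  }
  blocks
}

# --- independent straightforward Markov-clustering run (no pruning,
# cluster extraction by graph components of the limit matrix) ---
ref_mcl <- function(A, inflation = 2, iters = 200) {
  diag(A) <- apply(A, 1, max)
  diag(A)[diag(A) == 0] <- 1
  M <- sweep(A, 2, colSums(A), "/")
  for (i in seq_len(iters)) {
    M2 <- (M %*% M)^inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    if (max(abs(M2 - M)) < 1e-10) { M <- M2; break }
    M <- M2
  }
  g <- igraph::graph_from_adjacency_matrix((M > 1e-6) | t(M > 1e-6),
                                           mode = "undirected")
  comp <- igraph::components(g)$membership
  split(rownames(A), comp)
}

# --- shared 9-taxon dated tree (My) with arthropod-scale divergence
# depths ---
tree9 <- function() {
  as_dated_tree(paste0("((((A:50,B:50):50,(C:60,D:60):40):100,",
                       "((E:80,F:80):70,(G:40,H:40):110):50):150,O:350);"))
}

canonical_points <- function(pairs, genes) {
  ia <- match(pairs$gene_a, genes$gene_id)
  ib <- match(pairs$gene_b, genes$gene_id)
  pts <- data.frame(r1 = genes$rank[ia], r2 = genes$rank[ib])
  swap <- pts$r1 > pts$r2
  tmp <- pts$r1[swap]; pts$r1[swap] <- pts$r2[swap]; pts$r2[swap] <- tmp
  pts
}
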