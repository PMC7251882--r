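#' Linear birth-death transition probability
#'
#' Exact probability that a gene-family lineage count moves from `n` to
#' `m` along a branch of duration `t` under a linear birth-death process
#' with per-lineage duplication rate `lambda` and loss rate `mu`,
#' computed from the classical closed form
#' \deqn{P_{nm}(t) = \sum_j \binom{n}{j}\binom{n+m-j-1}{n-1}
#'       \alpha^{n-j}\beta^{m-j}(1-\alpha-\beta)^j}
#' with the critical case `lambda == mu` and the pure-birth/pure-death
#' limits handled analytically; the sum is accumulated in log space for
#' numerical stability.
#'
#' @param n,m non-negative start and end counts.
#' @param lambda,mu non-negative rates (events/gene lineage/My).
#' @param t non-negative duration (My).
#' @return the transition probability.
#' @examples
#' bd_transition_probability(1, 0, 0, 0.01, 100)  # 1 - exp(-1)
#' @export
bd_transition_probability <- function(n, m, lambda, mu, t) {
  if (n < 0 || m < 0 || t < 0 || lambda < 0 || mu < 0)
    stop("negative inputs are not allowed")
  if (t == 0) return(as.numeric(n == m))
  if (n == 0) return(as.numeric(m == 0))
  ab <- bd_alpha_beta(lambda, mu, t)
  a <- ab[1]; b <- ab[2]
  g <- 1 - a - b   # may be negative (alternating series) at large rates*t
  jmax <- min(n, m)
  lg_terms <- sg_terms <- numeric(jmax + 1L)
  for (j in 0:jmax) {
    # x^k with 0^0 = 1 handled via log terms; sign tracked for g < 0
    lb <- if (m - j == 0) 0 else if (b == 0) -Inf else (m - j) * log(b)
    lg <- if (j == 0) 0 else if (g == 0) -Inf else j * log(abs(g))
    la <- if (n - j == 0) 0 else if (a == 0) -Inf else (n - j) * log(a)
    lg_terms[j + 1L] <- lchoose(n, j) + lchoose(n + m - j - 1, n - 1) + la + lb + lg
    sg_terms[j + 1L] <- if (g < 0) (-1)^j else 1
  }
  mx <- max(lg_terms)
  if (!is.finite(mx)) return(0)
  min(max(exp(mx) * sum(sg_terms * exp(lg_terms - mx)), 0), 1)
}

# alpha (extinction) and beta (geometric growth) parameters of the
# Kendall solution
bd_alpha_beta <- function(lambda, mu, t) {
  if (lambda == 0 && mu == 0) return(c(0, 0))
  if (lambda == 0) return(c(1 - exp(-mu * t), 0))
  if (mu == 0) return(c(0, 1 - exp(-lambda * t)))
  if (isTRUE(all.equal(lambda, mu))) {
    x <- lambda * t / (1 + lambda * t)
    return(c(x, x))
  }
  r <- lambda - mu
  # written to stay stable for both signs of r
  em <- exp(-r * t)
  denom <- lambda - mu * em
  c(mu * (1 - em) / denom, lambda * (1 - em) / denom)
}

# full transition matrix on states 0..N: row n is the n-fold convolution
# of the single-lineage row (lineages evolve independently), built by
# iterated multiplication with the upper-triangular Toeplitz matrix of
# the single-lineage row. Entries 0..N of every row are exact: the
# convolution only ever looks at lower indices, so truncation cannot
# contaminate the kept states.
bd_transition_matrix <- function(N, lambda, mu, t) {
  P <- matrix(0, N + 1L, N + 1L)
  P[1, 1] <- 1
  if (N == 0L) return(P)
  row1 <- vapply(0:N, function(m) bd_transition_probability(1L, m, lambda, mu, t),
                 numeric(1))
  idx <- outer(0:N, 0:N, function(k, m) m - k + 1L)
  Tm <- matrix(0, N + 1L, N + 1L)
  pos <- idx >= 1L
  Tm[pos] <- row1[idx[pos]]
  P[2, ] <- row1
  for (n in 2:N) P[n + 1L, ] <- P[n, ] %*% Tm
  pmax(P, 0)
}

# WGD retention operator: each of s genes independently adds a retained
# copy with probability q, so s -> s + Binomial(s, q)
wgd_retention_matrix <- function(N, q) {
  W <- matrix(0, N + 1L, N + 1L)
  for (s in 0:N) {
    kmax <- min(s, N - s)
    if (s == 0) { W[1, 1] <- 1; next }
    k <- 0:kmax
    W[s + 1L, s + 1L + k] <- stats::dbinom(k, s, q)
  }
  W
}

# operator mapping the count distribution at the top (parent end) of a
# branch to the bottom, with any WGDs on the branch applied at their ages
branch_operator <- function(N, t, lambda, mu, branch_wgds = NULL, q = NULL) {
  if (is.null(branch_wgds) || nrow(branch_wgds) == 0L)
    return(bd_transition_matrix(N, lambda, mu, t))
  o <- order(-branch_wgds$age)          # oldest (closest to parent) first
  ages <- branch_wgds$age[o]
  qs <- q[o]
  M <- bd_transition_matrix(N, lambda, mu, t - ages[1])
  for (k in seq_along(ages)) {
    M <- M %*% wgd_retention_matrix(N, qs[k])
    seg <- if (k < length(ages)) ages[k] - ages[k + 1] else ages[k]
    M <- M %*% bd_transition_matrix(N, lambda, mu, seg)
  }
  M
}

# extinction probability generating machinery: probability that a single
# gene at the top of a branch leaves no observed descendant below the
# child, given the child's subtree extinction probability z
branch_extinction <- function(z, t, lambda, mu, branch_wgds = NULL, q = NULL) {
  G <- function(z, tt) {
    ab <- bd_alpha_beta(lambda, mu, tt)
    (ab[1] + (1 - ab[1] - ab[2]) * z) / (1 - ab[2] * z)
  }
  if (is.null(branch_wgds) || nrow(branch_wgds) == 0L) return(G(z, t))
  o <- order(branch_wgds$age)           # compose from the child upward
  ages <- branch_wgds$age[o]
  qs <- q[o]
  val <- G(z, ages[1])
  for (k in seq_along(ages)) {
    val <- val * (1 - qs[k] + qs[k] * val)   # retained copy must also vanish
    seg <- if (k < length(ages)) ages[k + 1] - ages[k] else t - ages[k]
    val <- G(val, seg)
  }
  val
}
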