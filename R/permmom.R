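## Exact permutation moments of quadratic-form statistics.
##
## For fixed symmetric matrices A (weights) and B (score outer product),
## the statistic Q(sigma) = sum_{i != j} A_ij B_{sigma(i) sigma(j)} has
## closed-form moments over the uniform permutation sigma, obtained by
## classifying index coincidence patterns (Mantel-type formulas).  These
## exact moments calibrate the asymptotic null of the weighted U
## statistic; the third moment uses sums over the eight isomorphism
## classes of three-edge multigraphs, whose integer combination
## coefficients (4, 24, 6, 8, 8, 24, 12, 1) are verified against full
## enumeration in the test suite.

## pattern sums over ordered distinct-vertex tuples for a symmetric
## zero-diagonal matrix x: triple edge, double+adjacent, double+disjoint,
## triangle, 3-star, 3-path, path+edge, 3-matching
pattern_sums <- function(x) {
  n <- nrow(x)
  r <- rowSums(x); s2 <- rowSums(x * x)
  S <- sum(r); S2 <- sum(s2); S3 <- sum(x^3); R <- sum(r * r)
  x2 <- x %*% x
  xr <- drop(x %*% r)
  s2r <- sum(s2 * r)
  rxr <- drop(r %*% x %*% r)
  trx3 <- sum(x2 * x)
  P1 <- S3
  P2 <- s2r - S3
  P3 <- S * S2 - 4 * s2r + 2 * S3
  P4 <- trx3
  P5 <- sum(r^3) - 3 * s2r + 2 * S3
  P6 <- rxr - 2 * s2r + S3 - trx3
  P7 <- S * (R - S2) - 2 * sum(r^3) + 10 * s2r - 4 * rxr - 4 * S3 + 2 * trx3
  Sij <- S - 2 * outer(r, r, "+") + 2 * x
  S2ij <- S2 - 2 * outer(s2, s2, "+") + 2 * x * x
  Aterm <- (matrix(r, n, n) - x)^2
  Bterm <- (matrix(r, n, n, byrow = TRUE) - x)^2
  Rij <- R - 2 * outer(xr, xr, "+") + outer(s2, s2, "+") + 2 * x2 - Aterm - Bterm
  D2ij <- Sij^2 + 2 * S2ij - 4 * Rij
  diag(D2ij) <- 0
  P8 <- sum(x * D2ij)
  c(P1, P2, P3, P4, P5, P6, P7, P8)
}

## first and second moment pieces shared by the formulas below
.mantel_stats <- function(A) {
  r <- rowSums(A)
  c(S = sum(r), S2 = sum(A * A), R = sum(r * r))
}

## exact mean and variance of sum_{i!=j} A_ij B_{s(i)s(j)} for symmetric
## zero-diagonal A, B
mantel_moments <- function(A, B) {
  n <- nrow(A)
  a <- .mantel_stats(A); b <- .mantel_stats(B)
  Ta <- a[["R"]] - a[["S2"]]; Tb <- b[["R"]] - b[["S2"]]
  Qa <- a[["S"]]^2 - 2 * a[["S2"]] - 4 * Ta
  Qb <- b[["S"]]^2 - 2 * b[["S2"]] - 4 * Tb
  m1 <- a[["S"]] * b[["S"]] / (n * (n - 1))
  m2 <- 2 * a[["S2"]] * b[["S2"]] / (n * (n - 1)) +
    4 * Ta * Tb / (n * (n - 1) * (n - 2)) +
    Qa * Qb / (n * (n - 1) * (n - 2) * (n - 3))
  c(mean = m1, var = m2 - m1^2)
}

#' Exact permutation cumulants of a weighted U statistic
#'
#' First three cumulants of \eqn{Q(\sigma) = \sum_{i \ne j} M_{ij}
#' z_{\sigma(i)} z_{\sigma(j)}} over the uniform random permutation
#' \eqn{\sigma}, for a fixed symmetric zero-diagonal weight matrix `M`
#' and fixed score vector `z`.  This is the exact finite-sample null of
#' the weighted U statistic under phenotype exchangeability.
#'
#' Both `M` and the score outer product are split into their off-diagonal
#' mean and a centered remainder before the pattern sums are formed; the
#' constant parts contribute deterministically (centered scores satisfy
#' \eqn{\sum_{i \ne j} z_i z_j = -\sum z_i^2} for every permutation), so
#' the computation is free of the catastrophic cancellation that direct
#' evaluation on near-constant kernel matrices would incur.
#'
#' @param M Symmetric numeric matrix with zero diagonal (combined
#'   similarity weights).
#' @param z Numeric score vector (standardized centered ranks).
#' @return Named vector `mean`, `var`, `k3`.
#' @export
perm_cumulants <- function(M, z) {
  n <- length(z)
  stopifnot(nrow(M) == n, ncol(M) == n)
  B <- tcrossprod(z); diag(B) <- 0
  cM <- sum(M) / (n * (n - 1)); cB <- sum(B) / (n * (n - 1))
  E <- M - cM; diag(E) <- 0
  Eb <- B - cB; diag(Eb) <- 0
  mm <- mantel_moments(E, Eb)
  v <- c(2, 3, 4, 3, 4, 4, 5, 6)
  cf <- c(4, 24, 6, 8, 8, 24, 12, 1)
  Pa <- pattern_sums(E); Pb <- pattern_sums(Eb)
  m3 <- sum(cf * vapply(1:8, function(j) {
    Pa[j] * Pb[j] / prod(n:(n - v[j] + 1))
  }, 0))
  m1 <- mm[["mean"]]
  m2 <- mm[["var"]] + m1^2
  k3 <- m3 - 3 * m1 * m2 + 2 * m1^3
  c(mean = m1 + cM * sum(B), var = mm[["var"]], k3 = k3)
}

## exact permutation mean of z_s' C z_s for symmetric C (diagonal allowed)
perm_mean_qf <- function(C, z) {
  n <- length(z)
  d <- diag(C); Co <- C; diag(Co) <- 0
  B <- tcrossprod(z); diag(B) <- 0
  sum(Co) * sum(B) / (n * (n - 1)) + sum(d) * sum(z^2) / n
}

## exact permutation variance of z_s' C z_s for symmetric C (diagonal
## allowed): off-diagonal Mantel part + diagonal (without-replacement
## pairing of diag(C) with z^2) + their exact covariance
perm_var_qf <- function(C, z) {
  n <- length(z)
  d <- diag(C); Co <- C; diag(Co) <- 0
  B <- tcrossprod(z); diag(B) <- 0
  cM <- sum(Co) / (n * (n - 1)); cB <- sum(B) / (n * (n - 1))
  E <- Co - cM; diag(E) <- 0
  Eb <- B - cB; diag(Eb) <- 0
  var_off <- mantel_moments(E, Eb)[["var"]]
  x <- z^2
  var_diag <- sum((d - mean(d))^2) * sum((x - mean(x))^2) / (n - 1)
  ## covariance between off-diagonal part and diagonal part
  S4 <- sum(z^4); S2z <- sum(z^2)
  rE <- rowSums(E); Sd <- sum(d)
  e_same <- -S4 / (n * (n - 1))                       # E[z_a z_b z_a^2]
  e_dist <- (2 * S4 - S2z^2) / (n * (n - 1) * (n - 2))  # E[z_a z_b z_c^2]
  EQoQd <- 2 * sum(rE * d) * e_same +
    (sum(rE) * Sd - 2 * sum(rE * d)) * e_dist
  EQo <- 0                                             # E sums to zero
  EQd <- Sd * S2z / n
  cov_od <- EQoQd - EQo * EQd
  ## the centered split leaves a deterministic cross term:
  ## Q_off = cM * sum(B) + sum E_ij Eb  (constant + centered part), so
  ## Cov(Q_off, Q_diag) is the covariance of the centered part only.
  var_off + var_diag + 2 * cov_od
}
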