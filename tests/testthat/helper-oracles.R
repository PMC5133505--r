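## Independent oracles used across the suite.  These stay deliberately
## naive (double loops, full enumeration) so they share no code with the
## implementation paths they check.

## U statistic by a literal double loop over ordered pairs
u_brute <- function(f, g, h) {
  n <- nrow(h)
  if (is.null(f)) f <- matrix(1, n, n)
  if (is.null(g)) g <- matrix(1, n, n)
  u <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) u <- u + f[i, j] * g[i, j] * h[i, j]
  }
  u
}

## Benjamini-Hochberg by sort / scale / cumulative minimum
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

## all permutations of 1..n (small n only)
perm_all <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- perm_all(n - 1)
  out <- NULL
  for (i in seq_len(n)) out <- rbind(out, cbind(i, p + (p >= i)))
  out
}

## quick null gene: dosages + expression + phenotype with no association
sim_null_gene <- function(n, K, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  maf <- ifelse(runif(K) < 0.8, runif(K, 0.001, 0.01), runif(K, 0.01, 0.5))
  repeat {
    dos <- matrix(rbinom(n * K, 2, rep(maf, each = n)), n, K, byrow = TRUE)
    p_hat <- colMeans(dos) / 2
    keep <- p_hat > 0 & p_hat < 1
    if (any(keep)) break
  }
  dos <- dos[, keep, drop = FALSE]
  rownames(dos) <- sprintf("S%03d", seq_len(n))
  colnames(dos) <- paste0("v", seq_len(ncol(dos)))
  list(
    dosages = dos,
    expression = setNames(rnorm(n), rownames(dos)),
    phenotype = setNames(rnorm(n), rownames(dos))
  )
}

## combined zero-diagonal similarity weight for a null gene, given mode
gene_weight_matrix <- function(gene, mode, config = kernel_config()) {
  n <- length(gene$phenotype)
  f <- if (mode %in% c("GT", "G")) {
    gaussian_similarity(burden_scores(gene$dosages)$burden, config)
  }
  g <- if (mode %in% c("GT", "T")) {
    gaussian_similarity(as.numeric(gene$expression), config, standardize = TRUE)
  }
  m <- if (is.null(f) && is.null(g)) matrix(1, n, n)
  else if (is.null(f)) g else if (is.null(g)) f else f * g
  diag(m) <- 0
  m
}
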