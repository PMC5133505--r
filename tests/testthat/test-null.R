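test_that("mixture weights reproduce the hand eigen-decomposition", {
  ## n = 3, f = g = 1: M = J - I, PMP = -P with eigenvalues (0, -1, -1)
  mix <- mixture_weights(n = 3, norm_adjust = FALSE)
  expect_equal(sort(mix$lambdas), c(-1, -1, 0), tolerance = 1e-12)
  expect_equal(mix$trace, -2, tolerance = 1e-12)
  ## trace identity on a random kernel
  set.seed(3)
  f <- gaussian_similarity(runif(9))
  mix2 <- mixture_weights(f = f, norm_adjust = FALSE)
  M <- f; diag(M) <- 0
  P <- diag(9) - 1 / 9
  A <- P %*% M %*% P
  expect_equal(sum(mix2$lambdas), sum(diag(A)), tolerance = 1e-8)
  ## independent dense eigensolver oracle on a random symmetric 6x6
  S <- matrix(rnorm(36), 6); S <- (S + t(S)) / 2; diag(S) <- 1
  S <- (S - min(S)) / (max(S) - min(S)) * 0.5 + 0.5; S <- (S + t(S)) / 2
  diag(S) <- 1
  mix3 <- mixture_weights(f = S, norm_adjust = FALSE)
  M3 <- S; diag(M3) <- 0
  P6 <- diag(6) - 1 / 6
  oracle <- eigen(P6 %*% M3 %*% P6)$values   # general (non-symmetric) path
  expect_equal(sort(mix3$lambdas), sort(Re(oracle)), tolerance = 1e-8)
})

test_that("norm adjustment drops the fixed-norm direction", {
  mix <- mixture_weights(n = 3, norm_adjust = TRUE)
  ## -P shifted by trace/(n-1) = -1: both support eigenvalues land on 0
  expect_equal(mix$lambdas, c(0, 0), tolerance = 1e-12)
  set.seed(4)
  f <- gaussian_similarity(runif(12))
  mix2 <- mixture_weights(f = f)
  expect_equal(sum(mix2$lambdas), 0, tolerance = 1e-10)
  expect_length(mix2$lambdas, 11)
})

test_that("a zero weight matrix is a degenerate test", {
  expect_error(davies_pvalue(numeric(0), 1),
               class = "wujoint_degenerate_test")
  expect_error(davies_pvalue(c(0, 0), 1), class = "wujoint_degenerate_test")
})

test_that("davies tail matches the chi-square family", {
  for (k in c(1, 2, 5, 10)) {
    for (q in qchisq(c(0.5, 0.95, 0.99, 0.9999), df = k)) {
      pv <- davies_pvalue(rep(1, k), q - k)
      expect_lt(abs(pv$p - pchisq(q, df = k, lower.tail = FALSE)), 1e-6)
      expect_equal(pv$method, "davies")
    }
  }
  ## documented anchors
  expect_lt(abs(davies_pvalue(1, qchisq(0.95, 1) - 1)$p - 0.05), 1e-6)
  expect_lt(abs(davies_pvalue(c(1, 1), qchisq(0.95, 2) - 2)$p - 0.05), 1e-6)
})

test_that("the left tail saturates at 1 and the floor holds", {
  ## q far below the support of sum lambda (chi2 - 1)
  expect_equal(davies_pvalue(c(0.5, 0.3, 0.2), -1.5)$p, 1)
  expect_gte(davies_pvalue(1, 500)$p, 1e-14)   # clamped, never exactly 0
})

test_that("davies handles mixed-sign mixtures against Monte Carlo", {
  lam <- c(0.5, 0.3, 0.2)
  set.seed(5)
  draws <- colSums(lam * (matrix(rchisq(3 * 2e5, 1), 3) - 1))
  for (q in c(-0.5, 0, 1, 3)) {
    expect_lt(abs(davies_pvalue(lam, q)$p - mean(draws >= q)), 6e-3)
  }
  lam2 <- c(1.5, -1, 0.4, -0.3)
  draws2 <- colSums(lam2 * (matrix(rchisq(4 * 2e5, 1), 4) - 1))
  for (q in c(-2, 0, 2)) {
    expect_lt(abs(davies_pvalue(lam2, q)$p - mean(draws2 >= q)), 6e-3)
  }
})

test_that("the moment fallback is a sane shifted-gamma tail", {
  lam <- c(0.6, 0.3, 0.1)
  k2 <- 2 * sum(lam^2); k3 <- 8 * sum(lam^3)
  for (q in c(-0.5, 0.5, 2)) {
    p_d <- davies_pvalue(lam, q)$p
    p_m <- wujoint:::moment_tail(q, 0, k2, k3)
    expect_lt(abs(p_m - p_d), 0.02)
  }
})

test_that("pattern sums agree with brute-force enumeration", {
  set.seed(6)
  n <- 7
  x <- matrix(rnorm(n * n), n); x <- x + t(x); diag(x) <- 0
  P <- wujoint:::pattern_sums(x)
  brute <- numeric(8)
  idx <- seq_len(n)
  for (i in idx) for (j in idx) if (i != j) {
    brute[1] <- brute[1] + x[i, j]^3
    for (k in idx) if (!(k %in% c(i, j))) {
      brute[2] <- brute[2] + x[i, j]^2 * x[i, k]
      brute[4] <- brute[4] + x[i, j] * x[j, k] * x[k, i]
      for (l in idx) if (!(l %in% c(i, j, k))) {
        brute[3] <- brute[3] + x[i, j]^2 * x[k, l]
        brute[5] <- brute[5] + x[i, j] * x[i, k] * x[i, l]
        brute[6] <- brute[6] + x[i, j] * x[j, k] * x[k, l]
        for (m in idx) if (!(m %in% c(i, j, k, l))) {
          brute[7] <- brute[7] + x[i, j] * x[j, k] * x[l, m]
          for (o in idx) if (!(o %in% c(i, j, k, l, m))) {
            brute[8] <- brute[8] + x[i, j] * x[k, l] * x[m, o]
          }
        }
      }
    }
  }
  expect_equal(P, brute, tolerance = 1e-10)
})

test_that("exact permutation cumulants match full enumeration", {
  set.seed(8)
  n <- 7
  M <- matrix(runif(n * n), n); M <- (M + t(M)) / 2; diag(M) <- 0
  y <- rnorm(n)
  z <- (rank(y) - mean(rank(y))) / sd(rank(y))
  km <- perm_cumulants(M, z)
  perms <- perm_all(n)
  u <- apply(perms, 1, function(s) {
    zz <- z[s]
    drop(zz %*% M %*% zz)
  })
  expect_equal(km[["mean"]], mean(u), tolerance = 1e-10)
  expect_equal(km[["var"]], mean(u^2) - mean(u)^2, tolerance = 1e-10)
  expect_equal(km[["k3"]], mean((u - mean(u))^3), tolerance = 1e-9)
})

test_that("quadratic-form permutation variance handles diagonals exactly", {
  set.seed(10)
  n <- 6
  C <- matrix(rnorm(n * n), n); C <- C + t(C)   # diagonal retained
  z <- rnorm(n); z <- z - mean(z)
  perms <- perm_all(n)
  q <- apply(perms, 1, function(s) {
    zz <- z[s]
    drop(zz %*% C %*% zz)
  })
  expect_equal(wujoint:::perm_mean_qf(C, z), mean(q), tolerance = 1e-10)
  expect_equal(wujoint:::perm_var_qf(C, z), mean(q^2) - mean(q)^2,
               tolerance = 1e-9)
})

test_that("the gamma-mixture inversion matches Monte Carlo with a gaussian", {
  set.seed(12)
  g <- c(0.7, -0.2); k <- c(0.9, 1.7); sig2 <- 0.04
  draws <- g[1] * (rgamma(2e5, k[1]) - k[1]) +
    g[2] * (rgamma(2e5, k[2]) - k[2]) + rnorm(2e5, sd = sqrt(sig2))
  for (q in c(-1, 0, 1, 2.5)) {
    r <- wujoint:::qform_tail(g, k, q, sig2)
    expect_false(r$fault)
    expect_lt(abs(r$p - mean(draws >= q)), 6e-3)
  }
})

test_that("permutation p-values are deterministic and bounded", {
  set.seed(13)
  gene <- sim_null_gene(30, 20)
  rp <- rank_phenotype(gene$phenotype)
  f <- gaussian_similarity(burden_scores(gene$dosages)$burden)
  p1 <- permutation_pvalue(-20, f = f, ranks = rp, n_perm = 300, seed = 5)
  p2 <- permutation_pvalue(-20, f = f, ranks = rp, n_perm = 300, seed = 5)
  expect_identical(p1$p, p2$p)
  expect_equal(permutation_pvalue(-1e9, f = f, ranks = rp, n_perm = 200,
                                  seed = 1)$p, 1)
  expect_equal(permutation_pvalue(1e9, f = f, ranks = rp, n_perm = 200,
                                  seed = 1)$p, 1 / 201)
  expect_error(permutation_pvalue(0, f = f, ranks = rp, n_perm = 10))
})

test_that("the per-gene null model is calibrated conditional on a gene", {
  ## permuted phenotypes through the full p-value path: rejection rates
  ## near nominal and no gross non-uniformity
  set.seed(14)
  n <- 60
  gene <- sim_null_gene(n, 60)
  M <- gene_weight_matrix(gene, "GT")
  rp <- rank_phenotype(gene$phenotype)
  z <- (rp$ranks - rp$mean) / sqrt(rp$variance)
  nm <- null_model(M, z)
  ps <- replicate(400, {
    zz <- sample(z)
    wujoint:::null_tail(nm, drop(zz %*% M %*% zz))$p
  })
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 1e-3)
})
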