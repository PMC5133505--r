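test_that("residualization reduces to plain ranking without covariates", {
  d <- tibble::tibble(phenotype = c(3.1, 9.9, 5.0))
  rr <- residualize_and_rank(d)
  expect_equal(rr$ranks, c(1, 3, 2))
})

test_that("a perfectly explained phenotype degenerates via tie-averaging", {
  d <- tibble::tibble(phenotype = 2 * (1:6) + 1, x = 1:6)
  expect_warning(residualize_and_rank(d, covariates = "x"),
                 class = "wujoint_degenerate_phenotype")
})

test_that("residual ranks are uncorrelated with the covariate", {
  set.seed(21)
  n <- 200
  for (rep in 1:5) {
    x <- rnorm(n)
    d <- tibble::tibble(phenotype = 1.5 * x + rnorm(n), x = x)
    rr <- residualize_and_rank(d, covariates = "x")
    expect_lt(abs(cor(rr$ranks, rank(x), method = "spearman")), 3 / sqrt(n))
  }
})

test_that("collinear covariates are rejected", {
  d <- tibble::tibble(phenotype = rnorm(8), a = 1:8, b = 2 * (1:8))
  expect_error(residualize_and_rank(d, covariates = c("a", "b")),
               class = "wujoint_collinear")
})

test_that("genotype PCA separates simulated subpopulations", {
  set.seed(22)
  n <- 80; K <- 300
  pop <- rep(0:1, each = n / 2)
  p1 <- runif(K, 0.1, 0.5)
  p2 <- pmin(0.9, pmax(0.01, p1 + runif(K, -0.3, 0.3)))
  dos <- t(vapply(pop, function(g) {
    rbinom(K, 2, if (g == 0) p1 else p2)
  }, numeric(K)))
  pcs <- genotype_pca(dos, k = 4)
  expect_gt(abs(cor(pcs[, 1], pop)), 0.9)
  ## orthogonality of score columns
  gram <- crossprod(pcs)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8 * max(diag(gram)))
  ## deterministic (sign-canonicalized)
  expect_identical(pcs, genotype_pca(dos, k = 4))
  ## k = 0 gives an empty matrix
  expect_equal(dim(genotype_pca(dos, k = 0)), c(n, 0))
  expect_error(genotype_pca(dos, k = n), "smaller")
})

test_that("BH adjustment matches hand values and the brute-force oracle", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.37), 0.37)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  set.seed(23)
  for (m in c(1, 7, 100, 1000)) {
    p <- runif(m)^2
    q <- fdr_adjust(p)
    expect_equal(q, bh_brute(p), tolerance = 1e-12)
    expect_true(all(q >= p))
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), class = "wujoint_bad_input")
})

test_that("G mode is bitwise identical to GT with constant expression", {
  set.seed(24)
  gene <- sim_null_gene(40, 30)
  const_expr <- setNames(rep(2.5, 40), names(gene$phenotype))
  g1 <- wu_test(gene$dosages, ranks = gene$phenotype, mode = "G")
  g2 <- wu_test(gene$dosages, const_expr, gene$phenotype, mode = "GT")
  expect_identical(g1$u, g2$u)
  expect_identical(g1$p, g2$p)
})

test_that("T mode ignores genotypes entirely", {
  set.seed(25)
  gene <- sim_null_gene(40, 30)
  t1 <- wu_test(gene$dosages, gene$expression, gene$phenotype, mode = "T")
  perturbed <- gene$dosages
  perturbed[1, ] <- 2 - perturbed[1, ]
  t2 <- wu_test(perturbed, gene$expression, gene$phenotype, mode = "T")
  expect_identical(t1$u, t2$u)
  expect_identical(t1$p, t2$p)
})

test_that("misaligned samples are a hard error, never reordered", {
  set.seed(26)
  gene <- sim_null_gene(20, 15)
  rownames(gene$dosages)[1] <- "INTRUDER"
  expect_error(
    wu_test(gene$dosages, gene$expression, gene$phenotype, mode = "G",
            sample_ids = names(gene$phenotype)),
    class = "wujoint_misaligned"
  )
})

test_that("tidy and glance summarize a test", {
  set.seed(27)
  gene <- sim_null_gene(30, 20)
  tst <- wu_test(gene$dosages, gene$expression, gene$phenotype, mode = "GT")
  td <- tidy(tst)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$mode, "GT")
  expect_true(td$p >= 0 && td$p <= 1)
  expect_equal(glance(tst)$n, 30)
})

test_that("the screen returns complete, FDR-adjusted, deterministic records", {
  cfg <- sim_config(n = 40, n_genes = 6, n_causal = 0, snv_range = c(15, 30),
                    seed = 28)
  sim <- simulate_study(cfg)
  run <- function(sim_obj, regions = sim_obj$regions) {
    wu_screen(regions, sim_obj$genotypes, sim_obj$expression,
              sim_obj$phenotypes, phenotype_cols = "qt",
              covariates = c("age", "sex"))
  }
  scr <- run(sim)
  expect_equal(nrow(scr), 6)
  expect_true(all(!is.na(scr$p_gt)))
  expect_true(all(scr$q_gt >= scr$p_gt - 1e-12))
  expect_true(all(scr$p_gt >= 0 & scr$p_gt <= 1))
  expect_equal(scr$n_snv,
               vapply(scr$gene_id, function(g) ncol(sim$genotypes[[g]]), 0L),
               ignore_attr = TRUE)
  ## re-run: byte-identical
  expect_identical(as.data.frame(run(sim)), as.data.frame(scr))
  ## region order invariance
  scr2 <- run(sim, regions = sim$regions[rev(seq_len(6)), ])
  expect_identical(as.data.frame(scr2), as.data.frame(scr))
})

test_that("the screen is invariant to sample ordering via id alignment", {
  cfg <- sim_config(n = 30, n_genes = 3, n_causal = 1, snv_range = c(15, 25),
                    seed = 29)
  sim <- simulate_study(cfg)
  scr1 <- wu_screen(sim$regions, sim$genotypes, sim$expression,
                    sim$phenotypes, phenotype_cols = "qt",
                    covariates = c("age", "sex"))
  o <- sample(nrow(sim$phenotypes))
  shuffled <- sim$phenotypes[o, ]
  geno_shuffled <- lapply(sim$genotypes, function(m) m[shuffled$sample_id, ])
  expr_shuffled <- sim$expression[, shuffled$sample_id]
  scr2 <- wu_screen(sim$regions, geno_shuffled, expr_shuffled, shuffled,
                    phenotype_cols = "qt", covariates = c("age", "sex"))
  expect_equal(scr1$p_gt, scr2$p_gt, tolerance = 1e-12)
  expect_equal(scr1$p_g, scr2$p_g, tolerance = 1e-12)
})

test_that("degenerate regions are recorded with missing p, not fatal", {
  cfg <- sim_config(n = 30, n_genes = 2, n_causal = 0, snv_range = c(10, 15),
                    seed = 30)
  sim <- simulate_study(cfg)
  ## make one gene monomorphic-in-effect: identical burden for everyone
  sim$genotypes[[1]][] <- 0
  sim$genotypes[[1]][, 1] <- 1   # constant burden across samples
  scr <- suppressMessages(
    wu_screen(sim$regions, sim$genotypes, sim$expression, sim$phenotypes,
              phenotype_cols = "qt", covariates = c("age", "sex"),
              modes = "G")
  )
  expect_equal(nrow(scr), 2)
  expect_true(is.na(scr$p_g[scr$gene_id == "G001"]))
  expect_false(is.na(scr$p_g[scr$gene_id == "G002"]))
})
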