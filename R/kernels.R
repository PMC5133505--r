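#' Kernel configuration for the weighted U test
#'
#' Bundles the tunable choices of the similarity kernels.  The Gaussian
#' similarity between two samples with values \eqn{x_i, x_j} is
#' \eqn{\exp(-(x_i - x_j)^2 / d)} with shared denominator
#' \eqn{d = 2N} by default, where \eqn{N} is the sample count.  Because
#' burden scores live in `[0, 1]`, this default keeps the genotype
#' kernel within a few tenths of a percent of 1; the test is insensitive
#' to that overall scale (statistic and null rescale together), but the
#' denominator is exposed for users who prefer a data-driven bandwidth.
#'
#' @param bandwidth_denominator Positive scalar, or `NULL` (default) to
#'   use `2 * n` at evaluation time.
#' @param standardize_expression Standardize expression to zero mean and
#'   unit variance before the kernel (default `TRUE`; expression units
#'   are arbitrary and the shared denominator is scale sensitive).
#' @param standardize_burden Standardize burden scores before the kernel
#'   (default `FALSE`, matching the printed definition on the raw
#'   `[0, 1]` scale).
#' @return An object of class `wu_kernel_config`.
#' @export
kernel_config <- function(bandwidth_denominator = NULL,
                          standardize_expression = TRUE,
                          standardize_burden = FALSE) {
  if (!is.null(bandwidth_denominator) &&
      (!is.numeric(bandwidth_denominator) || bandwidth_denominator <= 0)) {
    abort("`bandwidth_denominator` must be positive.",
          class = "wujoint_bad_config")
  }
  structure(
    list(
      bandwidth_denominator = bandwidth_denominator,
      standardize_expression = isTRUE(standardize_expression),
      standardize_burden = isTRUE(standardize_burden)
    ),
    class = "wu_kernel_config"
  )
}

#' Gaussian similarity matrix
#'
#' Entry \eqn{(i, j)} is \eqn{\exp(-(x_i - x_j)^2 / d)}: symmetric, unit
#' diagonal, all entries in `(0, 1]`, decreasing in the distance
#' \eqn{|x_i - x_j|}.
#'
#' @param x Numeric vector of per-sample values (burden scores or
#'   expression), all finite.
#' @param config A [kernel_config()]; its `bandwidth_denominator`
#'   (default `2 * length(x)`) sets \eqn{d}.
#' @param standardize Standardize `x` to zero mean / unit variance
#'   first.  Constant vectors are left untouched (the kernel is then the
#'   all-ones matrix either way).
#' @return An `n x n` numeric matrix.
#' @export
gaussian_similarity <- function(x, config = kernel_config(), standardize = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort("`x` must be finite numeric.", class = "wujoint_bad_input")
  }
  n <- length(x)
  d <- config$bandwidth_denominator %||% (2 * n)
  if (standardize && sd(x) > 0) x <- (x - mean(x)) / sd(x)
  exp(-outer(x, x, "-")^2 / d)
}

#' Rank a phenotype for the U kernel
#'
#' Ranks the phenotype with ties averaged and records the empirical mean
#' and sample variance (denominator `n - 1`) of the realized rank
#' vector.  Binary phenotypes are ranked the same way: all cases share
#' one averaged rank and all controls another.  A constant phenotype has
#' zero rank variance and triggers a classed warning, since no kernel
#' can be formed from it.
#'
#' @param y Numeric (or logical/integer) phenotype vector, length >= 2,
#'   no missing values.
#' @return An object of class `wu_ranks`: a list with `ranks`, `mean`,
#'   `variance`, and `n`.
#' @examples
#' rank_phenotype(c(3.1, 9.9, 5.0))
#' @export
rank_phenotype <- function(y) {
  if (anyNA(y)) abort("`y` must not contain missing values.")
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2) abort("need at least two samples to rank.")
  r <- rank(y, ties.method = "average")
  v <- var(r)
  if (v == 0) {
    warn("degenerate phenotype: all values tied, rank variance is zero",
         class = "wujoint_degenerate_phenotype")
  }
  structure(list(ranks = r, mean = mean(r), variance = v, n = n),
            class = "wu_ranks")
}

#' @export
print.wu_ranks <- function(x, ...) {
  cat("<wu_ranks> n =", x$n, " mean =", format(x$mean),
      " variance =", format(x$variance), "\n")
  invisible(x)
}

#' Phenotype similarity kernel
#'
#' The U kernel
#' \eqn{h(y_i, y_j) = (y_i - \bar y)(y_j - \bar y) / \mathrm{Var}(Y)}
#' on the ranks: the outer product of centered ranks divided by their
#' sample variance.  With the `n - 1` variance denominator the
#' off-diagonal entries always sum to exactly `-(n - 1)` (centered ranks
#' sum to zero), which pins down the value of the U statistic under
#' constant similarity weights.
#'
#' @param rp A `wu_ranks` object from [rank_phenotype()] (or a numeric
#'   vector, ranked first).
#' @return An `n x n` matrix.
#' @export
phenotype_kernel <- function(rp) {
  if (!inherits(rp, "wu_ranks")) rp <- rank_phenotype(rp)
  if (rp$variance <= 0) {
    abort("degenerate phenotype: zero rank variance, no kernel defined",
          class = "wujoint_degenerate_phenotype")
  }
  c0 <- rp$ranks - rp$mean
  tcrossprod(c0) / rp$variance
}

## standardized centered ranks: h(y_i, y_j) = z_i z_j exactly
rank_scores <- function(rp) {
  if (rp$variance <= 0) {
    abort("degenerate phenotype: zero rank variance",
          class = "wujoint_degenerate_phenotype")
  }
  (rp$ranks - rp$mean) / sqrt(rp$variance)
}

#' Weighted U statistic
#'
#' \deqn{U = \sum_{i \ne j} f(a_i, a_j)\, g(t_i, t_j)\, h(y_i, y_j),}
#' summed over ordered pairs with the diagonal excluded.  Passing `NULL`
#' for `f` or `g` fixes that similarity to the constant 1, which is how
#' the genotype-only (G) and expression-only (T) modes arise.
#'
#' @param f Genotype similarity matrix, or `NULL` for the unit weight.
#' @param g Expression similarity matrix, or `NULL` for the unit weight.
#' @param h Phenotype kernel matrix from [phenotype_kernel()].
#' @return An object of class `wu_ustat`: list with the statistic `u`,
#'   the `mode` implied by which weights are present (`"GT"`, `"G"`,
#'   `"T"` or `"none"`), and the sample count `n`.
#' @examples
#' h <- phenotype_kernel(rank_phenotype(c(1, 2, 3)))
#' u_statistic(NULL, NULL, h)$u  # equals -(n - 1) = -2
#' @export
u_statistic <- function(f = NULL, g = NULL, h) {
  n <- nrow(h)
  if (!is.matrix(h) || ncol(h) != n) abort("`h` must be a square matrix.")
  for (m in list(f, g)) {
    if (!is.null(m) && (!is.matrix(m) || any(dim(m) != n))) {
      abort("similarity matrices must match the dimension of `h`.",
            class = "wujoint_dim_mismatch")
    }
  }
  fg <- similarity_product(f, g, n)
  u <- sum(fg * h) - sum(diag(fg) * diag(h))
  mode <- if (!is.null(f) && !is.null(g)) "GT"
          else if (!is.null(f)) "G"
          else if (!is.null(g)) "T"
          else "none"
  structure(list(u = u, mode = mode, n = n), class = "wu_ustat")
}

#' @export
print.wu_ustat <- function(x, ...) {
  cat("<wu_ustat> mode =", x$mode, " n =", x$n, " U =", format(x$u), "\n")
  invisible(x)
}

## elementwise product of the similarity weights, unit where NULL
similarity_product <- function(f, g, n) {
  if (is.null(f) && is.null(g)) return(matrix(1, n, n))
  if (is.null(f)) return(g)
  if (is.null(g)) return(f)
  f * g
}

## combined similarity weight with zero diagonal, as used by the null
combined_weight <- function(f, g, n) {
  m <- similarity_product(f, g, n)
  diag(m) <- 0
  m
}
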