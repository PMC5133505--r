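#' Eigenvalue weights of the asymptotic null mixture
#'
#' Under phenotype exchangeability the weighted U statistic is a
#' quadratic form in the standardized centered ranks, and its limiting
#' null distribution is a linear combination of chi-square(1) variables.
#' The weights are the eigenvalues of \eqn{P M P}, where `M` is the
#' elementwise product of the genotype and expression similarity
#' matrices with zeroed diagonal and \eqn{P = I - J/n} is the centering
#' projector (the rank vector always sums to a constant).
#'
#' Rank vectors also have exactly fixed length, not just fixed sum.
#' With `norm_adjust = TRUE` (the default, used by the test pipeline)
#' the component of \eqn{P M P} along that fixed-norm direction -- its
#' trace -- is removed by dropping the null-space eigenvalue and
#' subtracting \eqn{\mathrm{tr}(PMP)/(n-1)} from the rest, so the
#' returned weights sum to zero and the mixture
#' \eqn{\sum_i \lambda_i (\chi^2_1 - 1)} needs no further centering.
#' With `norm_adjust = FALSE` the raw \eqn{P M P} spectrum is returned
#' (summing to the trace), which is only appropriate when the scores are
#' genuinely independent rather than a permuted fixed vector.
#'
#' @param f,g Similarity matrices or `NULL` for the unit weight (at
#'   least one must be non-`NULL` for a non-degenerate mixture).
#' @param n Sample count; required when both `f` and `g` are `NULL`.
#' @param norm_adjust Remove the fixed-norm (trace) component.
#' @return Object of class `wu_mixture`: list with `lambdas` (decreasing
#'   in absolute value), `trace` (of \eqn{PMP}), `n`, `adjusted`, and
#'   `centered = TRUE` (the mixture is of centered chi-squares).
#' @export
mixture_weights <- function(f = NULL, g = NULL, n = NULL, norm_adjust = TRUE) {
  n <- n %||% nrow(f) %||% nrow(g)
  if (is.null(n)) abort("supply `n` when both similarities are NULL.")
  if (n < 3) abort("need n >= 3 for the asymptotic null.")
  for (m in list(f, g)) {
    if (!is.null(m)) {
      if (!is.matrix(m) || any(dim(m) != n)) {
        abort("similarity matrices must be n x n.", class = "wujoint_dim_mismatch")
      }
      if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) {
        abort("similarity matrices must be symmetric.", class = "wujoint_bad_input")
      }
    }
  }
  M <- combined_weight(f, g, n)
  A <- center_project(M)
  lam <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  tr <- sum(diag(A))
  if (norm_adjust) {
    i0 <- which.min(abs(lam))          # exact zero along the 1-vector
    lam <- lam[-i0] - tr / (n - 1)
  }
  lam <- lam[order(abs(lam), decreasing = TRUE)]
  structure(
    list(lambdas = lam, trace = tr, n = n,
         adjusted = isTRUE(norm_adjust), centered = TRUE),
    class = "wu_mixture"
  )
}

#' @export
print.wu_mixture <- function(x, ...) {
  cat("<wu_mixture>", length(x$lambdas), "weights, |lambda|_max =",
      format(max(abs(x$lambdas))), if (x$adjusted) "(norm-adjusted)" else "", "\n")
  invisible(x)
}

## doubly-centered symmetrized P M P
center_project <- function(M) {
  n <- nrow(M)
  Mc <- M - rowMeans(M)
  A <- Mc - rep(colMeans(Mc), each = n)
  (A + t(A)) / 2
}

#' Tail probability of a centered chi-square mixture (Davies method)
#'
#' Computes \eqn{p = \Pr\{\sum_i \lambda_i (\chi^2_{1,i} - 1) \ge q\}}
#' by numerical inversion of the characteristic function, the approach
#' introduced by Davies for linear combinations of chi-squares.  The
#' integrator targets an absolute accuracy of `1e-6`; if it cannot
#' certify that (a "fault"), the result falls back to a shifted-gamma
#' approximation matched to the first three cumulants of the mixture and
#' the fall-back is recorded in `method`.
#'
#' Eigenvalues smaller than `1e-10` times the largest are truncated
#' (numerical rank control; the trace identity is checked upstream
#' before truncation).  The p-value is clamped to `[1e-14, 1]` so that
#' integrator underflow never reports an exact zero.
#'
#' @param mix A `wu_mixture`, or a numeric vector of eigenvalue weights.
#' @param q Observed statistic on the centered scale.
#' @return Object of class `wu_pvalue`: list with `p`, `method`
#'   (`"davies"` or `"moment_fallback"`), and `diagnostics` (integration
#'   error estimate and fault flag).
#' @examples
#' davies_pvalue(1, qchisq(0.95, 1) - 1)$p   # ~0.05
#' @export
davies_pvalue <- function(mix, q) {
  lam <- if (inherits(mix, "wu_mixture")) mix$lambdas else as.numeric(mix)
  if (!length(lam) || all(lam == 0)) {
    abort("degenerate mixture: all eigenvalue weights are zero.",
          class = "wujoint_degenerate_test")
  }
  lam <- lam[abs(lam) >= 1e-10 * max(abs(lam))]
  res <- qform_tail(g = 2 * lam, k = rep(0.5, length(lam)), x = q)
  method <- "davies"
  p <- res$p
  if (is.na(p) || res$fault) {
    method <- "moment_fallback"
    p <- moment_tail(q, k1 = 0, k2 = 2 * sum(lam^2), k3 = 8 * sum(lam^3))
  }
  structure(
    list(p = min(max(p, 1e-14), 1), method = method,
         diagnostics = list(error = res$error, fault = res$fault)),
    class = "wu_pvalue"
  )
}

#' @export
print.wu_pvalue <- function(x, ...) {
  cat("<wu_pvalue> p =", format(x$p), " method =", x$method, "\n")
  invisible(x)
}

#' Per-gene null model for the weighted U statistic
#'
#' Builds the asymptotic approximation to the exact permutation null of
#' \eqn{U = \sum_{i \ne j} M_{ij} z_i z_j} for a fixed combined
#' similarity matrix `M` and standardized centered rank scores `z`.
#'
#' The construction keeps the few dominant eigen-components of the
#' norm-adjusted spectrum (see [mixture_weights()]) as explicit
#' mixture components and treats the many near-zero ones -- whose joint
#' permutation variance is far smaller than independent chi-squares
#' would suggest -- as a Gaussian remainder:
#' \itemize{
#'   \item each retained component is represented by a gamma variable
#'     with unit mean and that component's \emph{exact} permutation
#'     variance, so the hard support edge of \eqn{w_j^2 \ge 0} stays at
#'     its exact location while the fourth-moment deficit of permuted
#'     rank projections is absorbed into the gamma shape;
#'   \item the covariance between each retained component and the
#'     remainder (a linear-in-\eqn{w_j^2} coupling) is folded into an
#'     effective eigenvalue;
#'   \item the Gaussian remainder is sized so the total \emph{exact}
#'     permutation variance of `U` is matched.
#' }
#' All moments come from closed-form permutation moment formulas
#' ([perm_cumulants()] and relatives), so no resampling is involved.
#'
#' @param M Symmetric similarity-product matrix with zero diagonal.
#' @param z Standardized centered rank scores (`rank_scores()` of a
#'   [rank_phenotype()] result).
#' @param tau Relative eigenvalue threshold for the dominant set.
#' @param kmax Maximum number of explicit components.
#' @return Object of class `wu_null`: list with `g`, `k` (gamma
#'   component scales and shapes), `sig2`, `mean`, `var`, `lambdas`
#'   (full adjusted spectrum), `degenerate`.
#' @export
null_model <- function(M, z, tau = 0.1, kmax = 16L) {
  n <- length(z)
  stopifnot(nrow(M) == n, ncol(M) == n)
  mu <- perm_mean_qf(M, z)
  vT <- perm_var_qf(M, z)
  A <- center_project(M)
  lam0 <- eigen(A, symmetric = TRUE)
  tr <- sum(diag(A))
  i0 <- which.min(abs(lam0$values))
  lam <- lam0$values[-i0] - tr / (n - 1)
  V <- lam0$vectors[, -i0, drop = FALSE]
  amax <- max(abs(lam))
  scale0 <- max(abs(lam0$values), abs(tr) / (n - 1), 1e-300)
  if (!is.finite(vT) || vT <= 0 || amax <= 1e-10 * scale0) {
    return(structure(
      list(g = numeric(), k = numeric(), sig2 = 0, mean = mu, var = vT,
           lambdas = lam, degenerate = TRUE),
      class = "wu_null"
    ))
  }
  sel <- which(abs(lam) >= tau * amax)
  if (length(sel) > kmax) sel <- order(abs(lam), decreasing = TRUE)[seq_len(kmax)]
  lt <- lam[sel]
  shift <- tr / (n - 1)
  ## Atil = A - shift * P; z' Atil z = U - shift * (n - 1) on the
  ## centered-score subspace, i.e. the trace-adjusted quadratic form
  Atil <- A + shift / n
  diag(Atil) <- diag(Atil) - shift
  lam_eff <- numeric(length(sel))
  v2 <- numeric(length(sel))
  for (j in seq_along(sel)) {
    u <- V[, sel[j]]
    uu <- tcrossprod(u)
    v2[j] <- max(perm_var_qf(uu, z), 1e-3)
    vrem_j <- perm_var_qf(Atil - lt[j] * uu, z)
    cov_j <- (vT - lt[j]^2 * v2[j] - vrem_j) / 2
    lam_eff[j] <- lt[j] + cov_j / (lt[j] * v2[j])
  }
  topvar <- sum(lam_eff^2 * v2)
  sig2 <- vT - topvar
  if (sig2 < 0) {
    lam_eff <- lam_eff * sqrt(vT / topvar)
    sig2 <- 0
  }
  structure(
    list(g = lam_eff * v2, k = 1 / v2, sig2 = sig2, mean = mu, var = vT,
         lambdas = lam, degenerate = FALSE),
    class = "wu_null"
  )
}

#' @export
print.wu_null <- function(x, ...) {
  if (x$degenerate) cat("<wu_null> degenerate (no usable spectrum)\n")
  else cat("<wu_null>", length(x$g), "explicit components, sd =",
           format(sqrt(x$var)), "\n")
  invisible(x)
}

## p-value of an observed raw U under a wu_null model
null_tail <- function(nm, u_obs) {
  if (nm$degenerate) {
    abort("degenerate test: similarity weights carry no usable signal",
          class = "wujoint_degenerate_test")
  }
  res <- qform_tail(nm$g, nm$k, u_obs - nm$mean, nm$sig2)
  method <- "davies"
  p <- res$p
  if (is.na(p) || res$fault) {
    method <- "moment_fallback"
    mc <- model_cumulants(nm$g, nm$k, nm$sig2)
    p <- moment_tail(u_obs - nm$mean, 0, mc[["k2"]], mc[["k3"]])
  }
  structure(
    list(p = min(max(p, 1e-14), 1), method = method,
         diagnostics = list(error = res$error, fault = res$fault)),
    class = "wu_pvalue"
  )
}

#' Permutation p-value for the weighted U statistic
#'
#' Validation oracle for the asymptotic approximation: permutes the rank
#' scores, recomputes the statistic, and reports the add-one estimate
#' \eqn{p = (1 + \#\{U^{(b)} \ge U_{obs}\}) / (B + 1)}.
#'
#' @param u_obs Observed statistic (raw scale, as from [u_statistic()]).
#' @param f,g Similarity matrices or `NULL` for unit weights.
#' @param ranks A `wu_ranks` object.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed; same seed, same p.
#' @return A `wu_pvalue` with `method = "permutation"`.
#' @export
permutation_pvalue <- function(u_obs, f = NULL, g = NULL, ranks,
                               n_perm = 1000L, seed = 1L) {
  if (n_perm < 100) abort("`n_perm` must be at least 100.")
  if (!inherits(ranks, "wu_ranks")) ranks <- rank_phenotype(ranks)
  z <- rank_scores(ranks)
  n <- length(z)
  M <- combined_weight(f, g, n)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  Z <- matrix(z[replicate(n_perm, sample.int(n))], n)
  up <- colSums(Z * (M %*% Z))
  p <- (1 + sum(up >= u_obs)) / (n_perm + 1)
  structure(
    list(p = p, method = "permutation",
         diagnostics = list(n_perm = n_perm, seed = seed)),
    class = "wu_pvalue"
  )
}

## save/restore the RNG state so oracle calls do not disturb the caller
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible()
}
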