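## Tail probabilities of centered gamma mixtures plus a Gaussian component,
## by numerical inversion of the characteristic function (Gil-Pelaez /
## Imhof form, the approach of Davies).  This is the p-value engine behind
## davies_pvalue() and the per-gene null approximation.
##
## The target is
##   Q = sum_j g_j (Gamma(k_j, 1) - k_j) + N(0, sig2),    P(Q >= x).
## A chi-square mixture sum lambda_j (chisq_1 - 1) is the special case
## k_j = 1/2, g_j = 2 lambda_j.
##
## P(Q >= x) = 1/2 + (1/pi) Int_0^Inf Im[phi(u) e^{-iux}] / u du with
##   |phi|(u)  = prod (1 + g^2 u^2)^{-k/2} exp(-sig2 u^2 / 2)
##   phase(u)  = sum k atan(g u) - u sum g k - u x.
## The integral is truncated at the first U where either an envelope bound
## (integrand modulus decays polynomially of order sum k + ...) or an
## integration-by-parts bound on the oscillatory tail is below tolerance;
## in the latter case the leading by-parts term is added as a correction.

qform_tail <- function(g, k, x, sig2 = 0, tol = 1e-8, u_cap = 2e5) {
  stopifnot(length(g) == length(k), all(k > 0), sig2 >= 0)
  keep <- abs(g) > 0
  g <- g[keep]; k <- k[keep]
  if (!length(g)) {
    if (sig2 <= 0) return(list(p = NA_real_, error = Inf, fault = TRUE))
    return(list(p = pnorm(x, sd = sqrt(sig2), lower.tail = FALSE),
                error = 0, fault = FALSE))
  }
  s <- max(abs(g))
  g <- g / s; x <- x / s; sg2 <- sig2 / s^2
  m <- sum(k)
  lw <- function(u) -0.5 * colSums(k * log1p((g * g) %o% (u * u))) -
    sg2 * u * u / 2 - log(u)
  w <- function(u) exp(lw(u))
  th <- function(u) colSums(k * atan(g %o% u)) - sum(g * k) * u - x * u
  thp <- function(u) colSums((k * g) / (1 + (g * g) %o% (u * u))) -
    sum(g * k) - x
  f <- function(u) {
    out <- sin(th(u)) * w(u)
    out[u == 0] <- -x
    out
  }
  env_bound <- function(U) {
    h <- 1e-3 * U
    sl <- -(lw(U + h) - lw(U - h)) / (log(U + h) - log(U - h))
    if (!is.finite(sl) || sl <= 1.01) return(Inf)
    w(U) * U / (sl - 1) / pi
  }
  parts_bound <- function(U) {
    tp <- thp(U)
    if (!is.finite(tp) || abs(tp) * U < 3) return(Inf)
    abs(w(U) / tp) * (2 + m) / (abs(tp) * U) / pi
  }
  U <- 5; trunc_mode <- "env"
  repeat {
    if (env_bound(U) < tol / 3) { trunc_mode <- "env"; break }
    if (parts_bound(U) < tol / 3) { trunc_mode <- "parts"; break }
    if (U >= u_cap) { trunc_mode <- "parts"; break }
    U <- U * 1.4
  }
  tail_corr <- 0
  tail_err <- env_bound(U)
  if (trunc_mode == "parts") {
    tail_corr <- cos(th(U)) * w(U) / thp(U) / pi
    tail_err <- parts_bound(U)
  }
  I <- tryCatch(
    integrate(f, 0, U, rel.tol = 1e-11, abs.tol = tol / 3,
              subdivisions = 100000L),
    error = function(e) NULL
  )
  if (is.null(I)) return(list(p = NA_real_, error = Inf, fault = TRUE))
  err <- I$abs.error + tail_err
  p <- 0.5 + I$value / pi + tail_corr
  list(p = min(max(p, 0), 1), error = err, fault = !is.finite(err) || err > 1e-6)
}

## Shifted-gamma (Pearson type III) tail matched to the first three
## cumulants; the fallback when the integrator reports a fault.
## k1 is the mean of the distribution of Q; x on the same scale.
moment_tail <- function(x, k1, k2, k3) {
  if (k2 <= 0) return(NA_real_)
  if (abs(k3) < 1e-12 * k2^1.5) {
    return(pnorm(x, mean = k1, sd = sqrt(k2), lower.tail = FALSE))
  }
  sg <- sign(k3)
  q <- sg * (x - k1)
  a <- abs(k3) / (4 * k2)      # scale
  d <- 8 * k2^3 / k3^2         # shape (gamma with shape d/2 scaled by 2a)
  b <- -a * d                  # shift so the mean is zero
  pchisq((q - b) / a, df = d, lower.tail = sg < 0)
}

## cumulants (2nd, 3rd) of the centered gamma-mixture + gaussian model
model_cumulants <- function(g, k, sig2) {
  c(k2 = sum(g^2 * k) + sig2, k3 = 2 * sum(g^3 * k))
}
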