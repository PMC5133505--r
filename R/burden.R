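#' Minor allele frequencies for a dosage matrix
#'
#' Computes the per-SNV alternate-allele frequency among non-missing
#' genotypes and recodes to the minor allele where needed, so that every
#' returned frequency lies in `[0, 0.5]`.  Dosages are minor-allele counts
#' in `{0, 1, 2}`; `NA` marks a missing genotype call.
#'
#' @param dosages Integer matrix, samples in rows and SNVs in columns,
#'   entries in `{0, 1, 2}` or `NA`.  Column names identify SNVs.
#' @return A tibble with one row per SNV: `snv_id`, `maf` (frequency of
#'   the minor allele, 0 for monomorphic sites), `flipped` (`TRUE` when
#'   the alternate allele was the major allele and dosages must be
#'   recoded as `2 - dosage`), and `n_called`.
#' @examples
#' g <- cbind(a = c(0L, 1L, 1L, 0L), b = c(2L, 2L, 2L, 1L))
#' compute_maf(g)
#' @export
compute_maf <- function(dosages) {
  dosages <- as_dosage_matrix(dosages)
  n_called <- colSums(!is.na(dosages))
  if (any(n_called == 0)) {
    abort(
      paste0(
        "uncallable SNV: no non-missing genotypes in column(s) ",
        paste(which(n_called == 0), collapse = ", ")
      ),
      class = "wujoint_uncallable_snv"
    )
  }
  alt <- unname(colSums(dosages, na.rm = TRUE) / (2 * n_called))
  flipped <- alt > 0.5
  tibble(
    snv_id = colnames(dosages) %||% paste0("snv", seq_len(ncol(dosages))),
    maf = ifelse(flipped, 1 - alt, alt),
    flipped = flipped,
    n_called = as.integer(unname(n_called))
  )
}

#' Rare-variant weight from a minor allele frequency
#'
#' The weight \eqn{w = 1/\sqrt{p(1-p)}} grows as the minor allele
#' frequency `p` shrinks, so rare variants dominate the burden score.
#' Strictly decreasing on `(0, 0.5]`; `p = 0.5` gives the minimum
#' weight 2.
#'
#' @param maf Numeric vector of minor allele frequencies in `(0, 0.5]`.
#' @return Numeric vector of positive weights.
#' @export
snv_weight <- function(maf) {
  if (any(!is.finite(maf)) || any(maf <= 0) || any(maf > 0.5)) {
    abort("`maf` must lie in (0, 0.5]; drop monomorphic SNVs first.",
          class = "wujoint_bad_maf")
  }
  1 / sqrt(maf * (1 - maf))
}

#' Weighted-sum burden scores for one gene region
#'
#' For sample \eqn{j} with minor-allele dosages \eqn{v_{jk}} over the
#' region's \eqn{K} SNVs, the burden score is
#' \deqn{a_j = \frac{\sum_k w_k v_{jk}}{2 \sum_k w_k},}
#' with \eqn{w_k = 1/\sqrt{p_k(1-p_k)}}.  Scores always lie in
#' `[0, 1]`: 0 means no minor allele at any SNV, 1 means homozygous for
#' the minor allele everywhere.
#'
#' Dosages are recoded to minor-allele counts using `freqs` (columns
#' flagged `flipped` become `2 - dosage`).  Missing dosages are imputed
#' to the SNV mean `2 * maf` by default, which keeps every sample
#' scored; `impute = "complete"` drops samples with any missing call
#' instead.
#'
#' @param dosages Samples x SNVs dosage matrix (`{0,1,2}` or `NA`).
#' @param freqs Optional tibble from [compute_maf()]; computed from
#'   `dosages` when omitted.  Must have one row per SNV column.
#' @param impute `"mean"` (default) or `"complete"`.
#' @return A tibble with columns `sample_id` and `burden`, carrying the
#'   per-SNV weights as the `"weights"` attribute (tibble with `snv_id`,
#'   `maf`, `weight`).
#' @examples
#' g <- rbind(c(1L, 0L), c(0L, 2L), c(0L, 0L))  # 3 samples x 2 SNVs
#' colnames(g) <- c("v1", "v2")
#' burden_scores(g)
#' @export
burden_scores <- function(dosages, freqs = NULL, impute = c("mean", "complete")) {
  impute <- match.arg(impute)
  dosages <- as_dosage_matrix(dosages)
  if (is.null(freqs)) freqs <- compute_maf(dosages)
  if (nrow(freqs) != ncol(dosages)) {
    abort("`freqs` must have one row per SNV column of `dosages`.",
          class = "wujoint_dim_mismatch")
  }
  if (any(freqs$maf <= 0)) {
    abort("monomorphic SNVs (MAF = 0) must be removed before scoring.",
          class = "wujoint_bad_maf")
  }
  flip <- which(freqs$flipped)
  if (length(flip)) dosages[, flip] <- 2L - dosages[, flip]
  if (impute == "mean") {
    if (anyNA(dosages)) {
      means <- rep(2 * freqs$maf, each = nrow(dosages))
      idx <- which(is.na(dosages))
      dosages[idx] <- means[idx]
    }
  } else {
    keep <- complete.cases(dosages)
    dosages <- dosages[keep, , drop = FALSE]
  }
  w <- snv_weight(freqs$maf)
  a <- as.vector(dosages %*% w) / (2 * sum(w))
  out <- tibble(
    sample_id = rownames(dosages) %||% paste0("S", seq_len(nrow(dosages))),
    burden = a
  )
  attr(out, "weights") <- tibble(snv_id = freqs$snv_id, maf = freqs$maf, weight = w)
  out
}

## coerce and validate a dosage matrix
as_dosage_matrix <- function(dosages) {
  if (is.data.frame(dosages)) dosages <- as.matrix(dosages)
  if (!is.matrix(dosages)) abort("`dosages` must be a matrix (samples x SNVs).")
  storage.mode(dosages) <- "double"
  bad <- !is.na(dosages) & !(dosages %in% c(0, 1, 2))
  if (any(bad)) {
    abort("dosages must be 0, 1, 2 or NA", class = "wujoint_bad_dosage")
  }
  dosages
}
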