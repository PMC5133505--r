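#' Residualize a phenotype on covariates and rank the residuals
#'
#' Fits an ordinary least-squares regression of the phenotype on an
#' intercept plus covariates and (optionally) genotype principal
#' components, then rank-transforms the residuals with ties averaged.
#' Binary phenotypes are handled identically (a linear probability
#' residual), keeping the downstream rank kernel the same for
#' quantitative and case/control traits.  With no covariates this
#' reduces exactly to [rank_phenotype()] of the raw phenotype.
#'
#' @param data A data frame with one row per sample.
#' @param phenotype Column name of the phenotype.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @param pcs Optional matrix of principal-component scores (rows
#'   aligned with `data`), or character vector of PC column names in
#'   `data`.
#' @return A `wu_ranks` object for the residuals.
#' @export
residualize_and_rank <- function(data, phenotype = "phenotype",
                                 covariates = character(), pcs = NULL) {
  y <- data[[phenotype]]
  if (is.null(y)) abort(paste0("no column `", phenotype, "` in `data`."))
  if (anyNA(y)) abort("phenotype contains missing values; filter first.")
  y <- as.numeric(y)
  X <- matrix(1, nrow = length(y), ncol = 1)
  if (length(covariates)) {
    miss <- setdiff(covariates, names(data))
    if (length(miss)) abort(paste0("missing covariate column(s): ",
                                   paste(miss, collapse = ", ")))
    X <- cbind(X, as.matrix(as.data.frame(lapply(data[covariates], as.numeric))))
  }
  if (!is.null(pcs)) {
    if (is.character(pcs)) pcs <- as.matrix(as.data.frame(data[pcs]))
    if (nrow(pcs) != length(y)) abort("`pcs` rows must match samples.")
    if (ncol(pcs)) X <- cbind(X, pcs)
  }
  if (ncol(X) > 1) {
    sd_y <- sd(y)
    qrx <- qr(X)
    if (qrx$rank < ncol(X)) {
      abort("collinear covariates: design matrix is rank deficient",
            class = "wujoint_collinear")
    }
    y <- y - X %*% qr.coef(qrx, y)
    ## numerically-tied residuals (a perfectly explained phenotype)
    ## collapse to exact ties instead of rank-ordering round-off dust
    y[abs(y) < 1e-8 * max(sd_y, .Machine$double.eps)] <- 0
  }
  rank_phenotype(as.numeric(y))
}

#' Principal components of a genome-wide genotype matrix
#'
#' Sample-level PC scores for population-stratification adjustment.
#' Columns are standardized to mean zero and scaled by
#' \eqn{\sqrt{\hat p (1 - \hat p)}} with \eqn{\hat p} the sample allele
#' frequency, then the top right singular directions of the sample-space
#' are extracted.  Signs are canonicalized (largest-magnitude loading
#' positive) so results are deterministic.
#'
#' @param dosages Samples x SNVs dosage matrix pooled across the screen
#'   (monomorphic columns are dropped).
#' @param k Number of components, `0 <= k < n`.
#' @return An `n x k` matrix of PC scores (orthogonal columns), with
#'   singular values as attribute `"d"`.  `k = 0` gives a zero-column
#'   matrix, equivalent downstream to no PC adjustment.
#' @export
genotype_pca <- function(dosages, k = 20L) {
  dosages <- as_dosage_matrix(dosages)
  n <- nrow(dosages)
  if (n <= 2) abort("need more than 2 samples for PCA.")
  if (k >= n) abort("`k` must be smaller than the sample count.")
  if (k == 0) return(matrix(numeric(0), nrow = n, ncol = 0))
  if (anyNA(dosages)) {
    mu <- colMeans(dosages, na.rm = TRUE)
    idx <- which(is.na(dosages))
    dosages[idx] <- rep(mu, each = n)[idx]
  }
  p <- colMeans(dosages) / 2
  keep <- p > 0 & p < 1
  dosages <- dosages[, keep, drop = FALSE]
  p <- p[keep]
  if (!ncol(dosages)) abort("no polymorphic SNVs for PCA.")
  Xs <- sweep(dosages, 2, 2 * p, "-")
  Xs <- sweep(Xs, 2, sqrt(p * (1 - p)), "/")
  sv <- svd(Xs, nu = k, nv = 0)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(dosages)
  attr(scores, "d") <- sv$d[seq_len(k)]
  scores
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; a thin, range-checked
#' wrapper around [stats::p.adjust()] so the screen's q-values have a
#' single documented entry point.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return Adjusted q-values, `q >= p` elementwise.
#' @export
fdr_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    abort("p-values must be in [0, 1].", class = "wujoint_bad_input")
  }
  p.adjust(p, method = "BH")
}

#' Weighted U test for one gene region
#'
#' Runs the similarity-based weighted U test in one of three modes:
#' `"GT"` (joint genotype + expression), `"G"` (genotype only; the
#' expression similarity is fixed at 1), or `"T"` (expression only).
#' The p-value comes from the calibrated mixture approximation to the
#' permutation null ([null_model()]); an optional permutation oracle
#' p-value can be requested alongside.
#'
#' Inputs are aligned by sample identifier and never reordered
#' silently: mismatched identifier sets are an error.
#'
#' @param genotypes Samples x SNVs dosage matrix (rownames are sample
#'   ids), or a tibble from [burden_scores()].  Ignored in mode `"T"`.
#' @param expression Named numeric vector of per-sample expression for
#'   the matched probe.  Ignored in mode `"G"`.
#' @param ranks A `wu_ranks` object (named, see Details) or a named
#'   numeric phenotype vector which is ranked internally.
#' @param mode `"GT"`, `"G"` or `"T"`.
#' @param config A [kernel_config()].
#' @param sample_ids Optional explicit sample ordering; defaults to the
#'   phenotype's names.  All sources must contain exactly these ids.
#' @param n_perm If > 0, also compute [permutation_pvalue()] with this
#'   many permutations.
#' @param seed Seed for the permutation oracle.
#' @return Object of class `wu_test`: list with `u`, `p`, `method`,
#'   `mode`, `n`, `n_snv`, `p_perm` (or `NA`), `null` (the `wu_null`),
#'   and `diagnostics`.
#' @export
wu_test <- function(genotypes = NULL, expression = NULL, ranks,
                    mode = c("GT", "G", "T"), config = kernel_config(),
                    sample_ids = NULL, n_perm = 0L, seed = 1L) {
  mode <- match.arg(mode)
  ph_names <- NULL
  if (!inherits(ranks, "wu_ranks")) {
    ph_names <- names(ranks)
    ranks <- rank_phenotype(ranks)
  }
  n <- ranks$n
  z <- rank_scores(ranks)
  sample_ids <- sample_ids %||% ph_names
  f <- NULL; g <- NULL; n_snv <- NA_integer_
  if (mode %in% c("GT", "G")) {
    if (is.null(genotypes)) abort("mode ", mode, " needs `genotypes`.")
    if (is.matrix(genotypes) || is.data.frame(genotypes)) {
      geno <- as_dosage_matrix(genotypes)
      geno <- align_rows(geno, sample_ids, "genotypes")
      b <- burden_scores(geno)
      a <- b$burden
      n_snv <- ncol(geno)
    } else {
      a <- align_values(genotypes$burden, genotypes$sample_id, sample_ids,
                        "burden scores")
      n_snv <- nrow(attr(genotypes, "weights") %||% tibble())
    }
    f <- gaussian_similarity(a, config, standardize = config$standardize_burden)
  }
  if (mode %in% c("GT", "T")) {
    if (is.null(expression)) abort("mode ", mode, " needs `expression`.")
    t_vec <- align_values(as.numeric(expression), names(expression),
                          sample_ids, "expression")
    if (any(!is.finite(t_vec))) abort("expression values must be finite.")
    g <- gaussian_similarity(t_vec, config,
                             standardize = config$standardize_expression)
  }
  us <- u_statistic(f, g, tcrossprod(z))
  M <- combined_weight(f, g, n)
  nm <- null_model(M, z)
  pv <- tryCatch(null_tail(nm, us$u), wujoint_degenerate_test = function(e) NULL)
  p_perm <- NA_real_
  if (n_perm > 0) {
    p_perm <- permutation_pvalue(us$u, f, g, ranks, n_perm = n_perm,
                                 seed = seed)$p
  }
  structure(
    list(
      u = us$u, p = if (is.null(pv)) NA_real_ else pv$p,
      method = if (is.null(pv)) "degenerate" else pv$method,
      mode = mode, n = n, n_snv = n_snv, p_perm = p_perm, null = nm,
      diagnostics = if (is.null(pv)) list(degenerate = TRUE) else pv$diagnostics
    ),
    class = "wu_test"
  )
}

#' @export
print.wu_test <- function(x, ...) {
  cat("Weighted U test (", x$mode, " mode), n = ", x$n, "\n", sep = "")
  cat("  U = ", format(x$u), ",  p = ", format(x$p),
      "  [", x$method, "]\n", sep = "")
  if (!is.na(x$p_perm)) cat("  permutation p =", format(x$p_perm), "\n")
  invisible(x)
}

#' @rdname wu_test
#' @param x A `wu_test` object.
#' @param ... Unused.
#' @method tidy wu_test
#' @export
tidy.wu_test <- function(x, ...) {
  tibble(
    mode = x$mode, u = x$u, p = x$p, method = x$method,
    p_perm = x$p_perm, n = x$n, n_snv = x$n_snv
  )
}

#' @rdname wu_test
#' @method glance wu_test
#' @export
glance.wu_test <- function(x, ...) {
  tibble(n = x$n, n_snv = x$n_snv, mode = x$mode, p = x$p)
}

## align a matrix's rows (or a vector) to the reference id ordering
align_rows <- function(m, ids, what) {
  if (is.null(ids)) {
    if (is.null(rownames(m))) return(m)  # positional alignment
    ids <- rownames(m)
  }
  if (is.null(rownames(m))) {
    if (nrow(m) != length(ids)) {
      abort(paste0(what, ": no sample names and length mismatch."),
            class = "wujoint_misaligned")
    }
    return(m)
  }
  if (!all(ids %in% rownames(m))) {
    abort(paste0(what, ": sample ids missing; no silent reordering."),
          class = "wujoint_misaligned")
  }
  m[ids, , drop = FALSE]
}

align_values <- function(x, x_names, ids, what) {
  if (is.null(ids) || is.null(x_names)) {
    if (!is.null(ids) && length(x) != length(ids)) {
      abort(paste0(what, ": length mismatch."), class = "wujoint_misaligned")
    }
    return(x)
  }
  if (!all(ids %in% x_names)) {
    abort(paste0(what, ": sample ids missing; no silent reordering."),
          class = "wujoint_misaligned")
  }
  x[match(ids, x_names)]
}

#' Genome screen: weighted U tests over many gene regions
#'
#' Runs [wu_test()] for every (region, probe) pair and phenotype, in the
#' requested modes, and attaches Benjamini-Hochberg q-values computed
#' per phenotype and per mode across all regions.  Per-region failures
#' (for example degenerate kernels) are caught, logged, and reported
#' with missing p-values; the screen never aborts on a single region.
#'
#' @param regions Tibble of testing regions: columns `chrom`, `start`,
#'   `end`, `gene_id`, `probe_id` (one row per region-probe pair, as
#'   produced by [pair_regions_probes()] + [tidyr::unnest()], or by
#'   [simulate_study()]).
#' @param genotypes Either a named list of dosage matrices keyed by
#'   `gene_id`, or a path to a VCF file (regions are then read with
#'   [read_genotypes()]).
#' @param expression Probes x samples expression matrix.
#' @param phenotypes A data frame with a `sample_id` column, one or more
#'   phenotype columns, covariates, and optional `PC`-prefixed columns.
#' @param phenotype_cols Character vector naming the phenotype columns.
#' @param covariates Character vector of covariate columns (default:
#'   all non-phenotype, non-PC, non-id columns).
#' @param pcs Matrix of PC scores, character vector of PC column names,
#'   or `NULL` for the `PC`-prefixed columns found in `phenotypes`.
#' @param modes Modes to run, subset of `c("GT", "G", "T")`.
#' @param config A [kernel_config()].
#' @return A tibble of class `wu_screen` with one row per (region,
#'   probe, phenotype): `chrom`, `bp1`, `bp2`, `gene_id`, `probe_id`,
#'   `phenotype`, `n_snv`, `p_gt`, `p_g`, `p_t`, `q_gt`, `q_g`, `q_t`
#'   (columns for modes not run are omitted), ordered by (phenotype,
#'   chrom, bp1, gene_id).  Metadata (modes, kernel config, package
#'   version) is attached as attributes.
#' @export
wu_screen <- function(regions, genotypes, expression, phenotypes,
                      phenotype_cols, covariates = NULL, pcs = NULL,
                      modes = c("GT", "G", "T"), config = kernel_config()) {
  modes <- match.arg(modes, several.ok = TRUE)
  stopifnot(is.data.frame(regions), all(c("chrom", "start", "end", "gene_id",
                                          "probe_id") %in% names(regions)))
  if (!"sample_id" %in% names(phenotypes)) {
    abort("`phenotypes` needs a `sample_id` column.")
  }
  if (is.null(pcs)) {
    pc_cols <- grep("^PC", names(phenotypes), value = TRUE)
    pcs <- if (length(pc_cols)) as.matrix(phenotypes[pc_cols]) else NULL
  } else if (is.character(pcs)) {
    pcs <- as.matrix(phenotypes[pcs])
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(phenotypes),
                          c("sample_id", phenotype_cols,
                            grep("^PC", names(phenotypes), value = TRUE)))
  }
  fetch <- genotype_fetcher(genotypes)
  ## sample alignment: phenotype order is the reference
  ids <- as.character(phenotypes$sample_id)
  expr_ids <- colnames(expression)
  if (!is.null(expr_ids) && !all(ids %in% expr_ids)) {
    abort("expression matrix is missing phenotype samples.",
          class = "wujoint_misaligned")
  }
  regions <- dplyr::arrange(regions, .data$chrom, .data$start, .data$gene_id,
                            .data$probe_id)
  out <- vector("list", length(phenotype_cols))
  for (ip in seq_along(phenotype_cols)) {
    ph <- phenotype_cols[ip]
    inform(paste0("screening ", nrow(regions), " region-probe pairs for ",
                  ph))
    ranks <- residualize_and_rank(phenotypes, ph, covariates, pcs)
    rows <- vector("list", nrow(regions))
    for (i in seq_len(nrow(regions))) {
      if (i %% 250 == 0) inform(paste0("  ... ", i, " regions done (", ph, ")"))
      rg <- regions[i, ]
      geno <- fetch(rg)
      expr <- expression[rg$probe_id, , drop = TRUE]
      if (!is.null(expr_ids)) expr <- setNames(as.numeric(expr), expr_ids)
      row <- list(chrom = rg$chrom, bp1 = rg$start, bp2 = rg$end,
                  gene_id = rg$gene_id, probe_id = rg$probe_id,
                  phenotype = ph, n_snv = NA_integer_)
      for (md in modes) {
        tst <- tryCatch(
          wu_test(genotypes = geno, expression = expr, ranks = ranks,
                  mode = md, config = config, sample_ids = ids),
          error = function(e) {
            inform(paste0("region ", rg$gene_id, " (", ph, ", ", md,
                          "): ", conditionMessage(e)))
            NULL
          }
        )
        pcol <- paste0("p_", tolower(md))
        row[[pcol]] <- if (is.null(tst)) NA_real_ else tst$p
        if (!is.null(tst) && !is.na(tst$n_snv)) row$n_snv <- tst$n_snv
      }
      rows[[i]] <- as_tibble(row)
    }
    out[[ip]] <- list_rbind(rows)
  }
  res <- list_rbind(out)
  for (md in modes) {
    pcol <- paste0("p_", tolower(md))
    qcol <- paste0("q_", tolower(md))
    res <- res |>
      group_by(.data$phenotype) |>
      mutate(!!qcol := fdr_adjust(.data[[pcol]])) |>
      ungroup()
  }
  res <- arrange(res, .data$phenotype, .data$chrom, .data$bp1, .data$gene_id,
                 .data$probe_id)
  attr(res, "modes") <- modes
  attr(res, "config") <- config
  attr(res, "version") <- as.character(packageVersion("wujoint"))
  class(res) <- c("wu_screen", class(res))
  res
}

## normalize the genotype source to a fetch function(region) -> matrix
genotype_fetcher <- function(genotypes) {
  if (is.function(genotypes)) return(genotypes)
  if (is.list(genotypes) && !is.data.frame(genotypes)) {
    return(function(rg) {
      m <- genotypes[[rg$gene_id]]
      if (is.null(m)) abort(paste0("no genotypes for region ", rg$gene_id))
      m
    })
  }
  if (is.character(genotypes) && length(genotypes) == 1) {
    vcf <- read_genotypes(genotypes)     # read once, subset per region
    info <- attr(vcf, "snv_info")
    return(function(rg) {
      fl <- if ("flank" %in% names(rg)) rg$flank else 0
      sel <- which(info$chrom == rg$chrom &
                     info$pos >= rg$start - fl &
                     info$pos <= rg$end + fl)
      vcf[, sel, drop = FALSE]
    })
  }
  abort("unsupported `genotypes` source.")
}
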