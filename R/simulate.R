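#' Configuration for the synthetic-study generator
#'
#' Defaults emulate the study conditions the test is designed for:
#' 142 unrelated samples; per-gene SNV counts spanning 115-411 (the
#' interquartile range typical of flanked gene regions in whole-genome
#' sequencing); a rare-heavy MAF mixture (80% of SNVs with
#' MAF uniform on 0.001-0.01, the rest uniform on 0.01-0.5, so most
#' SNVs are rare, MAF < 0.01); expression partially driven by the
#' gene's burden (an eQTL link of strength `gamma`); and a quantitative
#' phenotype built from burden, expression, covariates and unit
#' Gaussian noise, with a binary phenotype thresholded at a configured
#' prevalence.
#'
#' Effect sizes are per standardized burden / expression unit.  The
#' defaults (`beta_g = 0.1`, `beta_t = 0.1`, `gamma = 0.7`) give
#' causal genes moderate, non-saturated power at n = 142, so that mode
#' comparisons remain informative.
#'
#' @param n Sample count.
#' @param n_genes Number of gene regions.
#' @param n_causal How many genes (the first ones) carry effects.
#' @param snv_range Inclusive range the per-gene SNV count is drawn
#'   from (uniformly).
#' @param maf_rare_frac Fraction of SNVs drawn from the rare stratum.
#' @param maf_rare,maf_common Uniform MAF ranges of the two strata.
#' @param beta_g Genetic effect on the phenotype per standardized
#'   burden unit (causal genes).
#' @param beta_t Expression effect on the phenotype (causal genes).
#' @param gamma eQTL strength: expression is
#'   `gamma * standardized burden + N(0, 1)` (causal genes).
#' @param covar_effects Named vector of effects for the generated
#'   covariates `age` (standardized) and `sex`.
#' @param prevalence Case fraction of the thresholded binary phenotype.
#' @param flank Flank recorded in the emitted annotation regions.
#' @param ensure_carrier Redraw rare SNVs that realize zero carriers
#'   (keeps every emitted SNV polymorphic; disable to allow MAF = 0
#'   columns).
#' @param seed Mandatory integer seed.
#' @return Object of class `wu_sim_config`.
#' @export
sim_config <- function(n = 142L, n_genes = 10L, n_causal = 0L,
                       snv_range = c(115L, 411L),
                       maf_rare_frac = 0.8,
                       maf_rare = c(0.001, 0.01),
                       maf_common = c(0.01, 0.5),
                       beta_g = 0.1, beta_t = 0.1, gamma = 0.7,
                       covar_effects = c(age = 0.2, sex = 0.3),
                       prevalence = 0.3, flank = 5000,
                       ensure_carrier = TRUE, seed) {
  if (missing(seed)) abort("`seed` is mandatory for reproducibility.")
  if (n < 10) abort("`n` must be at least 10.")
  if (n_causal > n_genes) abort("`n_causal` cannot exceed `n_genes`.")
  structure(
    list(n = as.integer(n), n_genes = as.integer(n_genes),
         n_causal = as.integer(n_causal), snv_range = as.integer(snv_range),
         maf_rare_frac = maf_rare_frac, maf_rare = maf_rare,
         maf_common = maf_common, beta_g = beta_g, beta_t = beta_t,
         gamma = gamma, covar_effects = covar_effects,
         prevalence = prevalence, flank = flank,
         ensure_carrier = isTRUE(ensure_carrier), seed = as.integer(seed)),
    class = "wu_sim_config"
  )
}

#' Simulate one gene region
#'
#' Dosages are Binomial(2, maf) per SNV with MAF from the configured
#' rare/common mixture; expression is `gamma * standardized burden +
#' N(0, 1)`; the returned phenotype contribution is
#' `beta_g * standardized burden + beta_t * expression`.  Uses the
#' current RNG state (seed at study level).
#'
#' @param config A [sim_config()].
#' @param causal Apply the config's effect sizes (else all zero).
#' @return List with `dosages` (n x K), `maf` (generating values),
#'   `expression`, `phen_contribution`, `burden_std`.
#' @export
simulate_gene <- function(config, causal = FALSE) {
  n <- config$n
  K <- sample(seq(config$snv_range[1], config$snv_range[2]), 1)
  dos <- matrix(0, n, K)
  maf <- numeric(K)
  for (k in seq_len(K)) {
    for (try in 1:100) {
      mk <- if (runif(1) < config$maf_rare_frac) {
        runif(1, config$maf_rare[1], config$maf_rare[2])
      } else {
        runif(1, config$maf_common[1], config$maf_common[2])
      }
      col <- rbinom(n, 2, mk)
      if (!config$ensure_carrier || sum(col) > 0) break
    }
    dos[, k] <- col
    maf[k] <- mk
  }
  b <- burden_scores(dos)
  a <- b$burden
  a_std <- if (sd(a) > 0) (a - mean(a)) / sd(a) else a * 0
  gm <- if (causal) config$gamma else 0
  bg <- if (causal) config$beta_g else 0
  bt <- if (causal) config$beta_t else 0
  t_vec <- gm * a_std + rnorm(n)
  list(
    dosages = dos, maf = maf, expression = t_vec,
    phen_contribution = bg * a_std + bt * t_vec,
    burden_std = a_std
  )
}

#' Simulate a complete synthetic study
#'
#' Generates genotypes, expression, phenotypes and covariates for all
#' configured genes, together with the region annotation and the
#' gene-to-probe map, and optionally writes the same standard files the
#' readers consume (VCF, expression TSV, phenotype CSV, BED annotation,
#' probe-map TSV).  Genes are laid out on odd-numbered chromosomes with
#' enough spacing that flanked regions do not overlap.
#'
#' @param config A [sim_config()].
#' @param dir If non-`NULL`, write the file bundle into this directory.
#' @return Object of class `wu_sim`: list with `genotypes` (named list
#'   of dosage matrices), `expression` (probes x samples matrix),
#'   `phenotypes` (tibble: `sample_id`, `qt`, `qt2`, `bin`, `age`,
#'   `sex`),
#'   `regions` (tibble incl. `probe_id` and `flank`), `probe_map`,
#'   `snvs`, `truth` (per-gene effect sizes), `config`, and `files`
#'   (paths, when written).
#' @export
simulate_study <- function(config, dir = NULL) {
  set.seed(config$seed)
  n <- config$n
  ids <- sprintf("S%03d", seq_len(n))
  age <- rnorm(n, 50, 10)
  sex <- rbinom(n, 1, 0.5)
  genotypes <- list()
  expr <- matrix(NA_real_, nrow = config$n_genes, ncol = n)
  contrib <- 0
  regions <- vector("list", config$n_genes)
  snvs <- vector("list", config$n_genes)
  truth <- vector("list", config$n_genes)
  chroms <- as.character(seq(1, 21, by = 2))
  for (gi in seq_len(config$n_genes)) {
    causal <- gi <= config$n_causal
    gene <- simulate_gene(config, causal = causal)
    gid <- sprintf("G%03d", gi)
    chrom <- chroms[(gi - 1) %% length(chroms) + 1]
    slot <- (gi - 1) %/% length(chroms)
    start <- 1000000L + slot * 2000000L
    K <- ncol(gene$dosages)
    span <- max(20000L, 10L * K)
    end <- start + span
    pos <- sort(sample(seq(start, end), K))
    snv_ids <- paste0(gid, "_v", seq_len(K))
    rownames(gene$dosages) <- ids
    colnames(gene$dosages) <- snv_ids
    genotypes[[gid]] <- gene$dosages
    expr[gi, ] <- gene$expression
    contrib <- contrib + gene$phen_contribution
    regions[[gi]] <- tibble(chrom = chrom, start = start, end = end,
                            gene_id = gid, flank = config$flank,
                            probe_id = paste0("P_", gid))
    snvs[[gi]] <- tibble(chrom = chrom, pos = pos, snv_id = snv_ids,
                         gene_id = gid)
    truth[[gi]] <- tibble(
      gene_id = gid, causal = causal,
      beta_g = if (causal) config$beta_g else 0,
      beta_t = if (causal) config$beta_t else 0,
      gamma = if (causal) config$gamma else 0
    )
  }
  regions <- list_rbind(regions)
  snvs <- list_rbind(snvs)
  truth <- list_rbind(truth)
  rownames(expr) <- regions$probe_id
  colnames(expr) <- ids
  ce <- config$covar_effects
  fixed <- contrib + ce[["age"]] * as.numeric(scale(age)) + ce[["sex"]] * sex
  qt <- fixed + rnorm(n)
  ## a second quantitative trait sharing the same structural signal but
  ## with independent noise (correlated traits, like systolic/diastolic
  ## blood pressure), plus a thresholded binary trait
  qt2 <- fixed + rnorm(n)
  bin <- as.integer(qt > quantile(qt, 1 - config$prevalence))
  phen <- tibble(sample_id = ids, qt = qt, qt2 = qt2, bin = bin,
                 age = age, sex = sex)
  out <- structure(
    list(genotypes = genotypes, expression = expr, phenotypes = phen,
         regions = regions, probe_map = regions[c("gene_id", "probe_id")],
         snvs = snvs, truth = truth, config = config, files = NULL),
    class = "wu_sim"
  )
  if (!is.null(dir)) out$files <- write_sim_files(out, dir)
  out
}

#' @export
print.wu_sim <- function(x, ...) {
  cat("<wu_sim>", x$config$n, "samples,", x$config$n_genes, "genes (",
      x$config$n_causal, "causal ), seed", x$config$seed, "\n")
  invisible(x)
}

## emit the file bundle the io readers consume
write_sim_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    expression = file.path(dir, "expression.tsv"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    annotation = file.path(dir, "annotation.bed"),
    probe_map = file.path(dir, "probe_map.tsv")
  )
  write_sim_vcf(sim, paths$vcf)
  expr <- as.data.frame(sim$expression)
  readr::write_tsv(
    tibble::rownames_to_column(expr, "probe_id"),
    paths$expression
  )
  readr::write_csv(sim$phenotypes, paths$phenotypes)
  ## BED is 0-based half-open: start - 1
  bed <- sim$regions |>
    mutate(bed_start = .data$start - 1L) |>
    select("chrom", "bed_start", "end", "gene_id")
  readr::write_tsv(bed, paths$annotation, col_names = FALSE)
  readr::write_tsv(sim$probe_map, paths$probe_map)
  paths
}

write_sim_vcf <- function(sim, path) {
  ids <- sim$phenotypes$sample_id
  recs <- vector("list", length(sim$genotypes))
  for (gid in names(sim$genotypes)) {
    dos <- sim$genotypes[[gid]]
    info <- sim$snvs[sim$snvs$gene_id == gid, ]
    gt <- matrix(c("0/0", "0/1", "1/1")[dos + 1], nrow = nrow(dos))
    gt[is.na(dos)] <- "./."
    recs[[gid]] <- data.frame(
      CHROM = info$chrom, POS = info$pos, ID = info$snv_id,
      REF = "A", ALT = "C", QUAL = ".", FILTER = "PASS", INFO = ".",
      FORMAT = "GT", t(gt), check.names = FALSE
    )
  }
  body <- do.call(rbind, recs)
  body <- body[order(suppressWarnings(as.integer(body$CHROM)), body$POS), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  ), con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
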