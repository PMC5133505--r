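#' Read biallelic SNV genotypes from a VCF
#'
#' Dosages are alternate-allele counts parsed from the `GT` field
#' (phased `|` and unphased `/` separators are equivalent); `./.` is
#' missing.  Multiallelic records are skipped and counted, not split --
#' the 0/1/2 coding presumes biallelic sites.  Coordinates stay 1-based
#' as in the VCF.
#'
#' @param path VCF file (plain or bgzipped).
#' @param region Optional region tibble row (`chrom`, `start`, `end`,
#'   optionally `flank`) to subset sites.
#' @return Samples x SNVs numeric dosage matrix with rownames = sample
#'   ids and colnames = variant ids, plus attributes `snv_info` (tibble
#'   `chrom`, `pos`, `snv_id`, `ref`, `alt`) and
#'   `n_multiallelic_skipped`.
#' @export
read_genotypes <- function(path, region = NULL) {
  if (!file.exists(path)) abort(paste0("no such VCF: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  n_multi <- sum(multi)
  if (n_multi) inform(paste0("skipping ", n_multi, " multiallelic record(s)"))
  keep <- !multi
  if (!is.null(region)) {
    fl <- if ("flank" %in% names(region)) region$flank else 0
    keep <- keep & fix$CHROM == region$chrom &
      as.integer(fix$POS) >= region$start - fl &
      as.integer(fix$POS) <= region$end + fl
  }
  gt <- v@gt[keep, -1, drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ## dosage from the GT subfield only
  gt_field <- sub(":.*$", "", gt)
  dos <- matrix(NA_real_, nrow = nrow(gt_field), ncol = ncol(gt_field))
  dos[gt_field %in% c("0/0", "0|0")] <- 0
  dos[gt_field %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  dos[gt_field %in% c("1/1", "1|1")] <- 2
  unparsed <- !is.na(gt_field) & is.na(dos) &
    !gt_field %in% c("./.", ".|.", ".")
  if (any(unparsed)) {
    bad <- which(unparsed, arr.ind = TRUE)[1, ]
    abort(paste0("malformed GT value '", gt_field[unparsed][1],
                 "' at record ", rownames(fix)[bad[1]] %||% bad[1]),
          class = "wujoint_bad_vcf")
  }
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  out <- t(dos)
  rownames(out) <- colnames(gt)
  colnames(out) <- ids
  attr(out, "snv_info") <- tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS), snv_id = ids,
    ref = fix$REF, alt = fix$ALT
  )
  attr(out, "n_multiallelic_skipped") <- n_multi
  out
}

#' Read an expression matrix
#'
#' Expects a TSV whose first column holds probe identifiers and whose
#' remaining columns are per-sample values with a header row of sample
#' ids.  Duplicate probe rows and non-numeric cells are hard errors.
#'
#' @param path TSV file.
#' @return Probes x samples numeric matrix.
#' @export
read_expression <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, col_types = readr::cols())
  if (ncol(tb) < 2) abort("expression table needs a probe column and samples.")
  probes <- as.character(tb[[1]])
  if (anyDuplicated(probes)) {
    abort(paste0("duplicate probe row(s): ",
                 paste(unique(probes[duplicated(probes)]), collapse = ", ")),
          class = "wujoint_bad_expression")
  }
  vals <- tb[-1]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1]
      abort(paste0("non-numeric expression value at probe ", probes[bad],
                   ", sample ", names(vals)[j]),
            class = "wujoint_bad_expression")
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- probes
  m
}

#' Read a phenotype and covariate table
#'
#' CSV with mandatory columns `sample_id` and at least one phenotype
#' column; remaining columns are treated as covariates unless their
#' name is prefixed `PC` (principal-component scores).
#'
#' @param path CSV file.
#' @return Tibble.
#' @export
read_phenotypes <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  if (!"sample_id" %in% names(tb)) {
    abort("phenotype table must contain a `sample_id` column.")
  }
  tb$sample_id <- as.character(tb$sample_id)
  tb
}

#' Read a gene-to-probe map
#'
#' Two-column TSV (`gene_id`, `probe_id`).
#'
#' @param path TSV file.
#' @return Tibble with `gene_id`, `probe_id`.
#' @export
read_probe_map <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  names(tb)[1:2] <- c("gene_id", "probe_id")
  tb$gene_id <- as.character(tb$gene_id)
  tb$probe_id <- as.character(tb$probe_id)
  tb
}

#' Align samples across data sources
#'
#' The alignment is the ordered intersection of sample ids, in the
#' order of the first (reference, normally phenotype) source.  Ids
#' dropped from any source are recorded and reported; an empty
#' intersection is an error.  All downstream joins go through this
#' single alignment -- nothing reorders samples implicitly.
#'
#' @param ... Named character vectors of sample ids, reference first.
#' @return Object of class `wu_alignment`: list with `sample_ids` and
#'   `dropped` (named list per source).
#' @export
align_samples <- function(...) {
  sources <- list(...)
  if (length(sources) < 1) abort("supply at least one id vector.")
  if (is.null(names(sources)) || any(names(sources) == "")) {
    names(sources) <- paste0("source", seq_along(sources))
  }
  sources <- lapply(sources, as.character)
  common <- Reduce(intersect, sources)
  if (!length(common)) {
    abort("no samples shared across all sources.",
          class = "wujoint_empty_alignment")
  }
  ids <- sources[[1]][sources[[1]] %in% common]
  dropped <- lapply(sources, function(s) setdiff(s, common))
  n_drop <- sum(lengths(dropped))
  if (n_drop) {
    inform(paste0("dropped ", n_drop, " sample id(s) absent from some source"))
  }
  structure(list(sample_ids = ids, dropped = dropped),
            class = "wu_alignment")
}

#' @export
print.wu_alignment <- function(x, ...) {
  cat("<wu_alignment>", length(x$sample_ids), "samples;",
      sum(lengths(x$dropped)), "dropped\n")
  invisible(x)
}

#' Write screen results as TSV
#'
#' Mirrors the screen's summary table layout (chromosome, first and last
#' base pair, gene, probe, phenotype, per-mode p- and q-values, SNV
#' count).  A header comment embeds the package version, the seed and a
#' configuration hash so outputs are traceable.
#'
#' @param screen A `wu_screen` tibble.
#' @param path Output file.
#' @param seed Seed to record in the header.
#' @return `path`, invisibly.
#' @export
write_results <- function(screen, path, seed = NA) {
  cfg <- attr(screen, "config")
  hash <- substr(digest_config(cfg), 1, 12)
  hdr <- c(
    paste0("# wujoint v", attr(screen, "version") %||%
             as.character(packageVersion("wujoint"))),
    paste0("# seed: ", seed),
    paste0("# config: ", hash),
    paste0("# modes: ", paste(attr(screen, "modes"), collapse = ","))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  out <- as.data.frame(screen)
  names(out) <- toupper(names(out))
  old <- options(scipen = 15)
  on.exit(options(old), add = TRUE)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## small deterministic config fingerprint (no external digest dependency)
digest_config <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  raw <- utils::head(charToRaw(s), 1e4)
  sprintf("%08x", sum(as.integer(raw) * seq_along(raw)) %% .Machine$integer.max)
}

#' Observed vs expected quantiles for a QQ plot
#'
#' @param p Vector of p-values (NA dropped).
#' @return Tibble with `expected` and `observed` `-log10` p quantiles.
#' @export
qq_data <- function(p) {
  p <- sort(p[!is.na(p)])
  m <- length(p)
  tibble(
    expected = -log10((seq_len(m) - 0.5) / m),
    observed = -log10(pmax(p, 1e-300))
  )
}
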