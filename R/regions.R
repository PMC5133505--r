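#' Read gene regions from a GFF3 or BED annotation
#'
#' Parses gene features into a region table with 1-based closed
#' coordinates.  GFF3 input keeps rows whose `type` is `gene` (all rows
#' if none are typed so); BED input (0-based half-open) is converted to
#' 1-based closed at parse time by the importer.  Each annotation row
#' becomes one region; reconciliation of alternate assemblies is the
#' caller's responsibility.
#'
#' @param path Annotation file (`.gff3`/`.gff` or `.bed`).
#' @return Tibble with `chrom`, `start`, `end`, `gene_id`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort(paste0("no such annotation file: ", path))
  md <- as.data.frame(rtracklayer::import(path))
  tb <- tibble(
    chrom = as.character(md$seqnames),
    start = as.integer(md$start),
    end = as.integer(md$end),
    gene_id = annotation_ids(md)
  )
  if ("type" %in% names(md) && any(md$type == "gene")) {
    tb <- tb[md$type == "gene", , drop = FALSE]
  }
  tb
}

annotation_ids <- function(md) {
  for (col in c("gene_id", "ID", "Name", "name")) {
    if (col %in% names(md) && !all(is.na(md[[col]]))) {
      return(as.character(md[[col]]))
    }
  }
  paste0("region", seq_len(nrow(md)))
}

#' Build flanked testing regions
#'
#' Attaches the flank width used for SNV assignment (the screen tests
#' each gene plus `flank` base pairs on both ends, strand ignored) and
#' validates coordinates.
#'
#' @param annotation Tibble with `chrom`, `start`, `end`, `gene_id`
#'   (e.g. from [read_annotation()]), or a path handed to it.
#' @param flank Non-negative flank in base pairs (default 5000).
#' @return The region tibble with a `flank` column, ordered by
#'   (chrom, start, gene_id) so construction is independent of input
#'   row order.
#' @export
gene_regions <- function(annotation, flank = 5000) {
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  stopifnot(all(c("chrom", "start", "end", "gene_id") %in% names(annotation)))
  if (flank < 0) abort("`flank` must be non-negative.")
  if (any(annotation$start > annotation$end)) {
    abort("region start must not exceed end.", class = "wujoint_bad_region")
  }
  annotation |>
    mutate(flank = flank) |>
    arrange(.data$chrom, .data$start, .data$gene_id)
}

#' Assign SNVs to flanked regions
#'
#' An SNV at position `pos` on the region's chromosome is retained if
#' and only if `start - flank <= pos <= end + flank` -- a closed
#' interval on both ends.  SNVs may belong to several overlapping
#' regions; assignment is independent per region.
#'
#' @param regions Region tibble from [gene_regions()].
#' @param snvs Tibble with `chrom`, `pos`, `snv_id` (1-based positions).
#' @return Tibble with one row per retained (gene, SNV): `gene_id`,
#'   `snv_id`, `chrom`, `pos`.  Regions whose chromosome is absent from
#'   `snvs` get an empty assignment (a message is emitted).
#' @export
assign_snvs <- function(regions, snvs) {
  stopifnot(all(c("chrom", "pos", "snv_id") %in% names(snvs)))
  missing_chroms <- setdiff(unique(regions$chrom), unique(snvs$chrom))
  if (length(missing_chroms)) {
    inform(paste0("no SNVs on chromosome(s): ",
                  paste(missing_chroms, collapse = ", ")))
  }
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    rg <- regions[i, ]
    hit <- snvs[snvs$chrom == rg$chrom &
                  snvs$pos >= rg$start - rg$flank &
                  snvs$pos <= rg$end + rg$flank, , drop = FALSE]
    if (nrow(hit)) {
      out[[i]] <- tibble(gene_id = rg$gene_id, snv_id = hit$snv_id,
                         chrom = hit$chrom, pos = hit$pos)
    }
  }
  list_rbind(out[!vapply(out, is.null, TRUE)])
}

#' Drop monomorphic SNVs and emptied regions
#'
#' Removes index entries whose SNV has `maf = 0` in the analysis
#' sample, then removes regions whose SNV list became empty.
#'
#' @param index Assignment tibble from [assign_snvs()].
#' @param freqs Tibble with `snv_id` and `maf` computed on the analysis
#'   sample.
#' @return Filtered index; the gene ids dropped entirely are recorded in
#'   attribute `"dropped_regions"`.
#' @export
filter_monomorphic <- function(index, freqs) {
  before <- unique(index$gene_id)
  keep_snv <- freqs$snv_id[freqs$maf > 0]
  out <- index[index$snv_id %in% keep_snv, , drop = FALSE]
  attr(out, "dropped_regions") <- setdiff(before, unique(out$gene_id))
  out
}

#' Pair regions with expression probes
#'
#' Regions without any matched expression probe are discarded (with a
#' reason recorded); retained regions carry all matched probes, one row
#' per (region, probe) pair.  Duplicate map rows are deduplicated with a
#' warning.  An empty map is almost certainly a configuration mistake
#' and triggers a hard warning: the screen would be vacuous.
#'
#' @param regions Region tibble ([gene_regions()]).
#' @param probe_map Tibble (or 2-column data frame) with `gene_id`,
#'   `probe_id`.
#' @return Region tibble expanded to one row per (region, probe), with
#'   the dropped gene ids in attribute `"dropped_regions"`.
#' @export
pair_regions_probes <- function(regions, probe_map) {
  probe_map <- as_tibble(probe_map)
  if (ncol(probe_map) < 2) abort("`probe_map` needs gene_id and probe_id.")
  names(probe_map)[1:2] <- c("gene_id", "probe_id")
  if (anyDuplicated(probe_map[c("gene_id", "probe_id")])) {
    warn("duplicate (gene, probe) rows in probe map; deduplicating.")
    probe_map <- distinct(probe_map, .data$gene_id, .data$probe_id)
  }
  if (!nrow(probe_map)) {
    warn("empty probe map: every region will be discarded (vacuous screen)",
         class = "wujoint_vacuous_screen")
  }
  out <- dplyr::inner_join(regions, probe_map[c("gene_id", "probe_id")],
                           by = "gene_id", relationship = "many-to-many")
  attr(out, "dropped_regions") <- setdiff(regions$gene_id, out$gene_id)
  out
}

#' Region retention report
#'
#' Applies probe pairing, SNV assignment, and the monomorphic filter in
#' the screen's order and reconciles the counts: every input region is
#' accounted for exactly once as retained or dropped with a reason code
#' (`no_probe`, `no_snv`, `all_monomorphic`).
#'
#' @param regions Region tibble ([gene_regions()]).
#' @param snvs SNV position tibble (see [assign_snvs()]).
#' @param freqs MAF tibble (see [filter_monomorphic()]).
#' @param probe_map Gene-probe map (see [pair_regions_probes()]).
#' @return List with `report` (tibble: `gene_id`, `status`, `reason`,
#'   `n_snv`), `regions` (retained region-probe rows), and `index`
#'   (retained SNV assignment).
#' @export
region_report <- function(regions, snvs, freqs, probe_map) {
  paired <- pair_regions_probes(regions, probe_map)
  no_probe <- attr(paired, "dropped_regions")
  idx <- assign_snvs(regions[!regions$gene_id %in% no_probe, , drop = FALSE],
                     snvs)
  with_probe <- setdiff(regions$gene_id, no_probe)
  no_snv <- setdiff(with_probe, unique(idx$gene_id))
  idx2 <- filter_monomorphic(idx, freqs)
  all_mono <- attr(idx2, "dropped_regions")
  retained <- setdiff(with_probe, c(no_snv, all_mono))
  n_snv <- table(idx2$gene_id)
  report <- tibble(gene_id = regions$gene_id) |>
    distinct() |>
    mutate(
      status = ifelse(.data$gene_id %in% retained, "retained", "dropped"),
      reason = dplyr::case_when(
        gene_id %in% no_probe ~ "no_probe",
        gene_id %in% no_snv ~ "no_snv",
        gene_id %in% all_mono ~ "all_monomorphic",
        TRUE ~ NA_character_
      ),
      n_snv = as.integer(n_snv[.data$gene_id])
    )
  list(
    report = report,
    regions = paired[paired$gene_id %in% retained, , drop = FALSE],
    index = idx2
  )
}
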