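make_regions <- function() {
  gene_regions(tibble::tibble(
    chrom = "1", start = 10000L, end = 20000L, gene_id = "GX"
  ), flank = 5000)
}

test_that("SNV assignment uses closed intervals on both ends", {
  rg <- make_regions()
  snvs <- tibble::tibble(
    chrom = "1",
    pos = c(4999L, 5000L, 12000L, 25000L, 25001L),
    snv_id = paste0("v", 1:5)
  )
  idx <- assign_snvs(rg, snvs)
  expect_setequal(idx$snv_id, c("v2", "v3", "v4"))
})

test_that("flank zero reduces to within-gene assignment", {
  rg <- gene_regions(tibble::tibble(chrom = "1", start = 10000L,
                                    end = 20000L, gene_id = "GX"), flank = 0)
  snvs <- tibble::tibble(chrom = "1", pos = c(9999L, 10000L, 20000L, 20001L),
                         snv_id = paste0("v", 1:4))
  expect_setequal(assign_snvs(rg, snvs)$snv_id, c("v2", "v3"))
})

test_that("chromosome mismatch yields an empty assignment with a message", {
  rg <- make_regions()
  snvs <- tibble::tibble(chrom = "2", pos = 12000L, snv_id = "v1")
  expect_message(idx <- assign_snvs(rg, snvs), "chromosome")
  expect_equal(nrow(idx), 0)
})

test_that("SNVs may belong to multiple overlapping regions", {
  rg <- gene_regions(tibble::tibble(
    chrom = c("1", "1"), start = c(100L, 150L), end = c(200L, 260L),
    gene_id = c("A", "B")
  ), flank = 0)
  snvs <- tibble::tibble(chrom = "1", pos = 180L, snv_id = "shared")
  idx <- assign_snvs(rg, snvs)
  expect_equal(sort(idx$gene_id), c("A", "B"))
})

test_that("monomorphic SNVs and emptied regions are dropped", {
  idx <- tibble::tibble(
    gene_id = c("A", "A", "A", "B", "B"),
    snv_id = c("v1", "v2", "v3", "v4", "v5"),
    chrom = "1", pos = 1:5
  )
  freqs <- tibble::tibble(snv_id = paste0("v", 1:5),
                          maf = c(0.1, 0, 0.2, 0, 0))
  out <- filter_monomorphic(idx, freqs)
  expect_setequal(out$snv_id, c("v1", "v3"))
  expect_equal(attr(out, "dropped_regions"), "B")
  ## identity when nothing is monomorphic
  freqs2 <- tibble::tibble(snv_id = paste0("v", 1:5), maf = rep(0.1, 5))
  expect_equal(nrow(filter_monomorphic(idx, freqs2)), 5)
})

test_that("probe pairing keeps matched regions and expands multi-probes", {
  rg <- gene_regions(tibble::tibble(
    chrom = "1", start = c(1L, 100L, 200L), end = c(50L, 150L, 250L),
    gene_id = c("A", "B", "C")
  ), flank = 0)
  map <- tibble::tibble(gene_id = c("A", "B", "B"),
                        probe_id = c("p1", "p2", "p3"))
  paired <- pair_regions_probes(rg, map)
  expect_equal(nrow(paired), 3)                     # A x 1, B x 2
  expect_equal(attr(paired, "dropped_regions"), "C")
  expect_setequal(paired$probe_id[paired$gene_id == "B"], c("p2", "p3"))
  ## duplicates collapse with a warning; empty map warns hard
  expect_warning(pair_regions_probes(rg, map[c(1, 1), ]), "duplicate")
  expect_warning(pair_regions_probes(rg, map[0, ]),
                 class = "wujoint_vacuous_screen")
})

test_that("region construction ignores annotation row order", {
  ann <- tibble::tibble(
    chrom = c("2", "1", "1"), start = c(5L, 300L, 10L),
    end = c(50L, 400L, 100L), gene_id = c("C", "B", "A")
  )
  expect_identical(gene_regions(ann), gene_regions(ann[c(3, 1, 2), ]))
})

test_that("retention counts reconcile across all filter rules", {
  ## 5 genes: 2 retained, 1 per drop reason
  rg <- gene_regions(tibble::tibble(
    chrom = "1",
    start = c(1000L, 3000L, 5000L, 7000L, 9000L) * 10L,
    end = c(1000L, 3000L, 5000L, 7000L, 9000L) * 10L + 500L,
    gene_id = paste0("G", 1:5)
  ), flank = 100)
  snvs <- tibble::tibble(
    chrom = "1",
    pos = c(10100L, 10200L, 30300L, 90300L),
    snv_id = c("a", "b", "c", "d")
  )                                    # G4 (70000..70500): no SNV
  freqs <- tibble::tibble(snv_id = c("a", "b", "c", "d"),
                          maf = c(0.1, 0, 0.05, 0))   # G5's d: monomorphic
  map <- tibble::tibble(gene_id = c("G1", "G2", "G4", "G5"),
                        probe_id = paste0("p", c(1, 2, 4, 5)))  # G3: no probe
  rr <- region_report(rg, snvs, freqs, map)
  rep_tbl <- rr$report
  expect_equal(nrow(rep_tbl), 5)
  expect_equal(rep_tbl$status[rep_tbl$gene_id %in% c("G1", "G2")],
               rep(c("retained"), 2))
  expect_equal(rep_tbl$reason[rep_tbl$gene_id == "G3"], "no_probe")
  expect_equal(rep_tbl$reason[rep_tbl$gene_id == "G4"], "no_snv")
  expect_equal(rep_tbl$reason[rep_tbl$gene_id == "G5"], "all_monomorphic")
  expect_equal(sum(rep_tbl$status == "retained") +
                 sum(rep_tbl$status == "dropped"), 5)
  ## the surviving index re-scans clean against the closed-interval rule
  joined <- dplyr::left_join(rr$index, rg, by = "gene_id")
  expect_true(all(joined$pos >= joined$start - joined$flank &
                    joined$pos <= joined$end + joined$flank))
  expect_equal(rep_tbl$n_snv[rep_tbl$gene_id == "G1"], 1L)  # "b" is MAF 0
})
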