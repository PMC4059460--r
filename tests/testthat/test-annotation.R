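test_that("GTF coordinates convert to 0-based half-open and dedup", {
  fs <- read_features(gtf_fixture())
  expect_equal(nrow(fs$exons), 3L)          # duplicate collapsed
  e1 <- fs$exons[fs$exons$exon_id == "E1", ]
  expect_equal(e1$start, 100L)
  expect_equal(e1$end, 200L)
  g1 <- fs$genes[fs$genes$gene_id == "G1", ]
  expect_equal(c(g1$start, g1$end), c(100L, 400L))

  bed <- tempfile(fileext = ".bed")
  writeLines("chrY\t99\t200\tE1", bed)
  fb <- read_features(bed)
  expect_equal(fb$exons$start, 99L)
  expect_equal(fb$exons$end, 200L)
  expect_equal(fb$exons$exon_id, "E1")
})

test_that("regions classify as exonic, intronic or intergenic", {
  exons <- data.frame(chrom = "chrS", start = c(150L, 1000L),
                      end = c(250L, 1200L), exon_id = c("E1", "E3"),
                      gene_id = c("G1", "G2"), strand = "+")
  # G1 spans [150, 600) via a second exon far downstream
  exons <- rbind(exons, data.frame(chrom = "chrS", start = 500L, end = 600L,
                                   exon_id = "E2", gene_id = "G1",
                                   strand = "+"))
  fs <- structure(list(
    exons = exons,
    genes = data.frame(gene_id = c("G1", "G2"), chrom = "chrS",
                       start = c(150L, 1000L), end = c(600L, 1200L))),
    class = "feature_set")
  regions <- data.frame(chrom = c("chrS", "chrS", "chr9"),
                        start = c(100L, 300L, 5L),
                        end = c(200L, 400L, 50L))
  ann <- annotate_regions(regions, fs)
  expect_equal(ann$class, c("exonic", "intronic", "intergenic"))
  expect_equal(ann$best_exon_id[1], "E1")
  expect_equal(ann$overlap_bases[1], 50L)
  expect_equal(ann$frac_region[1], 0.5)
  expect_equal(ann$frac_exon[1], 0.5)
  expect_equal(ann$gene_ids[2], "G1")
  expect_equal(ann$overlap_bases[3], 0L)
  # best-exon overlap can never exceed either interval length
  expect_true(all(ann$overlap_bases <=
                    pmin(ann$end - ann$start, Inf), na.rm = TRUE))
  # classification is exhaustive and exclusive
  expect_true(all(ann$class %in% c("exonic", "intronic", "intergenic")))
})

test_that("empty region lists annotate and roll up to empty tables", {
  fs <- read_features(gtf_fixture())
  ann <- annotate_regions(data.frame(chrom = character(), start = integer(),
                                     end = integer()), fs)
  expect_equal(nrow(ann), 0L)
  ann$q <- numeric(0)
  ru <- feature_rollup(ann)
  expect_equal(ru$n_exons_called, 0L)
  expect_equal(ru$n_genes_called, 0L)
})

test_that("exon and gene rollup applies q and overlap-fraction rules", {
  fs <- read_features(gtf_fixture())
  # one significant region fully covering exon E1 [100, 200)
  regions <- data.frame(chrom = "chrS", start = 90L, end = 210L,
                        q = 0.01)
  ann <- annotate_regions(regions, fs)
  ru <- feature_rollup(ann, q_threshold = 0.05, exon_frac_threshold = 0.2)
  expect_equal(ru$n_exons_called, 1L)
  expect_equal(ru$n_genes_called, 1L)
  # not significant -> nothing called
  regions$q <- 0.5
  ann <- annotate_regions(regions, fs)
  expect_equal(feature_rollup(ann)$n_exons_called, 0L)
  # two regions hitting two exons of one gene -> 2 exons, 1 gene
  regions2 <- data.frame(chrom = "chrS", start = c(90L, 290L),
                         end = c(210L, 410L), q = 0.01)
  ann2 <- annotate_regions(regions2, fs)
  ru2 <- feature_rollup(ann2)
  expect_equal(ru2$n_exons_called, 2L)
  expect_equal(ru2$n_genes_called, 1L)
  # overlap fraction below threshold does not call the exon
  regions3 <- data.frame(chrom = "chrS", start = 195L, end = 400L, q = 0.01)
  ann3 <- annotate_regions(regions3, fs)
  ru3 <- feature_rollup(ann3, exon_frac_threshold = 0.2)
  called <- ru3$exons[ru3$exons$called, "exon_id"]
  expect_false("E1" %in% called)   # only 5 of E1's 100 bases covered
  expect_true("E2" %in% called)
})
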