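test_that("written bundles read back identically across two slices", {
  sim <- simulate_srt(sim_config(n_rows = 2, n_cols = 4, n_slices = 2,
                                 M = 2, n_chrom = 2, bins_per_chrom = 3,
                                 snps_per_bin = 1, genes_per_bin = 2,
                                 transcripts_per_spot = 200,
                                 allele_umis_per_spot = 80, n_loh = 1,
                                 mirrored = FALSE, seed = 4))
  dir <- withr::local_tempdir()
  paths <- write_bundle(sim, dir)
  rb <- read_bundle(paths$slices, paths$annotation)
  expect_equal(ncol(rb$X0), 16)
  expect_setequal(unique(rb$slice_id), c("s1", "s2"))
  expect_equal(as.matrix(rb$X0), as.matrix(sim$bundle$X0),
               ignore_attr = TRUE)
  expect_equal(as.matrix(rb$Y0), as.matrix(sim$bundle$Y0),
               ignore_attr = TRUE)
  expect_equal(as.matrix(rb$D0), as.matrix(sim$bundle$D0),
               ignore_attr = TRUE)
  expect_equal(rb$snp_index$pos, sim$bundle$snp_index$pos)
})

test_that("spots are restricted to barcodes shared by all inputs", {
  sim <- simulate_srt(sim_config(n_rows = 2, n_cols = 3, M = 1, n_chrom = 1,
                                 bins_per_chrom = 3, snps_per_bin = 2,
                                 genes_per_bin = 2, transcripts_per_spot = 150,
                                 allele_umis_per_spot = 60, n_loh = 0,
                                 mirrored = FALSE, seed = 9))
  dir <- withr::local_tempdir()
  paths <- write_bundle(sim, dir)
  # drop one barcode from the coordinate file only
  posfile <- paths$slices$s1$positions
  pos <- read.csv(posfile)
  write.csv(pos[-1, ], posfile, row.names = FALSE)
  rb <- read_bundle(paths$slices, paths$annotation)
  expect_equal(ncol(rb$X0), 5)
})

test_that("allele counts exceeding totals are rejected", {
  X0 <- matrix(5, 2, 3); D0 <- matrix(2, 2, 3)
  Y0 <- matrix(c(1, 3, 1, 1, 1, 1), 2, 3)   # one entry Y0 > D0
  expect_error(toy_bundle(X0, Y0, D0), "Y0 must be <= D0")
})

test_that("spot filter enforces both UMI thresholds jointly", {
  # spot 1: 49 transcript UMIs but 200 SNP UMIs -> removed (AND rule)
  X0 <- cbind(c(24, 25), c(40, 30), c(100, 100))
  D0 <- cbind(c(100, 100), c(15, 15), c(40, 40))
  Y0 <- D0 * 0
  b <- toy_bundle(X0, Y0, D0)
  out <- filter_spots(b, min_umi = 50, min_snp_umi = 50)
  expect_equal(ncol(out$bundle$X0), 1)
  expect_equal(nrow(out$report), 2)
  expect_setequal(out$report$reason, c("low_umi", "low_snp_umi"))
  # defaults are 50/50 and a clean bundle passes unchanged
  expect_equal(formals(filter_spots)$min_umi, 50)
  expect_equal(formals(filter_spots)$min_snp_umi, 50)
  clean <- toy_bundle(matrix(60, 2, 2), matrix(0, 2, 2), matrix(60, 2, 2))
  expect_equal(ncol(filter_spots(clean)$bundle$X0), 2)
})

test_that("gene filter applies expression fraction, outliers and ig/hla flags", {
  set.seed(1)
  n <- 100
  X0 <- matrix(rpois(5 * n, 2), 5, n)
  X0[1, ] <- 0                      # never expressed
  X0[2, ] <- c(3, rep(0, n - 1))    # exactly 1/100 spots: boundary, retained
  b <- toy_bundle(X0, matrix(0, 2, n), matrix(0, 2, n),
                  ig = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  out <- filter_genes(b, min_frac_spots = 0.005,
                      outlier_detector = function(tot) rep(FALSE, length(tot)))
  kept <- out$bundle$gene_index$gene
  expect_false("g1" %in% kept)      # zero expression
  expect_true("g2" %in% kept)       # 1/100 >= 0.005
  expect_false("g3" %in% kept)      # immunoglobulin flag
  expect_true(all(c("g4", "g5") %in% kept))
  expect_equal(formals(filter_genes)$min_frac_spots, 0.005)
  # order-independence: retained set is the intersection of the three rules
  frac_keep <- rowSums(X0 > 0) / n >= 0.005
  flag_keep <- !b$gene_index$ig & !b$gene_index$hla
  expect_setequal(kept, b$gene_index$gene[frac_keep & flag_keep])
})

test_that("SNP filter keeps genic non-HLA positions only", {
  X0 <- matrix(10, 3, 4)
  Y0 <- matrix(0, 3, 4); D0 <- matrix(1, 3, 4)
  b <- toy_bundle(X0, Y0, D0,
                  snp_pos = c(1100, 2100, 9000),       # in g1, in g2, intergenic
                  gene_start = c(1000, 2000, 3000),
                  gene_end = c(1500, 2500, 3500),
                  hla = c(FALSE, TRUE, FALSE))
  out <- filter_snps(b)
  expect_equal(out$bundle$snp_index$pos, 1100)
  expect_setequal(out$report$reason, c("hla_region", "intergenic"))
})

test_that("filters are idempotent and conserve items", {
  sim <- simulate_srt(sim_config(n_rows = 4, n_cols = 4, M = 1, n_chrom = 2,
                                 bins_per_chrom = 4, snps_per_bin = 3,
                                 genes_per_bin = 2, transcripts_per_spot = 300,
                                 allele_umis_per_spot = 100, n_loh = 1,
                                 mirrored = FALSE, seed = 2))
  b <- sim$bundle
  once <- apply_filters(b)
  twice <- apply_filters(once$bundle)
  expect_equal(dim(twice$bundle$X0), dim(once$bundle$X0))
  expect_equal(dim(twice$bundle$Y0), dim(once$bundle$Y0))
  expect_equal(nrow(twice$report), 0)
  # conservation: removed + retained = original
  rep1 <- once$report
  expect_equal(sum(rep1$kind == "spot") + ncol(once$bundle$X0), ncol(b$X0))
  expect_equal(sum(rep1$kind == "gene") + nrow(once$bundle$X0), nrow(b$X0))
})
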