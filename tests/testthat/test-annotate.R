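test_that("contained genes appear in 'within' and never on a side", {
  genes <- data.frame(chrom = "chr1", start = c(150, 40, 400),
                      end = c(180, 60, 450),
                      symbol = c("IN", "LEFT", "RIGHT"),
                      biotype = "protein_coding", stringsAsFactors = FALSE)
  res <- closest_genes(list(chrom = "chr1", start = 100, end = 300), genes)
  expect_equal(res$within$symbol, "IN")
  expect_equal(res$upstream$symbol, "LEFT")
  expect_equal(res$upstream$distance, 100 - 60 - 1)
  expect_equal(res$downstream$symbol, "RIGHT")
  expect_equal(res$downstream$distance, 400 - 300 - 1)
  expect_false("IN" %in% c(res$upstream$symbol, res$downstream$symbol))
})

test_that("non-protein-coding records are excluded before the search", {
  genes <- data.frame(chrom = "chr1", start = c(10, 20), end = c(15, 90),
                      symbol = c("PC", "LNC"),
                      biotype = c("protein_coding", "lncRNA"),
                      stringsAsFactors = FALSE)
  res <- closest_genes(list(chrom = "chr1", start = 100, end = 200), genes)
  expect_equal(res$upstream$symbol, "PC")
})

test_that("an absent chromosome yields an empty flagged result", {
  genes <- data.frame(chrom = "chr2", start = 1, end = 10, symbol = "A",
                      biotype = "protein_coding", stringsAsFactors = FALSE)
  res <- closest_genes(list(chrom = "chrX", start = 5, end = 9), genes)
  expect_false(res$found)
  expect_equal(nrow(res$within), 0L)
})

test_that("closest genes equal the exhaustive scan on many random intervals", {
  genes <- random_genes(200, seed = 50)
  set.seed(51)
  for (r in 1:300) {
    s <- sample.int(5e5, 1)
    ccm <- list(chrom = sample(c("chr1", "chr2"), 1), start = s,
                end = s + sample.int(3e5, 1))
    got <- closest_genes(ccm, genes)
    want <- scan_closest(ccm, genes)
    expect_identical(sort(got$within$symbol), want$within)
    expect_identical(got$upstream$symbol, want$up)
    expect_identical(got$downstream$symbol, want$down)
    if (!is.null(want$up)) expect_equal(got$upstream$distance, want$up_d)
    # partition property: within never intersects the side picks
    expect_false(any(c(got$upstream$symbol, got$downstream$symbol)
                     %in% got$within$symbol))
  }
})

test_that("anchor span validation applies the [10 kb, 300 kb) rule", {
  mk <- function(s, w = 1000) list(chrom = "chr22", start = s, end = s + w - 1)
  # anchors at the ends of the chr22:20707691-20999032 region (~290 kb apart)
  a <- list(chrom = "chr22", start = 20707691, end = 20709691)
  b <- list(chrom = "chr22", start = 20997032, end = 20999032)
  res <- validate_ccm_span(a, b)
  expect_true(res$pass)
  expect_lt(res$distance, 3e5)
  expect_gt(res$distance, 2.8e5)

  # boundaries are sharp: 9,999 fails, 10,000 passes, 300,000 fails
  expect_false(validate_ccm_span(mk(1), mk(1 + 9999))$pass)
  expect_true(validate_ccm_span(mk(1), mk(1 + 10000))$pass)
  expect_false(validate_ccm_span(mk(1), mk(1 + 300000))$pass)
  expect_true(validate_ccm_span(mk(1), mk(1 + 299999))$pass)

  tr <- validate_ccm_span(mk(1), list(chrom = "chr3", start = 1, end = 10))
  expect_false(tr$pass)
  expect_true(tr$trans)
})

test_that("multi-coverage reproduces printed fractions and handles degeneracies", {
  # 44 genes of which 29 covered by more than one marker -> 66%
  map <- rbind(
    data.frame(ccm_id = "M01", gene = sprintf("G%02d", 1:44)),
    data.frame(ccm_id = "M02", gene = sprintf("G%02d", 1:29)))
  cov <- multi_coverage(map)
  expect_equal(cov$n_genes, 44L)
  expect_equal(cov$n_multi, 29L)
  expect_equal(cov$percent, 66L)

  # every gene covered once -> 0%; duplicates in the map are ignored
  map1 <- data.frame(ccm_id = c("A", "B", "B"), gene = c("g1", "g2", "g2"))
  expect_equal(multi_coverage(map1)$percent, 0L)

  emp <- multi_coverage(data.frame(ccm_id = character(0), gene = character(0)))
  expect_true(emp$empty)
  expect_true(is.na(emp$fraction))
})

test_that("multi-coverage equals a brute-force recount on random maps", {
  set.seed(52)
  for (r in 1:20) {
    map <- data.frame(ccm_id = sample(sprintf("M%02d", 1:8), 60, replace = TRUE),
                      gene = sample(sprintf("g%02d", 1:25), 60, replace = TRUE))
    cov <- multi_coverage(map)
    u <- unique(map)
    counts <- sapply(split(u$ccm_id, u$gene), function(v) length(unique(v)))
    expect_equal(cov$n_genes, length(counts))
    expect_equal(cov$n_multi, sum(counts > 1))
    expect_equal(cov$fraction, sum(counts > 1) / length(counts))
  }
})

test_that("coordinate conversions round-trip", {
  f <- list(start = 20707691L, end = 20999032L)
  i <- coords_to_internal(f$start, f$end)
  expect_equal(i$start, 20707690L)
  expect_equal(coords_to_file(i$start, i$end), f)
})

test_that("BED and GFF3 gene models load onto the same 1-based coordinates", {
  skip_if_not_installed("rtracklayer")
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200\tGENE_A\t0\t+", bed)  # 0-based half-open
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste0("chr1\ttest\tgene\t100\t200\t.\t+\t.\t",
                      "ID=g1;gene_name=GENE_A;gene_type=protein_coding")), gff)
  gb <- read_gene_models(bed)
  gg <- read_gene_models(gff)
  expect_equal(GenomicRanges::start(gb), 100L)
  expect_equal(GenomicRanges::start(gg), 100L)
  expect_equal(GenomicRanges::end(gb), 200L)
  expect_equal(GenomicRanges::end(gg), 200L)
  expect_equal(S4Vectors::mcols(gb)$symbol, "GENE_A")
  expect_equal(S4Vectors::mcols(gg)$symbol, "GENE_A")
  expect_equal(S4Vectors::mcols(gg)$biotype, "protein_coding")

  # GRanges input to closest_genes behaves like the data-frame path
  res <- closest_genes(list(chrom = "chr1", start = 300, end = 400), gg)
  expect_equal(res$upstream$symbol, "GENE_A")
  expect_equal(res$upstream$distance, 300 - 200 - 1)
})
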