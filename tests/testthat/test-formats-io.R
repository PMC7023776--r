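test_that("read_beta_matrix parses, validates bounds, rejects degenerate files", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tchrom\tpos\tA\tB",
               "cpg1\tchr1\t100\t0.1\t0.9",
               "cpg2\tchr1\t200\t0.5\t0.25",
               "cpg3\tchr2\t300\t0\t1"), tf)
  bm <- read_beta_matrix(tf)
  expect_equal(dim(bm), c(3L, 2L))
  expect_equal(unname(bm$values["cpg1", ]), c(0.1, 0.9))
  expect_equal(bm$samples, c("A", "B"))
  expect_equal(bm$sites$pos, c(100L, 200L, 300L))

  writeLines("id\tchrom\tpos\tA", tf)
  expect_error(read_beta_matrix(tf), "no CpG rows")

  writeLines(c("id\tchrom\tpos\tA",
               "cpg1\tchr1\t100\t0.5",
               "cpg2\tchr1\t200\t1.2"), tf)
  expect_error(read_beta_matrix(tf), "row 2")

  writeLines(c("id\tchrom\tpos\tA",
               "cpg1\tchr1\t100\toops"), tf)
  expect_error(read_beta_matrix(tf), "non-numeric")
})

test_that("beta matrix round-trips through disk to 6 decimals", {
  set.seed(42)
  bm <- make_beta(matrix(runif(60), 20, 3))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(bm, tf)
  back <- read_beta_matrix(tf)
  expect_equal(back$values, bm$values, tolerance = 1e-6)
  expect_identical(back$sites, bm$sites)
})

test_that("read_bismark_cov parses, recomputes percentages, flags depth 0", {
  tf <- withr::local_tempfile(fileext = ".cov")
  writeLines(c("chr1\t100\t100\t75.0\t3\t1",
               "chr1\t200\t200\t0.0\t0\t0"), tf)
  cov <- read_bismark_cov(tf)
  expect_equal(cov$depth, c(4L, 0L))
  expect_equal(cov$pct_meth[1], 75)
  expect_equal(cov$no_coverage, c(FALSE, TRUE))

  writeLines("chr1\t100\t100\t50.0\t3\t1", tf)
  expect_warning(read_bismark_cov(tf), "disagrees")

  writeLines("chr1\t100\t100\t50.0\t-3\t1", tf)
  expect_error(read_bismark_cov(tf), "negative")
})

test_that("coverage records round-trip bit-exactly for counts", {
  set.seed(7)
  cov <- data.frame(chrom = "chr2", start = sort(sample(1e6, 50)),
                    count_meth = rpois(50, 20), count_unmeth = rpois(50, 30))
  cov$end <- cov$start
  cov$pct_meth <- 100 * cov$count_meth / (cov$count_meth + cov$count_unmeth)
  tf <- withr::local_tempfile(fileext = ".cov")
  write_bismark_cov(cov, tf)
  back <- read_bismark_cov(tf)
  expect_identical(back$count_meth, cov$count_meth)
  expect_identical(back$count_unmeth, cov$count_unmeth)
  expect_identical(back$start, cov$start)
})

test_that("promoter windows are strand-aware with inclusive endpoints", {
  genes <- data.frame(gene = c("GP", "GM"), chrom = "chr1",
                      tss = c(10000L, 10000L), strand = c("+", "-"))
  sites <- data.frame(id = c("a", "b", "c", "d"), chrom = "chr1",
                      pos = c(8000L, 10400L, 7999L, 12000L))
  pm <- annotate_promoters(sites, genes)
  expect_true("a" %in% pm$GP)          # exactly 2000 bp upstream, + strand
  expect_false("c" %in% pm$GP)         # 2001 bp upstream
  expect_true("b" %in% pm$GM)          # upstream on - strand
  expect_true("d" %in% pm$GM)          # 2000 bp upstream of - gene
  expect_false("d" %in% pm$GP)

  g1 <- data.frame(gene = "G", chrom = "chr1", tss = 5000L, strand = "+")
  s1 <- data.frame(id = paste0("p", 1:4), chrom = "chr1",
                   pos = c(2999L, 3000L, 5500L, 5501L))
  expect_setequal(annotate_promoters(s1, g1)$G, c("p2", "p3"))

  expect_error(annotate_promoters(s1, transform(g1, strand = "*")), "strand")
})

test_that("annotate_promoters matches an exhaustive interval scan and mirrors under strand flip", {
  set.seed(11)
  genes <- data.frame(gene = sprintf("G%02d", 1:40),
                      chrom = sample(paste0("chr", 1:3), 40, TRUE),
                      tss = sample(1e5, 40), strand = sample(c("+", "-"), 40, TRUE))
  sites <- data.frame(id = sprintf("c%04d", 1:3000),
                      chrom = sample(paste0("chr", 1:3), 3000, TRUE),
                      pos = sample(1e5, 3000, TRUE))
  pm <- annotate_promoters(sites, genes)
  # brute force oracle: per (gene, CpG) pair
  for (i in sample(nrow(genes), 10)) {
    lo <- if (genes$strand[i] == "+") genes$tss[i] - 2000 else genes$tss[i] - 500
    hi <- if (genes$strand[i] == "+") genes$tss[i] + 500 else genes$tss[i] + 2000
    ora <- sites$id[sites$chrom == genes$chrom[i] & sites$pos >= lo & sites$pos <= hi]
    expect_setequal(pm[[genes$gene[i]]], ora)
  }
  flipped <- transform(genes, strand = ifelse(strand == "+", "-", "+"))
  pmf <- annotate_promoters(sites, flipped)
  for (i in sample(nrow(genes), 5)) {
    g <- genes$gene[i]; tss <- genes$tss[i]
    # mirror CpG offsets around the TSS
    off <- sites$pos[match(pm[[g]], sites$id)] - tss
    off_f <- sites$pos[match(pmf[[g]], sites$id)] - tss
    # flipped window covers the mirrored offsets present among the sites
    mirror <- sites$id[sites$chrom == genes$chrom[i] &
                         (sites$pos - tss) %in% (-off)]
    expect_true(all(mirror %in% pmf[[g]]))
  }
})

test_that("sample sheet and signature readers validate their invariants", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient\tsample\tday\tstatus\toutcome",
               "P1\tP1_t1\t0\tstart\tresponse",
               "P1\tP1_t2\t30\tend_of_study\tresponse"), tf)
  sheet <- read_sample_sheet(tf)
  expect_equal(nrow(sheet), 2)

  writeLines(c("patient\tsample\tday\tstatus\toutcome",
               "P1\tP1_t1\t30\tstart\tresponse",
               "P1\tP1_t2\t30\tend_of_study\tresponse"), tf)
  expect_error(read_sample_sheet(tf), "strictly increasing")

  writeLines(c("gene\tklass", "CDH1\tepithelial", "VIM\tmesenchymal"), tf)
  expect_equal(nrow(read_signature(tf)), 2)
  writeLines(c("gene\tklass", "CDH1\tepithelial", "CDH1\tmesenchymal"), tf)
  expect_error(read_signature(tf), "duplicate")
  writeLines(c("gene\tklass", "CDH1\tepithelial", "VIM\tweird"), tf)
  expect_error(read_signature(tf), "unknown class")
})

test_that("BED export is 0-based half-open and round-trips", {
  regions <- data.frame(chrom = "chr3", start = c(101L, 500L), end = c(160L, 700L))
  tf <- withr::local_tempfile(fileext = ".bed")
  write_bed(regions, tf)
  raw <- read.delim(tf, header = FALSE)
  expect_equal(raw$V2, c(100L, 499L))
  expect_equal(raw$V3, c(160L, 700L))
  back <- read_bed(tf)
  expect_equal(back$start, regions$start)
  expect_equal(back$end, regions$end)
})
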