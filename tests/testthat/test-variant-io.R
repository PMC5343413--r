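vcfHeader <- function(samples) c(
  "##fileformat=VCFv4.2",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
  "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
  "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
  "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
  paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
    "FORMAT", samples), collapse = "\t"))

ped1 <- data.frame(family = "F1", trio = "C", father = "D", mother = "M",
  sex = "female", phenotype = "affected", stringsAsFactors = FALSE)

writeVcf1 <- function(lines, samples = c("C", "D", "M")) {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(vcfHeader(samples), lines), f)
  f
}

test_that("a clean het trio site maps fields directly", {
  f <- writeVcf1(paste("1", "100", ".", "A", "G", ".", ".", ".",
    "GT:DP:AD:GQ", "0/1:40:20,20:99", "0/0:30:30,0:80", "0/0:28:28,0:75",
    sep = "\t"))
  ts <- readTrioVcf(f, ped1)
  s <- siteData(ts)
  expect_equal(nrow(s), 1L)
  expect_equal(s$pb_gt, "het")
  expect_equal(s$pb_alt_dp / s$pb_dp, 0.5)
  expect_equal(s$fa_gt, "homref")
  expect_equal(s$mo_gq, 75)
  expect_false(s$non_autosomal)
})

test_that("multiallelic records decompose into one row per alt with per-alt depths", {
  f <- writeVcf1(paste("1", "100", ".", "A", "C,T", ".", ".", ".",
    "GT:DP:AD:GQ", "1/2:40:4,20,16:99", "0/0:30:30,0,0:80", "0/0:28:28,0,0:75",
    sep = "\t"))
  ts <- readTrioVcf(f, ped1)
  s <- siteData(ts)
  expect_equal(nrow(s), 2L)
  expect_equal(s$alt, c("C", "T"))
  expect_equal(s$pb_alt_dp, c(20L, 16L))
  # other-alt reads count toward depth but not alt_dp
  expect_equal(s$pb_dp, c(40L, 40L))
  # genotype is relative to the row's own alt: 1/2 is het for each
  expect_equal(s$pb_gt, c("het", "het"))
  # total depth conserved across the decomposition, per sample
  expect_equal(unique(s$fa_dp), 30L)
})

test_that("a half-missing parental genotype is retained as missing", {
  f <- writeVcf1(paste("1", "100", ".", "A", "G", ".", ".", ".",
    "GT:DP:AD:GQ", "0/1:40:20,20:99", "./.:.:.:.", "0/0:28:28,0:75",
    sep = "\t"))
  s <- siteData(readTrioVcf(f, ped1))
  expect_equal(s$fa_gt, "missing")
  expect_true(is.na(s$fa_gq))
})

test_that("records with all three genotypes missing are dropped and counted", {
  f <- writeVcf1(c(
    paste("1", "100", ".", "A", "G", ".", ".", ".",
      "GT:DP:AD:GQ", "./.:.:.:.", "./.:.:.:.", "./.:.:.:.", sep = "\t"),
    paste("1", "200", ".", "G", "A", ".", ".", ".",
      "GT:DP:AD:GQ", "0/1:40:20,20:99", "0/0:30:30,0:80", "0/0:28:28,0:75",
      sep = "\t")))
  ts <- readTrioVcf(f, ped1)
  expect_equal(nrow(siteData(ts)), 1L)
  expect_equal(attr(ts, "dropped"), 1L)
})

test_that("a pedigree sample absent from the VCF header is a fatal, named error", {
  f <- writeVcf1(paste("1", "100", ".", "A", "G", ".", ".", ".",
    "GT:DP:AD:GQ", "0/1:40:20,20:99", "0/0:30:30,0:80", "0/0:28:28,0:75",
    sep = "\t"), samples = c("C", "D", "OTHER"))
  expect_error(readTrioVcf(f, ped1), "M")
})

test_that("X-chromosome sites are flagged non-autosomal but processed", {
  f <- writeVcf1(paste("X", "100", ".", "A", "G", ".", ".", ".",
    "GT:DP:AD:GQ", "0/1:40:20,20:99", "0/0:30:30,0:80", "0/0:28:28,0:75",
    sep = "\t"))
  s <- siteData(readTrioVcf(f, ped1))
  expect_true(s$non_autosomal)
  expect_equal(s$pb_gt, "het")
})

test_that("PED parsing keeps complete trios, skips duos, maps sex", {
  f <- tempfile(fileext = ".ped")
  writeLines(c(
    "FAM1 DAD 0 0 1 1", "FAM1 MOM 0 0 2 1", "FAM1 CHILD DAD MOM 2 2",
    "FAM2 P2 DAD2 0 1 2"), f)
  expect_warning(ped <- readPedigree(f), "duo")
  expect_equal(nrow(ped), 1L)
  expect_equal(ped$trio, "CHILD")
  expect_equal(ped$sex, "female")
  expect_equal(ped$father, "DAD")
})

test_that("24 valid trio families give 24 pedigrees", {
  f <- tempfile(fileext = ".ped")
  lines <- unlist(lapply(1:24, function(i) c(
    sprintf("F%d D%d 0 0 1 1", i, i),
    sprintf("F%d M%d 0 0 2 1", i, i),
    sprintf("F%d C%d D%d M%d %d 2", i, i, i, i, 1 + i %% 2))))
  writeLines(lines, f)
  ped <- readPedigree(f)
  expect_equal(nrow(ped), 24L)
  expect_setequal(ped$trio, sprintf("C%d", 1:24))
})

test_that("gene rate tables: lookup, absent marker, duplicates and negatives", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tmu", "RET\t0.000133", "OTHER\t0.0005"), f)
  rates <- readGeneRates(f)
  expect_equal(geneRate(rates, "RET"), 1.33e-4)
  expect_true(is.na(geneRate(rates, "ABSENT")))
  expect_equal(geneRate(rates, "ABSENT", default = 1e-5), 1e-5)

  empty <- tempfile(fileext = ".tsv")
  writeLines("gene\tmu", empty)
  expect_true(is.na(geneRate(readGeneRates(empty), "ANY")))

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tmu", "RET\t1e-4", "RET\t2e-4"), dup)
  expect_error(readGeneRates(dup), "RET")

  neg <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tmu", "RET\t-1e-4"), neg)
  expect_error(readGeneRates(neg), "negative")
})

test_that("the DNM report round-trips through TSV with identical records", {
  cohort <- simulateTrioCohort(TrioSimParam(nTrios = 4L,
    nInheritedSites = 60L, seed = 42L))
  calls <- callDnms(cohort$sites)
  f <- tempfile(fileext = ".tsv")
  writeDnmReport(calls, f)
  back <- readDnmReport(f)
  a <- callData(calls); b <- callData(back)
  expect_equal(names(a), names(b))
  for (col in names(a)) expect_equal(b[[col]], a[[col]], tolerance = 1e-9,
    info = col)
})

test_that("simulator-written VCFs read back to the in-memory observations", {
  dir <- tempfile()
  cohort <- simulateTrioCohort(TrioSimParam(nTrios = 2L,
    nInheritedSites = 40L, seed = 7L), dir = dir)
  ped <- readPedigree(file.path(dir, "cohort.ped"))
  expect_equal(nrow(ped), 2L)
  anno <- read.table(file.path(dir, "annotation.tsv"), header = TRUE,
    sep = "\t", stringsAsFactors = FALSE)
  anno$chrom <- as.character(anno$chrom)
  tr <- ped$trio[1]
  ts <- readTrioVcf(file.path(dir, paste0(tr, ".vcf")),
    ped[1, , drop = FALSE], annotation = anno)
  s <- siteData(ts)
  mem <- siteData(cohort$sites)
  mem <- mem[mem$trio == tr, ]
  key <- function(d) paste(d$chrom, d$pos)
  m <- match(key(mem), key(s))
  expect_false(anyNA(m))
  for (col in c("pb_gt", "pb_dp", "pb_alt_dp", "pb_gq", "fa_gt", "fa_dp",
    "mo_alt_dp", "pb_alt_fwd", "pb_ref_rev"))
    expect_equal(s[[col]][m], mem[[col]], info = col)
  expect_equal(s$gene[m], mem$gene)
  expect_equal(s$af_popdb[m], mem$af_popdb, tolerance = 1e-6)
})

test_that("CNV segments are written with BED-style start conversion", {
  gr <- GenomicRanges::GRanges("1", IRanges::IRanges(10001, 160000))
  gr$kind <- "loss"; gr$n_probes <- 5L; gr$mean_lrr <- -0.3
  f <- tempfile(fileext = ".tsv")
  writeCnvSegments(gr, f)
  df <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(df$start0, 10000L)
  expect_equal(df$end, 160000L)
})
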