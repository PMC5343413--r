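test_that("candidate screen agrees with the exhaustive genotype truth table", {
  gts <- c("homref", "het", "homalt", "missing")
  grid <- expand.grid(pb = gts, fa = gts, mo = gts,
    stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i)
    makeSite(pos = 100L + i, pb_gt = grid$pb[i], fa_gt = grid$fa[i],
      mo_gt = grid$mo[i]))
  ts <- do.call(makeTrioSites, rows)
  got <- siteData(candidateDnms(ts))
  # independent brute-force oracle over all 64 configurations
  oracle <- grid$pb %in% c("het", "homalt") & grid$fa == "homref" &
    grid$mo == "homref"
  expect_equal(sort(got$pos), sort((100L + seq_len(nrow(grid)))[oracle]))
  # homozygous-alt probands are kept but flagged implausible
  expect_true(all(got$implausible_hom == (got$pb_gt == "homalt")))
})

test_that("inherited and missing-parent configurations are never candidates", {
  ts <- makeTrioSites(
    makeSite(pos = 1L, fa_gt = "het", fa_alt_dp = 20L),       # inherited
    makeSite(pos = 2L, mo_gt = "missing"),                    # unobserved
    makeSite(pos = 3L))                                       # true candidate
  expect_equal(siteData(candidateDnms(ts))$pos, 3L)
})

test_that("all four filter thresholds are inclusive at their printed values", {
  boundary <- makeSite(pb_dp = 5L, pb_alt_dp = 1L, pb_gq = 10,
    fa_dp = 5L, fa_alt_dp = 0L, fa_gq = 10,
    mo_dp = 10L, mo_alt_dp = 1L, mo_gq = 10)
  # proband fraction 1/5 >= 0.10; mother fraction 1/10 == 0.10 exactly
  boundary$pb_dp <- 10L  # make proband fraction exactly 0.10
  calls <- applyDnmFilters(makeTrioSites(boundary))
  cl <- callData(calls)
  expect_true(cl$passed)
  expect_equal(cl$filter_failures, "")
  expect_equal(cl$pb_alt_frac, 0.10)
})

test_that("each criterion fails independently and is labelled", {
  cases <- list(
    list(makeSite(pb_dp = 4L, pb_alt_dp = 2L), "coverage"),
    list(makeSite(fa_gq = 9), "genotype_quality"),
    list(makeSite(pb_alt_dp = 3L), "proband_alt_fraction"),   # 3/40 < 0.10
    list(makeSite(fa_alt_dp = 5L, fa_dp = 45L), "parent_alt_fraction"))
  for (cs in cases) {
    cl <- callData(applyDnmFilters(makeTrioSites(cs[[1]])))
    expect_false(cl$passed)
    expect_equal(cl$filter_failures, cs[[2]])
  }
  # father fraction 0.11 fails criterion 4 only
  cl <- callData(applyDnmFilters(makeTrioSites(
    makeSite(fa_dp = 100L, fa_alt_dp = 11L))))
  expect_equal(cl$filter_failures, "parent_alt_fraction")
})

test_that("zero-depth members are uninformative, not evidence of absence", {
  cl <- callData(applyDnmFilters(makeTrioSites(
    makeSite(fa_dp = 0L, fa_alt_dp = 0L))))
  expect_false(cl$passed)
  expect_match(cl$filter_failures, "coverage")
  # zero-depth parent with zero alt depth still passes criterion 4
  expect_false(grepl("parent_alt_fraction", cl$filter_failures))
  # missing GQ cannot certify the minimum
  cl <- callData(applyDnmFilters(makeTrioSites(makeSite(mo_gq = NA))))
  expect_match(cl$filter_failures, "genotype_quality")
})

test_that("relaxing any single threshold never removes a passing call", {
  set.seed(11)
  rows <- lapply(1:120, function(i) {
    dp <- sample(0:60, 3, replace = TRUE)
    makeSite(pos = i,
      pb_dp = dp[1], pb_alt_dp = rbinom(1, dp[1], 0.4), pb_gq = sample(0:99, 1),
      fa_dp = dp[2], fa_alt_dp = rbinom(1, dp[2], 0.05), fa_gq = sample(0:99, 1),
      mo_dp = dp[3], mo_alt_dp = rbinom(1, dp[3], 0.05), mo_gq = sample(0:99, 1))
  })
  ts <- do.call(makeTrioSites, rows)
  base <- DnmFilterParam()
  passed0 <- callData(applyDnmFilters(ts, base))$passed
  relaxed <- list(
    DnmFilterParam(minDepth = 3L), DnmFilterParam(minGQ = 5),
    DnmFilterParam(minProbandAltFrac = 0.05),
    DnmFilterParam(maxParentAltFrac = 0.2))
  for (p in relaxed) {
    passed1 <- callData(applyDnmFilters(ts, p))$passed
    expect_true(all(passed1[passed0]))
  }
})

test_that("clean balanced het calls get rank 1", {
  s <- makeSite(pb_dp = 50L, pb_alt_dp = 24L, pb_gq = 99,
    strand = c(13L, 13L, 12L, 12L))
  cl <- callData(assignConfidenceRank(applyDnmFilters(makeTrioSites(s))))
  expect_equal(cl$confidence_rank, 1L)
})

test_that("severe strand bias forces rank 4 or worse", {
  # all 20 alt reads on the forward strand, reference balanced
  s <- makeSite(pb_dp = 60L, pb_alt_dp = 20L, pb_gq = 99,
    strand = c(20L, 20L, 20L, 0L))
  # independent oracle: two-tailed exact test by direct hypergeometric
  # enumeration over the 2x2 table with fixed margins
  tailP <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    support <- max(0, k - n):min(k, m)
    probs <- stats::dhyper(support, m, n, k)
    pObs <- stats::dhyper(a, m, n, k)
    sum(probs[probs <= pObs * (1 + 1e-7)])
  }
  phred <- -10 * log10(tailP(20, 20, 20, 0))
  expect_gte(phred, 30)  # the worst strand level
  cl <- callData(assignConfidenceRank(applyDnmFilters(makeTrioSites(s))))
  expect_equal(cl$strand_bias_phred, phred, tolerance = 1e-6)
  expect_gte(cl$confidence_rank, 4L)
})

test_that("missing strand counts leave the strand axis neutral", {
  s <- makeSite(pb_dp = 50L, pb_alt_dp = 24L, pb_gq = 99)
  cl <- callData(assignConfidenceRank(applyDnmFilters(makeTrioSites(s))))
  expect_equal(cl$confidence_rank, 2L)  # grid (neutral strand, good quality)
  expect_true(is.na(cl$strand_bias_phred))
})

test_that("a trained model promotes convincing rank >= 3 calls to rank 2", {
  # training set separable on GQ: high-GQ candidates validated, low-GQ not
  train <- do.call(rbind, c(
    lapply(1:20, function(i) makeSite(pos = i, pb_gq = 90 + i %% 10,
      pb_dp = 40L, pb_alt_dp = 18L)),
    lapply(21:40, function(i) makeSite(pos = i, pb_gq = i %% 10,
      pb_dp = 40L, pb_alt_dp = 5L))))
  model <- suppressWarnings(trainRankModel(train, rep(c(TRUE, FALSE), each = 20)))
  # a low-quality-axis call (implausible hom) that the model likes
  s <- makeSite(pb_gt = "homalt", pb_dp = 40L, pb_alt_dp = 19L, pb_gq = 95)
  cand <- applyDnmFilters(candidateDnms(makeTrioSites(s)))
  without <- callData(assignConfidenceRank(cand))
  expect_gte(without$confidence_rank, 3L)
  with <- callData(assignConfidenceRank(cand, model = model))
  expect_equal(with$confidence_rank, 2L)
  prob <- predictRankModel(model, callData(cand))
  expect_gte(prob, 0.5)
})

test_that("the mosaic band is half-open at the configured fractions", {
  mk <- function(alt) makeSite(pb_dp = 100L, pb_alt_dp = alt)
  ts <- makeTrioSites(mk(15L), mk(50L), mk(30L), mk(10L))
  ts <- TrioSites(within(siteData(ts), pos <- 1:4), pedigree(ts))
  cl <- callData(flagMosaic(applyDnmFilters(ts)))
  expect_equal(cl$mosaic, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("consequence classes match published annotation vocabulary", {
  expect_equal(classifyConsequence("Nonsense"), "LOF")      # e.g. NCLN p.Q166X
  expect_equal(classifyConsequence("Frameshift"), "LOF")
  expect_equal(classifyConsequence("Splicing"), "LOF")
  expect_equal(classifyConsequence("Non-frameshift"), "inframe_indel")
  expect_equal(classifyConsequence("Missense"), "missense")
  expect_equal(classifyConsequence("Synonymous"), "synonymous")
  expect_equal(
    classifyConsequence(c("stopgain", "frameshift deletion", "splicing",
      "nonsynonymous SNV", "nonframeshift insertion", "synonymous SNV")),
    c("LOF", "LOF", "LOF", "missense", "inframe_indel", "synonymous"))
  expect_warning(out <- classifyConsequence("upstream"), "unrecognized")
  expect_equal(out, "other")
  expect_equal(lofSubtype(c("stopgain", "frameshift deletion", "splicing",
    "synonymous SNV")), c("nonsense", "frameshift", "splicing", NA))
})

test_that("the rare-variant filter excludes only frequencies above threshold", {
  af <- data.frame(af_dbsnp = c(NA, 0.02, NA), af_exac = c(2.8e-3, NA, NA))
  expect_equal(filterRare(af), c(TRUE, FALSE, TRUE))
  expect_true(filterRare(c(0.01, NA)))       # boundary: 0.01 is not > 0.01
  expect_false(filterRare(c(0.010001, NA)))
})

test_that("detection on clean high-depth trios is sensitive and specific", {
  # no genotyping noise, no mosaics: inherited het sites must never be called
  cohort <- simulateTrioCohort(TrioSimParam(nTrios = 24L,
    nInheritedSites = 300L, genotypingError = 0, mosaicProb = 0,
    meanDepth = 40, seed = 99L))
  res <- callDnms(cohort$sites)
  cl <- callData(res)
  called <- cl[cl$validated, ]
  key <- function(d) paste(d$trio, d$chrom, d$pos)
  truth <- cohort$truth
  expect_gte(mean(key(truth) %in% key(called)), 0.95)
  expect_equal(sum(!key(called) %in% key(truth)), 0L)  # specificity 1
})
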