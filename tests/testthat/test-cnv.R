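test_that("loss and gain rules are inclusive at their printed boundaries", {
  p5 <- as.integer(seq(10001, 160000, length.out = 5))
  expect_equal(p5[5] - p5[1] + 1L, 150000L)
  seg <- callCnvSegments(probeTrack(p5, rep(-0.2, 5)))
  expect_equal(length(seg), 1L)
  expect_equal(seg$kind, "loss")
  expect_equal(seg$n_probes, 5L)
  expect_equal(GenomicRanges::start(seg), p5[1])

  # four probes below the minimum: no call however deep
  expect_equal(length(callCnvSegments(probeTrack(p5[1:4], rep(-0.5, 4)))), 0L)
  # five probes but spanning one bp beyond the window: no call
  p5wide <- p5; p5wide[5] <- p5[1] + 150000L
  expect_equal(length(callCnvSegments(probeTrack(p5wide, rep(-0.5, 5)))), 0L)

  p7 <- as.integer(seq(10001, 210000, length.out = 7))
  expect_equal(p7[7] - p7[1] + 1L, 200000L)
  seg <- callCnvSegments(probeTrack(p7, rep(0.15, 7)))
  expect_equal(seg$kind, "gain")
  expect_equal(seg$n_probes, 7L)
  # six probes at gain intensity: below the gain probe minimum
  expect_equal(length(callCnvSegments(probeTrack(p7[1:6], rep(0.5, 6)))), 0L)
  # LRR just inside the neutral band calls nothing
  expect_equal(length(callCnvSegments(probeTrack(p5, rep(-0.19, 5)))), 0L)
  expect_equal(length(callCnvSegments(probeTrack(p7, rep(0.14, 7)))), 0L)
})

test_that("gap tolerance extends runs but never assembles the probe minimum", {
  pos <- as.integer(seq(20000, by = 20000, length.out = 12))
  # 5 consecutive deep probes + gap + 2 more: one segment spanning all 8
  lrr <- c(rep(-0.5, 5), 0.0, rep(-0.5, 2), rep(0, 4))
  seg <- callCnvSegments(probeTrack(pos, lrr))
  expect_equal(length(seg), 1L)
  expect_equal(seg$n_probes, 8L)
  expect_equal(seg$n_qualifying, 7L)
  expect_lte(seg$mean_lrr, -0.2)
  # 3 + gap + 2 qualifying probes never reach the minimum via bridging
  lrr2 <- c(rep(-0.5, 3), 0.0, rep(-0.5, 2), rep(0, 6))
  expect_equal(length(callCnvSegments(probeTrack(pos, lrr2))), 0L)
  # two sub-threshold probes in a row always break the run
  lrr3 <- c(rep(-0.5, 5), 0.0, 0.0, rep(-0.5, 5))
  seg3 <- callCnvSegments(probeTrack(pos, lrr3))
  expect_equal(length(seg3), 2L)
})

test_that("unsorted positions and non-finite probes are handled as specified", {
  tr <- probeTrack(c(100L, 50L), c(-0.5, -0.5))
  expect_error(callCnvSegments(tr), "increasing")
  p6 <- as.integer(seq(20000, by = 20000, length.out = 6))
  tr2 <- probeTrack(p6, c(rep(-0.5, 5), NaN))
  seg <- callCnvSegments(tr2)
  expect_equal(attr(seg, "dropped"), 1L)
  expect_equal(length(seg), 1L)
})

test_that("ROH span is inclusive at 2 Mb and tolerates isolated hets", {
  pos <- as.integer(seq(0, by = 20000, length.out = 101) + 1)
  expect_equal(pos[101] - pos[1] + 1L, 2000001L)
  gt <- rep("AA", 101)
  seg <- callRoh(probeTrack(pos, rnorm(101, 0, 0.01), gt = gt))
  expect_equal(seg$kind, "roh")
  expect_gte(GenomicRanges::end(seg) - GenomicRanges::start(seg) + 1L, 2000000L)

  # same run compressed below 2 Mb: no call
  short <- as.integer(seq(0, by = 19000, length.out = 101) + 1)
  expect_equal(length(callRoh(probeTrack(short, rnorm(101), gt = gt))), 0L)

  # one interior het inside 2.5 Mb is tolerated at the default 1/Mb
  pos2 <- as.integer(seq(0, by = 25000, length.out = 101) + 1)
  gt2 <- gt; gt2[50] <- "AB"
  seg2 <- callRoh(probeTrack(pos2, rnorm(101), gt = gt2))
  expect_equal(length(seg2), 1L)
  expect_equal(seg2$n_probes, 101L)

  # BAF-only homozygosity works when genotypes are absent
  baf <- rep(c(0.01, 0.99), length.out = 101)
  seg3 <- callRoh(probeTrack(pos, rnorm(101), baf = baf))
  expect_equal(length(seg3), 1L)
  expect_error(callRoh(probeTrack(pos, rnorm(101))), "gt|baf")
})

test_that("emitted segments satisfy their own invariants on noisy tracks", {
  param <- CnvRuleParam()
  for (seed in 1:10) {
    seg <- data.frame(kind = c("loss", "gain"),
      start = c(1000001L, 5000001L), end = c(1300000L, 5300000L),
      meanLrr = c(-0.5, 0.5))
    tr <- simulateProbeTrack(ArraySimParam(plantedSegments = seg, seed = seed))
    calls <- callCnvSegments(tr$track)
    if (!length(calls)) next
    df <- as.data.frame(calls)
    # sorted, non-overlapping within kind
    for (k in unique(df$kind)) {
      sub <- df[df$kind == k, ]
      if (nrow(sub) > 1)
        expect_true(all(sub$start[-1] > sub$end[-nrow(sub)]))
    }
    expect_true(all(df$mean_lrr[df$kind == "loss"] <= param@lossLrrMax))
    expect_true(all(df$mean_lrr[df$kind == "gain"] >= param@gainLrrMin))
    expect_true(all(df$n_qualifying[df$kind == "loss"] >= param@lossMinProbes))
    expect_true(all(df$n_qualifying[df$kind == "gain"] >= param@gainMinProbes))
    # loss and gain never overlap
    loss <- calls[calls$kind == "loss"]; gain <- calls[calls$kind == "gain"]
    if (length(loss) && length(gain))
      expect_equal(length(GenomicRanges::findOverlaps(loss, gain)), 0L)
  }
})

test_that("planted segments are recovered and shrinking below minima drops them", {
  hits <- 0
  for (seed in 1:25) {
    seg <- data.frame(kind = "loss", start = 3000001L, end = 3300000L,
      meanLrr = -0.45)
    tr <- simulateProbeTrack(ArraySimParam(plantedSegments = seg, seed = seed))
    calls <- callCnvSegments(tr$track)
    hits <- hits + any(calls$kind == "loss" &
      GenomicRanges::start(calls) <= seg$end &
      GenomicRanges::end(calls) >= seg$start)
  }
  expect_gte(hits / 25, 0.9)

  # same depth of signal over too few probes: monotone drop of the call
  seg <- data.frame(kind = "loss", start = 3000001L, end = 3060000L,
    meanLrr = -0.45)  # 3 probes at 20 kb spacing
  tr <- simulateProbeTrack(ArraySimParam(plantedSegments = seg,
    lrrNoiseSd = 0, seed = 1L))
  expect_equal(sum(callCnvSegments(tr$track)$kind == "loss"), 0L)
})

test_that("a noiseless gain at exactly +0.15 is called (boundary inclusive)", {
  seg <- data.frame(kind = "gain", start = 2000001L, end = 2300000L,
    meanLrr = 0.15)
  tr <- simulateProbeTrack(ArraySimParam(lrrNoiseSd = 0,
    plantedSegments = seg, seed = 3L))
  calls <- callCnvSegments(tr$track)
  expect_true(any(calls$kind == "gain"))
})
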