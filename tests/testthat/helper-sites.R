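# Builders for small hand-crafted trio site tables.

makeSite <- function(trio = "T01", chrom = "1", pos = 100L, ref = "A",
                     alt = "G", gene = "G1",
                     consequence = "nonsynonymous SNV",
                     pb_gt = "het", pb_dp = 40L, pb_alt_dp = 20L, pb_gq = 99,
                     fa_gt = "homref", fa_dp = 40L, fa_alt_dp = 0L, fa_gq = 99,
                     mo_gt = "homref", mo_dp = 40L, mo_alt_dp = 0L, mo_gq = 99,
                     strand = NULL, ...) {
  df <- data.frame(trio = trio, chrom = chrom, pos = pos, ref = ref,
    alt = alt, gene = gene, consequence = consequence,
    pb_gt = pb_gt, pb_dp = pb_dp, pb_alt_dp = pb_alt_dp, pb_gq = pb_gq,
    fa_gt = fa_gt, fa_dp = fa_dp, fa_alt_dp = fa_alt_dp, fa_gq = fa_gq,
    mo_gt = mo_gt, mo_dp = mo_dp, mo_alt_dp = mo_alt_dp, mo_gq = mo_gq,
    stringsAsFactors = FALSE)
  if (!is.null(strand)) {
    df$pb_ref_fwd <- strand[1]; df$pb_ref_rev <- strand[2]
    df$pb_alt_fwd <- strand[3]; df$pb_alt_rev <- strand[4]
  }
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

makeTrioSites <- function(..., trios = NULL) {
  rows <- list(...)
  sites <- do.call(rbind, lapply(rows, function(r) {
    common <- Reduce(intersect, lapply(rows, names))
    r[, common, drop = FALSE]
  }))
  if (is.null(trios)) trios <- unique(sites$trio)
  ped <- data.frame(family = paste0("F", seq_along(trios)), trio = trios,
    father = paste0(trios, "_fa"), mother = paste0(trios, "_mo"),
    sex = "female", phenotype = "affected", stringsAsFactors = FALSE)
  TrioSites(sites, ped)
}

probeTrack <- function(pos, lrr, chrom = "1", baf = NULL, gt = NULL) {
  df <- data.frame(chrom = chrom, pos = as.integer(pos), lrr = lrr,
    stringsAsFactors = FALSE)
  if (!is.null(baf)) df$baf <- baf
  if (!is.null(gt)) df$gt <- gt
  df
}
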