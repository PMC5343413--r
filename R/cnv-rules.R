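## Rule-based CNV and run-of-homozygosity calling from probe-level
## SNP-array tracks. Internal coordinates are 1-based fully closed; the
## TSV writer converts to BED conventions.

.checkTrackSorted <- function(track) {
  for (ch in unique(track$chrom)) {
    p <- track$pos[track$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop(sprintf("probe positions not strictly increasing on chromosome %s", ch))
  }
}

## Greedy maximal-run construction over a per-probe qualification mask:
## qualifying blocks are merged across interior sub-threshold stretches while
## the total bridged probes stay within `gap` and `meanOk` still holds for
## the merged stretch. Returns list of c(startIdx, endIdx).
.qualRuns <- function(qual, gap, meanOk) {
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qIdx <- which(r$values)
  runs <- list()
  i <- 1L
  while (i <= length(qIdx)) {
    b <- qIdx[i]
    s <- starts[b]; e <- ends[b]
    used <- 0L
    j <- i
    while (j < length(qIdx)) {
      nb <- qIdx[j + 1L]
      gapLen <- sum(r$lengths[(b + 1L):(nb - 1L)])
      if (used + gapLen > gap) break
      if (!meanOk(s, ends[nb])) break
      used <- used + gapLen
      e <- ends[nb]
      b <- nb
      j <- j + 1L
    }
    runs[[length(runs) + 1L]] <- c(s, e)
    i <- j + 1L
  }
  runs
}

## window rule: the probe minimum must be attained by an *uninterrupted*
## stretch of qualifying probes spanning at most `spanBp` base pairs. Gap
## tolerance merges and extends runs but never assembles the minimum itself
## (bridging marginal clusters up to the minimum would admit noise clusters
## as calls).
.windowOk <- function(qual, pos, minProbes, spanBp) {
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (b in which(r$values & r$lengths >= minProbes)) {
    qpos <- pos[starts[b]:ends[b]]
    m <- length(qpos)
    if (any(qpos[minProbes:m] - qpos[1:(m - minProbes + 1L)] + 1L <= spanBp))
      return(TRUE)
  }
  FALSE
}

.callOneKind <- function(pos, lrr, kind, minProbes, spanBp, lrrThresh, gap) {
  sgn <- if (kind == "loss") -1 else 1
  qual <- sgn * lrr >= sgn * lrrThresh        # inclusive boundary
  meanOk <- function(s, e) sgn * mean(lrr[s:e]) >= sgn * lrrThresh
  runs <- .qualRuns(qual, gap, meanOk)
  out <- list()
  for (run in runs) {
    idx <- run[1]:run[2]
    if (!.windowOk(qual[idx], pos[idx], minProbes, spanBp)) next
    if (!meanOk(run[1], run[2])) next
    out[[length(out) + 1L]] <- data.frame(
      start = pos[run[1]], end = pos[run[2]], kind = kind,
      n_probes = length(idx), n_qualifying = sum(qual[idx]),
      mean_lrr = mean(lrr[idx]))
  }
  out
}

#' Call copy-number gains and losses from a probe track
#'
#' Applies fixed intensity rules per chromosome: a probe qualifies for loss
#' when its log R ratio is at or below \code{lossLrrMax} and for gain when at
#' or above \code{gainLrrMin} (boundaries inclusive). Qualifying probes are
#' assembled into maximal runs, tolerating up to \code{gapProbes} interior
#' sub-threshold probes as long as the run mean still clears the threshold.
#' A run is emitted as a segment iff at least \code{lossMinProbes}
#' (\code{gainMinProbes}) consecutive qualifying probes fall within some
#' window of at most \code{lossSpanBp} (\code{gainSpanBp}) base pairs: gap
#' tolerance widens a called segment and protects long events from
#' fragmentation, but the probe minimum itself must be met by an
#' uninterrupted stretch, which keeps marginal noise clusters out. Non-finite LRR
#' probes are dropped before calling (count in attribute \code{"dropped"});
#' unsorted positions are a fatal error. Loss and gain segments can never
#' overlap (their probe criteria are disjoint).
#'
#' @param track data.frame with \code{chrom}, \code{pos}, \code{lrr}.
#' @param param a \code{\link{CnvRuleParam}}.
#' @return GRanges (1-based closed, sorted, non-overlapping within kind) with
#'   metadata columns \code{kind}, \code{n_probes}, \code{n_qualifying},
#'   \code{mean_lrr}.
#' @export
callCnvSegments <- function(track, param = CnvRuleParam()) {
  .checkTrackSorted(track)
  finite <- is.finite(track$lrr)
  dropped <- sum(!finite)
  track <- track[finite, , drop = FALSE]
  segs <- list()
  for (ch in unique(track$chrom)) {
    sub <- track[track$chrom == ch, , drop = FALSE]
    for (kind in c("loss", "gain")) {
      rows <- if (kind == "loss")
        .callOneKind(sub$pos, sub$lrr, "loss", param@lossMinProbes,
          param@lossSpanBp, param@lossLrrMax, param@gapProbes)
      else
        .callOneKind(sub$pos, sub$lrr, "gain", param@gainMinProbes,
          param@gainSpanBp, param@gainLrrMin, param@gapProbes)
      for (r in rows) { r$chrom <- ch; segs[[length(segs) + 1L]] <- r }
    }
  }
  gr <- .segsToGRanges(segs)
  attr(gr, "dropped") <- dropped
  gr
}

.segsToGRanges <- function(segs) {
  if (!length(segs)) {
    gr <- GenomicRanges::GRanges()
    gr$kind <- character(); gr$n_probes <- integer()
    gr$n_qualifying <- integer(); gr$mean_lrr <- numeric()
    return(gr)
  }
  df <- do.call(rbind, segs)
  gr <- GenomicRanges::GRanges(df$chrom,
    IRanges::IRanges(df$start, df$end))
  gr$kind <- as.character(df$kind)
  gr$n_probes <- as.integer(df$n_probes)
  gr$n_qualifying <- as.integer(df$n_qualifying)
  gr$mean_lrr <- df$mean_lrr
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

## per-probe homozygosity state: "hom", "het" or "unknown"
.homState <- function(track, bafHomMax) {
  n <- nrow(track)
  state <- rep("unknown", n)
  if ("gt" %in% names(track)) {
    state[track$gt %in% c("AA", "BB")] <- "hom"
    state[track$gt %in% "AB"] <- "het"
  }
  if ("baf" %in% names(track)) {
    b <- track$baf
    fill <- state == "unknown" & !is.na(b)
    state[fill & (b <= bafHomMax | b >= 1 - bafHomMax)] <- "hom"
    state[state == "unknown" & !is.na(b) & b > bafHomMax & b < 1 - bafHomMax] <- "het"
  }
  state
}

#' Call runs of homozygosity from a probe track
#'
#' A probe is homozygous when its hard genotype is \code{AA}/\code{BB} or,
#' lacking genotypes, when its B-allele frequency is at or below
#' \code{bafHomMax} (or at or above \code{1 - bafHomMax}). Maximal runs of
#' homozygous probes are assembled, tolerating interior heterozygous probes
#' up to \code{rohHetPerMb} per megabase of current run span; a run is
#' emitted iff it spans at least \code{rohMinBp} (inclusive). At least one of
#' \code{gt}/\code{baf} must be present.
#'
#' @param track data.frame with \code{chrom}, \code{pos} and \code{gt}
#'   and/or \code{baf} (and optionally \code{lrr}, used only for the
#'   reported segment mean).
#' @param param a \code{\link{CnvRuleParam}}.
#' @return GRanges with \code{kind = "roh"}, \code{n_probes},
#'   \code{n_het} and \code{mean_lrr} metadata.
#' @export
callRoh <- function(track, param = CnvRuleParam()) {
  if (!any(c("gt", "baf") %in% names(track)))
    stop("ROH calling needs a 'gt' or 'baf' column")
  .checkTrackSorted(track)
  segs <- list()
  for (ch in unique(track$chrom)) {
    sub <- track[track$chrom == ch, , drop = FALSE]
    state <- .homState(sub, param@bafHomMax)
    notHet <- state != "het"
    r <- rle(notHet)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    blocks <- which(r$values)
    i <- 1L
    while (i <= length(blocks)) {
      b <- blocks[i]
      s <- starts[b]; e <- ends[b]
      hetUsed <- 0L
      j <- i
      while (j < length(blocks)) {
        nb <- blocks[j + 1L]
        hetLen <- sum(r$lengths[(b + 1L):(nb - 1L)])
        newSpanMb <- (sub$pos[ends[nb]] - sub$pos[s] + 1L) / 1e6
        if (hetUsed + hetLen > param@rohHetPerMb * newSpanMb) break
        hetUsed <- hetUsed + hetLen
        e <- ends[nb]; b <- nb; j <- j + 1L
      }
      span <- sub$pos[e] - sub$pos[s] + 1L
      if (span >= param@rohMinBp && any(state[s:e] == "hom")) {
        lrr <- if ("lrr" %in% names(sub)) sub$lrr[s:e] else NA_real_
        segs[[length(segs) + 1L]] <- data.frame(
          start = sub$pos[s], end = sub$pos[e], kind = "roh",
          n_probes = e - s + 1L, n_qualifying = sum(state[s:e] == "hom"),
          mean_lrr = mean(lrr[is.finite(lrr)]), chrom = ch)
      }
      i <- j + 1L
    }
  }
  gr <- .segsToGRanges(segs)
  names(S4Vectors::mcols(gr))[names(S4Vectors::mcols(gr)) == "n_qualifying"] <- "n_hom"
  gr
}
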