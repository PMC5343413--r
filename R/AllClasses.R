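#' @import methods
#' @importFrom stats pbinom ppois dpois qpois pchisq pnorm qnorm rbeta rbinom
#'   rnbinom rnorm rpois runif chisq.test fisher.test glm predict binomial
#'   ecdf setNames
#' @importFrom utils read.table write.table
NULL

.CONSEQUENCE_LEVELS <- c("LOF", "missense", "inframe_indel", "synonymous", "other")
.GT_LEVELS <- c("homref", "het", "homalt", "missing")

## columns every TrioSites table must carry; af_* columns are free-form extras
.SITE_COLS <- c(
  "trio", "chrom", "pos", "ref", "alt", "gene", "consequence",
  "pb_gt", "pb_dp", "pb_alt_dp", "pb_gq",
  "fa_gt", "fa_dp", "fa_alt_dp", "fa_gq",
  "mo_gt", "mo_dp", "mo_alt_dp", "mo_gq"
)
.STRAND_COLS <- c("pb_ref_fwd", "pb_ref_rev", "pb_alt_fwd", "pb_alt_rev")

#' Filtering thresholds for de novo mutation candidates
#'
#' Container for the four candidate-DNM filter criteria applied to a trio
#' genotype observation, plus the population-frequency cutoff and the mosaic
#' allele-fraction band. Defaults are the thresholds used for small exome trio
#' cohorts: minimum coverage of five in proband and parents, minimum genotype
#' quality of ten, at least 10\% alternate reads in the proband, and at most
#' 10\% alternate reads in either parent; variants above 1\% population
#' frequency in any database are removed. All boundaries are inclusive, so the
#' stated threshold values themselves pass.
#'
#' @slot minDepth integer, minimum total read depth in all three members.
#' @slot minGQ numeric, minimum genotype quality in all three members.
#' @slot minProbandAltFrac numeric, minimum proband alternate-allele read
#'   fraction.
#' @slot maxParentAltFrac numeric, maximum parental alternate-allele read
#'   fraction.
#' @slot mafThreshold numeric, variants with any population allele frequency
#'   strictly above this are excluded as not rare.
#' @slot mosaicBand numeric(2), half-open proband allele-fraction interval
#'   \code{[lo, hi)} in which a passing call is flagged as a candidate
#'   post-zygotic mosaic.
#' @export
setClass("DnmFilterParam",
  slots = c(
    minDepth = "integer",
    minGQ = "numeric",
    minProbandAltFrac = "numeric",
    maxParentAltFrac = "numeric",
    mafThreshold = "numeric",
    mosaicBand = "numeric"
  )
)

setValidity("DnmFilterParam", function(object) {
  msg <- character()
  if (object@minDepth < 1L) msg <- c(msg, "minDepth must be >= 1")
  fr <- c(object@minProbandAltFrac, object@maxParentAltFrac, object@mafThreshold)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
  if (length(object@mosaicBand) != 2L || diff(object@mosaicBand) < 0)
    msg <- c(msg, "mosaicBand must be an ordered pair")
  if (length(msg)) msg else TRUE
})

#' @rdname DnmFilterParam-class
#' @param minDepth,minGQ,minProbandAltFrac,maxParentAltFrac,mafThreshold,mosaicBand
#'   see slot documentation.
#' @return A \code{DnmFilterParam} object.
#' @examples
#' DnmFilterParam()
#' DnmFilterParam(minDepth = 10L, mafThreshold = 0.001)
#' @export
DnmFilterParam <- function(minDepth = 5L, minGQ = 10, minProbandAltFrac = 0.10,
                           maxParentAltFrac = 0.10, mafThreshold = 0.01,
                           mosaicBand = c(0.10, 0.30)) {
  new("DnmFilterParam",
    minDepth = as.integer(minDepth), minGQ = as.numeric(minGQ),
    minProbandAltFrac = as.numeric(minProbandAltFrac),
    maxParentAltFrac = as.numeric(maxParentAltFrac),
    mafThreshold = as.numeric(mafThreshold),
    mosaicBand = as.numeric(mosaicBand)
  )
}

setMethod("show", "DnmFilterParam", function(object) {
  cat("DnmFilterParam\n")
  cat(sprintf("  depth >= %d, GQ >= %g (proband and both parents)\n",
    object@minDepth, object@minGQ))
  cat(sprintf("  proband alt fraction >= %g, parent alt fraction <= %g\n",
    object@minProbandAltFrac, object@maxParentAltFrac))
  cat(sprintf("  population MAF <= %g; mosaic band [%g, %g)\n",
    object@mafThreshold, object@mosaicBand[1], object@mosaicBand[2]))
})

#' Rule thresholds for SNP-array CNV and ROH calling
#'
#' Thresholds for rule-based calling of copy-number losses, gains and runs of
#' homozygosity (ROH) from probe-level log R ratio (LRR) and B-allele
#' frequency (BAF) tracks. Defaults: a loss requires at least five probes
#' within a 150-kb window at LRR of \eqn{-0.2} or below; a gain at least seven
#' probes within 200 kb at LRR of \eqn{+0.15} or above; an ROH must span at
#' least 2 Mb. Run construction tolerates \code{gapProbes} interior probes
#' that miss the per-probe threshold provided the run mean still satisfies it.
#'
#' @slot lossMinProbes,gainMinProbes integer probe minima.
#' @slot lossSpanBp,gainSpanBp integer window sizes (bp) within which the
#'   probe minimum must be attained.
#' @slot lossLrrMax,gainLrrMin numeric per-probe and run-mean LRR thresholds.
#' @slot rohMinBp integer minimum ROH span (bp).
#' @slot gapProbes integer, sub-threshold interior probes tolerated per run.
#' @slot rohHetPerMb numeric, heterozygous probes tolerated per Mb inside an
#'   ROH run.
#' @slot bafHomMax numeric, BAF at or below this (or at or above one minus
#'   this) marks a probe homozygous when hard genotypes are absent.
#' @export
setClass("CnvRuleParam",
  slots = c(
    lossMinProbes = "integer", lossSpanBp = "integer", lossLrrMax = "numeric",
    gainMinProbes = "integer", gainSpanBp = "integer", gainLrrMin = "numeric",
    rohMinBp = "integer", gapProbes = "integer", rohHetPerMb = "numeric",
    bafHomMax = "numeric"
  )
)

setValidity("CnvRuleParam", function(object) {
  msg <- character()
  if (object@lossMinProbes < 1L || object@gainMinProbes < 1L)
    msg <- c(msg, "probe minima must be >= 1")
  if (object@lossSpanBp <= 0L || object@gainSpanBp <= 0L || object@rohMinBp <= 0L)
    msg <- c(msg, "spans must be positive")
  if (object@lossLrrMax >= 0) msg <- c(msg, "lossLrrMax must be negative")
  if (object@gainLrrMin <= 0) msg <- c(msg, "gainLrrMin must be positive")
  if (object@bafHomMax < 0 || object@bafHomMax > 0.5)
    msg <- c(msg, "bafHomMax must lie in [0, 0.5]")
  if (length(msg)) msg else TRUE
})

#' @rdname CnvRuleParam-class
#' @param lossMinProbes,lossSpanBp,lossLrrMax,gainMinProbes,gainSpanBp,gainLrrMin,rohMinBp,gapProbes,rohHetPerMb,bafHomMax
#'   see slot documentation.
#' @return A \code{CnvRuleParam} object.
#' @examples
#' CnvRuleParam()
#' @export
CnvRuleParam <- function(lossMinProbes = 5L, lossSpanBp = 150000L,
                         lossLrrMax = -0.2, gainMinProbes = 7L,
                         gainSpanBp = 200000L, gainLrrMin = 0.15,
                         rohMinBp = 2000000L, gapProbes = 1L,
                         rohHetPerMb = 1, bafHomMax = 0.05) {
  new("CnvRuleParam",
    lossMinProbes = as.integer(lossMinProbes),
    lossSpanBp = as.integer(lossSpanBp), lossLrrMax = as.numeric(lossLrrMax),
    gainMinProbes = as.integer(gainMinProbes),
    gainSpanBp = as.integer(gainSpanBp), gainLrrMin = as.numeric(gainLrrMin),
    rohMinBp = as.integer(rohMinBp), gapProbes = as.integer(gapProbes),
    rohHetPerMb = as.numeric(rohHetPerMb), bafHomMax = as.numeric(bafHomMax)
  )
}

setMethod("show", "CnvRuleParam", function(object) {
  cat("CnvRuleParam\n")
  cat(sprintf("  loss: >= %d probes / %d kb / LRR <= %g\n",
    object@lossMinProbes, object@lossSpanBp %/% 1000L, object@lossLrrMax))
  cat(sprintf("  gain: >= %d probes / %d kb / LRR >= %g\n",
    object@gainMinProbes, object@gainSpanBp %/% 1000L, object@gainLrrMin))
  cat(sprintf("  ROH : span >= %g Mb, %g het/Mb tolerated\n",
    object@rohMinBp / 1e6, object@rohHetPerMb))
})

#' Per-trio variant observations
#'
#' One row per trio and biallelic alternate allele, carrying the variant
#' description (coordinates, alleles, gene, raw consequence annotation,
#' population allele frequencies in \code{af_*} columns) and the three
#' genotype observations of proband (\code{pb_}), father (\code{fa_}) and
#' mother (\code{mo_}): per-allele genotype (\code{homref}, \code{het},
#' \code{homalt} or \code{missing}), total depth, alternate-supporting depth
#' and genotype quality, plus optional proband strand counts. Multiallelic
#' VCF records are decomposed into one row per alternate allele, so all
#' genotype codes are relative to the row's own alternate allele.
#'
#' @slot sites data.frame of per-site observations (see Details).
#' @slot pedigree data.frame with one row per trio: \code{family},
#'   \code{trio} (proband id), \code{father}, \code{mother}, \code{sex},
#'   \code{phenotype}.
#' @export
setClass("TrioSites",
  slots = c(sites = "data.frame", pedigree = "data.frame")
)

setValidity("TrioSites", function(object) {
  msg <- character()
  missing <- setdiff(.SITE_COLS, names(object@sites))
  if (length(missing))
    msg <- c(msg, paste("missing site columns:", paste(missing, collapse = ", ")))
  else {
    s <- object@sites
    if (nrow(s)) {
      if (any(s$pos < 1L)) msg <- c(msg, "positions must be >= 1")
      if (any(s$ref == s$alt)) msg <- c(msg, "ref and alt alleles must differ")
      for (p in c("pb", "fa", "mo")) {
        gt <- s[[paste0(p, "_gt")]]
        if (!all(gt %in% .GT_LEVELS))
          msg <- c(msg, paste0(p, "_gt has codes outside ", paste(.GT_LEVELS, collapse = "/")))
        dp <- s[[paste0(p, "_dp")]]; ad <- s[[paste0(p, "_alt_dp")]]
        bad <- !is.na(dp) & !is.na(ad) & (ad > dp | ad < 0 | dp < 0)
        if (any(bad)) msg <- c(msg, paste0(p, ": alt depth must lie in [0, depth]"))
      }
      af <- grep("^af_", names(s), value = TRUE)
      for (a in af) {
        v <- s[[a]]
        if (any(!is.na(v) & (v < 0 | v > 1)))
          msg <- c(msg, paste(a, "must lie in [0, 1]"))
      }
    }
  }
  ped <- object@pedigree
  need <- c("trio", "father", "mother")
  if (!all(need %in% names(ped)))
    msg <- c(msg, "pedigree needs trio/father/mother columns")
  if (length(msg)) msg else TRUE
})

#' @rdname TrioSites-class
#' @param sites,pedigree see slot documentation.
#' @return A \code{TrioSites} object.
#' @export
TrioSites <- function(sites, pedigree) {
  sites$trio <- as.character(sites$trio)
  sites$chrom <- as.character(sites$chrom)
  if (!"non_autosomal" %in% names(sites))
    sites$non_autosomal <- !grepl("^(chr)?([0-9]+)$", sites$chrom)
  rownames(sites) <- NULL
  new("TrioSites", sites = sites, pedigree = pedigree)
}

setMethod("show", "TrioSites", function(object) {
  cat(sprintf("TrioSites: %d sites across %d trio(s)\n",
    nrow(object@sites), length(unique(object@sites$trio))))
  if (nrow(object@pedigree))
    cat("  trios:", paste(utils::head(object@pedigree$trio, 6), collapse = ", "),
      if (nrow(object@pedigree) > 6) "..." else "", "\n")
})

#' De novo mutation calls with filter, rank and class annotations
#'
#' The result of running DNM detection on a \code{\link{TrioSites}} object:
#' every candidate site (proband carries the alternate allele, both parents
#' homozygous reference) annotated with per-criterion filter outcomes, a
#' 1--5 confidence rank for passing calls, a mosaic flag, the consequence
#' class and the rare-variant status.
#'
#' @slot calls data.frame, one row per candidate with columns
#'   \code{passed}, \code{filter_failures}, \code{confidence_rank},
#'   \code{mosaic}, \code{class}, \code{rare} in addition to the site columns.
#' @slot pedigree data.frame as in \code{\link{TrioSites}}.
#' @export
setClass("DnmCalls", slots = c(calls = "data.frame", pedigree = "data.frame"))

setValidity("DnmCalls", function(object) {
  msg <- character()
  cl <- object@calls
  if (nrow(cl)) {
    if (!all(c("passed", "filter_failures") %in% names(cl)))
      msg <- c(msg, "calls need passed/filter_failures columns")
    else {
      ok <- cl$passed == (!nzchar(cl$filter_failures))
      if (any(!ok)) msg <- c(msg, "passed must mirror an empty filter_failures set")
      if ("confidence_rank" %in% names(cl)) {
        r <- cl$confidence_rank
        if (any(!is.na(r) & !cl$passed))
          msg <- c(msg, "confidence_rank defined only for passing calls")
        if (any(!is.na(r) & (r < 1L | r > 5L)))
          msg <- c(msg, "confidence_rank must lie in 1..5")
      }
    }
    if ("class" %in% names(cl) && !all(is.na(cl$class) | cl$class %in% .CONSEQUENCE_LEVELS))
      msg <- c(msg, "unknown consequence class")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname DnmCalls-class
#' @param calls,pedigree see slot documentation.
#' @return A \code{DnmCalls} object.
#' @export
DnmCalls <- function(calls, pedigree = data.frame()) {
  rownames(calls) <- NULL
  new("DnmCalls", calls = calls, pedigree = pedigree)
}

setMethod("show", "DnmCalls", function(object) {
  cl <- object@calls
  cat(sprintf("DnmCalls: %d candidate(s), %d passing all filters\n",
    nrow(cl), sum(cl$passed)))
  if (nrow(cl) && "class" %in% names(cl)) {
    tab <- table(factor(cl$class[cl$passed], levels = .CONSEQUENCE_LEVELS))
    cat("  passing by class:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  }
})

#' Cohort-level summary of de novo mutation counts
#'
#' Per-trio DNM counts for a whole cohort with the class breakdown and the
#' fitted Poisson mean. Trios without any call are included with count zero;
#' \code{lambdaHat} is the full-precision per-trio mean.
#'
#' @slot nTrios integer number of trios in the cohort.
#' @slot perTrioCounts named integer vector, one entry per trio.
#' @slot classCounts named integer vector over the consequence classes.
#' @slot lambdaHat numeric, mean DNMs per trio.
#' @export
setClass("CohortDnmSummary",
  slots = c(
    nTrios = "integer", perTrioCounts = "integer",
    classCounts = "integer", lambdaHat = "numeric"
  )
)

setValidity("CohortDnmSummary", function(object) {
  msg <- character()
  if (object@nTrios != length(object@perTrioCounts))
    msg <- c(msg, "perTrioCounts must have one entry per trio")
  if (sum(object@perTrioCounts) != sum(object@classCounts))
    msg <- c(msg, "per-trio and per-class totals disagree")
  if (object@nTrios > 0 &&
      abs(object@lambdaHat - sum(object@perTrioCounts) / object@nTrios) > 1e-12)
    msg <- c(msg, "lambdaHat must equal total / nTrios")
  if (any(object@perTrioCounts < 0L)) msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CohortDnmSummary", function(object) {
  cat(sprintf("CohortDnmSummary: %d DNMs over %d trios (lambda = %.4f, reported %.1f)\n",
    sum(object@perTrioCounts), object@nTrios, object@lambdaHat,
    round(object@lambdaHat, 1)))
  cat(sprintf("  trios with >= 1 DNM: %d\n", sum(object@perTrioCounts > 0L)))
  tab <- object@classCounts
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

#' @rdname CohortDnmSummary-class
#' @param object a \code{CohortDnmSummary}.
#' @export
setGeneric("lambdaHat", function(object) standardGeneric("lambdaHat"))

#' @rdname CohortDnmSummary-class
#' @export
setMethod("lambdaHat", "CohortDnmSummary", function(object) object@lambdaHat)

#' @rdname CohortDnmSummary-class
#' @export
setGeneric("perTrioCounts", function(object) standardGeneric("perTrioCounts"))

#' @rdname CohortDnmSummary-class
#' @export
setMethod("perTrioCounts", "CohortDnmSummary", function(object) object@perTrioCounts)

#' @rdname CohortDnmSummary-class
#' @export
setGeneric("classCounts", function(object) standardGeneric("classCounts"))

#' @rdname CohortDnmSummary-class
#' @export
setMethod("classCounts", "CohortDnmSummary", function(object) object@classCounts)

#' Accessors for site- and call-level tables
#'
#' \code{siteData} returns the per-site data.frame of a \code{TrioSites}
#' object; \code{callData} the per-candidate data.frame of a \code{DnmCalls};
#' \code{pedigree} the trio table of either.
#'
#' @param object a \code{TrioSites} or \code{DnmCalls} object.
#' @return A data.frame.
#' @export
setGeneric("siteData", function(object) standardGeneric("siteData"))

#' @rdname siteData
#' @export
setMethod("siteData", "TrioSites", function(object) object@sites)

#' @rdname siteData
#' @export
setGeneric("callData", function(object) standardGeneric("callData"))

#' @rdname siteData
#' @export
setMethod("callData", "DnmCalls", function(object) object@calls)

#' @rdname siteData
#' @export
setGeneric("pedigree", function(object) standardGeneric("pedigree"))

#' @rdname siteData
#' @export
setMethod("pedigree", "TrioSites", function(object) object@pedigree)

#' @rdname siteData
#' @export
setMethod("pedigree", "DnmCalls", function(object) object@pedigree)

setMethod("as.data.frame", "TrioSites", function(x, ...) x@sites)
setMethod("as.data.frame", "DnmCalls", function(x, ...) x@calls)
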