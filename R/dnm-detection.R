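## Candidate de novo mutation detection: Mendelian-inconsistency screen,
## the four quality filter criteria, confidence ranking, mosaic flagging,
## consequence classification and the rare-variant frequency filter.

#' Screen trio sites for candidate de novo mutations
#'
#' Retains sites where the proband genotype contains the alternate allele and
#' both parental genotypes are homozygous reference. Sites with a missing
#' parental genotype are excluded: an unobserved parent cannot certify
#' absence of the allele. Proband homozygous-alternate candidates are kept
#' but flagged \code{implausible_hom} (two independent de novo events at one
#' site are essentially impossible; such calls are genotyping artifacts until
#' proven otherwise and the flag feeds the confidence ranking).
#'
#' @param x a \code{\link{TrioSites}} object.
#' @return A \code{TrioSites} holding only the candidate rows, with the extra
#'   logical column \code{implausible_hom}.
#' @export
candidateDnms <- function(x) {
  s <- siteData(x)
  keep <- s$pb_gt %in% c("het", "homalt") &
    s$fa_gt == "homref" & s$mo_gt == "homref"
  out <- s[keep, , drop = FALSE]
  out$implausible_hom <- out$pb_gt == "homalt"
  TrioSites(out, pedigree(x))
}

.altFrac <- function(alt, dp) ifelse(!is.na(dp) & dp > 0, alt / dp, NA_real_)

#' Apply the four de novo mutation filter criteria
#'
#' Evaluates each candidate against four independent criteria, all inclusive
#' at their boundary so the configured threshold values themselves pass:
#' \enumerate{
#'   \item \code{coverage}: read depth at least \code{minDepth} in proband
#'     and both parents (a parent with depth 0 is uninformative and fails
#'     here, never counted as evidence of absence);
#'   \item \code{genotype_quality}: GQ at least \code{minGQ} in all three
#'     members; a missing GQ fails (absence cannot certify a minimum);
#'   \item \code{proband_alt_fraction}: at least \code{minProbandAltFrac} of
#'     the proband's reads support the alternate allele;
#'   \item \code{parent_alt_fraction}: at most \code{maxParentAltFrac} of
#'     each parent's reads support the alternate allele (a zero-depth parent
#'     passes this criterion only when its alternate depth is zero).
#' }
#' Every failed criterion is recorded in \code{filter_failures};
#' \code{passed} is true iff the failure set is empty.
#'
#' @param x a \code{\link{TrioSites}} of candidates from
#'   \code{\link{candidateDnms}}.
#' @param param a \code{\link{DnmFilterParam}}.
#' @return A \code{\link{DnmCalls}} object with per-criterion logical columns
#'   \code{crit_coverage}, \code{crit_genotype_quality},
#'   \code{crit_proband_alt_fraction}, \code{crit_parent_alt_fraction}.
#' @export
applyDnmFilters <- function(x, param = DnmFilterParam()) {
  s <- siteData(x)
  dpOk <- function(dp) !is.na(dp) & dp >= param@minDepth
  gqOk <- function(gq) !is.na(gq) & gq >= param@minGQ
  n <- nrow(s)
  if (n == 0L) {
    s$crit_coverage <- s$crit_genotype_quality <- logical()
    s$crit_proband_alt_fraction <- s$crit_parent_alt_fraction <- logical()
    s$passed <- logical(); s$filter_failures <- character()
    s$pb_alt_frac <- numeric()
    return(DnmCalls(s, pedigree(x)))
  }
  c1 <- dpOk(s$pb_dp) & dpOk(s$fa_dp) & dpOk(s$mo_dp)
  c2 <- gqOk(s$pb_gq) & gqOk(s$fa_gq) & gqOk(s$mo_gq)
  pbFrac <- .altFrac(s$pb_alt_dp, s$pb_dp)
  c3 <- !is.na(pbFrac) & pbFrac >= param@minProbandAltFrac
  parentOk <- function(alt, dp) {
    frac <- .altFrac(alt, dp)
    zero <- !is.na(dp) & dp == 0L
    (!is.na(frac) & frac <= param@maxParentAltFrac) |
      (zero & !is.na(alt) & alt == 0L)
  }
  c4 <- parentOk(s$fa_alt_dp, s$fa_dp) & parentOk(s$mo_alt_dp, s$mo_dp)
  crit <- cbind(coverage = c1, genotype_quality = c2,
    proband_alt_fraction = c3, parent_alt_fraction = c4)
  s$crit_coverage <- c1
  s$crit_genotype_quality <- c2
  s$crit_proband_alt_fraction <- c3
  s$crit_parent_alt_fraction <- c4
  s$pb_alt_frac <- pbFrac
  s$filter_failures <- apply(crit, 1L, function(r)
    paste(colnames(crit)[!r], collapse = ","))
  s$passed <- !nzchar(s$filter_failures)
  DnmCalls(s, pedigree(x))
}

#' Phred-scaled strand-bias score
#'
#' Two-tailed exact test (hypergeometric, Fisher's construction) on the
#' 2x2 table of reference/alternate by forward/reverse read counts, returned
#' on the phred scale \eqn{-10 \log_{10} p}. 0 means no evidence of strand
#' bias; large values mean the alternate allele is confined to one strand.
#'
#' @param refFwd,refRev,altFwd,altRev read counts.
#' @return numeric vector of phred-scaled p-values (\code{NA} where any count
#'   is missing).
#' @export
strandBiasPhred <- function(refFwd, refRev, altFwd, altRev) {
  mapply(function(a, b, c, d) {
    if (any(is.na(c(a, b, c, d)))) return(NA_real_)
    p <- stats::fisher.test(matrix(c(a, b, c, d), 2L))$p.value
    -10 * log10(max(p, .Machine$double.xmin))
  }, refFwd, refRev, altFwd, altRev)
}

## 3x3 grid: rows = strand-bias level (0 good, 1 neutral/missing, 2 biased),
## columns = quality level. Worst strand bias alone forces rank >= 4.
.RANK_GRID <- matrix(c(
  1L, 2L, 3L,
  2L, 3L, 4L,
  4L, 4L, 5L), nrow = 3L, byrow = TRUE)

#' Assign five-level confidence ranks to passing DNM calls
#'
#' Deterministic rank from two axes. The quality axis scores the proband
#' genotype quality and alternate-allele fraction: level 0 when GQ is at
#' least \code{gqGood} and the fraction lies within \code{fracGood} (a clean
#' germline heterozygote), level 2 when GQ is below \code{gqPoor} or the
#' fraction falls outside \code{fracPoor} or the candidate was flagged
#' implausible-homozygous, level 1 otherwise. The default \code{fracPoor}
#' floor coincides with the proband-fraction filter threshold so that a
#' depressed-but-passing mosaic fraction does not by itself demote a call
#' out of the trusted ranks; tighten it only together with a widened filter
#' band. The strand axis phred-scales a
#' two-tailed exact test on the proband strand table
#' (\code{\link{strandBiasPhred}}): level 0 below \code{sbGood}, level 2 at
#' or above \code{sbPoor}, level 1 between or when strand counts are absent
#' (neutral). The two axes index a fixed grid giving ranks 1--5 (1 best);
#' severe strand bias alone forces rank 4 or worse.
#'
#' Ranks 1--2 are the trusted tier intended for direct validation. When a
#' trained \code{\link{RankModel}} is supplied, ranks 3--5 are re-evaluated:
#' a model probability of at least 0.5 promotes the call to rank 2.
#'
#' @param calls a \code{\link{DnmCalls}} from \code{\link{applyDnmFilters}}.
#' @param model optional \code{\link{RankModel}}.
#' @param gqGood,gqPoor,fracGood,fracPoor,sbGood,sbPoor axis cutoffs.
#' @return The \code{DnmCalls} with \code{confidence_rank} (NA for
#'   non-passing rows) and \code{strand_bias_phred} columns.
#' @export
assignConfidenceRank <- function(calls, model = NULL, gqGood = 50, gqPoor = 20,
                                 fracGood = c(0.30, 0.70),
                                 fracPoor = c(0.10, 0.90),
                                 sbGood = 10, sbPoor = 30) {
  cl <- callData(calls)
  n <- nrow(cl)
  frac <- .altFrac(cl$pb_alt_dp, cl$pb_dp)
  implausible <- if ("implausible_hom" %in% names(cl)) cl$implausible_hom
    else rep(FALSE, n)
  q <- rep(1L, n)
  q[cl$pb_gq >= gqGood & frac >= fracGood[1] & frac <= fracGood[2]] <- 0L
  q[cl$pb_gq < gqPoor | frac < fracPoor[1] | frac > fracPoor[2] | implausible] <- 2L

  if (all(.STRAND_COLS %in% names(cl)))
    sb <- strandBiasPhred(cl$pb_ref_fwd, cl$pb_ref_rev,
      cl$pb_alt_fwd, cl$pb_alt_rev)
  else sb <- rep(NA_real_, n)
  sLev <- rep(1L, n)
  sLev[!is.na(sb) & sb < sbGood] <- 0L
  sLev[!is.na(sb) & sb >= sbPoor] <- 2L

  rank <- .RANK_GRID[cbind(sLev + 1L, q + 1L)]
  if (!is.null(model) && any(cl$passed)) {
    reEval <- which(cl$passed & rank >= 3L)
    if (length(reEval)) {
      prob <- predictRankModel(model, cl[reEval, , drop = FALSE])
      rank[reEval][!is.na(prob) & prob >= 0.5] <- 2L
    }
  }
  cl$strand_bias_phred <- sb
  cl$confidence_rank <- ifelse(cl$passed, rank, NA_integer_)
  DnmCalls(cl, pedigree(calls))
}

#' Logistic re-evaluation model for low-confidence DNM calls
#'
#' A logistic regression trained on candidate calls with validated true/false
#' outcomes (e.g. orthogonal Sanger results), over four features of the
#' proband observation: genotype quality, alternate-allele fraction,
#' strand-bias phred score and read depth. Used by
#' \code{\link{assignConfidenceRank}} to promote rank 3--5 calls whose
#' predicted probability of being real is at least 0.5.
#'
#' @slot fit a fitted \code{glm} (binomial family).
#' @export
setClass("RankModel", slots = c(fit = "ANY"))

#' @rdname RankModel-class
#' @param calls a \code{\link{DnmCalls}} (or its data.frame) of training
#'   candidates.
#' @param labels logical vector, TRUE for validated real DNMs.
#' @return A \code{RankModel}.
#' @export
trainRankModel <- function(calls, labels) {
  df <- .rankFeatures(if (is(calls, "DnmCalls")) callData(calls) else calls)
  df$label <- as.logical(labels)
  fit <- stats::glm(label ~ gq + alt_frac + sb + dp, data = df,
    family = stats::binomial())
  new("RankModel", fit = fit)
}

.rankFeatures <- function(cl) {
  sb <- if (all(.STRAND_COLS %in% names(cl)))
    strandBiasPhred(cl$pb_ref_fwd, cl$pb_ref_rev, cl$pb_alt_fwd, cl$pb_alt_rev)
  else rep(NA_real_, nrow(cl))
  sb[is.na(sb)] <- 0
  data.frame(gq = cl$pb_gq, alt_frac = .altFrac(cl$pb_alt_dp, cl$pb_dp),
    sb = sb, dp = cl$pb_dp)
}

#' @rdname RankModel-class
#' @param model a \code{RankModel}.
#' @param newdata data.frame of candidate rows.
#' @return probabilities in [0, 1].
#' @export
predictRankModel <- function(model, newdata) {
  unname(stats::predict(model@fit, newdata = .rankFeatures(newdata),
    type = "response"))
}

#' Flag candidate post-zygotic mosaic mutations
#'
#' A passing call is flagged as mosaic when the proband alternate-allele
#' fraction lies in the half-open band \code{[band[1], band[2])}: a germline
#' heterozygote is expected near 0.5, while a depressed fraction indicates
#' the mutation arose post-zygotically and is present in only part of the
#' proband's cells. The upper bound is exclusive, so a fraction exactly at
#' \code{band[2]} is not flagged.
#'
#' @param calls a \code{\link{DnmCalls}}.
#' @param band numeric(2) fraction interval; defaults to the band of the
#'   supplied \code{param}.
#' @param param a \code{\link{DnmFilterParam}}.
#' @return The \code{DnmCalls} with a logical \code{mosaic} column.
#' @export
flagMosaic <- function(calls, band = NULL, param = DnmFilterParam()) {
  if (is.null(band)) band <- param@mosaicBand
  cl <- callData(calls)
  frac <- .altFrac(cl$pb_alt_dp, cl$pb_dp)
  cl$mosaic <- !is.na(frac) & frac >= band[1] & frac < band[2]
  DnmCalls(cl, pedigree(calls))
}

#' Classify raw consequence annotations into mutation classes
#'
#' Maps free-text consequence annotations onto the five classes used for
#' rate modelling: nonsense/stop-gain SNVs, frameshift indels and canonical
#' splice-site changes (exon +/- 2 bp) are loss-of-function (\code{LOF});
#' non-synonymous SNVs are \code{missense}; length-preserving coding indels
#' are \code{inframe_indel}; \code{synonymous} SNVs form their own class;
#' anything unrecognized becomes \code{other} with a warning.
#'
#' @param x character vector of raw annotation strings (e.g. "stopgain",
#'   "frameshift deletion", "splicing", "nonsynonymous SNV", "synonymous").
#' @return character vector over
#'   \code{c("LOF", "missense", "inframe_indel", "synonymous", "other")}.
#' @examples
#' classifyConsequence(c("Nonsense", "Non-frameshift", "Synonymous"))
#' @export
classifyConsequence <- function(x) {
  lx <- tolower(as.character(x))
  out <- rep(NA_character_, length(lx))
  out[grepl("stopgain|nonsense|stop_gained|stoploss", lx)] <- "LOF"
  isFs <- grepl("frameshift", lx) & !grepl("non[-_ ]?frameshift", lx)
  out[is.na(out) & isFs] <- "LOF"
  out[is.na(out) & grepl("splic", lx)] <- "LOF"
  out[is.na(out) & grepl("nonsynonymous|non[-_ ]synonymous|missense", lx)] <- "missense"
  out[is.na(out) & grepl("non[-_ ]?frameshift|inframe|in[-_ ]frame", lx)] <- "inframe_indel"
  out[is.na(out) & grepl("synonymous|silent", lx)] <- "synonymous"
  unknown <- is.na(out) & !is.na(x)
  if (any(unknown))
    warning(sprintf("unrecognized consequence annotation(s): %s",
      paste(unique(x[unknown]), collapse = ", ")), call. = FALSE)
  out[unknown] <- "other"
  out
}

#' Loss-of-function subtype of a raw consequence annotation
#'
#' @param x character vector of raw annotations.
#' @return \code{"nonsense"}, \code{"frameshift"}, \code{"splicing"} or
#'   \code{NA} for non-LOF annotations.
#' @export
lofSubtype <- function(x) {
  lx <- tolower(as.character(x))
  out <- rep(NA_character_, length(lx))
  out[grepl("stopgain|nonsense|stop_gained|stoploss", lx)] <- "nonsense"
  isFs <- grepl("frameshift", lx) & !grepl("non[-_ ]?frameshift", lx)
  out[is.na(out) & isFs] <- "frameshift"
  out[is.na(out) & grepl("splic", lx)] <- "splicing"
  out
}

#' Rare-variant filter over population allele frequencies
#'
#' A variant is retained iff no population database reports a minor allele
#' frequency above the threshold. Missing frequencies count as rare: absence
#' from every database is itself evidence of rarity.
#'
#' @param af data.frame or matrix of allele-frequency columns (one column per
#'   database; NA = no data), or a numeric vector for a single variant.
#' @param threshold maximum tolerated frequency (default 0.01).
#' @return logical vector, TRUE = rare (retained).
#' @examples
#' filterRare(data.frame(af_exac = c(2.8e-3, 0.02, NA)))
#' @export
filterRare <- function(af, threshold = 0.01) {
  if (is.null(dim(af))) af <- matrix(as.numeric(af), nrow = 1L)
  af <- as.matrix(af)
  if (ncol(af) == 0L) return(rep(TRUE, nrow(af)))
  apply(af, 1L, function(r) !any(!is.na(r) & r > threshold))
}

#' Run the full DNM detection stage
#'
#' Convenience wrapper chaining \code{\link{candidateDnms}},
#' \code{\link{applyDnmFilters}}, \code{\link{assignConfidenceRank}},
#' \code{\link{flagMosaic}}, \code{\link{classifyConsequence}} and
#' \code{\link{filterRare}}.
#'
#' @param x a \code{\link{TrioSites}}.
#' @param param a \code{\link{DnmFilterParam}}.
#' @param model optional \code{\link{RankModel}}.
#' @return A \code{\link{DnmCalls}} with all annotation columns; the
#'   \code{validated} column marks passing, rare calls in the trusted ranks
#'   (1--2).
#' @export
callDnms <- function(x, param = DnmFilterParam(), model = NULL) {
  calls <- applyDnmFilters(candidateDnms(x), param)
  calls <- assignConfidenceRank(calls, model = model)
  calls <- flagMosaic(calls, param = param)
  cl <- callData(calls)
  cl$class <- classifyConsequence(cl$consequence)
  afCols <- grep("^af_", names(cl), value = TRUE)
  cl$rare <- if (length(afCols))
    filterRare(cl[, afCols, drop = FALSE], param@mafThreshold)
  else rep(TRUE, nrow(cl))
  cl$validated <- cl$passed & cl$rare &
    !is.na(cl$confidence_rank) & cl$confidence_rank <= 2L
  DnmCalls(cl, pedigree(calls))
}
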