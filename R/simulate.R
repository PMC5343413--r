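## Seeded generators for every input the pipeline consumes: trio cohorts
## with planted de novo mutations, case/control genotype matrices with
## configurable gene enrichment, and SNP-array probe tracks with planted
## CNV/ROH segments. The exome is abstracted as (gene, site) slots with
## synthetic gene symbols; no real genomic sequence is used.

#' Trio cohort simulation parameters
#'
#' Defaults emulate a 24-trio exome study: DNMs arise at a Poisson mean of
#' 1.2 per proband per generation, 6.5\% of them post-zygotic mosaics with
#' depressed allele fractions; mean coverage 46x with per-sample means spread
#' over roughly 18--74x; inherited variation segregates at Hardy-Weinberg
#' proportions from a Beta-distributed population allele-frequency law.
#'
#' @slot nTrios integer number of trios.
#' @slot dnmRate numeric, mean planted DNMs per proband.
#' @slot nInheritedSites integer inherited (Mendelian) site slots per trio.
#' @slot mafShape numeric(2), Beta shape parameters of the population
#'   allele-frequency law.
#' @slot mafRange numeric(2), truncation interval for sampled frequencies.
#' @slot meanDepth numeric, cohort mean sequencing depth.
#' @slot sampleDepthSd numeric, between-sample SD of per-sample mean depth
#'   (per-sample means are truncated to [18, 74]).
#' @slot depthDispersion numeric, negative-binomial size for per-site depth
#'   around the sample mean.
#' @slot mosaicProb numeric, probability a planted DNM is mosaic.
#' @slot mosaicRange numeric(2), uniform range of mosaic allele fractions.
#' @slot genotypingError numeric, per-genotype probability that the written
#'   genotype call is replaced by a different one.
#' @slot baseError numeric, per-read base error used both to sample
#'   alternate reads on homozygous genotypes and in the genotype-likelihood
#'   model behind GQ.
#' @slot nGenes integer size of the synthetic gene universe.
#' @slot seed integer RNG seed; identical seed and parameters give
#'   byte-identical outputs.
#' @export
setClass("TrioSimParam",
  slots = c(nTrios = "integer", dnmRate = "numeric",
    nInheritedSites = "integer", mafShape = "numeric", mafRange = "numeric",
    meanDepth = "numeric", sampleDepthSd = "numeric",
    depthDispersion = "numeric", mosaicProb = "numeric",
    mosaicRange = "numeric", genotypingError = "numeric",
    baseError = "numeric", nGenes = "integer", seed = "integer"))

setValidity("TrioSimParam", function(object) {
  msg <- character()
  pr <- c(object@mosaicProb, object@genotypingError, object@baseError)
  if (any(pr < 0 | pr > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
  if (object@meanDepth < 1) msg <- c(msg, "meanDepth must be >= 1")
  if (object@nTrios < 1L) msg <- c(msg, "nTrios must be >= 1")
  if (object@dnmRate < 0) msg <- c(msg, "dnmRate must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname TrioSimParam-class
#' @param nTrios,dnmRate,nInheritedSites,mafShape,mafRange,meanDepth,sampleDepthSd,depthDispersion,mosaicProb,mosaicRange,genotypingError,baseError,nGenes,seed
#'   see slot documentation.
#' @return A \code{TrioSimParam}.
#' @export
TrioSimParam <- function(nTrios = 24L, dnmRate = 1.2, nInheritedSites = 500L,
                         mafShape = c(0.2, 2), mafRange = c(1e-4, 0.5),
                         meanDepth = 46, sampleDepthSd = 8,
                         depthDispersion = 20, mosaicProb = 0.065,
                         mosaicRange = c(0.08, 0.30),
                         genotypingError = 0.001, baseError = 0.005,
                         nGenes = 150L, seed = 1L) {
  new("TrioSimParam", nTrios = as.integer(nTrios), dnmRate = dnmRate,
    nInheritedSites = as.integer(nInheritedSites), mafShape = mafShape,
    mafRange = mafRange, meanDepth = meanDepth,
    sampleDepthSd = sampleDepthSd, depthDispersion = depthDispersion,
    mosaicProb = mosaicProb, mosaicRange = mosaicRange,
    genotypingError = genotypingError, baseError = baseError,
    nGenes = as.integer(nGenes), seed = as.integer(seed))
}

.CONSEQ_POOL <- c("nonsynonymous SNV", "synonymous SNV", "stopgain",
  "frameshift deletion", "splicing", "nonframeshift deletion")
.CONSEQ_PROBS <- c(0.50, 0.28, 0.05, 0.07, 0.04, 0.06)

## genotype-likelihood GQ: phred difference between the two most likely of
## {homref, het, homalt} under a binomial read model with fixed base error
.gqFromReads <- function(dp, alt, baseError) {
  p <- c(baseError, 0.5, 1 - baseError)
  l1 <- alt * log(p[1]) + (dp - alt) * log(1 - p[1])
  l2 <- alt * log(p[2]) + (dp - alt) * log(1 - p[2])
  l3 <- alt * log(p[3]) + (dp - alt) * log(1 - p[3])
  top <- pmax(l1, l2, l3)
  second <- pmax(pmin(pmax(l1, l2), pmax(l2, l3), pmax(l1, l3)))
  gq <- 10 / log(10) * (top - second)
  out <- pmin(round(gq), 99)
  out[dp == 0L] <- 0
  out
}

.truncNorm <- function(n, mean, sd, lo, hi) pmin(pmax(rnorm(n, mean, sd), lo), hi)

## sample reads for a vector of true genotypes (0/1/2 alt alleles) and true
## alt fractions; returns dp, alt_dp, gq and the called genotype code
.sampleMember <- function(gCount, trueF, meanDp, param) {
  n <- length(gCount)
  dp <- rnbinom(n, size = param@depthDispersion, mu = meanDp)
  alt <- rbinom(n, dp, trueF)
  gq <- .gqFromReads(dp, alt, param@baseError)
  gt <- c("homref", "het", "homalt")[gCount + 1L]
  flip <- runif(n) < param@genotypingError
  if (any(flip)) {
    others <- lapply(gCount[flip], function(g) setdiff(0:2, g))
    gt[flip] <- c("homref", "het", "homalt")[
      vapply(others, function(o) sample(o, 1L), integer(1)) + 1L]
  }
  list(dp = as.integer(dp), alt = as.integer(alt), gq = as.numeric(gq), gt = gt)
}

#' Simulate an exome trio cohort with planted de novo mutations
#'
#' Generates, per trio: inherited sites with parental genotypes drawn at
#' Hardy-Weinberg proportions from sampled population frequencies and the
#' child by Mendelian transmission; a Poisson number of de novo mutations
#' planted as child-het / parents-homozygous-reference, each mosaic with
#' probability \code{mosaicProb} (alternate fraction uniform over
#' \code{mosaicRange}, otherwise 0.5). Read depth is negative-binomial
#' around a per-sample mean, alternate reads binomial at the true fraction
#' (homozygous genotypes see alternate reads at the base-error rate), GQ
#' comes from a three-genotype binomial likelihood model, and genotype calls
#' are corrupted at the configured error rate. Population frequencies are
#' exported as \code{af_popdb} annotation (de novo sites are absent from the
#' database, i.e. NA).
#'
#' @param param a \code{\link{TrioSimParam}}.
#' @param dir optional directory; when given, per-trio VCFs, a cohort PED,
#'   an annotation TSV and the truth TSV are written there.
#' @return list with \code{sites} (a \code{\link{TrioSites}} over all
#'   trios), \code{pedigree}, and \code{truth} (one row per planted DNM:
#'   trio, chrom, pos, gene, consequence, mosaic, true alternate fraction).
#' @export
simulateTrioCohort <- function(param = TrioSimParam(), dir = NULL) {
  set.seed(param@seed)
  nT <- param@nTrios
  trios <- sprintf("T%02d", seq_len(nT))

  ## shared site universe
  nS <- param@nInheritedSites
  genes <- sprintf("G%04d", seq_len(param@nGenes))
  geneChrom <- as.character(sample(1:22, param@nGenes, replace = TRUE))
  siteGene <- sample(seq_len(param@nGenes), nS, replace = TRUE)
  sitePos <- sort(sample.int(5e7, nS + 200L * nT))  # pool, DNMs draw later
  bases <- c("A", "C", "G", "T")
  maf <- pmin(pmax(rbeta(nS, param@mafShape[1], param@mafShape[2]),
    param@mafRange[1]), param@mafRange[2])
  siteConseq <- sample(.CONSEQ_POOL, nS, replace = TRUE, prob = .CONSEQ_PROBS)
  siteRef <- sample(bases, nS, replace = TRUE)
  siteAlt <- vapply(siteRef, function(r) sample(setdiff(bases, r), 1L),
    character(1))

  ## per-sample mean depths (3 members per trio)
  mDepth <- matrix(.truncNorm(3L * nT, param@meanDepth, param@sampleDepthSd,
    18, 74), nrow = nT)

  allRows <- vector("list", nT)
  truthRows <- vector("list", nT)
  posCursor <- nS
  for (t in seq_len(nT)) {
    ## inherited genotypes
    faG <- rbinom(nS, 2L, maf)
    moG <- rbinom(nS, 2L, maf)
    childG <- rbinom(nS, 1L, faG / 2) + rbinom(nS, 1L, moG / 2)

    ## planted DNMs at fresh loci
    nD <- rpois(1L, param@dnmRate)
    dnmGene <- if (nD) sample(seq_len(param@nGenes), nD, replace = TRUE) else integer()
    dnmPos <- if (nD) sitePos[posCursor + seq_len(nD)] else integer()
    posCursor <- posCursor + nD
    dnmMosaic <- if (nD) runif(nD) < param@mosaicProb else logical()
    dnmF <- ifelse(dnmMosaic,
      runif(nD, param@mosaicRange[1], param@mosaicRange[2]), 0.5)
    dnmConseq <- sample(.CONSEQ_POOL, nD, replace = TRUE, prob = .CONSEQ_PROBS)
    dnmRef <- sample(bases, nD, replace = TRUE)
    dnmAlt <- vapply(dnmRef, function(r) sample(setdiff(bases, r), 1L),
      character(1))

    gAll <- list(
      pb = c(childG, rep(1L, nD)),
      fa = c(faG, rep(0L, nD)),
      mo = c(moG, rep(0L, nD)))
    eps <- param@baseError
    fOf <- function(g) c(eps, 0.5, 1 - eps)[g + 1L]
    fPb <- c(fOf(childG), dnmF)

    df <- data.frame(
      trio = trios[t],
      chrom = c(geneChrom[siteGene], geneChrom[dnmGene]),
      pos = c(sitePos[seq_len(nS)], dnmPos),
      ref = c(siteRef, dnmRef), alt = c(siteAlt, dnmAlt),
      gene = c(genes[siteGene], genes[dnmGene]),
      consequence = c(siteConseq, dnmConseq),
      af_popdb = c(maf, rep(NA_real_, nD)),
      is_dnm = c(rep(FALSE, nS), rep(TRUE, nD)),
      stringsAsFactors = FALSE)

    for (m in c("pb", "fa", "mo")) {
      mi <- match(m, c("pb", "fa", "mo"))
      trueF <- if (m == "pb") fPb else fOf(gAll[[m]])
      obs <- .sampleMember(gAll[[m]], trueF, mDepth[t, mi], param)
      df[[paste0(m, "_gt")]] <- obs$gt
      df[[paste0(m, "_dp")]] <- obs$dp
      df[[paste0(m, "_alt_dp")]] <- obs$alt
      df[[paste0(m, "_gq")]] <- obs$gq
    }
    ## proband strand counts
    refDp <- df$pb_dp - df$pb_alt_dp
    df$pb_ref_fwd <- rbinom(nrow(df), refDp, 0.5)
    df$pb_ref_rev <- refDp - df$pb_ref_fwd
    df$pb_alt_fwd <- rbinom(nrow(df), df$pb_alt_dp, 0.5)
    df$pb_alt_rev <- df$pb_alt_dp - df$pb_alt_fwd

    allRows[[t]] <- df
    truthRows[[t]] <- if (nD) data.frame(trio = trios[t],
      chrom = geneChrom[dnmGene], pos = dnmPos, gene = genes[dnmGene],
      consequence = dnmConseq, mosaic = dnmMosaic, true_alt_frac = dnmF,
      stringsAsFactors = FALSE)
    else NULL
  }
  sites <- do.call(rbind, allRows)
  sites <- sites[order(sites$trio, sites$chrom, sites$pos), ]
  truth <- do.call(rbind, truthRows)
  if (is.null(truth))
    truth <- data.frame(trio = character(), chrom = character(),
      pos = integer(), gene = character(), consequence = character(),
      mosaic = logical(), true_alt_frac = numeric())
  ped <- data.frame(family = sub("^T", "F", trios), trio = trios,
    father = paste0(trios, "_fa"), mother = paste0(trios, "_mo"),
    sex = rep(c("female", "male"), length.out = nT),
    phenotype = "affected", stringsAsFactors = FALSE)
  out <- list(sites = TrioSites(sites, ped), pedigree = ped, truth = truth)
  if (!is.null(dir)) .writeCohortFiles(out, dir)
  out
}

## plain-text VCF emitter for one trio (reading is done by VariantAnnotation)
.writeTrioVcf <- function(df, samples, path) {
  hdr <- c("##fileformat=VCFv4.2",
    "##source=trioDNM-simulator",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=ADF,Number=R,Type=Integer,Description=\"Forward allelic depths\">",
    "##FORMAT=<ID=ADR,Number=R,Type=Integer,Description=\"Reverse allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", samples), collapse = "\t"))
  gtStr <- c(homref = "0/0", het = "0/1", homalt = "1/1", missing = "./.")
  fmt <- function(p) {
    gt <- gtStr[df[[paste0(p, "_gt")]]]
    dp <- df[[paste0(p, "_dp")]]
    ad <- paste(dp - df[[paste0(p, "_alt_dp")]], df[[paste0(p, "_alt_dp")]],
      sep = ",")
    gq <- df[[paste0(p, "_gq")]]
    base <- paste(gt, dp, ad, gq, sep = ":")
    if (p == "pb")
      paste(base,
        paste(df$pb_ref_fwd, df$pb_alt_fwd, sep = ","),
        paste(df$pb_ref_rev, df$pb_alt_rev, sep = ","), sep = ":")
    else paste(base, ".", ".", sep = ":")
  }
  lines <- paste(df$chrom, df$pos, ".", df$ref, df$alt, ".", ".", ".",
    "GT:DP:AD:GQ:ADF:ADR", fmt("pb"), fmt("fa"), fmt("mo"), sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

.writeCohortFiles <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- siteData(cohort$sites)
  ped <- cohort$pedigree
  for (i in seq_len(nrow(ped))) {
    tr <- ped$trio[i]
    sub <- s[s$trio == tr, , drop = FALSE]
    sub <- sub[order(as.integer(sub$chrom), sub$pos), ]
    .writeTrioVcf(sub, c(tr, ped$father[i], ped$mother[i]),
      file.path(dir, paste0(tr, ".vcf")))
  }
  pedOut <- data.frame(ped$family,
    c(ped$trio, ped$father, ped$mother),
    c(ped$father, rep("0", nrow(ped) * 2L)),
    c(ped$mother, rep("0", nrow(ped) * 2L)),
    c(ifelse(ped$sex == "female", 2L, 1L), rep(1L, nrow(ped)),
      rep(2L, nrow(ped))),
    c(rep(2L, nrow(ped)), rep(1L, nrow(ped) * 2L)))
  write.table(pedOut, file.path(dir, "cohort.ped"), sep = " ",
    quote = FALSE, row.names = FALSE, col.names = FALSE)
  anno <- unique(s[, c("chrom", "pos", "ref", "alt", "gene", "consequence",
    "af_popdb")])
  write.table(anno, file.path(dir, "annotation.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Case/control burden simulation parameters
#'
#' @slot nCases,nControls integer cohort sizes.
#' @slot nGenes,variantsPerGene integer gene universe.
#' @slot baselineCarrierP numeric per-variant carrier probability.
#' @slot enrichedGenes named numeric vector of case carrier odds multipliers
#'   (names must be genes of the universe).
#' @slot seed integer RNG seed.
#' @export
setClass("BurdenSimParam",
  slots = c(nCases = "integer", nControls = "integer", nGenes = "integer",
    variantsPerGene = "integer", baselineCarrierP = "numeric",
    enrichedGenes = "numeric", seed = "integer"))

setValidity("BurdenSimParam", function(object) {
  msg <- character()
  if (object@nCases < 1L || object@nControls < 1L)
    msg <- c(msg, "both cohorts must be non-empty")
  if (object@baselineCarrierP <= 0 || object@baselineCarrierP >= 1)
    msg <- c(msg, "baselineCarrierP must lie in (0, 1)")
  genes <- sprintf("BG%03d", seq_len(object@nGenes))
  if (length(object@enrichedGenes) &&
      !all(names(object@enrichedGenes) %in% genes))
    msg <- c(msg, "enriched genes must belong to the simulated gene set")
  if (length(msg)) msg else TRUE
})

#' @rdname BurdenSimParam-class
#' @param nCases,nControls,nGenes,variantsPerGene,baselineCarrierP,enrichedGenes,seed
#'   see slot documentation.
#' @return A \code{BurdenSimParam}.
#' @export
BurdenSimParam <- function(nCases = 48L, nControls = 212L, nGenes = 20L,
                           variantsPerGene = 5L, baselineCarrierP = 0.03,
                           enrichedGenes = numeric(), seed = 1L) {
  new("BurdenSimParam", nCases = as.integer(nCases),
    nControls = as.integer(nControls), nGenes = as.integer(nGenes),
    variantsPerGene = as.integer(variantsPerGene),
    baselineCarrierP = baselineCarrierP, enrichedGenes = enrichedGenes,
    seed = as.integer(seed))
}

#' Simulate a case/control rare-variant genotype matrix
#'
#' Each sample's carrier status at each variant is Bernoulli with the
#' baseline probability; for genes listed in \code{enrichedGenes}, the case
#' carrier odds are multiplied by the gene's factor. Gene symbols are
#' synthetic (\code{BG001}, ...).
#'
#' @param param a \code{\link{BurdenSimParam}}.
#' @return list with \code{dosage} (samples x variants 0/1 matrix),
#'   \code{variantGenes}, \code{status} (logical, TRUE = case) and
#'   \code{truth} (the enriched-gene multipliers).
#' @export
simulateCaseControl <- function(param = BurdenSimParam()) {
  set.seed(param@seed)
  genes <- sprintf("BG%03d", seq_len(param@nGenes))
  variantGenes <- rep(genes, each = param@variantsPerGene)
  nV <- length(variantGenes)
  nS <- param@nCases + param@nControls
  status <- rep(c(TRUE, FALSE), c(param@nCases, param@nControls))
  p0 <- param@baselineCarrierP
  pCase <- rep(p0, nV)
  if (length(param@enrichedGenes)) {
    idx <- variantGenes %in% names(param@enrichedGenes)
    mult <- param@enrichedGenes[variantGenes[idx]]
    odds <- mult * p0 / (1 - p0)
    pCase[idx] <- odds / (1 + odds)
  }
  pMat <- matrix(rep(p0, nS * nV), nrow = nS)
  pMat[status, ] <- matrix(rep(pCase, each = param@nCases), nrow = param@nCases)
  dosage <- matrix(rbinom(nS * nV, 1L, as.vector(pMat)), nrow = nS)
  colnames(dosage) <- sprintf("%s_v%d", variantGenes,
    sequence(rep(param@variantsPerGene, param@nGenes)))
  rownames(dosage) <- sprintf("S%04d", seq_len(nS))
  list(dosage = dosage, variantGenes = variantGenes, status = status,
    truth = param@enrichedGenes)
}

#' SNP-array track simulation parameters
#'
#' @slot nProbes integer probes on the simulated chromosome.
#' @slot probeSpacingBp integer distance between adjacent probes.
#' @slot lrrNoiseSd numeric SD of the log R ratio noise.
#' @slot bafNoiseSd numeric SD of B-allele frequency noise.
#' @slot chrom character chromosome label.
#' @slot plantedSegments data.frame with \code{kind} (loss/gain/roh),
#'   \code{start}, \code{end} (1-based closed, bp) and \code{meanLrr}
#'   (ignored for roh); segments must not overlap.
#' @slot seed integer RNG seed.
#' @export
setClass("ArraySimParam",
  slots = c(nProbes = "integer", probeSpacingBp = "integer",
    lrrNoiseSd = "numeric", bafNoiseSd = "numeric", chrom = "character",
    plantedSegments = "data.frame", seed = "integer"))

setValidity("ArraySimParam", function(object) {
  msg <- character()
  if (object@probeSpacingBp <= 0L) msg <- c(msg, "probe spacing must be positive")
  seg <- object@plantedSegments
  if (nrow(seg)) {
    if (!all(c("kind", "start", "end") %in% names(seg)))
      msg <- c(msg, "plantedSegments needs kind/start/end columns")
    else {
      o <- order(seg$start)
      if (any(seg$end[o][-nrow(seg)] >= seg$start[o][-1]))
        msg <- c(msg, "planted segments must not overlap")
      if (any(seg$end > object@nProbes * object@probeSpacingBp))
        msg <- c(msg, "planted segments must lie within the track")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname ArraySimParam-class
#' @param nProbes,probeSpacingBp,lrrNoiseSd,bafNoiseSd,chrom,plantedSegments,seed
#'   see slot documentation.
#' @return An \code{ArraySimParam}.
#' @export
ArraySimParam <- function(nProbes = 400L, probeSpacingBp = 20000L,
                          lrrNoiseSd = 0.15, bafNoiseSd = 0.03, chrom = "1",
                          plantedSegments = data.frame(kind = character(),
                            start = integer(), end = integer(),
                            meanLrr = numeric()), seed = 1L) {
  new("ArraySimParam", nProbes = as.integer(nProbes),
    probeSpacingBp = as.integer(probeSpacingBp), lrrNoiseSd = lrrNoiseSd,
    bafNoiseSd = bafNoiseSd, chrom = chrom,
    plantedSegments = plantedSegments, seed = as.integer(seed))
}

#' Simulate a probe-level SNP-array track with planted segments
#'
#' Baseline log R ratio is Gaussian noise around zero; planted loss/gain
#' segments shift the mean to their \code{meanLrr}. Probe genotypes follow
#' Hardy-Weinberg at uniform(0.2, 0.5) allele frequencies, with noisy BAF
#' around 0, 0.5 and 1; inside loss segments heterozygous probes lose one
#' allele (loss of heterozygosity) and inside ROH segments all probes are
#' homozygous.
#'
#' @param param an \code{\link{ArraySimParam}}.
#' @return list with \code{track} (data.frame chrom/pos/lrr/baf/gt) and
#'   \code{truth} (GRanges of planted segments).
#' @export
simulateProbeTrack <- function(param = ArraySimParam()) {
  set.seed(param@seed)
  validObject(param)
  n <- param@nProbes
  pos <- param@probeSpacingBp * seq_len(n)
  lrr <- rnorm(n, 0, param@lrrNoiseSd)
  maf <- runif(n, 0.2, 0.5)
  g <- rbinom(n, 2L, maf)  # B-allele count
  seg <- param@plantedSegments
  for (i in seq_len(nrow(seg))) {
    idx <- which(pos >= seg$start[i] & pos <= seg$end[i])
    kind <- seg$kind[i]
    if (kind %in% c("loss", "gain")) lrr[idx] <- lrr[idx] + seg$meanLrr[i]
    if (kind == "loss" || kind == "roh")
      g[idx] <- ifelse(g[idx] == 1L, 2L * rbinom(length(idx), 1L, 0.5), g[idx])
  }
  baf <- pmin(pmax(c(0, 0.5, 1)[g + 1L] + rnorm(n, 0, param@bafNoiseSd), 0), 1)
  track <- data.frame(chrom = param@chrom, pos = pos, lrr = lrr, baf = baf,
    gt = c("AA", "AB", "BB")[g + 1L], stringsAsFactors = FALSE)
  truth <- if (nrow(seg)) GenomicRanges::GRanges(param@chrom,
    IRanges::IRanges(seg$start, seg$end), kind = seg$kind)
  else GenomicRanges::GRanges()
  list(track = track, truth = truth)
}
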