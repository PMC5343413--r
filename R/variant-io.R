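## Reading the standard formats into the internal trio data model.
## Coordinates are 1-based fully closed throughout, as in VCF.

#' Read a 6-column PED pedigree file
#'
#' Parses a whitespace-delimited PED file (family, individual, father, mother,
#' sex, phenotype) and returns one row per complete trio, i.e. per offspring
#' whose father and mother ids are both non-missing. Offspring with a single
#' listed parent (duos) are skipped with a warning: the trio design requires
#' both parental genotypes to certify a de novo event.
#'
#' @param path path to a PED file.
#' @return data.frame with columns \code{family}, \code{trio} (the proband
#'   id), \code{father}, \code{mother}, \code{sex} (\code{male}/\code{female}/
#'   \code{unknown}) and \code{phenotype} (the raw column-6 label).
#' @examples
#' ped <- tempfile(fileext = ".ped")
#' writeLines(c("FAM1 DAD 0 0 1 1", "FAM1 MOM 0 0 2 1",
#'              "FAM1 CHILD DAD MOM 2 2"), ped)
#' readPedigree(ped)
#' @export
readPedigree <- function(path) {
  ped <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
    col.names = c("family", "id", "father", "mother", "sex", "phenotype"),
    colClasses = c(rep("character", 4), "character", "character"))
  isMissing <- function(x) x %in% c("0", ".", "", NA)
  offspring <- !isMissing(ped$father) | !isMissing(ped$mother)
  out <- list()
  for (i in which(offspring)) {
    row <- ped[i, ]
    if (isMissing(row$father) || isMissing(row$mother)) {
      warning(sprintf("offspring '%s' has only one listed parent; duo skipped",
        row$id), call. = FALSE)
      next
    }
    ids <- c(row$id, row$father, row$mother)
    if (anyDuplicated(ids))
      stop(sprintf("pedigree for '%s' does not name three distinct samples", row$id))
    out[[length(out) + 1L]] <- data.frame(
      family = row$family, trio = row$id, father = row$father,
      mother = row$mother,
      sex = c("1" = "male", "2" = "female")[row$sex],
      phenotype = row$phenotype, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(family = character(), trio = character(), father = character(),
      mother = character(), sex = character(), phenotype = character())
  res$sex[is.na(res$sex)] <- "unknown"
  rownames(res) <- NULL
  res
}

## map a VCF GT string onto this row's alternate allele index (1-based among
## ALTs): alleles equal to altIndex count as alt, anything else as ref,
## any missing allele makes the whole genotype missing.
.gtForAlt <- function(gt, altIndex) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("missing")
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return("missing")
  nAlt <- sum(alleles == as.character(altIndex))
  c("homref", "het", "homalt")[nAlt + 1L]
}

.adEntry <- function(ad, k) {
  if (is.null(ad) || length(ad) < k || all(is.na(ad))) return(NA_integer_)
  as.integer(ad[[k]])
}

#' Read a multi-sample trio VCF into a TrioSites object
#'
#' Reads a VCF containing the three samples of one trio (via
#' \code{VariantAnnotation::readVcf}) and maps every biallelic alternate
#' allele to one row. Multiallelic records are decomposed into one row per
#' alternate allele, with the alternate-supporting depth taken from the
#' corresponding AD entry; reads supporting other alternate alleles still
#' count toward total depth, and genotype codes are expressed relative to the
#' row's own alternate. Records where all three genotypes are missing are
#' dropped (the number dropped is reported in the \code{"dropped"} attribute).
#' Sites on non-numeric chromosomes (X, Y, MT) are retained and flagged
#' \code{non_autosomal}; no ploidy-aware handling is applied.
#'
#' Missing genotype quality is stored as \code{NA} and later treated as
#' failing the quality criterion: absence of a score cannot certify a minimum.
#'
#' @param path path to a VCF (plain text or bgzipped).
#' @param pedigree one-row data.frame as returned by
#'   \code{\link{readPedigree}} (or a list with \code{trio}, \code{father},
#'   \code{mother}).
#' @param annotation optional data.frame keyed by
#'   \code{chrom,pos,ref,alt} with extra columns \code{gene},
#'   \code{consequence} and \code{af_*} population frequencies; merged onto
#'   the sites (see \code{\link{annotateSites}}).
#' @return A \code{\link{TrioSites}} object.
#' @export
readTrioVcf <- function(path, pedigree, annotation = NULL) {
  pedRow <- as.data.frame(pedigree, stringsAsFactors = FALSE)[1, , drop = FALSE]
  vcf <- VariantAnnotation::readVcf(path)
  samples <- colnames(vcf)
  members <- c(proband = pedRow$trio, father = pedRow$father, mother = pedRow$mother)
  absent <- members[!members %in% samples]
  if (length(absent))
    stop(sprintf("pedigree sample(s) not in VCF header: %s",
      paste(absent, collapse = ", ")))

  gtM <- VariantAnnotation::geno(vcf)$GT
  g <- VariantAnnotation::geno(vcf)
  dpM <- if ("DP" %in% names(g)) g$DP else NULL
  adM <- if ("AD" %in% names(g)) g$AD else NULL
  gqM <- if ("GQ" %in% names(g)) g$GQ else NULL
  adfM <- if ("ADF" %in% names(g)) g$ADF else NULL
  adrM <- if ("ADR" %in% names(g)) g$ADR else NULL

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  altList <- VariantAnnotation::alt(vcf)

  pre <- c(proband = "pb", father = "fa", mother = "mo")
  rows <- vector("list", length(vcf) * 2L)
  nr <- 0L
  dropped <- 0L
  for (i in seq_along(vcf)) {
    alts <- as.character(altList[[i]])
    alts <- alts[alts != ""]
    gts <- gtM[i, members]
    names(gts) <- names(members)
    for (k in seq_along(alts)) {
      perAlt <- vapply(gts, .gtForAlt, character(1), altIndex = k)
      if (all(perAlt == "missing")) { dropped <- dropped + 1L; next }
      row <- list(trio = unname(members[["proband"]]), chrom = chrom[i],
        pos = pos[i], ref = refs[i], alt = alts[k],
        gene = NA_character_, consequence = NA_character_)
      for (m in names(members)) {
        p <- pre[[m]]; s <- members[[m]]
        ad <- if (!is.null(adM)) adM[[i, s]] else NULL
        dp <- if (!is.null(dpM)) dpM[i, s] else NA_integer_
        if (is.na(dp) && !is.null(ad) && !all(is.na(ad)))
          dp <- as.integer(sum(ad, na.rm = TRUE))
        row[[paste0(p, "_gt")]] <- perAlt[[m]]
        row[[paste0(p, "_dp")]] <- as.integer(dp)
        row[[paste0(p, "_alt_dp")]] <- .adEntry(ad, k + 1L)
        row[[paste0(p, "_gq")]] <- if (!is.null(gqM)) as.numeric(gqM[i, s]) else NA_real_
      }
      if (!is.null(adfM) && !is.null(adrM)) {
        adf <- adfM[[i, members[["proband"]]]]
        adr <- adrM[[i, members[["proband"]]]]
        row$pb_ref_fwd <- .adEntry(adf, 1L); row$pb_ref_rev <- .adEntry(adr, 1L)
        row$pb_alt_fwd <- .adEntry(adf, k + 1L); row$pb_alt_rev <- .adEntry(adr, k + 1L)
      }
      nr <- nr + 1L
      rows[[nr]] <- row
    }
  }
  sites <- if (nr) do.call(rbind, lapply(rows[seq_len(nr)], function(r)
    as.data.frame(r, stringsAsFactors = FALSE))) else .emptySites()
  out <- TrioSites(sites, pedRow)
  if (!is.null(annotation)) out <- annotateSites(out, annotation)
  attr(out, "dropped") <- dropped
  out
}

.emptySites <- function() {
  df <- data.frame(trio = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), gene = character(),
    consequence = character(), stringsAsFactors = FALSE)
  for (p in c("pb", "fa", "mo")) {
    df[[paste0(p, "_gt")]] <- character()
    df[[paste0(p, "_dp")]] <- integer()
    df[[paste0(p, "_alt_dp")]] <- integer()
    df[[paste0(p, "_gq")]] <- numeric()
  }
  df
}

#' Attach gene, consequence and population-frequency annotations
#'
#' Left-joins an annotation table onto the sites of a \code{TrioSites} object
#' by \code{chrom}, \code{pos}, \code{ref}, \code{alt}. The annotation table
#' supplies \code{gene}, \code{consequence} and any number of \code{af_*}
#' allele-frequency columns (values in [0, 1], NA for "no data").
#'
#' @param x a \code{TrioSites} object.
#' @param annotation data.frame as described above.
#' @return The annotated \code{TrioSites}.
#' @export
annotateSites <- function(x, annotation) {
  s <- siteData(x)
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  idx <- match(key(s), key(annotation))
  for (col in setdiff(names(annotation), c("chrom", "pos", "ref", "alt"))) {
    vals <- annotation[[col]][idx]
    if (col %in% c("gene", "consequence")) {
      fill <- is.na(s[[col]])
      s[[col]][fill] <- vals[fill]
    } else s[[col]] <- vals
  }
  TrioSites(s, pedigree(x))
}

#' Read a per-gene expected de novo mutation rate table
#'
#' Reads a two-column TSV (\code{gene}, \code{mu}) of expected DNMs per gene
#' per trio per generation (a sequence-context mutational null model, e.g. a
#' Samocha-style prior). Duplicate genes and negative rates are fatal.
#'
#' @param path path to the TSV (header required).
#' @return named numeric vector of per-trio rates.
#' @seealso \code{\link{geneRate}}, \code{\link{geneEnrichmentTest}}
#' @export
readGeneRates <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene", "mu") %in% names(tab)))
    stop("gene rate table needs 'gene' and 'mu' columns")
  dup <- tab$gene[duplicated(tab$gene)]
  if (length(dup))
    stop(sprintf("duplicate gene rate row(s): %s", paste(unique(dup), collapse = ", ")))
  if (any(tab$mu < 0)) stop("negative per-gene mutation rate")
  stats::setNames(as.numeric(tab$mu), tab$gene)
}

#' Look up a per-gene expected mutation rate
#'
#' @param rates named numeric vector from \code{\link{readGeneRates}}.
#' @param gene gene symbol.
#' @param default value returned when the gene is absent (default \code{NA},
#'   an explicit absent marker; pass a genome-wide average to fall back).
#' @return the per-trio rate, or \code{default}.
#' @export
geneRate <- function(rates, gene, default = NA_real_) {
  if (gene %in% names(rates)) unname(rates[[gene]]) else default
}

#' Write and re-read the per-candidate DNM report
#'
#' The DNM report is a TSV with one row per candidate: coordinates, alleles,
#' gene, consequence class, confidence rank, mosaic flag and every filter
#' criterion's outcome. \code{readDnmReport} restores the table with the
#' original column types so that a write/read round trip reproduces identical
#' records.
#'
#' @param calls a \code{\link{DnmCalls}} object.
#' @param path output TSV path.
#' @return \code{writeDnmReport} returns \code{path} invisibly;
#'   \code{readDnmReport} returns a \code{DnmCalls}.
#' @export
writeDnmReport <- function(calls, path) {
  write.table(callData(calls), path, sep = "\t", quote = FALSE,
    row.names = FALSE, na = ".")
  invisible(path)
}

#' @rdname writeDnmReport
#' @export
readDnmReport <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    na.strings = ".", colClasses = NA)
  for (col in intersect(c("passed", "mosaic", "rare", "implausible_hom",
      "non_autosomal"), names(df)))
    df[[col]] <- as.logical(df[[col]])
  if ("filter_failures" %in% names(df))
    df$filter_failures[is.na(df$filter_failures)] <- ""
  if ("trio" %in% names(df)) df$trio <- as.character(df$trio)
  if ("chrom" %in% names(df)) df$chrom <- as.character(df$chrom)
  DnmCalls(df)
}

#' Read a probe-level SNP-array track
#'
#' Reads a TSV with columns \code{chrom}, \code{pos}, \code{lrr} and
#' optionally \code{baf} and \code{gt} (\code{AA}/\code{AB}/\code{BB} or
#' missing). Positions must be strictly increasing within each chromosome.
#'
#' @param path path to the TSV (header required).
#' @return data.frame usable by \code{\link{callCnvSegments}} /
#'   \code{\link{callRoh}}.
#' @export
readProbeTrack <- function(path) {
  tr <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    na.strings = c("NA", "."))
  if (!all(c("chrom", "pos", "lrr") %in% names(tr)))
    stop("probe track needs chrom/pos/lrr columns")
  tr$chrom <- as.character(tr$chrom)
  tr
}

#' Write called CNV/ROH segments as a BED-like table
#'
#' Internally segments are 1-based fully closed; the file uses BED
#' conventions (0-based half-open start, 1-based end), so \code{start0 =
#' start - 1}.
#'
#' @param segments GRanges from \code{\link{callCnvSegments}} or
#'   \code{\link{callRoh}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeCnvSegments <- function(segments, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(segments)),
    start0 = GenomicRanges::start(segments) - 1L,
    end = GenomicRanges::end(segments),
    kind = segments$kind, n_probes = segments$n_probes,
    mean_lrr = segments$mean_lrr, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
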