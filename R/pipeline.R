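## Orchestration: run the full analysis on a (simulated or real) cohort and
## recompute the reference study's headline numbers from the bundled call
## table.

#' Published reference cohorts for LOF DNM rate comparisons
#'
#' Trio cohorts used as comparators for the rate of loss-of-function de novo
#' mutations: healthy control trios and unaffected siblings of
#' neuropsychiatric patients, each given as the number of trios carrying at
#' least one LOF DNM out of the cohort size.
#'
#' @return data.frame with \code{label}, \code{events}, \code{trios}.
#' @export
referenceCohorts <- function() {
  data.frame(
    label = c("healthy_trios", "unaffected_siblings"),
    events = c(4L, 54L),
    trios = c(54L, 677L),
    stringsAsFactors = FALSE)
}

#' Run the full trio DNM pipeline on a cohort
#'
#' Chains detection (\code{\link{callDnms}}), cohort summary
#' (\code{\link{summarizeCohort}}), Poisson goodness of fit
#' (\code{\link{poissonGof}}), LOF-rate comparisons against reference
#' cohorts (\code{\link{cohortRateTest}}) and per-gene over-representation
#' (\code{\link{geneEnrichmentTest}}) for genes with a rate entry. When
#' \code{outDir} is given, the DNM report and summary tables are written as
#' TSV.
#'
#' @param cohort list with \code{sites} (\code{\link{TrioSites}}) and
#'   \code{pedigree}, as returned by \code{\link{simulateTrioCohort}}.
#' @param param a \code{\link{DnmFilterParam}}.
#' @param rates optional named gene-rate vector
#'   (\code{\link{readGeneRates}}).
#' @param refCohorts optional data.frame as \code{\link{referenceCohorts}}.
#' @param model optional \code{\link{RankModel}}.
#' @param outDir optional output directory.
#' @return list with \code{calls}, \code{summary}, \code{gof},
#'   \code{rateTests}, \code{geneTests}.
#' @export
runPipeline <- function(cohort, param = DnmFilterParam(), rates = NULL,
                        refCohorts = NULL, model = NULL, outDir = NULL) {
  calls <- callDnms(cohort$sites, param, model = model)
  summary <- summarizeCohort(calls, cohort$pedigree)
  gof <- if (summary@nTrios >= 2L) poissonGof(summary) else NULL

  rateTests <- NULL
  if (!is.null(refCohorts)) {
    cl <- callData(calls)
    lofTrios <- unique(cl$trio[cl$validated & !is.na(cl$class) &
      cl$class == "LOF"])
    rateTests <- do.call(rbind, lapply(seq_len(nrow(refCohorts)), function(i) {
      r <- cohortRateTest(length(lofTrios), summary@nTrios,
        refCohorts$events[i], refCohorts$trios[i])
      data.frame(reference = refCohorts$label[i], k_case = length(lofTrios),
        n_case = summary@nTrios, k_ref = refCohorts$events[i],
        n_ref = refCohorts$trios[i], p = r$p.value, stringsAsFactors = FALSE)
    }))
  }

  geneTests <- NULL
  if (!is.null(rates)) {
    cl <- callData(calls)
    tab <- table(cl$gene[cl$validated])
    geneTests <- do.call(rbind, lapply(names(tab), function(g) {
      r <- geneEnrichmentTest(g, tab[[g]], summary@nTrios, rates)
      data.frame(gene = g, observed = r$observed,
        rate_observed = r$rate.observed, expected = r$expected,
        p = r$p.value, stringsAsFactors = FALSE)
    }))
  }

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeDnmReport(calls, file.path(outDir, "dnm_report.tsv"))
    write.table(data.frame(trio = names(perTrioCounts(summary)),
      n_dnm = perTrioCounts(summary)), file.path(outDir, "per_trio_counts.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(rateTests))
      write.table(rateTests, file.path(outDir, "rate_tests.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(geneTests))
      write.table(geneTests, file.path(outDir, "gene_tests.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(calls = calls, summary = summary, gof = gof, rateTests = rateTests,
    geneTests = geneTests)
}

#' Load the bundled reference DNM call table
#'
#' The package ships the validated de novo mutation calls of a 24-trio
#' Hirschsprung disease exome study as a machine-readable table (one row per
#' DNM: trio, phenotype, sex, gene, HGVS description, reported mutation
#' type, population frequencies in three databases, mosaic status). Trios
#' 15--24 of that cohort carried no DNM and therefore have no rows.
#'
#' @return data.frame of 28 calls.
#' @export
referenceDnmCalls <- function() {
  path <- system.file("extdata", "hscr_dnm_calls.tsv", package = "trioDNM",
    mustWork = TRUE)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    na.strings = "N")
  df$trio <- as.character(df$trio)
  df
}

#' Recompute the reference study's headline numbers
#'
#' Re-derives, from the bundled call table and the published cohort
#' constants, every summary statistic of the reference 24-trio analysis:
#' total DNM and gene counts, the consequence-class partition, the Poisson
#' mean and its Kolmogorov-Smirnov goodness of fit, the LOF rate comparisons
#' against both reference cohorts, the RET over-representation test and the
#' RET diagnostic rate. Pure computation on bundled data: no network, no
#' external files, runs in well under a second.
#'
#' @param nTrios cohort size behind the call table (24).
#' @return data.frame with \code{quantity}, \code{value} and
#'   \code{reference} (the value reported by the study, for side-by-side
#'   comparison).
#' @export
reproduceStudy <- function(nTrios = 24L) {
  df <- referenceDnmCalls()
  trios <- as.character(seq_len(nTrios))
  df$class <- classifyConsequence(df$type)
  summ <- summarizeCohort(df, trios)
  cls <- classwiseSummary(df)
  gof <- poissonGof(summ)
  refs <- referenceCohorts()
  lofTrios <- unique(df$trio[df$class == "LOF"])
  lofHealthy <- cohortRateTest(length(lofTrios), nTrios,
    refs$events[1], refs$trios[1])
  lofSibs <- cohortRateTest(length(lofTrios), nTrios,
    refs$events[2], refs$trios[2])
  rates <- readGeneRates(system.file("extdata", "gene_rates.tsv",
    package = "trioDNM", mustWork = TRUE))
  retObs <- sum(df$gene == "RET")
  ret <- geneEnrichmentTest("RET", retObs, nTrios, rates)
  retTrios <- length(unique(df$trio[df$gene == "RET"]))
  rare <- filterRare(df[, c("maf_dbsnp", "maf_esp", "maf_exac")])

  row <- function(q, v, ref) data.frame(quantity = q, value = v,
    reference = ref, stringsAsFactors = FALSE)
  out <- rbind(
    row("total_dnms", sum(perTrioCounts(summ)), 28),
    row("distinct_genes", length(unique(df$gene)), 21),
    row("trios_with_dnm", sum(perTrioCounts(summ) > 0), 14),
    row("ret_dnms", retObs, 8),
    row("class_lof", cls[["LOF"]], 8),
    row("class_missense", cls[["missense"]], 12),
    row("class_inframe", cls[["inframe_indel"]], 1),
    row("class_synonymous", cls[["synonymous"]], 7),
    row("mosaic_dnms", sum(df$mosaic), 2),
    row("rare_dnms", sum(rare), 28),
    row("lambda_hat", lambdaHat(summ), 1.2),
    row("dnm_rate_reported", round(lambdaHat(summ), 1), 1.2),
    row("ks_p", gof$rounded$p.value, 0.893),
    row("ks_p_mean_lambda", gof$p.value, 0.893),
    row("lof_trios", length(lofTrios), 8),
    row("lof_vs_healthy_p", lofHealthy$p.value, 0.011),
    row("lof_vs_siblings_p", lofSibs$p.value, 0.001),
    row("ret_rate_per_trio", ret$rate.observed, 0.33),
    row("ret_enrichment_p", ret$p.value, 2e-16),
    row("ret_diagnostic_rate_pct", 100 * retTrios / nTrios, 33))
  rownames(out) <- NULL
  out
}
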