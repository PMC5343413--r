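## Gene-wise rare-variant collapsing burden (CMC-style carrier collapse with
## asymptotic chi-square) and sample-size-weighted Z-score meta-analysis.

#' Collapse a gene's rare variants into per-cohort carrier counts
#'
#' CMC-style collapse: a sample is a carrier of a gene iff it has alternate
#' dosage of at least 1 at any of the gene's variants; carrying several
#' variants still counts once. Missing dosages are treated as 0 (reference).
#'
#' @param dosage numeric matrix, samples x variants, entries 0/1/2/NA.
#' @param variantGenes character vector, gene of each dosage column.
#' @param status logical or character vector per sample; \code{TRUE} /
#'   \code{"case"} marks cases.
#' @param gene gene symbol to collapse.
#' @return named integer vector \code{c(case_carriers, n_cases,
#'   control_carriers, n_controls)}, or \code{NULL} when the gene has no
#'   variant in the matrix (an explicit absent result).
#' @export
collapseCarriers <- function(dosage, variantGenes, status, gene) {
  stopifnot(ncol(dosage) == length(variantGenes),
    nrow(dosage) == length(status))
  cols <- which(variantGenes == gene)
  if (!length(cols)) return(NULL)
  isCase <- if (is.logical(status)) status else status == "case"
  d <- dosage[, cols, drop = FALSE]
  d[is.na(d)] <- 0
  carrier <- rowSums(d >= 1) > 0
  c(case_carriers = sum(carrier & isCase), n_cases = sum(isCase),
    control_carriers = sum(carrier & !isCase), n_controls = sum(!isCase))
}

#' Carrier-collapse burden test on a 2x2 table
#'
#' 1-df chi-square test (without continuity correction by default) comparing
#' carrier frequency between cases and controls. The direction is the sign
#' of (case carrier rate - control carrier rate). Tables with a zero margin
#' (no carriers at all, or everyone a carrier) carry no information and
#' return p = 1 with direction 0.
#'
#' @param carriers vector as returned by \code{\link{collapseCarriers}}.
#' @param correct logical, apply Yates continuity correction (default FALSE,
#'   the plain asymptotic statistic).
#' @param gene optional gene label carried through.
#' @return list with \code{gene}, \code{statistic}, \code{p.value},
#'   \code{direction} (+1 case-enriched, -1 control-enriched, 0),
#'   \code{n_samples} and \code{carriers}.
#' @examples
#' cmcTest(c(8, 10, 2, 10))  # chi-square 7.2, p ~0.0073, direction +1
#' @export
cmcTest <- function(carriers, correct = FALSE, gene = NA_character_) {
  a <- carriers[[1]]; n1 <- carriers[[2]]
  b <- carriers[[3]]; n2 <- carriers[[4]]
  stopifnot(n1 >= 1, n2 >= 1, a <= n1, b <= n2)
  tab <- matrix(c(a, n1 - a, b, n2 - b), 2L)
  out <- list(gene = gene, statistic = 0, p.value = 1, direction = 0L,
    n_samples = n1 + n2,
    carriers = stats::setNames(c(a, n1, b, n2),
      c("case_carriers", "n_cases", "control_carriers", "n_controls")))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) return(out)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  out$statistic <- unname(ct$statistic)
  out$p.value <- ct$p.value
  out$direction <- as.integer(sign(a / n1 - b / n2))
  out
}

#' Per-gene burden tests for one study
#'
#' Runs \code{\link{collapseCarriers}} and \code{\link{cmcTest}} for every
#' gene present in a study's dosage matrix.
#'
#' @param study list with elements \code{dosage} (samples x variants matrix),
#'   \code{variantGenes} and \code{status}, as produced by
#'   \code{\link{simulateCaseControl}}.
#' @param genes genes to test; default all genes in the matrix.
#' @param correct see \code{\link{cmcTest}}.
#' @return data.frame with one row per gene: \code{gene}, \code{statistic},
#'   \code{p}, \code{direction}, \code{n}, carrier counts.
#' @export
burdenTest <- function(study, genes = NULL, correct = FALSE) {
  if (is.null(genes)) genes <- unique(study$variantGenes)
  rows <- lapply(genes, function(g) {
    cc <- collapseCarriers(study$dosage, study$variantGenes, study$status, g)
    if (is.null(cc)) return(NULL)
    r <- cmcTest(cc, correct = correct, gene = g)
    data.frame(gene = g, statistic = r$statistic, p = r$p.value,
      direction = r$direction, n = r$n_samples,
      case_carriers = r$carriers[["case_carriers"]],
      n_cases = r$carriers[["n_cases"]],
      control_carriers = r$carriers[["control_carriers"]],
      n_controls = r$carriers[["n_controls"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sample-size-weighted Z-score meta-analysis
#'
#' Stouffer-type combination of per-study two-sided p-values with explicit
#' burden directions: each study contributes
#' \eqn{z_i = \Phi^{-1}(1 - p_i/2) \cdot d_i} (0 when its direction is 0),
#' weighted by \eqn{w_i = \sqrt{n_i}}; the combined statistic is
#' \eqn{Z = \sum w_i z_i / \sqrt{\sum w_i^2}} with two-sided p-value
#' \eqn{2(1 - \Phi(|Z|))}. With equal sample sizes this reduces to
#' Stouffer's method; a single study returns its own p-value.
#'
#' @param p per-study two-sided p-values.
#' @param direction per-study directions in \{-1, 0, +1\}.
#' @param n per-study sample sizes.
#' @return list with \code{z}, \code{p.value}, \code{studies}.
#' @examples
#' weightedZMeta(c(0.05, 0.05), c(1, 1), c(100, 100))  # Z ~2.772, p ~0.00557
#' @export
weightedZMeta <- function(p, direction, n) {
  ok <- is.finite(p) & !is.na(direction) & is.finite(n)
  p <- p[ok]; direction <- direction[ok]; n <- n[ok]
  if (!length(p)) stop("meta-analysis needs at least one study with a finite p-value")
  stopifnot(all(p >= 0 & p <= 1), all(direction %in% c(-1, 0, 1)), all(n > 0))
  z <- qnorm(pmin(p, 1) / 2, lower.tail = FALSE) * direction
  z[direction == 0] <- 0
  w <- sqrt(n)
  Z <- sum(w * z) / sqrt(sum(w^2))
  list(z = Z, p.value = 2 * pnorm(-abs(Z)), studies = length(p))
}

#' Meta-analyze per-gene burden results across studies
#'
#' Applies \code{\link{weightedZMeta}} gene by gene over the per-study tables
#' of \code{\link{burdenTest}}. Genes absent from a study simply use the
#' remaining studies. An optional Bonferroni-adjusted column is appended for
#' convenience; per-gene p-values themselves are reported uncorrected.
#'
#' @param studyResults list of data.frames from \code{\link{burdenTest}}.
#' @return data.frame with \code{gene}, \code{z}, \code{p},
#'   \code{p_bonferroni}, \code{studies}.
#' @export
metaBurden <- function(studyResults) {
  all <- do.call(rbind, studyResults)
  genes <- unique(all$gene)
  rows <- lapply(genes, function(g) {
    sub <- all[all$gene == g, , drop = FALSE]
    m <- weightedZMeta(sub$p, sub$direction, sub$n)
    data.frame(gene = g, z = m$z, p = m$p.value, studies = m$studies,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p * length(genes), 1)
  rownames(out) <- NULL
  out
}
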