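## Cohort-level DNM rate statistics: Poisson fit + goodness of fit, exact
## conditional binomial cohort comparisons, per-gene expected-rate
## over-representation.

#' Summarize validated DNM calls over a trio cohort
#'
#' Counts every validated call once per trio, including trios with zero calls,
#' and fits the Poisson mean \code{lambdaHat} at full precision (report
#' rounded to one decimal for display). Input is either a
#' \code{\link{DnmCalls}} object (rows with \code{validated == TRUE} are
#' counted; if that column is absent, rows with \code{passed == TRUE}) or a
#' plain data.frame with \code{trio} and \code{class} columns in which every
#' row counts (e.g. an externally validated call table).
#'
#' @param calls \code{DnmCalls} or data.frame.
#' @param trios character vector of all trio ids in the cohort, or a pedigree
#'   data.frame with a \code{trio} column.
#' @return A \code{\link{CohortDnmSummary}}.
#' @export
summarizeCohort <- function(calls, trios) {
  if (is.data.frame(trios)) trios <- trios$trio
  trios <- as.character(trios)
  if (is(calls, "DnmCalls")) {
    cl <- callData(calls)
    keep <- if ("validated" %in% names(cl)) cl$validated else cl$passed
    cl <- cl[keep, , drop = FALSE]
  } else cl <- calls
  unknown <- setdiff(unique(cl$trio), trios)
  if (length(unknown))
    stop(sprintf("call(s) reference trio(s) not in the cohort: %s",
      paste(unknown, collapse = ", ")))
  perTrio <- table(factor(as.character(cl$trio), levels = trios))
  classes <- if ("class" %in% names(cl)) cl$class
    else classifyConsequence(cl$consequence)
  classCounts <- table(factor(classes, levels = .CONSEQUENCE_LEVELS))
  n <- length(trios)
  new("CohortDnmSummary",
    nTrios = n,
    perTrioCounts = stats::setNames(as.integer(perTrio), trios),
    classCounts = stats::setNames(as.integer(classCounts), .CONSEQUENCE_LEVELS),
    lambdaHat = if (n > 0) sum(perTrio) / n else 0)
}

#' Consequence-class breakdown with LOF subtypes
#'
#' Exact partition counts of the validated calls over the five consequence
#' classes, with loss-of-function subdivided into nonsense, frameshift and
#' splice-site changes.
#'
#' @param calls \code{\link{DnmCalls}} or data.frame with \code{class} (or a
#'   raw \code{consequence}) column; for a \code{DnmCalls}, validated rows
#'   are counted as in \code{\link{summarizeCohort}}.
#' @return named integer vector over the classes plus
#'   \code{LOF_nonsense}, \code{LOF_frameshift}, \code{LOF_splicing}.
#' @export
classwiseSummary <- function(calls) {
  if (is(calls, "DnmCalls")) {
    cl <- callData(calls)
    keep <- if ("validated" %in% names(cl)) cl$validated else cl$passed
    cl <- cl[keep, , drop = FALSE]
  } else cl <- calls
  raw <- if ("consequence" %in% names(cl)) cl$consequence else cl$type
  classes <- if ("class" %in% names(cl) && !all(is.na(cl$class))) cl$class
    else classifyConsequence(raw)
  main <- table(factor(classes, levels = .CONSEQUENCE_LEVELS))
  sub <- table(factor(lofSubtype(raw),
    levels = c("nonsense", "frameshift", "splicing")))
  out <- c(as.integer(main), as.integer(sub))
  stats::setNames(out, c(.CONSEQUENCE_LEVELS,
    paste0("LOF_", c("nonsense", "frameshift", "splicing"))))
}

## Exact n-sample Kolmogorov CDF P(D_n < d), Marsaglia-Tsang-Wang
## matrix-power algorithm.
.kolmogorovCdfExact <- function(d, n) {
  if (d <= 0) return(0)
  if (d >= 1) return(1)
  k <- ceiling(n * d); h <- k - n * d; m <- 2L * k - 1L
  H <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) if (i - j + 1L >= 0L) H[i, j] <- 1
  for (i in seq_len(m)) {
    H[i, 1L] <- H[i, 1L] - h^i
    H[m, i] <- H[m, i] - h^(m - i + 1L)
  }
  if (2 * h - 1 > 0) H[m, 1L] <- H[m, 1L] + (2 * h - 1)^m
  for (i in seq_len(m)) for (j in seq_len(m)) if (i - j + 1L > 0L)
    H[i, j] <- H[i, j] / factorial(i - j + 1L)
  ## H^n with overflow rescaling
  Q <- diag(m); eQ <- 0; B <- H; eB <- 0; pw <- n
  repeat {
    if (pw %% 2L == 1L) {
      Q <- Q %*% B; eQ <- eQ + eB
      if (Q[k, k] > 1e140) { Q <- Q * 1e-140; eQ <- eQ + 140 }
    }
    pw <- pw %/% 2L
    if (pw == 0L) break
    B <- B %*% B; eB <- 2 * eB
    if (B[k, k] > 1e140) { B <- B * 1e-140; eB <- eB + 140 }
  }
  s <- Q[k, k]
  for (i in seq_len(n)) {
    s <- s * i / n
    if (s < 1e-140) { s <- s * 1e140; eQ <- eQ - 140 }
  }
  min(max(s * 10^eQ, 0), 1)
}

.kolmogorovPAsymptotic <- function(d, n) {
  t <- sqrt(n) * d
  if (t < 1e-8) return(1)
  k <- seq_len(101)
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
}

#' Poisson goodness of fit for per-trio DNM counts
#'
#' One-sample two-sided Kolmogorov-Smirnov test of the empirical per-trio
#' count distribution against the Poisson CDF. Because the null is discrete,
#' the statistic is the supremum of \eqn{|F_n(x) - F(x)|} over the integer
#' support (the continuous-data construction, which also compares left
#' limits, grossly overstates D for count data). The p-value is exact
#' (Marsaglia-Tsang-Wang) for cohorts of at most \code{exactMax} trios and
#' asymptotic otherwise; both variants are returned, as are the fits at the
#' full-precision mean and at the mean rounded to one decimal. A KS test
#' against a discrete null is conservative; a chi-square goodness of fit
#' (\code{\link{poissonChisqGof}}) is provided as a cross-check.
#'
#' @param x a \code{\link{CohortDnmSummary}} or an integer vector of per-trio
#'   counts.
#' @param lambda Poisson mean for the null; default the observed full
#'   precision mean.
#' @param exactMax largest n for which the exact p-value is used as
#'   \code{p.value}.
#' @return list with \code{lambda}, \code{statistic} (D), \code{p.value}
#'   (exact when n <= exactMax), \code{p.exact}, \code{p.asymptotic},
#'   \code{rounded} (the same test at \code{round(lambda, 1)}) and \code{n}.
#' @export
poissonGof <- function(x, lambda = NULL, exactMax = 30L) {
  counts <- if (is(x, "CohortDnmSummary")) as.integer(perTrioCounts(x))
    else as.integer(x)
  n <- length(counts)
  if (n < 2L) stop("goodness of fit needs at least two trios")
  if (is.null(lambda)) lambda <- mean(counts)
  one <- function(lam) {
    if (lam == 0) {
      D <- max(abs(ecdf(counts)(0) - 1))  # degenerate null: all mass at 0
      return(list(lambda = lam, statistic = D,
        p.exact = if (D == 0) 1 else 1 - .kolmogorovCdfExact(D, n),
        p.asymptotic = if (D == 0) 1 else .kolmogorovPAsymptotic(D, n)))
    }
    support <- 0:max(max(counts), qpois(1 - 1e-12, lam))
    D <- max(abs(ecdf(counts)(support) - ppois(support, lam)))
    list(lambda = lam, statistic = D,
      p.exact = 1 - .kolmogorovCdfExact(D, n),
      p.asymptotic = .kolmogorovPAsymptotic(D, n))
  }
  main <- one(lambda)
  rounded <- one(round(lambda, 1))
  pick <- function(r) if (n <= exactMax) r$p.exact else r$p.asymptotic
  list(lambda = main$lambda, statistic = main$statistic,
    p.value = pick(main), p.exact = main$p.exact,
    p.asymptotic = main$p.asymptotic,
    rounded = c(rounded, list(p.value = pick(rounded))), n = n)
}

#' Chi-square goodness of fit against a Poisson null
#'
#' Bins the count support so every expected cell count is at least
#' \code{minExpected} (pooling the right tail), then applies the chi-square
#' statistic with degrees of freedom = bins - 2 (one parameter estimated).
#'
#' @param x counts as in \code{\link{poissonGof}}.
#' @param lambda Poisson mean (default observed mean).
#' @param minExpected minimum expected count per bin.
#' @return list with \code{statistic}, \code{df}, \code{p.value}.
#' @export
poissonChisqGof <- function(x, lambda = NULL, minExpected = 1) {
  counts <- if (is(x, "CohortDnmSummary")) as.integer(perTrioCounts(x))
    else as.integer(x)
  n <- length(counts)
  if (is.null(lambda)) lambda <- mean(counts)
  hi <- max(max(counts), qpois(0.999, lambda)) + 1L
  probs <- c(dpois(0:(hi - 1L), lambda), ppois(hi - 1L, lambda, lower.tail = FALSE))
  obs <- tabulate(pmin(counts, hi) + 1L, nbins = hi + 1L)
  ## pool from the right until every expected count clears the floor
  while (length(probs) > 2L && n * probs[length(probs)] < minExpected) {
    k <- length(probs)
    probs[k - 1L] <- probs[k - 1L] + probs[k]; probs <- probs[-k]
    obs[k - 1L] <- obs[k - 1L] + obs[k]; obs <- obs[-k]
  }
  expd <- n * probs
  stat <- sum((obs - expd)^2 / expd)
  df <- max(length(probs) - 2L, 1L)
  list(statistic = stat, df = df,
    p.value = pchisq(stat, df, lower.tail = FALSE))
}

#' Exact conditional binomial comparison of two cohort event rates
#'
#' Compares the per-trio event rate of a case cohort (\code{kCase} events in
#' \code{nCase} trios) against a reference cohort by conditioning on the
#' total number of events \eqn{m = k_{case} + k_{ref}}: under the null of
#' equal per-trio rates, each event falls in the case cohort independently
#' with probability \eqn{\pi_0 = n_{case} / (n_{case} + n_{ref})}, and the
#' one-sided p-value is the exact binomial upper tail
#' \eqn{P(X \ge k_{case})}, inclusive of the observed value. With no events
#' at all the p-value is 1.
#'
#' @param kCase,nCase events and trios in the case cohort.
#' @param kRef,nRef events and trios in the reference cohort.
#' @return list with \code{p.value}, \code{rate.case}, \code{rate.ref},
#'   \code{m} (total events) and \code{pi0}.
#' @examples
#' cohortRateTest(8, 24, 4, 54)$p.value    # ~0.011
#' cohortRateTest(8, 24, 54, 677)$p.value  # ~0.001
#' @export
cohortRateTest <- function(kCase, nCase, kRef, nRef) {
  stopifnot(kCase >= 0, kRef >= 0, nCase >= 1, nRef >= 1)
  m <- kCase + kRef
  pi0 <- nCase / (nCase + nRef)
  p <- if (m == 0) 1 else pbinom(kCase - 1, m, pi0, lower.tail = FALSE)
  list(p.value = p, rate.case = kCase / nCase, rate.ref = kRef / nRef,
    m = m, pi0 = pi0)
}

#' Per-gene over-representation of de novo mutations
#'
#' Tests whether a gene harbors more DNMs across the cohort than expected
#' under its per-trio mutation-rate prior \eqn{\mu_g}: the default mode is
#' the exact Poisson upper tail \eqn{P(X \ge k)} at rate
#' \eqn{n_{trios} \cdot \mu_g}. A secondary \code{"fisher"} mode tests the
#' 2x2 table of observed versus (rounded) expected mutation counts with
#' Fisher's exact test. Zero observed mutations give p = 1.
#'
#' @param gene gene symbol (used for the rate lookup and labelling).
#' @param observed number of DNMs observed in the gene.
#' @param nTrios cohort size.
#' @param rates named rate vector from \code{\link{readGeneRates}}, or a
#'   single numeric rate.
#' @param mode \code{"poisson"} (default) or \code{"fisher"}.
#' @return list with \code{gene}, \code{observed}, \code{rate.observed}
#'   (per trio), \code{expected} (\eqn{n \mu_g}), \code{p.value},
#'   \code{mode}; if the gene has no rate in the table, \code{p.value} and
#'   \code{expected} are NA (an explicit absent marker, never 0).
#' @examples
#' rates <- c(RET = 0.000133)
#' geneEnrichmentTest("RET", 8, 24, rates)$p.value  # < 2e-16
#' @export
geneEnrichmentTest <- function(gene, observed, nTrios, rates,
                               mode = c("poisson", "fisher")) {
  mode <- match.arg(mode)
  stopifnot(observed >= 0, nTrios >= 1)
  mu <- if (is.numeric(rates) && is.null(names(rates)) && length(rates) == 1L)
    rates else geneRate(rates, gene)
  out <- list(gene = gene, observed = as.integer(observed),
    rate.observed = observed / nTrios, expected = NA_real_,
    p.value = NA_real_, mode = mode)
  if (is.na(mu)) return(out)
  out$expected <- nTrios * mu
  if (mode == "poisson") {
    p <- ppois(observed - 1, out$expected, lower.tail = FALSE)
    out$p.value <- max(p, .Machine$double.xmin)
  } else {
    expInt <- round(out$expected)
    tab <- matrix(c(observed, nTrios - observed, expInt, nTrios - expInt), 2L)
    out$p.value <- stats::fisher.test(tab, alternative = "greater")$p.value
  }
  out
}
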