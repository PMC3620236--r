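# Case-control odds-ratio association for haplotypes (chromosome level)
# and genotypes (individual level).
#
# The 2x2 table for a row with a exposed cases and b exposed controls is
#   [[a, b], [n_case - a, n_control - b]]
# i.e. exposure is carriage of this haplotype/genotype versus all others,
# with the full cohort totals as denominators.

#' Odds ratio of a 2x2 exposure-by-status table with Woolf interval
#'
#' \code{OR = a (n_control - b) / (b (n_case - a))}.  The 95\% confidence
#' interval uses Woolf's logit method: \code{exp(log OR +/- 1.96 sqrt(1/a +
#' 1/b + 1/c + 1/d))}.  With a zero cell the point estimate degenerates to
#' 0 or Inf, the interval is undefined and the \code{zero_cell} flag is
#' set; an optional Haldane-Anscombe correction (add 0.5 to every cell) is
#' available but off by default so that degenerate transmissions report
#' OR = 0 rather than a shrunken estimate.
#'
#' @param a exposed case count.
#' @param b exposed control count.
#' @param nCase,nControl cohort totals (chromosomes or individuals).
#' @param conf confidence level, default 0.95.
#' @param haldane add 0.5 to all cells when any cell is zero.
#' @return List with \code{odds_ratio}, \code{ci_low}, \code{ci_high},
#'   \code{zero_cell}.
#' @examples
#' oddsRatio2x2(97, 16, 5110, 2730)   # OR 3.3, CI 1.9-5.6
#' @export
oddsRatio2x2 <- function(a, b, nCase, nControl, conf = 0.95,
                         haldane = FALSE) {
    if (nCase <= 0 || nControl <= 0)
        stop("cohort totals must be positive")
    if (a > nCase || b > nControl || a < 0 || b < 0)
        stop("cell counts must satisfy 0 <= a <= nCase, 0 <= b <= nControl")
    cc <- nCase - a
    d <- nControl - b
    zero <- any(c(a, b, cc, d) == 0)
    if (zero && haldane) {
        a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
    }
    or <- (a * d) / (b * cc)        # 0/Inf/NaN arithmetic is intended
    if (any(c(a, b, cc, d) == 0)) {
        lo <- hi <- NA_real_
    } else {
        z <- stats::qnorm(1 - (1 - conf) / 2)
        se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
        lo <- exp(log(or) - z * se)
        hi <- exp(log(or) + z * se)
    }
    list(odds_ratio = or, ci_low = lo, ci_high = hi, zero_cell = zero)
}

#' Pearson chi-square test of a 2x2 exposure-by-status table
#'
#' One degree of freedom, no continuity correction; \code{p} is the
#' upper-tail chi-square probability.  An empty margin yields statistic 0
#' and p = 1 with a warning.
#'
#' @inheritParams oddsRatio2x2
#' @return List with \code{chi2} and \code{p}.
#' @examples
#' chisqP2x2(97, 16, 5110, 2730)   # chi2 ~21.6, p ~3.4e-6
#' @export
chisqP2x2 <- function(a, b, nCase, nControl) {
    if (nCase <= 0 || nControl <= 0)
        stop("cohort totals must be positive")
    m <- matrix(c(a, nCase - a, b, nControl - b), nrow = 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
        warning("empty margin: chi2 = 0, p = 1")
        return(list(chi2 = 0, p = 1))
    }
    ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    list(chi2 = unname(ht$statistic), p = unname(ht$p.value))
}

#' Bonferroni correction
#'
#' \code{min(1, m p)}, the conservative correction for \code{m}
#' comparisons.
#'
#' @param p probability (vectorised).
#' @param m number of comparisons, >= 1.
#' @return Corrected probabilities.
#' @export
bonferroni <- function(p, m) {
    if (m < 1) stop("m must be >= 1")
    pmin(1, m * p)
}

#' Case-control association for every row of a count table
#'
#' Computes, per haplotype or genotype, the case and control percentage,
#' the odds ratio against all other chromosomes/individuals with its Woolf
#' 95\% interval, the Pearson chi-square p-value, and the Bonferroni-
#' corrected p over \code{m} comparisons.  Rows are returned sorted by
#' descending odds ratio; \code{significant} marks rows whose corrected p
#' stays below \code{sigLevel}.
#'
#' @param x a \code{\link{HaplotypeCounts}} or \code{\link{GenotypeCounts}}
#'   table, already frequency-filtered.
#' @param m number of comparisons for the correction; defaults to the
#'   number of rows.
#' @param sigLevel significance threshold applied to the corrected p.
#' @param haldane passed to \code{\link{oddsRatio2x2}}.
#' @return A data frame with one row per label: \code{label},
#'   \code{case_count}, \code{control_count}, \code{case_pct},
#'   \code{control_pct}, \code{odds_ratio}, \code{ci_low}, \code{ci_high},
#'   \code{chi2}, \code{p}, \code{p_corrected}, \code{significant},
#'   \code{zero_cell}.
#' @examples
#' tab <- readCountTable(hlaFixture("haplotypes"), "haplotype")
#' head(associateTable(tab), 3)
#' @export
associateTable <- function(x, m = length(x), sigLevel = 0.05,
                           haldane = FALSE) {
    stopifnot(is(x, "CountTable"))
    rows <- lapply(seq_along(x@label), function(i) {
        or <- oddsRatio2x2(x@caseCount[i], x@controlCount[i],
                           x@caseTotal, x@controlTotal, haldane = haldane)
        ct <- chisqP2x2(x@caseCount[i], x@controlCount[i],
                        x@caseTotal, x@controlTotal)
        data.frame(label = x@label[i],
                   case_count = x@caseCount[i],
                   control_count = x@controlCount[i],
                   case_pct = 100 * x@caseCount[i] / x@caseTotal,
                   control_pct = 100 * x@controlCount[i] / x@controlTotal,
                   odds_ratio = or$odds_ratio, ci_low = or$ci_low,
                   ci_high = or$ci_high, chi2 = ct$chi2, p = ct$p,
                   p_corrected = bonferroni(ct$p, m),
                   zero_cell = or$zero_cell, stringsAsFactors = FALSE)
    })
    ans <- do.call(rbind, rows)
    ans$significant <- ans$p_corrected < sigLevel
    ans <- ans[order(-ans$odds_ratio, ans$label), ]
    rownames(ans) <- NULL
    ans
}
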