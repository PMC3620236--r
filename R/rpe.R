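# Sequential relative predispositional effect (RPE) procedure.
#
# Each round compares the observed case counts of the remaining haplotypes
# with the counts expected from the control distribution under no
# differential predisposition, E_i = control_i * caseTotal / controlTotal
# at the current (post-removal) totals.  The haplotype with the largest
# chi-square contribution (O - E)^2 / E is removed from both cohorts, the
# totals shrink, and the procedure repeats until the overall goodness-of-
# fit chi-square across the remaining haplotypes is no longer significant.
#
# Cohort totals may exceed the displayed row sums (rare chromosomes below
# the reporting threshold).  That remainder is carried as an implicit
# category in the overall chi-square and its degrees of freedom — so the
# expected counts over all categories add up to the remaining case total —
# but it is never selectable for removal.

#' Expected case counts from the control distribution
#'
#' \code{E_i = controlCount_i * caseTotal / controlTotal}: what each
#' haplotype's case count would be if cases followed the control
#' distribution (no differential predispositional effect).
#'
#' @param controlCounts control counts per haplotype.
#' @param caseTotal,controlTotal current cohort totals.
#' @return Numeric vector of expected case counts.
#' @examples
#' rpeExpected(607, 5110, 2730)   # 1136.2
#' @export
rpeExpected <- function(controlCounts, caseTotal, controlTotal) {
    if (controlTotal <= 0) stop("controlTotal must be positive")
    controlCounts * caseTotal / controlTotal
}

#' Two-proportion z statistic with unpooled variance
#'
#' \code{z = (p1 - p2) / sqrt(p1 (1 - p1) / n1 + p2 (1 - p2) / n2)} with
#' \code{p1 = x1/n1}, \code{p2 = x2/n2}; the p-value is two-sided normal.
#' The unpooled form is used throughout the RPE trace.  When both
#' proportions are 0 or both are 1 the statistic is undefined and
#' \code{NA} is returned with a warning.
#'
#' @param x1,n1 count and total in the first group (cases).
#' @param x2,n2 count and total in the second group (controls).
#' @return List with \code{z} and two-sided \code{p}.
#' @examples
#' unpooledZ(1680, 5110, 607, 2730)   # z = 10.31
#' @export
unpooledZ <- function(x1, n1, x2, n2) {
    if (n1 <= 0 || n2 <= 0) stop("totals must be positive")
    p1 <- x1 / n1
    p2 <- x2 / n2
    v <- p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2
    if (v == 0) {
        if (p1 == p2) return(list(z = 0, p = 1))
        warning("degenerate proportions: z undefined")
        return(list(z = NA_real_, p = NA_real_))
    }
    z <- (p1 - p2) / sqrt(v)
    list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Run the sequential relative predispositional effect procedure
#'
#' Starting from the full table, each round (i) computes expected case
#' counts for all remaining haplotypes at the current totals, (ii) tests
#' the overall deviation with a goodness-of-fit chi-square (degrees of
#' freedom = number of remaining categories minus one, the implicit
#' remainder of undisplayed rare chromosomes counting as a category when
#' present), (iii) stops if the overall p is at or above \code{stopP},
#' otherwise removes the haplotype with the maximal contribution from both
#' cohorts and records its observed/expected counts, contribution, and
#' unpooled two-proportion z at the totals in force when it was selected.
#'
#' Two overall stopping tests are available.  The default \code{"gof"}
#' treats the control-derived expectations as known and sums
#' \code{(O - E)^2 / E} over the remaining categories — this is the
#' statistic whose per-haplotype contributions the procedure ranks, and it
#' reproduces published RPE traces column for column.  Because the
#' expectations are in fact estimated from the control sample, this test
#' overstates significance by a factor of roughly \code{1 +
#' caseTotal/controlTotal}; the \code{"contingency"} option replaces the
#' stopping decision with the two-sample 2-by-k contingency chi-square,
#' which has the nominal type-I level at any case/control balance (it
#' stops earlier on the same data).  The selection rule and the recorded
#' per-round columns are identical under both options.
#'
#' @param x a \code{\link{HaplotypeCounts}} table (>= 2 rows).
#' @param stopP overall significance threshold for continuing; default
#'   0.001.
#' @param maxRounds optional cap on the number of removals.
#' @param includeRemainder carry the undisplayed remainder (totals minus
#'   row sums) as an extra, non-selectable category in the overall test.
#' @param overallTest stopping statistic: \code{"gof"} (control-scaled
#'   goodness of fit, default) or \code{"contingency"} (calibrated
#'   two-sample test); see Details.
#' @return An \code{\link{RPETrace-class}} object; see
#'   \code{\link{rpeRounds}}.
#' @examples
#' trace <- runRPE(readCountTable(hlaFixture("haplotypes"), "haplotype"))
#' trace
#' @export
runRPE <- function(x, stopP = 0.001, maxRounds = Inf,
                   includeRemainder = TRUE,
                   overallTest = c("gof", "contingency")) {
    overallTest <- match.arg(overallTest)
    stopifnot(is(x, "HaplotypeCounts"))
    if (length(x) < 2L) stop("need at least 2 haplotypes")
    lab <- x@label
    ca <- as.numeric(x@caseCount)
    co <- as.numeric(x@controlCount)
    nCa <- as.numeric(x@caseTotal)
    nCo <- as.numeric(x@controlTotal)
    remCa <- nCa - sum(ca)
    remCo <- nCo - sum(co)
    useRem <- includeRemainder && (remCa > 0 || remCo > 0)
    rounds <- list()
    reason <- "exhausted"
    repeat {
        E <- rpeExpected(co, nCa, nCo)
        contrib <- ifelse(E > 0, (ca - E)^2 / E, ifelse(ca > 0, Inf, 0))
        if (overallTest == "gof") {
            chi2 <- sum(contrib)
            k <- length(ca)
            if (useRem) {
                Erem <- rpeExpected(remCo, nCa, nCo)
                chi2 <- chi2 + if (Erem > 0) (remCa - Erem)^2 / Erem else
                    (remCa > 0) * Inf
                k <- k + 1L
            }
            df <- k - 1L
            overallP <- pchisq(chi2, df, lower.tail = FALSE)
        } else {
            oc <- ca; occ <- co
            if (useRem) { oc <- c(oc, remCa); occ <- c(occ, remCo) }
            nz <- oc + occ > 0
            ht <- suppressWarnings(stats::chisq.test(rbind(oc[nz], occ[nz]),
                                                     correct = FALSE))
            chi2 <- unname(ht$statistic)
            df <- unname(ht$parameter)
            overallP <- unname(ht$p.value)
        }
        if (overallP >= stopP) { reason <- "overall_not_significant"; break }
        if (length(rounds) >= maxRounds) { reason <- "max_rounds"; break }
        i <- which.max(contrib)
        zt <- unpooledZ(ca[i], nCa, co[i], nCo)
        rounds[[length(rounds) + 1L]] <- data.frame(
            round = length(rounds) + 1L, label = lab[i],
            observed = ca[i], expected = E[i], contribution = contrib[i],
            z = zt$z, p_z = zt$p, overall_chi2 = chi2, overall_df = df,
            overall_p = overallP, case_total = nCa, control_total = nCo,
            stringsAsFactors = FALSE)
        nCa <- nCa - ca[i]
        nCo <- nCo - co[i]
        lab <- lab[-i]; ca <- ca[-i]; co <- co[-i]
        if (length(ca) < 2L) { reason <- "exhausted"; break }
    }
    rr <- if (length(rounds)) do.call(rbind, rounds) else
        data.frame(round = integer(), label = character(),
                   observed = numeric(), expected = numeric(),
                   contribution = numeric(), z = numeric(), p_z = numeric(),
                   overall_chi2 = numeric(), overall_df = integer(),
                   overall_p = numeric(), case_total = numeric(),
                   control_total = numeric(), stringsAsFactors = FALSE)
    new("RPETrace", rounds = rr, stopReason = reason,
        caseTotal = x@caseTotal, controlTotal = x@controlTotal)
}

#' @rdname accessors
setMethod("rpeRounds", "RPETrace", function(x, ...) x@rounds)

#' @rdname accessors
setMethod("stopReason", "RPETrace", function(x, ...) x@stopReason)

setMethod("show", "RPETrace", function(object) {
    r <- object@rounds
    cat("RPETrace:", nrow(r), "rounds ( stop:", object@stopReason, ")\n")
    if (nrow(r)) {
        disp <- data.frame(round = r$round, label = r$label,
                           observed = r$observed,
                           expected = round(r$expected),
                           chi2 = sprintf("%.2f", r$contribution),
                           z = sprintf("%.2f", abs(r$z)),
                           p_z = signif(r$p_z, 2))
        print(disp, row.names = FALSE)
    }
})
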