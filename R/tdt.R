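# Stratified transmission analysis of the haplotype inherited from the
# parent not carrying the risk haplotype (the "X/Y parent").
#
# Offspring of the requested affection status are stratified by carriage
# of the risk haplotype.  Within each stratum, every heterozygous parent
# carrying neither copy of the risk haplotype contributes one transmitted
# (T) and one not-transmitted (NT) chromosome; homozygous parents are
# uninformative, and families where both parents carry the risk haplotype
# have no eligible X/Y parent and are excluded from both strata.

.riskCarrier <- function(h1, h2, risk) h1 == risk | h2 == risk

# Transmitted haplotype from one eligible parent to one child, resolved
# through the Mendelian phase assignments; NA when the valid assignments
# disagree (ambiguous) or none is valid.
.transmittedFrom <- function(child, father, mother, parent = c("F", "M")) {
    parent <- match.arg(parent)
    validA <- child[1] %in% father && child[2] %in% mother
    validB <- child[2] %in% father && child[1] %in% mother
    tr <- character(0)
    if (validA) tr <- c(tr, if (parent == "F") child[1] else child[2])
    if (validB) tr <- c(tr, if (parent == "F") child[2] else child[1])
    tr <- unique(tr)
    if (length(tr) == 1L) tr else NA_character_
}

#' Count stratified transmissions from the non-carrier parent
#'
#' For every child of the given affection status, the child is assigned to
#' the \code{risk_positive} or \code{risk_negative} stratum by carriage of
#' \code{risk}, and each heterozygous parent carrying neither copy of
#' \code{risk} contributes the haplotype it transmitted to the child (T)
#' and the one it did not (NT).  Mendelian-inconsistent families, families
#' where both parents carry the risk haplotype, homozygous parents, and
#' parents whose transmission cannot be resolved unambiguously from phase
#' are skipped and tallied in the \code{"exclusions"} attribute.
#'
#' In the risk-negative stratum both parents can qualify, so that stratum
#' typically counts more informative parents than children.
#'
#' @param trios a \code{\link{TrioSet}} of phased families.
#' @param risk the risk haplotype label indexing the stratification.
#' @param status which offspring to analyse: \code{"affected"} or
#'   \code{"unaffected"}.
#' @return Named list with \code{risk_positive} and \code{risk_negative}
#'   \code{\link{TransmissionTable}}s and an \code{"exclusions"} attribute
#'   (counts of skipped families/parents).
#' @export
countTransmissions <- function(trios, risk,
                               status = c("affected", "unaffected")) {
    stopifnot(is(trios, "TrioSet"))
    status <- match.arg(status)
    wanted <- if (status == "affected") 2L else 1L
    risk <- normalizeHaplotypeLabel(risk)
    excl <- c(inconsistent_families = 0L, both_parents_carry = 0L,
              ambiguous_parents = 0L)
    acc <- list(risk_positive = list(T = character(0), NT = character(0)),
                risk_negative = list(T = character(0), NT = character(0)))
    for (fam in .familySplit(trios)) {
        f <- unlist(fam[fam$member == "F", c("hap1", "hap2")], use.names = FALSE)
        m <- unlist(fam[fam$member == "M", c("hap1", "hap2")], use.names = FALSE)
        kids <- fam[fam$member == "C" & fam$status == wanted, , drop = FALSE]
        if (!nrow(kids)) next
        ok <- vapply(seq_len(nrow(kids)), function(i)
            .childConsistent(c(kids$hap1[i], kids$hap2[i]), f, m), logical(1))
        if (!all(ok)) {
            excl["inconsistent_families"] <- excl["inconsistent_families"] + 1L
            next
        }
        if (.riskCarrier(f[1], f[2], risk) && .riskCarrier(m[1], m[2], risk)) {
            excl["both_parents_carry"] <- excl["both_parents_carry"] + 1L
            next
        }
        for (i in seq_len(nrow(kids))) {
            child <- c(kids$hap1[i], kids$hap2[i])
            stratum <- if (.riskCarrier(child[1], child[2], risk))
                "risk_positive" else "risk_negative"
            for (pcode in c("F", "M")) {
                par <- if (pcode == "F") f else m
                if (.riskCarrier(par[1], par[2], risk)) next  # not an X/Y parent
                if (par[1] == par[2]) next                    # uninformative
                tr <- .transmittedFrom(child, f, m, pcode)
                if (is.na(tr)) {
                    excl["ambiguous_parents"] <- excl["ambiguous_parents"] + 1L
                    next
                }
                nt <- if (tr == par[1]) par[2] else par[1]
                acc[[stratum]]$T <- c(acc[[stratum]]$T, tr)
                acc[[stratum]]$NT <- c(acc[[stratum]]$NT, nt)
            }
        }
    }
    build <- function(stratum) {
        labs <- sort(unique(c(acc[[stratum]]$T, acc[[stratum]]$NT)),
                     method = "radix")
        TransmissionTable(stratum, labs,
            as.integer(table(factor(acc[[stratum]]$T, levels = labs))),
            as.integer(table(factor(acc[[stratum]]$NT, levels = labs))))
    }
    ans <- list(risk_positive = build("risk_positive"),
                risk_negative = build("risk_negative"))
    attr(ans, "exclusions") <- excl
    ans
}

#' Haplotype-versus-rest transmission test
#'
#' Tests one haplotype's transmitted/not-transmitted counts against all
#' other haplotypes in the same stratum with the 2x2 table
#' \code{[[T, NT], [n - T, n - NT]]} (this haplotype vs the rest,
#' transmitted vs not): \code{OR = T (n - NT) / (NT (n - T))} and a
#' Pearson chi-square (1 df, no continuity correction) with two-sided p.
#' The paired McNemar statistic \code{(T - NT)^2 / (T + NT)} is available
#' as an alternative via \code{method = "mcnemar"}.
#'
#' @param T,NT transmitted and not-transmitted counts of the haplotype.
#' @param nInformative number of informative parents in the stratum (the
#'   common T and NT column total).
#' @param method \code{"vsrest"} (default) or \code{"mcnemar"}.
#' @return List with \code{odds_ratio}, \code{chi2}, \code{p}.
#' @examples
#' tdtVsRest(35, 12, 269)   # OR 3.2, p 4.5e-4
#' @export
tdtVsRest <- function(T, NT, nInformative, method = c("vsrest", "mcnemar")) {
    method <- match.arg(method)
    if (nInformative <= 0) stop("nInformative must be positive")
    if (T > nInformative || NT > nInformative)
        stop("T and NT cannot exceed nInformative")
    if (method == "mcnemar") {
        if (T + NT == 0) return(list(odds_ratio = NaN, chi2 = 0, p = 1))
        chi2 <- (T - NT)^2 / (T + NT)
        return(list(odds_ratio = T / NT, chi2 = chi2,
                    p = pchisq(chi2, 1, lower.tail = FALSE)))
    }
    or <- oddsRatio2x2(T, NT, nInformative, nInformative)
    ct <- chisqP2x2(T, NT, nInformative, nInformative)
    list(odds_ratio = or$odds_ratio, chi2 = ct$chi2, p = ct$p)
}

#' Compare a haplotype's transmission between two strata
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 table
#' \code{[[T_pos, NT_pos], [T_neg, NT_neg]]} of transmitted and
#' not-transmitted counts in the risk-positive and risk-negative strata.
#' A zero margin yields chi-square 0 and p = 1 with a warning.
#'
#' @param Tpos,NTpos transmitted / not-transmitted counts, risk-positive
#'   stratum.
#' @param Tneg,NTneg the same in the risk-negative stratum.
#' @return List with \code{chi2} and \code{p}.
#' @examples
#' compareStrata(8, 14, 29, 14)   # chi2 5.7, p 1.7e-2
#' @export
compareStrata <- function(Tpos, NTpos, Tneg, NTneg) {
    m <- matrix(c(Tpos, Tneg, NTpos, NTneg), nrow = 2)
    if (any(m < 0)) stop("counts must be non-negative")
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
        warning("empty margin: chi2 = 0, p = 1")
        return(list(chi2 = 0, p = 1))
    }
    ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    list(chi2 = unname(ht$statistic), p = unname(ht$p.value))
}

#' Per-haplotype stratified transmission analysis
#'
#' Combines a pair of per-stratum \code{\link{TransmissionTable}}s into
#' one result table: per haplotype the T/NT counts, haplotype-vs-rest odds
#' ratio and test in each stratum, and the between-strata comparison.
#'
#' @param tables named list with \code{risk_positive} and
#'   \code{risk_negative} \code{TransmissionTable}s (as returned by
#'   \code{\link{countTransmissions}}).
#' @param method per-haplotype test, see \code{\link{tdtVsRest}}.
#' @return Data frame, one row per haplotype.
#' @export
analyzeTransmissions <- function(tables, method = c("vsrest", "mcnemar")) {
    method <- match.arg(method)
    pos <- tables$risk_positive
    neg <- tables$risk_negative
    stopifnot(is(pos, "TransmissionTable"), is(neg, "TransmissionTable"))
    labs <- sort(unique(c(pos@label, neg@label)), method = "radix")
    nPos <- nInformative(pos)
    nNeg <- nInformative(neg)
    get <- function(tab, lab, slot) {
        i <- match(lab, tab@label)
        if (is.na(i)) 0L else slot(tab)[[i]]
    }
    rows <- lapply(labs, function(lab) {
        Tp <- get(pos, lab, transmitted); NTp <- get(pos, lab, notTransmitted)
        Tn <- get(neg, lab, transmitted); NTn <- get(neg, lab, notTransmitted)
        tp <- if (nPos > 0) tdtVsRest(Tp, NTp, nPos, method) else
            list(odds_ratio = NA_real_, chi2 = NA_real_, p = NA_real_)
        tn <- if (nNeg > 0) tdtVsRest(Tn, NTn, nNeg, method) else
            list(odds_ratio = NA_real_, chi2 = NA_real_, p = NA_real_)
        bt <- if (Tp + NTp > 0 && Tn + NTn > 0)
            suppressWarnings(compareStrata(Tp, NTp, Tn, NTn)) else
            list(chi2 = NA_real_, p = NA_real_)
        data.frame(label = lab, T_pos = Tp, NT_pos = NTp,
                   or_pos = tp$odds_ratio, chi2_pos = tp$chi2, p_pos = tp$p,
                   T_neg = Tn, NT_neg = NTn, or_neg = tn$odds_ratio,
                   chi2_neg = tn$chi2, p_neg = tn$p,
                   between_chi2 = bt$chi2, between_p = bt$p,
                   stringsAsFactors = FALSE)
    })
    ans <- do.call(rbind, rows)
    attr(ans, "n_informative") <- c(risk_positive = nPos, risk_negative = nNeg)
    ans
}

#' Stratified TDT of the haplotype from the non-carrier parent
#'
#' End-to-end driver: validates that the risk haplotype is informative in
#' enough heterozygous parents, counts stratified transmissions with
#' \code{\link{countTransmissions}}, and analyses them with
#' \code{\link{analyzeTransmissions}}.
#'
#' @inheritParams countTransmissions
#' @param minHetParents minimum number of heterozygous parents carrying
#'   the risk haplotype for the stratification to be attempted (default
#'   250, matching the informativeness gate of the original design).
#' @param method per-haplotype test, see \code{\link{tdtVsRest}}.
#' @return Data frame as from \code{\link{analyzeTransmissions}}, with
#'   \code{"exclusions"} and \code{"n_informative"} attributes.
#' @export
stratifiedTDT <- function(trios, risk, status = c("affected", "unaffected"),
                          minHetParents = 250,
                          method = c("vsrest", "mcnemar")) {
    stopifnot(is(trios, "TrioSet"))
    risk <- normalizeHaplotypeLabel(risk)
    ped <- trios@ped
    par <- ped[ped$member %in% c("F", "M"), ]
    nHet <- sum(xor(par$hap1 == risk, par$hap2 == risk))
    if (nHet < minHetParents)
        stop("risk haplotype ", risk, " carried by only ", nHet,
             " heterozygous parents (< ", minHetParents, ")")
    tabs <- countTransmissions(trios, risk, status)
    ans <- analyzeTransmissions(tabs, method)
    attr(ans, "exclusions") <- attr(tabs, "exclusions")
    ans
}
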