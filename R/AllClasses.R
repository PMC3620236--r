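# Class definitions. Count tables carry their cohort totals separately from
# the displayed rows: rows need not exhaust the totals, because haplotypes
# below the reporting threshold are kept in the denominators.

#' @rdname CountTable
#' @export
setClass("CountTable",
    representation("VIRTUAL",
        label        = "character",
        caseCount    = "integer",
        controlCount = "integer",
        caseTotal    = "integer",
        controlTotal = "integer"))

.validCountTable <- function(object) {
    msg <- NULL
    n <- length(object@label)
    if (length(object@caseCount) != n || length(object@controlCount) != n)
        msg <- c(msg, "label, caseCount and controlCount must have equal length")
    if (n == 0L)
        msg <- c(msg, "no rows")
    if (anyNA(object@label) || any(!nzchar(object@label)))
        msg <- c(msg, "labels must be non-empty")
    if (anyDuplicated(object@label)) {
        dup <- unique(object@label[duplicated(object@label)])
        msg <- c(msg, paste0("duplicate label(s): ",
                             paste(dup, collapse = ", ")))
    }
    if (anyNA(object@caseCount) || anyNA(object@controlCount) ||
        any(object@caseCount < 0L) || any(object@controlCount < 0L))
        msg <- c(msg, "counts must be non-negative integers")
    if (length(object@caseTotal) != 1L || length(object@controlTotal) != 1L ||
        anyNA(object@caseTotal) || anyNA(object@controlTotal))
        msg <- c(msg, "missing totals")
    else {
        if (object@caseTotal <= 0L || object@controlTotal <= 0L)
            msg <- c(msg, "totals must be positive")
        if (!anyNA(object@caseCount) && sum(object@caseCount) > object@caseTotal)
            msg <- c(msg, "row case counts exceed caseTotal")
        if (!anyNA(object@controlCount) &&
            sum(object@controlCount) > object@controlTotal)
            msg <- c(msg, "row control counts exceed controlTotal")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("CountTable", .validCountTable)

#' Count-table containers
#'
#' \code{HaplotypeCounts} holds per-haplotype case and control chromosome
#' counts; \code{GenotypeCounts} holds per-genotype (unordered haplotype
#' pair) case and control individual counts.  Both carry cohort totals that
#' may exceed the sum of the displayed rows, so that rare, undisplayed
#' chromosomes or individuals stay in the denominators.
#'
#' @param label character vector of haplotype labels, or of genotype labels
#'   written as \code{"hapA/hapB"} (order-insensitive; pairs are
#'   canonicalised).
#' @param caseCount,controlCount non-negative integer counts per row
#'   (chromosomes for haplotypes, individuals for genotypes).
#' @param caseTotal,controlTotal cohort totals (total chromosomes or total
#'   individuals genotyped), at least the corresponding row sums.
#' @return An object of class \code{HaplotypeCounts} or
#'   \code{GenotypeCounts}.
#' @examples
#' tab <- HaplotypeCounts(c("A", "B"), c(30L, 10L), c(15L, 20L), 50L, 40L)
#' caseCounts(tab)
#' @aliases CountTable-class HaplotypeCounts-class GenotypeCounts-class
#' @name CountTable
NULL

#' @rdname CountTable
#' @export
setClass("HaplotypeCounts", contains = "CountTable")

#' @rdname CountTable
#' @export
setClass("GenotypeCounts", contains = "CountTable")

setValidity("GenotypeCounts", function(object) {
    bad <- !grepl("/", object@label, fixed = TRUE)
    if (any(bad))
        return(paste0("genotype labels must be 'hapA/hapB' pairs: ",
                      paste(object@label[bad], collapse = ", ")))
    TRUE
})

#' @rdname CountTable
#' @export
HaplotypeCounts <- function(label, caseCount, controlCount,
                            caseTotal, controlTotal) {
    new("HaplotypeCounts",
        label = normalizeHaplotypeLabel(as.character(label)),
        caseCount = as.integer(caseCount),
        controlCount = as.integer(controlCount),
        caseTotal = as.integer(caseTotal),
        controlTotal = as.integer(controlTotal))
}

#' @rdname CountTable
#' @export
GenotypeCounts <- function(label, caseCount, controlCount,
                           caseTotal, controlTotal) {
    new("GenotypeCounts",
        label = canonicalGenotype(as.character(label)),
        caseCount = as.integer(caseCount),
        controlCount = as.integer(controlCount),
        caseTotal = as.integer(caseTotal),
        controlTotal = as.integer(controlTotal))
}

#' Phased trio-family container
#'
#' A pedigree-like table of phased trio families: per member one row with
#' the two haplotype labels and the affection status.  Member codes are
#' \code{"F"} (father), \code{"M"} (mother) and \code{"C"} (child; several
#' children per family are allowed, e.g. an affected proband plus a healthy
#' sibling).  Status follows PED conventions: 2 affected, 1 unaffected,
#' 0 unknown.
#'
#' @param family character vector of family identifiers.
#' @param member character vector of member codes (\code{F}, \code{M},
#'   \code{C}).
#' @param hap1,hap2 phased haplotype labels of the two chromosomes.
#' @param status integer affection status (0, 1 or 2).
#' @return A \code{TrioSet}.
#' @examples
#' trio <- TrioSet(family = rep("fam1", 3),
#'                 member = c("F", "M", "C"),
#'                 hap1 = c("A", "B", "A"), hap2 = c("C", "D", "B"),
#'                 status = c(1L, 1L, 2L))
#' validateTrios(trio)
#' @aliases TrioSet-class
#' @export
TrioSet <- function(family, member, hap1, hap2, status) {
    new("TrioSet", ped = data.frame(
        family = as.character(family),
        member = as.character(member),
        hap1 = normalizeHaplotypeLabel(as.character(hap1)),
        hap2 = normalizeHaplotypeLabel(as.character(hap2)),
        status = as.integer(status),
        stringsAsFactors = FALSE))
}

#' @rdname TrioSet
#' @export
setClass("TrioSet", representation(ped = "data.frame"))

setValidity("TrioSet", function(object) {
    ped <- object@ped
    need <- c("family", "member", "hap1", "hap2", "status")
    if (!all(need %in% names(ped)))
        return(paste("ped must have columns", paste(need, collapse = ", ")))
    msg <- NULL
    if (!all(ped$member %in% c("F", "M", "C")))
        msg <- c(msg, "member codes must be F, M or C")
    if (!all(ped$status %in% 0:2))
        msg <- c(msg, "status must be 0 (unknown), 1 (unaffected) or 2 (affected)")
    tab <- table(ped$family, factor(ped$member, levels = c("F", "M", "C")))
    if (nrow(tab) && any(tab[, "F"] != 1L | tab[, "M"] != 1L | tab[, "C"] < 1L))
        msg <- c(msg,
            "each family needs exactly one father, one mother, >=1 child")
    if (is.null(msg)) TRUE else msg
})

#' Per-stratum transmission counts
#'
#' Transmitted (T) and not-transmitted (NT) counts of parental haplotypes
#' within one offspring stratum.  Every informative parent contributes
#' exactly one transmitted and one untransmitted chromosome, so the T and
#' NT columns both sum to the number of informative parents.
#'
#' @param stratum single string naming the stratum (e.g.
#'   \code{"risk_positive"}).
#' @param label haplotype labels.
#' @param transmitted,notTransmitted integer counts per label.
#' @return A \code{TransmissionTable}.
#' @aliases TransmissionTable-class
#' @export
TransmissionTable <- function(stratum, label, transmitted, notTransmitted) {
    new("TransmissionTable", stratum = as.character(stratum),
        label = normalizeHaplotypeLabel(as.character(label)),
        transmitted = as.integer(transmitted),
        notTransmitted = as.integer(notTransmitted))
}

#' @rdname TransmissionTable
#' @export
setClass("TransmissionTable",
    representation(stratum = "character", label = "character",
                   transmitted = "integer", notTransmitted = "integer"))

setValidity("TransmissionTable", function(object) {
    msg <- NULL
    n <- length(object@label)
    if (length(object@transmitted) != n || length(object@notTransmitted) != n)
        msg <- c(msg, "label, transmitted, notTransmitted lengths differ")
    if (anyDuplicated(object@label))
        msg <- c(msg, "duplicate haplotype labels")
    if (any(object@transmitted < 0L) || any(object@notTransmitted < 0L))
        msg <- c(msg, "counts must be non-negative")
    if (sum(object@transmitted) != sum(object@notTransmitted))
        msg <- c(msg,
            "transmitted and not-transmitted totals must both equal the number of informative parents")
    if (is.null(msg)) TRUE else msg
})

#' Trace of the sequential relative predispositional effect procedure
#'
#' Ordered record of RPE rounds: the haplotype removed in each round, its
#' observed and expected counts at the round's running totals, its
#' chi-square contribution and two-proportion z statistic, and the overall
#' goodness-of-fit test that drives the stopping rule.
#'
#' @aliases RPETrace-class rpeRounds stopReason
#' @seealso \code{\link{runRPE}}
#' @export
setClass("RPETrace",
    representation(rounds = "data.frame", stopReason = "character",
                   caseTotal = "integer", controlTotal = "integer"))

#' Log-additivity interaction records
#'
#' One row per genotype: the two haplotypic odds ratios, the observed and
#' expected (product) genotypic odds ratios, the alpha deviation statistic
#' and its classification against the neutral band.
#'
#' @aliases AlphaTable-class alphaRecords
#' @seealso \code{\link{buildAlphaTable}}
#' @export
setClass("AlphaTable", representation(records = "data.frame"))

#' Simulation configuration
#'
#' Parameters of the synthetic-cohort and trio-family generator: haplotype
#' frequencies in the source population, a baseline disease risk, per-
#' haplotype multiplicative relative risks, optional per-genotype
#' interaction terms expressed directly as the target alpha (a log10
#' multiplier on the genotype risk), sample sizes and a seed.
#'
#' @aliases SimulationConfig-class
#' @seealso \code{\link{simulationConfig}}
#' @export
setClass("SimulationConfig",
    representation(haplotypeFreqs = "numeric", baselineRisk = "numeric",
                   haplotypeRR = "numeric", interactionAlpha = "numeric",
                   nCases = "integer", nControls = "integer",
                   nFamilies = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- NULL
    f <- object@haplotypeFreqs
    if (is.null(names(f)) || any(!nzchar(names(f))) || anyDuplicated(names(f)))
        msg <- c(msg, "haplotypeFreqs must have unique non-empty names")
    if (any(f < 0) || abs(sum(f) - 1) > 1e-9)
        msg <- c(msg, "haplotype frequencies must be non-negative and sum to 1")
    if (length(object@baselineRisk) != 1L || object@baselineRisk <= 0 ||
        object@baselineRisk >= 1)
        msg <- c(msg, "baselineRisk must lie in (0, 1)")
    if (any(object@haplotypeRR <= 0))
        msg <- c(msg, "relative risks must be positive")
    if (!all(names(object@haplotypeRR) %in% names(f)))
        msg <- c(msg, "haplotypeRR names must be haplotype labels")
    if (any(object@nCases < 0L, object@nControls < 0L, object@nFamilies < 0L))
        msg <- c(msg, "sample sizes must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' Simulated case-control cohort
#'
#' Phased genotypes (pairs of haplotype labels) with case/control status,
#' together with the configuration that generated them.  Count tables for
#' the association stages are derived with \code{\link{haplotypeCounts}}
#' and \code{\link{genotypeCounts}}.
#'
#' @aliases SimulatedCohort-class
#' @seealso \code{\link{generateCohort}}
#' @export
setClass("SimulatedCohort",
    representation(individuals = "data.frame", config = "SimulationConfig"))

setValidity("SimulatedCohort", function(object) {
    need <- c("hap1", "hap2", "status")
    if (!all(need %in% names(object@individuals)))
        return("individuals must have columns hap1, hap2, status")
    if (!all(object@individuals$status %in% c("case", "control")))
        return("status must be 'case' or 'control'")
    TRUE
})
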