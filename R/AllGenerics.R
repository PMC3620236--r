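#' Accessors for count tables and derived objects
#'
#' Small accessor family in the Bioconductor idiom: slot access stays
#' behind functions.
#'
#' @param x an object of one of the package's classes.
#' @param ... passed to methods.
#' @return The corresponding component (labels, counts, totals, ...).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("countLabels", function(x, ...) standardGeneric("countLabels"))

#' @rdname accessors
#' @export
setGeneric("caseCounts", function(x, ...) standardGeneric("caseCounts"))

#' @rdname accessors
#' @export
setGeneric("controlCounts", function(x, ...) standardGeneric("controlCounts"))

#' @rdname accessors
#' @export
setGeneric("caseTotal", function(x, ...) standardGeneric("caseTotal"))

#' @rdname accessors
#' @export
setGeneric("controlTotal", function(x, ...) standardGeneric("controlTotal"))

#' @rdname accessors
#' @export
setGeneric("pedigree", function(x, ...) standardGeneric("pedigree"))

#' @rdname accessors
#' @export
setGeneric("transmitted", function(x, ...) standardGeneric("transmitted"))

#' @rdname accessors
#' @export
setGeneric("notTransmitted", function(x, ...) standardGeneric("notTransmitted"))

#' @rdname accessors
#' @export
setGeneric("nInformative", function(x, ...) standardGeneric("nInformative"))

#' @rdname accessors
#' @export
setGeneric("rpeRounds", function(x, ...) standardGeneric("rpeRounds"))

#' @rdname accessors
#' @export
setGeneric("stopReason", function(x, ...) standardGeneric("stopReason"))

#' @rdname accessors
#' @export
setGeneric("alphaRecords", function(x, ...) standardGeneric("alphaRecords"))

#' @rdname accessors
#' @export
setGeneric("individuals", function(x, ...) standardGeneric("individuals"))

#' Collapse fine haplotype labels into haplogroups
#'
#' @param x a \code{\link{HaplotypeCounts}} table.
#' @param map a grouping map: named character vector (names = fine labels,
#'   values = haplogroup labels), or a two-column data frame.  Labels
#'   absent from the map keep their own name (identity).
#' @return A table of the same class with counts summed within each group;
#'   totals unchanged.
#' @seealso \code{\link{readGroupingMap}}
#' @export
setGeneric("collapseHaplogroups",
           function(x, map) standardGeneric("collapseHaplogroups"))

#' Keep rows reaching a frequency threshold in either cohort
#'
#' A row is retained when its frequency reaches \code{threshold} in cases
#' \emph{or} in controls (the either-group rule: a haplotype rare in cases
#' but common in controls is still informative).
#'
#' @param x a \code{\link{HaplotypeCounts}} or \code{\link{GenotypeCounts}}
#'   table.
#' @param threshold proportion in (0, 1); default 0.01 (1 percent).
#' @return The filtered table; totals unchanged.
#' @export
setGeneric("filterByFrequency",
           function(x, threshold = 0.01) standardGeneric("filterByFrequency"))

#' @rdname haplotypeCounts
#' @export
setGeneric("haplotypeCounts", function(x, ...) standardGeneric("haplotypeCounts"))

#' @rdname haplotypeCounts
#' @export
setGeneric("genotypeCounts", function(x, ...) standardGeneric("genotypeCounts"))
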