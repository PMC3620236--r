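# Log-additivity interaction model: under statistical independence of the
# two haplotypes, the expected genotypic odds ratio is the product of the
# haplotypic ones (additivity on the log scale); alpha measures the
# deviation of the observed genotypic OR from that expectation.

#' Expected genotypic odds ratio under haplotypic independence
#'
#' \code{ORgexp = ORha * ORhb}: if the two haplotypes combine their risks
#' independently, the genotype's odds ratio is the product of the two
#' haplotypic odds ratios (log-additivity).
#'
#' @param orHa,orHb haplotypic odds ratios (positive; vectorised).
#' @return Expected genotypic odds ratio(s).
#' @examples
#' expectedGenotypicOR(1.7, 2.1)   # 3.57
#' @export
expectedGenotypicOR <- function(orHa, orHb) {
    if (any(orHa <= 0) || any(orHb <= 0))
        stop("haplotypic odds ratios must be positive")
    orHa * orHb
}

#' Alpha: log-scale deviation of the observed genotypic OR
#'
#' \code{alpha = log10(ORgobs) - log10(ORgexp)} (base configurable).
#' Zero means exact log-additivity; negative values mean the genotype is
#' less extreme than the haplotypes predict (negative interaction),
#' positive values the opposite.
#'
#' @param orGObs observed genotypic odds ratio (positive; vectorised).
#' @param orGExp expected genotypic odds ratio (positive; vectorised).
#' @param base logarithm base, default 10.
#' @return Alpha value(s).
#' @examples
#' alphaStat(0.2, 0.30)   # -0.18
#' @export
alphaStat <- function(orGObs, orGExp, base = 10) {
    if (any(orGObs <= 0) || any(orGExp <= 0))
        stop("odds ratios must be positive")
    log(orGObs, base) - log(orGExp, base)
}

#' Classify alpha against the neutral band
#'
#' Values inside the band (endpoints inclusive) are \code{"neutral"}
#' (additive combination); above it \code{"positive_interaction"}; below
#' it \code{"negative_interaction"}.  The default band [0.01, 0.09] is
#' asymmetric about zero, so small non-negative alphas below 0.01 classify
#' as negative interaction while carrying a positive sign — the sign is
#' therefore reported separately by \code{\link{alphaSign}}.
#'
#' @param alpha alpha value(s).
#' @param band numeric length-2 neutral band, low < high.
#' @return Character vector of classifications.
#' @examples
#' classifyAlpha(c(0.03, -0.11, 0.09))
#' @export
classifyAlpha <- function(alpha, band = c(0.01, 0.09)) {
    if (length(band) != 2L || band[1] >= band[2])
        stop("band must be an increasing length-2 interval")
    ifelse(alpha > band[2], "positive_interaction",
           ifelse(alpha < band[1], "negative_interaction", "neutral"))
}

#' @rdname classifyAlpha
#' @export
alphaSign <- function(alpha) {
    ifelse(alpha > 0, "predisposing", ifelse(alpha < 0, "protective", "none"))
}

#' Build the alpha interaction table from association results
#'
#' For each requested genotype, looks up the two haplotypic odds ratios
#' and the observed genotypic odds ratio in the association outputs,
#' computes the expected genotypic OR as their product and the alpha
#' deviation.  In \code{"reproduction"} mode all odds ratios are first
#' rounded to one decimal — the precision at which published tables report
#' them — so alphas can be compared digit-for-digit with printed values;
#' \code{"full"} mode combines the odds ratios at full precision.
#'
#' @param hapResults data frame from \code{\link{associateTable}} on the
#'   haplotype table.
#' @param genResults data frame from \code{\link{associateTable}} on the
#'   genotype table.
#' @param pairs character vector of genotype labels (\code{"hapA/hapB"});
#'   default: the genotypes marked significant in \code{genResults}.
#' @param mode \code{"reproduction"} (1-decimal odds ratios) or
#'   \code{"full"}.
#' @param base logarithm base for alpha, default 10.
#' @param band neutral band passed to \code{\link{classifyAlpha}}.
#' @return An \code{\link{AlphaTable-class}} object; see
#'   \code{\link{alphaRecords}}.
#' @export
buildAlphaTable <- function(hapResults, genResults, pairs = NULL,
                            mode = c("reproduction", "full"), base = 10,
                            band = c(0.01, 0.09)) {
    mode <- match.arg(mode)
    if (is.null(pairs))
        pairs <- genResults$label[genResults$significant]
    pairs <- canonicalGenotype(pairs)
    hapOR <- setNames(hapResults$odds_ratio, hapResults$label)
    genOR <- setNames(genResults$odds_ratio, canonicalGenotype(genResults$label))
    rows <- lapply(pairs, function(pr) {
        hp <- strsplit(pr, "/", fixed = TRUE)[[1]]
        missing <- hp[!(hp %in% names(hapOR))]
        if (length(missing))
            stop("haplotype not present in hapResults: ",
                 paste(missing, collapse = ", "))
        if (!(pr %in% names(genOR)))
            stop("genotype not present in genResults: ", pr)
        orA <- unname(hapOR[hp[1]]); orB <- unname(hapOR[hp[2]])
        orObs <- unname(genOR[pr])
        if (mode == "reproduction") {
            orA <- round(orA, 1); orB <- round(orB, 1)
            orObs <- round(orObs, 1)
        }
        orExp <- expectedGenotypicOR(orA, orB)
        a <- alphaStat(orObs, orExp, base)
        data.frame(genotype = pr,
                   character = paste(
                       ifelse(c(orA, orB) < 1, "protective", "predisposing"),
                       collapse = "/"),
                   or_ha = orA, or_hb = orB, or_g_obs = orObs,
                   or_g_exp = orExp, alpha = a,
                   classification = classifyAlpha(a, band),
                   sign = alphaSign(a), stringsAsFactors = FALSE)
    })
    new("AlphaTable", records = do.call(rbind, rows))
}

#' @rdname accessors
setMethod("alphaRecords", "AlphaTable", function(x, ...) x@records)

#' @export
setMethod("as.data.frame", "AlphaTable",
    function(x, row.names = NULL, optional = FALSE, ...) x@records)

setMethod("show", "AlphaTable", function(object) {
    r <- object@records
    cat("AlphaTable with", nrow(r), "genotypes\n")
    disp <- data.frame(genotype = r$genotype, ORha = round(r$or_ha, 2),
                       ORhb = round(r$or_hb, 2),
                       ORgobs = round(r$or_g_obs, 2),
                       ORgexp = round(r$or_g_exp, 2),
                       alpha = sprintf("%.2f", r$alpha),
                       class = r$classification)
    print(disp, row.names = FALSE)
})
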