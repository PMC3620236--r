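# Bundled reference data: published Sardinian multiple-sclerosis
# case-control and trio-transmission count tables, shipped as plain TSV so
# every analysis stage can be exercised and checked against printed
# values without access to individual-level data.

#' Paths to the bundled Sardinian HLA count tables
#'
#' @param name which fixture: \code{"haplotypes"} (per-haplotype
#'   chromosome counts, 2,555 patients / 1,365 controls),
#'   \code{"genotypes"} (per-genotype individual counts), or
#'   \code{"transmissions"} (stratified trio transmission counts indexed
#'   by carriage of the *03:01-*02:01 risk haplotype).
#' @return Path to the installed TSV file.
#' @examples
#' readCountTable(hlaFixture("haplotypes"), "haplotype")
#' @export
hlaFixture <- function(name = c("haplotypes", "genotypes", "transmissions")) {
    name <- match.arg(name)
    system.file("extdata", paste0("sardinia_", name, ".tsv"),
                package = "hlaRisk", mustWork = TRUE)
}

#' Bundled Sardinian case-control and transmission tables
#'
#' Convenience loaders for the fixtures described in
#' \code{\link{hlaFixture}}.
#'
#' @return \code{sardinianHaplotypes}: a \code{\link{HaplotypeCounts}}
#'   (15 haplogroup-collapsed haplotypes, chromosome totals 5,110 /
#'   2,730).  \code{sardinianGenotypes}: a \code{\link{GenotypeCounts}}
#'   (28 genotypes, individual totals 2,555 / 1,365).
#'   \code{sardinianTransmissions}: a named list of two
#'   \code{\link{TransmissionTable}}s (\code{risk_positive},
#'   \code{risk_negative}).
#' @export
sardinianHaplotypes <- function()
    readCountTable(hlaFixture("haplotypes"), "haplotype")

#' @rdname sardinianHaplotypes
#' @export
sardinianGenotypes <- function()
    readCountTable(hlaFixture("genotypes"), "genotype")

#' @rdname sardinianHaplotypes
#' @export
sardinianTransmissions <- function() {
    df <- read.delim(hlaFixture("transmissions"), stringsAsFactors = FALSE)
    out <- lapply(split(df, df$stratum), function(s)
        TransmissionTable(s$stratum[1], s$label, s$transmitted,
                          s$not_transmitted))
    out[c("risk_positive", "risk_negative")]
}

#' Sardinian-like simulation configuration
#'
#' Builds a \code{\link{SimulationConfig-class}} emulating the study
#' population: haplotype frequencies taken from the bundled control
#' chromosome counts (with an explicit \code{"(other)"} category for the
#' rare undisplayed haplotypes), and per-haplotype relative risks set to
#' the case-control odds-ratio estimates — the odds ratio approximates
#' the risk ratio at the default 5\% baseline.  Defaults reproduce the
#' study's sample sizes (2,555 cases, 1,365 controls, 961 trio families).
#'
#' @param baselineRisk baseline disease probability; default 0.05.
#' @param nCases,nControls,nFamilies sample sizes.
#' @param seed integer seed (NA = current RNG state).
#' @return A \code{\link{SimulationConfig-class}}.
#' @export
sardinianConfig <- function(baselineRisk = 0.05, nCases = 2555,
                            nControls = 1365, nFamilies = 961, seed = NA) {
    tab <- sardinianHaplotypes()
    co <- controlCounts(tab)
    other <- controlTotal(tab) - sum(co)
    freqs <- c(co, "(other)" = other) / controlTotal(tab)
    assoc <- associateTable(tab)
    rr <- setNames(assoc$odds_ratio, assoc$label)
    simulationConfig(haplotypeFreqs = freqs, baselineRisk = baselineRisk,
                     haplotypeRR = rr, nCases = nCases,
                     nControls = nControls, nFamilies = nFamilies,
                     seed = seed)
}
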