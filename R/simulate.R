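# Seeded generator of haplotype pools, case-control cohorts and
# ascertained trio families.
#
# The population model: haplotypes are atomic labels drawn independently
# for the two chromosomes of an individual (random mating / Hardy-
# Weinberg at the haplotype level); disease risk is multiplicative across
# the two haplotypes, baseline * rr(ha) * rr(hb), optionally scaled by
# 10^alpha for specific genotypes so that a configured interaction is the
# target alpha by construction.  Cohorts are rejection-sampled to the
# requested case/control quotas; trio families are ascertained on an
# affected child.

#' Create a simulation configuration
#'
#' @param haplotypeFreqs named numeric vector of haplotype frequencies
#'   (must sum to 1).
#' @param baselineRisk disease probability of a genotype with relative
#'   risk 1 on both chromosomes; default 0.05.
#' @param haplotypeRR named numeric vector of per-haplotype multiplicative
#'   relative risks (unnamed haplotypes default to 1).
#' @param interactionAlpha named numeric vector of per-genotype
#'   interaction terms, names \code{"hapA/hapB"} (canonicalised); each is
#'   the target alpha, applied as a \code{10^alpha} multiplier on the
#'   genotype risk.
#' @param nCases,nControls case-control sample sizes.
#' @param nFamilies number of ascertained trio families.
#' @param seed integer seed; \code{NA} uses the current RNG state.
#' @return A \code{\link{SimulationConfig-class}} object.
#' @examples
#' cfg <- simulationConfig(c(A = 0.3, B = 0.2, C = 0.5),
#'                         haplotypeRR = c(A = 2), nCases = 100,
#'                         nControls = 100, seed = 1)
#' @export
simulationConfig <- function(haplotypeFreqs, baselineRisk = 0.05,
                             haplotypeRR = numeric(0),
                             interactionAlpha = numeric(0),
                             nCases = 0, nControls = 0, nFamilies = 0,
                             seed = NA) {
    if (length(interactionAlpha))
        names(interactionAlpha) <- canonicalGenotype(names(interactionAlpha))
    new("SimulationConfig",
        haplotypeFreqs = haplotypeFreqs, baselineRisk = baselineRisk,
        haplotypeRR = haplotypeRR, interactionAlpha = interactionAlpha,
        nCases = as.integer(nCases), nControls = as.integer(nControls),
        nFamilies = as.integer(nFamilies), seed = as.integer(seed))
}

#' Read a simulation configuration from JSON
#'
#' Expected fields mirror the \code{\link{simulationConfig}} arguments:
#' \code{haplotype_freqs} (object label -> frequency), optional
#' \code{baseline_risk}, \code{haplotype_rr}, \code{interaction_alpha}
#' (object "hapA/hapB" -> alpha), \code{n_cases}, \code{n_controls},
#' \code{n_families}, \code{seed}.
#'
#' @param path path to the JSON file.
#' @return A \code{\link{SimulationConfig-class}} object.
#' @export
readSimulationConfig <- function(path) {
    js <- jsonlite::fromJSON(path)
    simulationConfig(
        haplotypeFreqs = unlist(js$haplotype_freqs),
        baselineRisk = if (is.null(js$baseline_risk)) 0.05 else js$baseline_risk,
        haplotypeRR = if (is.null(js$haplotype_rr)) numeric(0) else
            unlist(js$haplotype_rr),
        interactionAlpha = if (is.null(js$interaction_alpha)) numeric(0) else
            unlist(js$interaction_alpha),
        nCases = if (is.null(js$n_cases)) 0 else js$n_cases,
        nControls = if (is.null(js$n_controls)) 0 else js$n_controls,
        nFamilies = if (is.null(js$n_families)) 0 else js$n_families,
        seed = if (is.null(js$seed)) NA else js$seed)
}

#' Draw phased genotypes under random mating
#'
#' The two chromosomes of each individual are independent draws from the
#' haplotype frequency vector (Hardy-Weinberg at the haplotype level).
#'
#' @param n number of individuals.
#' @param freqs named frequency vector, or a
#'   \code{\link{SimulationConfig-class}}.
#' @return Data frame with columns \code{hap1}, \code{hap2}.
#' @export
sampleGenotypes <- function(n, freqs) {
    if (is(freqs, "SimulationConfig")) freqs <- freqs@haplotypeFreqs
    labs <- names(freqs)
    draws <- sample(labs, 2 * n, replace = TRUE, prob = freqs)
    data.frame(hap1 = draws[seq_len(n)], hap2 = draws[n + seq_len(n)],
               stringsAsFactors = FALSE)
}

#' Disease probability of a genotype
#'
#' \code{baseline * rr(hap1) * rr(hap2) * 10^alpha(hap1/hap2)}, clipped at
#' 1 (clipping is reported with a warning: it signals a configuration
#' whose risks are no longer multiplicative at the top end).
#'
#' @param hap1,hap2 haplotype labels (vectorised).
#' @param config a \code{\link{SimulationConfig-class}}.
#' @return Numeric vector of probabilities.
#' @export
diseaseProbability <- function(hap1, hap2, config) {
    stopifnot(is(config, "SimulationConfig"))
    rr <- function(h) {
        r <- config@haplotypeRR[h]
        r[is.na(r)] <- 1
        unname(r)
    }
    key <- paste(pmin(hap1, hap2), pmax(hap1, hap2), sep = "/")
    ia <- config@interactionAlpha[key]
    ia[is.na(ia)] <- 0
    p <- config@baselineRisk * rr(hap1) * rr(hap2) * 10^unname(ia)
    if (any(p > 1)) {
        warning(sum(p > 1), " genotype risk(s) clipped to 1")
        p <- pmin(p, 1)
    }
    p
}

.withConfigSeed <- function(config, offset, expr) {
    if (is.na(config@seed)) expr
    else withr::with_seed(config@seed + offset, expr)
}

#' Generate a case-control cohort
#'
#' Rejection-samples individuals from the population model until the
#' configured case and control quotas are both filled.  Reproducible for
#' a given seed.
#'
#' @param config a \code{\link{SimulationConfig-class}} with positive
#'   \code{nCases} and \code{nControls}.
#' @param maxBatches iteration cap; exceeded quotas raise an error (e.g. a
#'   baseline risk too extreme to ever fill the case quota).
#' @return A \code{\link{SimulatedCohort-class}}.
#' @examples
#' cfg <- simulationConfig(c(A = 0.3, B = 0.7), haplotypeRR = c(A = 2),
#'                         nCases = 200, nControls = 200, seed = 7)
#' cohort <- generateCohort(cfg)
#' haplotypeCounts(cohort)
#' @export
generateCohort <- function(config, maxBatches = 10000L) {
    stopifnot(is(config, "SimulationConfig"))
    if (config@nCases < 1L || config@nControls < 1L)
        stop("config must request at least one case and one control")
    .withConfigSeed(config, 0L, {
        need <- config@nCases + config@nControls
        batch <- max(1000L, 2L * need)
        cases <- controls <- list()
        nca <- nco <- 0L
        it <- 0L
        while ((nca < config@nCases || nco < config@nControls)) {
            it <- it + 1L
            if (it > maxBatches)
                stop("could not fill case/control quotas within ",
                     maxBatches, " batches; baseline risk too extreme?")
            g <- sampleGenotypes(batch, config@haplotypeFreqs)
            p <- diseaseProbability(g$hap1, g$hap2, config)
            y <- rbinom(batch, 1L, p) == 1L
            if (nca < config@nCases) {
                cases[[it]] <- g[y, ][seq_len(min(sum(y),
                                      config@nCases - nca)), ]
                nca <- nca + nrow(cases[[it]])
            }
            if (nco < config@nControls) {
                controls[[it]] <- g[!y, ][seq_len(min(sum(!y),
                                          config@nControls - nco)), ]
                nco <- nco + nrow(controls[[it]])
            }
        }
        ca <- do.call(rbind, cases)
        co <- do.call(rbind, controls)
        ind <- rbind(cbind(ca, status = "case"),
                     cbind(co, status = "control"))
        rownames(ind) <- NULL
        new("SimulatedCohort", individuals = ind, config = config)
    })
}

#' Generate trio families ascertained on an affected child
#'
#' Parents are drawn from the population model; each child inherits one
#' uniformly chosen haplotype from each parent; families are kept when the
#' child is affected under \code{\link{diseaseProbability}} (parental
#' affection is ignored).  Optionally an unaffected sibling, drawn from
#' the same parents, is attached to families where the sibling draw came
#' out unaffected.
#'
#' @param config a \code{\link{SimulationConfig-class}} with positive
#'   \code{nFamilies}.
#' @param sibling also generate a healthy-sibling row where available.
#' @param maxBatches iteration cap, as in \code{\link{generateCohort}}.
#' @return A \code{\link{TrioSet}} (children coded \code{C}; the affected
#'   proband has status 2, the optional sibling status 1).
#' @export
generateTrios <- function(config, sibling = FALSE, maxBatches = 10000L) {
    stopifnot(is(config, "SimulationConfig"))
    if (config@nFamilies < 1L) stop("config must request >= 1 family")
    .withConfigSeed(config, 1L, {
        batch <- max(1000L, 2L * config@nFamilies)
        kept <- list()
        got <- 0L
        it <- 0L
        while (got < config@nFamilies) {
            it <- it + 1L
            if (it > maxBatches)
                stop("could not ascertain ", config@nFamilies,
                     " affected-child families within ", maxBatches,
                     " batches")
            f <- sampleGenotypes(batch, config@haplotypeFreqs)
            m <- sampleGenotypes(batch, config@haplotypeFreqs)
            cf <- ifelse(rbinom(batch, 1L, 0.5) == 1L, f$hap1, f$hap2)
            cm <- ifelse(rbinom(batch, 1L, 0.5) == 1L, m$hap1, m$hap2)
            aff <- rbinom(batch, 1L, diseaseProbability(cf, cm, config)) == 1L
            take <- which(aff)[seq_len(min(sum(aff), config@nFamilies - got))]
            if (length(take))
                kept[[it]] <- data.frame(f1 = f$hap1[take], f2 = f$hap2[take],
                                         m1 = m$hap1[take], m2 = m$hap2[take],
                                         c1 = cf[take], c2 = cm[take],
                                         stringsAsFactors = FALSE)
            got <- got + length(take)
        }
        fam <- do.call(rbind, kept)
        n <- nrow(fam)
        id <- sprintf("fam%05d", seq_len(n))
        ped <- rbind(
            data.frame(family = id, member = "F", hap1 = fam$f1,
                       hap2 = fam$f2, status = 1L, stringsAsFactors = FALSE),
            data.frame(family = id, member = "M", hap1 = fam$m1,
                       hap2 = fam$m2, status = 1L, stringsAsFactors = FALSE),
            data.frame(family = id, member = "C", hap1 = fam$c1,
                       hap2 = fam$c2, status = 2L, stringsAsFactors = FALSE))
        if (sibling) {
            s1 <- ifelse(rbinom(n, 1L, 0.5) == 1L, fam$f1, fam$f2)
            s2 <- ifelse(rbinom(n, 1L, 0.5) == 1L, fam$m1, fam$m2)
            healthy <- rbinom(n, 1L, diseaseProbability(s1, s2, config)) == 0L
            if (any(healthy))
                ped <- rbind(ped, data.frame(
                    family = id[healthy], member = "C", hap1 = s1[healthy],
                    hap2 = s2[healthy], status = 1L, stringsAsFactors = FALSE))
        }
        ped <- ped[order(ped$family, match(ped$member, c("F", "M", "C")),
                         ped$status), ]
        rownames(ped) <- NULL
        new("TrioSet", ped = ped)
    })
}

#' Derive count tables from a simulated cohort
#'
#' \code{haplotypeCounts} counts chromosomes per haplotype label (two per
#' individual; totals are twice the number of individuals);
#' \code{genotypeCounts} counts individuals per unordered haplotype pair.
#' All configured haplotype labels appear as rows, including unobserved
#' ones.
#'
#' @param x a \code{\link{SimulatedCohort-class}}.
#' @param ... unused.
#' @return A \code{\link{HaplotypeCounts}} or \code{\link{GenotypeCounts}}.
#' @name haplotypeCounts
NULL

#' @rdname haplotypeCounts
setMethod("haplotypeCounts", "SimulatedCohort", function(x, ...) {
    ind <- x@individuals
    labs <- names(x@config@haplotypeFreqs)
    isCase <- ind$status == "case"
    chromCase <- factor(c(ind$hap1[isCase], ind$hap2[isCase]), levels = labs)
    chromCtrl <- factor(c(ind$hap1[!isCase], ind$hap2[!isCase]), levels = labs)
    HaplotypeCounts(labs, as.integer(table(chromCase)),
                    as.integer(table(chromCtrl)),
                    2L * sum(isCase), 2L * sum(!isCase))
})

#' @rdname haplotypeCounts
setMethod("genotypeCounts", "SimulatedCohort", function(x, ...) {
    ind <- x@individuals
    key <- paste(pmin(ind$hap1, ind$hap2), pmax(ind$hap1, ind$hap2), sep = "/")
    labs <- sort(unique(key), method = "radix")
    isCase <- ind$status == "case"
    GenotypeCounts(labs,
                   as.integer(table(factor(key[isCase], levels = labs))),
                   as.integer(table(factor(key[!isCase], levels = labs))),
                   sum(isCase), sum(!isCase))
})

#' @rdname accessors
setMethod("individuals", "SimulatedCohort", function(x, ...) x@individuals)

setMethod("show", "SimulatedCohort", function(object) {
    st <- table(object@individuals$status)
    cat("SimulatedCohort:", st[["case"]], "cases,", st[["control"]],
        "controls;", length(object@config@haplotypeFreqs), "haplotypes\n")
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", length(object@haplotypeFreqs), "haplotypes,",
        "baseline risk", object@baselineRisk, "\n")
    cat("  non-unit RR:", sum(object@haplotypeRR != 1),
        "| interaction terms:", length(object@interactionAlpha),
        "| n:", object@nCases, "cases /", object@nControls, "controls /",
        object@nFamilies, "families\n")
})
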