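# Shared helpers: independent oracles and compact fixture builders.
# Oracles here deliberately re-derive quantities from first principles
# (closed-form enumeration, hand-rolled formulas) so they never share code
# with the implementation paths they check.

# Closed-form population tables for a simulation configuration: exact
# genotype probabilities under random mating, exact case/control genotype
# distributions under the configured risk model, and the implied
# chromosome-level and genotype-level odds ratios.  Pure enumeration — no
# sampling, no package statistics code.
popOracle <- function(cfg) {
    f <- cfg@haplotypeFreqs
    labs <- names(f)
    g <- expand.grid(h1 = labs, h2 = labs, stringsAsFactors = FALSE)
    g$pr <- f[g$h1] * f[g$h2]
    rr <- function(h) {
        r <- cfg@haplotypeRR[h]; r[is.na(r)] <- 1; unname(r)
    }
    key <- paste(pmin(g$h1, g$h2), pmax(g$h1, g$h2), sep = "/")
    ia <- cfg@interactionAlpha[key]; ia[is.na(ia)] <- 0
    g$pd <- pmin(cfg@baselineRisk * rr(g$h1) * rr(g$h2) * 10^unname(ia), 1)
    caseP <- g$pr * g$pd / sum(g$pr * g$pd)
    ctrlP <- g$pr * (1 - g$pd) / sum(g$pr * (1 - g$pd))
    chromCase <- (rowsum(caseP, g$h1) + rowsum(caseP, g$h2)) / 2
    chromCtrl <- (rowsum(ctrlP, g$h1) + rowsum(ctrlP, g$h2)) / 2
    genCase <- rowsum(caseP, key)
    genCtrl <- rowsum(ctrlP, key)
    odds <- function(p) p / (1 - p)
    list(
        chromOR = function(h) odds(chromCase[h, 1]) / odds(chromCtrl[h, 1]),
        genOR = function(k) odds(genCase[k, 1]) / odds(genCtrl[k, 1]),
        popAlpha = function(a, b) {
            k <- paste(sort(c(a, b), method = "radix"), collapse = "/")
            or <- odds(genCase[k, 1]) / odds(genCtrl[k, 1])
            exp_ <- (odds(chromCase[a, 1]) / odds(chromCtrl[a, 1])) *
                    (odds(chromCase[b, 1]) / odds(chromCtrl[b, 1]))
            log10(or) - log10(exp_)
        })
}

# Pooled two-proportion z statistic, squared: analytically identical to
# the Pearson chi-square of the corresponding 2x2 table.
pooledZ2 <- function(a, b, n1, n2) {
    p <- (a + b) / (n1 + n2)
    z <- (a / n1 - b / n2) / sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
    z^2
}

# Build a TrioSet from a list of family tuples:
# list(f = c(h1, h2), m = c(h1, h2), kids = list(list(h = c(h1, h2), s = 2)))
makeTrioSet <- function(families) {
    rows <- list()
    for (i in seq_along(families)) {
        fam <- families[[i]]
        id <- sprintf("fam%03d", i)
        rows[[length(rows) + 1L]] <- data.frame(
            family = id, member = c("F", "M"),
            hap1 = c(fam$f[1], fam$m[1]), hap2 = c(fam$f[2], fam$m[2]),
            status = 1L, stringsAsFactors = FALSE)
        for (kid in fam$kids)
            rows[[length(rows) + 1L]] <- data.frame(
                family = id, member = "C", hap1 = kid$h[1], hap2 = kid$h[2],
                status = kid$s, stringsAsFactors = FALSE)
    }
    ped <- do.call(rbind, rows)
    TrioSet(ped$family, ped$member, ped$hap1, ped$hap2, ped$status)
}

# Random small count table for property checks.
randomCountTable <- function(k = 6, nCase = 2000, nControl = 1000) {
    freqs <- as.vector(rmultinom(1, 100, rep(1, k)) + 1)
    freqs <- freqs / sum(freqs)
    HaplotypeCounts(paste0("h", seq_len(k)),
                    as.vector(rmultinom(1, nCase, freqs)),
                    as.vector(rmultinom(1, nControl, freqs)),
                    nCase, nControl)
}

# Printed reference rows used across tests: genotype pairs of the
# published alpha table and their printed alphas.
table5pairs <- c("*16:01-*05:02/*14:01-4-*05:031",
                 "*16:01-*05:02/*16:01-*05:02",
                 "*07/*11",
                 "*16:01-*05:02/*03:01-*02:01",
                 "*03:01-*02:01/*04:05-*03:01",
                 "*03:01-*02:01/*03:01-*02:01",
                 "*03:01-*02:01/*15:01-*06:02",
                 "*03:01-*02:01/*13:03-*03:01")
table5alphas <- c(-0.18, -0.08, -0.15, -0.23, -0.11, 0.03, 0.06, -0.12)
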