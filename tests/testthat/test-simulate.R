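test_that("configuration invariants are enforced", {
    expect_error(simulationConfig(c(A = 0.5, B = 0.4)), "sum to 1")
    expect_error(simulationConfig(c(A = 0.5, B = 0.5), baselineRisk = 0),
                 "baselineRisk")
    expect_error(simulationConfig(c(A = 0.5, B = 0.5),
                                  haplotypeRR = c(A = -1)), "positive")
    expect_error(simulationConfig(c(A = 0.5, B = 0.5),
                                  haplotypeRR = c(Z = 2)), "labels")
})

test_that("JSON configurations round-trip through the reader", {
    p <- withr::local_tempfile(fileext = ".json")
    writeLines('{
      "haplotype_freqs": {"A": 0.3, "B": 0.2, "C": 0.5},
      "baseline_risk": 0.02,
      "haplotype_rr": {"A": 2.0},
      "interaction_alpha": {"A/B": -0.2},
      "n_cases": 100, "n_controls": 50, "n_families": 10, "seed": 9
    }', p)
    cfg <- readSimulationConfig(p)
    expect_equal(cfg@haplotypeFreqs, c(A = 0.3, B = 0.2, C = 0.5))
    expect_equal(cfg@baselineRisk, 0.02)
    expect_equal(cfg@interactionAlpha, c("A/B" = -0.2))
    expect_identical(cfg@nCases, 100L)
    expect_identical(cfg@seed, 9L)
})

test_that("genotype sampling follows Hardy-Weinberg at the haplotype level", {
    # degenerate pool
    g <- sampleGenotypes(50, c(A = 1))
    expect_true(all(g$hap1 == "A" & g$hap2 == "A"))
    # heterozygote share of a two-haplotype pool: 2pq
    set.seed(51)
    g <- sampleGenotypes(1e5, c(A = 0.5, B = 0.5))
    het <- mean(g$hap1 != g$hap2)
    se <- sqrt(0.5 * 0.5 / 1e5)
    expect_lt(abs(het - 0.5), 3 * se)
    # marginal haplotype frequencies recover the inputs
    fA <- mean(c(g$hap1, g$hap2) == "A")
    expect_lt(abs(fA - 0.5), 3 * sqrt(0.25 / 2e5))
})

test_that("disease probability composes baseline, risks and interaction", {
    cfg <- simulationConfig(c(A = 0.3, B = 0.2, C = 0.5),
                            baselineRisk = 0.05,
                            haplotypeRR = c(A = 2, B = 0.5),
                            interactionAlpha = c("A/B" = -0.2))
    expect_equal(diseaseProbability("C", "C", cfg), 0.05)
    expect_equal(diseaseProbability("A", "C", cfg), 0.1)
    expect_equal(diseaseProbability("A", "B", cfg), 0.05 * 2 * 0.5 * 10^-0.2)
    # unordered pair: same either way round
    expect_equal(diseaseProbability("B", "A", cfg),
                 diseaseProbability("A", "B", cfg))
    hot <- simulationConfig(c(A = 0.5, B = 0.5), baselineRisk = 0.9,
                            haplotypeRR = c(A = 5))
    expect_warning(p <- diseaseProbability("A", "A", hot), "clipped")
    expect_equal(p, 1)
})

test_that("cohort generation is seed-deterministic and fills its quotas", {
    cfg <- simulationConfig(c(A = 0.3, B = 0.7), haplotypeRR = c(A = 2),
                            nCases = 300, nControls = 200, seed = 52)
    c1 <- generateCohort(cfg)
    c2 <- generateCohort(cfg)
    expect_identical(individuals(c1), individuals(c2))
    st <- table(individuals(c1)$status)
    expect_identical(as.integer(st[c("case", "control")]), c(300L, 200L))
})

test_that("derived count tables conserve chromosomes and individuals", {
    cfg <- simulationConfig(c(A = 0.25, B = 0.25, C = 0.5),
                            haplotypeRR = c(A = 1.8), nCases = 400,
                            nControls = 300, seed = 53)
    ch <- generateCohort(cfg)
    hc <- haplotypeCounts(ch)
    gc <- genotypeCounts(ch)
    expect_identical(caseTotal(hc), 800L)        # 2 chromosomes per case
    expect_identical(controlTotal(hc), 600L)
    expect_identical(sum(caseCounts(hc)), 800L)
    expect_identical(caseTotal(gc), 400L)
    expect_identical(sum(caseCounts(gc)), 400L)
    # chromosome counts re-derived from the genotype table agree
    pairs <- strsplit(countLabels(gc), "/", fixed = TRUE)
    for (lab in countLabels(hc)) {
        fromGen <- sum(vapply(seq_along(pairs), function(i)
            sum(pairs[[i]] == lab) * caseCounts(gc)[[i]], numeric(1)))
        expect_identical(unname(caseCounts(hc)[lab]), as.integer(fromGen))
    }
})

test_that("generated trio families are Mendelian-consistent and seeded", {
    cfg <- simulationConfig(c(A = 0.3, B = 0.3, C = 0.4),
                            haplotypeRR = c(A = 2), nFamilies = 120,
                            seed = 54)
    t1 <- generateTrios(cfg)
    t2 <- generateTrios(cfg)
    expect_identical(pedigree(t1), pedigree(t2))
    rep <- validateTrios(t1)
    expect_true(all(rep$mendelian_consistent))
    expect_identical(nrow(rep), 120L)
    # every proband is affected
    ped <- pedigree(t1)
    expect_true(all(ped$status[ped$member == "C"] == 2L))
})

test_that("optional siblings are unaffected children of the same parents", {
    cfg <- simulationConfig(c(A = 0.3, B = 0.7), haplotypeRR = c(A = 3),
                            baselineRisk = 0.1, nFamilies = 150, seed = 55)
    tri <- generateTrios(cfg, sibling = TRUE)
    ped <- pedigree(tri)
    sibs <- ped[ped$member == "C" & ped$status == 1L, ]
    expect_gt(nrow(sibs), 0)
    expect_true(all(validateTrios(tri)$mendelian_consistent))
})

test_that("null transmissions are balanced and a simulated risk haplotype is
           over-transmitted", {
    cfg0 <- simulationConfig(c(A = 0.25, B = 0.35, C = 0.4),
                             nFamilies = 400, seed = 56)
    tt <- countTransmissions(generateTrios(cfg0), "B")
    # pooled transmission odds of each haplotype ~ 1 under the null
    Tall <- transmitted(tt$risk_positive)[c("A", "C")] +
        transmitted(tt$risk_negative)[c("A", "C")]
    NTall <- notTransmitted(tt$risk_positive)[c("A", "C")] +
        notTransmitted(tt$risk_negative)[c("A", "C")]
    for (h in c("A", "C")) {
        n <- Tall[h] + NTall[h]
        expect_lt(abs(Tall[h] / n - 0.5), 3 * sqrt(0.25 / n))
    }
    # with rr(A) = 2 the A haplotype is over-transmitted to affected
    # children (expected share 2/3 from carrier parents)
    cfg2 <- simulationConfig(c(A = 0.25, B = 0.35, C = 0.4),
                             haplotypeRR = c(A = 2), nFamilies = 400,
                             seed = 57)
    t2 <- countTransmissions(generateTrios(cfg2), "B")
    TA <- transmitted(t2$risk_positive)["A"] +
        transmitted(t2$risk_negative)["A"]
    NTA <- notTransmitted(t2$risk_positive)["A"] +
        notTransmitted(t2$risk_negative)["A"]
    expect_gt(TA / (TA + NTA), 0.5 + 3 * sqrt(0.25 / (TA + NTA)))
})

test_that("null cohorts rarely produce corrected significance", {
    base <- sardinianConfig()
    cfg <- simulationConfig(base@haplotypeFreqs, baselineRisk = 0.05,
                            nCases = 1000, nControls = 500)
    set.seed(58)
    anySig <- replicate(100, {
        a <- associateTable(haplotypeCounts(generateCohort(cfg)))
        any(a$significant)
    })
    # familywise rate under Bonferroni stays at or below the nominal 5%
    expect_lte(mean(anySig), 0.05 + 2 * sqrt(0.05 * 0.95 / 100))
})

test_that("an end-to-end Sardinian-like run recovers every association sign", {
    cfg <- sardinianConfig()
    sig <- c("*13:03-*03:01", "*04:05-*03:01", "*15:01-*06:02",
             "*03:01-*02:01", "*11", "*16:01-*05:02",
             "*14:01-4-*05:031", "*15:02-*06:01")
    expected <- sign(log(cfg@haplotypeRR[sig]))
    set.seed(59)
    ok <- replicate(50, {
        a <- associateTable(haplotypeCounts(generateCohort(cfg)))
        got <- sign(log(setNames(a$odds_ratio, a$label)[sig]))
        all(got == expected)
    })
    expect_gte(mean(ok), 0.9)
})
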