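test_that("the X/Y parent's transmission is counted in the child's stratum", {
    # child (R, A) from father (R, C) and mother (A, B): the child carries
    # the risk haplotype, the father carries it too (not an X/Y parent),
    # the mother is the informative non-carrier: T = A, NT = B
    trios <- makeTrioSet(list(
        list(f = c("R", "C"), m = c("A", "B"),
             kids = list(list(h = c("R", "A"), s = 2L)))))
    tt <- countTransmissions(trios, "R")
    pos <- tt$risk_positive
    expect_identical(nInformative(pos), 1L)
    expect_identical(unname(transmitted(pos)["A"]), 1L)
    expect_identical(unname(notTransmitted(pos)["B"]), 1L)
    expect_identical(nInformative(tt$risk_negative), 0L)
})

test_that("families where both parents carry the risk haplotype are excluded,
           homozygous parents are uninformative", {
    trios <- makeTrioSet(list(
        list(f = c("R", "B"), m = c("R", "C"),        # both carry risk
             kids = list(list(h = c("R", "R"), s = 2L))),
        list(f = c("B", "B"), m = c("R", "C"),        # father homozygous
             kids = list(list(h = c("B", "R"), s = 2L)))))
    tt <- countTransmissions(trios, "R")
    excl <- attr(tt, "exclusions")
    expect_identical(unname(excl["both_parents_carry"]), 1L)
    expect_identical(nInformative(tt$risk_positive), 0L)
    expect_identical(nInformative(tt$risk_negative), 0L)
})

test_that("Mendelian-inconsistent families are skipped and tallied", {
    trios <- makeTrioSet(list(
        list(f = c("C", "D"), m = c("B", "E"),
             kids = list(list(h = c("A", "B"), s = 2L)))))
    tt <- countTransmissions(trios, "R")
    expect_identical(unname(attr(tt, "exclusions")["inconsistent_families"]),
                     1L)
    expect_identical(nInformative(tt$risk_negative), 0L)
})

test_that("exhaustive two-haplotype mating/transmission enumeration matches
           the hand oracle", {
    # every ordered parental genotype over {B, C} crossed with every
    # transmission choice; the risk haplotype A is absent, so all children
    # sit in the risk-negative stratum.  The oracle recomputes, from first
    # principles, which parents are informative, whether the transmission
    # is phase-resolvable, and what was actually transmitted.
    genos <- list(c("B", "B"), c("B", "C"), c("C", "B"), c("C", "C"))
    fams <- list()
    oracleT <- c(B = 0L, C = 0L)
    oracleNT <- c(B = 0L, C = 0L)
    for (f in genos) for (m in genos) for (i in 1:2) for (j in 1:2) {
        child <- c(f[i], m[j])
        fams[[length(fams) + 1L]] <-
            list(f = f, m = m, kids = list(list(h = child, s = 2L)))
        for (p in c("F", "M")) {
            par <- if (p == "F") f else m
            if (par[1] == par[2]) next           # homozygous: skip
            # phase resolution as defined: candidate transmitted haps of
            # this parent across the Mendelian-valid orderings
            cand <- character(0)
            if (child[1] %in% f && child[2] %in% m)
                cand <- c(cand, if (p == "F") child[1] else child[2])
            if (child[2] %in% f && child[1] %in% m)
                cand <- c(cand, if (p == "F") child[2] else child[1])
            cand <- unique(cand)
            if (length(cand) != 1L) next         # ambiguous: skip
            truth <- if (p == "F") f[i] else m[j]
            expect_identical(cand, truth)        # resolution is correct
            oracleT[truth] <- oracleT[truth] + 1L
            other <- setdiff(par, truth)
            oracleNT[other] <- oracleNT[other] + 1L
        }
    }
    tt <- countTransmissions(makeTrioSet(fams), "A")
    neg <- tt$risk_negative
    expect_identical(transmitted(neg)[c("B", "C")], oracleT)
    expect_identical(notTransmitted(neg)[c("B", "C")], oracleNT)
    expect_identical(nInformative(tt$risk_positive), 0L)
})

test_that("transmission accounting: T and NT totals equal informative parents", {
    cfg <- simulationConfig(c(A = 0.2, B = 0.3, C = 0.5),
                            haplotypeRR = c(A = 1.5), nFamilies = 150,
                            seed = 21)
    tt <- countTransmissions(generateTrios(cfg), "A")
    for (tab in tt) {
        expect_identical(sum(transmitted(tab)), sum(notTransmitted(tab)))
        expect_identical(sum(transmitted(tab)), nInformative(tab))
    }
})

test_that("haplotype-vs-rest test reproduces the printed stratified rows", {
    r <- tdtVsRest(35, 12, 269)
    expect_equal(round(r$odds_ratio, 1), 3.2)
    expect_equal(signif(r$p, 2), 4.5e-4)

    r0 <- tdtVsRest(0, 10, 269)
    expect_identical(r0$odds_ratio, 0)
    expect_equal(signif(r0$p, 2), 1.4e-3)

    # (9, 1): the 2x2 odds ratio is 9.3, not the naive 9/1
    expect_equal(round(tdtVsRest(9, 1, 269)$odds_ratio, 1), 9.3)
    expect_equal(signif(tdtVsRest(30, 61, 269)$p, 2), 3.6e-4)

    # balanced transmission is exactly null
    rb <- tdtVsRest(20, 20, 100)
    expect_equal(rb$odds_ratio, 1)
    expect_equal(rb$chi2, 0)
})

test_that("the paired McNemar alternative differs as documented", {
    # (T - NT)^2 / (T + NT) for (30, 61) gives p = 1.2e-3 where the
    # vs-rest table gives 3.6e-4
    rm <- tdtVsRest(30, 61, 269, method = "mcnemar")
    expect_equal(signif(rm$p, 2), 1.2e-3)
    expect_equal(rm$chi2, (30 - 61)^2 / 91, tolerance = 1e-12)
})

test_that("vs-rest odds ratio of the complement is the reciprocal", {
    set.seed(22)
    for (i in 1:20) {
        n <- sample(50:300, 1)
        T <- sample(seq_len(n - 1), 1); NT <- sample(seq_len(n - 1), 1)
        expect_equal(tdtVsRest(n - T, n - NT, n)$odds_ratio,
                     1 / tdtVsRest(T, NT, n)$odds_ratio, tolerance = 1e-12)
    }
})

test_that("between-strata comparison reproduces the printed rows", {
    r <- compareStrata(8, 14, 29, 14)
    expect_equal(round(r$chi2, 1), 5.7)
    expect_equal(signif(r$p, 2), 1.7e-2)

    r2 <- compareStrata(30, 61, 101, 148)
    expect_equal(round(r2$chi2, 1), 1.6)
    expect_equal(signif(r2$p, 2), 2.0e-1)

    expect_equal(compareStrata(10, 20, 30, 60)$chi2, 0)
    expect_warning(rz <- compareStrata(0, 0, 5, 7), "empty margin")
    expect_identical(rz$chi2, 0)
})

test_that("analysis of the bundled transmission tables matches the published
           stratified TDT", {
    res <- suppressWarnings(analyzeTransmissions(sardinianTransmissions()))
    expect_identical(unname(attr(res, "n_informative")), c(269L, 634L))
    r45 <- res[res$label == "*04:05-*03:01", ]
    expect_equal(round(r45$or_pos, 1), 3.2)
    expect_equal(signif(r45$p_pos, 2), 4.5e-4)
    expect_equal(round(r45$or_neg, 1), 2.6)
    r13 <- res[res$label == "*13", ]
    expect_equal(round(r13$between_chi2, 1), 5.7)
    expect_equal(signif(r13$between_p, 2), 1.7e-2)
    # opposite transmission trend of *13 across strata
    expect_lt(r13$or_pos, 1)
    expect_gt(r13$or_neg, 1)
})

test_that("the informativeness gate blocks rarely-carried risk haplotypes", {
    cfg <- simulationConfig(c(A = 0.02, B = 0.48, C = 0.5), nFamilies = 50,
                            seed = 23)
    trios <- generateTrios(cfg)
    expect_error(stratifiedTDT(trios, "A"), "heterozygous parents")
    res <- suppressWarnings(stratifiedTDT(trios, "A", minHetParents = 1))
    expect_true(is.data.frame(res))
})
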