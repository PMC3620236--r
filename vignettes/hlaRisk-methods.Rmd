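---
title: "Models and methods behind hlaRisk"
author: "hlaRisk authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hlaRisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlaRisk)
```

# The scientific problem

At the HLA class II *DRB1* and *DQB1* loci, alleles travel together on one
chromosome in tight linkage disequilibrium, so the natural unit of analysis
is the two-locus *haplotype*, treated here as an atomic label such as
`*03:01-*02:01`.  An individual's *genotype* is the unordered pair of
haplotypes on their two chromosomes.  In autoimmune disease, several
haplotypes at these loci predispose and several protect, and the risk
carried by a genotype need not be the simple combination of its two
haplotypes' risks: haplotypes can interact.  hlaRisk implements the full
analysis chain for this question — case-control association at the
chromosome and individual level, a sequential procedure separating real
(negative) associations from displacement artefacts, a family-based
transmission analysis that conditions on carriage of a major risk
haplotype, and a log-additivity statistic that quantifies interaction —
together with a seeded simulator so that every stage can be validated
end to end without individual-level patient data.

The package ships, as plain-TSV fixtures, the published summary count
tables of a large Sardinian multiple-sclerosis case-control and
trio-family cohort (2,555 patients / 1,365 controls, i.e. 5,110 / 2,730
chromosomes; 961 trio families).  All headline statistics in the test
suite are recomputed from these counts.

# Data model

`HaplotypeCounts` and `GenotypeCounts` hold one row per haplotype or
genotype with case and control counts, plus cohort totals carried
*separately* from the rows: published tables only display categories
above a reporting threshold, and the chromosomes below it must stay in
the denominators.  The bundled haplotype table, for instance, displays
5,038 of 5,110 case chromosomes; the remaining 72 are retained as an
implicit remainder wherever a computation needs the full distribution.

The frequency filter (`filterByFrequency`) keeps a row when it reaches
the threshold (default 1%) in cases *or* controls.  The either-group rule
matters: a haplotype at 0.9% in cases and 2.0% in controls is strongly
informative about protection and must not be dropped.

Rare fine haplotypes are pooled into haplogroups (`collapseHaplogroups`)
through an explicit grouping map that defaults to the identity for
unmapped labels; counts are summed and totals untouched, so collapsing
commutes exactly with summation.

Trio families arrive phased (PED-like TSV, one row per member).  The
package validates Mendelian consistency and flags intercross families —
both parents heterozygous for the same two haplotypes, for which phase
cannot identify which parent transmitted what — but deliberately never
imputes or statistically phases: ambiguous material is surfaced, not
repaired.

# Case-control association

Each row is tested against all other chromosomes (or individuals) with
the 2×2 table \([[a, b], [N_1-a, N_2-b]]\):

* odds ratio \(\mathrm{OR} = a(N_2-b)\,/\,b(N_1-a)\);
* 95% Woolf (logit) interval
  \(\exp(\ln \mathrm{OR} \pm 1.96\sqrt{1/a + 1/b + 1/c + 1/d})\);
* Pearson \(\chi^2\) with 1 df and no continuity correction, two-sided;
* Bonferroni correction \(P_c = \min(1, m\,p)\) over the \(m\) tested
  rows (15 haplotypes, 28 genotypes for the bundled tables).

Zero cells degenerate to OR 0 or \(\infty\) with a flag and an undefined
interval; a Haldane–Anscombe 0.5 correction is available behind
`haldane = TRUE` but off by default, so that fully one-sided
transmission counts report OR 0 rather than a shrunken estimate.
Results always carry a numeric corrected p plus a `significant` flag
rather than a blank/"NS" mix.

# The sequential relative predispositional effect (RPE) procedure

When one haplotype is strongly over-represented in cases, other
haplotypes' frequencies drop mechanically (displacement), mimicking
protection.  The RPE procedure separates real effects from displacement:

1. compute, for every remaining haplotype, the case count expected from
   the control distribution,
   \(E_i = \mathrm{control}_i \times N_{case}/N_{control}\), at the
   *current* (post-removal) totals;
2. test the overall deviation of observed from expected;
3. if significant (default \(P < 0.001\)), remove the haplotype with the
   largest contribution \((O_i - E_i)^2/E_i\) from both cohorts, record
   its unpooled two-proportion z statistic
   \(z = (\hat p_1 - \hat p_2)/\sqrt{\hat p_1(1-\hat p_1)/n_1 +
   \hat p_2(1-\hat p_2)/n_2}\) at the totals in force, shrink the totals,
   and repeat.

Three conventions deserve note:

* **Expectations use the grand totals**, including the undisplayed rare
  chromosomes, which are carried as an implicit, non-selectable remainder
  category in the overall test so that the expected counts over all
  categories sum exactly to the remaining case total.
* **The unpooled variance** is used for z.  The pooled form gives visibly
  different values on large imbalanced cohorts and does not match
  published RPE traces.
* **Two overall stopping tests are provided.**  The default (`"gof"`)
  sums \((O-E)^2/E\) over remaining categories with df = categories − 1.
  This is the statistic whose per-haplotype contributions the procedure
  ranks, and it reproduces published traces round for round; but it
  treats control-derived expectations as known, and when controls are
  fewer than cases it overstates significance by a factor of roughly
  \(1 + N_{case}/N_{control}\) — under the null it removes haplotypes far
  more often than the nominal level.  The `"contingency"` option replaces
  only the stopping decision with the two-sample 2×k contingency
  \(\chi^2\), which holds the nominal type-I level at any case/control
  balance and stops earlier on the same data (after 7 rather than 9
  rounds on the bundled tables).  The test suite asserts type-I control
  for the calibrated stop and demonstrates the anticonservatism of the
  control-scaled one; users reproducing published traces want the
  default, users screening their own data at a guaranteed level want
  `"contingency"`.

Full precision is kept internally; the show method rounds expectations to
integers and statistics to two decimals, the convention in which such
traces are printed.

# Stratified transmission analysis

To ask whether a second haplotype modifies the risk of a major risk
haplotype R (here `*03:01-*02:01`), affected children are stratified by
carriage of R, and transmissions are counted *only from the parent
carrying neither copy of R* (the "X/Y parent"): each such heterozygous
parent contributes one transmitted (T) and one not-transmitted (NT)
chromosome, so the T and NT columns both sum to the number of informative
parents — an identity enforced by the `TransmissionTable` validity
method.  In the R-negative stratum both parents can qualify, which is why
that stratum counts more informative parents than children.  Families in
which both parents carry R have no eligible parent and are excluded from
both strata (tallied, since the convention is not obvious); homozygous
parents are uninformative; transmissions that phase cannot resolve
uniquely (parents sharing haplotypes) are skipped and tallied.

The per-haplotype test is the haplotype-vs-rest 2×2
\([[T, NT], [n-T, n-NT]]\) Pearson \(\chi^2\) with
\(\mathrm{OR} = T(n-NT)/NT(n-T)\) — not the paired McNemar statistic
\((T-NT)^2/(T+NT)\), which gives materially different p-values (for
counts (30, 61) in 269 parents: 1.2×10⁻³ against 3.6×10⁻⁴) and whose OR
would be the naive T/NT.  The vs-rest form is what published stratified
trio tables report; McNemar remains available via `method = "mcnemar"`
and is the exactly calibrated choice for a single pre-specified
haplotype.  Between-strata differences are tested by the 2×2 Pearson
\(\chi^2\) on \([[T_+, NT_+], [T_-, NT_-]]\).

A stratification is only attempted when the risk haplotype is carried by
at least `minHetParents` heterozygous parents (default 250): below that,
stratum-specific counts are too sparse for the vs-rest asymptotics.

# The log-additivity interaction statistic

If the two haplotypes of a genotype act independently, the expected
genotypic odds ratio is the product of the haplotypic ones,
\(\mathrm{OR}_{g,exp} = \mathrm{OR}_{ha}\,\mathrm{OR}_{hb}\) —
additivity on the log scale.  The deviation

\[\alpha = \log_{10}\mathrm{OR}_{g,obs} - \log_{10}\mathrm{OR}_{g,exp}\]

is the interaction probe: \(\alpha < 0\) means the genotype is less
extreme than its haplotypes predict (negative interaction), \(\alpha > 0\)
the opposite.  The logarithm base defaults to 10, the scale on which the
conventional neutral band [0.01, 0.09] is expressed; the base is
configurable.  Band endpoints are inclusive; note the band is asymmetric
about zero and excludes zero itself, so a small non-negative alpha
classifies as "negative interaction" while carrying a positive sign —
the classification and the sign are therefore reported as separate
columns rather than silently merged.

`buildAlphaTable` computes, never copies, the expected OR.  Two modes are
exposed: *reproduction* first rounds every odds ratio to one decimal —
the precision at which published tables report them — so alphas can be
compared digit for digit with printed values; *full* combines unrounded
odds ratios and is the mode to use for new analyses (the two can differ
in the second decimal, e.g. −0.18 vs −0.19 for the most protective
genotype of the bundled tables).  By default the table covers the
genotypes significant after correction; any explicit pair list can be
supplied.  No p-value is attached to alpha: its sampling distribution
depends on the full joint model of the three odds ratios, and a
principled interval is out of scope — the genotypic OR's own p-value is
the relevant significance guide.

# The synthetic-data generator

`simulationConfig` describes a population: haplotype frequencies
(chromosomes are drawn independently — random mating, Hardy–Weinberg at
the haplotype level), a baseline disease probability (default 0.05),
multiplicative per-haplotype relative risks, and optional per-genotype
interaction terms expressed directly as the target alpha (a
\(10^{\alpha}\) multiplier on the genotype risk), so that interaction
recovery is an identity check by construction.  Probabilities are clipped
at 1 with a warning.  `generateCohort` rejection-samples to the case and
control quotas; `generateTrios` ascertains on an affected child (parental
status is ignored, matching the trio design) and can attach an unaffected
sibling where the sibling draw came out healthy.  All randomness flows
through R's RNG; configurations carry an optional seed applied locally
(via `withr`), so the same config yields byte-identical data.

`sardinianConfig` builds a study-like population: frequencies from the
bundled control chromosome counts (with an explicit `"(other)"` category
for the undisplayed rare haplotypes) and relative risks set to the
case-control odds-ratio estimates, which approximate risk ratios at the
default 5% baseline.

What the generator emulates — and what it does not: haplotypes are atomic
labels, so within-haplotype linkage structure, class I loci, genotyping
error, population stratification and non-random mating are all outside
the model.  Passing recovery tests therefore demonstrate that the
estimators correctly invert the generative model they assume, not that
real cohorts are free of confounding.

## A note on what "recovery" can mean

Two identities hold only in the rare-disease, rare-haplotype limit and
are treated carefully in the tests:

* the chromosome-level odds ratio equals the configured relative risk up
  to a control-depletion factor \((1-p_{\bar A})/(1-p_A)\);
* the marginal alpha equals the configured interaction exponent up to a
  first-order contamination of the haplotypic odds ratios of magnitude
  \(\approx 2f(1-10^{\alpha})/\ln 10\) for partner frequency \(f\).

Rather than pretending the naive identities hold at Monte-Carlo
precision, the test suite compares Monte-Carlo means against the *exact*
population values from a closed-form enumeration oracle (genotype
probabilities × risk model, no sampling), and separately bounds the
population-vs-configured offsets by the analytic terms above at the
chosen study conditions.

# Numerical choices and degenerate inputs

* Pearson \(\chi^2\) everywhere without continuity correction; empty
  margins yield statistic 0 and p 1 with a warning rather than an error.
* Degenerate proportions (both 0 or both 1) make z undefined: `NA` with
  a warning.
* Genotype labels are canonicalised by radix-sorting the two haplotype
  labels, so `A/B` and `B/A` are one genotype everywhere.
* Typographic glyphs in haplotype labels (ratio colons, en-dashes) are
  normalised to ASCII on input.
* Ties in the RPE argmax (exactly equal contributions) resolve to the
  earlier row — counts are integers, so exact ties are possible but
  carry no information either way.
* Display rounding (1-decimal ORs, 2-significant-figure p-values,
  integer expectations) is applied only in show methods and in the alpha
  table's reproduction mode; every computation keeps full precision.

# Problem sizes used by the test suite

Deterministic checks run on the bundled tables (15 haplotypes / 28
genotypes).  The stochastic properties use: 1,000 null tables at
4,000/2,000 chromosomes for RPE type-I; 1,000 sets of 300 null trio
families for TDT calibration and 300 sets for the unaffected-sibling
negative control; 400 cohorts of 2,500/1,250 individuals for odds-ratio
coverage; 200 cohorts of 4,000/2,000 for alpha recovery; and 50
full-size Sardinian-like cohorts for end-to-end sign recovery.  These
sizes put every Monte-Carlo standard error well below the asserted
tolerances while keeping a complete run of the suite in the
single-digit-minute range on one CPU.

# Known limitations

* Statistical phasing is not implemented; trio files must arrive phased,
  and ambiguous transmissions are dropped, not modelled.
* The vs-rest transmission \(\chi^2\) treats the 2n parental chromosomes
  of a stratum as independent; for a haplotype carried by a fraction
  \(c\) of informative parents it is mildly anticonservative (inflation
  \(2n/(2n - cn)\)), which is negligible for rare haplotypes and worth
  remembering for very common ones — `method = "mcnemar"` is exact.
* Alpha has no significance measure (see above).
* Exact (Fisher) tests, covariate adjustment and regression-based
  conditioning are deliberately out of scope; standard GLM tooling
  covers them.
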