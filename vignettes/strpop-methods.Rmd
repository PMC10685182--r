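---
title: "Models and methods in strpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in strpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strpop)
```

strpop implements the statistical machinery of a forensic STR population
study: building allele-frequency databases from genotype samples,
summarizing how informative each locus is for identification and kinship
testing, testing the equilibrium assumptions those summaries rest on, and
quantifying what goes wrong when a match probability is computed against a
frequency database from the *wrong* population. This vignette explains the
models, the default parameters, and the design decisions that were open.

## Data model

A `genotype_table` holds samples (with sex and population label), a panel
(locus names and chromosome class), and calls. Autosomal loci are diploid
in everyone; X loci are diploid in females and hemizygous in males (one
allele, stored with `a2 = NA`). Allele names are repeat counts with
optional microvariant suffixes (`"9.3"`); they are kept as strings and
compared through parsed (repeat, step) keys, which avoids floating-point
traps — `9.3` is nine repeats plus three bases, not a decimal number. The
sentinel `"OL"` (off-ladder) marks alleles outside any reference ladder.
Missing calls are absent rows and are excluded from every denominator
rather than imputed.

Allele frequencies estimated from a table use plain counting. For X loci
the pooled denominator is $n_m + 2 n_f$: each typed male contributes one
allele copy, each female two. This is the standard hemizygous convention;
sex-restricted estimates (`male_only`, `female_only`) are available for
comparisons between the sexes.

## The simulator

Downstream methods are tested against data with known structure. The
generator is the Balding–Nichols model: a subpopulation's frequency vector
at a locus is one Dirichlet draw with concentrations
$\alpha_i = p_i (1 - F) / F$ around the ancestral vector $p$, so that
$E[q_i] = p_i$ and $\mathrm{Var}[q_i] = F p_i (1 - p_i)$. The draw is made
once per (subpopulation, locus) and shared by all individuals — this
models drift, not family structure; there is no inbreeding within
individuals and no linkage between loci. Individuals are then sampled in
Hardy–Weinberg proportions (two independent copies per diploid, one per
male X). Alleles with ancestral frequency zero are excluded from the
Dirichlet, whose concentration would be undefined at zero.

This divergence model was chosen deliberately: the theta-corrected match
probability formulas below are exactly the conditional genotype
probabilities of the Balding–Nichols model, so simulator and audit are
mutually consistent and the Weir–Cockerham estimator can be checked
against the known $F$.

The bundled demo model (`demo_model()`) fixes the study conditions used
throughout the examples and tests: 21 autosomal and 19 X loci, per-locus
allele counts between 5 and 22 (the two five-allele loci and the
22-allele locus are placed at the loci that carry those counts in
published X panels), ancestral frequencies drawn once from a symmetric
Dirichlet and clipped to 0.0025–0.85 — the range typical of published
forensic databases — and two subpopulations at $F = 0.01$ each: a cohort
of 333 males and 88 females and a non-cognate reference population of
2793 individuals, mirroring the sampling structure of real cognate /
non-cognate database comparisons. With both subpopulations drawn at
$F = 0.01$ from a common ancestor, the expected pairwise Weir–Cockerham
theta is about 0.01, while the effective divergence of the cohort
*relative to the other population's database* is roughly the sum of the
two (about 0.02) — worth remembering when reading audit output.

`inject_unseen_alleles()` recreates the off-ladder phenomenon: a
Bernoulli-chosen subset of samples has one allele of one call replaced by
`"OL"`, which no reference database contains.

## Forensic parameters

Writing $a_k = \sum_i p_i^k$ for the frequency power sums, the per-locus
parameters are:

| quantity | formula | notes |
|---|---|---|
| $H_o$ | heterozygote fraction | counted from genotypes |
| $H_e$ | $\frac{n}{n-1}(1 - a_2)$ | unbiased; $n$ = allele copies |
| PIC | $1 - a_2 - a_2^2 + a_4$ | |
| MP | $\sum_j g_j^2$ | observed genotype proportions by default |
| PD | $1 - \mathrm{MP}$ | |
| PE | $h^2(1 - 2 h H^2)$ | $h = H_o$, $H = 1 - h$ |
| TPI | $1 / (2H)$ | $\infty$ sentinel when $H = 0$ |
| $PD_m$ (X) | $1 - a_2$ | hemizygous males expose alleles |
| $PD_f$ (X) | $1 - 2 a_2^2 + a_4$ | $= 1 - \sum g^2$ under HWE |
| HD (X) | $\frac{n}{n-1}(1 - a_2)$ | gene diversity |

MP defaults to the observed-genotype convention (the one forensic
summary tools report); an expected (HWE) mode is available. Combined
values multiply across loci: $\mathrm{CPM} = \prod \mathrm{MP}_l$,
$\mathrm{CPD} = 1 - \mathrm{CPM}$,
$\mathrm{CPE} = 1 - \prod(1 - \mathrm{PE}_l)$, and the X metrics combine
by the same product-of-complements rule. Adding a locus can never
decrease CPD or CPE.

### Mean exclusion chance

The X-chromosomal mean exclusion chance family is defined here
*operationally*, by an exact pedigree-enumeration engine
(`mec_enumerate()`): enumerate every family configuration — mother
genotype under HWE, transmitted maternal allele, true paternal allele
from the population — determine the obligate paternal allele set from the
(mother, child) genotypes alone, and average the probability that a
random man is excluded. Three scenarios are covered: father–daughter duo
at an X locus, mother–daughter trio at an X locus, and the autosomal
trio. The closed forms

$$\mathrm{MEC}_{duo} = 1 - 2a_2 + a_3, \qquad
\mathrm{MEC}_{X\,trio} = 1 - a_2 - a_2^2 + a_4,$$
$$\mathrm{MEC}_{auto\,trio} = 1 - 2a_2 + a_3 + 3a_2 a_3 - 3a_5
 - 2a_2^2 + 2a_4$$

are verified against the engine to $10^{-12}$ on random frequency vectors
in the test-suite; the engine refuses vectors longer than 60 alleles
(cost grows as $k^4$), where the closed forms serve alone. Published
reports name several trio-style MEC variants whose printed values differ
slightly between sources without printed formulas; this package reports
the enumerated scenarios under scenario names rather than author names,
which keeps the definitions unambiguous.

## Exact tests

**Hardy–Weinberg.** The exact test conditions on the observed allele
counts and orders tables by their conditional probability
$P(T) = n!\,\prod_i m_i!\,2^H / ((2n)!\,\prod_{i \le j} n_{ij}!)$. For at
most 3 alleles and 50 individuals every table is enumerated. Otherwise a
Monte Carlo chain performs random transpositions of allele copies between
individuals: conditional on allele counts, a uniformly random pairing of
the $2n$ copies induces exactly the null distribution of tables, so every
swap is accepted and the chain's equilibrium is correct by construction.
The p-value is the proportion of visited tables no more probable than the
observed one, with the $(b+1)/(m+1)$ correction so Monte Carlo p-values
are never zero; the Monte Carlo standard error is estimated by batch
means (50 batches). Chain defaults are 100,000 dememorization and
1,000,000 recorded steps — generous for a single locus; the bundled demo
configuration uses 20,000/200,000 per locus, which keeps the error well
below the resolution any multiple-testing decision needs.

**Linkage disequilibrium.** For hemizygous males the two-locus haplotypes
are observed directly and the G (likelihood-ratio) statistic of the
haplotype contingency table is tested by permuting one locus's alleles
across individuals. For females, phase is unknown: haplotype frequencies
under association are estimated by EM (only double heterozygotes are
phase-ambiguous), the likelihood is compared with the independence model
(haplotype frequencies equal to products of allele frequencies, which is
the constrained MLE), and the LR statistic is permuted the same way. The
permutation EM uses a bounded iteration count (60 iterations, tolerance
$10^{-6}$) applied identically to the observed and permuted statistics;
the LR stabilizes well inside that bound, and the permutation ranking is
insensitive to the EM tail. Permutation p-values use $(b+1)/(m+1)$.

**Multiple testing.** Family-wise control is Bonferroni: `bonferroni(0.05,
19)` gives 0.0026 at four decimals, the threshold for a 19-locus X panel.

## Population structure

Pairwise $F_{ST}$ is the Weir–Cockerham (1984) theta, combining loci and
alleles by the ratio of summed variance components (never averaging
ratios). Autosomal loci use the diploid $a/b/c$ components, which use
observed heterozygosity; X loci are treated as haploid allele-copy
samples (one per male, two per female) with the corresponding one-way
ANOVA components — consistent with the pooled-frequency convention.
Negative estimates are retained, as is conventional. Significance comes
from permuting individuals between the two populations (default 10,000
permutations). The estimator is exactly invariant to allele relabeling,
recovers $F = 0.01$ from Balding–Nichols simulations within sampling
error, returns ~0 for identically sourced populations and exactly 1 for
fixed allelic differences.

PCoA is classical metric scaling: Gower double-centering of $-D^2/2$ and
eigendecomposition, with coordinates scaled by the square root of the
eigenvalues (delegated to `stats::cmdscale`, which implements exactly
this). Negative eigenvalues — the non-embeddable part of a distance
matrix, common for $F_{ST}$ matrices — are reported but excluded from the
percent-variance denominator. The heatmap export is an average-linkage
ordered distance matrix written to TSV; no graphics device is required.

## The match-probability audit

The probability that a random member of the suspect's subpopulation
matches the profile genotype, when allele frequencies come from a
reference population at divergence $F$, is

$$P(AA) = \frac{[2F + (1-F)p_A][3F + (1-F)p_A]}{(1+F)(1+2F)}, \qquad
P(AB) = \frac{2[F + (1-F)p_A][F + (1-F)p_B]}{(1+F)(1+2F)}.$$

At $F = 0$ these are exactly $p_A^2$ and $2 p_A p_B$; as $F \to 1$ the
homozygote probability tends to 1. For rare alleles the probability
increases with $F$ — the correction is conservative where it matters. A
profile's RMP is the product over its typed panel loci.

The audit compares, per profile, the RMP computed from the cognate
database (at $F = 0$: a cognate database needs no subpopulation
correction — configurable) with the RMP from a non-cognate database at
each correction level $F$, through

$$d = \log_{10}\!\frac{\mathrm{RMP}_{cognate}}{\mathrm{RMP}_{non\text{-}cognate}},$$

so $d > 0$ means the non-cognate calculation overstated the weight of the
evidence. The direction of the ratio is a convention fixed here so that
positive values flag the forensically dangerous case. Profiles carrying
alleles absent from either database are removed first (`filter_unseen()`,
the off-ladder screening); alternatively a minimum-frequency floor of
$5/(2N)$ can be enabled for single-profile calculations. The report gives
the percentage of profiles with $d$ strictly above 0, 0.5, 1 and 2, plus
mean and SD (sample SD; a single profile reports SD 0 with a note). On
synthetic cognate/non-cognate pairs at true $F = 0.01$ the uncorrected
audit shows mean $d$ well above zero with most profiles positive, and
correcting at the true $F$ collapses the exceedance — the qualitative
pattern such audits show on real databases. Because the demo's two
populations each diverge from a common ancestor, correcting at the
*pairwise* theta still under-corrects slightly; the audit output makes
this visible rather than hiding it.

## Pipeline and reproducibility

`run_pipeline()` chains the stages (simulate/read → frequencies → forensic
parameters → HWE → LD → $F_{ST}$/PCoA → audit) from one YAML
configuration. Every stage derives its seed deterministically from the
root seed and the stage name, so stages can be re-run in isolation and
identical configurations give byte-identical outputs (checksummed in
`manifest.tsv`). Outputs are written as `<name>.partial` and renamed on
success, so a failed stage leaves its partial file and aborts with the
stage name. A thin command-line wrapper lives at
`inst/cli/strpop.R`.

## Numerical choices and problem sizes

* Frequency-table sums within 0.5% of 1 are renormalized (published
  tables carry rounding residue); larger deviations are rejected.
* Table-probability comparisons in the exact tests use a $10^{-9}$
  additive tolerance on log-probabilities, so ties count as "no more
  probable".
* Diploid genotypes are stored in canonical allele order; all statistics
  are invariant to allele relabeling and input order.
* The test-suite and the acceptance script run their simulations at
  deliberately modest sizes — hundreds of individuals, tens to hundreds
  of loci, $10^4$–$10^5$ chain steps — chosen so the whole suite
  completes in a few minutes while keeping Monte Carlo error an order of
  magnitude below every asserted tolerance.

## What the synthetic data does not show

The generator draws loci independently with a single drift event per
subpopulation; it contains no mutation model, no stutter/dropout
artifacts, no family structure, and no linkage. Passing tests therefore
demonstrate the *estimators and tests* are correct under the stated
model, not that real populations satisfy that model; on real data the
usual caveats (relatives in the sample, null alleles, genuine linkage
between syntenic X loci) apply. Reported X linkage groups are a real
phenomenon the independent-locus simulator deliberately does not emulate
— the LD machinery is tested instead on data with known constructed
haplotype structure.
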