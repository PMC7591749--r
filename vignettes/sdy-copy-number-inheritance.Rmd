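---
title: "Autosomal sdY pseudocopies: model, copy-number assay and family scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autosomal sdY pseudocopies: model, copy-number assay and family scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdyped)
library(dplyr)
```

## The problem

In salmonids, maleness is conferred by a functional copy of the
master sex-determining gene *sdY* on the Y chromosome, and presence/absence
PCR assays for *sdY* are widely used to type genetic sex. Yet a variable
fraction of accurately phenotyped females test *sdY*-positive. `sdyped`
implements, end to end, the analysis chain that resolves this discordance
under a simple genetic hypothesis: some fish carry one or two
**non-functional autosomal copies** ("pseudocopies") of *sdY* that amplify
in the assay but play no role in sex determination and segregate as an
ordinary autosomal biallelic locus.

The package covers four analysis stages plus a synthetic-data generator:

1. **qPCR copy-number calling** (`aggregate_replicates()`,
   `compute_fold_change()`, `call_copy_number()`),
2. **exclusion-based parentage** (`assign_parentage()`),
3. **the inheritance model** (`offspring_distribution()`,
   `classify_discordance()`, `infer_parental_config()`, `gof_test()`),
4. **per-family linkage scans** (`infer_transmission()`, `scan_trait()`,
   `summarize_scan()`),

orchestrated by `run_pipeline()`.

## The inheritance model

Let an individual's *sdY* state be $(y, a)$: $y \in \{0, 1, 2\}$ Y-linked
functional copies and $a \in \{0, 1, 2\}$ pseudocopy alleles at one
autosomal locus. The qPCR assay measures only the **total** $c = y + a$.
For a standard cross (sire $y=1$, dam $y=0$) with parental pseudocopy
counts $a_s$ and $a_d$:

* each parent transmits a pseudocopy allele independently with probability
  $a_s/2$ and $a_d/2$ (Mendelian segregation of a biallelic locus);
* offspring sex is male iff the sire's Y-linked copy is transmitted
  (probability $1/2$), independent of the pseudocopy when the loci are on
  different chromosomes;
* an offspring's total count is $a + 1$ for sons and $a$ for daughters.

`offspring_distribution()` returns the exact joint distribution. The two
configurations that matter most in practice are the heterozygous-carrier
crosses: $a_s = 0, a_d = 1$ gives 50/50 zero- vs one-copy daughters (and
50/50 one- vs two-copy sons); $a_s = 1, a_d = 1$ gives 25/50/25 over
0/1/2-copy daughters and 1/2/3-copy sons. A unit-tested gamete-enumeration
oracle reproduces the function exactly for all nine $(a_s, a_d)$
configurations.

Assumptions worth stating: exactly one pseudocopy locus segregates per
family (two distinct loci in one family are not modelled), there is no sex
reversal (phenotypic sex equals genetic sex), and a YY super-male sire is
supported only as the all-male extension used for assay validation.

## Copy number from qPCR

The assay multiplexes a reference gene (*gapdh*) with two *sdY* amplicons
(exon 2, exon 4). Replicates are averaged per target
(`aggregate_replicates()`); a target whose replicates all fail to amplify
is *absent*, and a mixture of amplifying and non-amplifying replicates, or
an all-numeric set spanning more than `max_spread` (default 1) cycles, is
*failed* — partial dropout is never silently averaged.

Fold change follows the comparative-Ct method with a one-copy male
calibrator panel:
$\mathrm{FC} = 2^{-[(Ct_t - Ct_r)_{\text{sample}} - (Ct_t - Ct_r)_{\text{calibrator}}]}$,
so under perfect doubling efficiency a $c$-copy sample has expected FC
$= c$. The calibrator is the mean over the designated reference males of a
run; a missing calibrator aborts the run.

`call_copy_number()` bands each amplicon independently: absent $\to 0$;
$(0.5, 1.5] \to 1$; $(1.5, 2.5] \to 2$; $(2.5, 3.5] \to 3$. Only the 1.5
edge is empirically anchored (it separates the validated XY and YY
clusters); 2.5 extends the rule symmetrically on the linear scale, 0.5
guards against partial-degradation artefacts, and 3.5 caps the assay's
range. A definite call requires the two amplicon bands to **agree**;
anything else is `ambiguous`, never averaged. This makes abstention, not
miscalling, the failure mode near band edges: with Gaussian Ct noise of
0.15 cycles and two replicates, zero- and one-copy samples are called
essentially perfectly, while two- and three-copy samples abstain on a few
percent and ~20% of samples respectively, with the issued calls >99%
correct (these rates are measured in the test suite). Fold change is
scale-free in Ct: shifting every Ct of a sample by a constant leaves FC
unchanged.

## Parentage and the cohort filter

`assign_parentage()` implements strict exclusion over a shared
microsatellite panel: a locus mismatches when no assignment of the
offspring's two alleles (one to each parent) is consistent with both
parental genotypes; an offspring is assigned when exactly one candidate
pair is compatible at the mismatch tolerance (default 0). Loci with any
missing allele are skipped; ties at `max_mismatch > 0` are broken by
mismatch count only, and equal-mismatch ties stay ambiguous — no
likelihood ranking is attempted. `filter_families()` then drops families
with fewer than 10 assigned offspring, the usual maturity filter for this
kind of cross design.

## Goodness of fit

Observed per-family, per-sex offspring counts over copy classes are tested
against the model expectation with Pearson's $X^2$ and a Monte-Carlo
p-value: `gof_test()` simulates multinomial samples under the expected
probabilities and reports
$p = (1 + \#\{X^2_{sim} \ge X^2_{obs}\})/(1 + B)$, with $B = 10^6$ as the
conventional default ($10^3$–$10^5$ in tests and pipelines for speed).
Zero-expectation categories with zero observations are dropped; a
zero-expectation category with observations flags the configuration as
impossible and reports the floor p-value $1/(B+1)$. The seed is stored in
the result, and the suite checks the Monte-Carlo p against exact binomial
enumeration and its null uniformity by Kolmogorov–Smirnov.

Parental configurations entering the test come from the parents' own
copy-number calls when definite (sire pseudocopies $=$ copies $- 1$);
otherwise `infer_parental_config()` maximises the multinomial likelihood
over the nine configurations. The $(0,1)$ vs $(1,0)$ symmetry is
unresolvable from offspring data and is broken only by parental calls,
never arbitrarily.

## Transmission inference and family scans

`infer_transmission()` attributes each offspring allele to a parent when
exactly one attribution is consistent with the trio; Mendelian
inconsistencies are flagged and excluded from all downstream tables.
Because a fully heterozygous trio is phase-ambiguous, a second,
linkage-informed pass (on by default when a map is supplied) phases each
parent's heterozygous markers per chromosome by majority vote over
offspring resolved at consecutive marker pairs, and imputes an unresolved
transmission from the offspring's nearest resolved marker of the same
phased segment. This recovers most of the offspring that single-marker
deduction must discard — the binding constraint on per-family scan power —
and emulates the pedigree-plus-genotype IBD estimators used for such
scans. When the sire- and dam-side imputations conflict the trio stays
unresolved; a family in which both parents are heterozygous at *every*
marker is information-theoretically unrescuable and is left untouched (a
dedicated test documents this limit).

`scan_trait()` cross-tabulates a binary phenotype (sex, or
discrepant/non-discrepant) against the transmitted allele of each
heterozygous parent at each marker and computes the 2x2 Pearson
chi-squared statistic (1 df, no continuity correction, matching the plain
chi-squared tests such scans report); markers with fewer than two
informative offspring, a single phenotype class, or monomorphic
transmission are skipped with a reason. No genome-wide multiple-testing
correction is applied by default; `summarize_scan()` reports a per-family
Sidak-adjusted top p-value alongside the raw one, and
`compare_scan_traits()` flags families whose sex-trait and
discordance-trait scans converge on the same chromosome — the situation
expected when the pseudocopy locus sits on the sex-determining chromosome
itself.

## What the synthetic generator emulates

`generate_study()` produces the full study layout from a single seed: by
default 64 full-sib families of 32 offspring (~2,000 offspring, matching
the scale of the cohort the pipeline is designed for), a 6-locus
microsatellite panel with 8 equifrequent alleles (enough exclusion power
for near-complete assignment), 109 biallelic SNPs spread over the 29
Atlantic salmon chromosome pairs, and triplex qPCR with two replicates and
Gaussian Ct noise (sd 0.15 cycles, independent across replicates and
amplicons, perfect doubling efficiency, dropout above Ct 40).

Design choices that deserve justification:

* **Carrier layout.** Eight families segregate a heterozygous pseudocopy:
  five through a carrier sire, two through both parents, one through a
  carrier dam — the structure reported for the cross design being
  emulated, where most carriers were sires.
* **Gene drop.** Gametes are drawn by a Haldane-model walk along each
  chromosome (`simulate_gametes()`), and both special loci — the Y-linked
  *sdY* locus and the pseudocopy locus — ride along this walk like
  markers, so their marginal transmission is exactly Mendelian *and* they
  co-segregate with the SNPs of their chromosome, which is what the scans
  must detect. `linked_pseudo = TRUE` places the pseudocopy on the
  sex-determining chromosome.
* **Male recombination suppression.** Sire meioses use map distances
  scaled by `male_recombination_ratio` (default 0.25): Atlantic salmon
  males recombine far less than females (reported female:male map ratios
  of roughly 4–8), and this heterochiasmy is the biological reason
  per-family sex mapping works with a sparse genome-wide panel.
* **Locus placement.** The default sdY and pseudocopy positions (40 cM)
  sit a few cM from the nearest panel SNP. A panel assembled for linkage
  mapping tags the loci of interest; placing the simulated loci far from
  every marker would emulate a panel no study would use.

What the generator does **not** emulate: genotyping error and null
alleles, plate/batch effects or amplification-efficiency drift,
multi-generation pedigrees, sex reversal, or a second pseudocopy locus
segregating in one family. Passing tests therefore demonstrate the
correctness and power of the analysis chain under clean Mendelian
segregation with replicate-level assay noise — not robustness to
systematic genotyping artefacts, which real studies handle upstream.

## Numerical choices and problem sizes

All randomness flows through explicit seeds (`generate_study(config,
seed)`, `gof_test(..., seed)`, `run_pipeline(..., seed)`); the same seed
reproduces a study byte-identically through `write_study()`. Monte-Carlo
p-values use the add-one correction, so $p \ge 1/(B+1)$ always. Likelihood
ties in `infer_parental_config()` are declared at $10^{-9}$ log-likelihood
units. The test suite exercises the full stated conditions — 500 simulated
20-offspring families for parental-configuration recovery, 1,000 samples
per copy class for call accuracy, 200 simulated 30-offspring families with
the 109-SNP panel for scan recovery, plus exhaustive 2x2 tables to
$n = 20$ against a contingency oracle — and completes in a few minutes on
one CPU; the complete default pipeline (64 x 32 offspring, scans included)
runs in about two minutes.

## Known limitations

The copy-number caller trusts the calibrator panel; a mis-genotyped
reference male biases every fold change of its run. Scan power depends on
parental heterozygosity around the causal locus; with four SNPs per
chromosome a family in which neither tagging SNP is heterozygous in the
transmitting parent (~6% of families at allele frequency 0.5) cannot map
the locus, which bounds attainable top-hit recovery. The per-family 2x2
chi-squared is asymptotic; for very small informative counts the
Monte-Carlo mode of `gof_test()` is the safer tool. Finally, the
inference that a discordant family's parent carries the pseudocopy
collapses at $(0,1)$/$(1,0)$ symmetry without parental qPCR calls.
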