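---
title: "Combined allele-specific expression: model, decisions, and limits"
author: "casekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined allele-specific expression: model, decisions, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casekit)
```

## The problem

A transcribed variant at which a sample is heterozygous acts as a
*reporter*: RNA-seq reads covering it can be assigned to the reference
or the alternative gene copy, and a departure of the reference-read
fraction from 0.5 reveals that one copy is transcribed (or its mRNA
retained) more than the other.  Because both copies share the same
nucleus, the comparison is internally controlled — donor health,
ischemia time, batch and other sample-level covariates cancel.
Combining the imbalance across many heterozygous samples ("combined
allele-specific expression", cASE) turns a collection of noisy
per-sample binomial observations into one powerful test per reporter,
and a genotype-subgroup comparison then asks *which* nearby variant
could drive the imbalance in cis.

## The statistic

For sample $i$ with $r_i$ reference and $a_i$ alternative reads
($n_i = r_i + a_i$), the exact two-sided binomial p-value against a
balanced fraction is

$$p_i = P\left(|X - n_i/2| \ge |r_i - n_i/2|\right),
  \qquad X \sim \mathrm{Bin}(n_i, 1/2),$$

converted to a signed probit deviate
$z_i = \mathrm{sign}(r_i - a_i)\,\Phi^{-1}(1 - p_i/2)$ (positive =
reference excess).  The exact test rather than a normal approximation
matters at the low coverages where many reporters live.  Two numerical
details: $p_i$ is floored at the smallest positive double so the probit
stays finite (|z| then tops out near 37.5; a hard cap at 38 guards the
transform), and the minimal imbalance at odd coverage is snapped to
$p_i = 1$ — by the symmetry of the null pmf its two-sided tail covers
the whole support, and one-ulp rounding in the tail sum must not turn an
uninformative sample into a signed one.  A consequence worth knowing:
$z_i = 0$ whenever $p_i = 1$, which includes counts like 3 vs 2, not
only exact ties.

Per-sample deviates are combined with read coverage as weight by the
weighted Stouffer rule

$$Z = \frac{\sum_i w_i z_i}{\sqrt{\sum_i w_i^2}}, \qquad w_i = n_i,$$

which keeps unit variance under the null of independent standard-normal
deviates — that property is what makes the calibration of the whole
pipeline testable, and it is why the denominator is $\sqrt{\sum w_i^2}$
and not $\sum w_i$.  The test suite guards this with an algebraic check
that duplicating a sample is *not* equivalent to doubling its weight.

## The permutation null and the two p-values

Significance is assessed against a null built from the same read
counts with allele labels shuffled across heterozygous samples, 1000
draws by default.  One scheme choice is forced by algebra: reassigning
intact $(r_i, a_i)$ pairs *between* individuals leaves every $z_i$
attached to its own $w_i$ and the combined $Z$ literally unchanged, so
it cannot form a null.  The shuffle that does is the per-sample
allele-label flip — with probability 1/2, independently per sample,
swap which count is "reference".  The two-sided $p_i$ is invariant
under the swap and $z_i$ is exactly negated, so the flip is applied as
a sign flip on $z_i$.  Flips are drawn for samples in sorted-id order,
making the whole analysis invariant to input row order at a fixed seed.

Two p-values are reported per reporter:

* `p_perm`, the add-one empirical estimate
  $(1 + \#\{|Z_k| \ge |Z_{obs}|\})/(1 + N)$, floored at $1/(N+1)$;
* `p_tail`, a Gaussian tail after fitting mean and standard deviation
  to the permutation draws, which resolves significance far below the
  empirical floor.

Both are interpretations, not reproductions, of printed significance
levels in this literature: an empirical null of 1000 draws cannot go
below $10^{-3}$, and published Z-to-p mappings for this statistic are
not always recoverable.  Benjamini–Hochberg adjustment across reporters
(on `p_tail`) yields `q_value`; the across-reporter adjustment rule is
a package choice.  Note that under a strong true effect the sign-flip
null is wider than standard normal (its variance is
$\sum w_i^2 z_i^2 / \sum w_i^2$), which makes both p-values
conservative in exactly the situations where conservatism is cheap.

Reporters whose every sample fails the coverage floor are kept in the
output with `direction = "none"`, both p-values 1 and a `low_coverage`
flag, so that filtering is visible rather than silent.  A reporter
whose every deviate is zero has a degenerate (zero-variance) flip null;
it carries no allelic information and is likewise reported with
`p_tail = 1`.

## Candidate mediation within TADs

Regulatory contacts concentrate within topologically associating
domains, so candidates for mediating a reporter's imbalance are the
variants sharing a TAD with it (union over overlapping TADs, the
reporter itself excluded).  Coordinates follow each format's native
convention — variants 1-based, TAD intervals 0-based half-open — with
the membership test $s < p \le e$ applied explicitly at the boundary.

For each candidate, samples heterozygous at the reporter are split by
candidate genotype.  If the candidate is the true cis-driver, the
candidate-heterozygous subgroup concentrates the signal — its combined
Z (`C_Z`) should be more extreme than the all-sample reporter Z
(`R_Z`) — while candidate-homozygous samples, whose two gene copies
sit on the same regulatory background, should show no imbalance.  The
rule implemented is:

```
is_candidate  <-  |C_Z| > |R_Z|          (strictly)
              AND hom_p >= alpha          (alpha = 0.05)
              AND n_het >= min_subgroup   (default 3)
              AND n_hom >= min_subgroup
```

Choices the source procedure leaves open, fixed here as package
defaults: "more significant" is compared on the combined Z scale (both
subgroup statistics are unit-variance under the null by construction);
`hom_p` is the two-sided standard-normal tail of the homozygous-subgroup
Z, again justified by the unit-variance construction, rather than a
per-subgroup permutation fit; homozygous-reference and
homozygous-alternative samples are pooled into one subgroup; the
minimum subgroup size of 3 exists because a one-sample Z is degenerate
in this comparison; missing genotypes drop the sample from both
subgroups, never imputed.  Every assessment records which clause
failed, and a candidate in perfect LD with the reporter can never be
flagged (its `C_Z` equals `R_Z` exactly and its homozygous subgroup is
empty) — the rule is honest about indistinguishability under perfect
linkage.  LD between candidate and reporter is annotated as the squared
Pearson correlation of unphased dosages (composite r²), the scale on
which standard tooling reports it; it is symmetric and sign-blind by
construction.

This is a screening heuristic, not a causal-mediation model: no
conditional likelihood, no colocalization, no adjustment across the
many candidates a large TAD contains.

## What the generator simulates, and what it does not

The synthetic-data module exists so that every stage above is testable
against known truth with no external data.  Its model:

* **Haplotypes.** Within an LD block the first variant's allele is
  Bernoulli(MAF); each subsequent variant copies the previous variant's
  allele with probability $c$, else is redrawn.  For equal MAFs the
  haplotype correlation of adjacent variants is exactly $c$ and decays
  multiplicatively along a block, so pairwise r² is directly dialled:
  $c = \sqrt{0.96}$ gives the near-perfect tag pair, $c = 0.7$ the
  moderate-LD causal candidate, $c = \sqrt{0.05}$ a weakly linked one.
  Genotypes are sums of two independent haplotypes (HWE).  This is a
  first-order copying model, not a coalescent: it produces the LD
  structure the mediation rule needs and nothing subtler.
* **Coverage.** Negative binomial with mean 50 and dispersion 0.3
  (variance $\mu + 0.3\mu^2$), floored at one read.  RNA-seq depth is
  overdispersed; the specific values are package defaults, since
  nothing in the re-analyzed islet data pins them down.
* **Allelic skew.** Only reporter-heterozygous samples emit counts.
  The reference-read fraction is $\theta$ when the haplotype carrying
  the reporter's reference allele also carries the causal risk allele,
  $1 - \theta$ when anti-phased, and exactly 0.5 when the sample is
  homozygous at the causal variant — cis-regulation rides the
  haplotype.  $\theta = 0.5$ is a null generator.
* **Default MAF 0.3** for all scenario variants, typical of the common
  regulatory variants this analysis targets.

Packaged scenarios: `"mediation"` (60 samples, $\theta = 0.75$, causal
at $c = 0.7$, two unlinked in-TAD variants, one variant outside the
TAD, the TAD being a super-enhancer-scale interval on chr8) and
`"tagging"` (a causal reporter with tag and weakly linked partners at
r² targets 0.96 / 0.05 / 0.05, $\theta = 0.7$).

What passing tests on these simulations do **not** show about real
data: there is no read-mapping bias toward the reference allele (no
WASP-style correction is implemented or needed here), no within-sample
overdispersion of the allelic fraction (a beta-binomial per-sample test
is deliberately out of scope — the per-sample test is exact binomial),
no genotyping error, and one reporter per gene rather than
haplotype-aware aggregation across reporters.  Results on real counts
inherit whatever upstream allele-assignment pipeline produced them.

## Assay quantifications and motif scoring

The closed-form wet-lab normalizations are implemented exactly as their
definitions: editing efficiency
$(1 - 2^{-\Delta\Delta C_t}) \times 100$ with the sign convention that
a *later* target $C_t$ in edited cells (fewer intact alleles) gives
positive efficiency — the only direction consistent with deletions
detected by amplifying the intact allele; negative efficiencies are
reported unclamped with a warning.  Relative expression is
$2^{-\Delta\Delta C_t}$; insulin secretion is percent of content and
fold over the low-glucose basal; luciferase is firefly/Renilla
normalized to the empty-vector control; growth curves divide by day 0.
Technical duplicates are averaged by a thin batch layer before the
formulas apply.

Motif scoring uses the JASPAR relative profile score: log-odds of the
window against a uniform background, rescaled to $[0, 1]$ by the
column-wise worst/best sums, with 0.80 as the default call threshold.
One numerical decision: PFM columns are rescaled to a common total of
100 observations before the background-split pseudocount (0.8) is
added.  An absolute pseudocount on raw counts would make scores depend
on the sequencing depth behind the matrix; after rescaling, the score
is exactly invariant to multiplying all counts by a positive constant,
which is the behaviour a *relative* score should have.  Both alleles of
a variant are scanned over every motif placement covering the variant
site, on both strands, and called `both` / `ref_only` / `alt_only` /
`neither` by thresholding each allele's best score.  Reproducing
database-specific TF lists would require pinning a JASPAR release and
is out of scope; the operator is validated on constructed matrices.

## Problem sizes used by the test suite

The shipped tests run the pipeline at the following scales, chosen as
the package's standing verification conditions: calibration on 2,000
null reporters (20 samples, coverage 30, 200 permutations each,
empirical rejection at $\alpha = 0.05$ expected in $[0.04, 0.06]$);
power monotonicity at 10 samples and coverage 20, where
$\theta = 0.6$ sits mid-power and $\theta = 0.8$ near saturation, 100
replicates per level; mediation recovery over 100 seeded replicates of
the mediation scenario (causal flagged in at least 80, each unlinked
variant in at most 10); a 100-replicate power check at 30 samples and
coverage 50 for $\theta = 0.8$; and exactness checks (Stouffer oracle,
binomial enumeration, LD r², motif arithmetic) at $10^{-12}$.  The
full suite completes in well under a minute on one core.

## Known limitations

* The Z-to-p mapping of published cASE tables is not recoverable from
  their description; both reported p-values here are defined
  constructions, documented above, and should be compared with
  published values qualitatively (sign and ranking), not numerically.
* The sign-flip null conditions on the observed per-sample deviates;
  under strong effects it is conservative (see above).
* The mediation rule is a screen.  In dense LD it flags the credible
  cis-drivers, including tags of the true driver; it cannot separate
  variants in very high mutual LD, and does not try.
* `ld_r2` is composite (dosage) r²; with phased data, haplotype r² can
  differ, and monomorphic variants report missing LD rather than 0.
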