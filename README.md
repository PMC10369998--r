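# casekit

Combined allele-specific expression (cASE) analysis with TAD-constrained
candidate-variant mediation, for regulatory-genetics studies that start
from allele-resolved RNA-seq read counts.

In every sample heterozygous for a transcribed *reporter* variant, the
reads supporting the reference and alternative alleles measure the
relative expression of the two gene copies under identical cellular
conditions.  `casekit` turns those counts into a single significance
measure per reporter and then screens the reporter's topologically
associating domain (TAD) for the regulatory variant most likely to
drive the imbalance in cis.

The statistic: for sample *i* with *rᵢ* reference / *aᵢ* alternative
reads (*nᵢ = rᵢ + aᵢ*),

- exact two-sided binomial p-value
  *pᵢ = P(|X − nᵢ/2| ≥ |rᵢ − nᵢ/2|)*, *X* ~ Bin(*nᵢ*, ½),
  as a signed probit deviate *zᵢ* = sign(*rᵢ − aᵢ*) Φ⁻¹(1 − *pᵢ*/2);
- coverage-weighted Stouffer combination
  **Z = Σ wᵢ zᵢ / √(Σ wᵢ²)** with *wᵢ = nᵢ* (unit variance under the
  null);
- significance against a sign-flip permutation null (1000 draws by
  default): an empirical p-value with floor 1/(N+1) and a Gaussian-tail
  p-value fitted to the null, BH-adjusted across reporters;
- mediation rule per TAD candidate: flag a candidate when the
  candidate-heterozygous subgroup Z is strictly more extreme than the
  all-sample Z (|C.Z| > |R.Z|), the candidate-homozygous subgroup is
  non-significant, and both subgroups have at least 3 samples; dosage
  LD r² against the reporter is annotated.

Also included: a synthetic-data generator (phased haplotypes under HWE
with tunable block LD, overdispersed coverage, haplotype-borne allelic
skew) that makes the whole pipeline verifiable without external data;
closed-form assay quantifications (CRISPR editing efficiency from
qPCR, 2^−ΔΔCt relative expression, insulin secretion as percent of
content and fold over basal, dual-luciferase, growth curves); and
JASPAR PFM relative-profile scoring of variant alleles with the 80%
call threshold.

## Worked example

```r
library(casekit)

# packaged scenario: 60 samples, one reporter, a causal regulatory
# variant in moderate LD inside the same TAD, two unlinked variants
sim <- simulate_scenario("mediation", seed = 7)

res <- run_case(sim$counts, n_perm = 1000, seed = 7)
res[, c("variant_id", "n_samples", "Z", "p_perm", "p_tail", "direction")]
#>   variant_id n_samples     Z p_perm p_tail  direction
#> 1   reporter        20 -4.83  0.047 0.0561 alt-biased
```

Twenty of the 60 samples are heterozygous at the reporter and pass the
10-read coverage floor.  Z = −4.83 means the alternative allele is
preferentially transcribed; the empirical permutation p-value is 0.047
(the Gaussian-tail value 0.056 is close because at 20 informative
samples the fitted null is near the empirical one).

```r
med <- run_mediation(sim$counts, sim$genotypes, sim$variants, sim$tads,
                     reporter_id = "reporter")
med[, c("candidate_id", "R_Z", "C_Z", "hom_p", "n_het", "n_hom",
        "ld_r2", "is_candidate", "reason")]
#>   candidate_id   R_Z   C_Z    hom_p n_het n_hom   ld_r2 is_candidate
#> 1       causal -4.83 -8.80 6.17e-01    11     9 0.62091         TRUE
#> 2    unlinked1 -4.83 -3.53 3.18e-04     8    12 0.00982        FALSE
#> 3    unlinked2 -4.83 -2.87 6.71e-05     8    12 0.01690        FALSE
```

The causal variant concentrates the signal: among its 11 heterozygous
carriers the combined Z strengthens to −8.80 while its 9 homozygous
carriers show no imbalance (hom p = 0.62), so it is proposed as the
putative cis-mediator.  The unlinked variants dilute the signal and
their homozygous subgroups stay significant — both reasons are recorded
per row.

A command-line wrapper over the same functions is installed under the
package's `exec/` directory:

```sh
casekit=$(Rscript -e 'cat(system.file("exec", "casekit", package = "casekit"))')
Rscript "$casekit" simulate --out-dir sim/ --scenario mediation --seed 7
Rscript "$casekit" run --counts sim/counts.tsv --out results/ --n-perm 1000 --seed 7
Rscript "$casekit" mediate --counts sim/counts.tsv --vcf sim/geno.vcf \
        --tads sim/tads.bed --reporter reporter --out mediation.tsv
```

See `vignettes/case-methods.Rmd` for the model, the permutation-scheme
choice, all tunable defaults, and known limitations.

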