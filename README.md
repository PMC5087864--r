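# cogsvd — comparative GSVD of patient-matched copy-number profiles

`cogsvd` is an R package for the joint analysis of **two patient-matched
DNA copy-number datasets** — typically primary tumor and normal profiles
of the same patients — with the generalized singular value decomposition
(GSVD) read as a comparative spectral decomposition. It is aimed at
researchers who want to separate tumor-exclusive copy-number alteration
(CNA) patterns from germline variation and experimental artifacts that
two matched datasets share or carry separately, and to test whether a
recovered pattern stratifies patient survival.

## The model

Given a tumor matrix $D_1 \in \mathbb{R}^{M_1 \times N}$ and a normal
matrix $D_2 \in \mathbb{R}^{M_2 \times N}$ (probes × patients, log2
relative copy number, matched patient columns, independent probe rows,
both of full column rank), the GSVD factors both at once:

$$D_i = U_i \Sigma_i V^T = \sum_{n=1}^{N} \sigma_{i,n}\, u_{i,n} \otimes v_n^T , \qquad i = 1,2,$$

with one shared set of unit-norm probelets $v_n$ (patterns across
patients) and dataset-specific orthonormal arraylets $u_{i,n}$ (patterns
across the genome). Each component's tumor-vs-normal balance is its
**angular distance**

$$\theta_n = \arctan\!\left(\sigma_{1,n}/\sigma_{2,n}\right) - \pi/4 \in [-\pi/4, \pi/4],$$

$+\pi/4$ = tumor-exclusive, $0$ = common, $-\pi/4$ = normal-exclusive
(exclusive beyond $2\pi/15$, common within $\pi/16$ by default). On top of
the decomposition the package provides:

* **CNA calling** from an arraylet at chromosome / arm / segment / probe
  resolution (2-sd genomic rule, 1-sd sign-consistent chromosomal rule);
* **cross-platform probe matching** (one-to-one, ≥1 bp overlap, documented
  greedy tie-break) and projection of patterns across platforms;
* **patient classification** into low/high pattern weight by probelet
  coefficient or pattern correlation, with the norm-scaled 0.15 cutoff;
* **survival statistics**: Kaplan–Meier curves and medians, log-rank,
  univariate/bivariate Cox (Efron ties, Wald CIs), Harrell's concordance,
  exact hypergeometric enrichment, Mann–Whitney tests;
* a **synthetic cohort generator** that plants a survival-linked
  tumor-exclusive pattern, a gender-linked X-deletion common to both
  datasets, a tumor-only batch effect and i.i.d. probe noise — a full
  ground-truth test bed for the pipeline.

## Worked example

Simulate a 60-patient cohort (2,200 probes; gains on chr1 and chr3p, loss
on chr2, carried by half the patients; hazard ratio 9 between carriers
and non-carriers) and run the discovery flow:

```r
library(cogsvd)

co  <- generate_cohort(cohort_params(seed = 42))
cfg <- discovery_config(tumor = co$tumor, normal = co$normal,
                        clinical = co$clinical,
                        exclude = c("chr1", "chr2", "chr3p"), seed = 42)
rep <- run_discovery(cfg)

head(summary(rep$model)[, c("component", "sigma1", "sigma2", "theta", "label")], 4)
#>   component    sigma1   sigma2     theta           label
#> 1         1 58.720325 5.131777 0.6982261 tumor_exclusive
#> 2         2 11.562731 4.868439 0.3868816    intermediate
#> 3         3  5.706539 4.590241 0.1079906          common
#> 4         4  9.156196 7.462808 0.1015442          common

rep$calls$chromosome[, c("region", "direction", "genomic_dev")]
#>   region direction   genomic_dev
#> 1   chr1      gain  10.661894837
#> 2   chr2      loss -10.767513862
#> 3   chr3      gain   5.347156612
#> 4   chr4      none  -0.001948359
#> 5   chrX      none  -0.207378498

rep$classification
#> <patient_classification> mode coefficient, cutoff 0.7149: 30 high / 30 low

rep$survival$groups
#>   group  n events km_median
#> 1   low 30     13 67.549052
#> 2  high 30     28  5.217826
```

Reading the output: the first component is tumor-exclusive
($\theta = 0.70 > 2\pi/15$) and its arraylet reproduces the planted CNA
pattern — chr1/chr3 gains and the chr2 loss exceed twice the genomic
standard deviation (the `genomic_dev` column is in sd units), while chr4
and chrX are quiet. Classifying patients by that component's probelet
coefficients against the norm-scaled cutoff splits the cohort 30/30, and
the two groups separate sharply in survival: Kaplan–Meier medians 67.5 vs
5.2 months, log-rank $P = 3.6\times10^{-10}$, Cox hazard ratio 13.7
(95% CI 5.0–37.3), concordance 0.72 — the high-weight group carries the
planted 9-fold hazard.

An independent cohort is classified against a fixed cutoff with
`run_validation(profiles, pattern, clinical, cutoff = 0.15)`, optionally
through a cross-platform probe matching (`match_probes()` +
`pairs`/`side` arguments).

## Command line

`inst/cli/cogsvd.R` exposes the flows as subcommands
(`simulate | gsvd | call | match | classify | survival | discover |
validate`), e.g.

```sh
Rscript inst/cli/cogsvd.R simulate --out cohort/ --seed 1
Rscript inst/cli/cogsvd.R discover \
  --tumor cohort/tumor.tsv --normal cohort/normal.tsv \
  --annotation cohort/annotation.tsv --centromeres cohort/centromeres.tsv \
  --clinical cohort/clinical.tsv --out run1/
```

All formats are plain TSV (matrix: `probe_id` + patient columns;
annotation: `probe_id, chrom, start, end`, 0-based half-open; centromeres:
`chrom, centromere_start, centromere_end`; clinical: one row per patient
with `patient_id, survival_time, event` and optional `chemotherapy,
radiation, age_group, grade, mgmt_status, idh1_status, gender, batch`).
Reruns of `discover` with identical inputs produce byte-identical output
files.

## Further reading

`vignettes/comparative-gsvd.Rmd` documents the model and its assumptions,
every convention the implementation pins down (sign/order canonicalization,
strict call boundaries, tie-breaks, censoring model), what the synthetic
generator does and does not emulate, and the design decisions taken where
the published description was ambiguous.
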