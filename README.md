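# TCRcta

Recover T-cell receptor (TCR) CDR3 amino-acid sequences from bulk
sequencing reads, score their chemical complementarity against
cancer-testis antigens (CTAs), and test whether that complementarity
stratifies clinical outcome.

## Who this is for

Tumor immunologists and bioinformaticians who want a scalable,
structure-free answer to "could the T cells resident in this tumor
engage this antigen?" — and a reproducible harness for the cohort
statistics that usually follow (survival stratification, antigen-loss
odds, methylation and proliferation-marker correlates). The motivating
use case is the DDX53 (CAGE) antigen in esophageal carcinoma, whose
real cohort inputs are access-controlled; the package therefore ships
a fully seeded synthetic-data generator that emulates every input with
known ground truth under an immuno-editing generative model (high
complementarity → worse disease-free survival, more antigen-negative
tumors, higher antigen-gene methylation).

## The score

For CDR3 residues $c_1..c_L$ slid ungapped along antigen residues
$t_1..t_M$, the per-offset score is

$$S(o) = \sum_i f(c_i, t_{o+i}) + w \sum_i \big[f(c_i, t_{o+i-1}) + f(c_i, t_{o+i+1})\big]$$

where $f$ is either the electrostatic attraction $-q(a)q(b)$ (unit
charges for D/E/K/R, +0.5 for H) or the hydropathy product
$u(a)u(b)$ on the min–max-normalized Kyte–Doolittle scale, and
$w = 0.5$ attenuates the one-position-shifted partner terms. The best
offset is retained per pair; the *Combo CS* maximizes the sum of the
z-standardized electrostatic and hydropathy per-offset scores.
Per-sample scores are the mean Combo CS over the sample's CDR3s.
Details, defaults and their rationale are in the vignette
(`vignettes/tcr-cta-complementarity.Rmd`).

## Worked example

```r
library(TCRcta)

## a CDR3 with a DKR motif against the bundled 60-aa DDX53 fragment
scorePair("CASSDKRGF", ddx53Fragment())
#>        cdr3     antigen_id electro_cs hydro_cs combo_cs best_offset_electro
#> 1 CASSDKRGF DDX53_fragment        2.5 4.816852  3.02816                  10
#>   best_offset_hydro best_offset_combo
#> 1                13                10
```

The electrostatic CS of 2.5 says that at offset 10 (0-based, placing
the CDR3's DKR core over the fragment's `DEADK` region) the pair
accumulates 2.5 units of net opposite-charge attraction, shift terms
included; the Combo CS of 3.03 is the best combined standardized
score, reached at the same offset.

The full pipeline on synthetic data:

```r
config  <- simulationConfig(seed = 1)       # 72 samples, HR 3.4, ...
segs    <- toySegmentLibrary()
cohort  <- genCohort(config)                # CDR3s + clinical tables
reads   <- genReads(config, segs, repertoire = cohort$cdr3)
rec     <- recoverRepertoire(reads$reads, segs)   # exact on synthetic data
scores  <- scoreRepertoire(rec$cdr3, cohort$antigen)
cs      <- aggregateSampleCS(scores)
runCohortAnalysis(cs, cohort$survival, cohort$expression,
                  cohort$methylation, cohort$covariates,
                  markerGenes = c("POLG", "EIF2AK3"))
#> CohortReport — 72 samples
#>   lower: n=36, events=22, median DFS=35.92004 months
#>   upper: n=36, events=33, median DFS=12.89539 months
#>   logrank p = 1.91e-07
#>   Cox (univariate): Exp(beta) = 4.3, p = 1.151e-06
#>   zero expression: 80.6% vs 61.1%, OR = 2.64, p = 0.1187
#>   methylation beta: 0.915 vs 0.870, p = 2.296e-05
#>   CS~POLG: r = 0.429, p = 0.0001678
#>   CS~EIF2AK3: r = 0.421, p = 0.0002267
```

The upper 50th-percentile complementarity group shows the planted
immuno-editing signature: shorter median DFS (12.9 vs 35.9 months,
hazard ratio 4.3), a larger share of antigen-negative tumors (80.6%
vs 61.1%) and higher DDX53 methylation (β 0.92 vs 0.87).

A command-line wrapper with `simulate` / `recover` / `score` /
`analyze` subcommands is installed at `inst/scripts/tcrcta`
(`Rscript inst/scripts/tcrcta --help`).

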