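# accessmap

Quantitative analysis linking chromatin accessibility (DNase tag-density
tracks) to transcription-factor occupancy (scored ChIP peak lists).

Sequence-specific transcription factors in animal cells bind chromatin
in broad, overlapping, graded patterns. Under the *widespread binding*
model, factors are expressed at concentrations high enough to occupy
their recognition sequences wherever chromatin is accessible, so in
vivo occupancy at a site is set jointly by local accessibility and the
site's intrinsic affinity — no direct protein-protein cooperativity
required. `accessmap` is an R package for testing this model
quantitatively. It provides:

* **Accessible-region calling**: Poisson window tests against the local
  50-kb background rate, genome-wide Benjamini-Hochberg control (5% FDR
  default), replicate concordance, and local-maximum accessibility
  peaks (20-bp windows, 75-bp radius).
* **Motif analysis**: MEME-minimal PWM I/O, genome scanning on both
  strands with exact score-distribution p-values (dynamic programming;
  conservative grid mode for wide motifs), affinity cohorts
  (−5: *P* < 10⁻⁴·⁵ through −2), and scrambled-PWM null motifs with
  permutation-based similarity rejection.
* **Occupancy statistics**: the ≥ 200-bp / encompassment overlap rule
  with an exact hypergeometric base-pair overlap test, binding coverage
  of ranked accessibility peaks (cohorts of 1,000), ChIP-rank
  accessibility curves with notch 95% CIs (cohorts of 200),
  accessible-vs-closed affinity-cohort occupancy tables, and
  accessibility-rank correlation matrices.
* **Temporal analysis**: between-stage ratios of occupancy and
  accessibility over the top-400 bound regions and their Pearson
  correlation.
* **A seeded synthetic-study generator** implementing the
  thermodynamic occupancy model
  `O = c · Σ_sites A(site)^α · 2^(S − S_max)` with Poisson tag counts
  and log-normal ChIP noise, providing full ground truth for
  parameter-recovery validation of every stage.

The in vivo occupancy at a genuine recognition sequence in accessible
chromatin exceeds that of an equal-affinity sequence in closed
chromatin, and exceeds matches to column-scrambled versions of the same
PWM; temporal changes in accessibility explain most of the temporal
change in binding. The package reproduces all of these signatures from
its own synthetic studies.

## Worked example

```r
library(accessmap)

res <- run_pipeline(run_config(seed = 1), out_dir = "run1")
writeLines(make_report("run1"))
```

The pipeline simulates the default two-stage study (2-Mb genome, 400
accessible regions, 16 factors), calls concordant 5% FDR accessible
regions, scans genuine and scrambled PWMs, and writes every analysis
table. The report it printed for seed 1:

```
accessmap pipeline report
=========================

ChIP peak overlap with accessible chromatin:
  mean fraction 0.691 over 16 factors (range 0.611-0.795)

Binding coverage of ranked accessibility peaks:
  top cohort 1.000, last full cohort 1.000 (2 cohorts)

ChIP-rank accessibility curves (first stage):
  884 factor x cohort rows; top-cohort median 50.5

Affinity cohorts (genuine motifs):
  accessible median of medians 10.61 vs closed 1.16

Accessibility-rank correlations:
  r(ChIP, density) 0.12-0.28; r(sites, density) -0.04-0.02

Temporal ratio correlations:
  r = 0.75-0.93 over 16 factor/stage pairs
```

Reading the numbers: about two thirds of each factor's strongest ChIP
peaks lie in accessible chromatin under the ≥ 200-bp rule; matches to
genuine motifs in accessible regions are occupied roughly tenfold above
equal-affinity matches in closed chromatin (10.61 vs 1.16 in IP/input
units); measured occupancy correlates with accessibility down the peak
rank list while motif content does not (r ≈ 0.2 vs r ≈ 0); and
between-stage accessibility ratios explain most of the occupancy
change (r = 0.75–0.93) under the generator's σ = 0.3 ChIP noise.

Individual steps are plain functions — `simulate_study()`,
`call_accessible_regions()`, `scan_pwm()`, `scramble_pwm()`,
`affinity_cohort_analysis()`, `stage_ratio_correlation()` — see their
help pages and the methods vignette (`vignettes/accessmap-methods.Rmd`)
for the model, parameter meanings and validation design.

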