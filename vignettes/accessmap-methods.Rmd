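---
title: "Methods: linking chromatin accessibility to factor occupancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking chromatin accessibility to factor occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question and the model

Sequence-specific transcription factors bind chromatin in broad,
overlapping, graded patterns. The *widespread binding* model explains
this quantitatively: factors are present at concentrations high enough
to occupy their recognition sequences wherever the DNA is accessible, so
in vivo occupancy at a site is driven jointly by (i) the local chromatin
accessibility and (ii) the intrinsic affinity of the site, without
requiring direct protein-protein cooperativity. `accessmap` implements
the analyses that test this model against DNase tag-density data
(accessibility) and ChIP score data (occupancy), together with a fully
seeded generator that *embodies* the model, so every statistic in the
package can be validated against known ground truth.

The generator's occupancy model for a candidate 1-kb window anchored at
position $x$ is

$$ O(x) \;=\; c \left( A(x)^{\alpha}\, a_0 \;+\;
   \sum_{s \in \text{window}} A(s)^{\alpha}\, 2^{\,S(s) - S_{\max}}\,
   e^{-|s - x| / \rho}
   \right), \qquad
   \text{score} = O(x)\, e^{\varepsilon},\;
   \varepsilon \sim N(0, \sigma^2), $$

where $A(\cdot)$ is the fold accessibility over background (1 in closed
chromatin), $S(s)$ the PWM log-odds of site $s$ in bits so that
$2^{S - S_{\max}}$ is a Boltzmann relative affinity in $(0, 1]$, $a_0$ a
small residual affinity representing sequence-independent occupancy of
accessible DNA, $c$ an arbitrary IP/input scale, and $\sigma$ the
multiplicative log-normal ChIP noise (ratios of positive signals).
Accessibility enters *per site*: each recognition sequence in the window
is weighted by the accessibility at its own position. The exponential
kernel with resolution $\rho$ (default 250 bp) expresses that ChIP
signal is localized to within a fragment length of the bound site; a
window reports mostly the occupancy of sites near its anchor, not a
flat sum over a kilobase. Without this kernel the measured window value
at a weak genuine site is indistinguishable from the value at a nearby
random position (both are dominated by the same window sums), and the
weak-cohort genuine-versus-scrambled contrast that motivates the
scrambled-motif null degenerates into exact ties. Tag counts are
Poisson per 20-bp bin with mean $\lambda_{bg}$ outside accessible
regions and $\lambda_{bg} A_i$ inside region $i$ — counts are event
counts, and the region caller is framed against a background rate.

## Accessible-region calling

`call_accessible_regions()` slides a window (default 150 bp, rounded to
whole bins — 160 bp on a 20-bp track, since the default window is not a
bin multiple) along the track in bin-size steps, computes the Poisson
upper-tail probability of the window sum against the rate estimated
from the surrounding 50 kb (clipped at chromosome ends), adjusts all
window p-values genome-wide by Benjamini-Hochberg, keeps windows with
$q \le$ FDR (default 5%) and merges survivors across gaps of at most
50 bp. The test window is kept inside its own background by default;
this biases the rate up for narrow peaks and is therefore conservative
(`include_self = FALSE` switches it off). Region score is the maximum
constituent window sum, and region p/q are the minima — a region is as
significant as its best window.

Replicate concordance retains replicate-1 regions that overlap a
replicate-2 region by at least 1 bp and intersects the coordinates,
keeping replicate-1 statistics; the concordance rule itself (any
overlap, intersection) is the package's choice, since only the
requirement of concordance is standard.

Peaks in accessibility are 20-bp windows that are maximal among all
windows whose centers lie within 75 bp, strictly exceed at least one of
them, with ties broken leftmost; every region contributes at least one
peak. Whether the underlying 20-bp window steps by 1 bp or one bin is
not standardized; the package steps by bin size.

## PWM scanning with exact p-values

Motifs are position probability matrices (MEME-minimal I/O), regularized
with a background-proportional pseudocount (default 0.001) so zero
entries remain scoreable. The null distribution of the log-odds score of
a random background word is computed by dynamic programming over
per-column score sums: exactly (aggregating equal sums) for widths up to
8, and on a 10,000-point grid with per-column floor rounding beyond
that. Grid rounding only ever *lowers* the score a query is compared at,
so grid-mode p-values are conservative, never anti-conservative. Both
strands are scanned at every offset; windows containing non-ACGT letters
are skipped; overlapping matches and both strands are retained
independently, because all downstream statistics are windowed maxima or
counts and are insensitive to duplicate loci.

Matches are binned into affinity cohorts by p-value: $-5$
($P < 10^{-4.5}$), $-4$, $-3$, $-2$ (up to the 0.04 scan threshold),
with boundary values assigned to the looser cohort. The default scan
background is the 0-order letter composition of the scanned sequence
(uniform by option).

Scrambled-motif nulls permute column order, preserving the per-column
probability multiset and hence total information content. Candidates are
rejected when they reproduce the original matrix, duplicate an accepted
scramble, or are significantly similar (permutation $p < 0.05$) to
another factor's genuine PWM or an accepted scramble. The similarity
statistic is the maximum, over ungapped offsets with $\ge 4$ overlapping
columns and both orientations, of the mean per-column Pearson
correlation; its null is generated by column-order permutation. Under a
0-order background the distribution of a sum of independent per-column
scores is invariant under column permutation, so every scramble shares
the genuine motif's score distribution exactly — "the scramble's own
distribution" is the same object, computed once.

## Occupancy statistics

* **Median with 95% CI** — Tukey hinges and the notch rule
  $\mathrm{med} \pm 1.58\,\mathrm{IQR}/\sqrt{n}$, the interval drawn by
  R's notched box plots, which is the field's convention for cohort
  medians.
* **Overlap rule** — a 1-kb ChIP peak is "in accessible chromatin" iff
  an accessible region overlaps it by $\ge 200$ bp or the peak entirely
  encompasses a region; significance comes from an upper-tail
  hypergeometric model of shared base pairs (draws without replacement
  from the genome). The tail is reported exactly, without a numerical
  floor, so extremely strong overlaps may underflow to 0.
* **Binding coverage** — ChIP peak point locations (all factors) are
  padded by 500 bp and merged once; an accessibility peak is covered
  when a merged region lies within 75 bp (edge distance, boundary
  inclusive); coverage is reported per 1,000-peak cohort down the
  accessibility rank list.
* **Rank cohorts** — ChIP peaks ranked by score in cohorts of 200; per
  peak, the maximum tag density within 500 bp; per cohort, median with
  CI and the overlap fraction. Trailing partial cohorts are flagged and
  excluded from figures but kept in tables.
* **Affinity cohorts** — per match, the maximum ChIP score within
  250 bp of the match midpoint, against a score surface in which each
  1-kb peak's score is spread uniformly over its interval and all other
  positions take the study's minimum reported score. This surface is a
  stated approximation: real tiled-array signal is probe-local, and
  smearing scores over 1 kb dilutes per-site contrasts, which mostly
  shrinks (never inflates) the genuine-vs-scrambled separation at weak
  cohorts. Compartment is assigned by match midpoint. Scrambled matches
  are pooled over the whole scramble set before the median is taken.
* **Accessibility-rank matrices** — per peak and factor, the maximum
  ChIP score and the count of strong matches ($P < 0.003$) within
  75 bp; Pearson correlations are computed over all peaks (not cohort
  averages); heat-map rows are scaled by their median (count rows by
  their maximum when the median is 0), with z-scoring as an option.

## Temporal analysis

For each factor the 400 most highly bound 1-kb regions (peak position
$\pm 500$ bp) are taken at the reference stage; per region, the ChIP
ratio is the maximum overlapping peak score at stage X over stage Y and
the DNase ratio is the region's total tag count (plus a 1-tag
pseudocount) at X over Y; the statistic is the Pearson correlation of
the two ratio vectors on the natural scale (log scale by option). Total
tags per region is used rather than the maximum window density because
the quantity being ratioed is the region's cleavage *density*, and a
max-of-bins statistic is biased under rate changes, which would break
the exact zero-noise model identity the generator is designed to
exhibit. Regions with no overlapping peak at a stage take the stage's
minimum reported score — a floor that keeps ratios finite and is the
main approximation in this module.

## What the generator emulates, and what it does not

The defaults define the standard study: one 2-Mb chromosome, 400
non-overlapping accessible regions of 0.5-2 kb spaced at least 1 kb
apart, fold-enrichments log-uniform on 2-50, Poisson background of
2 tags/bin, 16 random informative width-8 PWMs, 40 planted sites per
factor per compartment in each of the two strongest affinity tiers,
$\alpha = 1$, $c = 10$, $\sigma = 0.3$, residual affinity 0.003, and a
second stage in which half the regions change accessibility by a
log-uniform 0.1-10-fold factor. The top 15% of ranked candidate windows
carry the strict FDR tier label and the top 85% the relaxed one, by
rank, standing in for a peak-calling FDR procedure that is out of scope.
Planted sites are draws from a *tempered* PWM
($p^t \mathrm{bg}^{1-t}$, rejection-sampled into the requested cohort
with a small log-margin so a re-scan reproduces the tier); $t = 1$ is a
pure PWM draw and is what the strongest tier uses. The occupancy
substrate is the union of planted sites and all scanned genuine matches
with $P < 10^{-2.5}$, so weak background recognition sites carry
low-level occupancy as the model demands.

The generator does not emulate read-level artifacts (no FASTQ,
mappability or GC bias), nucleosome positioning, probe-level array
noise, or the empirical FDR machinery of real peak callers. Passing
tests therefore demonstrate correctness of the statistics and
recoverability of the model's signatures — not robustness to those
real-data features.

### Validation configurations

Three deliberate validation designs are used by the test-suite and the
acceptance script, chosen a priori to isolate what they test:

* **Zero-noise identity** ($\alpha = 1$, $\sigma = 0$): with occupancy
  proportional to per-site accessibility, the between-stage ChIP ratio
  of a window lying inside a single accessibility domain equals the
  domain's modulation exactly, and the DNase total-tag ratio equals it
  up to counting noise. The identity configuration therefore uses
  regions of 1.5-2.5 kb, enrichments of at least 8-fold, no closed
  planted sites, window anchors kept 500 bp inside region edges
  (`anchor_interior_bp`), 3-fold modulations (so regions stay accessible
  at both stages and windows never switch to closed neighbours), and
  evaluates only top windows fully contained in one truth region. Each
  relaxation of these conditions reintroduces a real measurement
  artifact — window heterogeneity, anchor switching, pseudocount
  curvature — and the observed correlation falls from ~1 toward the
  0.5-0.8 range seen with realistic noise.
* **Independent-placement study** for the rank-matrix analysis: no
  planted sites on a 10-Mb genome with 2,600 spaced regions, so motif
  occurrences are i.i.d. background matches, independent of
  accessibility by construction; the match-count correlation is then a
  true null while the occupancy correlation is not.
* **Strong-signal study** (enrichments 10-200, no closed planting) for
  the rank-cohort curves: top ChIP ranks are then almost exclusively
  accessible, so the overlap fraction stays high while the median
  density halves — the "declines more slowly" signature.

## Numerical choices and degenerate inputs

Coordinates are 0-based half-open throughout (BED convention); the
1-kb ChIP peak region is $[x - 500, x + 500)$. Chromosome names match
by exact string equality. Poisson tails use `ppois` on
`ceiling(count) - 1`; window sums are prefiltered against score
thresholds with a $10^{-7}$ slack so float summation order cannot drop
boundary matches; exact-mode DP keys are rounded at $10^{-9}$.
Degenerate cases are defined, not errors: an all-zero track calls no
regions; a factor with no sites yields an empty peak list; an empty
cohort cell reports $n = 0$ with missing median; a region flatter than
its window yields its leftmost maximum bin as the peak. A PWM whose
columns are all identical admits no non-identical scramble and errors
after the stated candidate budget.

Problem sizes in the tests — the 2-Mb default study, a 10-Mb
independent-placement study, 100 1-Mb null tracks, five seeds for the
factor-level orderings — were chosen as the smallest scales at which
the cohort statistics are well populated ($n \ge 500$ where confidence
intervals are compared) while a full run of the suite remains
comfortable on a laptop.

## Known limitations

The score surface smears 1-kb peak scores (see above); compartment
assignment is binary at the match midpoint; the similarity filter is a
pragmatic exchangeable test, not a reimplementation of alignment-based
motif comparison tools; the hypergeometric overlap model ignores the
spatial autocorrelation of genomic features (block-bootstrap
corrections are out of scope); and FDR tiers in synthetic ChIP data are
rank-based labels, not the output of a real symmetric-null peak caller.
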