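---
title: "Mapping cis- and trans-regulation of expression plasticity in RILs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cis- and trans-regulation of expression plasticity in RILs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastiqtl)
```

## Scope and model

`plastiqtl` analyses a biparental selfed RIL population expression-profiled
under two treatments (a control and a salicylic-acid induction), with the
goal of locating the loci that control within-treatment expression and its
plasticity, and characterising whether they act in cis or in trans. The
pipeline is seven stages: input/simulation, variance partitioning,
phenotype construction, Haley–Knott genome scans, cis/trans classification
with cross-phenotype merging and effect sizes, hotspot detection, and
reporting.

### Variance partitioning

For every transcript we fit the fixed-effects linear model

    abundance ~ replicate + genotype + treatment + genotype:treatment

under sum-to-zero contrasts and report each term's type III sum of squares
(the increase in residual SS from deleting that term's columns from the full
model) and its share of total corrected SS. The experimental replicate is a
two-level batch factor. A random-intercept formulation of replicate would be
the textbook choice for a batch term, but an "SS per term" decomposition is
not well defined in the mixed model; with only two replicate levels the
fixed-block fit captures the same batch shift, so we made the fixed-block
decomposition the package's definition. Type III SS are computed through
`car::Anova`; exact zero-residual fits (which `car` refuses) fall back to an
internal drop-term refit that computes the same quantity.

Zero-variance transcripts are flagged degenerate: their SS and proportions
are reported as 0 and they are excluded from clustering and from mean
profiles, because proportions of a zero total are undefined. Profiles are
clustered with `stats::kmeans` (default k = 10, 10 seeded restarts keeping
the best inertia; the restart count is our choice — the underlying analysis
idiom specifies k but not initialisation).

### Expression phenotypes

Per genotype and transcript: the control replicate mean, the SA replicate
mean, and the plasticity ratio

    delta = (SA - control) / ((SA + control) / 2).

For non-negative abundances delta is bounded in [-2, 2], is zero at
equality, and is invariant to rescaling both means by the same positive
constant — which is why it is the natural unit-free plasticity phenotype.
The ratio is numerically unstable when the denominator approaches zero; we
set cells with |(SA + control)/2| below a floor (default 1e-8 on the data's
scale) to missing and count them, rather than propagating huge ratios. The
abundance scale itself (log2 vs linear microarray estimates) is an input
property, not something the pipeline can infer; a `log_expression` switch
records the user's choice and defaults to off (values are used as given).

### Haley–Knott scans

Observed genotype calls map to Sha-allele dosages 0/1; missing calls are
imputed as conditional expectations given the nearest non-missing flanks
under the selfed-RIL Markov transition R = 2r/(1+2r) with Haldane
r = (1 - exp(-2d/100))/2, d in cM. At each marker we regress the phenotype
on dosage and take LOD = (n/2) log10(RSS0/RSS1). Scans run at observed
markers only: the target map density (sub-cM spacing) makes a pseudomarker
grid pointless, and at the 2 cM grids used in simulations the localisation
error this induces (≤ 1 cM) is far below the 5.5 cM merge radius.

Numerical choices: a perfect fit (RSS1 underflow) is capped at LOD 50
rather than reported infinite; a zero-variance phenotype yields a flagged
all-zero curve; a monomorphic marker contributes LOD 0. Peaks are local
maxima at or above the 2-LOD threshold, retained greedily by descending LOD
with an 11 cM suppression radius (twice the merge window), LOD ties breaking
to the smaller position. The suppression radius is a design decision the
method idiom leaves open; 2× the merge radius guarantees that two retained
peaks can never merge into one cluster later. The genome-wide 2-LOD
threshold is applied per scan with no correction across transcripts —
deliberately permissive, and the scan tests document that under a permuted
null a non-trivial fraction of scans clears it. Downstream counts therefore
include linkage satellites and false positives; the recovery analysis
(below) is the controlled view.

### Classification, merging, effect size

Gene physical positions are interpolated piecewise-linearly (bp → cM)
between anchor markers, clamping positions outside the anchor span to the
terminal anchor. An eQTL is cis iff it lies on the gene's chromosome within
10 cM (inclusive — "within w" most naturally includes the boundary);
transcripts without positions are labelled unplaced and excluded from
proportions but kept in tables. Records of one transcript within 5.5 cM
across phenotypes merge by single linkage. In one dimension single linkage
is exactly "split at gaps > 5.5 cM", so chained runs (0, 5, 10) merge
transitively; whether the original procedure chained is unknowable from its
description, and single linkage is the simplest deterministic closure. If
one phenotype contributes two records to a cluster the higher-LOD record
stays and the other re-clusters — one phenotype cannot occupy one locus
twice. The consensus position is the arithmetic member mean; effect size is
the R² of the genotype regression at the marker nearest the consensus (one
locus, one genotype vector), with per-phenotype R² retained and their mean
reported. On complete data R² at the scanned marker satisfies
R² = 1 - 10^(-2·LOD/n) exactly; the acceptance suite enforces this identity
at 1e-9.

### Hotspots

Trans-eQTL consensus positions are counted in half-open 10 cM windows
stepping 1 cM (half-open so a shared edge is never double-counted; a window
ending at the chromosome end is closed there so terminal positions are not
lost). The null redraws the same number of positions uniformly over the
genetic map — chromosome proportional to length, position uniform within —
and pools all window counts over all permutations (default 1,000); the 95th
percentile of the pooled distribution is the global threshold. Uniform
redraw is the minimal null consistent with permuting "QTL position";
re-scanning permuted phenotypes would couple the null to phenotype
correlation structure at prohibitive cost, and is not what a
position-permutation describes. Runs of windows strictly above the
threshold merge into intervals. Cis profiles are computed for inspection but
never thresholded: cis-eQTL density tracks gene density, not hotspot
structure.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes, at
the study's stated conditions: ~210 selfed lines, five chromosomes ending at
100/70/80/80/100 cM, two treatments × two replicates, parents available as
all-A/all-B lines.

* **Genotypes** are two-state Markov chains along each chromosome with
  transition R = 2r/(1+2r) — the stationary (F-infinity) law for selfed
  RILs, used directly instead of simulating seven meiosis generations. For
  F8 the difference is negligible; residual heterozygosity (~0.8% expected
  at F8) is not modelled because the analysis treats lines as inbred.
* **Effects** use ±1/2 allele coding so a planted `baseline_effect` *is*
  the parental mean difference, and effect magnitudes are parameterised by
  target R² against the noise SD (b = 2σ·sqrt(R²/(1-R²))); in noise-free
  runs the reference scale is 1 so planted effects stay nonzero.
  Treatment-interaction components are added only under SA — they are the
  plasticity effects. Opposing pairs place +e and -e on one transcript at
  two distant loci, so the parental sums cancel and only recombinants
  express the difference: the transgression mechanism, which the tests
  verify produces parent-identical delta with RILs outside the parental
  range.
* **Noise** is Gaussian and homoscedastic per transcript (the source
  analysis states no noise model; this is the neutral default), plus one
  shared additive shift per replicate per transcript for the batch term.
  Marker spacing in simulations defaults to 2 cM rather than the real map's
  0.17 cM — detection operates at multi-cM resolution, so the 10-fold
  coarser grid changes nothing the tests measure while keeping scans cheap.

What the generator does not emulate — and hence what passing tests do not
show about real data: microarray measurement artefacts (probe saturation,
cross-hybridisation), heteroscedastic or heavy-tailed expression noise,
segregation distortion, genotyping error, epistasis, and correlated
expression between transcripts beyond shared planted loci. Recovery rates on
synthetic data are upper bounds for real-data performance.

## Problem sizes and determinism

The reference simulation used by the test suite and the acceptance script
runs 210 lines × 300 transcripts on 2 cM grids with 200 permutations —
sizes chosen so the complete pipeline stays interactive on a laptop while
every stage still has enough signal for tight assertions (recovery
experiments use 500 transcripts and 50 planted effects at target R² ≥ 0.2).
A single master seed fans out to per-stage seeds via a stable hash of the
stage name, so re-running one stage in isolation reproduces its in-pipeline
draw and identical configurations give byte-identical outputs. Written
numeric output uses 6 significant digits; exact reproducibility is
guaranteed under a fixed seed and single-threaded execution.

## Known limitations

* Single-QTL scans only: no multi-QTL models, covariates or kinship
  correction (unnecessary within a biparental RIL cross, but real
  populations with structure need more).
* The permissive 2-LOD threshold means raw record counts mix true loci,
  linkage satellites and false positives; interpretation should lean on the
  merged, classified tables and on hotspot calls, which are
  permutation-calibrated.
* The delta ratio is undefined where both treatment means vanish and
  unstable near zero; such cells are dropped, which biases plasticity maps
  away from barely-expressed transcripts.
* Real-data curation (retired gene annotations, fragment probes) is the
  user's responsibility; unplaced transcripts are excluded from cis/trans
  proportions.
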