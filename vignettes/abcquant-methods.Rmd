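---
title: "Quantifying genome instability at AID break clusters with drop-off dPCR and amplicon profiling"
author: "abcquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying genome instability at AID break clusters with drop-off dPCR and amplicon profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abcquant)
```

## The assay and its model

Activation-induced cytidine deaminase (AID) deaminates cytosines in
single-stranded DNA, preferring WGCW > WRC > RCG contexts. At a handful
of focal loci — AID break clusters (ABCs), such as the region upstream of
*CRLF2* in the X/Y pseudoautosomal region and the *BCL2* 3' region —
this activity leads to double-strand breaks whose repair by
non-homologous end joining leaves indels concentrated at and around CpG
dinucleotides. `abcquant` implements the computational readout of a
multiplexed digital PCR (dPCR) *drop-off* assay for such loci, an
amplicon-sequencing indel profiler for the same regions, and the
simulators needed to test both end to end.

In the drop-off design, one amplicon carries up to three hydrolysis
probes placed directly over mutation-prone CpG sites (read on the FAM,
TAMRA and Cy5 channels) plus one *reference* probe (SUN/HEX) placed
where no breaks map. An indel under a drop-off probe abolishes its
binding, so a mutant template lights the reference channel but not that
probe's channel. The partition-level model is standard digital PCR:
template molecules of species $s$ (intact, edited, or
reference-site-deleted) land in each of $n$ partitions independently as
$\mathrm{Poisson}(\lambda_s)$ with
$\lambda_s = C_s \cdot v_p$, where $C_s$ is the species concentration
(copies/µL) and $v_p$ the partition volume. A channel is truly positive
iff the partition holds at least one template with that probe's site
intact. From the fraction of negative partitions the per-channel rate is
recovered by the Poisson correction

$$\hat\lambda = -\ln\left(\frac{N_{neg}}{N}\right), \qquad
  \hat C = \hat\lambda / v_p = \frac{\hat\lambda \, n}{V \cdot a},$$

with $V$ the reaction volume and $a$ the analyzed fraction. Confidence
intervals transform Clopper–Pearson bounds on the negative fraction
through $-\ln(\cdot)$; a channel with no negative partitions is
*saturated* and only a lower bound is reported.

## Drop-off estimators and co-encapsulation

The quantity of interest per drop-off probe is the mutant concentration
$\hat C_{mut}$ and the drop-off fraction
$\hat f = \hat C_{mut} / \hat C_{ref}$. Two estimators are implemented:

* **difference** (default): $\hat\lambda_{mut} = \hat\lambda_{ref} -
  \hat\lambda_{probe}$, each term from its own channel's negatives.
  Negative differences — possible only under gating noise, since with
  perfect calls the reference-negative partitions are a subset of the
  probe-negative ones — are floored at zero and flagged.
* **joint**: solves
  $P(\text{ref}^+, \text{probe}^-) = (1 - e^{-\lambda_{mut}})\,
  e^{-\lambda_{intact}}$ using the joint pattern frequency and the
  probe-channel negative fraction. This is the explicit
  co-encapsulation correction: the naive ratio "(ref⁺, probe⁻) over
  ref⁺ partitions" is badly biased at high template load, because
  partitions holding both a mutant and an intact template light every
  probe (at $\lambda_{ref} = 1.5$ the naive ratio underestimates a 10%
  edit by more than half; the test suite demonstrates both the bias and
  the correction).

The two estimators agree within bootstrap error across template loads
on clean data, and the difference method is the default because it is
markedly more robust to partition misclassification: per-channel
misgating losses largely cancel in the difference, whereas the joint
pattern $(\text{ref}^+, \text{probe}^-)$ is inflated directly by any
probe-channel false negative (about +11% at $\lambda = 1.5$ with 1%
"rain"; see below).

Intervals for $\hat C_{mut}$, $\hat f$ and the CNV ratio use a
partition-resampling bootstrap, implemented as multinomial resampling of
the $2^k$ joint pattern counts — exactly equivalent to resampling
partition rows, but independent of chip size. One mechanism serves all
derived quantities, and it keeps honest small-count behavior near
baseline where delta-method intervals would not.

## Copy-number inference

A hemizygous loss of the reference-probe binding site halves the
reference channel only: `cnv_ratio()` reports
$\hat r = \hat C_{ref} / \hat C_{probe}$ per drop-off probe with a
bootstrap interval and calls `hemizygous-reference` only when *every*
per-probe interval excludes 1 and contains 0.5 (`euploid` when all
contain 1, `other` otherwise). Because the intervals are nominal 95%,
any single chip has a ~5% chance of a technically correct interval
missing the true ratio; the test suite therefore asserts calibrated
behavior over replicate chips rather than one draw. The union-based
total concentration over all four probes is reported alongside as a
consistency check.

## Gating

Auto-thresholding performs a two-center 1-D k-means partition per
channel with the threshold at the midpoint of the centers — chosen over
density-valley finding because it stays stable at the small positive
fractions this assay runs at ($\lambda \approx 0.15$, ~14% positive).
Calls use strict inequality, with ties negative (conservative for
drop-off detection). A channel whose centers separate by less than
three pooled within-cluster standard deviations is treated as a single
cluster and resolved against the chip's baseline level (the lower
centers of the bimodal channels, or the dimmest channel otherwise):
all-negative near baseline, all-positive far above it. A fully
saturated chip with no bimodal channel anywhere is ambiguous by
construction; manual thresholds cover that case.

## The simulators

`simulate_chip()` generates the partition table the pipeline consumes:
Poisson loading per species, truth-conditional two-component Gaussian
fluorescence (baseline 1000 ± 100, positive 5000 ± 250, arbitrary
units), and a ground-truth record (per-partition template counts, true
states, true drop-off fractions) for recovery testing. Defaults follow
the assay's stated scale: 20,480 partitions, 9 µL reaction, no dead
volume ($a = 1$), and 10 ng of human gDNA converted at 3.3 pg per
haploid genome ($\approx 337$ copies/µL, $\lambda \approx 0.148$).

An optional *rain* component draws a fraction of positive partitions
midway between the clusters. Its default is 0, deliberately: rain
partitions sit at the gating threshold and classify as fair coin flips,
which injects *differential* misclassification noise between channels
of order $\tfrac{1}{2}\,\text{rain} \times P(\text{pos})$ per
partition. At 1% rain that is $\sim 2\times10^{-5}$ — larger than the
entire mutant signal of a sample 1000-fold below a 10% edit
($\lambda_{mut} = 1.5\times10^{-5}$) — so no estimator could recover
the assay's demonstrated baseline dynamic range under that default,
and the clean cluster structure of real chips is the better default
model. Rain remains available as a robustness knob; gating keeps
whole-chip state recovery error below $10^{-3}$ at 1% rain, and the
flooring path of the difference estimator is tested under it.

`simulate_reads()` emits full-length amplicon reads (FASTQ at constant
Q30, SAM v1.6 with exact CIGARs, JSON truth sidecar). Each read is
edited with probability `p_edit`; the edit position is a CpG hotspot
center (sampled by weight) plus a discretized Gaussian offset
(`kernel_sd`), its type a deletion with probability 0.8 (deletions
dominate insertions after end-joining; the 0.8:0.2 split is a fixture
choice, not a measured value), and its length $1+\mathrm{Geometric}$.
Small `kernel_sd` reproduces the focal indel piles seen in some cell
backgrounds; larger values the spread pattern seen in others. Out-of-
bounds placements are resampled up to 20 times, then the read is
emitted unedited and logged. The simulator models neither PCR
efficiency nor sequencing substitution errors: partitions are endpoint
binary, and reads differ from the reference only by the introduced
indels. Passing tests therefore validate the estimators against the
assumed statistical structure, not against amplification kinetics,
aligner behavior, or substitution noise in real data.

## Indel profiling and motif enrichment

`parse_alignments()` re-derives the per-position profile from CIGARs
(via `GenomicAlignments`): a deletion of length $L$ at position $p$
increments deletion counts at $p \ldots p+L-1$; an insertion between
$p-1$ and $p$ is assigned to $p$ (left-neighbor convention); depth is
the read's reference footprint including deletions; substitutions are
ignored, matching what the assay's indel panels display (AID's direct
C→T signature would be a natural extension). All coordinates are
0-based half-open.

`proximity_enrichment()` asks whether indel events concentrate near
CpGs: the observed fraction of events within ±8 bp (default) of a CpG
is compared against a depth-weighted uniform re-placement null
(permutation $p = (1 + \#\{null \ge obs\})/(n_{perm}+1)$). The null is
depth-weighted uniform rather than sequence-composition-matched
because that is exactly what the profiler can know without assuming a
mutational model. Zero events or zero CpGs yield an explicit
"not evaluable" result. `probe_window_dropoff()` is the sequence-level
analog of the dPCR readout: the fraction of probe-spanning reads with
an indel footprint overlapping the probe window (insertions at $p$
count as $[p-1, p+1)$); requiring full probe-span coverage in the
denominator avoids edge-read bias. On matched simulations the
read-level and chip-level drop-off estimates agree.

## Dose–response trend

Because inducer doses are ordinal and group sizes tiny, monotone trend
is tested with the Jonckheere–Terpstra statistic
$JT = \sum_{i<j} \#\{x_i < x_j\} + \tfrac12 \#\{x_i = x_j\}$
(ties by the ½ convention), implemented from scratch with an exhaustive
enumeration null for $n \le 8$ and a label-permutation null otherwise —
the statistic itself is part of the tested surface, and its invariance
under monotone transforms plus its type-I control are asserted in the
suite. No EC50-style curve is fitted; the claim under test is monotone
increase only. `trend_summary()` reports per-dose mean ± SEM and fold
change against the lowest dose, supporting both pooled and per-replicate
inputs.

## Numerical and design choices

* Thresholds: strict `>`; ties negative. k-means with 3 restarts;
  degenerate-channel rule as above.
* $\hat\lambda$ intervals: Clopper–Pearson (exact, conservative;
  empirical coverage at $\lambda = 0.15$, $n = 20{,}480$ sits within
  [93%, 97%]).
* Negative mutant estimates floored at 0 with a flag — concentration is
  physical.
* Multiple drop-off probes are quantified independently; no joint
  multi-probe haplotype model.
* Replicates: copies/µL and fractions averaged across chips with SEM;
  for few-event baselines, pattern counts are pooled across chips
  *before* the Poisson correction (`pool_pattern_counts()`), which is
  what makes a $10^{-4}$ fraction measurable at all (~30 mutant
  templates across 100 chips).
* Seeds are explicit everywhere; identical seeds give bit-identical
  tables, reads and truth. RNG state is restored after each call.
* Fixture amplicons/panels are synthetic constructions (labelled as
  such) with the CpG layout the assays target, not genome sequence.

## Problem sizes in the shipped checks

The test suite and acceptance script size their simulations to what the
statistics require: 24 replicate chips for recovering a 10% edit (SEM
≈ 1.5% relative), 100 pooled chips per condition for the 1000-fold
baseline contrast (≈ 30 mutant templates pooled, ≈ 20% relative error),
8 replicate chips for CNV call behavior, 10,000–50,000 reads for
profiler truth recovery, and 1000 draws for interval-coverage checks.

## Known limitations

* No vendor-file ingestion; the partition CSV dialect is the contract.
* Chips are gated independently; no cross-chip fluorescence
  normalization.
* The joint estimator should not be used on chips with visible rain.
* The profiler counts indel events against depth; if a per-read
  normalization is preferred, `probe_window_dropoff()` provides it for
  probe windows.
* No de novo alignment and no VCF emission; amplicon-local SAM only.
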