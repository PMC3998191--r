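---
title: "Detecting genomic deletions with ultra-high-density tiling CGH arrays"
author: "tilecgh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genomic deletions with ultra-high-density tiling CGH arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilecgh)
```

## The problem

Array comparative genomic hybridization (CGH) detects copy-number changes by
co-hybridizing differentially labelled mutant and control genomic DNA to a
microarray of oligonucleotide probes tiled across a reference genome. A probe
whose target is deleted in the mutant loses its mutant-channel signal, so its
normalized log2(mutant/control) ratio drops sharply below zero; duplications
mirror this on the positive side. For multi-kilobase deletions almost any
tiling is adequate, but irradiation mutagenesis (fast neutrons in plants,
radiation panels elsewhere) routinely produces deletions of only a few base
pairs. Whether such a deletion is detectable is governed almost entirely by
*probe density*: how many probes geometrically overlap the deleted interval,
and how many of those must respond before a caller will believe them.

`tilecgh` packages the four pieces needed to reason about this quantitatively:

1. **probe design** — isothermal, uniqueness-filtered probe sets placed at an
   arbitrary start-spacing ("stagger") over a reference sequence;
2. **coverage geometry** — closed-form accounting of probe/deletion overlap;
3. **simulation** — per-probe log2-ratio profiles under an empirically
   motivated noise model, which also generates all test fixtures;
4. **calling and power analysis** — the 2-SD threshold with the
   k-consecutive-probe rule and the feature-fraction rule, and Monte-Carlo
   estimation of the stagger required to detect a deletion of a given size.

Coordinates are 0-based half-open everywhere internally and in BED output;
GFF3 is converted on read.

## Probe design

Probes are 50–75-mers ("isothermal" design: the length is chosen within that
range to bring each probe's melting temperature as close as possible to a
common target, 76 °C by default). The default Tm model is nearest-neighbor
thermodynamics with the unified Allawi–SantaLucia parameter set, an entropy
salt correction of $0.368\,(N-1)\ln[\mathrm{Na}^+]$ at 50 mM monovalent
cation, and a 12.5 nM duplex concentration term; a GC/length approximation
($64.9 + 41\,(n_{GC} - 16.4)/N$) is available as a fast fallback
(`design_config(tm_method = "gc")`). Ties between candidate lengths are broken
toward the shorter probe, so designs are deterministic.

A staggered set places probe starts at `region_start + i*s` for stagger `s`.
The first start coincides with the region start: the grid phase is otherwise
arbitrary, and fixing it makes designs reproducible; phase is an explicit
parameter wherever it matters (coverage geometry, power analysis). Windows
containing an ambiguous base are rejected and logged rather than redesigned,
and probes whose sequence (on either strand) occurs more than once in the full
reference are removed by `uniqueness_filter()` — exact full-length matching,
as near-matches are a cross-hybridization question outside this package's
scope.

```{r design}
ref <- generate_synthetic_reference(5000, seed = 42)
set <- generate_staggered_set(ref, "chr1", 0, 5000, stagger = 49)
set
range(set$probes$tm)
```

## Coverage geometry

A probe of length $L$ overlaps a deletion of size $d$ by at least $m$ bases
exactly when its start falls in a window of width $w = d + L - 2m + 1$
(default $m = 1$, so $w = d + L - 1$). On a start grid of spacing $s$ that
window holds $\lfloor w/s \rfloor$ or $\lfloor w/s \rfloor + 1$ probes
depending on phase. Three consequences the package exposes directly:

* `count_overlapping()` — the per-phase count. For $L = 50$, $s = 17$,
  $d = 104$ the window is $153 = 9 \times 17$, so every phase yields exactly
  9 overlapping probes.
* `per_base_depth()` — a single position is covered
  $\lfloor L/s \rfloor$ or $\lceil L/s \rceil$ times; 74-mers staggered every
  2 bp cover every base 37 times, against a maximum of twice for conventional
  half-overlapping tiling.
* `max_stagger_guaranteeing_k()` — the largest stagger guaranteeing $k$
  overlapping probes at *every* phase is $\lfloor (d + L - 1)/k \rfloor$.

The minimum-overlap parameter $m$ is configurable because published designed
counts for very small deletions are sensitive to the (usually unstated)
counting convention; the package asserts only the $m = 1$ bracket
$\{\lfloor w/s\rfloor, \lfloor w/s\rfloor + 1\}$ against the shipped
19-stagger reference table (`phyb104_table1()`), whose empirical "detected"
column is never treated as reproducible.

## The noise model

`noise_model()` captures what a mutant-vs-control hybridization looks like
after normalization:

* null probes: $\mathcal{N}(0, \sigma)$ with $\sigma = 0.2$ log2 units, the
  dispersion observed for equal-copy loci;
* deletion-overlapping probes *respond* with probability `sensitivity`
  (default 0.94; reported per-mutant values span 0.86–0.99). A responding
  probe draws $\mathcal{N}(\mu_d, 0.5)$ with $\mu_d = -2$ for deletions below
  1 kb and $-6$ above (configurable cutoff); a non-responding probe draws the
  null distribution. Duplications mirror positively.
* optionally, spurious variant-like regions at a Poisson rate, mimicking the
  false-positive regions real self–self hybridizations show.

The default response is **empirical**: a probe overlapping a deletion by even
a single base responds with the full deletion-channel signal. This choice
follows the observation that probes overlapping a 4 bp deletion by a tiny
fraction of their length still give ratios at or below −0.4 — behaviour a
proportional-overlap model cannot produce, presumably because a mismatch
bubble destabilizes the whole duplex. The alternative
`response = "proportional"` (mean $\log_2(1 - f + 2^{-6})$ for overlap
fraction $f$) is retained for sensitivity analysis.

`simulate_two_channel()` wraps the same draw in positive log-normal
intensities whose ratio reproduces the single-channel profile exactly, so
channel-level code paths (e.g. self-self slope checks) can be exercised.
All randomness flows through one recorded seed.

## Calling

`normalize_profile()` centres ratios on their median and estimates noise with
the scaled median absolute deviation, which is robust to the small fraction
of true variant probes. The flagging threshold is `sd_multiplier` (default 2)
times that estimate — the canonical $2\sigma = 0.4$ — or can be pinned with
`fixed_threshold = 0.4`. Thresholds are inclusive (≤ −0.4 flags a probe):
the boundary convention is stated here once and applied consistently.

`call_segments()` reports every maximal run of at least `k_consecutive`
flagged probes (default 3; 2 is the relaxed setting). Segmentation is
deliberately run-based rather than a change-point method such as circular
binary segmentation: the criterion of interest *is* literally "k consecutive
probes with a deletion profile", and a run scanner is exactly verifiable
against brute force. Runs never span chromosomes; `max_gap` (default 0)
optionally tolerates isolated non-responding probes inside a segment. A
segment's interval spans the first to the last flagged probe, so the boundary
error against truth is bounded by one probe length plus one stagger.

`feature_fraction_calls()` implements the complementary gene-model rule: a
feature is called deleted when at least 50% of its probes sit at or below
−0.8. Both fractions are inclusive at the boundary ("≥ 50%").

## Power analysis

`designed_vs_detected()` reproduces the designed/detected accounting per
stagger set, with `called` evaluated *within* each set (pooling sets into one
genome-wide profile is possible, but per-set evaluation is what the
per-stagger performance question asks). `min_detectable_stagger()` estimates,
for each candidate stagger, the probability over random grid phases and noise
replicates that the deletion is called, and returns the largest stagger
meeting `power_target` (default 0.95).

Two design choices deserve a note:

* **Phase handling.** The default draws a uniform random phase per replicate.
  `phases = "all"` enumerates every phase exactly once, which makes the
  noise-free limit deterministic: with sensitivity 1 and no noise the
  detection event depends only on geometry, and requiring power 1 over all
  phases recovers the closed form $\lfloor (d+L-1)/k \rfloor$ exactly. With
  the default 0.95 target a slightly larger stagger can legitimately qualify
  when ≥ 95% of phases still carry $k$ probes — the target expresses how much
  phase risk the user accepts, and the guarantee semantics corresponds to a
  target of 1.
* **Expected detection fraction.** Under the empirical response model the
  probability a designed probe is flagged is
  $q = p\,\Phi\!\big(\tfrac{-0.4-\mu_d}{0.5}\big) + (1-p)\,\Phi\!\big(\tfrac{-0.4}{0.2}\big)
  \approx p + 0.023(1-p)$ for sensitivity $p$, so the mean percent detected
  converges to ~100 p (94/86/99% at the three reported sensitivities) — a law
  of large numbers the test suite checks at $10^3$ replicates.

## What the simulator does and does not capture

The generator emulates: null dispersion of 0.2 log2 units, the −2 / −6
deletion-signal regimes, per-probe response probabilities in the 0.86–0.99
range, duplications, and (optionally) spurious variant-like regions. It does
**not** model dye bias, spatial artefacts, probe-specific hybridization
thermodynamics, scanner physics, or vendor normalization internals. Passing
tests therefore demonstrate that the geometry, the caller and the power
estimates are correct *given* the signal model — not that the signal model
exhausts real-array behaviour. Real hybridizations additionally show
false-positive regions of biological origin (segregating background variants,
mobile elements), which the caller reports but does not adjudicate.

## Numerical and scale choices

* Tm evaluation shares dinucleotide cumulative sums across candidate lengths,
  so isothermal search costs O(max_len) per start.
* Uniqueness filtering counts exact occurrences with Biostrings pattern
  matching; palindromic probes are counted once per genomic location.
* Degenerate inputs fail loudly: constant profiles (SD 0) demand a fixed
  threshold; regions shorter than the minimum probe length yield an empty set
  with a warning; `max_stagger_guaranteeing_k` signals when $k > d + L - 1$
  admits no stagger.
* Test problem sizes are chosen to keep Monte-Carlo error well inside the
  asserted tolerances at interactive runtimes: $10^6$ draws for the null
  exceedance check (standard error ~0.02 percentage points), $10^3$
  replicates for expectation convergence, $10^4$ random profiles for the
  caller-vs-brute-force equivalence sweep, and a 50 kb synthetic genome for
  the end-to-end pipeline.

## Worked example

```{r pipeline}
ref <- generate_synthetic_reference(50000, seed = 61)
res <- pipeline_run(
  ref,
  region = list(chrom = "chr1", start = 23000, end = 27000),
  variants = data.frame(chrom = "chr1", start = 25000, end = 25104,
                        kind = "deletion", label = "d104"),
  design_cfg = design_config(staggers = c(6, 17, 49)),
  caller_cfg = caller_config(fixed_threshold = 0.4),
  seed = 7, out_dir = tempfile())
res$calls[res$calls$kind == "deletion", c("start", "end", "n_probes", "mean_ratio")]
res$reports
```

## Limitations

* Uniqueness is exact full-length matching; near-identical paralogues that
  cross-hybridize in practice are not flagged.
* The per-probe sensitivity is a free parameter, not derived from sequence
  thermodynamics; fit it to a known deletion before trusting absolute power
  numbers for a new platform.
* The piecewise deletion mean (−2 below 1 kb, −6 above) is a coarse summary
  of observed magnitudes; the real transition presumably depends on local
  probe composition.
* Single-array designs (no replicates, no dye swap) are assumed throughout;
  replicate combination is out of scope.
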