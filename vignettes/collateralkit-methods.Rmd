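---
title: "Models and methods behind collateralkit"
author: "collateralkit maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind collateralkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collateralkit)
```

# The problem

When a Cas13 ribonucleoprotein (RNP) is activated by its target RNA inside a
human cell, its composite HEPN RNase site faces outward and cleaves RNA
indiscriminately. This *collateral cleavage* produces four measurable
signatures:

1. **Bulk degradation** of total RNA, visible as novel fragments preceding the
   18S rRNA peak on an electropherogram (Bioanalyzer/Femto Pulse trace).
2. **Loss of transcript integrity** measurable by 5′−3′ RT-qPCR: oligo-dT-primed
   reverse transcription only reads sequence that is still physically connected
   to the poly(A) tail, so a break between a 5′ amplicon and the tail raises
   the 5′ Cq relative to the 3′ Cq.
3. **Near-global depletion of cytoplasmic mRNA**, which whole-library
   normalization cannot see (every gene drops together, so column totals
   renormalize it away) but ERCC spike-ins — added at fixed mass after RNA
   isolation, hence immune to intracellular cleavage — reveal.
4. **Recurrent cleavage positions** visible as 10–20 nt dips in long-read
   transcript coverage, preferentially at uracils in single-stranded loops with
   a US (S = G or C) dinucleotide context.

`collateralkit` implements the quantitative analysis for each signature, plus a
molecule-level simulator that generates all four data modalities from a known
ground truth so that every analysis stage can be tested for parameter recovery.

# The simulator

## Cleavage model

Each transcript carries candidate cleavage sites at uracil positions. A site at
U-index $p$ (0-based) cuts immediately 3′ of the U, so a molecule cut at $p$
splits into `[0, p+1)` and `[p+1, L)`; fragment lengths always sum to $L$ and
exactly one fragment per molecule keeps the native poly(A) end. Per molecule,
each site cuts independently with probability

$$P(\text{cut}) = 1 - \exp\{-A(t)\; w \; m_{\text{class}} \; a\}$$

where $A(t) \in [0,1]$ is the activation level at time $t$ after RNP delivery,
$w$ the site's dinucleotide hazard weight, $m$ a biotype multiplier and
$a = (\text{abundance}/\text{median abundance})^{s}$ a mild abundance term.
Choices and defaults:

* **Site weights** default to `UC = UG = 10`, `UA = UU = 1`: the US
  dinucleotide preference reported for LbuCas13a. Non-U positions have weight 0
  by construction.
* **Loop accessibility** is a Bernoulli mask over uracils (default fraction
  0.35) standing in for single-stranded-loop structure. Real secondary
  structure prediction is deliberately out of scope; the mask preserves the
  statistical property the downstream tests need (a known subset of uracils is
  cleavable) without pretending to fold RNA.
* **Activation curve**: piecewise values at the assayed timepoints,
  `(0, 0.05), (50, 0.7), (100, 1), (200, 1), (500, 0.2), (1440, 0.02)`.
  The shape encodes: collateral cleavage starts within 50 min of delivery, is
  maximal at 100–200 min, and integrity largely recovers from ~500 min with a
  small residual at 24 h. We anchor $A(0)$ near zero (0.05) because at the
  moment of delivery essentially no RNP has entered cells; under the
  exponential cut model the intact fraction obeys
  $I(0) = I(200)^{A(0)/A(200)}$, so a substantially non-zero $A(0)$ would
  contradict the observation that 0-min samples look like untreated controls
  while 200-min samples are mostly fragmented.
* **Class multipliers** default to `protein_coding = 0.13` and 0 for
  mitochondrial mRNAs, nuclear ncRNAs and spike-ins. Mito/nuclear transcripts
  are compartmentally shielded from the cytoplasmic RNP; spike-ins are added
  to purified RNA and *cannot* be cleaved (the constructor enforces 0). The
  protein-coding value is the one free scale nothing in the source system pins
  numerically; it was calibrated once, before any test was written, so that a
  US site cuts with probability $1-e^{-1.3} \approx 0.73$ at peak activation
  and (with the default 1.4 sites/kb density) a median-length mRNA is ~90%
  cut at peak but ~90% intact at $t=0$ — the qualitative content of the
  degradation time course and the full-length read-density plots. It was not
  revisited after the tests existed.
* **Site density** (1.4 per kb, `plant_cleavage_sites`) controls the expected
  planted sites per transcript; each eligible uracil (accessible, positive
  weight) is kept with equal probability so the expected count is
  `density * length / 1000` exactly.
* **Guide-directed target cleavage** is a separate per-molecule probability,
  active from $t = 0$ (target cleavage starts immediately, before the
  collateral phase ramps up). Whether the cut falls inside the protospacer or
  at the nearest upstream uracil is experimentally unresolved — the
  protospacer-coincident coverage dip could be a reverse-transcription artifact
  of RNP still bound after purification — so `target_cut_mode` exposes both
  readings rather than resolving them; the default is `"protospacer"`.

## Read simulation and why dips look the way they do

`simulate_read_alignments` emits Poisson(`depth`) reads per fragment: after
poly(A) tailing of the fragmented RNA, every fragment is independently
reverse-transcribed, so sequencing samples fragments by molar count. Reads are
full-length with probability 0.97, otherwise truncated 10–50% from one end.

Coverage dips arise from end under-representation at *cut-created* fragment
termini: the new 5′ end of the downstream fragment loses 8–20 nt (poor adapter
recovery/RT run-in at free 5′ ends), while the new 3′ end of the upstream
fragment loses only 0–2 nt (it is rescued by polyadenylation). Native
transcript ends are untouched. The asymmetry is what places the cleaved uracil
at the dip's 5′ boundary — precisely the assumption the annotation heuristic
("the U closest to the dip's 5′ side") relies on — and makes dip widths land in
the observed 10–20 nt range. A mass-weighted emission model (reads
proportional to fragment length) was evaluated and rejected during design: it
dilutes dip contrast below the detection geometry and does not correspond to
the per-fragment cDNA chemistry.

## Counts, Cq tables and traces

* `simulate_count_matrix`: negative-binomial counts with mean
  `abundance × library_scale × 2^(log2FC)` for cellular genes in targeting
  samples and `spike abundance × library_scale` for spike-ins in *all*
  samples. Expected depletion is `a + b·log10(abundance) + class offset +
  gene offset`, applied only to affected biotypes. Spike-ins emulate a
  single-mix commercial design: 92 species, concentrations log2-spaced over
  2^20, carrying 2% of cellular RNA mass.
* `simulate_cq_table`: the effective template of an amplicon is the number of
  molecules with no cut between the amplicon's 5′ boundary and the 3′ end
  (oligo-dT priming); `Cq = intercept − log(template)/log(1+E)` plus Gaussian
  noise (default sd 0.15 cycles, qPCR-replicate scale). RT processivity and
  per-primer efficiency differences are deliberately ignored: the mechanism
  under test is connectivity to the poly(A) tail. A deterministic
  expected-template mode supports exact closed-form oracles; a fragment-pool
  mode connects the simulator end to end.
* `simulate_electropherogram`: a sum of Gaussian peaks in log10 size — one per
  fragment-length class, mass-weighted, plus static 18S/28S rRNA peaks — so
  total AUC is proportional to loaded RNA mass by construction. rRNA cleavage
  is not modeled (rRNA-targeting experiments are out of scope), so the
  degradation signal in the sub-18S window comes from mRNA fragments.

# Analysis methods

## Electropherogram AUC

Integration is trapezoidal on the given (possibly non-uniform) grid; region
AUC interpolates linearly at region boundaries, so a partition of the axis sums
exactly to the total. Loading normalization divides each trace by its own
total AUC and multiplies by the batch mean. The degradation window defaults to
[200, 1700] nt — the sub-18S region where collateral fragments accumulate; the
reference experiments define this region only graphically, so the boundary is a
declared default, not an inferred one.

## 5′−3′ RT-qPCR integrity

`dCq = Cq(5′) − Cq(3′)` per sample; `ddCq = dCq − mean(dCq of empty-transfection
controls)`. The *difference* (not the historical 3′/5′ ratio) is invariant to
expression level: Cq pairs (25, 20) and (30, 25) represent the same degradation
and give the same dCq. Technical qPCR replicates are averaged *before* the
subtraction (they are replicates of one cDNA, not of the biology); undetected
replicates are dropped, never imputed, and all-undetected groups propagate as
missing with a warning. Condition summaries report SEM. Under the simulator's
generative model the noiseless statistic has the closed form
`ddCq = −log2(1−f)/log2(1+E)` for a cut fraction `f` between the amplicons,
which the test suite verifies to 1e-9.

## Spike-in normalization and outlier selection

Size factors are median-of-ratios restricted to spike-in rows (reference:
per-spike geometric mean over samples, using spikes nonzero everywhere). One
subtlety: scaling one sample's counts by $c$ moves its factor by
$c^{1-1/n}$ and every other factor by $c^{-1/n}$ because the geometric-mean
reference absorbs $c^{1/n}$ — exactly as in the standard whole-library
median-of-ratios estimator. Factor *ratios* are exactly equivariant and
normalized counts change only by one global constant, which is what fold
changes and base means depend on; the tests assert that form.

Fold changes use a deliberately simple moderated ratio,
`log2((mean_targeting + 0.5)/(mean_control + 0.5))` on normalized counts with a
minimum-count filter (≥5 in at least one contrast sample), instead of a
negative-binomial GLM: the scientific claims this package supports concern
normalization geometry and selection, not shrunken test statistics, and the
simple estimator keeps every acceptance property analytically checkable.
Spike-ins are excluded from fold-change tables and regression.

The abundance–depletion trend is an OLS fit of `log2fc` on `log10(base_mean)`
over protein-coding genes; transcripts escaping depletion are selected by
residual thresholds of +1 log2FC at 50 min and +2 at 200/1440 min
(overridable). Whether the original analysis fit per replicate or on pooled
fold changes is unstated; this package fits pooled per-gene fold changes for a
targeting-vs-non-targeting contrast by default, with the contrast configurable.

## Dip calling

Per-transcript depth counts primary alignments only; relative coverage divides
by the per-transcript *mean* (not maximum — robust to isolated spikes). After
a 5 nt running-median smoothing, a dip is a maximal run below 0.5× the local
baseline (median of 50 nt flanks), runs separated by <3 nt merged before the
width test, widths restricted to 8–30 nt (the observed 10–20 nt plus slack),
25 nt edge exclusion, and a 20× mean-depth floor. The cleavage position is the
uracil nearest the dip's 5′ boundary, searching inside the dip and up to 5 nt
upstream, ties resolved upstream (the cut is 3′ of the U, so the U sits just
outside the lost region). Context summaries build a position frequency matrix
over ±5 nt windows (truncated windows excluded), per-position information
content `2 − H` bits without small-sample correction by default (site counts
are user-visible; a correction flag exists), and the (0, +1) dinucleotide
table.

# What a green test does and does not establish

The generator emulates the *statistical structure* of the real experiments:
activation kinetics, abundance-correlated depletion, spike-in immunity,
US-context preference, oligo-dT 3′ bias, and dip geometry. It does not emulate
long-read error profiles, spliced/genome-space alignment, real RNA secondary
structure, rRNA cleavage, or the cellular stress-response transcription that
shapes real selected-gene lists. Green acceptance tests therefore establish
that the analysis methods recover planted parameters under the stated
generative model — not that they would reproduce any particular study's gene
lists, which depend on deposited data outside desk scale.

Numeric margins worth knowing: the full-length read fraction statistic excludes
the top-2%-abundance transcripts (the analog of excluding hyper-abundant
histone transcripts and WDR74), because a handful of dominant transcripts
otherwise control the tail of the statistic; the dip caller's planted-site
recovery assumes per-site cut fractions above the 0.5 depth-ratio threshold,
which the default hazard scale provides (0.73 per US site at peak activation).

# Known limitations

* The hazard calibration is a package choice; absolute cut probabilities per
  site are not identified by any published quantity.
* The qPCR model omits RT processivity, primer efficiency differences and
  amplification-curve processing (Cq values are taken as given).
* `detect_dips` assumes transcript-space, forward-strand alignments; spliced
  genome-space input is out of scope.
* The electropherogram simulator keeps rRNA static; degradation AUC reflects
  mRNA fragments only.
* Selection thresholds (+1/+2 log2FC) are conventions of the emulated
  analysis, not optimized decision boundaries.
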