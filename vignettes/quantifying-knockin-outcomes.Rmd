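---
title: "Quantifying CRISPR knock-in outcomes with flank-anchored windows"
author: "flankQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CRISPR knock-in outcomes with flank-anchored windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flankQuant)
```

## The problem

When a locus is edited by CRISPR with a homology-directed repair (HDR)
donor — here the model system is an iPSC pool carrying the TIE2 L914F
gain-of-function substitution, enriched by diphtheria-toxin co-selection —
the composition of the resulting cell pool is read out by deep sequencing
of a short PCR amplicon spanning the edit site. Each read is one
observation of one allele. The quantities of interest are the fraction of
reads carrying the programmed substitution (knock-in efficiency), the
fraction carrying insertions or deletions (error-prone repair), and the
per-position base composition at the edit site.

flankQuant implements the window-anchored classification scheme for this
readout, a seeded simulator that generates amplicon pools of known
composition so the estimator can be validated by parameter recovery, and
the small closed-form metrics used for downstream cellular assays.

## The classification model

An `AmpliconSpec` fixes two short **flank anchors** (10 bp by convention)
that occur exactly once in the reference amplicon and delimit an
**editing window** — the segment where edits are expected. For each read:

1. Every placement of each flank with at most `maxMismatch` mismatches
   (Hamming distance; default 1 per flank) is enumerated. An `N` in the
   read always counts as a mismatch.
2. Among placements with the left anchor strictly before and
   non-overlapping the right anchor, the pair with the **smallest total
   mismatch count** is selected; ties go to the leftmost left placement,
   then the leftmost right placement. The forward read is searched first;
   the reverse complement is adopted only when it has a valid pair and the
   forward read does not, or when its best total is strictly smaller.
3. A read with no valid pair in either orientation is **excluded**.
4. Otherwise the **observed window** is the read segment strictly between
   the two anchors. If its length deviates from the reference window the
   read is an **indel** (signed length difference; positive = insertion,
   negative = deletion). If the length matches, the read is **intact**.

Two modelling points deserve emphasis:

* **"Matching the reference" means matching in length.** An intact read
  may carry any number of substitutions inside the window; those are
  exactly the base edits the per-position frequency matrix is meant to
  capture. If sequence identity were required, a successfully edited read
  would be pushed out of the intact class and base-edit frequencies would
  degenerate to the reference.
* **Indel calls are length calls.** A sequencing indel error inside the
  window is indistinguishable from a biological indel under this scheme.
  The simulator therefore uses a substitution-only error model by default,
  and offers an optional indel-error rate (`indelErrorRate`) purely to
  stress-test this failure mode.

Frequencies are reported over the **analyzed** reads (indel + intact);
excluded reads never enter a denominator. The programmed-edit frequency is
the fraction of analyzed reads that are intact *and* carry the donor base
at every programmed position. Because an indel allele is also a failed
knock-in, analyzed reads are the natural denominator; the same count
divided by intact reads only is reported as
`programmed_edit_freq_intact` for comparison.

Read-level frequencies are a proxy for the "percentage of edited cells":
no ploidy or allele-dropout correction is attempted, matching how such
pools are conventionally reported.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `maxMismatch` | 1 | per-flank mismatch allowance (units: bases). 0 makes anchoring exact and discards more reads; 2+ admits spurious placements on short flanks. |
| `noRC` | `FALSE` | disable reverse-complement search; useful when reads are known to be strand-oriented. |
| `minMeanQ` | off | optional mean-Phred filter applied before anchoring. Off by default: the reference procedure applies none, and constant-quality simulated reads make it moot. |
| `errorRate` (simulator) | 0.001 in the bundled profile | per-base substitution probability, the order of Illumina amplicon error after merging. |

Coordinates throughout are 1-based and closed, the R/Bioconductor
convention; flank starts refer to the oriented read (the
reverse-complemented sequence for `reverse_complement` hits) and donor
positions to the window.

## What the simulator emulates — and what it does not

`simulatePool()` draws each read's allele class from a fixed mixture
(multinomial with the given proportions), embeds the allele's window
between the flanks in the full amplicon context, and applies i.i.d.
substitution errors. Reads are full-amplicon by default (amplicon
sequencing of a ~100 bp PCR product), emitted in forward orientation with
constant Q30 qualities, and are byte-identical for identical seeds.

The bundled profile `pool_enriched.yaml` encodes the study condition the
package validates against: a selection-enriched pool of 98.5% precise
edit, 1.0% indel (a 4 bp deletion) and 0.5% wild type, 20,000 reads,
0.001/base error. The indel spectrum of real repair outcomes is not
published for this locus; the single-deletion default (and the 1–10 bp
deletion / 1–3 bp insertion range used in randomized tests) is an
acknowledged invention.

Not modelled: PCR amplification bias, chimeric reads, duplicates,
position- or platform-specific quality profiles, paired-end structure
(the pipeline expects single-end or externally merged reads; unmerged
mates are processed independently, and both anchors must lie on the same
read). Passing parameter-recovery tests therefore demonstrates
correctness of the estimator under the stated error model, not robustness
to every artefact of a real sequencing run.

The synthetic TIE2 fixture deserves the same honesty: the published PCR
primers bracket an invented internal sequence, and the donor edit is
modelled as a single C>T turning a CTC (Leu) codon into TTC (Phe) — the
natural DNA-level reading of an L914F substitution, chosen as an
assumption because the true donor design is not machine-readable from the
source figures.

## Numerical and degenerate-input choices

* An empty pool, or one where every read is excluded, yields zero counts
  and `NaN` frequencies with a warning — never an error, and the JSON
  writer serializes these as `null` with an `undefined_frequencies` flag.
* Base-frequency rows over zero intact reads are all-zero rather than
  `NaN`, so the matrix stays numeric and writable.
* `N` (or any non-ACGT letter) in an intact window is tallied in the `N`
  column; rows always sum to 1 over A, C, G, T, N.
* A full window deletion (anchors abutting) is a valid indel of delta
  `-len(window)` with an empty observed window.
* Tie-breaking is deterministic (leftmost), so classification is a pure
  function of the read; exact reverse-complement invariance of pool
  summaries holds whenever one orientation is strictly better, which is
  the generic case for anchors that are not near-palindromic.

## Validation strategy and problem sizes

The test suite validates the classifier against an independent
brute-force oracle (exhaustive enumeration of all placements in both
orientations with plain character comparisons) on 1,000 randomized reads
of up to 60 bp with 0–2 planted mismatches per flank; it checks exact
read-by-read truth recovery on error-free pools (4,000 reads); binomial
3-standard-error recovery of the mixture fractions across 20 seeds at
5,000 reads; the headline enriched-pool condition at 20,000 reads; and
property suites (partition of counts, denominator contracts,
reverse-complement invariance, mismatch-tolerance monotonicity, AUC
additivity, orientation folding) under seeded random generation. These
sizes give the binomial checks their intended power while keeping the
whole suite inexpensive.

## Assay metrics

The downstream helpers implement printed closed forms on tidy tables:

* `pctPhosphoMultiplex(p, t)` = \(200\,p/(p+t)\), the phospho/total
  electrochemiluminescence kit convention (range [0, 200]; 100 at equal
  signals); `pctPhosphoWB(p, t)` = \(100\,p/t\) for densitometry.
* `orientationFraction(angles, tolerance = 5)` reports the fraction of
  cells whose long axis lies within ±tolerance of the flow direction.
  Cell axes are undirected, so angles are folded modulo 180° into
  (−90°, 90°] before thresholding — the folding convention is this
  package's documented choice (whether the original ±5° count preceded or
  followed folding is not stated anywhere we could verify), made because
  an axis at 176° is physically 4° off the flow axis.
* `aucTrapezoid(time, value)` integrates impedance/confluence time
  courses by the trapezoidal rule, the default of the commercial software
  such curves are usually summarised in.
* `diameterSummary(segments)` reduces traced vessel segments to
  per-explant mean/median diameters (the explant being the unit of
  analysis) plus a pooled histogram. Default bins: 10° for angles, 5 µm
  for diameters — configurable, chosen to match conventional display
  resolution.

## A worked run

```{r run}
spec <- tie2Example()
spec

pool <- readPoolConfig(system.file("extdata", "pool_enriched.yaml",
                                   package = "flankQuant"))
sim <- simulatePool(pool)
summ <- quantifyPool(sim$reads, spec)
summ

## estimate vs. simulated truth
c(estimate = programmedEditFreq(summ),
  truth = mean(sim$truth$kind == "HDR"))
```

## Known limitations

* Indel = length change: balanced substitution-rich alleles of reference
  length are counted as intact, and sequencing indel errors as indels.
* Both flank anchors must lie on one read; amplicons longer than the read
  length require upstream merging.
* Read-level frequencies, not cell-level: a heterozygous cell contributes
  both alleles.
* The per-flank Hamming model tolerates substitutions but not indels
  *inside* an anchor; a read with a 1 bp indel in a flank is excluded
  unless the shifted placement still fits the mismatch budget.
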