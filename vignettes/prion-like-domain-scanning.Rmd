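---
title: "Scanning proteins for Q/N-rich prion-like domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning proteins for Q/N-rich prion-like domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prionScan)
```

## The model

Yeast prions such as Sup35, Ure2 or Rnq1 convert between a soluble state and
a self-propagating amyloid. In most of them the conversion is driven by a
prion-forming domain (PFD) that is intrinsically disordered and strongly
enriched in glutamine and asparagine (Q/N). Composition alone, however, is a
poor discriminator: many Q/N-rich disordered domains never behave as prions.
The discriminating feature exploited here is the presence, inside the
disordered Q/N-rich context, of a short amyloid-nucleating core whose
sequence-intrinsic amyloid potency can be scored.

`prionScan` operationalizes this as three sequential filters per protein:

1. **Disorder.** A sliding-window fold index
   $FI = 2.785\,\langle H \rangle - |\langle R \rangle| - 1.151$
   is computed per residue, where $\langle H \rangle$ is the window mean of
   Kyte–Doolittle hydrophobicity rescaled to $[0,1]$ as $(KD + 4.5)/9$ and
   $\langle R \rangle$ is the window mean net charge (K, R $= +1$; D, E
   $= -1$; all others, including histidine, 0). Residues with $FI < 0$ are
   called disordered; maximal disordered runs of at least 60 residues are
   retained, a length sufficient for prion-like behaviour of Q/N-rich
   domains. When a protein has several such regions each is evaluated
   independently.
2. **Compositional bias.** Within each disordered region the longest
   contiguous stretch with Q/N fraction at or above a threshold (default
   25%) is located; with threshold 0 the whole region qualifies, which
   reduces the tool to a disordered-region finder.
3. **Amyloid core.** Every 21-residue window of the stretch is scored with a
   position-specific scoring matrix; the best-scoring window is the putative
   amyloid core. Among all disordered regions of the protein, the stretch
   containing the highest-scoring core is reported as the prion-like domain
   (PrLD), and the protein is called positive when that score reaches the
   cut-off (default 73.55 on the normalized 0–100 scale).

## Core scoring and the pluggable matrix

A candidate core of 21 residues is scored by summing the matrix score of all
consecutive motif-length placements inside it (16 hexamer placements for a
6-position matrix) and min–max normalizing to $[0, 100]$ with the matrix's
analytically smallest and largest achievable raw 21-mer scores. This
sum-of-placements aggregation is this package's documented contract for
combining per-hexapeptide scores over the 21-mer; the matrix itself is a
pluggable asset loaded with `readScoringMatrix()` (TSV, one row per motif
position, one column per standard residue). Users with an externally derived
amyloid matrix (e.g. a WALTZ-family matrix) supply it there. The package
ships three *synthetic* toy matrices (`toyScoringMatrix("q" | "a" | "qn")`)
whose score ranges are known in closed form; they exist so that every stage
of the pipeline can be validated against constructions with known ground
truth, and they make no claim of biological realism. A matrix under which
every 21-mer scores identically (e.g. residue-uniform weights) leaves the
normalization undefined and is rejected at load time.

## Parameters

| parameter | default | allowed | meaning |
|---|---|---|---|
| `window` | 51 aa | odd, ≥ 3 | fold-index averaging window |
| `minDRLength` | 60 aa | ≥ 1 | minimum disordered-region length |
| `qnThreshold` | 0.25 | [0, 1] | minimum Q/N fraction of the stretch |
| `pwaltzCutoff` | 73.55 | [50, 75] | positive-call score cut-off |
| `maxSequences` | 10 000 | ≥ 1 | batch cap, rejected before scanning |

Cut-offs below 50 are disallowed: at such permissive settings accuracy on
the yeast parameterization set falls below 50% and the MCC below 0.4, so the
calls no longer discriminate prions from non-prions. Two presets bundle the
two documented parameterizations: `"yeast-default"` (0.25 / 73.55) and
`"human-prionlike"` (0.15 / 64.00), the latter a permissive setting that
retrieves human proteins with prion-like behaviour whose nucleating cores
are weaker than those of bona fide yeast prions.

## Numerical and design choices

* **Coordinates.** All coordinates, internal and reported, are 1-based
  inclusive — the R/IRanges convention. CSV output is therefore directly
  comparable to standard protein annotation.
* **Terminal residues.** Residues closer than half a window to a sequence
  end have no full window; they inherit the nearest full-window value rather
  than being scored with a shrinking window, keeping the averaging scale
  uniform. Region boundaries near termini depend on this choice. Sequences
  shorter than the window receive one whole-sequence fold index.
* **Disorder boundary.** $FI = 0$ exactly is classified *ordered*; disorder
  requires strictly negative values.
* **Fraction comparison.** When the Q/N threshold corresponds to a whole
  percent (as the 25% default does), qualification is tested in exact
  integer arithmetic (`100·count ≥ percent·length`); otherwise a `1e-9`
  floating tolerance is applied. This removes float-boundary
  misclassification of stretches sitting exactly at the threshold.
* **Tie-breaks.** Equal-length qualifying stretches: leftmost wins. Equal
  core scores within a stretch: leftmost window wins. Equal best-core scores
  across disordered regions: leftmost region wins. All scans are therefore
  deterministic.
* **Stretches shorter than 21 residues** cannot host a core and make the
  protein negative (`"stretch too short"`); a 21-residue core is a hard
  requirement of the model.
* **Degenerate inputs** (no disordered region, no qualifying stretch) yield
  negative predictions with reason codes, never errors; within a batch, a
  record that fails to scan is reported negative with reason `"scan error"`
  and the batch continues.
* **Score retention.** The best core score is recorded even for negative
  calls, so `sweepCutoff()` re-thresholds stored scores over its 551-point
  35–90 grid without re-scanning; tests verify the equivalence of both
  routes at cut-offs inside the configurable range.
* **Benchmark conventions.** Ratio metrics with a zero denominator are
  reported as `NaN` and flagged; the MCC with any zero marginal is defined
  as 0 (flagged). Display rounding is to 3 decimals.
* **Ambiguity codes** (B, Z, X, U, O, J) are accepted on input with a
  warning; they take neutral values in the fold index (scaled hydrophobicity
  0.5, charge 0) and score the per-position minimum in the core matrix, so
  they can only lower, never raise, a core score.

## What the synthetic generator emulates

`makeLabeledDataset()` builds proteins from three deterministic building
blocks: ordered flanks over {I, V, L, F} (strongly hydrophobic, uncharged —
every full window they dominate has positive fold index), and disordered
segments over {G, S, P} plus Q/N at an exact requested fraction. The G/S/P
background is sampled with weights 0.1/0.3/0.6; this keeps the mean scaled
hydrophobicity of any 51-residue window about seven standard deviations
below the disorder boundary, so planted segments are never fragmented by
sampling noise. Positives carry a disordered Q/N-enriched segment (default
120 aa; window smoothing against the flanks erodes roughly 19 residues per
side, so the detected region stays well above the 60-residue minimum) with a
poly-Q 21-mer planted at its centre, which scores 100 under the paired
Q-rewarding toy matrix. Each negative violates exactly one requirement:
fully ordered, disordered but Q/N-free, or disordered and N-enriched with no
scoring core.

These constructions validate the *machinery* — window arithmetic, region
extraction, stretch search, scoring, thresholding, benchmarking — under
perfect separability. They do not emulate real proteomes: natural sequences
have graded disorder, mixed compositions, charged residues inside disordered
regions, and cores of intermediate potency, so passing these tests says
nothing about the biological error rate of any particular scoring matrix.
Proteome-scale results additionally depend on the externally supplied
matrix asset and reference proteome, neither of which ships with the
package.

## Problem sizes used by the tests

The test-suite and the acceptance script run on deliberately small inputs:
random-sequence oracle comparisons up to 300 residues, labeled synthetic
sets of 10–20 proteins of ~240 residues, and the full 551-point cut-off
sweep on stored scores. These sizes exercise every code path (including both
sides of every boundary: 59- vs 60-residue regions, 20- vs 21-residue
stretches, thresholds at exact percent boundaries) while keeping the whole
suite in the tens of seconds.

## Worked example

```{r example}
cfg <- scanConfig(toyScoringMatrix("q"), preset = "yeast-default")
ds <- makeLabeledDataset(nPositive = 2, nNegative = 2, seed = 42)
res <- scanBatch(readFasta(ds$fasta), cfg)
res
predictionTable(res)[, c("id", "positive", "reason", "core_score")]
```

```{r benchmark}
metricsFromCounts(tp = 11, fp = 2, tn = 37, fn = 1)
```

## Limitations

* The tool flags candidate PrLDs; it does not delimit exact domain
  boundaries — the reported bounds are those of the longest qualifying
  stretch, which is a compositional object, not a structural one.
* Classification quality is entirely conditional on the supplied scoring
  matrix; the toy matrices are for validation only.
* Parameterizations are organism-dependent: the yeast defaults miss known
  human prion-like proteins, which require the permissive preset.
* The fold-index disorder model is a two-feature linear predictor; proteins
  whose disorder is driven by features it ignores (e.g. proline periodicity,
  phosphorylation) may be mis-stratified at step 1.
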