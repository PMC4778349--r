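---
title: "Scoring FACS-binned 3'UTR reporter screens: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring FACS-binned 3'UTR reporter screens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utrscreen)
```

## The measurement model

A sort-seq reporter screen measures the regulatory effect of a short 3'UTR
element indirectly: each candidate 8mer sits in the 3'UTR of an integrated
single-copy GFP reporter, cells are sorted into GFP-intensity percentile
bins, and sequencing of each bin's amplicon library estimates how each
8mer's cells are distributed across the expression range. Repressive
elements shift their cells toward dim bins, activating elements toward
bright bins. A co-integrated dsRed reporter, driven independently at the
same locus, flags cells whose transcription is aberrant for reasons
unrelated to the inserted element; all analyses are conditioned on cells
inside a central dsRed window.

Per 8mer the pipeline computes the bin-weighted **expression score**

$$S \;=\; \frac{\sum_b w_b\,\mathrm{RPM}_b}{\sum_b \mathrm{RPM}_b},
\qquad w = (-2, -1, 0, +1, +2),$$

over the five bins (0–10, 20–30, 40–60, 70–80, 90–100 % of GFP intensity).
Because $S$ is a weighted average of the weights themselves, it is bounded
in $[-2, 2]$, invariant to rescaling all RPM values, and moving read mass
from a lower- to a higher-weight bin can never decrease it — three
properties the test suite asserts directly. The score is ordinal /
semi-quantitative by design: it predicts the direction and approximate
strength of regulation, not absolute GFP intensity.

Separate from the score, each bin's **enrichment** is the 8mer's RPM in the
bin divided by its RPM in the GFP-ALL population (all GFP-positive cells in
the middle-50 % dsRed gate). The score uses within-bin RPM values only; the
enrichment profile uses the background ratio. These are two different
normalizations of the same counts, and the package keeps them separate
rather than mixing them.

## Stages and their parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| GFP bins | 0–10/20–30/40–60/70–80/90–100 % | percentiles | the screen's sorting gates; weights −2…+2 |
| dsRed gate | middle 50 % (25–75) | percentiles | transcriptional-noise control |
| stringent dsRed gate | middle 25 % (37.5–62.5) | percentiles | defines the robust analysis universe |
| `min_phred` | 20 (strict `>`) | Phred | the filtering rule is quoted as a strict inequality; a base at exactly Q20 fails |
| flanks | `CATAC` / `ATA` | DNA | constant amplicon sequence around the variable 8mer |
| read length | 50 | nt | sequencing format being emulated |
| `min_count` (robust set) | 1 per replicate | reads | "robustly included" is otherwise undefined; one read in every stringent-background replicate is the smallest defensible rule, and it is configurable |
| score thresholds | ±1 (strict) | score units | calls: activating > +1, repressive < −1 |
| stability cutoffs | ±0.5 (strict) | log2(RNA/DNA) | brackets the −0.55 ratio of the destabilizing miR-10 target-site control |
| replicates | 2 | — | duplicate sorts per population |

Filter failures are attributed first-failure in a fixed, documented order —
quality, then upstream flank, then downstream flank, then barcode — so
filter statistics are reproducible and sum exactly to the read total.
Unassigned reads (unknown barcode) belong to no library and are excluded
from every library's RPM denominator; restricting denominators to a motif
whitelist is available but off by default, because the screen's
normalization is "reads in the sequencing library", not "reads in the
whitelist".

Replicate libraries are **summed** (raw counts, per population) before RPM
normalization and scoring. Whether published screen scores of this design
used summed or averaged replicates is not stated anywhere we could anchor
on; summing preserves count statistics at low depth, and the averaged mode
plus per-replicate QC scores are also provided.

## What the simulator states, and what it does not

The generator's defaults are the screen's stated world:

- **Library**: 3,918 candidate 8mers, with activating/repressive fractions
  0.118/0.095 (the screen's 461/372 calls out of 3,918, used purely as an
  emulated class balance).
- **Integrations**: Poisson per motif with mean 8 — independent rare
  site-specific integration events. (The screen also reports >3×10⁵ total
  cells; that figure and ~8 integrations per 3,918 motifs are not mutually
  consistent as a simple quotient, so both knobs are exposed independently
  and the discrepancy is left unresolved.)
- **Fluorescence**: log-GFP is a lognormal baseline plus the motif's effect
  expressed in population-SD units, plus Gaussian noise — fluorescence is
  right-skewed and regulatory effects act multiplicatively on expression,
  hence additively on the log scale. dsRed is drawn independently of the
  motif.
- **Sequencing**: multinomial sampling of each library at configurable
  depth (the screen's libraries ran 5.6×10⁶–1.6×10⁷ reads), with optional
  Dirichlet-multinomial overdispersion whose concentration defaults to
  effectively infinite: PCR jackpotting is real but unquantified in the
  design being emulated, so the default stays at the stated multinomial.
- **Stability**: expected RNA abundance per motif is the DNA (cell) count
  times $2^{\text{stability effect}}$; by default 70 % of non-neutral
  motifs carry a stability effect of magnitude 0.55 (the miR-10 exemplar),
  the remainder modelling purely translational regulation.
- **Reads**: barcode + `CATAC` + 8mer (DNA alphabet) + `ATA` + filler, Q40
  qualities; a stated fraction of reads is corrupted (a barcode/8mer base
  dropped to exactly Q20, or a flank substitution) to exercise the filters.
  Motifs live in the RNA alphabet everywhere except the read boundary.

**Replicates.** Duplicate sorts are modelled, by default, as independent
sequencing draws from the same gated cell composition
(`gate_and_sort(replicate_mode = "sequencing")`). At the screen's physical
scale (≥5×10⁵ cells per sorted population) duplicate tubes differ
negligibly in cell composition, and replicate disagreement is dominated by
library sampling — which is what this mode reproduces. At desk scale
(~5×10⁴ simulated cells) a physically-split model (`"split"`, also
provided) would make per-motif bin occupancy so sparse (a few cells per
motif per replicate) that replicate concordance collapses regardless of
sequencing depth — an artifact of the scaled-down cell count, not a
property of the assay. The default therefore keeps the cell composition
shared so that desk-scale simulations occupy the same noise regime as the
real screen.

What the simulator does **not** emulate: integration-site biology and
selection dynamics, transcriptional-noise outliers beyond the dsRed gate,
PCR chimeras, position-specific sequencing error profiles, and luciferase
assay chemistry. A green recovery test therefore establishes that the
pipeline's arithmetic and filtering recover known effects under the stated
sampling model — not that the wet-lab assay has any particular sensitivity.

## Numerical conventions and edge cases

- All classification comparisons are strict (score exactly +1 is neutral;
  ratio exactly +0.5 is neutral), matching the quoted call definitions.
- Zero-RPM bins contribute zero to both numerator and denominator of the
  score; no pseudocount enters the score. A motif with zero RPM in every
  bin has an undefined score and is dropped with a warning. Pseudocounts
  are available for enrichment ratios only, where a reconfigured background
  gate could make division by zero possible.
- Ranking is descending by score with lexicographic motif tie-breaks, so
  ranks are total and reproducible.
- The two-sided Fisher exact test uses the minimum-likelihood convention
  (sum of all outcome probabilities ≤ the observed one, with the customary
  1e-7 relative tie tolerance); the doubling convention is available as an
  option. The test suite checks the implementation against exhaustive
  hypergeometric enumeration for every valid table with N ≤ 30.
- Half-lives are fitted by ordinary least squares on log abundance — the
  standard, exactly solvable estimator for first-order decay — with
  replicates pooled into one fit; $t_{1/2} = \ln 2 / k$ with the standard
  error propagated as $\ln 2 \cdot \mathrm{se}(k)/k^2$. A fitted $k \le 0$
  is flagged non-decaying rather than producing a negative half-life.
  qPCR input is accepted as Ct pairs via the 2^−ΔΔCt helper (reference-gene
  normalization implicit in the subtraction).
- Conserved-instance counting treats every gap-free window where all four
  species rows spell the motif as one instance; overlapping instances all
  count. Shuffled controls (default 50, configurable; the construction is
  not specified in the design being emulated) preserve the motif's
  nucleotide multiset, exclude shuffles equal to the motif, and are seeded.
  A homopolymer, whose only permutation is itself, has signal 1 by
  definition; a motif observed while its shuffles never are yields an
  explicitly flagged undefined signal rather than infinity.
- Reverse complements are computed in the RNA sense. Even-length RNA words
  can be their own reverse complement (e.g. AAAAUUUU); such motifs cannot
  form a score-correlation pair and are excluded from that analysis.
- All stochastic operations take explicit seeds; multi-stage operations
  derive per-stage sub-seeds deterministically from one master seed, so
  pipeline reruns are byte-identical.
- Enrichment is tested per 8mer (the screened unit) even where assay
  descriptions of this design speak loosely of "genes".

## Known limitations

- The RNA/DNA ratio cannot separate elements acting on stability alone
  from elements acting on both stability and translation; the package
  reports the discordant sets (high score / low ratio and vice versa) as
  candidate translational regulators and goes no further.
- The expression score compresses a full GFP distribution into one number;
  bimodal or context-dependent effects are not representable.
- miRNA-target-site categories are accepted as input lists; the package
  does not compute them from miRNA sequences, and small-RNA quantification
  is out of scope.
- Genome-scale alignment extraction is out of scope; conservation analyses
  expect pre-extracted aligned 3'UTR blocks (aligned multi-FASTA, four
  species, reference first).

## A small end-to-end run

```{r, eval = FALSE}
cfg <- run_config(out_dir = tempfile("screen_"), seed = 1,
                  n_motifs = 300, depth = 2e4)
report <- run_pipeline(cfg)
str(report$stages)
```

The run writes the truth table, multiplexed FASTQ, filter statistics, count
table, score table, stability table, enrichment table, the echoed
configuration and a JSON report whose counts reconcile with the output
files — the pipeline tests assert this reconciliation and byte-identical
reruns.
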