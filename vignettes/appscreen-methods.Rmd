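---
title: "Models and methods behind appscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind appscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(appscreen)
```

`appscreen` implements the analysis chain of a genome-wide, high-content
siRNA screen read out by a dual-tagged mCherry–APP–YFP reporter: intracellular
APP fragments accumulate or deplete as APP processing is perturbed, and the
mean per-cell cytoplasmic fluorescence of each well is the screen's
measurement. This vignette explains the statistical model at each stage, the
defaults and why they were chosen, what the synthetic-data generators emulate,
and what the package's tests can and cannot establish about real screens.

## The screen model

A screen consists of `n_replicates` (default 3) independent passes over a
library of genes arrayed one per well on 384-well plates. Each plate carries
three control groups: non-targeting siRNA (NT, the normalization reference),
siAPP (knocks the reporter itself down — both channels fall), and siPSEN1
(blocks the gamma-secretase cleaving APP — intracellular fragments accumulate
and both channels rise). The two positive controls move the read-out in
opposite directions, which is why quality control compares the *magnitude* of
the strictly standardized mean difference (SSMD) to its threshold.

The intensity-level simulator (`simulate_screen()`) generates well means as

```
intensity = baseline × 2^(gene log2-effect) × plate factor × well noise
```

with log-normal plate factors and well noise (multiplicative, because
fluorescence is positive and fold-change is the unit of analysis). With all
noise switched off the pipeline returns the injected effects exactly, which
the test suite uses as an algebraic oracle.

### Default parameters

| parameter | default | units | rationale |
|---|---|---|---|
| plate size | 384 | wells | screening-plate standard |
| replicates | 3 | — | triplicate screen design |
| siAPP / siPSEN1 wells | 14 each | wells/plate | positive-control group size |
| NT wells | 14 | wells/plate | mirrors the positive controls (symmetric design; the count is otherwise unconstrained) |
| well noise CV | 0.1 | — | ~10% well-to-well spread, a typical HCS figure giving SSMD magnitudes comfortably above 3 for the default control effects |
| plate effect CV | 0.1 | — | plate-level factor; cancelled by within-plate normalization, so its size only stresses the invariance |
| siAPP effect | 0.4× both channels | — | strong knock-down of the reporter itself |
| siPSEN1 effect | 2.2× mCherry, 1.8× YFP | — | substrate accumulation; YFP responds more weakly because of its faster turnover at the membrane |
| cell count | mean 795, SD 345 | cells/well | detected-count calibration (below) |
| min cells | 300 | cells/well | exclusion rule for under-populated wells |
| SSMD threshold | 3 | — | HCS quality-control guideline |
| tail fraction | 0.025 per tail | — | strongest 5% of variations, split evenly |
| min replicates | 2 | — | wells, not genes, are excluded; requiring all 3 would over-drop genes that lost a single well |

### Cell-count calibration

Analyzable cells per well are modelled as a zero-truncated normal whose
*truncated* distribution has mean 795 and latent SD 345 cells. The latent
location is solved numerically (`uniroot`) because truncating N(795, 345) at
zero would inflate the mean by about 10 cells; calibrating the truncated mean
keeps the generator's long-run average at the stated 795. Counts are drawn
independently of the intensities — in real screens sparse wells are also
noisier, a coupling the simulator does not model.

## Image simulation and quantification

The image generator renders each cell as a circular nucleus (radius 6 px,
Hoechst channel) inside a concentric annular cytoplasm (outer radius 14 px)
carrying the mCherry/YFP signal, on a 1536×1536 field. The field is sized so
that 795 non-overlapping footprints occupy ~21% of its area, where rejection
sampling terminates quickly; per-cell true means are log-normal around the
well mean with CV 0.3 so that averaging over cells is non-trivial; pixel
noise is additive Gaussian truncated at zero. Point-spread functions,
illumination gradients and shot noise are deliberately out of scope: the
generator exists to test mean-intensity estimators, not to photorealistically
model microscopy.

Segmentation proceeds nucleus-first, from the Hoechst channel alone: Gaussian
smoothing (σ = 2 px), Otsu threshold, distance-transform watershed to split
touching nuclei, minimum area 30 px. A single global threshold makes bright
nuclei too large and dim ones too small after smoothing, so each nucleus
boundary is then refined at the midpoint between local background and that
nucleus's smoothed peak — the half-peak contour of a blurred symmetric edge
sits at the true edge regardless of brightness. Cells are grown from a 1-px
padded nuclear mask by a bounded dilation (ring width 6 px), contested pixels
going to the nearest seed; the cytoplasm is the cell minus the padded
nucleus. The padding keeps perinuclear pixels, where the reporter signal is
absent, out of the cytoplasmic mean. Cells touching the image border are
excluded by default since their footprints are clipped.

Backgrounds are estimated per image and channel as the median over non-cell
pixels, and per-cell means are floored at zero after subtraction. The
per-well intensity is the unweighted mean of per-cell means — each cell
counts equally, rather than each pixel.

On noiseless synthetic wells this pipeline recovers counts and per-cell
means exactly (to floating-point precision); at the default noise the test
suite bounds the count error at 5% and the per-cell mean absolute intensity
error at 2% over 20 wells (512×512 fields, 60 cells — sizes chosen so the
whole suite runs in about a minute; accuracy at the full 1536×1536 field is
spot-checked separately with a 795-cell well).

## Plate statistics and hit calling

SSMD is computed with unbiased variances on raw (pre-normalization) well
means, positive controls versus NT, per channel. Passing requires both
controls to reach |SSMD| ≥ 3 on mCherry only, by default: mCherry is the main
read-out (YFP's weak detection limits its dynamic range downward), and the
channels required are configurable. A failing plate excludes that plate ×
replicate's wells; other replicates of the same genes are kept.

Fold-change is computed within plate against the arithmetic mean of included
NT wells. Per gene, log2 is applied per replicate *before* averaging (the
geometric-mean convention, matching a read-out plotted as mean log2
fold-change); the robustness metric is the SD of the *linear* fold-changes
expressed in percent, the only scale on which an "SD of 11.5%" is
dimensionally meaningful. Hits are the ⌊0.025·N⌋ extreme genes per tail of
the mean mCherry log2 fold-change, ties broken lexicographically by gene id
so the call is deterministic and order-invariant; `floor` is the rounding
rule consistent with an 832-gene hit list arising from 16,653 scored genes.

## Genetics cross-reference

Hits are intersected (case-insensitively, set semantics) with GWAS-locus
candidate genes. The packaged eight-gene association table records, for each
candidate, its screen fold-changes and the strongest SNP association with
cerebrospinal-fluid Aβ42 in AD cases. The gene-wide Bonferroni filter uses
the exact threshold α/m (0.05/8 = 0.00625), displays it rounded to 0.006, and
compares strictly (`p < threshold`); with the packaged table only FERMT2
(p = 0.0006) survives. The SNP-level regressions behind the table (covariates,
imputation, meta-analysis) are consumed as summaries, never refitted: the
cohort genotypes are not distributable, and the filter is the only step the
pipeline owns.

## Design choices where the design was open

* **NT well count (14/plate).** Unconstrained by the screen design we
  emulate; chosen symmetric with the positive controls.
* **Plate layout.** Controls occupy a fixed block, samples fill plates in
  well order, and gene-to-well assignment is fixed across replicates;
  randomized re-arraying between replicates is not modelled.
* **QC failure scope.** A plate failing in one replicate excludes only that
  replicate's wells — the gene survives if two other replicates remain.
* **`min_replicates = 2`.** Exclusion operates on wells; a gene is only
  dropped when fewer than two usable replicates remain.
* **Per-gene robustness uses the mCherry channel**, consistent with its role
  as the main read-out.

## Numerical and degenerate-input behaviour

SSMD raises a distinct error (not `NaN`) when both groups are constant, and
refuses groups smaller than 2. Normalization errors when a plate has no
included NT well. A well with zero segmented cells is flagged rather than
erroring. `ring_width = 0` warns and returns empty cytoplasm masks. All
stochastic entry points accept a seed, and identical seeds give bit-identical
outputs; the pipeline writes an MD5 manifest over its output tables so
end-to-end determinism is checkable byte-for-byte.

## What passing tests do and do not show

The simulators establish that the statistics are implemented correctly:
exact recovery without noise, calibrated recovery (hit recall ≥ 0.95 for
|log2 effect| ≥ 1 at default noise), and the structural invariants
(NT self-normalization, plate-factor cancellation, hit-count arithmetic,
Bonferroni monotonicity). They do not certify performance on real screens:
empirical pass rates, attrition counts and replicate-SD summaries are
properties of a particular screen's data, and the generators' Gaussian/log-
normal noise, circular geometry and independence assumptions are idealisations
of real microscopy and transfection variability.
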