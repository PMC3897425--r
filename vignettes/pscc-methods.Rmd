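---
title: "Read-depth CNV calling against a control panel: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-depth CNV calling against a control panel: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pscc)
```

This vignette documents the statistical model behind the package, the
parameters that matter, the synthetic-data generator used to validate it,
and the design choices made where the methodology was genuinely open.

## The signal model

At copy number $c$, the read count of window $i$ in sample $j$ is modelled
as

$$m_{ij} \sim \mathrm{Poisson}\!\left(\tfrac{c}{2}\, E \, g(\mathrm{GC}_i)\, b_i \, u_{ij}\right),$$

where $E$ is the expected read count of a diploid window, $g(\cdot)$ a
sample-specific GC efficiency curve, $b_i$ a window-specific multiplicative
bias **shared across samples** (mappability, genomic structure — the
"multiplex-related" bias), and $u_{ij}$ residual sample-specific noise.
Neither $g$ nor $b_i$ is estimated parametrically; both are removed
empirically:

* $g$ by median-matching within 1% GC bins (`gc_correct`): each count is
  scaled by the ratio of the sample's overall median to its GC bin's
  median. Median, not mean, so that CNVs themselves barely perturb the
  correction.
* $b_i$ by dividing by the control panel's per-window mean $\mu_i$
  (`normalize_rcr`), after rescaling every sample to a common overall
  median so that controls sequenced at a different depth than cases remain
  comparable. The panel SD $\sigma_i$ is kept: windows where controls
  disagree are exactly the windows where a case-control difference is not
  evidence of a CNV.

The result is the relative copy ratio (RCR) $r_{ij}$ with
$\mathbb{E}[r_{ij}] = c/2$.

## Windows

Windows hold a constant number of uniquely mappable simulated read starts,
so every window has the same *expected* count and windows are directly
comparable in the corrections above. `simulate_mappability` performs an
exact-occurrence census of read-length substrings on both strands — a
deterministic, desk-scale equivalent of remapping simulated reads; no
mismatches are modelled. Boundaries sit at midpoints between the last
simulated start of one window and the first of the next, so unmappable gaps
are split evenly (boundary placement is unspecified in the methodology this
follows; midpoints are symmetric and deterministic). The trailing remainder
of each chromosome becomes a window flagged `partial` and is excluded from
panel statistics and segmentation, since its expectation differs.
Coordinates are 0-based half-open throughout; reads are assigned by their
leftmost mapped base, and properly paired fragments are counted once via
their plus-strand read.

## Segmentation

Breakpoints are found with a two-sample Wald–Wolfowitz runs test: pool the
flanking blocks, sort, count runs of same-block labels; few runs mean
separated distributions. The test is rank-based, so it is robust to the
skewed, occasionally heavy-tailed RCR noise ("polymorphic conditions") that
would mislead a t-type statistic.

Numerical conventions, all deterministic:

* **Exact vs approximate.** For pooled sizes $\le$ 40 (`exact_limit`) the
  p-value comes from the closed-form null distribution of the run count;
  beyond that, from the normal approximation with continuity correction.
  The scan (10-window flanks, pooled $n = 20$) is therefore always exact;
  pruning re-tests with flanks up to 200 windows, where the approximation
  is sound.
* **Two-sided convention.** Double the smaller tail of the run count,
  capped at 1. Too *many* runs (anti-clustering) is also flagged, though it
  never arises from a copy-number step.
* **Ties** across blocks are laid out alternately in sorted order —
  deterministic, and conservative for breakpoint detection since ties are
  evidence of similarity.
* **Sentinels.** Blocks under 5 usable values, or all-identical pooled
  values, return p = 1.

The scan keeps non-strict local minima of the p curve at or below `p_enter`
(0.01) as candidates; plateaus of the discrete p-value enter whole and are
thinned by pruning. Pruning iteratively re-tests every surviving candidate
against its full inter-breakpoint flanks (capped at `max_flank` = 200
windows, so a breakpoint's significance never depends on megabase-distant
data) and removes the least significant while it exceeds the genome-wide
threshold — by default Bonferroni, 0.05 over the number of scanned
positions, reflecting a deliberate bias toward false-positive control.

Removal ties are resolved by weakest scan evidence first, then highest
position. The first key matters: candidates crowded around a true boundary
all carry sentinel p = 1 while their flanks overlap, and removing by
position alone can evict the true boundary in favour of a plateau
neighbour. With the scan-evidence key, boundary recovery for 10-window
events at 2×-equivalent noise is within ±2 windows in ≥95% of replicates;
without it, about 77%.

Segments shorter than `min_seg_windows` (3) merge into the neighbour with
the closer mean. Chromosome ends are implicit breakpoints; unusable windows
are skipped and segments are mapped back to genomic coordinates afterwards.

## Genotyping: the combined tests

Two tests, both at $\alpha = 0.001$, classify every segment:

* **Self-test (ST)**: two-sided Mann–Whitney U of the segment's RCRs
  against all *other* usable windows of the sample. The segment is excluded
  from its own background so that large events (up to whole-chromosome
  aneuploidies) do not contaminate the reference distribution.
* **Parallelism-test (PT)**: $z = (\bar r - 1)/\mathrm{SE}$ with
  $\mathrm{SE} = \sqrt{\sum_i (\sigma_i/\mu_i)^2}\,/\,n$ — the standard
  error of the segment mean implied by the panel's per-window relative
  SDs. In regions the panel itself shows to be unstable (tandem repeats,
  CNV polymorphisms), $\sigma_i/\mu_i$ is large, the SE balloons, and PT
  refuses to certify the signal.

The 2×2 grid: both significant → CNV; ST only → unstable region; PT only →
sample-quality issue (a sample with more than `quality_frac` = 1% of its
segments in this category is flagged for replication, with a strict
inequality at the boundary); neither → normal. Calls additionally require
an integer copy number $\mathrm{round}(2\bar r) \ne 2$ (half rounded away
from zero) — a segment statistically distinct from the panel but rounding
to diploid is not a reportable CNV, and mosaic states are out of scope —
and a genomic size of at least `min_size` (100 kb, expressed in bp so it is
depth-independent). Adjacent same-state calls separated only by unusable
windows are merged and re-tested.

## The simulator: what it emulates, and what it does not

`sim_experiment` draws the shared structure of an experiment — the window
grid, per-window GC (Beta(24, 35): mean 0.41, SD 0.063, a human-like
autosomal profile), and the shared bias $b_i$ (lognormal, sdlog 0.1) — and
every control and case inherits it, matching the model's central assumption
that multiplex bias is reproducible across samples. The GC curve is flat on
[0.35, 0.50] and halves every 0.10 GC outside it (2-fold suppression at GC
0.60), reproducing the under-representation of GC-poor and GC-rich windows
that motivates the first correction step. Sample noise is Poisson times an
independent lognormal whose variance is calibrated so the per-window
relative SD is 20% above the Poisson floor $1/\sqrt{E}$ — a conservative
margin standing in for residual real-data noise, since real cohort RCRs are
not shipped with the package.

Depth is realized through the window-sizing rule: windows are rebuilt per
depth at constant $E = 150$ with width $E \cdot \ell / d$ ($\ell$ = 36 bp
reads), i.e. 2 700 bp at 2× and 27 000 bp at 0.2×. An event's size in bp
therefore maps to ten-fold fewer windows at 0.2×, which is what makes small
events undetectable at low depth and gives power its characteristic shape
across the size × depth grid. Truth sets place one event per chromosome
(sizes log-uniform, deletions CN 1 and duplications CN 3 in equal numbers),
so events never overlap by construction.

What passing simulated tests does **not** show about real data: no
alignment artefacts, reference errors, or batch-varying GC curves; the
shared bias is exactly reproducible across samples rather than merely
correlated; noise is symmetric in log scale with no CNV polymorphisms
segregating in the panel. The unstable-region filter is therefore exercised
synthetically (by inflating panel SDs) rather than emerging from the data.

## Problem sizes and defaults

Power studies in the test-suite and the acceptance script use genomes of 12
chromosomes × 4 500 windows at 2× (54 000 windows, chromosomes of ~12 Mb so
a 10 Mb event fits) and 12 × 500 at 0.2×, with a 90-control panel, 55 case
samples and 10 events per case per cell — greater than 500 events per cell,
which bounds the standard error of a sensitivity estimate near 100% at
about 0.4 points. These are the package's own choices balancing precision
against desk-scale runtime (each 2× cell runs in a few minutes on one CPU).

Key defaults, with the reasoning:

| parameter | default | why |
|---|---|---|
| `expected_rc` | 150 | balances detection power per window against resolution |
| `gc_bin_width` | 0.01 | per-GC-percentage correction granularity |
| `gc_min_bin` | 50 | bins with fewer usable windows borrow the nearest bin's median rather than trust a noisy one |
| `mu_floor_frac` | 0.1 | windows whose panel mean falls below 10% of the median mean are unusable (division guards in unmappable regions) |
| `block` | 10 | smallest flank with useful exact runs-test resolution (minimum attainable p ≈ 2·10⁻⁵) |
| `p_enter` | 0.01 | candidate entry; permissive, pruning does the control |
| `p_genome` | Bonferroni 0.05 | family-wise false-breakpoint control per genome |
| `max_flank` | 200 | locality cap for pruning re-tests |
| `alpha_st`, `alpha_pt` | 0.001 | per-segment significance of the combined tests |
| `min_size` | 100 kb | reportable call size, in bp so it is depth-independent |

## Known limitations

Only integer copy-number states rounding away from 2 are reported: mosaic
and multi-allelic events are out of scope. Events spanning fewer than ~3
windows at the working depth are invisible by design, and two events closer
than one scan block may merge. The panel must be sequenced with the same
protocol as the cases; a panel carrying common CNV polymorphisms will
absorb them into $\mu_i$ and mask them in cases (and conversely inflate
$\sigma_i$, suppressing calls there via PT). Breakpoint resolution is one
window — split-read or assembly refinement is deliberately not attempted.
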