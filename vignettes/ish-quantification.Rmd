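---
title: "Quantifying and comparing spatial ISH expression patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and comparing spatial ISH expression patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ishquant)
```

## The model

`ishquant` treats a whole-mount in situ hybridization (ISH) image of an
embryo as a noisy rendering of a one-dimensional staining function. The
central assumption is **cylindrical symmetry**: for the genes the pipeline
quantifies, staining intensity depends only on position along the
oral–aboral body axis, not on the angle around it. Under that assumption a
2D image section carries no more information than intensity as a function
of arc length along the cell layer, and profiles from different embryos,
magnifications and stains become comparable after two normalizations:

* **position** is normalized cumulative arc length of the cell-layer
  midline, 0 at the animal/oral pole and 1 at the vegetal/aboral pole
  along a half-meridian;
* **intensity** is linearly interpolated at 100 equidistant positions
  (both endpoints included, step 1/99) and divided by its maximum, so
  every standardized profile peaks at exactly 1.

Max-scaling discards absolute staining strength deliberately: ISH
intensity is not calibrated across experiments, so only the spatial shape
is retained. A consequence worth knowing is that profiles with no real
signal would amplify pure background; all-zero (or non-positive-maximum)
profiles are therefore rejected rather than scaled.

Genes whose patterns break cylindrical symmetry (e.g. expression on the
siphonoglyph side only) are carried through the domain tables with a
`noncylindrical` flag but are excluded from 1D quantification; they would
need a 2D or 3D method.

### From image to profile

The cell layer is described by a *boundary morphology*: two ordered,
index-paired polylines (inner and outer boundary). Consecutive point
pairs bound a quadrilateral; `segment_cell_layer()` assigns each quad the
normalized midline arc length at its center. `segment_mean_intensity()`
averages the pixels whose centers fall inside each quad. Manual editing
of the intensity plot — how an annotator removes bubbles, annotations and
segmentation slips — is reproduced by `edit_profile()`: intensities inside
masked arc intervals are replaced by linear interpolation between the
nearest unmasked neighbors (runs touching an end take the nearest
unmasked value). Boundary placement itself is out of scope: morphologies
arrive as data (CSV), not from an interactive tool.

### Clustering

Per stage, profiles are compared with the Pearson correlation distance
*d* = 1 − *r*, which ranges over [0, 2]; values above 1 mean
anti-correlation and are **not clamped** — the early-gastrula cutoff of
1.3 only makes sense on that scale. Trees are built with unweighted
average linkage (UPGMA): the distance between two clusters is the
arithmetic mean of all inter-member leaf distances. Two partitions are
reported side by side, because they answer different questions and need
not agree:

* a **height cut** at the stage's cutoff (0.7, 1.3, 1.1, 0.6, 0.9, 0.9,
  0.9 from blastula to late planula; their mean rounds to 0.9), giving
  clusters of profiles whose mutual dissimilarity stays below a fixed
  threshold;
* the **2-vs-3 main-cluster rule**: the root split gives two branches,
  and if the second-highest merge lies inside the strictly larger branch,
  that branch is split again. With equal-sized branches there is no
  "largest branch to reduce" and two clusters are returned; a height tie
  between the two root children resolves toward the larger branch.

Subclusters ("blocks" in a correlation matrix) are obtained by cutting a
main cluster's subtree at a secondary, user-chosen threshold; no default
is asserted as correct.

### Transition statistics

The comparative layer works on curated expression-domain descriptions,
not on profiles. Domains are mapped to three major regions — R1 central
domain/endoderm, R2 central ring/external ring/oral ectoderm, R3 vegetal
hemisphere/aboral ectoderm — and, for each gene, every pair of
*consecutive available* stages is classified:

| initial set | final set | category |
|---|---|---|
| empty | empty | none |
| empty | nonempty | appeared |
| nonempty | empty | vanished |
| nonempty | same set | minor |
| nonempty | different nonempty set | major |

"Minor" requires region-set **equality**. That is the strictest reading
of "remained within the same major region", and the only one consistent
with the reference count tables: gaining a second region counts as a
major change even though the original region is still stained. For the
region-filtered tables only pairs starting with expression in exactly one
region are counted (three categories); multi-region starts appear only in
the all-regions table (five categories).

Counts per (initial, final) stage pair are summed into two-stage periods
by the **period-inclusion rule**: a transition observed between stages
*i* and *f* could have happened in any intervening period, so it is
credited to every period (s, s+1) with index(i) ≤ s < index(f). The total
contribution of a cell therefore equals its count times the stage span —
a conservation law the test suite checks. Period sums become integer
percentages via round-half-away-from-zero; no printed reference
percentage sits on a tie, so the choice is observationally safe there,
but it is fixed for determinism.

`fisher_exact_two_tail()` computes the two-tailed Fisher p-value by
exhaustive hypergeometric enumeration (sum of all table probabilities not
exceeding the observed one, with a 1e-7 relative slack for floating-point
ties — the same convention `stats::fisher.test` uses, which serves as an
independent cross-check in the tests).

### Domain→region map

The published groupings name the three regions but no complete
domain-by-domain lookup, so `default_region_map()` is an inference and is
deliberately user-overridable. Lineage-unambiguous names (Cd, pEn, En,
PhEn … → R1; Cr, Er, bEc, OrEc, PhEc, M → R2; VeHe, Ve, AbEc, At, AtEc →
R3) are mapped; pan-regional names (Ec, AnHe) and names whose regional
fate is uncertain (body-wall ectoderm) stay `unmapped`. We additionally
map An (animal pole) to R1 since the pole lies inside the central domain.
Unmapped domains are reported, never silently dropped; a stage whose
domain set is nonempty but maps entirely to unmapped regions has unknown
membership, and such pairs are skipped with a warning — an empty domain
set, by contrast, genuinely means "not expressed".

## The synthetic-data generator

The generator exists so that every downstream stage has inputs with known
ground truth.

**Images.** A scene is an elliptical annulus half (a half-meridian),
optionally with an invagination dent at the oral pole for gastrula-like
morphologies; both are the same radial-boundary model. Staining inside
the layer is a function of arc position only (the cylindrical-symmetry
assumption made literal), plus additive Gaussian noise truncated at zero,
plus optional hard-edged disc artifacts whose exact arc extent is
recorded. Defaults: 240×240 px frame, outer semi-axes 90×100 px, layer
thickness 26 px, background 0.1 — proportions matching a typical
micrograph of an embryo filling most of the frame. Full closed outlines
are handled by quantifying each half as its own morphology and averaging
the two standardized profiles; the generator itself emits half-scenes.

**Window edges.** Staining domains are logistic ramps of width 0.04 of
the body axis rather than hard steps: real expression boundaries are
gradients over a few cell diameters, and a step function is not
recoverable by *any* finite-resolution segment-averaging extractor at its
discontinuity. A window touching an axis end extends fully to the pole
(no ramp there). With these defaults, noise-free extraction round-trips
the true profile to within about 0.02 maximum absolute deviation; the
tests assert 0.05.

**Profile sets.** Planted-cluster fixtures sample archetype window
functions at the 100-point grid, apply per-window amplitude jitter and
truncated Gaussian noise, and re-scale. For the recovery tests the
archetypes occupy disjoint axis windows, which makes between-archetype
correlations negative and distances ≳ 1.2 — comfortably above the stage
cutoffs used — while noise sd 0.05 keeps within-archetype distances small
(separation ≥ 4× noise).

**Domain tables.** A transition kernel gives per-period category
probabilities. Feasibility depends on state, which the published category
set leaves implicit, so the kernel is applied conditionally: a nonempty
region set renormalizes over {minor, major, vanished}, an empty one over
{appeared, none}; the initial state is empty with probability equal to
the appeared+none mass (configurable). Every drawn category is realized
through stage-legal domain names that map back to the intended regions,
so the downstream classifier recovers the recorded truth exactly, and
empirical category frequencies converge to the kernel (checked at 2000
genes within 3 percentage points).

**What passing tests do and do not show.** The generator reproduces the
geometry, the noise floor and the bookkeeping of real data, not its
biology: no probe chemistry, no staining saturation, no out-of-focus
blur, no curation error, and annotation noise only through the additive
model. Green tests demonstrate that the algorithms are implemented
correctly and are self-consistent under the stated assumptions; they do
not validate the cylindrical-symmetry assumption or the curated domain
calls on any particular real image.

## Numerical choices

* **Pixel membership**: a pixel belongs to a quad when its center lies
  inside it (even-odd rule, boundary inclusive); pixels on a shared edge
  are claimed by the first segment that reaches them, so each pixel
  counts once. Deterministic, at the price of a half-pixel asymmetry that
  is far below the round-trip tolerance.
* **UPGMA tie-break**: clusters are indexed by their smallest member
  leaf; among equal minimal distances the smallest (index_a, index_b)
  pair merges first. Display order puts the branch with the smaller
  minimum leaf index on the left. Both choices exist purely for
  determinism.
* **Endpoint interpolation**: standardization evaluates outside the raw
  position range (segment midpoints start at ~0.005) by taking the
  nearest raw value (`approx(rule = 2)`).
* **Degenerate inputs**: zero-area quads error with the segment index;
  constant profiles error with the sample name (their Pearson distance is
  undefined); masks covering every point error; segments thinner than a
  pixel are dropped with a warning.
* **Scale invariance**: multiplying an image by a constant leaves the
  standardized profile unchanged; bit-for-bit under binary factors,
  within machine epsilon otherwise (floating-point division is not
  exactly associative).
* **Problem sizes** used by the tests and the acceptance script — 200
  random matrices of up to 12 leaves for the linkage oracle, three
  240×240 noise-free scenes for the round trip, 2–4 archetypes × 10
  replicates for recovery, 2000 genes for kernel recovery, all 2×2
  margins ≤ 30 for Fisher — were chosen as the smallest sets that
  exercise every code path with tight statistical bounds.

## Known limitations

* Boundary polylines must be supplied; there is no automatic cell-layer
  segmentation.
* The domain→region map is an inference; analyses sensitive to the
  body-wall ectoderm or other unmapped names must supply their own map.
* The MAT container reader is minimal (uncompressed little-endian double
  matrices), sufficient for stage-grouped profile arrays; it discovers
  stage grouping from variable names and reports what it found.
* Percentages are reported as integers to match the reference tables;
  downstream arithmetic on them inherits the rounding.
* The Fisher helper tests association between period compositions; the
  package deliberately does not assert any particular published p-value,
  because the exact 2×2 construction behind the headline test is not
  reconstructible from the printed tables.
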