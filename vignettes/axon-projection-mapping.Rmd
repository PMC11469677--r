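---
title: "Quantifying brain-wide axonal projections and their motor-cortex topography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying brain-wide axonal projections and their motor-cortex topography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonmapr)
```

## The problem

Anterograde tracing with cell class-specific Cre driver lines labels the
long-range axons of a defined population of cortical neurons — for example
layer 2/3 intratelencephalic neurons of the whisker-related primary
somatosensory barrel cortex (SSp-bfd) or the supplemental somatosensory
cortex (SSs). Light-sheet imaging of cleared brains produces whole-brain
volumes at roughly 5 µm resolution in which a segmentation network assigns
each voxel a probability of containing axon. `axonmapr` takes the analysis
from that point: it converts probabilistic segmentations into curated axon
skeletons, maps them into a 25 µm reference atlas, normalizes by the number
of labeled neurons, and quantifies where each cell class projects — per
region and hemisphere, as cross-injection correlation structure, and as the
fine-scale topography of the dense motor-cortex (MO) innervation "hotspot".
A companion wide-field module quantifies the functional counterpart:
optogenetic stimulation of somatosensory cortex combined with calcium
imaging of the evoked frontal activity.

The headline scientific quantity in both modalities is a mirror map: the
anteroposterior (AP) position of the MO hotspot is linear in the absolute
mediolateral (|ML|) position of the somatosensory source,

$$\mathrm{AP} = a + s\,|\mathrm{ML}|,$$

with slope $s$ around 0.5 mm AP per mm |ML| — more lateral sources project
to more anterior motor cortex.

## Weighted skeletonization

The segmentation output is a probability volume in $[0, 1]$. A single
binarization threshold either fragments dim axons (high threshold) or
inflates bright artifacts (low threshold). The weighted skeleton therefore
binarizes at eight thresholds, $0.2, 0.3, \dots, 0.9$, skeletonizes each
binary stack separately, multiplies each skeleton by its threshold value,
and sums. A voxel recovered at every threshold carries weight
$0.2 + \dots + 0.9 = 4.4$; a dim but real axon fragment still appears, with
a smaller weight. Because the thresholds increase, the binary masks are
nested; the implementation asserts this before thinning.

Choices the procedure leaves open, and how this package resolves them:

* **Thinning algorithm.** 3D medial-axis thinning on the voxel lattice
  with 26-connectivity for the object and 6-connectivity for the
  background. Simple points (deletable without changing local topology,
  in the standard digital-topology characterization) are removed in six
  directional subiterations per pass, with sequential re-checking inside
  each subiteration, so the result is deterministic. Endpoints — voxels
  with a single neighbor — are preserved, keeping the tips of open axon
  segments.
* **Anisotropy.** Native voxels are 5.3 × 5.3 × 5 µm. Thinning operates on
  the voxel lattice and ignores this mild anisotropy; the voxel size is
  carried in metadata and used for any physical-unit conversion.
* **Weights downstream.** Every skeleton voxel counts as exactly one
  axon-containing voxel regardless of its weight. The weight exists to
  rescue dim axons during construction and is retained as metadata only;
  all densities are binary voxel counts per cell.

Artifact control follows two stages: connected components (26-connectivity)
with fewer than 10,000 voxels are removed automatically (the rule is
strictly "less than", so a 10,000-voxel component survives), and the
handful of remaining components can be kept or dropped through an explicit
curation table that is persisted in the output provenance.

## Atlas mapping with exact count conservation

Skeleton voxels become a coordinate list, are scaled to physical
micrometres, passed through the native-to-atlas transform chain (a 4 × 4
affine, a trilinearly interpolated displacement field, or both — estimating
the registration itself is out of scope), divided by the 25 µm atlas voxel
size, and binned. Two conventions are fixed deliberately:

* **Rounding.** Real-valued atlas coordinates are rounded half-up per
  axis. Any rule conserves counts; reproducibility requires choosing one,
  and half-up treats the half-voxel boundary symmetrically.
* **One count, one voxel.** Each native axon voxel increments exactly one
  atlas voxel (no trilinear splatting), so the atlas voxel value is the
  number of original-resolution axon-containing voxels it received.
  Out-of-grid coordinates are tallied, never silently dropped, giving the
  exact invariant: skeleton voxels = grid total + out-of-bounds tally.
  This invariant is asserted across the pipeline and reported by the
  acceptance script (observed error ~1e-14, i.e. float bookkeeping only).

Densities are then normalized per labeled neuron (counts divided by the
number of fluorescently labeled cells at the injection site), making
samples with different infection efficiencies comparable. Injection-site
quality control computes the unweighted mask centroid and the fraction of
mask voxels inside SSp-bfd or SSs (descendants included, so cortical layers
count); samples with fraction ≥ 0.8 are included, and the rule is
inclusive at exactly 0.8. Excluded samples are still written, flagged
`included = FALSE`, for auditability.

**Midline bucket.** Source material rarely states how voxels exactly on
the sagittal midplane were assigned. Here, voxels within half a voxel of
the midline go to a separate "midline" bucket, excluded from ipsi/contra
totals, so ipsi + contra + midline (+ unassigned) partitions every total
exactly. The choice is recorded in output metadata.

## Region tables, rollup and ranking

Every atlas voxel's density accrues to its annotation leaf structure
(e.g. `MOp5`) and hemisphere relative to the injection side. Voxels with
annotation id 0 form an "unassigned" row, so region tables partition the
map total exactly — a property tested at every rollup level. Rolling up
one level replaces each leaf by its immediate parent (individual cortical
layers sum into their region); where a real atlas interposes intermediate
nodes, "one level" means the immediate parent, and deeper rollups compose
(`rollup(rollup(t, 1), 1) = rollup(t, 2)`). Ranking averages axon totals
over all group averages and both hemispheres, sorts descending (ties
broken by acronym for determinism) and keeps the top 75 regions; midline
and unassigned buckets never enter the ranking.

## Correlation matrices

Two complementary similarity analyses across injections:

* **Categorical**: each sample is the vector of per-structure axon totals
  at the finest parcellation level. The ipsi and contra hemispheres are
  kept as separate vector entries, since the region tables tabulate them
  separately; pooling them is the main alternative reading and would mix
  distinct projection classes (e.g. crossed versus uncrossed pathways).
* **Spatial**: each 25 µm density map is filtered with an isotropic 3D
  Gaussian (σ = 4 voxels), flattened, and correlated voxel-wise, using no
  parcellation information.

Both use Pearson correlation. Samples are ordered first by transgenic line
(in a configured canonical order) and then by |ML| of the injection
centroid, most medial first. A sample whose vector has zero variance gets
`NA` correlations and a warning — never a silent zero. Gaussian boundary
handling is half-sample reflection, which avoids attenuating map edges;
σ = 0 reduces exactly to the raw-voxel correlation, which the tests
exploit by comparing against an independent direct convolution and
two-pass covariance implementation.

## Motor-cortex hotspot topography

Axons in layers 2/3 and 5 of MOp and MOs are summed along the
dorsoventral axis into a horizontal map, Gaussian-filtered (σ = 4 pixels of
25 µm), and summarized:

* the pixel set ≥ 75 % of the filtered maximum, whose area (pixel count ×
  (25 µm)²) measures the horizontal spread of the innervation;
* the pixel set ≥ 95 % of the maximum, whose **unweighted** centroid — all
  supra-level pixels, even if disconnected — is the hotspot location
  (an intensity-weighted variant is a one-line change but the unweighted
  reading is the simplest faithful one);
* the mean of the **filtered** map in a 225 × 225 µm (9 × 9 pixel) window
  centered on the peak pixel, converted to axon voxels per mm² per
  neuron, as the peak innervation density. The peak is defined on the
  filtered map, so the ROI is measured there too; ties at the maximum are
  broken by the first position in the array's column-major scan order
  (relevant only for degenerate synthetic inputs).

For a Gaussian spot of spread $\sigma_0$ pixels, filtering gives an
effective spread $\sqrt{\sigma_0^2 + \sigma_f^2}$ and the 75 % area has
the closed form $2\pi(\sigma_0^2+\sigma_f^2)\ln(4/3)$ px²; the tests verify
the pixel-count area against this and against a dense-grid enumeration,
and the centroid against the known center to half a pixel.

An all-zero MO map (a sample with no axons in MO, which occurs in real
cohorts) produces a no-hotspot result whose metrics are `NA`; downstream
regressions drop such samples. The topography fit itself is ordinary least
squares of hotspot AP on injection |ML| with the Pearson correlation and
its two-sided p-value on $n-2$ degrees of freedom.

Caudoputamen axis profiles mask the density map to CP, filter (σ = 4) and
extract summed-density curves: AP and DV from the ipsilateral hemisphere
only, ML bilaterally, all in bregma-referenced millimetres.

## Wide-field functional mapping

Sessions hold trials × frames × pixels movies with frame times relative to
stimulation onset. All temporal selection is by timestamp, never by frame
index, because acquisition alternates rates around the stimulus (e.g.
100 Hz peri-stimulus, 50 Hz interleaved during stimulation). The chain is:
2 × 2 mean binning (320 × 256 → 160 × 128 pixels, 31.25 → 62.5 µm);
per-trial ΔF/F₀ with F₀ the mean image over the 300 ms before onset
(non-positive F₀ pixels become `NA` and are tallied); evoked maps as the
mean over 10–260 ms and over each stimulation point's trials; population
maps as trial-count-weighted averages; and localization as the
value-weighted center of mass of pixels ≥ 80 % of the within-mask maximum
inside a 40 × 25 pixel frontal rectangle placed relative to bregma. Two
ambiguities are resolved by documented defaults: the center of mass is
value-weighted (not binary) over the supra-threshold set, and the 80 %
threshold references the within-mask maximum. The stimulation-site
regression pools (|stim ML|, response AP) points across mice for the
population line and fits per-mouse lines for mice with at least two
distinct stimulation positions.

## The synthetic-data module

The generators produce every input with complete ground truth:

* **Toy atlas** — a compact mirror-symmetric parcellation (MOp, MOs,
  SSp-bfd, SSs with L1/L2-3/L5/L6 stacked along DV, plus CP) on a
  160 × 60 × 160 grid of 25 µm voxels spanning roughly bregma +2.5 to
  −1.5 mm. The voxel size matches the real atlas; the extent is kept
  modest so that full cohorts simulate in well under a second each.
* **Axon phantoms** — Gaussian-profile tubes around known polyline
  centerlines (composed by maximum, so joints are not double-counted),
  bright spherical artifact blobs near the volume edge, additive Gaussian
  noise, clipped to [0, 1]; deterministic per seed.
* **Injection cohorts** — per sample: a cuboid injection mask in SSp-bfd
  or SSs at a requested |ML|, a labeled-cell count drawn uniformly from
  200–1200 (the order of magnitude of real injections), and an integer
  axon-voxel budget (80 voxels per cell) sampled multinomially from a
  Gaussian hotspot (σ = 6 pixels = 150 µm) restricted to layers 2/3 and 5
  of MO and centered at $AP = 0.9 + 0.5\,|ML| + \varepsilon$ mm,
  $\varepsilon \sim N(0, 0.1\ \mathrm{mm})$. Because the budget is
  sampled, density total × cell count reproduces it exactly — the
  bookkeeping oracle used in the tests. Cohorts are generated directly in
  atlas space; the native-resolution stages (thinning, transformation,
  binning) are exercised end-to-end by the tube phantoms combined with a
  known affine instead, which separates skeletonization fidelity from
  registration plumbing.
* **Wide-field sessions** — baseline F₀ = 100, separable Gaussian-in-space
  (σ = 4 binned pixels), boxcar-in-time (0–300 ms) responses of amplitude
  0.05 ΔF/F at centers obeying $AP = -0.75 + 0.5\,|\mathrm{ML_{stim}}|$
  for stimulation points at |ML| 3.0–4.5 mm in 0.5 mm steps, plus one
  per-session AP offset drawn from $N(0, 0.1\ \mathrm{mm})$ emulating
  between-mouse map variability, and per-pixel frame noise (SD 0.5, i.e.
  0.5 % of baseline). Because every mouse contributes all stimulation
  points, the per-mouse offset shifts intercepts but leaves the pooled
  slope estimate unbiased.

What the phantoms deliberately do **not** model: photon statistics and
shot noise, scattering and depth-dependent blur, registration error beyond
a single affine, axon morphology beyond tubes (boutons, fasciculation),
and hemodynamic or stimulation artifacts in the wide-field movies.
Passing tests therefore demonstrate that the analysis code implements its
stated mathematics and recovers known generative parameters through the
full chain — not that the upstream segmentation or registration of real
data is accurate.

## Numerical choices and degenerate inputs

* Gaussian kernels are truncated at 4σ and renormalized; boundaries are
  half-sample reflected.
* Binning rounds half-up; the midline bucket is ±0.5 voxel.
* Empty probability volumes skeletonize to empty skeletons (not errors);
  empty injection masks, regressions with fewer than 3 finite points or
  zero |ML| variance, and evoked maps with zero trials are errors.
* Replicated analyses use seeds derived from one base seed by a stable
  per-stage hash, so adding a pipeline stage never perturbs earlier draws.

## Problem sizes

The shipped tests and the acceptance script run, per invocation: five 50³
phantom volumes through the eight-threshold skeleton oracle; cohorts of 7
injections on the 1.5-million-voxel toy atlas (200 replicates for the
slope-recovery coverage checks); and wide-field cohorts of 6 mice × 4
stimulation points (full 160 × 128 geometry for single-session checks,
48 × 40 at 20 Hz for the replicated recovery simulations). These sizes were
chosen so a complete run stays in the minutes range on one CPU while every
stage is still exercised end-to-end.

## Known limitations

* The thinning algorithm is a standard simple-point procedure, not a
  reimplementation of any specific published variant; different valid
  medial-axis algorithms produce slightly different (equally valid)
  skeletons, which is why the equivalence oracle shares the thinning
  primitive and checks the weighted accumulation around it.
* Real structure graphs contain intermediate nodes at varying depths, so
  "one level up" can land at different granularities across branches;
  rollup uses the immediate parent and documents it.
* Wide-field movies are held in memory; very long sessions should be
  chunked by trial before calling `compute_dff()`.
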