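---
title: "cycim: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cycim: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycim)
```

## The analysis problem

Cyclic (sequential-round) multiplexed immunofluorescence images many more
protein markers than the four-fluorophore spectral limit allows: antibodies
carry short DNA docking strands, fluorophore-bearing imager strands hybridize
to them, two probe markers are imaged per round, and a low-salt wash releases
the imagers before the next round. Two persistent stains — a nuclear dye and
actin phalloidin — are imaged in every round and serve as fiducials.

`cycim` implements the downstream analysis for such experiments on
iPSC-derived neural cultures: align the rounds, segment and track cells,
quantify each marker per cell, call per-marker positivity, and combine the
calls through a rule tree into cell classes (neurons and their synaptic
subtypes, astrocytes, radial glia, neural progenitors, residual pluripotent
cells), reporting a culture composition table with explicit exclusion
accounting. A ground-truthed synthetic image generator makes the entire
chain testable without any external data.

## Registration

Rounds are repeated acquisitions of a fixed well, so misalignment is
dominated by stage drift and modeled as a rigid translation. Shifts are
estimated by phase correlation on each fiducial channel, refined to
subpixel precision by evaluating the cross-correlation on an upsampled grid
around the integer peak (matrix-multiply DFT, default 1/20 px resolution).
The nuclear and actin estimates are combined by quality-weighted averaging
(default weights 0.5/0.5 — the protocol names both channels without
precedence), and the single combined shift is applied to every channel of
the round by bilinear interpolation with background fill. First-order
interpolation was chosen over higher-order schemes to avoid ringing in
low-signal probe channels. A round whose fiducial correlation after
alignment falls below `quality_floor` (default 0.5) is flagged but still
reported. On synthetic fixtures with drift SD up to 10 px and fiducial SNR
well above 5, all shifts are recovered within 0.5 px (50 seeded trials in
the acceptance suite; typical error is below 0.05 px).

## Segmentation and tracking

Nuclei: Otsu threshold (configurable to fixed or median + k·MAD) followed by
a distance-transform watershed seeded at distance-map peaks, so touching
nuclei with distinct peaks split; regions outside `[min_area, max_area]`
(default 10–400 px²) are discarded. Cell bodies: seeded watershed on
inverted actin intensity, each nucleus expanding over above-threshold actin
to at most `max_expand` px (default 10) from the nucleus; the nucleus is
always contained in its cell.

Cells are tracked across rounds by greedy nearest-centroid matching under
`max_centroid_distance` (default 10 px, post-registration), with a total
deterministic order (ascending distance, then record id, then detection
label) — reproducibility was preferred over assignment optimality, and at
realistic densities the greedy matching equals the brute-force optimum
(property-tested). Only cells present in **all** rounds are analyzed; cells
touching the field border are also excluded by default because their
intensities are partially measured. Both exclusions are counted, and
`analyzed + excluded = sampled` is an invariant of the composition table.

## Quantification

Per-cell marker measurement reports mean, median and integrated intensity
plus background-corrected variants floored at zero (negative corrected
intensities would break monotone thresholding). Background defaults to the
median over pixels outside all cell regions.

**Robust gating intensity.** The pipeline does *not* gate on the whole-cell
corrected mean. In dense neural cultures, neurites from neighbouring
neurons transit other cells' regions; on the synthetic standard fixture
this inflates whole-region means enough to turn a third of the
filament-marker-negative glia falsely positive. The pipeline instead reads
each marker at a perinuclear *soma core* (the nucleus dilated by
`core_dilate` = 3 px) and uses the corrected 25th percentile
(`intensity_quantile`) as the gating statistic: a transiting process must
cover most of the core to flip a low quantile. For filament-kind markers,
ridge-like pixels (see below) are additionally excluded from the core
before the quantile is taken — a neighbour's process is a ridge, a cell's
own somatic cytoplasm is flat. With these two measures, per-class
composition error on the standard fixture drops from ~9–23 to ≤3
percentage points over 20 seeds.

**SNR** follows the conventional definition: the mean over n = 6 signal-ROI
means divided by the mean over n = 6 background-ROI means. ROI placement is
auto-proposed (top-6 regions by mean intensity; 6 seeded random background
patches) when not supplied, since only n, not placement, is conventionally
specified. **Pearson correlation** between a cyclic-imaging stain and its
conventional immunofluorescence control is computed pixel-wise, whole-field
by default with an optional mask (whether published values used masks is
unknowable; both are supported). **Washout residual** checks that a
post-rinse control image's mean is within `tolerance_fold` (default 1.5×)
of the pre-stain background, confirming imager-strand removal between
rounds.

**Puncta** are counted by scale-normalized Laplacian-of-Gaussian detection
(default sigma 2 px, prominence 3× the image MAD) with plateau maxima
merged; counts are translation-invariant. **Filament score** is a Hessian
ridge analysis: a pixel is *active* if above background plus a noise
margin, and *ridge-like* if it lies on a bright anisotropic intensity crest
— principal curvature negative, curvature anisotropy above 0.6, and
gradient small relative to curvature. The gradient condition is what
separates genuine crests (gradient ≈ 0) from the boundaries of isotropic
blobs, which are anisotropic in curvature but sit on a steep gradient. The
score is the fraction of active pixels that are ridge-like: a documented
monotone map onto [0, 1] that is exactly 0 on blank or pure-noise regions.
A logistic of the mean ridge response was considered and rejected: it needs
an absolute intensity midpoint the protocol does not define, and cannot
return exactly 0 on blank input. Because somatic signal dilutes the ridge
fraction, realistic neuron regions score ~0.2 against ~0.05 for diffuse
cells, and the default structural gate is a deliberately modest 0.1.

## Threshold derivation and gating

Per-marker positivity thresholds are data-driven by default
(`method = "otsu"`), with `kmad` (background + k·MAD) and `fixed`
alternatives. The default is an *Otsu-anchored two-sided rule* on the raw
corrected intensities: the Otsu split is only an anchor, and the final
threshold is `max(0.25 × upper-class mean, lower-class median + 3 MAD)`.
Two findings drove this. First, a log1p transform (a natural first choice)
interacts badly with corrected intensities floored at zero — the zero spike
and the compressed positive mode pull the split inside the negative mode.
Second, structural markers have broad positive modes (neurite geometry
varies per cell), so a plain Otsu split can land *inside* the positive
mode; anchoring the threshold at 25% of the positive-mode level and just
above the negative mode is robust to both.

An **absent-marker guard** (`rel_floor`, default 0.25) handles markers not
expressed in the culture at all (e.g. Oct4A in a differentiated culture):
all channels share one intensity scale, so a marker whose upper-mode mean
falls below 25% of the panel-median upper-mode mean is called all-negative
rather than split inside its noise. The guard prefers false negatives
because the classification is all-markers-positive: one false positive on a
required-negative marker silently reassigns a cell. Its known limitation is
a marker genuinely positive in essentially *every* cell **and** dim relative
to the rest of the panel — not a configuration the default panels produce —
and it is disabled for single-marker tables.

Classification evaluates rules in priority order; the first class whose
required-positive markers are all positive and required-negative all
negative wins. Subtype rules are listed before their parent, so a
Tuj1+/MAP2+ cell with neither VGLUT1 nor VGAT stays a generic `neuron`
(synaptic type unresolved) rather than being dropped. Unmatched cells are
counted as `unclassified`, never silently removed. The engine is
property-tested against a brute-force rule interpreter over all 2^10
positivity vectors. Structural gates (puncta ≥ 3 for Synapsin, filament
score ≥ 0.1 for Tuj1) ship as an opt-in variant
(`cortical_ruleset(structure_gates = TRUE)`) because the published class
signatures are intensity-based; the gates exist to suppress bright-but-
amorphous staining artifacts. One documented ambiguity: the published
immature-astrocyte signature is CD44+ at one timepoint and CD44− at
another; the default keeps CD44+ and the rule set is fully overridable
(JSON round-trip via `read_ruleset()`/`write_ruleset()`).

## The synthetic generator: what it emulates, what it does not

`simulate_culture()` + `render_round_stacks()` produce the world the
analysis assumes: 5 rounds × (2 fiducial + 2 probe) channels; 10 probe
markers; classes drawn from a seeded multinomial; marker expression derived
mechanically from the gating rules (required-positive at `separation` ×
`baseline_expression`, default 10 × 30 AU, everything else baseline, with
CV-0.2 lognormal per-cell variation); nuclei as Gaussian blobs (σ 3 px),
somata as flat-topped disks (radius 6 px), neurites as random-walk
polylines (2–4 per neuron, 25–60 px) carried by the actin and filament
channels, puncta as 2.5-px Gaussian spots confined to the soma; per-round
Gaussian drift (`drift_sd`, default 2 px) rendered analytically at shifted
positions (exact subpixel ground truth); geometric per-round detachment
(default 2%); constant background (100 AU) plus additive Gaussian noise
(default 15 AU ≈ 5% of the positive level; Poisson optional). Cytoplasmic
filament proteins stain somata at full expression level, matching real
β-III-tubulin micrographs.

Deliberate stress: at 500 cells per 512×512 field the neurite meshwork
covers a large fraction of the field, so cross-cell contamination is the
dominant error source — this is what forced the robust core-quantile
measurement above. Not emulated: optical PSF and chromatic effects,
photobleaching, 3D structure, spectral crosstalk, autofluorescence
gradients, segmentation-hostile cell shapes. A green end-to-end test
therefore establishes that the chain is correct under the stated noise,
drift, detachment and crosstalk model — not that it would meet the same
tolerance on arbitrary real micrographs.

Intensities are arbitrary floats clamped to [0, 65535] and quantized to
16-bit on TIFF export; fixture bundles round-trip exactly at integer
precision. The TIFF layer is a minimal baseline uncompressed 16-bit
grayscale reader/writer implemented in the package because no TIFF package
is available in the supported environment; it was cross-validated against
an independent TIFF library during development. Configs, manifests and rule
sets are JSON.

## Strand design

Docking/imager pairs are exact reverse complements, 11–12 nt with GC
0.30–0.40 (the published optimum for salt-cycled imaging strands). Melting
temperatures use two-state nearest-neighbor thermodynamics with the unified
DNA/DNA parameter set (SantaLucia 1998) and the entropic salt correction
`ΔS(Na+) = ΔS(1M) + 0.368·N·ln[Na+]`; the model and buffer assumptions are
attached to every Tm as metadata. The Tm window (20–50 °C) at 500 mM
monovalent salt and 500 nM strand concentration are *conventions* — the
protocol cycles strands by salt concentration but publishes no numeric Tm
targets — and are labelled as such. Panels are designed by seeded rejection
sampling; orthogonality requires the longest complementary contiguous run
between any strands of two different pairs to stay ≤ 6 nt (checked in
tests by an independent naive substring oracle). LNA thermodynamics are out
of scope.

## Numerical and degenerate-input choices

- Constant fiducials error with "no fiducial structure"; constant inputs to
  Pearson error with "zero variance"; zero background errors for SNR and
  washout ratios (undefined), while blank images segment to zero labels
  (valid empty result).
- Watershed flooding uses 4-connectivity with FIFO tie-breaking on equal
  elevation, so labels are deterministic; component labelling assigns ids in
  raster order.
- All generator and pipeline randomness flows from single integer seeds via
  a local-RNG helper that never perturbs the caller's RNG state.
- `summarize_composition()` enforces Σ counts = analyzed and
  analyzed + excluded = sampled exactly.

## Known limitations

- Translation-only registration: rotation, scale and nonrigid deformation
  are out of scope by design.
- The greedy tracker can mis-pair cells closer than `max_centroid_distance`
  under extreme drift between consecutive rounds.
- The absent-marker guard assumes at least one well-expressed marker in the
  panel (see above).
- The filament score's absolute scale is a pipeline convention; compare
  scores only within a processing configuration.
- Supplementary per-cell tables from the source study are not bundled;
  `run_gating_from_table()` provides the documented schema and
  column-mapping layer to reanalyze them when available.
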