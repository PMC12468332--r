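---
title: "Microwave breast imaging with mwbim: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microwave breast imaging with mwbim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwbim)
```

## The problem

Microwave breast imaging (MWBI) images the breast with low-power
electromagnetic waves in the 0.8--4.1 GHz band, exploiting the dielectric
contrast between lesions and the surrounding tissue. The scanner emulated
here is a 21-probe circular array around a pendulous breast immersed in a
lossy transition liquid; the array steps vertically in 2 mm increments, and
at each height every probe transmits while the others receive, yielding a
multistatic S21 matrix per frequency and slice. The uppermost scan position
sits 24 mm below the examination table.

`mwbim` implements the full desk-scale computational chain: a synthetic
scan generator, the preprocessing scheme, sectorized wideband TR-MUSIC
reconstruction under parametric tissue-composition assumptions, ROI
extraction, a 25-feature radiomic characterization, and the
malignant-vs-benign separability and false-positive analyses. No clinical
data are used anywhere; every input is synthesized by the package.

## The forward model

The scan generator works under the Born approximation: every lesion voxel
within the ±2 mm slab of a scan height is an independent point scatterer,
and a bistatic channel response is the contrast-weighted sum of two-way
two-media Green's functions,

$$ S_{21}(i,j,f) = \sum_v c_v\, G(p_i \to v, f)\, G(v \to p_j, f), \qquad
   G = \frac{e^{-(\alpha + i\beta)(d_\mathrm{out} + d_\mathrm{in})}}{d}, $$

with the lossy propagation constant of each medium

$$ \alpha = \frac{2\pi f}{c_0}\sqrt{\frac{\varepsilon_r}{2}
   \left(\sqrt{1+\tan^2\delta} - 1\right)}, \qquad
   \beta = \frac{2\pi f}{c_0}\sqrt{\frac{\varepsilon_r}{2}
   \left(\sqrt{1+\tan^2\delta} + 1\right)}. $$

The straight ray from probe to voxel is split at the breast envelope into an
out-of-breast leg (transition liquid) and an in-breast leg whose medium is
the `pc_fib`-weighted mixture of adipose and fibroglandular dielectric
profiles; `pc_fib` is the assumed fibroglandular fraction of the interior.
Reciprocity holds exactly before noise and the monostatic diagonal is absent,
as in the physical system. Three artifact terms can be injected: a
frequency-smooth inter-probe coupling common to all channel pairs (by default
about 30 dB above a nominal lesion echo), a specular skin reflection with its
delay set by the envelope, and an optional localized skin-fold echo. Noise is
circular complex Gaussian scaled relative to the pre-noise RMS.

The dielectric table is configurable because the physical transition liquid's
profile is not published; the defaults (transition liquid
$\varepsilon_r \approx 23$, $\tan\delta \approx 0.13$; adipose 4.5/0.12;
fibroglandular 35/0.25; all mildly dispersive) sit in the range reported by
the microwave tissue-dielectric literature. Lesions carry a bulk contrast
multiplier (default presets 3.5, consistent with tumor-to-mixed-tissue
permittivity ratios) and, for the malignant-like preset, a spatially
correlated (~4 mm) interior heterogeneity field plus spiculation and surface
roughness; the benign-like preset is a smooth homogeneous ellipsoid.

## Preprocessing

Each channel spectrum is converted to the time domain by inverse DFT (the
measured spectrum is one-sided, so the result is the analytic signal
directly), with 4x zero-padding and a Tukey 0.25 spectral taper that keeps
the range sidelobes of strong early echoes from leaking across the distance
axis. The time axis is annotated with one-way distance at the
transition-liquid velocity.

*PCA coupling removal.* The channels of an extended probe group around each
imaging sector (N_PCA = 12 probes by default, 10 under the CUSTOM2 mode)
are stacked and the leading principal component subtracted. The chain groups
the channels by Tx--Rx probe separation and removes the leading component
per ensemble: the coupling is identical across all pairs, while the skin
reflection is (nearly) identical only within an equal-separation ensemble,
so the grouped removal also captures the surface bounce (the classical
rotation-subtraction idea), while lesion echoes, whose delays vary quickly
from pair to pair, survive. The exported `pca_coupling_removal()` keeps the
ungrouped single-ensemble behaviour as its default.

*EMD and distance filtering.* The real part of each cleaned channel is
decomposed into intrinsic mode functions by classical sifting
(standard-deviation stop criterion 0.2, at most 10 sifting passes and 10
IMFs; completeness is exact by construction). Each IMF is annotated with the
distance of its dominant echo and dropped when it peaks in the probes'
immediate vicinity (< 10 mm, residual coupling) or at unrealistically long
distances (beyond ring diameter + 2 max chords, multipath). The residual is
classified the same way: short gated packets can carry most of their energy
there. The far end of the distance axis (last 5%) is always cut as an IDFT
wrap guard.

*Propagation loss compensation.* The published compensation is a
multiplicative frequency-domain term $e^{\alpha_\mathrm{trans} d_\mathrm{out}
+ \alpha_\mathrm{in} d_\mathrm{in}}$ per echo, with $\alpha_\mathrm{in}$ the
`pc_fib`-weighted mixture; `loss_multiplier()` implements exactly this. The
chain applies it as a per-sample time-localized gain: over a 3.3 GHz band the
attenuation disperses strongly and deep echoes red-shift, so the gain inverts
the band-integrated envelope-peak decay (for a nonnegative model spectrum the
IDFT envelope peak equals the spectral mean, giving a closed form), with the
in-breast leg rescaled from annotated to physical length by the velocity
ratio, plus quadratic spreading correction. For an isolated echo this
coincides with the published multiplier; unlike a per-IMF constant it also
equalizes several echoes of different depths sharing one IMF.

*Amplitude filter.* The integrated PSD of a channel (its energy, by
Parseval) is normalized by the median channel energy of an empty-container
calibration scan, so the fixed threshold 5 is dimensionally meaningful on
synthetic data; channels at or above it are dropped. This normalization
convention is ours.

*Modes.* DEFAULT (N_PCA 12, amplitude filter on), CUSTOM1 (amplitude filter
disabled; very small breasts or large superficial lesions, where the fixed
threshold over-filters), CUSTOM2 (N_PCA 10; very large breasts, skin folds,
extreme density, where more severe common-mode filtering helps).
`select_mode()` applies rule-based attribution with configurable volume
thresholds (350 / 1300 mL defaults).

## Sectorized TR-MUSIC imaging

A contiguous 8-of-21 probe sub-array is formed around every centre probe
(3 left / 4 right, wrap-around). Per frequency, the 8x8 multistatic matrix
has its absent monostatic diagonal restored by iterative low-rank completion
(alternate a rank-truncated SVD with diagonal replacement until the diagonal
converges), which is the reciprocity-consistent interpolation that restores
exact subspace structure for low-rank data. The signal-subspace rank is the
largest relative singular-value gap, capped at 4. The pseudospectrum is

$$ P(\mathbf r) = \left(\sum_{k > r} |\langle u_k, g(\mathbf r)
   \rangle|^2\right)^{-1}, $$

with unit-norm steering vectors from the same two-media straight-ray model
as the simulator; wideband fusion is the incoherent mean of per-frequency
unit-max pseudospectra.

Images are formed per azimuthal sector under each candidate `pc_fib` of the
active search range (5-point grid by default). The best-fitting assumption
per sector maximizes the peak-to-mean focus score; the comparison runs on
uncompensated spectra with attenuation-matched steering, because the
exponential compensation envelope tilts packet group delays and would bias
the selection towards higher permittivity. Candidates within 2% relative
focus of the best are treated as ties and resolved towards the range
midpoint, so sectors without focusing evidence fall back to the least
informative assumption. The selected assumption's final image is built from
compensated data with phase-and-spreading steering. The 21 partially
overlapping sector images (each 8-probe arc plus a 10 degree raised-cosine
margin) are stitched by taper-weighted averaging of unit-max-normalized
images (a partition of unity over the covered disc), raised to a power
`gamma = 3` (pseudospectra carry a compressed dynamic range; detection and
contrast metrics operate on the power-rendered image), and stacked into a
volume with triangular ±2 mm slab weights.

The full 3D image is produced once per search range of the published
11-range set ({10:30, 20:40, 30:50, 40:60, 50:70, 60:80, 70:90, 20:50,
50:80, 10:60, 40:90} percent), and three composites are averaged from them:
GLOBAL (all 11), LOW (the 4 ranges entirely at or below 50%) and HIGH (the
4 entirely at or above 50%). The GLOBAL composite is the default analysis
volume.

The reconstruction support excludes a 6 mm interior margin below the
envelope: residual surface reflections image onto the skin shell, and
surface blobs belong to the recognized artifact categories rather than the
analyzable interior.

## ROI extraction and radiomics

Candidates are segmented by thresholding the in-breast voxels below the
cut-out plane -- Otsu by default at the operation level, a fixed intensity
quantile (default 0.90 in the pipeline configuration) as the
config-overridable alternative that is robust across pseudospectrum
histograms -- followed by a morphological opening and closing with a 1-voxel
ball and 26-connected labelling. A candidate is persistent when a centroid
match within 5 mm exists in a quorum of the per-range volumes (majority, at
most 6). Validated ROIs must pass volume (0.25 mL), solidity (0.3, voxel
volume over the convex hull of the corner points) and CNR (2) gates; SNR and
CNR use the in-breast background outside all candidates dilated by 2 voxels.

The 25-feature vector per ROI comprises 4 shape, 7 first-order, 9 GLCM and
5 NGTDM features with fixed-bin-number 64 quantization over the ROI min-max
range. GLCM uses the 13 unique 3D directions at distance 1, symmetrized and
normalized per direction, features averaged over directions; NGTDM uses
valid 26-neighbourhoods with a 1e-6 coarseness guard; kurtosis is
uncorrected (normal = 3). Surface area for sphericity uses exposed voxel
faces scaled by 2/3 (the orientation average of $|n_x|+|n_y|+|n_z|$ for a
smooth patch is 3/2); solidity and sphericity are capped at their
theoretical maximum of 1 on the digital lattice. All formulas follow the
standard radiomics definitions and every feature is pinned to brute-force
enumeration oracles in the tests.

## Separability and the false-positive workflow

Per-feature separability between labelled classes is the one-way ANOVA F
statistic with its upper-tail p-value. The unspecified-findings workflow
retains, per symptomatic case, the non-clinical ROIs whose mean intensity is
at least 0.9 of the detected index lesion's ("comparable or superior"; the
factor is configurable since the published criterion is qualitative), places
malignant and benign centroids in the standardized space of the three most
discriminative features (first-order entropy, GLCM joint entropy, NGTDM
strength), assigns each retained finding to the nearer centroid, and reports
`100 * n_confused / n_healthy_breasts`. Standardization is fitted on the
lesion rows only, before classification. The nearest-centroid rule is our
quantitative stand-in for what was a visual scatter-plot assessment.

## Validation experiment sizes

The package's validation experiments are sized for a desk run: 64 x 64
voxel slices, 6--34 frequency points depending on the experiment, and
single-slice reconstructions for the localization and assumption-recovery
experiments. The end-to-end cohort experiment uses 10 + 10 single-lesion
breasts on a 48 x 48 lattice, 5 coronal slices, 12 frequencies and three
pc_fib search ranges; per-class lesion sizes are drawn from the detected
maximal linear dimensions reported for the respective clinical lesion
classes, so the synthetic cohort mirrors the size structure of the clinical
one. The point-scatterer experiments use a clean calibration-target
configuration (artifact terms disabled), as for a physical point-spread
measurement in a test tank; the 20 dB SNR condition is relative to the
scattered signal.

## What the generator does and does not emulate

The simulator reproduces the geometry (21 probes, 2 mm steps, 24 mm table
offset, pendulous envelope in a lossy liquid), the two-media lossy
propagation, the coupling / skin / fold artifact structure, reciprocity,
and dispersive attenuation. It does not model multiple scattering, antenna
patterns, ductal or vascular anatomy, real surface reconstruction from
radar, or patient positioning variability. Passing tests therefore
demonstrate the chain's internal correctness and its behaviour under
Born-level physics, not clinical performance.

## Known limitations

* Under the Born model with subspace imaging, the pseudospectrum is a
  geometric quantity: its value at a voxel measures steering-vector
  alignment with the signal subspace, not local reflectivity. In matched
  experiments (same lesion size and position, classes differing only in
  interior heterogeneity and surface texture), the intra-ROI image texture
  is dominated by aperture and stitching interference common to both
  classes -- even with artifact terms and noise disabled -- and the 2--4 mm
  interior heterogeneity of the malignant-like preset does not transfer
  into ROI texture at the chain's ~10 mm resolution. Consequently the
  end-to-end malignant-vs-benign separability experiment computes the full
  feature and ANOVA analysis but does not, in this emulation, produce
  strong texture-feature separability between the classes; the package
  reports the statistics it actually measures. This is a property
  of the Born + noise-subspace pseudospectrum emulation, in which image
  amplitude is not proportional to local tissue reflectivity, and is the
  main known gap between the synthetic chain and the physical system.
* The digital solidity of smooth round masks underestimates 1 (corner-point
  hull versus voxel volume, about 0.84 for an 8-voxel-radius ball); ordering
  between smooth and spiculated shapes is preserved.
* The assumption-recovery rate is measured on a compact scatterer; extended
  lesions blur the per-sector focus comparison.
* Per-slice 2D propagation within ±2 mm slabs ignores cross-slab leakage.
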