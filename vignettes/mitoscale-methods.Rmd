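---
title: "mitoscale: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitoscale: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoscale)
```

# Scope

Budding yeast keeps its mitochondrial DNA (mtDNA) copy number roughly
proportional to cell volume. `mitoscale` packages the quantitative machinery
needed to measure and explain that scaling:

1. a **steady-state model** of mtDNA homeostasis in which the nuclear-encoded
   maintenance machinery (the polymerase Mip1 and the packaging factor Abf2)
   is limiting;
2. an **image pipeline** that counts nucleoids and measures mitochondrial
   network volume per cell in two-channel 3D confocal stacks;
3. a **qPCR calculus** turning quantification-cycle (Cq) tables into mtDNA
   copies per nuclear genome, per cell, and per femtolitre;
4. **scaling statistics** (binned means ± s.e., linear fits to replicate
   means, constant-amount expectation ratios, copies-per-nucleoid,
   flow-cytometry background subtraction);
5. **synthetic-data generators** that emit ground-truthed microscopy stacks,
   qPCR plates, and cell populations, so that every stage of the analysis is
   testable without any external data.

Cell segmentation, deconvolution, skeletonization and raw Cq calling are out
of scope: cell masks, Cq tables and population summaries are inputs.

# The limiting-factor model

The mtDNA concentration $n$ obeys

$$\frac{dn}{dt} = k_R\,\frac{m}{K_1 + m/n}
               \;-\; k_D\,\frac{n}{K_2 + a/n}
               \;-\; \frac{n \ln 2}{T},$$

with $m$ the Mip1 concentration, $a$ the Abf2 concentration, $K_1$ the
Mip1–mtDNA dissociation constant, $K_2$ the degradation saturation constant,
and $T$ the population doubling time. Replication saturates with the
polymerase-per-mtDNA ratio; degradation is stoichiometrically suppressed by
DNA-bound Abf2; dilution follows exponential growth. Concentrations share one
arbitrary unit and times another; the model predicts ratios, not absolute
numbers.

Setting $dn/dt = 0$ and clearing denominators gives
$A n^2 + B n + C = 0$ with

* $A = K_1 K_2 \ln 2 + k_D K_1 T$
* $B = a K_1 \ln 2 - K_2 m k_R T + K_2 m \ln 2 + k_D m T$
* $C = a m \ln 2 - a m k_R T$.

Some presentations of this polynomial write the rate constants as $K_D$ and
$K_R$; re-deriving the expansion symbolically shows these are the same
constants $k_D$, $k_R$ of the rate equation, and `mitoscale` treats them so.

**Existence and uniqueness.** $A > 0$ always. $C < 0$ exactly when
$k_R T > \ln 2$; in that case the product of the roots $C/A$ is negative, so
exactly one root is positive and `steady_state()` returns it (via the
numerically stable citardauq form). When $C \ge 0$ every coefficient is
non-negative, no positive root exists, and the only non-negative fixed point
is extinction, $n = 0$. The test suite asserts this criterion on a random
parameter sweep and checks the returned root against long-time integration of
the rate equation.

**Homogeneity.** The balance has the form
$n f(m/n) - n g(a/n) - n \ln 2 / T$, so scaling $m$ and $a$ by a common
factor scales the steady state by that factor exactly. This is why a double
hemizygote (both factors halved) sits at exactly 50% of wild type, and double
overexpression at exactly 200%, independent of every other parameter — the
model's sharpest testable prediction. Single hemizygotes interpolate between
50% and 100% depending on whether replication ($k_R$) or degradation ($k_D$)
dominates; `sweep_dosage()` over the reference grid
($k_R \in \{0.01, 0.1\}$, $k_D \in \{1, 10\}$, $m = 5$, $a = 100$, $T = 150$,
$K_1 = 5$, $K_2 = 100$) reproduces the regime pattern.

**Numerics.** `integrate_model()` delegates to `deSolve::ode()` (lsoda,
`atol = 1e-12`, `rtol = 1e-10`) with a non-negativity clamp inside the
right-hand side. It deliberately does not share code with the quadratic
solution so the two act as independent cross-checks; the suite requires
agreement to a relative error below $10^{-6}$ over 100 random parameter sets
(observed: machine precision).

# The nucleoid-counting pipeline

`analyze_cell()` runs, per cell and in 3D:

1. Gaussian prefilter of both channels, sigma 0.75 voxel (separable
   convolution, replicate-edge padding).
2. Li minimum-cross-entropy threshold of the mitochondrial channel →
   network mask; network volume = in-mask voxel count (× voxel volume for
   µm³); fragments = 26-connected components.
3. Median normalization of the mitochondrial channel over the network mask.
4. 3D local-maxima detection in the nucleoid channel (26-neighborhood;
   plateaus reduced to their lexicographically smallest voxel).
5. Li intensity filter of the candidate peaks.
6. Resolution-spheroid deduplication: lateral radius $0.61\lambda/\mathrm{NA}$
   (0.222 µm at NA 1.4, λ 509 nm), axial radius 1 µm; greedy by descending
   intensity, boundary-inclusive membership, lexicographic tie-break.
7. Iterative Welch validation: in-network voxels within any retained peak's
   spheroid are "inside"; the nucleoid channel is normalized by the mean over
   in-network voxels outside all nucleoids; per peak, a Welch two-sample
   t-test compares normalized nucleoid vs normalized mitochondrial
   intensities over the peak's inside voxels, discarding the peak when
   $p > 0.025$ or $t \le 0$; iterate to a fixed point of the retained count.

Parameter notes, with defaults in `pipeline_config()`:

* **Lateral dedup radius.** The 0.222 µm figure equals the Rayleigh form
  $0.61\lambda/\mathrm{NA}$ (sometimes loosely called the Abbe limit, which
  would be $\lambda/2\mathrm{NA} \approx 0.182$ µm); `mitoscale` implements
  the form that reproduces 0.222 µm.
* **Sidedness of the Welch p.** The pairing "$p > 0.025$ or $t$ negative" can
  be read as a two-sided p with a sign gate, or as a one-sided test at 0.025.
  Both are offered (`p_side = "two.sided"` default, `"greater"` halves the p
  for positive $t$); they differ by a factor of two in p and rarely change
  counts on well-resolved foci.
* **Thresholding scope.** Li thresholds are computed over the voxels of the
  cell being analyzed (pass `cell_mask = NULL` to use the whole grid). The
  per-cell scope makes cells statistically independent of their neighbors.
* **Small samples.** A peak whose spheroid holds fewer than 3 in-network
  voxels cannot support the Welch test and is discarded with a warning.
* **Degenerate channels.** A constant mitochondrial channel has no defined
  threshold: the segmentation is returned empty with a warning and the cell
  reports zero nucleoids and zero network volume, so mtDNA-free (ρ0-like)
  cells flow through rather than erroring.
* **Coordinates** are 1-based `(z, y, x)` voxel indices, the natural R array
  convention; all physical distances use the anisotropic voxel size in µm,
  so the convention has no numeric consequence.

**Termination.** Each Welch pass can only discard peaks, so the retained
count is non-increasing and the iteration reaches a fixed point in at most
`initial count` passes (capped by `max_iter`).

# qPCR copy-number calculus

`quantify_plate()` implements the chain:

1. **Replicate pooling** (`pool_technical_replicates()`): mean Cq per well
   triple; if the s.d. exceeds 0.5 cycles, the single replicate farthest from
   the median is excluded and the criterion retested; a well that still fails
   propagates as `NA`, never as zero. The exclusion runs once by default
   (`iterate = TRUE` repeats it), the minimal deterministic reading of
   "single replicates were excluded".
2. **Calibration** (`fit_standard_curve()`): ordinary least squares of Cq on
   $\log_{10}$(concentration) over a $10^{-4}$–$1$ pg/µL dilution series of a
   single template carrying all amplicons; per-primer slope and intercept.
   The efficiency $E = 10^{-1/\mathrm{slope}} - 1$ is reported but not used
   to re-correct concentrations — the curve itself is the correction.
3. **Concentration and pooling**: $c = 10^{(Cq - b)/s}$ per gene; nuclear
   concentrations (ACT1, MIP1, MRX6) and mitochondrial ones (COX2, COX3)
   averaged per group; MIP1 excluded where its dosage is manipulated.
4. **Budding-index ploidy correction** (`ndna_per_cell()`): with budding
   index %buds on the 0–100 scale, haploids carry
   $(\%\text{buds} \times 2 + \%\text{no-buds} \times 1)/100$ nuclear genome
   copies per cell on average, diploids
   $(\%\text{buds} \times 4 + \%\text{no-buds} \times 2)/100$.
5. **Copy numbers** (`copy_number()`): mtDNA/nDNA × nDNA per cell = mtDNA per
   cell; divided by mean volume = copies per fL.

Because the calibration standard maps concentrations, not molecule counts,
absolute copies follow from the ratio times the nuclear genome count — the
standards alone cannot give absolute copies, and nothing downstream needs
them to.

# Scaling statistics

* `binned_means()` reports per-bin mean, s.e. ($s/\sqrt{n}$) and count at bin
  centres. Bin edges are rarely reported alongside binned-mean figures, so
  the default is equal-width bins between the 1st and 99th volume
  percentiles; bins with
  fewer than `min_count = 5` points are suppressed (single-point bins report
  `se = 0` flagged `se_defined = FALSE`).
* `fit_linear()` fits replicate means by default — the figure-legend
  convention — though nothing stops fitting pooled single cells.
* `constant_amount_ratio()` is the null expectation $v_\text{small}/v_\text{big}$
  for the big-to-small concentration ratio of a species kept at constant
  amount per cell.
* `mtdna_per_nucleoid()` matches qPCR copies and imaging nucleoid counts on a
  shared volume binning and reports their per-bin ratio (≈ 2 copies per
  nucleoid on data generated under that law); zero-nucleoid bins are flagged
  undefined rather than dropped.
* `flow_background_subtract()` subtracts, per scatter bin, the mean
  autofluorescence of a non-fluorescent control from the mean signal of the
  tagged strain; with two measurement days the point estimate is the day mean
  and the error envelope spans the smaller day signal minus its s.e. to the
  larger plus its s.e.

# The synthetic generators

The generators define the conditions under which the pipeline is validated.

* `make_cell()`: prolate ellipsoid (axis ratio 1.2) voxelized at
  (0.35, 0.1, 0.1) µm — the 0.35-µm z-increment of the acquisition, lateral
  sampling near Nyquist for the 0.222-µm lateral resolution.
* `make_network()`: persistent random-walk tubes of radius 0.175 µm (a
  realistic yeast tubule half-diameter) confined to the cell, grown to a
  target fraction (default 8%) of cell volume; one walk = one connected
  component; multiple fragments grow in z-slabs separated by more than the
  tube diameter so the component count is exact by construction.
* `place_nucleoids()`: centerline points with an exclusion spheroid of
  0.5 µm lateral / 2.2 µm axial radius by default — at least twice the
  deduplication spheroid in both directions, so planted spots are mutually
  resolvable under the anisotropic optics.
* `render_cell()`: the mitochondrial channel is the network mask times an
  amplitude (default 12), blurred by a Gaussian PSF of sigma
  (0.5, 0.09, 0.09) µm (lateral ≈ $r_{xy}/2.355$); the nucleoid channel is a
  bleed-through fraction (0.3) of that signal plus a diffraction-limited
  Gaussian spot (amplitude 30) per nucleoid; both receive a constant offset
  (10), Poisson shot noise (50 photons per intensity unit) and Gaussian read
  noise (s.d. 1). The defaults put foci at SNR ≈ 10 and the network at
  SNR ≈ 9. The bleed-through exists precisely to exercise the Welch stage.
* `simulate_qpcr()`: per-gene template concentrations follow from the true
  copies per cell and the budding-index genome count; Cq values come from
  per-gene calibration lines (slopes near −3.3) plus i.i.d. Gaussian noise;
  the standards series is measured with the same triplication and noise.
* `simulate_population()`: lognormal volumes (CV 0.3, emulating an
  engineered >4-fold volume range), copies $= c \cdot V$, nucleoids
  $=$ copies / 2.

Not emulated: spherical aberration, bleaching, bud-neck geometry, spatially
correlated noise, plate-position effects. Passing tests therefore demonstrate
algorithmic correctness under the stated statistical structure, not
performance on arbitrary real data.

# Known limitations (each verified by the test suite)

**Network volume at confocal resolution.** Yeast tubules (~0.35 µm diameter)
are below the axial resolution: the rendering PSF spreads a one-z-plane tube
over about three planes, and the Li-thresholded volume lands near 3× the
painted voxel count. No threshold can undo this — the half-max isosurface is
still ~1.7× — so thresholded network volume is a relative, not absolute,
measure. On blur-free noisy renders (SNR ≈ 10) the same code recovers the
painted count to a fraction of a percent, isolating the effect in the optics,
not the algorithm. Comparisons of network volume across cells imaged
identically remain valid; comparisons to physical volumes do not.

**qPCR precision at 0.1-cycle well noise.** With i.i.d. per-well Cq noise of
0.1 cycles and triplicate pooling, each gene's concentration carries ≈ 4%
relative error; averaging three nuclear and two mitochondrial genes leaves
≈ 3.7% on the mtDNA/nDNA ratio, so roughly one recovery in five misses a ±5%
band even with exact calibration. Tighter recovery requires either lower well
noise, more genes, or noise that is correlated within a sample (as real
pipetting error partly is) and cancels in the ratio.

**Spot-free nucleoid channels.** The validation iteration normalizes the
nucleoid channel by the outside-of-nucleoid in-network mean but the
mitochondrial channel by its in-network median. When the nucleoid channel
contains no true foci (ρ0-like cells with bleed-through), that asymmetry lets
a small residual of noise peaks over dim network regions pass the Welch gate
(≈ 5% of initial candidates in our renders). With real foci present the Li
intensity gate removes bleed-through candidates first and the effect
disappears (pooled precision 1.0 on the validation stacks). Counting
nucleoids in cells suspected to be mtDNA-free should rely on an independent
control rather than the counter alone.

# Problem sizes

The validation suite analyzes 50 rendered cells of 34–108 fL carrying 12–39
nucleoids each, checks the model oracle on 100 random parameter sets, the
local-maxima oracle on 20 random 16³ stacks, and the qPCR round trip on 100
simulated single-sample plates; these sizes make every property
statistically meaningful while keeping the full suite under a minute of
compute for the numerical parts and a few tens of seconds for the imaging
parts.
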