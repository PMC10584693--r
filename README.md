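# mitoscale

Tools for quantifying how mitochondrial DNA (mtDNA) copy number scales with
cell volume in budding yeast — for microscopists counting nucleoids in 3D
confocal stacks, for molecular biologists converting qPCR plates into
absolute copy numbers, and for modelers asking why the scaling arises at all.

## What it computes

**The limiting-factor model.** mtDNA concentration *n* balances replication
by the polymerase Mip1 (concentration *m*), degradation suppressed by the
packaging factor Abf2 (concentration *a*), and dilution by growth:

```
dn/dt = kR · m/(K1 + m/n) − kD · n/(K2 + a/n) − n·ln2/T
```

At steady state this reduces to a quadratic `A n² + B n + C = 0`; a positive
steady state exists exactly when `kR·T > ln 2`. Because replication and
degradation depend only on the ratios `m/n` and `a/n`, scaling *m* and *a*
together scales *n* by the same factor: a double hemizygote sits at exactly
50% of wild type whatever the other parameters, while single hemizygotes
fall between 50% and 100% depending on the replication/degradation regime.

**The nucleoid counter.** Per cell, in 3D: Gaussian prefilter (σ = 0.75
voxel) → Li thresholding of the mitochondrial channel (network mask, volume,
fragment count) → median normalization → 3D local maxima in the nucleoid
channel → Li intensity filter → deduplication inside a resolution spheroid
(0.61·λ/NA = 0.222 µm lateral at NA 1.4 / λ 509 nm, 1 µm axial) → iterative
Welch-test validation of each focus against the mitochondrial signal at the
same voxels (discard when p > 0.025 or t ≤ 0, iterate to a fixed point).

**The qPCR calculus.** Technical replicates pooled with a 0.5-cycle s.d.
cut-off; per-primer standard curves (Cq vs log10 concentration, 10⁻⁴–1
pg/µL); nuclear (ACT1, MIP1, MRX6) and mitochondrial (COX2, COX3)
concentrations pooled; the mtDNA/nDNA ratio times the budding-index genome
count — haploid `(%buds·2 + %nobuds·1)/100`, diploid `(%buds·4 +
%nobuds·2)/100` — gives copies per cell, and per fL after dividing by mean
volume.

**Scaling statistics and generators.** Binned means ± s.e., linear fits to
replicate means, constant-amount concentration ratios, copies-per-nucleoid
across matched volume bins, flow-cytometry background subtraction with a
two-day error envelope — plus seeded generators for ground-truthed synthetic
microscopy stacks, qPCR plates, and cell populations that make every stage
testable without external data.

## Worked example

```r
library(mitoscale)

p <- model_params(kR = 0.1, kD = 1, K1 = 5, K2 = 100, T = 150, m = 5, a = 100)
steady_state(p)
#> steady-state mtDNA concentration n* = 6.52343

sweep_dosage(wild_type_grid(),
             list(dosage_perturbation(0.5, 0.5),   # double hemizygote
                  dosage_perturbation(0.5, 1),     # MIP1 hemizygote
                  dosage_perturbation(1, 0.5)))    # ABF2 hemizygote
#>      params_id   kR kD  fm  fa relative_mtdna
#> 1   kR0.01_kD1 0.01  1 0.5 0.5          0.500
#> 2   kR0.01_kD1 0.01  1 0.5 1.0          0.688
#> 3   kR0.01_kD1 0.01  1 1.0 0.5          0.688
#> 4    kR0.1_kD1 0.10  1 0.5 0.5          0.500
#> 5    kR0.1_kD1 0.10  1 0.5 1.0          0.541
#> 6    kR0.1_kD1 0.10  1 1.0 0.5          0.951
#> ...
```

Every double hemizygote lands on exactly 0.500; the single hemizygotes span
0.52–0.95 across the parameter grid: fast replication (kR = 0.1) makes the
MIP1 hemizygote drop toward 50% while leaving the ABF2 hemizygote nearly at
wild type, and fast degradation (kD = 10) does the opposite.

```r
img <- make_synthetic_cell_image(volume_fl = 50, n_nucleoids = 15, seed = 7)
analyze_cell(img$nucleoid, img$mito, img$cell_mask)
#> cell_result: 15 nucleoid(s); network 3430 voxels (12 um^3), 1 fragment(s)
```

All 15 planted nucleoids recovered. Note the network volume (3430 voxels)
exceeds the painted tube voxels (~1150): a diffraction-blurred sub-resolution
tubule thresholds to roughly 3× its physical voxel count, which is why
confocal network volume is a relative measure (see the methods vignette).

```r
sim <- simulate_qpcr(mt_per_cell = c(30, 60, 120), volumes_fl = c(30, 60, 120),
                     budding_index = c(30, 45, 60), cq_noise_sd = 0.1, seed = 2)
quantify_plate(sim$plate, sim$standards, sim$populations)$results
#>   sample mean_volume_fl mt_per_ndna ndna_per_cell mt_per_cell mt_per_fl
#> 1    s01             30       23.00          1.30       29.91    0.9968
#> 2    s02             60       41.51          1.45       60.18    1.0031
#> 3    s03            120       75.18          1.60      120.29    1.0024
```

True copies per cell (30, 60, 120) are recovered to within ~0.5% in this
draw, and the copies-per-fL column is flat at ≈ 1 — the constant-concentration
signature of copy number scaling with volume.

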