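# nucloc

Quantify where a GFP fusion protein sits in the cell — nucleus, cytoplasm,
or both — from two-channel fluorescence microscopy, and test whether
treatment groups differ.

## What it does, and for whom

In a standard localization assay, a protein of interest is expressed as a
GFP fusion in cultured cells (e.g. MDCK), nuclei are counterstained with
Hoechst 33342, and fields are imaged on a blue (DAPI-like) and a green
(FITC) channel. Every transfected cell is scored by where its green signal
lies relative to the blue-stained nuclear area:

* **NUCLEAR** — green signal inside the stained nuclear area only,
* **CYTOPLASMIC** — green signal outside the nuclei only,
* **BOTH** — green signal covering the whole cell,
* **UNLABELED** — no green signal (untransfected; excluded from
  percentages).

`nucloc` is for cell biologists running this assay who want the scoring to
be automatic, reproducible, and statistically explicit. It segments nuclei
from the blue channel (Otsu threshold, morphological cleanup, optional
watershed), delineates a cytoplasmic annulus per cell (nearest-nucleus
partition of dilated nuclei), computes per-cell positive-pixel fractions
`f_nuc` and `f_cyt`, and calls each cell by threshold presence in each
compartment. Calls aggregate to per-well percentages of labeled cells —
the plate **well** is the experimental unit — and groups are compared with
two-tailed independent-samples t-tests computed from the per-well data or
directly from published group summaries:

    sd_i = se_i * sqrt(n_i)
    t    = (mean_A - mean_B) / sqrt(s2_pooled * (1/n_A + 1/n_B)),
    df   = n_A + n_B - 2          (Welch variant available)

with the fold difference of group means (larger/smaller, 1 decimal) as the
effect size.

Because such studies rarely deposit raw images, the package includes a
seeded synthetic two-channel field generator with per-cell ground truth
(concentric-disk cells, binomial transfection, multinomial class mixtures,
Gaussian/Poisson noise) emulating a full plate design: triplicate wells
across two plates in two experiments (n = 6 wells/treatment), 15 fields
per well. Every pipeline stage is validated against this ground truth.

## Worked example

Compare two groups straight from summary statistics (mean, SE, n = 6
wells each), here for the cytoplasmic class:

```r
library(nucloc)
tt <- t_test_from_summary(45.12, 6.14, 6,   # group A: mean, SE, n wells
                          67.29, 6.61, 6)   # group B
tt[c("t", "df", "p")]
#> $t   -2.457895
#> $df  10
#> $p   0.03382674
ratio_effect(45.12, 67.29)
#> [1] 1.5
```

The p-value (0.03 after rounding) says the two constructs differ in how
often cells show purely cytoplasmic localization; the ratio says the
second construct is found in the cytoplasm 1.5× as often.

Or run the whole pipeline on a simulated experiment:

```r
design <- experiment_design(
  treatments = list(
    WT   = list(mixture = c(0.0621, 0.4512, 0.4867), transfection_rate = 0.6),
    RISK = list(mixture = c(0.0386, 0.6729, 0.2874) / 0.9989,
                transfection_rate = 0.6)),
  fields_per_well = 5, cells_per_field = 30, shape = c(384, 384),
  master_seed = 1)
sim <- cmd_simulate(design, "sim_out")     # 2-page TIFFs + ground-truth manifest
q   <- cmd_quantify("sim_out", "quant")    # per-cell + per-well CSVs
cmp <- cmd_compare(q$wells, "WT", "RISK")
cat(cmp$report, sep = "\n")
#> | | Nuclei labeled (%) | Cytoplasm labeled (%) | Nuclei and Cytoplasm labeled (%) |
#> |---|---|---|---|
#> | WT | 5.13 ± 0.91 | 43.52 ± 2.55 | 51.35 ± 2.76 |
#> | RISK | 4.54 ± 1.09 | 65.88 ± 2.06 | 29.58 ± 1.55 |
#> | p-value | 0.69 | 0.00 | 0.00 |
#> | ratio (larger/smaller) | 1.1 | 1.5 | 1.7 |
```

The recovered group means sit close to the generating mixtures (45.12 →
43.52, 67.29 → 65.88), and the simulated p-values are smaller than the
published ones only because simulated wells lack the extra between-well
biological variability of real transfections.

The same stages are available from a shell via
`Rscript inst/cli/nucloc.R <simulate|quantify|compare|all> ...`; see the
vignette in `vignettes/localization-quantification.Rmd` for the model,
parameter meanings and design choices.

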