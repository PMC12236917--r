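# cestquant

Quantification of CEST MRI Z-spectra: WASSR B0 correction, five-pool
Lorentzian decomposition, AUC contrast maps, and region-of-interest group
statistics — with a seeded synthetic phantom generator and an independent
Bloch–McConnell simulator for validation.

## The problem

Chemical exchange saturation transfer (CEST) MRI detects low-concentration
metabolites by saturating their exchangeable protons at a characteristic
frequency offset and measuring the attenuation of the water signal. The
measurement per voxel is a *Z-spectrum*: the normalized signal
$S/S_0$ versus saturation offset $\Delta\omega$ in ppm. In brain studies at
7 T the spectrum is decomposed into five Lorentzian pools,

$$Z(\Delta\omega) = 1 - \sum_{i=1}^{5}
A_i\,\frac{(\Gamma_i/2)^2}{(\Gamma_i/2)^2+(\Delta\omega-\delta_i)^2},$$

with centers fixed at 0 ppm (direct water saturation), −1 ppm
(semi-solid magnetization transfer), 2 ppm (creatine), 3 ppm (glutamate)
and −3.5 ppm (relayed nuclear Overhauser effect). The contrast reported
per pool is the area under its fitted Lorentzian, $A\,\pi\,\Gamma/2$.
Before fitting, each voxel's spectrum is re-referenced using the minimum
of a paired low-power WASSR acquisition, which locates the local B0
offset.

The package is aimed at preclinical imaging groups who need this chain —
from offset axis to per-region ANOVA/t-test reports and heatmaps — as
tested, reproducible code rather than ad-hoc scripts.

## Worked example

Simulate a study-shaped group table from the phantom's ground truth
(four arms, 14/14/5/4 subjects, 5% between-subject CV; the untreated
12-week arm carries a 20% cortical glutamate reduction) and run the
comparison suite:

```r
library(cestquant)
cfg <- phantom_config(grid_shape = c(24L, 24L),
                      region_layout = default_region_layout(c(24L, 24L)),
                      seed = 42L)
tab <- simulate_group_table(cfg, seed = 42L)
st  <- comparison_suite(tab)
st$tests[st$tests$pool == "glutamate" & st$tests$region == "cortex",
         c("comparison", "variant", "statistic", "df", "p", "tier")]
```

```
                               comparison variant statistic   df        p tier
 baseline | wk12_art | wk12_vehicle | wk6   anova     46.65  3.0 5.72e-12 ****
                          baseline vs wk6  pooled      0.76 26.0 4.54e-01   ns
                 baseline vs wk12_vehicle   welch     14.59 16.8 5.61e-11 ****
                 wk12_art vs wk12_vehicle  pooled      9.81  7.0 2.43e-05 ****
```

Reading the rows: glutamate contrast in cortex is unchanged at week 6
(`ns`), collapses in the untreated arm at week 12 (Welch t, four-star
tier), and the treated arm differs sharply from the untreated one —
i.e. treatment restored the contrast. The accompanying `st$summary` holds
the mean ± SEM per arm that the bar plots display (baseline 0.0958 ±
0.0013 vs untreated 0.0738 ± 0.0008 ppm·normalized-signal).

The full imaging pipeline (B0 map → corrected stacks → voxelwise fits →
contrast maps/heatmaps → table → reports) runs the same way from files on
disk:

```r
ph <- simulate_phantom(cfg)        # or your own data in the same layout
write_phantom(ph, "demo_in")
res <- run_pipeline(pipeline_config("demo_in", "demo_out"))
```

`demo_out/` then contains per-subject B0/parameter/contrast NIfTIs,
`region_group_table.csv`, `test_reports.csv`/`.json`, per-arm heatmaps
with a shared color window, bar plots, and a `manifest.json` with the
echoed configuration and md5 checksums of every data artifact (reruns are
byte-identical). A thin shell wrapper with `simulate` and `run`
subcommands lives at `inst/cli/cestquant`.

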