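# releaseflow

Circuit-theory prediction of where translocated animals move after release.

Reintroduction programs for wide-ranging soaring birds (the motivating case
is the California condor, *Gymnogyps californianus*) need quantitative
predictions of post-release movement to plan release sites, outreach and
hazard mitigation. `releaseflow` implements that prediction pipeline
end-to-end:

1. **Telemetry filtering** — keep proofed GPS fixes of birds in flight
   (ground speed strictly between 2.78 and 30.0 m/s), drop offshore points
   and points within 5 km of release sites, thin to one point per bird per
   day; build a 10,000-point background sample inside the movement-point
   convex hull buffered by 10 km.
2. **Conductance modelling** — a maximum-entropy presence-background model
   (linear + quadratic features, clamping, L1 regularisation) fitted to the
   movement points; candidates compared by 5-fold cross-validated AIC; the
   logistic output is the landscape conductance surface *C* ∈ (0, 1).
3. **Circuit solving** — the raster becomes a resistor lattice (8-neighbour
   edges, mean-conductance weights, √2 diagonal scaling). Current is
   injected at the release site and drained at ground nodes placed every
   10 km along a buffer ring around the sites; solving the Kirchhoff system
   **L v = b** per source–ground pair and averaging the per-cell current
   magnitudes gives a direction-neutral mean current map in mA, read as net
   movement probability.
4. **Calibration** — the continuous Boyce index (Spearman correlation of
   window position vs the predicted/expected ratio of movement points to
   available cells) and reverse cumulative frequency of current at movement
   points in 1-mA bins, evaluated within 300 km of the sites.
5. **Linkage networks** — resistance 1/*C*, core habitat patches from a
   suitability raster (threshold 0.04, minimum 10 km²), cost-weighted
   distances by multi-source Dijkstra, network adjacency by CWD allocation
   zones, and least-cost links dropped where they cross a third patch.

A synthetic-data module generates autocorrelated covariate fields, a
known-truth conductance surface and raw telemetry with counted removal
categories, so the entire pipeline runs, and is tested, without any field
data or GIS downloads. Rasters use a lightweight in-package class with
plain-text ESRI ASCII grid I/O; vector outputs are GeoJSON.

## Worked example

```r
library(releaseflow)
manifest <- run_pipeline(pipeline_config(seed = 7))
print(manifest)
```

```
simulate: 22020 raw fixes over 101x101 grid
filter: 22020 raw -> 17700 flight -> 17280 zoned -> 1800 daily-thinned
background: 10000 points in the buffered movement hull
covariates: 6 of 6 retained after |rs| > 0.70 screen
fit: selected model6 (mean AIC 32029.0, mean AUC 0.713)
circuit: 26 source-ground connections averaged
calibrate: Boyce index 0.927 over 1800 movement points
linkage: 17 patches, 34 links, mean CWD 47.7
```

Reading the output: 22,020 simulated fixes reduce to 1,800 daily-thinned
movement points after the speed/proof, offshore and near-site filters; the
lowest-AIC candidate model is projected to a conductance surface; 26
circuits (one per ground node on the 40-km ring) are solved and averaged;
the Boyce index of 0.93 says the mean current map ranks where the simulated
birds actually flew — the synthetic analogue of a well-calibrated movement
prediction; and the linkage stage finds 34 least-cost links among 17 core
patches with a mean cost-weighted distance of 47.7 (cost units, not km —
higher means weaker connectivity).

The same stages can be run as numbered drivers that write tables under
`results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_filter.R
Rscript analysis/03_conductance.R   # writes results/model_selection.csv
Rscript analysis/04_circuit.R
Rscript analysis/05_calibrate.R     # writes results/pe_curve.csv etc.
Rscript analysis/06_linkage.R
```

The methods vignette (`vignettes/methods.Rmd`) documents the model
formulas, parameter defaults, numerical choices and the limits of what the
synthetic tests demonstrate.

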