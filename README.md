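# hotspotpet

Hotspot geometry biomarkers and recurrence statistics from PET images.

## The problem

On an ¹⁸F-FDG PET scan of a solid tumor, the voxel of maximum tracer
uptake (SUVmax, the "hotspot") tends to migrate from the tumor core toward
its rim as the disease progresses. Two dimensionless descriptors capture
this geometry for a segmented lesion with metabolic tumor volume *V*:

- **NHOCmax** — the Euclidean distance from the SUVmax voxel to the tumor
  centroid, divided by the radius of the sphere with the tumor's volume,
  *R* = (3*V* / 4π)^(1/3). It grows as the hotspot moves outward.
- **NHOPmax** — the minimum Euclidean distance from the SUVmax voxel to
  the tumor perimeter (the outermost layer of mask voxels), divided by the
  same *R*. It shrinks toward 0 as the hotspot nears the edge; low values
  are associated with postoperative recurrence in resectable lung
  adenocarcinoma.

`hotspotpet` implements the full measurement chain — isotropic resampling
(3 mm default), hotspot location, segmentation at 40% of SUVmax
(26-connected component containing the hotspot), perimeter extraction
(6-neighbor boundary test), and the metric set SUVmax / SUVmean / MTV /
TLG / NHOCmax / NHOPmax — plus the downstream statistics used to evaluate
such biomarkers against a recurrence outcome: Spearman correlation
matrices, ROC analysis with Youden-index cut-offs and bootstrap AUC CIs,
univariate/multivariate logistic regression, Cox proportional hazards
(Efron ties), and Kaplan–Meier curves with the log-rank test.

Because no patient imaging is distributed, the package ships first-class
synthetic data generators: ellipsoidal PET phantoms with a hotspot planted
at a known normalized offset (analytic ground-truth NHOC/NHOP), and
simulated cohorts in which recurrence and disease-free survival depend on
NHOPmax in the protective direction (OR < 1, HR < 1).

Intended users: imaging scientists prototyping hotspot-geometry radiomics,
and statisticians who need a reproducible end-to-end testbed for
ROC/regression/survival pipelines on PET-derived features.

## Worked example

```r
library(hotspotpet)

# A 21 mm sphere phantom with the hotspot planted halfway to the surface
ph <- make_phantom(radii_mm = 21, hotspot_offset_frac = 0.5, seed = 1)
m  <- extract_metrics(ph$volume)   # resample -> hotspot -> segment -> metrics
m
#> <tumor_metrics>
#>   SUVmax 9.624  SUVmean 7.664  MTV 38.313 mL  TLG 293.622
#>   NHOCmax 0.430  NHOPmax 0.454  (r_equiv 20.91 mm)
ph$truth$true_nhoc; ph$truth$true_nhop
#> [1] 0.5
#> [1] 0.5
```

The phantom's analytic truth is NHOC = NHOP = 0.5; the extracted values
(0.430, 0.454) differ by voxel-snapping of the hotspot and the discrete
perimeter layer — the vignette quantifies these discretization errors.

```r
# A simulated 500-patient cohort with a protective NHOP effect
tab <- simulate_cohort(n = 500, seed = 7)
roc <- roc_youden(tab$nhop_max, tab$recurrence, n_boot = 500, seed = 7)
roc
#> <roc_result> AUC 0.644 (95% CI 0.588-0.698), cutoff 0.3775 (lower_predicts_event)
#>   sensitivity 0.762  specificity 0.465  (J = 0.226)

logistic_fit(tab, "recurrence", c("nhop_max", "suv_max"), mode = "multivariate")
#> <fit_result> logistic regression (multivariate)
#>      term estimate     se   ratio  ci_low ci_high   p_value flagged
#>  nhop_max  -3.2269 0.6005 0.03968 0.01223  0.1287 7.721e-08   FALSE
#>   suv_max   0.1376 0.0229 1.14752 1.09715  1.2002 1.872e-09   FALSE

cox_fit(tab, "dfs_months", "event", "nhop_max")
#> <fit_result> cox regression (univariate)
#>      term estimate     se  ratio  ci_low ci_high   p_value flagged
#>  nhop_max    -3.13 0.5096 0.0437 0.01609  0.1187 8.129e-10   FALSE

km_logrank(dichotomize(tab, "nhop_max", roc$cutoff),
           "dfs_months", "event", "group")
#> <km_result> 2 groups; log-rank chi2 = 29.37, p = 5.977e-08
```

Read: a higher NHOPmax (hotspot buried deeper in the lesion) lowers both
the odds of recurrence (OR 0.04 per unit) and the hazard of a DFS event
(HR 0.04 per unit) in this simulation; splitting the cohort at the Youden
cut-off separates the survival curves decisively.

## Command line

```sh
Rscript -e 'hotspotpet::pet_cli()' extract --in lesion.nii.gz --out metrics.csv
Rscript -e 'hotspotpet::pet_cli()' phantom --out ph.nii.gz --offset 0.5 --seed 7
Rscript -e 'hotspotpet::pet_cli()' cohort  --out cohort.csv --n 500 --seed 7
Rscript -e 'hotspotpet::pet_cli()' analyze --in cohort.csv --out-prefix results/run1
Rscript -e 'hotspotpet::pet_cli()' all     --outdir demo --seed 7
```

Every run writes a JSON config sidecar so outputs are reproducible from
(inputs, flags, seed).

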