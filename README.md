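# mlshift

Fully automatic measurement of brain **midline shift (MLS)** on axial head
CT, for neuroimaging researchers and methodologists who need a transparent,
dependency-light reference implementation of the keypoint-based MLS pipeline
— from raw DICOM/NIfTI volumes to cohort-level agreement statistics — plus a
synthetic phantom generator so the whole pipeline can be trained and
validated with no clinical data.

## The measurement

On an axial slice the ideal midline is the line between the anterior and
posterior attachments of the falx cerebri; the displaced structure is the
septum pellucidum. From four landmarks — falx anterior `A`, falx posterior
`B`, septum anterior `C`, septum posterior `D` — the slice-level shift is

```
MLS = || midpoint(A, B) − midpoint(C, D) ||   (mm, per-axis pixel spacing applied)
```

and the scan-level MLS is the maximum over slices. Landmarks are found
automatically by a two-stage detector (region proposals on a convolutional
backbone, then classification / box-regression / keypoint-heatmap heads —
the Keypoint R-CNN construction), implemented natively in R + Rcpp with a
desk-scale `tiny` backbone that trains on phantoms in minutes on one CPU.

Evaluation follows the standard agreement protocol: mean absolute error,
ICC(2,1) (two-way random effects, absolute agreement), and sensitivity /
specificity for detecting MLS greater than 2, 5 and 10 mm (strict
thresholds).

## Worked example

Generate a phantom with a known 7.5 mm shift, measure it through the full
pipeline with the noise-free oracle detector, then evaluate a small cohort:

```r
library(mlshift)

scan <- generate_phantom(phantom_spec(true_mls_mm = 7.5, seed = 3))
scan
#> <labeled_scan> s001 (patient p001): true MLS 7.50 mm, type none, 9 annotated slice(s)

om  <- oracle_detector(scan$annotations, sigma_px = 0, dropout_rate = 0)
res <- run_pipeline(scan$volume, om)
res
#> <mls_result> scan s001  source: prediction
#>   scan MLS 7.500 mm at slice 12 (9 slice(s) measured)
```

The scan's shift peaks at slice 12 (the central ventricle slice of the
24-slice volume) and the pipeline returns exactly the 7.5 mm that was built
into the phantom — the geometry chain is exact when the keypoints are exact.

Training the detector end to end on a phantom cohort:

```r
cohort <- build_dataset(20, mls_distribution = "uniform:0,15", seed = 1)
ds_tr  <- detector_dataset(cohort$train, image_size = 192)
ds_va  <- detector_dataset(cohort$valid, image_size = 192)
cfg    <- detector_config(image_size = 192, heatmap_size = 32, epochs = 30,
                          lr_initial = 1e-3, lr_drop_epoch = 20)
model  <- train_detector(ds_tr, ds_va, cfg)
result <- run_pipeline(cohort$test[[1]]$volume, model)
```

Command-line wrappers for the same steps live in `inst/cli/`
(`generate-phantoms.R`, `train.R`, `predict.R`, `evaluate.R`), e.g.

```sh
Rscript inst/cli/generate-phantoms.R --n-patients 20 --mls-dist "uniform:0,15" --seed 1 --out phantoms/
Rscript inst/cli/evaluate.R --gt gt.csv --pred pred.csv --thresholds 2,5,10 --out report.json
```

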