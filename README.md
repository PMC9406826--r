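# renasl

Synthetic renal arterial spin labeling (ASL) MRI and a complete
processing pipeline, for benchmarking renal perfusion analysis end-to-end
against known ground truth.

ASL measures perfusion by magnetically labeling inflowing blood water and
subtracting labeled from control images; the tiny difference signal dM is
converted to renal blood flow (rbf, mL/100 g/min) with the consensus
single-compartment equations

    rbf_PASL  = 6000 * lambda * dM * e^{+TI/T1b} / (2 * alpha * 0.93^2 * M0 * TI1)
    rbf_PCASL = 6000 * lambda * dM * e^{+PLD/T1b} / (2 * alpha * 0.93^2 * M0 * T1b * (1 - e^{-tau/T1b}))

(lambda = 0.9 mL/g, T1b = 1650 ms, alpha = 0.95/0.85 for PASL/PCASL,
0.93^2 for two background-suppression pulses). Because real acquisitions
have no voxelwise ground truth, pipeline errors — residual respiratory
motion, quantification bias, segmentation leakage — are hard to
attribute. `renasl` closes that gap: it simulates the whole acquisition
from a procedural abdominal phantom with known perfusion (healthy
cortex/medulla 250/50 mL/100 g/min; an abnormal-right scenario with
100/20), including spin-echo signal formation, the Buxton general kinetic
model for both PASL and PCASL, background suppression to 20 %,
free-breathing craniocaudal motion sampled over 100 breathing phases, and
Gaussian noise. The processing side mirrors a production renal ASL
pipeline: per-kidney cropping, groupwise non-rigid motion correction (one
cubic B-spline free-form deformation per frame, optimised jointly against
the eigenvalue-based PCA groupwise metric with an implicit-mean
constraint), consensus quantification, and semi-automatic cortex/medulla
segmentation (manual or emulated-manual whole-kidney mask, two-cluster
k-means on the perfusion map, erosion cleanup with side-specific
structuring elements). An evaluation harness scores every stage: all-pairs
MSSIM before/after registration, Dice overlap against transformed
ground-truth masks, perfusion recovery statistics, and time-line profiles.

Intended users: developers of renal ASL processing pipelines and groups
comparing processing choices across centres.

## Worked example

Simulate a noise-free, motion-free healthy PCASL dataset and quantify it:

```r
library(renasl)

ds  <- simulate_asl_dataset("PCASL", "healthy", model_seed = 1,
                            snr = Inf, amplitude_mm = 0)
md  <- mean_difference(series_frames(ds$series))
map <- quantify(md$delta_m, md$m0, ds$series$protocol)

gm <- ds$series$gt_masks[[1]]
perfusion_stats(map, list(cortex  = gm$cortex_left  | gm$cortex_right,
                          medulla = gm$medulla_left | gm$medulla_right))
#> # A tibble: 2 x 4
#>   region  n_voxels  mean       sd
#>   <chr>      <int> <dbl>    <dbl>
#> 1 cortex       398   250 7.07e-14
#> 2 medulla      198    50 7.14e-14
```

The quantification inverts the forward kinetic model exactly in the fully
delivered bolus regime: cortex 250 and medulla 50 mL/100 g/min are the
values the simulator assumed, recovered to machine precision (the sd
column is numerical noise).

A realistic run exercises the full pipeline — default conditions are 16 mm
peak breathing excursion and M0 SNR 40:

```r
ds   <- simulate_asl_dataset("PCASL", "healthy", model_seed = 1)
proc <- process_series(ds$series)       # crop, register, quantify, segment
ev   <- evaluate_processing(proc)
ev$mssim_summary
#> # A tibble: 4 x 3
#>   side  stage  mssim
#>   <chr> <chr>  <dbl>
#> 1 left  after  0.758
#> 2 right after  0.747
#> 3 left  before 0.632
#> 4 right before 0.624
ev$dice
#> # A tibble: 6 x 3
#>   side  structure  dice
#>   <chr> <chr>     <dbl>
#> 1 left  whole     0.942
#> 2 left  cortex    0.827
#> 3 left  medulla   0.725
#> 4 right whole     0.940
#> 5 right cortex    0.858
#> 6 right medulla   0.833
```

Registration raises the mean all-pairs MSSIM of each kidney crop (0.63 to
0.76 on the left here — the residual gap to 1 is the noise floor, which no
motion correction can recover), and the segmentation overlaps the
transformed ground truth with Dice around 0.94/0.84/0.78 for whole
kidney/cortex/medulla. `plot_mssim(ev)`, `plot_line_profile()` and
`plot_perfusion_map()` visualise the report.

A thin command-line interface wraps the same stages for directory-based
workflows (`inst/exec/renasl`):

```sh
renasl simulate --scheme PCASL --scenario healthy --seed 1 --out data/
renasl process  --in data/ --out results/
renasl evaluate --data data/ --results results/ --out report/
```

Datasets are NIfTI series with a JSON sidecar; any directory with a
conforming layout is accepted by `process`.

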