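# ocuclean

Detection and mitigation of ocular (eye-blink) artifacts in multichannel
EEG epochs.

Eye blinks generate electro-oculographic (EOG) potentials 10–100× stronger
than cortical EEG that overlap it in time and frequency, corrupting
downstream analyses such as brain–computer interfacing. `ocuclean`
implements a two-phase scheme on epoched multichannel recordings:

* **Detection.** Each epoch is decomposed by a five-level, four-band
  wavelet filter cascade (per level: two cascaded orthogonal splits giving
  LFLF/LFHF/HFLF/HFHF, recursing on LFLF) and each of the 20 subbands
  receives Pisarenko harmonic analysis — the pseudospectrum
  `P(f) = 1/|e(f)ᴴ v_min|²` built from the minimum-eigenvalue eigenvector
  of the order-M autocorrelation matrix. Per-subband statistics are reduced
  by PCA and ICA (83 components each, 166 concatenated features) and
  classified by a one-dimensional **deformable convolutional network**:
  convolutions that sample at learned fractional offsets through the
  triangular kernel `GS(v, it) = max(0, 1 − |v − it|)`.
* **Hyperparameter tuning.** The network's epoch count `E ∈ [10, 20]` and
  learning rate `η ∈ [0.1, 0.9]` are chosen by **DS-EFO** (distance-sorted
  Electric Fish Optimization), a swarm optimizer whose individuals switch
  between local "active electrolocation" and global "passive
  electrolocation" by comparing their distance to the best solution with
  the population mean distance. Detection minimizes
  `fr1 = 1/(accuracy + precision)`; denoising minimizes the MAE to the
  clean target.
* **Mitigation.** Flagged epochs are split per channel by **Empirical Mean
  Curve Decomposition** (EMCD): iterated subtraction of the mean of the
  spline envelopes through maxima and minima, yielding oscillatory modes
  plus a leftover trend that sum exactly to the input. A deformable-network
  denoiser restores the artifact-bearing modes and the inverse EMCD
  (summation with the untouched leftover) produces the retrieved signal.

Because real recordings have no artifact-free ground truth, the package
ships a first-class **semisimulation module**: synthetic clean EEG
(theta/alpha/beta oscillators plus 1/f noise; default geometry 25 channels
= 22 EEG + 3 EOG, 288 epochs of 6 s at 250 Hz) contaminated by blink-like
squared-half-sine pulses at a configurable clean/artifact power ratio
(SNR), with the exact artifact component and clean target stored alongside.

## Worked example

```r
library(ocuclean)

# Semisimulated dataset: 10 channels (7 EEG + 3 EOG), 80 epochs of 3 s,
# half of them contaminated at SNR 1
ds <- semisim_dataset(seed = 8, n_channels = 10, n_epochs = 80, duration = 3)
ds
#> <epoch_tensor> 10 channels (7 EEG, 3 EOG) x 750 time points x 80 epochs @ 250 Hz
#>   contaminated epochs: 40 / 80

cfg <- default_config(seed = 8)
cfg$features$n_components <- 20L   # small fixture; the default 83 needs >= 84 epochs
res <- run_full(ds, cfg)
res
#> <run_result>
#>   detection: 39 epochs flagged
#>     held-out accuracy 0.958, precision 1.000
#>   mitigation: 39 epochs, mean MAE 4.173 (baseline 4.526), mean corr 0.910 (baseline 0.722)
```

Reading the output: the tuned detector labels 39 of the 80 epochs as
artifactual and reaches 95.8% accuracy on the held-out 30% test split.
Mitigation then processes exactly those 39 epochs: relative to the stored
clean target, the mean per-epoch Pearson correlation rises from 0.722
(contaminated) to 0.910 (retrieved) and the mean absolute error in µV falls
from 4.53 to 4.17. Epochs predicted clean are passed through untouched.

The same machinery is exposed piecewise — `generate_clean_eeg()`,
`contaminate()`, `dwt5_decompose()`, `pisarenko_analyze()`,
`pca_fit_transform()` / `ica_fit_transform()`, `efo_optimize()`,
`dcn_train()`, `emcd_decompose()` / `inverse_emcd()`,
`detection_report()` — and a thin CLI wraps the pipeline:

```sh
Rscript inst/scripts/ocuclean simulate --seed 1 --out data/
Rscript inst/scripts/ocuclean run --input data/semisim_data.csv --seed 1 --out out/
```

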