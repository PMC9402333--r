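# emdecg — adaptive ECG denoising by empirical mode decomposition

Electrocardiograms pick up white Gaussian noise from the acquisition
chain, electromyographic (EMG) muscle artifact, 50/60 Hz powerline
interference, and respiration-driven baseline wander. Classical filters
trade these off against the ECG's own broadband QRS complex; `emdecg`
instead decomposes the record into intrinsic mode functions (IMFs) by
empirical mode decomposition (EMD) and decides *adaptively*, per record,
which modes are noise.

For a record $x(t)$, sifting repeatedly subtracts the mean of the cubic
spline envelopes through the local maxima and minima until the iterate is
an IMF (extrema and zero-crossing counts agree to within one), using the
normalised standard difference

$$\mathrm{NSD} = \sum_t \frac{(h_{i-1}(t)-h_i(t))^2}{h_i(t)^2}$$

as the convergence statistic. The denoiser then

1. computes the cumulative means $R_k = \mathrm{mean}\sum_{i\le k}\mathrm{IMF}_i$
   and mode powers $P_k = \sum_t \mathrm{IMF}_k(t)^2$;
2. marks the leading modes with $|R_k|$ below an adaptive threshold (at
   most the first two) as noise candidates, and confirms a candidate only
   if its amplitude is small against the record's peak deflection;
3. optionally strips baseline wander by detaching the residue and the
   sub-0.5 Hz modes while a piecewise slope metric does not increase,
   preserving the record's DC reference;
4. reconstructs $\widehat{\mathrm{ECG}} = \sum_l g_l\,\mathrm{IMF}_l\;(+\,\text{residue})$.

Denoising quality is scored by output-SNR improvement, MSE and PRD
(percentage root-mean-square difference). A synthetic generator provides
controlled ECG + noise mixtures at exact input SNRs, and a seeded
Monte-Carlo harness evaluates the pipeline over a noise × SNR grid.

## Worked example

```r
library(emdecg)

ecg   <- synth_ecg(duration_s = 30, fs = 360, heart_rate_bpm = 72, seed = 1)
noise <- gen_noise("gaussian", length(ecg), ecg$fs, seed = 2)
noisy <- mix_at_snr(ecg, noise, target_snr_db = 5)

den <- ecg_denoise(noisy$corrupted)
den
#> Adaptive EMD denoising of 'synthetic ECG + noise @ 5 dB' (10800 samples @ 360 Hz)
#>   12 IMFs; noise IMFs removed/attenuated: 1, 2
#>   baseline components detached: residue, IMF 12, IMF 11

snr_improvement(ecg$samples, noisy$corrupted$samples, fitted(den))
#> [1] 5.169528
c(mse = mse(ecg$samples, fitted(den)), prd_pct = 100 * prd(ecg$samples, fitted(den)))
#>        mse    prd_pct
#> 0.00346048 30.9612...
```

The record was corrupted at 5 dB input SNR; denoising removed the two
noise-bearing high-frequency modes plus the slow wander components and
moved the record 5.2 dB closer to the clean reference. `summary(den)`
prints the per-mode table (cumulative mean, power, gain, zero crossings)
behind that decision; `fitted()`, `residuals()`, `coef()` and `plot()`
work as on any fitted-model object. `emd()` exposes the bare
decomposition.

A Monte-Carlo sweep over the standard grid:

```r
res <- run_grid(ecg, noise_kinds = c("gaussian", "emg", "powerline"),
                snr_levels_db = seq(0, 25, 5), reps = 100, master_seed = 1)
write_report(res, "report.json")
```

## Command line

A thin CLI over the same functions ships in `inst/cli/emdecg.R`:

```sh
Rscript inst/cli/emdecg.R synth --fs 360 --duration 30 --hr 72 --seed 1 -o ecg.csv
Rscript inst/cli/emdecg.R decompose -i ecg.csv -o imfs/
Rscript inst/cli/emdecg.R denoise -i noisy.csv -o denoised.csv --diagnostics diag.json
Rscript inst/cli/emdecg.R evaluate --noise gaussian,emg --snr 0,5,10,15,20,25 \
        --reps 100 --seed 1 -o report.json
```

Signals travel as `time_s,amplitude` CSV (or a single amplitude column
plus `--fs`); reports as JSON or CSV with a documented schema. Every flag
can also live in a flat `key=value` config file (`--config`); flags win.

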