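# ssarhythm

Adaptive singular spectrum analysis (SSA) for extracting brain rhythms —
delta, theta, alpha, beta — from single-channel EEG recordings, with a
principled rule for the one parameter SSA is most sensitive to: the
embedding dimension.

## Who this is for

EEG and biomedical-signal researchers who need to isolate a narrowband
rhythm (most commonly the 8–13 Hz alpha rhythm) from a recording
contaminated by ocular artifacts, baseline drift and measurement noise,
where a plain bandpass filter cannot reject contamination that overlaps the
rhythm's own band. The package also ships a Markov Process Amplitude (MPA)
EEG simulator, so every claim can be checked against synthetic records with
known ground truth.

## The method

SSA maps a length-N series **s** into the K×L Hankel *trajectory matrix*
(K = N − L + 1 lagged windows of length L), decomposes it by SVD into
rank-one elementary matrices, groups the components that carry the rhythm
of interest, and maps the grouped matrix back to a series by diagonal
averaging. Each reconstructed component (RC) has its spectrum confined to a
band of width roughly

```
f_b = (K/L) · (f_s/K) = f_s / L
```

so the embedding dimension controls the spectral granularity of the
decomposition. The package's selection rule chooses the smallest window
compatible with the target rhythm bandwidth `f_b`:

```
L = ⌈ f_s / f_b ⌉        (alpha band at f_s = 200 Hz:  L = 200/5 = 40)
```

Too small an L lets out-of-band energy into the rhythm's components; too
large an L splits and mixes components once artifacts are present. Two
diagnostics back the rule: a DFT-based approximation of the Toeplitz
lag-covariance eigenvalues (each eigenvalue averages a spectral slice of
width ≈ f_s/L), and the trace profile, whose change rate
`Tr_L − Tr_{L−1} = Σ_{j=L}^{K} s_j²` decays as L grows.

Grouping is adaptive: an RC joins the rhythm when its Welch-PSD peak lies
inside the band and clears a power floor, so the same call adapts to
records with different artifact and rhythm levels.

## Worked example

Simulate an 8 s eyes-closed record at 200 Hz (four Markov-amplitude rhythms
plus EOG pulses, baseline drift and Gaussian noise), then pull out the alpha
rhythm:

```r
library(ssarhythm)

sim <- simulate_eeg(mpa_config("eyes-closed", seed = 42))
eeg <- sim_channel(sim, "eeg")

alpha <- extract_rhythm(eeg, rhythm_band("alpha"))
attr(alpha, "L")             # 40    <- ceiling(fs / fb) = 200 / 5
selected_components(alpha)   # 2 3   <- RCs whose PSD peaks fall in 8-13 Hz
rhythm_power(alpha)          # 91.6 uV^2 (ground-truth alpha: 135.3 uV^2)

eps_ave(
  estimate_psd(sim_channel(sim, "alpha")),
  estimate_psd(alpha)
)                            # 0.542 uV^2/Hz mean absolute PSD error
```

The decomposition itself is a first-class fitted object:

```r
fit <- ssa(eeg, L = 40)
generics::tidy(fit)
#> # A tibble: 40 x 4
#>   rc_index eigenvalue singular_value energy_share
#>      <int>      <dbl>          <dbl>        <dbl>
#> 1        1   8564834.          2927.       0.358
#> 2        2   4483132.          2117.       0.187
#> 3        3   3954669.          1989.       0.165
#> ...
autoplot(fit)                      # eigenvalue scree
autoplot(estimate_psd(alpha))      # spectrum of the extraction
```

The same extraction on the matching eyes-open record (alpha innovation
scaled by 0.3) returns a power of 14.4 µV², an order of magnitude below the
eyes-closed 91.6 µV² — the separation that drives eyes-open/eyes-closed
classification:

```r
cls <- run_state_classification(n_per_class = 30, seeds = 1:60)
generics::glance(cls)   # per-method best threshold and accuracy
autoplot(cls)
```

A thin command-line front end wraps the same functions
(`inst/scripts/ssarhythm`, subcommands `simulate`, `extract`, `diagnose`,
`evaluate`, `classify`, `sweep`).

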