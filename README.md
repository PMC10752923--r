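# topodep

Simulate multivariate time series whose frequency-specific dependence
network has a **prescribed topology** — one cycle, two cycles, a torus, a
sphere — and recover that topology from the data with coherence-based
Vietoris–Rips persistent homology.

Topological data analysis of brain signals (EEG, LFP) works on the
dependence network of the recording: channels are nodes and distances are a
decreasing function of coherence.  There is no ground truth in real
recordings, so TDA pipelines for time series cannot be validated on them.
`topodep` provides the missing benchmark generator plus the complete
analysis half, for statisticians and methods developers who need to
evaluate sensitivity, specificity and power of topological methods, or to
build simulation-based null distributions for hypothesis tests.

## The model

Each node of a dependence graph `G` carries an independent latent AR(2)
oscillation

    Z(t) = φ₁ Z(t−1) + φ₂ Z(t−2) + W(t),   φ₁ = (2/M) cos(2πf/SR),  φ₂ = −1/M²,

whose characteristic roots `M e^{±i2πf/SR}` (`M > 1`, close to 1)
concentrate spectral power at the peak frequency `f`.  Observed channels
are distance-decaying mixtures plus Gaussian noise:

    Y_p(t) = Σ_q W_{p,q} Z_q(t) + ε_p(t),   W_{p,q} = 1/(1 + d_G(p,q))  if d_G(p,q) ≤ K, else 0.

Channels within `2K` hops share latent oscillations and cohere; channels
farther apart are independent — so the coherence-distance network inherits
the topology of `G`.  Recovery runs: periodogram → Daniell smoothing →
band coherence `C` → distance `D = 1 − C` → Vietoris–Rips persistence
diagram (computed by the package's own persistent-cohomology engine) →
total persistence `P_k = Σ (death − birth)` and prominent-feature counts
(empirical Betti numbers).

## Worked example

The 30-node circular ladder (one main cycle) has closed-form channel
correlations; adjacent channels correlate at 60/79 and channels five hops
apart share no latents:

```r
library(topodep)
g <- circular_ladder(15)
W <- mixing_weights(shortest_path_distances(g), K = 2)
R <- theoretical_correlation(W)
round(R[1, 2], 2)
#> [1] 0.76
R[1, 6]
#> [1] 0
```

Simulate 20 s of a 153-channel series on a 9×17 torus and recover its Betti
numbers (β₁ = 2, β₂ = 1) from mid-band (8–12 Hz) coherence:

```r
y <- simulate_network_series(torus_grid(9, 17), band_preset("alpha"),
                             K = 3, n_time = 2000, noise_sd = 1, seed = 1)
pd <- coherence_persistence(y, band_hz = c(8, 12), max_dim = 2)
c(cycles = prominent_features(pd, 1), cavities = prominent_features(pd, 2))
#>   cycles cavities
#>        2        1
```

The two prominent 1-dimensional features are the torus's two independent
cycles; the prominent 2-dimensional feature is its cavity.  Finally, the
bootstrap group comparison: one-cycle vs two-cycle models (both 32
channels) separate in their cyclic structure but not in connectivity:

```r
two_group_experiment(N = 20, B = 200, seed = 1)
#> two_group_result: N = 20 per group, B = 200
#>   dim 0: mean one_cycle 13.7880, two_cycle 13.8496, diff CI [-0.0798, 0.1877]
#>   dim 1: mean one_cycle 1.8378, two_cycle 2.1578, diff CI [0.1852, 0.4465] *separated*
```

A command-line interface wrapping the same functions (subcommands
`simulate`, `persist`, `snr-study`, `infer`, `presets`; YAML configs with
every default recorded back into a resolved config) ships in
`inst/cli/topodep.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/topodep.R", package="topodep"))')" \
    simulate --preset torus --out torus_run
```

See `vignette("topodep-methods")` for the model's assumptions, parameter
guidance, and the design of the SNR robustness study and the bootstrap
comparison.

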