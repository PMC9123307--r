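# synaptoquant

Quantification toolkit for the bespoke measurements that recur in studies
of synaptic cytokine-receptor signaling — for electrophysiologists and
imaging scientists who need the exact published procedures as tested,
reusable code rather than one-off scripts:

- **Puncta colocalization** (super-resolution imaging): iterative-threshold
  connected-component detection — cutoff swept 255 → 95, components > 25 px,
  intensity-weighted centroids, marker-dependent exclusion margins — and
  object-based colocalization of r = 4 px synapse disks between channels.
- **Readily releasable pool (RRP)**: back-extrapolation of the cumulative
  EPSC amplitude plot of 100-pulse / 20 Hz trains. With cumulative amplitude
  $C_n$, an OLS fit over stimuli 90–100 gives the effective pool (intercept,
  pA) and vesicle recruitment rate (slope, pA/stimulus). Includes the sweep
  QC rules (≥ 10 sweeps, ≤ 30 MΩ series resistance, AP-sweep removal).
- **Miniature PSCs**: automated event detection (2 kHz low-pass, sliding
  median baseline, robust 4 SD threshold, kinetic and width gates) and
  frequency/amplitude statistics.
- **LFP**: multitaper band power over δ 1–3, θ 4–10, α 11–15, β 16–30,
  low γ 31–70, high γ 71–100 Hz, and negative-threshold spike detection
  (5 × SD, 30 SD artifact exclusion, −0.5…+3 ms snippets).
- **Bayesian two-group comparison**: BEST-style t-likelihood model
  ($y_j \sim t(\nu, \mu_j, \sigma_j)$, published default priors, 100,000
  MCMC draws), with the accuracy rule
  $\mathrm{acc} = 100\cdot\max(P(\Delta\mu>0), P(\Delta\mu<0))$ mapped to
  significance stars at 80/90/95%, plus Monte-Carlo-calibrated univariate
  outlier gating.
- **Morphology**: Sholl crossings (6 µm rings to 720 µm) on SWC trees,
  spine classification (stubby/mushroom/long-thin/filopodia with the 4 µm /
  0.2 µm gates), spine density, and 50 nm vesicle distance binning.

Every input has a synthetic generator with planted ground truth (depressing
trains from a vesicle-depletion model, Poisson mini traces, band-limited
LFP with embedded spikes, planted-colocalization image pairs, heavy-tailed
group samples, random SWC trees), so the whole pipeline is testable without
any raw data. See `vignettes/synaptoquant-methods.Rmd` for the models,
parameter choices, and limitations.

## Worked example

```r
library(synaptoquant)

# a depressing 20 Hz train from the depletion model: N0 = 1000 vesicles,
# p = 0.3, r = 300 vesicles/s, q = 4 pA  =>  RRP = q*(N0 - Nss) = 3800 pA
rec <- simulate_train(train_sim_spec(), seed = 1)
est <- estimate_pools(qc_filter_sweeps(rec))
est
#> <pool_estimate> RRP 3528.0 pA, replenishment 62.22 pA/stimulus (fit 90-100, R^2 0.9905)

# two-channel puncta field with 30% planted colocalization
field <- gen_puncta_image_pair(puncta_field_spec(), seed = 1)
ref <- detect_puncta(normalize_to_255(field$image_a))
mark <- detect_puncta(normalize_to_255(field$image_b))
colocalize(ref, mark)
#> <coloc_result> 60/200 reference puncta colocalized (30.0%), 200 marker puncta

# Bayesian comparison of two groups
g <- gen_group_samples(group_sample_spec(n1 = 12, n2 = 12, mu1 = 1), seed = 2)
post <- fit_best(g, n_draws = 20000, seed = 3)
classify_accuracy(post)
#> <significance_call> accuracy 99.2% (***); 95% HDI of delta_mu [0.286, 2.393]
```

The pool estimate recovers the simulator's closed form (3800 pA, 60
pA/stimulus) to within the noise of one 15-sweep recording (the estimator
is unbiased across recordings; a single back-extrapolation carries ~10%
spread); the colocalization fraction recovers the planted 30%; the
accuracy call says 99.2% of the posterior mass of $\Delta\mu$ lies on the
observed side of zero, crossing the 95% threshold for the highest
significance tier.

## Command line

```sh
inst/cli/synaptoquant simulate puncta --seed 1 --out field
inst/cli/synaptoquant coloc --ref field_a.tif --marker field_b.tif \
    --marker-type vglut1 --out coloc.json
inst/cli/synaptoquant train-pool --in sweeps.csv --out pools.json
inst/cli/synaptoquant best --in groups.csv --seed 7 --out best.json
```

Each run writes a `.manifest.json` (subcommand, parameters, seed, inputs,
version) sufficient to reproduce it exactly.

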