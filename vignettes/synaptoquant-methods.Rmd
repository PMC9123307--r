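---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptoquant)
```

synaptoquant bundles the bespoke quantification procedures used in studies
of synaptic cytokine-receptor signaling: object-based colocalization of
super-resolution synaptic puncta, readily-releasable-pool (RRP) estimation
from high-frequency stimulus trains, miniature postsynaptic current (mPSC)
statistics, local field potential (LFP) band power and extracellular spike
counts, a BEST-style Bayesian two-group comparison with an accuracy-based
significance rule, and neuronal morphology metrics (Sholl profiles, spine
classes, vesicle distance histograms). No raw recordings accompany the
procedures, so every stage ships with a synthetic-data generator that plants
a known ground truth; the test suite and the acceptance criteria are
property-based against that truth or against independent brute-force
oracles.

## Puncta detection and colocalization

Two channels (a receptor as the reference channel and a presynaptic marker,
VGLUT1 for excitatory or VGAT for inhibitory terminals) are processed
independently. Pixel intensities are min-max normalized to the 0–255 range
and rounded; a constant image has no dynamic range and maps to all zeros
with a warning, so it can never yield detections. Detection then sweeps an
intensity cutoff from 255 down to 95. The decrement per iteration is 1
intensity unit — the source procedure states only that the cutoff decreases
per iteration, and one unit is the finest step consistent with the 8-bit
range. At each cutoff, pixels at or above the cutoff are labeled as
connected components (8-neighbor by default, configurable to 4); components
strictly larger than 25 px are accepted if their intensity-weighted centroid
(first image moments) does not fall inside the exclusion margin of a
previously accepted punctum, and a disk of the marker-dependent exclusion
margin (10 px for VGAT, 5 px for the denser VGLUT1) is masked from all later
cutoffs. Accepted components within one cutoff are scanned in row-major
order and take effect immediately for the centroid-exclusion check; their
masks apply from the next cutoff, since the current binarization is already
fixed.

Accepted regions represent synapses as nominal disks of radius 4 px at the
centroid. No circularity criterion is applied by default — the source
procedure states no shape gate beyond the size cutoff — but a roundness
filter (component area over the disk spanned by its farthest pixel) can be
switched on via `coloc_params(roundness_min =)`. A reference punctum is
colocalized when its disk overlaps any marker disk, i.e. when the center
distance is at most `2 * 4` px with closed disks (touching counts); the
reported fraction is over reference puncta, and one marker punctum may
serve several reference puncta. Whether the exclusion margin should also
suppress detections in the *other* channel is ambiguous in the source; the
channels are processed fully independently here (same-channel masking
only), which keeps detection a per-channel operation.

The synthetic puncta generator plants `round(fraction * n_A)` colocalized
pairs within a stated center offset (2 px by default) and keeps every other
center pair at least four punctum radii apart, so planted truth is
unambiguous under the overlap rule. Spots are isotropic Gaussians with
`sigma = radius / 2`, truncated at 3 sigma, approximating
diffraction-limited super-resolution spots; background noise is Gaussian.
The generator's default punctum radius is 6 px: with the stated rendering,
a 4 px spot holds only ~21 px above the 95 cutoff and would sit below the
strict >25 px size gate, whereas 6 px (~0.12 µm at the ~0.02 µm/px pitch of
the targeted acquisitions) yields ~50 px and is a realistic synapse spot
size. Pixel pitch is carried as metadata only; all thresholds are in
pixels.

## Stimulus trains and the readily releasable pool

The train simulator implements a single-pool depletion model of 100 pulses
at 20 Hz: with pool $N_1 = N_0$, release fraction $p$, replenishment $r$
(vesicles/s, $\Delta t = 1/\text{rate}$) and quantal amplitude $q$,

$$A_k = q\,p\,N_k, \qquad N_{k+1} = N_k - p\,N_k + r\,\Delta t,$$

whose closed form is $A_k = q p (N_{ss} + (N_0 - N_{ss})(1-p)^{k-1})$ with
$N_{ss} = r\Delta t / p$. The pool is deliberately not capped at $N_0$:
replenishment over a 5 s train is small against the resting pool, so a cap
would never engage at realistic parameters. Sweep noise is i.i.d. additive
Gaussian per pulse (default SD 5% of the first-pulse amplitude); no
run-down is modelled because the emulated protocol models none.

Estimation mirrors the published back-extrapolation: sweeps that carry
action potentials are removed (the flags are input metadata — removal was a
manual step in the source workflow, so no automatic AP detector is in
scope), recordings with fewer than 10 surviving sweeps or any sweep above
30 MΩ series resistance are rejected with a machine-readable reason,
amplitudes are averaged across sweeps per stimulus, cumulated, and an
unweighted ordinary least squares line is fit to cumulative amplitude over
stimuli 90–100 (11 points). The y-intercept estimates the effective RRP in
pA and the slope the recruitment rate in pA/stimulus. Averaging before
cumulating (fit the averaged cumulative curve once, rather than fitting per
sweep and averaging fits) follows the stated order of operations in the
source; for noiseless data the two are identical, and for additive noise
the single fit has the lower variance. For the noiseless model the fit
window is deep in steady state ($(1-p)^{90} \approx 10^{-14}$ at $p=0.3$),
so intercept and slope equal $q(N_0-N_{ss})$ and $q r \Delta t$ to well
under 1%.

## Miniature events

The automated detector stands in for an undisclosed in-house script, so its
rules are documented and configurable rather than canonical: the trace is
low-pass filtered at 2 kHz (the acquisition filter), detrended by a 200 ms
sliding-median baseline, and the noise SD is estimated robustly as the
median absolute deviation divided by 0.6745. Deflections beyond 4 SD in the
negative (inward) direction are events if they stay above threshold for at
least 1 ms in total (band-limited noise excursions last ~0.2 ms and are
rejected by this width gate), have a 10–90% rise time under 5 ms, and are
separated by more than a 5 ms dead time — segments with shorter gaps are
fused into one event, so a decay that dips through threshold in noise is
not double-counted. Amplitude is the extremum minus the mean of the 2 ms
pre-onset baseline, reported positive. Frequency is events over duration;
the mean amplitude of an empty event set is reported as missing rather
than zero.

The mini generator draws homogeneous Poisson event times and adds
peak-normalized difference-of-exponentials transients (default rise
0.5 ms, decay 5 ms) negatively onto Gaussian noise at 10 kHz. Defaults
(120 s, 3 Hz, 20 pA events over 4 pA noise — signal-to-noise 5) are the
regime of the emulated recordings.

## LFP band power and spike detection

Wideband traces (20 kHz) are band-pass filtered 0.1–250 Hz, decimated to
~512 Hz, and transformed with a multitaper estimator. The taper parameters
are unstated in the source and fixed here as 2 s windows, 50% overlap,
time-bandwidth 3, 5 DPSS tapers (all configurable); DPSS tapers come from
the Slepian tridiagonal eigenproblem and are cached. Band power integrates
the one-sided PSD over closed intervals exactly as printed — δ 1–3, θ 4–10,
α 11–15, β 16–30, low γ 31–70, high γ 71–100 Hz. The printed table leaves
gaps (e.g. 3–4 Hz); fidelity to the printed definition is preserved by
excluding gap bins from every band *and* from the total, so the six band
powers sum to the reported total exactly. Both absolute and relative
(power/total) values are returned, since the source's normalization is
unstated.

Spike detection band-passes 0.3–3 kHz and thresholds in the negative range
at 5 times the noise SD. The source says "SD of signal"; the default
estimator is the robust `median(|x|)/0.6745`, which spike energy cannot
inflate, with the plain SD available via `robust_sd = FALSE`. Peaks beyond
30 SD are excluded as artifacts, a 1 ms dead time prevents double-counting
one transient, and a −0.5 to +3 ms snippet (`round(3.5 ms * fs) + 1`
samples) is cut around each retained peak. Both thresholds apply to the
*filtered* trace and its noise SD; the generator's spike scale is defined
on the raw noise SD, so a planted "−10 SD" template measures higher after
filtering (noise shrinks more than the spike) — comfortably detected and
still far from the exclusion limit, while planted "−40 SD" artifacts land
far beyond it. Spike sorting into single units is out of scope; counts and
rates are multi-unit. All filtering is zero-phase FFT filtering with
raised-cosine transitions (no IIR package is among the supported
dependencies), which also guarantees that detection does not displace
event times.

## Bayesian two-group estimation and the accuracy rule

Groups are modelled with independent t likelihoods sharing the normality
parameter: $y_{ji} \sim t(\nu, \mu_j, \sigma_j)$, with the published BEST
default priors — normal on each mean centered at the pooled mean with SD
$1000 \times$ the pooled SD, uniform on each group SD over
$[\text{pooled SD}/1000,\ \text{pooled SD} \times 1000]$, and a shifted
exponential with mean 29 on $\nu - 1$. The sampler is a Gibbs scheme over
the normal scale-mixture representation of the t, with an adaptive
random-walk Metropolis step (five sweeps per scan) on $\log(\nu - 1)$;
three chains with overdispersed starts run until the default 100,000 draws
are retained. Split-R̂ is reported per parameter; a clean run sits below
1.01, and the error threshold is 1.05 to leave Monte-Carlo headroom at
reduced draw counts — crossing it raises an error rather than returning
draws silently. The error gate covers the means and SDs (the quantities
every downstream summary uses); $\nu$ is weakly identified whenever the
data are near-Gaussian — the likelihood is almost flat above $\nu \approx
50$ — so its diagnostic is reported, and warned about when elevated, but
does not abort a run whose reported quantities have converged. The effect size uses the pooled-SD form
$(\mu_1-\mu_2)/\sqrt{(\sigma_1^2+\sigma_2^2)/2}$.

The source gives "accuracy" no formula. It is implemented as the larger
posterior tail probability of the mean difference,
$100 \cdot \max(P(\Delta\mu > 0), P(\Delta\mu < 0))$ — the posterior
probability that the group ordering is as observed — which reproduces the
monotone mapping onto the printed 80/90/95% star thresholds
(ns / * / ** / ***). A posterior-predictive variant (probability that a
predictive draw from one group exceeds one from the other) is available
behind `classify_accuracy(method = "posterior_predictive")`. The source's
claimed equivalence between 80% accuracy and a 5% (or 20%) type-I rate is
internally inconsistent and is not reproduced numerically. The companion
outlier gate flags points outside mean ± c(n)·SD, with c(n) calibrated by
seeded Monte-Carlo simulation of Gaussian samples so that a clean sample of
size n (3–100; extendable) is flagged anywhere with probability exactly 5%.
Gating precedes model fitting, and removals are always recorded by the
pipeline rather than silent.

The two-group generator draws from shifted/scaled t distributions. For
$\nu > 2$ the scale is chosen so the *standard deviation* equals the stated
SD (raw t scale divided by $\sqrt{\nu/(\nu-2)}$), so generated samples match
their stated moments; for $\nu \le 2$, where no SD exists, the stated value
is the raw scale. Injected outliers replace points of group 1 at a stated
SD offset, and the truth records their indices.

## Morphology

Sholl analysis counts crossings of concentric spheres (6 µm steps to
720 µm, 120 radii) around the soma, taken as the centroid of the SWC
type-1 nodes (multi-point somata collapse to their centroid). Crossings
are computed exactly per straight segment from the quadratic
$|P(t)|^2 = r^2$: one crossing when the endpoint distances straddle the
radius, *two* when both endpoints lie outside but the segment dips inside
between them. The simpler endpoint-straddling rule misses the dip case;
the exact rule is what a dense sampling of the segment converges to, and
the test suite pins equality against such a brute-force oracle. An
endpoint exactly at the radius counts once.

Spine records are first gated by the published size limits (maximum length
4 µm, minimum end diameter 0.2 µm; violations are labeled `rejected`) and
then classified by an explicit surrogate for a commercial classifier whose
internal rules are not public: stubby = under 1 µm with no neck
constriction; mushroom = head wider than twice the neck; filopodia = over
2 µm without head enlargement; long/thin = remainder. Every record gets
exactly one label, thresholds are configurable, and the rule set is
validated for internal consistency only. Spine density is spines per µm of
dendrite, and presynaptic vesicle distances are binned in half-open 50 nm
bins from the synaptic cleft.

The tree generator grows equal-length straight segments from the soma with
exactly the requested number of bifurcations (daughters leave at the stated
branch angle, continuations wobble by ~8°); segment lengths sum exactly to
the requested total. It produces connected, acyclic, parent-before-child
SWC — adequate for exercising Sholl geometry, but it does not emulate real
dendrite taper, tortuosity, or type annotations.

## What the generators do not emulate

Synthetic images use Gaussian spots, not an optical PSF, and contain no
tissue background structure; synthetic trains have no run-down, failures,
or stimulus artifacts; mini traces have no overlapping-kinetics diversity
or seal instability; LFP noise is white rather than 1/f; group samples have
no animal-level covariance. A green test therefore establishes that each
algorithm does what it claims on data obeying its own model assumptions —
it does not certify performance on tissue with structured background, nor
reproduce the source study's tissue-derived numbers (e.g. ~29%
colocalization, ~2,300 vs ~4,000 pA pools), which came from recordings
that were never deposited.

## Numerical and interface choices

Seeded generators route all randomness through a seed argument and are
bit-reproducible. Traces interchange as `(time_s, value)` CSV and images as
uncompressed grayscale TIFF via a built-in minimal baseline codec (no HDF5
or TIFF package is in the supported dependency set; the CSV/TIFF halves of
the stated interfaces are kept, HDF5 dropped). The command-line interface
(`inst/cli/synaptoquant`) accepts JSON configuration files with
flag-override semantics, rejects unknown keys, writes a machine-readable
manifest (subcommand, parameters, seed, inputs, package version — enough to
reproduce any run exactly), logs to stderr, and exits 2 when an input file
is missing, 1 on any other failure.
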