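---
title: "Resting-state EEG network analysis: models, parameters, and numerical choices"
author: "restnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state EEG network analysis: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Resting-state EEG in clinical cohorts (here: chronic stroke survivors against
age-matched controls) carries two kinds of information: *where the power is* —
the distribution of oscillatory power across frequency bands and electrodes —
and *how regions talk* — the co-fluctuation of band-limited amplitude
envelopes between brain regions. Both are confounded at the sensor level:
absolute power depends on electrode impedance and on how much synchronous
tissue sits under an electrode, and zero-lag correlations between sensors are
dominated by volume conduction, the instantaneous spread of a single source
across many electrodes (up to several centimetres of scalp). `restnet`
implements a pipeline that addresses both confounds and carries the result
through to group-level inference.

## Sensor-level model

Recordings are cut into consecutive, non-overlapping 2-s epochs (a 3-min
recording yields ~90), zero-meaned per epoch. Channels and epochs whose
variance or kurtosis exceeds the across-channel (across-epoch) mean by more
than 2 SD are flagged; flagged channels are rebuilt by inverse-distance-squared
weighting of good neighbours within 0.35 rad on the unit sphere (sparser
montages need a larger radius; the 19-channel layout uses 0.8), and flagged
epochs are dropped. For stroke subjects with a right-sided lesion, homologous
electrode pairs (odd/even 10-20 labels) are swapped so the lesioned hemisphere
is always analysed as "left". Data are then re-referenced to the common
average, which reintroduces the recording reference (FCz) as an extra channel,
and separated into ten non-overlapping 5-Hz bands from 1 to 50 Hz (the first
band starts at 1 Hz because of the broadband high-pass) with a fourth-order
zero-phase Butterworth filter applied per epoch.

Power is estimated by Welch's method with epochs as the measure of
consistency: each epoch is one segment (Hann-tapered, power-normalized so
Parseval holds), periodograms averaged across epochs, 0.5-Hz resolution. Band
power sums half-open bins $[f_{lo}, f_{hi})$, so the ten bands partition the
spectrum. Normalized power removes the gain confound:

$$NP = 100 \times \frac{\sum F}{\sum Total}$$

where $\sum F$ is power in one band and $\sum Total$ is power over 1–50 Hz at
that electrode; rows sum to 100 and the quantity is exactly invariant to any
per-recording gain. Hemispheric imbalance is summarized by the electrode
directional asymmetry

$$EDA = 100 \times \frac{1}{n}\sum \frac{NP_L - NP_R}{NP_L + NP_R}$$

over homologous pairs (midline ignored): positive means more normalized power
in the left (lesioned) hemisphere. Group contrasts run a pooled two-sample t
test per electrode per band with Benjamini–Hochberg FDR across electrodes
within each band at $\alpha = 0.05$ (the correction scope follows how such
topographies are plotted: one map per band).

## Region-level connectivity

Source localization itself is out of scope: the pipeline consumes a
user-supplied linear inverse operator (voxels x sensors). In the synthetic
studies shipped with the package the operator is the Moore–Penrose
pseudo-inverse of the known mixing matrix, with a zero column appended for the
reinserted reference channel. Dipole triplets, if present, and voxels within a
region are each collapsed to one series by PCA (first principal component,
sign-aligned with the voxel mean; covariance computed on the concatenated
retained epochs). An AAL-shaped atlas utility reduces 116 regions to a
rank-compatible 61: cerebellar regions merge to one per hemisphere, the eight
vermis regions to one, subcortical regions stay, and left cortical regions are
merged iteratively — smallest into nearest centroid, sizes summed, centroids
size-weight-averaged, ties broken lexicographically — with the identical
sequence mirrored on the right so the result stays symmetric. (With 45
cerebrum regions per hemisphere of which 6 are subcortical, 39 cortical per
hemisphere reduce to 23; 12 + 2 + 1 + 2 x 23 = 61, the rank limit of a
61-channel dataset.)

Within each band, region series are orthogonalized by the symmetric
multivariate correction: the iterative closest-orthonormal-basis fit that
alternates (i) polar decomposition of the scaled signal matrix (SVD) to get
the nearest orthonormal basis and (ii) per-region scale refit by projection,
run for a fixed 20 iterations with no early stopping. This removes all shared
zero-lag components without privileging any seed region; afterwards pairwise
zero-lag correlations are below 1e-6. The scheme requires the region count not
to exceed the rank of the data and errors out otherwise. One property worth
knowing: because the scales are refit by projection, the result is only
*approximately* invariant to a per-region gain change (a 3x rescaling of one
region moves envelope correlations by ~0.01 on typical leaky data). Envelope
correlation itself, and normalized power, are exactly gain-invariant.

Amplitude envelopes are the magnitude of the analytic signal (one-sided FFT
Hilbert transform) of the epoch-concatenated band series; samples within 12
samples (3 x filter order) of an epoch junction are excluded from
correlations, confining filter transients. Envelope pairs are Pearson
correlated and Fisher z-transformed ($z = \mathrm{atanh}\, r$; $|r| = 1$ maps
to missing rather than infinity).

Raw envelope correlations fall with frequency for a fixed window simply
because higher bands carry more independent envelope samples. The pipeline
therefore normalizes against a surrogate null: each region's series is
phase-randomized (independent uniform phases per region and frequency bin, DC
and Nyquist kept real, amplitude spectrum exactly preserved), the full
downstream pipeline — orthogonalization included — is re-run, and the per-edge
mean and SD over iterations define

$$z = \frac{\mathrm{atanh}(r) - \mu_{null}}{\sigma_{null}}.$$

The study-scale iteration count is 1000; the package default is 200 (desk
scale), which calibrates to |mean| < 0.03 and SD within 1% of 1 on
independent data at ~500 edges. A `null_skip_orthogonalization` flag drops the
orthogonalization inside the surrogate loop for speed, but it defaults to off:
the observed statistic passes through orthogonalization and the null should
match.

Connectivity directional asymmetry mirrors EDA at the edge level:

$$CDA = 100 \times \frac{1}{n}\sum \frac{C_L - C_R}{C_L + C_R}$$

over homologous within-hemisphere edge pairs (each left edge against its
mirrored right edge); inter-hemispheric edges and region-to-own-mirror edges
are excluded. Connectivity spectra average bias-corrected z over all
within-hemisphere edges per band; each subject's spectrum is correlated with
the control-group mean spectrum and Fisher z-transformed, with $|r|$ capped at
$1 - 10^{-12}$ so downstream statistics stay finite.

## Network statistics

The Network Based Statistic treats supra-threshold graph components the way
cluster-based methods treat contiguous pixels. Edge-wise t statistics
(one-sample against zero within a group; pooled two-sample between groups) are
thresholded — positive and negative tails tested separately — and connected
components are measured by extent (edge count). The null distribution of the
*maximum* extent is built by permutation: random sign flips of each subject's
matrix for one-sample designs, group-label shuffles for two-sample; `p_fwer =
(1 + #{perm >= obs}) / (1 + n_perm)`, which includes the observed statistic
and is valid at any permutation count. Edge thresholds come from the inverse
Student-t: two-tailed p = .01 within groups (t = 3.169 at df 10, 3.012 at df
13) and p = .02 between groups (t = 2.5 at df 23). Because extent is a
discrete statistic, permutation p-values are sub-uniform (valid), not exactly
uniform; the test suite checks $P(p \le \alpha) \le \alpha$ rather than a
distributional identity no discrete statistic can satisfy.

## Group-level battery

Directional asymmetries are analysed with a two-way mixed ANOVA (frequency
within, group between) using classical split-plot sums of squares. Sphericity
is assessed by Mauchly's test on the pooled within-group covariance of
orthonormal contrasts (the convention of mainstream commercial packages; some
toolboxes pool across groups instead, which changes W and epsilon but not F);
when Mauchly rejects at 0.05, within and interaction p-values are
Greenhouse–Geisser corrected by scaling both degrees of freedom by
$\epsilon = (\mathrm{tr}\, S_c)^2 / ((k-1)\,\mathrm{tr}\, S_c^2)$, falling
back to the lower bound $1/(k-1)$ when the contrast covariance is singular
(bands >= subjects). GG conservativeness ($p_{GG} \ge p$) holds in the
relevant $F \ge 1$ regime; for $F < 1$ shrinking both df can lower p, which is
why the suite tests the invariant with a planted within-subject effect.
Families of follow-up tests are corrected step-down by Holm–Šidák
($p_{(i)} < 1 - (1-\alpha)^{1/(m-i+1)}$); pairwise band comparisons use a
bootstrap Tukey test: observed Tukey–Kramer studentized ranges referred to the
distribution of the bootstrap maximum q under the pooled, group-centered
residual distribution (10,000 iterations, seeded). Finally, any measure that
distinguishes the groups is regressed on the upper-extremity motor score
(OLS; stroke subjects only by default, controls optionally pinned at the
ceiling score of 66 for plotting).

## The synthetic cohort: what it emulates and what it does not

No public recordings exist for this design, so the package generates its own
world with known truth. Each region source in band $b$ is
$a_{rb}\, e_r(t)\, \Re\, c_r(t)$:

* **Envelopes** $e_r(t)$: latent white Gaussians correlated via the Cholesky
  factor of a calibrated latent correlation matrix, low-pass filtered
  (Butterworth, 2 Hz cutoff — the timescale of cortical power envelopes),
  standardized, then mapped through the shifted rectifier $|1 + 0.5 z|$.
  The rectifier attenuates correlations (pure $|z|$ would map a latent 0.5 to
  ~0.22 and cannot represent negative coupling), so the latent correlation is
  calibrated by numerically inverting the attenuation with 2-D Gauss–Hermite
  quadrature; empirical envelope correlations land within +-0.02 of target at
  60 s of data.
* **Carriers** $c_r(t)$: unit-modulus band-limited analytic noise — Fourier
  coefficients drawn only inside the band (inset by a fifth of the bandwidth
  so modulation sidebands stay in band), normalized to constant modulus. A
  plain Gaussian carrier would contribute its own Rayleigh-distributed
  envelope fluctuation and cap the achievable envelope-tracking correlation
  near 0.76; the constant-modulus carrier lets the Hilbert envelope track the
  requested one at r > 0.99.
* **Amplitudes** $a_{rb}$: the band profile (default $1/\sqrt{f}$, i.e. 1/f
  power) times the per-band left-hemisphere asymmetry factor. Each source is
  normalized to exact unit RMS before scaling, so planted powers hold by
  construction, not just in expectation.
* **Mixing**: a Gaussian spatial kernel from region centroid to sensors
  (width 0.4 on the unit sphere, roughly a 4-cm spread on a 10-cm head) stands
  in for volume conduction; 1/f background noise is added at a configurable
  source-to-noise power ratio and the whole recording scaled to ~20 uV RMS.

The default two-group world plants the study's qualitative findings: stroke
subjects lose half their source power in the 10–20 Hz bands, lose
left-hemisphere amplitude (factor 0.6) in the 15–50 Hz bands, drop planted
envelope coupling from 0.6 to 0.15 in the 10–20 Hz bands and raise it to 0.85
at 35–40 Hz, on a connected four-region clique spanning both hemispheres
(about half the planted edges inter-hemispheric). Between-subject variability
is a 10% log-normal jitter on band power. Group sizes default to 11 controls
and 14 stroke subjects. No quantitative effect sizes are published for this
design; these values were chosen once for testability — large enough that a
desk-scale cohort (8+8 subjects, 40-s recordings) recovers them, small enough
that recovery is not trivial — and are not calibrated to reproduce any
published group mean.

The generator does **not** emulate: blink/EMG artifacts (the rejection stage
is exercised by planted variance/kurtosis outliers instead), realistic head
geometry (the Gaussian kernel is rotationally symmetric), 1/f slope
variation, non-stationarity across the recording, or between-region leakage
beyond linear instantaneous mixing. A green recovery test therefore
establishes that the pipeline inverts its own stated forward model — linear
mixing, band-limited AM sources, 1/f noise — not that it is robust to every
pathology of real EEG.

## Numerical choices

* Filters are designed by bilinear transform with pre-warping and applied as
  cascaded second-order sections; the expanded order-8 direct form loses ~6
  digits on narrow bands. Zero phase comes from forward–backward application
  with odd-reflection padding, so the realized magnitude response is the
  square of the design's.
* Epochs are filtered individually (matching the stated processing order)
  and concatenated; envelope samples within 3 x order of a junction are
  masked out of correlations.
* Welch uses each epoch as one segment — no sub-windowing — with a
  power-normalized Hann taper (rectangular available); integrated PSD matches
  signal power within 5%.
* The interpolation kernel is inverse-distance-squared within an angular
  radius; spherical-spline interpolation was not implemented (no installed
  implementation, and the synthetic montage is idealized anyway).
* Fisher z of a perfect correlation is treated as missing; spectrum
  correlations are capped at atanh(1 - 1e-12).
* All stochastic stages take explicit integer seeds; reruns are bit-identical.
  Derived seeds stay below 2^31.
* Atlas merge ties (equal size or equal distance) break lexicographically by
  label, making the reduction deterministic.
* EDF output quantizes to 16 bits (~1e-4 relative); the internal container is
  lossless.

## Limitations

The ICA-based artifact separation used in practice is replaced by a pluggable
cleaning callback: component identification is manual and non-deterministic,
and belongs outside a reproducible pipeline. Forward/inverse modelling is
consumed, not computed. The bootstrap Tukey procedure implements pooled
centered-residual resampling — the cited methodology is a family of related
schemes, so results are documented as "similar to" rather than identical. The
mixed ANOVA pools within-group covariance for sphericity (see above); with
ten bands and small cohorts Mauchly is unavailable and the epsilon lower
bound applies, which is conservative. Desk-scale defaults (200 surrogate
iterations, reduced permutations) trade precision for runtime and are stated
wherever they differ from study-scale values.
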