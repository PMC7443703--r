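---
title: "Simulating and removing DBS artefacts in MEG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and removing DBS artefacts in MEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(megdbs)
```

## The problem

Deep brain stimulation (DBS) delivers trains of narrow electrical pulses
(here 130 Hz, 140 microsecond biphasic pulses) through implanted
electrodes. Recording MEG with the stimulator on is attractive for
studying DBS mechanisms, but the stimulation current and the movement of
the stimulator's extension wires contaminate the magnetometer signals
severely: the pulse train produces a dominant spectral line at the
stimulation frequency plus *aliased* lines scattered across the spectrum
(a pulse train has substantial energy far above any practical sampling
rate, so the acquisition chain folds high harmonics into the band), and
wire movement driven by arterial pulsation adds strong low-frequency
power on the channels nearest the wires.

`megdbs` re-creates this measurement situation synthetically with a
controllable spherical-phantom model — a single current dipole
oscillating at 12 Hz inside a conducting sphere, plus fully
parameterized artefact generators — and implements four sensor-level
artefact-rejection algorithms together with the sensor- and
source-level evaluation framework used to compare them: band-wise
log-power RMSE against an artefact-free Reference condition, LCMV
beamformer source maps with bootstrap activation thresholds, and the
intersection-over-union overlap `D` between activation maps.

## The generative model

Four linked conditions are simulated from shared noise streams
(`make_condition_set()`), so their differences are *exactly* the
artefact terms:

* **empty room** — white sensor noise (10 fT/sqrt(Hz) amplitude
  spectral density) plus fixed-topography line-noise sinusoids at 50,
  100, ..., 550 Hz with seeded phases;
* **Reference** — empty room + the dipole term;
* **DMW** — Reference + the movement-wire term;
* **DSMW** — DMW + the stimulation term, with the stimulation waveform
  additionally modulated by `(1 + displacement / 3 mm)` so the movement
  and DBS artefacts are coupled, as they are when the wires themselves
  carry the stimulation current.

**Forward physics.** All spatial patterns of intracranial sources go
through the closed-form field of a current dipole in a homogeneous
conducting sphere. For a spherical phantom this model is exact, and the
same code path builds the beamformer leadfield, so simulation and
source analysis share one physics. Two classic sphere properties are
exploited as tests: radial dipole moments are silent, and the radial
field component equals the free-space Biot-Savart field.

**Dipole.** Placed on the z axis at 60% of the sphere radius (depth is
not otherwise constrained by the phantom design), tangential moment of
20 nA m oscillating at 12 Hz. The depth is a design choice: deep enough
to be a realistic "brain" source, shallow enough that the order-8
interior multipole expansion converges comfortably at the sensors.

**DBS pulse train.** A charge-balanced biphasic rectangular train is
rendered at 192 kHz, passed through a deliberately weak 4th-order
Butterworth anti-alias filter cutting at 0.4 x 19.2 kHz, subsampled to
the 19.2 kHz acquisition rate, then decimated with a sharp linear-phase
FIR to the 2400 Hz output rate. Because 19200/130 is not an integer,
the pulses are sampled inconsistently and fold into aliased peaks at
frequencies that are not multiples of 130 Hz; setting the stimulation
frequency to a divisor of the acquisition rate (e.g. 150 Hz) makes the
aliases vanish, which is tested. The stimulation topography is a
mixture (default 50/50) of an intracranial bipolar-electrode dipole
field and the smooth posterior wire topography — the same current flows
through both paths, and the wire component is also what gives temporal
signal space separation a residual-space trace to detect.

**Stimulation gain calibration.** The paper-matched condition is a
*ratio*: the DBS spectral peak sits ~1.75 log10 power units above the
12 Hz dipole peak in the channel-mean Welch spectrum of DSMW (the ratio
observed between DBS and alpha peaks in patient recordings).
`calibrate_stim_gain()` solves for the gain from the component spectra
in closed form and then verifies/bisects on the fully recombined
recording's measured ratio. "Channel-mean log10 spectrum" here means
log10 of the channel-averaged power, used consistently for calibration
and measurement.

**Movement.** Displacement events every 2.5 s: a raised-cosine rise
over 40 ms to 3 mm, then an exponential-like decay (time constant 1/5
of the event duration, cosine-tapered to zero) whose duration is drawn
uniformly from 0.5-1.0 s per event (seeded). The spectrum is
concentrated below 15 Hz and strongest below 5 Hz; the sharp 40 ms rise
is also what gives the movement artefact genuine 12 Hz content, which
is why the DSMW source map at 12 Hz spreads beyond the dipole. The
wire-artefact field is this waveform times a fixed smooth random
topography weighted toward the posterior-most sensors (where the wires
are taped), scaled by `wire_gain`. The default `wire_gain = 1.8e-9` T/m
was tuned once so that DMW channel-mean power below 5 Hz is roughly ten
times the Reference level, the qualitative relation seen in the
phantom recordings; the value is configurable.

**DBS reference channel.** The movement-coupled stimulation waveform
plus a 5% 12 Hz leakage term (amplitude 5% of the waveform's RMS). The
leakage makes the 12 Hz notch applied before mutual-information ranking
meaningful: without notching, the reference would attract the dipole
component.

**Sensor array.** `n_channels` (default 128) point magnetometers on a
Fibonacci spiral over the upper 60% of a 12 cm sphere, *quasi*-radial:
orientations carry a small seeded tangential tilt (~10 degrees typical).
The tilt is not cosmetic — for exactly radial sensors on a single
shell, interior and exterior multipoles with the same degree and order
produce identical sensor patterns, so the inner/outer separation at the
heart of signal space separation is singular. Real helmets break this
degeneracy through varied sensor orientations and radii; the tilt plays
that role here (verified: the joint basis condition number drops from
~1e13 to ~1e4).

## The four cleaning algorithms

**Hampel filter** (`hampel_clean()`). Full-length FFT per channel (no
windowing); a Hampel identifier slides bin-by-bin over the one-sided
spectrum, flagging a bin as an outlier in the real or imaginary part
when it deviates from the window median by more than `C` robust SDs.
The robust scale is `1.4826 x MAD` (the classic identifier pairing;
plain window SD is selectable since the original description says only
"standard deviations above the median"). Medians are computed from the
input spectrum, outliers replaced by the window median, conjugate
symmetry restored, inverse FFT. The default 6 Hz window is at least
twice the ~0.2 Hz artefact width. In `dbs_band` mode only bins within
+/- 3 Hz of the stimulation harmonics are eligible, making the filter
exactly the identity elsewhere; `wide_band` mode runs everywhere (and
then also removes the sharp 12 Hz dipole peak — narrow peaks are
exactly what it detects). The sliding median/MAD is implemented in
C++ with an incrementally maintained sorted window and an O(window)
two-pointer median-of-deviations, since the per-bin windows are far too
numerous for an R loop.

**S3P** (`s3p_clean()`). STFT with 4 s Kaiser windows (beta = 14,
strong side-lobe suppression to keep the 0.25 Hz bins independent) at
50% overlap; per frequency, the cross-spectral density over windows is
eigen-decomposed and the projector `P(f) = I - U_k U_k^H` removes the
leading `k`-dimensional subspace; inverse FFT per window and weighted
overlap-add with window-sum-of-squares normalization. The signal is
zero-padded by one hop on each side so every sample is covered by two
windows (the Kaiser window's near-zero endpoints would otherwise make
the overlap-add denominator degenerate at the edges); `k = 0` is the
identity to numerical precision. Scope is `dbs_band` (stimulation
harmonics only) or `wide_band`.

**ICA-MI** (`ica_mi_clean()`). PCA to 75% of the channel count (the
full decomposition is rank deficient), sphering, then extended Infomax
ICA — implemented natively: natural-gradient ascent in blocks with
sub/super-Gaussian switching by the kurtosis sign of the unmixed
sources, learning-rate annealing on the gradient-direction angle, and
blow-up restarts. Any ICA of this class that passes the
planted-component test (a component whose time course copies the
reference channel must attain the top mutual-information rank) would
do; the decomposition itself is standard methodology, not this
package's contribution. Component ranking uses histogram mutual
information on rank-transformed signals (64 equal-width bins on the
unit square — rank transformation removes marginal effects and the bin
count balances bias and variance at the ~1e5-sample recordings used).
The reference channel is notched at 12 Hz first; the `ceil(R% x
n_components)` highest-MI components are zeroed and the rest
back-projected.

**tSSS** (`tsss_clean()`). Per non-overlapping 10 s segment, the data
are decomposed on interior (order 8, 80 components) and exterior
(order 3, 15 components) multipole bases evaluated on the sensor array
(fields obtained by high-accuracy central differences of the
spherical-harmonic scalar potentials; columns unit-normalized;
truncated-SVD pseudoinverse at a 1e-8 relative cutoff). Temporal
orthonormal bases of the inner reconstruction and of the residual are
intersected by canonical correlation; directions correlated above the
correlation limit `CL` are projected out of the inner part. Residual
temporal directions participate only if their singular value exceeds
1% of the segment's leading singular value (`res_floor`): weaker
residual directions are indistinguishable from the basis-truncation
leakage of the signal itself, and projecting them out would destroy a
noiseless interior source (the no-noise dipole reconstruction test
pins this). `CL = 1` reduces tSSS to the plain SSS inner
reconstruction. tSSS rescales the broadband noise floor (it keeps only
the 80-dimensional inner subspace of a 128-channel noise field), which
is the baseline shift the study corrects: `baseline_correct()`
subtracts each channel's mean log10-power offset over 15-125 Hz
(excluding 49-51 and 99-101 Hz) from its whole spectrum.

## Evaluation framework

**Bands and RMSE.** Per channel, `pi(band)` is the mean log10 Welch
power (4 s Hamming, 50% overlap) over the band's bins; bands are the
dipole band 11.5-12.5 Hz, the movement band 1-15 Hz excluding the
dipole band, and the DBS band `f_peak +/- 1` Hz around the *detected*
peak. The sensor-level score is
`RMSE(band) = sqrt(mean(((pi_clean - pi_ref) / pi_ref)^2))` over
channels. "Averaged log power" is implemented literally (mean of logs,
not log of mean); log base 10 is used for every logarithmic power
quantity, including the 1.75 calibration target.

**Source level.** 5 mm cubic grid clipped to 95% of the sphere radius;
three-column unit-dipole leadfields from the same sphere model; vector
LCMV with median-eigenvalue covariance regularization (every eigenvalue
below the median is raised to it) and noise-covariance whitening from
the empty-room recording. Two numerical facts shape the implementation:

* For a sphere, every voxel's radial moment column is exactly zero, so
  `L' C^-1 L` is always rank 2. The weights use a rank-truncated
  eigeninverse; unit gain holds on the voxel's visible (tangential)
  moment subspace, where `W L` equals the orthogonal projector onto it.
* Unit-gain beamformer power amplifies sensor noise quadratically where
  the leadfield is weak, so raw power maps peak at the sphere centre
  regardless of the sources. Per-window source power is therefore
  normalized by the voxel's noise gain (squared Frobenius norm of the
  whitened weights — the neural-activity-index family). With this
  normalization the Reference map peaks at the true dipole location;
  without it, it demonstrably does not.

Activation thresholds come from resampling the per-window power
estimates: 1000 bootstrap draws of the windows with replacement,
voxel-wise means pooled over voxels and iterations, threshold at the
95th percentile. The Reference map is thresholded first with no
exclusions; for every other dataset the Reference-active voxels are
excluded from the percentile pool (but may still be declared active) —
this avoids the genuine activation inflating its own threshold.
`D = |A intersect B| / |A union B|` compares active sets; both-empty is
an error (0/0).

**Parameter selection.** Sensor level: the swept value minimizing the
unweighted mean of the three band RMSEs, ties broken toward the
weaker-cleaning end (larger C, smaller k, smaller R, larger CL).
Source level: walk the sweep from each method's starting value and keep
strengthening while D improves by more than 0.01. Robustness is the
mean +/- sample SD of RMSE over the sweep — over the DBS band only for
Hampel/S3P (whose recommended mode acts only there), pooled over all
three bands for ICA-MI and tSSS.

## Problem sizes and reproducibility

The study conditions default to 128 channels, 120 s at 2400 Hz. The
bundled analysis scripts run at 60 s and the test suite's end-to-end
checks at 40 s with reduced sweep grids ({2,5,8} for C, {1,3,5} for k,
{10,20} for R, {0.95,0.8} for CL) — the qualitative orderings they
assert are stable at these sizes, and the methods-scale quantities
(calibration ratio, band definitions, thresholds) do not depend on
duration. Everything random draws from named substreams of one master
seed: identical configurations give bit-identical condition sets, and
the full pipeline (`run_pipeline()`) yields identical output digests
across runs.

## What the synthetic data does and does not show

The generator reproduces the *structure* of the phantom recordings:
exact condition nesting, a calibrated stimulation-to-dipole power
ratio, aliased pulse lines, movement-coupled wire artefacts
concentrated posteriorly, and line noise. It does not emulate vendor
electronics, SQUID jumps, gradiometer arrays, third-order gradient
compensation, multi-source brain activity, or head-shaped conductor
geometry; movement is strictly vertical and rank-1 in sensor space,
which is more benign than patient head movement. Passing tests
therefore show that the algorithms behave as described on data with
these statistics — e.g. that ICA-MI separates a reference-locked
artefact of realistic strength, or that wide-band Hampel filtering
removes the sharp dipole peak along with the artefact — not that the
numerical RMSE values transfer to any particular real acquisition.

Known limitations: the Hampel identifier detects narrow peaks only (a
smooth movement-related power elevation is by construction not an
outlier to it); S3P with a constant `k` across frequencies removes a
fixed-rank subspace even where no artefact is present; the ICA contract
is stochastic (seeded, with a bounded iteration budget like the
standard runica implementation); and tSSS inherits the `res_floor`
sensitivity — artefacts weaker than 1% of the segment's leading
singular value are left untouched by design.
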