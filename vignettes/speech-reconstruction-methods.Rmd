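---
title: "Reconstructing speech from auditory-cortex recordings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing speech from auditory-cortex recordings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neurovoc)
```

## The problem

Invasive recordings over human auditory cortex carry enough information to
reconstruct the speech a listener heard. `neurovoc` implements the full
pipeline of such a speech neuroprosthesis study as a tested library: neural
feature extraction, linear and deep-network decoders, two acoustic target
representations (an auditory spectrogram and a vocoder parameter set
compressed by an autoencoder), waveform resynthesis, and objective
intelligibility scoring. Because clinical recordings cannot be redistributed,
the package ships a forward encoding simulator whose ground truth is known
exactly; every claim the test suite makes is made on data from that
simulator, and this vignette is explicit about what that does and does not
demonstrate.

## Neural features

Two frequency bands of the field potential are used, mirroring standard
practice in electrocorticography:

* **Low frequency (LF, 0–50 Hz)** — a zero-phase FIR lowpass (Hamming
  design, at least 40 dB attenuation by 60 Hz), resampled to 100 frames/s.
  The band is signed.
* **High-gamma envelope (HG, 70–150 Hz)** — the signal is split into eight
  equal-width bands with 4th-order zero-phase Butterworth filters, the
  Hilbert envelope of each band is averaged, resampled to 100 frames/s, and
  z-scored per electrode against a pre-stimulus quiet interval of at least
  10 s. The z-units make electrodes commensurable and remove per-site gain.

Resampling throughout the package is Fourier-domain rational resampling
(spectrum truncation/extension with reflection padding). It is deterministic,
alias-free and has exactly unit DC gain; we chose it over the polyphase
resampler available in the environment, whose passband gain error (several
percent) would leak into every downstream feature.

Decoders see a sliding window of **300 ms** of both bands, hopped every
10 ms. The window is centered on the target frame (150 ms before to 140 ms
after): stimulus-reconstruction filters are acausal in this setting because
the neural response *lags* the stimulus, so a symmetric window captures the
response evoked by the target frame. Windows reaching outside the recording
are zero-padded so the design matrix has one row per frame. Within a row,
electrodes are ordered by their grid position so that spatially adjacent
sites occupy adjacent feature blocks — the locally connected and
convolutional extractors rely on that arrangement.

## The auditory spectrogram

The spectrogram target comes from a three-stage model of the auditory
periphery:

1. a bank of **128 constant-Q filters** spaced at 24 channels/octave from
   180 Hz (~5.3 octaves, topping out near 7 kHz), realized as Gaussian
   magnitude responses on the log-frequency axis with a standard deviation
   of one channel spacing;
2. a hair-cell stage: half-wave rectification, a ~2 kHz lowpass, and
   cube-root amplitude compression;
3. a lateral inhibitory network: first difference along the ascending
   frequency axis followed by half-wave rectification.

Band envelopes are averaged over 10 ms frames, giving a nonnegative
time–frequency matrix at 100 frames/s. Two implementation notes. First, the
lateral-inhibition difference is applied after framing rather than before:
channel differencing commutes exactly with time averaging except through the
rectifier, and the swap lets the model stream one channel at a time instead
of holding a 128 × n_samples envelope matrix. Second, the filter bandwidth
is the narrowest that keeps the model's tonotopy sharp — with cube-root
compression (which widens a Gaussian tuning profile by √3) and the
rectified spectral derivative, a pure tone at a channel's center frequency
excites a peak within one channel of that center only if the filters are
about one channel wide. Both the bandwidth and the compression exponent are
arguments of `compute_auditory_spectrogram()`.

### Inversion

The spectrogram discards phase, so waveform recovery is iterative. The
spectral derivative is undone in closed form on its rising edges (where the
rectifier passed the difference through); falling edges are unobserved and
are filled with a geometric decay, later replaced by envelopes measured from
the running estimate and projected back onto the rising-edge constraints.
The compression is undone by cubing. The resulting band envelopes are mapped
to a linear-frequency short-time magnitude through the filterbank responses
— with multiplicative nonnegative-least-squares updates deconvolving the
channel overlap — and the waveform is recovered by seeded random-phase
alternating projection (512-sample windows, 5 ms hop, default 200
iterations, every 25th iteration re-measuring the envelope through the full
forward model).

A limitation worth stating plainly: with one-channel-wide constant-Q
filters, the low-frequency channels are a few hertz wide, and their envelope
detail depends on spectral structure finer than any short-time magnitude
bin. Phase retrieval given the *true* short-time magnitude of a speech-like
token already caps near 0.77–0.84 mean per-channel correlation on
re-analysis; the full inversion lands around 0.75–0.83 depending on the
token. Reconstruction error decreases monotonically with iteration count,
but a round-trip correlation of 0.85+ is not attainable for broadband
tokens under this filterbank, and the acceptance measurements report the
honest value. Sharper tonotopy and invertibility pull in opposite
directions here; we kept the tonotopy.

## The vocoder contract

The second reconstruction target is a vocoder parameter set with the
classic four streams, 516 parameters per 10 ms frame: a 513-bin spectral
envelope (1024-point FFT at 16 kHz), the fundamental frequency (Hz, zero
when unvoiced), a binary voicing flag, and one coarse band aperiodicity in
[0, 1]. No WORLD binding exists in this R environment, so the package
provides its own analysis/synthesis behind the same contract:
autocorrelation pitch tracking (60–400 Hz search, parabolic peak
refinement, periodicity-and-energy voicing gate), an across-harmonic
smoothed short-time magnitude envelope, aperiodicity from the complement of
the normalized autocorrelation peak (squared — the raw peak under-reports
periodicity for vibrato and shimmer-modulated voiced frames), and
pulse-plus-noise excitation synthesis with frequency-domain envelope shaping
and 50% overlap-add. On a synthetic vowel glide the analysis–synthesis
round trip scores ESTOI ≥ 0.8 against the original.

For network training the 516 streams are conditioned: log envelope, log f0
with unvoiced gaps filled by linear interpolation (the voicing column keeps
the truth), and per-dimension z-scoring with stored statistics;
normalization and denormalization invert each other exactly.

## The autoencoder bottleneck

Estimating 516 correlated vocoder parameters directly from neural data is
fragile, so the parameters are compressed to a **256-dimensional tanh
bottleneck** by a fully connected ladder (516–400–320–256–320–400–516,
LeakyReLU except tanh at the bottleneck). Gaussian noise (SD 0.1 by
default) is added to the codes *during training only*, which teaches the
decoder half to tolerate the amplitude jitter of neurally estimated codes;
no dropout or weight penalty is used inside the autoencoder. The training
corpus is the package's own synthetic speech (a real corpus can be
substituted through the same interface).

The ladder is initialized at the nested principal-component solution in its
linear regime: the first rotation whitens the principal coordinates,
rectifier layers start with a positive bias shift that keeps them on their
linear branch, and the bottleneck feeds tanh well inside its linear range.
From that start, a few dozen Adam epochs reach a held-out relative
reconstruction error (Frobenius ratio) below 0.1; from random initialization
the same error takes roughly an order of magnitude longer. We report the
Frobenius-norm ratio rather than a mean per-frame ratio because frames near
the corpus mean have z-scored norms near zero and make a per-frame ratio
ill-conditioned.

## Decoders

**Linear baseline.** One ridge-regularized spatiotemporal filter per output
dimension, solved in closed form (symmetric solve of the normal equations
when overdetermined, SVD otherwise; the SVD also serves the whole penalty
path during validation-split selection). Features are centered and targets
z-scored per dimension before solving so the penalty acts evenly across
output channels.

**Deep network.** A two-stage architecture: a feature extractor — fully
connected (FCN), locally connected (LCN, unshared local weights), or
convolutional (CNN, shared kernels) over the (lag × electrode) grid with
the two bands as input channels, or an FCN concatenated with one grid
network — followed by a two-layer fully connected summation network. Grid
extractors keep the full spatial extent (no striding or downsampling) and
flatten only at their output. LeakyReLU, batch normalization and dropout
sit between extractor layers, ELU in the summation stage, and the output
nonlinearity is identity for spectrogram targets or tanh for bottleneck
codes (matching the range the codes were trained in). He initialization for
rectified layers, Xavier at the output.

The loss is, per sample, the mean squared error minus the Pearson
correlation across output dimensions, averaged over the batch; a
zero-variance sample contributes a correlation of zero. Training uses Adam
(batch 256, initial rate 1e-4) with the rate halved whenever the validation
loss fails to improve by at least 1e-4 for four consecutive epochs —
the absolute improvement threshold matches the semantics of the plateau
schedulers in mainstream deep-learning toolkits. The validation split is
the final 10% of frames, time-contiguous, to avoid temporal leakage. Batch
normalization running statistics are warm-started from one pass over the
training rows so evaluation losses are meaningful from the first epoch.
Training is exactly reproducible from the configuration seed. Exact layer
widths are configurable; the tests and experiments use widths in the
96–256 range, which one CPU trains in seconds to minutes at the problem
sizes below.

## The synthetic-data generator

`make_speech_tokens()` produces harmonic-plus-noise utterances at 16 kHz:
voiced syllables (glottal pulse train, smoothly varying fundamental within
80–250 Hz, three formant resonators with per-syllable targets, slight
breathiness) interleaved with fricative-like noise bursts and pauses.
`make_vowel()` and `make_vowel_glide()` are fixed-pitch probes; the glide
sweeps its formants through three vowel targets, giving the spectrotemporal
variation that modulation-based scores such as ESTOI require (on a
stationary vowel, ESTOI's segment normalization divides by near-zero
variance and the score is meaningless — a property of the measure, not of
the synthesis).

`make_encoder_ground_truth()` and `simulate_neural()` implement the forward
model: per electrode *and per band*, a Gabor-like spectrotemporal receptive
field (Gaussian patch over lag × channel; an optional spectral cosine
carrier is off by default) is convolved with the stimulus spectrogram. The
LF band is the signed, lightly smoothed drive; the HG band is rectified
(nonnegative before normalization, as an envelope must be). Optional
saturating nonlinearities (scaled tanh at half the drive SD) create the
regime where nonlinear decoders outperform linear ones. Gaussian noise is
added per band, a silent prelude provides the baseline statistics, and the
HG band is z-scored against it, mirroring the treatment of real recordings.

Defaults encode the study conditions: 100 Hz frame rate, receptive-field
latencies 0–120 ms (inside the centered 300 ms window — longer latencies
would place the evoked response outside the decoder's context by
construction), narrow spectral tuning (0.6–1.2 channels) with centers
tiling the tonotopic axis in a stratified, jittered arrangement, the two
bands' centers interleaved. The tiling matters: the lateral-inhibition
stage decorrelates neighboring spectrogram channels, so a population whose
two bands share receptive fields can carry at most one linear functional
per electrode per frame and cannot support faithful linear reconstruction
of 128 channels from 64 electrodes. Giving the bands distinct receptive
fields is also the physiologically motivated choice — the premise of using
both bands is precisely that low-frequency phase and high-gamma firing
carry complementary stimulus information. With `complementary = TRUE` the
two bands instead tile disjoint halves of the spectrum, the configuration
used by the band-ablation experiment.

What passing tests on this generator show: that the decoding machinery
recovers what the encoding provably put into the signals, at the stated
noise levels, and that the qualitative orderings (deep beats linear under
saturation; two bands beat one; more electrodes and more data help) emerge
for the stated reasons. What they cannot show: robustness to real ECoG
artifacts, electrode correlation structure, non-stationarity, or
behavioral/attentional state — no synthetic claim transfers to patients.

## ESTOI

Objective intelligibility uses the extended short-time objective
intelligibility measure: both signals resampled to 10 kHz, frames more than
40 dB below the loudest clean frame removed, 15 third-octave bands from
150 Hz (256-sample hann frames, 50% overlap, 512-point FFT), 384 ms
segments (30 frames) row- and column-normalized, and the mean segment
correlation reported, clamped to [0, 1]. The implementation is checked for
the defining properties: self-comparison scores 1, gain invariance,
monotone degradation with SNR, and near-zero scores against independent
noise.

## Experiments

`run_four_models()` trains {linear, DNN} × {spectrogram, bottleneck →
vocoder} on one dataset, renders audio for each condition (spectrogram
inversion or vocoder synthesis) and scores ESTOI against the clean stimulus,
alongside per-parameter correlations (envelope, f0, aperiodicity, voicing).
`run_band_ablation()` compares HG-only, LF-only and combined inputs with
the deep spectrogram decoder. `run_electrode_curve()` and
`run_duration_curve()` subsample electrodes (20 random subsets per count)
or contiguous training segments and trace mean score against resources.

Two reconstruction-correlation conventions appear, and they are not
interchangeable. Correlating each *channel's* time course (and averaging
over channels) is the quantity a mean-squared-error fit optimizes; it is
used for the linear-recovery property and the resource curves. Correlating
each *frame's* spectral profile (and averaging over frames) is exactly the
correlation term of the combined training loss, sample-wise; it is the
right scale on which to compare the deep decoder with the linear baseline,
and it is where the deep model's advantage under saturating encodings shows
(the ridge baseline, optimizing squared error directly, retains a small
edge on the channel-wise convention even when its per-frame spectral
profiles are clearly worse). `reconstruction_correlation()` exposes both.

The ablation and resource curves score reconstructions by mean
spectrogram-channel correlation by default rather than ESTOI: the curves
need hundreds of fits, ESTOI requires a full iterative waveform inversion
per evaluation, and the qualitative trends the curves exist to show are the
same under both scores. `metric = "estoi"` restores waveform scoring.
Desk-scale problem sizes (tens of seconds of audio, 16–64 electrodes,
tens of epochs) are the defaults; they were chosen as the smallest sizes at
which the orderings stabilize, and all of them scale up by argument.

Every experiment records (condition, seed, score) rows plus its full
configuration, and identical master seeds reproduce identical tables.

## Known limitations

* The spectrogram inversion cap discussed above (~0.8 round-trip channel
  correlation on broadband tokens).
* The vocoder is a deliberately simple pulse-plus-noise implementation
  behind the WORLD-style contract; its round-trip quality (~0.8 ESTOI on
  clean glides) bounds the quality of any vocoder-path reconstruction.
* The grid networks (LCN/CNN) are exercised and gradient-checked, but the
  desk-scale experiment defaults use FCN extractors for runtime; LCN/CNN
  training at realistic sizes is possible but slow in pure R.
* Synthetic neural data only; see the generator section for what that
  implies.
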