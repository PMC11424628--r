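---
title: "Methods: anonymizing pathological speech and measuring what it costs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anonymizing pathological speech and measuring what it costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pathanon)
```

## The problem

Speech recorded in a clinic is a biometric: a verification system that embeds
two utterances and compares them by cosine similarity can decide, far above
chance, whether they come from the same person. Pathological speech (motor
speech disorders, articulation disorders, voice disorders, cleft lip and
palate) is *more* identifiable than healthy speech, and at the same time more
sensitive — so sharing it for research requires speaker anonymization that
conceals identity while preserving the acoustic markers a disorder classifier
relies on. `pathanon` implements two anonymizers, the three measurement axes
(privacy, utility, fairness), an inversion-attack protocol, and the
identification-risk arithmetic for a 1-vs-gallery re-identification attempt,
all exercised end to end on a synthetic corpus because clinical corpora of
this kind are access-restricted.

## Privacy: verification trials and the equal error rate

Privacy is measured by how badly an automatic speaker verification (ASV)
system does. Utterances are gated at 30 dB above the noise-floor estimate,
silent segments are removed by an energy-based voice activity detector
(30 ms window, 6 ms maximum retained silence, 8 ms moving average), and
40-band log-Mel features (25 ms window, 10 ms hop, 512-point STFT) are
embedded into a fixed-length vector. Same-speaker and different-speaker trial
pairs are scored by cosine similarity, and `compute_eer()` sweeps thresholds:
FAR(t) is the fraction of different-speaker trials scoring at or above t,
FRR(t) the fraction of same-speaker trials below t, and the equal error rate
(EER) is the value at the FAR = FRR crossing, linearly interpolated between
bracketing thresholds (ties resolved toward the lower threshold). Higher EER
after anonymization means better privacy.

The default embedder is deliberately training-free so the whole pipeline is
deterministic and reproducible offline: per-band temporal mean, standard
deviation, and mean absolute frame delta of the 40-band features (120
dimensions), each block smoothed across bands with a 5-point moving average
and centered, then length-normalized. The smoothing emphasizes the spectral
*envelope* (vocal-tract shape) over harmonic ripple; the centering makes
cosine similarity compare spectral shape rather than overall level. Without
these two steps all cosine scores compress toward 1 and the metric carries
almost no identity information. Any function with the same signature can be
registered in place of the default — the inversion attack does exactly that.

## The two anonymizers

**McAdams (signal-level).** Per 20 ms Hann-windowed frame (50% overlap), an
order-20 LPC analysis yields a prediction polynomial; the residual is
obtained by inverse filtering. Each complex pole pair's upper-half-plane
angle phi (radians) is replaced by phi^alpha with the radius preserved (real
poles untouched; radii clipped at 0.998 for stability), and the frame is
resynthesized by filtering the residual through the transformed all-pole
filter, overlap-added. alpha = 1 is the identity; alpha < 1 moves formants
below ~2.5 kHz upward. The randomized mode draws alpha uniformly in
[0.75, 0.90].

*Randomization grain.* We draw one coefficient **per utterance** by default,
not per speaker. With a per-speaker-constant coefficient the transform is a
fixed invertible map of each speaker's spectrum: enrollment and test
utterances move together, and the coefficient itself becomes an extra
distinguishing feature — on the default corpus EER *decreased* (7.3% to
4.0%). Per-utterance draws, the grain of the published randomized-coefficient
baseline this method descends from, break enrollment/test consistency and
raise EER (7.3% to 26.7%), reproducing the direction reported for clinical
data. The per-speaker grain remains available via
`mcadams_config(grain = "per_speaker")`.

**Pitch shift (DL-pipeline stand-in).** One signed semitone shift per
speaker, magnitude uniform in [1, 4] (a configurable placeholder for the
original system's supplementary distribution), sign random but flipped — or
the magnitude reduced — so the shifted F0 stays inside the speaker's
gender/age F0 band (male 85–155 Hz, female 155–255 Hz, child 200–320 Hz):
gender preservation by construction. The shift itself is a phase-vocoder
time-scale modification followed by resampling (duration preserved, measured
F0 accurate to ~1.5%). The neural vocoder of the original pipeline is out of
scope; `resynthesize()` is a deterministic stand-in that inverts clf-preset
log-Mel features through the pseudo-inverse mel filterbank and fixed-iteration
Griffin–Lim phase reconstruction, behind the same interface, so a trained
vocoder can be plugged in later. An optional noise-addition/spectral-
subtraction step is included; the denoiser uses the closed-form expected
noise magnitude since the added noise level is known.

## Utility: disorder detection under paired repetition

Utility is the ability to detect the disorder after anonymization. Features
are 80-band log-Mel (1024-point STFT) after zero-phase drift removal; each
scoring draw crops 180 frames (~3 s). The reference system's ImageNet-
pretrained ResNet is replaced by a pluggable contract whose default is a
class-weighted ridge logistic model (binomial or multinomial) over per-band
crop statistics — small enough to fit in seconds, strong enough to reach
AUROC > 0.95 on the synthetic task. Evaluation draws 8 utterances per test
speaker and one crop each, aggregates to speaker level by mean probability
(threshold 0.5 for accuracy/sensitivity/specificity), and repeats 50 times;
the draw sequence depends only on the seed and the speaker/utterance counts,
so original and anonymized runs consume identical draws (strictly paired;
the logs are compared in tests). Significance uses a two-tailed unpaired
Welch t-test (p < 0.05); the privacy–utility tradeoff across a coefficient
sweep is summarized by Pearson correlation between EER and AUROC.

## Fairness

`fairness_report()` computes per-subgroup accuracy (gender or age group) and
the statistical parity difference PtD = accuracy(minority) −
accuracy(majority), minority being the smaller test subgroup with ties broken
alphabetically; positive values favor the minority.

## Inversion attack

The attacker knows the anonymization family and refits the verifier treating
anonymized utterances as authentic utterances of their true speakers.
`train_inverse_asv()` fits a regularized linear discriminant projection on
pooled original + anonymized base embeddings and returns a drop-in embedder.
On the default corpus the attack pulls anonymized EER from 24.6% back to
15.8% while leaving original-audio verification intact — the qualitative
pattern reported for clinical data.

## Identification risk

For a gallery of n published speakers and a verifier at a given EER, a
person searching for their own recording expects FA = (n−1)·EER false
accepts, TA = 1−EER, FR = EER, TR = (n−1)·(1−EER); the manual-verification
burden is summarized as odds 1:round(FA) (half-up, floor 1). `odds_summary()`
reports the before/after odds and two fold changes: the ratio of rounded
odds (the headline "N-fold harder" number) and the raw ratio of expected
counts to one decimal. The bundled `clinical_eer_reference()` table carries
the published aggregate EERs of a 2742-speaker restricted clinical corpus so
this arithmetic is demonstrable without audio access.

## The synthetic corpus: what it is and is not

Real pathological corpora are restricted, so `make_population()` /
`generate_corpus()` produce a stated world with the structure the pipeline
needs:

* **Speakers** differ by base F0 (drawn inside gender/age bands), by ±5%
  per-speaker formant placement around a neutral four-formant template
  scaled for gender/age, and by bandwidths.
* **Within-speaker session variability** — 2% per-utterance perturbation of
  F0 and formant centers — is essential, not cosmetic: with zero
  within-speaker variance every EER is exactly 0 and no anonymization effect
  is measurable. The value was fixed from the design argument (within-speaker
  spread must sit well below the ±5% between-speaker spread), not tuned
  against test outcomes.
* **Disorders** are controlled marker intensities in [0,1]: jitter
  (cycle-length std), shimmer (cycle-amplitude std), formant blurring
  (bandwidth widening / center imprecision), nasality (added 250–450 Hz
  resonance). Controls sit at or below 0.1, patients center on 0.6 —
  separable but not degenerate. Dysphonia raises jitter/shimmer plus
  aspiration noise; dysarthria adds slow F0/energy drift and widened
  bandwidths; dysglossia perturbs formant centers; CLP mixes in the nasal
  resonance. Each marker maps monotonically to an independently measured
  acoustic quantity (tested).
* Every utterance embeds a deterministic ≥100 ms mid-utterance silence so
  the VAD path is always exercised; excitation is an impulse train plus
  aspiration noise (Klatt-style cascade), giving analytically known F0 and
  formants for the oracles.

A green end-to-end test therefore establishes that the *operations* behave
correctly and that the anonymization *directions* hold in a world with known
structure. It does not establish clinical validity of the marker
definitions, phonetic realism, or the magnitudes of the clinical EER/AUROC
tables — those depend on restricted data and pretrained networks that are
explicitly out of scope.

## Numerical choices and edge cases

* All STFT analyses use periodic Hann windows; mel filters are triangular,
  HTK-spaced, over 0–8000 Hz; log-Mel cells are 20·log10(max(mel, 1e-6)), so
  scaling the waveform by g shifts un-floored cells by 20·log10(g).
* The 30 dB gate has no sound-pressure reference in a digital recording; the
  default reference is the utterance's own noise-floor estimate (5th
  percentile frame energy), with an absolute-dBFS fallback mode. If the
  dynamic range is below the threshold, nothing counts as silence. A fully
  gated-out utterance is flagged empty, not an error.
* Overlap-add inversion caps the window-sum normalization gain (at 4x) so
  near-zero window sums at signal edges cannot produce spikes; consequently
  McAdams reconstruction tapers over the first/last frame, and the
  alpha = 1 identity check measures log-spectral distance over interior
  frames (< 1 dB).
* The Griffin–Lim round trip is limited by the 80-band mel filterbank, not
  the phase estimate: its mel-domain mean absolute error is ~2.4 dB, i.e.
  ~0.28 natural-log units; the round-trip tolerance (< 1.0) is checked in
  natural-log units, since < 1 dB is information-theoretically out of reach
  for an 80-to-513-bin pseudo-inverse.
* Degenerate EER input (all scores identical) is defined as 0.5 with a
  warning; a speaker with one utterance cannot enter positive trials and
  requesting more trials than distinct pairs errors with the bound.
* All randomness flows through explicit seeds via per-purpose derived
  substreams (FNV-style string hashing kept below 2^31), so whole
  experiment runs are bit-reproducible and never touch the caller's RNG
  state.

## Known limitations

The synthesizer makes stationary vowel-like signals, not speech: no
phonetics, no language content, no channel effects. The default embedder and
classifier are deliberately small; absolute EER/AUROC values on the
synthetic corpus are not comparable to systems with pretrained networks —
only directions and orderings are meaningful. The supplementary parameters
of the original pitch-shift system (shift-magnitude distribution, noise
level, denoiser) are not in the main text; the defaults here are documented
placeholders, configurable at the interface.
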