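---
title: "Measuring excess attenuation from playback transects: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring excess attenuation from playback transects: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(callprop)
```

## The measurement model

A playback propagation experiment broadcasts a standardized stimulus through
a natural environment and re-records it at fixed distances. The stimulus
here is a single program: for each of thirteen individuals (seven of the
native species, six of the invasive one) six advertisement calls, then a
29-tone series — 200 to 2400 Hz in 100-Hz steps, 2500 to 5000 Hz in 500-Hz
steps, each tone 0.5 s — then 3 s of white noise and a 1-kHz
broadcast-level reference tone. Every segment is 100 % peak-normalized
before assembly so all signals share one relative amplitude scale.

Levels are tied to an absolute scale by a calibrator: a 1-kHz tone of known
sound pressure level (94 dB re 20 μPa) recorded through the full chain at
the start and end of each transect. If the calibration segment has digital
RMS $r$, then

$$\text{offset} = 94 - 20\log_{10} r,$$

and any segment of digital RMS $x$ measures $20\log_{10}x + \text{offset}$
dB SPL. Two consequences are contractual and tested: a recorder gain step
applied to a whole recording cancels exactly (the calibrator passes through
the same gain), and a full-scale sine under a 94-dB reference reads
$94 - 20\log_{10}\sqrt{2} = 90.99$ dB RMS.

The propagation statistic is excess attenuation,

$$EA(d) = \big[SPL(d_0) - SPL(d)\big] - 20\log_{10}(d/d_0),$$

with reference $d_0 = 0.5$ m and $d \in \{1, 2, 4, 8\}$ m: the attenuation
beyond what spherical spreading predicts, positive when the medium is worse
than geometry and negative under channeling (common over water below
2 kHz). Because the loudspeaker's coloration $S(f)$ adds identically to
both SPL terms, it cancels from $EA$; the measurement chain is therefore
insensitive to speaker response within its stated ±8 dB bound, and the test
suite verifies cancellation to better than 0.2 dB.

The published source states the spreading term as "20 log [dB RMS SPL at
far distance / dB RMS SPL at 0.5]", which mixes level and distance labels;
the distance-ratio form above is the only reading consistent with the
6.02-dB-per-doubling structure of the design and is what this package
implements.

## Decibel averaging

All summary cells average on the linear pressure scale:

$$\bar v = 20\log_{10}\Big(\tfrac1n\sum_i 10^{v_i/20}\Big).$$

The divisor 20 (amplitude/pressure convention, units N·m⁻²) rather than 10
(power) is not a matter of taste here: recomputing every derivable cell of
the published tone and call summary tables — five pooled-substrate category
means, four per-species substrate means, two species grand means — matches
all eleven at two decimals under ÷20 and fails under ÷10
(`verify_printed_tables()`). By Jensen's inequality this mean never falls
below the arithmetic dB mean, and it nests: the grand mean of equal-sized
cells equals the mean of their cell means, which is exactly why the species
grand means are recomputable from the distance cells. Minima and maxima in
summary tables are plain extrema of the dB values, which is the only
convention consistent with the published extrema bracketing their cells.
The standard deviation column is reported on the dB scale; whether the
published SDs were dB-scale or linear-scale statistics is not recoverable
from the printed data, so the package documents its convention rather than
claiming a reproduction.

Rounding for table comparison is two decimals, half away from zero
(`round_half_away()`), matching how the printed values behave.

## The transect simulator

The original field recordings are held in a museum sound archive and are
not programmatically available, so the package generates its own transects
with known ground truth. A scenario imposes, per (locality, substrate):

* an **excess-attenuation profile** $EA(f)$ in dB per distance doubling —
  the frequency-domain gain at distance $d$ is
  $-[20\log_{10}(d/d_0) + EA(f)\log_2(d/d_0)] + S(f)$, applied zero-phase
  by FFT multiplication;
* **receiver-side Gaussian background noise** realizing a chosen noise
  floor (noise is position-local in the field, so it is added after
  attenuation, never propagated);
* **recorder gain steps** per distance (default +10 dB at 4 and 8 m; the
  instrument's actual step sizes are unpublished, so the default is
  config-exposed), absorbed by per-recording calibration;
* a bounded **loudspeaker coloration** $S(f)$, |S| ≤ 8 dB.

The seven-locality study fixture draws water profiles as a sigmoid rising
from a negative plateau (−3 to −1 dB/doubling) below 2 kHz to +2 to
+5 dB/doubling above a transition at 2–3 kHz — the qualitative water
pattern of channeling at low frequency with a sharp penalty near the native
species' dominant band — and soil profiles as a larger, slowly undulating
baseline (1–4 ± 0.5–1.5 dB/doubling). These are descriptive scenario
shapes, not physical impedance models: there is no ground-reflection comb
filtering in the default path (a single-reflection two-ray option exists,
off by default), no time-domain dispersion, and no atmospheric absorption —
the last omitted deliberately because temperature and humidity effects are
negligible at these frequencies and distances.

The default noise floor is 15 dB SPL, a quiet pre-sunset field site. It was
chosen a priori so that the complete 7 × 2 × 5 design passes the 6-dB
signal-to-noise validity screen at every distance: the repeated-measures
analysis requires a complete crossing, and the original study analysed
complete data. Parameter-recovery tests that quote sub-decibel tolerances
use noiseless or ≥ 30 dB SNR scenarios, as those tolerances presume.

What passing tests on this generator do show: the calibration algebra, the
EA decomposition, the linear-averaging rule, and the inference layer are
correct against closed-form and simulated ground truth. What they cannot
show: anything about real water or soil surfaces — the fixture's profiles
are qualitative stand-ins, and figure-level values from the original field
campaign are out of reach without the archived audio.

## SPL measurement details

RMS is computed over the scheduled segment minus 5-ms edges, excluding the
raised-cosine onset/offset ramps the synthesizer applies (the original
study's interactive measurement tool does not document its window, so the
package states its own). Segments clipped for more than 1 % of samples are
invalid. The signal-to-noise screen compares segment level against the
background-noise level in a matched band — ±1/3 octave around a tone's
frequency, the full 0.2–5 kHz band for calls — with a default 6-dB
threshold; records failing it are excluded, never zeroed. Background-noise
statistics tile the 60-s noise recording into 15-s windows and report the
maximum per-window RMS and peak SPL.

## Stimulus synthesis choices

Tones get 5-ms raised-cosine ramps (the source is silent on ramps; unramped
tones splatter spectrally). Synthetic calls are harmonic stacks whose
strongest partial sits exactly at the specified dominant frequency, with
partial amplitudes halving per step, an optional weaker low-frequency band,
and a raised-cosine amplitude-modulation envelope; individual dominant
frequencies and durations are drawn once, seeded, from the published
truncated normal ranges (native 2678.3 ± 279.5 Hz, 430 ± 183 ms; invasive
1405.2 ± 552.6 Hz, 641 ± 101 ms). This reproduces dominant frequency,
duration, harmonic content and AM rate — not the temporal fine structure of
real calls, which the propagation analysis does not use.

The stimulus description "previously filtered between 0 and 300 Hz" is
implemented as an optional zero-phase 4th-order Butterworth high-pass at
300 Hz, on by default for call segments (standard removal of wind and
handling rumble) and off for tones. The phrase is genuinely ambiguous —
the invasive species' fundamental is quoted as 0.2–0.4 kHz, which a 300-Hz
high-pass would partly remove — so both behaviours are exposed
(`filter_calls`, `filter_tones`, `hp_cutoff`) and no claim is made about
the original intent. White noise is Gaussian, band-limited to 0.1–10 kHz
(bandwidth unstated in the source), peak-normalized. Inter-segment silence
defaults to 0.5 s, which puts the full program near the stated 3-minute
duration. All synthesis is bit-reproducible given (spec, seed, sample
rate).

## The inference layer

Excess attenuation can be negative, so the default normalizing transform is
a shifted log, $\log(v - \min v + 1)$; identity and the exact linear-scale
rescaling $v\ln 10/20$ are selectable, and the choice is recorded in the
output, because the original transform's base and shift are unstated — none
of the three is asserted as "the" original.

`rm_anova()` fits the univariate mixed model with `stats::aov` subject
error strata (Type-III-equivalent in these balanced-within designs;
incomplete crossings are rejected by name, not approximated). For every
within-subject effect it computes Mauchly's W, Greenhouse–Geisser and
Huynh–Feldt epsilons from the subject scores on orthonormal effect
contrasts, truncating Huynh–Feldt at 1, and reports the corrected p-value
when Mauchly's test rejects at 0.05 (a flag forces always- or
never-corrected output). Huynh–Feldt rather than Greenhouse–Geisser is the
default correction because it is the one the published tables used. The
implementation is cross-validated against the multivariate route in `car`
(F, dfs, W, and both epsilons agree to numerical precision; the Mauchly
p-value differs in the third decimal because `car` uses a higher-order
chi-square approximation where this package uses the standard first-order
one).

Subjects in the tone analysis are the 29 individual tones with frequency
category (F1–F5) between subjects — the only reading consistent with the
published between-subjects degrees of freedom 4, 24 (29 − 5 = 24). The
category counts are 4, 5, 10, 6, 4: the 2.1–3.0 kHz category contains
2100–2400 Hz from the 100-Hz series plus the 2500- and 3000-Hz tones from
the 500-Hz series. Subjects in the call analysis are the 13 individuals
with species between subjects (degrees of freedom 1, 11), each cell being
the linear-scale average of that individual's six calls. Locality is
treated as a within-subject factor in both analyses, which is what the
published df pattern (6, 144 and 6, 66) implies. Within-factor levels with
only two levels are trivially spherical (W = 1 by convention). The
published F statistics themselves are not reproduction targets — they
require the undeposited field recordings — but the df structure is, and it
is checked exactly.

Bonferroni pairwise comparisons multiply paired-t p-values by the number of
level pairs, capped at 1.

## Problem sizes and determinism

Defaults are study-scale: 44.1 kHz / 16-bit audio, the full 78-call +
29-tone program, 7 localities × 2 substrates × 5 distances, 60-s background
segments. The test suite and the acceptance script run the identical code
paths at reduced sizes chosen to keep the suite fast while leaving every
contract testable: 22.05 or 11.025 kHz audio, 5–10 tones spanning all five
categories, 2–4 individuals, 16-s background segments, and a compact null
design (24 subjects in 3 groups, 4 × 2 within cells, 1000 replicates) for
the size calibration of the corrected ANOVA. Every stochastic component is
seeded; simulated transects are byte-reproducible given a seed.

## Known limitations

* Scenario profiles are descriptive; no physical boundary-impedance model.
* Synthetic calls carry no pulse fine structure beyond the AM envelope.
* A-weighted spectra and figure reproduction are out of scope.
* The SD columns of the published tables are not reproducible in principle
  (convention unstated); only means and extrema are verified.
* With fewer error degrees of freedom than contrast dimensions (possible
  for high-order interactions in small designs) Mauchly's W is
  inestimable; the package then reports NA and treats sphericity as
  failed, applying the correction.
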