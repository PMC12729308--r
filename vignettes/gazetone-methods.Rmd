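---
title: "Methods: from gaze to melody"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from gaze to melody}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazetone)
```

This vignette explains the models and procedures behind `gazetone`, the
assumptions they make, the parameters that matter, and the design choices
taken where more than one reasonable realization existed. It states no
empirical result that the test suite does not itself compute.

## The colour–note matrix

The mapping rests on two anchors: pure red at 100% saturation and brightness
sounds middle C (MIDI 60), and moving by 12 pitch steps corresponds to an
octave. Around those anchors the package partitions HSV space into
`hue_sector_count` (default 12) hue sectors crossed with `value_band_count`
(default 4) brightness bands:

$$\mathrm{pitch}(h, s, v) = p_0 + \sigma(h) - 12\,(B - 1 - \beta(v)),$$

with anchor $p_0 = 60$, sector index
$\sigma = \lfloor ((h + 15) \bmod 360)/30 \rfloor$ and band
$\beta = \min(\lfloor vB \rfloor, B-1)$. Sector 0 is *centred* on red
(hues $[345^\circ, 15^\circ)$) so near-red hues are stable; a colour exactly
on a boundary belongs to the half-open interval above it. With the defaults,
the chromatic part of the matrix spans pitches 24–71; the full 128-value
MIDI codomain is reachable through the configurable anchor and clamping
bounds. Brightness bands below the pitch floor clamp rather than wrap, so a
very dark colour can never leap to a high register.

Achromatic colours are handled by replacement notes rather than by the
matrix: saturation below 0.1 routes to white (C5, 72) when $v \ge 0.9$, to
black (C3, 48) when dark, and to the nearer of the two otherwise (the
brightness midpoint 0.5 is the divide); anything with $v < 0.1$ is black
regardless of saturation. These thresholds are exposed in
`color_note_map()` but deliberately fixed as defaults: they encode the idea
that near-greys carry no usable hue information.

Two derived attributes complete a note: duration scales with a colour's
visual *prominence* (the fraction of its grid cell occupied by its map
region), `base_unit * max(1, round(4p))`, giving one to four sixteenths and
never a zero-length note; velocity scales linearly with saturation onto
1–127, never silent.

## Grid scanning

Images are decomposed into a 10 × 10 grid — 100 cells read left-to-right,
top-to-bottom like text. Pixels are assigned to cells by a half-open floor
partition (`cell r` spans pixel rows $\lfloor rH/10 \rfloor$ to
$\lfloor (r{+}1)H/10 \rfloor - 1$), so every pixel belongs to exactly one
cell and non-divisible dimensions produce cells differing by at most one
pixel row or column. This partition rule for ragged dimensions is a package
choice; any exact partition would do, and the tests assert the conservation
property rather than a particular split.

Two colour summaries circulate in this literature — the *most frequent*
colour of a region and its *median RGB* — and they serve different purposes.
The package reconciles them: each pixel is first quantized to its map
region; the **modal region** decides dominance (and hence prominence);
the cell's representative colour is then the **channel-wise median RGB
within the winning region**, which suppresses pixel noise without letting a
minority colour outvote the mode. Modal ties break toward the lower mapped
pitch, then the lower region code — arbitrary, but deterministic.

## Fixation detection and gaze analytics

Gaze streams are 133 Hz samples on a 1920 × 1080 display with per-sample
tracker validity flags. Fixations are identified with a dispersion-threshold
(I-DT) algorithm: a window of consecutive valid samples grows while its
bounding box fits within 100 × 100 px; the window closes when the next
sample would exceed the box, or at a gap of two or more consecutive invalid
samples. Isolated single dropouts are bridged because consumer trackers lose
individual frames routinely; longer gaps are treated as real signal loss. A
closed window is a fixation iff it spans at least two samples and
`min_fix_ms` of time. The dispersion bound comes with the measurement
design; the 100 ms minimum duration is the field's conventional floor for
separating fixations from noise and is configurable. The implementation is
verified in the tests against an independent brute-force maximal-window
search on seeded random streams.

Quality control marks a recording unreliable when *more than* 25% of samples
are missing or *more than* 20% of fixations fall outside the painting — both
strict inequalities, so a recording exactly at a threshold passes. Note that
the rule is evaluated on a fixed set of detected fixations; the missing
fraction is monotone in the number of invalid samples, which is the
invariant the tests check.

Gaze *elements* — the hotspots that later seed the melody — are formed by
snapping fixation centroids to a fixed 100 px lattice and accumulating dwell
per lattice cell; cells with cumulative dwell strictly above 2000 ms become
elements, ranked by first entry. Snapping to a lattice rather than running a
free clustering algorithm keeps the definition deterministic and matches the
100 × 100 px region definition used throughout.

AOI *gaze frequency* is operationalized as the count of valid samples inside
the AOI rectangle. The alternative reading (fixation visits) is coarser;
sample counts conserve exactly over disjoint AOIs plus the outside
remainder, which makes the metric auditable. Units are consistent within any
one analysis; comparisons across analyses should use one convention.

Heatmaps deposit a duration-weighted isotropic Gaussian (default
$\sigma = 50$ px) at each fixation centroid on a 10 px lattice, normalized
to a maximum of 1 when any fixation exists.

## Event encoding and the melody model

Melodies are sequences of events with four categorical axes: pitch (128
values), duration class (1–16 sixteenth-note units), velocity class (16
bins of width 8), and inter-onset offset class (0–16 units). MIDI corpora
are parsed, merged across tracks, and reduced to monophony by keeping the
highest note at each onset — the generator's output is melodic, and the
highest voice is the conventional carrier of melody in keyboard textures.

The model is a stacked LSTM over the one-hot concatenation of the four axes
(input width 177), with four softmax heads trained by teacher forcing under
summed cross-entropy to predict the next event. The factored output is the
natural parameterization of the four-axis encoding and keeps every head's
support small. Two profiles share this architecture:

* **paper** — 3 layers × 512 units, 30% dropout, 100 epochs: the full-scale
  configuration for training on a real corpus.
* **desk** — 2 layers × 32 units, 30% dropout, 5 epochs: the configuration
  used throughout the tests; it trains in a few seconds on one CPU while
  exercising every code path of the full model.

Optimisation is minibatch Adam (learning rate 0.01, 10 sequences per batch,
teacher-forcing chunks of 64 events). Initialisation, batch shuffling,
dropout masks and sampling all derive from a single RNG seed, so training
and generation are exactly reproducible — the tests assert identical loss
traces and byte-identical MIDI across repeated runs.

Generation is autoregressive: the seed events are fed through the network
(and emitted verbatim as the output prefix), then events are sampled at the
configured temperature. Each sampled event is validity-checked — pitch
within the configured range, duration a positive grid multiple, velocity
step from the previous event at most 32 — and resampled up to 8 times, after
which the offending fields are projected to the nearest valid value. The
velocity bound operationalizes "smooth, natural dynamics"; 32 is a quarter
of the velocity scale and permits phrase-level swells while excluding jolts.
The resample-then-project policy keeps generation total: no rejection loop
can stall, and the projection preserves the sampled event's intent as
closely as possible. An empty seed (no gaze elements) starts from a default
event — a middle-C quarter note at moderate velocity — which becomes the
first output event.

## Seed construction

One event per gaze element, in rank order: pitch from the dominant colour of
the grid cell containing the element's region centre, duration from dwell at
one sixteenth-note unit per 500 ms (clamped to 1–16 units, i.e. up to a
whole note for 8 s of dwell), velocity from that colour's saturation, and
gapless offsets so scan order becomes temporal order. The 500 ms/unit scale
maps the 2–8 s dwells typical of the element threshold onto musically
sensible note values.

## Post-processing

* **Rhythm quantization** replaces each duration by the nearest member of
  {1, 2, 3, 4, 6, 8, 12, 16} units (sixteenth through whole note, with
  dotted values); ties round up, favouring the longer, calmer value. Offsets
  are re-normalized so gapless runs stay gapless. The operation is
  idempotent and preserves event count.
* **Pitch clamping** transposes by whole octaves into the comfort range
  36–96 (C2–C7) — a register comfortably audible to children on piano
  timbre. Octave transposition rather than hard clipping preserves pitch
  class, and with it the colour → pitch-class semantics of the mapping. The
  range must span at least an octave or some pitch classes would be
  unreachable.
* **Structural validation** measures the fraction of distinct seed pitch
  classes that reappear after the seed prefix; at least half (default) must
  survive. "Framework consistency" has no canonical formula; pitch-class
  coverage is a concrete, order-invariant realization, and the threshold is
  configurable.

## The pipeline

`compose_from_gaze()` chains detection → QC → element extraction → grid scan
→ seed → generation → quantization → clamping → validation → MIDI. A
recording that fails QC aborts the run with a classed error and writes no
output — mirroring how unreliable recordings are excluded from analysis
rather than patched. The run report (QC fractions, element/seed/output
lengths, structure coverage, config hash) serializes losslessly to JSON.

## Group statistics

All comparisons operate on (n, mean, SD) triples so printed tables are
sufficient input. Cohen's *d* uses the pooled standard deviation
$s_p = \sqrt{((n_1{-}1)s_1^2 + (n_2{-}1)s_2^2)/(n_1{+}n_2{-}2)}$; the 95% CI
uses the Hedges–Olkin normal-approximation standard error
$\sqrt{(n_1{+}n_2)/(n_1 n_2) + d^2/(2(n_1{+}n_2))}$ — the CI method behind
published intervals of this kind is rarely stated, so printed CI bounds are
treated as approximate and only the point estimates are reproduced. The
*t*-test defaults to the Student pooled-variance form (df = n₁ + n₂ − 2) for
consistency with pooled-SD effect sizes; a Welch option exists. Bonferroni
thresholds are α/m to four decimals; percent changes are reported to one
decimal, as such values are conventionally printed.

The bundled `study_group_summaries()` table carries the fixation-duration
and AOI gaze-frequency summaries of a three-arm artwork-viewing study
(no-music n = 31, gaze-conditioned music n = 33, expert-selected music
n = 32). Where a source prints slightly different SDs in text and tables,
the table values are used.

## What the synthetic data does and does not emulate

The generators provide every input the pipeline needs, with analytic ground
truth:

* `make_painting()` tiles the canvas with coloured rectangles, so per-cell
  modal colours are known by construction. It emulates block-coloured,
  poster-like artworks — not photographic gradients, texture, or soft edges.
* `make_gaze()` plants hotspot fixations with Gaussian jitter, saccade-length
  recording gaps, and Bernoulli sample dropout. It reproduces the
  spatio-temporal structure a dispersion detector cares about, but not
  main-sequence saccade kinematics, smooth pursuit, drift, or blink
  artefacts. Default scenarios mirror the study shape: 60 s viewings at
  133 Hz with about four hotspots above the 2 s element threshold.
* `make_corpus()` writes seeded random walks on the C-major scale — tonal,
  monophonic, rhythmically simple material adequate for verifying learning
  dynamics, not a model of any musical style.
* `make_groups()` draws zero-truncated normal fixation durations matching
  requested (n, mean, SD); at study-scale parameters the truncation is
  negligible.

Passing tests on these inputs therefore demonstrate algorithmic
correctness — exact recovery where ground truth is exact, statistical
recovery at the study's sample sizes — not performance on real artworks,
real children's gaze, or real corpora.

## Problem sizes and numerical tolerances

The test suite runs the desk model profile on a 50-melody × 64-event corpus,
checks the fixation detector against the brute-force oracle on 200 random
streams of up to 2000 samples, recovery on 100 jittered scenarios
(σ = 10 px, ≥ 95% recovery required), and effect-size recovery over 1000
simulated replicates at n = 31/33 with a true standardized difference of
1.3 (mean estimate within ±0.1 — the small-sample positive bias of *d* at
these n is about 1.6%, well inside that band). These sizes were chosen as
the smallest that exercise the asymptotics convincingly. Floating-point
comparisons against oracles use exact equality where both routes perform
identical arithmetic (fixation geometry) and 1e-10 tolerances where they do
not (summary vs. raw-data statistics).

## Known limitations

* The colour matrix is one consistent realization of the red-anchored,
  octave-banded scheme; other partitions of the 128 pitch regions satisfy
  the same anchors.
* The LSTM is CPU-bound pure R; the paper-scale profile trains, but slowly —
  the desk profile is the supported test-time configuration.
* Polyphony is discarded at corpus encoding; harmony is out of scope.
* MIDI output is single-track format 0 at a fixed tempo (default 100 BPM);
  tempo curves and multi-track writing are not supported.
* The QC rule takes recordings as given; it does not truncate at look-away
  events, and aggregated multi-recording seeds, while supported through the
  same API, carry no special semantics.
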