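# gazetone

Turns a child's gaze over a painting into a short piano melody, and provides
the eye-tracking analytics and group statistics that go with that kind of
study.

The package is aimed at researchers in audiovisual cross-modal perception and
early aesthetic education who want a reproducible, fully scripted version of
the gaze-to-music loop: extract colour structure from an artwork, detect
where a child actually looked, condition a generative melody model on those
gaze hotspots, and post-process the result into playable MIDI — plus the
summary-statistic machinery (pooled-SD Cohen's *d*, *t*-tests, Bonferroni
thresholds, percent changes) used to compare viewing behaviour between
groups.

## What it computes

**Colour → note mapping.** HSV colour space is partitioned into 12 hue
sectors × 4 value (brightness) bands, each carrying one MIDI pitch, with
white/black replacement notes for achromatic colours. Pure red at full
saturation and brightness anchors the matrix at middle C:

> pitch = 60 + σ(h) − 12 · (3 − β(v)),  σ ∈ {0..11}, β ∈ {0..3}

so dropping one brightness band moves the pitch down exactly one octave.
Duration scales with a colour's visual prominence within its grid cell,
velocity with its saturation.

**Image scanning.** Images are split into a 10 × 10 grid (100 cells), each
cell quantized to map regions; the modal region wins and the cell's dominant
colour is the median RGB within it. Cells are read left-to-right,
top-to-bottom into a note sequence.

**Fixation detection (I-DT).** A dispersion-threshold algorithm grows a
window of gaze samples while its bounding box fits in 100 × 100 px; windows
of at least 100 ms become fixations. Recordings with > 25% missing samples
or > 20% of fixations off the painting are rejected. Regions accumulating
more than 2000 ms of dwell become *gaze elements*, ranked by first entry.

**Melody generation.** Gaze elements seed a stacked-LSTM next-event
predictor over a four-axis event encoding (pitch 0–127, duration in
sixteenth-note units, velocity, inter-onset offset). Generation is
autoregressive with per-event validity checks; post-processing quantizes
rhythm to standard note values, clamps pitches into a child-comfortable
register by octave transposition (preserving pitch class), and validates
that the seed's pitch-class framework survives into the continuation.

**Group statistics.** Effect sizes from printed summary statistics:
*d* = (m₂ − m₁)/s_p with the pooled SD, Hedges–Olkin standard errors for the
95% CI, Student *t* with df = n₁ + n₂ − 2, Bonferroni thresholds, and
percent changes.

## Worked example

Everything below runs on synthetic data generated by the package itself:

```r
library(gazetone)

dir    <- tempfile()
paths  <- simulate_study_bundle(dir, seed = 1)        # painting, gaze, corpus
corpus <- encode_corpus(list.files(paths$corpus, full.names = TRUE))
model  <- train_melody_model(corpus, model_config("desk", seed = 42))
tidy(model)
#> # A tibble: 5 × 2
#>   epoch  loss
#> 1     1 13.1
#> 2     2 11.7
#> 3     3 10.3
#> 4     4  9.21
#> 5     5  8.50

comp <- compose_from_gaze(paths$painting, paths$gaze, model,
                          length = 60, out_midi = file.path(dir, "melody.mid"))
comp
#> <gaze_composition>
#>   4 elements -> seed of 4 events -> 60 post-processed events
#>   QC: missing 2.8%, outside 0.0% (reliable: TRUE)
#>   structure coverage 1.00 (pass: TRUE)
```

The four planted gaze hotspots become a four-event seed (one note per
hotspot colour; dwell sets duration), the model continues it to 60 events,
and the post-processed melody is written as a Standard MIDI File. The loss
trace shows the desk-scale model learning the toy corpus; QC confirms the
synthetic recording is reliable; structure coverage 1.00 means every seed
pitch class reappears in the continuation.

Group comparisons work straight from summary statistics:

```r
s <- tidyr::unite(study_group_summaries(), "measure", "measure", "artwork")
compare_groups(s, "none", "ai_music") |>
  dplyr::filter(measure == "fixation_duration_s_overall")
#>   measure                     mean_diff percent_change     d ci_low ci_high        p
#> 1 fixation_duration_s_overall      17.5           42.5  1.29  0.753    1.83  2.69e-6
```

i.e. children hearing gaze-conditioned music fixated 17.53 s longer on
average than the no-music group — a 42.5% improvement, pooled-SD
Cohen's *d* = 1.29.

A thin command-line front end with `scan`, `analyze`, `train`, `compose`,
`postprocess`, `stats`, `simulate` and `map-table` subcommands lives at
`inst/cli/gaze2tone.R`.

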