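# End-to-end orchestration: image + gaze recording -> fixations -> QC ->
# gaze elements -> seed -> LSTM generation -> post-processing -> MIDI, with a
# machine-readable run report.

qc_abort <- function(qc) {
  abort(
    sprintf(
      "Recording failed quality control (missing %.1f%%, outside %.1f%%); no output written.",
      100 * qc$missing_fraction, 100 * qc$outside_fraction
    ),
    class = "gazetone_qc_error", qc = qc
  )
}

#' Compose a melody from an image and a gaze recording
#'
#' Runs the full closed loop: detect fixations, quality-control the
#' recording (aborting with a `gazetone_qc_error` and writing nothing if it
#' is unreliable), extract gaze elements, scan the image grid, build the
#' gaze-conditioned seed, generate with the melody model, quantize rhythm,
#' clamp the pitch range, validate structure against the seed, and
#' optionally write the result as a MIDI file.
#'
#' @param image Image path or array (see [grid_scan()]).
#' @param gaze Gaze sample tibble or CSV path.
#' @param model A trained [train_melody_model()] model.
#' @param map A [color_note_map()].
#' @param length Total number of events to generate.
#' @param comfort_range `c(low, high)` pitch clamp after generation.
#' @param out_midi Optional output MIDI path.
#' @param settings A [midi_settings()] for the output file.
#' @param config Generation settings (defaults to the model's).
#' @return A list of class `gaze_composition`: `events` (post-processed),
#'   `seed`, `fixations`, `elements`, and `report` (QC, element/seed/output
#'   lengths, structure validation, output path, config hash) which
#'   serializes losslessly to JSON.
#' @export
compose_from_gaze <- function(image, gaze, model, map = color_note_map(),
                              length = 100L, comfort_range = c(36L, 96L),
                              out_midi = NULL, settings = midi_settings(),
                              config = model$config) {
  if (is.character(gaze)) gaze <- read_gaze_csv(gaze)
  scan <- grid_scan(image, map = map)
  w <- attr(scan, "image_width")
  h <- attr(scan, "image_height")

  fixations <- detect_fixations(gaze)
  qc <- qc_recording(gaze, fixations, c(0, 0, w, h))
  if (!qc$reliable) qc_abort(qc)

  elements <- extract_elements(fixations)
  seed <- build_seed(elements, scan, map)
  gen_length <- max(length, nrow(seed))
  raw_events <- generate_melody(model, seed, gen_length, config = config)
  events <- raw_events |>
    quantize_rhythm() |>
    clamp_pitch_range(comfort_range[1], comfort_range[2])
  structure_check <- if (nrow(seed)) {
    validate_structure(events, seed)
  } else {
    tibble(coverage = NA_real_, pass = NA)
  }
  if (!is.null(out_midi)) {
    write_midi(events, out_midi, settings)
  }
  report <- list(
    qc = as.list(qc),
    n_elements = nrow(elements),
    seed_length = nrow(seed),
    generated_length = nrow(events),
    structure = as.list(structure_check),
    output_path = out_midi %||% NA_character_,
    config_hash = rlang::hash(list(config, map, comfort_range, length))
  )
  structure(
    list(
      events = events, seed = seed, fixations = fixations,
      elements = elements, report = report
    ),
    class = "gaze_composition"
  )
}

#' @export
print.gaze_composition <- function(x, ...) {
  cat("<gaze_composition>\n")
  cat(sprintf(
    "  %d elements -> seed of %d events -> %d post-processed events\n",
    x$report$n_elements, x$report$seed_length, x$report$generated_length
  ))
  cat(sprintf(
    "  QC: missing %.1f%%, outside %.1f%% (reliable: %s)\n",
    100 * x$report$qc$missing_fraction, 100 * x$report$qc$outside_fraction,
    x$report$qc$reliable
  ))
  if (!is.na(x$report$structure$coverage)) {
    cat(sprintf(
      "  structure coverage %.2f (pass: %s)\n",
      x$report$structure$coverage, x$report$structure$pass
    ))
  }
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' @param composition A `gaze_composition` from [compose_from_gaze()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(composition, path) {
  stopifnot(inherits(composition, "gaze_composition"))
  jsonlite::write_json(composition$report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
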