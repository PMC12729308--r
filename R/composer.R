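# Gaze-conditioned melody generation: seed construction from gaze elements,
# corpus encoding, LSTM training and autoregressive sampling.

#' Melody model configuration
#'
#' The `"paper"` profile is the full-scale architecture (3 LSTM layers of 512
#' hidden units, 30% dropout, 100 epochs); the `"desk"` profile is a small
#' configuration of the same architecture (2 layers, 32 units, 5 epochs) that
#' trains in seconds on a laptop CPU and is the default throughout the tests.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param layers,hidden_units,dropout,epochs Architecture/training overrides.
#' @param seed RNG seed driving initialisation, dropout and sampling.
#' @param temperature Softmax sampling temperature for generation.
#' @param learning_rate,batch_size,chunk_length Optimisation settings
#'   (Adam step size; sequences per minibatch; teacher-forcing chunk length
#'   in events).
#' @param pitch_range Valid pitch interval enforced during generation.
#' @param max_velocity_step Largest admissible velocity change between
#'   consecutive generated events.
#' @return A list of class `model_config`.
#' @export
model_config <- function(profile = c("desk", "paper"),
                         layers = NULL, hidden_units = NULL, dropout = 0.3,
                         epochs = NULL, seed = 42L, temperature = 1.0,
                         learning_rate = 0.01, batch_size = 10L,
                         chunk_length = 64L, pitch_range = c(0L, 127L),
                         max_velocity_step = 32L) {
  profile <- match.arg(profile)
  defaults <- switch(profile,
    desk = list(layers = 2L, hidden_units = 32L, epochs = 5L),
    paper = list(layers = 3L, hidden_units = 512L, epochs = 100L)
  )
  layers <- layers %||% defaults$layers
  hidden_units <- hidden_units %||% defaults$hidden_units
  epochs <- epochs %||% defaults$epochs
  check_number(layers, "layers", 1, Inf, integerish = TRUE)
  check_number(hidden_units, "hidden_units", 1, Inf, integerish = TRUE)
  check_number(epochs, "epochs", 1, Inf, integerish = TRUE)
  check_number(dropout, "dropout", 0, 1 - 1e-9)
  check_number(temperature, "temperature", 1e-6, Inf)
  structure(
    list(
      profile = profile, layers = as.integer(layers),
      hidden_units = as.integer(hidden_units), dropout = dropout,
      epochs = as.integer(epochs), seed = as.integer(seed),
      temperature = temperature, learning_rate = learning_rate,
      batch_size = as.integer(batch_size), chunk_length = as.integer(chunk_length),
      pitch_range = as.integer(pitch_range),
      max_velocity_step = as.integer(max_velocity_step)
    ),
    class = "model_config"
  )
}

#' Build the gaze-conditioned seed sequence
#'
#' One note per gaze element, in rank (first-entry) order: the pitch comes
#' from the dominant colour of the grid cell containing the element's region
#' centre, the duration quantizes the element's dwell at one time unit per
#' 500 ms (clamped to 1-16 units), and the velocity follows that colour's
#' saturation. Events are gapless (offset = previous duration).
#'
#' @param elements Gaze elements from [extract_elements()].
#' @param scan A [grid_scan()] of the same image the gaze was recorded on.
#' @param map A [color_note_map()].
#' @param region_px Lattice pitch used when the elements were extracted.
#' @return A tibble of class `seed_sequence` with note columns `pitch`,
#'   `duration`, `velocity`, `offset` plus provenance columns `rank`,
#'   `region_x`, `region_y`, `r`, `g`, `b`.
#' @export
build_seed <- function(elements, scan, map = color_note_map(), region_px = 100) {
  check_columns(elements, c("region_x", "region_y", "dwell", "rank"), "elements")
  check_columns(scan, c("row", "col", "r", "g", "b"), "scan")
  w <- attr(scan, "image_width")
  h <- attr(scan, "image_height")
  rows <- attr(scan, "rows") %||% (max(scan$row) + 1L)
  cols <- attr(scan, "cols") %||% (max(scan$col) + 1L)
  if (is.null(w) || is.null(h)) {
    stop_input("`scan` must carry image_width/image_height attributes (use grid_scan()).")
  }
  empty <- tibble(
    pitch = integer(), duration = integer(), velocity = integer(),
    offset = integer(), rank = integer(), region_x = double(),
    region_y = double(), r = integer(), g = integer(), b = integer()
  )
  if (nrow(elements) == 0L) {
    return(structure(empty, class = c("seed_sequence", class(empty))))
  }
  el <- arrange(elements, .data$rank)
  cx <- el$region_x + region_px / 2
  cy <- el$region_y + region_px / 2
  if (any(cx < 0 | cx >= w | cy < 0 | cy >= h)) {
    stop_input("Element region centre falls outside the image.")
  }
  cell_row <- cell_index(floor(cy), h, rows)
  cell_col <- cell_index(floor(cx), w, cols)
  idx <- match(cell_row * cols + cell_col, scan$row * cols + scan$col)
  colr <- scan[idx, c("r", "g", "b")]
  mapped <- color_to_pitch(colr, map)
  out <- tibble(
    pitch = mapped$pitch,
    duration = as.integer(clamp(round(el$dwell / 500), 1, 16)),
    velocity = velocity_from_saturation(mapped$s),
    offset = 0L,
    rank = el$rank,
    region_x = el$region_x, region_y = el$region_y,
    r = colr$r, g = colr$g, b = colr$b
  )
  out$offset <- c(0L, out$duration[-nrow(out)])
  structure(out, class = c("seed_sequence", class(out)))
}

#' Encode a MIDI corpus as event sequences
#'
#' Reads each Standard MIDI File, merges its tracks, reduces polyphony to a
#' monophonic stream (the highest note sounding at each onset is retained)
#' and re-expresses it in the four-axis event encoding. Unreadable files are
#' skipped with a warning rather than aborting the corpus.
#'
#' @param midi_files Character vector of `.mid` paths.
#' @param settings A [midi_settings()].
#' @return A named list of event tibbles (one per readable file).
#' @export
encode_corpus <- function(midi_files, settings = midi_settings()) {
  out <- list()
  for (f in midi_files) {
    ev <- tryCatch(read_midi(f, settings), error = function(e) {
      warn(sprintf("Skipping unreadable MIDI file '%s': %s", f, conditionMessage(e)))
      NULL
    })
    if (!is.null(ev)) out[[basename(f)]] <- ev
  }
  out
}

#' Train the melody model
#'
#' Fits the stacked-LSTM next-event predictor on an encoded corpus by teacher
#' forcing: at every position the four softmax heads (pitch, duration class,
#' velocity class, offset class) are trained with summed cross-entropy to
#' predict the following event. Optimisation is minibatch Adam; all
#' randomness (initialisation, shuffling, dropout) derives from
#' `config$seed`, so identical inputs give an identical loss trace.
#'
#' @param corpus A list of event tibbles (e.g. from [encode_corpus()] or
#'   [make_corpus()]).
#' @param config A [model_config()].
#' @return An object of class `melody_model`: parameters, config and the
#'   per-epoch mean training loss trace. Inspect with [tidy()] / [glance()].
#' @export
train_melody_model <- function(corpus, config = model_config("desk")) {
  stopifnot(inherits(config, "model_config"))
  if (!is.list(corpus) || length(corpus) == 0L) {
    stop_input("`corpus` must be a non-empty list of event tibbles.")
  }
  purrr::walk(corpus, check_events)
  set.seed(config$seed)
  H <- config$hidden_units
  params <- init_lstm_params(config$layers, H)
  opt <- list(t = 0L, m = zero_like(params), v = zero_like(params))
  tensors <- corpus_tensors(corpus, config$chunk_length)
  B_all <- length(corpus)
  loss_trace <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(B_all)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    epoch_loss <- 0
    n_steps <- 0
    for (idx in batches) {
      ix <- purrr::map(tensors$ix, function(m) m[idx, , drop = FALSE])
      mask <- tensors$mask[idx, , drop = FALSE]
      if (sum(mask) == 0) next
      fb <- lstm_forward_backward(params, ix, mask, H, config$dropout)
      upd <- adam_update(params, fb$grads, opt, config$learning_rate)
      params <- upd$params
      opt <- upd$opt
      epoch_loss <- epoch_loss + fb$loss
      n_steps <- n_steps + 1
    }
    loss_trace[epoch] <- epoch_loss / max(n_steps, 1)
  }

  structure(
    list(params = params, config = config, loss_trace = loss_trace,
         n_sequences = B_all),
    class = "melody_model"
  )
}

#' @export
print.melody_model <- function(x, ...) {
  cat("<melody_model>\n")
  cat(sprintf(
    "  %d-layer LSTM, %d hidden units, trained %d epochs on %d sequences\n",
    x$config$layers, x$config$hidden_units, x$config$epochs, x$n_sequences
  ))
  cat(sprintf("  final training loss: %.4f\n", tail(x$loss_trace, 1)))
  invisible(x)
}

#' @rdname train_melody_model
#' @param x A `melody_model`.
#' @param ... Unused.
#' @export
tidy.melody_model <- function(x, ...) {
  tibble(epoch = seq_along(x$loss_trace), loss = x$loss_trace)
}

#' @rdname train_melody_model
#' @export
glance.melody_model <- function(x, ...) {
  n_par <- sum(rapply(x$params, length, how = "unlist"))
  tibble(
    layers = x$config$layers, hidden_units = x$config$hidden_units,
    epochs = x$config$epochs, n_sequences = x$n_sequences,
    n_parameters = n_par, final_loss = tail(x$loss_trace, 1)
  )
}

default_seed_event <- function() {
  tibble(pitch = 60L, duration = 4L, velocity = 64L, offset = 0L)
}

sample_class <- function(logits, temperature) {
  p <- drop(softmax_rows(matrix(logits / temperature, 1)))
  sample.int(length(p), 1L, prob = p)
}

#' Generate a melody from a seed sequence
#'
#' Autoregressive sampling at the configured temperature. The seed events are
#' emitted verbatim as the prefix and condition the network state; each
#' sampled event is validity-checked (pitch inside `config$pitch_range`,
#' duration a positive grid multiple, velocity step from the previous event
#' at most `config$max_velocity_step`) and resampled up to 8 times, after
#' which the offending fields are projected to the nearest valid value. An
#' empty seed starts from a configured default event (middle C quarter note)
#' which becomes the first output event.
#'
#' @param model A trained [train_melody_model()] model.
#' @param seed_events Seed tibble (`pitch`, `duration`, `velocity`, `offset`).
#' @param length Total number of events to return (must be at least the seed
#'   length).
#' @param config Generation settings; defaults to the model's config.
#' @param rng_seed Seed for the sampling RNG (defaults to `config$seed`).
#' @return A tibble of `length` note events beginning with the seed.
#' @export
generate_melody <- function(model, seed_events, length,
                            config = model$config, rng_seed = config$seed) {
  if (!inherits(model, "melody_model")) {
    stop_input("`model` must be a trained melody_model.")
  }
  if (nrow(seed_events) == 0L) {
    seed_events <- default_seed_event()
  }
  seed_events <- as_tibble(seed_events)[, c("pitch", "duration", "velocity", "offset")]
  check_events(seed_events)
  n_seed <- nrow(seed_events)
  check_number(length, "length", n_seed, Inf, integerish = TRUE)
  set.seed(rng_seed)
  H <- model$config$hidden_units
  L <- model$config$layers
  state <- purrr::map(seq_len(L), function(l) {
    list(h = matrix(0, 1, H), c = matrix(0, 1, H))
  })
  feed <- function(state, event) {
    cls <- encode_classes(event)
    X <- onehot_batch(cls, 1L)
    lstm_step(model$params, X, state, H, dropout = 0, training = FALSE)
  }
  events <- seed_events
  step <- NULL
  for (k in seq_len(n_seed)) {
    step <- feed(state, seed_events[k, ])
    state <- step$state
  }
  lo <- config$pitch_range[1]
  hi <- config$pitch_range[2]
  max_step <- config$max_velocity_step
  while (nrow(events) < length) {
    logits <- head_logits(model$params, step$top)
    prev_vel <- events$velocity[nrow(events)]
    cand <- NULL
    for (try in seq_len(8L)) {
      cand <- decode_classes(
        sample_class(logits$pitch, config$temperature),
        sample_class(logits$dur, config$temperature),
        sample_class(logits$vel, config$temperature),
        sample_class(logits$off, config$temperature)
      )
      ok <- cand$pitch >= lo && cand$pitch <= hi &&
        cand$duration >= 1 && cand$duration == round(cand$duration) &&
        abs(cand$velocity - prev_vel) <= max_step
      if (ok) break
      if (try == 8L) { # project to nearest valid values
        cand$pitch <- as.integer(clamp(cand$pitch, lo, hi))
        cand$duration <- as.integer(max(1, round(cand$duration)))
        cand$velocity <- as.integer(clamp(cand$velocity, prev_vel - max_step, prev_vel + max_step))
        cand$velocity <- as.integer(clamp(cand$velocity, 1, 127))
      }
    }
    events <- bind_rows(events, cand)
    step <- feed(state, cand)
    state <- step$state
  }
  events
}

check_events <- function(events, name = "events") {
  check_columns(events, c("pitch", "duration", "velocity", "offset"), name)
  if (nrow(events) == 0L) {
    return(invisible(events))
  }
  if (any(events$pitch < 0 | events$pitch > 127)) {
    stop_input("Event pitches must be in [0, 127].")
  }
  if (any(events$duration < 1 | events$duration != round(events$duration))) {
    stop_input("Event durations must be positive whole time units.")
  }
  if (any(events$velocity < 0 | events$velocity > 127)) {
    stop_input("Event velocities must be in [0, 127].")
  }
  if (any(events$offset < 0)) {
    stop_input("Event offsets must be non-negative.")
  }
  invisible(events)
}
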