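# Standard MIDI File reader/writer over the four-axis event encoding.
# Written directly on raw vectors (variable-length quantities, running
# status, meta events) since the event grid makes the mapping to note-on /
# note-off pairs exact: one time unit = one sixteenth note =
# ticks_per_quarter / 4 ticks.

#' MIDI file settings
#'
#' @param ticks_per_quarter Pulses per quarter note; must be divisible by 4 so
#'   a sixteenth-note time unit is an exact tick count.
#' @param tempo_bpm Fixed tempo written into the file.
#' @param program General-MIDI program (default 0, acoustic grand piano).
#' @return A list of class `midi_settings`.
#' @export
midi_settings <- function(ticks_per_quarter = 480L, tempo_bpm = 100, program = 0L) {
  check_number(ticks_per_quarter, "ticks_per_quarter", 4, 32767, integerish = TRUE)
  if (ticks_per_quarter %% 4 != 0) {
    stop_input("`ticks_per_quarter` must be divisible by 4.")
  }
  check_number(tempo_bpm, "tempo_bpm", 1, 1000)
  check_number(program, "program", 0, 127, integerish = TRUE)
  structure(
    list(
      ticks_per_quarter = as.integer(ticks_per_quarter),
      tempo_bpm = tempo_bpm, program = as.integer(program)
    ),
    class = "midi_settings"
  )
}

# variable-length quantity encoding
vlq_encode <- function(value) {
  stopifnot(value >= 0)
  bytes <- as.integer(value %% 128)
  value <- value %/% 128
  while (value > 0) {
    bytes <- c(as.integer(value %% 128) + 128L, bytes)
    value <- value %/% 128
  }
  as.raw(bytes)
}

int_to_bytes <- function(value, n) {
  as.raw((value %/% 256^((n - 1):0)) %% 256)
}

bytes_to_int <- function(raw) {
  sum(as.integer(raw) * 256^((length(raw) - 1):0))
}

#' Write note events to a Standard MIDI File
#'
#' Produces a single-track (format 0) file: a tempo meta event, a program
#' change, then one note-on/note-off pair per event at tick positions derived
#' from the offsets and durations (one time unit = a sixteenth note). The
#' output parses under any standard MIDI reader and round-trips through
#' [read_midi()] exactly for grid-aligned sequences.
#'
#' @param events Event tibble (`pitch`, `duration`, `velocity`, `offset`).
#' @param path Output file path.
#' @param settings A [midi_settings()].
#' @return `path`, invisibly.
#' @export
write_midi <- function(events, path, settings = midi_settings()) {
  check_events(events)
  stopifnot(inherits(settings, "midi_settings"))
  unit <- settings$ticks_per_quarter %/% 4L
  usec_per_quarter <- round(60e6 / settings$tempo_bpm)

  msgs <- list() # each: list(tick, order, bytes)
  msgs[[1]] <- list(tick = 0, order = 0, bytes = c(
    as.raw(c(0xFF, 0x51, 0x03)), int_to_bytes(usec_per_quarter, 3)
  ))
  msgs[[2]] <- list(tick = 0, order = 0, bytes = as.raw(c(0xC0, settings$program)))
  if (nrow(events)) {
    onset_units <- cumsum(as.numeric(events$offset))
    for (k in seq_len(nrow(events))) {
      on_tick <- onset_units[k] * unit
      off_tick <- (onset_units[k] + events$duration[k]) * unit
      msgs[[length(msgs) + 1]] <- list(
        tick = on_tick, order = 1,
        bytes = as.raw(c(0x90, events$pitch[k], max(1L, events$velocity[k])))
      )
      msgs[[length(msgs) + 1]] <- list(
        tick = off_tick, order = 0, # offs before ons at the same tick
        bytes = as.raw(c(0x80, events$pitch[k], 0x40))
      )
    }
  }
  ord <- order(
    vapply(msgs, function(m) m$tick, numeric(1)),
    vapply(msgs, function(m) m$order, numeric(1))
  )
  msgs <- msgs[ord]

  track <- raw(0)
  prev_tick <- 0
  for (m in msgs) {
    track <- c(track, vlq_encode(m$tick - prev_tick), m$bytes)
    prev_tick <- m$tick
  }
  track <- c(track, vlq_encode(0), as.raw(c(0xFF, 0x2F, 0x00)))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("MThd"), con)
  writeBin(int_to_bytes(6, 4), con)
  writeBin(int_to_bytes(0, 2), con) # format 0
  writeBin(int_to_bytes(1, 2), con) # one track
  writeBin(int_to_bytes(settings$ticks_per_quarter, 2), con)
  writeBin(charToRaw("MTrk"), con)
  writeBin(int_to_bytes(length(track), 4), con)
  writeBin(track, con)
  invisible(path)
}

stop_format <- function(msg) {
  abort(msg, class = "gazetone_format_error")
}

# Parse one MTrk chunk into a tibble of absolute-tick channel note messages.
parse_track <- function(bytes) {
  pos <- 1L
  tick <- 0
  status <- NULL
  out <- list()
  nbytes <- length(bytes)
  read_vlq <- function() {
    value <- 0
    repeat {
      if (pos > nbytes) stop_format("Truncated MIDI track (in delta time).")
      b <- as.integer(bytes[pos])
      pos <<- pos + 1L
      value <- value * 128 + (b %% 128)
      if (b < 128) break
    }
    value
  }
  while (pos <= nbytes) {
    tick <- tick + read_vlq()
    b <- as.integer(bytes[pos])
    if (b >= 0x80) {
      status <- b
      pos <- pos + 1L
    } else if (is.null(status)) {
      stop_format("Running status before any status byte.")
    }
    hi <- status %/% 16
    if (status == 0xFF) { # meta
      type <- as.integer(bytes[pos])
      pos <- pos + 1L
      len <- read_vlq()
      pos <- pos + len
      status <- NULL # meta events cancel running status
      if (type == 0x2F) break
    } else if (status %in% c(0xF0, 0xF7)) { # sysex
      len <- read_vlq()
      pos <- pos + len
      status <- NULL
    } else if (hi %in% c(0x9, 0x8)) { # note on/off
      pitch <- as.integer(bytes[pos])
      vel <- as.integer(bytes[pos + 1L])
      pos <- pos + 2L
      on <- hi == 0x9 && vel > 0
      out[[length(out) + 1]] <- tibble(
        tick = tick, on = on, pitch = pitch, velocity = vel
      )
    } else if (hi %in% c(0xA, 0xB, 0xE)) { # two data bytes
      pos <- pos + 2L
    } else if (hi %in% c(0xC, 0xD)) { # one data byte
      pos <- pos + 1L
    } else {
      stop_format(sprintf("Unsupported status byte 0x%X.", status))
    }
  }
  if (length(out)) bind_rows(out) else tibble(
    tick = double(), on = logical(), pitch = integer(), velocity = integer()
  )
}

#' Read a Standard MIDI File as note events
#'
#' Parses format 0/1 files (unknown chunk types are skipped per the SMF
#' specification), merges all tracks on the absolute tick axis, pairs note-on
#' with note-off messages, reduces polyphony to the highest note at each
#' onset, and quantizes timing to the sixteenth-note unit grid (off-grid
#' durations round to the nearest unit, minimum 1).
#'
#' @param path MIDI file path.
#' @param settings A [midi_settings()] supplying the unit grid. The file's own
#'   ticks-per-quarter header is used for quantization.
#' @return An event tibble (`pitch`, `duration`, `velocity`, `offset`).
#' @export
read_midi <- function(path, settings = midi_settings()) {
  if (!file.exists(path)) stop_input(sprintf("No such file: '%s'.", path))
  bytes <- readBin(path, "raw", file.info(path)$size)
  pos <- 1L
  read_chunk <- function() {
    if (pos + 8L > length(bytes) + 1L) {
      return(NULL)
    }
    id <- rawToChar(bytes[pos:(pos + 3L)])
    len <- bytes_to_int(bytes[(pos + 4L):(pos + 7L)])
    body_start <- pos + 8L
    if (body_start + len - 1L > length(bytes)) stop_format("Truncated MIDI chunk.")
    body <- if (len > 0) bytes[body_start:(body_start + len - 1L)] else raw(0)
    pos <<- body_start + len
    list(id = id, body = body)
  }
  header <- read_chunk()
  if (is.null(header) || header$id != "MThd" || length(header$body) < 6L) {
    stop_format("Not a Standard MIDI File (missing MThd).")
  }
  division <- bytes_to_int(header$body[5:6])
  if (division >= 0x8000) stop_format("SMPTE time division is not supported.")
  msgs <- list()
  repeat {
    chunk <- read_chunk()
    if (is.null(chunk)) break
    if (chunk$id != "MTrk") next # skip unknown chunk types
    msgs[[length(msgs) + 1]] <- parse_track(chunk$body)
  }
  msgs <- bind_rows(msgs)
  if (nrow(msgs) == 0L) {
    return(tibble(
      pitch = integer(), duration = integer(), velocity = integer(), offset = integer()
    ))
  }

  # pair ons with offs (FIFO per pitch)
  msgs <- arrange(msgs, .data$tick, .data$on)
  open <- list()
  notes <- list()
  for (k in seq_len(nrow(msgs))) {
    key <- as.character(msgs$pitch[k])
    if (msgs$on[k]) {
      open[[key]] <- c(open[[key]], k)
    } else if (length(open[[key]])) {
      j <- open[[key]][1]
      open[[key]] <- open[[key]][-1]
      notes[[length(notes) + 1]] <- tibble(
        onset = msgs$tick[j], pitch = msgs$pitch[j],
        velocity = msgs$velocity[j], dur_ticks = msgs$tick[k] - msgs$tick[j]
      )
    }
  }
  if (length(notes) == 0L) {
    return(tibble(
      pitch = integer(), duration = integer(), velocity = integer(), offset = integer()
    ))
  }
  notes <- bind_rows(notes) |>
    arrange(.data$onset, dplyr::desc(.data$pitch)) |>
    group_by(.data$onset) |>
    dplyr::slice(1L) |> # monophonic reduction: highest note per onset
    ungroup()

  unit <- division / 4
  dur <- pmax(1L, as.integer(round(notes$dur_ticks / unit)))
  onset_units <- round(notes$onset / unit)
  tibble(
    pitch = as.integer(notes$pitch),
    duration = dur,
    velocity = as.integer(notes$velocity),
    offset = as.integer(c(0, diff(onset_units)))
  )
}
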