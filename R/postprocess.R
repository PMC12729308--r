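# Post-generation clean-up: rhythm quantization onto standard note values,
# octave-preserving pitch clamping into a comfortable register, and a
# structural check that the generated material keeps the seed's pitch-class
# framework.

#' Quantize durations to standard note values
#'
#' Replaces each duration with the nearest member of `grid` (in time units;
#' the default grid spans a sixteenth note through a whole note, including
#' dotted values). Ties round up. Offsets are re-normalized so that the piece
#' stays gapless wherever it was gapless (an event whose offset equalled the
#' previous event's duration keeps that property after quantization); other
#' offsets are quantized to the nearest grid value (or 0). Idempotent.
#'
#' @param events Event tibble (`pitch`, `duration`, `velocity`, `offset`).
#' @param grid Allowed duration values in time units, ascending.
#' @return The events tibble with quantized `duration` and `offset`.
#' @export
quantize_rhythm <- function(events, grid = c(1L, 2L, 4L, 8L, 16L, 3L, 6L, 12L)) {
  check_events(events)
  grid <- sort(unique(as.integer(grid)))
  if (nrow(events) == 0L) {
    return(as_tibble(events))
  }
  nearest_up <- function(x) {
    # nearest grid member; tie -> larger value
    vapply(x, function(v) {
      d <- abs(grid - v)
      cand <- grid[d == min(d)]
      max(cand)
    }, integer(1))
  }
  out <- as_tibble(events)
  old_dur <- out$duration
  gapless <- c(FALSE, out$offset[-1] == old_dur[-nrow(out)])
  out$duration <- nearest_up(out$duration)
  off_grid <- sort(unique(c(0L, grid)))
  new_off <- vapply(out$offset, function(v) {
    d <- abs(off_grid - v)
    cand <- off_grid[d == min(d)]
    max(cand)
  }, integer(1))
  new_off[gapless] <- out$duration[which(gapless) - 1L]
  new_off[1] <- out$offset[1]
  out$offset <- new_off
  out
}

#' Clamp pitches into a comfort range by octave transposition
#'
#' Pitches above `high` are transposed down by whole octaves until they fit;
#' pitches below `low` are transposed up. The pitch class is preserved
#' exactly, so the colour -> pitch-class mapping survives the clamp. The
#' default range 36-96 (C2-C7) spans a child-comfortable piano register.
#'
#' @param events Event tibble.
#' @param low,high MIDI pitch bounds; must span at least one octave.
#' @return The events tibble with clamped `pitch`.
#' @export
clamp_pitch_range <- function(events, low = 36L, high = 96L) {
  check_events(events)
  check_number(low, "low", 0, 127, integerish = TRUE)
  check_number(high, "high", 0, 127, integerish = TRUE)
  if (high - low < 12L) {
    stop_input("Comfort range must span at least one octave (high - low >= 12).")
  }
  out <- as_tibble(events)
  p <- out$pitch
  while (any(p > high)) p[p > high] <- p[p > high] - 12L
  while (any(p < low)) p[p < low] <- p[p < low] + 12L
  out$pitch <- as.integer(p)
  out
}

#' Structural validation against the seed
#'
#' Measures how much of the seed's pitch-class material survives into the
#' generated continuation: coverage is the fraction of distinct seed pitch
#' classes that appear anywhere after the seed prefix. The sequence passes
#' when coverage reaches `min_coverage`.
#'
#' @param events Full event tibble (seed prefix + continuation).
#' @param seed The seed tibble used for generation (non-empty).
#' @param min_coverage Pass threshold in `[0, 1]`.
#' @return One-row tibble: `coverage`, `pass`.
#' @export
validate_structure <- function(events, seed, min_coverage = 0.5) {
  check_events(events)
  if (!is.data.frame(seed) || nrow(seed) == 0L) {
    stop_input("`seed` must be a non-empty event tibble (coverage is undefined otherwise).")
  }
  check_events(seed, "seed")
  check_number(min_coverage, "min_coverage", 0, 1)
  seed_pc <- unique(seed$pitch %% 12L)
  post <- events$pitch[-seq_len(min(nrow(seed), nrow(events)))]
  coverage <- mean(seed_pc %in% (post %% 12L))
  tibble(coverage = coverage, pass = coverage >= min_coverage)
}
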