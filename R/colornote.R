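# Colour -> note mapping. The mapping partitions HSV space into hue sectors
# crossed with value (brightness) bands, plus achromatic fallbacks; each region
# carries one MIDI pitch. Pure red at full saturation/brightness anchors the
# partition at middle C (60), and dropping one value band moves the pitch down
# exactly one octave (12 semitones).

#' Configuration of the colour-to-note mapping
#'
#' Defines how HSV colour space is partitioned into pitch regions. The default
#' partition uses 12 hue sectors (one per chromatic pitch class, sector 0
#' centred on red) crossed with 4 brightness bands (one octave apart), plus
#' white/black replacement notes for achromatic colours. Pure red at full
#' saturation and brightness maps to MIDI pitch 60 (middle C).
#'
#' @param hue_sector_count Number of hue sectors; must divide 360 evenly.
#' @param value_band_count Number of brightness bands; adjacent bands are one
#'   octave (12 semitones) apart.
#' @param anchor_pitch MIDI pitch of hue sector 0 in the top brightness band.
#' @param achromatic_sat_threshold Saturation below which a colour is treated
#'   as achromatic.
#' @param achromatic_value_low Brightness below which any colour maps to the
#'   black replacement note.
#' @param white_pitch,black_pitch Replacement pitches for white/black regions.
#' @param pitch_floor,pitch_ceiling Clamp range for the mapped pitch.
#'
#' @return An object of class `color_note_map`.
#' @examples
#' m <- color_note_map()
#' color_to_pitch(tibble::tibble(r = 255, g = 0, b = 0), m)$pitch # 60
#' @export
color_note_map <- function(hue_sector_count = 12L,
                           value_band_count = 4L,
                           anchor_pitch = 60L,
                           achromatic_sat_threshold = 0.1,
                           achromatic_value_low = 0.1,
                           white_pitch = 72L,
                           black_pitch = 48L,
                           pitch_floor = 0L,
                           pitch_ceiling = 127L) {
  check_number(hue_sector_count, "hue_sector_count", 1, 360, integerish = TRUE)
  if (360 %% hue_sector_count != 0) {
    stop_input("`hue_sector_count` must divide 360 evenly.")
  }
  check_number(value_band_count, "value_band_count", 1, 12, integerish = TRUE)
  check_number(anchor_pitch, "anchor_pitch", 0, 127, integerish = TRUE)
  check_number(achromatic_sat_threshold, "achromatic_sat_threshold", 0, 1)
  check_number(achromatic_value_low, "achromatic_value_low", 0, 1)
  check_number(white_pitch, "white_pitch", 0, 127, integerish = TRUE)
  check_number(black_pitch, "black_pitch", 0, 127, integerish = TRUE)
  check_number(pitch_floor, "pitch_floor", 0, 127, integerish = TRUE)
  check_number(pitch_ceiling, "pitch_ceiling", 0, 127, integerish = TRUE)
  if (!(pitch_floor <= anchor_pitch && anchor_pitch <= pitch_ceiling)) {
    stop_input("Require pitch_floor <= anchor_pitch <= pitch_ceiling.")
  }
  structure(
    list(
      hue_sector_count = as.integer(hue_sector_count),
      value_band_count = as.integer(value_band_count),
      anchor_pitch = as.integer(anchor_pitch),
      achromatic_sat_threshold = achromatic_sat_threshold,
      achromatic_value_low = achromatic_value_low,
      white_pitch = as.integer(white_pitch),
      black_pitch = as.integer(black_pitch),
      pitch_floor = as.integer(pitch_floor),
      pitch_ceiling = as.integer(pitch_ceiling)
    ),
    class = "color_note_map"
  )
}

#' @export
print.color_note_map <- function(x, ...) {
  cat("<color_note_map>\n")
  cat(sprintf(
    "  %d hue sectors x %d value bands, anchor pitch %d (pure red)\n",
    x$hue_sector_count, x$value_band_count, x$anchor_pitch
  ))
  cat(sprintf(
    "  achromatic: s < %.2f -> white %d / black %d; clamp [%d, %d]\n",
    x$achromatic_sat_threshold, x$white_pitch, x$black_pitch,
    x$pitch_floor, x$pitch_ceiling
  ))
  invisible(x)
}

check_rgb <- function(r, g, b) {
  for (ch in list(r = r, g = g, b = b)) {
    if (!is.numeric(ch) || anyNA(ch) || any(ch < 0 | ch > 255)) {
      stop_input("RGB channel values must be numbers in [0, 255].")
    }
  }
  invisible(NULL)
}

# Vectorised RGB (0-255) -> HSV with h in degrees [0, 360).
rgb_to_hsv_deg <- function(r, g, b) {
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  list(h = hsv[1, ] * 360, s = hsv[2, ], v = hsv[3, ])
}

# Region assignment shared by color_to_pitch() and grid_scan(). Regions are
# encoded as integers: chromatic sector*band_count + band in
# [0, sectors*bands); white = -1; black = -2. Vectorised.
map_region <- function(h, s, v, m) {
  sector_width <- 360 / m$hue_sector_count
  sector <- floor(((h + sector_width / 2) %% 360) / sector_width)
  band <- pmin(floor(v * m$value_band_count), m$value_band_count - 1)
  region <- as.integer(sector * m$value_band_count + band)
  achrom <- s < m$achromatic_sat_threshold
  white <- achrom & v >= 0.9
  nearest_white <- achrom & !white & v >= 0.5
  region[achrom] <- ifelse(white[achrom] | nearest_white[achrom], -1L, -2L)
  region[v < m$achromatic_value_low] <- -2L
  region
}

# Pitch of each region code (before per-colour computation; vectorised).
region_pitch <- function(region, m) {
  sector <- region %/% m$value_band_count
  band <- region %% m$value_band_count
  pitch <- m$anchor_pitch + sector - 12L * (m$value_band_count - 1L - band)
  pitch[region == -1L] <- m$white_pitch
  pitch[region == -2L] <- m$black_pitch
  as.integer(pmin(pmax(pitch, m$pitch_floor), m$pitch_ceiling))
}

#' Map colours to MIDI pitches
#'
#' Assigns each RGB colour to a pitch region of the map and returns the region
#' and pitch alongside the derived HSV coordinates. Chromatic colours take
#' `anchor_pitch + hue_sector - 12 * (bands_below_top)`, clamped to the map's
#' pitch range; achromatic colours fall back to the white/black replacement
#' notes (bright -> white, dark -> black, nearest by brightness in between).
#'
#' @param colors A data frame with integer columns `r`, `g`, `b` in 0-255.
#' @param map A [color_note_map()].
#' @return The input as a tibble with columns `h`, `s`, `v`, `region`, `pitch`
#'   added. `region` is an integer region code (negative for white/black).
#' @examples
#' color_to_pitch(tibble::tibble(r = c(255, 0), g = c(0, 0), b = c(0, 0)))
#' @export
color_to_pitch <- function(colors, map = color_note_map()) {
  check_columns(colors, c("r", "g", "b"), "colors")
  stopifnot(inherits(map, "color_note_map"))
  check_rgb(colors$r, colors$g, colors$b)
  out <- as_tibble(colors)
  if (nrow(out) == 0L) {
    return(mutate(out,
      h = double(), s = double(), v = double(),
      region = integer(), pitch = integer()
    ))
  }
  hsv <- rgb_to_hsv_deg(out$r, out$g, out$b)
  region <- map_region(hsv$h, hsv$s, hsv$v, map)
  mutate(out,
    h = hsv$h, s = hsv$s, v = hsv$v,
    region = region, pitch = region_pitch(region, map)
  )
}

#' Note duration from visual prominence
#'
#' A colour's visual prominence (fraction of a grid cell occupied by its
#' region) scales the note length: `base_unit * max(1, round(p * 4))`, so with
#' the default sixteenth-note unit the codomain is 1-4 sixteenths (a quarter
#' note at full prominence, never zero length).
#'
#' @param p Prominence fraction(s) in 0-1.
#' @param base_unit Duration of one time unit (sixteenth note = 1).
#' @return Integer duration(s) in time units.
#' @export
duration_from_prominence <- function(p, base_unit = 1L) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop_input("`p` must be in [0, 1].")
  }
  as.integer(base_unit) * pmax(1L, as.integer(round(p * 4)))
}

#' MIDI velocity from saturation
#'
#' Maps saturation linearly onto `[1, 127]` so even fully desaturated colours
#' remain audible: `round(s * 126) + 1`.
#'
#' @param s Saturation fraction(s) in 0-1.
#' @return Integer MIDI velocity(ies) in 1-127.
#' @export
velocity_from_saturation <- function(s) {
  if (!is.numeric(s) || anyNA(s) || any(s < 0 | s > 1)) {
    stop_input("`s` must be in [0, 1].")
  }
  as.integer(round(s * 126)) + 1L
}

#' Enumerate the full colour-region -> pitch table
#'
#' Dumps one row per region of the map (every hue sector x value band plus the
#' white and black fallbacks) with a representative HSV/RGB colour and the
#' assigned pitch. Useful for inspecting or exporting the mapping matrix.
#'
#' @param map A [color_note_map()].
#' @return A tibble with columns `region`, `hue_sector`, `value_band`, `h`,
#'   `s`, `v`, `r`, `g`, `b`, `pitch`.
#' @export
map_table <- function(map = color_note_map()) {
  stopifnot(inherits(map, "color_note_map"))
  sector_width <- 360 / map$hue_sector_count
  grid <- tidyr::expand_grid(
    hue_sector = seq_len(map$hue_sector_count) - 1L,
    value_band = seq_len(map$value_band_count) - 1L
  )
  # representative colour: sector-centre hue, full saturation, band-centre value
  grid <- mutate(grid,
    h = .data$hue_sector * sector_width,
    s = 1,
    v = (.data$value_band + 0.5) / map$value_band_count,
    region = as.integer(.data$hue_sector * map$value_band_count + .data$value_band)
  )
  fallback <- tibble(
    hue_sector = NA_integer_, value_band = NA_integer_,
    h = c(0, 0), s = c(0, 0), v = c(1, 0),
    region = c(-1L, -2L)
  )
  tab <- bind_rows(grid, fallback)
  rgb <- grDevices::hsv(tab$h / 360, tab$s, tab$v)
  chan <- grDevices::col2rgb(rgb)
  mutate(tab,
    r = as.integer(chan[1, ]), g = as.integer(chan[2, ]), b = as.integer(chan[3, ]),
    pitch = region_pitch(.data$region, map)
  ) |>
    select("region", "hue_sector", "value_band", "h", "s", "v", "r", "g", "b", "pitch") |>
    arrange(.data$region)
}
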