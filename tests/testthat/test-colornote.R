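test_that("the mapping anchors pure red at middle C and steps octaves by value band", {
  m <- color_note_map()
  expect_identical(color_to_pitch(tibble::tibble(r = 255, g = 0, b = 0), m)$pitch, 60L)
  # one value band below the top (v = 0.6 with 4 bands) is exactly one octave down
  expect_identical(color_to_pitch(tibble::tibble(r = 153, g = 0, b = 0), m)$pitch, 48L)
  # the anchor holds for any configuration with anchor_pitch 60
  for (sectors in c(6L, 12L, 36L)) {
    m2 <- color_note_map(hue_sector_count = sectors)
    expect_identical(color_to_pitch(tibble::tibble(r = 255, g = 0, b = 0), m2)$pitch, 60L)
  }
})

test_that("achromatic colours fall back to the white/black replacement notes", {
  m <- color_note_map()
  got <- color_to_pitch(tibble::tibble(
    r = c(255, 0, 200, 40), g = c(255, 0, 200, 40), b = c(255, 0, 200, 40)
  ), m)
  expect_identical(got$pitch, c(72L, 48L, 72L, 48L)) # white, black, light grey, dark grey
  # saturated but nearly black -> black note, not a chromatic pitch
  expect_identical(color_to_pitch(tibble::tibble(r = 20, g = 0, b = 0), m)$pitch, 48L)
})

test_that("every RGB triple maps to exactly one valid pitch (totality)", {
  m <- color_note_map()
  lv <- seq(0, 255, length.out = 16)
  lattice <- tidyr::expand_grid(r = lv, g = lv, b = lv)
  got <- color_to_pitch(lattice, m)
  expect_identical(nrow(got), nrow(lattice))
  expect_true(all(got$pitch >= 0 & got$pitch <= 127))
  expect_false(anyNA(got$pitch))
  # determinism: identical inputs give identical outputs
  expect_identical(got$pitch, color_to_pitch(lattice, m)$pitch)
})

test_that("decreasing value by one band lowers pitch by exactly 12 when unclamped", {
  m <- color_note_map()
  hues <- seq(0, 350, by = 10)
  for (band_hi in 3:1) {
    v_hi <- (band_hi + 0.5) / 4
    v_lo <- (band_hi - 0.5) / 4
    col_hi <- grDevices::col2rgb(grDevices::hsv(hues / 360, 1, v_hi))
    col_lo <- grDevices::col2rgb(grDevices::hsv(hues / 360, 1, v_lo))
    p_hi <- color_to_pitch(tibble::tibble(
      r = col_hi[1, ], g = col_hi[2, ], b = col_hi[3, ]
    ), m)$pitch
    p_lo <- color_to_pitch(tibble::tibble(
      r = col_lo[1, ], g = col_lo[2, ], b = col_lo[3, ]
    ), m)$pitch
    expect_true(all(p_lo <= p_hi))
    unclamped <- p_hi - 12 >= m$pitch_floor
    expect_true(all((p_hi - p_lo)[unclamped] == 12))
  }
})

test_that("malformed channel values are rejected", {
  expect_error(color_to_pitch(tibble::tibble(r = 300, g = 0, b = 0)), class = "gazetone_input_error")
  expect_error(color_to_pitch(tibble::tibble(r = -1, g = 0, b = 0)), class = "gazetone_input_error")
  expect_error(color_note_map(hue_sector_count = 7), class = "gazetone_input_error")
})

test_that("prominence scales duration on a 1-4 sixteenth codomain", {
  expect_identical(duration_from_prominence(1.0), 4L)
  expect_identical(duration_from_prominence(0.0), 1L) # floor, never zero length
  expect_identical(duration_from_prominence(0.6), 2L) # round(2.4)
  expect_identical(duration_from_prominence(seq(0, 1, by = 0.05)) %in% 1:4, rep(TRUE, 21))
  expect_error(duration_from_prominence(1.2), class = "gazetone_input_error")
})

test_that("saturation maps linearly onto audible velocity", {
  expect_identical(velocity_from_saturation(c(1, 0, 0.5)), c(127L, 1L, 64L))
  s <- seq(0, 1, by = 0.01)
  expect_true(all(velocity_from_saturation(s) >= 1 & velocity_from_saturation(s) <= 127))
  expect_error(velocity_from_saturation(-0.1), class = "gazetone_input_error")
})

test_that("map_table enumerates every region once with consistent pitches", {
  m <- color_note_map()
  tab <- map_table(m)
  expect_identical(nrow(tab), 12L * 4L + 2L)
  expect_identical(anyDuplicated(tab$region), 0L)
  # the representative colour of each chromatic region maps back to its pitch
  chrom <- tab[tab$region >= 0, ]
  back <- color_to_pitch(chrom[, c("r", "g", "b")], m)$pitch
  expect_identical(back, chrom$pitch)
})
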