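test_that("make_painting enforces tiling and reports analytic cell truth", {
  rects <- tibble::tibble(
    x0 = c(0L, 500L), y0 = 0L, x1 = c(500L, 1000L), y1 = 1000L,
    r = c(255L, 0L), g = 0L, b = c(0L, 255L)
  )
  p <- make_painting(rects, 1000L, 1000L)
  expect_identical(dim(p$image), c(1000L, 1000L, 3L))
  expect_identical(nrow(p$truth), 100L)
  expect_true(all(p$truth$prominence == 1))
  expect_identical(p$truth$r[p$truth$col <= 4], rep(255L, 50))
  expect_identical(p$truth$b[p$truth$col >= 5], rep(255L, 50))
  # grid_scan recovers every cell colour exactly
  gs <- grid_scan(p$image)
  expect_identical(gs$r, p$truth$r)
  expect_identical(gs$b, p$truth$b)
  expect_equal(gs$prominence, p$truth$prominence)
  # gaps or overlaps are rejected
  expect_error(make_painting(rects[1, ], 1000L, 1000L), class = "gazetone_input_error")
  overl <- dplyr::mutate(rects, x1 = c(600L, 1000L))
  expect_error(make_painting(overl, 1000L, 1000L), class = "gazetone_input_error")
})

test_that("a random mosaic painting is recovered cell-for-cell by grid_scan", {
  set.seed(19)
  palette <- tibble::tibble(
    r = c(255L, 0L, 0L, 255L, 255L), g = c(0L, 128L, 0L, 215L, 255L),
    b = c(0L, 0L, 255L, 0L, 255L)
  )
  pick <- sample(5, 100, replace = TRUE)
  rects <- tidyr::expand_grid(i = 0:9, j = 0:9) |>
    dplyr::mutate(
      x0 = .data$j * 50L, x1 = .data$x0 + 50L,
      y0 = .data$i * 50L, y1 = .data$y0 + 50L
    ) |>
    dplyr::bind_cols(palette[pick, ])
  p <- make_painting(rects, 500L, 500L)
  gs <- grid_scan(p$image)
  expect_identical(gs$r, p$truth$r)
  expect_identical(gs$g, p$truth$g)
  expect_identical(gs$b, p$truth$b)
})

test_that("make_gaze plants recoverable fixations and is seed-deterministic", {
  sc <- gaze_scenario(
    tibble::tibble(x = c(300, 900), y = c(400, 600), dwell_ms = c(2500, 3000)),
    seed = 12
  )
  gz <- make_gaze(sc)
  expect_identical(make_gaze(sc)$samples, gz$samples) # pure function of the seed
  fx <- detect_fixations(gz$samples)
  expect_identical(nrow(fx), 2L)
  expect_equal(fx$cx, gz$truth$x, tolerance = 1e-9)
  expect_equal(fx$duration, gz$truth$duration, tolerance = 1e-9)
  # scenario invariants
  expect_error(
    gaze_scenario(tibble::tibble(x = 1, y = 1, dwell_ms = 70000)),
    class = "gazetone_input_error"
  )
})

test_that("heavy missingness makes the recording fail QC", {
  sc <- gaze_scenario(
    tibble::tibble(x = 500, y = 500, dwell_ms = 20000),
    missing_rate = 0.3, seed = 3
  )
  gz <- make_gaze(sc)
  fx <- detect_fixations(gz$samples)
  qc <- qc_recording(gz$samples, fx, c(0, 0, 1920, 1080))
  expect_false(qc$reliable)
  expect_gt(qc$missing_fraction, 0.25)
})

test_that("the toy corpus stays on the C-major scale and round-trips losslessly", {
  paths <- make_corpus(5, 32, seed = 2)
  events <- attr(paths, "events")
  scale_pc <- c(0, 2, 4, 5, 7, 9, 11)
  for (ev in events) {
    expect_true(all(ev$pitch %% 12 %in% scale_pc))
    expect_true(all(ev$duration %in% 1:4))
  }
  enc <- encode_corpus(paths)
  expect_identical(unname(enc), events)
  paths2 <- make_corpus(5, 32, seed = 2, dir = tempfile())
  expect_identical(attr(paths2, "events"), events)
})

test_that("group draws are truncated at zero and match their targets in the large-n limit", {
  draws <- make_groups(
    tibble::tibble(group = "g", n = 100000L, mean = 50, sd = 10),
    seed = 6
  )
  expect_true(all(draws$value > 0))
  expect_equal(mean(draws$value), 50, tolerance = 0.01)
  expect_equal(sd(draws$value), 10, tolerance = 0.01)
  d2 <- make_groups(tibble::tibble(group = "g", n = 50L, mean = 5, sd = 2), seed = 9)
  expect_identical(
    d2, make_groups(tibble::tibble(group = "g", n = 50L, mean = 5, sd = 2), seed = 9)
  )
})

test_that("the study bundle is complete and internally consistent", {
  dir <- withr::local_tempdir()
  paths <- simulate_study_bundle(dir, seed = 4)
  expect_true(all(file.exists(unlist(paths[c("painting", "gaze", "aois", "truth")]))))
  samples <- read_gaze_csv(paths$gaze)
  expect_true(nrow(samples) > 1000)
  aois <- read_aoi_json(paths$aois)
  expect_identical(nrow(aois), 4L)
  expect_gte(length(list.files(paths$corpus, pattern = "\\.mid$")), 20L)
})
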