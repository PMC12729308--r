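dt <- 1000 / 133

test_that("a stationary burst then a jump produces two fixations with exact geometry", {
  samples <- tibble::tibble(
    t_ms = (0:499) * dt,
    x = c(rep(400, 300), rep(900, 200)),
    y = 400,
    valid = TRUE
  )
  fx <- detect_fixations(samples)
  expect_identical(nrow(fx), 2L)
  expect_equal(fx$cx, c(400, 900))
  expect_equal(fx$cy, c(400, 400))
  expect_equal(fx$duration[1], 299 * dt) # ~2248 ms
  expect_equal(fx$n_samples, c(300L, 200L))
  expect_true(all(fx$bbox_w <= 100 & fx$bbox_h <= 100))
})

test_that("a monotone drift closes the window at the last sample inside the box", {
  samples <- tibble::tibble(
    t_ms = (0:199) * dt,
    x = 100 + (0:199), # exceeds 100 px range at sample index 101 (x = 201)
    y = 500,
    valid = TRUE
  )
  fx <- detect_fixations(samples)
  expect_identical(fx$n_samples[1], 101L) # x in [100, 200] inclusive
  expect_equal(fx$bbox_w[1], 100)
  expect_equal(oracle_fixations(samples), fx)
})

test_that("invalid samples bridge singly and break on longer gaps", {
  base <- tibble::tibble(t_ms = (0:299) * dt, x = 500, y = 500, valid = TRUE)
  lone <- base
  lone$valid[150] <- FALSE
  expect_identical(nrow(detect_fixations(lone)), 1L) # single dropout bridged
  expect_identical(detect_fixations(lone)$n_samples, 299L)
  gap <- base
  gap$valid[150:151] <- FALSE
  fx <- detect_fixations(gap)
  expect_identical(nrow(fx), 2L) # a two-sample gap splits the fixation
  all_bad <- dplyr::mutate(base, valid = FALSE)
  expect_identical(nrow(detect_fixations(all_bad)), 0L)
  expect_identical(nrow(detect_fixations(base[0, ])), 0L)
})

test_that("detection matches the brute-force dispersion oracle on random streams", {
  set.seed(1001)
  for (rep in 1:40) {
    n <- sample(50:800, 1)
    samples <- random_gaze_stream(n)
    expect_equal(detect_fixations(samples), oracle_fixations(samples))
  }
})

test_that("QC applies the strict 25% missing / 20% outside rules", {
  mk <- function(n_invalid, n_out, n = 100) {
    samples <- tibble::tibble(
      t_ms = (0:(n - 1)) * dt, x = 500, y = 500,
      valid = rep(c(FALSE, TRUE), c(n_invalid, n - n_invalid))
    )
    fx_in <- tibble::tibble(
      cx = 500, cy = 500, onset = 0, duration = 300,
      n_samples = 10L, bbox_w = 0, bbox_h = 0
    )
    fx <- dplyr::bind_rows(
      fx_in[rep(1, 10 - n_out), ],
      dplyr::mutate(fx_in, cx = 3000)[rep(1, n_out), ]
    )
    qc_recording(samples, fx, c(0, 0, 1920, 1080))
  }
  expect_false(mk(26, 0)$reliable) # > 25% missing
  expect_false(mk(10, 3)$reliable) # 30% of fixations outside
  expect_true(mk(25, 2)$reliable) # exactly at both thresholds: still reliable
  expect_equal(mk(25, 2)$missing_fraction, 0.25)
  expect_equal(mk(25, 2)$outside_fraction, 0.2)
  no_samples <- tibble::tibble(t_ms = double(), x = double(), y = double(), valid = logical())
  expect_error(
    qc_recording(no_samples, detect_fixations(no_samples), c(0, 0, 1920, 1080)),
    class = "gazetone_input_error"
  )
})

test_that("adding invalid samples never flips a recording back to reliable", {
  set.seed(77)
  samples <- random_gaze_stream(400, invalid_prob = 0.2)
  fx <- detect_fixations(samples)
  prev_reliable <- qc_recording(samples, fx, c(0, 0, 1920, 1080))$reliable
  bad_order <- sample(which(samples$valid))
  for (k in bad_order[1:60]) {
    samples$valid[k] <- FALSE
    rel <- qc_recording(samples, fx, c(0, 0, 1920, 1080))$reliable
    expect_false(!prev_reliable && rel)
    prev_reliable <- rel
  }
})

test_that("element extraction applies the strict 2000 ms dwell rule", {
  fx <- function(dur, cx = 450) {
    tibble::tibble(
      cx = cx, cy = 450, onset = 0, duration = dur,
      n_samples = 10L, bbox_w = 10, bbox_h = 10
    )
  }
  expect_identical(nrow(extract_elements(fx(2500))), 1L)
  expect_identical(nrow(extract_elements(fx(2000))), 0L) # exactly 2000 ms: excluded
  # dwell accumulates across fixations snapped to the same 100 px region
  two <- dplyr::bind_rows(
    dplyr::mutate(fx(1200), onset = 0),
    dplyr::mutate(fx(1100, cx = 480), onset = 5000)
  )
  el <- extract_elements(two)
  expect_identical(nrow(el), 1L)
  expect_equal(el$dwell, 2300)
  expect_equal(el$region_x, 400)
})

test_that("planted hotspots are extracted in viewing order", {
  hs <- tibble::tibble(
    x = c(300, 1200, 700, 1600), y = c(300, 300, 800, 800), dwell_ms = 3000
  )
  gz <- make_gaze(gaze_scenario(hs, seed = 5))
  fx <- detect_fixations(gz$samples)
  el <- extract_elements(fx)
  expect_identical(nrow(el), 4L)
  expect_equal(el$region_x, floor(hs$x / 100) * 100)
  expect_identical(el$rank, 1:4)
})

test_that("AOI metrics conserve the valid-sample total over a partition", {
  set.seed(31)
  samples <- random_gaze_stream(600) |>
    dplyr::mutate(x = pmin(pmax(x, 0), 1900), y = pmin(pmax(y, 0), 1000))
  fx <- detect_fixations(samples)
  aois <- tibble::tibble(
    label = c("left", "right"),
    x0 = c(-10, 960), y0 = c(-10, -10), x1 = c(960, 2000), y1 = c(1200, 1200)
  )
  met <- aoi_metrics(samples, fx, aois)
  expect_identical(sum(met$gaze_frequency), sum(samples$valid))
  expect_identical(sum(met$fixation_count), nrow(fx))
  # all samples inside one AOI
  inside <- tibble::tibble(t_ms = (0:99) * dt, x = 100, y = 100, valid = TRUE)
  met2 <- aoi_metrics(inside, detect_fixations(inside), aois)
  expect_identical(met2$gaze_frequency, c(100L, 0L))
  expect_identical(nrow(aoi_metrics(samples, fx, aois[0, ])), 0L)
  expect_error(
    aoi_metrics(samples, fx, dplyr::mutate(aois, x0 = c(-10, 900))),
    class = "gazetone_input_error"
  )
})

test_that("the heatmap peaks at fixation centroids and respects symmetry", {
  fx1 <- tibble::tibble(
    cx = 105, cy = 105, onset = 0, duration = 1000,
    n_samples = 10L, bbox_w = 0, bbox_h = 0
  )
  hm <- gaze_heatmap(fx1, width = 1000, height = 1000)
  peak <- hm[which.max(hm$intensity), ]
  expect_equal(c(peak$x, peak$y), c(105, 105))
  expect_equal(max(hm$intensity), 1)
  # empty input -> all zeros
  hm0 <- gaze_heatmap(fx1[0, ], width = 200, height = 200)
  expect_true(all(hm0$intensity == 0))
  # two equal fixations far apart -> two equal maxima
  fx2 <- dplyr::bind_rows(fx1, dplyr::mutate(fx1, cx = 905, cy = 905))
  hm2 <- gaze_heatmap(fx2, width = 1000, height = 1000)
  tops <- sort(hm2$intensity, decreasing = TRUE)[1:2]
  expect_equal(tops[1], tops[2], tolerance = 1e-12)
})

test_that("gaze CSV and AOI JSON readers round-trip through analyze_recording", {
  gz <- make_gaze(gaze_scenario(
    tibble::tibble(x = 500, y = 500, dwell_ms = 2500),
    seed = 9
  ))
  gaze_path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(gz$samples, gaze_path)
  aoi_path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    tibble::tibble(label = "a", x0 = 0, y0 = 0, x1 = 1000, y1 = 1000),
    aoi_path, auto_unbox = TRUE
  )
  res <- analyze_recording(gaze_path, c(0, 0, 1920, 1080), aois = aoi_path)
  expect_identical(nrow(res$fixations), 1L)
  expect_true(res$qc$reliable)
  expect_identical(res$aoi$gaze_frequency, sum(gz$samples$valid))
  expect_s3_class(res$heatmap, "gaze_heatmap")
})
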