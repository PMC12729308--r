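# Seeded generators for every input the pipeline consumes: block-colour
# paintings with analytic cell ground truth, gaze streams with planted
# fixation hotspots, a toy tonal MIDI corpus, and per-group fixation-duration
# samples. Each generator is a pure function of its seed.

#' Generate a block-colour painting with analytic ground truth
#'
#' Rasterizes a set of axis-aligned coloured rectangles that must tile the
#' canvas exactly (every pixel covered once). Because region colours are
#' known, the modal colour of every grid cell can be computed analytically,
#' giving a ground-truth table against which [grid_scan()] can be checked.
#'
#' @param rects Tibble with half-open pixel rectangles `x0`, `y0`, `x1`, `y1`
#'   and colours `r`, `g`, `b` (0-255).
#' @param width,height Canvas size in pixels.
#' @param rows,cols Grid shape for the ground-truth table.
#' @return A list of class `synthetic_painting`: `image` (height x width x 3
#'   array in `[0, 1]`), `truth` (tibble `row`, `col`, `r`, `g`, `b`,
#'   `prominence` for the modal colour of each cell), `width`, `height`.
#' @export
make_painting <- function(rects, width = 1000L, height = 1000L,
                          rows = 10L, cols = 10L) {
  check_columns(rects, c("x0", "y0", "x1", "y1", "r", "g", "b"), "rects")
  check_rgb(rects$r, rects$g, rects$b)
  idx <- matrix(0L, height, width)
  for (k in seq_len(nrow(rects))) {
    xs <- (rects$x0[k] + 1L):rects$x1[k]
    ys <- (rects$y0[k] + 1L):rects$y1[k]
    if (min(xs) < 1 || max(xs) > width || min(ys) < 1 || max(ys) > height) {
      stop_input("Rectangle extends outside the canvas.")
    }
    if (any(idx[ys, xs] != 0L)) stop_input("Rectangles overlap; they must tile the canvas.")
    idx[ys, xs] <- k
  }
  if (any(idx == 0L)) stop_input("Rectangles do not cover the canvas; they must tile it.")

  image <- array(0, dim = c(height, width, 3))
  image[, , 1] <- rects$r[idx] / 255
  image[, , 2] <- rects$g[idx] / 255
  image[, , 3] <- rects$b[idx] / 255

  cell_r <- cell_index(rep(0:(height - 1L), times = width), height, rows)
  cell_c <- cell_index(rep(0:(width - 1L), each = height), width, cols)
  truth <- tibble(
    cell = cell_r * cols + cell_c,
    rect = as.vector(idx)
  ) |>
    dplyr::count(.data$cell, .data$rect) |>
    group_by(.data$cell) |>
    mutate(cell_total = sum(.data$n)) |>
    arrange(dplyr::desc(.data$n), .data$rect, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    ungroup() |>
    arrange(.data$cell)
  truth <- tibble(
    row = truth$cell %/% cols,
    col = truth$cell %% cols,
    r = as.integer(rects$r[truth$rect]),
    g = as.integer(rects$g[truth$rect]),
    b = as.integer(rects$b[truth$rect]),
    prominence = truth$n / truth$cell_total
  )
  structure(
    list(image = image, truth = truth, width = width, height = height),
    class = "synthetic_painting"
  )
}

#' Gaze scenario description
#'
#' @param hotspots Tibble `x`, `y`, `dwell_ms`: screen position and dwell of
#'   each planted fixation, in viewing order.
#' @param jitter_sigma_px Isotropic Gaussian jitter added to each sample.
#' @param missing_rate Probability that any sample is tracker-invalid.
#' @param saccade_ms Recording gap between consecutive hotspots.
#' @param duration_s Nominal viewing duration (total dwell + saccades must
#'   fit inside it).
#' @param rate_hz Sampling rate (133 Hz emulates the study tracker).
#' @param seed RNG seed.
#' @return A list of class `gaze_scenario`.
#' @export
gaze_scenario <- function(hotspots, jitter_sigma_px = 0, missing_rate = 0,
                          saccade_ms = 80, duration_s = 60, rate_hz = 133,
                          seed = 1L) {
  check_columns(hotspots, c("x", "y", "dwell_ms"), "hotspots")
  check_number(jitter_sigma_px, "jitter_sigma_px", 0, Inf)
  check_number(missing_rate, "missing_rate", 0, 1 - 1e-12)
  check_number(saccade_ms, "saccade_ms", 0, Inf)
  check_number(rate_hz, "rate_hz", 1, Inf)
  total <- sum(hotspots$dwell_ms) + saccade_ms * max(nrow(hotspots) - 1, 0)
  if (total > duration_s * 1000) {
    stop_input("Hotspot dwells plus saccade gaps exceed the viewing duration.")
  }
  structure(
    list(
      hotspots = as_tibble(hotspots), jitter_sigma_px = jitter_sigma_px,
      missing_rate = missing_rate, saccade_ms = saccade_ms,
      duration_s = duration_s, rate_hz = rate_hz, seed = as.integer(seed)
    ),
    class = "gaze_scenario"
  )
}

#' Generate a gaze stream with known fixation ground truth
#'
#' Emits, for each hotspot in order, `dwell_ms` worth of samples at the
#' hotspot position plus Gaussian jitter, separated by `saccade_ms` recording
#' gaps; each sample is flagged invalid with probability `missing_rate`.
#' The returned ground truth lists the planted fixations (centroid, onset,
#' duration) as a dispersion-based detector should recover them on a clean
#' stream.
#'
#' @param scenario A [gaze_scenario()].
#' @return A list: `samples` (tibble `t_ms`, `x`, `y`, `valid`), `truth`
#'   (tibble `x`, `y`, `onset`, `duration`, `n_samples`), and the scenario.
#' @export
make_gaze <- function(scenario) {
  stopifnot(inherits(scenario, "gaze_scenario"))
  set.seed(scenario$seed)
  dt <- 1000 / scenario$rate_hz
  samples <- list()
  truth <- list()
  t0 <- 0
  for (k in seq_len(nrow(scenario$hotspots))) {
    hs <- scenario$hotspots[k, ]
    n_k <- round(hs$dwell_ms / dt) + 1L
    t_k <- t0 + (seq_len(n_k) - 1L) * dt
    x_k <- hs$x + rnorm(n_k, 0, scenario$jitter_sigma_px)
    y_k <- hs$y + rnorm(n_k, 0, scenario$jitter_sigma_px)
    valid_k <- runif(n_k) >= scenario$missing_rate
    samples[[k]] <- tibble(
      t_ms = t_k, x = round(x_k), y = round(y_k), valid = valid_k
    )
    truth[[k]] <- tibble(
      x = hs$x, y = hs$y, onset = t_k[1],
      duration = (n_k - 1L) * dt, n_samples = n_k
    )
    t0 <- t_k[n_k] + scenario$saccade_ms
  }
  list(
    samples = if (length(samples)) bind_rows(samples) else
      tibble(t_ms = double(), x = double(), y = double(), valid = logical()),
    truth = if (length(truth)) bind_rows(truth) else
      tibble(x = double(), y = double(), onset = double(),
             duration = double(), n_samples = integer()),
    scenario = scenario
  )
}

#' Generate a toy tonal MIDI corpus
#'
#' Writes `n_melodies` seeded random walks on the C-major scale (pitches
#' between C3 and C6, durations drawn from the short end of the quantization
#' grid, gapless offsets) as Standard MIDI Files.
#'
#' @param n_melodies Number of melodies.
#' @param length Events per melody.
#' @param seed RNG seed.
#' @param dir Output directory (created if needed).
#' @param settings A [midi_settings()].
#' @return Character vector of file paths, with the generated event tibbles
#'   attached as attribute `"events"`.
#' @export
make_corpus <- function(n_melodies = 50L, length = 64L, seed = 1L,
                        dir = tempfile("corpus"), settings = midi_settings()) {
  check_number(n_melodies, "n_melodies", 1, Inf, integerish = TRUE)
  check_number(length, "length", 2, Inf, integerish = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  scale_pc <- c(0, 2, 4, 5, 7, 9, 11) # C major
  scale <- as.integer(outer(scale_pc, 12 * (4:7), "+")) # C3..B6
  scale <- sort(scale[scale >= 48 & scale <= 84])
  paths <- character(n_melodies)
  events <- vector("list", n_melodies)
  for (m in seq_len(n_melodies)) {
    deg <- match(60L, scale)
    pitches <- integer(length)
    for (k in seq_len(length)) {
      deg <- clamp(deg + sample(-2:2, 1), 1, base::length(scale))
      pitches[k] <- scale[deg]
    }
    dur <- sample(c(1L, 2L, 3L, 4L), length, replace = TRUE, prob = c(2, 3, 1, 2))
    vel <- as.integer(clamp(round(rnorm(length, 80, 10)), 30, 110))
    ev <- tibble(
      pitch = pitches, duration = dur, velocity = vel,
      offset = c(0L, dur[-length])
    )
    paths[m] <- file.path(dir, sprintf("melody_%03d.mid", m))
    write_midi(ev, paths[m], settings)
    events[[m]] <- ev
  }
  structure(paths, events = events)
}

#' Simulate per-group fixation-duration samples
#'
#' Draws seeded normal samples truncated at zero (durations cannot be
#' negative) for each group row, for parameter-recovery checks of the
#' summary-statistic comparisons.
#'
#' @param groups Tibble with columns `group`, `n`, `mean`, `sd`.
#' @param seed RNG seed.
#' @return Long tibble `group`, `value`.
#' @export
make_groups <- function(groups, seed = 1L) {
  check_columns(groups, c("group", "n", "mean", "sd"), "groups")
  if (any(groups$n < 2) || any(groups$sd < 0)) {
    stop_input("Each group needs n >= 2 and sd >= 0.")
  }
  set.seed(seed)
  purrr::pmap_dfr(groups, function(group, n, mean, sd, ...) {
    draws <- rnorm(n, mean, sd)
    while (any(draws <= 0)) { # truncate at zero by redrawing
      bad <- draws <= 0
      draws[bad] <- rnorm(sum(bad), mean, sd)
    }
    tibble(group = group, value = draws)
  })
}

#' Write a complete synthetic study bundle
#'
#' Emits everything one pipeline run needs into a directory: a block-colour
#' painting (PNG), a clean gaze recording (CSV), AOI definitions (JSON), a
#' toy MIDI corpus, and a ground-truth JSON.
#'
#' @param dir Output directory.
#' @param seed RNG seed.
#' @param n_hotspots Number of planted gaze hotspots.
#' @return Invisibly, a list of the written paths.
#' @export
simulate_study_bundle <- function(dir, seed = 1L, n_hotspots = 4L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  palette <- tibble(
    r = c(255L, 0L, 0L, 255L), g = c(0L, 128L, 0L, 215L),
    b = c(0L, 0L, 255L, 0L)
  )
  rects <- tidyr::expand_grid(i = 0:1, j = 0:1) |>
    mutate(
      x0 = .data$j * 500L, x1 = .data$x0 + 500L,
      y0 = .data$i * 500L, y1 = .data$y0 + 500L
    ) |>
    bind_cols(palette[sample.int(4), ])
  painting <- make_painting(rects, 1000L, 1000L)
  png_path <- file.path(dir, "painting.png")
  png::writePNG(painting$image, png_path)

  centers <- tibble(
    x = c(250, 750, 250, 750), y = c(250, 250, 750, 750)
  )[seq_len(n_hotspots), ]
  gz <- make_gaze(gaze_scenario(
    mutate(centers, dwell_ms = 3000),
    jitter_sigma_px = 5, missing_rate = 0.02, seed = seed
  ))
  gaze_path <- file.path(dir, "gaze.csv")
  readr::write_csv(gz$samples, gaze_path)

  aois <- tibble(
    label = c("top_left", "top_right", "bottom_left", "bottom_right"),
    x0 = c(0, 500, 0, 500), y0 = c(0, 0, 500, 500),
    x1 = c(500, 1000, 500, 1000), y1 = c(500, 500, 1000, 1000)
  )
  aoi_path <- file.path(dir, "aois.json")
  jsonlite::write_json(aois, aoi_path, auto_unbox = TRUE, digits = NA)

  corpus_dir <- file.path(dir, "corpus")
  corpus <- make_corpus(20L, 48L, seed = seed, dir = corpus_dir)

  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(cells = painting$truth, fixations = gz$truth),
    truth_path, auto_unbox = TRUE, digits = NA
  )
  invisible(list(
    painting = png_path, gaze = gaze_path, aois = aoi_path,
    corpus = corpus_dir, truth = truth_path
  ))
}
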