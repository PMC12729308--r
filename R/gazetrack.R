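# Dispersion-based (I-DT) fixation detection and downstream gaze analytics.
# Coordinates are 0-based screen pixels, origin top-left; rectangles are
# half-open. The nominal recording is a 133 Hz stream on a 1920 x 1080 display.

check_samples <- function(samples) {
  check_columns(samples, c("t_ms", "x", "y", "valid"), "samples")
  if (nrow(samples) && is.unsorted(samples$t_ms)) {
    stop_input("`samples$t_ms` must be non-decreasing.")
  }
  invisible(samples)
}

#' Read a gaze-sample CSV
#'
#' Expects the header `t_ms,x,y,valid` (timestamp in ms, screen pixels,
#' tracker validity flag 0/1 or logical).
#'
#' @param path CSV file path.
#' @return A tibble with columns `t_ms`, `x`, `y`, `valid` (logical).
#' @export
read_gaze_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_samples(df)
  mutate(df, valid = as.logical(.data$valid))
}

#' Detect fixations with a dispersion (I-DT) algorithm
#'
#' Grows a window of consecutive valid samples while its bounding box stays
#' within `dispersion_px` on both axes; the window closes when the next sample
#' would exceed the box or when two or more consecutive invalid samples occur
#' (a single invalid sample is bridged, as trackers routinely drop isolated
#' frames). A closed window becomes a fixation iff it spans at least two
#' samples and `min_fix_ms` of time.
#'
#' @param samples Tibble with `t_ms`, `x`, `y`, `valid`.
#' @param dispersion_px Maximum bounding-box side in pixels.
#' @param min_fix_ms Minimum fixation duration in ms.
#' @return A tibble of fixations ordered by onset: `cx`, `cy` (centroid),
#'   `onset`, `duration` (ms), `n_samples`, `bbox_w`, `bbox_h`.
#' @export
detect_fixations <- function(samples, dispersion_px = 100, min_fix_ms = 100) {
  check_samples(samples)
  check_number(dispersion_px, "dispersion_px", 1, Inf)
  check_number(min_fix_ms, "min_fix_ms", 0, Inf)
  n <- nrow(samples)
  empty <- tibble(
    cx = double(), cy = double(), onset = double(), duration = double(),
    n_samples = integer(), bbox_w = double(), bbox_h = double()
  )
  if (n == 0L) {
    return(empty)
  }
  t <- samples$t_ms
  x <- samples$x
  y <- samples$y
  valid <- as.logical(samples$valid)

  out <- vector("list", n)
  n_out <- 0L
  win <- integer(0) # indices of window members
  minx <- Inf; maxx <- -Inf; miny <- Inf; maxy <- -Inf
  inv_run <- 0L

  close_window <- function(win) {
    if (length(win) >= 2L) {
      dur <- t[win[length(win)]] - t[win[1L]]
      if (dur >= min_fix_ms) {
        return(tibble(
          cx = mean(x[win]), cy = mean(y[win]),
          onset = t[win[1L]], duration = dur,
          n_samples = length(win),
          bbox_w = max(x[win]) - min(x[win]),
          bbox_h = max(y[win]) - min(y[win])
        ))
      }
    }
    NULL
  }

  for (i in seq_len(n)) {
    if (!valid[i]) {
      inv_run <- inv_run + 1L
      if (inv_run > 1L && length(win)) { # gap longer than one sample
        fix <- close_window(win)
        if (!is.null(fix)) { n_out <- n_out + 1L; out[[n_out]] <- fix }
        win <- integer(0)
        minx <- Inf; maxx <- -Inf; miny <- Inf; maxy <- -Inf
      }
      next
    }
    inv_run <- 0L
    nminx <- min(minx, x[i]); nmaxx <- max(maxx, x[i])
    nminy <- min(miny, y[i]); nmaxy <- max(maxy, y[i])
    if (nmaxx - nminx > dispersion_px || nmaxy - nminy > dispersion_px) {
      fix <- close_window(win)
      if (!is.null(fix)) { n_out <- n_out + 1L; out[[n_out]] <- fix }
      win <- i
      minx <- x[i]; maxx <- x[i]; miny <- y[i]; maxy <- y[i]
    } else {
      win <- c(win, i)
      minx <- nminx; maxx <- nmaxx; miny <- nminy; maxy <- nmaxy
    }
  }
  fix <- close_window(win)
  if (!is.null(fix)) { n_out <- n_out + 1L; out[[n_out]] <- fix }
  if (n_out == 0L) {
    return(empty)
  }
  bind_rows(out[seq_len(n_out)])
}

#' Recording-level quality control
#'
#' A recording is unreliable if more than 25% of its samples are missing
#' (tracker-invalid) or more than 20% of its fixations fall outside the
#' painting; both comparisons are strict, so a recording at exactly the
#' threshold is still reliable.
#'
#' @param samples Tibble with `t_ms`, `x`, `y`, `valid`.
#' @param fixations Fixations derived from `samples` ([detect_fixations()]).
#' @param painting_bounds Numeric `c(x0, y0, x1, y1)` half-open rectangle.
#' @param max_missing,max_outside Reliability thresholds (fractions).
#' @return One-row tibble: `missing_fraction`, `outside_fraction`, `reliable`.
#' @export
qc_recording <- function(samples, fixations, painting_bounds,
                         max_missing = 0.25, max_outside = 0.20) {
  check_samples(samples)
  if (nrow(samples) == 0L) stop_input("`samples` must contain at least one sample.")
  if (!is.numeric(painting_bounds) || length(painting_bounds) != 4L) {
    stop_input("`painting_bounds` must be numeric c(x0, y0, x1, y1).")
  }
  missing_fraction <- mean(!as.logical(samples$valid))
  if (nrow(fixations) == 0L) {
    outside_fraction <- 0
  } else {
    inside <- fixations$cx >= painting_bounds[1] & fixations$cx < painting_bounds[3] &
      fixations$cy >= painting_bounds[2] & fixations$cy < painting_bounds[4]
    outside_fraction <- mean(!inside)
  }
  tibble(
    missing_fraction = missing_fraction,
    outside_fraction = outside_fraction,
    reliable = !(missing_fraction > max_missing || outside_fraction > max_outside)
  )
}

#' Extract gaze elements (hotspot regions)
#'
#' Snaps fixation centroids to a `region_px` lattice and accumulates dwell per
#' lattice cell; cells whose cumulative dwell strictly exceeds
#' `dwell_threshold_ms` become gaze elements, ranked by first entry time.
#'
#' @param fixations Fixation tibble ordered by onset.
#' @param dwell_threshold_ms Strict dwell threshold in ms (default 2000).
#' @param region_px Lattice pitch in pixels (default 100).
#' @return A tibble ordered by rank: `region_x`, `region_y` (anchor top-left
#'   corner of the 100 x 100 region), `dwell`, `first_entry`, `n_fixations`,
#'   `rank`.
#' @export
extract_elements <- function(fixations, dwell_threshold_ms = 2000, region_px = 100) {
  check_columns(fixations, c("cx", "cy", "onset", "duration"), "fixations")
  check_number(dwell_threshold_ms, "dwell_threshold_ms", 0, Inf)
  check_number(region_px, "region_px", 1, Inf)
  if (nrow(fixations) == 0L) {
    return(tibble(
      region_x = double(), region_y = double(), dwell = double(),
      first_entry = double(), n_fixations = integer(), rank = integer()
    ))
  }
  fixations |>
    mutate(
      region_x = floor(.data$cx / region_px) * region_px,
      region_y = floor(.data$cy / region_px) * region_px
    ) |>
    group_by(.data$region_x, .data$region_y) |>
    summarise(
      dwell = sum(.data$duration),
      first_entry = min(.data$onset),
      n_fixations = dplyr::n(),
      .groups = "drop"
    ) |>
    filter(.data$dwell > dwell_threshold_ms) |>
    arrange(.data$first_entry) |>
    mutate(rank = row_number())
}

check_aois <- function(aois) {
  check_columns(aois, c("label", "x0", "y0", "x1", "y1"), "aois")
  if (any(aois$x0 >= aois$x1) || any(aois$y0 >= aois$y1)) {
    stop_input("Each AOI must satisfy x0 < x1 and y0 < y1.")
  }
  n <- nrow(aois)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (aois$x0[i] < aois$x1[j] && aois$x0[j] < aois$x1[i] &&
            aois$y0[i] < aois$y1[j] && aois$y0[j] < aois$y1[i]) {
          stop_input(sprintf(
            "AOIs '%s' and '%s' overlap.", aois$label[i], aois$label[j]
          ))
        }
      }
    }
  }
  invisible(aois)
}

#' Read AOI definitions from JSON
#'
#' Expects a JSON array of objects `{label, x0, y0, x1, y1}` (half-open
#' pixel rectangles).
#'
#' @param path JSON file path.
#' @return A tibble with one row per AOI.
#' @export
read_aoi_json <- function(path) {
  df <- as_tibble(jsonlite::fromJSON(path))
  check_aois(df)
  df
}

#' Per-AOI gaze metrics
#'
#' For each (non-overlapping) area of interest: `gaze_frequency` is the number
#' of valid gaze samples inside the rectangle, `dwell_ms` the summed duration
#' of fixations whose centroid lies inside, and `fixation_count` the number of
#' such fixations. Over disjoint AOIs the sample counts plus the outside
#' remainder always sum to the valid-sample total.
#'
#' @param samples Tibble with `t_ms`, `x`, `y`, `valid`.
#' @param fixations Fixations from [detect_fixations()].
#' @param aois AOI tibble (`label`, `x0`, `y0`, `x1`, `y1`).
#' @return A tibble with one row per AOI: `label`, `gaze_frequency`,
#'   `dwell_ms`, `fixation_count`.
#' @export
aoi_metrics <- function(samples, fixations, aois) {
  check_samples(samples)
  check_aois(aois)
  if (nrow(aois) == 0L) {
    return(tibble(
      label = character(), gaze_frequency = integer(),
      dwell_ms = double(), fixation_count = integer()
    ))
  }
  vs <- filter(samples, as.logical(.data$valid))
  purrr::pmap_dfr(aois, function(label, x0, y0, x1, y1, ...) {
    in_s <- vs$x >= x0 & vs$x < x1 & vs$y >= y0 & vs$y < y1
    if (nrow(fixations)) {
      in_f <- fixations$cx >= x0 & fixations$cx < x1 &
        fixations$cy >= y0 & fixations$cy < y1
    } else {
      in_f <- logical(0)
    }
    tibble(
      label = label,
      gaze_frequency = sum(in_s),
      dwell_ms = sum(fixations$duration[in_f]),
      fixation_count = sum(in_f)
    )
  })
}

#' Duration-weighted gaze heatmap
#'
#' Deposits an isotropic Gaussian at each fixation centroid, weighted by the
#' fixation's duration, on a `grid_px`-spaced lattice over the display; the
#' grid is normalized to a maximum of 1 when any fixation exists.
#'
#' @param fixations Fixation tibble.
#' @param width,height Display extent in pixels.
#' @param kernel_sigma_px Gaussian kernel standard deviation.
#' @param grid_px Output cell size in pixels.
#' @return A tibble of class `gaze_heatmap` with columns `x`, `y` (cell
#'   centres) and `intensity`.
#' @export
gaze_heatmap <- function(fixations, width = 1920, height = 1080,
                         kernel_sigma_px = 50, grid_px = 10) {
  check_number(width, "width", 1, Inf)
  check_number(height, "height", 1, Inf)
  check_number(kernel_sigma_px, "kernel_sigma_px", 1e-6, Inf)
  check_number(grid_px, "grid_px", 1, Inf)
  gx <- seq(grid_px / 2, width, by = grid_px)
  gy <- seq(grid_px / 2, height, by = grid_px)
  grid <- tidyr::expand_grid(y = gy, x = gx)
  intensity <- rep(0, nrow(grid))
  if (nrow(fixations)) {
    for (k in seq_len(nrow(fixations))) {
      d2 <- (grid$x - fixations$cx[k])^2 + (grid$y - fixations$cy[k])^2
      intensity <- intensity + fixations$duration[k] * exp(-d2 / (2 * kernel_sigma_px^2))
    }
    if (max(intensity) > 0) intensity <- intensity / max(intensity)
  }
  out <- mutate(grid, intensity = intensity)[, c("x", "y", "intensity")]
  structure(out,
    class = c("gaze_heatmap", class(out)),
    width = width, height = height, grid_px = grid_px
  )
}

#' Analyze one gaze recording end to end
#'
#' Convenience wrapper: fixation detection, quality control, optional AOI
#' metrics and heatmap for a single recording.
#'
#' @param samples Gaze sample tibble or CSV path.
#' @param painting_bounds `c(x0, y0, x1, y1)` stimulus rectangle.
#' @param aois Optional AOI tibble or JSON path.
#' @param dispersion_px,min_fix_ms Passed to [detect_fixations()].
#' @return A list with elements `fixations`, `qc`, `elements`, `aoi`
#'   (NULL without AOIs) and `heatmap`.
#' @export
analyze_recording <- function(samples, painting_bounds = c(0, 0, 1920, 1080),
                              aois = NULL, dispersion_px = 100, min_fix_ms = 100) {
  if (is.character(samples)) samples <- read_gaze_csv(samples)
  if (is.character(aois)) aois <- read_aoi_json(aois)
  fx <- detect_fixations(samples, dispersion_px, min_fix_ms)
  list(
    fixations = fx,
    qc = qc_recording(samples, fx, painting_bounds),
    elements = extract_elements(fx),
    aoi = if (!is.null(aois)) aoi_metrics(samples, fx, aois) else NULL,
    heatmap = gaze_heatmap(
      fx,
      width = painting_bounds[3] - painting_bounds[1],
      height = painting_bounds[4] - painting_bounds[2]
    )
  )
}
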