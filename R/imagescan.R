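# 10 x 10 grid decomposition of an image. Each cell is quantized to colour-map
# regions, the modal region wins, and the cell's representative colour is the
# channel-wise median RGB within the winning region.

# Accepts a file path (PNG via the png package; JPEG/BMP via EBImage when
# installed) or an in-memory array, and returns integer 0-255 channels.
load_image_channels <- function(image) {
  if (is.character(image)) {
    if (length(image) != 1L || !file.exists(image)) {
      stop_input("`image` path does not exist.")
    }
    if (grepl("\\.png$", image, ignore.case = TRUE)) {
      image <- png::readPNG(image)
    } else if (requireNamespace("EBImage", quietly = TRUE)) {
      img <- EBImage::readImage(image)
      image <- aperm(EBImage::imageData(img), c(2, 1, 3))
    } else {
      stop_input("Only PNG is supported unless EBImage is installed.")
    }
  }
  if (is.matrix(image)) { # greyscale -> replicate channels
    image <- array(rep(image, 3L), dim = c(dim(image), 3L))
  }
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] < 3L) {
    stop_input("`image` must be a height x width x >=3 numeric array or a raster path.")
  }
  if (dim(image)[1] < 1L || dim(image)[2] < 1L) {
    stop_input("`image` is empty.")
  }
  vals <- image[, , 1:3, drop = FALSE]
  if (max(vals) <= 1) vals <- vals * 255 # png convention [0,1] -> 0-255
  list(
    r = round(vals[, , 1]), g = round(vals[, , 2]), b = round(vals[, , 3]),
    height = dim(image)[1], width = dim(image)[2]
  )
}

# Half-open floor partition: pixel index p (0-based) along an axis of length n
# split into k cells belongs to the cell whose [floor(c*n/k), floor((c+1)*n/k))
# interval contains it.
cell_index <- function(p, n, k) {
  bounds <- floor((0:k) * n / k)
  findInterval(p, bounds, rightmost.closed = FALSE) - 1L
}

#' Decompose an image into a colour grid
#'
#' Splits an image into `rows` x `cols` cells (half-open floor partition, so
#' every pixel belongs to exactly one cell), quantizes each pixel to its
#' colour-map region, and selects the modal region per cell. The cell's
#' dominant colour is the channel-wise median RGB over the pixels of the modal
#' region; its prominence is the modal region's pixel fraction. Modal ties are
#' broken towards the lower mapped pitch, then the lower region code.
#'
#' @param image A raster file path (PNG; JPEG/BMP with EBImage) or a numeric
#'   `height x width x 3` array (values in `[0, 1]` or 0-255).
#' @param rows,cols Grid dimensions (default 10 x 10, i.e. 100 cells).
#' @param map A [color_note_map()].
#' @return A tibble of class `grid_scan` with one row per cell in row-major
#'   (reading) order: `row`, `col` (0-based), `r`, `g`, `b` (dominant colour),
#'   `prominence`, `pixel_count`, `region`, `pitch`. Image dimensions and the
#'   grid shape are carried in attributes `image_width`, `image_height`,
#'   `rows`, `cols`.
#' @examples
#' img <- array(rep(c(1, 0, 0), each = 40 * 40), dim = c(40, 40, 3))
#' grid_scan(img, rows = 2, cols = 2)
#' @export
grid_scan <- function(image, rows = 10L, cols = 10L, map = color_note_map()) {
  check_number(rows, "rows", 1, Inf, integerish = TRUE)
  check_number(cols, "cols", 1, Inf, integerish = TRUE)
  stopifnot(inherits(map, "color_note_map"))
  ch <- load_image_channels(image)
  if (ch$width < cols || ch$height < rows) {
    stop_input("Image must be at least `cols` x `rows` pixels.")
  }

  h_px <- ch$height
  w_px <- ch$width
  r <- as.vector(ch$r) # column-major: pixel (i,j) at index (j-1)*h + i
  g <- as.vector(ch$g)
  b <- as.vector(ch$b)
  px_row <- rep(0:(h_px - 1L), times = w_px)
  px_col <- rep(0:(w_px - 1L), each = h_px)
  cell_r <- cell_index(px_row, h_px, rows)
  cell_c <- cell_index(px_col, w_px, cols)
  cell_id <- cell_r * cols + cell_c

  hsv <- rgb_to_hsv_deg(r, g, b)
  region <- map_region(hsv$h, hsv$s, hsv$v, map)

  px <- tibble(
    cell = cell_id, region = region, r = r, g = g, b = b,
    pitch = region_pitch(region, map)
  )
  cells <- px |>
    group_by(.data$cell, .data$region, .data$pitch) |>
    summarise(
      n = dplyr::n(),
      med_r = median(.data$r), med_g = median(.data$g), med_b = median(.data$b),
      .groups = "drop"
    ) |>
    group_by(.data$cell) |>
    mutate(cell_total = sum(.data$n)) |>
    # modal region; ties -> lower pitch, then lower region code
    arrange(dplyr::desc(.data$n), .data$pitch, .data$region, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    ungroup() |>
    arrange(.data$cell)

  out <- tibble(
    row = cells$cell %/% cols,
    col = cells$cell %% cols,
    r = as.integer(round(cells$med_r)),
    g = as.integer(round(cells$med_g)),
    b = as.integer(round(cells$med_b)),
    prominence = cells$n / cells$cell_total,
    pixel_count = as.integer(cells$cell_total),
    region = cells$region,
    pitch = cells$pitch
  )
  structure(out,
    class = c("grid_scan", class(out)),
    image_width = w_px, image_height = h_px,
    rows = as.integer(rows), cols = as.integer(cols)
  )
}

#' Turn a grid scan into a reading-order note sequence
#'
#' Emits one note per cell in left-to-right, top-to-bottom order: pitch from
#' the cell's dominant colour, duration from its prominence
#' ([duration_from_prominence()]), velocity from its saturation
#' ([velocity_from_saturation()]). Events are strictly sequential (each
#' offset equals the previous event's duration).
#'
#' @param scan A `grid_scan` tibble from [grid_scan()].
#' @param map A [color_note_map()].
#' @return A tibble of note events: `pitch`, `duration` (time units),
#'   `velocity`, `offset` (time units since the previous event's onset).
#' @export
scan_to_notes <- function(scan, map = color_note_map()) {
  check_columns(scan, c("row", "col", "r", "g", "b", "prominence"), "scan")
  cols <- attr(scan, "cols") %||% (max(scan$col) + 1L)
  ord <- order(scan$row * cols + scan$col)
  scan <- scan[ord, ]
  sat <- rgb_to_hsv_deg(scan$r, scan$g, scan$b)$s
  pitch <- color_to_pitch(scan[, c("r", "g", "b")], map)$pitch
  dur <- duration_from_prominence(scan$prominence)
  tibble(
    pitch = pitch,
    duration = dur,
    velocity = velocity_from_saturation(sat),
    offset = c(0L, dur[-length(dur)])
  )
}
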