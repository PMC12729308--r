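# Independent oracles used across the suite. These deliberately re-derive
# results by a different route than the package implementation.

# Brute-force dispersion-window search. The stream is split at "hard breaks"
# (runs of >= 2 consecutive invalid samples); within each segment the valid
# samples are scanned with an exhaustive maximal-window search: starting at
# s, the window extends to the largest e such that the bounding box of
# samples s..e (recomputed from scratch with cummax/cummin) fits within the
# dispersion bound, then closes and the next window starts at e + 1.
oracle_fixations <- function(samples, dispersion_px = 100, min_fix_ms = 100) {
  v <- as.logical(samples$valid)
  n <- nrow(samples)
  inv_run <- rle(!v)
  # segment label per sample: increments after every run of >=2 invalids
  breaks <- rep(inv_run$values & inv_run$lengths >= 2, inv_run$lengths)
  seg <- cumsum(breaks & !c(FALSE, breaks[-n]))
  out <- list()
  for (s_id in unique(seg)) {
    ix <- which(seg == s_id & v)
    while (length(ix) >= 1) {
      x <- samples$x[ix]
      y <- samples$y[ix]
      w <- cummax(x) - cummin(x)
      h <- cummax(y) - cummin(y)
      fits <- which(w <= dispersion_px & h <= dispersion_px)
      e <- max(fits) # position 1 always fits
      win <- ix[seq_len(e)]
      if (length(win) >= 2) {
        dur <- samples$t_ms[win[length(win)]] - samples$t_ms[win[1]]
        if (dur >= min_fix_ms) {
          out[[length(out) + 1]] <- data.frame(
            cx = mean(samples$x[win]), cy = mean(samples$y[win]),
            onset = samples$t_ms[win[1]], duration = dur,
            n_samples = length(win),
            bbox_w = max(samples$x[win]) - min(samples$x[win]),
            bbox_h = max(samples$y[win]) - min(samples$y[win])
          )
        }
      }
      ix <- ix[-seq_len(e)]
    }
  }
  if (length(out)) {
    tibble::as_tibble(do.call(rbind, out))
  } else {
    tibble::tibble(
      cx = double(), cy = double(), onset = double(), duration = double(),
      n_samples = integer(), bbox_w = double(), bbox_h = double()
    )
  }
}

random_gaze_stream <- function(n, jump_prob = 0.02, invalid_prob = 0.08) {
  x <- numeric(n)
  y <- numeric(n)
  x[1] <- runif(1, 0, 1920)
  y[1] <- runif(1, 0, 1080)
  for (i in seq_len(n)[-1]) {
    if (runif(1) < jump_prob) {
      x[i] <- runif(1, 0, 1920)
      y[i] <- runif(1, 0, 1080)
    } else {
      x[i] <- x[i - 1] + rnorm(1, 0, 15)
      y[i] <- y[i - 1] + rnorm(1, 0, 15)
    }
  }
  tibble::tibble(
    t_ms = (seq_len(n) - 1) * (1000 / 133),
    x = round(x), y = round(y),
    valid = runif(n) >= invalid_prob
  )
}

# --- minimal Standard MIDI File byte tools, independent of R/midiio.R ------

smf_vlq <- function(v) {
  out <- v %% 128L
  v <- v %/% 128L
  while (v > 0) {
    out <- c((v %% 128L) + 128L, out)
    v <- v %/% 128L
  }
  as.raw(out)
}

smf_int <- function(v, n) as.raw((v %/% 256^((n - 1):0)) %% 256)

# Build a single-track SMF from absolute-tick note on/off tuples
# (data.frame tick, on, pitch, velocity), no running status.
build_smf_bytes <- function(msgs, tpq = 480L, ntracks_decl = 1L, extra_chunk = FALSE) {
  msgs <- msgs[order(msgs$tick, msgs$on), ]
  track <- raw(0)
  prev <- 0L
  for (i in seq_len(nrow(msgs))) {
    status <- if (msgs$on[i]) 0x90 else 0x80
    track <- c(
      track, smf_vlq(msgs$tick[i] - prev),
      as.raw(c(status, msgs$pitch[i], msgs$velocity[i]))
    )
    prev <- msgs$tick[i]
  }
  track <- c(track, smf_vlq(0L), as.raw(c(0xFF, 0x2F, 0x00)))
  out <- c(
    charToRaw("MThd"), smf_int(6L, 4), smf_int(0L, 2),
    smf_int(ntracks_decl, 2), smf_int(tpq, 2)
  )
  if (extra_chunk) { # unknown chunk type, must be skipped by readers
    junk <- charToRaw("XFIH")
    out <- c(out, junk, smf_int(4L, 4), as.raw(1:4))
  }
  c(out, charToRaw("MTrk"), smf_int(length(track), 4), track)
}

# Independent check that a file is a well-formed SMF containing balanced
# note on/off pairs; returns the note-on count.
smf_note_on_count <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  stopifnot(rawToChar(bytes[1:4]) == "MThd")
  pos <- 9L + sum(as.integer(bytes[5:8]) * 256^(3:0))
  ons <- 0L
  offs <- 0L
  while (pos + 8L <= length(bytes) + 1L) {
    id <- rawToChar(bytes[pos:(pos + 3L)])
    len <- sum(as.integer(bytes[(pos + 4L):(pos + 7L)]) * 256^(3:0))
    body <- bytes[(pos + 8L):(pos + 7L + len)]
    pos <- pos + 8L + len
    if (id != "MTrk") next
    i <- 1L
    status <- NULL
    repeat {
      repeat { # delta time
        b <- as.integer(body[i]); i <- i + 1L
        if (b < 128) break
      }
      b <- as.integer(body[i])
      if (b >= 0x80) { status <- b; i <- i + 1L }
      if (status == 0xFF) {
        type <- as.integer(body[i]); i <- i + 1L
        len2 <- 0L
        repeat {
          b2 <- as.integer(body[i]); i <- i + 1L
          len2 <- len2 * 128L + (b2 %% 128L)
          if (b2 < 128) break
        }
        i <- i + len2
        if (type == 0x2F) break
      } else if (status %/% 16 == 0x9) {
        if (as.integer(body[i + 1L]) > 0) ons <- ons + 1L else offs <- offs + 1L
        i <- i + 2L
      } else if (status %/% 16 == 0x8) {
        offs <- offs + 1L
        i <- i + 2L
      } else {
        i <- i + 2L # other channel messages in our files: C0 handled below
      }
      if (status %/% 16 == 0xC) i <- i - 1L
    }
  }
  stopifnot(ons == offs)
  ons
}

# Raw-sample pooled Cohen's d, computed directly from the data.
raw_cohens_d <- function(xa, xb) {
  na <- length(xa); nb <- length(xb)
  sp <- sqrt(((na - 1) * var(xa) + (nb - 1) * var(xb)) / (na + nb - 2))
  (mean(xb) - mean(xa)) / sp
}

desk_corpus <- function(n = 50, len = 64, seed = 3) {
  paths <- make_corpus(n, len, seed = seed)
  attr(paths, "events")
}
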