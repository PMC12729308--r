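red_scan <- function() {
  img <- array(rep(c(1, 0, 0), each = 1000 * 1000), dim = c(1000, 1000, 3))
  grid_scan(img)
}

test_that("build_seed turns ranked elements into gapless colour-mapped events", {
  elements <- tibble::tibble(
    region_x = c(200, 700, 200, 900), region_y = c(200, 200, 700, 700),
    dwell = c(2500, 5000, 3000, 2200), first_entry = c(0, 3, 6, 9) * 1000,
    n_fixations = 1L, rank = 1:4
  )
  seed <- build_seed(elements, red_scan())
  expect_identical(nrow(seed), 4L)
  expect_true(all(seed$pitch == 60L)) # uniform red painting
  expect_identical(seed$duration, c(5L, 10L, 6L, 4L)) # 1 unit per 500 ms
  expect_identical(seed$offset, c(0L, seed$duration[-4]))
  expect_identical(seed$rank, 1:4)
  # empty element list -> empty seed
  expect_identical(nrow(build_seed(elements[0, ], red_scan())), 0L)
  # element centre outside the image is an error
  expect_error(
    build_seed(dplyr::mutate(elements, region_x = 1500), red_scan()),
    class = "gazetone_input_error"
  )
})

test_that("dwell quantization clamps to the 1-16 unit grid", {
  el <- tibble::tibble(
    region_x = 100, region_y = 100, dwell = c(100, 20000),
    first_entry = c(0, 1000), n_fixations = 1L, rank = 1:2
  )
  seed <- build_seed(el[1, ], red_scan())
  expect_identical(seed$duration, 1L)
  seed2 <- build_seed(el[2, ], red_scan())
  expect_identical(seed2$duration, 16L)
})

test_that("encode_corpus reads known content and reduces chords to the top note", {
  # C-major scale assembled byte-by-byte, independently of write_midi()
  pitches <- c(60, 62, 64, 65, 67, 69, 71, 72)
  msgs <- data.frame(
    tick = rep((0:7) * 480, each = 2) + rep(c(0, 480), 8),
    on = rep(c(TRUE, FALSE), 8),
    pitch = rep(pitches, each = 2),
    velocity = rep(c(100, 0), 8)
  )
  path <- withr::local_tempfile(fileext = ".mid")
  writeBin(build_smf_bytes(msgs), path)
  enc <- encode_corpus(path)
  expect_length(enc, 1L)
  expect_identical(enc[[1]]$pitch, as.integer(pitches))
  expect_true(all(enc[[1]]$duration == 4L)) # quarter notes at 480 tpq

  # simultaneous C-E-G collapses to the highest note
  chord <- data.frame(
    tick = c(0, 0, 0, 480, 480, 480),
    on = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    pitch = c(60, 64, 67, 60, 64, 67),
    velocity = c(90, 90, 90, 0, 0, 0)
  )
  path2 <- withr::local_tempfile(fileext = ".mid")
  writeBin(build_smf_bytes(chord), path2)
  enc2 <- encode_corpus(path2)
  expect_identical(nrow(enc2[[1]]), 1L)
  expect_identical(enc2[[1]]$pitch, 67L)

  # corrupt files are skipped with a warning, not an error
  bad <- withr::local_tempfile(fileext = ".mid")
  writeBin(charToRaw("not a midi file"), bad)
  expect_warning(enc3 <- encode_corpus(c(path, bad)), "Skipping")
  expect_length(enc3, 1L)
})

test_that("training reduces the loss and is reproducible", {
  corpus <- desk_corpus()
  cfg <- model_config("desk")
  model <- train_melody_model(corpus, cfg)
  expect_length(model$loss_trace, cfg$epochs)
  expect_lt(tail(model$loss_trace, 1), model$loss_trace[1])
  # mean loss strictly decreases over the first three epochs
  expect_true(all(diff(model$loss_trace[1:3]) < 0))
  # identical seed + corpus + config -> identical trace
  model2 <- train_melody_model(corpus, cfg)
  expect_identical(model$loss_trace, model2$loss_trace)
  expect_error(train_melody_model(list(), cfg), class = "gazetone_input_error")
})

test_that("a single-note corpus is learned to near-certainty", {
  one_note <- tibble::tibble(
    pitch = 60L, duration = 2L, velocity = 64L, offset = 2L
  )[rep(1, 40), ]
  corpus <- rep(list(one_note), 10)
  cfg <- model_config("desk", epochs = 30L, dropout = 0, seed = 8L)
  model <- train_melody_model(corpus, cfg)
  # summed cross-entropy over all four heads approaches zero
  expect_lt(tail(model$loss_trace, 1), 0.2)
  gen <- generate_melody(model, one_note[1, ], 20)
  expect_true(all(gen$pitch == 60L))
})

test_that("generation preserves the seed and satisfies validity predicates", {
  corpus <- desk_corpus()
  model <- train_melody_model(corpus, model_config("desk"))
  seed <- tibble::tibble(
    pitch = c(60L, 64L, 67L, 72L), duration = c(4L, 4L, 2L, 8L),
    velocity = c(100L, 96L, 90L, 84L), offset = c(0L, 4L, 4L, 2L)
  )
  out <- generate_melody(model, seed, 100)
  expect_identical(nrow(out), 100L)
  expect_identical(out[1:4, ], seed) # seed is an exact prefix
  expect_true(all(out$pitch >= 0 & out$pitch <= 127))
  expect_true(all(out$duration >= 1 & out$duration == round(out$duration)))
  expect_true(all(abs(diff(out$velocity[4:100])) <= 32)) # smooth velocity
  # identity case and determinism
  expect_identical(generate_melody(model, seed, 4), seed)
  expect_identical(generate_melody(model, seed, 100), out)
  # empty seed starts from the default event
  gen0 <- generate_melody(model, seed[0, ], 10)
  expect_identical(nrow(gen0), 10L)
  expect_identical(gen0$pitch[1], 60L)
})

test_that("tidy and glance summarise a fitted model", {
  model <- train_melody_model(desk_corpus(n = 10, len = 24), model_config("desk", epochs = 2L))
  td <- tidy(model)
  expect_identical(td$epoch, 1:2)
  gl <- glance(model)
  expect_identical(gl$layers, 2L)
  expect_gt(gl$n_parameters, 0)
  expect_equal(gl$final_loss, td$loss[2])
})
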