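test_that("generate_beat is deterministic without jitter and linear in amplitudes", {
  m <- default_morphologies()$N
  b1 <- generate_beat(m, fs = 360, r = 250, jitter = 0)
  b2 <- generate_beat(m, fs = 360, r = 250, jitter = 0)
  expect_identical(b1, b2)

  zero <- m
  zero$wave_params[, "amplitude"] <- 0
  expect_equal(generate_beat(zero, fs = 360, r = 64, jitter = 0),
               rep(0, 64))
})

test_that("the R deflection peaks at its configured center", {
  m <- default_morphologies()$N
  b <- generate_beat(m, fs = 360, r = 250, jitter = 0)
  peak <- which.max(b) - 1L   # 0-based sample index
  expected <- round(m$wave_params["R", "center"] * 360)
  expect_lte(abs(peak - expected), 1L)
})

test_that("invalid morphologies are rejected", {
  wp <- default_morphologies()$N$wave_params
  wp["T", "center"] <- wp["P", "center"] - 0.01  # T before P
  expect_error(beat_morphology("N", wp), "strictly increasing")
  wp2 <- default_morphologies()$N$wave_params
  wp2["R", "width"] <- 0
  expect_error(beat_morphology("N", wp2), "strictly positive")
})

test_that("generate_record honours beat counts, class mix and determinism", {
  r0 <- generate_record(0, seed = 4)
  expect_equal(nrow(r0$annotations), 0L)
  expect_gt(length(r0$samples), 0L)

  r10 <- generate_record(10, class_mix = c(N = 1, S = 0, V = 0), seed = 4)
  expect_equal(nrow(r10$annotations), 10L)
  expect_true(all(r10$annotations$symbol == "N"))

  ra <- generate_record(25, seed = 9)
  rb <- generate_record(25, seed = 9)
  expect_identical(ra$samples, rb$samples)
  expect_identical(ra$annotations, rb$annotations)
  expect_equal(nrow(ra$annotations), 25L)
})

test_that("a noise-free jitter-free record reproduces the per-beat waveforms", {
  morphs <- default_morphologies()
  rec <- generate_record(5, class_mix = c(N = 1, S = 0, V = 0),
                         morphologies = morphs, noise = noise_preset("clean"),
                         jitter = 0, seed = 11)
  fs <- rec$fs
  support <- round(0.70 * fs)
  r_off <- round(100 / 360 * fs)
  beat <- generate_beat(morphs$N, fs = fs, r = support, jitter = 0)
  for (k in seq_len(nrow(rec$annotations))) {
    start <- rec$annotations$sample_index[k] - r_off
    window <- rec$samples[(start + 1L):(start + support)]
    expect_lt(max(abs(window - beat)), 1e-10)
  }
})

test_that("powerline frequency above Nyquist is an aliasing error", {
  ns <- noise_spec(powerline_amp = 0.1, powerline_freq = 200)
  expect_error(generate_record(3, noise = ns, fs = 360, seed = 1),
               "aliasing")
})

test_that("make_dataset respects counts, separation and determinism", {
  ds <- make_dataset(c(N = 5, S = 5, V = 5), seed = 2)
  expect_equal(nrow(ds$x), 15L)
  expect_equal(as.integer(table(ds$label)), c(5L, 5L, 5L))

  d1 <- make_dataset(c(N = 4, S = 4, V = 4), seed = 7)
  d2 <- make_dataset(c(N = 4, S = 4, V = 4), seed = 7)
  expect_identical(d1$x, d2$x)
  expect_identical(d1$label, d2$label)

  # at separation 0 the S morphology equals the N morphology
  m0 <- default_morphologies(separation = 0)
  expect_equal(m0$S$wave_params, m0$N$wave_params)
  expect_equal(m0$S$qrs_width_scale, m0$N$qrs_width_scale)
})

test_that("record class frequencies converge to the class mix", {
  mix <- c(N = 0.6, S = 0.3, V = 0.1)
  rec <- generate_record(600, class_mix = mix, seed = 5)
  freq <- table(factor(rec$annotations$symbol, levels = names(mix))) / 600
  expect_lt(max(abs(as.numeric(freq) - mix)), 0.07)
})
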