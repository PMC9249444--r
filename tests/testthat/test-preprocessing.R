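test_that("periodized DWT round trip is the identity at several lengths", {
  set.seed(31)
  for (n in c(512, 1000, 4096)) {
    x <- rnorm(n)
    y <- idwt(dwt(x, levels = 9, wavelet_name = "db6"))
    expect_lt(max(abs(y - x)) / max(abs(x)), 1e-8)
  }
  # Parseval: the transform is orthonormal
  x <- rnorm(1024)
  d <- dwt(x, levels = 6)
  expect_equal(sum(d$approx^2) + sum(unlist(d$details)^2), sum(x^2),
               tolerance = 1e-12)
})

test_that("denoise_wavelet passes zero signals and respects the identity mode", {
  expect_equal(denoise_wavelet(numeric(600), threshold_scale = 1),
               numeric(600))
  set.seed(5)
  x <- rnorm(700)
  y <- denoise_wavelet(x, threshold_scale = 0, remove_baseline = FALSE)
  expect_lt(max(abs(y - x)) / max(abs(x)), 1e-8)
})

test_that("signals too short for the decomposition depth are an error", {
  expect_error(dwt(rnorm(500), levels = 9), "too short")
  expect_error(denoise_wavelet(rnorm(100), levels = 9), "too short")
  expect_error(dwt(rnorm(100), levels = 9, wavelet_name = "nope"), "too short|unsupported")
  expect_error(dwt(rnorm(1024), wavelet_name = "nope"), "unsupported")
})

test_that("wavelet thresholding improves the SNR of a noisy beat train", {
  rec <- generate_record(20, class_mix = c(N = 1, S = 0, V = 0),
                         noise = noise_preset("clean"), jitter = 0, seed = 7)
  clean <- rec$samples
  set.seed(7)
  noisy <- clean + rnorm(length(clean), 0, 0.1)
  den <- denoise_wavelet(noisy, levels = 9, threshold_scale = 1)
  snr <- function(est) 10 * log10(sum(clean^2) / sum((est - clean)^2))
  expect_gt(snr(den), snr(noisy))
})

test_that("segmentation extracts exactly the annotated windows", {
  rec <- generate_record(10, seed = 3)
  seg <- segment_beats(rec, r = 250, pre_samples = 100)
  expect_equal(nrow(seg$slices$x), 10L)
  expect_equal(seg$n_dropped, 0L)
  # direct index arithmetic oracle
  for (k in seq_len(10)) {
    s0 <- rec$annotations$sample_index[k] - 100L
    expect_identical(seg$slices$x[k, ], rec$samples[(s0 + 1L):(s0 + 250L)])
  }
  expect_identical(seg$slices$label, rec$annotations$symbol)
})

test_that("boundary-violating annotations are dropped and reported", {
  rec <- raw_record(rnorm(1000), fs = 360,
                    annotations = data.frame(sample_index = c(10L, 500L),
                                             symbol = c("N", "V")))
  seg <- segment_beats(rec, r = 250, pre_samples = 100)
  expect_equal(seg$n_dropped, 1L)
  expect_equal(seg$dropped_indices, 1L)
  expect_equal(nrow(seg$slices$x), 1L)
  expect_equal(seg$slices$label, "V")

  empty <- segment_beats(raw_record(rnorm(500), 360), r = 250, pre_samples = 100)
  expect_equal(nrow(empty$slices$x), 0L)
})

test_that("segmentation conserves the labels of retained annotations", {
  rec <- generate_record(40, seed = 13)
  seg <- segment_beats(rec, r = 250, pre_samples = 100)
  kept <- setdiff(seq_len(40), seg$dropped_indices)
  expect_identical(sort(seg$slices$label),
                   sort(rec$annotations$symbol[kept]))
})

test_that("L2 normalisation is exact, idempotent and scale invariant", {
  expect_equal(normalize_slice(c(3, 4)), c(0.6, 0.8))
  v <- rnorm(50)
  u <- normalize_slice(v)
  expect_equal(sqrt(sum(u^2)), 1, tolerance = 1e-12)
  expect_equal(normalize_slice(u), u, tolerance = 1e-12)
  expect_equal(normalize_slice(17.3 * v), u, tolerance = 1e-12)
  expect_error(normalize_slice(numeric(10)), "degenerate")

  ds <- small_dataset(n = 3)
  nd <- normalize_dataset(ds)
  expect_true(nd$normalized)
  expect_equal(unname(rowSums(nd$x^2)), rep(1, nrow(nd$x)), tolerance = 1e-12)
})

test_that("resampling rescales signal and annotation indices", {
  fs_from <- 257
  t <- (0:2569) / fs_from
  x <- sin(2 * pi * 5 * t)
  rec <- raw_record(x, fs_from,
                    annotations = data.frame(sample_index = c(257L, 1285L),
                                             symbol = c("N", "N")))
  out <- resample_record(rec, 360)
  expect_equal(out$fs, 360)
  expect_equal(length(out$samples) / length(x), 360 / 257, tolerance = 0.01)
  # annotation at 1 s stays at 1 s
  expect_lt(abs(out$annotations$sample_index[1] - 360), 2)
  # interior waveform preserved
  tt <- (0:3599) / 360
  ref <- sin(2 * pi * 5 * tt)
  mid <- 500:3000
  expect_lt(max(abs(out$samples[mid] - ref[mid])), 0.05)
})
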