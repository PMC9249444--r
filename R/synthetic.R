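# Synthetic annotated single-lead ECG records and labelled beat datasets.
#
# A beat is modelled as the sum of five Gaussian deflections (P, Q, R, S, T)
# on a linear time grid -- the standard analytic surrogate for ECG morphology
# when limit-cycle dynamics are not needed. Classes differ in which waves are
# present, QRS width and T polarity, which is what the downstream feature
# extractor has to pick up after per-slice L2 normalisation.

WAVE_NAMES <- c("P", "Q", "R", "S", "T")

#' Beat morphology description
#'
#' Defines one beat class as five Gaussian deflections (P, Q, R, S, T), each
#' with an amplitude (mV), a center (seconds from the start of the beat
#' window) and a width (seconds, the Gaussian standard deviation), plus a
#' dimensionless QRS width multiplier applied to the Q, R and S widths.
#'
#' @param class_label class symbol, one of `"N"`, `"S"`, `"V"`.
#' @param wave_params 5 x 3 numeric matrix with rows P, Q, R, S, T and
#'   columns `amplitude`, `center`, `width`.
#' @param qrs_width_scale multiplier (>= 0) for the Q/R/S widths.
#' @return An object of class `beat_morphology`.
#' @export
beat_morphology <- function(class_label, wave_params, qrs_width_scale = 1) {
  stopifnot(is.character(class_label), length(class_label) == 1L)
  wave_params <- as.matrix(wave_params)
  if (!all(dim(wave_params) == c(5L, 3L))) {
    stop_mb("`wave_params` must be a 5 x 3 matrix (P,Q,R,S,T x amp,center,width)")
  }
  dimnames(wave_params) <- list(WAVE_NAMES, c("amplitude", "center", "width"))
  if (any(wave_params[, "width"] <= 0)) {
    stop_mb("invalid morphology: all wave widths must be strictly positive")
  }
  check_number(qrs_width_scale, "qrs_width_scale", lower = 0)
  active <- wave_params[, "amplitude"] != 0
  if (sum(active) >= 2L) {
    ctr <- wave_params[active, "center"]
    if (any(diff(ctr) <= 0)) {
      stop_mb("invalid morphology: wave centers must be strictly increasing in P,Q,R,S,T order")
    }
  }
  structure(
    list(class_label = class_label, wave_params = wave_params,
         qrs_width_scale = qrs_width_scale),
    class = "beat_morphology"
  )
}

#' Default class morphologies
#'
#' Class templates used throughout the package:
#' * `N` -- full P-QRS-T complex;
#' * `S` -- supraventricular ectopic: absent P wave, 10% narrower QRS;
#' * `V` -- ventricular ectopic: absent P wave, QRS 2.5x wider, inverted T.
#'
#' `separation` in `[0, 1]` linearly interpolates the S morphology toward the
#' N morphology; at 0 the two classes are identical (maximally confusable),
#' at 1 they are the well-separated defaults.
#'
#' @param separation class-separation control in `[0, 1]`.
#' @param r_center R-wave center in seconds from the start of the beat window.
#' @return Named list of `beat_morphology` objects (`N`, `S`, `V`).
#' @export
default_morphologies <- function(separation = 1, r_center = 100 / 360) {
  check_number(separation, "separation", lower = 0, upper = 1)
  cr <- r_center
  n_mat <- rbind(
    P = c(0.15, cr - 0.170, 0.022),
    Q = c(-0.10, cr - 0.026, 0.009),
    R = c(1.20, cr, 0.011),
    S = c(-0.25, cr + 0.026, 0.009),
    T = c(0.35, cr + 0.240, 0.050)
  )
  s_mat <- n_mat
  s_mat["P", 1] <- 0            # absent P wave
  v_mat <- n_mat
  v_mat["P", 1] <- 0
  v_mat["R", 1] <- 1.10
  v_mat["T", 1] <- -0.35        # inverted T
  morph_n <- beat_morphology("N", n_mat, qrs_width_scale = 1)
  morph_v <- beat_morphology("V", v_mat, qrs_width_scale = 2.5)
  # interpolate S toward N as separation decreases
  s_interp <- (1 - separation) * n_mat + separation * s_mat
  qrs_s <- (1 - separation) * 1 + separation * 0.9
  morph_s <- beat_morphology("S", s_interp, qrs_width_scale = qrs_s)
  list(N = morph_n, S = morph_s, V = morph_v)
}

#' Additive noise specification
#'
#' @param baseline_amp baseline-wander amplitude (mV).
#' @param baseline_freq baseline-wander frequency (Hz).
#' @param powerline_amp mains-interference amplitude (mV).
#' @param powerline_freq mains frequency (Hz), typically 50 or 60.
#' @param white_sd white-noise standard deviation (mV).
#' @param seed integer seed for the noise stream.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(baseline_amp = 0, baseline_freq = 0.3,
                       powerline_amp = 0, powerline_freq = 50,
                       white_sd = 0, seed = 1L) {
  check_number(baseline_amp, "baseline_amp", lower = 0)
  check_number(powerline_amp, "powerline_amp", lower = 0)
  check_number(white_sd, "white_sd", lower = 0)
  check_number(baseline_freq, "baseline_freq", lower = 0)
  check_number(powerline_freq, "powerline_freq", lower = 0)
  structure(
    list(baseline_amp = baseline_amp, baseline_freq = baseline_freq,
         powerline_amp = powerline_amp, powerline_freq = powerline_freq,
         white_sd = white_sd, seed = as.integer(seed)),
    class = "noise_spec"
  )
}

#' Named noise presets
#'
#' `"clean"` is noise-free; `"ambulatory"` adds baseline wander (0.1 mV at
#' 0.3 Hz), 50 Hz mains pickup (0.02 mV) and white noise (0.03 mV sd),
#' roughly the residual disturbance level of an ambulatory recording.
#'
#' @param name `"clean"` or `"ambulatory"`.
#' @param seed seed for the noise stream.
#' @return A [noise_spec()].
#' @export
noise_preset <- function(name = c("clean", "ambulatory"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    clean = noise_spec(seed = seed),
    ambulatory = noise_spec(baseline_amp = 0.1, baseline_freq = 0.3,
                            powerline_amp = 0.02, powerline_freq = 50,
                            white_sd = 0.03, seed = seed)
  )
}

#' Generate one synthetic beat waveform
#'
#' Evaluates the sum of the morphology's five Gaussian deflections on an
#' `r`-sample grid at sampling rate `fs`. With `jitter > 0`, each wave's
#' amplitude and width receive independent multiplicative log-normal
#' perturbations `exp(N(0, jitter^2))` drawn from the current RNG stream, so
#' wrap calls in [with_seed()]/`set.seed()` for reproducibility.
#'
#' @param morph a [beat_morphology()].
#' @param fs sampling rate (Hz).
#' @param r number of samples (>= 8).
#' @param jitter standard deviation of the log-scale perturbation (>= 0).
#' @return Numeric vector of length `r` (mV).
#' @export
generate_beat <- function(morph, fs = 360, r = 250, jitter = 0) {
  stopifnot(inherits(morph, "beat_morphology"))
  check_number(fs, "fs", lower = 0, strict_lower = TRUE)
  r <- check_count(r, "r", lower = 8L)
  check_number(jitter, "jitter", lower = 0)
  wp <- morph$wave_params
  amp <- wp[, "amplitude"]
  ctr <- wp[, "center"]
  wid <- wp[, "width"]
  wid[c("Q", "R", "S")] <- wid[c("Q", "R", "S")] * morph$qrs_width_scale
  if (jitter > 0) {
    amp <- amp * exp(stats::rnorm(5L, 0, jitter))
    wid <- wid * exp(stats::rnorm(5L, 0, jitter))
  }
  t <- (seq_len(r) - 1L) / fs
  y <- numeric(r)
  for (k in seq_len(5L)) {
    if (amp[k] != 0) y <- y + amp[k] * exp(-(t - ctr[k])^2 / (2 * wid[k]^2))
  }
  y
}

#' Construct a raw annotated record
#'
#' @param samples numeric signal (mV).
#' @param fs sampling rate (Hz).
#' @param annotations data frame with columns `sample_index` (0-based,
#'   strictly increasing, inside the record) and `symbol` (character).
#' @param record_id record identifier.
#' @return An object of class `raw_record`.
#' @export
raw_record <- function(samples, fs, annotations = NULL, record_id = "rec") {
  check_number(fs, "fs", lower = 0, strict_lower = TRUE)
  samples <- as.numeric(samples)
  if (is.null(annotations)) {
    annotations <- data.frame(sample_index = integer(), symbol = character())
  }
  stopifnot(all(c("sample_index", "symbol") %in% names(annotations)))
  annotations <- data.frame(sample_index = as.integer(annotations$sample_index),
                            symbol = as.character(annotations$symbol))
  if (nrow(annotations) > 0) {
    if (any(diff(annotations$sample_index) <= 0)) {
      stop_mb("annotation indices must be strictly increasing")
    }
    if (any(annotations$sample_index < 0L) ||
        any(annotations$sample_index >= length(samples))) {
      stop_mb("annotation indices must lie within [0, length(samples))")
    }
  }
  structure(list(samples = samples, fs = fs, annotations = annotations,
                 record_id = record_id),
            class = "raw_record")
}

#' @export
print.raw_record <- function(x, ...) {
  cat(sprintf("<raw_record '%s': %d samples @ %g Hz, %d annotations>\n",
              x$record_id, length(x$samples), x$fs, nrow(x$annotations)))
  invisible(x)
}

noise_signal <- function(n, fs, noise) {
  t <- (seq_len(n) - 1L) / fs
  with_seed(noise$seed, {
    y <- numeric(n)
    if (noise$baseline_amp > 0) {
      y <- y + noise$baseline_amp *
        sin(2 * pi * noise$baseline_freq * t + stats::runif(1, 0, 2 * pi))
    }
    if (noise$powerline_amp > 0) {
      y <- y + noise$powerline_amp *
        sin(2 * pi * noise$powerline_freq * t + stats::runif(1, 0, 2 * pi))
    }
    if (noise$white_sd > 0) y <- y + stats::rnorm(n, 0, noise$white_sd)
    y
  })
}

#' Generate a continuous annotated record
#'
#' Lays `n_beats` beats on a continuous time axis with truncated-normal RR
#' intervals, sums per-beat Gaussian-deflection waveforms, adds baseline /
#' powerline / white noise per `noise`, and returns a [raw_record()] whose
#' annotations mark each beat's R center with its class symbol.
#'
#' @param n_beats number of beats (>= 0).
#' @param class_mix probability triple over the classes in `morphologies`
#'   order; must sum to 1.
#' @param morphologies named list of [beat_morphology()] (default
#'   [default_morphologies()]).
#' @param fs sampling rate (Hz).
#' @param rr_mean,rr_sd mean and sd of the RR interval (s); intervals are
#'   truncated below at 0.4 s so consecutive beats never overlap.
#' @param noise a [noise_spec()].
#' @param jitter per-beat morphology jitter (see [generate_beat()]).
#' @param seed integer seed; the full record is a deterministic function of
#'   the arguments.
#' @param record_id record identifier.
#' @return A [raw_record()] with exactly `n_beats` annotations.
#' @export
generate_record <- function(n_beats, class_mix = c(N = 1/3, S = 1/3, V = 1/3),
                            morphologies = default_morphologies(),
                            fs = 360, rr_mean = 0.8, rr_sd = 0.05,
                            noise = noise_preset("clean"), jitter = 0.05,
                            seed = 1L, record_id = "synth") {
  n_beats <- check_count(n_beats, "n_beats", lower = 0L)
  if (abs(sum(class_mix) - 1) > 1e-9) stop_mb("`class_mix` must sum to 1")
  if (any(class_mix < 0)) stop_mb("`class_mix` must be non-negative")
  if (length(class_mix) != length(morphologies)) {
    stop_mb("`class_mix` length must match `morphologies`")
  }
  if (noise$powerline_amp > 0 && noise$powerline_freq >= fs / 2) {
    stop_mb(sprintf("aliasing: powerline_freq (%g Hz) must be below fs/2 (%g Hz)",
                    noise$powerline_freq, fs / 2))
  }
  # beat support window: generous enough for the widest default QRS and T
  support <- round(0.70 * fs)
  r_off <- round(100 / 360 * fs)   # R center offset inside the support window
  if (rr_mean <= support / fs / 2) {
    stop_mb("`rr_mean` too short for the beat support duration")
  }
  labels <- names(morphologies)

  with_seed(seed, {
    classes <- if (n_beats > 0) {
      sample(labels, n_beats, replace = TRUE, prob = class_mix)
    } else character()
    rr <- pmax(stats::rnorm(max(n_beats, 1L), rr_mean, rr_sd), 0.4)
    r_pos <- round(fs * (0.5 + cumsum(c(0, rr))[seq_len(max(n_beats, 0L))]))
    n_samples <- if (n_beats > 0) max(r_pos) + round(0.5 * fs) else round(fs)
    sig <- numeric(n_samples)
    for (b in seq_len(n_beats)) {
      beat <- generate_beat(morphologies[[classes[b]]], fs = fs, r = support,
                            jitter = jitter)
      start <- r_pos[b] - r_off           # 0-based start of the support window
      idx <- (start + seq_len(support) - 1L) + 1L  # 1-based R indexing
      keep <- idx >= 1L & idx <= n_samples
      sig[idx[keep]] <- sig[idx[keep]] + beat[keep]
    }
    sig <- sig + noise_signal(n_samples, fs, noise)
    ann <- data.frame(sample_index = as.integer(r_pos),
                      symbol = classes)
    raw_record(sig, fs, ann, record_id = record_id)
  })
}

#' Generate a labelled beat-slice dataset
#'
#' Draws `n_per_class` jittered beats per class (plus a small white-noise
#' floor) directly on the segmentation grid, bypassing record assembly.
#' `separation` interpolates the S morphology toward N (see
#' [default_morphologies()]); at 0 the S and N generating distributions are
#' identical.
#'
#' @param n_per_class counts for classes N, S, V (each >= 1).
#' @param separation class-separation control in `[0, 1]`.
#' @param fs sampling rate (Hz).
#' @param r slice length in samples.
#' @param jitter per-beat morphology jitter.
#' @param white_sd additive white-noise sd (mV), the residual noise level a
#'   denoised record would retain.
#' @param seed integer seed.
#' @return A `beat_dataset`: list with `x` (matrix `n x r`, one beat per
#'   row), `label` (character), `fs`, `r`, `normalized` flag.
#' @export
make_dataset <- function(n_per_class = c(N = 200, S = 200, V = 200),
                         separation = 1, fs = 360, r = 250,
                         jitter = 0.05, white_sd = 0.02, seed = 1L) {
  if (length(n_per_class) != 3L) stop_mb("`n_per_class` must have length 3 (N, S, V)")
  n_per_class <- vapply(seq_along(n_per_class), function(i)
    check_count(n_per_class[[i]], "n_per_class", lower = 1L), integer(1))
  check_number(separation, "separation", lower = 0, upper = 1)
  r <- check_count(r, "r", lower = 8L)
  morphs <- default_morphologies(separation = separation)
  labels <- rep(names(morphs), times = n_per_class)
  n <- length(labels)
  with_seed(seed, {
    x <- matrix(0, nrow = n, ncol = r)
    for (i in seq_len(n)) {
      x[i, ] <- generate_beat(morphs[[labels[i]]], fs = fs, r = r, jitter = jitter)
    }
    if (white_sd > 0) x <- x + matrix(stats::rnorm(n * r, 0, white_sd), n, r)
    beat_dataset(x, labels, fs = fs)
  })
}

#' Construct a beat dataset
#'
#' @param x numeric matrix, one beat slice per row.
#' @param label character vector of class symbols, one per row.
#' @param fs sampling rate (Hz).
#' @param normalized whether rows are L2-normalised.
#' @return An object of class `beat_dataset`.
#' @export
beat_dataset <- function(x, label, fs = 360, normalized = FALSE) {
  x <- as.matrix(x)
  label <- as.character(label)
  if (nrow(x) != length(label)) stop_mb("`label` length must match nrow(x)")
  structure(list(x = x, label = label, fs = fs, r = ncol(x),
                 normalized = isTRUE(normalized)),
            class = "beat_dataset")
}

#' @export
print.beat_dataset <- function(x, ...) {
  tab <- table(x$label)
  cat(sprintf("<beat_dataset: %d slices x %d samples @ %g Hz%s; %s>\n",
              nrow(x$x), x$r, x$fs,
              if (x$normalized) ", L2-normalised" else "",
              paste(names(tab), as.integer(tab), sep = ":", collapse = " ")))
  invisible(x)
}

#' Subset a beat dataset
#'
#' @param ds a `beat_dataset`.
#' @param idx integer or logical row index.
#' @return A `beat_dataset` with the selected slices.
#' @export
subset_dataset <- function(ds, idx) {
  stopifnot(inherits(ds, "beat_dataset"))
  beat_dataset(ds$x[idx, , drop = FALSE], ds$label[idx], fs = ds$fs,
               normalized = ds$normalized)
}
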