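# Annotation-driven beat segmentation and per-slice normalisation.
# Pipeline order: denoise the whole record, segment on the annotations,
# then L2-normalise each slice.

#' Construct a beat slice
#'
#' @param values numeric vector of length `r`.
#' @param label class symbol (or `NA` for unknown).
#' @param source optional list `(record_id, annotation_index)`.
#' @param normalized whether `values` has unit L2 norm.
#' @return An object of class `beat_slice`.
#' @export
beat_slice <- function(values, label = NA_character_, source = NULL,
                       normalized = FALSE) {
  structure(list(values = as.numeric(values), label = label, source = source,
                 normalized = isTRUE(normalized)),
            class = "beat_slice")
}

#' Segment a record into fixed-length beat slices
#'
#' Cuts one `r`-sample window per annotation, starting `pre_samples` before
#' the annotated sample (the R point). Windows that would cross a record
#' boundary are dropped and counted; slices keep annotation order and carry
#' the annotation symbols as labels.
#'
#' @param record a [raw_record()].
#' @param r slice length in samples.
#' @param pre_samples samples retained before the annotation index
#'   (`0 < pre_samples < r`).
#' @return An object of class `segmentation`: list with `slices` (a
#'   `beat_dataset`), `n_dropped` and `dropped_indices` (annotation rows
#'   whose windows fell outside the record).
#' @export
segment_beats <- function(record, r = 250L, pre_samples = 100L) {
  stopifnot(inherits(record, "raw_record"))
  r <- check_count(r, "r", lower = 2L)
  pre_samples <- check_count(pre_samples, "pre_samples", lower = 1L)
  if (pre_samples >= r) stop_mb("`pre_samples` must be smaller than `r`")
  ann <- record$annotations
  n_sig <- length(record$samples)
  starts <- ann$sample_index - pre_samples          # 0-based window starts
  ok <- starts >= 0L & (starts + r) <= n_sig
  kept <- which(ok)
  x <- matrix(0, nrow = length(kept), ncol = r)
  for (j in seq_along(kept)) {
    s0 <- starts[kept[j]]
    x[j, ] <- record$samples[(s0 + 1L):(s0 + r)]
  }
  ds <- beat_dataset(x, if (length(kept)) ann$symbol[kept] else character(),
                     fs = record$fs)
  structure(list(slices = ds,
                 n_dropped = sum(!ok),
                 dropped_indices = which(!ok),
                 record_id = record$record_id,
                 r = r, pre_samples = pre_samples),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation of '%s': %d slices (r = %d, pre = %d), %d dropped>\n",
              x$record_id, nrow(x$slices$x), x$r, x$pre_samples, x$n_dropped))
  invisible(x)
}

#' L2-normalise a beat slice
#'
#' Divides each sample by the slice 2-norm, `S[j] / ||S||_2`, so the output
#' has unit norm and preserved direction. Idempotent and invariant to
#' positive rescaling of the input.
#'
#' @param slice a [beat_slice()] or bare numeric vector.
#' @return Normalised object of the same kind.
#' @export
normalize_slice <- function(slice) {
  v <- if (inherits(slice, "beat_slice")) slice$values else as.numeric(slice)
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) stop_mb("degenerate slice: zero vector cannot be L2-normalised")
  v <- v / nrm
  if (inherits(slice, "beat_slice")) {
    slice$values <- v
    slice$normalized <- TRUE
    slice
  } else {
    v
  }
}

#' L2-normalise every slice in a dataset
#'
#' @param ds a `beat_dataset`.
#' @return The dataset with unit-norm rows and `normalized = TRUE`.
#' @export
normalize_dataset <- function(ds) {
  stopifnot(inherits(ds, "beat_dataset"))
  nrm <- sqrt(rowSums(ds$x^2))
  if (any(nrm == 0)) stop_mb("degenerate slice: zero vector cannot be L2-normalised")
  ds$x <- ds$x / nrm
  ds$normalized <- TRUE
  ds
}

#' Resample a record to a target rate
#'
#' Polyphase resampling of the signal with annotation indices rescaled and
#' rounded. Used to bring non-360 Hz sources (e.g. 257 Hz lead-II records)
#' onto the segmentation grid.
#'
#' @param record a [raw_record()].
#' @param fs_to target sampling rate (Hz).
#' @return A [raw_record()] at `fs_to`.
#' @export
resample_record <- function(record, fs_to = 360) {
  stopifnot(inherits(record, "raw_record"))
  check_number(fs_to, "fs_to", lower = 0, strict_lower = TRUE)
  if (record$fs == fs_to) return(record)
  frac <- .rational_ratio(fs_to / record$fs)
  new_sig <- as.numeric(signal::resample(record$samples, p = frac[1], q = frac[2]))
  scale <- fs_to / record$fs
  ann <- record$annotations
  ann$sample_index <- pmin(as.integer(round(ann$sample_index * scale)),
                           length(new_sig) - 1L)
  raw_record(new_sig, fs_to, ann, record_id = record$record_id)
}

# continued-fraction rational approximation p/q of a positive ratio
.rational_ratio <- function(x, max_q = 10000L) {
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L
  r <- x
  for (i in 1:64) {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_q) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < 1e-12) break
    if (abs(r - a) < 1e-12) break
    r <- 1 / (r - a)
  }
  c(as.integer(p1), as.integer(q1))
}

#' Denoise, segment and normalise a record
#'
#' Convenience composition in the standard order: whole-record wavelet
#' denoising, beat segmentation on the annotations, per-slice L2
#' normalisation.
#'
#' @param record a [raw_record()].
#' @param r,pre_samples segmentation window (see [segment_beats()]).
#' @param levels,wavelet_name,threshold_scale,rule,remove_baseline
#'   denoising controls (see [denoise_wavelet()]).
#' @param target_fs records at other rates are first resampled here.
#' @return A `segmentation` whose `slices` are normalised.
#' @export
preprocess_record <- function(record, r = 250L, pre_samples = 100L,
                              levels = 9L, wavelet_name = "db6",
                              threshold_scale = 1, rule = "hard",
                              remove_baseline = TRUE, target_fs = 360) {
  record <- resample_record(record, target_fs)
  record$samples <- denoise_wavelet(record$samples, levels = levels,
                                    wavelet_name = wavelet_name,
                                    threshold_scale = threshold_scale,
                                    rule = rule,
                                    remove_baseline = remove_baseline)
  seg <- segment_beats(record, r = r, pre_samples = pre_samples)
  seg$slices <- normalize_dataset(seg$slices)
  seg
}
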