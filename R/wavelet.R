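# Periodized orthogonal discrete wavelet transform.
#
# No wavelet backend is required at run time: the transform is the classic
# pyramid algorithm with periodic boundary handling, built from frozen
# published Daubechies/Symlet scaling-filter coefficients. Periodization
# keeps the transform exactly orthogonal at every even length, so the
# round trip is the identity to machine precision; odd intermediate lengths
# are replicate-padded by one sample and truncated on inversion.

# scaling (lowpass reconstruction) filters; wavelet filter is the QMF mirror
WAVELET_FILTERS <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314453416, 0.8365163037378079, 0.2241438680420134,
          -0.12940952255126037),
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.0328830116668852, -0.010597401785069032),
  db6 = c(0.11154074335010947, 0.49462389039845306, 0.7511339080210954,
          0.31525035170919763, -0.22626469396543983, -0.12976686756726194,
          0.09750160558732304, 0.027522865530305727, -0.03158203931748603,
          0.0005538422011614961, 0.004777257510945511, -0.0010773010853084796),
  db8 = c(0.05441584224310401, 0.31287159091429995, 0.6756307362972898,
          0.5853546836542067, -0.015829105256349306, -0.2840155429615469,
          0.0004724845739132828, 0.12874742662047847, -0.017369301001807547,
          -0.044088253930794755, 0.013981027917398282, 0.008746094047405777,
          -0.004870352993451574, -0.00039174037337694705,
          0.0006754494064505693, -0.00011747678412476953),
  sym4 = c(0.0322231006040427, -0.012603967262037833, -0.09921954357684722,
           0.29785779560527736, 0.8037387518059161, 0.49761866763201545,
           -0.02963552764599851, -0.07576571478927333),
  sym8 = c(0.0018899503327594609, -0.0003029205147213668, -0.01495225833704823,
           0.003808752013890615, 0.049137179673607506, -0.027219029917056003,
           -0.05194583810770904, 0.3644418948353314, 0.7771857517005235,
           0.4813596512583722, -0.061273359067658524, -0.1432942383508097,
           0.007607487324917605, 0.03169508781149298, -0.0005421323317911481,
           -0.0033824159510061256)
)

wavelet_filter_pair <- function(wavelet_name) {
  h <- WAVELET_FILTERS[[wavelet_name]]
  if (is.null(h)) {
    stop_mb(sprintf("unsupported wavelet '%s' (available: %s)", wavelet_name,
                    paste(names(WAVELET_FILTERS), collapse = ", ")))
  }
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1L)   # quadrature mirror filter
  list(h = h, g = g)
}

# one analysis step on an even-length signal; returns approx and detail,
# each of length n/2: a[k] = <s, h shifted by 2k> (periodic)
dwt_step <- function(s, h, g) {
  n <- length(s)
  L <- length(h)
  half <- n %/% 2L
  # index matrix: row k (0-based shift 2k), columns j = 0..L-1
  base <- 2L * (seq_len(half) - 1L)
  idx <- outer(base, 0L:(L - 1L), "+") %% n + 1L
  sm <- matrix(s[idx], nrow = half)
  list(a = drop(sm %*% h), d = drop(sm %*% g))
}

idwt_step <- function(a, d, h, g) {
  half <- length(a)
  n <- 2L * half
  L <- length(h)
  s <- numeric(n)
  base <- 2L * (seq_len(half) - 1L)
  for (j in seq_len(L)) {
    pos <- (base + (j - 1L)) %% n + 1L   # distinct for fixed j
    s[pos] <- s[pos] + a * h[j] + d * g[j]
  }
  s
}

#' Multi-level periodized discrete wavelet transform
#'
#' Decomposes `x` into `levels` scales with the orthogonal pyramid
#' algorithm under periodic boundary handling. Odd-length intermediate
#' signals are padded by replicating the final sample; [idwt()] undoes the
#' padding, so the round trip is exact.
#'
#' @param x numeric signal, `length(x) >= 2^levels`.
#' @param levels decomposition depth.
#' @param wavelet_name filter name (see `names(microbeat:::WAVELET_FILTERS)`).
#' @return List with `approx` (coarsest approximation), `details` (list,
#'   finest scale first), `lengths` (pre-padding length per level) and the
#'   transform settings.
#' @export
dwt <- function(x, levels = 9L, wavelet_name = "db6") {
  levels <- check_count(levels, "levels", lower = 1L)
  if (length(x) < 2^levels) {
    stop_mb(sprintf(
      "signal of length %d is too short for a %d-level decomposition (needs >= %d)",
      length(x), levels, 2^levels))
  }
  fl <- wavelet_filter_pair(wavelet_name)
  details <- vector("list", levels)
  lengths <- integer(levels)
  s <- as.numeric(x)
  for (lev in seq_len(levels)) {
    lengths[lev] <- length(s)
    if (length(s) %% 2L == 1L) s <- c(s, s[length(s)])
    st <- dwt_step(s, fl$h, fl$g)
    details[[lev]] <- st$d
    s <- st$a
  }
  structure(list(approx = s, details = details, lengths = lengths,
                 levels = levels, wavelet_name = wavelet_name),
            class = "dwt_decomposition")
}

#' Inverse periodized discrete wavelet transform
#'
#' @param dec a decomposition from [dwt()].
#' @return Numeric signal of the original length.
#' @export
idwt <- function(dec) {
  stopifnot(inherits(dec, "dwt_decomposition"))
  fl <- wavelet_filter_pair(dec$wavelet_name)
  s <- dec$approx
  for (lev in rev(seq_len(dec$levels))) {
    s <- idwt_step(s, dec$details[[lev]], fl$h, fl$g)
    s <- s[seq_len(dec$lengths[lev])]    # drop replicate padding
  }
  s
}

#' Wavelet denoising of a continuous signal
#'
#' Decomposes the signal into `levels` scales, thresholds every detail band
#' with the universal threshold `sigma * sqrt(2 log N) * threshold_scale`
#' (`sigma` estimated from the finest detail band as `median(|d1|)/0.6745`),
#' optionally zeroes the sub-0.7 Hz drift bands (baseline wander), and
#' reconstructs by the inverse transform. With `threshold_scale = 0` and
#' `remove_baseline = FALSE` the operation is the identity up to round-off.
#'
#' @param signal numeric signal, `length >= 2^levels`.
#' @param levels decomposition depth (default 9).
#' @param wavelet_name wavelet filter (default `"db6"`).
#' @param threshold_scale multiplier on the universal threshold (>= 0).
#' @param rule `"hard"` (zero below the threshold, keep above unchanged,
#'   the default) or `"soft"` (shrink every coefficient by the threshold).
#'   Soft shrinkage biases the large coefficients that carry the QRS
#'   complex; hard keeps sharp deflections intact.
#' @param threshold_levels integer vector of detail levels (1 = finest) to
#'   threshold; `NULL` processes all `levels` scales.
#' @param remove_baseline zero the coarsest approximation band and the
#'   coarsest detail band (drift below ~0.7 Hz at 360 Hz / 9 levels).
#' @return Denoised signal, same length as the input.
#' @export
denoise_wavelet <- function(signal, levels = 9L, wavelet_name = "db6",
                            threshold_scale = 1, rule = c("hard", "soft"),
                            threshold_levels = NULL,
                            remove_baseline = FALSE) {
  check_number(threshold_scale, "threshold_scale", lower = 0)
  rule <- match.arg(rule)
  dec <- dwt(signal, levels = levels, wavelet_name = wavelet_name)
  if (threshold_scale > 0) {
    d1 <- dec$details[[1L]]
    sigma <- stats::median(abs(d1)) / 0.6745
    thr <- sigma * sqrt(2 * log(length(signal))) * threshold_scale
    lev_set <- if (is.null(threshold_levels)) seq_len(levels) else
      intersect(as.integer(threshold_levels), seq_len(levels))
    if (thr > 0) {
      for (lev in lev_set) {
        d <- dec$details[[lev]]
        dec$details[[lev]] <- if (rule == "soft") {
          sign(d) * pmax(abs(d) - thr, 0)
        } else {
          d * (abs(d) > thr)
        }
      }
    }
  }
  if (isTRUE(remove_baseline)) {
    dec$approx[] <- 0
    dec$details[[levels]][] <- 0
  }
  idwt(dec)
}
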