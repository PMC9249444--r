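# AAMI-style grouping of annotation symbols into the N/S/V superclasses.

#' AAMI label map
#'
#' The standard EC57 grouping restricted to the three reported classes:
#' `N <- {N, L, R, e, j}`, `S <- {A, a, J, S}`, `V <- {V, E}`. Fusion (F),
#' paced and unknown beats, and non-beat annotations are unmapped and get
#' excluded (with counts) by [map_labels()].
#'
#' @return Named character vector mapping annotation symbols to class
#'   symbols.
#' @export
aami_label_map <- function() {
  c(N = "N", L = "N", R = "N", e = "N", j = "N",
    A = "S", a = "S", J = "S", S = "S",
    V = "V", E = "V")
}

#' Map annotation symbols to classes, excluding unmapped symbols
#'
#' Applies a symbol-to-class map to a [raw_record()]'s annotations or a
#' `beat_dataset`'s labels. Retained items carry their class symbol;
#' unmapped symbols are dropped and reported per symbol, and
#' `retained + excluded` always equals the input count.
#'
#' @param x a `raw_record` or `beat_dataset`.
#' @param label_map named character vector (default [aami_label_map()]).
#' @return List with `data` (the relabelled, filtered object) and
#'   `exclusions` (named integer vector of dropped counts per symbol).
#' @export
map_labels <- function(x, label_map = aami_label_map()) {
  if (inherits(x, "raw_record")) {
    sym <- x$annotations$symbol
    mapped <- unname(label_map[sym])
    keep <- !is.na(mapped)
    excl <- table(sym[!keep])
    x$annotations <- data.frame(
      sample_index = x$annotations$sample_index[keep],
      symbol = mapped[keep])
    list(data = x,
         exclusions = stats::setNames(as.integer(excl), names(excl)))
  } else if (inherits(x, "beat_dataset")) {
    mapped <- unname(label_map[x$label])
    keep <- !is.na(mapped)
    excl <- table(x$label[!keep])
    out <- beat_dataset(x$x[keep, , drop = FALSE], mapped[keep], fs = x$fs,
                        normalized = x$normalized)
    list(data = out,
         exclusions = stats::setNames(as.integer(excl), names(excl)))
  } else {
    stop_mb("`x` must be a raw_record or beat_dataset")
  }
}
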