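# Dataset splitting and precision/recall/F1 evaluation.

#' Split specification
#'
#' @param fractions train/validation/test fractions (positive, sum 1);
#'   default 6:2:2.
#' @param stratified preserve class proportions in every split.
#' @param seed integer seed for the shuffles.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(fractions = c(train = 0.6, val = 0.2, test = 0.2),
                       stratified = TRUE, seed = 1L) {
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop_mb("`fractions` must be three positive numbers summing to 1")
  }
  names(fractions) <- c("train", "val", "test")
  structure(list(fractions = fractions, stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "split_spec")
}

# largest-remainder apportionment of n into parts proportional to fracs
largest_remainder <- function(n, fracs) {
  ideal <- n * fracs
  base <- floor(ideal)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(ideal - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Split a labelled dataset into train / validation / test
#'
#' Produces a disjoint, exhaustive partition with exact global sizes
#' (largest-remainder rounding of the fractions). Under stratification the
#' per-class allocation also follows largest remainders, constrained so the
#' global split sizes stay exact; class proportions are preserved within
#' one example per split. Deterministic for a fixed seed.
#'
#' @param ds a `beat_dataset`.
#' @param spec a [split_spec()].
#' @return List of `beat_dataset`s: `train`, `val`, `test`.
#' @export
split_dataset <- function(ds, spec = split_spec()) {
  stopifnot(inherits(ds, "beat_dataset"), inherits(spec, "split_spec"))
  n <- nrow(ds$x)
  fr <- spec$fractions
  totals <- largest_remainder(n, fr)
  assign_idx <- vector("list", 3L)

  with_seed(spec$seed, {
    if (!spec$stratified) {
      ord <- sample.int(n)
      cuts <- cumsum(c(0L, totals))
      for (s in 1:3) assign_idx[[s]] <- ord[(cuts[s] + 1L):cuts[s + 1L]]
    } else {
      classes <- sort(unique(ds$label))
      counts <- vapply(classes, function(cl) sum(ds$label == cl), integer(1))
      if (any(counts < 3L)) {
        stop_mb(sprintf(
          "stratified split needs >= 3 examples per class; short: %s",
          paste(classes[counts < 3L], collapse = ", ")))
      }
      ideal <- outer(counts, fr)                # class x split quotas
      alloc <- floor(ideal)
      # distribute the leftovers greedily by fractional part, honouring both
      # the per-class totals and the exact global split sizes
      frac <- ideal - alloc
      split_room <- totals - colSums(alloc)
      class_room <- counts - rowSums(alloc)
      cells <- order(frac, decreasing = TRUE)
      for (cell in cells) {
        if (sum(class_room) == 0L) break
        cl <- (cell - 1L) %% length(classes) + 1L
        sp <- (cell - 1L) %/% length(classes) + 1L
        if (class_room[cl] > 0L && split_room[sp] > 0L) {
          alloc[cl, sp] <- alloc[cl, sp] + 1L
          class_room[cl] <- class_room[cl] - 1L
          split_room[sp] <- split_room[sp] - 1L
        }
      }
      # any residue (quota deadlock) resolved by first-fit
      while (sum(class_room) > 0L) {
        cl <- which(class_room > 0L)[1L]
        sp <- which(split_room > 0L)[1L]
        alloc[cl, sp] <- alloc[cl, sp] + 1L
        class_room[cl] <- class_room[cl] - 1L
        split_room[sp] <- split_room[sp] - 1L
      }
      for (s in 1:3) assign_idx[[s]] <- integer()
      for (ci in seq_along(classes)) {
        rows <- sample(which(ds$label == classes[ci]))
        cuts <- cumsum(c(0L, alloc[ci, ]))
        for (s in 1:3) {
          if (alloc[ci, s] > 0L) {
            assign_idx[[s]] <- c(assign_idx[[s]],
                                 rows[(cuts[s] + 1L):cuts[s + 1L]])
          }
        }
      }
      assign_idx <- lapply(assign_idx, sort)
    }
  })
  list(train = subset_dataset(ds, assign_idx[[1L]]),
       val = subset_dataset(ds, assign_idx[[2L]]),
       test = subset_dataset(ds, assign_idx[[3L]]))
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 * pre * rec / (pre + rec)` on the percent scale. When
#' both inputs are zero the score is defined as 0 and flagged via the
#' `"degenerate"` attribute.
#'
#' @param pre,rec precision and recall in percent (`[0, 100]`).
#' @return F1 in percent.
#' @export
compute_f1 <- function(pre, rec) {
  check_number(pre, "pre", lower = 0, upper = 100)
  check_number(rec, "rec", lower = 0, upper = 100)
  if (pre + rec == 0) {
    return(structure(0, degenerate = TRUE))
  }
  2 * pre * rec / (pre + rec)
}

#' Metrics from a confusion matrix
#'
#' Rows are true classes, columns predicted classes. Per-class precision is
#' `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 the harmonic mean; a class never
#' predicted reports precision 0 and is flagged in `zero_predicted`.
#'
#' @param cm square confusion matrix with identical, named row/column order.
#' @return An object of class `metrics_report`: per-class `precision`,
#'   `recall`, `f1` (percent), `accuracy` (percent), `support`,
#'   `confusion`, `zero_predicted`.
#' @export
confusion_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop_mb("confusion matrix must be square")
  classes <- rownames(cm) %||% paste0("class", seq_len(nrow(cm)))
  tp <- diag(cm)
  support <- rowSums(cm)
  pred_tot <- colSums(cm)
  precision <- ifelse(pred_tot > 0, tp / pred_tot, 0) * 100
  recall <- ifelse(support > 0, tp / support, 0) * 100
  f1 <- numeric(length(tp))
  for (i in seq_along(tp)) f1[i] <- as.numeric(compute_f1(precision[i], recall[i]))
  names(precision) <- names(recall) <- names(f1) <- classes
  rep_ <- structure(
    list(precision = precision, recall = recall, f1 = f1,
         accuracy = 100 * sum(tp) / sum(cm),
         support = stats::setNames(as.integer(support), classes),
         confusion = cm,
         zero_predicted = classes[pred_tot == 0]),
    class = "metrics_report")
  .check_report(rep_)
  rep_
}

# internal consistency assertions, run on every evaluation
.check_report <- function(rep_) {
  cm <- rep_$confusion
  stopifnot(all(rowSums(cm) == rep_$support))
  stopifnot(abs(rep_$accuracy - 100 * sum(diag(cm)) / sum(cm)) < 1e-9)
  for (i in seq_along(rep_$f1)) {
    p <- rep_$precision[i]; r <- rep_$recall[i]
    expect <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    stopifnot(abs(rep_$f1[i] - expect) < 1e-9)
  }
  invisible(TRUE)
}

#' Evaluate a trained ensemble on a test set
#'
#' Predicts every slice, builds the confusion matrix over the ensemble's
#' class symbols and derives the percent-scale metrics.
#'
#' @param model a trained `micro_ensemble`.
#' @param test a `beat_dataset`.
#' @param normalize L2-normalise the test slices first (skipped if already
#'   normalised).
#' @return A `metrics_report`.
#' @export
evaluate_model <- function(model, test, normalize = TRUE) {
  stopifnot(inherits(model, "micro_ensemble"), inherits(test, "beat_dataset"))
  if (nrow(test$x) == 0L) stop_mb("empty test set")
  if (normalize && !test$normalized) test <- normalize_dataset(test)
  pred <- predict(model, test$x)
  lv <- model$class_symbols
  cm <- table(factor(test$label, levels = lv), factor(pred, levels = lv))
  cm <- matrix(as.integer(cm), nrow = length(lv),
               dimnames = list(true = lv, predicted = lv))
  confusion_metrics(cm)
}

#' @export
print.metrics_report <- function(x, digits = 1, ...) {
  cat(sprintf("Overall accuracy: %.*f%%\n", digits, x$accuracy))
  df <- data.frame(Pre = round(x$precision, digits),
                   Rec = round(x$recall, digits),
                   F1 = round(x$f1, digits),
                   support = x$support)
  print(df)
  if (length(x$zero_predicted) > 0) {
    cat("Classes never predicted (precision reported as 0):",
        paste(x$zero_predicted, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a metrics report as a delimited table
#'
#' One row per model in the layout `ACC`, then `Pre`/`Rec`/`F1` per class.
#'
#' @param rep_ a `metrics_report`.
#' @param path output file (tab-separated).
#' @return The path, invisibly.
#' @export
write_metrics <- function(rep_, path) {
  classes <- names(rep_$f1)
  row <- c(ACC = round(rep_$accuracy, 4))
  for (cl in classes) {
    row[paste0(cl, "_Pre")] <- round(rep_$precision[[cl]], 4)
    row[paste0(cl, "_Rec")] <- round(rep_$recall[[cl]], 4)
    row[paste0(cl, "_F1")] <- round(rep_$f1[[cl]], 4)
  }
  df <- as.data.frame(as.list(row), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
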