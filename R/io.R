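# Readers and writers for the formats the tool touches.
#
# Two record dialects:
#  * "delimited": plain-text two-column signal file (sample_index, value)
#    with a sidecar annotation table (sample_index, symbol) at
#    <stem>.ann.tsv and the sampling rate in a one-line header comment.
#  * "wfdb": PhysioNet-style header (.hea) + binary signal (.dat, format 16
#    or 212) + MIT-format annotations (.atr).
# Sample indices are 0-based throughout; the annotation index marks the
# R-point sample.

#' Write a record
#'
#' @param record a [raw_record()].
#' @param path output stem (extensions are appended per dialect).
#' @param dialect `"delimited"` or `"wfdb"`.
#' @return The stem path, invisibly.
#' @export
write_record <- function(record, path, dialect = c("delimited", "wfdb")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(record, "raw_record"))
  switch(dialect,
         delimited = .write_delimited(record, path),
         wfdb = .write_wfdb(record, path))
  invisible(path)
}

#' Read a record
#'
#' @param path stem written by [write_record()] (or a WFDB record stem).
#' @param dialect `"delimited"` or `"wfdb"`.
#' @param lead for WFDB, signal name to select; falls back to channel 1
#'   with a warning when `NULL`; errors naming the available leads when the
#'   request is absent.
#' @return A [raw_record()].
#' @export
read_record <- function(path, dialect = c("delimited", "wfdb"), lead = NULL) {
  dialect <- match.arg(dialect)
  switch(dialect,
         delimited = .read_delimited(path),
         wfdb = .read_wfdb(path, lead = lead))
}

## ---- delimited dialect -------------------------------------------------

.write_delimited <- function(record, stem) {
  sig_path <- paste0(stem, ".sig.tsv")
  ann_path <- paste0(stem, ".ann.tsv")
  con <- file(sig_path, "w")
  writeLines(sprintf("# record_id=%s fs=%.10g", record$record_id, record$fs), con)
  utils::write.table(
    data.frame(sample_index = seq_along(record$samples) - 1L,
               value = record$samples),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  utils::write.table(record$annotations, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(stem)
}

.read_delimited <- function(stem) {
  sig_path <- paste0(stem, ".sig.tsv")
  ann_path <- paste0(stem, ".ann.tsv")
  if (!file.exists(sig_path)) stop_mb(sprintf("no signal file at '%s'", sig_path))
  header <- readLines(sig_path, n = 1L)
  m <- regmatches(header, regexec("record_id=(\\S+) fs=([0-9.eE+-]+)", header))[[1]]
  if (length(m) != 3L) stop_mb(sprintf("malformed delimited header: '%s'", header))
  tab <- utils::read.table(sig_path, header = TRUE, sep = "\t", comment.char = "#")
  ann <- if (file.exists(ann_path)) {
    a <- utils::read.table(ann_path, header = TRUE, sep = "\t",
                           colClasses = c("integer", "character"))
    if (nrow(a) == 0) NULL else a
  } else NULL
  raw_record(tab$value, fs = as.numeric(m[3]), annotations = ann,
             record_id = m[2])
}

## ---- WFDB dialect ------------------------------------------------------

# MIT annotation code <-> symbol table (beat subset + common non-beat codes)
WFDB_ANN_CODES <- c(
  "1" = "N", "2" = "L", "3" = "R", "4" = "a", "5" = "V", "6" = "F",
  "7" = "J", "8" = "A", "9" = "S", "10" = "E", "11" = "j", "12" = "/",
  "13" = "Q", "14" = "~", "16" = "|", "22" = "\"", "28" = "+", "30" = "?",
  "31" = "!", "34" = "e", "35" = "n", "37" = "f", "38" = "x"
)

.write_wfdb <- function(record, stem) {
  rec_name <- basename(stem)
  gain <- 200           # ADC units per mV, the MIT-BIH convention
  adc <- as.integer(round(record$samples * gain))
  if (any(abs(adc) > 32767)) stop_mb("signal exceeds the 16-bit ADC range")
  hea <- c(sprintf("%s 1 %.10g %d", rec_name, record$fs, length(adc)),
           sprintf("%s.dat 16 %d 16 0 %d 0 0 MLII", rec_name, gain, adc[1]))
  writeLines(hea, paste0(stem, ".hea"))
  writeBin(adc, paste0(stem, ".dat"), size = 2L, endian = "little")
  .write_wfdb_annotations(record$annotations, paste0(stem, ".atr"))
  invisible(stem)
}

.write_wfdb_annotations <- function(ann, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  sym_to_code <- stats::setNames(as.integer(names(WFDB_ANN_CODES)),
                                 WFDB_ANN_CODES)
  prev <- 0L
  for (k in seq_len(nrow(ann))) {
    code <- sym_to_code[[ann$symbol[k]]]
    if (is.null(code) || is.na(code)) {
      stop_mb(sprintf("no MIT annotation code for symbol '%s'", ann$symbol[k]))
    }
    dt <- ann$sample_index[k] - prev
    prev <- ann$sample_index[k]
    if (dt > 1023L) {
      # SKIP pseudo-annotation carries a 32-bit interval; PDP-11 word order
      writeBin(as.integer(59L * 1024L), con, size = 2L, endian = "little")
      hi <- dt %/% 65536L; lo <- dt %% 65536L
      writeBin(as.integer(hi), con, size = 2L, endian = "little")
      writeBin(as.integer(lo), con, size = 2L, endian = "little")
      dt <- 0L
    }
    writeBin(as.integer(code * 1024L + dt), con, size = 2L, endian = "little")
  }
  writeBin(0L, con, size = 2L, endian = "little")   # EOF word
}

.read_wfdb_annotations <- function(path) {
  raw_len <- file.info(path)$size
  words <- readBin(path, "integer", n = raw_len / 2, size = 2L,
                   endian = "little", signed = FALSE)
  idx <- integer(); sym <- character()
  t <- 0L; k <- 1L; pending_skip <- 0L
  while (k <= length(words)) {
    w <- words[k]
    code <- w %/% 1024L
    dt <- w %% 1024L
    if (code == 0L && dt == 0L) break
    if (code == 59L) {                 # SKIP: next two words hold the interval
      hi <- words[k + 1L]; lo <- words[k + 2L]
      pending_skip <- hi * 65536L + lo
      k <- k + 3L
      next
    }
    if (code == 63L) {                 # AUX: dt bytes of payload, word padded
      k <- k + 1L + ceiling(dt / 2)
      next
    }
    if (code %in% c(60L, 61L, 62L)) {  # NUM/SUB/CHN modifiers
      k <- k + 1L
      next
    }
    t <- t + dt + pending_skip
    pending_skip <- 0L
    symbol <- WFDB_ANN_CODES[as.character(code)]
    if (!is.na(symbol)) {
      idx <- c(idx, t)
      sym <- c(sym, symbol)
    }
    k <- k + 1L
  }
  data.frame(sample_index = idx, symbol = sym)
}

.read_wfdb <- function(stem, lead = NULL) {
  hea_path <- paste0(stem, ".hea")
  if (!file.exists(hea_path)) stop_mb(sprintf("no WFDB header at '%s'", hea_path))
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n_sig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(top[3]) else 250
  n_samp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig_lines <- lines[1 + seq_len(n_sig)]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    gain_field <- f[3]
    gain <- as.numeric(sub("^([0-9.eE+-]+).*", "\\1", gain_field))
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field))
    } else 0
    list(file = f[1], fmt = f[2], gain = if (is.na(gain) || gain == 0) 200 else gain,
         baseline = baseline,
         name = if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else
           sprintf("sig%d", NA))
  }
  sigs <- lapply(sig_lines, parse_sig)
  names_avail <- vapply(sigs, `[[`, character(1), "name")
  ch <- if (is.null(lead)) {
    if (n_sig > 1) warning("no lead requested; falling back to channel 1 (",
                           names_avail[1], ")")
    1L
  } else {
    hit <- which(names_avail == lead)
    if (length(hit) == 0) {
      stop_mb(sprintf("lead '%s' not present; available leads: %s", lead,
                      paste(names_avail, collapse = ", ")))
    }
    hit[1]
  }
  sig <- sigs[[ch]]
  dat_path <- file.path(dirname(stem), sig$file)
  fmt <- sig$fmt
  if (fmt == "16") {
    vals <- readBin(dat_path, "integer", n = file.info(dat_path)$size / 2,
                    size = 2L, endian = "little", signed = TRUE)
    vals <- matrix(vals, nrow = n_sig)[ch, ]
  } else if (fmt == "212") {
    vals <- .read_fmt212(dat_path)
    vals <- matrix(vals, nrow = n_sig)[ch, ]
  } else {
    stop_mb(sprintf("unsupported WFDB signal format '%s' (supported: 16, 212)", fmt))
  }
  if (!is.na(n_samp)) vals <- vals[seq_len(min(n_samp, length(vals)))]
  mv <- (vals - sig$baseline) / sig$gain
  atr_path <- paste0(stem, ".atr")
  ann <- if (file.exists(atr_path)) .read_wfdb_annotations(atr_path) else NULL
  if (!is.null(ann)) ann <- ann[ann$sample_index < length(mv), , drop = FALSE]
  raw_record(mv, fs = fs, annotations = ann, record_id = basename(stem))
}

# format 212: two 12-bit samples packed into 3 bytes
.read_fmt212 <- function(path) {
  b <- as.integer(readBin(path, "raw", n = file.info(path)$size))
  n3 <- (length(b) %/% 3) * 3
  b <- b[seq_len(n3)]
  b1 <- b[seq(1, n3, 3)]; b2 <- b[seq(2, n3, 3)]; b3 <- b[seq(3, n3, 3)]
  s1 <- (b2 %% 16) * 256 + b1
  s2 <- (b2 %/% 16) * 256 + b3
  s1 <- ifelse(s1 > 2047, s1 - 4096, s1)
  s2 <- ifelse(s2 > 2047, s2 - 4096, s2)
  as.vector(rbind(s1, s2))
}

## ---- beat matrices -----------------------------------------------------

#' Write a beat dataset as delimited text
#'
#' One row per slice: the class label followed by the `r` sample values.
#'
#' @param ds a `beat_dataset`.
#' @param path output file (tab-separated).
#' @return The path, invisibly.
#' @export
write_beats <- function(ds, path) {
  stopifnot(inherits(ds, "beat_dataset"))
  con <- file(path, "w")
  writeLines(sprintf("# beats fs=%.10g r=%d normalized=%d", ds$fs, ds$r,
                     as.integer(ds$normalized)), con)
  df <- data.frame(label = ds$label, ds$x, check.names = FALSE)
  colnames(df) <- c("label", sprintf("v%d", seq_len(ds$r)))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a beat dataset written by [write_beats()]
#'
#' @param path file path.
#' @return A `beat_dataset`.
#' @export
read_beats <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header,
                  regexec("fs=([0-9.eE+-]+) r=([0-9]+) normalized=([01])",
                          header))[[1]]
  if (length(m) != 4L) stop_mb(sprintf("malformed beats header: '%s'", header))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           colClasses = c("character", rep("numeric",
                                                           as.integer(m[3]))))
  beat_dataset(as.matrix(tab[, -1, drop = FALSE]), tab$label,
               fs = as.numeric(m[2]), normalized = m[4] == "1")
}

## ---- model serialization -----------------------------------------------

#' Save a trained ensemble to a single-file archive
#'
#' The archive embeds a format version, the extractor configuration and
#' parameters, every classifier's theta, the hyperparameters and the class
#' symbol order.
#'
#' @param model a `micro_ensemble`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "micro_ensemble"))
  obj <- list(format = "microbeat-ensemble", version = 1L, model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' Load an ensemble saved with [save_model()]
#'
#' @param path archive path.
#' @return A `micro_ensemble`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_mb(sprintf("no model archive at '%s'", path))
  obj <- readRDS(path)
  if (!identical(obj$format, "microbeat-ensemble")) {
    stop_mb("not a microbeat ensemble archive")
  }
  obj$model
}
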