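# Reading ECG records and cutting them into fixed-length segments.

#' Construct an ECG record
#'
#' Container for a sampled single-lead voltage trace. Annotations, when
#' present, are `(sample, symbol)` pairs with 0-based sample indices.
#'
#' @param samples numeric vector of voltages (millivolts), non-empty.
#' @param fs sampling frequency in Hz, > 0.
#' @param record_id opaque identifier.
#' @param annotations optional `data.frame` with columns `sample` (0-based
#'   integer) and `symbol` (character).
#' @param label optional rhythm-class label for single-rhythm strips.
#' @return Object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, record_id = "", annotations = NULL,
                       label = NULL) {
  if (length(samples) == 0) stop("empty record")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be > 0")
  if (!is.null(annotations)) {
    stopifnot(is.data.frame(annotations),
              all(c("sample", "symbol") %in% names(annotations)))
    bad <- annotations$sample < 0 | annotations$sample >= length(samples)
    if (any(bad)) {
      stop(sprintf("annotation sample index out of range: %d",
                   annotations$sample[which(bad)[1]]))
    }
  }
  structure(list(samples = as.numeric(samples), fs = fs,
                 record_id = record_id, annotations = annotations,
                 label = label),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record '%s': %d samples @ %g Hz (%.1f s)%s%s>\n",
              x$record_id, length(x$samples), x$fs,
              length(x$samples) / x$fs,
              if (!is.null(x$annotations))
                sprintf(", %d annotations", nrow(x$annotations)) else "",
              if (!is.null(x$label)) paste0(", label ", x$label) else ""))
  invisible(x)
}

#' Read an ECG record from CSV
#'
#' One numeric amplitude per row. A header row and an optional leading index
#' column are auto-detected; no resampling is performed.
#'
#' @param path file path.
#' @param fs sampling frequency of the stored samples (Hz).
#' @param record_id identifier; defaults to the file name.
#' @return An [ecg_record()].
#' @export
read_csv_record <- function(path, fs, record_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty record")
  fields <- strsplit(lines, ",", fixed = TRUE)
  first <- suppressWarnings(as.numeric(trimws(fields[[1]])))
  start <- if (anyNA(first)) 2L else 1L  # header row
  if (start > length(lines)) stop("empty record")
  amp_col <- length(fields[[start]])  # last column is the amplitude
  vals <- vapply(seq.int(start, length(lines)), function(i) {
    v <- suppressWarnings(as.numeric(trimws(fields[[i]][amp_col])))
    if (is.na(v)) stop(sprintf("non-numeric value at row %d of %s", i, path))
    v
  }, numeric(1))
  if (length(vals) == 0) stop("empty record")
  ecg_record(vals, fs, record_id = record_id)
}

#' Write an ECG record to CSV
#'
#' One amplitude per line, no header, full double precision (round-trips
#' through [read_csv_record()] to better than 1e-9).
#'
#' @param record an [ecg_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_csv_record <- function(record, path) {
  writeLines(sprintf("%.17g", record$samples), path)
  invisible(path)
}

#' Construct an ECG segment
#'
#' @param values numeric window of samples.
#' @param label class label or `NA` when unlabeled.
#' @param source_record identifier of the record the window came from.
#' @param start_index 0-based offset of the window in the source record.
#' @return Object of class `ecg_segment`.
#' @export
ecg_segment <- function(values, label = NA_character_, source_record = "",
                        start_index = 0L) {
  structure(list(values = as.numeric(values), label = label,
                 source_record = source_record,
                 start_index = as.integer(start_index)),
            class = "ecg_segment")
}

#' @export
print.ecg_segment <- function(x, ...) {
  cat(sprintf("<ecg_segment: %d samples from '%s' @ %d, label %s>\n",
              length(x$values), x$source_record, x$start_index,
              if (is.na(x$label)) "<none>" else x$label))
  invisible(x)
}

#' Cut a record into fixed-length windows
#'
#' Windows are half-open `[start, start + window)` at 0-based start indices
#' `0, stride, 2*stride, ...` for as long as the window fits; a record
#' shorter than `window` yields an empty list. The default window of 2000
#' samples matches the block size the classifier consumes.
#'
#' @param record an [ecg_record()].
#' @param window window length in samples (>= 2).
#' @param stride hop between window starts in samples (>= 1); defaults to
#'   `window` (non-overlapping).
#' @return List of [ecg_segment()] objects.
#' @export
segment_record <- function(record, window = 2000L, stride = window) {
  stopifnot(inherits(record, "ecg_record"))
  window <- as.integer(window); stride <- as.integer(stride)
  if (window < 2) stop("window must be >= 2")
  if (stride < 1) stop("stride must be >= 1")
  n <- length(record$samples)
  if (n < window) return(list())
  starts <- seq.int(0L, n - window, by = stride)
  lapply(starts, function(s) {
    ecg_segment(record$samples[(s + 1L):(s + window)],
                label = if (is.null(record$label)) NA_character_ else record$label,
                source_record = record$record_id, start_index = s)
  })
}

#' Default beat-annotation symbol to rhythm-class map
#'
#' Maps the standard beat annotation mnemonics to the seven rhythm classes:
#' `N`/`L`/`R`/`.` to N, `A`/`a` to PAC, `V` to PVC. Rhythm classes that are
#' annotated as rhythm changes rather than beats (AF, AT, SBR, VT) must be
#' added to the map by the caller for corpora that encode them as beat-level
#' symbols. The map is an editable named character vector.
#'
#' @return Named character vector: names are annotation symbols, values are
#'   classes.
#' @export
default_symbol_map <- function() {
  c("N" = "N", "L" = "N", "R" = "N", "." = "N",
    "A" = "PAC", "a" = "PAC",
    "V" = "PVC")
}

#' Label segments from beat annotations
#'
#' Each segment receives the class of the majority of mapped annotation
#' symbols falling inside its window; ties go to the class that comes first
#' in `class_order`. Segments whose window contains no mapped symbol (or only
#' unmapped ones) are labeled `"unknown"` and dropped; the number dropped is
#' reported via a message.
#'
#' @param segments list of [ecg_segment()] objects.
#' @param annotations `data.frame` with 0-based `sample` and `symbol`.
#' @param symbol_map named character vector mapping symbols to classes; see
#'   [default_symbol_map()].
#' @param class_order tie-break order; defaults to [arrhythmia_classes()].
#' @return List of labeled segments (unlabeled ones removed).
#' @export
label_segments <- function(segments, annotations,
                           symbol_map = default_symbol_map(),
                           class_order = arrhythmia_classes()) {
  n_unknown <- 0L
  out <- lapply(segments, function(seg) {
    lo <- seg$start_index
    hi <- seg$start_index + length(seg$values)  # half-open
    sym <- annotations$symbol[annotations$sample >= lo & annotations$sample < hi]
    cls <- unname(symbol_map[sym])
    cls <- cls[!is.na(cls)]
    if (length(cls) == 0) return(NULL)
    tab <- table(cls)
    winners <- names(tab)[tab == max(tab)]
    pick <- winners[order(match(winners, class_order))][1]
    seg$label <- pick
    seg
  })
  n_unknown <- sum(vapply(out, is.null, logical(1)))
  if (n_unknown > 0) {
    message(sprintf("label_segments: %d segment(s) had no mapped symbol and were excluded",
                    n_unknown))
  }
  out[!vapply(out, is.null, logical(1))]
}
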