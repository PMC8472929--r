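# Minimal WFDB reader/writer (.hea header, .dat signal, .atr annotations).
# Supports signal formats 16 (little-endian int16) and 212 (packed 12-bit),
# which cover the standard arrhythmia corpora. The writer exists mainly to
# build round-trip fixtures and small exports.

# Standard annotation code <-> mnemonic table.
.wfdb_codes <- c(
  "1" = "N", "2" = "L", "3" = "R", "4" = "a", "5" = "V", "6" = "F",
  "7" = "J", "8" = "A", "9" = "S", "10" = "E", "11" = "j", "12" = "/",
  "13" = "Q", "14" = "~", "16" = "|", "18" = "s", "19" = "T", "20" = "*",
  "21" = "D", "22" = "\"", "23" = "=", "24" = "p", "25" = "B", "26" = "^",
  "27" = "t", "28" = "+", "29" = "u", "30" = "?", "31" = "!", "32" = "[",
  "33" = "]", "34" = "e", "35" = "n", "36" = "@", "37" = "x", "38" = "f",
  "39" = "(", "40" = ")", "41" = "r")

wfdb_symbol_for_code <- function(code) {
  s <- .wfdb_codes[as.character(code)]
  ifelse(is.na(s), paste0("<", code, ">"), s)
}

wfdb_code_for_symbol <- function(symbol) {
  codes <- as.integer(names(.wfdb_codes))
  m <- codes[match(symbol, .wfdb_codes)]
  if (anyNA(m)) stop("no annotation code for symbol: ",
                     symbol[which(is.na(m))[1]])
  m
}

parse_hea <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  name <- sub("/.*$", "", rec[1])
  nsig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(sub("[/(].*$", "", rec[3])) else 250
  nsamp <- if (length(rec) >= 4) as.numeric(rec[4]) else NA_real_
  sigs <- lapply(seq_len(nsig), function(i) {
    f <- strsplit(trimws(lines[1 + i]), "\\s+")[[1]]
    fmt <- as.integer(sub("^(\\d+).*$", "\\1", f[2]))
    gainfield <- if (length(f) >= 3) f[3] else "200"
    gain <- as.numeric(sub("^([-0-9.]+).*$", "\\1", gainfield))
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gainfield)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gainfield))
    } else if (length(f) >= 5) {
      v <- suppressWarnings(as.integer(f[5])); if (is.na(v)) 0L else v
    } else 0L
    list(file = f[1], format = fmt, gain = gain, baseline = baseline)
  })
  list(name = name, nsig = nsig, fs = fs, nsamp = nsamp, signals = sigs)
}

read_dat_16 <- function(path, nsig) {
  sz <- file.info(path)$size
  con <- file(path, "rb"); on.exit(close(con))
  raw <- readBin(con, "integer", n = sz %/% 2, size = 2, signed = TRUE,
                 endian = "little")
  n <- length(raw) %/% nsig
  matrix(raw[seq_len(n * nsig)], nrow = nsig)  # row i = channel i
}

read_dat_212 <- function(path, nsig) {
  sz <- file.info(path)$size
  con <- file(path, "rb"); on.exit(close(con))
  b <- as.integer(readBin(con, "raw", n = sz))
  ntrip <- length(b) %/% 3
  b1 <- b[seq(1, ntrip * 3, 3)]; b2 <- b[seq(2, ntrip * 3, 3)]
  b3 <- b[seq(3, ntrip * 3, 3)]
  s1 <- bitwOr(bitwShiftL(bitwAnd(b2, 15L), 8L), b1)
  s2 <- bitwOr(bitwShiftL(bitwAnd(b2, 240L), 4L), b3)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  flat <- as.vector(rbind(s1, s2))
  n <- length(flat) %/% nsig
  matrix(flat[seq_len(n * nsig)], nrow = nsig)
}

#' Read a WFDB record
#'
#' Reads `<prefix>.hea` and the associated `.dat` file; if `<prefix>.atr`
#' exists its annotations are attached with symbols preserved verbatim.
#' When the record holds several channels, channel `channel` (default the
#' first) is returned, matching single-lead acquisition.
#'
#' @param path_prefix record path without extension.
#' @param channel 1-based channel to extract.
#' @return An [ecg_record()] with amplitudes in physical units
#'   (`(adc - baseline) / gain`).
#' @export
read_wfdb_record <- function(path_prefix, channel = 1L) {
  hea <- paste0(path_prefix, ".hea")
  if (!file.exists(hea)) stop("WFDB header not found: ", hea)
  h <- parse_hea(hea)
  sig <- h$signals[[channel]]
  dat <- file.path(dirname(hea), sig$file)
  if (!file.exists(dat)) stop("WFDB signal file not found: ", dat)
  adc <- switch(as.character(sig$format),
                "16" = read_dat_16(dat, h$nsig),
                "212" = read_dat_212(dat, h$nsig),
                stop("unsupported WFDB format code: ", sig$format))
  samples <- (adc[channel, ] - sig$baseline) / sig$gain
  if (!is.na(h$nsamp) && h$nsamp > 0 && h$nsamp <= length(samples)) {
    samples <- samples[seq_len(h$nsamp)]
  }
  ann <- NULL
  atr <- paste0(path_prefix, ".atr")
  if (file.exists(atr)) {
    ann <- read_wfdb_annotations(atr)
    ann <- ann[ann$sample < length(samples), , drop = FALSE]
  }
  ecg_record(samples, h$fs, record_id = h$name, annotations = ann)
}

#' Read a WFDB annotation file
#'
#' Decodes the MIT annotation format: 16-bit little-endian words holding a
#' 6-bit type code and a 10-bit sample interval, with SKIP (long-interval)
#' and NUM/SUB/CHN/AUX pseudo-annotations handled.
#'
#' @param path annotation file path.
#' @return `data.frame` with 0-based `sample` and `symbol`.
#' @export
read_wfdb_annotations <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb"); on.exit(close(con))
  b <- as.integer(readBin(con, "raw", n = sz))
  i <- 1L; t <- 0; samples <- integer(0); symbols <- character(0)
  while (i + 1L <= length(b)) {
    b1 <- b[i]; b2 <- b[i + 1L]
    code <- b2 %/% 4L
    intv <- b1 + 256L * (b2 %% 4L)
    if (b1 == 0L && b2 == 0L) break  # EOF
    if (code == 59L) {               # SKIP: 4-byte interval, high word first
      hw <- b[i + 2L] + 256L * b[i + 3L]
      lw <- b[i + 4L] + 256L * b[i + 5L]
      t <- t + hw * 65536 + lw
      i <- i + 6L
    } else if (code %in% c(60L, 61L, 62L)) {  # NUM/SUB/CHN: no time change
      i <- i + 2L
    } else if (code == 63L) {        # AUX: intv = byte count, padded to even
      i <- i + 2L + intv + (intv %% 2L)
    } else {
      t <- t + intv
      samples <- c(samples, t)
      symbols <- c(symbols, wfdb_symbol_for_code(code))
      i <- i + 2L
    }
  }
  data.frame(sample = samples, symbol = symbols, stringsAsFactors = FALSE)
}

#' Write a WFDB record
#'
#' Writes `<record_id>.hea` and `<record_id>.dat` (format 16 or 212) and, if
#' the record carries annotations, `<record_id>.atr`. Intended for building
#' fixtures and small exports; amplitudes are quantized by `gain`.
#'
#' @param record an [ecg_record()], or a numeric matrix with one row per
#'   channel wrapped in one (channel 1 is taken as `record$samples`).
#' @param dir output directory.
#' @param extra_channels optional numeric matrix (channels x samples) of
#'   additional channels appended after the record's own samples.
#' @param format WFDB signal format code, 16 or 212.
#' @param gain ADC units per millivolt.
#' @return The path prefix, invisibly.
#' @export
write_wfdb_record <- function(record, dir, extra_channels = NULL,
                              format = 16L, gain = 200) {
  stopifnot(inherits(record, "ecg_record"))
  sig <- rbind(record$samples,
               if (!is.null(extra_channels)) extra_channels)
  nsig <- nrow(sig); n <- ncol(sig)
  adc <- round(sig * gain)
  lim <- if (format == 212L) 2047 else 32767
  adc[adc > lim] <- lim; adc[adc < -lim - 1] <- -lim - 1
  name <- if (nzchar(record$record_id)) record$record_id else "rec"
  prefix <- file.path(dir, name)
  hea <- c(sprintf("%s %d %g %d", name, nsig, record$fs, n),
           sprintf("%s.dat %d %g 12 0 0 0 0 ch%d", name, format, gain,
                   seq_len(nsig)))
  writeLines(hea, paste0(prefix, ".hea"))
  flat <- as.integer(as.vector(adc))  # interleaved channel-major per frame
  con <- file(paste0(prefix, ".dat"), "wb")
  if (format == 16L) {
    writeBin(flat, con, size = 2, endian = "little")
  } else if (format == 212L) {
    if (length(flat) %% 2L == 1L) flat <- c(flat, 0L)
    u <- ifelse(flat < 0L, flat + 4096L, flat)  # 12-bit two's complement
    s1 <- u[seq(1, length(u), 2)]; s2 <- u[seq(2, length(u), 2)]
    trip <- as.raw(rbind(s1 %% 256L,
                         bitwOr(s1 %/% 256L, bitwShiftL(s2 %/% 256L, 4L)),
                         s2 %% 256L))
    writeBin(as.vector(trip), con)
  } else {
    close(con)
    stop("unsupported WFDB format code: ", format)
  }
  close(con)
  if (!is.null(record$annotations) && nrow(record$annotations) > 0) {
    write_wfdb_annotations(record$annotations, paste0(prefix, ".atr"))
  }
  invisible(prefix)
}

#' Write a WFDB annotation file
#'
#' @param annotations `data.frame` with 0-based `sample` and `symbol`,
#'   sorted by sample.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wfdb_annotations <- function(annotations, path) {
  ann <- annotations[order(annotations$sample), , drop = FALSE]
  codes <- wfdb_code_for_symbol(ann$symbol)
  bytes <- integer(0)
  prev <- 0
  for (k in seq_len(nrow(ann))) {
    intv <- ann$sample[k] - prev
    prev <- ann$sample[k]
    if (intv >= 1024) {  # SKIP pair + 4-byte interval (high word first)
      hw <- intv %/% 65536; lw <- intv %% 65536
      bytes <- c(bytes, 0L, 59L * 4L,
                 hw %% 256L, hw %/% 256L, lw %% 256L, lw %/% 256L)
      intv <- 0
    }
    bytes <- c(bytes, intv %% 256L, codes[k] * 4L + intv %/% 256L)
  }
  bytes <- c(bytes, 0L, 0L)  # EOF
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(bytes), con)
  invisible(path)
}
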