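# Gramian Angular Summation Field encoding: rescale to [-1, 1], optionally
# compress with piecewise aggregate approximation, map to polar angles, and
# form the matrix of cosines of pairwise angle sums.

#' Min-max rescale to [-1, 1]
#'
#' Affine map sending the minimum to -1 and the maximum to +1. A constant
#' sequence has no scale; it maps to all zeros (with a warning), which keeps
#' the polar step well-defined.
#'
#' @param values non-empty numeric vector.
#' @return Numeric vector in `[-1, 1]`.
#' @export
rescale_unit <- function(values) {
  if (length(values) == 0) stop("empty input")
  lo <- min(values); hi <- max(values)
  if (hi == lo) {
    warning("constant sequence rescaled to all zeros")
    return(rep(0, length(values)))
  }
  pmin(1, pmax(-1, 2 * (values - lo) / (hi - lo) - 1))
}

#' Piecewise aggregate approximation
#'
#' Splits the series into `m` consecutive frames of near-equal cardinality
#' (any remainder goes to the leading frames) and returns the frame means.
#' This is what keeps a 2000-sample segment from producing a 2000 x 2000
#' image.
#'
#' @param values numeric vector.
#' @param m target length, `1 <= m <= length(values)`.
#' @return Numeric vector of length `m`.
#' @export
paa <- function(values, m) {
  n <- length(values)
  m <- as.integer(m)
  if (m < 1) stop("m must be >= 1")
  if (m > n) stop("m must not exceed the series length")
  if (m == n) return(values)
  sizes <- rep(n %/% m, m)
  r <- n %% m
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  vapply(seq_len(m), function(i) mean(values[starts[i]:ends[i]]), numeric(1))
}

#' Polar angle encoding
#'
#' `phi_i = arccos(x_i)` for a rescaled series in `[-1, 1]`; values within
#' `1e-12` outside the interval are clamped, anything further is an error.
#'
#' @param x_tilde rescaled numeric vector.
#' @return Angles in `[0, pi]`.
#' @export
to_polar <- function(x_tilde) {
  tol <- 1e-12
  if (any(x_tilde > 1 + tol | x_tilde < -1 - tol)) {
    stop("input outside [-1, 1]: rescale before polar encoding")
  }
  acos(pmin(1, pmax(-1, x_tilde)))
}

#' Gramian angular summation field of an angle sequence
#'
#' `G[i, j] = cos(phi_i + phi_j)`. The matrix is symmetric with entries in
#' `[-1, 1]`, and its diagonal is `cos(2 phi_i) = 2 x_i^2 - 1`, so the
#' magnitude of the rescaled series can be read back off the diagonal.
#'
#' @param phi angle vector from [to_polar()].
#' @param source optional provenance (record id / start index).
#' @return A `gaf_image` object.
#' @export
gasf <- function(phi, source = NULL) {
  if (length(phi) == 0) stop("empty angle sequence")
  m <- cos(outer(phi, phi, `+`))
  structure(list(matrix = m, size = length(phi), source = source,
                 encoding = "GASF"),
            class = "gaf_image")
}

#' @export
print.gaf_image <- function(x, ...) {
  cat(sprintf("<gaf_image %dx%d (%s)%s>\n", x$size, x$size, x$encoding,
              if (!is.null(x$source)) paste0(" from ", x$source$record) else ""))
  invisible(x)
}

#' Plot a GASF image
#'
#' Renders the matrix with time running from the top-left corner down the
#' main diagonal.
#'
#' @param x a `gaf_image`.
#' @param ... passed to [graphics::image()].
#' @export
plot.gaf_image <- function(x, ...) {
  m <- x$matrix
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)),
                  t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  zlim = c(-1, 1), xlab = "time index", ylab = "time index",
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Encode a segment as a GASF image
#'
#' Pipeline: min-max rescale, PAA to `size` points, polar encoding, GASF.
#' Encoding is deterministic: identical input and size give a bit-identical
#' image.
#'
#' @param segment an [ecg_segment()] or a plain numeric vector.
#' @param size image side in pixels; must not exceed the segment length.
#' @return A `gaf_image` with provenance recorded.
#' @export
encode_segment <- function(segment, size = 224L) {
  values <- if (inherits(segment, "ecg_segment")) segment$values else segment
  if (length(values) < size) stop("segment shorter than the requested size")
  x <- rescale_unit(values)
  x <- paa(x, size)
  img <- gasf(to_polar(x),
              source = if (inherits(segment, "ecg_segment")) {
                list(record = segment$source_record,
                     start_index = segment$start_index,
                     label = segment$label)
              } else NULL)
  img
}

#' Export a GASF image as an 8-bit grayscale PNG
#'
#' Maps `[-1, 1]` linearly to `[0, 255]`; for visualization only (training
#' consumes the float matrices).
#'
#' @param img a `gaf_image`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gaf_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export")
  }
  png::writePNG((img$matrix + 1) / 2, path)
  invisible(path)
}

#' Write / read a GASF image as CSV
#'
#' Plain-text float container: one matrix row per line.
#'
#' @param img a `gaf_image`.
#' @param path file path.
#' @return `path` (writer) or a `gaf_image` (reader).
#' @export
write_gaf_csv <- function(img, path) {
  write.table(img$matrix, path, sep = ",", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_gaf_csv
#' @export
read_gaf_csv <- function(path) {
  m <- as.matrix(read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  structure(list(matrix = m, size = nrow(m), source = list(record = path),
                 encoding = "GASF"),
            class = "gaf_image")
}

# Stack segments into the (H, W, C=1, N) array consumed by the network.
#' Encode a list of segments into an image array
#'
#' @param segments list of [ecg_segment()] objects.
#' @param size image side in pixels.
#' @return List with `x` (array `size x size x 1 x n`) and `y` (character
#'   labels, `NA` where unlabeled).
#' @export
encode_segments <- function(segments, size = 64L) {
  n <- length(segments)
  x <- array(0, dim = c(size, size, 1L, n))
  y <- character(n)
  for (i in seq_len(n)) {
    x[, , 1L, i] <- encode_segment(segments[[i]], size)$matrix
    y[i] <- segments[[i]]$label
  }
  list(x = x, y = y)
}
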