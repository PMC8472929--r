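# Shared fixtures, all generated in code at test time.

# The published confusion matrix of the seven-class classifier on its 2347
# held-out segments (rows = real, columns = predicted).
reference_confusion <- function() {
  m <- rbind(
    AF  = c(357, 0,   4,   1,  3,   2,   2),
    AT  = c(0,   100, 0,   0,  0,   0,   0),
    N   = c(3,   0,   950, 3,  4,   0,   0),
    PAC = c(1,   0,   1,   62, 0,   2,   0),
    PVC = c(1,   0,   3,   1,  415, 2,   0),
    SBR = c(4,   0,   0,   0,  0,   366, 1),
    VT  = c(2,   1,   1,   0,  0,   0,   55))
  colnames(m) <- rownames(m)
  as_confusion_matrix(m)
}

# A synthetic sine-on-noise record for reader round trips.
sine_record <- function(n = 1000, fs = 360, record_id = "fx1",
                        annotations = NULL) {
  ecg_record(sin(2 * pi * 1.3 * (0:(n - 1)) / fs) +
               0.05 * cos(2 * pi * 17 * (0:(n - 1)) / fs),
             fs = fs, record_id = record_id, annotations = annotations)
}

# Brute-force GASF: explicit double loop over cos(phi_i + phi_j).
gasf_bruteforce <- function(x_tilde) {
  phi <- acos(pmin(1, pmax(-1, x_tilde)))
  n <- length(phi)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) m[i, j] <- cos(phi[i] + phi[j])
  }
  m
}

# Brute-force window enumerator for segment counting.
count_windows_bruteforce <- function(len, window, stride) {
  n <- 0L
  s <- 0L
  while (s + window <= len) {
    n <- n + 1L
    s <- s + stride
  }
  n
}

# Tiny two-blob image classification task, linearly separable.
toy_blob_data <- function(n = 20, side = 32, seed = 1) {
  set.seed(seed)
  x <- array(0, c(side, side, 1, n))
  y <- rep(c("a", "b"), length.out = n)
  for (i in seq_len(n)) {
    m <- matrix(rnorm(side * side, sd = 0.1), side)
    if (y[i] == "a") m[4:12, 4:12] <- m[4:12, 4:12] + 1
    else m[20:28, 20:28] <- m[20:28, 20:28] + 1
    x[, , 1, i] <- m
  }
  list(x = x, y = y)
}
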