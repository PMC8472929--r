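# Shared numeric helpers.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; reported percentages follow the
#' convention of rounding .5 away from zero instead (97.45 -> 97.5).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Fraction -> percentage at one decimal, the reporting convention used
# throughout the evaluation tables.
percent1 <- function(x) round_half_away(100 * x, 1)

# Derive a child seed from a master seed; kept below 2^31 (computed in
# double precision to avoid integer overflow).
derive_seed <- function(seed, k) {
  as.integer(((as.numeric(seed) %% 1000003) * 2039 + as.numeric(k) * 7919) %%
               2147483629)
}

# md5 of a canonical string, via a temp file (tools::md5sum is file-based).
hash_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}
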