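#' Derive a reproducible sub-stream seed
#'
#' Combines a master seed with any number of integer-valued components
#' (replicate index, a scaled alpha value, a subject hash, ...) into a single
#' positive integer seed. The scheme is a fixed multiplicative hash, so the
#' same components always give the same seed and sub-streams do not shift
#' when unrelated components (e.g. additional grid points) are added.
#'
#' @param master integer master seed.
#' @param ... further integer-valued components identifying the sub-stream.
#' @return A positive integer seed suitable for [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  parts <- c(master, ...)
  stopifnot(length(parts) >= 1, all(is.finite(parts)))
  h <- 0
  for (p in parts) {
    h <- (h * 69069 + (abs(round(p)) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h) + 1L
}

#' Hash a character id to an integer seed component
#' @param x character vector.
#' @return integer vector of the same length, each in [0, 2^31).
#' @keywords internal
.string_seed <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (cc in utf8ToInt(s)) h <- (h * 31 + cc) %% 2147483647
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# sample variance of three values per row, divisor 2
.var3 <- function(t1, t2, t3) {
  m <- (t1 + t2 + t3) / 3
  ((t1 - m)^2 + (t2 - m)^2 + (t3 - m)^2) / 2
}

.groups <- c("CON", "ETL", "MTL")
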