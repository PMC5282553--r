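# Small internal helpers shared across the package.

clamp01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)

# Row-wise mean/variance ignoring NA, for site-by-sample matrices.
row_means_na <- function(m) rowMeans(m, na.rm = TRUE)

row_vars_na <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  ss <- rowSums((m - mu)^2, na.rm = TRUE)
  v <- ss / pmax(n - 1, 1)
  v[n < 2] <- NA_real_
  v
}
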