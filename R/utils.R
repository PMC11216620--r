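stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# cumulative trapezoid wrapper keeping a zero first sample
cumtrapz1 <- function(x, y) {
  as.vector(pracma::cumtrapz(x, y))
}

check_odd_window <- function(w, n, what) {
  if (length(w) != 1L || !is.finite(w) || w < 1 || w %% 2 == 0)
    stopf("%s must be a positive odd integer, got %s", what, format(w))
  if (w > n)
    stopf("%s (%d) exceeds the number of frames (%d)", what, w, n)
  as.integer(w)
}
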