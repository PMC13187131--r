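# internal helpers

clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# row-major pixel index <-> (row, col)
px_index <- function(row, col, ncol) (row - 1L) * ncol + col
px_rowcol <- function(idx, ncol) {
  cbind(row = (idx - 1L) %/% ncol + 1L, col = (idx - 1L) %% ncol + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
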