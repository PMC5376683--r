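`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop2(msg)
  invisible(TRUE)
}

# sample (n-1) standard deviation, NA-free input expected
sd_sample <- function(x) stats::sd(x)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
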