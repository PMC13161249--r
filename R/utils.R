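# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

warn_ <- function(...) warning(..., call. = FALSE)

# integer seeds for independent substreams, drawn from the current stream
draw_seeds <- function(n) sample.int(.Machine$integer.max - 1L, n)

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

fmt_num <- function(x) sprintf("%.17g", x)
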