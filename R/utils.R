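`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

msgf <- function(fmt, ...) message(sprintf(fmt, ...))

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == floor(x)

# derive a child seed from a base seed; keeps results inside 32-bit range
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483647)
}
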