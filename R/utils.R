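`%||%` <- function(a, b) if (is.null(a)) b else a

geometric_mean <- function(x) exp(mean(log(x)))

#' @importFrom methods is
.assert_granges <- function(x, what = "intervals") {
  if (!is(x, "GRanges"))
    stop(sprintf("expected a GRanges for %s, got %s", what, class(x)[1]),
         call. = FALSE)
  invisible(x)
}

## seed streams: derive independent sub-seeds from a master seed, kept
## within 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + offset * 12347L) %% 2147483629)
}
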