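# Shared internal helpers.

clamp1 <- function(x) pmin(1, pmax(-1, x))

# Deterministic per-pair substream seed: adding pairs to a spec never
# perturbs the draws of earlier pairs. Kept inside 32-bit integer range.
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483647L) * 48271 %% 2147483647 + index) %% 2147483647L
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "mmpv_error_domain")
  }
  invisible(x)
}

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name), class = "mmpv_error_domain")
  }
  invisible(x)
}
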