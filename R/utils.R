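# Exponent arguments are clamped so exp() stays finite on extreme raw-unit
# inputs (e.g. CRP * NSE products); only affects values beyond +-700.
clamp_exp <- function(x) pmin(pmax(x, -700), 700)

# One deterministic RNG substream per named stage, derived from a single
# global seed; keeps every draw below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) * 48271 + 7919 * k) %% 2147483629 + 1)
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "gepdx_parameter_error")
  }
  invisible(x)
}

param_error <- function(msg) abort(msg, class = "gepdx_parameter_error")
format_error <- function(msg) abort(msg, class = "gepdx_format_error")
structural_error <- function(msg) abort(msg, class = "gepdx_structural_error")
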