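abort_param <- function(msg, ...) abort(msg, class = "pttbp_parameter_error", ...)
abort_format <- function(msg, ...) abort(msg, class = "pttbp_format_error", ...)
abort_config <- function(msg, ...) abort(msg, class = "pttbp_config_error", ...)

warn_validation <- function(msg) warn(msg, class = "pttbp_validation_warning")

# Run `code` under a temporary RNG state when a seed is given; leave the
# ambient stream untouched when seed is NULL (callers inside with_seed blocks
# rely on that to keep a single deterministic stream).
maybe_with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
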