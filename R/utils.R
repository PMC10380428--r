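# Classed conditions so callers (and the CLI) can branch on failure type
# without string matching.
vx_abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "volatax_error", "error")))
}

vx_warn <- function(message, class = "volatax_warning") {
  warning(warningCondition(message, class = c(class, "volatax_warning", "warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All randomness in the package flows through this: RNG state is restored
# afterwards so seeded operations never perturb the caller's stream.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
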