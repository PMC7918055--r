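# Internal helpers: validation, seed handling, numeric plumbing.

stop_emg <- function(msg, class) {
  rlang::abort(msg, class = c(class, "emgdecode_error"))
}

assert_numeric_vector <- function(x, name, min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len) {
    stop_emg(
      sprintf("`%s` must be a numeric vector of length >= %d.", name, min_len),
      "emgdecode_input_error"
    )
  }
  invisible(x)
}

#' Evaluate an expression with a locally-scoped RNG seed
#'
#' All randomness in the package flows through this helper so that the
#' caller's RNG state is never disturbed and identical seeds give
#' bit-identical results.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @noRd
with_seed_ <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Deterministically derive a child seed from a master seed and a stream
# label; keeps every derived seed inside 32-bit integer range.
derive_seed <- function(master, ...) {
  label <- paste(c(master, ...), collapse = "/")
  bytes <- utf8ToInt(label)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  as.integer(h + 1L)
}

# %.17g formatting so numeric CSV round-trips are bit-exact.
format_full_precision <- function(x) {
  formatC(x, format = "g", digits = 17)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
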