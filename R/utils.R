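# Classed conditions used across the package.  Every user-facing failure mode
# carries a subclass so callers (and tests) can distinguish, e.g., a profile
# with no detectable vessel from a scan line that leaves the image.
stop_octfwhm <- function(msg, class) {
  abort(msg, class = c(paste0("octfwhm_error_", class), "octfwhm_error"))
}

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (finite && !is.finite(x)) || (positive && x <= 0)) {
    stop_octfwhm(
      sprintf("`%s` must be a single %sfinite number.",
              name, if (positive) "positive " else ""),
      "validation"
    )
  }
  invisible(x)
}

# Evaluate a thunk under a fixed RNG seed without disturbing the caller's RNG
# state; a NULL seed uses the current stream.
with_seed_or_current <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
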