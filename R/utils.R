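# internal helpers shared across modules

# leveled logging to stderr; silenced via options(hacoef.verbose = FALSE)
ha_log <- function(..., level = "INFO") {
  if (isFALSE(getOption("hacoef.verbose", TRUE))) return(invisible(NULL))
  message(sprintf("[hacoef %s] %s", level, paste0(...)))
}

# antiderivative of (y/x - 1): the closed form behind the area computations
ha_antideriv <- function(x, y) y * log(x) - x

# relative tie test among sorted means; scale-free so it survives rescaling
means_tied <- function(means, tol) {
  if (length(means) < 2L) return(FALSE)
  s <- sort(means)
  scale <- max(abs(s))
  if (scale == 0) return(TRUE)
  any(diff(s) <= tol * scale)
}

clamp01 <- function(x) pmin(1, pmax(0, x))
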