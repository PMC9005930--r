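# internal helpers shared across modules

#' Inverse logit
#' @param x numeric vector.
#' @return `1 / (1 + exp(-x))`, computed stably.
#' @keywords internal
invlogit <- function(x) {
  ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
}

# Deterministic fan-out of a master seed into sub-seeds.  Tags (strings or
# integers) are hashed into [0, 2^31 - 2] so that per-species / per-run /
# per-draw streams never collide by accident and stay valid R seeds.
fanout_seed <- function(master, ...) {
  tags <- list(...)
  h <- as.double(master) %% 2147483647
  for (tag in tags) {
    bytes <- if (is.character(tag)) utf8ToInt(tag) else as.integer(tag)
    for (b in bytes) h <- (h * 31 + (as.double(b) %% 2147483647)) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
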