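# Internal helpers: argument checking and deterministic seed sub-streams.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min ||
      x != round(x)) {
    stop_config(field, sprintf("must be a single integer >= %d", min))
  }
  as.integer(x)
}

check_positive <- function(x, field, strict = TRUE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop_config(field, if (strict) "must be a single value > 0" else
      "must be a single value >= 0")
  }
  as.numeric(x)
}

# Deterministic 31-bit sub-stream seed from a base seed and a key string.
# Keys hash through their characters so streams are stable when unrelated
# dimensions (e.g. the number of regions) change.
derive_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "\x1f")
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% m
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Sample standard deviation z-scoring; returns list(values, mean, sd).
zscore <- function(x) {
  m <- mean(x)
  s <- sd(x)
  list(values = if (s > 0) (x - m) / s else x - m, mean = m, sd = s)
}
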