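# Typed conditions so callers can distinguish recoverable feature failures
# (e.g. undefined correlation on constant texture) from genuine misuse.

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = c("stromatex_error_validation", "stromatex_error"), ...)
}

abort_io <- function(msg, ...) {
  rlang::abort(msg, class = c("stromatex_error_io", "stromatex_error"), ...)
}

abort_format <- function(msg, ...) {
  rlang::abort(msg, class = c("stromatex_error_format", "stromatex_error"), ...)
}

abort_undefined_feature <- function(msg, ...) {
  rlang::abort(msg, class = c("stromatex_error_undefined_feature", "stromatex_error"), ...)
}

abort_placement <- function(msg, ...) {
  rlang::abort(msg, class = c("stromatex_error_placement", "stromatex_error"), ...)
}

abort_config <- function(msg, ...) {
  rlang::abort(msg, class = c("stromatex_error_config", "stromatex_error"), ...)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random number stream.
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministically mix a base seed with stage/index integers; stays below
# 2^31 so the result is always a valid set.seed() argument.
derive_seed <- function(seed, ...) {
  m <- 2147483647
  s <- abs(as.numeric(seed)) %% m
  for (k in c(...)) {
    s <- (s * 48271 + abs(as.numeric(k)) + 1) %% m
  }
  as.integer(s)
}
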