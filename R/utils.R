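# internal helpers shared across modules

# round-half-up per element (round() in R rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# stable integer seed derived from a base seed and a stage name, < 2^31
stage_seed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 1000003L
  as.integer((as.numeric(seed) %% 2147481563 + h) %% 2147483647)
}

assert_array3 <- function(x, name = "volume") {
  if (!is.array(x) || length(dim(x)) != 3L)
    stopf("%s must be a 3D array", name)
  invisible(x)
}
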