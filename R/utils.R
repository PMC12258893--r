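# Internal helpers: deterministic stream splitting and scoped RNG use.

# Polynomial hash of a key vector onto [0, 2^31 - 20).  Used to derive
# independent-looking sub-seeds for per-group random number streams, so that
# editing one arm of a simulated design never perturbs the draws of another.
split_seed <- function(...) {
  key <- paste(unlist(list(...)), collapse = "\x1f")
  bytes <- utf8ToInt(key)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  as.integer(h)
}

# Evaluate `code` under `seed` and restore the caller's RNG state afterwards.
local_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
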