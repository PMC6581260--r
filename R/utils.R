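# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. All package randomness flows through this.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Deterministic 31-bit seed from a master seed plus arbitrary labels, so that
# per-cell restart draws do not depend on subject ordering.
derive_seed <- function(seed, ...) {
  h <- as.double(seed %% 2147483647L)
  for (lab in list(...)) {
    for (v in utf8ToInt(paste0(as.character(lab), collapse = "|"))) {
      h <- (h * 31 + v) %% 2147483647
    }
  }
  as.integer(h %% 2147483646) + 1L
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

softmax_log <- function(logw) {
  w <- exp(logw - max(logw))
  w / sum(w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
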