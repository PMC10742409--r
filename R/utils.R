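# Shared plumbing: seed derivation and scoped RNG use.

#' Derive a stage-specific seed from a global seed
#'
#' One global run seed is expanded into independent per-stage seeds so each
#' pipeline stage (cohort draw, molecule sampling, band noise, replicate k)
#' is individually reproducible. The derivation is a fixed affine map modulo
#' the Mersenne prime 2^31 - 1, keeping results in valid integer-seed range.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label (or an integer replicate index).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  offset <- if (is.character(stage)) {
    sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  } else {
    as.double(stage) * 2654435761
  }
  m <- 2147483647
  s <- ((as.double(seed) %% m) * 48271 + (offset %% m)) %% m
  as.integer(s %% (m - 2) + 1)
}

# Evaluate code under a temporary seed, restoring the caller's RNG state.
# seed = NULL runs the code against the ambient RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Tiny FNV-1a hash of a deterministic text rendering of an R object; used to
# fingerprint run configurations in logs.
config_hash <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "keepInteger", "niceNames",
                                      "showAttributes")), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (as.double(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
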