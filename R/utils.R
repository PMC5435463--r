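# Internal utilities: reproducible per-cell seed streams and provenance.

# FNV-1a 32-bit hash of a character string, folded into [0, 2^31 - 1].
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(enc2utf8(s))) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    # 16777619 * h mod 2^32, kept in double precision
    h <- (h * 16777619) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

#' Derive a stable per-entity random seed from a global seed
#'
#' All randomness in the synthetic generator flows from one global seed;
#' per-cell streams are derived by stable hashing of `(seed, key)` so that
#' adding or removing one cell does not perturb the draws of the others.
#'
#' @param seed Integer global seed.
#' @param key Character key (for example a cell id).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
stable_seed <- function(seed, key) {
  as.integer((fnv1a32(paste0(key, ":", seed)) + as.numeric(seed)) %% 2147483647)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Short stable hash of an R object (via its canonical JSON), for provenance.
# Output location is not part of a run's scientific identity.
config_hash <- function(x) {
  x$out_dir <- NULL
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                        force = TRUE)
  sprintf("%08x", fnv1a32(as.character(s)))
}

provenance_line <- function(config) {
  sprintf("t4connectome provenance: seed=%s config=%s",
          as.character(config$seed %||% NA), config_hash(config))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
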