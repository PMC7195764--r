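#' Derive independent child seeds from a master seed
#'
#' All randomized stages take explicit integer seeds.  To keep runs
#' reproducible while avoiding accidental stream reuse, child seeds are
#' drawn from a generator seeded with the master seed; the i-th child is
#' the same regardless of how many children are requested later.
#'
#' @param master_seed single integer.
#' @param n number of child seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seeds(1, 3)
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run expr with a locally-seeded RNG, restoring the caller's stream after.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("ascoh_invalid_argument", "error")))
}

stop_insufficient <- function(...) {
  stop(errorCondition(paste0(...), class = c("ascoh_insufficient_data", "error")))
}

stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("ascoh_degenerate_signal", "error")))
}

# 32-bit FNV-1a over the deparsed object; provenance stamp for outputs.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256                       # b < 256: xor touches low byte only
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply in two 16-bit halves (doubles lose bits past 2^53)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
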