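#' Derive a stage-specific child seed from a global seed
#'
#' One user-facing seed fans out deterministically to per-stage seeds so that
#' stages (simulation, initialization, fold assignment, permutation draws) are
#' isolated from each other while the whole run stays reproducible.
#'
#' @param seed Integer global seed.
#' @param stage Character tag naming the consumer stage.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(stage) == 1L)
  # cheap string hash (djb2 variant) folded with the seed; kept below 2^31
  h <- 5381
  for (ch in utf8ToInt(as.character(stage))) {
    h <- (h * 33 + ch) %% 2147483647
  }
  as.integer((abs(as.numeric(seed)) * 2654435761 + h) %% 2147483646)
}

# run expr with a local RNG state seeded by `seed` (restores caller's state)
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

frob <- function(m) sqrt(sum(m^2))

# largest singular value; 0 for an all-zero or empty matrix
spectral_norm <- function(m) {
  if (length(m) == 0L || all(m == 0)) {
    return(0)
  }
  svd(m, nu = 0L, nv = 0L)$d[1L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
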