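# Seeded, isolated RNG helpers.
#
# Every source of randomness in the package (direction field, connectivity
# draws, patch selection, external noise per run) is attributed to a named
# seed.  `local_rng` switches .Random.seed to a private state and returns a
# restore function, so seeded package code never disturbs the caller's RNG.

local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Derive a named sub-seed from a master seed
#'
#' Deterministically maps `(master_seed, label)` to an integer seed below
#' 2^31, so that independent randomness sources (connectivity, direction
#' field, per-run noise, patch selection) get independent, reproducible
#' streams from one experiment seed.
#'
#' @param master_seed integer master seed.
#' @param label character stream label, e.g. `"noise"`; an optional `index`
#'   distinguishes repeats (noise realization 1..S).
#' @param index integer, default 0.
#' @return integer seed.
#' @export
derive_seed <- function(master_seed, label, index = 0L) {
  h <- as.double(master_seed %% 2147483647L)
  for (ch in utf8ToInt(paste0(label, ":", index))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("`", name, "` must be a single finite number")
  if (positive && x <= 0) stop("`", name, "` must be > 0")
  invisible(x)
}
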