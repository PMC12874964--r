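#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom tibble as_tibble
NULL

#' @export
tibble::as_tibble

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Keeps every generator a pure function of (parameters, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic fan-out of a master seed into per-component sub-seeds.
# Documented scheme: sub_seed(seed, i) = (seed * 7919 + i * 104729) mod (2^31 - 1),
# kept strictly positive so it is always a valid 32-bit seed.
sub_seed <- function(seed, i) {
  m <- 2^31 - 1
  s <- (as.numeric(seed) %% m) * 7919 + as.numeric(i) * 104729
  as.integer(s %% m) + 1L
}

`%||%` <- function(x, y) if (is.null(x)) y else x
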