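# Internal helpers shared across modules.

# Round half away from zero. base::round() rounds half to even, which would
# treat too-easy and too-hard staircase overshoots asymmetrically.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

clamp <- function(x, lo, hi) {
  if (length(x) == 1L) max(lo, min(x, hi)) else pmin(pmax(x, lo), hi)
}

#' Derive a reproducible sub-stream seed
#'
#' Maps a master seed plus a named stream (e.g. one participant's thresholding
#' phase) to an integer seed below 2^31, so that every stage of a run draws
#' from its own stream and one participant's trial count cannot perturb
#' another's random numbers.
#'
#' @param master Integer master seed.
#' @param stream Character scalar naming the stream.
#' @return A single integer seed in `[0, 2^31 - 1]`.
#' @export
#' @examples
#' derive_seed(1, "p01/threshold")
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stream))
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(stream)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

with_stream_seed <- function(master, stream, code) {
  if (is.null(master)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(derive_seed(master, stream))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
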