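#' Build a 49-level difficulty ladder
#'
#' The two trained tasks are made harder or easier along fixed 49-level
#' ladders. For visuomotor tracking the difficulty parameter is the target's
#' speed (dps, degrees of visual angle per second as displayed); higher levels
#' are faster. Speeds rise in 0.0040 steps from 0.0100 (level 1) to 0.0820
#' (level 19) and in 0.0010 steps thereafter, reaching 0.1120 at level 49.
#' For shape discrimination the parameter is the response window (ms) within
#' which a key press counts; higher levels give less time. Windows shrink in
#' 25 ms steps from 1000 ms (level 1) to 550 ms (level 19) and in 10 ms steps
#' down to 250 ms (level 49).
#'
#' @param kind `"tracking_speed"` or `"rt_window"`.
#' @return A tibble with class `difficulty_ladder` and columns `level`
#'   (1..49) and `value` (dps or ms); the kind is stored as an attribute and
#'   retrievable with [ladder_kind()].
#' @export
#' @examples
#' build_ladder("tracking_speed")
#' ladder_value(build_ladder("rt_window"), 29)  # 450 ms start window
build_ladder <- function(kind = c("tracking_speed", "rt_window")) {
  kind <- match.arg(kind)
  cached <- .ladder_cache[[kind]]
  if (!is.null(cached)) return(cached)
  value <- if (kind == "tracking_speed") {
    c(0.0100 + 0.0040 * 0:18, 0.0820 + 0.0010 * 1:30)
  } else {
    c(1000 - 25 * 0:18, 550 - 10 * 1:30)
  }
  ladder <- tibble::tibble(level = 1:49, value = value)
  attr(ladder, "kind") <- kind
  class(ladder) <- c("difficulty_ladder", class(ladder))
  .ladder_cache[[kind]] <- ladder
  ladder
}

# ladders are deterministic constants; memoise them
.ladder_cache <- new.env(parent = emptyenv())

#' @rdname build_ladder
#' @export
ladder_kind <- function(ladder) {
  stopifnot(inherits(ladder, "difficulty_ladder"))
  attr(ladder, "kind")
}

#' @rdname build_ladder
#' @param ladder A `difficulty_ladder`.
#' @param level Integer level(s) in 1..49.
#' @export
ladder_value <- function(ladder, level) {
  stopifnot(inherits(ladder, "difficulty_ladder"))
  if (any(level < 1 | level > 49 | level != floor(level))) {
    stop("ladder levels must be integers in 1..49", call. = FALSE)
  }
  ladder$value[level]
}

#' Read or write a ladder as CSV
#'
#' Serializes a ladder to a plain `level,value,kind` table so generated
#' configurations can be inspected outside R.
#'
#' @param ladder A `difficulty_ladder`.
#' @param path File path.
#' @return `write_ladder_csv()` returns `path` invisibly; `read_ladder_csv()`
#'   returns a `difficulty_ladder`.
#' @export
write_ladder_csv <- function(ladder, path) {
  stopifnot(inherits(ladder, "difficulty_ladder"))
  df <- data.frame(level = ladder$level, value = ladder$value,
                   kind = ladder_kind(ladder))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ladder_csv
#' @export
read_ladder_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("level", "value", "kind") %in% names(df)))
  kind <- unique(df$kind)
  if (length(kind) != 1) stop("ladder file mixes kinds", call. = FALSE)
  ladder <- tibble::tibble(level = as.integer(df$level), value = df$value)
  attr(ladder, "kind") <- kind
  class(ladder) <- c("difficulty_ladder", class(ladder))
  validate_ladder(ladder)
  ladder
}

# Invariant checks: 49 gap-free levels, monotone values, exact step structure.
validate_ladder <- function(ladder) {
  stopifnot(nrow(ladder) == 49, identical(as.integer(ladder$level), 1:49))
  kind <- ladder_kind(ladder)
  steps <- diff(ladder$value)
  if (kind == "tracking_speed") {
    stopifnot(all(steps > 0))
    stopifnot(all(abs(steps[1:18] - 0.0040) < 1e-12),
              all(abs(steps[19:48] - 0.0010) < 1e-12))
  } else if (kind == "rt_window") {
    stopifnot(all(steps < 0))
    stopifnot(all(steps[1:18] == -25), all(steps[19:48] == -10))
  } else {
    stop("unknown ladder kind: ", kind, call. = FALSE)
  }
  invisible(ladder)
}
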