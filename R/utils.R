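`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's random number
#' generator state afterwards, so seeded helpers do not perturb the global
#' stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Parse a numeric range expression
#'
#' Parses `start:stop[:step]` segments joined by commas into a sorted unique
#' numeric vector, e.g. `"1:200,210:860:10"`.
#'
#' @param text Range expression.
#' @return Sorted numeric vector.
#' @export
#' @examples
#' parse_range("1:5")
#' parse_range("1:200,210:260:10")
parse_range <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  parts <- strsplit(text, ",", fixed = TRUE)[[1]]
  vals <- unlist(lapply(parts, function(p) {
    f <- suppressWarnings(as.numeric(strsplit(p, ":", fixed = TRUE)[[1]]))
    if (any(is.na(f)) || length(f) < 1L || length(f) > 3L)
      stop("cannot parse range segment '", p, "'", call. = FALSE)
    if (length(f) == 1L) return(f)
    step <- if (length(f) == 3L) f[3] else 1
    if (step <= 0) stop("range step must be positive in '", p, "'", call. = FALSE)
    seq(f[1], f[2], by = step)
  }))
  if (length(vals) == 0L) stop("empty range expression", call. = FALSE)
  sort(unique(vals))
}
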