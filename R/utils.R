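#' Clip values to the unit interval
#'
#' Images are represented on \[0, 1\] throughout the package; this clips
#' out-of-range values at export boundaries.
#' @param x numeric vector or array.
#' @export
clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded operations never perturb the global random stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# dimension helpers -----------------------------------------------------------

img_dim <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected a matrix or array image")
  d
}

n_channels <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) 1L else d[3L]
}

stopifnot_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s must have identical dimensions (%s vs %s)", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
}

#' Relative luminance of an RGB image
#'
#' Rec. 601 luma of an `[H, W, 3]` array in `[0, 1]`.
#' @param rgb RGB array.
#' @return Matrix of luminance values.
#' @export
luminance <- function(rgb) {
  if (length(dim(rgb)) == 2L) return(rgb)
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

# trapezoidal integral over an ordered grid
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)
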