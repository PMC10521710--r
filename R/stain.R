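#' Overlapping tile grid over a whole-slide image
#'
#' Tiles of `tile_size` pixels on a regular grid with the given overlap;
#' the last row/column is shifted flush with the image border so the grid
#' always covers the full extent.
#'
#' @param wsi_shape (height, width) in pixels.
#' @param tile_size tile side (pixels).
#' @param overlap overlap between neighbouring tiles (pixels).
#' @return List of class `tile_grid`: `origins` (0-based (row, col) matrix),
#'   `tile_size`, `overlap`, `wsi_shape`.
#' @export
tile_grid <- function(wsi_shape, tile_size = 512L, overlap = 64L) {
  H <- wsi_shape[1]; W <- wsi_shape[2]
  if (overlap >= tile_size) stop("overlap must be smaller than tile_size")
  if (tile_size > H || tile_size > W) stop("tile_size exceeds image")
  axis_origins <- function(L) {
    step <- tile_size - overlap
    o <- seq(0L, max(L - tile_size, 0L), by = step)
    if (o[length(o)] + tile_size < L) o <- c(o, L - tile_size)
    as.integer(o)
  }
  or <- axis_origins(H); oc <- axis_origins(W)
  origins <- as.matrix(expand.grid(row = or, col = oc))
  structure(list(origins = origins, tile_size = as.integer(tile_size),
                 overlap = as.integer(overlap),
                 wsi_shape = as.integer(c(H, W))), class = "tile_grid")
}

#' Stitching configuration
#'
#' Feathered blending uses a raised-cosine ramp over the overlap region on
#' every tile edge that has a neighbouring tile; per-pixel weights are
#' normalised so contributions always sum to one.
#' @param blend "feather" (cosine ramp) or "average" (uniform).
#' @param overlap overlap in pixels.
#' @export
stitch_config <- function(blend = c("feather", "average"), overlap = 64L) {
  structure(list(blend = match.arg(blend), overlap = as.integer(overlap)),
            class = "stitch_config")
}

# weight profile along one axis of a tile
ramp_profile <- function(n, v, ramp_lo, ramp_hi, blend) {
  w <- rep(1, n)
  if (blend == "average" || v <= 0) return(pmax(w, 1e-6))
  r <- 0.5 - 0.5 * cos(pi * (seq_len(v) - 0.5) / v)
  if (ramp_lo) w[seq_len(v)] <- r
  if (ramp_hi) w[n - seq_len(v) + 1L] <- r
  pmax(w, 1e-6)
}

#' Tile-wise virtual staining of a whole-slide image
#'
#' Runs the generator on overlapping tiles and reassembles a seamless
#' whole-slide output with feathered (raised-cosine) blending in the
#' overlaps; output values are clipped to `[0, 1]`.
#'
#' @param af_wsi `[H, W, 4]` autofluorescence WSI (or any channel count the
#'   model accepts).
#' @param model a `vstain_generator`, a `virtual_stainer`, or a plain
#'   function mapping an AF tile to an RGB tile (useful for stubs).
#' @param grid a [tile_grid()]; defaults to 512-pixel tiles with the
#'   stitch overlap.
#' @param stitch a [stitch_config()].
#' @param normalize apply the model's stored AF normalisation (only for
#'   `virtual_stainer` input).
#' @return `[H, W, 3]` stained WSI.
#' @export
stain_wsi <- function(af_wsi, model, grid = NULL,
                      stitch = stitch_config(), normalize = TRUE) {
  d <- dim(af_wsi)
  if (inherits(model, "virtual_stainer")) {
    if (normalize) af_wsi <- apply_af_norm(af_wsi, model$norm)
    model <- model$generator
  }
  infer <- if (is.function(model)) model
  else {
    if (d[3] != model$cfg$in_channels)
      stop(sprintf("WSI has %d channels; model expects %d", d[3],
                   model$cfg$in_channels))
    function(tile) generator_forward(model, tile)
  }
  if (is.null(grid))
    grid <- tile_grid(d[1:2], min(512L, 16L * (min(d[1:2]) %/% 16L)),
                      stitch$overlap)
  ts <- grid$tile_size
  if (!is.function(model) && ts %% 16L != 0L)
    stop("tile size must be divisible by 16")
  out <- array(0, c(d[1], d[2], 3L))
  wsum <- matrix(0, d[1], d[2])
  v <- grid$overlap
  for (k in seq_len(nrow(grid$origins))) {
    r0 <- grid$origins[k, 1]; c0 <- grid$origins[k, 2]
    rows <- (r0 + 1L):(r0 + ts); cols <- (c0 + 1L):(c0 + ts)
    tile <- af_wsi[rows, cols, , drop = FALSE]
    pred <- infer(tile)
    wr <- ramp_profile(ts, v, r0 > 0L, r0 + ts < d[1], stitch$blend)
    wc <- ramp_profile(ts, v, c0 > 0L, c0 + ts < d[2], stitch$blend)
    w <- outer(wr, wc)
    for (ch in 1:3)
      out[rows, cols, ch] <- out[rows, cols, ch] + w * pred[, , ch]
    wsum[rows, cols] <- wsum[rows, cols] + w
  }
  for (ch in 1:3) out[, , ch] <- out[, , ch] / wsum
  clamp01(out)
}
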