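# Image and table I/O. All images live in [0, 1] internally with 0-based
# (row, col) pixel coordinates; AF stacks are multi-page TIFFs in channel
# order DAPI, FITC, TxRed, Cy5.

#' Read / write a 4-channel autofluorescence stack as a multi-page TIFF
#'
#' Pages are the channels, in the order DAPI, FITC, TxRed, Cy5.
#' @param path TIFF path.
#' @export
read_af_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  af <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    af[, , i] <- if (length(dim(p)) == 3L) p[, , 1] else p
  }
  dimnames(af) <- list(NULL, NULL,
                       c("DAPI", "FITC", "TxRed", "Cy5")[seq_along(pages)])
  af
}

#' @rdname read_af_tiff
#' @param af `[H, W, 4]` array in `[0, 1]`.
#' @export
write_af_tiff <- function(af, path) {
  pages <- lapply(seq_len(dim(af)[3]), function(i) clamp01(af[, , i]))
  tiff::writeTIFF(pages, path)
  invisible(path)
}

#' Read / write an RGB brightfield image (TIFF or PNG)
#' @param path image path; format chosen by extension.
#' @export
read_rgb <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3L && dim(img)[3] > 3L) img <- img[, , 1:3]
  img
}

#' @rdname read_rgb
#' @param rgb `[H, W, 3]` array in `[0, 1]`.
#' @export
write_rgb <- function(rgb, path) {
  rgb <- clamp01(rgb)
  if (grepl("\\.png$", path, ignore.case = TRUE)) png::writePNG(rgb, path)
  else tiff::writeTIFF(rgb, path)
  invisible(path)
}

#' Write a per-tile metrics report as JSON
#'
#' Serialises nucleus statistics, characteristic curves and quality
#' metrics (any list of vstain metric objects) into one JSON document.
#' @param report named list of metric objects.
#' @param path output path.
#' @export
write_metrics_json <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, c("nucleus_stats"))) x$segmentation <- NULL
    if (is.list(x)) x <- lapply(x, strip)
    x
  }
  jsonlite::write_json(strip(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' One nested list with a section per stage (synth, register, network,
#' train, stain, metrics, stats) carrying every tunable default; can be
#' written to / read from YAML for the command-line tools.
#' @export
vstain_config <- function() {
  list(
    synth = list(tile = 256L, cells_per_kpx = 0.9, min_separation = 20,
                 nucleus_radius = c(4, 7), membrane_gap = 2.5,
                 af_noise_sd = 0.02, poisson_noise = FALSE, hema_od = 0.7),
    register = list(tile_size = 1024L, levels = 3L, block_size = 256L,
                    search_radius = 16L, ncc_min = 0.3, smooth_bound = 1,
                    max_rounds = 5L, tol = 0.5, ncc_clean = 0.5,
                    tissue_clean = 0.1),
    network = list(scale = 1L, leaky_slope = 0.1, fc_hidden = 512L,
                   alpha = 10, lambda = 0.2, gamma = 0.5, beta = 1,
                   c1 = 1e-4, c2 = 9e-4),
    train = list(crop = 256L, batch = 28L, lr_g = 1e-4, lr_d = 1e-5,
                 weight_decay = 1e-5, g_d_ratio = c(2L, 1L),
                 gamma_warmup = 0L, adaptive_adv = FALSE,
                 fractions = c(0.8, 0.1, 0.1), checkpoint_every = 100L),
    stain = list(tile = 512L, overlap = 64L, blend = "feather",
                 norm_probs = c(0.001, 0.999)),
    metrics = list(s_grid = seq(0.10, 0.50, by = 0.02), s_conn = 0.25,
                   morph_radius = 2L, min_area = 30L, psnr_cap = 100,
                   connectivity = 8L),
    stats = list(n_rois_per_wsi = 10L, roi_size = 8000L, alpha = 0.05))
}

#' @rdname vstain_config
#' @param config configuration list.
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname vstain_config
#' @export
read_config <- function(path) {
  utils::modifyList(vstain_config(), yaml::read_yaml(path))
}
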