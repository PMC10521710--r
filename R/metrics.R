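#' Default hematoxylin / DAB stain matrix
#'
#' Rows are unit optical-density vectors for hematoxylin (nucleus stain),
#' DAB (membrane stain) and a residual third stain taken as the normalised
#' cross product of the first two — the standard colour-deconvolution
#' conventions for HE/DAB slides.
#' @return 3x3 matrix with unit rows.
#' @export
default_stain_matrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.778)
  h <- h / sqrt(sum(h^2)); d <- d / sqrt(sum(d^2))
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  r <- r / sqrt(sum(r^2))
  m <- rbind(hematoxylin = h, dab = d, residual = r)
  colnames(m) <- c("r", "g", "b")
  m
}

#' Colour deconvolution of a brightfield IHC image
#'
#' Converts RGB transmittance to optical density, `OD = -log10(max(rgb, eps))`,
#' and unmixes per-pixel stain densities by inverting the stain matrix
#' (Beer-Lambert model). Negative densities are clipped to zero.
#'
#' @param rgb `[H, W, 3]` array in `[0, 1]`.
#' @param stain_matrix 3x3 matrix of unit stain OD row vectors.
#' @param eps transmittance floor avoiding `log(0)`.
#' @return List of class `stain_separation` with matrices `hematoxylin_od`,
#'   `dab_od`, `residual_od` and the `stain_matrix`.
#' @export
separate_stains <- function(rgb, stain_matrix = default_stain_matrix(),
                            eps = 1e-6) {
  d <- img_dim(rgb)
  if (length(d) != 3L || d[3] != 3L) stop("rgb must be an [H, W, 3] array")
  if (abs(det(stain_matrix)) < 1e-8) stop("stain matrix is singular")
  od <- -log10(pmax(rgb, eps))
  odm <- matrix(od, ncol = 3L)
  dens <- odm %*% solve(stain_matrix)   # od = dens %*% stain_matrix
  dens[dens < 0] <- 0
  structure(list(
    hematoxylin_od = matrix(dens[, 1], d[1], d[2]),
    dab_od = matrix(dens[, 2], d[1], d[2]),
    residual_od = matrix(dens[, 3], d[1], d[2]),
    stain_matrix = stain_matrix), class = "stain_separation")
}

#' Render an RGB image from stain densities (Beer-Lambert)
#'
#' Inverse of [separate_stains()]; used to reconstruct a single-stain image
#' (e.g. DAB only) for HSV-based membrane segmentation.
#' @param densities list or matrix-list with per-stain density maps; missing
#'   stains are treated as zero.
#' @param stain_matrix 3x3 matrix of unit stain OD row vectors.
#' @export
render_stains <- function(densities, stain_matrix = default_stain_matrix()) {
  nm <- rownames(stain_matrix)
  base <- densities[[1]]
  od <- array(0, c(dim(base), 3L))
  for (i in seq_along(nm)) {
    dmap <- densities[[nm[i]]]
    if (is.null(dmap)) next
    for (ch in 1:3) od[, , ch] <- od[, , ch] + dmap * stain_matrix[i, ch]
  }
  10^-od
}

#' Otsu threshold of a density image
#'
#' 256-bin Otsu threshold (maximum between-class variance) computed on the
#' image range. Errors on (near-)constant input where the threshold is
#' undefined.
#' @param x numeric matrix.
#' @param levels number of histogram bins.
#' @return Threshold on the scale of `x`.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  rng <- range(x)
  if (!is.finite(diff(rng)) || diff(rng) < 1e-9)
    stop("degenerate threshold: channel is constant, Otsu is undefined")
  xs <- (x - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(xs), range = c(0, 1), levels = levels)
  rng[1] + th * diff(rng)
}

#' Nucleus statistics from the hematoxylin channel
#'
#' Otsu threshold on the hematoxylin density, morphological opening with a
#' disk brush, removal of small components, then 8-connected component
#' counting.
#'
#' @param sep a `stain_separation` from [separate_stains()].
#' @param morph list with `radius` (opening disk radius, pixels) and
#'   `min_area` (smallest component kept, pixels).
#' @return List of class `nucleus_stats`: `count`, `mean_area`,
#'   `segmentation` (integer label image), `threshold`.
#' @export
nucleus_stats <- function(sep, morph = list(radius = 2, min_area = 30)) {
  h <- sep$hematoxylin_od
  th <- otsu_threshold(h)
  mask <- h > th
  if (morph$radius > 0) {
    brush <- EBImage::makeBrush(2L * morph$radius + 1L, shape = "disc")
    m <- EBImage::Image(mask * 1)
    mask <- EBImage::dilate(EBImage::erode(m, brush), brush) > 0.5
  }
  lab <- cpp_label_components(matrix(as.integer(mask), nrow(h)), 8L)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(areas >= morph$min_area)
    relabel <- integer(max(lab))
    relabel[keep] <- seq_along(keep)
    lab[lab > 0] <- relabel[lab[lab > 0]]
    areas <- areas[keep]
  } else areas <- numeric(0)
  structure(list(count = length(areas),
                 mean_area = if (length(areas)) mean(areas) else NA_real_,
                 segmentation = lab, threshold = th),
            class = "nucleus_stats")
}

#' Membrane characteristic curve, AUC and connectedness
#'
#' The separated DAB density is re-rendered as an RGB image (other stains
#' zeroed) and converted to HSV; for each threshold `s` the membrane mask is
#' `saturation > s` and the area ratio is the mask fraction of the full
#' field of view. The characteristic curve sweeps `s` from 0.10 to 0.50 in
#' steps of 0.02 (21 points); its trapezoidal integral is the AUC.
#' Connectedness is the area fraction of the largest 8-connected component
#' at `s = 0.25`.
#'
#' @param sep a `stain_separation`, or a saturation matrix (values in
#'   `[0, 1]`) to bypass the DAB re-rendering.
#' @param s_grid saturation thresholds.
#' @param s_conn threshold used for the connectedness measure.
#' @return List of class `characteristic_curve`: `s_values`, `area_ratio`,
#'   `auc`, `connectedness`.
#' @export
membrane_stats <- function(sep, s_grid = seq(0.10, 0.50, by = 0.02),
                           s_conn = 0.25) {
  if (length(s_grid) == 0) stop("s_grid must be non-empty")
  if (any(s_grid <= 0 | s_grid >= 1) || s_conn <= 0 || s_conn >= 1)
    stop("saturation thresholds must lie in (0, 1)")
  sat <- if (inherits(sep, "stain_separation")) {
    dab_rgb <- render_stains(list(dab = sep$dab_od), sep$stain_matrix)
    rgb_saturation(dab_rgb)
  } else sep
  n <- length(sat)
  area_ratio <- vapply(s_grid, function(s) sum(sat > s) / n, numeric(1))
  mask <- sat > s_conn
  conn <- 0
  if (any(mask)) {
    lab <- cpp_label_components(matrix(as.integer(mask), nrow(sat)), 8L)
    conn <- max(tabulate(lab[lab > 0], nbins = max(lab))) / n
  }
  structure(list(s_values = s_grid, area_ratio = area_ratio,
                 auc = trapz(s_grid, area_ratio), connectedness = conn),
            class = "characteristic_curve")
}

# HSV saturation of an [H, W, 3] array
rgb_saturation <- function(rgb) {
  m <- matrix(rgb, ncol = 3L)
  hsv <- grDevices::rgb2hsv(t(m), maxColorValue = 1)
  matrix(hsv[2, ], nrow(rgb), ncol(rgb))
}

#' Image quality metrics: PSNR, SSIM and SSIM of the DAB channel
#'
#' PSNR is `10*log10(1/MSE)` on the `[0, 1]` scale, capped for identical
#' images; SSIM uses the sliding-window mode (11x11 Gaussian window,
#' sigma 1.5); `ssim_dab` is the windowed SSIM of the colour-deconvolved DAB
#' density channels (clipped to `[0, 1]`), isolating membrane-stain
#' fidelity.
#'
#' @param virtual,target `[H, W, 3]` arrays in `[0, 1]`.
#' @param stain_matrix stain matrix for the DAB separation.
#' @param psnr_cap PSNR reported for identical images (dB).
#' @return List of class `quality_metrics`: `psnr`, `ssim`, `ssim_dab`.
#' @export
image_quality <- function(virtual, target,
                          stain_matrix = default_stain_matrix(),
                          psnr_cap = 100) {
  stopifnot_same_shape(virtual, target)
  mse <- mean((virtual - target)^2)
  psnr <- if (mse <= 10^(-psnr_cap / 10)) psnr_cap else 10 * log10(1 / mse)
  s <- ssim(virtual, target, mode = "window")
  dv <- clamp01(separate_stains(virtual, stain_matrix)$dab_od)
  dt <- clamp01(separate_stains(target, stain_matrix)$dab_od)
  sd_ <- ssim(dv, dt, mode = "window")
  structure(list(psnr = psnr, ssim = s, ssim_dab = sd_),
            class = "quality_metrics")
}

#' Normalised colour histogram of the separated stain channels
#'
#' Per stain channel: a histogram of pixel densities normalised by the total
#' pixel count (frequencies sum to 1), plus a Gaussian-kernel smoothed
#' profile renormalised to unit mass.
#'
#' @param sep a `stain_separation`.
#' @param bins number of histogram bins.
#' @param bandwidth Gaussian kernel bandwidth on the density scale.
#' @param range density range spanned by the bins.
#' @return Named list (hematoxylin, dab) of class-`color_histogram` lists
#'   with `bin_centers`, `raw_frequency`, `smoothed_profile`.
#' @export
color_histogram <- function(sep, bins = 64L, bandwidth = 0.02,
                            range = c(0, 1.5)) {
  if (bins < 2L) stop("bins must be >= 2")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  one <- function(x) {
    x <- pmin(pmax(x, range[1]), range[2])
    br <- seq(range[1], range[2], length.out = bins + 1L)
    centers <- (head(br, -1) + br[-1]) / 2
    counts <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), bins),
                       nbins = bins)
    freq <- counts / length(x)
    k <- stats::dnorm(outer(centers, centers, `-`), sd = bandwidth)
    sm <- as.numeric(k %*% freq)
    sm <- sm / sum(sm)
    structure(list(bin_centers = centers, raw_frequency = freq,
                   smoothed_profile = sm), class = "color_histogram")
  }
  list(hematoxylin = one(sep$hematoxylin_od), dab = one(sep$dab_od))
}
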