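# Cross-modality registration: global feature-based alignment, tile
# pairing, and style-bridge assisted pyramid elastic registration.

#' Representative channels for cross-modality feature matching
#'
#' The autofluorescence stack is represented by its DAPI channel; a
#' brightfield image by its inverted luminance, so tissue is bright in both.
#' @param af `[H, W, 4]` AF stack.
#' @param rgb `[H, W, 3]` brightfield image.
#' @export
af_reference_channel <- function(af) af[, , 1]

#' @rdname af_reference_channel
#' @export
bf_reference_channel <- function(rgb) 1 - luminance(rgb)

# determinant-of-Hessian blob keypoints over a small scale stack
doh_keypoints <- function(img, sigmas = c(2, 4, 8), thresh_rel = 0.05,
                          max_keypoints = 400L) {
  H <- nrow(img); W <- ncol(img)
  kps <- NULL
  for (s in sigmas) {
    L <- cpp_gauss_blur(img, s)
    sh <- function(dr, dc) {
      r <- pmin(pmax(seq_len(H) + dr, 1L), H)
      c_ <- pmin(pmax(seq_len(W) + dc, 1L), W)
      L[r, c_]
    }
    Lxx <- sh(1, 0) + sh(-1, 0) - 2 * L
    Lyy <- sh(0, 1) + sh(0, -1) - 2 * L
    Lxy <- (sh(1, 1) + sh(-1, -1) - sh(1, -1) - sh(-1, 1)) / 4
    resp <- s^4 * (Lxx * Lyy - Lxy^2)
    # 3x3 local maxima above threshold
    mx <- resp
    for (dr in -1:1) for (dc in -1:1)
      if (dr || dc) mx <- pmax(mx, sh2 <- {
        r <- pmin(pmax(seq_len(H) + dr, 1L), H)
        c_ <- pmin(pmax(seq_len(W) + dc, 1L), W)
        resp[r, c_]
      })
    th <- max(thresh_rel * max(resp), 1e-8)
    sel <- which(resp >= mx & resp > th, arr.ind = TRUE)
    # keep away from borders so descriptors fit
    margin <- ceiling(6 * s) + 1
    keep <- sel[, 1] > margin & sel[, 1] <= H - margin &
      sel[, 2] > margin & sel[, 2] <= W - margin
    sel <- sel[keep, , drop = FALSE]
    if (nrow(sel))
      kps <- rbind(kps, cbind(sel, sigma = s,
                              resp = resp[sel]))
  }
  if (is.null(kps) || nrow(kps) == 0L) return(NULL)
  kps <- kps[order(-kps[, "resp"]), , drop = FALSE]
  utils::head(kps, max_keypoints)
}

# bilinear sampling of scattered points
sample_bilinear <- function(img, rs, cs) {
  H <- nrow(img); W <- ncol(img)
  rs <- pmin(pmax(rs, 1), H); cs <- pmin(pmax(cs, 1), W)
  r0 <- pmin(floor(rs), H - 1); c0 <- pmin(floor(cs), W - 1)
  tr <- rs - r0; tc <- cs - c0
  i <- function(r, c) img[cbind(r, c)]
  (1 - tr) * (1 - tc) * i(r0, c0) + tr * (1 - tc) * i(r0 + 1, c0) +
    (1 - tr) * tc * i(r0, c0 + 1) + tr * tc * i(r0 + 1, c0 + 1)
}

# normalised intensity-patch descriptors at keypoint scale
patch_descriptors <- function(img, kps, grid = 11L) {
  if (is.null(kps)) return(NULL)
  offs <- seq(-1, 1, length.out = grid)
  desc <- matrix(0, nrow(kps), grid * grid)
  for (i in seq_len(nrow(kps))) {
    s <- kps[i, "sigma"]
    L <- if (i == 1 || kps[i, "sigma"] != kps[i - 1, "sigma"])
      cpp_gauss_blur(img, s / 2) else L
    half <- 5 * s
    g <- expand.grid(dr = offs * half, dc = offs * half)
    v <- sample_bilinear(L, kps[i, 1] + g$dr, kps[i, 2] + g$dc)
    v <- v - mean(v)
    n <- sqrt(sum(v^2))
    desc[i, ] <- if (n > 1e-12) v / n else v
  }
  desc
}

#' Global feature-based registration of two single-channel images
#'
#' Detects determinant-of-Hessian blob keypoints at several scales,
#' matches normalised patch descriptors (mutual nearest neighbour with a
#' ratio test), and estimates a similarity transform by RANSAC with a
#' least-squares refit on the inliers.
#'
#' @param moving,fixed single-channel images (use
#'   [af_reference_channel()] / [bf_reference_channel()] to extract them).
#' @param detector list of detector/matcher parameters: `sigmas`,
#'   `thresh_rel`, `max_keypoints`, `ratio`, `ransac_iter`, `inlier_tol`
#'   (pixels), `min_inliers`.
#' @return List of class `affine_transform`: `matrix` (2x3, maps moving
#'   (row, col, 1) to fixed coordinates), `inlier_count`, `residual`
#'   (RMS pixels over inliers).
#' @export
global_register <- function(moving, fixed, detector = list()) {
  p <- utils::modifyList(list(sigmas = c(2, 4, 8), thresh_rel = 0.05,
                              max_keypoints = 400L, ratio = 0.85,
                              ransac_iter = 600L, inlier_tol = 3,
                              min_inliers = 3L, seed = 0L), detector)
  kp_m <- doh_keypoints(moving, p$sigmas, p$thresh_rel, p$max_keypoints)
  kp_f <- doh_keypoints(fixed, p$sigmas, p$thresh_rel, p$max_keypoints)
  if (is.null(kp_m) || is.null(kp_f))
    stop("registration failure: insufficient features detected")
  dm <- patch_descriptors(moving, kp_m)
  df <- patch_descriptors(fixed, kp_f)
  sim <- dm %*% t(df)                       # cosine similarity
  d2 <- pmax(2 - 2 * sim, 0)                # squared distance
  best <- apply(d2, 1, which.min)
  bd <- d2[cbind(seq_len(nrow(d2)), best)]
  second <- apply(d2, 1, function(r) sort(r, partial = 2)[2])
  mutual <- apply(d2, 2, which.min)[best] == seq_len(nrow(d2))
  ok <- mutual & sqrt(bd) < p$ratio * sqrt(pmax(second, 1e-12))
  if (sum(ok) < 2L)
    stop("registration failure: fewer than 2 descriptor matches")
  zm <- complex(real = kp_m[ok, 1], imaginary = kp_m[ok, 2])
  zf <- complex(real = kp_f[best[ok], 1], imaginary = kp_f[best[ok], 2])

  n <- length(zm)
  best_inl <- logical(0)
  with_seed(p$seed, {
    for (it in seq_len(p$ransac_iter)) {
      i <- sample.int(n, 2L)
      dz <- zm[i[1]] - zm[i[2]]
      if (Mod(dz) < 1e-9) next
      a <- (zf[i[1]] - zf[i[2]]) / dz
      b <- zf[i[1]] - a * zm[i[1]]
      err <- Mod(a * zm + b - zf)
      inl <- err < p$inlier_tol
      if (sum(inl) > sum(best_inl)) best_inl <- inl
    }
  })
  if (sum(best_inl) < p$min_inliers)
    stop("registration failure: fewer than ", p$min_inliers,
         " inlier matches")
  # least-squares similarity refit on the inliers
  zmi <- zm[best_inl]; zfi <- zf[best_inl]
  a <- sum(Conj(zmi - mean(zmi)) * (zfi - mean(zfi))) /
    sum(Mod(zmi - mean(zmi))^2)
  b <- mean(zfi) - a * mean(zmi)
  res <- sqrt(mean(Mod(a * zmi + b - zfi)^2))
  m <- rbind(c(Re(a), -Im(a), Re(b)),
             c(Im(a),  Re(a), Im(b)))
  structure(list(matrix = m, inlier_count = sum(best_inl), residual = res),
            class = "affine_transform")
}

#' Resample an image into the fixed frame of an affine transform
#'
#' Builds the pull-back displacement field of the inverse transform and
#' warps the moving image so it aligns with the fixed image.
#' @param img moving image (matrix or `[H, W, C]`).
#' @param tf an `affine_transform` from [global_register()].
#' @param shape output (height, width); defaults to the input size.
#' @export
apply_affine <- function(img, tf, shape = dim(img)[1:2]) {
  A <- rbind(tf$matrix, c(0, 0, 1))
  Ai <- solve(A)
  H <- shape[1]; W <- shape[2]
  r <- matrix(0:(H - 1), H, W)
  c_ <- matrix(0:(W - 1), H, W, byrow = TRUE)
  dr <- Ai[1, 1] * r + Ai[1, 2] * c_ + Ai[1, 3] - r
  dc <- Ai[2, 1] * r + Ai[2, 2] * c_ + Ai[2, 3] - c_
  warp_image(img, deformation_field(dr, dc))
}

#' Crop a globally aligned WSI pair into co-located tile pairs
#'
#' Regular grid of `tile_size` tiles at the given stride; partial border
#' tiles are dropped. Tiles below `min_tissue_frac` tissue content (judged
#' on the brightfield member: luminance < 0.95) are skipped.
#'
#' @param moving_aligned aligned AF WSI (`[H, W, C]`).
#' @param fixed brightfield WSI (`[H, W, 3]`).
#' @param tile_size tile side in pixels (1024 at full scale).
#' @param stride grid stride; defaults to `tile_size` (non-overlapping).
#' @param min_tissue_frac minimum tissue fraction to keep a pair.
#' @return Named list of tile pairs: `af`, `ihc`, `origin` (0-based),
#'   `clean`, `registration_residual` (NA until elastic registration).
#' @export
crop_tile_pairs <- function(moving_aligned, fixed, tile_size = 1024L,
                            stride = tile_size, min_tissue_frac = 0) {
  dm <- dim(moving_aligned); df_ <- dim(fixed)
  if (tile_size > dm[1] || tile_size > dm[2])
    stop("tile_size exceeds WSI dimensions")
  pairs <- list()
  for (r0 in seq(0L, dm[1] - tile_size, by = stride))
    for (c0 in seq(0L, dm[2] - tile_size, by = stride)) {
      rows <- (r0 + 1L):(r0 + tile_size); cols <- (c0 + 1L):(c0 + tile_size)
      ihc <- fixed[rows, cols, , drop = FALSE]
      if (min_tissue_frac > 0 &&
          mean(luminance(ihc) < 0.95) < min_tissue_frac) next
      id <- sprintf("r%06d_c%06d", r0, c0)
      pairs[[id]] <- list(
        af = moving_aligned[rows, cols, , drop = FALSE], ihc = ihc,
        origin = c(r0, c0), clean = TRUE, registration_residual = NA_real_)
    }
  pairs
}

#' Pyramid elastic registration by block-wise normalised cross-correlation
#'
#' Coarse-to-fine block matching: at each pyramid level the best NCC shift
#' of each block (with 50% overlap) gives a sparse displacement estimate;
#' flat or unreliable blocks are imputed from their neighbours; the sparse
#' field is interpolated to a dense field, Gaussian-smoothed, and composed
#' across levels, with one extra refinement pass at the finest level.  The
#' returned field warps `target` onto the geometry of `reference`
#' (pull-back convention, see [warp_image()]).
#'
#' @param reference image to match (e.g. a style-bridge output); matrix or
#'   RGB array (luminance is used for matching).
#' @param target image to be warped; same size.
#' @param levels pyramid levels (scale factors `2^(levels-1) ... 1`).
#' @param block_size block side in pixels at full resolution.
#' @param search_radius NCC search extent at full resolution (pixels); each
#'   pyramid level searches `ceiling(search_radius / factor) + 1` so coarse
#'   levels cannot alias onto neighbouring texture.
#' @param ncc_min minimum NCC for a block estimate to be trusted.
#' @param smooth_bound maximum allowed local field gradient; extra
#'   smoothing passes are applied until satisfied. The default (1 px/px)
#'   guarantees the warp cannot fold over.
#' @return A [deformation_field()] with attributes `residual_median`
#'   (median block displacement magnitude of the final pass, pixels) and
#'   `smoothness` (max local gradient).
#' @export
pyramid_elastic_register <- function(reference, target, levels = 3L,
                                     block_size = 256L, search_radius = 16L,
                                     ncc_min = 0.3, smooth_bound = 1) {
  a <- if (length(dim(reference)) == 3L) luminance(reference) else reference
  b <- if (length(dim(target)) == 3L) luminance(target) else target
  stopifnot_same_shape(a, b)
  H <- nrow(a); W <- ncol(a)
  if (block_size > min(H, W)) stop("block_size larger than image")
  if (max(16L, block_size %/% 2^(levels - 1L)) >
      min(H, W) %/% 2^(levels - 1L))
    stop("block_size larger than image at coarsest level")
  # matching schedule: coarse levels track large displacements with a wide
  # search; the finest level refines with progressively smaller blocks and
  # a tight search radius (a wide fine-scale search would alias onto the
  # quasi-periodic cellular texture)
  passes <- list()
  blk_coarse <- max(16L, block_size %/% 2L^(levels - 1L))
  fs <- if (levels > 1L) 2L^((levels - 1L):1L) else integer(0)
  for (k in seq_along(fs))
    passes[[length(passes) + 1L]] <- list(
      f = fs[k], blk = blk_coarse,
      rad = if (k == 1L) as.integer(ceiling(search_radius / fs[k])) + 1L
            else 3L)
  passes[[length(passes) + 1L]] <- list(
    f = 1L, blk = max(16L, block_size %/% 2L),
    rad = if (levels > 1L) 4L else as.integer(search_radius) + 1L)
  for (i in 1:3)
    passes[[length(passes) + 1L]] <- list(
      f = 1L, blk = max(16L, block_size %/% 4L), rad = 3L)

  field <- deformation_field(matrix(0, H, W), matrix(0, H, W))
  res_med <- NA_real_
  for (ps in passes) {
    f <- ps$f; blk <- ps$blk
    bw <- warp_image(b, field)
    a_s <- if (f > 1) cpp_box_downsample(a, f) else a
    b_s <- if (f > 1) cpp_box_downsample(bw, f) else bw
    if (blk > min(dim(a_s))) next
    step <- max(4L, blk %/% 2L)
    m <- cpp_block_ncc(a_s, b_s, blk, step, ps$rad)
    ok <- m[, "valid"] == 1 & m[, "ncc"] >= ncc_min
    rs <- sort(unique(m[, "center_r"])); cs <- sort(unique(m[, "center_c"]))
    Dr <- matrix(NA_real_, length(rs), length(cs))
    Dc <- Dr
    ri <- match(m[, "center_r"], rs); ci <- match(m[, "center_c"], cs)
    Dr[cbind(ri[ok], ci[ok])] <- m[ok, "dr"]
    Dc[cbind(ri[ok], ci[ok])] <- m[ok, "dc"]
    # robustness: block estimates far from the field median are treated as
    # mismatches and re-imputed from their neighbours
    out <- outlier_blocks(Dr) | outlier_blocks(Dc)
    Dr[out] <- NA; Dc[out] <- NA
    Dr <- impute_neighbors(Dr); Dc <- impute_neighbors(Dc)
    # interpolate from the true block-centre positions (scaled to full
    # resolution) so the field stays spatially registered to the blocks
    upd_dr <- grid_interp(Dr, rs * f, cs * f, H, W) * f
    upd_dc <- grid_interp(Dc, rs * f, cs * f, H, W) * f
    sg <- blk * f / 4
    upd_dr <- cpp_gauss_blur(upd_dr, sg)
    upd_dc <- cpp_gauss_blur(upd_dc, sg)
    upd <- deformation_field(upd_dr, upd_dc)
    field <- compose_fields(field, upd)
    res_med <- stats::median(sqrt(m[ok, "dr"]^2 + m[ok, "dc"]^2) * f)
    if (!is.finite(res_med)) res_med <- 0
  }
  # enforce the smoothness bound by gentle extra smoothing, escalating only
  # if a localized spike survives
  sm <- field_smoothness(field)
  extra <- 1
  while (sm > smooth_bound) {
    field <- deformation_field(cpp_gauss_blur(field$dr, extra),
                               cpp_gauss_blur(field$dc, extra))
    sm <- field_smoothness(field)
    extra <- extra * 2
  }
  attr(field, "residual_median") <- res_med
  attr(field, "smoothness") <- sm
  field
}

field_smoothness <- function(field) {
  g <- function(m) {
    dr <- abs(diff(m)); dc <- abs(t(diff(t(m))))
    max(max(dr), max(dc))
  }
  max(g(field$dr), g(field$dc))
}

# bilinear interpolation of a coarse grid (values at given row/col centre
# coordinates, 0-based pixels) onto a dense H x W field; constant
# extrapolation beyond the outermost centres
grid_interp <- function(D, centers_r, centers_c, H, W) {
  axis_w <- function(centers, n) {
    p <- 0:(n - 1)
    if (length(centers) == 1L)
      return(list(i0 = rep(1L, n), t = rep(0, n)))
    i0 <- findInterval(p, centers, rightmost.closed = FALSE)
    i0 <- pmin(pmax(i0, 1L), length(centers) - 1L)
    t <- (p - centers[i0]) / (centers[i0 + 1L] - centers[i0])
    list(i0 = i0, t = pmin(pmax(t, 0), 1))
  }
  r <- axis_w(centers_r, H); c_ <- axis_w(centers_c, W)
  tr <- r$t; tc <- c_$t
  i0 <- r$i0; i1 <- pmin(i0 + 1L, length(centers_r))
  j0 <- c_$i0; j1 <- pmin(j0 + 1L, length(centers_c))
  outer(1 - tr, 1 - tc) * D[i0, j0] + outer(tr, 1 - tc) * D[i1, j0] +
    outer(1 - tr, tc) * D[i0, j1] + outer(tr, tc) * D[i1, j1]
}

# 3x3 median filter on the block grid (suppresses single-block mismatches)
median3 <- function(D) {
  H <- nrow(D); W <- ncol(D)
  if (H < 3 || W < 3) return(D)
  out <- D
  for (r in 1:H) for (c_ in 1:W)
    out[r, c_] <- stats::median(D[max(1, r - 1):min(H, r + 1),
                                  max(1, c_ - 1):min(W, c_ + 1)])
  out
}

# flag block displacements deviating strongly from the field median
outlier_blocks <- function(D) {
  med <- stats::median(D, na.rm = TRUE)
  madv <- stats::mad(D, na.rm = TRUE)
  !is.na(D) & abs(D - med) > max(3 * madv, 1.5)
}

# fill NA entries from the mean of finite neighbours, iteratively
impute_neighbors <- function(m) {
  if (!anyNA(m)) return(m)
  if (all(is.na(m))) return(matrix(0, nrow(m), ncol(m)))
  H <- nrow(m); W <- ncol(m)
  while (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)
    filled <- FALSE
    for (k in seq_len(nrow(idx))) {
      r <- idx[k, 1]; c_ <- idx[k, 2]
      nb <- m[max(1, r - 1):min(H, r + 1), max(1, c_ - 1):min(W, c_ + 1)]
      if (any(is.finite(nb))) {
        m[r, c_] <- mean(nb, na.rm = TRUE)
        filled <- TRUE
      }
    }
    if (!filled) break
  }
  m[is.na(m)] <- 0
  m
}

#' Style-bridge trainer for the registration loop
#'
#' Returns a trainer closure for [iterate_refine()]: a reduced virtual
#' staining generator (same architecture as the staining network) trained
#' supervised (smooth-L1 + SSIM) to map AF tiles to brightfield style, and
#' fine-tuned — not retrained — across refinement rounds.
#'
#' @param gen_cfg generator configuration (desk scale by default).
#' @param steps training steps per round.
#' @param crop,batch,lr crop size, batch size, learning rate.
#' @param seed seed.
#' @export
style_bridge_trainer <- function(gen_cfg = generator_config(scale = 8),
                                 steps = 150L, crop = 64L, batch = 4L,
                                 lr = 1e-3, seed = 7L) {
  function(pairs, state = NULL) {
    model <- if (is.null(state)) build_generator(gen_cfg, seed) else state$model
    astate <- if (is.null(state)) {
      e <- new.env(); e$t <- 0L; e$m <- list(); e$v <- list(); e
    } else state$astate
    gp <- model$params
    with_seed(seed + astate$t, {
      for (s in seq_len(steps)) {
        ids <- sample(seq_along(pairs), batch, replace = TRUE)
        af <- array(0, c(crop, crop, dim(pairs[[1]]$af)[3], batch))
        tg <- array(0, c(crop, crop, 3L, batch))
        for (i in seq_along(ids)) {
          cr <- sample_crops(pairs[[ids[i]]], crop, 1L,
                             seed = sample.int(.Machine$integer.max, 1L))[[1]]
          af[, , , i] <- cr$af; tg[, , , i] <- cr$target
        }
        tape <- tape_new()
        leaves <- lapply(gp, function(v) nn_leaf(tape, v))
        yhat <- generator_forward(model, af, tape = tape, P = leaves)
        l1 <- op_smooth_l1(tape, yhat, tg, 1)
        nls <- op_neg_log_ssim(tape, yhat, tg)
        loss <- op_scalar_comb(tape, list(l1, nls), c(10, 0.2))
        nn_backward(tape, loss)
        upd <- adamw_step(gp, lapply(leaves, function(nd) nd$grad), astate,
                          lr, 1e-5)
        gp <- upd$params
      }
    })
    model$params <- gp
    list(predict = function(af) {
      pad <- pad_to_16(af)
      out <- clamp01(generator_forward(model, pad$x))
      out[seq_len(pad$h), seq_len(pad$w), , drop = FALSE]
    }, state = list(model = model, astate = astate))
  }
}

pad_to_16 <- function(x) {
  d <- dim(x)
  H2 <- 16L * ((d[1] + 15L) %/% 16L); W2 <- 16L * ((d[2] + 15L) %/% 16L)
  if (H2 == d[1] && W2 == d[2]) return(list(x = x, h = d[1], w = d[2]))
  out <- array(0, c(H2, W2, d[3]))
  out[seq_len(d[1]), seq_len(d[2]), ] <- x
  # replicate edges into the padding
  if (H2 > d[1]) out[(d[1] + 1):H2, seq_len(d[2]), ] <-
      out[rep(d[1], H2 - d[1]), seq_len(d[2]), ]
  if (W2 > d[2]) out[, (d[2] + 1):W2, ] <- out[, rep(d[2], W2 - d[2]), ]
  list(x = out, h = d[1], w = d[2])
}

#' Iterated train-register refinement of tile pairs
#'
#' Alternates style-bridge training and elastic registration: each round
#' (a) refreshes the bridge on the current pairs, (b) elastically registers
#' each brightfield target to the bridge output of its AF tile, and
#' (c) applies the field to the target. Stops early once the median
#' residual block displacement falls below `tol`, halts if the residual
#' grows on two consecutive rounds, and finishes with an automated
#' cleaning pass (pairs with post-registration NCC < `ncc_clean` or tissue
#' fraction < `tissue_clean` are flagged `clean = FALSE`).
#'
#' @param pairs named list of tile pairs (`af`, `ihc`).
#' @param trainer a trainer closure such as [style_bridge_trainer()].
#' @param max_rounds maximum refinement rounds (3-5 in practice; capped
#'   at 5).
#' @param tol residual tolerance in pixels.
#' @param register_args extra arguments for [pyramid_elastic_register()].
#' @param ncc_clean,tissue_clean cleaning thresholds.
#' @return The refined pairs, with per-pair `registration_residual` and
#'   `clean`, and attributes `residuals` (per round), `rounds`,
#'   `converged`, `diverged`.
#' @export
iterate_refine <- function(pairs, trainer, max_rounds = 5L, tol = 0.5,
                           register_args = list(), ncc_clean = 0.5,
                           tissue_clean = 0.1) {
  max_rounds <- min(max_rounds, 5L)
  state <- NULL
  residuals <- numeric(0)
  diverged <- FALSE
  styles <- NULL
  for (round in seq_len(max_rounds)) {
    tr <- trainer(pairs, state)
    state <- tr$state
    styles <- lapply(pairs, function(p) tr$predict(p$af))
    round_res <- numeric(length(pairs))
    for (i in seq_along(pairs)) {
      field <- do.call(pyramid_elastic_register,
                       c(list(styles[[i]], pairs[[i]]$ihc), register_args))
      pairs[[i]]$ihc <- warp_image(pairs[[i]]$ihc, field)
      round_res[i] <- attr(field, "residual_median")
      pairs[[i]]$registration_residual <- round_res[i]
    }
    residuals <- c(residuals, stats::median(round_res))
    if (residuals[round] < tol) break
    if (round >= 3L && residuals[round] > residuals[round - 1L] &&
        residuals[round - 1L] > residuals[round - 2L]) {
      diverged <- TRUE
      warning("elastic refinement diverging; halting")
      break
    }
  }
  for (i in seq_along(pairs)) {
    sl <- luminance(styles[[i]]); tl <- luminance(pairs[[i]]$ihc)
    ncc <- suppressWarnings(stats::cor(as.numeric(sl), as.numeric(tl)))
    tissue <- mean(tl < 0.95)
    pairs[[i]]$clean <- is.finite(ncc) && ncc >= ncc_clean &&
      tissue >= tissue_clean
  }
  attr(pairs, "residuals") <- residuals
  attr(pairs, "rounds") <- length(residuals)
  attr(pairs, "converged") <- length(residuals) > 0 &&
    residuals[length(residuals)] < tol
  attr(pairs, "diverged") <- diverged
  pairs
}
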