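#' Smooth L1 (Huber-like) distance between two images
#'
#' Per pixel, `0.5 * d^2 / beta` where `|d| < beta` and `|d| - 0.5 * beta`
#' elsewhere, averaged over all pixels (and channels). Quadratic near zero,
#' linear in the tails, so gradients never explode.
#'
#' @param a,b numeric arrays of identical shape.
#' @param beta transition point between the quadratic and linear branch.
#' @export
smooth_l1 <- function(a, b, beta = 1) {
  stopifnot_same_shape(a, b)
  if (beta <= 0) stop("beta must be positive")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("inputs must be finite")
  d <- abs(a - b)
  quad <- (d < beta)
  mean(quad * (0.5 * d^2 / beta) + (1 - quad) * (d - 0.5 * beta))
}

#' Structural similarity index
#'
#' `SSIM = (2*mu_A*mu_B + c1)(2*cov_AB + c2) /
#'  ((mu_A^2 + mu_B^2 + c1)(var_A + var_B + c2))`.
#' In `"global"` mode a single set of statistics per image/channel is used
#' (the form used in the training loss); `"window"` mode computes local
#' statistics under an 11x11 Gaussian window (sigma 1.5) and averages the
#' SSIM map — the community norm for reporting. Multi-channel images are
#' averaged over channels. Constants default to the standard values for a
#' `[0, 1]` dynamic range, `c1 = 0.01^2`, `c2 = 0.03^2`.
#'
#' @param a,b images (matrix or `[H, W, C]`).
#' @param c1,c2 stabilising constants.
#' @param mode "global" or "window".
#' @param window_size,window_sigma Gaussian window parameters.
#' @return SSIM in `[-1, 1]`; 1 iff the images are identical.
#' @export
ssim <- function(a, b, c1 = 1e-4, c2 = 9e-4, mode = c("global", "window"),
                 window_size = 11L, window_sigma = 1.5) {
  mode <- match.arg(mode)
  stopifnot_same_shape(a, b)
  da <- dim(a)
  nc <- if (length(da) == 3L) da[3] else 1L
  chan <- function(x, i) if (length(da) == 3L) x[, , i] else x
  vals <- vapply(seq_len(nc), function(i) {
    A <- chan(a, i); B <- chan(b, i)
    if (mode == "global") {
      n <- length(A)
      muA <- mean(A); muB <- mean(B)
      vA <- sum((A - muA)^2) / n; vB <- sum((B - muB)^2) / n
      cAB <- sum((A - muA) * (B - muB)) / n
      ((2 * muA * muB + c1) * (2 * cAB + c2)) /
        ((muA^2 + muB^2 + c1) * (vA + vB + c2))
    } else {
      s <- window_sigma
      muA <- cpp_gauss_blur(A, s); muB <- cpp_gauss_blur(B, s)
      vA <- cpp_gauss_blur(A * A, s) - muA^2
      vB <- cpp_gauss_blur(B * B, s) - muB^2
      cAB <- cpp_gauss_blur(A * B, s) - muA * muB
      m <- ((2 * muA * muB + c1) * (2 * cAB + c2)) /
        ((muA^2 + muB^2 + c1) * (vA + vB + c2))
      mean(m)
    }
  }, numeric(1))
  mean(vals)
}

#' Binary cross-entropy with logits
#'
#' `-q*log(sigmoid(p)) - (1-q)*log(1-sigmoid(p))`, averaged over elements,
#' in the numerically stable form `max(p, 0) - p*q + log(1 + exp(-|p|))`
#' (no overflow for |p| up to at least 1e4).
#'
#' @param p logit(s).
#' @param q label(s) in \{0, 1\}.
#' @export
bce_logits <- function(p, q) {
  if (!all(q %in% c(0, 1))) stop("labels q must be 0 or 1")
  if (!all(is.finite(p))) stop("logits must be finite")
  mean(pmax(p, 0) - p * q + log1p(exp(-abs(p))))
}

#' Default composite-loss weights
#'
#' `alpha` scales the smooth-L1 term, `lambda` the SSIM log-term, `gamma`
#' the adversarial term; `beta` is the smooth-L1 transition point and
#' `c1`, `c2` the SSIM constants.
#' @export
loss_weights <- function(alpha = 10, lambda = 0.2, gamma = 0.5, beta = 1,
                         c1 = 1e-4, c2 = 9e-4) {
  w <- list(alpha = alpha, lambda = lambda, gamma = gamma, beta = beta,
            c1 = c1, c2 = c2)
  if (any(unlist(w) < 0) || beta <= 0) stop("invalid loss weights")
  structure(w, class = "loss_weights")
}

#' Generator composite loss
#'
#' `alpha * smoothL1(target, output) - lambda * log((1 + SSIM)/2)
#'  + gamma * BCE(d_logit, 1)`, with SSIM in global-statistics mode.
#'
#' @param output generator output image.
#' @param target ground-truth image.
#' @param d_logit discriminator logit for the generator output.
#' @param w a [loss_weights()] list.
#' @export
generator_loss <- function(output, target, d_logit, w = loss_weights()) {
  w$alpha * smooth_l1(target, output, w$beta) -
    w$lambda * log((1 + ssim(target, output, w$c1, w$c2, mode = "global")) / 2) +
    w$gamma * bce_logits(d_logit, 1)
}

#' Discriminator loss
#'
#' `BCE(d_logit_fake, 0) + BCE(d_logit_real, 1)`.
#' @param d_logit_fake,d_logit_real discriminator logits.
#' @export
discriminator_loss <- function(d_logit_fake, d_logit_real) {
  bce_logits(d_logit_fake, 0) + bce_logits(d_logit_real, 1)
}
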