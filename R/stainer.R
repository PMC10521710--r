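#' Fit a virtual HER2 stainer
#'
#' The package's central model-fitting function: splits registered
#' autofluorescence/brightfield tile pairs by patient, trains the
#' attention-gated conditional GAN with the composite smooth-L1 / SSIM /
#' adversarial loss, and returns the best generator (by validation MSE)
#' together with the normalisation policy needed at inference time.
#'
#' @param pairs named list of registered tile pairs; each element has `af`
#'   (`[H, W, 4]`) and `ihc` (`[H, W, 3]`), e.g. from [synth_dataset()] or
#'   [iterate_refine()].
#' @param records data.frame mapping `tile_id` to `patient_id`; defaults to
#'   the `manifest` attribute of `pairs`.
#' @param fractions train/validation/test tile fractions.
#' @param gen_cfg,disc_cfg network configurations; the defaults use the
#'   desk-scale (1/8 channel) networks.
#' @param weights composite [loss_weights()].
#' @param control a [train_control()].
#' @param seed seed for weight initialisation and the data split.
#' @return Object of class `virtual_stainer` with `generator`,
#'   `discriminator`, `checkpoints`, `best`, `norm`, `split`, `history` and
#'   the training `manifest`. Methods: [print()], [summary()],
#'   [predict.virtual_stainer()], [plot()], [coef()].
#' @seealso [stain_wsi()] for whole-slide inference.
#' @export
fit_virtual_stainer <- function(pairs, records = attr(pairs, "manifest"),
                                fractions = c(0.8, 0.1, 0.1),
                                gen_cfg = generator_config(scale = 8),
                                disc_cfg = discriminator_config(scale = 8),
                                weights = loss_weights(),
                                control = train_control(crop = 64, batch = 8,
                                                        max_steps = 500),
                                seed = control$seed) {
  if (is.null(records)) stop("no tile -> patient records supplied")
  split <- split_by_patient(records, fractions, seed)
  gen <- build_generator(gen_cfg, seed)
  disc <- build_discriminator(disc_cfg, seed + 1L)
  fit <- fit_gan(pairs, split, gen, disc, weights, control)
  best <- select_best(fit$checkpoints)
  gen_best <- fit$generator
  if (!is.null(best$params)) gen_best$params <- best$params
  structure(list(generator = gen_best, discriminator = fit$discriminator,
                 checkpoints = fit$checkpoints, best = best,
                 norm = fit$norm, split = split, history = fit$history,
                 manifest = fit$manifest, weights = weights,
                 control = control, updates = fit$updates,
                 call = match.call()),
            class = "virtual_stainer")
}

#' @export
print.virtual_stainer <- function(x, ...) {
  cat("Virtual HER2 stainer (conditional GAN)\n")
  cat(sprintf("  generator: attention U-Net, %s parameters (scale 1/%d)\n",
              format(x$generator$parameter_count, big.mark = ","),
              x$generator$cfg$scale))
  cat(sprintf("  trained: %d generator / %d discriminator updates\n",
              x$updates["generator"], x$updates["discriminator"]))
  cat(sprintf("  best checkpoint: step %d, validation MSE %.5f\n",
              x$best$step, x$best$val_mse))
  cat(sprintf("  split: %d train / %d val / %d test tiles (patient-disjoint)\n",
              length(x$split$train_ids), length(x$split$val_ids),
              length(x$split$test_ids)))
  invisible(x)
}

#' @export
summary.virtual_stainer <- function(object, ...) {
  h <- object$history
  cps <- data.frame(
    step = vapply(object$checkpoints, `[[`, numeric(1), "step"),
    val_mse = vapply(object$checkpoints, `[[`, numeric(1), "val_mse"))
  out <- list(best = object$best[c("step", "val_mse")],
              checkpoints = cps,
              final_g_loss = utils::tail(h$loss[h$kind == "G"], 1),
              final_d_loss = utils::tail(h$loss[h$kind == "D"], 1),
              updates = object$updates)
  class(out) <- "summary.virtual_stainer"
  out
}

#' @export
print.summary.virtual_stainer <- function(x, ...) {
  cat("Checkpoints (validation MSE):\n")
  print(x$checkpoints, row.names = FALSE)
  cat(sprintf("best step %d (val MSE %.5f); final losses G %.4f / D %.4f\n",
              x$best$step, x$best$val_mse, x$final_g_loss, x$final_d_loss))
  invisible(x)
}

#' Virtually stain autofluorescence images
#'
#' Applies the fitted generator to new autofluorescence data, using the
#' normalisation percentiles stored at training time. Inputs whose spatial
#' size exceeds `tile` are staine tile-by-tile with feathered stitching via
#' [stain_wsi()].
#'
#' @param object a `virtual_stainer`.
#' @param newdata `[H, W, 4]` autofluorescence array.
#' @param tile tile size above which tiled inference is used.
#' @param overlap stitching overlap in pixels.
#' @param ... unused.
#' @return `[H, W, 3]` virtual brightfield image in `[0, 1]`.
#' @export
predict.virtual_stainer <- function(object, newdata, tile = 256L,
                                    overlap = 32L, ...) {
  af <- apply_af_norm(newdata, object$norm)
  d <- dim(af)
  if (d[1] <= tile && d[2] <= tile && d[1] %% 16L == 0L && d[2] %% 16L == 0L)
    return(clamp01(generator_forward(object$generator, af)))
  stain_wsi(af, object$generator, grid = tile_grid(d[1:2], tile, overlap),
            normalize = FALSE)
}

#' @export
plot.virtual_stainer <- function(x, ...) {
  h <- x$history
  g <- h[h$kind == "G", ]
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(g$step, g$loss, type = "l", xlab = "generator step",
       ylab = "generator loss", main = "training loss", ...)
  cps <- vapply(x$checkpoints, `[[`, numeric(1), "val_mse")
  steps <- vapply(x$checkpoints, `[[`, numeric(1), "step")
  plot(steps, cps, type = "b", xlab = "generator step",
       ylab = "validation MSE", main = "model selection")
  invisible(x)
}

#' @export
coef.virtual_stainer <- function(object, ...) object$generator$params
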