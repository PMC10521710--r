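#' Patient-level dataset split
#'
#' Splits tiles into train/validation/test sets at approximately the
#' requested tile fractions while keeping every patient's tiles in exactly
#' one set, so test patients are never seen during training.
#'
#' @param records data.frame with columns `patient_id` and `tile_id`.
#' @param fractions (train, validation, test) tile fractions; roughly
#'   (0.8, 0.1, 0.1).
#' @param seed integer seed (patient shuffling).
#' @return List of class `dataset_split` with `train_ids`, `val_ids`,
#'   `test_ids` (tile identifiers) and the corresponding patient sets.
#' @export
split_by_patient <- function(records, fractions = c(0.8, 0.1, 0.1), seed = 0) {
  stopifnot(all(c("patient_id", "tile_id") %in% names(records)))
  patients <- unique(records$patient_id)
  if (length(patients) < 3L)
    stop("need at least 3 patients for a patient-disjoint 3-way split")
  fractions <- fractions / sum(fractions)
  total <- nrow(records)
  with_seed(seed, {
    ord <- sample(patients)
    tiles_of <- function(p) records$tile_id[records$patient_id %in% p]
    take <- function(ord, target) {
      got <- character(0); n <- 0
      while (length(ord) && n < target) {
        got <- c(got, ord[1])
        n <- n + length(tiles_of(ord[1]))
        ord <- ord[-1]
      }
      list(patients = got, rest = ord)
    }
    te <- take(ord, max(1, round(fractions[3] * total)))
    va <- take(te$rest, max(1, round(fractions[2] * total)))
    structure(list(
      train_ids = tiles_of(va$rest), val_ids = tiles_of(va$patients),
      test_ids = tiles_of(te$patients),
      train_patients = va$rest, val_patients = va$patients,
      test_patients = te$patients), class = "dataset_split")
  })
}

#' Sample co-located crops from a registered tile pair
#'
#' Draws `n` random crop offsets and extracts the same window from the
#' autofluorescence stack and the brightfield target; optional augmentation
#' applies the same flip/rotation to both members.
#'
#' @param pair list with `af` (`[H, W, 4]`) and `ihc`/`target` (`[H, W, 3]`).
#' @param crop crop size in pixels.
#' @param n number of crops.
#' @param seed integer seed.
#' @param augment apply random flips and 90-degree rotations.
#' @return List of `n` lists with `af`, `target`, `offset` (0-based).
#' @export
sample_crops <- function(pair, crop, n, seed = 0, augment = FALSE) {
  af <- pair$af
  tgt <- if (!is.null(pair$ihc)) pair$ihc else pair$target
  d <- dim(af)
  if (crop > d[1] || crop > d[2]) stop("crop exceeds tile size")
  if (n == 0) return(list())
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      r0 <- sample.int(d[1] - crop + 1L, 1L)
      c0 <- sample.int(d[2] - crop + 1L, 1L)
      a <- af[r0:(r0 + crop - 1L), c0:(c0 + crop - 1L), , drop = FALSE]
      t_ <- tgt[r0:(r0 + crop - 1L), c0:(c0 + crop - 1L), , drop = FALSE]
      if (augment) {
        k <- sample.int(4L, 1L) - 1L
        fl <- sample(c(TRUE, FALSE), 1L)
        a <- rot_flip(a, k, fl); t_ <- rot_flip(t_, k, fl)
      }
      list(af = a, target = t_, offset = c(r0 - 1L, c0 - 1L))
    })
  })
}

rot_flip <- function(x, k, flip) {
  if (flip) x <- x[, dim(x)[2]:1, , drop = FALSE]
  for (i in seq_len(k %% 4L))
    x <- aperm(x, c(2, 1, 3))[dim(x)[2]:1, , , drop = FALSE]
  x
}

#' Training control parameters
#'
#' Defaults mirror the full-scale schedule: 256-pixel crops, batch 28,
#' AdamW (Adam with decoupled weight decay) at learning rates 1e-4
#' (generator) and 1e-5 (discriminator), and a 2:1 generator:discriminator
#' update ratio. `max_steps` counts generator updates. Desk-scale runs
#' shrink `crop`, `batch` and `max_steps`.
#'
#' @param crop crop size (pixels); must divide by 16.
#' @param batch batch size.
#' @param lr_g,lr_d learning rates.
#' @param weight_decay decoupled weight decay coefficient.
#' @param g_d_ratio generator:discriminator update ratio (two integers).
#' @param max_steps total generator updates.
#' @param seed master seed for sampling and noise.
#' @param checkpoint_every validation/checkpoint period (generator steps).
#' @param gamma_warmup generator steps over which the adversarial weight
#'   ramps linearly from 0 to its configured value; 0 disables the ramp.
#' @param adaptive_adv cap the adversarial gradient at the reconstruction
#'   gradient's norm (measured at the generator output). The adversarial
#'   push then scales down together with the reconstruction error, which
#'   keeps short schedules stable when the discriminator is still poorly
#'   trained; off by default (the full-scale schedule does not need it).
#' @param augment random flip/rotation augmentation.
#' @param keep_checkpoints "best", "all" or "none" parameter snapshots.
#' @param verbose print progress lines.
#' @export
train_control <- function(crop = 256L, batch = 28L, lr_g = 1e-4, lr_d = 1e-5,
                          weight_decay = 1e-5, g_d_ratio = c(2L, 1L),
                          max_steps = 2000L, seed = 1L,
                          checkpoint_every = 100L, gamma_warmup = 0L,
                          adaptive_adv = FALSE, augment = TRUE,
                          keep_checkpoints = "best", verbose = FALSE) {
  stopifnot(batch >= 1L, all(g_d_ratio >= 1L), crop %% 16L == 0L)
  structure(list(crop = as.integer(crop), batch = as.integer(batch),
                 lr_g = lr_g, lr_d = lr_d, weight_decay = weight_decay,
                 g_d_ratio = as.integer(g_d_ratio),
                 max_steps = as.integer(max_steps), seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every),
                 gamma_warmup = as.integer(gamma_warmup),
                 adaptive_adv = isTRUE(adaptive_adv),
                 augment = augment, keep_checkpoints = keep_checkpoints,
                 verbose = verbose), class = "train_control")
}

# AdamW step; state holds m, v per parameter and the step counter
adamw_step <- function(params, grads, state, lr, wd, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    upd <- cpp_adamw_update(params[[nm]], g, state$m[[nm]], state$v[[nm]],
                            lr, wd, beta1, beta2, bc1, bc2, eps)
    state$m[[nm]] <- upd$m
    state$v[[nm]] <- upd$v
    params[[nm]] <- upd$p
  }
  list(params = params, state = state)
}

# per-channel affine normalisation from percentiles of the training AF tiles
af_normalization <- function(pairs, probs = c(0.001, 0.999)) {
  nch <- dim(pairs[[1]]$af)[3]
  lo <- numeric(nch); hi <- numeric(nch)
  for (ch in seq_len(nch)) {
    v <- unlist(lapply(pairs, function(p) as.numeric(p$af[, , ch])))
    q <- quantile(v, probs, names = FALSE)
    lo[ch] <- q[1]; hi[ch] <- q[2]
  }
  list(lo = lo, hi = hi, probs = probs)
}

apply_af_norm <- function(af, norm) {
  for (ch in seq_len(dim(af)[3]))
    af[, , ch] <- clamp01((af[, , ch] - norm$lo[ch]) /
                            max(norm$hi[ch] - norm$lo[ch], 1e-8))
  af
}

#' Adversarial training loop
#'
#' Alternating optimisation at the configured generator:discriminator
#' ratio. Each generator step minimises the composite loss
#' `alpha*smoothL1 - lambda*log((1+SSIM)/2) + gamma*BCE(D(G(x)), 1)`; each
#' discriminator step minimises `BCE(D(G(x)), 0) + BCE(D(y), 1)`. AdamW
#' updates, all randomness seeded, validation MSE logged periodically.
#'
#' @param pairs named list of registered tile pairs (`af`, `ihc`), names are
#'   tile ids.
#' @param split a [split_by_patient()] result; train and validation sets
#'   must be non-empty.
#' @param generator,discriminator models from [build_generator()] /
#'   [build_discriminator()].
#' @param weights a [loss_weights()].
#' @param control a [train_control()].
#' @return List of class `gan_fit`: final `generator`, `discriminator`,
#'   `checkpoints` (each with `step`, `val_mse`, optionally `params`),
#'   `history` (losses per step), `manifest` (tile ids per batch),
#'   `norm` (AF normalisation).
#' @export
fit_gan <- function(pairs, split, generator, discriminator,
                    weights = loss_weights(), control = train_control()) {
  train_pairs <- pairs[intersect(names(pairs), split$train_ids)]
  val_pairs <- pairs[intersect(names(pairs), split$val_ids)]
  if (!length(train_pairs) || !length(val_pairs))
    stop("train and validation sets must be non-empty")
  norm <- af_normalization(train_pairs)
  for (nm in names(train_pairs))
    train_pairs[[nm]]$af <- apply_af_norm(train_pairs[[nm]]$af, norm)
  for (nm in names(val_pairs))
    val_pairs[[nm]]$af <- apply_af_norm(val_pairs[[nm]]$af, norm)

  gp <- generator$params
  dp <- discriminator$params
  gstate <- new.env(); gstate$t <- 0L; gstate$m <- list(); gstate$v <- list()
  dstate <- new.env(); dstate$t <- 0L; dstate$m <- list(); dstate$v <- list()
  checkpoints <- list()
  history <- NULL
  manifest <- list()
  best_mse <- Inf

  draw_batch <- function() {
    ids <- sample(names(train_pairs), control$batch, replace = TRUE)
    crop <- control$crop
    af <- array(0, c(crop, crop, dim(train_pairs[[1]]$af)[3], control$batch))
    tg <- array(0, c(crop, crop, 3L, control$batch))
    for (i in seq_along(ids)) {
      cr <- sample_crops(train_pairs[[ids[i]]], crop, 1L,
                         seed = sample.int(.Machine$integer.max, 1L),
                         augment = control$augment)[[1]]
      af[, , , i] <- cr$af
      tg[, , , i] <- cr$target
    }
    list(af = af, target = tg, ids = ids)
  }

  val_mse <- function(gpars) {
    m <- generator
    m$params <- gpars
    mean(vapply(val_pairs, function(p) {
      out <- generator_forward(m, p$af)
      mean((clamp01(out) - p$ihc)^2)
    }, numeric(1)))
  }

  g_loss_step <- function() {
    b <- draw_batch()
    manifest[[length(manifest) + 1L]] <<- list(step = gstate$t + 1L,
                                               kind = "G", ids = b$ids)
    gamma_eff <- if (control$gamma_warmup > 0L)
      weights$gamma * min(1, gstate$t / control$gamma_warmup)
    else weights$gamma
    tape <- tape_new()
    leaves_g <- lapply(gp, function(v) nn_leaf(tape, v))
    leaves_d <- lapply(dp, function(v) nn_leaf(tape, v, frozen = TRUE))
    yhat <- generator_forward(generator, b$af, tape = tape, P = leaves_g)

    if (!control$adaptive_adv) {
      dlog <- discriminator_forward(discriminator, yhat, tape = tape,
                                    P = leaves_d)
      l1 <- op_smooth_l1(tape, yhat, b$target, weights$beta)
      nls <- op_neg_log_ssim(tape, yhat, b$target, weights$c1, weights$c2)
      adv <- op_bce_logits(tape, dlog, 1)
      loss <- op_scalar_comb(tape, list(l1, nls, adv),
                             c(weights$alpha, weights$lambda, gamma_eff))
      if (!is.finite(loss$value))
        stop("non-finite generator loss at step ", gstate$t + 1L)
      nn_backward(tape, loss)
      loss_value <- loss$value
    } else {
      # reconstruction and adversarial gradients are taken separately at
      # the generator output; the adversarial one is capped at the
      # reconstruction gradient's norm before backpropagating further
      yv <- nn_value(yhat)
      tape_r <- tape_new()
      yleaf <- nn_leaf(tape_r, yv)
      l1 <- op_smooth_l1(tape_r, yleaf, b$target, weights$beta)
      nls <- op_neg_log_ssim(tape_r, yleaf, b$target, weights$c1, weights$c2)
      lrec <- op_scalar_comb(tape_r, list(l1, nls),
                             c(weights$alpha, weights$lambda))
      nn_backward(tape_r, lrec)
      g_rec <- yleaf$grad

      tape_d <- tape_new()
      yleaf_d <- nn_leaf(tape_d, yv)
      dleaves <- lapply(dp, function(v) nn_leaf(tape_d, v, frozen = TRUE))
      dlog <- discriminator_forward(discriminator, yleaf_d, tape = tape_d,
                                    P = dleaves)
      ladv <- op_bce_logits(tape_d, dlog, 1)
      nn_backward(tape_d, ladv)
      g_adv <- yleaf_d$grad

      n_rec <- sqrt(sum(g_rec^2))
      n_adv <- gamma_eff * sqrt(sum(g_adv^2))
      scale <- gamma_eff * min(1, n_rec / max(n_adv, 1e-12))
      loss_value <- lrec$value + gamma_eff * ladv$value
      if (!is.finite(loss_value))
        stop("non-finite generator loss at step ", gstate$t + 1L)
      yhat$grad <- g_rec + scale * g_adv
      nn_backward(tape, yhat)
    }
    grads <- lapply(leaves_g, function(nd) nd$grad)
    upd <- adamw_step(gp, grads, gstate, control$lr_g, control$weight_decay)
    gp <<- upd$params
    loss_value
  }

  d_loss_step <- function() {
    b <- draw_batch()
    manifest[[length(manifest) + 1L]] <<- list(step = dstate$t + 1L,
                                               kind = "D", ids = b$ids)
    gmod <- generator; gmod$params <- gp
    fake <- generator_forward(gmod, b$af)          # detached
    # fake and real share one forward pass; the combined mean BCE is half
    # the sum of the two separate terms, hence the weight of 2
    both <- array(0, c(dim(fake)[1:3], 2L * control$batch))
    both[, , , seq_len(control$batch)] <- fake
    both[, , , control$batch + seq_len(control$batch)] <- b$target
    q <- rep(c(0, 1), each = control$batch)
    tape <- tape_new()
    leaves_d <- lapply(dp, function(v) nn_leaf(tape, v))
    lboth <- op_bce_logits(tape, discriminator_forward(discriminator, both,
                                                       tape = tape,
                                                       P = leaves_d), q)
    loss <- op_scalar_comb(tape, list(lboth), 2)
    if (!is.finite(loss$value))
      stop("non-finite discriminator loss at step ", dstate$t + 1L)
    nn_backward(tape, loss)
    grads <- lapply(leaves_d, function(nd) nd$grad)
    upd <- adamw_step(dp, grads, dstate, control$lr_d, control$weight_decay)
    dp <<- upd$params
    loss$value
  }

  checkpoint <- function(step) {
    mse <- val_mse(gp)
    keep <- control$keep_checkpoints == "all" ||
      (control$keep_checkpoints == "best" && mse < best_mse)
    if (mse < best_mse) best_mse <<- mse
    checkpoints[[length(checkpoints) + 1L]] <<- list(
      step = step, val_mse = mse,
      params = if (keep) gp else NULL)
    if (control$verbose)
      message(sprintf("step %d  val MSE %.5f", step, mse))
  }

  with_seed(control$seed, {
    gsteps <- 0L
    while (gsteps < control$max_steps) {
      for (j in seq_len(control$g_d_ratio[1])) {
        if (gsteps >= control$max_steps) break
        gl <- g_loss_step()
        gsteps <- gsteps + 1L
        history <- rbind(history,
                         data.frame(step = gsteps, kind = "G", loss = gl))
        if (gsteps %% control$checkpoint_every == 0L) checkpoint(gsteps)
      }
      for (j in seq_len(control$g_d_ratio[2])) {
        dl <- d_loss_step()
        history <- rbind(history,
                         data.frame(step = gsteps, kind = "D", loss = dl))
      }
    }
    if (!length(checkpoints) ||
        checkpoints[[length(checkpoints)]]$step < gsteps)
      checkpoint(gsteps)
  })

  generator$params <- gp
  discriminator$params <- dp
  structure(list(generator = generator, discriminator = discriminator,
                 checkpoints = checkpoints, history = history,
                 manifest = manifest, norm = norm, split = split,
                 control = control, weights = weights,
                 updates = c(generator = gstate$t, discriminator = dstate$t)),
            class = "gan_fit")
}

#' Select the best checkpoint by validation MSE
#'
#' Minimum validation MSE; ties resolve to the earliest step.
#' @param checkpoints list of checkpoints from [fit_gan()].
#' @export
select_best <- function(checkpoints) {
  if (!length(checkpoints)) stop("no checkpoints")
  mses <- vapply(checkpoints, function(cp) cp$val_mse, numeric(1))
  checkpoints[[which.min(mses)]]   # which.min takes the first minimum
}
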