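# Attention-gated U-Net generator and residual CNN discriminator.
#
# Wiring notes (channel accounting):
#  * Down path: 4 blocks, each a two-conv residual block (3x3 kernels, 1x1
#    conv on the residual path), Leaky ReLU (slope 0.1) after the residual
#    sum, then 2x2 max-pool stride 2. The pre-pool activation is the skip.
#  * Center: residual block mapping down_out[4] -> up_in[1] channels.
#  * Up path: block i receives the previous tensor (up_in[i] channels),
#    upsamples it 2x bilinearly, uses it as the gating signal of an additive
#    attention gate on the matching skip, concatenates (up_in[i] + skip
#    channels) and applies a residual block down to up_out[i] channels.
#    The printed in/out channel lists count the tensor entering each block
#    from below, i.e. before concatenation.
#  * Head: one more residual block then a 3x3 conv to 3 channels, linear
#    output (values are clipped to [0, 1] only at export time).
#  * No normalisation layers anywhere; all convs carry biases.

# plain-array ops (inference) ------------------------------------------------

ops_plain <- function() {
  list(
    conv = function(x, w, b, stride = 1L) cpp_conv2d_fwd(x, w, b, stride),
    lrelu = function(x, slope = 0.1) cpp_lrelu_fwd(x, slope),
    relu = function(x) {
      y <- pmax(x, 0); dim(y) <- dim(x); y
    },
    sigmoid = function(x) 1 / (1 + exp(-x)),
    add = function(x, y) x + y,
    maxpool = function(x) cpp_maxpool2_fwd(x)$y,
    upsample2 = function(x) cpp_upsample2_fwd(x),
    concat = function(x, y) {
      dx <- dim(x); dy <- dim(y)
      v <- array(0, c(dx[1], dx[2], dx[3] + dy[3], dx[4]))
      v[, , seq_len(dx[3]), ] <- x
      v[, , dx[3] + seq_len(dy[3]), ] <- y
      v
    },
    gate_mul = function(x, a) {
      dx <- dim(x)
      for (ci in seq_len(dx[3])) x[, , ci, ] <- x[, , ci, ] * a[, , 1, ]
      x
    },
    gap = function(x) {
      d <- dim(x)
      dim(x) <- c(d[1] * d[2], d[3] * d[4])
      v <- colMeans(x); dim(v) <- d[3:4]; v
    },
    fc = function(x, w, b) crossprod(w, x) + b,
    value = identity)
}

ops_tape <- function(tape) {
  list(
    conv = function(x, w, b, stride = 1L) op_conv(tape, x, w, b, stride),
    lrelu = function(x, slope = 0.1) op_leaky_relu(tape, x, slope),
    relu = function(x) op_relu(tape, x),
    sigmoid = function(x) op_sigmoid(tape, x),
    add = function(x, y) op_add(tape, x, y),
    maxpool = function(x) op_maxpool(tape, x),
    upsample2 = function(x) op_upsample2(tape, x),
    concat = function(x, y) op_concat(tape, x, y),
    gate_mul = function(x, a) op_gate_mul(tape, x, a),
    gap = function(x) op_gap(tape, x),
    fc = function(x, w, b) op_fc(tape, x, w, b),
    value = nn_value)
}

# --- configurations ---------------------------------------------------------

#' Generator configuration (attention-gated U-Net)
#'
#' Default channel counts follow the full-scale network: down path in/out
#' channels (4, 64, 128, 256) / (64, 128, 256, 512), up path
#' (1024, 1024, 512, 256) / (1024, 512, 256, 128), 3x3 kernels, Leaky ReLU
#' slope 0.1, 2x2 max pooling and bilinear 2x upsampling. `scale` divides
#' every internal channel count (e.g. `scale = 8` gives the desk-scale
#' network used in the examples and tests).
#'
#' @param scale integer divisor applied to all internal channel counts.
#' @param in_channels autofluorescence input channels.
#' @param out_channels output channels (3, RGB).
#' @param leaky_slope Leaky ReLU negative slope.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(scale = 1L, in_channels = 4L, out_channels = 3L,
                             leaky_slope = 0.1) {
  sc <- function(v) pmax(1L, as.integer(round(v / scale)))
  cfg <- list(
    in_channels = as.integer(in_channels),
    out_channels = as.integer(out_channels),
    levels = 4L,
    down_in = c(as.integer(in_channels), sc(c(64, 128, 256))),
    down_out = sc(c(64, 128, 256, 512)),
    up_in = sc(c(1024, 1024, 512, 256)),
    up_out = sc(c(1024, 512, 256, 128)),
    leaky_slope = leaky_slope,
    scale = as.integer(scale))
  stopifnot(length(cfg$down_in) == cfg$levels,
            cfg$up_in[1] == 2L * cfg$down_out[4L],
            all(cfg$up_in[-1] == cfg$up_out[-4L]))
  structure(cfg, class = "generator_config")
}

#' Discriminator configuration (residual CNN)
#'
#' An initial conv + Leaky ReLU to `init_channels`, then five residual
#' blocks each downsampling 2x (stride-2 second conv) and doubling the
#' channel count, global average pooling, and two fully connected layers to
#' a single logit.
#' @param scale integer divisor applied to all internal channel counts.
#' @param in_channels image channels (3).
#' @param init_channels channels after the initial convolution.
#' @param residual_blocks number of 2x-downsampling residual blocks.
#' @param fc_hidden hidden units of the first fully connected layer.
#' @export
discriminator_config <- function(scale = 1L, in_channels = 3L,
                                 init_channels = 64L, residual_blocks = 5L,
                                 fc_hidden = 512L) {
  sc <- function(v) pmax(1L, as.integer(round(v / scale)))
  ch <- sc(init_channels * 2^(0:residual_blocks))
  structure(list(in_channels = as.integer(in_channels),
                 channels = ch,          # length blocks + 1 (incl. initial)
                 residual_blocks = as.integer(residual_blocks),
                 fc_hidden = sc(fc_hidden),
                 leaky_slope = 0.1,
                 scale = as.integer(scale)),
            class = "discriminator_config")
}

# --- parameter initialisation (He-normal, seeded) ---------------------------

he_conv <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

init_resblock <- function(cin, cout) {
  list(conv1.w = he_conv(3L, cin, cout), conv1.b = numeric(cout),
       conv2.w = he_conv(3L, cout, cout), conv2.b = numeric(cout),
       proj.w = he_conv(1L, cin, cout), proj.b = numeric(cout))
}

init_attgate <- function(skip_ch, gate_ch) {
  fint <- max(1L, skip_ch %/% 2L)
  list(wg.w = he_conv(1L, gate_ch, fint), wg.b = numeric(fint),
       ws.w = he_conv(1L, skip_ch, fint), ws.b = numeric(fint),
       psi.w = he_conv(1L, fint, 1L), psi.b = numeric(1))
}

prefix_params <- function(lst, prefix)
  setNames(lst, paste0(prefix, ".", names(lst)))

#' Build the virtual-staining generator
#'
#' Instantiates the attention-gated U-Net with He-normal seeded weights.
#' The model is fully convolutional: any input whose spatial dimensions are
#' divisible by 16 is accepted.
#'
#' @param cfg a [generator_config()].
#' @param seed integer seed for the weight initialisation.
#' @return List of class `vstain_generator` with `cfg`, `params` and
#'   `parameter_count`.
#' @export
build_generator <- function(cfg = generator_config(), seed = 1) {
  params <- with_seed(seed, {
    p <- list()
    for (i in 1:4)
      p <- c(p, prefix_params(init_resblock(cfg$down_in[i], cfg$down_out[i]),
                              sprintf("down%d", i)))
    p <- c(p, prefix_params(init_resblock(cfg$down_out[4], cfg$up_in[1]),
                            "center"))
    for (i in 1:4) {
      skip_ch <- cfg$down_out[5L - i]
      p <- c(p, prefix_params(init_attgate(skip_ch, cfg$up_in[i]),
                              sprintf("up%d.att", i)))
      p <- c(p, prefix_params(init_resblock(cfg$up_in[i] + skip_ch,
                                            cfg$up_out[i]),
                              sprintf("up%d", i)))
    }
    p <- c(p, prefix_params(init_resblock(cfg$up_out[4], cfg$up_out[4]),
                            "head"))
    p$out.w <- he_conv(3L, cfg$up_out[4], cfg$out_channels)
    # brightfield background is full transmittance; starting the output
    # bias at white avoids spending early updates learning the background
    p$out.b <- rep(1, cfg$out_channels)
    p
  })
  structure(list(kind = "generator", cfg = cfg, params = params,
                 parameter_count = sum(vapply(params, length, numeric(1)))),
            class = c("vstain_generator", "vstain_model"))
}

#' Build the discriminator
#'
#' @param cfg a [discriminator_config()].
#' @param seed integer seed for the weight initialisation.
#' @return List of class `vstain_discriminator`.
#' @export
build_discriminator <- function(cfg = discriminator_config(), seed = 1) {
  params <- with_seed(seed, {
    p <- list(init.w = he_conv(3L, cfg$in_channels, cfg$channels[1]),
              init.b = numeric(cfg$channels[1]))
    for (i in seq_len(cfg$residual_blocks))
      p <- c(p, prefix_params(init_resblock(cfg$channels[i],
                                            cfg$channels[i + 1]),
                              sprintf("block%d", i)))
    cl <- cfg$channels[cfg$residual_blocks + 1]
    p$fc1.w <- matrix(rnorm(cl * cfg$fc_hidden, 0, sqrt(2 / cl)),
                      cl, cfg$fc_hidden)
    p$fc1.b <- numeric(cfg$fc_hidden)
    p$fc2.w <- matrix(rnorm(cfg$fc_hidden, 0, sqrt(2 / cfg$fc_hidden)),
                      cfg$fc_hidden, 1L)
    p$fc2.b <- numeric(1)
    p
  })
  structure(list(kind = "discriminator", cfg = cfg, params = params,
                 parameter_count = sum(vapply(params, length, numeric(1)))),
            class = c("vstain_discriminator", "vstain_model"))
}

# --- forward passes ---------------------------------------------------------

as_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) {
    dim(x) <- c(d, 1L)
    attr(x, "single") <- TRUE
  }
  x
}

resblock_fwd <- function(ops, P, prefix, x, slope = 0.1, stride2 = FALSE) {
  g <- function(s) P[[paste0(prefix, ".", s)]]
  h <- ops$lrelu(ops$conv(x, g("conv1.w"), g("conv1.b"), 1L), slope)
  h <- ops$conv(h, g("conv2.w"), g("conv2.b"), if (stride2) 2L else 1L)
  r <- ops$conv(x, g("proj.w"), g("proj.b"), if (stride2) 2L else 1L)
  ops$add(h, r)
}

attgate_fwd <- function(ops, P, prefix, skip, gate) {
  g <- function(s) P[[paste0(prefix, ".", s)]]
  q <- ops$relu(ops$add(ops$conv(gate, g("wg.w"), g("wg.b"), 1L),
                        ops$conv(skip, g("ws.w"), g("ws.b"), 1L)))
  a <- ops$sigmoid(ops$conv(q, g("psi.w"), g("psi.b"), 1L))
  list(gated = ops$gate_mul(skip, a), attention = a)
}

#' Generator forward pass
#'
#' Maps a 4-channel autofluorescence stack to a 3-channel brightfield
#' image. Accepts `[H, W, 4]` or batched `[H, W, 4, N]` input with H and W
#' divisible by 16.
#'
#' @param model a `vstain_generator`.
#' @param x input array.
#' @param tape internal: autodiff tape for training.
#' @param P internal: parameter override (arrays or tape nodes).
#' @param with_attention if TRUE also return the attention weight maps.
#' @return Output array (or a tape node during training).
#' @export
generator_forward <- function(model, x, tape = NULL, P = NULL,
                              with_attention = FALSE) {
  cfg <- model$cfg
  recording <- !is.null(tape)
  ops <- if (recording) ops_tape(tape) else ops_plain()
  if (is.null(P)) P <- model$params
  xv <- if (recording) nn_value(x) else x
  xv_in <- as_batch(xv)
  single <- isTRUE(attr(xv_in, "single"))
  d <- dim(xv_in)
  if (d[3] != cfg$in_channels)
    stop(sprintf("input has %d channels; generator expects %d", d[3],
                 cfg$in_channels))
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L)
    stop("input spatial dimensions must be divisible by 16")
  h <- if (recording) {
    if (is.environment(x)) x else nn_leaf(tape, xv_in)
  } else xv_in
  sl <- cfg$leaky_slope
  skips <- vector("list", 4L)
  for (i in 1:4) {
    h <- ops$lrelu(resblock_fwd(ops, P, sprintf("down%d", i), h, sl), sl)
    skips[[i]] <- h
    h <- ops$maxpool(h)
  }
  h <- ops$lrelu(resblock_fwd(ops, P, "center", h, sl), sl)
  atts <- vector("list", 4L)
  for (i in 1:4) {
    up <- ops$upsample2(h)
    ag <- attgate_fwd(ops, P, sprintf("up%d.att", i), skips[[5L - i]], up)
    atts[[i]] <- ag$attention
    h <- ops$concat(up, ag$gated)
    h <- ops$lrelu(resblock_fwd(ops, P, sprintf("up%d", i), h, sl), sl)
  }
  h <- ops$lrelu(resblock_fwd(ops, P, "head", h, sl), sl)
  out <- ops$conv(h, P[["out.w"]], P[["out.b"]], 1L)
  if (recording) return(out)
  y <- out
  if (single) {
    dm <- dim(y); dim(y) <- dm[1:3]
    atts <- lapply(atts, function(a) {
      da <- dim(a); dim(a) <- da[1:2]; a
    })
  }
  if (with_attention) list(output = y, attention = atts) else y
}

#' Discriminator forward pass
#'
#' Maps a 3-channel image (or batch) to one scalar logit per image — the
#' log-odds that the input is a chemically stained IHC image.
#' @param model a `vstain_discriminator`.
#' @inheritParams generator_forward
#' @return Numeric vector of logits (or a tape node during training).
#' @export
discriminator_forward <- function(model, x, tape = NULL, P = NULL) {
  cfg <- model$cfg
  recording <- !is.null(tape)
  ops <- if (recording) ops_tape(tape) else ops_plain()
  if (is.null(P)) P <- model$params
  xv <- if (recording) nn_value(x) else x
  xv_in <- as_batch(xv)
  if (dim(xv_in)[3] != cfg$in_channels)
    stop(sprintf("input has %d channels; discriminator expects %d",
                 dim(xv_in)[3], cfg$in_channels))
  h <- if (recording) {
    if (is.environment(x)) x else nn_leaf(tape, xv_in)
  } else xv_in
  sl <- cfg$leaky_slope
  h <- ops$lrelu(ops$conv(h, P[["init.w"]], P[["init.b"]], 1L), sl)
  for (i in seq_len(cfg$residual_blocks))
    h <- ops$lrelu(resblock_fwd(ops, P, sprintf("block%d", i), h, sl,
                                stride2 = TRUE), sl)
  pre_pool <- dim(nn_value(h))[1:2]
  h <- ops$gap(h)
  h <- ops$lrelu(ops$fc(h, P[["fc1.w"]], P[["fc1.b"]]), sl)
  out <- ops$fc(h, P[["fc2.w"]], P[["fc2.b"]])
  if (recording) return(out)
  structure(as.numeric(out), pre_pool_dim = pre_pool)
}

#' @export
print.vstain_model <- function(x, ...) {
  cat(sprintf("<%s> %s network, %s parameters (scale 1/%d)\n",
              paste(class(x)[1]), x$kind,
              format(x$parameter_count, big.mark = ","), x$cfg$scale))
  invisible(x)
}

#' Per-level channel counts of an instantiated model
#'
#' Introspects the actual parameter array dimensions; used to verify that
#' the built network matches its configuration exactly.
#' @param model a `vstain_model`.
#' @return For a generator, list with `down_in`, `down_out`, `up_in`,
#'   `up_out`; for a discriminator, the channel vector.
#' @export
model_channels <- function(model) {
  p <- model$params
  if (model$kind == "generator") {
    list(
      down_in = vapply(1:4, function(i)
        dim(p[[sprintf("down%d.conv1.w", i)]])[3], numeric(1)),
      down_out = vapply(1:4, function(i)
        dim(p[[sprintf("down%d.conv2.w", i)]])[4], numeric(1)),
      # channels entering each up block from below = gating channels
      up_in = vapply(1:4, function(i)
        dim(p[[sprintf("up%d.att.wg.w", i)]])[3], numeric(1)),
      up_out = vapply(1:4, function(i)
        dim(p[[sprintf("up%d.conv2.w", i)]])[4], numeric(1)))
  } else {
    c(dim(p$init.w)[4],
      vapply(seq_len(model$cfg$residual_blocks), function(i)
        dim(p[[sprintf("block%d.conv2.w", i)]])[4], numeric(1)))
  }
}
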