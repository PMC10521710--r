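# Minimal reverse-mode autodiff tape over 4-D feature maps [H, W, C, N].
#
# Nodes are environments appended to a tape in execution order; backward()
# walks the tape in reverse, each node adding into its parents' gradients.
# Only the operations needed by the staining networks are implemented.

tape_new <- function() new.env(parent = emptyenv())

nn_node <- function(tape, value, parents = list(), backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  if (!is.null(tape)) {
    if (is.null(tape$nodes)) tape$nodes <- list()
    tape$nodes[[length(tape$nodes) + 1L]] <- node
  }
  node
}

nn_leaf <- function(tape, value, frozen = FALSE) {
  node <- nn_node(tape, value)
  node$frozen <- frozen
  node
}

nn_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
}

nn_backward <- function(tape, loss) {
  if (is.null(loss$grad)) loss$grad <- 1
  for (i in rev(seq_along(tape$nodes))) {
    node <- tape$nodes[[i]]
    if (!is.null(node$backward) && !is.null(node$grad)) node$backward(node)
  }
  invisible(NULL)
}

nn_value <- function(x) if (is.environment(x)) x$value else x

# --- primitive ops (node in, node out) --------------------------------------

op_conv <- function(tape, x, w, b, stride = 1L) {
  xd <- dim(x$value)
  if (isTRUE(w$frozen)) {
    # weight gradients are not needed; keep the forward light as well
    y <- cpp_conv2d_fwd(x$value, w$value, b$value, stride)
    return(nn_node(tape, y, list(x = x), function(node)
      nn_accum(x, cpp_conv2d_bwd_x(xd, w$value, node$grad, stride))))
  }
  r <- cpp_conv2d_fwd_cache(x$value, w$value, b$value, stride)
  nn_node(tape, r$y, list(x = x, w = w, b = b), function(node) {
    g <- cpp_conv2d_bwd_cached(r$cache, xd, w$value, node$grad, stride)
    nn_accum(x, g$gx); nn_accum(w, g$gw); nn_accum(b, g$gb)
  })
}

op_leaky_relu <- function(tape, x, slope = 0.1) {
  y <- cpp_lrelu_fwd(x$value, slope)
  nn_node(tape, y, list(x = x), function(node)
    nn_accum(x, cpp_lrelu_bwd(y, node$grad, slope)))
}

op_relu <- function(tape, x) op_leaky_relu(tape, x, slope = 0)

op_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$value))
  nn_node(tape, y, list(x = x), function(node)
    nn_accum(x, node$grad * y * (1 - y)))
}

op_add <- function(tape, x, y) {
  nn_node(tape, x$value + y$value, list(x = x, y = y), function(node) {
    nn_accum(x, node$grad); nn_accum(y, node$grad)
  })
}

op_maxpool <- function(tape, x) {
  r <- cpp_maxpool2_fwd(x$value)
  H <- dim(x$value)[1]; W <- dim(x$value)[2]
  nn_node(tape, r$y, list(x = x), function(node)
    nn_accum(x, cpp_maxpool2_bwd(node$grad, r$idx, H, W)))
}

op_upsample2 <- function(tape, x) {
  nn_node(tape, cpp_upsample2_fwd(x$value), list(x = x), function(node)
    nn_accum(x, cpp_upsample2_bwd(node$grad)))
}

op_concat <- function(tape, x, y) {
  dx <- dim(x$value); dy <- dim(y$value)
  v <- array(0, c(dx[1], dx[2], dx[3] + dy[3], dx[4]))
  v[, , seq_len(dx[3]), ] <- x$value
  v[, , dx[3] + seq_len(dy[3]), ] <- y$value
  nn_node(tape, v, list(x = x, y = y), function(node) {
    nn_accum(x, node$grad[, , seq_len(dx[3]), , drop = FALSE])
    nn_accum(y, node$grad[, , dx[3] + seq_len(dy[3]), , drop = FALSE])
  })
}

# multiply feature maps x [H,W,C,N] by a single-channel gate a [H,W,1,N]
op_gate_mul <- function(tape, x, a) {
  dx <- dim(x$value)
  ab <- array(0, dx)
  for (ci in seq_len(dx[3])) ab[, , ci, ] <- a$value[, , 1, ]
  v <- x$value * ab
  nn_node(tape, v, list(x = x, a = a), function(node) {
    nn_accum(x, node$grad * ab)
    s <- node$grad * x$value
    dim(s) <- c(dx[1] * dx[2], dx[3], dx[4])
    ga <- s[, 1, ]
    for (ci in seq_len(dx[3])[-1]) ga <- ga + s[, ci, ]
    nn_accum(a, array(ga, c(dx[1], dx[2], 1, dx[4])))
  })
}

op_gap <- function(tape, x) {
  d <- dim(x$value)
  xm <- x$value
  dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  v <- colMeans(xm)
  dim(v) <- d[3:4]
  nn_node(tape, v, list(x = x), function(node) {
    g <- node$grad / (d[1] * d[2])
    gx <- array(rep(g, each = d[1] * d[2]), d)
    nn_accum(x, gx)
  })
}

# fully connected: x [Cin, N], w [Cin, Cout], b [Cout] -> [Cout, N]
op_fc <- function(tape, x, w, b) {
  v <- crossprod(w$value, x$value) + b$value
  nn_node(tape, v, list(x = x, w = w, b = b), function(node) {
    nn_accum(x, w$value %*% node$grad)
    if (!isTRUE(w$frozen)) {
      nn_accum(w, x$value %*% t(node$grad))
      nn_accum(b, rowSums(node$grad))
    }
  })
}

# --- scalar loss ops --------------------------------------------------------

op_smooth_l1 <- function(tape, x, target, beta = 1) {
  d <- x$value - target
  n <- length(d)
  ad <- abs(d)
  quad <- (ad < beta)
  v <- sum(quad * (0.5 * d * d / beta) + (1 - quad) * (ad - 0.5 * beta)) / n
  nn_node(tape, v, list(x = x), function(node) {
    g <- (quad * (d / beta) + (1 - quad) * sign(d)) / n
    dim(g) <- dim(x$value)
    nn_accum(x, node$grad * g)
  })
}

op_mse <- function(tape, x, target) {
  d <- x$value - target
  n <- length(d)
  nn_node(tape, mean(d^2), list(x = x), function(node) {
    g <- 2 * d / n
    dim(g) <- dim(x$value)
    nn_accum(x, node$grad * g)
  })
}

# -log((1 + SSIM(target, x))/2), global statistics per channel and image,
# averaged; analytic gradient through the SSIM ratio.
op_neg_log_ssim <- function(tape, x, target, c1 = 1e-4, c2 = 9e-4) {
  xv <- x$value
  d <- dim(xv)
  C <- d[3]; N <- d[4]; n <- d[1] * d[2]
  S <- matrix(0, C, N)
  grads <- vector("list", C * N)
  for (ni in seq_len(N)) for (ci in seq_len(C)) {
    A <- target[, , ci, ni]; B <- xv[, , ci, ni]
    muA <- mean(A); muB <- mean(B)
    Ac <- A - muA; Bc <- B - muB
    vA <- sum(Ac^2) / n; vB <- sum(Bc^2) / n
    cAB <- sum(Ac * Bc) / n
    P <- 2 * muA * muB + c1; Q <- 2 * cAB + c2
    R <- muA^2 + muB^2 + c1; TT <- vA + vB + c2
    S[ci, ni] <- (P * Q) / (R * TT)
    # dS/dB
    dP <- 2 * muA / n
    dQ <- 2 * Ac / n
    dR <- 2 * muB / n
    dT <- 2 * Bc / n
    dS <- (Q * dP + P * dQ) / (R * TT) -
      (P * Q) * (TT * dR + R * dT) / (R * TT)^2
    grads[[(ni - 1) * C + ci]] <- dS
  }
  Sbar <- mean(S)
  v <- -log((1 + Sbar) / 2)
  nn_node(tape, v, list(x = x), function(node) {
    g <- array(0, d)
    scale <- node$grad * (-1 / (1 + Sbar)) / (C * N)
    for (ni in seq_len(N)) for (ci in seq_len(C))
      g[, , ci, ni] <- scale * grads[[(ni - 1) * C + ci]]
    nn_accum(x, g)
  })
}

# mean BCE-with-logits; q is a scalar label or one label per element of p
op_bce_logits <- function(tape, p, q) {
  pv <- p$value
  if (length(q) > 1L) q <- as.numeric(q)
  n <- length(pv)
  v <- mean(pmax(pv, 0) - pv * q + log1p(exp(-abs(pv))))
  nn_node(tape, v, list(p = p), function(node) {
    s <- 1 / (1 + exp(-pv))
    g <- (s - q) / n
    if (!is.null(dim(pv))) dim(g) <- dim(pv)
    nn_accum(p, node$grad * g)
  })
}

op_scalar_comb <- function(tape, nodes, weights) {
  v <- sum(mapply(function(nd, w) w * nd$value, nodes, weights))
  nn_node(tape, v, nodes, function(node) {
    for (i in seq_along(nodes)) nn_accum(nodes[[i]], node$grad * weights[i])
  })
}
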