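test_that("loss primitives match brute-force oracles on random images", {
  set.seed(123)
  for (i in 1:100) {
    a <- matrix(runif(64, -1, 2), 8, 8)
    b <- matrix(runif(64, -1, 2), 8, 8)
    beta <- runif(1, 0.3, 2)
    expect_equal(smooth_l1(a, b, beta), smooth_l1_oracle(a, b, beta),
                 tolerance = 1e-10)
    expect_equal(ssim(a, b), ssim_oracle(a, b), tolerance = 1e-10)
    p <- runif(1, -8, 8); q <- sample(0:1, 1)
    expect_equal(bce_logits(p, q), bce_oracle(p, q), tolerance = 1e-10)
  }
})

test_that("loss closed-form spot values are exact", {
  one <- matrix(1, 4, 4)
  expect_equal(smooth_l1(one, one), 0)
  expect_equal(smooth_l1(one, one - 0.5, beta = 1), 0.125)
  expect_equal(smooth_l1(matrix(2, 1, 1), matrix(0, 1, 1), beta = 1), 1.5)

  set.seed(4); x <- matrix(runif(64), 8, 8)
  expect_equal(ssim(x, x), 1)
  expect_equal(ssim(matrix(0, 4, 4), matrix(0, 4, 4)), 1)
  expect_equal(ssim(matrix(0, 4, 4), matrix(1, 4, 4)),
               1e-4 / (1 + 1e-4), tolerance = 1e-12)

  expect_equal(bce_logits(0, 1), log(2), tolerance = 1e-12)
  expect_lt(bce_logits(100, 1), 1e-10)
  expect_equal(bce_logits(log(3), 1), -log(0.75), tolerance = 1e-12)
  expect_true(is.finite(bce_logits(1e4, 0)))
  expect_error(bce_logits(0, 0.5), "0 or 1")

  # generator loss at perfect reconstruction, d_logit 0
  expect_equal(generator_loss(x, x, 0), 0.5 * log(2), tolerance = 1e-12)
  # discriminator loss spot values
  expect_equal(discriminator_loss(0, 0), 2 * log(2), tolerance = 1e-12)
  expect_lt(discriminator_loss(-100, 100), 1e-10)
})

test_that("generator loss decreases monotonically toward the target", {
  set.seed(11)
  target <- array(runif(16 * 16 * 3), c(16, 16, 3))
  start <- array(runif(16 * 16 * 3), c(16, 16, 3))
  ts <- seq(0, 1, by = 0.1)
  losses <- sapply(ts, function(t)
    generator_loss(start + t * (target - start), target, d_logit = 0.3))
  expect_true(all(diff(losses) < 0))
})

test_that("windowed SSIM stays in range and detects distortion", {
  p <- simulate_pair(2, tiny_geometry(), seed = 2)
  s_self <- ssim(p$ihc, p$ihc, mode = "window")
  expect_equal(s_self, 1)
  noisy <- clamp01(p$ihc + array(rnorm(length(p$ihc), 0, 0.1), dim(p$ihc)))
  s_noisy <- ssim(p$ihc, noisy, mode = "window")
  expect_lt(s_noisy, 0.95)
  expect_gt(s_noisy, -1)
})

test_that("tape gradients match numeric differentiation per operation", {
  set.seed(21)
  num_grad <- function(f, v, eps = 1e-3) {
    g <- v * 0
    for (i in seq_along(v)) {
      vp <- v; vp[i] <- v[i] + eps
      vm <- v; vm[i] <- v[i] - eps
      g[i] <- (f(vp) - f(vm)) / (2 * eps)
    }
    g
  }
  x <- array(runif(4 * 4 * 2 * 1, -1, 1), c(4, 4, 2, 1))
  w <- array(rnorm(3 * 3 * 2 * 3, 0, 0.5), c(3, 3, 2, 3))
  b <- rnorm(3)
  run <- function(make_graph, leaf_val) {
    tape <- vstain:::tape_new()
    leaf <- vstain:::nn_leaf(tape, leaf_val)
    loss <- make_graph(tape, leaf)
    vstain:::nn_backward(tape, loss)
    leaf$grad
  }
  # conv wrt input
  tgt <- array(runif(4 * 4 * 3), c(4, 4, 3, 1))
  graph_conv <- function(tape, leaf) {
    wl <- vstain:::nn_leaf(tape, w); bl <- vstain:::nn_leaf(tape, b)
    y <- vstain:::op_conv(tape, leaf, wl, bl, 1L)
    vstain:::op_mse(tape, y, tgt)
  }
  g_tape <- run(graph_conv, x)
  f_num <- function(v) {
    y <- vstain:::cpp_conv2d_fwd(array(v, dim(x)), w, b, 1L)
    mean((y - tgt)^2)
  }
  # forward runs in single precision; central differences carry the
  # corresponding noise floor
  expect_equal(as.numeric(g_tape), as.numeric(num_grad(f_num, as.numeric(x))),
               tolerance = 2e-2)

  # ssim log-term gradient (smooth everywhere)
  t2 <- array(runif(6 * 6 * 1), c(6, 6, 1, 1))
  g2 <- run(function(tape, leaf) vstain:::op_neg_log_ssim(tape, leaf, t2),
            array(runif(36), c(6, 6, 1, 1)))
  x2 <- array(runif(36), c(6, 6, 1, 1))
  g2 <- run(function(tape, leaf) vstain:::op_neg_log_ssim(tape, leaf, t2), x2)
  f2 <- function(v) -log((1 + ssim_oracle(array(v, dim(x2)), t2)) / 2)
  expect_equal(as.numeric(g2), as.numeric(num_grad(f2, as.numeric(x2))),
               tolerance = 1e-6)

  # bce-with-logits gradient
  pv <- matrix(rnorm(4), 1, 4)
  g3 <- run(function(tape, leaf) vstain:::op_bce_logits(tape, leaf, 1), pv)
  f3 <- function(v) bce_oracle(v, 1)
  expect_equal(as.numeric(g3), as.numeric(num_grad(f3, as.numeric(pv))),
               tolerance = 1e-6)

  # gate multiply gradient wrt the gate
  xs <- array(runif(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  av <- array(runif(4 * 4 * 1 * 2), c(4, 4, 1, 2))
  tgt2 <- array(runif(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  g4 <- run(function(tape, leaf) {
    xl <- vstain:::nn_leaf(tape, xs)
    y <- vstain:::op_gate_mul(tape, xl, leaf)
    vstain:::op_mse(tape, y, tgt2)
  }, av)
  f4 <- function(v) {
    a <- array(v, dim(av))
    y <- xs
    for (ci in 1:3) y[, , ci, ] <- y[, , ci, ] * a[, , 1, ]
    mean((y - tgt2)^2)
  }
  expect_equal(as.numeric(g4), as.numeric(num_grad(f4, as.numeric(av))),
               tolerance = 1e-6)
})

test_that("generator architecture conforms to its configuration", {
  cfg <- generator_config(scale = 8)
  expect_equal(cfg$down_in, c(4, 8, 16, 32))
  expect_equal(cfg$down_out, c(8, 16, 32, 64))
  expect_equal(cfg$up_in, c(128, 128, 64, 32))
  expect_equal(cfg$up_out, c(128, 64, 32, 16))

  g <- build_generator(cfg, seed = 1)
  ch <- model_channels(g)
  expect_equal(ch$down_in, cfg$down_in)
  expect_equal(ch$down_out, cfg$down_out)
  expect_equal(ch$up_in, cfg$up_in)
  expect_equal(ch$up_out, cfg$up_out)

  # fully convolutional on any multiple of 16
  x <- array(runif(96 * 128 * 4), c(96, 128, 4))
  y <- generator_forward(g, x)
  expect_equal(dim(y), c(96, 128, 3))
  expect_error(generator_forward(g, array(0, c(40, 40, 4))), "divisible by 16")
  expect_error(generator_forward(g, array(0, c(96, 96, 3))), "channels")

  # attention maps are sigmoid outputs in [0, 1]
  r <- generator_forward(g, array(runif(64 * 64 * 4), c(64, 64, 4)),
                         with_attention = TRUE)
  for (a in r$attention) {
    expect_gte(min(a), 0); expect_lte(max(a), 1)
  }

  # seeded initialisation is reproducible
  g2 <- build_generator(cfg, seed = 1)
  expect_identical(g$params, g2$params)
})

test_that("discriminator reduces to a single logit through five 2x stages", {
  cfg <- discriminator_config(scale = 8)
  d <- build_discriminator(cfg, seed = 2)
  expect_equal(model_channels(d), c(8, 16, 32, 64, 128, 256))
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  lg <- discriminator_forward(d, x)
  expect_length(lg, 1)
  expect_equal(attr(lg, "pre_pool_dim"), c(2, 2))   # 64 / 2^5
  expect_error(discriminator_forward(d, array(0, c(64, 64, 4))), "channels")

  d2 <- build_discriminator(cfg, seed = 2)
  expect_identical(discriminator_forward(d2, x), lg)

  # batch input gives one logit per image
  xb <- array(runif(32 * 32 * 3 * 4), c(32, 32, 3, 4))
  expect_length(as.numeric(discriminator_forward(d, xb)), 4)
})
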