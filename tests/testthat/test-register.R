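# A reusable textured test slide: the DAPI-like channel of a synthetic tile.
make_slide <- function(size = 256, seed = 31) {
  p <- simulate_pair(3, her2_geometry(height = size, width = size),
                     seed = seed)
  list(af = p$af, ihc = p$ihc, chan = af_reference_channel(p$af),
       latent = p$latent)
}

test_that("global feature registration recovers known transforms", {
  sl <- make_slide(256)
  img <- sl$chan

  tf <- global_register(img, img)
  expect_equal(tf$matrix, rbind(c(1, 0, 0), c(0, 1, 0)), tolerance = 0.1)
  expect_lt(tf$residual, 0.1)
  expect_gte(tf$inlier_count, 3)

  # moving = fixed shifted by (12, -7): pull-back field (12, -7)
  shift <- deformation_field(matrix(12, 256, 256), matrix(-7, 256, 256))
  moving <- warp_image(img, shift)
  tf2 <- global_register(moving, img)
  expect_equal(tf2$matrix[, 3], c(12, -7), tolerance = 0.5)
  expect_equal(tf2$matrix[, 1:2], diag(2), tolerance = 0.01)

  # aligning the moving image back onto the fixed frame
  aligned <- apply_affine(moving, tf2)
  inner <- 30:220
  expect_lt(mean(abs(aligned[inner, inner] - img[inner, inner])), 0.02)

  expect_error(global_register(matrix(0.5, 128, 128), img),
               "registration failure")
})

test_that("tile pairing follows grid arithmetic with shared origins", {
  af <- array(runif(1024 * 1024 * 2), c(1024, 1024, 2))
  bf <- array(runif(1024 * 1024 * 3), c(1024, 1024, 3))
  p1 <- crop_tile_pairs(af, bf, tile_size = 256, stride = 256)
  expect_length(p1, 16)
  p2 <- crop_tile_pairs(af, bf, tile_size = 256, stride = 128)
  expect_length(p2, 49)   # ((1024 - 256) / 128 + 1)^2
  for (pr in p2[c(1, 25, 49)]) {
    o <- pr$origin
    expect_identical(pr$af,
                     af[(o[1] + 1):(o[1] + 256), (o[2] + 1):(o[2] + 256), ,
                        drop = FALSE])
    expect_identical(pr$ihc,
                     bf[(o[1] + 1):(o[1] + 256), (o[2] + 1):(o[2] + 256), ,
                        drop = FALSE])
  }
  expect_error(crop_tile_pairs(af, bf, tile_size = 2048), "exceeds")
})

test_that("pyramid elastic registration recovers a known sinusoidal warp", {
  sl <- make_slide(256, seed = 5)
  # displacement is only observable where there is texture; the AF channel
  # carries stromal signal everywhere
  img <- sl$chan

  # self-registration: essentially zero field
  f0 <- pyramid_elastic_register(img, img, block_size = 64)
  expect_lt(sqrt(mean(f0$dr^2 + f0$dc^2)), 0.1)

  spec <- warp_spec(shape = c(256, 256), elastic_amplitude = 6,
                    elastic_period = 128, seed = 3)
  truth <- make_warp(spec)
  warped <- warp_image(img, truth)
  f <- pyramid_elastic_register(img, warped, block_size = 64)
  # the recovered pull-back field must match the numeric inverse of the
  # applied warp (warping `warped` by it must undo the deformation)
  tinv <- field_inverse(truth)
  epe <- sqrt((f$dr - tinv$dr)^2 + (f$dc - tinv$dc)^2)
  inner <- 17:240
  expect_lt(mean(epe[inner, inner]), 1.0)
  expect_lte(attr(f, "smoothness"), 1)

  expect_error(pyramid_elastic_register(img, warped, block_size = 512),
               "block_size larger")
})

test_that("composite translation + elastic warps are recovered end to end", {
  sl <- make_slide(256, seed = 8)
  fixed <- sl$chan
  spec <- warp_spec(shape = c(256, 256),
                    affine = rbind(c(1, 0, 8), c(0, 1, -5)),
                    elastic_amplitude = 6, elastic_period = 128, seed = 9)
  truth <- make_warp(spec)
  moving <- warp_image(fixed, truth)

  tf <- global_register(moving, fixed)
  aligned <- apply_affine(moving, tf)
  f <- pyramid_elastic_register(fixed, aligned, block_size = 64)
  # total recovered field (affine then elastic) vs the inverse ground truth
  A <- rbind(tf$matrix, c(0, 0, 1))
  Ai <- solve(A)
  r <- matrix(0:255, 256, 256); cc <- matrix(0:255, 256, 256, byrow = TRUE)
  f_aff <- deformation_field(Ai[1, 1] * r + Ai[1, 2] * cc + Ai[1, 3] - r,
                             Ai[2, 1] * r + Ai[2, 2] * cc + Ai[2, 3] - cc)
  total <- compose_fields(f_aff, f)
  tinv <- field_inverse(truth)
  inner <- 25:232
  epe <- sqrt((total$dr - tinv$dr)^2 + (total$dc - tinv$dc)^2)
  expect_lt(mean(epe[inner, inner]), 1.0)
  recovered <- warp_image(aligned, f)
  expect_lt(mean(abs(recovered[inner, inner] - fixed[inner, inner])), 0.05)
})

test_that("iterated refinement converges and respects the round cap", {
  geo <- her2_geometry(height = 96, width = 96)
  mk <- function(seed) simulate_pair(2, geo, seed = seed)
  base <- lapply(1:3, mk)
  # oracle style bridge: returns the true aligned brightfield render
  oracle_trainer <- function(aligned) function(pairs, state = NULL) {
    k <- 0
    list(predict = function(af) {
      k <<- k + 1
      aligned[[k]]$ihc
    }, state = NULL)
  }

  # perfectly pre-aligned pairs stop after round 1
  pairs0 <- lapply(base, function(p) list(af = p$af, ihc = p$ihc))
  out0 <- iterate_refine(pairs0, oracle_trainer(base), tol = 0.5,
                         register_args = list(block_size = 32,
                                              levels = 2L))
  expect_equal(attr(out0, "rounds"), 1)
  expect_true(attr(out0, "converged"))
  expect_lt(attr(out0, "residuals")[1], 0.5)

  # 6-px elastic misalignment: residual decreases and ends < 1 px
  spec <- warp_spec(shape = c(96, 96), elastic_amplitude = 6,
                    elastic_period = 96, seed = 2)
  f <- make_warp(spec)
  pairs1 <- lapply(base, function(p)
    list(af = p$af, ihc = warp_image(p$ihc, f)))
  out1 <- iterate_refine(pairs1, oracle_trainer(base), max_rounds = 5,
                         tol = 0.3,
                         register_args = list(block_size = 32, levels = 2L))
  res <- attr(out1, "residuals")
  expect_lte(length(res), 5)
  expect_true(all(diff(res) < 0))
  expect_lt(res[length(res)], 1)
  expect_true(all(vapply(out1, `[[`, logical(1), "clean")))

  # max_rounds is hard-capped at 5
  out2 <- iterate_refine(pairs1, oracle_trainer(base), max_rounds = 99,
                         tol = 0,
                         register_args = list(block_size = 32, levels = 2L))
  expect_lte(attr(out2, "rounds"), 5)
})

test_that("re-registering an aligned pair is nearly idempotent", {
  sl <- make_slide(256, seed = 13)
  img <- sl$chan
  spec <- warp_spec(shape = c(256, 256), elastic_amplitude = 4,
                    elastic_period = 96, seed = 1)
  warped <- warp_image(img, make_warp(spec))
  f1 <- pyramid_elastic_register(img, warped, block_size = 64)
  once <- warp_image(warped, f1)
  f2 <- pyramid_elastic_register(img, once, block_size = 64)
  rms <- function(f) sqrt(mean(f$dr^2 + f$dc^2))
  # the overall solution barely changes when registration is repeated
  expect_lt(abs(rms(compose_fields(f1, f2)) - rms(f1)), 0.2)
  # and the repeat pass reports an essentially aligned pair
  expect_lt(attr(f2, "residual_median"), 0.5)
})
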