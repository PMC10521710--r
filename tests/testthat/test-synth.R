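test_that("latent maps encode the per-grade membrane phenotypes", {
  geo <- tiny_geometry()

  l0 <- generate_latent(0, geo, seed = 7)
  expect_equal(sum(l0$membrane_mask), 0)
  expect_false(any(l0$complete_ring_flags))

  l3 <- generate_latent(3, geo, seed = 1)
  expect_gte(mean(l3$complete_ring_flags), 0.10)
  expect_gt(sum(l3$membrane_mask), 0)

  l1 <- generate_latent("1+", geo, seed = 2)
  st <- l1$cells$completeness[l1$cells$stained & !l1$complete_ring_flags]
  expect_true(all(st < 0.5))

  # seeded determinism, bit identical
  a <- generate_latent(2, geo, seed = 5)
  b <- generate_latent(2, geo, seed = 5)
  expect_identical(a, b)

  expect_error(generate_latent(5, geo, 1), "0..3")
  expect_error(generate_latent(1, her2_geometry(height = -4), 1), "positive")
})

test_that("latent geometry invariants hold across grades and seeds", {
  geo <- tiny_geometry()
  for (g in 0:3) for (s in 1:3) {
    l <- generate_latent(g, geo, seed = s)
    # nucleus and membrane masks essentially disjoint
    expect_lt(mean(l$nucleus_mask & l$membrane_mask), 0.001)
    expect_equal(max(l$nucleus_labels), nrow(l$cells))
    if (any(l$membrane_mask)) {
      # every membrane pixel within the ring annulus of some nucleus centre
      mem <- which(l$membrane_mask, arr.ind = TRUE)
      rmax <- max(l$cells$radius) + geo$membrane_gap +
        max(geo$grade_table$ring_thickness) + 1.5
      d2 <- outer(mem[, 1], l$cells$row, `-`)^2 +
        outer(mem[, 2], l$cells$col, `-`)^2
      expect_true(all(apply(d2, 1, min) <= rmax^2))
    }
    expect_true(all(l$stroma_field >= 0 & l$stroma_field <= 1))
  }
})

test_that("rendered pairs follow Beer-Lambert and the AF mixing model", {
  geo <- tiny_geometry()
  # empty latent renders white
  l <- generate_latent(0, geo, seed = 3)
  l$nucleus_density[] <- 0; l$membrane_density[] <- 0
  l$cytoplasm_density[] <- 0
  p <- render_pair(l, her2_optics())
  expect_true(all(p$ihc >= 0.99))

  # DAPI channel dominated by nuclei
  p2 <- simulate_pair(2, geo, seed = 4)
  dapi <- p2$af[, , "DAPI"]
  expect_gt(mean(dapi[p2$latent$nucleus_mask]),
            mean(dapi[!p2$latent$nucleus_mask]))

  # DAB optical density concentrated on the membrane mask
  p3 <- simulate_pair(3, geo, seed = 1)
  sep <- separate_stains(p3$ihc)
  on <- mean(sep$dab_od[p3$latent$membrane_mask])
  off <- mean(sep$dab_od[!p3$latent$membrane_mask])
  expect_gt(on, 5 * off)

  # bit-identical seeded rendering
  expect_identical(simulate_pair(2, geo, seed = 9), simulate_pair(2, geo, seed = 9))

  expect_error(her2_optics(hema_od = -1), "non-negative")
})

test_that("AF channels carry learnable information about the latent maps", {
  p <- simulate_pair(3, tiny_geometry(), seed = 6)
  y <- as.numeric(p$latent$nucleus_mask)
  X <- cbind(as.numeric(p$af[, , 1]), as.numeric(p$af[, , 2]),
             as.numeric(p$af[, , 3]), as.numeric(p$af[, , 4]))
  r2 <- function(X) summary(lm(y ~ X))$r.squared
  set.seed(1)
  expect_gt(r2(X), r2(X[sample(nrow(X)), ]) + 0.3)
})

test_that("warp specifications materialise with the stated bounds", {
  # identity, zero amplitude
  f <- make_warp(warp_spec(shape = c(32, 48)))
  expect_equal(max(abs(f$dr)), 0)
  expect_equal(max(abs(f$dc)), 0)

  # pure translation
  tr <- warp_spec(shape = c(32, 32),
                  affine = rbind(c(1, 0, 12), c(0, 1, -7)))
  f <- make_warp(tr)
  expect_true(all(f$dr == 12) && all(f$dc == -7))

  # sinusoid magnitude bound
  f <- make_warp(warp_spec(shape = c(128, 128), elastic_amplitude = 6,
                           elastic_period = 128, seed = 2))
  expect_lte(max(sqrt(f$dr^2 + f$dc^2)), 6 + 1e-9)

  expect_error(warp_spec(elastic_amplitude = 3, elastic_period = 0),
               "positive")
  expect_error(warp_spec(elastic_amplitude = -1), ">= 0")
})

test_that("warping resamples correctly and inverts numerically", {
  set.seed(8)
  img <- vstain:::cpp_gauss_blur(matrix(runif(64 * 64), 64, 64), 2)

  zero <- deformation_field(matrix(0, 64, 64), matrix(0, 64, 64))
  expect_identical(warp_image(img, zero), img)

  const <- matrix(0.7, 64, 64)
  f <- make_warp(warp_spec(shape = c(64, 64), elastic_amplitude = 4,
                           elastic_period = 96, seed = 1))
  expect_equal(warp_image(const, f), const, tolerance = 1e-12)

  # warp then warp by the numeric inverse recovers the interior
  w <- warp_image(img, f)
  back <- warp_image(w, field_inverse(f))
  interior <- 9:56
  expect_lt(mean(abs(back[interior, interior] - img[interior, interior])),
            0.01)

  bad <- deformation_field(matrix(0, 8, 8), matrix(0, 8, 8))
  expect_error(warp_image(img, bad), "match")
})

test_that("warped values stay within the input range (interpolation property)", {
  set.seed(3)
  img <- matrix(runif(32 * 32), 32, 32)
  f <- make_warp(warp_spec(shape = c(32, 32), elastic_amplitude = 5,
                           elastic_period = 40, seed = 4))
  w <- warp_image(img, f)
  expect_gte(min(w), min(img) - 1e-12)
  expect_lte(max(w), max(img) + 1e-12)
})
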