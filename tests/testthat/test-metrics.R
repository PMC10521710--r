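test_that("colour deconvolution inverts Beer-Lambert rendering", {
  M <- default_stain_matrix()
  # white pixel carries no stain
  white <- array(1, c(2, 2, 3))
  s <- separate_stains(white, M)
  expect_equal(max(s$hematoxylin_od), 0)
  expect_equal(max(s$dab_od), 0)

  # pure hematoxylin density 0.5 round trip
  h <- matrix(0.5, 4, 4)
  rgb <- render_stains(list(hematoxylin = h), M)
  s <- separate_stains(rgb, M)
  expect_equal(s$hematoxylin_od, h, tolerance = 1e-6)
  expect_lt(max(s$dab_od), 1e-6)

  # log-domain linearity: doubling density doubles recovery
  rgb2 <- render_stains(list(hematoxylin = 2 * h), M)
  s2 <- separate_stains(rgb2, M)
  expect_equal(s2$hematoxylin_od, 2 * s$hematoxylin_od, tolerance = 1e-6)

  bad <- M; bad[3, ] <- bad[1, ]
  expect_error(separate_stains(rgb, bad), "singular")
})

test_that("stain separation round trip on full synthetic tiles", {
  for (g in c(1, 3)) {
    p <- simulate_pair(g, tiny_geometry(), seed = g + 10)
    h_true <- her2_optics()$hema_od * p$latent$nucleus_density
    d_true <- p$latent$membrane_density +
      p$latent$cyto_dab_od * p$latent$cytoplasm_density
    s <- separate_stains(p$ihc)
    expect_lt(max(abs(s$hematoxylin_od - h_true)), 1e-3)
    expect_lt(max(abs(s$dab_od - d_true)), 1e-3)
  }
})

test_that("Otsu threshold maximises between-class variance", {
  # two-delta histogram: half at 0.2, half at 0.8 -> threshold inside (0.2, 0.8)
  x <- matrix(rep(c(0.2, 0.8), each = 128), 16, 16)
  th <- otsu_threshold(x)
  expect_gt(th, 0.2); expect_lt(th, 0.8)

  set.seed(5)
  y <- matrix(c(rnorm(200, 0.25, 0.03), rnorm(56, 0.75, 0.03)), 16, 16)
  th <- otsu_threshold(y)
  # the argmax can sit anywhere on the empty-gap plateau; compare the
  # between-class variance achieved instead
  bcv <- function(x, t) {
    w0 <- mean(x <= t); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(0)
    w0 * w1 * (mean(x[x > t]) - mean(x[x <= t]))^2
  }
  ref <- otsu_oracle(y, candidates = seq(min(y), max(y), length.out = 512))
  expect_gte(bcv(y, th), bcv(y, ref) - 1e-10)

  expect_error(otsu_threshold(matrix(0.4, 8, 8)), "degenerate")
})

test_that("nucleus statistics match a pixel-count oracle on disks", {
  # 25 disjoint disks of radius 6 on a clean background
  H <- 200
  h <- matrix(0, H, H)
  centers <- as.matrix(expand.grid(seq(20, 180, by = 40), seq(20, 180, by = 40)))
  for (i in seq_len(nrow(centers))) {
    rr <- centers[i, 1]; cc <- centers[i, 2]
    for (r in (rr - 7):(rr + 7)) for (c in (cc - 7):(cc + 7))
      if ((r - rr)^2 + (c - cc)^2 <= 36) h[r, c] <- 0.8
  }
  disk_area <- sum((outer((-7):7, (-7):7, function(a, b) a^2 + b^2)) <= 36)
  rgb <- render_stains(list(hematoxylin = h))
  ns <- nucleus_stats(separate_stains(rgb),
                      morph = list(radius = 0, min_area = 10))
  expect_equal(ns$count, 25)
  expect_equal(ns$mean_area, disk_area)

  blank <- separate_stains(array(1, c(8, 8, 3)))
  expect_error(nucleus_stats(blank), "degenerate")
})

test_that("connected components agree with a flood-fill oracle", {
  set.seed(77)
  for (i in 1:5) {
    mask <- matrix(runif(64 * 64) < 0.35, 64, 64)
    lab <- vstain:::cpp_label_components(matrix(as.integer(mask), 64), 8L)
    ref <- flood_fill_label(mask, 8L)
    expect_equal(max(lab), max(ref))
    expect_equal(sort(tabulate(lab[lab > 0])), sort(tabulate(ref[ref > 0])))
  }
  # 4- vs 8-connectivity differ on a diagonal pair
  diagm <- matrix(0L, 4, 4); diagm[1, 1] <- 1L; diagm[2, 2] <- 1L
  expect_equal(max(vstain:::cpp_label_components(diagm, 8L)), 1)
  expect_equal(max(vstain:::cpp_label_components(diagm, 4L)), 2)
})

test_that("characteristic curve on constructed saturation maps", {
  # saturation 0.9 on exactly 10% of pixels, one blob
  sat <- matrix(0, 40, 40)
  sat[1:10, 1:16] <- 0.9          # 160 px = 10% of 1600
  cs <- membrane_stats(sat)
  expect_equal(cs$area_ratio, rep(0.1, 21))
  expect_equal(cs$auc, 0.1 * 0.4, tolerance = 1e-12)
  expect_equal(cs$connectedness, 0.1)

  # two blobs 6% and 4%: connectedness takes the largest
  sat2 <- matrix(0, 40, 40)
  sat2[1:8, 1:12] <- 0.9          # 96 px = 6%
  sat2[30:37, 30:37] <- 0.9       # 64 px = 4%
  cs2 <- membrane_stats(sat2)
  expect_equal(cs2$connectedness, 0.06)
  expect_equal(cs2$area_ratio[1], 0.1)

  # DAB-free tile
  p0 <- simulate_pair(0, tiny_geometry(), seed = 3)
  cs0 <- membrane_stats(separate_stains(p0$ihc))
  expect_equal(cs0$auc, 0)
  expect_equal(cs0$connectedness, 0)

  expect_error(membrane_stats(sat, s_grid = numeric(0)), "non-empty")
  expect_error(membrane_stats(sat, s_grid = c(0.2, 1.5)), "\\(0, 1\\)")
})

test_that("area ratio is non-increasing in the saturation threshold", {
  for (g in 1:3) {
    p <- simulate_pair(g, tiny_geometry(), seed = g)
    cs <- membrane_stats(separate_stains(p$ihc))
    expect_true(all(diff(cs$area_ratio) <= 0))
    expect_gte(cs$auc, 0); expect_lte(cs$auc, 0.4)
  }
})

test_that("characteristic AUC orders the HER2 grades", {
  n_seeds <- 20
  aucs <- sapply(0:3, function(g) {
    mean(sapply(seq_len(n_seeds), function(s) {
      p <- simulate_pair(g, tiny_geometry(), seed = 100 * g + s)
      membrane_stats(separate_stains(p$ihc))$auc
    }))
  })
  expect_true(all(diff(aucs) > 0))
})

test_that("image quality metrics behave as defined", {
  p <- simulate_pair(2, tiny_geometry(), seed = 12)
  q <- image_quality(p$ihc, p$ihc)
  expect_equal(q$psnr, 100)
  expect_equal(q$ssim, 1)
  expect_equal(q$ssim_dab, 1)

  off <- clamp01(p$ihc * 0 + 0.5)
  shifted <- off + 0.1
  q2 <- image_quality(off, shifted)
  expect_equal(q2$psnr, 20, tolerance = 1e-9)
  expect_equal(q2$psnr, image_quality(shifted, off)$psnr)

  expect_error(image_quality(p$ihc, p$ihc[1:10, 1:10, ]), "identical dim")
})

test_that("colour histograms are normalised and smoothing conserves mass", {
  p <- simulate_pair(3, tiny_geometry(), seed = 9)
  s <- separate_stains(p$ihc)
  h <- color_histogram(s)
  for (ch in h) {
    expect_equal(sum(ch$raw_frequency), 1, tolerance = 1e-12)
    expect_equal(sum(ch$smoothed_profile), 1, tolerance = 0.01)
  }
  # identical input, identical histogram
  expect_identical(color_histogram(s), h)
  # constant channel occupies a single bin
  s$dab_od[] <- 0.4
  h2 <- color_histogram(s)
  expect_equal(sum(h2$dab$raw_frequency > 0), 1)
  expect_error(color_histogram(s, bandwidth = 0), "positive")
})
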