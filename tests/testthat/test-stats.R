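scores_path <- system.file("extdata", "synthetic_scores_wsi.csv",
                           package = "vstain")
quality_path <- system.file("extdata", "synthetic_scores_quality.csv",
                            package = "vstain")

test_that("score tables parse and validate", {
  d <- read_score_records(scores_path)
  expect_equal(nrow(d), 72)
  expect_setequal(unique(d$modality), c("virtual", "ihc"))
  bad <- d; bad$assigned[1] <- "4+"
  tf <- tempfile(fileext = ".csv"); write.csv(bad, tf, row.names = FALSE)
  expect_error(read_score_records(tf), "unknown HER2")
  q <- read_quality_records(quality_path)
  expect_true(all(is.na(q$grade) | q$grade %in% 1:4))
})

test_that("confusion matrices count every record exactly once", {
  d <- read_score_records(scores_path)
  for (m in c("virtual", "ihc")) {
    cm <- build_confusion(d, m)
    expect_equal(sum(cm), sum(d$modality == m))
    expect_equal(sum(cm), 36)
  }
  # perfectly concordant records give a diagonal matrix
  conc <- data.frame(wsi_id = sprintf("w%d", 1:36),
                     patient_id = sprintf("p%d", 1:36),
                     modality = "virtual", reader_id = "R1",
                     assigned = rep(her2_levels(), 9),
                     reference = rep(her2_levels(), 9))
  cm <- build_confusion(conc, "virtual")
  expect_equal(sum(diag(cm)), 36)
  expect_equal(sum(cm) - sum(diag(cm)), 0)
  expect_error(build_confusion(conc, "ihc"), "no records")
})

test_that("confusion summaries match brute-force cell sums", {
  d <- read_score_records(scores_path)
  vm <- build_confusion(d, "virtual")
  im <- build_confusion(d, "ihc")
  expect_equal(unname(confusion_summaries(vm)), c(22, 14))
  expect_equal(unname(confusion_summaries(im)), c(19, 18))

  # brute force over all 16 cells on random matrices
  set.seed(10)
  for (i in 1:10) {
    m <- matrix(rpois(16, 3), 4, 4)
    class(m) <- c("confusion_matrix4", class(m))
    s <- confusion_summaries(m)
    ref_diag <- m[1, 1] + m[2, 2] + m[3, 3] + m[4, 4]
    ref_off <- 0
    for (a in 1:4) for (b in 1:4)
      if (a != b) ref_off <- ref_off + m[a, b] * abs(a - b)
    expect_equal(unname(s), c(ref_diag, ref_off))
    # zero weighted error iff perfectly diagonal
    expect_equal(s["weighted_offdiag_error"] == 0,
                 s["diag_sum"] == sum(m), ignore_attr = TRUE)
  }

  # single off-diagonal entry at distance 2
  m <- matrix(0L, 4, 4); m[1, 3] <- 1L
  class(m) <- c("confusion_matrix4", class(m))
  expect_equal(unname(confusion_summaries(m)), c(0, 2))
})

test_that("chi-square agreement equals the Pearson formula", {
  tab <- rbind(c(10, 20), c(20, 10))
  r <- chi_square_test(tab)
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(r$statistic, chisq_oracle(tab), tolerance = 1e-10)
  expect_equal(r$df, 1)

  set.seed(3)
  for (i in 1:10) {
    tab <- matrix(rpois(8, 10) + 1, 2, 4)
    r <- suppressWarnings(chi_square_test(tab))
    expect_equal(r$statistic, chisq_oracle(tab), tolerance = 1e-10)
    r_swap <- suppressWarnings(chi_square_test(tab[2:1, ]))
    expect_equal(r$statistic, r_swap$statistic, tolerance = 1e-12)
  }

  d <- read_score_records(scores_path)
  vm <- build_confusion(d, "virtual"); im <- build_confusion(d, "ihc")
  ag <- chi_square_agreement(vm, im)
  expect_equal(ag$statistic, chisq_oracle(ag$table), tolerance = 1e-10)
  expect_gte(ag$p_value, 0); expect_lte(ag$p_value, 1)
  # identical matrices: zero statistic, p = 1
  ag0 <- chi_square_agreement(vm, vm)
  expect_equal(ag0$statistic, 0, tolerance = 1e-12)
  expect_equal(ag0$p_value, 1, tolerance = 1e-12)
})

test_that("paired one-sided t-tests match the reference implementation", {
  mk <- function(dv, di, metric = "background", reader = "R1") {
    n <- length(dv)
    rbind(data.frame(roi_id = sprintf("r%d", 1:n), modality = "virtual",
                     reader_id = reader, metric = metric, grade = dv),
          data.frame(roi_id = sprintf("r%d", 1:n), modality = "ihc",
                     reader_id = reader, metric = metric, grade = di))
  }
  # all differences zero: uninformative, p = 0.5
  r0 <- paired_quality_ttest(mk(c(3, 3, 3, 3), c(3, 3, 3, 3)),
                             "background", "R1")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 0.5)

  # IHC uniformly better by one grade: decisive
  r1 <- paired_quality_ttest(mk(c(2, 2, 2, 2), c(3, 3, 3, 3)),
                             "background", "R1")
  expect_lt(r1$p_value, 0.05)

  # random inputs against stats::t.test
  set.seed(8)
  for (i in 1:20) {
    dv <- sample(1:4, 8, replace = TRUE)
    di <- sample(1:4, 8, replace = TRUE)
    if (sd(dv - di) == 0) next
    r <- paired_quality_ttest(mk(dv, di), "background", "R1")
    ref <- t.test(dv - di, alternative = "less", mu = 0)
    expect_equal(r$p_value, unname(ref$p.value), tolerance = 1e-10)
    expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-10)
  }

  # p monotone in the mean difference at fixed spread
  base <- c(-1, 0, 1, 0, -1, 1, 0, 0)
  ps <- sapply(c(-2, -1, 0, 1, 2), function(sh)
    paired_quality_ttest(mk(base + sh, rep(0, 8)), "background", "R1")$p_value)
  expect_true(all(diff(ps) > 0))

  # membrane clearness pairs with missing members are dropped
  q <- mk(c(3, 3, NA, 2), c(3, 2, 3, NA), metric = "membrane_clearness")
  r <- paired_quality_ttest(q, "membrane_clearness", "R1")
  expect_equal(r$n, 2)
  expect_error(paired_quality_ttest(mk(3, 3), "background", "R1"), "2 complete")
})

test_that("ROI sampling is paired, seeded and counts 240 patches", {
  set.seed(1)
  mk_wsi <- function(id) {
    base <- array(runif(64 * 64 * 3, 0, 0.8), c(64, 64, 3))
    list(id = id, virtual = base, ihc = clamp01(base + 0.02))
  }
  wsis <- lapply(sprintf("W%02d", 1:12), mk_wsi)
  rois <- sample_rois(wsis, n_per_wsi = 10, roi_size = 16, seed = 4)
  expect_equal(nrow(rois), 120)
  expect_equal(attr(rois, "n_patches"), 240)
  # identical origins in both modalities by construction; patch contents
  # correspond to the same coordinates
  patches <- attr(rois, "patches")
  p1 <- patches[[rois$roi_id[1]]]
  o <- rois[1, c("row", "col")]
  expect_identical(p1$virtual,
                   wsis[[1]]$virtual[(o$row + 1):(o$row + 16),
                                     (o$col + 1):(o$col + 16), , drop = FALSE])
  expect_identical(dim(p1$virtual), dim(p1$ihc))

  r2 <- sample_rois(wsis, n_per_wsi = 10, roi_size = 16, seed = 4)
  expect_identical(as.data.frame(rois), as.data.frame(r2))
  expect_error(sample_rois(wsis, 1, roi_size = 128, seed = 1), "smaller")
})
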