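test_that("patient-level splits are disjoint, covering and deterministic", {
  records <- data.frame(
    patient_id = rep(sprintf("P%02d", 1:10), each = 4),
    tile_id = sprintf("t%03d", 1:40))
  sp <- split_by_patient(records, c(0.8, 0.1, 0.1), seed = 0)
  all_ids <- c(sp$train_ids, sp$val_ids, sp$test_ids)
  expect_setequal(all_ids, records$tile_id)
  expect_equal(anyDuplicated(all_ids), 0)

  # every patient's tiles land in exactly one split
  for (p in unique(records$patient_id)) {
    tiles <- records$tile_id[records$patient_id == p]
    hits <- c(all(tiles %in% sp$train_ids), all(tiles %in% sp$val_ids),
              all(tiles %in% sp$test_ids))
    expect_equal(sum(hits), 1)
  }

  expect_identical(sp, split_by_patient(records, c(0.8, 0.1, 0.1), seed = 0))
  # some seed reshuffles the patient assignment
  others <- lapply(1:5, function(s) split_by_patient(records, seed = s))
  expect_true(any(!vapply(others, identical, logical(1), sp)))
  expect_error(split_by_patient(records[1:8, ], seed = 0), "3 patients")
})

test_that("crop sampling is co-located, seeded and validated", {
  p <- tiny_pairs()[[1]]
  crops <- sample_crops(p, crop = 32, n = 5, seed = 3)
  expect_length(crops, 5)
  for (cr in crops) {
    expect_equal(dim(cr$af), c(32, 32, 4))
    expect_equal(dim(cr$target), c(32, 32, 3))
    o <- cr$offset
    expect_identical(cr$af,
                     p$af[(o[1] + 1):(o[1] + 32), (o[2] + 1):(o[2] + 32), ])
  }
  expect_identical(crops, sample_crops(p, 32, 5, seed = 3))
  expect_length(sample_crops(p, 32, 0), 0)
  expect_error(sample_crops(p, 1024, 1), "exceeds")

  # the flip/rotation helper matches a base-R oracle, so identical calls on
  # af and target keep the members co-located
  x <- array(seq_len(4 * 4 * 2), c(4, 4, 2))
  r90 <- vstain:::rot_flip(x, 1, FALSE)
  oracle <- array(apply(x, 3, function(m) t(m)[ncol(m):1, ]), dim(x))
  expect_equal(r90, oracle)
  fl <- vstain:::rot_flip(x, 0, TRUE)
  expect_equal(fl, x[, 4:1, , drop = FALSE])
  a <- sample_crops(p, 32, 3, seed = 9, augment = TRUE)
  for (cr in a) expect_equal(dim(cr$af)[1:2], dim(cr$target)[1:2])
})

test_that("checkpoint selection minimises validation MSE with early ties", {
  cps <- list(list(step = 100, val_mse = 0.2),
              list(step = 200, val_mse = 0.05),
              list(step = 300, val_mse = 0.1))
  expect_equal(select_best(cps)$step, 200)
  expect_equal(select_best(cps[1])$step, 100)
  tie <- list(list(step = 1, val_mse = 0.1), list(step = 2, val_mse = 0.1))
  expect_equal(select_best(tie)$step, 1)
  expect_error(select_best(list()), "no checkpoints")
})

test_that("adversarial loop honours the 2:1 update ratio and determinism", {
  pairs <- tiny_pairs(n_per_grade = 2, size = 96)
  man <- attr(pairs, "manifest")
  split <- split_by_patient(man[c("patient_id", "tile_id")], seed = 2)
  g <- build_generator(generator_config(scale = 16), seed = 1)
  d <- build_discriminator(discriminator_config(scale = 16), seed = 2)
  ctrl <- train_control(crop = 32, batch = 2, max_steps = 6,
                        checkpoint_every = 6, seed = 4)
  fit <- fit_gan(pairs, split, g, d, control = ctrl)

  # 3 cycles of (2 G + 1 D)
  expect_equal(unname(fit$updates), c(6, 3))
  expect_true(all(is.finite(fit$history$loss)))
  expect_gte(length(fit$checkpoints), 1)
  expect_true(all(sapply(fit$checkpoints, function(cp) cp$val_mse) >= 0))

  # leakage guard: no test tile ever enters a training batch
  batch_ids <- unique(unlist(lapply(fit$manifest, `[[`, "ids")))
  expect_length(intersect(batch_ids, split$test_ids), 0)
  expect_length(intersect(batch_ids, split$val_ids), 0)

  # bitwise deterministic re-run
  fit2 <- fit_gan(pairs, split, g, d, control = ctrl)
  expect_identical(sapply(fit$checkpoints, `[[`, "val_mse"),
                   sapply(fit2$checkpoints, `[[`, "val_mse"))
  expect_identical(fit$history$loss, fit2$history$loss)

  expect_error(fit_gan(pairs, split, g, d,
                       control = train_control(crop = 128, batch = 2,
                                               max_steps = 2)),
               "exceeds")
})

test_that("the fitted stainer exposes the standard modelling interface", {
  pairs <- tiny_pairs(n_per_grade = 2, size = 96)
  man <- attr(pairs, "manifest")
  fit <- fit_virtual_stainer(
    pairs, records = man,
    gen_cfg = generator_config(scale = 16),
    disc_cfg = discriminator_config(scale = 16),
    control = train_control(crop = 32, batch = 2, max_steps = 4,
                            checkpoint_every = 2, seed = 1))
  expect_s3_class(fit, "virtual_stainer")
  expect_output(print(fit), "Virtual HER2 stainer")
  expect_output(print(summary(fit)), "Checkpoints")
  expect_named(coef(fit), names(fit$generator$params), ignore.order = TRUE)

  out <- predict(fit, pairs[[1]]$af)
  expect_equal(dim(out), c(96, 96, 3))
  expect_gte(min(out), 0); expect_lte(max(out), 1)

  # best checkpoint is the argmin of the logged val MSEs
  mses <- sapply(fit$checkpoints, `[[`, "val_mse")
  expect_equal(fit$best$val_mse, min(mses))
})
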