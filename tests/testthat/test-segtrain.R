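test_that("multiclass Jaccard loss matches its closed forms and oracle", {
  # perfect one-hot prediction: zero loss
  b <- random_batch(5, 12, 2, seed = 1)
  expect_lt(iou_loss(b$g, b$g), 1e-6)
  # uniform 1/C prediction, C = 5: L = 1 - 1/9
  N <- 30
  g <- b$g[, 1:10, 1:2, drop = FALSE]
  s_unif <- array(1 / 5, dim(g))
  expect_equal(iou_loss(s_unif, g), 1 - 1 / 9, tolerance = 1e-6)
  # random small batches against the nested-loop oracle
  for (seed in 2:8) {
    bb <- random_batch(3, 4, 2, seed)
    expect_equal(iou_loss(bb$s, bb$g), oracle_iou_loss(bb$s, bb$g),
                 tolerance = 1e-9)
    l <- iou_loss(bb$s, bb$g)
    expect_gte(l, 0); expect_lte(l, 1)
  }
  expect_error(iou_loss(b$s + 1, b$g), "\\[0, 1\\]")
  expect_error(iou_loss(b$s, b$s), "binary")
})

test_that("per-class loss reduction averages per-class Jaccard terms", {
  bb <- random_batch(4, 6, 1, seed = 9)
  sm <- bb$s[, , 1]; gm <- bb$g[, , 1]
  eps <- 1e-7
  manual <- mean(sapply(1:4, function(cc) {
    1 - (sum(gm[cc, ] * sm[cc, ]) + eps) /
      (sum(gm[cc, ] + sm[cc, ] - gm[cc, ] * sm[cc, ]) + eps)
  }))
  expect_equal(iou_loss(sm, gm, reduction = "per_class"), manual,
               tolerance = 1e-12)
})

test_that("loss gradient w.r.t. logits matches finite differences", {
  set.seed(4)
  C <- 5; N <- 16
  z <- matrix(rnorm(C * N), C, N)
  g <- matrix(0, C, N); g[cbind(sample(C, N, TRUE), 1:N)] <- 1
  for (red in c("pooled", "per_class")) {
    s <- cfzquant:::softmax_cols(z)
    ana <- cfzquant:::iou_loss_grad_logits(s, g, red)
    eps <- 1e-6
    for (probe in list(c(1, 3), c(4, 10), c(5, 16))) {
      zp <- z; zp[probe[1], probe[2]] <- z[probe[1], probe[2]] + eps
      zm <- z; zm[probe[1], probe[2]] <- z[probe[1], probe[2]] - eps
      num <- (iou_loss(cfzquant:::softmax_cols(zp), g, red) -
                iou_loss(cfzquant:::softmax_cols(zm), g, red)) / (2 * eps)
      expect_equal(ana[probe[1], probe[2]], num, tolerance = 1e-5)
    }
  }
})

test_that("segmentation metrics obey the Dice-IoU identity", {
  m <- random_label_map(20, 20, seed = 31)
  perfect <- seg_metrics(m, m)
  expect_equal(as.numeric(perfect), c(1, 1, 1))

  a <- label_map(matrix(c(rep(1L, 200), rep(0L, 200)), 20, 20))
  bdis <- label_map(matrix(c(rep(0L, 200), rep(2L, 200)), 20, 20))
  pc <- attr(seg_metrics(a, bdis), "per_class")
  expect_equal(unname(pc[c("1", "2"), "iou"]), c(0, 0))

  for (seed in 41:50) {
    p <- random_label_map(16, 16, seed)
    tr <- random_label_map(16, 16, seed + 100)
    pc <- attr(seg_metrics(p, tr), "per_class")
    ok <- !is.na(pc[, "iou"])
    expect_equal(pc[ok, "dice"], 2 * pc[ok, "iou"] / (1 + pc[ok, "iou"]),
                 tolerance = 1e-9)
  }
  expect_error(seg_metrics(matrix(0L, 3, 3), matrix(0L, 4, 4)), "differ")
})

test_that("metrics skip classes absent from both maps", {
  p <- label_map(matrix(0L, 10, 10))
  tr <- label_map(matrix(0L, 10, 10))
  m <- seg_metrics(p, tr)
  expect_equal(unname(m["mean_iou"]), 1)  # only background contributes
  pc <- attr(m, "per_class")
  expect_true(all(is.na(pc[as.character(1:4), "iou"])))
})

test_that("fold plans keep subjects intact and near-20% validation splits", {
  md10 <- do.call(rbind, lapply(1:10, function(i)
    eye_metadata(sprintf("s%02d", i), "OD", "control")))
  plan <- make_folds(md10, seed = 3)
  expect_equal(vapply(1:5, function(k) length(fold_split(plan, k)$val), 0L),
               rep(2L, 5))

  # both eyes of a subject stay together
  md_eyes <- rbind(
    do.call(rbind, lapply(1:8, function(i)
      eye_metadata(sprintf("p%d", i), "OD", "control"))),
    do.call(rbind, lapply(1:8, function(i)
      eye_metadata(sprintf("p%d", i), "OS", "control"))))
  plan2 <- make_folds(md_eyes, seed = 7)
  for (k in 1:5) {
    sp <- fold_split(plan2, k)
    expect_length(intersect(md_eyes$subject_id[sp$train],
                            md_eyes$subject_id[sp$val]), 0)
    expect_setequal(c(sp$train, sp$val), seq_len(nrow(md_eyes)))
  }

  # training-set scale: 80 images over 52 subjects
  set.seed(11)
  subj <- sprintf("t%02d", 1:52)
  two_eyed <- sample(subj, 28)
  md80 <- do.call(rbind, c(
    lapply(subj, function(s) eye_metadata(s, "OD", "control")),
    lapply(two_eyed, function(s) eye_metadata(s, "OS", "control"))))
  plan3 <- make_folds(md80, seed = 1)
  val_sizes <- vapply(1:5, function(k) length(fold_split(plan3, k)$val), 0L)
  expect_equal(sum(val_sizes), 80)
  expect_true(all(abs(val_sizes / 80 - 0.2) < 0.05))

  expect_error(make_folds(md10[1:4, ], seed = 1), "at least 5")
})

test_that("augmentation preserves the label alphabet and pairs transforms", {
  s <- generate_sample(synthetic_spec("control", seed = 51, image_size = 64))
  px <- s$image$pixels
  a1 <- augment_pair(px, s$truth, seed = 5)
  a2 <- augment_pair(px, s$truth, seed = 5)
  expect_identical(a1, a2)
  off <- augment_toggles(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  expect_identical(augment_pair(px, s$truth, seed = 5, toggles = off)$image, px)

  flip_only <- augment_toggles(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  # find a seed whose draw actually flips, then flipping twice is identity
  for (sd in 1:10) {
    once <- augment_pair(px, s$truth, seed = sd, toggles = flip_only)
    if (!identical(once$image, px)) {
      twice <- augment_pair(once$image, once$map, seed = sd, toggles = flip_only)
      expect_identical(twice$image, px)
      expect_identical(unclass(twice$map), unclass(s$truth))
      break
    }
  }

  for (sd in 1:20) {
    aa <- augment_pair(px, s$truth, seed = 100 + sd)
    expect_true(all(unclass(aa$map) %in% 0:4))
    expect_true(min(aa$image) >= 0 && max(aa$image) <= 1)
    expect_identical(dim(aa$image), dim(px))
  }
})

make_tiny_cohort <- function(n_subjects, size = 32, seed0 = 600) {
  lapply(seq_len(n_subjects), function(i) {
    st <- c("control", "NoDR", "mild")[(i %% 3) + 1]
    s <- generate_sample(synthetic_spec(st, seed = seed0 + i, image_size = size),
                         metadata = eye_metadata(sprintf("sub%02d", i), "OD", st))
    list(image = s$image, truth = s$truth, metadata = s$metadata)
  })
}

test_that("training is seeded, reproducible and supports zero epochs", {
  samples <- make_tiny_cohort(6)
  cfg0 <- train_config(max_epochs = 0, seed = 5)
  fit0 <- train_fold(samples[1:4], samples[5:6], cfg0)
  expect_equal(nrow(fit0$trace), 0)
  expect_s3_class(fit0$model, "tinyunet")

  cfg <- train_config(learning_rate = 3e-3, batch_size = 2, max_epochs = 2,
                      augment = TRUE, seed = 5, loss_reduction = "per_class")
  f1 <- train_fold(samples[1:4], samples[5:6], cfg)
  f2 <- train_fold(samples[1:4], samples[5:6], cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$model$params, f2$model$params)
  expect_equal(nrow(f1$trace), 2)
  # training does not disturb the caller's RNG
  set.seed(777); before <- .Random.seed
  invisible(train_fold(samples[1:4], samples[5:6], cfg))
  expect_identical(.Random.seed, before)
})

test_that("cross-validation reports fold metrics consistent with predictions", {
  samples <- make_tiny_cohort(10, size = 32)
  cfg <- train_config(learning_rate = 3e-3, batch_size = 4, max_epochs = 2,
                      augment = FALSE, seed = 2, loss_reduction = "per_class")
  cv <- cross_validate(samples, cfg)
  expect_equal(nrow(cv$per_fold), 5)
  expect_equal(cv$summary$metric, c("val_iou", "val_dice", "val_accuracy"))
  expect_equal(cv$summary$mean[1], mean(cv$per_fold$val_iou))
  # fold metrics equal recomputing metrics() from the saved predictions
  for (k in 1:5) {
    ms <- vapply(cv$predictions[[k]], function(pr)
      as.numeric(seg_metrics(pr$map, pr$truth)), numeric(3))
    expect_equal(mean(ms[1, ]), cv$per_fold$val_iou[k], tolerance = 1e-12)
    expect_equal(mean(ms[3, ]), cv$per_fold$val_accuracy[k], tolerance = 1e-12)
  }
})

test_that("the model factory only resolves known models", {
  expect_error(model_factory("unetpp"), "unknown model")
  net <- cfzquant:::with_seed(1, model_factory("tinyunet"))
  expect_s3_class(net, "tinyunet")
})
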