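#' Training configuration
#'
#' Defaults mirror the study protocol for the clinical-scale runs: Adam
#' with learning rate 5e-4 (beta1 0.9, beta2 0.999, eps 1e-8), step decay
#' by 0.8 every 150 epochs, mini-batch 15, up to 1000 epochs, on-the-fly
#' augmentation. Desk-scale smoke runs typically override
#' `learning_rate`, `batch_size` and `max_epochs` (see the package
#' vignette for the sizes used in the test suite).
#'
#' @param learning_rate Adam step size.
#' @param adam_beta1,adam_beta2,adam_eps Adam moment parameters.
#' @param lr_decay_factor,lr_decay_every multiply the learning rate by
#'   `lr_decay_factor` every `lr_decay_every` epochs.
#' @param batch_size images per gradient step (gradients are averaged).
#' @param max_epochs training epochs; 0 returns the untrained model.
#' @param augment logical: apply [augment_pair()] draws to each training
#'   image every epoch.
#' @param loss_reduction `"pooled"` (global Jaccard ratio) or
#'   `"per_class"`; see [iou_loss()].
#' @param seed master seed for initialisation, shuffling and
#'   augmentation.
#' @param model_name model resolved through [model_factory()].
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-4, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, adam_eps = 1e-8,
                         lr_decay_factor = 0.8, lr_decay_every = 150,
                         batch_size = 15, max_epochs = 1000,
                         augment = TRUE, loss_reduction = "pooled",
                         seed = 1, model_name = "tinyunet") {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 0,
            lr_decay_factor > 0, lr_decay_every >= 1)
  structure(list(learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, adam_eps = adam_eps,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 augment = isTRUE(augment),
                 loss_reduction = match.arg(loss_reduction, c("pooled", "per_class")),
                 seed = as.integer(seed), model_name = model_name),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + cfg$adam_eps)
  }
  list(params = params, state = state)
}

sample_pixels <- function(s) {
  if (!is.null(s$image)) {
    px <- if (inherits(s$image, "octa_image")) s$image$pixels else s$image
  } else px <- s[[1]]
  px
}

val_metrics <- function(net, val_samples, geom) {
  ms <- vapply(val_samples, function(s) {
    px <- sample_pixels(s)
    probs <- tinyunet_forward(net, input_row(px), geom)$probs
    cls <- max.col(t(probs), ties.method = "first") - 1L
    pred <- matrix(as.integer(cls), nrow(px), ncol(px))
    as.numeric(seg_metrics(pred, s$truth))
  }, numeric(3))
  rowMeans(ms)
}

#' Train the segmentation network on one fold
#'
#' Minimises the multiclass Jaccard loss ([iou_loss()]) with Adam under
#' the step-decay schedule of the supplied [train_config()], recording
#' validation mean IoU, mean Dice and accuracy after every epoch. The
#' run is fully seeded: the same seed, data and configuration reproduce
#' the trace exactly (single-threaded deterministic arithmetic). If the
#' loss turns non-finite, training aborts with an error carrying the
#' trace so far.
#'
#' @param train_samples,val_samples lists of `list(image, truth)` pairs
#'   (`image` an [octa_image()] or matrix with sides divisible by 4,
#'   `truth` a [label_map()]).
#' @param config a [train_config()].
#' @return `list(model, trace, best_epoch, best_val)`: `model` is the
#'   network state at the best-validation-IoU epoch, `trace` a
#'   data.frame with per-epoch `train_loss`, `val_iou`, `val_dice`,
#'   `val_accuracy`.
#' @export
train_fold <- function(train_samples, val_samples, config = train_config()) {
  stopifnot(inherits(config, "train_config"),
            length(train_samples) >= 1, length(val_samples) >= 1)
  px0 <- sample_pixels(train_samples[[1]])
  geom <- net_geometry(nrow(px0), ncol(px0))
  n_train <- length(train_samples)
  trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_iou = numeric(0), val_dice = numeric(0),
                      val_accuracy = numeric(0))
  result <- with_seed(config$seed, {
    net <- model_factory(config$model_name)
    astate <- adam_init(net$params)
    best <- list(epoch = 0L, val = c(-Inf, -Inf, -Inf), params = net$params)
    for (epoch in seq_len(config$max_epochs)) {
      lr <- config$learning_rate *
        config$lr_decay_factor^((epoch - 1) %/% config$lr_decay_every)
      ord <- sample(n_train)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      epoch_loss <- 0
      for (batch in batches) {
        acc <- NULL
        bloss <- 0
        for (i in batch) {
          s <- train_samples[[i]]
          px <- sample_pixels(s); lab <- s$truth
          if (config$augment) {
            aug <- augment_pair_impl(px, lab, augment_toggles(),
                                     list(zoom = 0.1, rotate_deg = 15,
                                          shift_frac = 0.05, shear_deg = 5,
                                          brightness = 0.1))
            px <- aug$image; lab <- aug$map
          }
          fwd <- tinyunet_forward(net, input_row(px), geom, keep = TRUE)
          g1 <- one_hot_map(lab)
          bloss <- bloss + iou_loss(fwd$probs, g1, config$loss_reduction)
          dz <- iou_loss_grad_logits(fwd$probs, g1, config$loss_reduction)
          gr <- tinyunet_backward(net, fwd, dz, geom)
          acc <- if (is.null(acc)) gr
                 else Map(`+`, acc, gr)
        }
        acc <- lapply(acc, function(x) x / length(batch))
        bloss <- bloss / length(batch)
        if (!is.finite(bloss))
          stop(structure(list(message = "training diverged (non-finite loss)",
                              call = NULL, trace = trace),
                         class = c("cfz_training_error", "error", "condition")))
        upd <- adam_step(net$params, acc, astate, lr, config)
        net$params <- upd$params
        astate <- upd$state
        epoch_loss <- epoch_loss + bloss * length(batch)
      }
      vm <- val_metrics(net, val_samples, geom)
      trace <- rbind(trace, data.frame(epoch = epoch,
                                       train_loss = epoch_loss / n_train,
                                       val_iou = vm[1], val_dice = vm[2],
                                       val_accuracy = vm[3]))
      if (vm[1] > best$val[1])
        best <- list(epoch = epoch, val = vm, params = net$params)
    }
    if (config$max_epochs == 0) {
      best$params <- net$params
    }
    net$params <- best$params
    list(model = net, trace = trace, best_epoch = best$epoch,
         best_val = if (best$epoch > 0)
           setNames(best$val, c("val_iou", "val_dice", "val_accuracy"))
         else NULL)
  })
  rownames(result$trace) <- NULL
  result
}

#' Grouped five-fold cross-validation of the segmentation harness
#'
#' Builds a subject-grouped [make_folds()] plan, trains one model per
#' fold with [train_fold()], and reports each fold's best-epoch
#' validation metrics with their mean and standard deviation (the usual
#' "mean (+/- sd) IoU / Dice / accuracy" presentation).
#'
#' @param samples list of `list(image, truth, metadata)` entries (e.g.
#'   from [generate_cohort()]).
#' @param config a [train_config()]; fold `k` trains with seed
#'   `config$seed + k` so folds are independent but reproducible.
#' @param n_folds number of folds.
#' @return `list(per_fold, summary, predictions)`: `per_fold` is a
#'   data.frame of best-epoch metrics per fold, `summary` holds their
#'   mean and sd, `predictions` the best model's validation label maps
#'   (per fold) for round-trip checking.
#' @export
cross_validate <- function(samples, config = train_config(), n_folds = 5) {
  metadata <- do.call(rbind, lapply(samples, `[[`, "metadata"))
  plan <- make_folds(metadata, n_folds = n_folds, seed = config$seed)
  per_fold <- NULL
  predictions <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    idx <- fold_split(plan, k)
    cfg_k <- config
    cfg_k$seed <- config$seed + k
    fit <- train_fold(samples[idx$train], samples[idx$val], cfg_k)
    preds <- lapply(idx$val, function(i)
      list(index = i, map = predict_label_map(fit$model, sample_pixels(samples[[i]])),
           truth = samples[[i]]$truth))
    predictions[[k]] <- preds
    per_fold <- rbind(per_fold,
                      data.frame(fold = k, best_epoch = fit$best_epoch,
                                 val_iou = fit$best_val[["val_iou"]],
                                 val_dice = fit$best_val[["val_dice"]],
                                 val_accuracy = fit$best_val[["val_accuracy"]]))
  }
  summary <- data.frame(
    metric = c("val_iou", "val_dice", "val_accuracy"),
    mean = vapply(c("val_iou", "val_dice", "val_accuracy"),
                  function(m) mean(per_fold[[m]]), 0),
    sd = vapply(c("val_iou", "val_dice", "val_accuracy"),
                function(m) sd(per_fold[[m]]), 0))
  rownames(summary) <- NULL
  list(per_fold = per_fold, summary = summary, predictions = predictions)
}
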