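#' Training configuration for the convolutional models
#'
#' Defaults follow the study protocol: classifiers train for 100 epochs
#' with a randomized single-transform augmentation policy and
#' cross-entropy loss; biomass regressors fine-tune for 10 epochs with
#' L1 loss and flips/lattice-rotations only (size-preserving, since the
#' silhouette scale carries the biomass signal). Desk-scale runs
#' override `epochs`, `input_size` and `channels`. One seed governs
#' parameter initialization, batch order and augmentation sampling.
#'
#' @param task `"classify"` or `"regress"`.
#' @param epochs training epochs; default 100 (classify) / 10 (regress).
#' @param lr AdamW learning rate.
#' @param batch_size minibatch size.
#' @param weight_decay AdamW decoupled weight decay.
#' @param channels conv-block widths of the backbone.
#' @param input_size network input side length T (px).
#' @param seed integer seed.
#' @return list of class `train_config`.
#' @export
train_config <- function(task = c("classify", "regress"),
                         epochs = NULL, lr = 1e-2, batch_size = 32,
                         weight_decay = 1e-2, channels = c(6, 12, 24),
                         input_size = 224, seed = 1) {
  task <- match.arg(task)
  epochs <- epochs %||% if (task == "classify") 100L else 10L
  stopifnot(epochs >= 1, lr > 0, batch_size >= 1)
  structure(list(task = task, epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, channels = channels,
                 input_size = as.integer(input_size), seed = seed),
            class = "train_config")
}

#' Build the normalized frame tensor for a curated dataset
#'
#' Selects the clean (unflagged) frames of curated specimens, applies
#' [resize_with_global_aspect()] with the dataset's global `G`, and
#' stacks them into one array. The result is the shared input store for
#' every training and prediction call, so train and inference are
#' guaranteed to use the same normalization.
#'
#' @param frames list of frames from [render_frames()].
#' @param features data.frame from [compute_features()] (supplies
#'   the non-target flags).
#' @param dataset curated dataset from [curate()].
#' @param T_px network input side length.
#' @param seed seed for the border padding.
#' @return list of class `frame_bundle`: `images` (T x T x n array),
#'   `info` (data.frame specimen_id, camera_id, frame_index), `G`,
#'   `input_size`.
#' @export
prepare_frame_bundle <- function(frames, features, dataset, T_px = 64,
                                 seed = 1) {
  G <- compute_global_max_dim(frames)
  keep_ids <- dataset$records$specimen_id
  key <- paste(features$specimen_id, features$camera_id,
               features$frame_index)
  flagged <- stats::setNames(features$nontarget_flag, key)
  sel <- vapply(frames, function(fr) {
    fr$specimen_id %in% keep_ids &&
      !isTRUE(flagged[paste(fr$specimen_id, fr$camera_id, fr$frame_index)])
  }, logical(1))
  frames <- frames[sel]
  if (length(frames) == 0) abort_invalid("no clean frames for curated specimens")
  images <- array(0, c(T_px, T_px, length(frames)))
  for (i in seq_along(frames)) {
    images[, , i] <- resize_with_global_aspect(frames[[i]], G, T_px,
                                               seed = seed + i)
  }
  info <- data.frame(
    specimen_id = vapply(frames, `[[`, "", "specimen_id"),
    camera_id = vapply(frames, `[[`, 0, "camera_id"),
    frame_index = vapply(frames, `[[`, 0, "frame_index"),
    stringsAsFactors = FALSE
  )
  structure(list(images = images, info = info, G = G, input_size = T_px),
            class = "frame_bundle")
}

frame_indices_for <- function(bundle, specimen_ids) {
  which(bundle$info$specimen_id %in% specimen_ids)
}

rank_labels <- function(dataset, rank = c("species", "genus", "family",
                                          "order")) {
  rank <- match.arg(rank)
  stats::setNames(dataset$records[[rank]], dataset$records$specimen_id)
}

#' Train a taxonomic classifier on one cross-validation fold
#'
#' Gradient-trains the convolutional backbone plus a softmax
#' classification head on the fold's training specimens, with
#' cross-entropy loss, AdamW, and a randomized single-transform
#' augmentation policy (one of flips, lattice rotations, brightness or
#' contrast per image). Validation loss is evaluated after every epoch
#' and the minimum-validation-loss checkpoint is returned together with
#' the full loss curve.
#'
#' @param bundle `frame_bundle` from [prepare_frame_bundle()].
#' @param dataset curated dataset from [curate()].
#' @param split fold split from [make_folds()].
#' @param rank taxonomic rank of the class labels.
#' @param fold_index which fold to train (its test set is untouched).
#' @param config `train_config` with `task = "classify"`.
#' @return object of class `trained_model`.
#' @export
train_classifier <- function(bundle, dataset, split, rank, fold_index,
                             config = train_config("classify")) {
  stopifnot(config$task == "classify")
  labels <- rank_labels(dataset, rank)
  classes <- sort(unique(unname(labels)))
  fold <- split$folds[[fold_index]]
  tr_idx <- frame_indices_for(bundle, fold$train)
  va_idx <- frame_indices_for(bundle, fold$validation)
  y <- match(labels[bundle$info$specimen_id], classes)
  if (!all(seq_along(classes) %in% y[tr_idx])) {
    missing <- classes[!(seq_along(classes) %in% y[tr_idx])]
    abort_invalid("invalid fold: class absent from training set: ",
                  paste(missing, collapse = ", "))
  }
  fit <- nn_train(bundle$images, y, tr_idx, va_idx, length(classes),
                  "classify", config$channels, config$epochs, config$lr,
                  config$batch_size, config$weight_decay, "trivial",
                  config$seed + fold_index)
  structure(
    list(task = "classify", rank = rank, classes = classes,
         params = fit$params, checkpoint_epoch = fit$checkpoint_epoch,
         loss_curve = fit$loss_curve, fold = fold_index, config = config),
    class = "trained_model"
  )
}

#' Fine-tune (or train from scratch) a biomass regressor on one fold
#'
#' Replaces the classification head with a single-output regression
#' head and optimizes mean absolute deviation of the transformed dry
#' mass. With a pre-trained `base` the backbone starts from the
#' classifier's weights; `frozen_base = TRUE` keeps every backbone
#' parameter bit-identical and trains only the head. Augmentation is
#' restricted to flips and 90-degree lattice rotations, which preserve
#' the silhouette scale. The minimum-validation-loss checkpoint is
#' returned.
#'
#' @param bundle,dataset,split,fold_index as in [train_classifier()].
#' @param base a classification `trained_model`, or `NULL` to train
#'   from random initialization.
#' @param frozen_base freeze the backbone (requires `base`).
#' @param transform target transform: `"identity"`, `"log"`, `"log1p"`.
#' @param config `train_config` with `task = "regress"`.
#' @return object of class `trained_model`.
#' @export
fine_tune_regressor <- function(bundle, dataset, split, fold_index,
                                base = NULL, frozen_base = FALSE,
                                transform = "log1p",
                                config = train_config("regress")) {
  stopifnot(config$task == "regress")
  if (frozen_base && is.null(base)) {
    abort_invalid("frozen_base = TRUE requires a pre-trained base")
  }
  if (!is.null(base)) {
    base_ch <- vapply(base$params$conv, function(l) length(l$b), integer(1))
    if (!identical(base_ch, as.integer(config$channels))) {
      abort_invalid("base backbone architecture does not match config ",
                    "(channels ", paste(base_ch, collapse = ","), " vs ",
                    paste(config$channels, collapse = ","), ")")
    }
  }
  tt <- target_transform(transform)
  masses <- stats::setNames(dataset$records$measured_mass_mg,
                            dataset$records$specimen_id)
  targets <- tt$fwd(unname(masses[bundle$info$specimen_id]))
  fold <- split$folds[[fold_index]]
  tr_idx <- frame_indices_for(bundle, fold$train)
  va_idx <- frame_indices_for(bundle, fold$validation)
  fit <- nn_train(bundle$images, targets, tr_idx, va_idx, 1L, "regress",
                  config$channels, config$epochs, config$lr,
                  config$batch_size, config$weight_decay, "geometric",
                  config$seed + fold_index, base_params = base$params,
                  frozen_base = frozen_base)
  structure(
    list(task = "regress", transform = transform, params = fit$params,
         checkpoint_epoch = fit$checkpoint_epoch,
         loss_curve = fit$loss_curve, fold = fold_index,
         frozen_base = frozen_base, config = config),
    class = "trained_model"
  )
}

#' Predict on frames with a trained model
#'
#' Runs the checkpointed model on the (non-augmented) normalized frames
#' of the given specimens; regression outputs are inverse-transformed
#' to mg and clipped below at 0. Repeated invocation gives identical
#' output: there is no augmentation and no stochastic layer at
#' inference.
#'
#' @param model `trained_model`.
#' @param bundle `frame_bundle` (must be the one built with the
#'   manifest's global `G`).
#' @param dataset curated dataset (supplies the truth columns).
#' @param specimen_ids specimens to predict (typically a fold's test
#'   set).
#' @param fold fold id recorded in the output rows.
#' @return prediction set data.frame: one row per clean frame, with
#'   `pred_label`/`true_label` (classification, at the model's rank) or
#'   `pred_mass_mg`/`true_mass_mg` (regression).
#' @export
predict_frames <- function(model, bundle, dataset, specimen_ids,
                           fold = model$fold %||% NA_integer_) {
  idx <- frame_indices_for(bundle, specimen_ids)
  if (length(idx) == 0) abort_invalid("no clean frames for these specimens")
  logits <- nn_predict(model$params, bundle$images, idx)
  info <- bundle$info[idx, , drop = FALSE]
  if (model$task == "classify") {
    labels <- rank_labels(dataset, model$rank)
    data.frame(
      specimen_id = info$specimen_id, camera_id = info$camera_id,
      frame_index = info$frame_index, fold = fold,
      pred_label = model$classes[max.col(logits, ties.method = "first")],
      true_label = unname(labels[info$specimen_id]),
      stringsAsFactors = FALSE
    )
  } else {
    tt <- target_transform(model$transform)
    masses <- stats::setNames(dataset$records$measured_mass_mg,
                              dataset$records$specimen_id)
    data.frame(
      specimen_id = info$specimen_id, camera_id = info$camera_id,
      frame_index = info$frame_index, fold = fold,
      pred_mass_mg = pmax(tt$inv(logits[, 1]), 0),
      true_mass_mg = unname(masses[info$specimen_id]),
      stringsAsFactors = FALSE
    )
  }
}
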