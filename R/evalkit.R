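#' Combine per-fold holdout predictions
#'
#' Jackknife-style fold combining: each fold's model predicts its own
#' holdout specimens, and the per-fold prediction sets are concatenated
#' so every curated specimen is predicted exactly once. Metrics on the
#' combined set are therefore metrics on the complete dataset.
#'
#' @param fold_preds list of prediction sets (one per fold).
#' @param expected_specimens character vector the combined specimen set
#'   must equal (typically the curated specimen ids); `NULL` skips the
#'   coverage check against a reference but still rejects overlaps.
#' @return single prediction set data.frame.
#' @export
combine_folds <- function(fold_preds, expected_specimens = NULL) {
  per_fold <- lapply(fold_preds, function(p) unique(p$specimen_id))
  all_ids <- unlist(per_fold)
  dup <- unique(all_ids[duplicated(all_ids)])
  if (length(dup) > 0) {
    abort_invalid("specimens predicted in more than one fold: ",
                  paste(utils::head(dup, 10), collapse = ", "))
  }
  if (!is.null(expected_specimens)) {
    missing <- setdiff(expected_specimens, all_ids)
    extra <- setdiff(all_ids, expected_specimens)
    if (length(missing) > 0 || length(extra) > 0) {
      abort_invalid(
        "fold coverage error; missing: ",
        paste(utils::head(missing, 10), collapse = ", "),
        "; unexpected: ", paste(utils::head(extra, 10), collapse = ", ")
      )
    }
  }
  out <- do.call(rbind, fold_preds)
  rownames(out) <- NULL
  out
}

#' Classification metrics with support-weighted averages
#'
#' Per-class precision, recall and F1, their support-weighted averages
#' (each class weighted by its number of true frames), and the
#' row-normalized confusion matrix in percent (each row of true labels
#' sums to 100). A class that is never predicted gets precision 0 by
#' convention rather than an error.
#'
#' @param pred prediction set with `pred_label`, `true_label`.
#' @return list: `per_class` (data.frame class, support, precision,
#'   recall, f1), `weighted` (named numeric precision/recall/f1),
#'   `confusion_pct` (matrix, rows = true classes), `n_frames`,
#'   `n_specimens`.
#' @export
classification_metrics <- function(pred) {
  stopifnot(nrow(pred) > 0)
  classes <- sort(union(pred$true_label, pred$pred_label))
  truth <- factor(pred$true_label, levels = classes)
  hat <- factor(pred$pred_label, levels = classes)
  cm <- table(truth, hat)
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  present <- support > 0
  w <- support[present] / sum(support)
  weighted <- c(
    precision = sum(w * precision[present]),
    recall = sum(w * recall[present]),
    f1 = sum(w * f1[present])
  )
  conf <- sweep(cm[present, , drop = FALSE], 1,
                rowSums(cm[present, , drop = FALSE]), "/") * 100
  list(
    per_class = data.frame(
      class = classes, support = as.integer(support),
      precision = as.numeric(precision), recall = as.numeric(recall),
      f1 = as.numeric(f1), stringsAsFactors = FALSE
    ),
    weighted = weighted,
    confusion_pct = unclass(conf),
    n_frames = nrow(pred),
    n_specimens = length(unique(pred$specimen_id))
  )
}

#' Group species-level predictions to a coarser rank
#'
#' Relabels truth and predictions by their ancestor at the target rank
#' (two same-order species confused with each other become an
#' order-level hit), then recomputes [classification_metrics()].
#'
#' @param pred species-level prediction set.
#' @param taxonomy data.frame from [generate_taxonomy()] (species ->
#'   ancestor map).
#' @param rank target rank: `"species"`, `"genus"`, `"family"`,
#'   `"order"`.
#' @return as [classification_metrics()].
#' @export
group_confusion <- function(pred, taxonomy, rank) {
  if (rank == "species") return(classification_metrics(pred))
  map <- stats::setNames(taxonomy[[rank]], taxonomy$species)
  missing <- setdiff(union(pred$true_label, pred$pred_label), names(map))
  if (length(missing) > 0) {
    abort_invalid("species missing from taxonomy map: ",
                  paste(missing, collapse = ", "))
  }
  pred$true_label <- unname(map[pred$true_label])
  pred$pred_label <- unname(map[pred$pred_label])
  classification_metrics(pred)
}

#' Regression metrics over a prediction set
#'
#' Frame-level (primary) and specimen-level (median prediction per
#' specimen, secondary) error bundles: mean and median absolute error
#' in mg, mean and median absolute percentage error as fractions, and
#' the coefficient of determination `R^2 = 1 - SS_res / SS_tot` (can be
#' negative on a holdout set).
#'
#' @param pred prediction set with `pred_mass_mg`, `true_mass_mg`.
#' @return list: `frame` and `specimen`, each a named numeric with
#'   `mae`, `mdae`, `mape`, `mdape`, `r2`, `n`.
#' @export
regression_metrics <- function(pred) {
  if (nrow(pred) == 0) abort_invalid("empty prediction set")
  bundle <- function(p, y) {
    err <- abs(p - y)
    c(mae = mean(err), mdae = stats::median(err),
      mape = mean(err / y), mdape = stats::median(err / y),
      r2 = 1 - sum((p - y)^2) / sum((y - mean(y))^2),
      n = length(y))
  }
  agg <- stats::aggregate(
    cbind(pred_mass_mg, true_mass_mg) ~ specimen_id,
    data = pred, FUN = stats::median
  )
  list(
    frame = bundle(pred$pred_mass_mg, pred$true_mass_mg),
    specimen = bundle(agg$pred_mass_mg, agg$true_mass_mg)
  )
}
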