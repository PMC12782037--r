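# target transforms shared by linear and CNN biomass models
target_transform <- function(name) {
  switch(name,
    identity = list(fwd = identity, inv = identity),
    log = list(fwd = log, inv = exp),
    log1p = list(fwd = log1p, inv = expm1),
    abort_invalid("unknown target transform '", name, "'")
  )
}

#' Fit an allometric OLS baseline
#'
#' Ordinary least squares of the transformed dry mass on log-transformed
#' morphometric predictors, one observation per clean frame of the
#' training specimens. The model is named by its predictor subset,
#' e.g. `linear(A,MFD,P)` uses area, maximum Feret diameter and
#' perimeter simultaneously.
#'
#' @param features per-frame feature table joined to specimen masses:
#'   columns `specimen_id`, `area_mm2`, `mfd_mm`, `perimeter_mm`,
#'   `mass_mg`, `nontarget_flag`.
#' @param predictors non-empty subset of `c("A", "MFD", "P")`.
#' @param transform target transform: `"identity"`, `"log"` or
#'   `"log1p"`.
#' @param train_ids specimen ids to fit on (grouping by specimen is the
#'   caller's contract: no specimen appears in both train and test).
#' @return object of class `linear_biomass`: predictors, transform,
#'   coefficients, and the underlying `lm` fit.
#' @export
fit_linear <- function(features, predictors, transform = "log1p",
                       train_ids = unique(features$specimen_id)) {
  if (length(predictors) == 0) abort_invalid("predictor subset must be non-empty")
  cols <- c(A = "area_mm2", MFD = "mfd_mm", P = "perimeter_mm")
  if (!all(predictors %in% names(cols))) {
    abort_invalid("predictors must be a subset of A, MFD, P")
  }
  df <- features[features$specimen_id %in% train_ids &
                   !features$nontarget_flag, , drop = FALSE]
  if (nrow(df) < length(predictors) + 2) {
    abort_invalid("need at least p + 2 training frames")
  }
  X <- df[, cols[predictors], drop = FALSE]
  if (any(X <= 0)) abort_invalid("log predictors require positive features")
  tt <- target_transform(transform)
  dat <- as.data.frame(log(X))
  names(dat) <- predictors
  dat$y <- tt$fwd(df$mass_mg)
  fit <- stats::lm(y ~ ., data = dat)
  if (anyNA(stats::coef(fit))) {
    abort_invalid("singular fit: predictors are collinear (",
                  paste(predictors, collapse = ","), ")")
  }
  structure(
    list(predictors = predictors, transform = transform,
         coefficients = stats::coef(fit), fit = fit),
    class = "linear_biomass"
  )
}

#' Predict per-frame masses from a fitted linear baseline
#'
#' Applies the inverse target transform to the linear predictor and
#' clips predictions below at 0 mg (identity-transform models can emit
#' negative masses).
#'
#' @param model `linear_biomass` object from [fit_linear()].
#' @param features per-frame feature table (same columns as in
#'   [fit_linear()]); flagged frames are skipped.
#' @param fold optional fold id stored in the output.
#' @return prediction set data.frame: specimen_id, camera_id,
#'   frame_index, fold, pred_mass_mg, true_mass_mg.
#' @export
predict_linear <- function(model, features, fold = NA_integer_) {
  cols <- c(A = "area_mm2", MFD = "mfd_mm", P = "perimeter_mm")
  df <- features[!features$nontarget_flag, , drop = FALSE]
  X <- df[, cols[model$predictors], drop = FALSE]
  if (any(X <= 0)) {
    bad <- which(X <= 0, arr.ind = TRUE)[1, 1]
    abort_invalid("non-positive feature in frame ", df$specimen_id[bad],
                  "/", df$frame_index[bad], ": log transform undefined")
  }
  dat <- as.data.frame(log(X))
  names(dat) <- model$predictors
  tt <- target_transform(model$transform)
  pred <- pmax(tt$inv(stats::predict(model$fit, newdata = dat)), 0)
  data.frame(
    specimen_id = df$specimen_id, camera_id = df$camera_id,
    frame_index = df$frame_index, fold = fold,
    pred_mass_mg = unname(pred), true_mass_mg = df$mass_mg,
    stringsAsFactors = FALSE
  )
}
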