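#' Curate the merged dataset
#'
#' Applies the exclusion rules in a fixed order, logging the first rule
#' that fires for each dropped specimen:
#' 1. `unassigned` — assignment status is not `assigned`;
#' 2. `below_detection` — recorded weight <= 0 mg (negative weights are
#'    what a below-detection-limit specimen looks like on the balance);
#' 3. `rare_species` — species with fewer than
#'    `min_specimens_per_species` remaining specimens (counted after
#'    the first two rules, so taxonomy cleaning precedes the rare-species
#'    rule and splits are computed on the cleaned set);
#' 4. `no_clean_frames` — specimen with zero unflagged frames.
#'
#' @param specimens data.frame with `specimen_id`, `measured_mass_mg`.
#' @param assignments data.frame from [assign_all()].
#' @param features data.frame from [compute_features()] (uses
#'   `nontarget_flag`).
#' @param min_specimens_per_species minimum specimens per species
#'   (default 5, matching 5-fold cross-validation).
#' @return list: `records` (curated specimen data.frame with assigned
#'   ranks and mass), `species` (character vector), `exclusion_log`
#'   (data.frame specimen_id, reason).
#' @export
curate <- function(specimens, assignments, features,
                   min_specimens_per_species = 5) {
  df <- merge(specimens[, c("specimen_id", "measured_mass_mg")],
              assignments, by = "specimen_id")
  reason <- stats::setNames(rep(NA_character_, nrow(df)), df$specimen_id)

  reason[df$status != "assigned"] <- "unassigned"
  ok <- is.na(reason)
  reason[ok & df$measured_mass_mg <= 0] <- "below_detection"
  ok <- is.na(reason)

  counts <- table(df$species[ok])
  rare <- names(counts)[counts < min_specimens_per_species]
  reason[ok & df$species %in% rare] <- "rare_species"
  ok <- is.na(reason)

  clean_counts <- table(features$specimen_id[!features$nontarget_flag])
  n_clean <- as.integer(clean_counts[df$specimen_id])
  n_clean[is.na(n_clean)] <- 0L
  reason[ok & n_clean == 0] <- "no_clean_frames"
  ok <- is.na(reason)

  records <- df[ok, c("specimen_id", "species", "genus", "family", "order",
                      "measured_mass_mg")]
  rownames(records) <- NULL
  if (nrow(records) == 0) abort_invalid("curation removed every specimen")
  list(
    records = records,
    species = sort(unique(records$species)),
    exclusion_log = data.frame(
      specimen_id = names(reason)[!is.na(reason)],
      reason = unname(reason[!is.na(reason)]),
      stringsAsFactors = FALSE
    )
  )
}

#' Stratified grouped k-fold splits
#'
#' Partitions curated specimens into `k` folds, stratified by species:
#' within each species, specimens are shuffled and dealt round-robin
#' (with a rotating start fold, so remainders spread evenly), which
#' guarantees every species appears in every test fold when it has at
#' least `k` specimens. The specimen is the group: all frames of a
#' specimen live in exactly one fold. For fold `i`, the test set is
#' fold `i`, the validation set is fold `i %% k + 1`, and the training
#' set is the remaining `k - 2` folds; the same fold definitions are
#' reused by the classification and biomass tasks.
#'
#' @param dataset list from [curate()].
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return list with `k`, `seed`, `fold_of` (named integer vector,
#'   specimen id -> fold), and `folds`: per fold, character vectors
#'   `test`, `validation`, `train`.
#' @export
make_folds <- function(dataset, k = 5, seed = 1) {
  recs <- dataset$records
  counts <- table(recs$species)
  if (any(counts < k)) {
    abort_invalid("species with fewer than k = ", k, " specimens: ",
                  paste(names(counts)[counts < k], collapse = ", "))
  }
  fold_of <- with_substream(seed, "folds", {
    out <- integer(0)
    start <- 0L
    for (sp in sort(unique(recs$species))) {
      ids <- sample(recs$specimen_id[recs$species == sp])
      f <- ((seq_along(ids) - 1L + start) %% k) + 1L
      out <- c(out, stats::setNames(f, ids))
      start <- (start + length(ids)) %% k
    }
    out
  })
  folds <- lapply(seq_len(k), function(i) {
    val <- (i %% k) + 1L
    list(
      test = names(fold_of)[fold_of == i],
      validation = names(fold_of)[fold_of == val],
      train = names(fold_of)[!(fold_of %in% c(i, val))]
    )
  })
  list(k = k, seed = seed, fold_of = fold_of, folds = folds)
}

#' Global maximum frame dimension
#'
#' `G` is the maximum of height and width over all clean frames of the
#' dataset. It is stored in the dataset manifest so training and
#' inference normalize images with the same global scale factor.
#'
#' @param frames list of frames (each with a `pixels` matrix), or a list
#'   of frame dimension pairs `c(h, w)`.
#' @return integer G (px).
#' @export
compute_global_max_dim <- function(frames) {
  if (length(frames) == 0) abort_invalid("no frames: cannot compute G")
  dims <- vapply(frames, function(fr) {
    if (is.list(fr) && !is.null(fr$pixels)) max(dim(fr$pixels)) else max(fr)
  }, numeric(1))
  as.integer(max(dims))
}
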