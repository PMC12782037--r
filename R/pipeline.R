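#' Default pipeline configuration
#'
#' One YAML-serializable config drives the whole pipeline; every stage
#' has its own seed sub-stream derived from the root seed. The defaults
#' define the desk-scale synthetic study: 8 species over 3 orders, 12
#' specimens per species, 16 two-camera frames each rendered at 3
#' px/mm into 80x80 frames, 5% junk frames, megabarcoding failure rates
#' of 7.2% / 3.4% / 3.1%, 5-fold grouped splits, and 64x64 network
#' inputs for a three-block backbone.
#'
#' @param output_root directory all stage outputs go under.
#' @param seed root seed; stage streams are derived from it.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(output_root = "mm_run", seed = 1) {
  list(
    output_root = output_root,
    seed = seed,
    synthgen = list(
      n_species = 8, n_genera = 7, n_families = 4, n_orders = 3,
      n_per_species = 12, n_frames = 16, img_size = c(80, 80),
      px_per_mm = 4.5, junk_rate = 0.05,
      failure_rates = c(noreads = 0.072, mismatch = 0.034,
                        nospecies = 0.031),
      p_repeat = 0.27, write_images = TRUE
    ),
    features = list(threshold = "auto", area_bounds = c(2, 200),
                    solidity_bounds = c(0, Inf)),
    assign = list(min_reads = 1000),
    build = list(k = 5, min_specimens_per_species = 5),
    models = list(
      input_size = 64, channels = c(6, 12, 24), batch_size = 32,
      lr = 1e-2, transform = "log1p",
      classifier = list(rank = "species", epochs = 20),
      scratch = list(epochs = 22),
      finetune = list(epochs = 10),
      enabled = c("classifier", "linear", "mean", "cnn_scratch",
                  "ft_unfrozen", "ft_frozen"),
      linear_sets = list("P", "A", "MFD", c("A", "MFD", "P"))
    ),
    evaluate = list(ranks = c("species", "genus", "family", "order"))
  )
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

dependency_error <- function(stage, what) {
  stop(structure(
    class = c("mm_dependency_error", "error", "condition"),
    list(message = paste0("stage '", stage, "' needs ", what,
                          "; run the upstream stage first"), call = NULL)
  ))
}

#' Run the pipeline end to end (or a subset of stages)
#'
#' Stages run in dependency order: `synthgen` -> `features` -> `assign`
#' -> `build` -> `models` -> `evaluate`. Each stage writes plain files
#' under the config's output root, so stages can also be run
#' independently in later calls; a stage whose inputs are neither in
#' memory nor on disk raises a dependency error naming the stage. Two
#' runs with identical config and seed produce byte-identical outputs.
#'
#' @param config list from [default_pipeline_config()] (or read from
#'   YAML via [yaml::read_yaml()]).
#' @param stages character subset of the six stage names.
#' @return run manifest list (also written to `run_manifest.json`).
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         stages = c("synthgen", "features", "assign",
                                    "build", "models", "evaluate")) {
  all_stages <- c("synthgen", "features", "assign", "build", "models",
                  "evaluate")
  if (!all(stages %in% all_stages)) {
    stop(structure(class = c("mm_config_error", "error", "condition"),
                   list(message = paste0("unknown stage: ",
                                         paste(setdiff(stages, all_stages),
                                               collapse = ", ")),
                        call = NULL)))
  }
  stages <- all_stages[all_stages %in% stages]
  root <- config$output_root
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  st <- new.env(parent = emptyenv())
  outputs <- list()
  for (stage in stages) {
    outputs[[stage]] <- switch(stage,
      synthgen = stage_synthgen(st, config),
      features = stage_features(st, config),
      assign = stage_assign(st, config),
      build = stage_build(st, config),
      models = stage_models(st, config),
      evaluate = stage_evaluate(st, config)
    )
    message("[megamorph] stage ", stage, " done")
  }
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   stages = stages, outputs = outputs,
                   package_version = as.character(utils::packageVersion("megamorph")))
  write_json_file(manifest, file.path(root, "run_manifest.json"))
  invisible(manifest)
}

# ---- stages ---------------------------------------------------------------

stage_synthgen <- function(st, config) {
  sg <- config$synthgen
  root <- config$output_root
  seed <- config$seed
  taxonomy <- generate_taxonomy(sg$n_species, sg$n_genera, sg$n_families,
                                sg$n_orders, seed)
  allom <- allometry_params(taxonomy, seed = seed)
  specimens <- generate_specimens(taxonomy, sg$n_per_species, allom,
                                  seed = seed)
  specimens$measured_mass_mg <- weigh(specimens$true_mass_mg, allom,
                                      seed = seed)
  frames <- unlist(lapply(seq_len(nrow(specimens)), function(i) {
    render_frames(specimens[i, ], sg$n_frames,
                  img_size = sg$img_size, px_per_mm = sg$px_per_mm,
                  junk_rate = sg$junk_rate, seed = seed)
  }), recursive = FALSE)
  fr <- unlist(sg$failure_rates)
  if (is.null(names(fr)) || !all(c("noreads", "mismatch", "nospecies") %in%
                                   names(fr))) {
    names(fr) <- c("noreads", "mismatch", "nospecies")  # YAML round trip
  }
  otu <- generate_otu_table(specimens, failure_rates = fr,
                            p_repeat = sg$p_repeat, seed = seed)
  st$taxonomy <- taxonomy
  st$specimens <- specimens
  st$frames <- frames
  st$otu <- otu
  write_table_csv(specimens, file.path(root, "specimens.csv"))
  write_table_csv(otu$records, file.path(root, "otu_table.tsv"), sep = "\t")
  write_table_csv(
    data.frame(specimen_id = specimens$specimen_id,
               morphological_order = specimens$order),
    file.path(root, "morphology.csv")
  )
  write_table_csv(otu$ledger, file.path(root, "truth_ledger.csv"))
  if (isTRUE(sg$write_images)) {
    write_frames_png(frames, file.path(root, "frames"))
  }
  c("specimens.csv", "otu_table.tsv", "morphology.csv", "truth_ledger.csv")
}

ensure_frames <- function(st, config, stage) {
  if (is.null(st$frames)) {
    dir <- file.path(config$output_root, "frames")
    if (!dir.exists(dir)) dependency_error(stage, "rendered frames")
    st$frames <- read_frames_png(dir, config$synthgen$px_per_mm)
  }
  st$frames
}

stage_features <- function(st, config) {
  frames <- ensure_frames(st, config, "features")
  fc <- config$features
  feats <- compute_features(frames, threshold = fc$threshold)
  feats <- flag_nontarget(feats, area_bounds = fc$area_bounds,
                          solidity_bounds = fc$solidity_bounds)
  st$features <- feats
  write_table_csv(feats, file.path(config$output_root, "features.csv"))
  "features.csv"
}

stage_assign <- function(st, config) {
  root <- config$output_root
  otu_records <- if (!is.null(st$otu)) {
    st$otu$records
  } else {
    read_table_csv(file.path(root, "otu_table.tsv"), sep = "\t")
  }
  morphology <- if (!is.null(st$specimens)) {
    data.frame(specimen_id = st$specimens$specimen_id,
               morphological_order = st$specimens$order)
  } else {
    read_table_csv(file.path(root, "morphology.csv"))
  }
  res <- assign_all(otu_records, morphology,
                    min_reads = config$assign$min_reads)
  st$assignments <- res$assignments
  st$assign_summary <- res$summary
  write_table_csv(res$assignments, file.path(root, "assignments.csv"))
  write_json_file(res$summary, file.path(root, "summary.json"))
  c("assignments.csv", "summary.json")
}

stage_build <- function(st, config) {
  root <- config$output_root
  specimens <- st$specimens %||% read_table_csv(file.path(root, "specimens.csv"))
  assignments <- st$assignments %||%
    read_table_csv(file.path(root, "assignments.csv"))
  features <- st$features %||% read_table_csv(file.path(root, "features.csv"))
  dataset <- curate(specimens, assignments, features,
                    min_specimens_per_species = config$build$min_specimens_per_species)
  split <- make_folds(dataset, k = config$build$k,
                      seed = substream_seed(config$seed, "split"))
  frames <- ensure_frames(st, config, "build")
  G <- compute_global_max_dim(frames)
  st$dataset <- dataset
  st$split <- split
  st$G <- G
  write_json_file(
    list(records = dataset$records, species = dataset$species,
         exclusion_log = dataset$exclusion_log, G = G, k = split$k,
         fold_of = as.list(split$fold_of)),
    file.path(root, "dataset_manifest.json")
  )
  "dataset_manifest.json"
}

ensure_built <- function(st, config, stage) {
  if (is.null(st$dataset)) {
    path <- file.path(config$output_root, "dataset_manifest.json")
    if (!file.exists(path)) dependency_error(stage, "the dataset manifest")
    m <- jsonlite::read_json(path, simplifyVector = TRUE)
    st$dataset <- list(records = m$records, species = m$species,
                       exclusion_log = m$exclusion_log)
    fold_of <- unlist(m$fold_of)
    folds <- lapply(seq_len(m$k), function(i) {
      val <- (i %% m$k) + 1L
      list(test = names(fold_of)[fold_of == i],
           validation = names(fold_of)[fold_of == val],
           train = names(fold_of)[!(fold_of %in% c(i, val))])
    })
    st$split <- list(k = m$k, fold_of = fold_of, folds = folds)
    st$G <- m$G
  }
  invisible(NULL)
}

# per-frame features of clean frames of curated specimens, with masses
frame_mass_table <- function(features, dataset) {
  df <- merge(features[!features$nontarget_flag, , drop = FALSE],
              dataset$records[, c("specimen_id", "measured_mass_mg")],
              by = "specimen_id")
  names(df)[names(df) == "measured_mass_mg"] <- "mass_mg"
  df
}

stage_models <- function(st, config) {
  root <- config$output_root
  mc <- config$models
  ensure_built(st, config, "models")
  frames <- ensure_frames(st, config, "models")
  features <- st$features %||% read_table_csv(file.path(root, "features.csv"))
  dataset <- st$dataset
  split <- st$split
  bundle <- prepare_frame_bundle(frames, features, dataset,
                                 T_px = mc$input_size, seed = config$seed)
  fmt <- frame_mass_table(features, dataset)
  enabled <- mc$enabled
  preds <- list()
  curves <- list()
  for (i in seq_len(split$k)) {
    fold <- split$folds[[i]]
    base <- NULL
    if ("classifier" %in% enabled) {
      cfg <- train_config("classify", epochs = mc$classifier$epochs,
                          lr = mc$lr, batch_size = mc$batch_size,
                          channels = mc$channels,
                          input_size = mc$input_size, seed = config$seed)
      base <- train_classifier(bundle, dataset, split, mc$classifier$rank,
                               i, cfg)
      p <- predict_frames(base, bundle, dataset, fold$test, fold = i)
      p$model <- "classifier"
      preds[[length(preds) + 1]] <- p
      curves[[paste0("classifier_f", i)]] <- base$loss_curve
    }
    if ("cnn_scratch" %in% enabled) {
      cfg <- train_config("regress", epochs = mc$scratch$epochs,
                          lr = mc$lr, batch_size = mc$batch_size,
                          channels = mc$channels,
                          input_size = mc$input_size, seed = config$seed)
      m <- fine_tune_regressor(bundle, dataset, split, i, base = NULL,
                               transform = mc$transform, config = cfg)
      p <- predict_frames(m, bundle, dataset, fold$test, fold = i)
      p$model <- "cnn_scratch"
      preds[[length(preds) + 1]] <- p
      curves[[paste0("cnn_scratch_f", i)]] <- m$loss_curve
    }
    for (frozen in c(FALSE, TRUE)) {
      key <- if (frozen) "ft_frozen" else "ft_unfrozen"
      if (!(key %in% enabled) || is.null(base)) next
      cfg <- train_config("regress", epochs = mc$finetune$epochs,
                          lr = mc$lr, batch_size = mc$batch_size,
                          channels = mc$channels,
                          input_size = mc$input_size, seed = config$seed)
      m <- fine_tune_regressor(bundle, dataset, split, i, base = base,
                               frozen_base = frozen,
                               transform = mc$transform, config = cfg)
      p <- predict_frames(m, bundle, dataset, fold$test, fold = i)
      p$model <- key
      preds[[length(preds) + 1]] <- p
    }
    if ("linear" %in% enabled) {
      for (set in mc$linear_sets) {
        set <- unlist(set)
        lmod <- fit_linear(fmt, set, transform = mc$transform,
                           train_ids = fold$train)
        p <- predict_linear(lmod, fmt[fmt$specimen_id %in% fold$test, ,
                                      drop = FALSE], fold = i)
        p$model <- paste0("linear(", paste(set, collapse = ","), ")")
        preds[[length(preds) + 1]] <- p
      }
    }
    if ("mean" %in% enabled) {
      train_m <- fmt$mass_mg[fmt$specimen_id %in% fold$train]
      test_rows <- fmt[fmt$specimen_id %in% fold$test, , drop = FALSE]
      preds[[length(preds) + 1]] <- data.frame(
        specimen_id = test_rows$specimen_id,
        camera_id = test_rows$camera_id,
        frame_index = test_rows$frame_index, fold = i,
        pred_mass_mg = mean(train_m), true_mass_mg = test_rows$mass_mg,
        model = "mean_baseline", stringsAsFactors = FALSE
      )
    }
  }
  pred_df <- do.call(rbind, lapply(preds, function(p) {
    if (is.null(p$pred_label)) {
      p$pred_label <- NA_character_; p$true_label <- NA_character_
    }
    if (is.null(p$pred_mass_mg)) {
      p$pred_mass_mg <- NA_real_; p$true_mass_mg <- NA_real_
    }
    p[, c("model", "specimen_id", "camera_id", "frame_index", "fold",
          "pred_label", "true_label", "pred_mass_mg", "true_mass_mg")]
  }))
  st$predictions <- pred_df
  write_table_csv(pred_df, file.path(root, "predictions.csv"))
  "predictions.csv"
}

stage_evaluate <- function(st, config) {
  root <- config$output_root
  ensure_built(st, config, "evaluate")
  preds <- st$predictions %||% read_table_csv(file.path(root, "predictions.csv"))
  dataset <- st$dataset
  taxonomy <- unique(st$dataset$records[, c("species", "genus", "family",
                                            "order")])
  expected <- dataset$records$specimen_id
  metrics <- list()
  for (model in unique(preds$model)) {
    mp <- preds[preds$model == model, , drop = FALSE]
    combined <- combine_folds(split(mp, mp$fold), expected)
    if (!all(is.na(combined$pred_label))) {
      cls <- lapply(config$evaluate$ranks, function(rk) {
        r <- group_confusion(combined, taxonomy, rk)
        write_table_csv(as.data.frame(r$confusion_pct),
                        file.path(root, paste0("confusion_", rk, ".csv")))
        list(rank = rk, weighted = as.list(r$weighted),
             n_frames = r$n_frames, n_specimens = r$n_specimens)
      })
      names(cls) <- config$evaluate$ranks
      metrics[[model]] <- cls
    } else {
      rm_ <- regression_metrics(combined)
      metrics[[model]] <- list(frame = as.list(rm_$frame),
                               specimen = as.list(rm_$specimen))
    }
  }
  st$metrics <- metrics
  write_json_file(metrics, file.path(root, "metrics.json"))
  "metrics.json"
}
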