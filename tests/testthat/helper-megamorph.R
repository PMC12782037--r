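# shared fixtures, all generated in code

square_mask <- function(n, pad = 2) {
  m <- matrix(FALSE, n + 2 * pad, n + 2 * pad)
  m[pad + seq_len(n), pad + seq_len(n)] <- TRUE
  m
}

disk_mask <- function(r, pad = 3) {
  side <- 2 * r + 2 * pad + 1
  cx <- r + pad + 1
  xs <- matrix(rep(seq_len(side), each = side), side, side) - cx
  ys <- matrix(rep(seq_len(side), side), side, side) - cx
  xs^2 + ys^2 <= r^2
}

# random connected-ish blob: union of overlapping random disks
blob_mask <- function(seed, side = 24) {
  set.seed(seed)
  m <- matrix(FALSE, side, side)
  cx <- stats::runif(1, side * 0.35, side * 0.65)
  cy <- stats::runif(1, side * 0.35, side * 0.65)
  for (k in 1:6) {
    r <- stats::runif(1, 2, 5)
    cx <- min(max(cx + stats::runif(1, -3, 3), r + 1), side - r - 1)
    cy <- min(max(cy + stats::runif(1, -3, 3), r + 1), side - r - 1)
    xs <- matrix(rep(seq_len(side), each = side), side, side) - cx
    ys <- matrix(rep(seq_len(side), side), side, side) - cy
    m <- m | (xs^2 + ys^2 <= r^2)
  }
  m
}

# O(n^2) oracle: max pairwise distance between boundary pixel centers
brute_feret <- function(mask, px_per_mm = 1) {
  bp <- megamorph:::boundary_pixels(mask)
  if (nrow(bp) < 2) return(0)
  d2 <- outer(bp[, 1], bp[, 1], "-")^2 + outer(bp[, 2], bp[, 2], "-")^2
  sqrt(max(d2)) / px_per_mm
}

# hand-built specimen row for the renderer
toy_specimen <- function(specimen_id = "SPX", length_mm = 8,
                         elongation = 3, taper = 0.4, n_appendages = 2L,
                         appendage_len = 0.2, cased = FALSE,
                         dorso_factor = 0.8) {
  data.frame(specimen_id = specimen_id, species = "SpX", genus = "GenX",
             family = "FamX", order = "Ephemeroptera",
             length_mm = length_mm, true_mass_mg = 1,
             elongation = elongation, taper = taper,
             n_appendages = n_appendages, appendage_len = appendage_len,
             cased = cased, dorso_factor = dorso_factor,
             plate = 1L, well = "A01", stringsAsFactors = FALSE)
}

# noiseless single-species allometry with hand-set coefficients
toy_allometry <- function(c_s = 1, b_s = 3, sigma = 0, species = "Sp01",
                          noise_sd = 0, readability = 0.01) {
  list(c_s = stats::setNames(rep(c_s, length(species)), species),
       b_s = stats::setNames(rep(b_s, length(species)), species),
       sigma = sigma, detection_limit = 0.01,
       readability = readability, noise_sd = noise_sd)
}

# small end-to-end synthetic state shared by heavier tests; built once
# per test run and cached in the test environment
small_pipeline_state <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- default_pipeline_config(output_root = tempfile("mmsmall"),
                                   seed = 11)
    cfg$synthgen$n_species <- 4
    cfg$synthgen$n_genera <- 4
    cfg$synthgen$n_families <- 3
    cfg$synthgen$n_orders <- 2
    cfg$synthgen$n_per_species <- 8
    cfg$synthgen$n_frames <- 6
    cfg$synthgen$write_images <- FALSE
    cfg$build$k <- 3
    st <- new.env(parent = emptyenv())
    megamorph:::stage_synthgen(st, cfg)
    megamorph:::stage_features(st, cfg)
    megamorph:::stage_assign(st, cfg)
    megamorph:::stage_build(st, cfg)
    cache <<- list(st = st, cfg = cfg)
    cache
  }
})

make_feature_frame <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    specimen_id = paste0("S", rep(seq_len(ceiling(n / 4)), each = 4)[1:n]),
    camera_id = rep(c(0, 1), length.out = n),
    frame_index = seq_len(n),
    area_mm2 = stats::rlnorm(n, 2, 0.5),
    mfd_mm = stats::rlnorm(n, 1.5, 0.3),
    perimeter_mm = stats::rlnorm(n, 2.5, 0.4),
    nontarget_flag = FALSE,
    stringsAsFactors = FALSE
  )
}

make_curation_input <- function() {
  # 3 good species (6 specimens each), 1 rare species (4 specimens),
  # plus one negative weight and one unassigned specimen
  ids <- sprintf("SP%02d", 1:24)
  species <- c(rep("SpA", 6), rep("SpB", 6), rep("SpC", 6), rep("SpD", 4),
               "SpA", "SpB")
  specimens <- data.frame(specimen_id = ids,
                          measured_mass_mg = rep(5, 24),
                          stringsAsFactors = FALSE)
  specimens$measured_mass_mg[23] <- -0.1          # below detection
  assignments <- data.frame(
    specimen_id = ids, status = "assigned", species = species,
    genus = paste0("G_", species), family = "FamX", order = "OrdX",
    stringsAsFactors = FALSE
  )
  assignments$status[24] <- "insufficient_reads"  # unassigned
  features <- data.frame(
    specimen_id = rep(ids, each = 2), camera_id = 0, frame_index = 1:2,
    area_mm2 = 5, mfd_mm = 5, perimeter_mm = 12, solidity = 0.9,
    nontarget_flag = FALSE, stringsAsFactors = FALSE
  )
  list(specimens = specimens, assignments = assignments,
       features = features)
}
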