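#' Generate a nested synthetic taxonomy
#'
#' Builds a four-rank taxonomy (species within genera within families
#' within orders) in which every species maps to exactly one ancestor at
#' each rank. Order names come from a closed pool of macroinvertebrate
#' orders; lower ranks get generated names.
#'
#' @param n_species,n_genera,n_families,n_orders rank sizes; must satisfy
#'   `n_species >= n_genera >= n_families >= n_orders >= 1` and
#'   `n_orders <= length(MACRO_ORDER_POOL)`.
#' @param seed integer seed; output is deterministic in the seed.
#' @return a data.frame with one row per species and columns
#'   `species`, `genus`, `family`, `order`.
#' @examples
#' tax <- generate_taxonomy(14, 13, 7, 3, seed = 1)
#' nrow(tax)            # 14
#' length(unique(tax$order))  # 3
#' @export
generate_taxonomy <- function(n_species, n_genera, n_families, n_orders, seed) {
  if (!(n_species >= n_genera && n_genera >= n_families &&
        n_families >= n_orders && n_orders >= 1)) {
    abort_invalid(
      "rank sizes must be nested: n_species >= n_genera >= n_families ",
      ">= n_orders >= 1 (got ", n_species, ", ", n_genera, ", ",
      n_families, ", ", n_orders, ")"
    )
  }
  if (n_orders > length(MACRO_ORDER_POOL)) {
    abort_invalid("at most ", length(MACRO_ORDER_POOL), " orders supported")
  }
  with_substream(seed, "taxonomy", {
    orders <- MACRO_ORDER_POOL[seq_len(n_orders)]
    # parent assignment: first children cover every parent, the rest are
    # assigned at random, so every rank size is hit exactly
    assign_parents <- function(n_child, parents) {
      n_parent <- length(parents)
      idx <- c(seq_len(n_parent), sample.int(n_parent, n_child - n_parent,
                                             replace = TRUE))
      parents[idx]
    }
    fam_order <- assign_parents(n_families, orders)
    families <- paste0("Fam", zero_pad(seq_len(n_families)))
    gen_family <- assign_parents(n_genera, families)
    genera <- paste0("Gen", zero_pad(seq_len(n_genera)))
    sp_genus <- assign_parents(n_species, genera)
    species <- paste0("Sp", zero_pad(seq_len(n_species)))

    gen_fam <- stats::setNames(gen_family, genera)
    fam_ord <- stats::setNames(fam_order, families)
    fam_of_sp <- unname(gen_fam[sp_genus])
    data.frame(
      species = species,
      genus = sp_genus,
      family = fam_of_sp,
      order = unname(fam_ord[fam_of_sp]),
      stringsAsFactors = FALSE
    )
  })
}

#' Species-specific allometric and weighing parameters
#'
#' Per-species power-law coefficients for the length-mass relation
#' `m = c_s * L^b_s * exp(eps)`, `eps ~ N(0, sigma^2)`, plus the
#' balance model (additive weighing noise, scale readability, detection
#' limit). Coefficients are drawn once per taxonomy, deterministically.
#'
#' @param taxonomy data.frame from [generate_taxonomy()].
#' @param c_range,b_range ranges the per-species `c_s` (mg/mm^b) and
#'   `b_s` (dimensionless) are drawn from; `b` must stay in `[1, 4]`.
#' @param sigma lognormal mass noise sd (log-mg).
#' @param detection_limit balance detection limit (mg).
#' @param readability balance readability: measured weights are rounded
#'   to multiples of this (mg).
#' @param noise_sd additive Normal weighing noise sd (mg), applied
#'   before quantization; near-zero true masses can therefore yield
#'   zero or negative recorded weights, as real balances do.
#' @param seed integer seed.
#' @return list with per-species named vectors `c_s`, `b_s` and scalars
#'   `sigma`, `detection_limit`, `readability`, `noise_sd`.
#' @export
allometry_params <- function(taxonomy,
                             c_range = c(0.008, 0.06),
                             b_range = c(2.2, 2.7),
                             sigma = 0.15,
                             detection_limit = 0.01,
                             readability = 0.01,
                             noise_sd = 0.01,
                             seed = 1) {
  if (any(c_range <= 0)) abort_invalid("c_range must be positive")
  if (b_range[1] < 1 || b_range[2] > 4) abort_invalid("b_range must lie in [1, 4]")
  if (sigma < 0) abort_invalid("sigma must be >= 0")
  if (detection_limit < 0) abort_invalid("detection_limit must be >= 0")
  if (readability <= 0) abort_invalid("readability must be > 0")
  if (noise_sd < 0) abort_invalid("noise_sd must be >= 0")
  sp <- taxonomy$species
  n <- length(sp)
  rank <- species_size_rank(taxonomy, seed)
  # interspecific allometry: larger-bodied taxa are heavier-built, so
  # the scale coefficient and exponent rise with the species' position
  # on the body-size grid; this is what spreads synthetic masses over
  # the multi-decade range seen in real weighed specimens
  c_grid <- exp(seq(log(c_range[1]), log(c_range[2]),
                    length.out = max(n, 2)))[seq_len(n)]
  b_grid <- seq(b_range[1], b_range[2], length.out = max(n, 2))[seq_len(n)]
  out <- list(
    c_s = stats::setNames(c_grid[rank], sp),
    b_s = stats::setNames(b_grid[rank], sp),
    sigma = sigma,
    detection_limit = detection_limit,
    readability = readability,
    noise_sd = noise_sd
  )
  attr(out, "size_rank") <- rank
  out
}

# species -> slot on the body-size grid; drawn in its own sub-stream of
# the root seed so the specimen generator and the allometry table agree
species_size_rank <- function(taxonomy, seed) {
  with_substream(seed, "sizerank", sample.int(nrow(taxonomy)))
}
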