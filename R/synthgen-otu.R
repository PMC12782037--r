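#' Generate a per-specimen OTU read table with injected failure modes
#'
#' Every specimen yields one sequencing sample (or two when a PCR repeat
#' is simulated) containing one dominant OTU carrying the specimen's
#' true taxonomy plus a heavy-tailed set of non-target contaminant OTUs
#' (parasite/gut-content analogues) with much lower expected reads.
#' Three failure modes are injected at configurable rates, mirroring how
#' real megabarcoding runs fail:
#' * `insufficient_reads`: the dominant OTU draws fewer reads than the
#'   downstream read threshold;
#' * `order_mismatch`: the dominant OTU's taxonomy is swapped to a
#'   different macroinvertebrate order;
#' * `no_species_hit`: the dominant taxonomy is truncated above species
#'   (empty species field), as when a reference database has no
#'   species-level hit.
#'
#' @param specimens data.frame from [generate_specimens()].
#' @param read_params list: `dominant_meanlog`/`dominant_sdlog` and
#'   `contaminant_meanlog`/`contaminant_sdlog` for lognormal read
#'   counts, `contaminant_lambda` (Poisson mean number of contaminant
#'   OTUs per sample), `min_contaminant_reads`.
#' @param failure_rates named numeric `c(noreads=, mismatch=, nospecies=)`,
#'   each in `[0,1]`, summing to at most 1.
#' @param p_repeat probability a specimen gets a second (repeated-PCR)
#'   sample.
#' @param noreads_max injected insufficient-reads specimens draw their
#'   dominant reads uniformly on `0..noreads_max`.
#' @param seed integer seed.
#' @return list with `records` (data.frame: sample_id, specimen_id,
#'   otu_id, reads, order, family, genus, species, target) and `ledger`
#'   (data.frame: specimen_id, injected_status, n_samples) recording
#'   which failure, if any, was injected per specimen.
#' @export
generate_otu_table <- function(specimens,
                               read_params = list(
                                 dominant_meanlog = log(2e5),
                                 dominant_sdlog = 0.5,
                                 contaminant_meanlog = log(2e3),
                                 contaminant_sdlog = 1.0,
                                 contaminant_lambda = 11.7,
                                 min_contaminant_reads = 10
                               ),
                               failure_rates = c(noreads = 0.072,
                                                 mismatch = 0.034,
                                                 nospecies = 0.031),
                               p_repeat = 0.27,
                               noreads_max = 999,
                               seed = 1) {
  fr <- failure_rates
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    abort_invalid("failure rates must lie in [0,1] and sum to at most 1")
  }
  with_substream(seed, "otus", {
    contam_pool <- contaminant_pool(300)
    n <- nrow(specimens)
    u <- stats::runif(n)
    status <- ifelse(
      u < fr[["noreads"]], "insufficient_reads",
      ifelse(u < fr[["noreads"]] + fr[["mismatch"]], "order_mismatch",
             ifelse(u < sum(fr), "no_species_hit", "none"))
    )
    repeats <- stats::runif(n) < p_repeat
    orders_pool <- unique(specimens$order)

    recs <- vector("list", n)
    for (i in seq_len(n)) {
      spm <- specimens[i, ]
      n_samples <- if (repeats[i]) 2L else 1L
      per_sample <- vector("list", n_samples)
      for (s in seq_len(n_samples)) {
        sid <- paste0(spm$specimen_id, "_S", s)
        dom <- dominant_record(spm, status[i], orders_pool, read_params,
                               noreads_max)
        k <- stats::rpois(1, read_params$contaminant_lambda)
        contam <- if (k > 0) {
          idx <- sample.int(nrow(contam_pool), min(k, nrow(contam_pool)))
          reads <- pmax(
            floor(stats::rlnorm(length(idx), read_params$contaminant_meanlog,
                                read_params$contaminant_sdlog)),
            read_params$min_contaminant_reads
          )
          cbind(contam_pool[idx, , drop = FALSE],
                data.frame(reads = as.integer(reads)))
        } else {
          NULL
        }
        tab <- rbind(dom, contam)
        if (!is.null(tab) && nrow(tab) > 0) {
          tab <- cbind(data.frame(sample_id = sid,
                                  specimen_id = spm$specimen_id,
                                  stringsAsFactors = FALSE), tab)
        }
        per_sample[[s]] <- tab
      }
      recs[[i]] <- do.call(rbind, per_sample)
    }
    records <- do.call(rbind, recs)
    records <- records[, c("sample_id", "specimen_id", "otu_id", "reads",
                           "order", "family", "genus", "species", "target")]
    rownames(records) <- NULL
    list(
      records = records,
      ledger = data.frame(
        specimen_id = specimens$specimen_id,
        injected_status = status,
        n_samples = ifelse(repeats, 2L, 1L),
        stringsAsFactors = FALSE
      )
    )
  })
}

# one dominant-OTU row for one sample, with the injected failure applied
dominant_record <- function(spm, status, orders_pool, read_params, noreads_max) {
  reads <- if (status == "insufficient_reads") {
    sample.int(noreads_max + 1L, 1L) - 1L
  } else {
    as.integer(floor(stats::rlnorm(1, read_params$dominant_meanlog,
                                   read_params$dominant_sdlog)))
  }
  if (reads == 0L) return(NULL)  # total dropout: no dominant row at all
  ord <- spm$order
  species <- spm$species
  otu_id <- paste0("OTU_", spm$species)
  if (status == "order_mismatch") {
    others <- setdiff(orders_pool, spm$order)
    ord <- if (length(others) > 0) sample(others, 1) else sample(MACRO_ORDER_POOL, 1)
    otu_id <- paste0("OTU_X_", spm$specimen_id)
  } else if (status == "no_species_hit") {
    species <- ""
    otu_id <- paste0("OTU_G_", spm$genus)
  }
  data.frame(
    otu_id = otu_id, reads = reads, order = ord, family = spm$family,
    genus = spm$genus, species = species, target = TRUE,
    stringsAsFactors = FALSE
  )
}

contaminant_pool <- function(n_otus) {
  data.frame(
    otu_id = sprintf("OTU_C%03d", seq_len(n_otus)),
    reads = NA_integer_,
    order = sample(NONTARGET_ORDER_POOL, n_otus, replace = TRUE),
    family = sprintf("ContamFam%02d", (seq_len(n_otus) - 1L) %% 40L + 1L),
    genus = sprintf("ContamGen%03d", seq_len(n_otus)),
    species = sprintf("contam_sp%03d", seq_len(n_otus)),
    target = FALSE,
    stringsAsFactors = FALSE
  )[, c("otu_id", "order", "family", "genus", "species", "target")]
}
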