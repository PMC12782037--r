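#' Choose between original and repeated-PCR samples
#'
#' When a specimen was sequenced twice (a failed PCR repeated with
#' diluted template), it is taxonomically assigned based on the sample
#' whose top macroinvertebrate OTU has more reads. Ties break toward
#' the lexicographically smaller sample id, for determinism.
#'
#' @param records OTU records (data.frame with at least `sample_id`,
#'   `reads`, `target`) for one specimen, one or two sample ids.
#' @return the chosen sample id (character scalar).
#' @export
resolve_repeats <- function(records) {
  sids <- sort(unique(records$sample_id))
  if (length(sids) == 0) abort_invalid("no samples for specimen")
  if (length(sids) == 1) return(sids)
  top <- vapply(sids, function(s) {
    r <- records[records$sample_id == s & records$target, "reads"]
    if (length(r) == 0) 0L else max(r)
  }, numeric(1))
  sids[which.max(top)]               # which.max takes the first maximum
}

#' Assign a taxon to one specimen from its OTU records
#'
#' Implements the dominant-OTU rule: among the macroinvertebrate OTUs of
#' the chosen sample, the OTU with most reads is the candidate (read
#' ties break toward the lexicographically smaller OTU id). The
#' candidate is rejected in this order: fewer than `min_reads` reads
#' (`insufficient_reads`; 999 reads fail, 1000 pass), order inconsistent
#' with the morphological identification (`order_mismatch`; no fallback
#' to a lower-read OTU), no species-level name (`no_species_hit`).
#' Otherwise the specimen is `assigned` the candidate's taxonomy.
#'
#' @param records OTU records of a single sample (may be empty).
#' @param morphological_order order from morphological pre-sorting.
#' @param min_reads read threshold (default 1000).
#' @return list with `status`, `otu_id`, `reads`, `sample_id` and (when
#'   assigned) `taxon` (named list species/genus/family/order).
#' @export
assign_specimen <- function(records, morphological_order, min_reads = 1000) {
  records <- records[records$target %||% TRUE, , drop = FALSE]
  if (nrow(records) == 0) {
    return(list(status = "insufficient_reads", otu_id = NA_character_,
                reads = 0L, sample_id = NA_character_, taxon = NULL))
  }
  stopifnot(length(unique(records$sample_id)) == 1)
  ord <- order(-records$reads, records$otu_id)
  cand <- records[ord[1], ]
  base <- list(otu_id = cand$otu_id, reads = cand$reads,
               sample_id = cand$sample_id, taxon = NULL)
  if (cand$reads < min_reads) {
    return(c(list(status = "insufficient_reads"), base))
  }
  if (!identical(cand$order, morphological_order)) {
    return(c(list(status = "order_mismatch"), base))
  }
  if (is.na(cand$species) || !nzchar(cand$species)) {
    return(c(list(status = "no_species_hit"), base))
  }
  base$taxon <- list(species = cand$species, genus = cand$genus,
                     family = cand$family, order = cand$order)
  c(list(status = "assigned"), base)
}

#' Assign all specimens and summarise recovery
#'
#' Applies [resolve_repeats()] then [assign_specimen()] to every
#' specimen in the morphology table. Specimens with no OTU rows at all
#' are recorded as `insufficient_reads` with 0 reads. The summary
#' partitions the total into the four statuses and reports
#' `recovery_rate = (n_total - n_insufficient) / n_total` (fraction of
#' specimens yielding a taxonomically valid sequence) and
#' `species_rate = n_assigned / n_total`.
#'
#' @param otu_records data.frame as produced by [generate_otu_table()].
#' @param morphology data.frame with `specimen_id`,
#'   `morphological_order`.
#' @param min_reads read threshold.
#' @return list with `assignments` (data.frame: specimen_id, status,
#'   species, genus, family, order, otu_id, reads, sample_id) and
#'   `summary` (list of counts and rates).
#' @export
assign_all <- function(otu_records, morphology, min_reads = 1000) {
  by_spm <- split(otu_records, otu_records$specimen_id)
  rows <- lapply(seq_len(nrow(morphology)), function(i) {
    spm <- morphology$specimen_id[i]
    recs <- by_spm[[spm]]
    res <- if (is.null(recs) || nrow(recs) == 0) {
      list(status = "insufficient_reads", otu_id = NA_character_,
           reads = 0L, sample_id = NA_character_, taxon = NULL)
    } else {
      chosen <- resolve_repeats(recs)
      assign_specimen(recs[recs$sample_id == chosen, , drop = FALSE],
                      morphology$morphological_order[i], min_reads)
    }
    data.frame(
      specimen_id = spm, status = res$status,
      species = res$taxon$species %||% NA_character_,
      genus = res$taxon$genus %||% NA_character_,
      family = res$taxon$family %||% NA_character_,
      order = res$taxon$order %||% NA_character_,
      otu_id = res$otu_id, reads = res$reads, sample_id = res$sample_id,
      stringsAsFactors = FALSE
    )
  })
  assignments <- do.call(rbind, rows)
  n_total <- nrow(assignments)
  counts <- table(factor(assignments$status,
                         levels = c("assigned", "insufficient_reads",
                                    "order_mismatch", "no_species_hit")))
  summary <- list(
    n_total = n_total,
    n_assigned = as.integer(counts[["assigned"]]),
    n_insufficient = as.integer(counts[["insufficient_reads"]]),
    n_mismatch = as.integer(counts[["order_mismatch"]]),
    n_nospecies = as.integer(counts[["no_species_hit"]]),
    recovery_rate = (n_total - counts[["insufficient_reads"]]) / n_total,
    species_rate = counts[["assigned"]] / n_total
  )
  list(assignments = assignments, summary = summary)
}
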