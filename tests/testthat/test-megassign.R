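otu_row <- function(sample_id, otu_id, reads, order = "Trichoptera",
                    genus = "GenX", species = "sp_x", target = TRUE) {
  data.frame(sample_id = sample_id, specimen_id = sub("_S.*", "", sample_id),
             otu_id = otu_id, reads = reads, order = order, family = "FamX",
             genus = genus, species = species, target = target,
             stringsAsFactors = FALSE)
}

test_that("repeat resolution picks the sample with more dominant reads", {
  recs <- rbind(otu_row("SPA_S1", "OTU1", 5000), otu_row("SPA_S2", "OTU1", 8000))
  expect_equal(resolve_repeats(recs), "SPA_S2")
  expect_equal(resolve_repeats(otu_row("SPA_S1", "OTU1", 10)), "SPA_S1")
  tie <- rbind(otu_row("SPA_S2", "OTU1", 5000), otu_row("SPA_S1", "OTU1", 5000))
  expect_equal(resolve_repeats(tie), "SPA_S1")
  # only macroinvertebrate reads count toward the comparison
  recs2 <- rbind(otu_row("SPA_S1", "OTU1", 5000),
                 otu_row("SPA_S2", "OTUC", 9000, target = FALSE),
                 otu_row("SPA_S2", "OTU1", 100))
  expect_equal(resolve_repeats(recs2), "SPA_S1")
})

test_that("dominant-OTU assignment applies the filtering rules in order", {
  recs <- rbind(otu_row("SPA_S1", "OTU1", 5000, order = "Trichoptera"),
                otu_row("SPA_S1", "OTU2", 1200, order = "Diptera"))
  res <- assign_specimen(recs, "Trichoptera")
  expect_equal(res$status, "assigned")
  expect_equal(res$otu_id, "OTU1")
  expect_equal(res$taxon$species, "sp_x")

  # the read threshold is a strict boundary: 999 fails, 1000 passes
  expect_equal(assign_specimen(otu_row("SPA_S1", "OTU1", 999),
                               "Trichoptera")$status, "insufficient_reads")
  expect_equal(assign_specimen(otu_row("SPA_S1", "OTU1", 1000),
                               "Trichoptera")$status, "assigned")

  mism <- assign_specimen(otu_row("SPA_S1", "OTU1", 5000, order = "Diptera"),
                          "Ephemeroptera")
  expect_equal(mism$status, "order_mismatch")

  nosp <- assign_specimen(otu_row("SPA_S1", "OTU1", 5000, species = ""),
                          "Trichoptera")
  expect_equal(nosp$status, "no_species_hit")

  empty <- assign_specimen(otu_row("SPA_S1", "OTU1", 10)[0, ], "Trichoptera")
  expect_equal(empty$status, "insufficient_reads")
  expect_equal(empty$reads, 0L)
})

test_that("non-target OTUs are excluded before picking the winner", {
  recs <- rbind(otu_row("SPA_S1", "OTUC", 50000, order = "Fungi_indet",
                        target = FALSE),
                otu_row("SPA_S1", "OTU1", 2000))
  res <- assign_specimen(recs, "Trichoptera")
  expect_equal(res$otu_id, "OTU1")
  expect_equal(res$status, "assigned")
})

test_that("read ties break toward the lexicographically smaller OTU id", {
  recs <- rbind(otu_row("SPA_S1", "OTU9", 5000), otu_row("SPA_S1", "OTU2", 5000))
  expect_equal(assign_specimen(recs, "Trichoptera")$otu_id, "OTU2")
})

test_that("the six-specimen fixture yields the four statuses exactly", {
  fixture <- rbind(
    otu_row("SP01_S1", "OTU1", 250000),                       # clean
    otu_row("SP01_S1", "OTUC", 3000, "Fungi_indet", target = FALSE),
    otu_row("SP02_S1", "OTU1", 999),                          # 999 boundary
    otu_row("SP03_S1", "OTU1", 1000),                         # 1000 boundary
    otu_row("SP04_S1", "OTU1", 80000, order = "Diptera"),     # mismatch
    otu_row("SP05_S1", "OTU1", 120000, species = ""),         # no species
    otu_row("SP06_S1", "OTU1", 4000),                         # repeat, S2 wins
    otu_row("SP06_S2", "OTU1", 9000, species = "sp_y")
  )
  morph <- data.frame(
    specimen_id = paste0("SP0", 1:6),
    morphological_order = rep("Trichoptera", 6)
  )
  res <- assign_all(fixture, morph, min_reads = 1000)
  expect_equal(res$assignments$status,
               c("assigned", "insufficient_reads", "assigned",
                 "order_mismatch", "no_species_hit", "assigned"))
  expect_equal(res$assignments$species[6], "sp_y")  # repeat resolved to S2
  s <- res$summary
  expect_equal(s$n_total, 6)
  expect_equal(s$n_assigned + s$n_insufficient + s$n_mismatch + s$n_nospecies,
               s$n_total)
  expect_equal(s$recovery_rate, 5 / 6)
  expect_equal(s$species_rate, 3 / 6)
})

test_that("assignment is invariant to input row order", {
  fixture <- rbind(otu_row("SP01_S1", "OTU1", 250000),
                   otu_row("SP01_S1", "OTU5", 1500),
                   otu_row("SP02_S1", "OTU3", 2000, species = ""))
  morph <- data.frame(specimen_id = c("SP01", "SP02"),
                      morphological_order = "Trichoptera")
  a <- assign_all(fixture, morph)
  b <- assign_all(fixture[rev(seq_len(nrow(fixture))), ], morph)
  expect_equal(a$assignments, b$assignments)
})

test_that("synthetic no-failure run assigns every specimen correctly", {
  tax <- generate_taxonomy(3, 3, 2, 2, seed = 4)
  al <- allometry_params(tax, seed = 4)
  spm <- generate_specimens(tax, 10, al, seed = 4)
  otu <- generate_otu_table(spm, failure_rates = c(noreads = 0, mismatch = 0,
                                                   nospecies = 0),
                            p_repeat = 0.3, seed = 4)
  morph <- data.frame(specimen_id = spm$specimen_id,
                      morphological_order = spm$order)
  res <- assign_all(otu$records, morph)
  expect_equal(res$summary$species_rate, 1.0, ignore_attr = TRUE)
  expect_equal(res$assignments$species,
               spm$species[match(res$assignments$specimen_id,
                                 spm$specimen_id)])
})

test_that("injected failures are recovered specimen-by-specimen", {
  tax <- generate_taxonomy(4, 4, 2, 2, seed = 8)
  al <- allometry_params(tax, seed = 8)
  spm <- generate_specimens(tax, 100, al, seed = 8)
  otu <- generate_otu_table(spm, seed = 8)
  morph <- data.frame(specimen_id = spm$specimen_id,
                      morphological_order = spm$order)
  res <- assign_all(otu$records, morph)
  expected <- ifelse(otu$ledger$injected_status == "none", "assigned",
                     otu$ledger$injected_status)
  got <- res$assignments$status[match(otu$ledger$specimen_id,
                                      res$assignments$specimen_id)]
  expect_equal(got, expected)
})
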