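test_that("taxonomy has exact rank sizes and a functional ancestor map", {
  tax <- generate_taxonomy(14, 13, 7, 3, seed = 1)
  expect_equal(nrow(tax), 14)
  expect_equal(length(unique(tax$genus)), 13)
  expect_equal(length(unique(tax$family)), 7)
  expect_equal(length(unique(tax$order)), 3)
  # each genus maps to one family, each family to one order
  expect_true(all(tapply(tax$family, tax$genus,
                         function(x) length(unique(x))) == 1))
  expect_true(all(tapply(tax$order, tax$family,
                         function(x) length(unique(x))) == 1))
})

test_that("taxonomy handles the degenerate case and is deterministic", {
  t1 <- generate_taxonomy(1, 1, 1, 1, seed = 0)
  expect_equal(nrow(t1), 1)
  a <- generate_taxonomy(3, 2, 2, 1, seed = 5)
  b <- generate_taxonomy(3, 2, 2, 1, seed = 5)
  expect_identical(a, b)
  expect_error(generate_taxonomy(3, 4, 2, 1, seed = 1), "nested")
})

test_that("noiseless specimens follow the power law exactly", {
  tax <- generate_taxonomy(1, 1, 1, 1, seed = 0)
  al <- toy_allometry(c_s = 1, b_s = 3, species = tax$species)
  sp <- generate_specimens(tax, 50, al, seed = 3)
  expect_equal(sp$true_mass_mg, sp$length_mm^3, tolerance = 1e-12)
  # the spec's worked value: c=1, b=3, L=2 gives exactly 8 mg
  expect_equal(1 * 2^3, 8)
})

test_that("lognormal mass noise has the configured log-scale moments", {
  tax <- generate_taxonomy(1, 1, 1, 1, seed = 0)
  al <- toy_allometry(c_s = 0.05, b_s = 2.5, sigma = 0.2,
                      species = tax$species)
  sp <- generate_specimens(tax, 10000, al, seed = 4)
  eps <- log(sp$true_mass_mg) - (log(0.05) + 2.5 * log(sp$length_mm))
  expect_lt(abs(mean(eps)), 3 * 0.2 / sqrt(10000))
  expect_equal(stats::sd(eps), 0.2, tolerance = 0.02)
})

test_that("specimen generation is seed-sensitive and rejects bad params", {
  tax <- generate_taxonomy(2, 2, 1, 1, seed = 1)
  al <- toy_allometry(c_s = 0.05, b_s = 2.5, sigma = 0.1,
                      species = tax$species)
  s1 <- generate_specimens(tax, 5, al, seed = 1)
  s2 <- generate_specimens(tax, 5, al, seed = 2)
  expect_true(any(s1$true_mass_mg != s2$true_mass_mg))
  bad <- al; bad$c_s[] <- -1
  expect_error(generate_specimens(tax, 5, bad, seed = 1), "positive")
})

test_that("weighing rounds to readability and can go non-positive", {
  al <- toy_allometry(noise_sd = 0, readability = 0.2)
  expect_equal(weigh(10.0000, al, seed = 1), 10.0)
  al2 <- toy_allometry(noise_sd = 0.13, readability = 0.2)
  w <- weigh(rep(1.37, 500), al2, seed = 2)
  expect_true(all(abs(w / 0.2 - round(w / 0.2)) < 1e-9))
  # tiny mass with 0.2 mg noise: non-positive records at the Normal rate
  al3 <- toy_allometry(noise_sd = 0.2, readability = 0.2)
  w3 <- weigh(rep(0.05, 4000), al3, seed = 3)
  p_hat <- mean(w3 <= 0)
  p_true <- stats::pnorm((0.1 - 0.05) / 0.2)   # measured < r/2 rounds to <= 0
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / 4000))
  expect_gt(sum(w3 <= 0), 0)
})

test_that("frames split across the two cameras and junk is flagged", {
  sp <- toy_specimen(length_mm = 8)
  fr <- render_frames(sp, 4, img_size = c(60, 60), px_per_mm = 3,
                      junk_rate = 0, seed = 1)
  expect_length(fr, 4)
  expect_equal(sort(table(vapply(fr, `[[`, 0, "camera_id"))), c(`0` = 2, `1` = 2),
               ignore_attr = TRUE)
  expect_false(any(vapply(fr, `[[`, NA, "nontarget")))
  frj <- render_frames(sp, 6, img_size = c(60, 60), px_per_mm = 3,
                       junk_rate = 1, seed = 1)
  expect_true(all(vapply(frj, `[[`, NA, "nontarget")))
})

test_that("rendered silhouette extent matches body length within 2 px", {
  for (s in 1:3) {
    sp <- toy_specimen(length_mm = 10, elongation = 2 + s,
                       n_appendages = 2L * s, cased = s == 3)
    fr <- render_frames(sp, 8, img_size = c(70, 70), px_per_mm = 4,
                        junk_rate = 0, seed = s)
    for (f in fr) {
      mask <- segment(f, 0.5)
      expect_lt(abs(brute_feret(mask) - 10 * 4), 2)
    }
  }
  # circle-bodied species: rasterized disk diameter
  spd <- toy_specimen(length_mm = 5, elongation = 1, taper = 0,
                      n_appendages = 0L, dorso_factor = 1)
  frd <- render_frames(spd, 4, img_size = c(70, 70), px_per_mm = 10,
                       seed = 2)
  for (f in frd) {
    expect_lt(abs(brute_feret(segment(f, 0.5)) - 50), 2)
  }
})

test_that("oversized silhouettes raise an error naming the specimen", {
  sp <- toy_specimen(specimen_id = "BIGONE", length_mm = 30)
  expect_error(render_frames(sp, 2, img_size = c(40, 40), px_per_mm = 3),
               "BIGONE")
})

test_that("failure-free OTU tables put the true species on top", {
  tax <- generate_taxonomy(4, 4, 2, 2, seed = 2)
  al <- allometry_params(tax, seed = 2)
  sp <- generate_specimens(tax, 5, al, seed = 2)
  otu <- generate_otu_table(sp, failure_rates = c(noreads = 0, mismatch = 0,
                                                  nospecies = 0),
                            p_repeat = 0, seed = 2)
  expect_true(all(otu$ledger$injected_status == "none"))
  top <- do.call(rbind, lapply(split(otu$records, otu$records$specimen_id),
    function(r) r[which.max(r$reads), c("specimen_id", "species")]))
  truth <- stats::setNames(sp$species, sp$specimen_id)
  expect_equal(unname(truth[top$specimen_id]), top$species)
})

test_that("PCR repeats yield two samples and injection rates converge", {
  tax <- generate_taxonomy(3, 3, 2, 1, seed = 3)
  al <- allometry_params(tax, seed = 3)
  sp <- generate_specimens(tax, 200, al, seed = 3)
  rates <- c(noreads = 0.072, mismatch = 0.034, nospecies = 0.031)
  otu <- generate_otu_table(sp, failure_rates = rates, p_repeat = 0.5,
                            seed = 3)
  n_samples <- tapply(otu$records$sample_id, otu$records$specimen_id,
                      function(x) length(unique(x)))
  expect_true(any(n_samples == 2))
  led_n <- otu$ledger$n_samples[match(names(n_samples),
                                      otu$ledger$specimen_id)]
  expect_equal(unname(n_samples), led_n, ignore_attr = TRUE)
  n <- nrow(sp)
  obs <- table(factor(otu$ledger$injected_status,
                      c("insufficient_reads", "order_mismatch",
                        "no_species_hit"))) / n
  for (k in 1:3) {
    se <- sqrt(rates[k] * (1 - rates[k]) / n)
    expect_lt(abs(obs[k] - rates[k]), 3 * se + 1e-12)
  }
})

test_that("generation is byte-deterministic for a fixed seed", {
  tax <- generate_taxonomy(2, 2, 2, 1, seed = 9)
  al <- allometry_params(tax, seed = 9)
  sp <- generate_specimens(tax, 3, al, seed = 9)
  f1 <- render_frames(sp[1, ], 4, img_size = c(60, 60), px_per_mm = 3,
                      junk_rate = 0.2, seed = 9)
  f2 <- render_frames(sp[1, ], 4, img_size = c(60, 60), px_per_mm = 3,
                      junk_rate = 0.2, seed = 9)
  expect_identical(f1, f2)
  o1 <- generate_otu_table(sp, seed = 9)
  o2 <- generate_otu_table(sp, seed = 9)
  expect_identical(o1, o2)
})
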