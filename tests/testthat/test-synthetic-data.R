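test_that("generators are deterministic under a fixed seed", {
  a <- simulate_variants(n_proteins = 10, seed = 123)
  b <- simulate_variants(n_proteins = 10, seed = 123)
  expect_identical(a, b)
  expect_false(identical(a$sequences,
                         simulate_variants(n_proteins = 10,
                                           seed = 124)$sequences))
  kit <- miha_kit_panel()
  expect_identical(simulate_events(kit, n_events = 500, seed = 5),
                   simulate_events(kit, n_events = 500, seed = 5))
  expect_identical(simulate_od(letters, seed = 9),
                   simulate_od(letters, seed = 9))
  expect_identical(simulate_genotypes(c(rs1 = 0.3), 100, seed = 7),
                   simulate_genotypes(c(rs1 = 0.3), 100, seed = 7))
})

test_that("variant generator embeds valid nonsynonymous substitutions", {
  sim <- simulate_variants(n_proteins = 0, seed = 1)
  expect_equal(length(sim$sequences), 0)
  expect_equal(nrow(sim$variants), 0)

  sim <- simulate_variants(n_proteins = 30, seed = 202)
  v <- sim$variants
  expect_equal(substr(sim$sequences[v$protein_id], v$position, v$position),
               stats::setNames(v$ref_aa, v$protein_id))
  expect_true(all(v$ref_aa != v$alt_aa))
  # windows enumerate cleanly from generated proteins
  pairs <- enumerate_windows(v, sim$sequences)
  expect_true(all(pairs$length %in% c(9, 10)))
  # truth flag is definitionally consistent with the band filter
  kept <- filter_by_frequency(v, band = c(0.15, 0.46))
  expect_setequal(kept$snp_id,
                  sim$truth$snp_id[sim$truth$truth_in_band])
})

test_that("variant frequencies fill the configured band at the analytic rate", {
  sim <- simulate_variants(n_proteins = 5000, length_range = c(30, 40),
                           freq_range = c(0.01, 0.6), seed = 77)
  frac <- mean(sim$truth$truth_in_band)
  expected <- (0.46 - 0.15) / (0.6 - 0.01)
  se <- sqrt(expected * (1 - expected) / 5000)
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("OD draws are class-consistent by construction", {
  od <- simulate_od(sprintf("p%d", 1:300), seed = 31)
  expect_equal(classify_od(od$od), od$truth_class)
})

test_that("event generator truth matches its own decode confusion-free when noise is off", {
  kit <- miha_kit_panel()
  spikes <- stats::setNames(rep(0.01, 10), kit$peptide_id)
  sim <- simulate_events(kit, n_events = 2e4, spike_freqs = spikes,
                         single_noise = 0, triple_noise = 0, seed = 41)
  g <- gate_cd8(sim$events)
  dec <- decode_events(g, kit)
  # no off-diagonal assignments: decoded label equals truth label row-wise
  truth_gated <- sim$truth$label[sim$truth$gateable]
  decoded <- rep(NA_character_, nrow(g))
  ok <- !is.na(dec$assignment)
  decoded[ok] <- kit$peptide_id[dec$assignment[ok]]
  expect_equal(decoded[truth_gated != "negative"],
               truth_gated[truth_gated != "negative"])
  expect_true(all(is.na(decoded[truth_gated == "negative"])))
})

test_that("a single 1% spike is recovered within binomial error", {
  kit <- miha_kit_panel()
  sim <- simulate_events(kit, n_events = 1e5,
                         spike_freqs = c(SMCY = 0.01),
                         single_noise = 0, triple_noise = 0, seed = 43)
  g <- gate_cd8(sim$events)
  td <- tidy(decode_events(g, kit))
  f <- td$frequency[td$peptide_id == "SMCY"] / 100
  se <- sqrt(0.01 * 0.99 / nrow(g))
  expect_lt(abs(f - 0.01), 3 * se)
})

test_that("spike mass above one is rejected", {
  kit <- miha_kit_panel()
  expect_error(simulate_events(kit, n_events = 10, spike_freqs = 0.2),
               "exceed 1")
})

test_that("genotype generator reproduces the HWE disparity rate", {
  sim <- simulate_genotypes(c(rsA = 0.15), n_pairs = 1e5, seed = 53)
  expect_equal(sim$truth_disparate,
               is_disparate(sim$recipient_alt_count, sim$donor_alt_count))
  rate <- mean(sim$truth_disparate)
  expected <- clinical_applicability(0.15)
  se <- sqrt(expected * (1 - expected) / 1e5)
  expect_lt(abs(rate - expected), 3 * se)
  # degenerate frequency: nobody carries the allele
  none <- simulate_genotypes(c(rs0 = 0), n_pairs = 100, seed = 3)
  expect_true(all(none$recipient_alt_count == 0))
  expect_false(any(none$truth_disparate))
})

test_that("simulated FASTA and variant tables round-trip through the readers", {
  sim <- simulate_variants(n_proteins = 8, seed = 15)
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_protein_fasta(sim$sequences, fa)
  readr::write_tsv(sim$variants, tsv, progress = FALSE)
  seqs <- read_protein_fasta(fa)
  expect_identical(seqs, sim$sequences)
  vars <- read_variant_table(tsv)
  expect_equal(vars$protein_id, sim$variants$protein_id)
  expect_equal(vars$alt_allele_freq, sim$variants$alt_allele_freq)
  # the full pipeline runs from files
  pairs <- enumerate_windows(vars, seqs)
  expect_gt(nrow(pairs), 0)
})

test_that("genotype strings map to allele counts via the declared positive letter", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp_id\trecipient\tdonor",
               "rs1\tAB\tAA",
               "rs2\tBB\tA/B",
               "rs3\tAA\tBB"), path)
  g <- read_genotype_table(path, positive_allele = "B")
  expect_equal(g$recipient_alt_count, c(1L, 2L, 0L))
  expect_equal(g$donor_alt_count, c(0L, 1L, 2L))
  expect_equal(is_disparate(g$recipient_alt_count, g$donor_alt_count),
               c(TRUE, FALSE, FALSE))
  expect_error(read_genotype_table(path), "positive_allele")
})
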