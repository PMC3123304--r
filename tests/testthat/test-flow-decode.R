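kit <- miha_kit_panel()

# tiny hand-built event table: intensities are raw a.u.; the default config
# calls > 500 positive
toy_events <- function(rows) {
  cols <- c(kit_channels, "cd8_intensity", "dump_intensity",
            "viability_intensity")
  df <- as.data.frame(matrix(50, nrow = length(rows), ncol = length(cols),
                             dimnames = list(NULL, cols)))
  df$cd8_intensity <- 5000
  for (i in seq_along(rows)) {
    for (ch in rows[[i]]) df[[ch]][i] <- 5000
  }
  tibble::as_tibble(df)
}

test_that("gating keeps live dump-negative CD8-positive events and logs counts", {
  ev <- toy_events(list(character(), character(), character(), character()))
  ev$viability_intensity[2] <- 5000 # dead
  ev$dump_intensity[3] <- 5000      # lineage dump
  ev$cd8_intensity[4] <- 50         # CD8-negative
  g <- gate_cd8(ev)
  expect_equal(nrow(g), 1)
  expect_equal(unname(attr(g, "gate_counts")),
               c(4L, 3L, 2L, 1L))
  expect_error(gate_cd8(ev[, setdiff(names(ev), "cd8_intensity")]),
               "cd8_intensity")
})

test_that("all-dead and identity gates behave as the conjunction implies", {
  ev <- toy_events(rep(list(character()), 5))
  expect_equal(nrow(gate_cd8(ev)), 5)
  ev$viability_intensity <- 5000
  expect_equal(nrow(gate_cd8(ev)), 0)
})

test_that("gated fraction tracks the configured CD8 fraction", {
  sim <- simulate_events(kit, n_events = 2e4, cd8_fraction = 0.7,
                         spike_freqs = 0, single_noise = 0,
                         triple_noise = 0, seed = 55)
  g <- gate_cd8(sim$events)
  counts <- attr(g, "gate_counts")
  frac <- counts[["n_cd8"]] / counts[["n_dump_neg"]]
  se <- sqrt(0.7 * 0.3 / counts[["n_dump_neg"]])
  expect_lt(abs(frac - 0.7), 3 * se)
})

test_that("exactly-two-positive events are assigned to their code", {
  ev <- toy_events(list(
    c("PE", "APC"),                      # SMCY code
    c("PE"),                             # single positive
    c("PE", "APC", "Qdot605"),           # triple positive
    character()                          # negative
  ))
  dec <- decode_events(ev, kit)
  td <- tidy(dec)
  expect_equal(td$n_events[td$peptide_id == "SMCY"], 1L)
  expect_equal(sum(td$n_events), 1L)
  expect_equal(dec$n_unassigned_single, 1L)
  expect_equal(dec$n_unassigned_multi, 1L)
  expect_equal(dec$n_negative, 1L)
  expect_equal(td$frequency[td$peptide_id == "SMCY"], 25)
})

test_that("a dual-positive pair matching no panel code is excluded, not assigned", {
  half_kit <- kit[1:3, ] # PE+APC, PE+Qdot605, PE+Qdot655 only
  attr(half_kit, "channels") <- kit_channels
  ev <- toy_events(list(c("Qdot655", "Qdot705")))
  dec <- decode_events(ev, half_kit)
  expect_equal(dec$n_assigned, 0L)
  expect_equal(dec$n_unassigned_multi, 1L)
})

test_that("an all-negative acquisition decodes to all-zero frequencies", {
  ev <- toy_events(rep(list(character()), 10))
  dec <- decode_events(ev, kit)
  expect_true(all(tidy(dec)$frequency == 0))
  expect_equal(dec$n_negative, 10L)
})

test_that("decoded counts always conserve the gated total", {
  set.seed(77)
  for (rep in 1:5) {
    sim <- simulate_events(kit, n_events = 5e3,
                           spike_freqs = stats::setNames(
                             runif(10, 0, 0.02), kit$peptide_id),
                           single_noise = runif(1, 0, 0.05),
                           triple_noise = runif(1, 0, 0.01),
                           seed = sample.int(1e6, 1))
    g <- gate_cd8(sim$events)
    gl <- glance(decode_events(g, kit))
    expect_equal(gl$n_assigned + gl$n_unassigned_single +
                   gl$n_unassigned_multi + gl$n_negative,
                 gl$n_cd8_gated)
  }
})

test_that("spiked specificities are recovered and noise events excluded", {
  spikes <- stats::setNames(seq(0.001, 0.01, length.out = 10),
                            kit$peptide_id)
  sim <- simulate_events(kit, n_events = 5e4, spike_freqs = spikes,
                         seed = 99)
  g <- gate_cd8(sim$events)
  dec <- decode_events(g, kit)
  truth <- table(sim$truth$label[sim$truth$gateable])
  td <- tidy(dec)
  for (sp in kit$peptide_id) {
    expect_equal(td$n_events[td$peptide_id == sp],
                 unname(as.integer(truth[sp])))
  }
  expect_equal(dec$n_unassigned_single,
               unname(as.integer(truth["noise_single"])))
  expect_equal(dec$n_unassigned_multi,
               unname(as.integer(truth["noise_triple"])))
})

test_that("dual-color frequency dominates the decoded frequency of the same code", {
  spikes <- stats::setNames(rep(0.005, 10), kit$peptide_id)
  sim <- simulate_events(kit, n_events = 3e4, spike_freqs = spikes,
                         single_noise = 0.02, triple_noise = 0.01,
                         seed = 13)
  g <- gate_cd8(sim$events)
  dec <- tidy(decode_events(g, kit))
  for (i in c(1, 5, 10)) {
    dcf <- dual_color_frequency(g, c(kit$channel_1[i], kit$channel_2[i]))
    expect_gte(dcf, dec$frequency[i])
  }
  expect_error(dual_color_frequency(g, c("PE", "NoSuch")), "NoSuch")
})

test_that("a constructed 11-in-10000 table reads out as 0.11%", {
  rows <- c(rep(list(c("PE", "APC")), 11), rep(list(character()), 9989))
  ev <- toy_events(rows)
  expect_equal(dual_color_frequency(ev, c("PE", "APC")), 0.11)
  expect_equal(format_frequency(0.11), "0.11%")
  expect_equal(format_frequency(0.009), "<0.01%")
})

test_that("raising a channel threshold never increases its positive count", {
  sim <- simulate_events(kit, n_events = 5e3, seed = 3)
  base <- gating_config()$threshold
  counts <- vapply(base * c(0.5, 1, 1.5, 2), function(thr) {
    cfg <- gating_config(channel_thresholds = c(PE = thr))
    sum(mihakit:::channel_positive(sim$events, "PE", cfg))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("quantile-of-negatives thresholds sit above nearly all negatives", {
  sim <- simulate_events(kit, n_events = 2e4, spike_freqs = 0,
                         single_noise = 0, triple_noise = 0, seed = 31)
  cfg <- gating_config()
  thr <- quantile_thresholds(sim$events, kit_channels, cfg, probs = 0.999)
  cfg2 <- gating_config(channel_thresholds = thr)
  dec <- decode_events(gate_cd8(sim$events, cfg), kit, cfg2)
  # at the 99.9th percentile about 0.1% of events per channel are called
  # positive; with 6 codes none should pair up into dual positives often
  expect_lte(dec$n_assigned, 5)
})
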