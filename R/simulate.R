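#' Seeded synthetic coefficient table
#'
#' Draws a full position-by-residue coefficient matrix from a log-normal
#' distribution. With the defaults the log half-time of a random peptide is
#' approximately normal with mean `log(constant)` and standard deviation
#' `sdlog * sqrt(length)`, so predicted half-times straddle a 30-second
#' threshold rather than falling uniformly on one side.
#'
#' @param length Peptide length the table covers.
#' @param seed Integer seed; identical seeds give identical tables.
#' @param constant Allele constant in seconds.
#' @param sdlog Log-scale spread of the coefficients.
#' @param allele Allele label.
#' @return A [coefficient_table()].
#' @export
simulate_coefficient_table <- function(length = 9, seed = 20110624,
                                       constant = 100, sdlog = 0.8,
                                       allele = "HLA-A2") {
  withr::with_seed(seed, {
    mat <- matrix(rlnorm(length * 20, meanlog = 0, sdlog = sdlog),
                  nrow = length, dimnames = list(NULL, AA_ALPHABET))
    coefficient_table(mat, constant = constant, allele = allele)
  })
}

#' Simulate proteins with embedded nonsynonymous SNPs
#'
#' Generates random protein sequences over the 20-letter alphabet, each with
#' one nonsynonymous substitution at a uniformly chosen position and a
#' MiHA-positive allele frequency drawn uniformly from `freq_range`. The
#' truth table records, per variant, whether its frequency falls inside the
#' operational applicability band so downstream frequency filtering can be
#' scored.
#'
#' @param n_proteins Number of proteins (one variant each).
#' @param length_range Length-2 integer range of protein lengths (uniform).
#' @param freq_range Length-2 range of allele frequencies (uniform).
#' @param band Applicability band used to set the truth flag.
#' @param seed Integer seed.
#' @return List with `sequences` (named character vector), `variants`
#'   (tibble as consumed by [enumerate_windows()]) and `truth` (tibble:
#'   `protein_id`, `snp_id`, `truth_in_band`).
#' @export
simulate_variants <- function(n_proteins = 50, length_range = c(30L, 300L),
                              freq_range = c(0.01, 0.6),
                              band = c(0.15, 0.46), seed = 20110624) {
  stopifnot(n_proteins >= 0, length_range[1] >= 3,
            freq_range[1] >= 0, freq_range[2] <= 1)
  if (n_proteins == 0) {
    return(list(
      sequences = setNames(character(), character()),
      variants = tibble(protein_id = character(), position = integer(),
                        ref_aa = character(), alt_aa = character(),
                        alt_allele_freq = double(), snp_id = character()),
      truth = tibble(protein_id = character(), snp_id = character(),
                     truth_in_band = logical())
    ))
  }
  withr::with_seed(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), n_proteins,
                   replace = TRUE)
    ids <- sprintf("PROT%04d", seq_len(n_proteins))
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
    }, character(1))
    names(seqs) <- ids
    pos <- vapply(lens, function(L) sample.int(L, 1), integer(1))
    ref <- substring(seqs, pos, pos)
    alt <- vapply(ref, function(a) sample(setdiff(AA_ALPHABET, a), 1),
                  character(1), USE.NAMES = FALSE)
    freq <- runif(n_proteins, freq_range[1], freq_range[2])
    variants <- tibble(
      protein_id = ids, position = as.integer(pos), ref_aa = ref,
      alt_aa = alt, alt_allele_freq = freq,
      snp_id = sprintf("rs%07d", sample.int(9999999, n_proteins))
    )
    list(
      sequences = seqs,
      variants = variants,
      truth = tibble(
        protein_id = ids, snp_id = variants$snp_id,
        truth_in_band = freq >= band[1] & freq <= band[2]
      )
    )
  })
}

#' Simulate a peptide-exchange ELISA OD table with known classes
#'
#' Each peptide is given a true affinity class (low / intermediate / high)
#' and an OD drawn uniformly from that class's range, so [classify_od()]
#' recovers the truth exactly and [triage_od()] counts can be scored against
#' the construction.
#'
#' @param peptide_ids Character vector of peptide identifiers.
#' @param class_weights Named numeric sampling weights for the three
#'   classes; the screening-campaign default is 32/33/42 low/intermediate/
#'   high out of 107.
#' @param class_counts Optional named integer vector (low/intermediate/high)
#'   forcing exact class counts (must sum to `length(peptide_ids)`);
#'   overrides `class_weights`.
#' @param od_ranges Named list of length-2 OD ranges per class. The defaults
#'   abut the 0.4 and 1.25 cutoffs without crossing them.
#' @param seed Integer seed.
#' @return Tibble (`peptide`, `od`, `truth_class`).
#' @export
simulate_od <- function(peptide_ids,
                        class_weights = c(low = 32, intermediate = 33,
                                          high = 42),
                        class_counts = NULL,
                        od_ranges = list(low = c(0, 0.39),
                                         intermediate = c(0.4, 1.24),
                                         high = c(1.25, 2.5)),
                        seed = 20110624) {
  n <- length(peptide_ids)
  classes <- c("low", "intermediate", "high")
  stopifnot(all(classes %in% names(od_ranges)))
  withr::with_seed(seed, {
    if (!is.null(class_counts)) {
      stopifnot(all(classes %in% names(class_counts)),
                sum(class_counts[classes]) == n)
      truth <- sample(rep(classes, times = class_counts[classes]))
    } else {
      stopifnot(all(classes %in% names(class_weights)))
      truth <- sample(classes, n, replace = TRUE,
                      prob = class_weights[classes])
    }
    od <- vapply(truth, function(cl) {
      r <- od_ranges[[cl]]
      runif(1, r[1], r[2])
    }, numeric(1), USE.NAMES = FALSE)
    tibble(peptide = as.character(peptide_ids), od = od,
           truth_class = factor(truth, levels = classes))
  })
}

#' Simulate a flow-cytometry event table with spiked-in specificities
#'
#' Emulates a combinatorially encoded multimer acquisition. Each event is
#' independently live/dead, dump-positive or not, and CD8-positive or not;
#' among CD8-positive live dump-negative ("gateable") events a label is
#' drawn: one of the panel's specificities (at its spike frequency),
#' single-positive noise, triple-positive noise, or negative. Labelled
#' events receive bright intensities in exactly their code's two channels;
#' noise events in 1 or 3 random channels. Intensities are two-component
#' log-normal per channel (dim negative component, bright positive
#' component), the simplest model under which fixed-threshold gating is
#' exact or noisy on demand.
#'
#' @param panel Panel assignment (`peptide_id`, `channel_1`, `channel_2`).
#' @param n_events Total events acquired.
#' @param cd8_fraction Fraction of live dump-negative events that are CD8+.
#' @param spike_freqs Named numeric vector (names in `panel$peptide_id`) of
#'   per-specificity frequencies among gateable events; unnamed scalar is
#'   recycled to all panel entries.
#' @param single_noise,triple_noise Fractions of gateable events that are
#'   single- / triple-positive artifacts.
#' @param dead_fraction,dump_fraction Fractions of events that are dead /
#'   dump-positive.
#' @param intensity List with `neg` and `pos` components, each
#'   `c(meanlog, sdlog)` of the log-normal intensity distribution.
#' @param seed Integer seed.
#' @return List with `events` (tibble: one column per multimer channel plus
#'   `cd8_intensity`, `dump_intensity`, `viability_intensity`) and `truth`
#'   (tibble: `event`, `gateable`, `label` — a specificity id,
#'   `"noise_single"`, `"noise_triple"` or `"negative"`).
#' @export
simulate_events <- function(panel, n_events = 1e5, cd8_fraction = 0.7,
                            spike_freqs = 0.005,
                            single_noise = 0.01, triple_noise = 0.002,
                            dead_fraction = 0.05, dump_fraction = 0.1,
                            intensity = list(neg = c(meanlog = log(40),
                                                     sdlog = 0.45),
                                             pos = c(meanlog = log(5000),
                                                     sdlog = 0.4)),
                            seed = 20110624) {
  panel <- as_tibble(panel)
  channels <- panel_channels(panel)
  if (is.null(names(spike_freqs))) {
    stopifnot(length(spike_freqs) %in% c(1, nrow(panel)))
    spike_freqs <- setNames(rep_len(spike_freqs, nrow(panel)),
                            panel$peptide_id)
  }
  stopifnot(all(names(spike_freqs) %in% panel$peptide_id),
            all(spike_freqs >= 0))
  mass <- sum(spike_freqs) + single_noise + triple_noise
  if (mass > 1) {
    abort(paste0("spike frequencies plus noise rates exceed 1 (",
                 format(mass), ")"))
  }
  withr::with_seed(seed, {
    dead <- runif(n_events) < dead_fraction
    dump <- runif(n_events) < dump_fraction
    cd8 <- runif(n_events) < cd8_fraction
    gateable <- !dead & !dump & cd8

    labels <- rep("negative", n_events)
    lab_space <- c(names(spike_freqs), "noise_single", "noise_triple",
                   "negative")
    lab_prob <- c(unname(spike_freqs), single_noise, triple_noise, 1 - mass)
    n_gate <- sum(gateable)
    labels[gateable] <- sample(lab_space, n_gate, replace = TRUE,
                               prob = lab_prob)

    draw <- function(n, comp) {
      rlnorm(n, meanlog = intensity[[comp]][["meanlog"]],
             sdlog = intensity[[comp]][["sdlog"]])
    }
    events <- as_tibble(setNames(
      lapply(channels, function(ch) draw(n_events, "neg")), channels))
    events$cd8_intensity <- ifelse(cd8, draw(n_events, "pos"),
                                   draw(n_events, "neg"))
    events$dump_intensity <- ifelse(dump, draw(n_events, "pos"),
                                    draw(n_events, "neg"))
    events$viability_intensity <- ifelse(dead, draw(n_events, "pos"),
                                         draw(n_events, "neg"))

    code_ch <- setNames(map2(panel$channel_1, panel$channel_2, c),
                        panel$peptide_id)
    for (sp in names(spike_freqs)) {
      rows <- which(labels == sp)
      for (ch in code_ch[[sp]]) {
        events[[ch]][rows] <- draw(length(rows), "pos")
      }
    }
    for (i in which(labels == "noise_single")) {
      ch <- sample(channels, 1)
      events[[ch]][i] <- draw(1, "pos")
    }
    for (i in which(labels == "noise_triple")) {
      for (ch in sample(channels, 3)) {
        events[[ch]][i] <- draw(1, "pos")
      }
    }
    list(
      events = events,
      truth = tibble(event = seq_len(n_events), gateable = gateable,
                     label = labels)
    )
  })
}

#' Simulate donor/recipient genotype pairs under Hardy-Weinberg
#'
#' Donor and recipient MiHA-positive allele counts are drawn independently
#' as Binomial(2, p) at each SNP, so the expected fraction of
#' GVT-direction-disparate pairs equals [clinical_applicability()]`(p)`.
#'
#' @param allele_freqs Named numeric vector of MiHA-positive allele
#'   frequencies (names are SNP ids).
#' @param n_pairs Donor/recipient pairs simulated per SNP.
#' @param seed Integer seed.
#' @return Tibble (`snp_id`, `pair`, `recipient_alt_count`,
#'   `donor_alt_count`, `truth_disparate`).
#' @export
simulate_genotypes <- function(allele_freqs, n_pairs = 1,
                               seed = 20110624) {
  stopifnot(all(allele_freqs >= 0), all(allele_freqs <= 1), n_pairs >= 0)
  if (is.null(names(allele_freqs))) {
    names(allele_freqs) <- sprintf("snp%03d", seq_along(allele_freqs))
  }
  withr::with_seed(seed, {
    out <- map_dfr(names(allele_freqs), function(snp) {
      p <- allele_freqs[[snp]]
      tibble(
        snp_id = snp,
        pair = seq_len(n_pairs),
        recipient_alt_count = rbinom(n_pairs, 2, p),
        donor_alt_count = rbinom(n_pairs, 2, p)
      )
    })
    out$truth_disparate <- is_disparate(out$recipient_alt_count,
                                        out$donor_alt_count)
    out
  })
}
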