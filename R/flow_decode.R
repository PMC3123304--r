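#' Gating configuration for event-table analysis
#'
#' Positivity calls are made on transformed intensities against per-channel
#' thresholds. The default transform is the inverse hyperbolic sine with a
#' cofactor of 150 — the conventional compromise that is linear near zero
#' and logarithmic for bright signals — with a single default threshold
#' placed at 500 intensity units (on the transformed scale). Any channel can
#' be given its own threshold, either fixed or derived from a negative
#' (unstained) control via [quantile_thresholds()].
#'
#' @param transform Intensity transform: `"asinh"` (default), `"log10"`
#'   (applied as `log10(1 + x)`), or `"linear"`.
#' @param cofactor Positive cofactor for the asinh transform
#'   (`asinh(x / cofactor)`).
#' @param threshold Default positivity threshold on the transformed scale,
#'   used for any channel without its own entry.
#' @param channel_thresholds Optional named numeric vector of per-channel
#'   thresholds (transformed scale), e.g. from [quantile_thresholds()].
#' @return An object of class `gating_config`.
#' @export
gating_config <- function(transform = c("asinh", "log10", "linear"),
                          cofactor = 150,
                          threshold = NULL,
                          channel_thresholds = NULL) {
  transform <- arg_match(transform)
  stopifnot(cofactor > 0)
  cfg <- structure(
    list(transform = transform, cofactor = cofactor,
         threshold = threshold, channel_thresholds = channel_thresholds),
    class = "gating_config"
  )
  if (is.null(cfg$threshold)) {
    cfg$threshold <- transform_intensity(500, cfg)
  }
  stopifnot(is.finite(cfg$threshold))
  cfg
}

#' @export
print.gating_config <- function(x, ...) {
  cat("<gating_config> transform = ", x$transform,
      if (x$transform == "asinh") paste0(" (cofactor ", x$cofactor, ")"),
      ", default threshold = ", format(x$threshold, digits = 4),
      if (length(x$channel_thresholds) > 0)
        paste0(", ", length(x$channel_thresholds), " per-channel threshold(s)"),
      "\n", sep = "")
  invisible(x)
}

transform_intensity <- function(x, cfg) {
  switch(cfg$transform,
    asinh = asinh(x / cfg$cofactor),
    log10 = log10(1 + x),
    linear = x
  )
}

threshold_for <- function(cfg, channel) {
  cfg$channel_thresholds[[channel]] %||% cfg$threshold
}

channel_positive <- function(events, channel, cfg) {
  if (!channel %in% names(events)) {
    abort(paste0("event table has no column '", channel, "'"))
  }
  transform_intensity(events[[channel]], cfg) > threshold_for(cfg, channel)
}

#' Derive per-channel thresholds from a negative control table
#'
#' Quantile-of-negatives auto-thresholding: each channel's threshold is set
#' at a high quantile of the transformed intensities observed in an
#' unstained (or otherwise negative) control acquisition.
#'
#' @param negatives Event table of negative-control events.
#' @param channels Channels to threshold.
#' @param cfg A [gating_config()] providing the transform.
#' @param probs Quantile used (default 0.999).
#' @return Named numeric vector suitable for
#'   `gating_config(channel_thresholds = ...)`.
#' @export
quantile_thresholds <- function(negatives, channels, cfg = gating_config(),
                                probs = 0.999) {
  vapply(channels, function(ch) {
    if (!ch %in% names(negatives)) {
      abort(paste0("negative-control table has no column '", ch, "'"))
    }
    quantile(transform_intensity(negatives[[ch]], cfg), probs, names = FALSE)
  }, numeric(1))
}

#' Gate events to live, dump-negative, CD8-positive lymphocytes
#'
#' Applies the standard pre-multimer gate: viability dye negative (live),
#' dump channel negative (excluding CD4/CD14/CD16/CD19-lineage events),
#' CD8 positive. The three conditions are a conjunction so their order does
#' not change the result, but per-gate event counts are recorded in that
#' order in the `gate_counts` attribute.
#'
#' @param events Event table with columns `viability_intensity`,
#'   `dump_intensity`, `cd8_intensity` plus multimer channels.
#' @param cfg A [gating_config()].
#' @return The gated subset of `events`, with attribute `gate_counts`
#'   (named: `n_input`, `n_live`, `n_dump_neg`, `n_cd8`).
#' @export
gate_cd8 <- function(events, cfg = gating_config()) {
  events <- as_tibble(events)
  for (col in c("viability_intensity", "dump_intensity", "cd8_intensity")) {
    if (!col %in% names(events)) {
      abort(paste0("event table has no column '", col, "'"))
    }
  }
  live <- !channel_positive(events, "viability_intensity", cfg)
  dump_neg <- !channel_positive(events, "dump_intensity", cfg)
  cd8 <- channel_positive(events, "cd8_intensity", cfg)
  keep <- live & dump_neg & cd8
  out <- events[keep, , drop = FALSE]
  attr(out, "gate_counts") <- c(
    n_input = nrow(events),
    n_live = sum(live),
    n_dump_neg = sum(live & dump_neg),
    n_cd8 = sum(keep)
  )
  out
}

#' Decode dual-positive multimer events into per-specificity frequencies
#'
#' Each gated event's set of positive multimer channels is computed. Events
#' positive in exactly two channels are assigned to the specificity whose
#' dual-color code equals that pair; dual-positive pairs matching no panel
#' code, and events positive in three or more channels, are counted as
#' unassigned-multi, single-positive events as unassigned-single — the
#' correction-by-exclusion that removes fluorochrome-level artifacts from
#' combinatorially encoded stainings. Frequencies are percentages of the
#' CD8-gated events.
#'
#' @param gated Gated event table from [gate_cd8()] (or any table whose rows
#'   are the denominator population).
#' @param panel Panel assignment (`peptide_id`, `channel_1`, `channel_2`),
#'   e.g. from [assign_codes()] or [miha_kit_panel()].
#' @param cfg A [gating_config()].
#' @return An object of class `decoded_result`; see [tidy.decoded_result()]
#'   and [glance.decoded_result()].
#' @export
decode_events <- function(gated, panel, cfg = gating_config()) {
  gated <- as_tibble(gated)
  panel <- as_tibble(panel)
  channels <- panel_channels(panel)
  missing <- setdiff(channels, names(gated))
  if (length(missing) > 0) {
    abort(paste0("event table lacks panel channel(s): ",
                 paste(missing, collapse = ", ")))
  }
  n_gated <- nrow(gated)
  pos <- vapply(channels,
                function(ch) channel_positive(gated, ch, cfg),
                logical(max(n_gated, 0)))
  if (n_gated == 0) pos <- matrix(FALSE, 0, length(channels),
                                  dimnames = list(NULL, channels))
  if (n_gated == 1) pos <- matrix(pos, 1, dimnames = list(NULL, channels))
  n_pos <- rowSums(pos)

  keys <- rep(NA_character_, n_gated)
  dual <- which(n_pos == 2)
  if (length(dual) > 0) {
    keys[dual] <- apply(pos[dual, , drop = FALSE], 1, function(r) {
      code_key(channels[r][1], channels[r][2])
    })
  }
  panel_keys <- code_key(panel$channel_1, panel$channel_2)
  assigned_idx <- match(keys, panel_keys)

  counts <- tabulate(assigned_idx, nbins = nrow(panel))
  n_unmatched_dual <- sum(!is.na(keys) & is.na(assigned_idx) &
                            seq_len(n_gated) %in% dual)
  gate_counts <- attr(gated, "gate_counts")
  summary <- mutate(
    select(panel, "peptide_id", "channel_1", "channel_2"),
    n_events = counts,
    frequency = if (n_gated > 0) 100 * counts / n_gated else 0
  )
  structure(
    list(
      summary = summary,
      assignment = assigned_idx,
      n_total_events = unname(gate_counts["n_input"]) %||% n_gated,
      n_cd8_gated = n_gated,
      n_assigned = sum(counts),
      n_unassigned_single = sum(n_pos == 1),
      n_unassigned_multi = sum(n_pos >= 3) + n_unmatched_dual,
      n_negative = sum(n_pos == 0),
      cfg = cfg
    ),
    class = "decoded_result"
  )
}

#' Conventional dual-color staining frequency
#'
#' Percentage of gated events positive in both named channels, ignoring all
#' other multimer channels — the single-specificity dual-color readout. For
#' the same events this is always at least the combinatorially decoded
#' frequency of that code, because decoding additionally excludes events
#' positive elsewhere.
#'
#' @param gated Gated event table.
#' @param code Character vector of exactly two channel names.
#' @param cfg A [gating_config()].
#' @return A percentage (numeric scalar).
#' @export
dual_color_frequency <- function(gated, code, cfg = gating_config()) {
  stopifnot(length(code) == 2, code[1] != code[2])
  gated <- as_tibble(gated)
  if (nrow(gated) == 0) return(0)
  both <- channel_positive(gated, code[1], cfg) &
    channel_positive(gated, code[2], cfg)
  100 * sum(both) / nrow(gated)
}

#' Format frequencies the way screening tables report them
#'
#' Two decimal places, with values below 0.01% reported as `"<0.01%"`.
#'
#' @param frequency Numeric vector of percentages.
#' @return Character vector.
#' @export
format_frequency <- function(frequency) {
  ifelse(frequency < 0.01, "<0.01%", sprintf("%.2f%%", frequency))
}

#' @export
print.decoded_result <- function(x, ...) {
  cat("<decoded_result> ", x$n_cd8_gated, " CD8-gated events (of ",
      x$n_total_events, " acquired): ", x$n_assigned, " assigned, ",
      x$n_unassigned_single, " single-positive and ", x$n_unassigned_multi,
      " multi/unmatched excluded, ", x$n_negative, " negative\n", sep = "")
  df <- mutate(x$summary, frequency = format_frequency(.data$frequency))
  print(df, ...)
  invisible(x)
}

#' Tidiers for decoded multimer screens
#'
#' `tidy()` returns the per-specificity table (code, event count, frequency
#' as % of CD8-gated events, plus a formatted `label`); `glance()` returns
#' the one-row event accounting, whose categories always sum to the gated
#' count.
#'
#' @param x A `decoded_result` from [decode_events()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.decoded_result <- function(x, ...) {
  mutate(x$summary, label = format_frequency(.data$frequency))
}

#' @rdname tidy.decoded_result
#' @export
glance.decoded_result <- function(x, ...) {
  tibble(
    n_total_events = x$n_total_events,
    n_cd8_gated = x$n_cd8_gated,
    n_assigned = x$n_assigned,
    n_unassigned_single = x$n_unassigned_single,
    n_unassigned_multi = x$n_unassigned_multi,
    n_negative = x$n_negative
  )
}
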