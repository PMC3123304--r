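#' Coding capacity of a dual-fluorochrome multimer panel
#'
#' With `k` distinguishable fluorochromes and each specificity encoded by an
#' unordered pair of two different ones, `choose(k, 2) = k (k - 1) / 2`
#' T cell populations can be resolved in a single staining: 15 with six
#' fluorochromes, 10 with five.
#'
#' @param k Integer number of fluorochromes, at least 2.
#' @return Integer number of distinct dual-color codes.
#' @examples
#' multimer_capacity(6) # 15
#' @export
multimer_capacity <- function(k) {
  if (any(k < 2)) abort("at least 2 fluorochromes are needed for dual-color codes")
  as.integer(k * (k - 1) / 2)
}

#' Assign unique dual-fluorochrome codes to peptides
#'
#' Codes are assigned deterministically: unordered channel pairs are
#' enumerated in lexicographic order of their indices in `channels`
#' ((1,2), (1,3), ..., (1,k), (2,3), ...) and handed to peptides in input
#' order, so a given peptide list and channel order always yield the same
#' panel.
#'
#' @param peptide_ids Character vector of specificity identifiers; at most
#'   [multimer_capacity()]`(length(channels))` of them.
#' @param channels Ordered character vector of fluorochrome names.
#' @return A tibble (`peptide_id`, `channel_1`, `channel_2`) with the
#'   channel vector attached as attribute `channels`.
#' @examples
#' assign_codes(c("HA-1", "HA-2"), c("PE", "APC", "Qdot605"))
#' @export
assign_codes <- function(peptide_ids, channels) {
  channels <- as.character(channels)
  if (anyDuplicated(channels)) abort("channel names must be unique")
  cap <- multimer_capacity(length(channels))
  n <- length(peptide_ids)
  if (n > cap) {
    abort(paste0("cannot encode ", n, " peptides with ", length(channels),
                 " fluorochromes: capacity is ", cap))
  }
  if (anyDuplicated(peptide_ids)) abort("peptide ids must be unique")
  codes <- combn(seq_along(channels), 2) # columns already lexicographic
  panel <- tibble(
    peptide_id = as.character(peptide_ids),
    channel_1 = channels[codes[1, seq_len(n)]],
    channel_2 = channels[codes[2, seq_len(n)]]
  )
  attr(panel, "channels") <- channels
  panel
}

panel_channels <- function(panel) {
  attr(panel, "channels") %||%
    unique(c(panel$channel_1, panel$channel_2))
}

code_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Validate a combinatorial panel assignment
#'
#' Checks that every code uses two distinct known channels and that no two
#' specificities share a code. Violations are returned, not raised, so a
#' panel file can be fully audited in one pass.
#'
#' @param panel Tibble with columns `peptide_id`, `channel_1`, `channel_2`
#'   (e.g. from [assign_codes()] or [read_panel_table()]).
#' @param channels Known fluorochrome names; defaults to the panel's
#'   `channels` attribute or the channels it mentions.
#' @return Tibble of violations (`type`, `peptide_id`, `detail`); zero rows
#'   for a clean panel.
#' @export
validate_panel <- function(panel, channels = NULL) {
  panel <- as_tibble(panel)
  channels <- channels %||% panel_channels(panel)
  violations <- list()
  unknown <- !(panel$channel_1 %in% channels) |
    !(panel$channel_2 %in% channels)
  if (any(unknown)) {
    violations <- c(violations, list(tibble(
      type = "unknown_channel",
      peptide_id = panel$peptide_id[unknown],
      detail = paste(panel$channel_1[unknown], panel$channel_2[unknown])
    )))
  }
  self_pair <- panel$channel_1 == panel$channel_2
  if (any(self_pair)) {
    violations <- c(violations, list(tibble(
      type = "self_pair",
      peptide_id = panel$peptide_id[self_pair],
      detail = panel$channel_1[self_pair]
    )))
  }
  keys <- code_key(panel$channel_1, panel$channel_2)
  dup <- duplicated(keys) | duplicated(keys, fromLast = TRUE)
  dup <- dup & !self_pair
  if (any(dup)) {
    violations <- c(violations, list(tibble(
      type = "duplicate_code",
      peptide_id = panel$peptide_id[dup],
      detail = keys[dup]
    )))
  }
  if (length(violations) == 0) {
    return(tibble(type = character(), peptide_id = character(),
                  detail = character()))
  }
  bind_rows(violations)
}

#' Pack multimers into screening pools with control placement
#'
#' Candidates and controls are distributed over pools of at most
#' `pool_capacity` multimers: controls go one per pool starting from the
#' first pool, candidates then fill each pool to capacity in input order,
#' and the final pool holds the remainder. Pools are labelled A, B, C, ...
#' A 75-candidate screen with 4 known-MiHA controls at capacity 15 gives
#' five pools of 15 plus one pool of 4, with the controls in pools A-D —
#' 79 multimers in total.
#'
#' @param candidate_ids,control_ids Character vectors of multimer
#'   identifiers (controls may be empty).
#' @param pool_capacity Maximum multimers per pool.
#' @return A tibble (`pool`, `peptide_id`, `role`), `role` being
#'   `"control"` or `"candidate"`.
#' @export
pack_pools <- function(candidate_ids, control_ids = character(),
                       pool_capacity = 15) {
  stopifnot(pool_capacity >= 1)
  candidate_ids <- as.character(candidate_ids)
  control_ids <- as.character(control_ids)
  n_total <- length(candidate_ids) + length(control_ids)
  if (n_total == 0) {
    return(tibble(pool = character(), peptide_id = character(),
                  role = character()))
  }
  n_pools <- ceiling(n_total / pool_capacity)
  if (length(control_ids) > n_pools) {
    abort(paste0(length(control_ids), " controls but only ", n_pools,
                 " pools result from ", n_total, " multimers at capacity ",
                 pool_capacity))
  }
  pool_names <- make_pool_names(n_pools)
  remaining <- candidate_ids
  out <- vector("list", n_pools)
  for (i in seq_len(n_pools)) {
    ids <- character()
    roles <- character()
    if (i <= length(control_ids)) {
      ids <- control_ids[i]
      roles <- "control"
    }
    take <- min(pool_capacity - length(ids), length(remaining))
    if (take > 0) {
      ids <- c(ids, remaining[seq_len(take)])
      roles <- c(roles, rep("candidate", take))
      remaining <- remaining[-seq_len(take)]
    }
    out[[i]] <- tibble(pool = pool_names[i], peptide_id = ids, role = roles)
  }
  bind_rows(out)
}

make_pool_names <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)] else as.character(seq_len(n))
}

#' The 10-MiHA dual-color multimer kit panel
#'
#' The reference monitoring kit: ten prevalent MiHA (SMCY, HY, HA-1, LRH-1,
#' ADIR, ACC-1, HA-8, SP110, PANE-1, HA-2), each encoded by one of the ten
#' unordered pairs of five fluorochromes (PE, APC, Qdot605, Qdot655,
#' Qdot705), so the complete code space is used exactly once.
#'
#' @return A tibble (`peptide_id`, `hla`, `peptide`, `channel_1`,
#'   `channel_2`) with the channel set attached as attribute `channels`.
#' @export
miha_kit_panel <- function() {
  path <- system.file("extdata", "miha_kit_panel.tsv", package = "mihakit",
                      mustWork = TRUE)
  panel <- read_tsv_quiet(path)
  attr(panel, "channels") <- c("PE", "APC", "Qdot605", "Qdot655", "Qdot705")
  panel
}
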