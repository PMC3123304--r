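read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(what, " is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Read protein sequences from a FASTA file
#'
#' Sequence ids are the first whitespace-delimited token of each header.
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase amino-acid sequences.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- stringr::word(names(set), 1)
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a nonsynonymous-SNP variant table
#'
#' Tab-separated with header columns `protein_id`, `position`, `ref_aa`,
#' `alt_aa`, `alt_allele_freq` (MiHA-positive allele frequency) and
#' `snp_id`.
#'
#' @param path File path.
#' @return A tibble as consumed by [enumerate_windows()].
#' @export
read_variant_table <- function(path) {
  df <- read_tsv_quiet(path)
  require_columns(df, c("protein_id", "position", "ref_aa", "alt_aa",
                        "alt_allele_freq", "snp_id"), "variant table")
  mutate(df, position = as.integer(.data$position))
}

#' Read an ELISA OD table
#'
#' Tab-separated with columns `peptide` and either `od` or replicate
#' columns `od_rep1`, `od_rep2`, ... which are averaged into `od`.
#'
#' @param path File path.
#' @return A tibble (`peptide`, `od`, plus any replicate columns).
#' @export
read_od_table <- function(path) {
  df <- read_tsv_quiet(path)
  require_columns(df, "peptide", "OD table")
  reps <- grep("^od_rep", names(df), value = TRUE)
  if (!"od" %in% names(df)) {
    if (length(reps) == 0) {
      abort("OD table needs an 'od' column or 'od_rep*' replicate columns")
    }
    df$od <- rowMeans(df[reps])
  }
  df
}

#' Read a flow-cytometry event table
#'
#' Delimited stand-in for an FCS export: one row per event, one column per
#' channel intensity. Any reader producing the same column contract (the
#' panel's multimer channels plus `cd8_intensity`, `dump_intensity`,
#' `viability_intensity`) can substitute.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_event_table <- function(path) {
  read_tsv_quiet(path)
}

#' Read a donor/recipient genotype table
#'
#' Either numeric columns `recipient_alt_count` / `donor_alt_count` (0, 1
#' or 2 copies of the MiHA-positive allele) or genotype strings in columns
#' `recipient` / `donor` (e.g. `"AB"`), in which case `positive_allele`
#' names the letter counted as MiHA-positive.
#'
#' @param path File path.
#' @param positive_allele Single character; required for genotype-string
#'   input.
#' @return A tibble with `snp_id`, `recipient_alt_count`,
#'   `donor_alt_count`.
#' @export
read_genotype_table <- function(path, positive_allele = NULL) {
  df <- read_tsv_quiet(path)
  require_columns(df, "snp_id", "genotype table")
  if (!all(c("recipient_alt_count", "donor_alt_count") %in% names(df))) {
    require_columns(df, c("recipient", "donor"), "genotype table")
    if (is.null(positive_allele)) {
      abort("genotype strings supplied: 'positive_allele' must name the MiHA-positive letter")
    }
    df$recipient_alt_count <- genotype_to_count(df$recipient,
                                                positive_allele)
    df$donor_alt_count <- genotype_to_count(df$donor, positive_allele)
  }
  df
}

genotype_to_count <- function(genotype, positive_allele) {
  stopifnot(nchar(positive_allele) == 1)
  genotype <- gsub("[/|]", "", genotype)
  if (any(nchar(genotype) != 2)) {
    abort("genotype strings must contain exactly two alleles (e.g. 'AB' or 'A/B')")
  }
  stringr::str_count(genotype, stringr::fixed(positive_allele))
}

#' Read / write panel assignment tables
#'
#' Tab-separated with columns `peptide_id`, `channel_1`, `channel_2` and
#' optionally `pool`.
#'
#' @param path File path.
#' @param channels Optional fluorochrome set (ordered) to attach; defaults
#'   to the channels appearing in the file.
#' @return A tibble with the `channels` attribute set.
#' @export
read_panel_table <- function(path, channels = NULL) {
  df <- read_tsv_quiet(path)
  require_columns(df, c("peptide_id", "channel_1", "channel_2"),
                  "panel table")
  attr(df, "channels") <- channels %||%
    unique(c(df$channel_1, df$channel_2))
  df
}

#' @rdname read_panel_table
#' @param panel Panel tibble to write.
#' @export
write_panel_table <- function(panel, path) {
  readr::write_tsv(panel, path, progress = FALSE)
  invisible(path)
}
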