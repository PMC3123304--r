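#' Enumerate allelic peptide windows around nonsynonymous SNPs
#'
#' For each variant, emits every peptide window of the requested lengths that
#' lies fully within the protein and covers the polymorphic residue, paired as
#' reference and alternate allelic peptides. These are the candidate MiHA
#' epitope pairs fed to HLA binding prediction.
#'
#' An interior variant with at least `L - 1` residues of flanking sequence on
#' both sides yields exactly `L` windows of length `L` (the polymorphism can
#' sit at any of the `L` offsets). Windows containing a non-standard residue
#' (anything outside the 20-letter alphabet, e.g. `X` or `U`) are skipped with
#' a warning because binding coefficient tables are only defined over the
#' standard alphabet.
#'
#' @param variants Data frame with columns `protein_id`, `position` (1-based
#'   residue index), `ref_aa`, `alt_aa`, `alt_allele_freq` (frequency of the
#'   MiHA-positive allele, in `[0, 1]`) and `snp_id`.
#' @param sequences Named character vector of protein sequences (names are
#'   protein ids), e.g. from [read_protein_fasta()].
#' @param lengths Integer vector of window lengths; the classic HLA class I
#'   scan uses `c(9, 10)`.
#' @param miha_positive Which allele carries the MiHA-positive (recipient-
#'   presented) peptide. By convention the alternate allele; `"ref"` swaps the
#'   roles when the reference allele is the immunogenic one.
#'
#' @return A tibble with one row per allelic peptide pair: `protein_id`,
#'   `snp_id`, `start` (1-based window start), `length`, `variant_offset`
#'   (1-based position of the polymorphism within the peptide), `ref_peptide`,
#'   `alt_peptide`, `alt_allele_freq`, `miha_allele`. Rows are ordered by
#'   variant (input order), then `(length, start)` ascending.
#' @examples
#' seqs <- c(P1 = "MRMFPNAPYLWT")
#' vars <- tibble::tibble(
#'   protein_id = "P1", position = 7L, ref_aa = "A", alt_aa = "T",
#'   alt_allele_freq = 0.3, snp_id = "rs9332973"
#' )
#' enumerate_windows(vars, seqs, lengths = 9)
#' @export
enumerate_windows <- function(variants, sequences, lengths = c(9L, 10L),
                              miha_positive = c("alt", "ref")) {
  miha_positive <- arg_match(miha_positive)
  stopifnot(length(lengths) >= 1, all(lengths >= 1))
  lengths <- sort(unique(as.integer(lengths)))
  variants <- as_tibble(variants)
  required <- c("protein_id", "position", "ref_aa", "alt_aa",
                "alt_allele_freq", "snp_id")
  missing <- setdiff(required, names(variants))
  if (length(missing) > 0) {
    abort(paste0("variant table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }

  n_skipped <- 0L
  out <- pmap(variants[required], function(protein_id, position, ref_aa,
                                           alt_aa, alt_allele_freq, snp_id) {
    seq <- sequences[[protein_id]]
    if (is.null(seq) || is.na(seq)) {
      abort(paste0("no sequence for protein '", protein_id, "'"))
    }
    validate_variant(seq, protein_id, position, ref_aa, alt_aa,
                     alt_allele_freq)
    prot_len <- nchar(seq)
    per_len <- map(lengths, function(L) {
      starts <- seq_len(prot_len)
      starts <- starts[starts <= position & starts + L - 1L >= position &
                         starts + L - 1L <= prot_len]
      if (length(starts) == 0) return(NULL)
      ref_pep <- substring(seq, starts, starts + L - 1L)
      keep <- is_standard_peptide(ref_pep)
      n_skipped <<- n_skipped + sum(!keep)
      starts <- starts[keep]
      ref_pep <- ref_pep[keep]
      if (length(starts) == 0) return(NULL)
      offset <- position - starts + 1L
      alt_pep <- ref_pep
      substr(alt_pep, offset, offset) <- alt_aa
      tibble(
        protein_id = protein_id, snp_id = snp_id,
        start = starts, length = L, variant_offset = offset,
        ref_peptide = ref_pep, alt_peptide = alt_pep,
        alt_allele_freq = alt_allele_freq
      )
    })
    bind_rows(per_len)
  })
  if (n_skipped > 0) {
    warn(paste0(n_skipped, " window(s) skipped: non-standard residue(s) ",
                "outside the 20-letter alphabet"))
  }
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    out <- tibble(
      protein_id = character(), snp_id = character(), start = integer(),
      length = integer(), variant_offset = integer(),
      ref_peptide = character(), alt_peptide = character(),
      alt_allele_freq = double()
    )
  }
  out$miha_allele <- rep(miha_positive, nrow(out))
  out
}

validate_variant <- function(seq, protein_id, position, ref_aa, alt_aa,
                             freq) {
  if (position < 1 || position > nchar(seq)) {
    abort(paste0("variant position ", position, " outside protein '",
                 protein_id, "' (length ", nchar(seq), ")"))
  }
  found <- substr(seq, position, position)
  if (found != ref_aa) {
    abort(paste0("reference mismatch in protein '", protein_id,
                 "' at position ", position, ": sequence has '", found,
                 "', variant claims '", ref_aa, "'"))
  }
  if (ref_aa == alt_aa) {
    abort(paste0("synonymous record for protein '", protein_id,
                 "' at position ", position, ": ref and alt are both '",
                 ref_aa, "'"))
  }
  if (is.na(freq) || freq < 0 || freq > 1) {
    abort(paste0("alt_allele_freq for '", protein_id,
                 "' must lie in [0, 1]"))
  }
  invisible(TRUE)
}

#' The MiHA-positive peptide of each allelic pair
#'
#' Convenience accessor: returns `alt_peptide` where `miha_allele == "alt"`
#' and `ref_peptide` where the reference allele was declared MiHA-positive.
#'
#' @param pairs A tibble from [enumerate_windows()].
#' @return Character vector of peptides, one per row of `pairs`.
#' @export
miha_peptide <- function(pairs) {
  allele <- pairs$miha_allele %||% rep("alt", nrow(pairs))
  ifelse(allele == "ref", pairs$ref_peptide, pairs$alt_peptide)
}
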