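#' Theoretical clinical applicability of a MiHA under Hardy-Weinberg
#'
#' The clinical applicability of a MiHA with positive-allele frequency `p` is
#' the probability that, in a random HLA-matched unrelated recipient-donor
#' pair, the recipient carries at least one MiHA-positive allele while the
#' donor carries none — the graft-versus-tumor-direction disparity that makes
#' donor T cells able to target recipient hematopoiesis. Under Hardy-Weinberg
#' genotype proportions and donor-recipient independence,
#' \deqn{A(p) = (1 - q^2)\, q^2, \qquad q = 1 - p,}
#' which is at most 0.25 (attained at \eqn{q^2 = 1/2}, i.e.
#' \eqn{p = 1 - \sqrt{1/2} \approx 0.293}).
#'
#' @param p Numeric vector of MiHA-positive allele frequencies in `[0, 1]`.
#' @return Numeric vector of disparity probabilities in `[0, 0.25]`.
#' @examples
#' clinical_applicability(c(0.15, 0.46)) # both exceed 0.20
#' @export
clinical_applicability <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    abort("allele frequencies must lie in [0, 1]")
  }
  q2 <- (1 - p)^2
  (1 - q2) * q2
}

#' Allele-frequency band achieving a minimum clinical applicability
#'
#' Solves `clinical_applicability(p) >= threshold` in closed form. Writing
#' `y = (1 - p)^2`, the boundary condition is the quadratic
#' `y^2 - y + threshold = 0`, whose two roots give the band endpoints. A
#' threshold of 0.20 yields approximately (0.1494, 0.4743), the exact version
#' of the operational 15--46% frequency window used to shortlist candidate
#' MiHA.
#'
#' @param threshold Minimum applicability, in `(0, 0.25)`; 0.25 is the
#'   maximum attainable so no band exists at or above it.
#' @return Named numeric vector `c(lower, upper)` of allele frequencies;
#'   applicability equals `threshold` exactly at both endpoints.
#' @examples
#' frequency_band(0.20)
#' @export
frequency_band <- function(threshold = 0.20) {
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 0.25) {
    abort("threshold must lie strictly between 0 and 0.25 (the maximum applicability)")
  }
  disc <- sqrt(1 - 4 * threshold)
  y <- c((1 + disc) / 2, (1 - disc) / 2) # y = (1 - p)^2, larger y = smaller p
  c(lower = 1 - sqrt(y[1]), upper = 1 - sqrt(y[2]))
}

#' Filter candidate pairs by MiHA-positive allele frequency
#'
#' Retains candidates whose MiHA-positive allele frequency falls inside a
#' band (inclusive at both ends). The default band is the operational
#' rounded window `[0.15, 0.46]`; the exact solution band for a given
#' applicability threshold is available via [frequency_band()].
#'
#' @param pairs Tibble with an `alt_allele_freq` column (the MiHA-positive
#'   allele frequency), e.g. from [enumerate_windows()] or
#'   [filter_binders()].
#' @param band Length-2 numeric `(low, high)` with `0 <= low <= high <= 1`.
#' @return The retained rows of `pairs`.
#' @export
filter_by_frequency <- function(pairs, band = c(0.15, 0.46)) {
  stopifnot(length(band) == 2, band[1] <= band[2],
            band[1] >= 0, band[2] <= 1)
  pairs <- as_tibble(pairs)
  pairs[pairs$alt_allele_freq >= band[1] &
          pairs$alt_allele_freq <= band[2], , drop = FALSE]
}

#' GVT-direction genotype disparity between recipient and donor
#'
#' A recipient-donor pair is disparate in the graft-versus-tumor direction
#' when the recipient carries at least one MiHA-positive allele (and so
#' presents the antigen) while the donor carries none (so donor T cells are
#' not tolerized to it).
#'
#' @param recipient_alt_count,donor_alt_count Integer vectors of
#'   MiHA-positive allele counts (0, 1 or 2 per genotype).
#' @return Logical vector.
#' @examples
#' is_disparate(1, 0) # TRUE
#' is_disparate(0, 2) # FALSE: reverse-direction mismatch
#' @export
is_disparate <- function(recipient_alt_count, donor_alt_count) {
  check_counts <- function(x, who) {
    if (any(!x %in% 0:2)) {
      abort(paste0(who, " allele counts must be 0, 1 or 2"))
    }
  }
  check_counts(recipient_alt_count, "recipient")
  check_counts(donor_alt_count, "donor")
  recipient_alt_count >= 1 & donor_alt_count == 0
}

#' Check detected T cell responses against donor/recipient genotypes
#'
#' Annotates a genotype table with the GVT-direction disparity flag and,
#' when a response table is supplied, joins it to report which detected
#' responses are concordant with the genotypes (a response should only be
#' possible at a disparate SNP).
#'
#' @param genotypes Tibble with columns `snp_id`, `recipient_alt_count`,
#'   `donor_alt_count` (see [read_genotype_table()]).
#' @param responses Optional tibble with columns `snp_id` and `detected`
#'   (logical).
#' @return `genotypes` with a `disparate` column; if `responses` is given,
#'   also `detected` and `concordant` (`detected == disparate`).
#' @export
check_concordance <- function(genotypes, responses = NULL) {
  genotypes <- as_tibble(genotypes)
  genotypes$disparate <- is_disparate(genotypes$recipient_alt_count,
                                      genotypes$donor_alt_count)
  if (!is.null(responses)) {
    genotypes <- left_join(genotypes,
                           select(as_tibble(responses), "snp_id", "detected"),
                           by = "snp_id")
    genotypes$concordant <- genotypes$detected == genotypes$disparate
  }
  genotypes
}
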