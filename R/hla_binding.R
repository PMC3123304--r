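#' Position-coefficient table for peptide-MHC half-time prediction
#'
#' A coefficient table predicts the dissociation half-time (T-half, seconds)
#' of a peptide from an MHC allele as an allele-specific constant multiplied
#' by one coefficient per peptide position, indexed by the residue at that
#' position (the Parker/BIMAS scheme). The table covers a single peptide
#' length.
#'
#' @param coefficients Numeric matrix with one row per peptide position
#'   (1..length) and one column per amino acid; column names must cover the
#'   full 20-letter alphabet. All entries must be non-negative.
#' @param constant Positive allele-specific multiplier, in seconds.
#' @param allele Allele label, e.g. `"HLA-A2"`.
#'
#' @return An object of class `coefficient_table`.
#' @seealso [score_t_half()], [read_coefficient_table()],
#'   [simulate_coefficient_table()]
#' @export
coefficient_table <- function(coefficients, constant, allele = "HLA-A2") {
  coefficients <- as.matrix(coefficients)
  missing <- setdiff(AA_ALPHABET, colnames(coefficients))
  if (length(missing) > 0) {
    abort(paste0("coefficients must cover all 20 amino acids; missing: ",
                 paste(missing, collapse = ", ")))
  }
  coefficients <- coefficients[, AA_ALPHABET, drop = FALSE]
  if (any(!is.finite(coefficients)) || any(coefficients < 0)) {
    abort("all coefficients must be finite and >= 0")
  }
  if (!is.finite(constant) || constant <= 0) {
    abort("constant must be a positive number (seconds)")
  }
  structure(
    list(
      allele = allele,
      length = nrow(coefficients),
      coefficients = coefficients,
      constant = as.numeric(constant)
    ),
    class = "coefficient_table"
  )
}

#' @export
print.coefficient_table <- function(x, ...) {
  cat("<coefficient_table> ", x$allele, ", ", x$length,
      "-mer, constant = ", format(x$constant), " s\n", sep = "")
  invisible(x)
}

#' Predict peptide-MHC dissociation half-times
#'
#' Scores peptides against a position-coefficient table: the predicted
#' half-time of dissociation is the allele constant times the product over
#' positions of the coefficient for the residue observed at each position.
#'
#' @param peptides Character vector of peptides, each exactly
#'   `table$length` residues over the standard alphabet.
#' @param table A [coefficient_table()].
#'
#' @return A tibble with columns `peptide` and `t_half_seconds`.
#' @examples
#' tab <- simulate_coefficient_table(length = 9, seed = 1)
#' score_t_half("RMFPNAPYL", tab)
#' @export
score_t_half <- function(peptides, table) {
  stopifnot(inherits(table, "coefficient_table"))
  L <- table$length
  bad_len <- nchar(peptides) != L
  if (any(bad_len)) {
    abort(paste0("peptide '", peptides[bad_len][1], "' has length ",
                 nchar(peptides[bad_len][1]), " but the ", table$allele,
                 " table covers ", L, "-mers"))
  }
  bad_res <- !is_standard_peptide(peptides)
  if (any(bad_res)) {
    abort(paste0("peptide '", peptides[bad_res][1],
                 "' contains residues outside the 20-letter alphabet"))
  }
  residues <- matrix(match(strsplit(paste(peptides, collapse = ""),
                                    "")[[1]], AA_ALPHABET),
                     nrow = L)
  idx <- cbind(rep(seq_len(L), length(peptides)), as.vector(residues))
  coefs <- matrix(table$coefficients[idx], nrow = L)
  tibble(
    peptide = peptides,
    t_half_seconds = table$constant * apply(coefs, 2, prod)
  )
}

#' Filter allelic peptide pairs by predicted HLA binding half-time
#'
#' Scores both allelic peptides of each pair and retains pairs passing a
#' minimum predicted half-time of dissociation. The study-style default keeps
#' a candidate when its MiHA-positive peptide reaches 30 seconds, read
#' inclusively.
#'
#' @param pairs Tibble of allelic peptide pairs from [enumerate_windows()]
#'   (columns `ref_peptide`, `alt_peptide`, `length`, optionally
#'   `miha_allele`).
#' @param tables A [coefficient_table()] or list of them, one per peptide
#'   length present in `pairs`.
#' @param min_t_half Minimum predicted half-time in seconds (inclusive).
#' @param policy Which allelic peptide must pass: `"alt_only"` (default; the
#'   MiHA-positive peptide), `"either"`, or `"both"`.
#'
#' @return The retained rows of `pairs` with `ref_t_half`, `alt_t_half` and
#'   `miha_t_half` columns attached (all rows scored; filtering applied per
#'   `policy`).
#' @export
filter_binders <- function(pairs, tables, min_t_half = 30,
                           policy = c("alt_only", "either", "both")) {
  policy <- arg_match(policy)
  stopifnot(min_t_half >= 0)
  pairs <- as_tibble(pairs)
  if (inherits(tables, "coefficient_table")) tables <- list(tables)
  stopifnot(all(map_lgl(tables, inherits, "coefficient_table")))
  by_len <- setNames(tables, map_dbl(tables, "length"))

  missing <- setdiff(unique(pairs$length), as.numeric(names(by_len)))
  if (length(missing) > 0) {
    abort(paste0("no coefficient table for peptide length(s): ",
                 paste(sort(missing), collapse = ", ")))
  }
  if (nrow(pairs) == 0) {
    return(mutate(pairs, ref_t_half = double(), alt_t_half = double(),
                  miha_t_half = double()))
  }
  score_with <- function(peps, lens) {
    out <- numeric(length(peps))
    for (L in unique(lens)) {
      sel <- lens == L
      out[sel] <- score_t_half(peps[sel], by_len[[as.character(L)]])$t_half_seconds
    }
    out
  }
  pairs$ref_t_half <- score_with(pairs$ref_peptide, pairs$length)
  pairs$alt_t_half <- score_with(pairs$alt_peptide, pairs$length)
  allele <- pairs$miha_allele %||% rep("alt", nrow(pairs))
  pairs$miha_t_half <- ifelse(allele == "ref", pairs$ref_t_half,
                              pairs$alt_t_half)
  other <- ifelse(allele == "ref", pairs$alt_t_half, pairs$ref_t_half)
  keep <- switch(policy,
    alt_only = pairs$miha_t_half >= min_t_half,
    either = pairs$miha_t_half >= min_t_half | other >= min_t_half,
    both = pairs$miha_t_half >= min_t_half & other >= min_t_half
  )
  pairs[keep, , drop = FALSE]
}

#' Write a coefficient table to a delimited file
#'
#' The format is a `#allele=<name> length=<L> constant=<float>` header line
#' followed by a tab-separated matrix (rows = positions 1..L, columns = the
#' 20 amino acids). Values are written with 17 significant digits so a
#' write/read round trip is bit-exact.
#'
#' @param table A [coefficient_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coefficient_table <- function(table, path) {
  stopifnot(inherits(table, "coefficient_table"))
  header <- sprintf("#allele=%s length=%d constant=%s", table$allele,
                    table$length, sprintf("%.17g", table$constant))
  mat <- apply(table$coefficients, c(1, 2), function(x) sprintf("%.17g", x))
  lines <- c(
    header,
    paste(c("position", AA_ALPHABET), collapse = "\t"),
    vapply(seq_len(nrow(mat)), function(i) {
      paste(c(i, mat[i, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a coefficient table written by [write_coefficient_table()]
#'
#' @param path File path.
#' @return A [coefficient_table()].
#' @export
read_coefficient_table <- function(path) {
  lines <- readLines(path)
  header <- lines[1]
  if (!startsWith(header, "#")) {
    abort("coefficient file must start with a '#allele=... length=... constant=...' header")
  }
  fields <- strsplit(sub("^#", "", header), "[[:space:]]+")[[1]]
  kv <- strsplit(fields, "=")
  keys <- map_chr(kv, 1)
  vals <- map_chr(kv, 2)
  allele <- vals[keys == "allele"]
  len <- as.integer(vals[keys == "length"])
  constant <- as.numeric(vals[keys == "constant"])
  # base strtod parsing is correctly rounded, keeping the round trip
  # bit-exact
  body <- utils::read.delim(text = lines[-1], check.names = FALSE)
  mat <- as.matrix(body[, AA_ALPHABET])
  rownames(mat) <- NULL
  if (nrow(mat) != len) {
    abort(paste0("header declares length ", len, " but matrix has ",
                 nrow(mat), " rows"))
  }
  coefficient_table(mat, constant = constant, allele = allele)
}
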