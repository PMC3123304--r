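#' Classify peptide-exchange ELISA readings into HLA affinity classes
#'
#' Optical densities (absorbance at 414 nm) from the UV-exchange sandwich
#' ELISA are classified as `low` (`od < low_cut`), `intermediate`
#' (`low_cut <= od < high_cut`) or `high` (`od >= high_cut`). An OD exactly
#' at the low cutoff counts as intermediate; classification is monotone in
#' OD.
#'
#' @param od Numeric vector of non-negative optical densities (means of
#'   replicate wells).
#' @param low_cut,high_cut Class boundaries; defaults 0.4 and 1.25.
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @examples
#' classify_od(c(0.39, 0.4, 1.24, 1.25))
#' @export
classify_od <- function(od, low_cut = 0.4, high_cut = 1.25) {
  if (any(!is.finite(od) | od < 0)) {
    abort("OD values must be finite and non-negative")
  }
  stopifnot(low_cut > 0, high_cut > low_cut)
  cls <- ifelse(od >= high_cut, "high",
                ifelse(od >= low_cut, "intermediate", "low"))
  factor(cls, levels = c("low", "intermediate", "high"))
}

#' Triage candidate peptides by ELISA-measured HLA affinity
#'
#' Applies [classify_od()] to an OD table and splits it into retained
#' (intermediate or high affinity — taken forward to multimerization) and
#' discarded (low affinity) peptides, with per-class counts.
#'
#' @param records Tibble with columns `peptide` and `od` (see
#'   [read_od_table()]).
#' @param low_cut,high_cut Class boundaries passed to [classify_od()].
#' @return An object of class `od_triage`: list with `records` (input plus
#'   `affinity_class` and `retained` columns), `retained`, `discarded`,
#'   `counts` (named: low/intermediate/high) and the cutoffs.
#' @examples
#' od <- tibble::tibble(peptide = c("A", "B", "C"), od = c(0.1, 0.8, 1.9))
#' triage_od(od)
#' @export
triage_od <- function(records, low_cut = 0.4, high_cut = 1.25) {
  records <- as_tibble(records)
  stopifnot(all(c("peptide", "od") %in% names(records)))
  records$affinity_class <- classify_od(records$od, low_cut, high_cut)
  records$retained <- records$affinity_class != "low"
  counts <- table(records$affinity_class)
  structure(
    list(
      records = records,
      retained = records[records$retained, , drop = FALSE],
      discarded = records[!records$retained, , drop = FALSE],
      counts = setNames(as.integer(counts), names(counts)),
      low_cut = low_cut, high_cut = high_cut
    ),
    class = "od_triage"
  )
}

#' @export
print.od_triage <- function(x, ...) {
  cat("<od_triage> ", nrow(x$records), " peptides: ",
      x$counts[["low"]], " low (OD < ", x$low_cut, ", discarded), ",
      x$counts[["intermediate"]], " intermediate, ",
      x$counts[["high"]], " high (OD >= ", x$high_cut, "); ",
      nrow(x$retained), " retained\n", sep = "")
  invisible(x)
}

#' @describeIn triage_od per-peptide classification as a tibble.
#' @param x An `od_triage` object.
#' @param ... Unused.
#' @export
tidy.od_triage <- function(x, ...) x$records

#' @describeIn triage_od one-row summary: class counts, totals, cutoffs.
#' @export
glance.od_triage <- function(x, ...) {
  tibble(
    n = nrow(x$records),
    n_low = x$counts[["low"]],
    n_intermediate = x$counts[["intermediate"]],
    n_high = x$counts[["high"]],
    n_retained = nrow(x$retained),
    low_cut = x$low_cut,
    high_cut = x$high_cut
  )
}
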