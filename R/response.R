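#' Patient record: paired scans plus PSA
#'
#' Bundles a patient's baseline and follow-up compartment scores with their
#' PSA values. `psa_pct_decrease` is derived from the PSA pair when both
#' are present, or may be supplied directly (as when transcribed from a
#' published table); supplying both inconsistently is an error.
#'
#' @param patient_id identifier.
#' @param baseline,followup `compartment_scores` objects.
#' @param psa_baseline,psa_followup positive PSA values (ng/mL), or `NA`.
#' @param psa_pct_decrease percent PSA reduction (positive = decline), or
#'   `NA`; computed from the PSA pair when omitted.
#' @param interval_months positive scan interval, or `NA`.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, baseline, followup,
                           psa_baseline = NA_real_, psa_followup = NA_real_,
                           psa_pct_decrease = NA_real_,
                           interval_months = NA_integer_) {
  stopifnot(inherits(baseline, "compartment_scores"),
            inherits(followup, "compartment_scores"))
  if (!is.na(psa_baseline) && psa_baseline <= 0)
    stop("psa_baseline must be positive")
  if (!is.na(psa_followup) && psa_followup < 0)
    stop("psa_followup must be non-negative")
  if (!is.na(psa_baseline) && !is.na(psa_followup)) {
    derived <- psa_percent_decrease(psa_baseline, psa_followup)
    if (!is.na(psa_pct_decrease) &&
        abs(psa_pct_decrease - derived) > 1e-6)
      stop("psa_pct_decrease inconsistent with the PSA values")
    psa_pct_decrease <- derived
  }
  if (!is.na(interval_months) && interval_months <= 0)
    stop("interval_months must be positive")
  structure(list(patient_id = patient_id, baseline = baseline,
                 followup = followup, psa_baseline = psa_baseline,
                 psa_followup = psa_followup,
                 psa_pct_decrease = psa_pct_decrease,
                 interval_months = interval_months),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record %s> composite %.2f -> %.2f", x$patient_id,
              x$baseline$composite, x$followup$composite))
  if (!is.na(x$psa_pct_decrease))
    cat(sprintf(", PSA decrease %.0f%%", x$psa_pct_decrease))
  cat("\n")
  invisible(x)
}

#' Signed percent change
#'
#' `100 * (after - before) / before`; negative values are declines. Defined
#' only for `before > 0`: a positive score appearing where the baseline was
#' zero is new disease, for which no percent is defined (handled by
#' [build_cohort_table()]), and 0 -> 0 is no information; both return `NA`.
#'
#' @param before,after numeric vectors; `before` must be non-negative.
#' @return Signed percent change, `NA` where `before` is 0 or missing.
#' @examples
#' percent_change(48.7, 91.1)   # +87.06...
#' @export
percent_change <- function(before, after) {
  if (any(before < 0, na.rm = TRUE)) stop("'before' must be non-negative")
  ifelse(!is.na(before) & before > 0 & !is.na(after),
         100 * (after - before) / before, NA_real_)
}

#' Percent PSA decrease
#'
#' `100 * (psa0 - psa1) / psa0`, positive for a decline (the convention of
#' clinical "% reduction in PSA" columns).
#'
#' @param psa0 baseline PSA, strictly positive.
#' @param psa1 follow-up PSA, non-negative.
#' @return Percent decrease (can exceed -Inf downward for rises; at most
#'   100 for psa1 = 0).
#' @export
psa_percent_decrease <- function(psa0, psa1) {
  if (any(psa0 <= 0, na.rm = TRUE)) stop("baseline PSA must be positive")
  100 * (psa0 - psa1) / psa0
}

#' Build the per-patient response table
#'
#' Applies [percent_change()] per compartment and to the composite, and
#' carries the PSA change as a signed percent (negative = decline, so
#' concordant imaging and PSA declines correlate positively). A compartment
#' cell is missing iff the baseline compartment is missing; a positive
#' follow-up score over a missing/zero baseline raises that compartment's
#' `new_disease` flag instead of a percent. Values are kept at full
#' precision; use [format_cohort_table()] for integer-percent display.
#'
#' @param records list of [patient_record] objects.
#' @return A data frame of class `cohort_table`: `patient_id`,
#'   `nodal_pct`, `osseous_pct`, `prostate_pct`, `composite_pct`,
#'   `psa_pct`, and logical `new_disease_*` flags.
#' @export
build_cohort_table <- function(records) {
  stopifnot(length(records) >= 1L,
            all(vapply(records, inherits, logical(1), "patient_record")))
  one <- function(r) {
    cell <- function(b, f) {
      if ((is.na(b) || b == 0) && !is.na(f) && f > 0)
        list(pct = NA_real_, new = TRUE)
      else list(pct = percent_change(b, f), new = FALSE)
    }
    nod <- cell(r$baseline$nodal, r$followup$nodal)
    oss <- cell(r$baseline$osseous, r$followup$osseous)
    pro <- cell(r$baseline$prostate_bed, r$followup$prostate_bed)
    cmp <- cell(r$baseline$composite, r$followup$composite)
    data.frame(patient_id = r$patient_id,
               nodal_pct = nod$pct, osseous_pct = oss$pct,
               prostate_pct = pro$pct, composite_pct = cmp$pct,
               psa_pct = if (is.na(r$psa_pct_decrease)) NA_real_
                         else -r$psa_pct_decrease,
               new_disease_nodal = nod$new, new_disease_osseous = oss$new,
               new_disease_prostate = pro$new, new_disease_composite = cmp$new,
               interval_months = r$interval_months)
  }
  out <- do.call(rbind, lapply(records, one))
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Round a cohort table for display
#'
#' Integer percents, half away from zero (so -99.5 prints as -100), as in
#' published response tables. Full-precision values remain in the input.
#'
#' @param table a `cohort_table`.
#' @return The table with percent columns rounded to integers.
#' @export
format_cohort_table <- function(table) {
  cols <- c("nodal_pct", "osseous_pct", "prostate_pct", "composite_pct",
            "psa_pct")
  for (cl in cols) table[[cl]] <- round_half_away(table[[cl]])
  table
}

#' Cohort summary statistics
#'
#' Median and range of declines per compartment and composite, of the PSA
#' decrease, and the median scan interval. Declines are the negated signed
#' percent changes (so a -100% change is a 100% decline); medians are over
#' non-missing entries only, and an all-missing column yields a missing
#' summary entry.
#'
#' @param table a `cohort_table`.
#' @return Data frame with one row per quantity: `measure`, `n`, `median`,
#'   `min`, `max` (of the decline, or of the interval).
#' @export
summarize_cohort <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  decl <- function(x) -x
  cols <- list(prostate_decline = decl(table$prostate_pct),
               nodal_decline = decl(table$nodal_pct),
               osseous_decline = decl(table$osseous_pct),
               composite_decline = decl(table$composite_pct),
               psa_decrease = decl(table$psa_pct),
               interval_months = table$interval_months)
  do.call(rbind, lapply(names(cols), function(nm) {
    x <- cols[[nm]][!is.na(cols[[nm]])]
    if (!length(x))
      data.frame(measure = nm, n = 0L, median = NA_real_, min = NA_real_,
                 max = NA_real_)
    else
      data.frame(measure = nm, n = length(x), median = stats::median(x),
                 min = min(x), max = max(x))
  }))
}

#' Write / read a cohort response table as CSV
#'
#' Mirrors the published table layout (`patient_id, nodal_pct, osseous_pct,
#' prostate_pct, composite_pct, psa_pct`) plus the new-disease flags and
#' interval; `NA` literal for missing. `read_cohort_table_csv()` is the
#' exact inverse.
#'
#' @param table a `cohort_table`.
#' @param path CSV file path.
#' @return The path (write, invisibly) or the `cohort_table` (read).
#' @export
write_cohort_table_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_cohort_table_csv
#' @export
read_cohort_table_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "nodal_pct", "osseous_pct", "prostate_pct",
            "composite_pct", "psa_pct")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("cohort table is missing columns: ", paste(miss, collapse = ", "))
  for (cl in setdiff(need, "patient_id")) d[[cl]] <- as.numeric(d[[cl]])
  for (cl in grep("^new_disease_", names(d), value = TRUE))
    d[[cl]] <- as.logical(d[[cl]])
  class(d) <- c("cohort_table", "data.frame")
  d
}
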