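#' Pearson correlation with pairwise deletion
#'
#' Sample Pearson product-moment correlation of two vectors after dropping
#' pairs with any missing entry.
#'
#' @param x,y numeric vectors of equal length.
#' @return `r` in `[-1, 1]`, with attribute `n` (pairwise-complete count).
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("fewer than 2 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  structure(stats::cor(x, y), n = n)
}

#' Two-tailed significance of a Pearson correlation
#'
#' `t = r * sqrt((n - 2) / (1 - r^2))` referred to a Student t distribution
#' with `n - 2` degrees of freedom, two-tailed.
#'
#' @param r correlation in `[-1, 1]`.
#' @param n number of pairs, at least 3.
#' @return List with `t`, `df`, `p_two_tailed`, and `degenerate` (`TRUE`
#'   when `|r| = 1`, where `p` is reported as 0).
#' @export
r_significance <- function(r, n) {
  stopifnot(is.numeric(r), length(r) == 1L, abs(r) <= 1)
  if (n < 3) stop("n must be >= 3")
  df <- n - 2
  if (abs(r) == 1)
    return(list(t = Inf * sign(r), df = df, p_two_tailed = 0,
                degenerate = TRUE))
  t <- r * sqrt(df / (1 - r^2))
  list(t = t, df = df, p_two_tailed = 2 * stats::pt(-abs(t), df),
       degenerate = FALSE)
}

# Share of the modal value among pairwise-complete entries; a column
# dominated by one value (e.g. -100 throughout) gives a correlation whose
# magnitude is driven by a handful of points.
modal_share <- function(x) max(table(x)) / length(x)

#' Correlate imaging response with PSA response
#'
#' One Pearson correlation per response column (nodal, osseous,
#' prostate/bed, composite) against the signed PSA percent change,
#' pairwise-complete per column. A compartment is suppressed (r and p
#' missing, `suppressed = TRUE`) when the correlation is undefined (< 3
#' complete pairs or zero variance). A computable correlation is
#' additionally flagged `low_variance` when at least `low_variance_share`
#' of its imaging values are identical — the situation in which published
#' analyses decline to report a p value.
#'
#' @param table a `cohort_table`.
#' @param low_variance_share modal-share threshold for the flag
#'   (default 0.8).
#' @return Data frame with one row per compartment: `compartment`, `r`,
#'   `n`, `t`, `p_two_tailed`, `suppressed`, `low_variance`.
#' @export
correlate_table <- function(table, low_variance_share = 0.8) {
  stopifnot(inherits(table, "cohort_table"))
  cols <- c(nodal = "nodal_pct", osseous = "osseous_pct",
            prostate_bed = "prostate_pct", composite = "composite_pct")
  psa <- table$psa_pct
  do.call(rbind, lapply(names(cols), function(comp) {
    x <- table[[cols[[comp]]]]
    ok <- !is.na(x) & !is.na(psa)
    res <- tryCatch({
      r <- pearson_r(x, psa)
      n <- attr(r, "n")
      if (n < 3) stop("fewer than 3 complete pairs")
      sig <- r_significance(as.numeric(r), n)
      data.frame(compartment = comp, r = as.numeric(r), n = n, t = sig$t,
                 p_two_tailed = sig$p_two_tailed, suppressed = FALSE,
                 low_variance = modal_share(x[ok]) >= low_variance_share)
    }, error = function(e) {
      data.frame(compartment = comp, r = NA_real_, n = sum(ok), t = NA_real_,
                 p_two_tailed = NA_real_, suppressed = TRUE,
                 low_variance = NA)
    })
    res
  }))
}

#' Correlate baseline burden with baseline PSA
#'
#' The same Pearson machinery applied to baseline compartment scores vs
#' baseline PSA across a cohort of [patient_record]s. Only exercisable on
#' simulated cohorts here, since per-patient baseline scores of the study
#' cohort are not published.
#'
#' @param records list of [patient_record] objects with baseline PSA.
#' @return Data frame as in [correlate_table()], one row per compartment
#'   plus composite.
#' @export
correlate_baseline <- function(records) {
  get <- function(f) vapply(records, f, numeric(1))
  psa <- get(function(r) r$psa_baseline)
  cols <- list(prostate_bed = function(r) r$baseline$prostate_bed,
               nodal = function(r) r$baseline$nodal,
               osseous = function(r) r$baseline$osseous,
               composite = function(r) r$baseline$composite)
  do.call(rbind, lapply(names(cols), function(comp) {
    x <- get(cols[[comp]])
    tryCatch({
      r <- pearson_r(x, psa)
      n <- attr(r, "n")
      sig <- r_significance(as.numeric(r), n)
      data.frame(compartment = comp, r = as.numeric(r), n = n, t = sig$t,
                 p_two_tailed = sig$p_two_tailed, suppressed = FALSE)
    }, error = function(e) {
      data.frame(compartment = comp, r = NA_real_, n = sum(!is.na(x) & !is.na(psa)),
                 t = NA_real_, p_two_tailed = NA_real_, suppressed = TRUE)
    })
  }))
}
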