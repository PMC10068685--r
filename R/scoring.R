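#' Per-lesion PSMA score
#'
#' The central quantity: lesion volume (mL) times lesion SUVmean, normalized
#' by the SUVmean of the reference tissue. The SUV ratio is dimensionless,
#' so the score carries units of mL. Because both the lesion SUVmean and the
#' reference SUVmean scale together, the score is invariant to a global
#' rescaling of PET intensities.
#'
#' @param lesion an accepted `psma_lesion`.
#' @param ref a `reference_uptake`; its active reference mean must be
#'   positive.
#' @return Non-negative lesion PSMA score (mL).
#' @examples
#' # volume 2 mL, SUVmean 4, reference 2 -> score 4
#' @export
lesion_psma_score <- function(lesion, ref) {
  stopifnot(inherits(lesion, "psma_lesion"), inherits(ref, "reference_uptake"))
  rv <- reference_value(ref)
  if (!is.finite(rv) || rv <= 0) stop("reference SUVmean must be positive")
  lesion$volume_ml * lesion$suv_mean / rv
}

# Compartment score container; composite = sum of non-missing scores
# (0 when all are missing). A compartment is missing, not zero, when the
# patient has no scoreable disease there.
make_compartment_scores <- function(prostate_bed = NA_real_, nodal = NA_real_,
                                    osseous = NA_real_,
                                    reference_used = NA_character_) {
  sc <- c(prostate_bed = unname(prostate_bed), nodal = unname(nodal),
          osseous = unname(osseous))
  if (any(!is.na(sc) & sc < 0)) stop("compartment scores must be non-negative")
  structure(list(prostate_bed = sc[["prostate_bed"]],
                 nodal = sc[["nodal"]],
                 osseous = sc[["osseous"]],
                 composite = sum(sc, na.rm = TRUE),
                 reference_used = reference_used),
            class = "compartment_scores")
}

#' @export
print.compartment_scores <- function(x, ...) {
  f <- function(v) if (is.na(v)) "N/A" else sprintf("%.1f", v)
  cat(sprintf("<compartment_scores> prostate/bed %s, nodal %s, osseous %s, composite %s\n",
              f(x$prostate_bed), f(x$nodal), f(x$osseous), f(x$composite)))
  invisible(x)
}

#' Compartment and composite PSMA scores for one scan
#'
#' Each anatomic compartment score is the sum of the accepted lesion scores
#' in that compartment; regional and non-regional nodal lesions pool into a
#' single nodal compartment. The composite is the sum of the compartment
#' scores. A compartment with no accepted lesion is missing (the "N/A"
#' convention), not zero; with no accepted lesions at all, every compartment
#' is missing and the composite is 0. Unclassified lesions never contribute.
#'
#' @param lesions list of classified `psma_lesion` objects.
#' @param ref a `reference_uptake`.
#' @return A `compartment_scores` object.
#' @export
compartment_scores <- function(lesions, ref) {
  acc <- Filter(function(l) isTRUE(l$accepted) && !is.na(l$compartment) &&
                  l$compartment != "unclassified", lesions)
  pool <- c(prostate_bed = "prostate_bed", regional_node = "nodal",
            nonregional_node = "nodal", osseous = "osseous")
  totals <- c(prostate_bed = NA_real_, nodal = NA_real_, osseous = NA_real_)
  for (l in acc) {
    comp <- pool[[l$compartment]]
    s <- lesion_psma_score(l, ref)
    totals[comp] <- if (is.na(totals[comp])) s else totals[comp] + s
  }
  make_compartment_scores(totals["prostate_bed"], totals["nodal"],
                          totals["osseous"],
                          reference_used = ref$reference_choice)
}

#' Write / read per-patient scores as CSV
#'
#' One row per patient and timepoint with columns `patient_id, timepoint,
#' prostate_bed, nodal, osseous, composite`; missing compartments written
#' as `NA`. Values round-trip at full precision.
#'
#' @param scores named list: for each patient id, a list with elements
#'   `baseline` and/or `followup`, each a `compartment_scores`.
#' @param path CSV file path.
#' @return `write_scores_csv()` returns `path` invisibly;
#'   `read_scores_csv()` returns the nested list form.
#' @export
write_scores_csv <- function(scores, path) {
  rows <- list()
  for (pid in names(scores)) {
    for (tp in names(scores[[pid]])) {
      s <- scores[[pid]][[tp]]
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, timepoint = tp,
        prostate_bed = s$prostate_bed, nodal = s$nodal, osseous = s$osseous,
        composite = s$composite,
        reference_used = s$reference_used)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_scores_csv
#' @export
read_scores_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(d))) {
    out[[as.character(d$patient_id[i])]][[d$timepoint[i]]] <-
      make_compartment_scores(d$prostate_bed[i], d$nodal[i], d$osseous[i],
                              reference_used = d$reference_used[i])
  }
  out
}
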