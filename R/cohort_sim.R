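#' PSA link parameters
#'
#' Parameters of the generative link between total tracer-avid burden and
#' serum PSA used by the cohort simulator:
#' `PSA = s * (composite + c0)^beta * exp(sigma * z)` with `z` standard
#' normal. A power law with multiplicative log-normal noise is the simplest
#' strictly positive model whose noise-free limit (`sigma = 0`, `c0 = 0`,
#' `beta = 1`) forces the PSA percent change to equal the composite-score
#' percent change exactly.
#'
#' @param scale `s`, positive multiplicative scale (PSA units, ng/mL).
#' @param offset `c0`, non-negative burden offset; keeps the link finite at
#'   zero burden.
#' @param exponent `beta`, power-law exponent.
#' @param noise_sd `sigma`, non-negative SD of the log-normal noise.
#' @return An object of class `psa_link_params`.
#' @export
psa_link_params <- function(scale = 1, offset = 1, exponent = 1, noise_sd = 0.3) {
  stopifnot(is.numeric(scale), scale > 0,
            is.numeric(offset), offset >= 0,
            is.numeric(exponent), length(exponent) == 1L, is.finite(exponent),
            is.numeric(noise_sd), noise_sd >= 0)
  structure(list(scale = scale, offset = offset, exponent = exponent,
                 noise_sd = noise_sd),
            class = "psa_link_params")
}

#' PSA from tumor burden
#'
#' Evaluates the power-law burden-to-PSA link
#' `PSA = s * (composite + c0)^beta * exp(sigma * noise_draw)`.
#'
#' @param composite_score non-negative composite PSMA score.
#' @param params a [psa_link_params].
#' @param noise_draw standard-normal draw (0 for the noise-free value).
#' @return Positive PSA value; exactly 0 only in the limit case of zero
#'   burden with zero offset and positive exponent (a complete responder
#'   with PSA at the detection floor, the "-100%" convention of clinical
#'   response tables).
#' @examples
#' psa_from_burden(0, psa_link_params(scale = 2, offset = 1, exponent = 1,
#'                                    noise_sd = 0))
#' @export
psa_from_burden <- function(composite_score, params, noise_draw = 0) {
  stopifnot(inherits(params, "psa_link_params"))
  if (!is.numeric(composite_score) || any(composite_score < 0))
    stop("'composite_score' must be non-negative")
  base <- composite_score + params$offset
  if (any(base == 0) && params$exponent <= 0)
    stop("PSA link degenerate: zero burden with non-positive exponent")
  psa <- params$scale * base^params$exponent * exp(params$noise_sd * noise_draw)
  if (any(!is.finite(psa)) || any(psa < 0))
    stop("PSA link produced an invalid value")
  psa
}

#' Cohort specification for the simulator
#'
#' Statistical structure of a simulated baseline/follow-up cohort. Defaults
#' mirror the marginals of a 30-patient castration-sensitive cohort:
#' compartment prevalence 27/30 (prostate/bed), 25/30 (nodal), 18/30
#' (osseous); log-normal baseline compartment scores with medians 21.6, 5.3
#' and 2.2 and sdlog 1; a treatment effect that is a complete response
#' (residual 0) with probability 0.5 and otherwise a log-normal
#' multiplicative residual (median 0.15, sdlog 1, so progression above 1 is
#' possible); scan intervals log-normal around 8 months clamped to 3-30.
#'
#' @param n_patients integer >= 2.
#' @param compartment_prevalence named probabilities for `prostate_bed`,
#'   `nodal`, `osseous`. A patient with no involved compartment is redrawn:
#'   the simulated cohort, like an imaging study cohort, is
#'   disease-positive by construction.
#' @param baseline_meanlog,baseline_sdlog named log-normal parameters of the
#'   baseline per-compartment scores.
#' @param treatment_effect list with `p_complete` (probability of residual
#'   0), `meanlog`, `sdlog` of the log-normal residual fraction; drawn
#'   independently per involved compartment.
#' @param psa_link a [psa_link_params].
#' @param seed integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 30,
                        compartment_prevalence = c(prostate_bed = 27 / 30,
                                                   nodal = 25 / 30,
                                                   osseous = 18 / 30),
                        baseline_meanlog = log(c(prostate_bed = 21.6,
                                                 nodal = 5.3,
                                                 osseous = 2.2)),
                        baseline_sdlog = c(prostate_bed = 1, nodal = 1,
                                           osseous = 1),
                        treatment_effect = list(p_complete = 0.5,
                                                meanlog = log(0.15),
                                                sdlog = 1),
                        psa_link = psa_link_params(),
                        seed = 1L) {
  comps <- c("prostate_bed", "nodal", "osseous")
  stopifnot(is.numeric(n_patients), n_patients >= 2,
            all(comps %in% names(compartment_prevalence)),
            all(compartment_prevalence >= 0 & compartment_prevalence <= 1),
            all(comps %in% names(baseline_meanlog)),
            all(comps %in% names(baseline_sdlog)),
            all(c("p_complete", "meanlog", "sdlog") %in% names(treatment_effect)),
            treatment_effect$p_complete >= 0, treatment_effect$p_complete <= 1,
            treatment_effect$sdlog >= 0,
            inherits(psa_link, "psa_link_params"))
  if (all(compartment_prevalence[comps] == 0))
    stop("at least one compartment must have positive prevalence")
  structure(list(n_patients = as.integer(n_patients),
                 compartment_prevalence = compartment_prevalence[comps],
                 baseline_meanlog = baseline_meanlog[comps],
                 baseline_sdlog = baseline_sdlog[comps],
                 treatment_effect = treatment_effect,
                 psa_link = psa_link, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a baseline/follow-up cohort
#'
#' Draws, per patient: which compartments are involved (per prevalence;
#' uninvolved compartments are structurally missing, not zero), baseline
#' compartment scores (log-normal), a multiplicative treatment residual per
#' involved compartment (follow-up = baseline x residual), and PSA at both
#' timepoints from the burden link. Deterministic given the spec's seed;
#' the caller's RNG stream is left untouched.
#'
#' @param spec a [cohort_spec].
#' @return List of [patient_record] objects of length `n_patients`.
#' @examples
#' rec <- generate_cohort(cohort_spec(n_patients = 5, seed = 7))
#' rec[[1]]
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_patients < 2)
    stop("n_patients must be >= 2 (correlation undefined otherwise)")
  comps <- names(spec$compartment_prevalence)
  te <- spec$treatment_effect
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_patients), function(i) {
      repeat {
        present <- stats::runif(length(comps)) < spec$compartment_prevalence
        if (any(present)) break
      }
      base <- ifelse(present,
                     stats::rlnorm(length(comps),
                                   meanlog = spec$baseline_meanlog,
                                   sdlog = spec$baseline_sdlog),
                     NA_real_)
      residual <- ifelse(stats::runif(length(comps)) < te$p_complete, 0,
                         stats::rlnorm(length(comps), te$meanlog, te$sdlog))
      fup <- ifelse(present, base * residual, NA_real_)
      names(base) <- names(fup) <- comps
      b <- make_compartment_scores(base["prostate_bed"], base["nodal"],
                                   base["osseous"], reference_used = "simulated")
      f <- make_compartment_scores(fup["prostate_bed"], fup["nodal"],
                                   fup["osseous"], reference_used = "simulated")
      psa0 <- psa_from_burden(b$composite, spec$psa_link, stats::rnorm(1))
      psa1 <- psa_from_burden(f$composite, spec$psa_link, stats::rnorm(1))
      interval <- min(30L, max(3L, as.integer(round(
        stats::rlnorm(1, meanlog = log(8), sdlog = 0.5)))))
      patient_record(patient_id = i, baseline = b, followup = f,
                     psa_baseline = psa0, psa_followup = psa1,
                     interval_months = interval)
    })
  })
}

#' Write / read a simulated cohort as CSV
#'
#' Long format, one row per patient-compartment: `patient_id, compartment,
#' score_baseline, score_followup, psa_baseline, psa_followup,
#' interval_months`, with `NA` for structurally missing compartments.
#' `read_cohort_csv()` inverts `write_cohort_csv()` exactly.
#'
#' @param records list of [patient_record] objects.
#' @param path CSV file path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns a list of [patient_record] objects.
#' @export
write_cohort_csv <- function(records, path) {
  rows <- do.call(rbind, lapply(records, function(r) {
    data.frame(patient_id = r$patient_id,
               compartment = c("prostate_bed", "nodal", "osseous"),
               score_baseline = c(r$baseline$prostate_bed, r$baseline$nodal,
                                  r$baseline$osseous),
               score_followup = c(r$followup$prostate_bed, r$followup$nodal,
                                  r$followup$osseous),
               psa_baseline = r$psa_baseline, psa_followup = r$psa_followup,
               interval_months = r$interval_months)
  }))
  utils::write.csv(rows, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(d, factor(d$patient_id, levels = unique(d$patient_id))),
         function(g) {
           sc <- function(col) {
             v <- g[[col]]
             names(v) <- g$compartment
             v
           }
           b <- sc("score_baseline")
           f <- sc("score_followup")
           patient_record(patient_id = g$patient_id[1],
                          baseline = make_compartment_scores(
                            b["prostate_bed"], b["nodal"], b["osseous"],
                            reference_used = "simulated"),
                          followup = make_compartment_scores(
                            f["prostate_bed"], f["nodal"], f["osseous"],
                            reference_used = "simulated"),
                          psa_baseline = g$psa_baseline[1],
                          psa_followup = g$psa_followup[1],
                          interval_months = g$interval_months[1])
         }) |> unname()
}
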