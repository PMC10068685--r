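# MD5 checksums of the packaged study tables, frozen at transcription time.
.fixture_md5 <- c(
  table1_patients.csv = "e6ac0423227ce809eb3f47350fea693e",
  table2_response.csv = "276b943c4e328cb529662adf4d5f3286",
  table2_pearson_row.csv = "87feca73acc79e0d4a4d71082de4c300"
)

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "psmaquant")
  if (p == "") stop("packaged fixture not found: ", file)
  p
}

#' Load the packaged study tables
#'
#' Returns the transcribed per-patient tables of the 30-patient
#' castration-sensitive cohort: clinicopathologic data with scan intervals
#' and percent PSA reduction (`table1`), the per-patient percent changes in
#' nodal / osseous / prostate-bed / composite PSMA score with the signed
#' PSA change (`table2`, a `cohort_table`), and the published correlation
#' row for cross-checking (`pearson_row`). One patient's PSA response is
#' unknown and is missing throughout; "N/A" compartment cells (no
#' scoreable disease) are missing values. File checksums are verified
#' against values frozen at transcription time.
#'
#' @param check verify MD5 checksums of the packaged files (default `TRUE`).
#' @return List with `table1` (data frame), `table2` (`cohort_table`),
#'   `pearson_row` (data frame with `compartment`, `r_printed`,
#'   `p_printed`).
#' @examples
#' fx <- load_paper_fixtures()
#' nrow(fx$table1)
#' @export
load_paper_fixtures <- function(check = TRUE) {
  paths <- vapply(names(.fixture_md5), fixture_path, character(1))
  if (check) {
    got <- tools::md5sum(paths)
    bad <- names(.fixture_md5)[got != .fixture_md5]
    if (length(bad))
      stop("fixture checksum mismatch: ", paste(bad, collapse = ", "))
  }
  table1 <- utils::read.csv(paths[["table1_patients.csv"]],
                            stringsAsFactors = FALSE)
  table2 <- read_cohort_table_csv(paths[["table2_response.csv"]])
  pearson_row <- utils::read.csv(paths[["table2_pearson_row.csv"]],
                                 stringsAsFactors = FALSE,
                                 colClasses = c("character", "numeric",
                                                "character"))
  list(table1 = table1, table2 = table2, pearson_row = pearson_row)
}
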