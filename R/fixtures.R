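fixture_registry <- c(
  table1_response_calls    = "table1_response_calls.tsv",
  table3_mgmt              = "table3_mgmt.tsv",
  sm1_mgmt_status          = "sm1_mgmt_status.tsv",
  sm1_mgmt_quant_synthetic = "sm1_mgmt_quant_synthetic.tsv"
)

#' Load a packaged study fixture
#'
#' The package ships plain-text transcriptions of the preclinical NCI-MPACT
#' study tables so the association layer can be exercised end-to-end:
#'
#' * `"table1_response_calls"` — one row per PDX model (51 rows): tumor type,
#'   actionable mutations of interest (aMOI) with pathway annotations
#'   (DDR, PI3K, RAS/RAF/MEK), clinical arm assignment, and per-regimen
#'   evaluability plus EFSx4 / regression response booleans for the four
#'   study regimens (`vt_` veliparib+temozolomide, `ac_`
#'   adavosertib+carboplatin, `tram_` trametinib, `evl_` everolimus) and the
#'   single-agent follow-ups (`tmz_`, `vel_`). Evaluability per model is not
#'   published per regimen; the flags are frozen so that the published
#'   denominators (50/47/46/46 evaluable) and association margins hold.
#' * `"table3_mgmt"` — the 10 temozolomide-relevant responders with published
#'   promoter-methylation and protein-expression calls.
#' * `"sm1_mgmt_status"` — the 49-model MGMT biomarker panel: promoter status
#'   and MGMT IHC protein calls at two passages per model.
#' * `"sm1_mgmt_quant_synthetic"` — synthetic MethyLight quantity means and
#'   IHC percent-positive values constructed to be consistent with each
#'   published call in `sm1_mgmt_status` (the raw assay quantities are
#'   unpublished); lets the PMR and IHC threshold callers run end-to-end.
#'
#' @param name Fixture name (see above).
#' @return A tibble.
#' @examples
#' nrow(load_fixture("table1_response_calls"))  # 51
#' @export
load_fixture <- function(name) {
  if (!name %in% names(fixture_registry)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(fixture_registry), collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", fixture_registry[[name]],
                      package = "pdxmpact", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

fixture_regimens <- c(
  vt = "velip_tmz", ac = "adav_carbo", tram = "trametinib",
  evl = "everolimus", tmz = "tmz", vel = "veliparib"
)

#' Pivot the model-response fixture to one row per model x regimen
#'
#' @param calls The `"table1_response_calls"` fixture (default: loaded).
#' @return Tibble with `model_id`, `patient_id`, `ddr_eligible`, `regimen`,
#'   `evaluable`, `efs_response`, `regression_response`, and the combined
#'   either-metric `responder` flag.
#' @export
response_calls_long <- function(calls = load_fixture("table1_response_calls")) {
  purrr::imap_dfr(fixture_regimens, function(reg, prefix) {
    tibble::tibble(
      model_id = calls$model_id,
      patient_id = calls$patient_id,
      ddr_eligible = calls$ddr_eligible,
      regimen = reg,
      evaluable = calls[[paste0(prefix, "_evaluable")]],
      efs_response = calls[[paste0(prefix, "_efs")]],
      regression_response = calls[[paste0(prefix, "_reg")]]
    )
  }) |>
    dplyr::mutate(
      responder = .data$evaluable &
        (dplyr::coalesce(.data$efs_response, FALSE) |
           dplyr::coalesce(.data$regression_response, FALSE))
    )
}
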