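#' Apply the PMR and IHC callers to the packaged MGMT fixtures
#'
#' Runs [compute_pmr()] on the MethyLight quantity means and [call_ihc()] on
#' the per-passage IHC values of the quantitative fixture, joins the
#' published status calls, and derives per-model protein status and passage
#' stability.
#'
#' @param status The `"sm1_mgmt_status"` fixture (default: loaded).
#' @param quant The `"sm1_mgmt_quant_synthetic"` fixture (default: loaded).
#' @return Tibble with one row per model: `pmr`, `methylated_call`,
#'   per-passage IHC calls, `protein_negative` (negative at every usable
#'   passage), and `protein_stability`.
#' @export
mgmt_fixture_calls <- function(status = load_fixture("sm1_mgmt_status"),
                               quant = load_fixture("sm1_mgmt_quant_synthetic")) {
  pmr_res <- compute_pmr(quant$mgmt_quantity_mean, quant$mgmt_methctrl_quantity_mean,
                         quant$actb_quantity_mean, quant$actb_methctrl_quantity_mean)
  ihc_a <- call_ihc(quant$pct_positive_a, quant$n_nuclei_a)
  ihc_b <- call_ihc(quant$pct_positive_b, quant$n_nuclei_b)
  dplyr::inner_join(status, quant["model_id"], by = "model_id") |>
    dplyr::mutate(
      pmr = pmr_res$pmr,
      methylated_call = pmr_res$methylated_call,
      ihc_call_a = ihc_a,
      ihc_call_b = ihc_b,
      protein_negative = purrr::map2_lgl(ihc_a, ihc_b, function(x, y) {
        calls <- stats::na.omit(c(x, y))
        length(calls) > 0 && all(calls == "negative")
      }),
      protein_stability = purrr::map2_chr(ihc_a, ihc_b,
                                          ~ passage_stability(c(.x, .y)))
    )
}

#' Collapse model-level rows to one row per originating patient
#'
#' Several PDX models can derive from one patient (different timepoints or
#' anatomic sites). For patient-level sensitivity analyses a patient counts
#' as biomarker-positive / responder if any of its models is.
#'
#' @param df Tibble with `patient_id` and logical columns to collapse.
#' @param cols Character vector of logical columns (default: all logicals).
#' @return One row per `patient_id` with `any()`-collapsed logical columns.
#' @export
collapse_to_patients <- function(df, cols = NULL) {
  if (is.null(cols)) cols <- names(df)[vapply(df, is.logical, logical(1))]
  df |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cols), ~ any(.x, na.rm = TRUE)),
                     .groups = "drop")
}

#' Headline summary report from the packaged fixtures
#'
#' Recomputes the study's headline numbers from the packaged transcriptions:
#' per-regimen response rates, the single-agent temozolomide EFSx4
#' concordance among combination responders, the DDR-aMOI and
#' promoter-methylation association tests (self-implemented two-sided Fisher
#' exact), and the MGMT calling rates.
#'
#' @return Named list: `regimen_summary` (tibble), `tmz_efs_concordance`,
#'   `ddr_fisher`, `mgmt_fisher` (one-row tibbles), and `mgmt_summary`
#'   (one-row tibble of calling rates).
#' @export
report_fixtures <- function() {
  calls <- load_fixture("table1_response_calls")
  long <- response_calls_long(calls)
  regimen_summary <- summarize_regimen(long)

  combo <- dplyr::filter(long, .data$regimen == "velip_tmz", .data$evaluable)
  combo_resp <- combo$model_id[combo$responder]
  tmz_efs <- dplyr::filter(long, .data$regimen == "tmz",
                           .data$model_id %in% combo_resp)
  tmz_conc <- tibble::tibble(
    n_combo_responders = length(combo_resp),
    n_also_tmz_efs = sum(tmz_efs$evaluable & tmz_efs$efs_response, na.rm = TRUE)
  ) |>
    dplyr::mutate(percent = 100 * .data$n_also_tmz_efs / .data$n_combo_responders)

  ddr_tab <- build_contingency(
    status = tibble::tibble(model_id = combo$model_id,
                            status = combo$ddr_eligible),
    calls = tibble::tibble(model_id = combo$model_id,
                           responder = combo$responder)
  )
  ddr_fisher <- fisher_exact_two_sided(ddr_tab)

  mgmt <- mgmt_fixture_calls()
  mgmt_tab <- build_contingency(
    status = tibble::tibble(model_id = mgmt$model_id,
                            status = mgmt$methylated_call),
    calls = tibble::tibble(model_id = combo$model_id,
                           responder = combo$responder)
  )
  mgmt_fisher <- fisher_exact_two_sided(mgmt_tab)

  by_patient <- collapse_to_patients(
    dplyr::select(mgmt, "patient_id", "methylated_call")
  )
  mgmt_summary <- tibble::tibble(
    n_models_tested = nrow(mgmt),
    n_methylated_models = sum(mgmt$methylated_call),
    pct_methylated_models = 100 * sum(mgmt$methylated_call) / nrow(mgmt),
    n_patients_tested = nrow(by_patient),
    n_methylated_patients = sum(by_patient$methylated_call),
    pct_methylated_patients = 100 * sum(by_patient$methylated_call) /
      nrow(by_patient),
    n_protein_negative = sum(mgmt$protein_negative),
    pct_protein_negative = 100 * sum(mgmt$protein_negative) / nrow(mgmt),
    changed_models = paste(mgmt$model_id[mgmt$protein_stability == "changed"],
                           collapse = ";")
  )

  list(regimen_summary = regimen_summary,
       tmz_efs_concordance = tmz_conc,
       ddr_fisher = ddr_fisher,
       mgmt_fisher = mgmt_fisher,
       mgmt_summary = mgmt_summary)
}
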