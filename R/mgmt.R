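#' Percentage of methylated reference (PMR) from MethyLight quantities
#'
#' MethyLight reports a qPCR quantity mean for the target gene (MGMT) and the
#' control gene (ACTB) in the sample and in a fully methylated positive
#' control. The PMR is the ratio of the sample/positive-control ratios,
#' expressed as a percentage:
#' \deqn{PMR = 100 \cdot \frac{MGMT_{sample}/MGMT_{meth.ctrl}}
#'                           {ACTB_{sample}/ACTB_{meth.ctrl}}}
#' A sample is called promoter-methylated at the clinical reporting threshold
#' PMR >= 2 (i.e. 2% of the fully methylated reference). PMR is invariant to
#' rescaling all four quantities by a common factor.
#'
#' @param mgmt_quantity_mean,mgmt_methctrl_quantity_mean MGMT quantity means
#'   for the sample and the methylated positive control.
#' @param actb_quantity_mean,actb_methctrl_quantity_mean ACTB quantity means
#'   for the sample and the methylated positive control.
#' @param threshold Methylation call threshold on PMR (default 2).
#' @return Tibble with `pmr` and `methylated_call`. Vectorized.
#' @examples
#' compute_pmr(100, 1000, 500, 5000)  # PMR 100, methylated
#' compute_pmr(0, 1000, 500, 5000)    # PMR 0, non-methylated
#' @export
compute_pmr <- function(mgmt_quantity_mean, mgmt_methctrl_quantity_mean,
                        actb_quantity_mean, actb_methctrl_quantity_mean,
                        threshold = 2) {
  ctrl_bad <- is.na(mgmt_methctrl_quantity_mean) | mgmt_methctrl_quantity_mean <= 0 |
    is.na(actb_methctrl_quantity_mean) | actb_methctrl_quantity_mean <= 0 |
    is.na(actb_quantity_mean) | actb_quantity_mean <= 0
  if (any(ctrl_bad)) {
    stop("assay QC failure: zero or missing control/ACTB quantity; no call",
         call. = FALSE)
  }
  if (any(mgmt_quantity_mean < 0, na.rm = TRUE)) {
    stop("quantities must be non-negative", call. = FALSE)
  }
  pmr <- 100 * (mgmt_quantity_mean / mgmt_methctrl_quantity_mean) /
    (actb_quantity_mean / actb_methctrl_quantity_mean)
  tibble::tibble(pmr = pmr, methylated_call = pmr >= threshold)
}

#' MGMT IHC expression call
#'
#' Positive iff the percent of tumor nuclei staining for MGMT is at or above
#' the cutoff (default 30%, the glioblastoma IHC scoring convention); slides
#' with fewer than `min_nuclei` evaluable tumor nuclei fail QC and yield no
#' call (`NA`).
#'
#' @param percent_positive_nuclei Percent positive nuclei in `[0, 100]`.
#' @param n_tumor_nuclei Evaluable tumor nuclei per slide.
#' @param cutoff Positivity cutoff in percent (default 30, inclusive).
#' @param min_nuclei QC minimum nuclei per slide (default 100).
#' @return Character vector: `"positive"`, `"negative"`, or `NA` (QC fail).
#' @export
call_ihc <- function(percent_positive_nuclei, n_tumor_nuclei = Inf,
                     cutoff = 30, min_nuclei = 100) {
  if (any(percent_positive_nuclei < 0 | percent_positive_nuclei > 100,
          na.rm = TRUE)) {
    stop("percent positive nuclei must lie in [0, 100]", call. = FALSE)
  }
  n_tumor_nuclei <- rep_len(n_tumor_nuclei, length(percent_positive_nuclei))
  out <- ifelse(percent_positive_nuclei >= cutoff, "positive", "negative")
  out[n_tumor_nuclei < min_nuclei] <- NA_character_
  out
}

#' Stability of MGMT protein expression across passages
#'
#' PDX tumors are re-evaluated at two (or more) passages; a model whose IHC
#' call flips between passages is flagged `"changed"` — MGMT expression is
#' not always stable with passaging.
#'
#' @param calls Character vector of per-passage IHC calls
#'   (`"positive"`/`"negative"`, `NA` = QC fail).
#' @return `"stable"`, `"changed"`, or `"indeterminate"` (< 2 usable passages).
#' @examples
#' passage_stability(c("positive", "negative"))  # "changed"
#' @export
passage_stability <- function(calls) {
  usable <- calls[!is.na(calls)]
  if (length(usable) < 2) return("indeterminate")
  if (length(unique(usable)) > 1) "changed" else "stable"
}

#' Cohort z-scores for expression values
#'
#' Standardizes `log2(normalizedCount + 1)` expression values against the
#' cohort mean and standard deviation and flags outliers at |z| > 2 (low
#' expression at z < -2, high at z > 2). A zero-variance cohort yields z = 0
#' for every sample and no flags, with a warning. Flags are invariant under
#' affine transformation of the cohort values.
#'
#' @param values Numeric expression values (one cohort).
#' @param id Optional identifiers (default index).
#' @param z_threshold Flag threshold (default 2).
#' @return Tibble: `id`, `value`, `zscore`, `low_expression_flag`,
#'   `high_expression_flag`.
#' @export
expression_zscore <- function(values, id = seq_along(values), z_threshold = 2) {
  if (length(values) < 3) stop("cohort size must be >= 3", call. = FALSE)
  s <- stats::sd(values)
  if (is.na(s) || s == 0) {
    warning("zero-variance cohort: z-scores set to 0, no flags")
    z <- rep(0, length(values))
  } else {
    z <- (values - mean(values)) / s
  }
  tibble::tibble(
    id = id, value = values, zscore = z,
    low_expression_flag = z < -z_threshold,
    high_expression_flag = z > z_threshold
  )
}

#' Composite MGMT deficiency profile
#'
#' Combines the available modalities — promoter methylation (PMR), protein
#' expression (IHC), and mRNA level (cohort z-score) — into per-modality
#' statuses plus a "deficient by any modality" flag. Disagreement between
#' modalities is never collapsed silently: the concordance between promoter
#' and protein calls is reported alongside.
#'
#' @param methylated_call Logical promoter methylation call (or `NA`).
#' @param ihc_calls Character vector of per-passage IHC calls (or `NULL`).
#' @param low_expression_flag Logical mRNA-low flag (z < -2; or `NA`).
#' @return One-row tibble: per-modality statuses, `deficient_any`,
#'   `concordant` (promoter vs protein, `NA` if either missing), and
#'   `protein_stability` from [passage_stability()].
#' @export
mgmt_deficiency_profile <- function(methylated_call = NA,
                                    ihc_calls = NULL,
                                    low_expression_flag = NA) {
  if (is.na(methylated_call) && is.null(ihc_calls) && is.na(low_expression_flag)) {
    stop("at least one modality is required", call. = FALSE)
  }
  protein_negative <- if (is.null(ihc_calls) || all(is.na(ihc_calls))) {
    NA
  } else {
    all(ihc_calls[!is.na(ihc_calls)] == "negative")
  }
  stability <- if (is.null(ihc_calls)) "indeterminate" else passage_stability(ihc_calls)
  deficient <- isTRUE(methylated_call) || isTRUE(protein_negative) ||
    isTRUE(low_expression_flag) || stability == "changed"
  concordant <- if (is.na(methylated_call) || is.na(protein_negative)) {
    NA
  } else {
    methylated_call == protein_negative
  }
  tibble::tibble(
    promoter_methylated = methylated_call,
    protein_negative = protein_negative,
    protein_stability = stability,
    mrna_low = low_expression_flag,
    deficient_any = deficient,
    concordant = concordant
  )
}
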