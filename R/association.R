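#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact conditional test on a 2x2 contingency table with both margins fixed.
#' The number of successes in the first row follows a hypergeometric
#' distribution under the null of no association; the two-sided p-value is
#' computed by the probability method — the sum of the point probabilities of
#' every table (with the observed margins) no more probable than the observed
#' one. Point probabilities are evaluated in log space via `lchoose`, and the
#' "no more probable" comparison uses a relative tolerance of 1e-7 to absorb
#' floating-point ties, the convention of standard statistical packages.
#' No normal approximation is involved at any table size.
#'
#' @param a,b,c,d Non-negative integer cell counts, rows = biomarker +/-,
#'   columns = responder / non-responder. Alternatively pass a 2x2 matrix as
#'   `a`.
#' @return One-row tibble: `p_two_sided`, `odds_ratio` (the sample odds ratio
#'   `(a d)/(b c)`, `Inf` when `b c = 0` and `a d > 0`, `NaN` for 0/0), and
#'   the four counts.
#' @examples
#' fisher_exact_two_sided(1, 1, 1, 1)$p_two_sided   # 1
#' fisher_exact_two_sided(7, 4, 4, 34)$p_two_sided  # ~0.000885
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  n <- a + b + c + d
  if (n == 0) stop("all-zero table", call. = FALSE)
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  k <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- p[k == a]
  p_two <- min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
  odds <- (a * d) / (b * c)
  tibble::new_tibble(
    list(p_two_sided = p_two, odds_ratio = odds,
         a = as.integer(a), b = as.integer(b),
         c = as.integer(c), d = as.integer(d)),
    nrow = 1L
  )
}

#' Build a biomarker-by-response 2x2 table
#'
#' Joins per-model biomarker status to per-model response calls; models
#' missing either value are excluded and reported in the `excluded`
#' attribute.
#'
#' @param status Data frame with `model_id` and a logical `status` column
#'   (biomarker positive).
#' @param calls Data frame with `model_id` and a logical `responder` column.
#' @return 2x2 integer matrix (rows: status TRUE/FALSE; columns: responder
#'   TRUE/FALSE) with dimnames, `excluded` attribute listing dropped models.
#' @export
build_contingency <- function(status, calls) {
  stopifnot(all(c("model_id", "status") %in% names(status)),
            all(c("model_id", "responder") %in% names(calls)))
  joined <- dplyr::inner_join(
    dplyr::select(status, "model_id", "status"),
    dplyr::select(calls, "model_id", "responder"),
    by = "model_id"
  ) |>
    dplyr::filter(!is.na(.data$status), !is.na(.data$responder))
  if (nrow(joined) == 0) {
    stop("no models present in both biomarker and response inputs",
         call. = FALSE)
  }
  excluded <- setdiff(union(status$model_id, calls$model_id), joined$model_id)
  tab <- matrix(
    c(sum(joined$status & joined$responder),
      sum(joined$status & !joined$responder),
      sum(!joined$status & joined$responder),
      sum(!joined$status & !joined$responder)),
    nrow = 2, byrow = TRUE,
    dimnames = list(status = c("positive", "negative"),
                    response = c("responder", "non-responder"))
  )
  attr(tab, "excluded") <- excluded
  tab
}

#' Per-regimen response-rate summary
#'
#' Counts evaluable models and responders (either-metric rule: EFSx4 >= 2 in
#' any experiment, or PR/CR) per regimen and reports the response rate in
#' percent, both exact and rounded half away from zero at the requested
#' printed precision.
#'
#' @param calls Long response-call table as from [response_calls_long()]:
#'   columns `model_id`, `regimen`, `evaluable`, `responder`.
#' @param digits Decimal places for the rounded rate (default 1).
#' @return Tibble: `regimen`, `n_evaluable`, `n_responders`, `rate_percent`,
#'   `rate_percent_rounded`, `responder_ids` (list column).
#' @export
summarize_regimen <- function(calls, digits = 1) {
  if (nrow(calls) == 0) {
    return(tibble::tibble(regimen = character(), n_evaluable = integer(),
                          n_responders = integer(), rate_percent = numeric(),
                          rate_percent_rounded = numeric(),
                          responder_ids = list()))
  }
  calls |>
    dplyr::group_by(.data$regimen) |>
    dplyr::summarise(
      n_evaluable = sum(.data$evaluable, na.rm = TRUE),
      n_responders = sum(.data$evaluable & .data$responder, na.rm = TRUE),
      responder_ids = list(.data$model_id[.data$evaluable & .data$responder]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      rate_percent = 100 * .data$n_responders / .data$n_evaluable,
      rate_percent_rounded = round_half_away(.data$rate_percent, digits)
    ) |>
    dplyr::relocate("responder_ids", .after = dplyr::last_col())
}

#' Round half away from zero
#'
#' Rounding convention used when comparing computed rates to printed values
#' (base `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Gene alteration frequencies across samples
#'
#' Computes, for each gene, the fraction of samples carrying a likely
#' oncogenic alteration and drops genes at or below `min_fraction` (strict
#' "over" filter, default 10%) — the OncoPrint-style shortlist.
#'
#' @param alterations Logical matrix or data frame, samples x genes.
#' @param min_fraction Strict lower bound on the retained fraction
#'   (default 0.10).
#' @param sample_model Optional factor/vector mapping samples to models; if
#'   given, a per-model altered fraction (fraction of models with >= 1
#'   altered sample) is reported too.
#' @return Tibble: `gene`, `n_samples`, `frac_samples`, `percent_samples`
#'   (and `frac_models` when `sample_model` is given), sorted by frequency.
#' @export
alteration_frequency <- function(alterations, min_fraction = 0.10,
                                 sample_model = NULL) {
  m <- as.matrix(alterations)
  if (nrow(m) == 0 || ncol(m) == 0) {
    return(tibble::tibble(gene = character(), n_samples = integer(),
                          frac_samples = numeric(), percent_samples = numeric()))
  }
  mode(m) <- "logical"
  out <- tibble::tibble(
    gene = colnames(m) %||% paste0("g", seq_len(ncol(m))),
    n_samples = unname(colSums(m, na.rm = TRUE)),
    frac_samples = unname(colMeans(m, na.rm = TRUE))
  ) |>
    dplyr::mutate(percent_samples = 100 * .data$frac_samples)
  if (!is.null(sample_model)) {
    per_model <- rowsum(m + 0, group = sample_model) > 0
    out$frac_models <- unname(colMeans(per_model))
  }
  out |>
    dplyr::filter(.data$frac_samples > min_fraction) |>
    dplyr::arrange(dplyr::desc(.data$frac_samples))
}

#' Null calibration of the Fisher test at the study margins
#'
#' Simulates biomarker-independent response at fixed margins (default: the
#' study's 11 methylated / 38 non-methylated split with 11 responders among
#' 49 models): responders are assigned uniformly at random, so the count of
#' biomarker-positive responders is hypergeometric. Reports the fraction of
#' replicates rejected at `alpha`; being an exact conditional test, the
#' rejection rate is conservative (at or below `alpha` up to Monte-Carlo
#' error).
#'
#' @param n_positive,n_negative Biomarker margin (default 11 / 38).
#' @param n_responders Response margin (default 11).
#' @param alpha Nominal level (default 0.05).
#' @param n_rep Replicates (default 2000).
#' @param seed RNG seed.
#' @return One-row tibble: `rejection_rate`, `mc_se`, `n_rep`, `alpha`.
#' @export
fisher_null_calibration <- function(n_positive = 11, n_negative = 38,
                                    n_responders = 11, alpha = 0.05,
                                    n_rep = 2000, seed = 1) {
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old(), add = TRUE)
  a <- stats::rhyper(n_rep, n_positive, n_negative, n_responders)
  pvals <- vapply(a, function(ai) {
    fisher_exact_two_sided(
      ai, n_positive - ai,
      n_responders - ai, n_negative - (n_responders - ai)
    )$p_two_sided
  }, numeric(1))
  rate <- mean(pvals <= alpha)
  tibble::tibble(
    rejection_rate = rate,
    mc_se = sqrt(alpha * (1 - alpha) / n_rep),
    n_rep = n_rep, alpha = alpha
  )
}

# save/restore the global RNG state so seeded helpers do not perturb callers
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }
  }
}
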