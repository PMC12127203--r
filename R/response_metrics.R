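#' Time to tumor quadrupling for one animal
#'
#' The event is the tumor volume reaching four times the animal's baseline
#' (staging) volume. Because measurements fall on a 2-3x weekly grid, the
#' event time is log-linearly interpolated between the last measurement below
#' threshold and the first at or above it — tumor growth is near-exponential
#' between measurements, so interpolating on log volume removes most of the
#' measurement-grid bias. If the first on-study measurement is already at or
#' above threshold the event is placed at that day. Animals that never reach
#' threshold are censored at the earlier of their last measurement while
#' alive and `study_end_day`; the censoring time itself (not a survival
#' model) is carried into downstream medians.
#'
#' @param days Numeric vector of study days (day 0 = treatment start;
#'   staging measurements may sit at days <= 0).
#' @param volumes Tumor volumes (mm^3) matching `days`.
#' @param alive Logical vector of vital status at each measurement
#'   (default all alive).
#' @param baseline Baseline volume; default is the measurement nearest day 0
#'   at or before it (the staging volume), falling back to the first
#'   measurement.
#' @param study_end_day End of the study window in days (default 300).
#' @return One-row tibble: `time_days`, `event_observed`, `baseline_volume_mm3`.
#' @examples
#' time_to_quadrupling(c(0, 10), c(200, 800))            # event at day 10
#' time_to_quadrupling(c(0, 7), c(200, 900))             # ~6.45 days
#' @export
time_to_quadrupling <- function(days, volumes, alive = rep(TRUE, length(days)),
                                baseline = NULL, study_end_day = 300) {
  if (length(days) == 0) stop("empty measurement series", call. = FALSE)
  ord <- order(days)
  days <- days[ord]; volumes <- volumes[ord]; alive <- alive[ord]
  if (is.null(baseline)) {
    b_day <- if (any(days <= 0)) max(days[days <= 0]) else days[1]
    baseline <- volumes[days == b_day][1]
  } else {
    b_day <- days[1]
  }
  if (is.na(baseline) || baseline <= 0) {
    stop("baseline volume must be positive", call. = FALSE)
  }
  thr <- 4 * baseline
  keep <- days >= b_day & alive & !is.na(volumes)
  d <- days[keep]; v <- volumes[keep]
  hit <- which(v >= thr)
  if (length(hit) > 0) {
    i <- hit[1]
    t_event <- if (i == 1 || v[i] == thr) {
      d[i]
    } else {
      d[i - 1] + (d[i] - d[i - 1]) * (log(thr) - log(v[i - 1])) /
        (log(v[i]) - log(v[i - 1]))
    }
    out_t <- t_event; out_e <- TRUE
  } else {
    out_t <- min(max(d), study_end_day); out_e <- FALSE
  }
  tibble::tibble(time_days = out_t, event_observed = out_e,
                 baseline_volume_mm3 = baseline)
}

#' Per-animal quadrupling event table for an arm
#'
#' @param arm A [study_arm()].
#' @inheritParams time_to_quadrupling
#' @return Tibble with one row per animal: `animal_id`, `time_days`,
#'   `event_observed`, `baseline_volume_mm3`.
#' @export
arm_event_times <- function(arm, study_end_day = 300) {
  stopifnot(inherits(arm, "study_arm"))
  # animals with no live measurement carry no event information
  arm$measurements |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::filter(any(.data$alive & !is.na(.data$volume_mm3))) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(~ time_to_quadrupling(
      .x$study_day, .x$volume_mm3, .x$alive, study_end_day = study_end_day
    )) |>
    dplyr::ungroup()
}

#' Relative median time-to-quadrupling event-free survival (EFSx4)
#'
#' EFSx4 is the ratio of the median per-animal time to tumor quadrupling (or
#' to the end of the study period, for animals that never quadruple) in the
#' treated arm over the vehicle arm. Censoring times enter the medians as-is,
#' so for heavily censored treated arms the ratio is a lower bound; the
#' conventional responder cut-off is EFSx4 >= 2, a two-fold delay in
#' quadrupling. Studies with substantial drug-related toxicity should be
#' excluded by the caller via `qc_pass = FALSE` (toxicity is not derivable
#' from the volume series alone).
#'
#' @param treated,vehicle [study_arm()] objects; `vehicle` must be flagged as
#'   the vehicle comparator.
#' @param study_end_day Study horizon in days (default 300).
#' @param qc_pass Logical quality-control flag carried into the result.
#' @param threshold Responder cut-off on the ratio (default 2).
#' @return One-row tibble: `model_id`, `regimen`, medians, `efs_x4`,
#'   `responder`, `qc_pass`.
#' @export
efs_x4 <- function(treated, vehicle, study_end_day = 300, qc_pass = TRUE,
                   threshold = 2) {
  stopifnot(inherits(treated, "study_arm"), inherits(vehicle, "study_arm"))
  if (!vehicle$is_vehicle) {
    stop("`vehicle` arm is not flagged as a vehicle comparator", call. = FALSE)
  }
  et_t <- arm_event_times(treated, study_end_day)
  et_v <- arm_event_times(vehicle, study_end_day)
  med_t <- stats::median(et_t$time_days)
  med_v <- stats::median(et_v$time_days)
  if (med_v <= 0) stop("degenerate vehicle arm: median event time is zero",
                       call. = FALSE)
  ratio <- med_t / med_v
  tibble::tibble(
    model_id = treated$model_id, regimen = treated$regimen,
    n_treated = nrow(et_t), n_vehicle = nrow(et_v),
    median_treated_days = med_t, median_vehicle_days = med_v,
    efs_x4 = ratio, responder = qc_pass & ratio >= threshold,
    qc_pass = qc_pass
  )
}

#' Group median percent volume change at a study day
#'
#' Median over animals alive (and measured) at the day of the per-animal
#' percent change from the staging baseline,
#' \eqn{100 (V_d - V_0) / V_0}. Dead animals are excluded from the median.
#'
#' @param arm A [study_arm()].
#' @param day A study day with at least one live-animal measurement.
#' @return Median percent change (scalar).
#' @export
group_percent_change <- function(arm, day) {
  stopifnot(inherits(arm, "study_arm"))
  base <- arm_baselines(arm)
  at_day <- arm$measurements |>
    dplyr::filter(.data$study_day == day, .data$alive, !is.na(.data$volume_mm3)) |>
    dplyr::inner_join(base, by = "animal_id")
  if (nrow(at_day) == 0) {
    stop("no live animal measured at day ", day, call. = FALSE)
  }
  stats::median(100 * (at_day$volume_mm3 - at_day$baseline_volume_mm3) /
                  at_day$baseline_volume_mm3)
}

#' Group-level regression (PR/CR) call for an arm
#'
#' Partial response (PR): the median per-animal percent change from staging
#' is <= -30% on at least two consecutive measurement days, each with at
#' least 60% of the randomized animals (`n_at_start`) still alive. Complete
#' response (CR): the group median absolute volume is <= `cr_volume_mm3`
#' (default 60 mm^3, the caliper measurement floor) under the same
#' consecutiveness and alive-fraction conditions. The reported duration spans
#' the first to last qualifying day of the longest qualifying run.
#'
#' @param arm A [study_arm()].
#' @param pr_pct_change PR threshold on the median percent change (default -30).
#' @param cr_volume_mm3 CR threshold on the median volume (default 60).
#' @param alive_fraction Minimum fraction of `n_at_start` alive (default 0.6).
#' @return One-row tibble: `model_id`, `regimen`, `pr`, `cr`, `pr_start_day`,
#'   `pr_end_day`, `duration_days`.
#' @export
classify_regression <- function(arm, pr_pct_change = -30, cr_volume_mm3 = 60,
                                alive_fraction = 0.6) {
  stopifnot(inherits(arm, "study_arm"))
  base <- arm_baselines(arm)
  days <- sort(unique(arm$measurements$study_day[arm$measurements$study_day >= 0]))
  per_day <- purrr::map_dfr(days, function(d) {
    m <- arm$measurements |>
      dplyr::filter(.data$study_day == d, .data$alive, !is.na(.data$volume_mm3)) |>
      dplyr::inner_join(base, by = "animal_id")
    tibble::tibble(
      study_day = d,
      n_alive = nrow(m),
      med_pct = if (nrow(m) > 0) {
        stats::median(100 * (m$volume_mm3 - m$baseline_volume_mm3) /
                        m$baseline_volume_mm3)
      } else NA_real_,
      med_vol = if (nrow(m) > 0) stats::median(m$volume_mm3) else NA_real_
    )
  })
  per_day$alive_ok <- per_day$n_alive / arm$n_at_start >= alive_fraction
  longest_run <- function(ok) {
    # longest run of TRUE over consecutive measurement days; NA -> FALSE
    ok[is.na(ok)] <- FALSE
    r <- rle(ok)
    if (!any(r$values & r$lengths >= 2)) return(NULL)
    idx <- which(r$values & r$lengths >= 2)
    best <- idx[which.max(r$lengths[idx])]
    start <- sum(r$lengths[seq_len(best - 1)]) + 1
    c(start, start + r$lengths[best] - 1)
  }
  pr_run <- longest_run(per_day$med_pct <= pr_pct_change & per_day$alive_ok)
  cr_run <- longest_run(per_day$med_vol <= cr_volume_mm3 & per_day$alive_ok)
  run <- if (!is.null(cr_run)) cr_run else pr_run
  tibble::tibble(
    model_id = arm$model_id, regimen = arm$regimen,
    pr = !is.null(pr_run), cr = !is.null(cr_run),
    pr_start_day = if (!is.null(run)) per_day$study_day[run[1]] else NA_real_,
    pr_end_day = if (!is.null(run)) per_day$study_day[run[2]] else NA_real_,
    duration_days = if (!is.null(run)) {
      per_day$study_day[run[2]] - per_day$study_day[run[1]]
    } else 0
  )
}

#' Combine durability and regression metrics into a model response call
#'
#' A model x regimen is a responder if EFSx4 >= 2 in at least one experiment
#' (repeat experiments may each contribute a row) or a PR/CR was achieved.
#'
#' @param efs Tibble of [efs_x4()] rows (one per experiment) for one
#'   model x regimen.
#' @param reg One-row tibble from [classify_regression()] (or `NULL`).
#' @return One-row tibble: `model_id`, `regimen`, `efs_response`,
#'   `regression_response`, `responder`.
#' @export
call_model_response <- function(efs, reg = NULL) {
  stopifnot(nrow(efs) >= 1)
  efs_resp <- any(efs$responder & efs$qc_pass)
  reg_resp <- !is.null(reg) && nrow(reg) == 1 && (reg$pr || reg$cr)
  tibble::tibble(
    model_id = efs$model_id[1], regimen = efs$regimen[1],
    efs_response = efs_resp, regression_response = reg_resp,
    responder = efs_resp || reg_resp
  )
}
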