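#' Study arm objects
#'
#' A `study_arm` bundles one treatment (or vehicle) group of one PDX model:
#' arm metadata plus the long-format caliper time series of every animal
#' randomized to the group. Measurements are kept as a tibble with one row per
#' animal x study day; `study_day` 0 is the first treatment day, staging
#' measurements may sit at negative days, and an animal's baseline volume is
#' the measurement nearest day 0 at or before it.
#'
#' @param model_id,arm_id,regimen Identifiers; `regimen` is the treatment
#'   label ("vehicle" flags the control comparator unless `is_vehicle` is
#'   given explicitly).
#' @param measurements Tibble with columns `animal_id`, `study_day`,
#'   `volume_mm3`, `alive` (and optionally `length_mm`, `width_mm`).
#' @param is_vehicle Logical; defaults to `regimen == "vehicle"`
#'   (case-insensitive).
#' @param n_at_start Number of randomized animals; defaults to the number of
#'   distinct animals in `measurements`.
#' @return An object of class `study_arm`.
#' @export
study_arm <- function(model_id, arm_id, regimen, measurements,
                      is_vehicle = NULL, n_at_start = NULL) {
  stopifnot(is.data.frame(measurements))
  req <- c("animal_id", "study_day", "volume_mm3", "alive")
  miss <- setdiff(req, names(measurements))
  if (length(miss) > 0) {
    stop("measurements missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  measurements <- dplyr::arrange(tibble::as_tibble(measurements),
                                 .data$animal_id, .data$study_day)
  dup <- measurements |>
    dplyr::count(.data$animal_id, .data$study_day) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate (animal, day) measurement(s): ",
         paste(paste0(dup$animal_id, "@d", dup$study_day), collapse = ", "),
         call. = FALSE)
  }
  # vital status must be monotone: once dead, never alive again
  revived <- measurements |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(bad = any(diff(as.integer(.data$alive)) > 0),
                     .groups = "drop") |>
    dplyr::filter(.data$bad)
  if (nrow(revived) > 0) {
    stop("alive=TRUE after alive=FALSE for animal(s): ",
         paste(revived$animal_id, collapse = ", "), call. = FALSE)
  }
  if (is.null(is_vehicle)) is_vehicle <- tolower(regimen) == "vehicle"
  if (is.null(n_at_start)) n_at_start <- dplyr::n_distinct(measurements$animal_id)
  structure(
    list(model_id = model_id, arm_id = arm_id, regimen = regimen,
         is_vehicle = is_vehicle, n_at_start = n_at_start,
         measurements = measurements),
    class = "study_arm"
  )
}

#' @export
print.study_arm <- function(x, ...) {
  cat(sprintf("<study_arm> %s / %s (%s)%s: %d animals, %d measurements\n",
              x$model_id, x$arm_id, x$regimen,
              if (x$is_vehicle) " [vehicle]" else "",
              dplyr::n_distinct(x$measurements$animal_id),
              nrow(x$measurements)))
  invisible(x)
}

#' Per-animal baseline volumes for an arm
#'
#' Baseline is the measurement nearest study day 0 at or before it (staging
#' measurements sit at day <= 0); if an animal has no measurement at or before
#' day 0 its first measurement is used.
#'
#' @param arm A `study_arm`.
#' @return Tibble with `animal_id`, `baseline_day`, `baseline_volume_mm3`.
#' @export
arm_baselines <- function(arm) {
  stopifnot(inherits(arm, "study_arm"))
  arm$measurements |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(
      baseline_day = if (any(.data$study_day <= 0)) {
        max(.data$study_day[.data$study_day <= 0])
      } else {
        min(.data$study_day)
      },
      baseline_volume_mm3 = .data$volume_mm3[.data$study_day == .data$baseline_day][1],
      .groups = "drop"
    )
}

required_measurement_cols <- c("model_id", "arm_id", "regimen", "animal_id",
                               "study_day", "alive")

#' Read a long-format caliper measurement table into study arms
#'
#' Expects one row per animal x study day with columns `model_id`, `arm_id`,
#' `regimen`, `animal_id`, `study_day`, `alive`, and either `volume_mm3` or
#' the caliper pair `length_mm`/`width_mm` (volumes are derived with
#' [compute_volume()] where absent, so width/length recording order does not
#' matter). The delimiter is auto-detected from the file extension
#' (`.csv` comma, anything else tab); a header row is mandatory.
#'
#' @param path Path to a CSV/TSV file.
#' @param vehicle_label Regimen label flagging vehicle arms (case-insensitive).
#' @return Named list of [study_arm()] objects (names `model_id/arm_id`), with
#'   a `validation` attribute summarising derived and flagged rows.
#' @export
read_measurements <- function(path, vehicle_label = "vehicle") {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  as_study_arms(df, vehicle_label = vehicle_label)
}

#' Convert a long measurement data frame into study arms
#'
#' @param df Data frame in the layout documented for [read_measurements()].
#' @inheritParams read_measurements
#' @return Named list of [study_arm()] objects.
#' @export
as_study_arms <- function(df, vehicle_label = "vehicle") {
  df <- tibble::as_tibble(df)
  miss <- setdiff(required_measurement_cols, names(df))
  if (length(miss) > 0) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  has_dims <- all(c("length_mm", "width_mm") %in% names(df))
  if (!("volume_mm3" %in% names(df)) && !has_dims) {
    stop("need either `volume_mm3` or both `length_mm` and `width_mm`",
         call. = FALSE)
  }
  n_derived <- 0L
  if (has_dims) {
    derived <- compute_volume(df$length_mm, df$width_mm)
    if (!("volume_mm3" %in% names(df))) {
      df$volume_mm3 <- derived
      n_derived <- sum(!is.na(derived))
    } else {
      fill <- is.na(df$volume_mm3) & !is.na(derived)
      df$volume_mm3[fill] <- derived[fill]
      n_derived <- sum(fill)
    }
  }
  flagged <- sum(df$alive & is.na(df$volume_mm3))
  df$alive <- as.logical(df$alive)
  arms <- df |>
    dplyr::group_by(.data$model_id, .data$arm_id) |>
    dplyr::group_split()
  out <- purrr::map(arms, function(g) {
    study_arm(
      model_id = g$model_id[1], arm_id = g$arm_id[1], regimen = g$regimen[1],
      measurements = dplyr::select(g, -dplyr::all_of(c("model_id", "arm_id", "regimen"))),
      is_vehicle = tolower(g$regimen[1]) == tolower(vehicle_label)
    )
  })
  names(out) <- purrr::map_chr(out, ~ paste(.x$model_id, .x$arm_id, sep = "/"))
  attr(out, "validation") <- tibble::tibble(
    n_rows = nrow(df), n_arms = length(out),
    n_volumes_derived = n_derived, n_alive_rows_missing_volume = flagged
  )
  out
}

#' Write study arms back to a long-format measurement file
#'
#' Inverse of [read_measurements()]; the delimiter follows the file extension.
#'
#' @param arms List of `study_arm` objects.
#' @param path Output path (`.csv` comma-delimited, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_measurements <- function(arms, path) {
  df <- purrr::map_dfr(arms, function(a) {
    dplyr::mutate(a$measurements, model_id = a$model_id, arm_id = a$arm_id,
                  regimen = a$regimen, .before = 1)
  })
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(df, path, progress = FALSE)
  } else {
    readr::write_tsv(df, path, progress = FALSE)
  }
  invisible(path)
}
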