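#' Dosing schedule as an explicit on-day set
#'
#' Normalizes a cyclic dosing pattern ("daily x 5 every 4 weeks", etc.) into
#' the set of on-treatment days within a repeating cycle. Day 0 is the first
#' treatment day.
#'
#' @param on_days Integer days within the cycle on which drug is given
#'   (0-based).
#' @param cycle_days Cycle length in days.
#' @return A `dosing_schedule` list.
#' @examples
#' dosing_schedule(0:4, 28)   # daily x 5 every 4 weeks
#' dosing_schedule(0:27, 28)  # continuous daily dosing
#' @export
dosing_schedule <- function(on_days, cycle_days) {
  stopifnot(length(on_days) > 0, cycle_days >= 1,
            all(on_days >= 0), all(on_days < cycle_days))
  structure(list(on_days = as.integer(sort(unique(on_days))),
                 cycle_days = as.integer(cycle_days)),
            class = "dosing_schedule")
}

#' @rdname dosing_schedule
#' @param schedule A `dosing_schedule`.
#' @param day Integer day(s) since treatment start.
#' @return `is_dosing_day()`: logical vector.
#' @export
is_dosing_day <- function(schedule, day) {
  (day %% schedule$cycle_days) %in% schedule$on_days
}

#' @rdname dosing_schedule
#' @return `on_fraction()`: fraction of cycle days on drug.
#' @export
on_fraction <- function(schedule) {
  length(schedule$on_days) / schedule$cycle_days
}

# study regimens as on-day sets (combination = union of component drug days)
study_schedules <- function() {
  list(
    velip_tmz  = dosing_schedule(0:6, 28),   # veliparib bid d0-6 + tmz d0-4, q4w
    adav_carbo = dosing_schedule(0:2, 21),   # adavosertib bid x5 (2.5 d) + carbo d0, q3w
    everolimus = dosing_schedule(0:27, 28),  # daily
    trametinib = dosing_schedule(0:27, 28)   # daily
  )
}

#' Treatment effect sized to a target time-to-quadrupling multiplier
#'
#' For a delay-mode effect (growth-rate multiplier `m` on dosing days,
#' `g_eff = g (1 - m)`), the long-run average growth rate is
#' `g (1 - m f)` with `f` the on-drug fraction of the cycle, so the time to
#' any fixed volume multiple is stretched by `1 / (1 - m f)`. This returns
#' the `m` achieving a target stretch `k` (`m = (1 - 1/k) / f`); `m > 1`
#' means net shrinkage during dosing.
#'
#' @param k Target time-to-quadrupling multiplier (>= 1).
#' @param schedule A [dosing_schedule()].
#' @return Growth-rate multiplier to use as a `delay`-mode magnitude.
#' @export
effect_for_ttq_multiplier <- function(k, schedule) {
  stopifnot(k >= 1)
  (1 - 1 / k) / on_fraction(schedule)
}

#' Simulation configuration for a synthetic PDX cohort
#'
#' Defaults mirror the design of a preclinical basket trial in
#' subcutaneously implanted PDX models: animals are staged to a median tumor
#' volume of ~200 mm^3 before randomization (day 0), tumors grow
#' exponentially with a vehicle doubling time of about a week, caliper
#' measurements are taken twice weekly with multiplicative lognormal noise
#' (CV 0.15, typical caliper repeatability), arms are n=16 vehicle / n=8
#' treated, and follow-up stops at a 4000 mm^3 tumor burden or day 300.
#' Treatment acts on dosing days only (cyclic schedules), either as a
#' growth-rate multiplier (`delay` mode) or an absolute kill rate
#' (`regression` mode). A latent biomarker (promoter methylation, prevalence
#' 0.22) gates sensitivity to the temozolomide-containing regimen with the
#' response rates observed in the study (0.64 methylated, 0.11
#' non-methylated); sensitive models receive an effect sized to a threefold
#' delay in quadrupling, placing true responders well clear of the
#' EFSx4 >= 2 decision boundary.
#'
#' @param n_models Number of PDX models.
#' @param regimens Character vector of regimen names (subset of
#'   `"velip_tmz"`, `"adav_carbo"`, `"everolimus"`, `"trametinib"`).
#' @param n_vehicle,n_treated Animals per vehicle / treated arm.
#' @param growth_rate Vehicle exponential growth rate per day
#'   (default `log(2)/7`, one doubling per week).
#' @param model_sdlog,animal_sdlog Lognormal SD of the growth rate across
#'   models and across animals within a model.
#' @param cv Lognormal coefficient of variation of measured volume.
#' @param measurement_days Days-of-week pattern (offsets within a 7-day
#'   week) on which calipering happens.
#' @param implant_volume_mm3 Mean implant volume at staging start.
#' @param staging_volume_mm3 Staging target volume (randomization trigger).
#' @param staging_check_days Interval between staging checks.
#' @param vol_cap_mm3 Tumor-burden stopping volume.
#' @param study_end_day Study horizon in days.
#' @param death_hazard Daily probability of on-study death (attrition).
#' @param effect_mode `"delay"` or `"regression"`.
#' @param sensitive_ttq_multiplier Target quadrupling-time stretch for
#'   sensitive models (delay mode).
#' @param regression_kill_rate Absolute shrinkage rate per day on dosing
#'   days (regression mode).
#' @param fraction_methylated Latent biomarker prevalence.
#' @param p_sensitive_methylated,p_sensitive_nonmethylated Probability a
#'   model is sensitive to the biomarker-linked regimen given its biomarker.
#' @param p_sensitive_other Sensitivity probability for the other regimens.
#' @param biomarker_regimen Regimen gated by the biomarker.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_models = 20,
                       regimens = "velip_tmz",
                       n_vehicle = 16, n_treated = 8,
                       growth_rate = log(2) / 7,
                       model_sdlog = 0.3, animal_sdlog = 0.15,
                       cv = 0.15,
                       measurement_days = c(0, 3),
                       implant_volume_mm3 = 50,
                       staging_volume_mm3 = 200,
                       staging_check_days = 1,
                       vol_cap_mm3 = 4000,
                       study_end_day = 300,
                       death_hazard = 0.002,
                       effect_mode = "delay",
                       sensitive_ttq_multiplier = 3,
                       regression_kill_rate = log(2) / 4,
                       fraction_methylated = 0.22,
                       p_sensitive_methylated = 0.64,
                       p_sensitive_nonmethylated = 0.11,
                       p_sensitive_other = 0.04,
                       biomarker_regimen = "velip_tmz") {
  stopifnot(growth_rate >= 0, cv >= 0, death_hazard >= 0, death_hazard <= 1,
            all(regimens %in% names(study_schedules())),
            effect_mode %in% c("delay", "regression"),
            fraction_methylated >= 0, fraction_methylated <= 1,
            p_sensitive_methylated >= 0, p_sensitive_methylated <= 1,
            p_sensitive_nonmethylated >= 0, p_sensitive_nonmethylated <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# piecewise-exponential true-volume path for one animal, daily grid
simulate_animal <- function(cfg, animal_id, g_animal, schedule = NULL,
                            effect = 0, mode = "delay") {
  # staging: untreated growth from implant until crossing the staging target
  v_implant <- cfg$implant_volume_mm3 * exp(stats::rnorm(1, 0, 0.2))
  if (v_implant >= cfg$staging_volume_mm3) {
    v0 <- v_implant
  } else {
    checks <- seq(0, 400, by = cfg$staging_check_days)
    v_checks <- v_implant * exp(g_animal * checks)
    v0 <- v_checks[which(v_checks >= cfg$staging_volume_mm3)[1]]
    if (is.na(v0)) v0 <- utils::tail(v_checks, 1)
  }
  days <- 0:cfg$study_end_day
  g_eff <- rep(g_animal, length(days))
  if (!is.null(schedule) && effect != 0) {
    on <- is_dosing_day(schedule, days)
    if (mode == "delay") {
      g_eff[on] <- g_animal * (1 - effect)
    } else {
      g_eff[on] <- -effect
    }
  }
  true_v <- v0 * exp(cumsum(c(0, g_eff[-length(days)])))
  death_day <- if (cfg$death_hazard > 0) {
    u <- stats::runif(length(days))
    u[1] <- 1  # alive at randomization
    hit <- which(u < cfg$death_hazard)
    if (length(hit) > 0) days[hit[1]] else Inf
  } else Inf
  meas_days <- days[(days %% 7) %in% cfg$measurement_days]
  sdlog <- sqrt(log(1 + cfg$cv^2))
  alive_days <- meas_days[meas_days < death_day]
  obs <- true_v[alive_days + 1] *
    exp(stats::rnorm(length(alive_days), 0, sdlog))
  capped <- which(obs >= cfg$vol_cap_mm3)
  if (length(capped) > 0) {
    # record the measurement that crossed the burden cap, then stop follow-up
    keep <- seq_len(capped[1])
    alive_days <- alive_days[keep]; obs <- obs[keep]
  }
  w <- (2 * obs / 1.3)^(1 / 3)
  out <- tibble::tibble(
    animal_id = animal_id, study_day = alive_days,
    length_mm = 1.3 * w, width_mm = w,
    volume_mm3 = (1.3 * w) * w^2 / 2, alive = TRUE
  )
  dead_day <- meas_days[meas_days >= death_day]
  if (length(capped) == 0 && length(dead_day) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      animal_id = animal_id, study_day = dead_day[1],
      length_mm = NA_real_, width_mm = NA_real_,
      volume_mm3 = NA_real_, alive = FALSE
    ))
  }
  out
}

#' Simulate one study arm
#'
#' Generates per-animal caliper series for one arm of one model under the
#' growth model in [sim_config()]: staged piecewise-exponential growth,
#' cyclic treatment effect, lognormal measurement noise, attrition, and the
#' volume-cap / day-300 stopping rules. Randomness is drawn from the current
#' RNG state; seed upstream (e.g. `set.seed()` or [simulate_trial()]).
#'
#' @param cfg A [sim_config()].
#' @param model_id,arm_id Identifiers for the generated arm.
#' @param regimen Regimen name (`"vehicle"` for the control arm).
#' @param g_model Model-level growth rate (default: `cfg$growth_rate`).
#' @param effect Effect magnitude (delay-mode growth multiplier or
#'   regression-mode kill rate); 0 = no effect.
#' @param n_animals Number of animals (default from `cfg` by arm type).
#' @return A [study_arm()].
#' @export
simulate_arm <- function(cfg, model_id, regimen, arm_id = regimen,
                         g_model = cfg$growth_rate, effect = 0,
                         n_animals = NULL) {
  is_veh <- tolower(regimen) == "vehicle"
  if (is.null(n_animals)) {
    n_animals <- if (is_veh) cfg$n_vehicle else cfg$n_treated
  }
  schedule <- if (is_veh) NULL else study_schedules()[[regimen]]
  meas <- purrr::map_dfr(seq_len(n_animals), function(i) {
    g_animal <- g_model * exp(stats::rnorm(1, 0, cfg$animal_sdlog))
    simulate_animal(cfg, animal_id = sprintf("%s_%s_a%02d", model_id, arm_id, i),
                    g_animal = g_animal, schedule = schedule,
                    effect = effect, mode = cfg$effect_mode)
  })
  study_arm(model_id = model_id, arm_id = arm_id, regimen = regimen,
            measurements = meas, is_vehicle = is_veh, n_at_start = n_animals)
}

#' Simulate a full multi-model cohort with ground truth
#'
#' Draws per-model growth kinetics, a latent biomarker (promoter
#' methylation), and latent sensitivity per regimen, then generates a
#' vehicle arm plus one arm per requested regimen for every model. The
#' emitted ground truth allows recovery tests: a sensitive model's effect is
#' sized (delay mode) to stretch its quadrupling time by
#' `cfg$sensitive_ttq_multiplier`.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the output is fully reproducible from it.
#' @return List with `arms` (named list of [study_arm()]s), `truth` (tibble:
#'   `model_id`, `methylated`, one `sensitive_<regimen>` column per
#'   regimen), and `measurements` (all arms bound into one long tibble).
#' @export
simulate_trial <- function(cfg, seed = 1) {
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old(), add = TRUE)
  schedules <- study_schedules()
  truth <- tibble::tibble(
    model_id = sprintf("SIM%03d", seq_len(cfg$n_models)),
    g_model = cfg$growth_rate * exp(stats::rnorm(cfg$n_models, 0, cfg$model_sdlog)),
    methylated = stats::runif(cfg$n_models) < cfg$fraction_methylated
  )
  for (reg in cfg$regimens) {
    p <- if (reg == cfg$biomarker_regimen) {
      ifelse(truth$methylated, cfg$p_sensitive_methylated,
             cfg$p_sensitive_nonmethylated)
    } else {
      rep(cfg$p_sensitive_other, cfg$n_models)
    }
    truth[[paste0("sensitive_", reg)]] <- stats::runif(cfg$n_models) < p
  }
  arms <- list()
  for (i in seq_len(cfg$n_models)) {
    mid <- truth$model_id[i]
    arms[[paste0(mid, "/vehicle")]] <-
      simulate_arm(cfg, mid, "vehicle", g_model = truth$g_model[i])
    for (reg in cfg$regimens) {
      eff <- if (truth[[paste0("sensitive_", reg)]][i]) {
        if (cfg$effect_mode == "delay") {
          effect_for_ttq_multiplier(cfg$sensitive_ttq_multiplier,
                                    schedules[[reg]])
        } else {
          cfg$regression_kill_rate
        }
      } else 0
      arms[[paste0(mid, "/", reg)]] <-
        simulate_arm(cfg, mid, reg, g_model = truth$g_model[i], effect = eff)
    }
  }
  measurements <- purrr::map_dfr(arms, function(a) {
    dplyr::mutate(a$measurements, model_id = a$model_id, arm_id = a$arm_id,
                  regimen = a$regimen, .before = 1)
  })
  list(arms = arms, truth = truth, measurements = measurements)
}

#' Score a simulated trial with the response metrics
#'
#' Convenience wrapper: computes [efs_x4()] (and optionally
#' [classify_regression()]) for every treated arm of a [simulate_trial()]
#' result against its model's vehicle arm.
#'
#' @param trial Result of [simulate_trial()].
#' @param study_end_day Study horizon (default 300).
#' @param regression Also compute PR/CR calls (default FALSE).
#' @return Tibble with one row per model x regimen, joined to the ground
#'   truth columns.
#' @export
score_trial <- function(trial, study_end_day = 300, regression = FALSE) {
  treated <- trial$arms[!purrr::map_lgl(trial$arms, ~ .x$is_vehicle)]
  res <- purrr::map_dfr(treated, function(a) {
    veh <- trial$arms[[paste0(a$model_id, "/vehicle")]]
    out <- efs_x4(a, veh, study_end_day = study_end_day)
    if (regression) {
      out <- dplyr::bind_cols(
        out, dplyr::select(classify_regression(a), "pr", "cr", "duration_days")
      )
    }
    out
  })
  dplyr::left_join(res, trial$truth, by = "model_id")
}
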