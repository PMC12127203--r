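test_that("time to quadrupling interpolates log-linearly between measurements", {
  # exact threshold hit on a measurement day
  et <- time_to_quadrupling(c(0, 10), c(200, 800))
  expect_true(et$event_observed)
  expect_equal(et$time_days, 10)
  # overshoot: closed-form log-linear interpolation oracle 7*ln(4)/ln(4.5)
  et <- time_to_quadrupling(c(0, 7), c(200, 900))
  expect_equal(et$time_days, 7 * log(4) / log(4.5))
  # never quadruples: censored at study end
  days <- seq(0, 300, by = 3)
  et <- time_to_quadrupling(days, rep(250, length(days)), baseline = 200)
  expect_false(et$event_observed)
  expect_equal(et$time_days, 300)
  # overshoot across a single interval still interpolates on log volume
  et <- time_to_quadrupling(c(0, 3), c(200, 1000))
  expect_equal(et$time_days, 3 * log(4) / log(5))
  # first measurement of the series already at/above threshold: event there
  et <- time_to_quadrupling(c(3, 7), c(1000, 1200), baseline = 200)
  expect_equal(et$time_days, 3)
  expect_error(time_to_quadrupling(numeric(0), numeric(0)), "empty")
})

test_that("baseline is the measurement nearest day 0 at or before it", {
  et <- time_to_quadrupling(c(-4, -1, 3, 10), c(150, 200, 300, 805))
  expect_equal(et$baseline_volume_mm3, 200)
  # censoring stops at the last measurement while alive
  et <- time_to_quadrupling(c(0, 3, 7), c(200, 210, 900),
                            alive = c(TRUE, TRUE, FALSE))
  expect_false(et$event_observed)
  expect_equal(et$time_days, 3)
})

test_that("EFSx4 identities hold", {
  days <- seq(0, 42, by = 3.5)
  set.seed(5)
  vols <- purrr::map(1:6, ~ 200 * 2^(days / 7) * exp(rnorm(length(days), 0, 0.1)))
  names(vols) <- paste0("a", 1:6)
  veh <- make_arm(vols, days, regimen = "vehicle")
  expect_equal(efs_x4(structure(veh, class = "study_arm"), veh)$efs_x4, 1)
  # ratio definition: treated median 60 d vs vehicle 30 d -> 2.0, responder
  tr <- make_arm(list(a1 = c(200, 800)), c(0, 60), regimen = "x")
  vv <- make_arm(list(a1 = c(200, 800)), c(0, 30))
  res <- efs_x4(tr, vv, study_end_day = 300)
  expect_equal(res$efs_x4, 2)
  expect_true(res$responder)
  # with all animals censored at study end in both arms the ratio is 1
  flat <- function(reg) make_arm(
    purrr::map(setNames(1:4, paste0("a", 1:4)), ~ rep(250, 11)),
    seq(0, 300, by = 30), regimen = reg
  )
  res <- efs_x4(flat("x"), flat("vehicle"))
  expect_equal(res$efs_x4, 1)
  expect_false(res$responder)
})

test_that("EFSx4 is invariant under uniform time rescaling of both arms", {
  set.seed(6)
  days <- seq(0, 56, by = 3.5)
  mk <- function(scale, reg, vols) make_arm(vols, days * scale, regimen = reg)
  vols_v <- purrr::map(setNames(1:5, paste0("a", 1:5)),
                       ~ 200 * 2^(days / 7) * exp(rnorm(length(days), 0, 0.1)))
  vols_t <- purrr::map(setNames(1:5, paste0("a", 1:5)),
                       ~ 200 * 2^(days / 14) * exp(rnorm(length(days), 0, 0.1)))
  r1 <- efs_x4(mk(1, "x", vols_t), mk(1, "vehicle", vols_v))
  r3 <- efs_x4(mk(3, "x", vols_t), mk(3, "vehicle", vols_v),
               study_end_day = 900)
  expect_equal(r1$efs_x4, r3$efs_x4)
})

test_that("group percent change is the median over live animals", {
  arm <- make_arm(
    list(a1 = c(200, 120), a2 = c(100, 65), a3 = c(300, 330)),
    c(0, 7)
  )
  expect_equal(group_percent_change(arm, 7), -35)
  expect_equal(group_percent_change(arm, 0), 0)
  # dead animal excluded from the median
  arm2 <- make_arm(
    list(a1 = c(200, 120), a2 = c(100, 65), a3 = c(300, 330)),
    c(0, 7), dead_from = list(a3 = 7)
  )
  expect_equal(group_percent_change(arm2, 7), median(c(-40, -35)))
  expect_error(group_percent_change(make_arm(list(a1 = c(200, 100)), c(0, 7),
                                             dead_from = list(a1 = 7)), 7),
               "no live animal")
})

test_that("PR requires >= 2 consecutive qualifying days with 60% alive", {
  days <- c(0, 3, 7, 10)
  shrink <- function(p) purrr::map(setNames(1:5, paste0("a", 1:5)),
                                   ~ 200 * c(1, 1, 1 + p / 100, 1 + p / 100))
  # -35% at two consecutive days, all alive -> PR
  r <- classify_regression(make_arm(shrink(-35), days, regimen = "x"))
  expect_true(r$pr); expect_false(r$cr)
  expect_equal(r$duration_days, 3)
  expect_equal(c(r$pr_start_day, r$pr_end_day), c(7, 10))
  # one qualifying day only -> no PR
  one <- purrr::map(setNames(1:5, paste0("a", 1:5)),
                    ~ 200 * c(1, 1, 0.65, 1.1))
  expect_false(classify_regression(make_arm(one, days, regimen = "x"))$pr)
  # alive fraction 0.5 of n_at_start -> no PR even at -50%
  deep <- purrr::map(setNames(1:2, paste0("a", 1:2)),
                     ~ 200 * c(1, 1, 0.5, 0.5))
  arm <- make_arm(deep, days, regimen = "x", n_at_start = 4)
  expect_false(classify_regression(arm)$pr)
})

test_that("CR needs the median volume <= 60 under the same run conditions", {
  days <- c(0, 3, 7, 10)
  vols <- purrr::map(setNames(1:5, paste0("a", 1:5)),
                     ~ c(200, 150, 50, 40))
  r <- classify_regression(make_arm(vols, days, regimen = "x"))
  expect_true(r$cr); expect_true(r$pr)
  # same depths but only 50% alive on the qualifying days -> no CR
  arm <- make_arm(vols[1:2], days, regimen = "x", n_at_start = 4)
  expect_false(classify_regression(arm)$cr)
})

test_that("model response combines EFSx4 (any experiment) with regression", {
  efs_row <- function(r, qc = TRUE) tibble::tibble(
    model_id = "M", regimen = "x", n_treated = 8, n_vehicle = 16,
    median_treated_days = r * 20, median_vehicle_days = 20,
    efs_x4 = r, responder = qc & r >= 2, qc_pass = qc
  )
  reg <- function(pr) tibble::tibble(model_id = "M", regimen = "x",
                                     pr = pr, cr = FALSE,
                                     pr_start_day = NA, pr_end_day = NA,
                                     duration_days = 0)
  expect_true(call_model_response(efs_row(2.5), reg(FALSE))$responder)
  r <- call_model_response(efs_row(1.4), reg(TRUE))
  expect_true(r$responder); expect_false(r$efs_response)
  expect_false(call_model_response(efs_row(1.4), reg(FALSE))$responder)
  # repeat experiments: responder if any experiment passes
  multi <- dplyr::bind_rows(efs_row(1.5), efs_row(2.2))
  expect_true(call_model_response(multi, reg(FALSE))$responder)
  # qc failure suppresses an above-threshold ratio
  expect_false(call_model_response(efs_row(2.5, qc = FALSE), reg(FALSE))$responder)
})
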