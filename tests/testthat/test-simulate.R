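test_that("dosing schedules expose on-days, cycling, and on-fractions", {
  s <- dosing_schedule(0:4, 28)
  expect_true(all(is_dosing_day(s, c(0, 4, 28, 32))))
  expect_false(any(is_dosing_day(s, c(5, 27, 33))))
  expect_equal(on_fraction(s), 5 / 28)
  expect_error(dosing_schedule(integer(0), 28))
  expect_error(dosing_schedule(28, 28))
  # effect sizing: continuous schedule, target doubling -> multiplier 0.5
  expect_equal(effect_for_ttq_multiplier(2, dosing_schedule(0:27, 28)), 0.5)
})

test_that("same seed gives byte-identical trials", {
  cfg <- sim_config(n_models = 3)
  a <- simulate_trial(cfg, seed = 9)
  b <- simulate_trial(cfg, seed = 9)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$truth, b$truth)
  c <- simulate_trial(cfg, seed = 10)
  expect_false(identical(a$measurements, c$measurements))
})

test_that("noiseless exponential vehicle quadruples in exactly 14 days at g = ln(2)/7", {
  cfg <- sim_config(cv = 0, death_hazard = 0, animal_sdlog = 0, model_sdlog = 0)
  set.seed(1)
  veh <- simulate_arm(cfg, "M1", "vehicle")
  et <- arm_event_times(veh)
  expect_equal(et$time_days, rep(14, cfg$n_vehicle))
  expect_true(all(et$event_observed))
})

test_that("staging puts the day-0 median volume near the 200 mm^3 target", {
  set.seed(12)
  cfg <- sim_config(n_models = 1, n_vehicle = 30)
  veh <- simulate_arm(cfg, "M1", "vehicle")
  day0 <- dplyr::filter(veh$measurements, study_day == 0)
  expect_equal(nrow(day0), 30)
  expect_lt(abs(median(day0$volume_mm3) / cfg$staging_volume_mm3 - 1), 0.15)
})

test_that("no measurement after death or burden cap; days within [0, 300]", {
  cfg <- sim_config(n_models = 2, death_hazard = 0.01, study_end_day = 300)
  trial <- simulate_trial(cfg, seed = 13)
  m <- trial$measurements
  expect_true(all(m$study_day >= 0 & m$study_day <= 300))
  per_animal <- m |>
    dplyr::group_by(animal_id) |>
    dplyr::summarise(
      dead_rows = sum(!alive),
      dead_is_last = all(alive) || (!alive[dplyr::n()] && all(alive[-dplyr::n()])),
      cap_rows = sum(volume_mm3 >= 4000, na.rm = TRUE),
      cap_is_last = cap_rows == 0 ||
        (which(volume_mm3 >= 4000)[1] == dplyr::n())
    )
  expect_true(all(per_animal$dead_rows <= 1))
  expect_true(all(per_animal$dead_is_last))
  expect_true(all(per_animal$cap_is_last))
})

test_that("latent methylation prevalence matches its binomial target", {
  cfg <- sim_config(n_models = 200, n_vehicle = 2, n_treated = 1,
                    study_end_day = 30, fraction_methylated = 0.22)
  trial <- simulate_trial(cfg, seed = 14)
  p_hat <- mean(trial$truth$methylated)
  se <- sqrt(0.22 * 0.78 / 200)
  expect_lt(abs(p_hat - 0.22), 3 * se)
})

test_that("EFSx4 is monotone non-decreasing in the growth-suppression effect", {
  cfg <- sim_config(cv = 0, death_hazard = 0, animal_sdlog = 0, model_sdlog = 0)
  set.seed(15)
  veh <- simulate_arm(cfg, "M1", "vehicle")
  ratios <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(eff) {
    efs_x4(simulate_arm(cfg, "M1", "trametinib", effect = eff), veh)$efs_x4
  }, numeric(1))
  expect_true(all(diff(ratios) >= 0))
  expect_equal(ratios[1], 1)
})

test_that("a null-effect regimen is indistinguishable from vehicle", {
  cfg <- sim_config(n_vehicle = 16, n_treated = 16)
  set.seed(16)
  veh <- simulate_arm(cfg, "M1", "vehicle")
  tr <- simulate_arm(cfg, "M1", "trametinib", effect = 0)
  res <- efs_x4(tr, veh)
  expect_lt(abs(res$efs_x4 - 1), 0.35)
  w <- wilcox.test(arm_event_times(tr)$time_days,
                   arm_event_times(veh)$time_days, exact = FALSE)
  expect_gt(w$p.value, 0.01)
})

test_that("an effect sized to double quadrupling time lands near EFSx4 = 2", {
  cfg <- sim_config()
  eff <- effect_for_ttq_multiplier(2, dosing_schedule(0:27, 28))
  ratios <- vapply(1:20, function(s) {
    set.seed(100 + s)
    veh <- simulate_arm(cfg, "M1", "vehicle")
    tr <- simulate_arm(cfg, "M1", "trametinib", effect = eff)
    efs_x4(tr, veh)$efs_x4
  }, numeric(1))
  expect_gt(mean(ratios), 1.8)
  expect_lt(mean(ratios), 2.2)
})

test_that("regression mode with a strong kill rate produces a PR in cycle 1", {
  cfg <- sim_config(cv = 0, death_hazard = 0, animal_sdlog = 0,
                    effect_mode = "regression")
  set.seed(17)
  arm <- simulate_arm(cfg, "M1", "velip_tmz", effect = log(2) / 4)
  r <- classify_regression(arm)
  expect_true(r$pr)
  expect_lte(r$pr_start_day, 28)
})

test_that("downstream Fisher power grows with cohort size", {
  pvals <- vapply(c(30, 120), function(n) {
    cfg <- sim_config(n_models = n, n_vehicle = 2, n_treated = 1,
                      study_end_day = 30,
                      p_sensitive_methylated = 0.9,
                      p_sensitive_nonmethylated = 0.05)
    trial <- simulate_trial(cfg, seed = 18)
    # latent sensitivity stands in for the scored response call here;
    # the growth layer is exercised by the recovery tests
    tab <- build_contingency(
      tibble::tibble(model_id = trial$truth$model_id,
                     status = trial$truth$methylated),
      tibble::tibble(model_id = trial$truth$model_id,
                     responder = trial$truth$sensitive_velip_tmz)
    )
    fisher_exact_two_sided(tab)$p_two_sided
  }, numeric(1))
  expect_lt(pvals[2], pvals[1])
})
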