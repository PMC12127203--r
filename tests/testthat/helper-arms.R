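# build a study_arm from a named list of per-animal volume vectors measured
# at common days; all animals alive unless listed in `dead_from` (day from
# which the animal is marked dead, volume NA)
make_arm <- function(volumes, days, model_id = "M1", arm_id = "arm",
                     regimen = "vehicle", dead_from = list(),
                     n_at_start = NULL) {
  meas <- purrr::imap_dfr(volumes, function(v, id) {
    stopifnot(length(v) == length(days))
    alive <- rep(TRUE, length(days))
    vol <- v
    if (!is.null(dead_from[[id]])) {
      dead <- days >= dead_from[[id]]
      alive[dead] <- FALSE
      vol[dead] <- NA_real_
    }
    tibble::tibble(animal_id = id, study_day = days,
                   volume_mm3 = vol, alive = alive)
  })
  study_arm(model_id = model_id, arm_id = arm_id, regimen = regimen,
            measurements = meas, n_at_start = n_at_start)
}

# brute-force two-sided Fisher p by direct enumeration of binomial
# coefficients (no log-space, independent of the implementation path)
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  k <- max(0, c1 - r2):min(r1, c1)
  pk <- choose(r1, k) * choose(r2, c1 - k) / choose(n, c1)
  min(1, sum(pk[pk <= pk[k == a] * (1 + 1e-7)]))
}
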