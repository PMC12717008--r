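test_that("blood volume and circulating iron follow the stated conventions", {
  expect_equal(blood_volume(160, 55), 3.461, tolerance = 1e-3)
  expect_equal(blood_volume(170, 60), 3.918, tolerance = 1e-3)
  expect_error(blood_volume(0, 55), "positive")
  expect_error(blood_volume(160, 55, formula = "nosuch"), "unknown")
  expect_equal(circulating_iron(3.461, 130), 1561.3, tolerance = 1e-4)
  expect_equal(circulating_iron(5, 0), 0)
  expect_equal(circulating_iron(1, 100), 347)
  expect_error(circulating_iron(-1, 100), "non-negative")
})

test_that("mixing-model inversion recovers known tracer increments", {
  nat <- natural_iron_pattern()
  trs <- default_tracer_patterns()
  total <- 0.028 # mol, ~1.56 g circulating iron

  # no isotopic shift, no incorporated tracer
  z <- solve_tracer_increments(nat, nat, trs, total)
  expect_true(all(abs(z$q_mol) < 1e-15 * total))

  # single tracer at q/N = 0.01, noiseless round trip < 1e-10 relative
  q57 <- 0.01 * total
  mix <- ((total - q57) * unclass(nat) + q57 * unclass(trs[["57Fe"]])) / total
  m <- ferrotrace:::as_iso_pattern(mix, tol = 1e-6)
  got <- solve_tracer_increments(m, nat, trs["57Fe"], total)
  expect_lt(abs(got$q_mol[["57Fe"]] / q57 - 1), 1e-10)

  # three tracers simultaneously at distinct small fractions, < 1e-8 relative
  q <- c(`54Fe` = 0.004, `57Fe` = 0.009, `58Fe` = 0.002) * total
  mix3 <- (total - sum(q)) * unclass(nat)
  for (lab in names(q)) mix3 <- mix3 + q[[lab]] * unclass(trs[[lab]])
  m3 <- ferrotrace:::as_iso_pattern(mix3 / total, tol = 1e-6)
  got3 <- solve_tracer_increments(m3, nat, trs, total)
  expect_true(all(abs(got3$q_mol / q - 1) < 1e-8))

  # ratio-space and abundance-space solvers agree on noiseless data
  gotA <- solve_tracer_increments(m3, nat, trs, total, space = "abundance")
  expect_true(all(abs(gotA$q_mol - got3$q_mol) < 1e-6 * total))

  # homogeneity: doubling the pool size doubles every increment
  got2x <- solve_tracer_increments(m3, nat, trs, 2 * total)
  expect_equal(unname(got2x$q_mol), unname(2 * got3$q_mol),
               tolerance = 1e-10)

  # a dosed-but-unabsorbed tracer leaves the other estimates unchanged
  m57 <- solve_tracer_increments(m, nat, trs[c("57Fe", "54Fe")], total)
  expect_lt(abs(m57$q_mol[["57Fe"]] / q57 - 1), 1e-8)
  expect_lt(abs(m57$q_mol[["54Fe"]]), 1e-10 * total)

  # degenerate tracer pattern (equal to baseline) is ill-conditioned
  expect_error(solve_tracer_increments(m, nat, list(x = nat), total),
               "ill-conditioned")
})

test_that("FIA inversion is invariant to pattern rescaling before renormalization", {
  nat <- natural_iron_pattern()
  trs <- default_tracer_patterns()
  total <- 0.028
  q57 <- 0.005 * total
  mix <- ((total - q57) * unclass(nat) + q57 * unclass(trs[["57Fe"]])) / total
  scaled <- ferrotrace:::as_iso_pattern((3.7 * mix) / sum(3.7 * mix),
                                        tol = 1e-6)
  plain <- ferrotrace:::as_iso_pattern(mix, tol = 1e-6)
  a <- solve_tracer_increments(plain, nat, trs["57Fe"], total)$q_mol
  b <- solve_tracer_increments(scaled, nat, trs["57Fe"], total)$q_mol
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("FIA follows the incorporation model and flags impossible values", {
  trs <- default_tracer_patterns()
  cfg <- absorption_config()
  expect_equal(fia_from_increment(0, 4, trs[["57Fe"]], cfg)$fia, 0)
  dose_mol <- 4 / (1000 * pattern_molar_mass(trs[["57Fe"]]))
  got <- fia_from_increment(0.8 * 0.20 * dose_mol, 4, trs[["57Fe"]],
                            absorption_config(incorporation_factor = 0.8))
  expect_equal(got$fia, 0.20, tolerance = 1e-12)
  expect_false(got$flag_gt1)
  big <- fia_from_increment(1.2 * 0.8 * dose_mol, 4, trs[["57Fe"]], cfg)
  expect_equal(big$fia, 1.2, tolerance = 1e-12)
  expect_true(big$flag_gt1)
  expect_error(fia_from_increment(0.1, 0, trs[["57Fe"]], cfg), "positive")
})

test_that("a noiseless trial inverts to the generating truth exactly", {
  tr <- quick_trial(n = 6, seed = 21, noise = 0, gsd = exp(0.3),
                    person_sd = 0.4)
  expect_equal(nrow(tr$merged), 36)
  expect_true(all(abs(tr$merged$fia / tr$merged$true_fia - 1) < 1e-9))
})

test_that("participants missing a sampling day are skipped with a reason", {
  tr <- quick_trial(n = 3, seed = 13, noise = 0, gsd = exp(0.2))
  m <- tr$sim$measurements
  drop_pid <- m$participant_id[1]
  m <- m[!(m$participant_id == drop_pid & m$day == 37), ]
  rec <- process_trial(m, tr$sim$design, tr$sim$cohort)
  expect_equal(sum(rec$participant_id == drop_pid), 3)
  expect_equal(nrow(rec), 15)
  skipped <- attr(rec, "skipped")
  expect_equal(skipped$participant_id, drop_pid)
  expect_match(skipped$reason, "37")
})

test_that("eligibility screening applies every threshold and is monotone", {
  ok <- list(sf_ug_l = 40, hb_g_l = 125, height_cm = 165, weight_kg = 60,
             age_y = 25, crp_mg_l = 1) # BMI 22.0
  expect_true(check_eligibility(ok)$eligible)
  cases <- list(
    list(field = "sf_ug_l", value = 55, reason = "SF"),
    list(field = "hb_g_l", value = 119.9, reason = "anaemia"),
    list(field = "weight_kg", value = 75, reason = "weight"),
    list(field = "age_y", value = 46, reason = "age"),
    list(field = "crp_mg_l", value = 6, reason = "inflammation"),
    list(field = "height_cm", value = 140, reason = "BMI")
  )
  for (cs in cases) {
    bad <- ok
    bad[[cs$field]] <- cs$value
    got <- check_eligibility(bad)
    expect_false(got$eligible)
    expect_true(cs$reason %in% got$reasons)
  }
  expect_error(check_eligibility(ok[-1]), "sf_ug_l")

  # monotone: worsening any single field never rescues an excluded record
  set.seed(404)
  worsen <- list(sf_ug_l = 10, hb_g_l = -10, weight_kg = 5, age_y = 5,
                 crp_mg_l = 2)
  for (i in 1:50) {
    rec <- list(sf_ug_l = runif(1, 20, 80), hb_g_l = runif(1, 100, 140),
                height_cm = 160, weight_kg = runif(1, 45, 80),
                age_y = runif(1, 16, 50), crp_mg_l = runif(1, 0, 8))
    if (check_eligibility(rec)$eligible) next
    f <- sample(names(worsen), 1)
    rec[[f]] <- rec[[f]] + worsen[[f]]
    expect_false(check_eligibility(rec)$eligible)
  }
})
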