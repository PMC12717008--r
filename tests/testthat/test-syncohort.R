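test_that("participant generation is deterministic and respects priors", {
  s <- cohort_spec(n_participants = 52, seed = 7)
  a <- generate_participants(s)
  b <- generate_participants(s)
  expect_identical(a, b)
  expect_equal(nrow(a), 52)
  expect_true(all(c("participant_id", "age_y", "height_cm", "weight_kg",
                    "hb_g_l", "sf_ug_l", "crp_mg_l") %in% names(a)))
  # law of large numbers on the haemoglobin prior
  big <- generate_participants(cohort_spec(n_participants = 2000, seed = 2,
                                           hb_prior = c(130, 10)))
  expect_lt(abs(mean(big$hb_g_l) - 130), 1)
  expect_error(cohort_spec(n_participants = 0), "at least 1")
  expect_error(cohort_spec(hb_prior = c(130, 0)), "positive")
})

test_that("cross-over design uses each tracer once per phase, uniformly", {
  d1 <- assign_crossover_design("P1", seed = 5)
  for (ph in 1:2) {
    expect_setequal(d1$tracer[d1$phase == ph], c("54Fe", "57Fe", "58Fe"))
  }
  expect_true(all(d1$day[d1$phase == 1] %in% c(1, 3, 5)))
  expect_true(all(d1$day[d1$phase == 2] %in% c(19, 21, 23)))
  expect_true(all(d1$matrix[d1$phase == 1] == "water"))
  expect_true(all(d1$matrix[d1$phase == 2] == "acai"))
  expect_error(assign_crossover_design(c("a", "a")), "duplicate")
  expect_error(assign_crossover_design(character(0)), "empty")

  # each of the 6 phase-1 orderings occurs with frequency 1/6 +/- 0.05
  d <- assign_crossover_design(sprintf("P%03d", 1:600), seed = 3)
  p1 <- d[d$phase == 1, ]
  p1 <- p1[order(p1$participant_id, p1$day), ]
  orderings <- tapply(p1$compound, p1$participant_id, paste, collapse = ">")
  freq <- table(orderings) / 600
  expect_equal(length(freq), 6)
  expect_true(all(abs(freq - 1 / 6) < 0.05))
})

test_that("true absorption draws follow the lognormal person/condition model", {
  design <- assign_crossover_design(sprintf("P%02d", 1:3), seed = 1)
  # zero-noise degeneracy: every participant gets exactly the condition GM
  tr0 <- toy_truths(gsd = 1, person_sd = 0)
  got <- generate_true_fia(design, tr0, seed = 9)
  expect_equal(got$true_fia,
               tr0$gm_fia[match(got$condition_id, tr0$condition_id)])
  # large-n geometric mean recovers the generating GM
  big <- assign_crossover_design(sprintf("P%04d", 1:5000), seed = 2)
  trb <- toy_truths(gsd = exp(0.4), person_sd = 0)
  trb$gm_fia <- 0.262
  gotb <- generate_true_fia(big, trb, seed = 3, truncate_at = 0.9999)
  sa <- gotb$true_fia[gotb$condition_id == "OatNF-SA-Fe|water"]
  expect_lt(abs(mean(log(sa)) - log(0.262)), 0.02)
  # missing condition truth is an error naming the condition
  expect_error(generate_true_fia(design, tr0[-1, ], seed = 1),
               tr0$condition_id[1], fixed = TRUE)
})

test_that("forward simulation preserves mass balance and normalization", {
  n <- 4
  cohort <- generate_participants(cohort_spec(n_participants = n, seed = 8))
  design <- assign_crossover_design(cohort$participant_id, seed = 8)
  # zero absorption, zero noise: every pattern stays at natural abundance
  design$true_fia <- 0
  m0 <- forward_simulate_measurements(cohort, design, noise_sd_rel = 0,
                                      seed = 1)
  nat <- unclass(natural_iron_pattern())
  for (d in c(1, 19, 37)) {
    rows <- m0[m0$day == d, c("a54", "a56", "a57", "a58")]
    expect_true(all(abs(t(rows) - nat) < 1e-12))
  }
  # simulated abundance patterns sum to 1 within 1e-12
  tr <- toy_truths(gsd = exp(0.3), person_sd = 0.3)
  dt <- generate_true_fia(design[setdiff(names(design), "true_fia")], tr,
                          seed = 4)
  m <- forward_simulate_measurements(cohort, dt, noise_sd_rel = 5e-4, seed = 5)
  expect_true(all(abs(rowSums(m[c("a54", "a56", "a57", "a58")]) - 1) < 1e-12))
  # same seed regenerates identical tables
  m2 <- forward_simulate_measurements(cohort, dt, noise_sd_rel = 5e-4,
                                      seed = 5)
  expect_identical(m, m2)
  # unphysical absorption (tracer >= circulating pool) is refused
  heavy <- dt
  heavy$true_fia <- 0.95
  tiny <- cohort
  tiny$hb_g_l <- 0.001 # near-zero circulating iron
  expect_error(forward_simulate_measurements(tiny, heavy, noise_sd_rel = 0,
                                             seed = 1),
               "circulating iron")
  # unknown tracer label is refused
  bad <- dt
  bad$tracer[1] <- "60Fe"
  expect_error(forward_simulate_measurements(cohort, bad, seed = 1), "60Fe")
})

test_that("recovered GMs stay inside the sampling band across replicates", {
  # coverage-style check: with ratio noise 5e-4 and n = 52, the per-trial GM
  # of recovered FIA falls within gm * exp(+/- 2 ln(gsd) / sqrt(52)) in at
  # least 90% of replicate trials (person effect off, so gsd is the full
  # between-participant dispersion)
  gsd <- exp(0.25)
  truths <- toy_truths(gsd = gsd, person_sd = 0)
  n_rep <- 200
  cond <- "OatNF-SA-Fe|water"
  gm_true <- truths$gm_fia[truths$condition_id == cond]
  band <- 2 * log(gsd) / sqrt(52)
  hits <- vapply(seq_len(n_rep), function(i) {
    tr <- quick_trial(n = 52, seed = 1000 + i, noise = 5e-4, truths = truths)
    g <- exp(mean(log(tr$records$fia[tr$records$condition_id == cond])))
    abs(log(g) - log(gm_true)) <= band
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
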