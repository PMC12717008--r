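# shared fixtures: small trials and truth tables built in code

# truth table with a single shared dispersion, defaults to no person effect
toy_truths <- function(gsd = 1, person_sd = 0) {
  default_condition_truths(gsd_fia = gsd, person_effect_sd = person_sd)
}

# simulate and invert a complete trial; returns records merged with truth
quick_trial <- function(n = 6, seed = 11, noise = 0, gsd = 1, person_sd = 0,
                        truths = toy_truths(gsd, person_sd)) {
  sim <- simulate_trial(cohort_spec(n_participants = n, seed = seed),
                        truths = truths, noise_sd_rel = noise)
  rec <- process_trial(sim$measurements, sim$design, sim$cohort)
  list(sim = sim,
       merged = merge(rec, sim$design[c("participant_id", "condition_id",
                                        "true_fia")]),
       records = rec)
}

# brute-force pairwise R-Index oracle: compare every (test, ref) rating pair
r_index_bruteforce <- function(test_counts, ref_counts) {
  k <- length(test_counts)
  # expand counts to individual ratings, category 1 = most "different"
  t_r <- rep(seq_len(k), test_counts)
  r_r <- rep(seq_len(k), ref_counts)
  score <- 0
  for (t in t_r) for (r in r_r) {
    score <- score + if (t < r) 1 else if (t == r) 0.5 else 0
  }
  100 * score / (length(t_r) * length(r_r))
}
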