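test_that("roster expands outcome counts with exclusion and placement flags", {
  cfg <- default_cohort_config()
  roster <- build_roster(cfg)
  expect_equal(nrow(roster), 48L)
  expect_equal(sum(roster$excluded), 8L)
  expect_equal(sum(!roster$excluded), 40L)
  expect_true(all(is.na(roster$placed[roster$excluded])))
  expect_equal(sum(roster$placed, na.rm = TRUE), 30L)

  tiny <- cohort_config(list(
    outcome_counts = c(service_dog = 3, behavioral_release = 1),
    conditions = "ramp"))
  r2 <- build_roster(tiny)
  expect_equal(nrow(r2), 4L)
  expect_equal(sum(r2$placed), 3L)

  empty <- cohort_config(list(outcome_counts = NULL, conditions = "ramp"))
  expect_equal(nrow(build_roster(empty)), 0L)

  expect_error(cohort_config(list(outcome_counts = c(a = -1))),
               "configuration error")
})

test_that("trial plans are reproducible, respect the zero flag, and never overlap", {
  profile <- wide_profile()
  set.seed(7); p1 <- plan_trial(profile, "ramp")
  set.seed(7); p2 <- plan_trial(profile, "ramp")
  expect_identical(p1, p2)

  z <- plan_trial(profile, "human", zero_interaction = TRUE)
  expect_true(z$zero_interaction)
  expect_equal(z$interaction_time, 0)
  expect_length(z$bite_onsets, 0L)

  set.seed(3)
  for (i in 1:50) {
    p <- plan_trial(profile, "ramp")
    expect_true(all(diff(p$bite_onsets) > 0))
    k <- length(p$bite_onsets)
    if (k > 1L) {
      expect_true(all(p$bite_onsets[-k] + p$bite_durations[-k] <=
                        p$bite_onsets[-1L]))
    }
    expect_true(all(p$bite_durations >= profile$duration_min))
    expect_true(all(p$bite_peaks >= profile$peak_min &
                      p$bite_peaks <= profile$peak_max))
  }

  bad <- wide_profile(); bad$duration_min <- 3; bad$duration_max <- 1
  expect_error(plan_trial(bad, "ramp"), "configuration error")
})

test_that("planned bite durations follow the configured truncated lognormal", {
  profile <- wide_profile(duration_mean = 0.21)
  set.seed(101)
  durs <- numeric(0)
  while (length(durs) < 1e4) {
    durs <- c(durs, plan_trial(profile, "ramp")$bite_durations)
  }
  oracle <- trunc_lnorm_mean(profile$duration_meanlog, profile$duration_sdlog,
                             profile$duration_min, profile$duration_max)
  expect_equal(oracle, 0.21, tolerance = 0.01)
  se <- sd(durs) / sqrt(length(durs))
  expect_lt(abs(mean(durs) - oracle), 3 * se + 1e-12)
  # and within 3 SE of the nominal 0.21 s mean (truncation shift is tiny)
  expect_lt(abs(mean(durs) - 0.21), 3 * se + abs(oracle - 0.21))
})

test_that("synthesized streams realize the plan: quiet baseline, exact pulses, ordered truth", {
  acq <- list(sample_rate = 100, baseline_pressure = 101.5, noise_sd = 0.05)
  set.seed(5)
  zero <- synthesize_stream(plan_trial(wide_profile(), "ramp", TRUE), acq)
  expect_equal(nrow(zero$events), 0L)
  expect_lt(max(abs(zero$stream$data$pressure_kpa - 101.5)), 5 * 0.05)

  one <- structure(list(condition = "ramp", zero_interaction = FALSE,
                        interaction_time = 3, bite_onsets = 1,
                        bite_durations = 0.5, bite_peaks = 120),
                   class = "trial_plan")
  syn <- synthesize_stream(one, list(sample_rate = 100,
                                     baseline_pressure = 101.5,
                                     noise_sd = 1e-9))
  p <- syn$stream$data$pressure_kpa
  expect_equal(max(p), 120, tolerance = 1e-6)
  span <- sum(p >= 101.5 + 2) / 100
  expect_lt(abs(span - 0.5), 0.02 + 1e-9)

  two <- structure(list(condition = "ramp", zero_interaction = FALSE,
                        interaction_time = 5, bite_onsets = c(1, 3),
                        bite_durations = c(0.3, 0.3),
                        bite_peaks = c(115, 118)),
                   class = "trial_plan")
  syn2 <- synthesize_stream(two, acq)
  expect_equal(nrow(syn2$events), 2L)
  expect_true(all(diff(syn2$events$onset_s) > 0))
  expect_equal(syn2$events$onset_s, c(1, 3), tolerance = 0.011)
})

test_that("cohort generation hits exact design counts, conserves bites, and is deterministic", {
  cfg <- small_config()
  man <- generate_cohort(cfg)
  # 4 dogs x 2 conditions x 3 trials
  expect_equal(nrow(man$annotations), 24L)
  expect_equal(length(man$streams), 24L)
  zt <- man$truth_trials
  analyzable <- man$roster$dog_id[!man$roster$excluded]
  expect_equal(sum(zt$zero_interaction & zt$condition == "ramp" &
                     zt$dog_id %in% analyzable), 2L)
  expect_equal(sum(zt$zero_interaction & zt$condition == "human" &
                     zt$dog_id %in% analyzable), 1L)
  # conservation: per-trial event rows match recorded counts
  ev_counts <- table(sprintf("%s_%s_%02d", man$truth_events$dog_id,
                             man$truth_events$condition,
                             man$truth_events$trial_index))
  for (i in seq_len(nrow(zt))) {
    key <- sprintf("%s_%s_%02d", zt$dog_id[i], zt$condition[i],
                   zt$trial_index[i])
    n_ev <- if (key %in% names(ev_counts)) as.integer(ev_counts[[key]]) else 0L
    expect_equal(zt$n_bites[i], n_ev, info = key)
  }

  man2 <- generate_cohort(cfg)
  expect_identical(man$truth_events, man2$truth_events)
  expect_identical(man$streams[[1]]$data, man2$streams[[1]]$data)

  single <- cohort_config(list(
    outcome_counts = c(service_dog = 1), conditions = "ramp",
    trials_per_condition = 1L, seed = 2,
    class_params = list(placed = list(ramp = wide_profile()))))
  m1 <- generate_cohort(single)
  expect_equal(length(m1$streams), 1L)

  infeasible <- small_config(zero = c(ramp = 100, human = 0))
  expect_error(generate_cohort(infeasible), "infeasible")
})

test_that("cohort files round-trip through the documented CSV layout", {
  cfg <- small_config(seed = 12)
  dir <- withr::local_tempdir()
  man <- generate_cohort(cfg, out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "roster.csv")))
  roster <- utils::read.csv(file.path(dir, "roster.csv"))
  expect_equal(names(roster), c("dog_id", "outcome", "placed", "excluded"))
  s <- read_stream(man$streams[[1L]])
  expect_s3_class(s, "sensor_stream")
  expect_equal(length(s), nrow(s$data))
})
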