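# Monte-Carlo trial engine, summaries, and the symphysis-tilt experiment.

test_that("a zero-noise trial is perfect and metrics vanish", {
  trial <- run_trial(trial_config(n_pelves = 3, noise = zero_noise(), seed = 2))
  s <- trial$screws
  expect_equal(nrow(s), 12)
  expect_true(all(s$correct))
  expect_lt(max(s$mld_mm), 1e-6)
  expect_lt(max(s$entry_dev_mm), 1e-6)
  expect_lt(max(s$angular_dev_deg), 1e-6)
})

test_that("trials are deterministic for a fixed seed", {
  cfg <- trial_config(n_pelves = 4, seed = 99)
  t1 <- run_trial(cfg)
  t2 <- run_trial(cfg)
  expect_identical(t1$screws, t2$screws)
  t3 <- run_trial(trial_config(n_pelves = 4, seed = 100))
  expect_false(identical(t1$screws, t3$screws))
})

test_that("the registration error is shared within each pelvis", {
  trial <- run_trial(trial_config(n_pelves = 5, seed = 3))
  per_pelvis <- tapply(trial$screws$reg_rotation_deg, trial$screws$pelvis,
                       function(x) diff(range(x)))
  expect_true(all(per_pelvis == 0))
})

test_that("summaries match independent statistics computations", {
  trial <- run_trial(trial_config(n_pelves = 6, seed = 8))
  s <- trial$screws
  summ <- summarize_trial(trial)
  for (type in c("S1", "S2")) {
    sub <- s[s$screw_type == type, ]
    row <- summ$by_type[summ$by_type$screw_type == type, ]
    expect_equal(row$correct_rate, mean(sub$correct))
    expect_equal(row$mld_median_mm, median(sub$mld_mm))
    expect_equal(row$angular_median_deg, median(sub$angular_dev_deg))
    q <- quantile(sub$entry_dev_mm, c(0.25, 0.75), names = FALSE)
    expect_equal(row$entry_iqr, sprintf("%.1f-%.1f", q[1], q[2]))
  }
  expect_equal(sum(summ$direction_histogram$n_screws), sum(s$perforated))
  # Mann-Whitney cross-check against a direct call
  w <- suppressWarnings(wilcox.test(
    s$mld_mm[s$screw_type == "S1"], s$mld_mm[s$screw_type == "S2"],
    exact = FALSE))
  row <- summ$comparisons[summ$comparisons$metric == "mld_mm", ]
  expect_equal(row$p_value, w$p.value)
})

test_that("degenerate summary inputs behave sensibly", {
  expect_error(summarize_trial(tibble::tibble()), "empty")
  one <- run_trial(trial_config(n_pelves = 1, seed = 5))$screws[1, ]
  summ <- summarize_trial(one)
  expect_equal(summ$by_type$mld_median_mm, one$mld_mm)
  same <- dplyr::bind_rows(one, one, one)
  summ2 <- summarize_trial(same)
  expect_equal(summ2$by_type$mld_iqr,
               sprintf("%.1f-%.1f", one$mld_mm, one$mld_mm))
})

test_that("shared-direction flag detects concordant perforations", {
  expect_true(shared_direction_flag_test(c("anterior", "anterior,superior")))
  expect_false(shared_direction_flag_test(c("anterior", "posterior")))
  expect_true(is.na(shared_direction_flag_test("anterior")))
})

test_that("correct rate decreases with landmark noise (coarse grid)", {
  rates <- vapply(c(0.5, 4), function(sig) {
    trial <- run_trial(trial_config(
      n_pelves = 40, noise = noise_model(sig, 0, 0.5, 0.5), seed = 21))
    mean(trial$screws$correct)
  }, numeric(1))
  expect_gt(rates[1], rates[2])
})

test_that("pure anterior symphysis bias tilts the registration about the inter-ASIS axis", {
  cfg <- trial_config(n_pelves = 20, noise = zero_noise(), seed = 12)
  tilt <- symphysis_tilt_experiment(c(0, 10), cfg)
  sweep <- tilt$sweep
  expect_equal(sweep$s1_correct_rate[1], 1)
  expect_equal(sweep$s2_correct_rate[1], 1)
  expect_equal(sweep$s1_n_perforated[1], 0)
  # the induced rotation axis is essentially the inter-ASIS axis
  expect_lt(sweep$axis_angle_to_interasis_deg[2], 5)
  expect_gt(sweep$rotation_deg[2], 0.5)
})

test_that("the narrow S2 corridor fails before S1 as the bias grows", {
  cfg <- trial_config(n_pelves = 30, noise = zero_noise(), seed = 14)
  tilt <- symphysis_tilt_experiment(c(0, 4, 8, 12, 16, 20), cfg)
  sw <- tilt$sweep
  expect_true(all(sw$s2_correct_rate <= sw$s1_correct_rate + 1e-9))
  # S2 perforations carry an anterior component
  with_perf <- sw[!is.na(sw$s2_anterior_fraction) & sw$s2_n_perforated > 0, ]
  expect_true(nrow(with_perf) > 0)
  expect_true(all(with_perf$s2_anterior_fraction >= 0.9))
})

test_that("plot methods return ggplot objects", {
  trial <- run_trial(trial_config(n_pelves = 3, seed = 6))
  expect_s3_class(autoplot(trial), "ggplot")
  tilt <- symphysis_tilt_experiment(c(0, 5),
                                    trial_config(n_pelves = 3, seed = 6))
  expect_s3_class(autoplot(tilt), "ggplot")
  expect_s3_class(tidy(trial), "tbl_df")
  expect_s3_class(tidy(tilt), "tbl_df")
  expect_s3_class(glance(trial), "tbl_df")
})
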