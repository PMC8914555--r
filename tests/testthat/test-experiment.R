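# Small shared fixture: generated once per test file, modest size so the
# grid stays fast (hidden-size search capped at 30 where the full 1..100
# range is not the point of the test).
small_profiles <- generate_profiles(config = generator_config(n_per_class = 12,
                                                              seed = 301))
fast_opts <- list(l_range = c(1L, 30L))

test_that("the configuration key grid is the 24-cell factorial", {
  keys <- config_keys()
  expect_equal(nrow(keys), 24L)
  expect_equal(nrow(unique(keys[, -1])), 24L)
  expect_equal(sort(unique(keys$activation)), c("hardlim", "sig", "sin"))
  expect_equal(nrow(keys) * 12L, 288L)
})

test_that("one configuration run is deterministic with per-rep ELM variation", {
  r1 <- run_configuration(small_profiles, "relative", "anova", "fisher_lda",
                          "sin", n_reps = 3, master_seed = 5,
                          options = fast_opts)
  r2 <- run_configuration(small_profiles, "relative", "anova", "fisher_lda",
                          "sin", n_reps = 3, master_seed = 5,
                          options = fast_opts)
  expect_identical(r1$accuracies, r2$accuracies)
  expect_length(r1$accuracies, 3L)
  expect_true(all(r1$accuracies >= 0 & r1$accuracies <= 100))
  expect_equal(r1$n_components, 3L)
  # single repetition: sd reported as 0 and flagged undefined
  r3 <- run_configuration(small_profiles, "relative", "anova", "fisher_lda",
                          "sin", n_reps = 1, master_seed = 5,
                          options = fast_opts)
  expect_equal(r3$sd, 0)
  expect_false(r3$sd_defined)
})

test_that("stage failures are reported with the stage name", {
  expect_error(run_configuration(small_profiles, "relative", "anova",
                                 "fisher_lda", "sin", n_reps = 1,
                                 options = list(bogus = 1)),
               "unknown run option")
  rel <- to_relative(small_profiles)
  expect_error(run_configuration(rel, "relative", "anova", "fisher_lda",
                                 "sin", n_reps = 1, options = fast_opts),
               "dataset_kind")
})

test_that("a reduced grid has the right shape and arithmetic", {
  keys <- config_keys()
  sub <- keys[keys$activation != "hardlim", ]  # 16 configs
  g <- run_grid(small_profiles, n_reps = 2, master_seed = 9, keys = sub,
                options = fast_opts)
  expect_equal(nrow(g$summary), 16L)
  expect_equal(g$total_fits, 32L)
  expect_equal(nrow(g$runs), 32L)
  expect_true(all(table(g$runs$config_id) == 2L))
  # per-config mean/sd recomputable from the run rows
  for (i in seq_len(nrow(g$summary))) {
    acc <- g$runs$test_accuracy[g$runs$config_id == g$summary$config_id[i]]
    expect_equal(mean(acc), g$summary$mean[i])
    expect_equal(stats::sd(acc), g$summary$sd[i])
  }
  # grid equals the composition of standalone configuration runs
  r <- run_configuration(small_profiles, sub$dataset_kind[1], sub$selector[1],
                         sub$reducer[1], sub$activation[1], n_reps = 2,
                         master_seed = 9, options = fast_opts)
  expect_identical(r$accuracies,
                   g$runs$test_accuracy[g$runs$config_id == r$config_id])
})

test_that("grid letters flag clearly different configurations", {
  g <- run_grid(small_profiles, n_reps = 2, master_seed = 9,
                keys = config_keys()[c(17, 18), ], options = fast_opts)
  # identical accuracies across all configs -> a single shared letter
  g_same <- g
  g_same$runs$test_accuracy <- rep(80, nrow(g_same$runs))
  expect_true(all(grid_letters(g_same) == "a"))
  # widely separated accuracies -> distinct letters
  g_diff <- g
  g_diff$runs$test_accuracy <- c(50.1, 49.9, 95.2, 94.8)
  expect_identical(sort(grid_letters(g_diff)), c("a", "b"))
})

test_that("the best-model summary reports structure and tie-breaks", {
  g <- run_grid(small_profiles, n_reps = 3, master_seed = 2,
                keys = config_keys()[17:18, ], options = fast_opts)
  best <- best_model_summary(g)
  expect_equal(best$test_accuracy, max(g$runs$test_accuracy))
  expect_match(best$structure, "^3-\\d+-5$")  # 3 DFs in, 5 one-hot outputs
  ties <- g$runs[g$runs$test_accuracy == best$test_accuracy, ]
  expect_true(all(best$train_accuracy >= ties$train_accuracy))
  # label encoding yields a single output neuron in the structure string
  gl <- run_grid(small_profiles, n_reps = 1, master_seed = 2,
                 keys = config_keys()[18, , drop = FALSE],
                 options = c(fast_opts, list(output_encoding = "label")))
  expect_match(best_model_summary(gl)$structure, "^3-\\d+-1$")
})
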