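test_that("per-subpopulation standardization centres and scales each group", {
  set.seed(61)
  pheno <- data.frame(
    individual_id = sprintf("i%02d", 1:30),
    generation = rep(c("F11", "F13"), c(12, 18)),
    trait = "wsc",
    value = c(rnorm(12, 10, 3), rnorm(18, -4, 0.5)))
  std <- standardize_by_subpopulation(pheno)
  for (g in c("F11", "F13")) {
    v <- std$value[std$generation == g]
    expect_lt(abs(mean(v)), 1e-12)
    expect_lt(abs(stats::var(v) - 1), 1e-12)
  }
  # pooled variance of unequal-size standardized groups is generally not 1
  expect_false(isTRUE(all.equal(stats::var(std$value), 1)))
  # idempotent to numerical precision
  std2 <- standardize_by_subpopulation(std)
  expect_equal(std2$value, std$value, tolerance = 1e-12)
  # constant group rejected by name
  bad <- pheno; bad$value[bad$generation == "F11"] <- 7
  expect_error(standardize_by_subpopulation(bad), "F11")
})

test_that("training sets compose named generations and drop incomplete individuals", {
  d <- toy_dataset(n_per_gen = c(F11 = 8, F12 = 6, F13 = 5, F14 = 7))
  spec <- training_set_spec("INT")
  tr <- compose_training_set(d, spec, "wsc")
  expect_equal(tr$n_train, 19)
  expect_setequal(unique(generations(tr$genotypes)), c("F11", "F12", "F13"))
  expect_equal(length(tr$y), 19)
  # y is aligned with the genotype rows
  ph <- d$phenotypes[d$phenotypes$trait == "wsc", ]
  expect_equal(tr$y, ph$value[match(rownames(tr$genotypes), ph$individual_id)])

  # an individual missing its phenotype is excluded and counted
  d2 <- d
  d2$phenotypes <- d2$phenotypes[d2$phenotypes$individual_id != "F12_03" |
                                   d2$phenotypes$trait != "wsc", ]
  tr2 <- compose_training_set(d2, spec, "wsc")
  expect_equal(tr2$n_train, 18)
  expect_gte(tr2$n_excluded, 1)

  expect_error(compose_training_set(d, training_set_spec("ALL"), "wsc"),
               "F5")
  expect_error(training_set_spec("custom"), "nonempty")
})

test_that("Spearman accuracy equals the rank-correlation formula", {
  expect_equal(spearman_accuracy(1:8, (1:8)^3), 1)       # monotone
  expect_equal(spearman_accuracy(1:8, -(1:8)), -1)       # antitone
  expect_equal(spearman_accuracy(1:5, c(2, 1, 4, 3, 5)), 0.8)
  expect_error(spearman_accuracy(1:5, rep(1, 5)), "constant")
  expect_error(spearman_accuracy(1:4, 1:5), "length")
})

test_that("the evaluation grid is leak-guarded, complete and reproducible", {
  d <- toy_dataset(n_per_gen = c(F11 = 15, F12 = 12, F13 = 12, F14 = 12),
                   m = 40, h2 = 0.7)
  expect_error(
    run_evaluation(d, specs = list(training_set_spec("custom",
                                                     c("F13", "F14")))),
    "leakage")
  specs <- list(training_set_spec("F13"), training_set_spec("INT"))
  ev <- run_evaluation(d, specs = specs, methods = c("BLUP", "KNN"),
                       seed = 9, ensemble = ensemble_config(
                         rf_n_trees = 50L, gbm_n_trees = 100L))
  expect_equal(dim(ev$tables$F13), c(2, 2))
  expect_equal(dim(ev$tables$INT), c(2, 2))
  expect_true(all(is.na(ev$results$spearman) |
                    abs(ev$results$spearman) <= 1))
  expect_equal(unique(ev$results$n_train[ev$results$spec == "INT"]), 39)
  ev2 <- run_evaluation(d, specs = specs, methods = c("BLUP", "KNN"),
                        seed = 9, ensemble = ensemble_config(
                          rf_n_trees = 50L, gbm_n_trees = 100L))
  expect_identical(ev$results, ev2$results)
})

test_that("a failing cell is recorded as missing, never fabricated", {
  d <- toy_dataset(n_per_gen = c(F13 = 12, F14 = 8), m = 20,
                   traits = c("wsc", "flat"))
  # constant observed values in the test generation break the rank correlation
  flat <- d$phenotypes$trait == "flat" & d$phenotypes$generation == "F13"
  d$phenotypes$value[flat] <- seq_len(sum(flat))  # fine in training
  flat_test <- d$phenotypes$trait == "flat" & d$phenotypes$generation == "F14"
  d$phenotypes$value[flat_test] <- 3
  expect_error(run_evaluation(d, specs = list(training_set_spec("F13")),
                              methods = "BLUP", seed = 2),
               "constant group")
  # drop the degenerate test records instead: cell reported as missing
  d$phenotypes <- d$phenotypes[!flat_test, ]
  ev <- run_evaluation(d, specs = list(training_set_spec("F13")),
                       methods = "BLUP", traits = c("flat", "wsc"), seed = 2)
  row <- ev$results[ev$results$trait == "flat", ]
  expect_true(is.na(row$spearman))
  expect_match(row$error, "empty test set")
  expect_false(is.na(ev$results$spearman[ev$results$trait == "wsc"]))
})

test_that("evaluation tables round-trip to disk with a manifest", {
  d <- toy_dataset(n_per_gen = c(F13 = 12, F14 = 8), m = 20)
  ev <- run_evaluation(d, specs = list(training_set_spec("F13")),
                       methods = c("BLUP"), seed = 4)
  dir <- withr::local_tempdir()
  write_evaluation(ev, dir)
  expect_true(file.exists(file.path(dir, "accuracy_F13.csv")))
  tab <- utils::read.csv(file.path(dir, "accuracy_F13.csv"))
  expect_equal(tab$BLUP, unname(ev$tables$F13[tab$trait, "BLUP"]))
})
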