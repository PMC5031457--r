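test_that("stratified splits honour the per-class ceiling rule", {
  df <- make_clusters(K = 2, n_per = 30, dim = 3, sep = 5, seed = 70)
  sp <- stratified_split(df, 0.9, seed = 1)
  expect_equal(as.integer(table(sp$train$label)), c(27L, 27L))
  expect_equal(as.integer(table(sp$test$label)), c(3L, 3L))
  # disjoint and exhaustive
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(df))

  # minimum contract: 2 samples per class at fraction 0.5 -> 1/1
  tiny <- make_clusters(K = 3, n_per = 2, dim = 2, sep = 5, seed = 71)
  sp2 <- stratified_split(tiny, 0.5, seed = 2)
  expect_equal(as.integer(table(sp2$train$label)), rep(1L, 3))
  expect_equal(as.integer(table(sp2$test$label)), rep(1L, 3))

  # each side keeps at least one sample per class even at extreme fractions
  sp3 <- stratified_split(tiny, 0.9, seed = 3)
  expect_true(all(table(sp3$test$label) >= 1L))

  # determinism
  expect_identical(stratified_split(df, 0.3, seed = 9),
                   stratified_split(df, 0.3, seed = 9))
  singleton <- df[c(which(df$label == "A")[1], which(df$label == "B")), ]
  expect_error(stratified_split(singleton, 0.5), ">= 2 samples")
  expect_error(stratified_split(df, 1.0), "in \\(0, 1\\)")
})

test_that("run_sweep aggregates the full algorithm-by-fraction grid", {
  df <- make_clusters(K = 3, n_per = 12, dim = 4, sep = 8, seed = 80)
  # knn's CV folds shrink at the small fraction; that warning is expected
  suppressWarnings(
    res <- run_sweep(df,
                     list(opf = opf_spec("euclidean"),
                          knn = baseline_spec("knn")),
                     fractions = c(0.3, 0.7), reps = 3, base_seed = 5)
  )
  expect_s3_class(res, "experiment_result")
  expect_equal(nrow(res$summary), 4L)
  expect_equal(nrow(res$results), 2L * 2L * 3L)
  expect_true(all(res$summary$acc_mean >= 0 & res$summary$acc_mean <= 1))
  expect_true(all(res$summary$acc_sem >= 0))
  expect_true(all(res$summary$time_ms_mean >= 0))
  # accumulated confusion counts equal reps x test size
  cm <- res$confusions[["opf@0.7"]]
  expect_equal(sum(cm), 3 * sum(table(df$label) - ceiling(0.7 * table(df$label))))
  expect_identical(tidy(res), res$summary)
})

test_that("single-repetition sweeps warn and report zero SEM", {
  df <- make_clusters(K = 2, n_per = 8, dim = 3, sep = 8, seed = 81)
  expect_warning(
    res <- run_sweep(df, list(opf = opf_spec()), fractions = 0.5, reps = 1),
    "SEM"
  )
  expect_equal(res$summary$acc_sem, 0)
})

test_that("a failing repetition aborts with algorithm/fraction/rep context", {
  df <- make_clusters(K = 2, n_per = 6, dim = 3, sep = 8, seed = 82)
  broken <- structure(list(algo = "nope"), class = "nonsense_spec")
  expect_error(run_sweep(df, list(bad = broken), fractions = 0.5, reps = 2),
               "algorithm=bad.*fraction=0.5.*rep=1")
})

test_that("accuracy tends upward with training fraction on separable data", {
  df <- make_clusters(K = 4, n_per = 20, dim = 5, sep = 3.5, seed = 83)
  res <- run_sweep(df, list(opf = opf_spec("euclidean")),
                   fractions = c(0.1, 0.9), reps = 20, base_seed = 11)
  s <- res$summary
  expect_gte(s$acc_mean[s$fraction == 0.9], s$acc_mean[s$fraction == 0.1])
})

test_that("sub-class labels collapse to the eight principal classes", {
  labs <- c("Alarm", "Phee-2", "Phee-3", "Phee-4", "Tsik", "Tsik-ek", "Trill")
  expect_equal(merge_principal_labels(labs),
               c("Alarm", "Phee", "Phee", "Phee", "Tsik", "Tsik", "Trill"))
  # merging then tabulating equals tabulating merged ground truth
  set.seed(84)
  truth <- sample(labs, 100, replace = TRUE)
  pred <- sample(labs, 100, replace = TRUE)
  cm_after <- confusion_matrix(merge_principal_labels(truth),
                               merge_principal_labels(pred))
  expect_equal(sum(diag(cm_after)),
               sum(merge_principal_labels(truth) == merge_principal_labels(pred)))
})

test_that("hierarchical evaluation reports principal and sub-class structure", {
  # small synthetic 11-type corpus; sub-classes share spectra so sub-class
  # accuracy is modest, but the plumbing contracts must hold exactly
  calls <- synth_dataset(4, call_archetypes(), seed = 31, noise_level = 0.05)
  feats <- pipeline_featurize(calls, order = 12)
  hr <- hierarchical_eval(feats, opf_spec("euclidean"),
                          train_fraction = 0.5, reps = 2, base_seed = 3)
  expect_equal(dim(hr$principal_cm), c(8L, 8L))
  expect_equal(dim(hr$phee_cm), c(3L, 3L))
  expect_equal(dim(hr$tsik_cm), c(2L, 2L))
  expect_equal(sort(rownames(hr$principal_cm)),
               c("Alarm", "Chirp", "Loud-shrill", "Phee", "Seep", "Trill",
                 "Tsik", "Twitter"))
  expect_equal(nrow(hr$compounded), 5L)
  expect_equal(hr$compounded$compounded,
               hr$compounded$parent_se * hr$compounded$child_se)
  expect_true(all(hr$compounded$compounded >= 0 &
                  hr$compounded$compounded <= 1))

  # a perfect principal stage makes compounded equal the child sensitivity
  expect_equal(compounded_accuracy(1.0, hr$compounded$child_se),
               hr$compounded$child_se)

  expect_error(hierarchical_eval(feats[feats$label != "Tsik-ek", ]),
               "Tsik-ek")
})

test_that("the 11-type corpus merges to the reported principal class sizes", {
  counts <- c("Alarm" = 30, "Chirp" = 30, "Loud-shrill" = 27, "Phee-2" = 30,
              "Phee-3" = 30, "Phee-4" = 30, "Seep" = 30, "Trill" = 27,
              "Tsik" = 27, "Tsik-ek" = 30, "Twitter" = 30)
  labs <- rep(names(counts), counts)
  merged <- table(merge_principal_labels(labs))
  expect_equal(unname(merged[["Phee"]]), 90L)
  expect_equal(unname(merged[["Tsik"]]), 57L)
  expect_equal(length(merged), 8L)
})
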