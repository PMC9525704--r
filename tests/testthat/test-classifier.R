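# A small, cleanly separable split cohort used across classifier tests.
separable_split <- function(seed = 3, n_per_class = 30, effect = 4) {
  coh <- generate_cohort(sim_config(
    n_features = 40, class_sizes = c(A = n_per_class, B = n_per_class, C = n_per_class),
    frac_informative = 0.3, n_redundant_blocks = 0, n_constant = 0,
    effect_size = effect, noise_sd = 0.3, seed = seed
  ))
  sp <- split_holdout(coh, seed = seed)
  minmax_normalize(sp, normalization_params(sp))
}

test_that("the auto-encoder classifier fits separable data and is seed-deterministic", {
  sc <- separable_split()
  m1 <- fit_classifier(sc, model_kind = "sodae", config = classifier_config(seed = 5))
  ev_train <- evaluate(m1, dplyr::filter(sc, partition == "train"), "train")
  expect_gte(ev_train$accuracy_multiclass, 99)

  m2 <- fit_classifier(sc, model_kind = "sodae", config = classifier_config(seed = 5))
  expect_equal(m1$model$val_accuracy, m2$model$val_accuracy)
  expect_identical(predict(m1, sc, type = "prob"), predict(m2, sc, type = "prob"))

  # oracle: a nearest-centroid linear rule also separates this cohort
  oracle <- fit_classifier(sc, model_kind = "nearest_centroid")
  expect_gte(evaluate(oracle, dplyr::filter(sc, partition == "train"),
                      "train")$accuracy_multiclass, 99)

  # well-separated subtypes classify near-perfectly on held-out data
  ev_test <- evaluate(m1, dplyr::filter(sc, partition == "test"), "test")
  expect_gte(ev_test$accuracy_multiclass, 95)
  expect_lte(abs(ev_test$accuracy_multiclass -
                   evaluate(oracle, dplyr::filter(sc, partition == "test"),
                            "test")$accuracy_multiclass), 5)
})

test_that("all classifier kinds share the fit/predict/report contract", {
  sc <- separable_split(seed = 9, n_per_class = 15)
  kinds <- c("sodae", "mlp_baseline", "nearest_centroid")
  reports <- lapply(kinds, function(k) {
    m <- fit_classifier(sc, model_kind = k,
                        config = classifier_config(seed = 2, finetune_epochs = 150))
    evaluate(m, dplyr::filter(sc, partition == "test"), "test")
  })
  shapes <- lapply(reports, function(r) dim(tidy(r)))
  expect_length(unique(shapes), 1)
  expect_true(all(vapply(reports, function(r) all(dim(r$confusion) == 3), logical(1))))

  m_mlp <- fit_classifier(sc, model_kind = "mlp_baseline",
                          config = classifier_config(seed = 4))
  m_mlp2 <- fit_classifier(sc, model_kind = "mlp_baseline",
                           config = classifier_config(seed = 4))
  expect_identical(predict(m_mlp, sc, type = "prob"), predict(m_mlp2, sc, type = "prob"))

  expect_error(fit_classifier(sc, model_kind = "no_such_kind"), "arg")
  one_class <- dplyr::mutate(sc, subtype = "A")
  expect_error(fit_classifier(one_class, model_kind = "sodae"), "single class")
})

test_that("evaluation metrics match the one-vs-rest formulas", {
  m <- ovr_metrics(tp = 3, fp = 1, fn = 1, tn = 5)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(m$accuracy, 80)

  # precision = recall = p implies F1 = p
  m2 <- ovr_metrics(tp = 6, fp = 2, fn = 2, tn = 10)
  expect_equal(m2$f1, m2$precision)

  # perfect predictor: accuracy 100 and all F1 = 1
  sc <- separable_split(seed = 12, n_per_class = 10)
  oracle <- fit_classifier(sc, model_kind = "nearest_centroid")
  ev <- evaluate(oracle, dplyr::filter(sc, partition == "train"), "train")
  if (ev$accuracy_multiclass == 100) {
    expect_true(all(ev$per_class$f1 == 1))
    expect_equal(ev$accuracy, 100)
  }

  # the headline accuracy is recomputable from the stored counts
  expect_equal(ev$accuracy,
               sum(ev$per_class$tp + ev$per_class$tn) /
                 sum(ev$per_class$tp + ev$per_class$tn +
                       ev$per_class$fp + ev$per_class$fn) * 100)
  expect_equal(sum(ev$confusion), ev$n)
})

test_that("rank AUC agrees with pROC and a random scorer sits at 0.5", {
  set.seed(55)
  for (i in 1:10) {
    y <- sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(y) || all(y)) next
    s <- rnorm(40) + y
    expect_equal(rank_auc(s, y),
                 as.numeric(pROC::auc(y, s, direction = "<", quiet = TRUE)))
  }
  # average over 20 seeds of a random scorer on balanced labels
  aucs <- vapply(1:20, function(seed) {
    set.seed(seed)
    y <- rep(c(TRUE, FALSE), each = 50)
    rank_auc(runif(100), y)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("a class absent from the partition yields NA AUC, not zero", {
  sc <- separable_split(seed = 21, n_per_class = 10)
  m <- fit_classifier(sc, model_kind = "nearest_centroid")
  sub <- dplyr::filter(sc, partition == "test", subtype != "C")
  ev <- evaluate(m, sub, "test")
  expect_true(is.na(ev$per_class$auc[ev$per_class$class == "C"]))
  expect_false(any(ev$per_class$auc == 0, na.rm = TRUE))
})
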