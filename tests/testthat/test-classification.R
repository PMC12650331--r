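test_that("assembled datasets are fixed-width, imputed and balanced", {
  feats <- tibble::tibble(
    patient_id = c("A", "A", "B"),
    cie_status = c("sepsis", "sepsis", "none"),
    signal = c("ECGRR", "SPO2", "ECGHR"),
    bound = c("upper", "lower", "upper"),
    modal_value = c(45, 88, 170), modal_duration = c(10, 5, 3),
    n_alarms = c(20L, 15L, 4L), largest_cluster_size = c(18L, 15L, 4L))
  man <- tibble::tibble(patient_id = c("A", "B", "C"),
                        cie_type = c("sepsis", "none", "none"))
  ds <- assemble_dataset(feats, man, balance = FALSE)
  expect_equal(nrow(ds), 3)           # C kept: alarm-free but monitored
  expect_equal(ncol(ds), 22)          # id + label + 5 channels x 4 fields
  expect_false(anyNA(ds))
  expect_equal(ds$modal_value_ecgrr_upper[ds$patient_id == "A"], 45)
  expect_equal(ds$present_ecgrr_upper, c(1, 0, 0))
  expect_equal(sum(ds[ds$patient_id == "C", -(1:2)]), 0)

  # balancing subsamples the none class to the CIE count, reproducibly
  big_man <- tibble::tibble(patient_id = sprintf("P%02d", 1:30),
                            cie_type = rep(c("sepsis", "none", "none"), 10))
  bal <- assemble_dataset(feats[0, ], big_man, balance = TRUE, seed = 1)
  expect_equal(as.vector(table(bal$label)[c("none", "sepsis")]), c(10L, 10L))
  expect_identical(bal, assemble_dataset(feats[0, ], big_man, TRUE, seed = 1))
})

test_that("patient-grouped splits are disjoint, stratified and seeded", {
  ds <- separable_dataset(n_per_class = 34)  # 102 patients
  sp <- patient_grouped_split(ds, 0.7, seed = 5)
  expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0)
  expect_equal(nrow(sp$train) + nrow(sp$test), 102)
  # stratified arithmetic at 0.7: 238 patients -> 166/72 within rounding
  ds238 <- dplyr::bind_rows(
    separable_dataset(40),
    dplyr::mutate(separable_dataset(40, seed = 100),
                  patient_id = paste0(patient_id, "b")))[1:238, ]
  sp238 <- patient_grouped_split(ds238, 0.7, seed = 1)
  expect_lte(abs(nrow(sp238$train) - 166), 2)
  expect_lte(abs(nrow(sp238$test) - 72), 2)
  # every class present on both sides
  expect_setequal(as.character(unique(sp$train$label)),
                  as.character(unique(sp$test$label)))
  expect_identical(patient_grouped_split(ds, 0.7, seed = 5)$train$patient_id,
                   sp$train$patient_id)
  expect_error(patient_grouped_split(ds, 1.2), "train_fraction")
  # single-member class is trained on, with a warning
  lone <- dplyr::bind_rows(ds[1:20, ],
                           dplyr::mutate(ds[21, ], label = factor(
                             "sepsis", levels = levels(ds$label))))
  expect_warning(patient_grouped_split(lone, 0.7, seed = 2), "single")
})

test_that("all three families separate the separable fixture perfectly", {
  ds <- separable_dataset()
  sp <- patient_grouped_split(ds, 0.7, seed = 3)
  for (fam in c("random_forest", "svm", "decision_tree")) {
    ev <- train_and_evaluate(model_spec(fam), sp$train, sp$test)
    expect_equal(ev$accuracy, 1.0)
    expect_true(all(ev$metrics$f1 == 1))
    expect_true(all(ev$auc == 1))
  }
})

test_that("reported metrics are internally consistent with the confusion matrix", {
  withr::with_seed(17, {
    ds <- separable_dataset(25)
    # blur the features so the problem is not trivially separable
    noisy <- dplyr::mutate(ds, dplyr::across(dplyr::starts_with("f"),
                                             ~.x + rnorm(length(.x), 0, 40)))
  })
  sp <- patient_grouped_split(noisy, 0.7, seed = 4)
  ev <- train_and_evaluate(model_spec("random_forest"), sp$train, sp$test)
  cm <- ev$confusion
  expect_equal(ev$accuracy, sum(diag(cm)) / sum(cm))
  expect_equal(unname(rowSums(cm)),
               as.vector(table(sp$test$label)))
  for (cl in ev$metrics$class) {
    row <- ev$metrics[ev$metrics$class == cl, ]
    expect_equal(row$recall, cm[cl, cl] / sum(cm[cl, ]))
    if (sum(cm[, cl]) > 0) {
      expect_equal(row$precision, cm[cl, cl] / sum(cm[, cl]))
    }
    expect_true(is.na(row$f1) || (row$f1 >= 0 && row$f1 <= 1))
  }
  # determinism: identical spec and split give identical reports
  ev2 <- train_and_evaluate(model_spec("random_forest"), sp$train, sp$test)
  expect_equal(ev$accuracy, ev2$accuracy)
  expect_equal(ev$auc, ev2$auc)
})

test_that("model comparison reuses one split and reports every family", {
  ds <- separable_dataset(20)
  cmp <- compare_models(list(model_spec("random_forest"), model_spec("svm"),
                             model_spec("decision_tree")), ds, seed = 6)
  expect_equal(cmp$family, c("random_forest", "svm", "decision_tree"))
  expect_true(all(cmp$accuracy == 1))
  # identical spec twice -> identical rows
  cmp2 <- compare_models(list(model_spec("svm"), model_spec("svm")), ds,
                         seed = 6)
  expect_equal(cmp2$accuracy[1], cmp2$accuracy[2])
  expect_equal(length(attr(cmp, "importances")), 1)
  expect_equal(nrow(attr(cmp, "importances")[[1]]), 6)
  # tidy/glance accessors expose the report schema
  ev <- attr(cmp, "evaluations")[[1]]
  td <- tidy(ev)
  expect_setequal(unique(td$metric),
                  c("precision", "recall", "f1", "support", "auc"))
  expect_named(glance(ev), c("family", "accuracy", "auc_micro", "n_test"))
})
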