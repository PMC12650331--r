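#' Assemble per-patient feature vectors from alarm-pattern features
#'
#' Pivots pattern features into one fixed-width row per patient: for each
#' of the five monitored (signal, bound) channels — ECGRR upper/lower,
#' ECGHR upper/lower, SPO2 lower — the modal alarm value, modal duration,
#' alarm count and a presence flag. Channels in which the patient raised
#' no alarms are encoded as zeros with presence 0; patients in the
#' manifest with no features at all still get a (all-zero) row, since an
#' alarm-free window is itself informative.
#'
#' With `balance = TRUE` the event-free class is randomly subsampled
#' (seeded) to the number of CIE patients, mirroring a balanced design of
#' equal CIE and non-CIE arms.
#'
#' @param features Pattern-feature tibble from
#'   [extract_pattern_features()].
#' @param manifest Cohort manifest (`patient_id`, `cie_type`).
#' @param balance Subsample the `none` class to the CIE count.
#' @param seed Seed for the balancing subsample.
#' @return Tibble: `patient_id`, `label` (factor `none` /
#'   `death_cpr_picu` / `sepsis`) and 20 numeric feature columns.
#' @export
assemble_dataset <- function(features, manifest, balance = TRUE, seed = 42L) {
  channels <- tibble::tibble(
    signal = c("ECGRR", "ECGRR", "ECGHR", "ECGHR", "SPO2"),
    bound = c("upper", "lower", "upper", "lower", "lower"))
  feats <- dplyr::semi_join(features, channels, by = c("signal", "bound"))
  feats <- dplyr::mutate(feats,
                         channel = paste0(tolower(.data$signal), "_",
                                          .data$bound),
                         present = 1)
  wide <- tidyr::pivot_wider(
    dplyr::select(feats, "patient_id", "channel", "modal_value",
                  "modal_duration", "n_alarms", "present"),
    names_from = "channel",
    values_from = c("modal_value", "modal_duration", "n_alarms", "present"),
    values_fill = 0)
  out <- dplyr::left_join(
    dplyr::select(manifest, "patient_id", "cie_type"), wide,
    by = "patient_id")
  # fixed width regardless of which channels appeared in this cohort
  want <- as.vector(outer(c("modal_value", "modal_duration", "n_alarms",
                            "present"),
                          paste0(tolower(channels$signal), "_",
                                 channels$bound), paste, sep = "_"))
  for (col in setdiff(want, names(out))) out[[col]] <- 0
  out <- dplyr::mutate(
    dplyr::select(out, "patient_id", "cie_type", dplyr::all_of(want)),
    dplyr::across(dplyr::all_of(want), ~tidyr::replace_na(.x, 0)),
    label = factor(.data$cie_type,
                   levels = c("none", "death_cpr_picu", "sepsis")))
  out <- dplyr::select(out, -"cie_type")
  if (balance) {
    n_cie <- sum(out$label != "none")
    none_ids <- out$patient_id[out$label == "none"]
    if (length(none_ids) > n_cie) {
      keep <- withr::with_seed(seed, sample(none_ids, n_cie))
      out <- dplyr::filter(out, .data$label != "none" |
                             .data$patient_id %in% keep)
    }
  }
  dplyr::relocate(out, "patient_id", "label")
}

#' Split a dataset by patient, stratified by label
#'
#' Patients are allocated wholly to the training or test partition — no
#' patient contributes rows to both — with per-class proportions held at
#' `train_fraction` (stratified rounding). Classes with a single member go
#' to the training set with a warning.
#'
#' @param dataset Feature tibble from [assemble_dataset()].
#' @param train_fraction Proportion of patients trained on, in (0, 1).
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return List of class `patient_split` with tibbles `train` and `test`.
#' @export
patient_grouped_split <- function(dataset, train_fraction = 0.7, seed = 42L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  ids <- dplyr::distinct(dataset, .data$patient_id, .data$label)
  train_ids <- withr::with_seed(seed, unlist(lapply(
    split(ids$patient_id, ids$label), function(members) {
      if (length(members) == 0) return(character())
      if (length(members) == 1) {
        warning("class with a single patient assigned to the training set",
                call. = FALSE)
        return(members)
      }
      n_tr <- max(1, min(length(members) - 1,
                         round(train_fraction * length(members))))
      sample(members, n_tr)
    })))
  res <- structure(
    list(train = dplyr::filter(dataset, .data$patient_id %in% train_ids),
         test = dplyr::filter(dataset, !.data$patient_id %in% train_ids)),
    class = "patient_split")
  stopifnot(length(intersect(res$train$patient_id,
                             res$test$patient_id)) == 0)
  res
}

#' Specify a classifier family with the study hyperparameters
#'
#' Defaults follow the published configuration: random forest with 200
#' trees, Gini impurity and unlimited depth; an RBF support vector machine
#' with `C = 1`, kernel width chosen by the "scale" rule (1 / (d * mean
#' feature variance), computed on the standardised training features) and
#' probability outputs; a Gini decision tree grown to full depth. Seeds
#' default to 42.
#'
#' @param family `"random_forest"`, `"svm"` or `"decision_tree"`.
#' @param seed Integer seed used when fitting.
#' @param ... Family-specific overrides (`ntree` for the forest, `cost`
#'   for the SVM).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family = c("random_forest", "svm", "decision_tree"),
                       seed = 42L, ...) {
  family <- match.arg(family)
  defaults <- switch(family,
                     random_forest = list(ntree = 200),
                     svm = list(cost = 1),
                     decision_tree = list())
  hp <- utils::modifyList(defaults, list(...))
  structure(list(family = family, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "model_spec")
}

feature_cols <- function(dataset) setdiff(names(dataset),
                                          c("patient_id", "label"))

fit_model <- function(spec, train) {
  cols <- feature_cols(train)
  x <- as.matrix(train[cols])
  y <- droplevels(train$label)
  withr::with_seed(spec$seed, switch(
    spec$family,
    random_forest = randomForest::randomForest(
      x = x, y = y, ntree = spec$hyperparameters$ntree),
    decision_tree = {
      df <- data.frame(x, label = y)
      rpart::rpart(label ~ ., data = df, method = "class",
                   parms = list(split = "gini"),
                   control = rpart::rpart.control(cp = 0, minsplit = 2,
                                                  minbucket = 1,
                                                  maxdepth = 30, xval = 0))
    },
    svm = {
      ctr <- apply(x, 2, mean)
      scl <- apply(x, 2, stats::sd)
      scl[scl == 0] <- 1
      xs <- scale(x, ctr, scl)
      gamma <- 1 / (ncol(xs) * mean(apply(xs, 2, stats::var)))
      fit <- e1071::svm(x = xs, y = y, kernel = "radial",
                        cost = spec$hyperparameters$cost, gamma = gamma,
                        probability = TRUE, scale = FALSE)
      attr(fit, "alarmscape_center") <- ctr
      attr(fit, "alarmscape_scale") <- scl
      fit
    }))
}

predict_probs <- function(fit, newdata) {
  cols <- setdiff(names(newdata), c("patient_id", "label"))
  x <- as.matrix(newdata[cols])
  if (inherits(fit, "randomForest")) {
    p <- stats::predict(fit, x, type = "prob")
  } else if (inherits(fit, "rpart")) {
    p <- stats::predict(fit, data.frame(x), type = "prob")
  } else {
    xs <- scale(x, attr(fit, "alarmscape_center"),
                attr(fit, "alarmscape_scale"))
    pred <- stats::predict(fit, xs, probability = TRUE)
    p <- attr(pred, "probabilities")
    p <- p[, order(match(colnames(p), fit$levels)), drop = FALSE]
  }
  p
}

#' Train one classifier and evaluate it on held-out patients
#'
#' Fits the specified family on the training partition and reports, on the
#' test partition: per-class precision, recall and F1 for the
#' death/CPR/PICU and sepsis classes, overall accuracy, one-vs-rest AUC
#' per reported class plus a micro-averaged AUC over all classes, and the
#' confusion matrix. A class absent from the test set gets `NA` metrics
#' with a reason, never a fabricated zero. The AUC vector carries, besides
#' the per-class entries, a macro average (prior-insensitive; 0.5 for a
#' skill-free classifier) and a micro average over pooled
#' indicator/probability pairs (a single-curve summary).
#'
#' @param spec A [model_spec()].
#' @param train,test Disjoint-patient partitions from
#'   [patient_grouped_split()].
#' @return An object of class `cie_eval`: list with `family`, `metrics`
#'   (per-class tibble), `accuracy`, `auc` (named: one-vs-rest per class
#'   and `micro`), `confusion` (table), `roc_points` (tibble), `notes`.
#' @export
train_and_evaluate <- function(spec, train, test) {
  stopifnot(nrow(train) > 0, nrow(test) > 0,
            length(intersect(train$patient_id, test$patient_id)) == 0)
  fit <- fit_model(spec, train)
  probs <- predict_probs(fit, test)
  lev <- levels(droplevels(train$label))
  pred <- factor(colnames(probs)[max.col(probs, ties.method = "first")],
                 levels = levels(test$label))
  truth <- test$label
  confusion <- table(truth = truth, predicted = pred)
  accuracy <- sum(diag(confusion)) / sum(confusion)
  notes <- character()
  classes <- intersect(c("death_cpr_picu", "sepsis"), lev)
  metrics <- purrr::map_dfr(classes, function(cl) {
    if (!any(truth == cl)) {
      notes <<- c(notes, paste0("class '", cl, "' absent from test set; ",
                                "metrics undefined"))
      return(tibble::tibble(class = cl, precision = NA_real_,
                            recall = NA_real_, f1 = NA_real_, support = 0L))
    }
    tp <- sum(truth == cl & pred == cl)
    prec <- if (sum(pred == cl) == 0) NA_real_ else tp / sum(pred == cl)
    rec <- tp / sum(truth == cl)
    f1 <- if (is.na(prec) || prec + rec == 0) NA_real_ else
      2 * prec * rec / (prec + rec)
    tibble::tibble(class = cl, precision = prec, recall = rec, f1 = f1,
                   support = sum(truth == cl))
  })
  auc <- c()
  roc_points <- list()
  for (cl in classes) {
    if (!cl %in% colnames(probs) || length(unique(truth == cl)) < 2) {
      auc[cl] <- NA_real_
      next
    }
    r <- pROC::roc(response = truth == cl, predictor = probs[, cl],
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    auc[cl] <- as.numeric(pROC::auc(r))
    roc_points[[cl]] <- tibble::tibble(
      class = cl, fpr = 1 - r$specificities, tpr = r$sensitivities)
  }
  # macro-average centres at 0.5 for a skill-free classifier whatever the
  # class priors; the micro-average pools indicator/probability pairs and
  # is prior-sensitive (a single-curve summary)
  auc["macro"] <- mean(auc[classes], na.rm = TRUE)
  pool_resp <- as.vector(vapply(colnames(probs), function(cl) truth == cl,
                                logical(nrow(test))))
  pool_pred <- as.vector(probs)
  auc["micro"] <- if (length(unique(pool_resp)) < 2) NA_real_ else
    as.numeric(pROC::auc(pROC::roc(pool_resp, pool_pred,
                                   levels = c(FALSE, TRUE), direction = "<",
                                   quiet = TRUE)))
  structure(list(family = spec$family, metrics = metrics,
                 accuracy = accuracy, auc = auc, confusion = confusion,
                 roc_points = dplyr::bind_rows(roc_points), notes = notes),
            class = "cie_eval")
}

#' @export
print.cie_eval <- function(x, ...) {
  cat("<cie_eval> ", x$family, " | accuracy ", sprintf("%.2f", x$accuracy),
      " | micro AUC ", sprintf("%.2f", x$auc[["micro"]]), "\n", sep = "")
  print(x$metrics)
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Compare classifier families on one shared patient split
#'
#' Runs [train_and_evaluate()] for each specification on the same
#' stratified patient split, so the families see identical training and
#' test patients. Feature importances of tree ensembles are attached.
#'
#' @param specs List of [model_spec()] objects (>= 1).
#' @param dataset Feature tibble from [assemble_dataset()].
#' @param train_fraction,seed Passed to [patient_grouped_split()].
#' @return A tibble of class `cie_comparison`: one row per family with
#'   accuracy, per-class metrics and AUCs; evaluations in
#'   `attr(, "evaluations")`, forest importances in
#'   `attr(, "importances")`.
#' @export
compare_models <- function(specs, dataset, train_fraction = 0.7,
                           seed = 42L) {
  split <- patient_grouped_split(dataset, train_fraction, seed)
  evals <- purrr::map(specs, train_and_evaluate, train = split$train,
                      test = split$test)
  rows <- purrr::map_dfr(evals, function(ev) {
    wide <- tidyr::pivot_wider(ev$metrics, names_from = "class",
                               values_from = c("precision", "recall", "f1",
                                               "support"))
    dplyr::bind_cols(tibble::tibble(family = ev$family,
                                    accuracy = ev$accuracy,
                                    auc_micro = ev$auc[["micro"]]), wide)
  })
  rf_specs <- which(purrr::map_chr(specs, "family") == "random_forest")
  importances <- purrr::map(rf_specs, function(i) {
    fit <- fit_model(specs[[i]], split$train)
    imp <- randomForest::importance(fit)
    tibble::tibble(feature = rownames(imp), importance = imp[, 1])
  })
  structure(rows, class = c("cie_comparison", class(rows)),
            evaluations = evals, importances = importances, split = split)
}
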