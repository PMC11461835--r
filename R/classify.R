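# Five tree-based classifiers with fixed hyperparameters, evaluated under
# holdout, stratified k-fold and subject-wise cross-validation. The positive
# class throughout is "insomnia".

POSITIVE_CLASS <- "insomnia"

#' The five classifier specifications
#'
#' Decision tree (entropy criterion, depth 10), ensemble-bagged decision
#' trees (100 bootstrap entropy trees), gradient boosting (100 rounds,
#' learning rate 0.1), random forest (100 trees) and a stacking classifier
#' (level 1: EBDT, RF, DT; meta-learner: GB), all seeded with
#' `random_state = 22`.
#'
#' @return Tibble with columns `name` and `params` (list-column).
#' @export
build_models <- function() {
  tibble::tibble(
    name = c("DT", "EBDT", "GB", "RF", "SC"),
    params = list(
      list(random_state = 22, max_depth = 10, criterion = "entropy"),
      list(random_state = 22, n_estimators = 100,
           base_estimator = "DT", criterion = "entropy"),
      list(random_state = 22, n_estimators = 100, learning_rate = 0.1),
      list(random_state = 22, n_estimators = 100),
      list(random_state = 22, layer1 = c("EBDT", "RF", "DT"),
           meta_classifier = "GB")))
}

model_frame <- function(features) {
  num <- names(features)[vapply(features, is.numeric, logical(1))]
  list(x = as.data.frame(features[num]),
       y = factor(features$label, levels = c("healthy", POSITIVE_CLASS)))
}

fit_dt <- function(x, y, seed = 22) {
  set.seed(seed)
  rpart::rpart(y ~ ., data = cbind(x, y = y), method = "class",
               parms = list(split = "information"),
               control = rpart::rpart.control(maxdepth = 10, cp = 0,
                                              minsplit = 2, xval = 0))
}
predict_dt <- function(fit, x) stats::predict(fit, x)[, POSITIVE_CLASS]

fit_ebdt <- function(x, y, seed = 22, n_estimators = 100) {
  set.seed(seed)
  n <- length(y)
  trees <- lapply(seq_len(n_estimators), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    rpart::rpart(y ~ ., data = cbind(x[idx, , drop = FALSE], y = y[idx]),
                 method = "class", parms = list(split = "information"),
                 control = rpart::rpart.control(cp = 0, minsplit = 2, xval = 0))
  })
  structure(list(trees = trees), class = "sleepaug_ebdt")
}
predict_ebdt <- function(fit, x) {
  p <- vapply(fit$trees, function(tr) stats::predict(tr, x)[, POSITIVE_CLASS],
              numeric(nrow(x)))
  rowMeans(matrix(p, nrow = nrow(x)))
}

fit_gb <- function(x, y, seed = 22, n_estimators = 100, learning_rate = 0.1) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x),
                                 label = as.integer(y == POSITIVE_CLASS))
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = learning_rate,
                  max_depth = 3, nthread = 1, seed = seed),
    data = dtrain, nrounds = n_estimators, verbose = 0)
}
predict_gb <- function(fit, x) {
  as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(x))))
}

fit_rf <- function(x, y, seed = 22, n_estimators = 100) {
  set.seed(seed)
  randomForest::randomForest(x = x, y = y, ntree = n_estimators)
}
predict_rf <- function(fit, x) {
  stats::predict(fit, x, type = "prob")[, POSITIVE_CLASS]
}

fit_sc <- function(x, y, seed = 22) {
  set.seed(seed)
  n <- length(y)
  k <- min(5L, max(2L, min(table(y))))
  folds <- stratified_folds(y, k, seed)
  meta_x <- matrix(NA_real_, n, 3,
                   dimnames = list(NULL, c("EBDT", "RF", "DT")))
  for (f in seq_len(k)) {
    te <- folds == f
    xi <- x[!te, , drop = FALSE]; yi <- y[!te]
    meta_x[te, "EBDT"] <- predict_ebdt(fit_ebdt(xi, yi, seed), x[te, , drop = FALSE])
    meta_x[te, "RF"] <- predict_rf(fit_rf(xi, yi, seed), x[te, , drop = FALSE])
    meta_x[te, "DT"] <- predict_dt(fit_dt(xi, yi, seed), x[te, , drop = FALSE])
  }
  base <- list(EBDT = fit_ebdt(x, y, seed), RF = fit_rf(x, y, seed),
               DT = fit_dt(x, y, seed))
  meta <- fit_gb(as.data.frame(meta_x), y, seed)
  structure(list(base = base, meta = meta), class = "sleepaug_sc")
}
predict_sc <- function(fit, x) {
  meta_x <- data.frame(
    EBDT = predict_ebdt(fit$base$EBDT, x),
    RF = predict_rf(fit$base$RF, x),
    DT = predict_dt(fit$base$DT, x))
  predict_gb(fit$meta, meta_x)
}

MODEL_FITTERS <- list(DT = fit_dt, EBDT = fit_ebdt, GB = fit_gb,
                      RF = fit_rf, SC = fit_sc)
MODEL_PREDICTORS <- list(DT = predict_dt, EBDT = predict_ebdt, GB = predict_gb,
                         RF = predict_rf, SC = predict_sc)

#' Classification metrics from predicted probabilities
#'
#' Thresholds class-1 probabilities at 0.5 and computes the confusion counts
#' and the derived metrics: accuracy, sensitivity (= recall), specificity,
#' precision, F1, AUC (trapezoidal ROC over the probabilities) and the
#' classification error rate CER = 1 - accuracy.
#'
#' @param truth Factor or character of true labels.
#' @param prob Predicted probability of the positive class (`"insomnia"`).
#' @return One-row tibble of metrics and confusion counts.
#' @export
eval_metrics <- function(truth, prob) {
  truth <- as.character(truth)
  pred <- ifelse(prob >= 0.5, POSITIVE_CLASS, "healthy")
  tp <- sum(pred == POSITIVE_CLASS & truth == POSITIVE_CLASS)
  fp <- sum(pred == POSITIVE_CLASS & truth != POSITIVE_CLASS)
  tn <- sum(pred != POSITIVE_CLASS & truth != POSITIVE_CLASS)
  fn <- sum(pred != POSITIVE_CLASS & truth == POSITIVE_CLASS)
  acc <- (tp + tn) / (tp + fp + tn + fn)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  auc <- if (length(unique(truth)) == 2 && length(unique(prob)) > 1) {
    as.numeric(pROC::auc(pROC::roc(truth, prob, levels = c("healthy", POSITIVE_CLASS),
                                   direction = "<", quiet = TRUE)))
  } else NA_real_
  tibble::tibble(accuracy = acc, sensitivity = sens, specificity = spec,
                 precision = prec, recall = sens, f1 = f1, auc = auc,
                 cer = 1 - acc, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Metrics from explicit confusion counts
#'
#' @param tp,fp,tn,fn Confusion-matrix counts.
#' @return One-row tibble as in [eval_metrics()] (AUC is `NA`: counts carry
#'   no ranking information).
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  truth <- c(rep(POSITIVE_CLASS, tp + fn), rep("healthy", tn + fp))
  prob <- c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp))
  eval_metrics(truth, prob)
}

stratified_folds <- function(y, k, seed = 22) {
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  folds <- integer(length(y))
  for (lev in unique(y)) {
    idx <- which(y == lev)
    folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  folds
}

#' Holdout evaluation of the five classifiers
#'
#' Stratified 75/25 train/test split (seeded with `random_state`), all
#' requested models fitted on the training partition and scored on the test
#' partition.
#'
#' @param features Feature tibble with a two-category `label` column.
#' @param test_fraction Test share (default 0.25).
#' @param models Character subset of `c("DT","EBDT","GB","RF","SC")`.
#' @param random_state Seed (default 22).
#' @return A tibble of class `sleepaug_eval`: one row per model with all
#'   metrics and confusion counts.
#' @export
holdout_eval <- function(features, test_fraction = 0.25,
                         models = c("DT", "EBDT", "GB", "RF", "SC"),
                         random_state = 22) {
  mf <- model_frame(features)
  if (nlevels(droplevels(mf$y)) < 2 || min(table(mf$y)) < 2) {
    abort("Holdout evaluation needs at least two rows of each class.",
          class = "sleepaug_eval_error")
  }
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(random_state)
  te <- logical(length(mf$y))
  for (lev in levels(mf$y)) {
    idx <- which(mf$y == lev)
    te[sample(idx, max(1L, round(length(idx) * test_fraction)))] <- TRUE
  }
  xtr <- mf$x[!te, , drop = FALSE]; ytr <- mf$y[!te]
  xte <- mf$x[te, , drop = FALSE]; yte <- mf$y[te]
  out <- purrr::map_dfr(models, function(m) {
    fit <- MODEL_FITTERS[[m]](xtr, ytr, seed = random_state)
    dplyr::bind_cols(tibble::tibble(model = m),
                     eval_metrics(yte, MODEL_PREDICTORS[[m]](fit, xte)))
  })
  class(out) <- c("sleepaug_eval", class(out))
  attr(out, "scheme") <- "holdout"
  out
}

#' Stratified k-fold cross-validation
#'
#' @param features Feature tibble.
#' @param k Number of folds (default 5).
#' @param model One model name (default `"RF"`).
#' @param random_state Seed (default 22).
#' @return Tibble of class `sleepaug_cv` with per-fold accuracy; the mean is
#'   available via [glance()].
#' @export
kfold_cv <- function(features, k = 5, model = "RF", random_state = 22) {
  mf <- model_frame(features)
  if (k > length(mf$y)) abort("More folds than rows.",
                              class = "sleepaug_input_error")
  folds <- stratified_folds(mf$y, k, random_state)
  out <- purrr::map_dfr(seq_len(k), function(f) {
    te <- folds == f
    fit <- MODEL_FITTERS[[model]](mf$x[!te, , drop = FALSE], mf$y[!te],
                                  seed = random_state)
    prob <- MODEL_PREDICTORS[[model]](fit, mf$x[te, , drop = FALSE])
    tibble::tibble(fold = f, n_test = sum(te),
                   accuracy = mean((prob >= 0.5) ==
                                     (mf$y[te] == POSITIVE_CLASS)))
  })
  out$model <- model
  class(out) <- c("sleepaug_cv", class(out))
  attr(out, "scheme") <- "kfold"
  out
}

# Pair one insomnia with one healthy subject per fold so each test fold is
# two-class; with unbalanced or scarce classes, remaining subjects are dealt
# round-robin.
pair_subject_folds <- function(subject, label, folds, seed = 22) {
  subj <- unique(subject)
  if (length(subj) < folds) {
    abort("Fewer subject groups than requested folds.",
          class = "sleepaug_input_error")
  }
  lab_of <- vapply(subj, function(s) as.character(label[match(s, subject)]),
                   character(1))
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  pos <- sample(subj[lab_of == POSITIVE_CLASS])
  neg <- sample(subj[lab_of != POSITIVE_CLASS])
  assign_f <- stats::setNames(integer(length(subj)), subj)
  if (length(subj) == folds) {
    # as many folds as subject groups: leave-one-group-out
    assign_f[c(pos, neg)] <- seq_len(folds)
  } else {
    assign_f[pos] <- rep(seq_len(folds), length.out = length(pos))
    assign_f[neg] <- rep(seq_len(folds), length.out = length(neg))
  }
  assign_f
}

#' Subject-wise cross-validation
#'
#' Group cross-validation keyed on `subject_id`: all rows of a held-out
#' subject appear only in that fold's test set, so no individual contributes
#' to both train and test (guarding against identity leakage). With a
#' balanced 12-subject cohort and 6 folds each test fold holds exactly one
#' insomnia and one healthy subject. Rows without a subject id (e.g.
#' GAN-synthesized rows) are dropped with a message.
#'
#' @param features Feature tibble with `subject_id`.
#' @param folds Number of folds (default 6).
#' @param model One model name (default `"RF"`).
#' @param random_state Seed (default 22).
#' @return Tibble of class `sleepaug_cv` with per-fold accuracy and the
#'   held-out subjects.
#' @export
subjectwise_cv <- function(features, folds = 6, model = "RF",
                           random_state = 22) {
  stopifnot("subject_id" %in% names(features))
  drop <- is.na(features$subject_id)
  if (any(drop)) {
    message(sprintf("Dropping %d rows without subject attribution.", sum(drop)))
    features <- features[!drop, ]
  }
  mf <- model_frame(features)
  fmap <- pair_subject_folds(features$subject_id, features$label, folds,
                             random_state)
  fold_of <- fmap[features$subject_id]
  out <- purrr::map_dfr(seq_len(folds), function(f) {
    te <- fold_of == f
    fit <- MODEL_FITTERS[[model]](mf$x[!te, , drop = FALSE], mf$y[!te],
                                  seed = random_state)
    prob <- MODEL_PREDICTORS[[model]](fit, mf$x[te, , drop = FALSE])
    tibble::tibble(
      fold = f, n_test = sum(te),
      test_subjects = paste(sort(unique(features$subject_id[te])),
                            collapse = ","),
      accuracy = mean((prob >= 0.5) == (mf$y[te] == POSITIVE_CLASS)))
  })
  out$model <- model
  class(out) <- c("sleepaug_cv", class(out))
  attr(out, "scheme") <- "subjectwise"
  out
}

#' @export
glance.sleepaug_cv <- function(x, ...) {
  tibble::tibble(scheme = attr(x, "scheme"), model = x$model[1],
                 folds = nrow(x), mean_accuracy = mean(x$accuracy),
                 sd_accuracy = stats::sd(x$accuracy))
}

#' @export
tidy.sleepaug_eval <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x)[c("model", "accuracy", "sensitivity",
                                             "specificity", "precision",
                                             "recall", "f1", "auc", "cer")],
                      -"model", names_to = "metric", values_to = "value")
}
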