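# Separable two-class toy feature table with subject structure.
make_table <- function(n_subj_per_class = 6, rows_per_subj = 10, gap = 3,
                       seed = 70, noise_cols = 3) {
  set.seed(seed)
  rows <- list()
  for (g in c("insomnia", "healthy")) {
    mu <- if (g == "insomnia") gap else 0
    for (s in seq_len(n_subj_per_class)) {
      subj_mu <- rnorm(1, mu, 0.5)
      d <- tibble::tibble(x1 = rnorm(rows_per_subj, subj_mu),
                          label = g,
                          subject_id = paste0(substr(g, 1, 1), s))
      for (k in seq_len(noise_cols)) d[[paste0("noise", k)]] <- rnorm(rows_per_subj)
      rows[[length(rows) + 1]] <- d
    }
  }
  dplyr::bind_rows(rows)
}

test_that("the five model specs carry the fixed hyperparameters", {
  specs <- build_models()
  expect_equal(nrow(specs), 5)
  expect_setequal(specs$name, c("DT", "EBDT", "GB", "RF", "SC"))
  expect_true(all(vapply(specs$params, function(p) p$random_state == 22, TRUE)))
  expect_equal(specs$params[[which(specs$name == "DT")]]$max_depth, 10)
  expect_equal(specs$params[[which(specs$name == "DT")]]$criterion, "entropy")
  expect_equal(specs$params[[which(specs$name == "SC")]]$meta_classifier, "GB")
  expect_setequal(specs$params[[which(specs$name == "SC")]]$layer1,
                  c("EBDT", "RF", "DT"))
})

test_that("constructed confusion matrix yields the textbook metric values", {
  m <- confusion_metrics(tp = 45, fp = 10, tn = 40, fn = 5)
  expect_equal(m$sensitivity, 0.90)
  expect_equal(m$specificity, 0.80)
  expect_equal(m$precision, 45 / 55, tolerance = 1e-12)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$f1, 2 * (45 / 55) * 0.9 / (45 / 55 + 0.9), tolerance = 1e-12)
  expect_equal(m$cer, 0.15)
})

test_that("CER = 1 - accuracy and F1 is the harmonic mean, on every report", {
  tab <- make_table(seed = 71)
  rep <- holdout_eval(tab)
  expect_equal(rep$cer, 1 - rep$accuracy)
  expect_equal(rep$recall, rep$sensitivity)
  f1 <- 2 * rep$precision * rep$recall / (rep$precision + rep$recall)
  expect_equal(rep$f1, f1)
  expect_equal(rep$accuracy, (rep$tp + rep$tn) /
                 (rep$tp + rep$fp + rep$tn + rep$fn))
  expect_true(all(rep$accuracy >= 0 & rep$accuracy <= 1))
})

test_that("a separable table is classified perfectly under holdout", {
  tab <- make_table(gap = 10, seed = 72)
  rep <- holdout_eval(tab, models = c("DT", "RF"))
  expect_equal(rep$accuracy, c(1, 1))
  expect_equal(rep$cer, c(0, 0))
})

test_that("label-permuted features give chance-level AUC", {
  set.seed(73)
  n <- 2000
  tab <- tibble::as_tibble(matrix(rnorm(n * 10), n,
                                  dimnames = list(NULL, paste0("x", 1:10))))
  tab$label <- sample(c("insomnia", "healthy"), n, TRUE)
  rep <- holdout_eval(tab, models = "RF")
  expect_lt(abs(rep$auc - 0.5), 0.05)
})

test_that("single-class tables are rejected", {
  tab <- make_table(seed = 74)
  expect_error(holdout_eval(tab[tab$label == "insomnia", ]),
               class = "sleepaug_eval_error")
})

test_that("stratified k-fold partitions rows exactly once", {
  tab <- make_table(n_subj_per_class = 5, rows_per_subj = 10, seed = 75)
  expect_equal(nrow(tab), 100)
  cv <- kfold_cv(tab, k = 5, model = "DT")
  expect_equal(nrow(cv), 5)
  expect_equal(cv$n_test, rep(20, 5))
  folds <- sleepaug:::stratified_folds(factor(tab$label), 5)
  expect_equal(as.integer(sort(table(folds))), rep(20L, 5))
  expect_length(folds, 100)
  cv2 <- kfold_cv(make_table(gap = 10, seed = 76), k = 5, model = "RF")
  expect_equal(mean(cv2$accuracy), 1.0)
  expect_error(kfold_cv(tab[1:3, ], k = 5), class = "sleepaug_input_error")
})

test_that("subject-wise folds pair classes and never leak subjects", {
  tab <- make_table(n_subj_per_class = 6, rows_per_subj = 8, seed = 77)
  cv <- subjectwise_cv(tab, folds = 6, model = "DT")
  expect_equal(nrow(cv), 6)
  for (f in seq_len(6)) {
    subj <- strsplit(cv$test_subjects[f], ",")[[1]]
    expect_length(subj, 2)
    expect_setequal(substr(subj, 1, 1), c("i", "h"))   # one of each class
  }
  expect_setequal(unlist(strsplit(cv$test_subjects, ",")),
                  unique(tab$subject_id))
})

test_that("no subject straddles train and test in any fold (property)", {
  for (seed in 78:80) {
    tab <- make_table(n_subj_per_class = sample(3:6, 1), rows_per_subj = 5,
                      seed = seed)
    folds <- min(3, length(unique(tab$subject_id)) / 2)
    fmap <- sleepaug:::pair_subject_folds(tab$subject_id, tab$label, folds)
    fold_of_row <- fmap[tab$subject_id]
    for (f in seq_len(folds)) {
      tr_subj <- unique(tab$subject_id[fold_of_row != f])
      te_subj <- unique(tab$subject_id[fold_of_row == f])
      expect_length(intersect(tr_subj, te_subj), 0)
    }
  }
})

test_that("six singleton subjects degenerate to leave-one-subject-out", {
  tab <- make_table(n_subj_per_class = 3, rows_per_subj = 6, gap = 10,
                    seed = 81)
  cv <- subjectwise_cv(tab, folds = 6, model = "DT")
  expect_equal(nrow(cv), 6)
  expect_true(all(lengths(strsplit(cv$test_subjects, ",")) == 1))
  expect_error(subjectwise_cv(tab, folds = 7),
               class = "sleepaug_input_error")
})

test_that("rows without subject attribution are dropped from subject-wise CV", {
  tab <- make_table(seed = 82)
  tab$subject_id[1:5] <- NA
  expect_message(cv <- subjectwise_cv(tab, folds = 3, model = "DT"),
                 "without subject attribution")
  expect_equal(sum(cv$n_test), nrow(tab) - 5)
})
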