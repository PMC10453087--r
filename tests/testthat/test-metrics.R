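test_that("the 30% / 3:1 split protocol yields 120/210/70 for N = 400", {
  labels <- rep(c("BaP+Pyr", "BaP+Nap", "Pyr+Nap", "BaP+Pyr+Nap"), each = 100)
  sp <- split_dataset(labels, seed = 1)
  expect_length(sp$prediction, 120)
  expect_length(sp$training, 210)
  expect_length(sp$validation, 70)
  # stratification: every class contributes 30 prediction spectra
  expect_true(all(table(labels[sp$prediction]) == 30))
  expect_true(all(table(labels[sp$training]) %in% c(52, 53)))
  expect_true(all(table(labels[sp$validation]) %in% c(17, 18)))
  expect_identical(split_dataset(labels, seed = 1),
                   split_dataset(labels, seed = 1))
  expect_false(identical(split_dataset(labels, seed = 2)$prediction,
                         sp$prediction))
})

test_that("splits partition the index set exactly, across seeds and sizes", {
  for (seed in 1:100) {
    n_k <- c(17, 23, 31, 9)
    labels <- rep(letters[1:4], times = n_k)
    sp <- split_dataset(labels, seed = seed)
    all_idx <- c(sp$training, sp$validation, sp$prediction)
    expect_identical(sort(all_idx), seq_along(labels))  # cover, no duplicates
    expect_length(sp$prediction, round(0.3 * length(labels)))
  }
  expect_error(split_dataset(c("a", "a", "b"), seed = 1), "at least")
  expect_error(split_dataset(rep(c("a", "b"), c(100, 3)), seed = 1),
               "too few|at least")
})

test_that("group-aware splitting keeps replicates of a sample together", {
  labels <- rep(c("x", "y"), each = 50)
  group <- paste0(labels, "_", rep(1:10, each = 5))
  sp <- split_dataset(labels, seed = 3, group = group)
  subsets <- list(sp$training, sp$validation, sp$prediction)
  for (g in unique(group)) {
    hit <- vapply(subsets, function(idx) any(group[idx] == g), TRUE)
    expect_equal(sum(hit), 1)  # each sample lives in exactly one subset
  }
})

test_that("per-class counts match a brute-force enumeration", {
  set.seed(42)
  for (rep_i in 1:20) {
    truth <- sample(letters[1:4], 60, replace = TRUE)
    pred <- sample(letters[1:4], 60, replace = TRUE)
    cm <- confusion_matrix(truth, pred)
    expect_equal(sum(cm), 60)
    expect_equal(unname(rowSums(cm)), unname(as.vector(table(factor(truth)))))
    for (k in 1:4) {
      cls <- letters[k]
      ct <- per_class_counts(cm, k)
      expect_equal(ct[["tp"]], sum(truth == cls & pred == cls))
      expect_equal(ct[["fp"]], sum(truth != cls & pred == cls))
      expect_equal(ct[["fn"]], sum(truth == cls & pred != cls))
      expect_equal(ct[["tn"]], sum(truth != cls & pred != cls))
      expect_equal(sum(ct), 60)  # partition identity
    }
  }
  dg <- diag(c(3, 5, 7))
  for (k in 1:3) {
    ct <- per_class_counts(dg, k)
    expect_equal(ct[["fp"]], 0)
    expect_equal(ct[["fn"]], 0)
  }
})

test_that("F1 reproduces the published worked examples to 2 decimals", {
  for (i in seq_len(nrow(table1_triples)))
    expect_equal(round(f1_score(table1_triples$precision[i],
                                table1_triples$recall[i]), 2),
                 table1_triples$f1[i])
})

test_that("report metrics obey their identities and bounds", {
  set.seed(7)
  for (rep_i in 1:25) {
    cm <- matrix(rpois(16, 8), 4, 4,
                 dimnames = list(true = letters[1:4],
                                 predicted = letters[1:4]))
    rp <- classification_metrics(cm)
    expect_equal(rp$accuracy, 100 * sum(diag(cm)) / sum(cm))  # trace identity
    ok <- !is.na(rp$per_class$f1)
    expect_true(all(rp$per_class$f1[ok] >=
                      pmin(rp$per_class$precision, rp$per_class$recall)[ok] - 1e-9))
    expect_true(all(rp$per_class$f1[ok] <=
                      pmax(rp$per_class$precision, rp$per_class$recall)[ok] + 1e-9))
    vals <- unlist(rp$per_class[c("precision", "recall", "f1")])
    expect_true(all(vals[!is.na(vals)] >= 0 & vals[!is.na(vals)] <= 100))
  }

  # a class never predicted has undefined precision, flagged not zeroed
  cm <- matrix(c(5, 0, 3, 0, 0, 0, 0, 0, 4), 3, 3,
               dimnames = list(true = c("a", "b", "c"),
                               predicted = c("a", "b", "c")))
  rp <- classification_metrics(cm)
  expect_true(is.na(rp$per_class$precision[rp$per_class$class == "b"]))
})

test_that("evaluation reports agree with an independent recount", {
  labels <- factor(rep(c("a", "b", "c", "d"), each = 10))
  perfect <- classification_metrics(confusion_matrix(labels, labels))
  expect_equal(perfect$accuracy, 100)
  expect_true(all(perfect$confusion[upper.tri(perfect$confusion)] == 0))
  expect_true(all(perfect$confusion[lower.tri(perfect$confusion)] == 0))

  # degenerate predictor: always class "a" on a balanced set
  const <- classification_metrics(
    confusion_matrix(labels, factor(rep("a", 40), levels = levels(labels))))
  expect_equal(const$accuracy, 25)
  expect_equal(const$per_class$recall, c(100, 0, 0, 0))

  set.seed(13)
  pred <- factor(sample(levels(labels), 40, replace = TRUE),
                 levels = levels(labels))
  rp <- classification_metrics(confusion_matrix(labels, pred))
  expect_equal(rp$accuracy, 100 * mean(as.character(pred) ==
                                         as.character(labels)))
})
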