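test_that("volume error: zero at equality, exact arithmetic, antisymmetry", {
  expect_equal(volume_error(100, 100)$fraction, 0)
  ve <- volume_error(150, 100)
  expect_equal(ve$fraction, 0.4)
  expect_equal(ve$percent, 40)
  set.seed(28)
  for (i in 1:20) {
    s <- sample(0:500, 1); g <- sample(1:500, 1)
    expect_equal(volume_error(s, g)$fraction, -volume_error(g, s)$fraction)
    expect_lte(abs(volume_error(s, g)$fraction), 2)
  }
  expect_warning(ve0 <- volume_error(0, 0), "empty")
  expect_equal(ve0$fraction, 0)
})

test_that("Dice and Jaccard: exact values, symmetry, and their algebraic
           identity", {
  a <- matrix(0L, 4, 4); a[1:2, 1:2] <- 1L
  expect_equal(dice(a, a), 1)
  b <- matrix(0L, 4, 4); b[3:4, 3:4] <- 1L
  expect_equal(dice(a, b), 0)
  # |S|=|G|=4, overlap 2
  c_ <- matrix(0L, 4, 4); c_[2:3, 1:2] <- 1L
  expect_equal(dice(a, c_), 0.5)
  expect_equal(jaccard(a, c_), 1 / 3)
  expect_equal(jaccard(a, a), 1)

  set.seed(29)
  for (i in 1:100) {
    s <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8, 8)
    g <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8, 8)
    d <- dice(s, g); j <- jaccard(s, g)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
    expect_lte(j, d + 1e-15)
    expect_equal(d, dice(g, s))
  }
  expect_warning(expect_equal(dice(matrix(0L, 2, 2), matrix(0L, 2, 2)), 1))
})

test_that("accuracy and F1 follow their closed forms and the precision/
           recall identity", {
  expect_equal(accuracy(90, 120), 75)
  expect_equal(accuracy(0, 10), 0)
  expect_equal(accuracy(7, 7), 100)
  expect_error(accuracy(5, 0), "m must be > 0")

  expect_equal(f1_score(confusion_counts(8, 0, 2, 2)), 0.8)
  expect_equal(f1_score(confusion_counts(5, 9, 0, 0)), 1)
  expect_warning(expect_equal(f1_score(confusion_counts(0, 5, 0, 0)), 0))

  set.seed(30)
  for (i in 1:20) {
    cc <- confusion_counts(sample(1:50, 1), sample(0:50, 1),
                           sample(0:50, 1), sample(0:50, 1))
    p <- cc$T_plus / (cc$T_plus + cc$F_plus)
    r <- cc$T_plus / (cc$T_plus + cc$F_minus)
    expect_equal(f1_score(cc), 2 * p * r / (p + r), tolerance = 1e-12)
  }

  # brute-force confusion loop agrees with confusion_from_labels
  pred <- rbinom(40, 1, 0.5); truth <- rbinom(40, 1, 0.5)
  cc <- confusion_from_labels(pred, truth)
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in 1:40) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1
    if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1
  }
  expect_equal(c(cc$T_plus, cc$T_minus, cc$F_plus, cc$F_minus),
               c(tp, tn, fp, fn))
})

test_that("rmse: zero at identity, exact value, absolute-scale homogeneity", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  set.seed(31)
  x <- rnorm(10); y <- rnorm(10); a <- -2.5
  expect_equal(rmse(a * x, a * y), abs(a) * rmse(x, y))
})

test_that("ventilation imbalance hits its closed-form endpoints", {
  expect_equal(lr_imbalance(3, 3), 0)
  expect_equal(lr_imbalance(5, 0), 1)
  expect_equal(lr_imbalance(0, 5), -1)
  expect_equal(lr_imbalance(2, 1), 1 / 3)
  expect_error(lr_imbalance(0, 0), "> 0")
})

test_that("fold plans partition the index set with balanced sizes", {
  plan <- kfold_plan(100, 10, seed = 7)
  expect_length(plan$folds, 10)
  expect_true(all(lengths(plan$folds) == 10))
  expect_setequal(unlist(plan$folds), 1:100)

  plan2 <- kfold_plan(10, 10, seed = 7)
  expect_true(all(lengths(plan2$folds) == 1))

  set.seed(32)
  for (i in 1:10) {
    n <- sample(5:40, 1); k <- sample(2:n, 1)
    p <- kfold_plan(n, k, seed = i)
    expect_setequal(unlist(p$folds), seq_len(n))
    expect_equal(sum(lengths(p$folds)), n)
    expect_lte(diff(range(lengths(p$folds))), 1)
  }
  expect_error(kfold_plan(5, 6), "exceed")
})

test_that("evaluate_run aggregates mean and population sd", {
  a <- matrix(0L, 4, 4); a[1:2, 1:2] <- 1L
  c_ <- matrix(0L, 4, 4); c_[2:3, 1:2] <- 1L
  rep1 <- evaluate_run(list(a, a), list(a, a))
  expect_equal(rep1$summary$mean[rep1$summary$metric == "dsc"], 1)
  expect_equal(rep1$summary$sd[rep1$summary$metric == "dsc"], 0)
  expect_equal(rep1$summary$mean[rep1$summary$metric == "ve_percent"], 0)

  # items with DSC 0.5 and 1.0 -> mean 0.75, population sd 0.25
  rep2 <- evaluate_run(list(c_, a), list(a, a))
  expect_equal(rep2$summary$mean[rep2$summary$metric == "dsc"], 0.75)
  expect_equal(rep2$summary$sd[rep2$summary$metric == "dsc"], 0.25)

  rep3 <- evaluate_run(list(a), list(a))
  expect_equal(rep3$summary$sd[rep3$summary$metric == "jss"], 0)

  expect_error(evaluate_run(list(a), list(a, a)), "misaligned")

  # labels add a classification block; report writes both formats
  rep4 <- evaluate_run(list(a, c_), list(a, a),
                       pred_labels = c(1, 0), true_labels = c(1, 1))
  expect_equal(rep4$classification$accuracy_percent, 50)
  fj <- withr::local_tempfile(fileext = ".json")
  fc <- withr::local_tempfile(fileext = ".csv")
  write_metrics_report(rep4, fj, fc)
  expect_true(jsonlite::validate(paste(readLines(fj), collapse = "")))
  expect_equal(nrow(read.csv(fc)), 4)
})
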