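#' Train a nodule classifier on LBP descriptors
#'
#' Two modes. `"sign-unit"` implements the hard threshold unit: hidden-to-
#' output weights constrained to `{-1, +1}`, bias fixed at 1, decision
#' `class = 1` when the weighted sum is `>= 0`. Training runs perceptron
#' updates on real-valued shadow weights, projecting to signs after every
#' epoch. `"logistic"` is the practical default: an L2-penalized logistic
#' regression (glmnet ridge), which is well-posed even when the descriptor
#' dimension exceeds the sample count.
#'
#' @param features list of `lbp_descriptor`s (or numeric feature rows).
#' @param labels 0/1 vector, one per feature; both classes must be present.
#' @param mode `"logistic"` or `"sign-unit"`.
#' @param epochs perceptron epochs (sign-unit mode).
#' @param lr perceptron learning rate.
#' @param lambda ridge penalty (logistic mode).
#' @param seed RNG seed for the sample order; identical seeds give
#'   identical models.
#' @return a `classifier_model` with `mode`, `weights`, `bias`.
#' @export
train_classifier <- function(features, labels,
                             mode = c("logistic", "sign-unit"),
                             epochs = 50L, lr = 0.1, lambda = 1e-2,
                             seed = 1L) {
  mode <- match.arg(mode)
  X <- features_matrix(features)
  y <- as.integer(labels)
  if (length(y) != nrow(X)) stop_input("one label per feature row required")
  if (!all(y %in% c(0L, 1L))) stop_input("labels must be 0/1")
  if (length(unique(y)) < 2L)
    stop_input("training requires both classes present (single-class input)")
  if (mode == "sign-unit") {
    d <- ncol(X)
    w <- numeric(d)                 # real-valued shadow weights
    with_seed(seed, {
      for (e in seq_len(epochs)) {
        ord <- sample.int(nrow(X))
        for (i in ord) {
          pred <- as.integer(sum(w * X[i, ]) + 1 >= 0)  # bias fixed at 1
          if (pred != y[i]) w <- w + lr * (y[i] - pred) * X[i, ]
        }
      }
    })
    ws <- ifelse(w >= 0, 1, -1)     # project to the {-1, +1} constraint
    model <- list(mode = "sign-unit", weights = ws, bias = 1,
                  shadow = w, dim = d)
  } else {
    fit <- with_seed(seed,
      glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                     lambda = lambda, standardize = TRUE))
    model <- list(mode = "logistic",
                  weights = as.numeric(coef(fit)[-1]),
                  bias = as.numeric(coef(fit)[1]),
                  dim = ncol(X))
  }
  structure(model, class = "classifier_model")
}

features_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  if (inherits(features, "lbp_descriptor")) features <- list(features)
  rows <- lapply(features, function(f) {
    if (inherits(f, "lbp_descriptor")) f$histogram
    else if (is.numeric(f)) f
    else stop_input("features must be lbp_descriptors or numeric vectors")
  })
  do.call(rbind, rows)
}

#' Classify a descriptor
#'
#' Sign-unit mode applies the hard rule: class 1 iff
#' `sum(w * x) + bias >= 0`. Logistic mode thresholds the fitted
#' probability at 0.5.
#'
#' @param model a `classifier_model` from [train_classifier].
#' @param descriptor an `lbp_descriptor` or numeric vector (dimension must
#'   match the model).
#' @return class label 0 or 1 (logistic mode: attribute `"prob"` carries
#'   the probability).
#' @export
classify <- function(model, descriptor) {
  x <- if (inherits(descriptor, "lbp_descriptor")) descriptor$histogram
  else as.numeric(descriptor)
  if (length(x) != model$dim)
    stop_input("descriptor dimension ", length(x),
               " does not match model dimension ", model$dim)
  score <- sum(model$weights * x) + model$bias
  if (model$mode == "sign-unit") {
    as.integer(score >= 0)
  } else {
    p <- 1 / (1 + exp(-score))
    structure(as.integer(p >= 0.5), prob = p)
  }
}

#' Cross-validated classification of a phantom set
#'
#' Extracts mask-restricted LBP descriptors from a list of phantoms (see
#' [make_phantom]) and reports k-fold cross-validation accuracy of the
#' chosen classifier mode.
#'
#' @param phantoms list of phantom items (image/mask/label).
#' @param cfg an [lbp_config].
#' @param folds number of folds.
#' @param mode classifier mode.
#' @param seed seed for fold assignment and training.
#' @return list with `accuracy_percent`, per-fold accuracies and the fold plan.
#' @export
classify_phantoms_cv <- function(phantoms, cfg = lbp_config(), folds = 5L,
                                 mode = "logistic", seed = 1L) {
  feats <- lapply(phantoms, function(p)
    extract_features(p$image, mask = p$mask, cfg = cfg))
  X <- features_matrix(feats)
  y <- vapply(phantoms, `[[`, integer(1), "label")
  plan <- kfold_plan(length(y), folds, seed = seed)
  acc <- vapply(plan$folds, function(test_idx) {
    train_idx <- setdiff(seq_along(y), test_idx)
    model <- train_classifier(X[train_idx, , drop = FALSE], y[train_idx],
                              mode = mode, seed = seed)
    pred <- vapply(test_idx, function(i)
      as.integer(classify(model, X[i, ])), integer(1))
    mean(pred == y[test_idx])
  }, numeric(1))
  list(accuracy_percent = 100 * mean(acc), fold_accuracy = acc, plan = plan)
}
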