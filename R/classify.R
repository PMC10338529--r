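# Three classification tasks on GRF feature vectors, evaluated under a
# nested, task-stratified four-fold cross-validation:
#   subject_x_footwear - one class per (subject, footwear) cell; each cell's
#                        trials are spread equally over the folds.
#   subject            - one class per subject; folds are footwear-disjoint
#                        (leave-one-condition-out with 4 conditions).
#   footwear           - one class per condition; folds are subject-disjoint
#                        (subjects partitioned into k groups).

#' Specification of a classification task
#'
#' @param name one of `"subject_x_footwear"`, `"subject"`, `"footwear"`.
#' @return an object of class `task_spec` with the task name, its label
#'   function (metadata -> factor) and its fold rule.
#' @export
task_spec <- function(name = c("subject_x_footwear", "subject", "footwear")) {
  name <- match.arg(name)
  labels <- switch(name,
    subject_x_footwear = function(meta)
      factor(paste(meta$subject_id, meta$footwear_id, sep = ":")),
    subject = function(meta) factor(meta$subject_id),
    footwear = function(meta) factor(meta$footwear_id)
  )
  rule <- switch(name,
    subject_x_footwear = "per-class-balanced",
    subject = "footwear-disjoint",
    footwear = "subject-disjoint"
  )
  structure(list(name = name, labels = labels, fold_rule = rule),
            class = "task_spec")
}

#' Build cross-validation folds for a task
#'
#' Fold construction follows the task's stratification rule:
#' `subject_x_footwear` spreads every (subject, footwear) cell's trials
#' equally over the `k` folds (10 trials -> 2 or 3 per fold); `subject`
#' assigns each footwear condition wholly to one fold
#' (leave-one-condition-out; requires exactly `k` conditions); `footwear`
#' partitions the subjects into `k` groups of near-equal size (30 subjects,
#' k = 4 -> sizes 8, 8, 7, 7) and assigns each group's recordings to one
#' fold.
#'
#' @param task a [task_spec()].
#' @param metadata data.frame with `subject_id` and `footwear_id` columns.
#' @param k number of folds (default 4).
#' @param seed RNG seed for the random assignments.
#' @return integer vector of fold indices (1..k), one per metadata row.
#' @export
make_folds <- function(task, metadata, k = 4, seed = 1) {
  stopifnot(inherits(task, "task_spec"))
  n <- nrow(metadata)
  folds <- integer(n)
  with_seed(seed, {
    if (task$fold_rule == "per-class-balanced") {
      cell <- paste(metadata$subject_id, metadata$footwear_id, sep = ":")
      for (cl in unique(cell)) {
        idx <- sample(which(cell == cl))
        start <- sample.int(k, 1)
        folds[idx] <- ((start + seq_along(idx) - 2L) %% k) + 1L
      }
    } else if (task$fold_rule == "footwear-disjoint") {
      conds <- sort(unique(metadata$footwear_id))
      if (length(conds) != k)
        stop(sprintf(
          "footwear-disjoint folds need exactly k = %d conditions, got %d",
          k, length(conds)), call. = FALSE)
      folds <- match(metadata$footwear_id, conds)
    } else {
      subjects <- sample(sort(unique(metadata$subject_id)))
      if (length(subjects) < k)
        stop("subject-disjoint folds need at least k subjects", call. = FALSE)
      sizes <- rep(length(subjects) %/% k, k)
      extra <- length(subjects) %% k
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      grp <- rep(seq_len(k), sizes)
      folds <- grp[match(metadata$subject_id, subjects)]
    }
  })
  folds
}

# Inner 2-fold splits used by the grid search, respecting the task's fold
# rule where the training data allow it.  For the subject task the (k - 1)
# training conditions cannot be split evenly into two condition-disjoint
# folds; the closest analogue is used: conditions are divided into two
# groups (2/1 for three conditions) and both train-on-one / test-on-other
# directions are evaluated and averaged.
inner_splits <- function(task, metadata, seed = 1) {
  n <- nrow(metadata)
  with_seed(seed, {
    if (task$fold_rule == "per-class-balanced") {
      half <- integer(n)
      cell <- paste(metadata$subject_id, metadata$footwear_id, sep = ":")
      for (cl in unique(cell)) {
        idx <- sample(which(cell == cl))
        half[idx] <- (seq_along(idx) %% 2L) + 1L
      }
    } else if (task$fold_rule == "footwear-disjoint") {
      conds <- sample(sort(unique(metadata$footwear_id)))
      grp1 <- conds[seq_len(ceiling(length(conds) / 2))]
      half <- ifelse(metadata$footwear_id %in% grp1, 1L, 2L)
    } else {
      subj <- sample(sort(unique(metadata$subject_id)))
      grp1 <- subj[seq_len(ceiling(length(subj) / 2))]
      half <- ifelse(metadata$subject_id %in% grp1, 1L, 2L)
    }
    list(list(train = which(half == 1L), test = which(half == 2L)),
         list(train = which(half == 2L), test = which(half == 1L)))
  })
}

#' The default regularisation grid
#'
#' Powers of two from `2^-5` to `2^15` in exponent steps of 0.25
#' (81 candidate values).
#'
#' @param from,to,by exponent range and step.
#' @return numeric vector of candidate `C` values.
#' @export
c_grid <- function(from = -5, to = 15, by = 0.25) {
  if (to < from || by <= 0) stop("invalid grid specification", call. = FALSE)
  2^seq(from, to, by = by)
}

#' Train a one-vs-rest linear SVM
#'
#' L2-regularised L2-loss support vector classification with a linear
#' kernel, fitted in the dual by coordinate descent.  One binary classifier
#' is trained per class (one-vs-rest); prediction is the class with the
#' highest decision score `W_k . x + b_k`.  The intercept is handled as an
#' augmented, regularised feature.
#'
#' @param x numeric feature matrix (scaled; rows = recordings).
#' @param y class labels (factor or coercible).
#' @param C regularisation constant.
#' @param eps dual optimality tolerance (default 0.1, the conventional default of this solver family).
#' @param max_iter maximum coordinate-descent epochs.
#' @param solver_seed seed of the solver's internal shuffling; fixed for
#'   reproducibility.
#' @return an object of class `linsvm` with the weight matrix `W`
#'   (n_classes x n_features), intercepts `b`, `C` and the class levels.
#' @export
train_svm <- function(x, y, C, eps = 0.1, max_iter = 1000,
                      solver_seed = 1L) {
  x <- as.matrix(x)
  if (!all(is.finite(x)))
    stop("feature matrix contains non-finite values", call. = FALSE)
  y <- factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2)
    stop("training data must contain at least 2 classes", call. = FALSE)
  if (C <= 0) stop("C must be positive", call. = FALSE)
  xa <- cbind(x, 1)
  K <- nlevels(y)
  W <- matrix(0, K, ncol(xa))
  for (k in seq_len(K)) {
    ybin <- ifelse(as.integer(y) == k, 1, -1)
    W[k, ] <- l2svc_dcd(xa, ybin, C, eps, as.integer(max_iter),
                        as.integer(solver_seed))
  }
  structure(list(W = W[, seq_len(ncol(x)), drop = FALSE],
                 b = W[, ncol(xa)], C = C, classes = levels(y),
                 eps = eps, solver_seed = solver_seed),
            class = "linsvm")
}

#' @export
print.linsvm <- function(x, ...) {
  cat(sprintf(
    "One-vs-rest linear SVM (L2-regularised L2-loss): %d classes, %d features, C = %g\n",
    length(x$classes), ncol(x$W), x$C))
  invisible(x)
}

#' Decision scores and predictions of a linear SVM
#'
#' @param object a `linsvm` model.
#' @param newx feature matrix or single feature vector (same scaling as the
#'   training data).
#' @param type `"class"` for predicted labels, `"scores"` for the decision
#'   score matrix.
#' @param ... unused.
#' @return factor of predicted classes or a score matrix (columns =
#'   classes).  Score ties are broken towards the first class level.
#' @export
predict.linsvm <- function(object, newx, type = c("class", "scores"), ...) {
  type <- match.arg(type)
  xm <- if (is.null(dim(newx))) matrix(newx, nrow = 1) else as.matrix(newx)
  scores <- xm %*% t(object$W) + rep(object$b, each = nrow(xm))
  colnames(scores) <- object$classes
  if (type == "scores") return(scores)
  factor(object$classes[max.col(scores, ties.method = "first")],
         levels = object$classes)
}

#' @export
coef.linsvm <- function(object, ...) {
  cbind(object$W, `(intercept)` = object$b)
}

#' Zero-rule baseline accuracy
#'
#' Accuracy of always predicting the most frequent training class; ties are
#' broken towards the first-encountered label.
#'
#' @param y training labels.
#' @return baseline accuracy in \[0, 1\].
#' @export
zero_rule_baseline <- function(y) {
  if (length(y) == 0) stop("empty label vector", call. = FALSE)
  counts <- table(factor(y, levels = unique(as.character(y))))
  max(counts) / length(y)
}

#' Grid search for the regularisation constant
#'
#' Evaluates every candidate `C` by mean accuracy over the supplied inner
#' splits (default: an inner two-fold cross-validation built by the task's
#' fold rule) and returns the maximiser; ties go to the smallest `C`.
#'
#' @param x scaled training feature matrix.
#' @param y training labels.
#' @param grid candidate `C` values (default [c_grid()], 81 values).
#' @param splits list of `list(train, test)` index pairs.
#' @param eps,max_iter,solver_seed passed to [train_svm()].
#' @return list with `C` (selected value) and `accuracy` (mean inner
#'   accuracy per grid value).
#' @export
grid_search_C <- function(x, y, grid = c_grid(), splits,
                          eps = 0.1, max_iter = 1000, solver_seed = 1L) {
  if (length(grid) == 0) stop("empty C grid", call. = FALSE)
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2)
    stop("grid search needs at least 2 classes", call. = FALSE)
  grid <- sort(grid)
  acc <- vapply(grid, function(C) {
    mean(vapply(splits, function(sp) {
      ytr <- droplevels(y[sp$train])
      if (nlevels(ytr) < 2) return(NA_real_)
      m <- train_svm(x[sp$train, , drop = FALSE], ytr, C,
                     eps = eps, max_iter = max_iter,
                     solver_seed = solver_seed)
      pred <- predict(m, x[sp$test, , drop = FALSE])
      mean(as.character(pred) == as.character(y[sp$test]))
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  list(C = grid[which.max(acc)], accuracy = acc)
}

#' Run a classification task under nested cross-validation
#'
#' The full evaluation of one task: outer task-stratified `k`-fold
#' cross-validation where, within each outer fold, the min-max scaler is
#' fitted on the training data only, `C` is selected by an inner two-fold
#' grid search on the training data, the final model is trained on the
#' whole outer-training set and evaluated on the held-out fold.  Every
#' recording is in the test data exactly once.
#'
#' @param task a [task_spec()] or task name.
#' @param features unscaled feature matrix (rows aligned with `metadata`).
#' @param metadata data.frame with `subject_id`, `footwear_id`, `trial_id`.
#' @param k number of outer folds (default 4).
#' @param seed seed controlling fold construction and solver shuffling.
#' @param grid candidate `C` values (default [c_grid()]).
#' @param eps,max_iter solver settings, see [train_svm()].
#' @return an object of class `grf_cv`: per-fold and aggregate accuracies,
#'   the zero-rule baseline, selected `C` per fold, pooled confusion
#'   matrix, post-hoc per-subject and per-footwear accuracies, fold
#'   assignment, per-fold models and scalers, and pooled predictions.
#' @export
run_task <- function(task, features, metadata, k = 4, seed = 1,
                     grid = c_grid(), eps = 0.1, max_iter = 1000) {
  if (is.character(task)) task <- task_spec(task)
  stopifnot(inherits(task, "task_spec"))
  features <- as.matrix(features)
  stopifnot(nrow(features) == nrow(metadata))
  y <- task$labels(metadata)
  folds <- make_folds(task, metadata, k = k, seed = seed)

  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  fold_acc <- numeric(k)
  fold_C <- numeric(k)
  fold_baseline <- numeric(k)
  models <- vector("list", k)
  scalers <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(folds != f)
    te <- which(folds == f)
    scaler <- fit_minmax(features[tr, , drop = FALSE])
    xtr <- apply_minmax(scaler, features[tr, , drop = FALSE])
    xte <- apply_minmax(scaler, features[te, , drop = FALSE])
    spl <- inner_splits(task, metadata[tr, , drop = FALSE],
                        seed = seed + f)
    gs <- grid_search_C(xtr, y[tr], grid = grid, splits = spl,
                        eps = eps, max_iter = max_iter,
                        solver_seed = seed)
    model <- train_svm(xtr, droplevels(y[tr]), gs$C, eps = eps,
                       max_iter = max_iter, solver_seed = seed)
    p <- predict(model, xte)
    pred[te] <- factor(as.character(p), levels = levels(y))
    fold_acc[f] <- mean(as.character(p) == as.character(y[te]))
    fold_C[f] <- gs$C
    fold_baseline[f] <- zero_rule_baseline(y[tr])
    models[[f]] <- model
    scalers[[f]] <- scaler
  }

  confusion <- table(truth = y, predicted = pred)
  correct <- as.character(pred) == as.character(y)
  structure(list(
    task = task$name,
    fold_accuracy = fold_acc,
    median_accuracy = median(fold_acc),
    mean_accuracy = mean(fold_acc),
    selected_C = fold_C,
    baseline = mean(fold_baseline),
    confusion = confusion,
    accuracy_by_subject = tapply(correct, metadata$subject_id, mean),
    accuracy_by_footwear = tapply(correct, metadata$footwear_id, mean),
    folds = folds, labels = y, predictions = pred,
    models = models, scalers = scalers,
    k = k, seed = seed, eps = eps
  ), class = "grf_cv")
}

#' @export
print.grf_cv <- function(x, ...) {
  cat(sprintf("Task '%s': %d-fold CV, %d recordings, %d classes\n",
              x$task, x$k, length(x$labels), nlevels(x$labels)))
  cat(sprintf("  median accuracy %.1f%% (folds: %s)\n",
              100 * x$median_accuracy,
              paste(sprintf("%.1f%%", 100 * x$fold_accuracy),
                    collapse = ", ")))
  cat(sprintf("  zero-rule baseline %.1f%%\n", 100 * x$baseline))
  cat(sprintf("  selected C per fold: %s\n",
              paste(signif(x$selected_C, 3), collapse = ", ")))
  invisible(x)
}

#' @export
summary.grf_cv <- function(object, ...) {
  print(object)
  cat("\nPost-hoc accuracy by footwear condition:\n")
  print(round(100 * object$accuracy_by_footwear, 1))
  cat("\nPost-hoc accuracy by subject (first 10):\n")
  print(round(100 * utils::head(object$accuracy_by_subject, 10), 1))
  invisible(object)
}
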