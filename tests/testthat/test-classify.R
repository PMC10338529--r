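# Task-stratified folds, the zero-rule baseline, the C grid and the
# one-vs-rest L2-loss linear SVM.

test_that("the default C grid holds 81 values from 2^-5 to 2^15", {
  g <- c_grid()
  expect_length(g, 81)
  expect_equal(g[1], 2^-5)
  expect_equal(g[81], 2^15)
  expect_equal(log2(g[2]) - log2(g[1]), 0.25)
  expect_error(c_grid(5, 1), "invalid grid")
})

test_that("subject-task folds are footwear-disjoint", {
  ds <- tiny_dataset()
  folds <- make_folds(task_spec("subject"), ds$metadata, k = 4, seed = 1)
  for (f in 1:4) {
    conds_test <- unique(ds$metadata$footwear_id[folds == f])
    conds_train <- unique(ds$metadata$footwear_id[folds != f])
    expect_length(conds_test, 1)
    expect_false(conds_test %in% conds_train)
  }
  meta3 <- ds$metadata[ds$metadata$footwear_id != "barefoot", ]
  expect_error(make_folds(task_spec("subject"), meta3, k = 4),
               "exactly k = 4 conditions")
})

test_that("footwear-task folds are subject-disjoint with balanced groups", {
  meta <- expand.grid(subject_id = 1:8, footwear_id = letters[1:4],
                      trial_id = 1:3)
  folds <- make_folds(task_spec("footwear"), meta, k = 4, seed = 2)
  for (f in 1:4) {
    subj_test <- unique(meta$subject_id[folds == f])
    expect_length(subj_test, 2)
    expect_length(intersect(subj_test, meta$subject_id[folds != f]), 0)
  }
  # 30 subjects split as 8, 8, 7, 7
  meta30 <- expand.grid(subject_id = 1:30, footwear_id = letters[1:4],
                        trial_id = 1)
  f30 <- make_folds(task_spec("footwear"), meta30, k = 4, seed = 2)
  sizes <- sort(vapply(1:4, function(f)
    length(unique(meta30$subject_id[f30 == f])), integer(1)))
  expect_equal(sizes, c(7, 7, 8, 8))
})

test_that("subject-x-footwear folds spread every cell equally", {
  meta <- expand.grid(subject_id = 1:3, footwear_id = letters[1:4],
                      trial_id = 1:10)
  folds <- make_folds(task_spec("subject_x_footwear"), meta, k = 4, seed = 5)
  expect_setequal(unique(folds), 1:4)
  cell <- paste(meta$subject_id, meta$footwear_id)
  for (cl in unique(cell)) {
    per_fold <- table(factor(folds[cell == cl], levels = 1:4))
    expect_equal(sort(as.integer(per_fold)), c(2, 2, 3, 3))
  }
  # partition: every recording is in exactly one fold
  expect_length(folds, nrow(meta))
  expect_true(all(folds %in% 1:4))
})

test_that("zero-rule baseline follows the class structure", {
  y120 <- rep(seq_len(120), each = 10)
  expect_equal(zero_rule_baseline(y120), 1 / 120)
  expect_equal(zero_rule_baseline(rep(1:30, each = 40)), 1 / 30)
  expect_equal(zero_rule_baseline(rep(letters[1:4], each = 300)), 1 / 4)
  expect_equal(zero_rule_baseline(c("A", "A", "B")), 2 / 3)
  expect_error(zero_rule_baseline(character(0)), "empty")
})

test_that("the linear SVM separates separable toy problems", {
  x <- matrix(c(0, 1), ncol = 1)
  y <- factor(c("A", "B"))
  for (C in c(1, 10, 100)) {
    m <- train_svm(x, y, C)
    expect_equal(as.character(predict(m, x)), c("A", "B"))
  }
  toy <- toy_three_class()
  m <- train_svm(toy$x, toy$y, C = 1)
  expect_equal(as.character(predict(m, toy$x)), as.character(toy$y))
  expect_equal(dim(coef(m)), c(3, 3))   # 2 features + intercept
  expect_error(train_svm(toy$x, rep("a", nrow(toy$x)), 1), "2 classes")
  expect_error(train_svm(matrix(c(1, NA), 2, 1), factor(c("a", "b")), 1),
               "non-finite")
})

test_that("training-row order does not change the predictions", {
  toy <- toy_three_class(n_per = 10, seed = 7)
  test_x <- toy_three_class(n_per = 5, seed = 8)$x
  m1 <- train_svm(toy$x, toy$y, C = 4, solver_seed = 11)
  perm <- with_seed_local(2, sample(nrow(toy$x)))
  m2 <- train_svm(toy$x[perm, ], toy$y[perm], C = 4, solver_seed = 11)
  expect_identical(as.character(predict(m1, test_x)),
                   as.character(predict(m2, test_x)))
})

test_that("the solver agrees with an independent SVM on separable data", {
  skip_if_not_installed("e1071")
  toy <- toy_three_class(n_per = 12, seed = 3)
  probe <- toy_three_class(n_per = 6, seed = 4)
  ours <- predict(train_svm(toy$x, toy$y, C = 10), probe$x)
  ref <- predict(e1071::svm(toy$x, toy$y, kernel = "linear", cost = 10,
                            scale = FALSE), probe$x)
  expect_equal(as.character(ours), as.character(ref))
})

test_that("decision scores are affine in the inputs", {
  toy <- toy_three_class()
  m <- train_svm(toy$x, toy$y, C = 1)
  x0 <- toy$x[1, ]
  s <- predict(m, x0, type = "scores")
  expect_equal(as.numeric(s), as.numeric(m$W %*% x0 + m$b), tolerance = 1e-12)
})

test_that("grid search returns the smallest C on ties", {
  toy <- toy_three_class(n_per = 6, seed = 5)
  splits <- list(list(train = seq(1, 18, by = 2), test = seq(2, 18, by = 2)),
                 list(train = seq(2, 18, by = 2), test = seq(1, 18, by = 2)))
  gs <- grid_search_C(toy$x, toy$y, grid = c_grid(by = 1), splits = splits)
  expect_equal(gs$C, 2^-5)     # separable: all C reach accuracy 1
  expect_true(all(gs$accuracy == 1))
  expect_error(grid_search_C(toy$x, toy$y, grid = numeric(0),
                             splits = splits), "empty")
  expect_error(grid_search_C(toy$x, rep("a", 18), splits = splits),
               "2 classes")
})
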