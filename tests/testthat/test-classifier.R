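test_that("the hyperparameter grid enumerates 60 combinations", {
  g <- hyperparameter_grid()
  expect_identical(nrow(g), 60L)
  expect_identical(nrow(unique(g)), 60L)
  expect_setequal(unique(g$max_depth), c(3L, 5L, 10L))
  expect_setequal(unique(g$max_features), c("0.1", "0.5", "sqrt", "log2", "all"))
  expect_setequal(unique(g$n_estimators), c(10L, 100L, 500L, 1000L))
})

test_that("balancing equalizes class counts by either method", {
  d <- sep_data(50)
  y <- rep(c("pos", "neg"), c(10, 40))
  b <- balance_classes(d$X, y, "smote", seed = 1)
  expect_identical(as.integer(table(b$y)[c("pos", "neg")]), c(40L, 40L))
  # synthetic rows interpolate minority points: here all minority rows are
  # binary, so synthetic values stay within [0, 1]
  expect_true(all(b$X >= 0 & b$X <= 1))
  dn <- balance_classes(d$X, y, "downsample", seed = 2)
  expect_identical(as.integer(table(dn$y)[c("pos", "neg")]), c(10L, 10L))
  dn2 <- balance_classes(d$X, y, "downsample", seed = 2)
  expect_identical(dn, dn2)                    # deterministic subset
  expect_error(balance_classes(d$X, rep("pos", 50), "smote"),
               "insufficient-examples")
})

test_that("SMOTE on identical minority points reproduces them exactly", {
  X <- rbind(matrix(1, 2, 4), matrix(0, 10, 4))
  colnames(X) <- paste0("f", 1:4)
  y <- rep(c("pos", "neg"), c(2, 10))
  b <- balance_classes(X, y, "smote", seed = 3)
  syn <- b$X[b$y == "pos", , drop = FALSE]
  expect_true(all(syn == 1))
})

test_that("stratified folds use every gene in exactly one validation fold", {
  y <- rep(c("pos", "neg"), c(40, 60))
  f <- stratified_folds(y, folds = 5, seed = 2)
  expect_identical(sort(unique(f)), 1:5)
  expect_identical(length(f), 100L)
  expect_true(all(table(f, y)[, "pos"] == 8))
  expect_true(all(table(f, y)[, "neg"] == 12))
  expect_error(stratified_folds(rep(c("pos", "neg"), c(3, 60)), 5),
               "insufficient-examples")
})

test_that("F1 follows its closed form", {
  expect_identical(f1_score(c("p", "p", "n"), c("p", "p", "n"), "p"), 1)
  # tp = 8, fp = 2, fn = 2 -> precision = recall = 0.8 -> F1 = 0.8
  truth <- rep(c("p", "n"), c(10, 10))
  pred <- c(rep("p", 8), rep("n", 2), rep("p", 2), rep("n", 8))
  expect_equal(f1_score(truth, pred, "p"), 0.8)
  expect_identical(f1_score(truth, rep("n", 20), "p"), 0)
})

test_that("grid search finds a perfect model on separable data", {
  d <- sep_data(100)
  cv <- grid_search_cv(d$X, d$y, positive = "pos", grid = small_grid(),
                       folds = 5, seed = 1)
  expect_equal(max(cv$cv_f1), 1)
  expect_identical(cv$balance_scope, "fold")
  # partition property: every gene in exactly one validation fold
  expect_identical(length(cv$folds), 100L)
  expect_setequal(unique(cv$folds), 1:5)
  # determinism
  cv2 <- grid_search_cv(d$X, d$y, positive = "pos", grid = small_grid(),
                        folds = 5, seed = 1)
  expect_identical(cv$cv_f1, cv2$cv_f1)
})

test_that("tie-breaking prefers fewer trees then shallower depth", {
  d <- sep_data(60)
  g <- hyperparameter_grid()
  g <- g[g$max_features == "sqrt" & g$n_estimators %in% c(100, 500), ]
  cv <- grid_search_cv(d$X, d$y, positive = "pos", grid = g, folds = 5,
                       seed = 2)
  ties <- which(cv$cv_f1 == max(cv$cv_f1))
  expect_identical(cv$best$n_estimators, min(g$n_estimators[ties]))
})

test_that("final model reports test F1 and min-max scaled importances", {
  d <- sep_data(120)
  tr <- c(1:48, 61:108); te <- setdiff(1:120, tr)
  rep_ <- train_final_and_test(d$X[tr, ], d$y[tr], d$X[te, ], d$y[te],
                               hp = data.frame(max_depth = 10,
                                               max_features = "sqrt",
                                               n_estimators = 100),
                               positive = "pos", seed = 1)
  expect_equal(rep_$test_f1, 1)
  imp <- rep_$importances
  expect_identical(imp$feature[1], "sig")
  expect_equal(range(imp$scaled_gini), c(0, 1))
  expect_identical(imp$rank, seq_len(nrow(imp)))
  expect_false(rep_$degenerate)
  expect_error(train_final_and_test(d$X[tr, ], d$y[tr], d$X[tr[1:10], ],
                                    d$y[tr[1:10]],
                                    hp = rep_$hp, positive = "pos"),
               "disjoint")
})

test_that("label permutation drops CV F1 to chance level", {
  set.seed(33)
  n <- 200
  X <- matrix(rbinom(n * 20, 1, 0.5), n, 20,
              dimnames = list(paste0("g", 1:n), paste0("f", 1:20)))
  f1s <- vapply(1:3, function(s) {
    y <- sample(rep(c("pos", "neg"), each = n / 2))
    cv <- grid_search_cv(X, y, positive = "pos", grid = small_grid()[1, ],
                         folds = 5, seed = s)
    mean(cv$cv_f1)
  }, numeric(1))
  expect_gt(mean(f1s), 0.35)
  expect_lt(mean(f1s), 0.65)
})

test_that("TFBM-presence models learn from a planted library", {
  cfg <- sim_config(n_genes = 120, upstream_len = 80,
                    body_len_range = c(40, 60), downstream_len = 40,
                    down_fraction = rep(0, 6),
                    planted_motifs = list(
                      planted_motif("GCGGCGC", targets = "0.5",
                                    p_signal = 1, p_background = 0)),
                    seed = 21)
  sim <- simulate_dataset(cfg)
  lab <- split_train_test(label_genes(sim$de), seed = 21)
  sp <- lab$split[["0.5"]]
  planted_lib <- Filter(function(r) r$family == "FAM_GCGGCGC",
                        sim$tfbm_library)
  rep_ <- tfbm_model(sim$genes, planted_lib, sp$up_train, sp$neg_train,
                     sp$up_test, sp$neg_test, grid = small_grid()[1, ],
                     seed = 3)
  expect_gt(rep_$test_f1, 0.6)
  expect_error(tfbm_model(sim$genes, list(), sp$up_train, sp$neg_train,
                          sp$up_test, sp$neg_test),
               "empty")
})
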