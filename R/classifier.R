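#' The random-forest hyperparameter grid
#'
#' Cartesian product of max_depth {3, 5, 10}, max_features {0.1, 0.5,
#' sqrt, log2, all} and n_estimators {10, 100, 500, 1000} - 60
#' combinations. "0.1"/"0.5" are fractions of the feature count; "all"
#' uses every feature.
#'
#' @return data.frame with 60 rows: max_depth, max_features, n_estimators.
#' @export
hyperparameter_grid <- function() {
  expand.grid(max_depth = c(3L, 5L, 10L),
              max_features = c("0.1", "0.5", "sqrt", "log2", "all"),
              n_estimators = c(10L, 100L, 500L, 1000L),
              stringsAsFactors = FALSE)
}

# mtry from a max_features specification.
.mtry <- function(max_features, p) {
  m <- switch(as.character(max_features),
              "sqrt" = floor(sqrt(p)),
              "log2" = floor(log2(p)),
              "all" = p,
              floor(as.numeric(max_features) * p))
  max(1L, min(p, as.integer(m)))
}

#' F1 score on the positive class
#'
#' Harmonic mean of precision and recall; 0 when no positive is predicted.
#'
#' @param truth,pred class vectors.
#' @param positive the positive class label.
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(truth, pred, positive) {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Balance a two-class training set
#'
#' `smote` synthesizes minority-class points by convex interpolation
#' between a minority point and one of its k nearest minority neighbours
#' (Euclidean distance); `downsample` subsamples the majority class
#' without replacement. Class counts are equal afterwards.
#'
#' @param X numeric feature matrix.
#' @param y class labels (two classes present).
#' @param method "smote" or "downsample".
#' @param k SMOTE neighbour count (default 5, capped at minority size - 1).
#' @param seed RNG seed.
#' @return list with balanced `X` and `y`.
#' @export
balance_classes <- function(X, y, method = c("smote", "downsample"), k = 5,
                            seed = 1) {
  method <- match.arg(method)
  y <- as.character(y)
  tab <- table(y)
  if (length(tab) < 2) stop("insufficient-examples: both classes must be present")
  if (tab[1] == tab[2]) return(list(X = X, y = y))
  min_cl <- names(tab)[which.min(tab)]
  maj_cl <- names(tab)[which.max(tab)]
  i_min <- which(y == min_cl); i_maj <- which(y == maj_cl)
  set.seed(seed)
  if (method == "downsample") {
    keep <- sort(c(i_min, sample(i_maj, length(i_min))))
    return(list(X = X[keep, , drop = FALSE], y = y[keep]))
  }
  n_syn <- length(i_maj) - length(i_min)
  Xm <- X[i_min, , drop = FALSE]
  k_use <- min(k, nrow(Xm) - 1)
  syn <- matrix(0, n_syn, ncol(X), dimnames = list(NULL, colnames(X)))
  if (k_use < 1) {
    syn[] <- rep(Xm[1, ], each = n_syn)     # single minority point: copies
  } else {
    D <- as.matrix(stats::dist(Xm))
    diag(D) <- Inf
    nn <- apply(D, 1, function(d) order(d)[seq_len(k_use)], simplify = FALSE)
    base <- sample.int(nrow(Xm), n_syn, replace = TRUE)
    for (s in seq_len(n_syn)) {
      i <- base[s]
      j <- nn[[i]][sample.int(k_use, 1)]
      u <- stats::runif(1)
      syn[s, ] <- Xm[i, ] + u * (Xm[j, ] - Xm[i, ])
    }
  }
  list(X = rbind(X, syn), y = c(y, rep(min_cl, n_syn)))
}

#' Stratified cross-validation fold assignment
#'
#' Shuffles each class and deals it round-robin so every sample lands in
#' exactly one fold and class ratios are preserved.
#'
#' @param y class labels.
#' @param folds number of folds.
#' @param seed RNG seed.
#' @return integer fold id per sample.
#' @export
stratified_folds <- function(y, folds = 5, seed = 1) {
  if (min(table(y)) < folds)
    stop("insufficient-examples: a class has fewer genes than folds")
  set.seed(seed)
  f <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

# ranger wrapper with the package conventions (single thread, seeded).
.rf <- function(X, y, n_estimators, max_depth, max_features, seed,
                importance = "none") {
  ranger::ranger(x = X, y = factor(y), num.trees = n_estimators,
                 max.depth = max_depth, mtry = .mtry(max_features, ncol(X)),
                 importance = importance, seed = seed, num.threads = 1,
                 oob.error = FALSE)
}

#' Grid search over random-forest hyperparameters with stratified CV
#'
#' Stratified k-fold cross-validation in which every gene appears in
#' exactly one validation fold; class balancing is applied inside each
#' fold to the training portion only (the validation portion is never
#' resampled). For one (max_depth, max_features) pair, a single forest
#' with the largest tree count is grown per fold and the smaller tree
#' counts are scored on its leading trees - trees are grown
#' independently, so this is equivalent to separate fits. Selection is by
#' mean validation F1; ties prefer fewer trees, then shallower depth.
#'
#' @param X feature matrix (genes x features, named columns).
#' @param y class labels.
#' @param positive positive class label.
#' @param grid hyperparameter data.frame (default [hyperparameter_grid()]).
#' @param folds CV folds (default 5).
#' @param seed RNG seed (folds, balancing, forests).
#' @param balance "smote", "downsample" or "none".
#' @return list: `best` (one-row grid entry), `cv_f1` (mean F1 per
#'   combination), `cv_folds` (per-fold F1 matrix), `folds` (assignment),
#'   `balance_scope` = "fold".
#' @export
grid_search_cv <- function(X, y, positive, grid = hyperparameter_grid(),
                           folds = 5, seed = 1,
                           balance = c("smote", "downsample", "none")) {
  balance <- match.arg(balance)
  y <- as.character(y)
  fold_id <- stratified_folds(y, folds, seed)
  groups <- unique(grid[, c("max_depth", "max_features")])
  f1s <- matrix(NA_real_, nrow(grid), folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f; va <- !tr
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    if (balance != "none") {
      bal <- balance_classes(Xtr, ytr, method = balance,
                             seed = seed * 100 + f)
      Xtr <- bal$X; ytr <- bal$y
    }
    Xva <- X[va, , drop = FALSE]; yva <- y[va]
    for (g in seq_len(nrow(groups))) {
      rows <- which(grid$max_depth == groups$max_depth[g] &
                    grid$max_features == groups$max_features[g])
      nts <- grid$n_estimators[rows]
      m <- .rf(Xtr, ytr, n_estimators = max(nts),
               max_depth = groups$max_depth[g],
               max_features = groups$max_features[g],
               seed = seed * 100 + f)
      for (r in seq_along(rows)) {
        pred <- stats::predict(m, data = Xva, num.trees = nts[r],
                               num.threads = 1)$predictions
        f1s[rows[r], f] <- f1_score(yva, as.character(pred), positive)
      }
    }
  }
  mean_f1 <- rowMeans(f1s)
  ord <- order(-mean_f1, grid$n_estimators, grid$max_depth)
  best <- grid[ord[1], , drop = FALSE]
  rownames(best) <- NULL
  list(best = best, cv_f1 = mean_f1, cv_folds = f1s, grid = grid,
       folds = fold_id, balance_scope = "fold", seed = seed)
}

#' Train the final model and evaluate on the held-out test set
#'
#' Fits one forest with the selected hyperparameters on the (balanced)
#' full training set, reports test F1 and Gini importances (raw and
#' min-max scaled per model), with features ranked by decreasing
#' importance (ties broken lexicographically).
#'
#' @param X_train,y_train training data.
#' @param X_test,y_test held-out test data (disjoint from training).
#' @param hp one-row hyperparameter data.frame.
#' @param positive positive class label.
#' @param seed RNG seed.
#' @param balance balancing method for the final training set.
#' @return list of class `model_report`: `hp`, `test_f1`, `degenerate`
#'   (no positive predicted), `importances` (feature, gini, scaled_gini,
#'   rank), `seed`.
#' @export
train_final_and_test <- function(X_train, y_train, X_test, y_test, hp,
                                 positive, seed = 1,
                                 balance = c("smote", "downsample", "none")) {
  balance <- match.arg(balance)
  if (length(intersect(rownames(X_train), rownames(X_test))) > 0)
    stop("train and test sets must be disjoint")
  y_train <- as.character(y_train); y_test <- as.character(y_test)
  if (balance != "none") {
    bal <- balance_classes(X_train, y_train, method = balance, seed = seed)
    X_train <- bal$X; y_train <- bal$y
  }
  m <- .rf(X_train, y_train, n_estimators = hp$n_estimators,
           max_depth = hp$max_depth, max_features = hp$max_features,
           seed = seed, importance = "impurity")
  pred <- stats::predict(m, data = X_test, num.threads = 1)$predictions
  pred <- as.character(pred)
  f1 <- f1_score(y_test, pred, positive)
  gini <- m$variable.importance
  rng <- range(gini)
  scaled <- if (diff(rng) > 0) (gini - rng[1]) / diff(rng) else rep(0, length(gini))
  ord <- order(-gini, names(gini))
  imp <- data.frame(feature = names(gini)[ord], gini = unname(gini[ord]),
                    scaled_gini = unname(scaled[ord]),
                    rank = seq_along(gini), stringsAsFactors = FALSE)
  structure(list(hp = hp, test_f1 = f1,
                 degenerate = !any(pred == positive),
                 importances = imp, seed = seed),
            class = "model_report")
}

#' Gene-level presence of TFBM matches
#'
#' Scans each gene's three regions (both strands) with the log-odds score
#' matrix of every library PWM via [Biostrings::countPWM()]; a gene is
#' positive for a motif when any region contains a window scoring at
#' least `min_score` of the score range.
#'
#' @param genes gene table with the three region sequence columns.
#' @param library list of [tfbm_record()] objects.
#' @param min_score score threshold, e.g. "90%".
#' @return integer 0/1 matrix, genes x motifs.
#' @export
tfbm_presence_matrix <- function(genes, library, min_score = "90%") {
  regions <- c("upstream_seq", "body_seq", "downstream_seq")
  out <- matrix(0L, nrow(genes), length(library),
                dimnames = list(genes$gene_id,
                                vapply(library, function(r) r$tf_name,
                                       character(1))))
  for (j in seq_along(library)) {
    sc <- log2(pmax(unclass(library[[j]]$pwm), 1e-4) / 0.25)
    sc_rc <- log2(pmax(unclass(pwm_revcomp(library[[j]]$pwm)), 1e-4) / 0.25)
    for (rg in regions) {
      for (i in seq_len(nrow(genes))) {
        if (out[i, j] == 1L) next
        s <- genes[[rg]][i]
        if (nchar(s) < ncol(sc)) next
        subj <- Biostrings::DNAString(s)
        hits <- Biostrings::countPWM(sc, subj, min.score = min_score) +
          Biostrings::countPWM(sc_rc, subj, min.score = min_score)
        if (hits > 0) out[i, j] <- 1L
      }
    }
  }
  out
}

#' Classify responsiveness from known-TFBM match features
#'
#' Recreates the feature table as binary presence of TFBM matches in each
#' gene and runs the identical modelling pipeline (grid search CV with
#' in-fold balancing, final fit, held-out F1).
#'
#' @param genes gene table covering all train/test genes.
#' @param library TFBM library (list of [tfbm_record()]).
#' @param train_pos,train_neg,test_pos,test_neg gene-id vectors.
#' @param min_score PWM match threshold (see [tfbm_presence_matrix()]).
#' @param grid hyperparameter grid.
#' @param folds,seed,balance as in [grid_search_cv()].
#' @return `model_report` with the grid-search result attached as `cv`.
#' @export
tfbm_model <- function(genes, library, train_pos, train_neg, test_pos,
                       test_neg, min_score = "90%",
                       grid = hyperparameter_grid(), folds = 5, seed = 1,
                       balance = "smote") {
  if (length(library) == 0) stop("TFBM library is empty")
  ids <- c(train_pos, train_neg, test_pos, test_neg)
  feat <- tfbm_presence_matrix(genes[match(ids, genes$gene_id), ], library,
                               min_score = min_score)
  if (all(feat == 0L)) stop("no-features: no TFBM matches anywhere")
  lab <- stats::setNames(rep(c("pos", "neg", "pos", "neg"),
                             c(length(train_pos), length(train_neg),
                               length(test_pos), length(test_neg))), ids)
  tr <- c(train_pos, train_neg); te <- c(test_pos, test_neg)
  cv <- grid_search_cv(feat[tr, , drop = FALSE], lab[tr], positive = "pos",
                       grid = grid, folds = folds, seed = seed,
                       balance = balance)
  rep_ <- train_final_and_test(feat[tr, , drop = FALSE], lab[tr],
                               feat[te, , drop = FALSE], lab[te],
                               cv$best, positive = "pos", seed = seed,
                               balance = balance)
  rep_$cv <- cv
  rep_
}
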