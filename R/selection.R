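#' F1-versus-feature-count performance ramp
#'
#' Re-evaluates the tuned model by cross-validation using only the top n
#' ranked features, for n = 10, 30, 50, ... (start 10, step 20) up to the
#' feature count. With fewer than 10 features the ramp is the single
#' point at all features, flagged. The full-feature CV F1 is always
#' reported as `full_model_f1`.
#'
#' @param X feature matrix (training genes x features).
#' @param y class labels.
#' @param ranked_features feature names in decreasing importance order.
#' @param hp selected hyperparameters (one-row data.frame).
#' @param positive positive class label.
#' @param folds,seed,balance as in [grid_search_cv()].
#' @param start,step ramp start and increment.
#' @return list of class `performance_ramp`: `points` (data.frame
#'   n_features, cv_f1), `full_model_f1`, `flagged`.
#' @export
performance_ramp <- function(X, y, ranked_features, hp, positive, folds = 5,
                             seed = 1, balance = "smote", start = 10,
                             step = 20) {
  stopifnot(all(ranked_features %in% colnames(X)))
  p <- length(ranked_features)
  flagged <- p < start
  ns <- if (flagged) p else seq(start, p, by = step)
  y <- as.character(y)
  fold_id <- stratified_folds(y, folds, seed)
  cv_at <- function(n_feat) {
    f1 <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      Xtr <- X[tr, ranked_features[seq_len(n_feat)], drop = FALSE]
      ytr <- y[tr]
      if (balance != "none") {
        bal <- balance_classes(Xtr, ytr, method = balance,
                               seed = seed * 100 + f)
        Xtr <- bal$X; ytr <- bal$y
      }
      m <- .rf(Xtr, ytr, n_estimators = hp$n_estimators,
               max_depth = hp$max_depth, max_features = hp$max_features,
               seed = seed * 100 + f)
      pred <- stats::predict(m, data = X[!tr, ranked_features[seq_len(n_feat)],
                                         drop = FALSE],
                             num.threads = 1)$predictions
      f1[f] <- f1_score(y[!tr], as.character(pred), positive)
    }
    mean(f1)
  }
  points <- data.frame(n_features = ns,
                       cv_f1 = vapply(ns, cv_at, numeric(1)))
  full <- if (p %in% ns) points$cv_f1[points$n_features == p] else cv_at(p)
  structure(list(points = points, full_model_f1 = full, flagged = flagged),
            class = "performance_ramp")
}

#' Fit the Michaelis-Menten curve to a performance ramp
#'
#' Nonlinear least squares of f(n) = f1_max * n / (k_half + n) on the
#' ramp points, initialized at f1_max = max observed F1 and k_half = the
#' feature count where F1 first reaches half of that, bounded to
#' f1_max in (0, 1] and k_half > 0. A two-point ramp is solved exactly; a
#' constant ramp is the saturated limit (k_half -> 0).
#'
#' @param ramp a `performance_ramp` (or data.frame with n_features, cv_f1).
#' @return list of class `mm_fit`: `f1_max`, `k_half`, `rss`, `converged`.
#' @export
fit_mm <- function(ramp) {
  pts <- if (inherits(ramp, "performance_ramp")) ramp$points else ramp
  n <- pts$n_features; f1 <- pts$cv_f1
  stopifnot(length(n) >= 1)
  mk <- function(f1_max, k_half, converged) {
    pred <- f1_max * n / (k_half + n)
    structure(list(f1_max = f1_max, k_half = k_half,
                   rss = sum((f1 - pred)^2), converged = converged),
              class = "mm_fit")
  }
  if (length(unique(f1)) == 1)               # saturated limit
    return(mk(f1[1], 1e-9, TRUE))
  if (length(n) == 2) {                      # exact algebraic interpolation
    k <- n[1] * n[2] * (f1[2] - f1[1]) / (f1[1] * n[2] - f1[2] * n[1])
    if (is.finite(k) && k > 0) {
      return(mk(f1[1] * (k + n[1]) / n[1], k, TRUE))
    }
  }
  k0 <- n[which(f1 >= max(f1) / 2)[1]]
  fit <- tryCatch(
    minpack.lm::nlsLM(f1 ~ f1_max * n / (k_half + n),
                      data = data.frame(n = n, f1 = f1),
                      start = list(f1_max = max(f1), k_half = max(k0, 1)),
                      lower = c(1e-9, 1e-9), upper = c(1, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("Michaelis-Menten fit did not converge; fall back to the fraction rule")
    return(mk(max(f1), 1e-9, FALSE))
  }
  cf <- stats::coef(fit)
  mk(unname(cf["f1_max"]), unname(cf["k_half"]), TRUE)
}

#' Minimal feature count from a ramp and its Michaelis-Menten fit
#'
#' `derivative` rule: the smallest evaluated n where the fitted slope
#' f1_max * k_half / (k_half + n)^2 drops below `eps` (a near-zero
#' differential). `fraction` rule: the smallest evaluated n whose observed
#' CV F1 reaches `fraction` of the full-model F1. `auto` uses the
#' derivative rule when the fit converged and it is satisfied at some
#' evaluated n, otherwise the fraction rule. If the chosen rule is never
#' satisfied, the largest evaluated n is returned, flagged.
#'
#' @param ramp a `performance_ramp`.
#' @param fit an `mm_fit` (required for the derivative rule).
#' @param rule "derivative", "fraction" or "auto".
#' @param eps slope threshold in F1 units per feature (default 1e-4).
#' @param fraction fraction of the full-model F1 (default 0.90).
#' @return integer count (an evaluated ramp point) with attributes
#'   `rule` (the rule actually applied) and `flagged`.
#' @export
minimal_feature_count <- function(ramp, fit = NULL,
                                  rule = c("auto", "derivative", "fraction"),
                                  eps = 1e-4, fraction = 0.90) {
  rule <- match.arg(rule)
  pts <- ramp$points
  ns <- pts$n_features
  pick_deriv <- function() {
    slope <- fit$f1_max * fit$k_half / (fit$k_half + ns)^2
    which(slope < eps)[1]
  }
  pick_frac <- function() which(pts$cv_f1 >= fraction * ramp$full_model_f1)[1]
  idx <- NA_integer_; used <- rule
  if (rule %in% c("auto", "derivative")) {
    if (is.null(fit)) stop("the derivative rule needs an mm_fit")
    idx <- pick_deriv(); used <- "derivative"
    if (rule == "auto" && (is.na(idx) || !isTRUE(fit$converged))) {
      idx <- pick_frac(); used <- "fraction"
    }
  } else {
    idx <- pick_frac()
  }
  flagged <- is.na(idx)
  if (flagged) idx <- length(ns)
  structure(ns[idx], rule = used, flagged = flagged)
}

#' Select the minimal pCRE set for one model
#'
#' Convenience wrapper: takes a trained model report's ranked features,
#' builds the ramp, fits the curve, applies the minimal-count rule, and
#' returns the top features with their importances.
#'
#' @param X,y training data (named feature columns).
#' @param report a `model_report` from [train_final_and_test()].
#' @param positive positive class label.
#' @param folds,seed,balance CV settings.
#' @param rule,eps,fraction see [minimal_feature_count()].
#' @return list: `pcres` (data.frame kmer, gini, scaled_gini, rank),
#'   `ramp`, `fit`, `n_minimal`.
#' @export
select_pcres <- function(X, y, report, positive, folds = 5, seed = 1,
                         balance = "smote", rule = "auto", eps = 1e-4,
                         fraction = 0.90) {
  ranked <- report$importances$feature
  ramp <- performance_ramp(X, y, ranked, report$hp, positive, folds = folds,
                           seed = seed, balance = balance)
  fit <- fit_mm(ramp)
  n_min <- minimal_feature_count(ramp, fit, rule = rule, eps = eps,
                                 fraction = fraction)
  sel <- report$importances[seq_len(n_min), , drop = FALSE]
  names(sel)[names(sel) == "feature"] <- "kmer"
  list(pcres = sel, ramp = ramp, fit = fit, n_minimal = n_min)
}

#' Categorize pCREs across time-point models
#'
#' A pCRE found (identical sequence) in the minimal sets of all time
#' points is `general`; in exactly one, `specific`; otherwise
#' `non_specific`. Every pCRE receives exactly one category.
#'
#' @param minimal_sets named list: time point -> character vector of
#'   minimal-set k-mers.
#' @return data.frame: kmer, n_time_points, time_points (comma-joined),
#'   category.
#' @export
categorize_pcres <- function(minimal_sets) {
  if (length(minimal_sets) < 2)
    stop("categorization needs at least two time points")
  all_k <- sort(unique(unlist(minimal_sets)))
  member <- vapply(minimal_sets, function(s) all_k %in% s,
                   logical(length(all_k)))
  if (length(all_k) == 1) member <- matrix(member, nrow = 1)
  n_tp <- rowSums(member)
  category <- ifelse(n_tp == length(minimal_sets), "general",
                     ifelse(n_tp == 1, "specific", "non_specific"))
  tps <- vapply(seq_along(all_k), function(i)
    paste(names(minimal_sets)[member[i, ]], collapse = ","), character(1))
  data.frame(kmer = all_k, n_time_points = n_tp, time_points = tps,
             category = category, stringsAsFactors = FALSE)
}
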