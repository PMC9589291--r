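#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the study
#' defaults: up/down log2FC thresholds +-1 at adjusted p <= 0.05,
#' non-responsive |log2FC| < 0.5, k = 5-8, five enrichment bins, five CV
#' folds, 80/20 train/test split, SMOTE balancing inside folds, the
#' 60-combination hyperparameter grid, ramp 10/+20 with Michaelis-Menten
#' selection (automatic derivative-then-fraction rule, fraction 0.90),
#' UPGMA cut at 1 - PCC distance 0.39, and within-family PCC background.
#'
#' @param up_fc,down_fc,alpha,null_fc labelling thresholds.
#' @param k_range k-mer lengths.
#' @param n_bins enrichment bins.
#' @param folds CV folds.
#' @param train_fraction training fraction of the split.
#' @param balance "smote" or "downsample".
#' @param grid hyperparameter grid data.frame.
#' @param selection_rule,selection_fraction,eps minimal-set rule settings.
#' @param cutoff UPGMA cut height.
#' @param scope TFBM background scope.
#' @param directions model directions to run ("up" and/or "down").
#' @param seed master seed; stage seeds are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(up_fc = 1.0, down_fc = -1.0, alpha = 0.05,
                            null_fc = 0.5, k_range = 5:8, n_bins = 5,
                            folds = 5, train_fraction = 0.8,
                            balance = "smote", grid = hyperparameter_grid(),
                            selection_rule = "auto",
                            selection_fraction = 0.90, eps = 1e-4,
                            cutoff = 0.39, scope = "within_family",
                            directions = "up", seed = 1) {
  structure(mget(c("up_fc", "down_fc", "alpha", "null_fc", "k_range",
                   "n_bins", "folds", "train_fraction", "balance", "grid",
                   "selection_rule", "selection_fraction", "eps", "cutoff",
                   "scope", "directions", "seed")),
            class = "pipeline_config")
}

# one time-point x direction model: enrichment screen -> grid search ->
# final test -> minimal pCRE set. `log_test_access` is called at the one
# stage allowed to touch the held-out ids.
.run_model <- function(presence, pos_train, neg_train, pos_test, neg_test,
                       cfg, seed, log_test_access) {
  scr <- binned_enrichment(presence, pos_train, neg_train,
                           n_bins = cfg$n_bins, alpha = cfg$alpha,
                           seed = seed)
  if (length(scr$kmers) == 0) {
    return(list(features = character(), screen = scr, cv = NULL,
                report = NULL, selection = NULL))
  }
  tr <- c(pos_train, neg_train)
  y_tr <- stats::setNames(rep(c("pos", "neg"),
                              c(length(pos_train), length(neg_train))), tr)
  X_tr <- build_feature_matrix(presence, scr$kmers, tr)
  cv <- grid_search_cv(X_tr, y_tr, positive = "pos", grid = cfg$grid,
                       folds = cfg$folds, seed = seed,
                       balance = cfg$balance)
  log_test_access("final_evaluation")
  te <- c(pos_test, neg_test)
  y_te <- stats::setNames(rep(c("pos", "neg"),
                              c(length(pos_test), length(neg_test))), te)
  X_te <- build_feature_matrix(presence, scr$kmers, te)
  report <- train_final_and_test(X_tr, y_tr, X_te, y_te, cv$best,
                                 positive = "pos", seed = seed,
                                 balance = cfg$balance)
  report$cv_f1 <- max(cv$cv_f1)
  sel <- select_pcres(X_tr, y_tr, report, positive = "pos",
                      folds = cfg$folds, seed = seed,
                      balance = cfg$balance, rule = cfg$selection_rule,
                      eps = cfg$eps, fraction = cfg$selection_fraction)
  list(features = scr$kmers, screen = scr, cv = cv, report = report,
       selection = sel)
}

#' Run the temporal pCRE discovery pipeline end to end
#'
#' Labels genes per time point, splits train/test, screens canonical
#' k-mers by five-bin Fisher enrichment, trains and tunes a random forest
#' per time point, selects minimal pCRE sets from the Michaelis-Menten
#' ramp, categorizes pCREs as general / time-point-specific /
#' non-specific, matches them to the TFBM library, clusters them by
#' UPGMA on 1 - PCC distance, and computes GO, expression-profile and
#' pCRE-presence enrichments. All stage seeds derive from `config$seed`;
#' the run manifest records them with per-stage counts and an access log
#' showing the held-out test sets are only touched at final evaluation.
#'
#' @param sim a `tempcre_sim` object (or an equivalent list with `genes`,
#'   `de`, `go`, `tfbm_library`).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, stage outputs and the
#'   manifest (JSON) are written as TSVs under it.
#' @return list of class `tempcre_run`.
#' @export
run_pipeline <- function(sim, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  test_access <- character()
  stage_log <- list()
  note <- function(stage, ...) stage_log[[stage]] <<- list(...)

  labels <- label_genes(sim$de, up_fc = config$up_fc, down_fc = config$down_fc,
                        alpha = config$alpha, null_fc = config$null_fc)
  profiles <- encode_profiles(sim$de, up_fc = config$up_fc,
                              down_fc = config$down_fc, alpha = config$alpha)
  note("label", n_genes = length(labels$genes),
       n_up = vapply(labels$up, length, integer(1)),
       n_down = vapply(labels$down, length, integer(1)),
       n_negatives = length(labels$negatives))
  labels <- split_train_test(labels, fraction = config$train_fraction,
                             seed = config$seed)
  presence <- kmer_presence_matrix(sim$genes, k_range = config$k_range)
  note("kmers", n_candidate = ncol(presence))

  models <- list()
  for (dir_ in config$directions) {
    for (i in seq_along(labels$time_points)) {
      tp <- labels$time_points[i]
      sp <- labels$split[[tp]]
      pos_tr <- if (dir_ == "up") sp$up_train else sp$down_train
      pos_te <- if (dir_ == "up") sp$up_test else sp$down_test
      if (length(pos_tr) == 0) next
      key <- paste(dir_, tp, sep = "@")
      models[[key]] <- .run_model(
        presence, pos_tr, sp$neg_train, pos_te, sp$neg_test, config,
        seed = config$seed + 13 * i + ifelse(dir_ == "up", 0, 7),
        log_test_access = function(stage) {
          test_access <<- c(test_access, stage)
        })
      models[[key]]$time <- tp
      models[[key]]$direction <- dir_
    }
  }
  fitted <- Filter(function(m) !is.null(m$report), models)
  note("models",
       f1 = vapply(fitted, function(m) m$report$test_f1, numeric(1)),
       n_features = vapply(models, function(m) length(m$features), integer(1)))

  ## categorization + downstream analyses on up-direction minimal sets
  up_models <- Filter(function(m) m$direction == "up" && !is.null(m$selection),
                      models)
  minimal_sets <- lapply(up_models, function(m) m$selection$pcres$kmer)
  names(minimal_sets) <- vapply(up_models, function(m) m$time, character(1))
  categories <- if (length(minimal_sets) >= 2) categorize_pcres(minimal_sets) else NULL
  all_pcres <- if (!is.null(categories)) categories$kmer else character()

  matches <- if (length(all_pcres) > 0 && length(sim$tfbm_library) > 0) {
    match_tfbm(all_pcres, sim$tfbm_library, scope = config$scope)
  } else NULL

  importance_long <- do.call(rbind, lapply(up_models, function(m) {
    data.frame(kmer = m$selection$pcres$kmer, time = m$time,
               scaled_gini = m$selection$pcres$scaled_gini,
               stringsAsFactors = FALSE)
  }))
  clusters <- NULL; summaries <- NULL
  if (length(all_pcres) >= 2) {
    D <- pcre_distance_matrix(all_pcres)
    cl <- upgma_cut(D, cutoff = config$cutoff)
    clusters <- cl$clusters
    summaries <- cluster_summary(clusters, categories, importance_long,
                                 matches, time_points = labels$time_points)
    note("clusters", n_clusters = length(unique(clusters)))
  }

  ## enrichment analyses
  go_tables <- lapply(labels$time_points, function(tp) {
    study <- labels$up[[tp]]
    if (length(study) == 0) return(NULL)
    go_enrichment(study, labels$genes, sim$go)
  })
  names(go_tables) <- labels$time_points
  pcre_enrich <- lapply(up_models, function(m) {
    pcre_upregulated_enrichment(presence, m$selection$pcres$kmer,
                                labels$up[[m$time]], labels$negatives)
  })
  profile_tables <- NULL
  if (!is.null(clusters)) {
    bearing <- function(kmers) {
      rownames(presence)[rowSums(presence[, kmers, drop = FALSE]) > 0]
    }
    profile_tables <- lapply(sort(unique(clusters)), function(cid) {
      inside <- bearing(names(clusters)[clusters == cid])
      outside <- bearing(names(clusters)[clusters != cid])
      outside <- setdiff(outside, inside)
      if (length(inside) == 0 || length(outside) == 0) return(NULL)
      profile_enrichment(inside, outside, profiles)
    })
  }

  manifest <- list(
    config = config[setdiff(names(config), "grid")],
    grid_size = nrow(config$grid),
    seed = config$seed, split_seed = labels$split_seed,
    stage_counts = stage_log,
    balance_scope = if (length(fitted) > 0) fitted[[1]]$cv$balance_scope else NA,
    decisions = list(selection_fraction = config$selection_fraction,
                     background_scope = config$scope,
                     test_sidedness = "greater"),
    test_access = unique(test_access))

  run <- structure(list(labels = labels, profiles = profiles,
                        models = models, categories = categories,
                        matches = matches, clusters = clusters,
                        cluster_summaries = summaries,
                        go_enrichment = go_tables,
                        pcre_enrichment = pcre_enrich,
                        profile_enrichment = profile_tables,
                        manifest = manifest),
                   class = "tempcre_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Write pipeline outputs as plain-text tables plus a JSON manifest
#'
#' @param run a `tempcre_run`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    if (!is.null(df) && nrow(df) > 0)
      utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                         row.names = FALSE)
  }
  w(run$profiles, "profiles.tsv")
  for (key in names(run$models)) {
    m <- run$models[[key]]
    if (is.null(m$selection)) next
    tag <- gsub("@", "_", key)
    sel <- m$selection$pcres
    sel$category <- if (!is.null(run$categories))
      run$categories$category[match(sel$kmer, run$categories$kmer)] else NA
    w(sel, sprintf("pcres_%s.tsv", tag))
    w(m$selection$ramp$points, sprintf("ramp_%s.tsv", tag))
    jsonlite::write_json(
      list(f1_max = m$selection$fit$f1_max,
           k_half = m$selection$fit$k_half, rss = m$selection$fit$rss,
           n_minimal = as.integer(m$selection$n_minimal),
           test_f1 = m$report$test_f1, cv_f1 = m$report$cv_f1,
           best_hyperparameters = as.list(m$report$hp)),
      file.path(dir, sprintf("model_%s.json", tag)), auto_unbox = TRUE)
  }
  w(run$categories, "pcre_categories.tsv")
  w(run$matches, "tfbm_matches.tsv")
  if (!is.null(run$clusters))
    w(data.frame(kmer = names(run$clusters), cluster_id = run$clusters),
      "pcre_clusters.tsv")
  for (tp in names(run$go_enrichment))
    w(run$go_enrichment[[tp]], sprintf("go_enrichment_%s.tsv", tp))
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
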