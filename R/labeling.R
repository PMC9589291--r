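#' Label genes as up-, down- or non-responsive per time point
#'
#' Applies the differential-expression thresholds to a DE table. A gene is
#' up-regulated at a time point when log2FC >= `up_fc` and adjusted
#' p <= `alpha` (inclusive, as are the down-regulation bounds), and a
#' negative (non-responsive) gene satisfies |log2FC| < `null_fc` OR
#' adjusted p > `alpha` for every cold time point and every other stress
#' condition. Genes meeting neither rule at a time point are excluded
#' from that time point's model.
#'
#' @param de data.frame with columns `gene_id`, `condition`, `time`,
#'   `log2fc`, `adj_p`; one record per (gene, condition, time).
#' @param up_fc,down_fc log2 fold-change thresholds for up/down calls.
#' @param alpha adjusted-p threshold.
#' @param null_fc |log2FC| bound of the non-responsive rule.
#' @param cold_condition condition label carrying the time course.
#' @return object of class `response_labels`: `time_points` (ordered),
#'   `up`/`down` (named lists of gene-id vectors per time point),
#'   `negatives` (shared across time points), `genes` (all gene ids).
#' @export
label_genes <- function(de, up_fc = 1.0, down_fc = -1.0, alpha = 0.05,
                        null_fc = 0.5, cold_condition = "cold") {
  need <- c("gene_id", "condition", "time", "log2fc", "adj_p")
  miss <- setdiff(need, names(de))
  if (length(miss) > 0)
    stop(sprintf("incomplete-table: missing column(s) %s",
                 paste(miss, collapse = ", ")))
  stopifnot(all(de$adj_p >= 0 & de$adj_p <= 1))
  cold <- de[de$condition == cold_condition, , drop = FALSE]
  genes <- sort(unique(de$gene_id))
  tps <- unique(cold$time)
  tps <- tps[order(as.numeric(tps))]
  per_gene_tp <- table(cold$gene_id, cold$time)
  if (any(per_gene_tp != 1) || nrow(per_gene_tp) != length(genes))
    stop("incomplete-table: every gene needs exactly one cold record per time point")

  up <- list(); down <- list()
  for (tp in tps) {
    sub <- cold[cold$time == tp, ]
    up[[as.character(tp)]] <- sort(sub$gene_id[sub$log2fc >= up_fc & sub$adj_p <= alpha])
    down[[as.character(tp)]] <- sort(sub$gene_id[sub$log2fc <= down_fc & sub$adj_p <= alpha])
  }
  # negatives: the OR rule must hold in every condition x time record
  null_ok <- abs(de$log2fc) < null_fc | de$adj_p > alpha
  neg <- tapply(null_ok, de$gene_id, all)
  negatives <- sort(names(neg)[neg])
  if (length(negatives) == 0) stop("no-negative-examples: no gene is non-responsive everywhere")
  structure(list(time_points = as.character(tps), up = up, down = down,
                 negatives = negatives, genes = genes,
                 thresholds = list(up_fc = up_fc, down_fc = down_fc,
                                   alpha = alpha, null_fc = null_fc)),
            class = "response_labels")
}

#' Encode U/D/N expression profiles
#'
#' One character per cold time point, ordered by time: U when the
#' up-regulation rule holds, D when the down-regulation rule holds, N
#' otherwise (e.g. "UUDDNN" = up at the first two time points, down at
#' the next two, unchanged at the last two).
#'
#' @inheritParams label_genes
#' @return data.frame with columns `gene_id`, `profile`.
#' @export
encode_profiles <- function(de, up_fc = 1.0, down_fc = -1.0, alpha = 0.05,
                            cold_condition = "cold") {
  cold <- de[de$condition == cold_condition, , drop = FALSE]
  if (nrow(cold) == 0) stop("incomplete-table: no cold records")
  tps <- unique(cold$time)
  tps <- as.character(tps[order(as.numeric(tps))])
  genes <- sort(unique(cold$gene_id))
  if (any(table(cold$gene_id, cold$time) != 1))
    stop("incomplete-table: every gene needs one record per time point")
  cold <- cold[order(match(cold$gene_id, genes),
                     match(as.character(cold$time), tps)), ]
  code <- ifelse(cold$log2fc >= up_fc & cold$adj_p <= alpha, "U",
                 ifelse(cold$log2fc <= down_fc & cold$adj_p <= alpha, "D", "N"))
  prof <- vapply(split(code, rep(seq_along(genes), each = length(tps))),
                 paste, character(1), collapse = "")
  data.frame(gene_id = genes, profile = unname(prof), stringsAsFactors = FALSE)
}

#' Stratified train/test split of labelled genes
#'
#' Per time point, each non-empty class (up, down, negatives) is split so
#' that floor((1 - fraction) * n) genes form the held-out test set and the
#' rest train. The split is deterministic given the seed; the test sets
#' must not be touched until final model evaluation.
#'
#' @param labels a `response_labels` object.
#' @param fraction training fraction (default 0.8).
#' @param seed RNG seed.
#' @return `labels` augmented with a `split` element: per time point a
#'   list with `up_train`, `up_test`, `down_train`, `down_test`,
#'   `neg_train`, `neg_test`.
#' @export
split_train_test <- function(labels, fraction = 0.8, seed = 1) {
  stopifnot(inherits(labels, "response_labels"), fraction > 0, fraction < 1)
  split_ids <- function(ids, tag, required = TRUE) {
    if (length(ids) == 0) return(list(train = character(), test = character()))
    if (length(ids) < 5) {
      # up and negative sets feed every model: too few is an error; a tiny
      # down set only disables that direction at this time point
      if (required)
        stop(sprintf("insufficient-examples: class %s has fewer than 5 genes", tag))
      warning(sprintf("insufficient-examples: class %s has fewer than 5 genes; kept in training only", tag))
      return(list(train = ids, test = character()))
    }
    n_test <- floor(length(ids) * (1 - fraction) + 1e-9)
    test <- sort(sample(ids, n_test))
    list(train = setdiff(ids, test), test = test)
  }
  out <- list()
  for (i in seq_along(labels$time_points)) {
    tp <- labels$time_points[i]
    set.seed(seed + i)
    u <- split_ids(labels$up[[tp]], paste0("up@", tp))
    d <- split_ids(labels$down[[tp]], paste0("down@", tp), required = FALSE)
    n <- split_ids(labels$negatives, paste0("negatives@", tp))
    out[[tp]] <- list(up_train = u$train, up_test = u$test,
                      down_train = d$train, down_test = d$test,
                      neg_train = n$train, neg_test = n$test)
  }
  labels$split <- out
  labels$split_seed <- seed
  labels
}
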