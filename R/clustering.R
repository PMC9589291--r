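#' Pairwise 1 - PCC distance matrix between pCREs
#'
#' Distances are 1 minus the maximal PWM Pearson correlation (over
#' ungapped alignments and both strands) between the one-hot PWMs of the
#' k-mers; the diagonal is zero and the matrix symmetric. Negative PCCs
#' give distances above 1, which is harmless above any sensible cutoff.
#'
#' @param pcres character vector of pCRE k-mers.
#' @param min_overlap,allow_rc alignment options passed to [pwm_pcc()].
#' @return symmetric numeric matrix with `pcres` as dimnames.
#' @export
pcre_distance_matrix <- function(pcres, min_overlap = 5, allow_rc = TRUE) {
  n <- length(pcres)
  stopifnot(n >= 2)
  pwms <- lapply(pcres, kmer_to_pwm)
  D <- matrix(0, n, n, dimnames = list(pcres, pcres))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- 1 - pwm_pcc(pwms[[i]], pwms[[j]], min_overlap = min_overlap,
                       allow_rc = allow_rc)$pcc
      D[i, j] <- d; D[j, i] <- d
    }
  }
  D
}

#' UPGMA clustering with a strict height cut
#'
#' Unweighted average-linkage (UPGMA) agglomerative clustering of a
#' distance matrix; clusters are the maximal subtrees whose merge heights
#' are strictly below `cutoff`. Cluster ids are assigned in order of each
#' cluster's smallest member index, which also breaks ties
#' deterministically.
#'
#' @param D symmetric distance matrix (zero diagonal).
#' @param cutoff height threshold (default 0.39).
#' @return list: `clusters` (named integer vector of cluster ids),
#'   `tree` (the `hclust` object).
#' @export
upgma_cut <- function(D, cutoff = 0.39) {
  D <- as.matrix(D)
  n <- nrow(D)
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n == 1) return(list(clusters = stats::setNames(1L, labels), tree = NULL))
  tree <- stats::hclust(stats::as.dist(D), method = "average")
  # union-find over merges below the cutoff (strict <)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  node_rep <- integer(nrow(tree$merge))   # leaf representative per internal node
  for (k in seq_len(nrow(tree$merge))) {
    ch <- tree$merge[k, ]
    reps <- ifelse(ch < 0, -ch, node_rep[pmax(ch, 1)])
    node_rep[k] <- reps[1]
    if (tree$height[k] < cutoff) {
      r1 <- find(reps[1]); r2 <- find(reps[2])
      parent[max(r1, r2)] <- min(r1, r2)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp_min <- tapply(seq_len(n), roots, min)       # smallest member index
  id_of_root <- stats::setNames(seq_along(comp_min), names(sort(comp_min)))
  ids <- as.integer(id_of_root[as.character(roots)])
  list(clusters = stats::setNames(ids, labels), tree = tree)
}

#' Summarize pCRE clusters
#'
#' Per cluster: members, fractions of the general / time-point-specific /
#' non-specific categories, median min-max-scaled Gini importance per
#' time point (NA when no member is in that time point's model), and the
#' fraction of members significantly matching each TF family.
#'
#' @param clusters named integer vector from [upgma_cut()].
#' @param categories data.frame from [categorize_pcres()].
#' @param importances data.frame with columns `kmer`, `time`,
#'   `scaled_gini` (one row per k-mer per time-point model using it).
#' @param matches optional match table from [match_tfbm()].
#' @param time_points ordered time-point labels.
#' @return list of per-cluster summaries.
#' @export
cluster_summary <- function(clusters, categories, importances,
                            matches = NULL, time_points = NULL) {
  if (is.null(time_points)) time_points <- sort(unique(importances$time))
  lapply(sort(unique(clusters)), function(cid) {
    members <- names(clusters)[clusters == cid]
    cat_m <- categories$category[match(members, categories$kmer)]
    frac <- function(x) mean(cat_m == x)
    med_imp <- vapply(time_points, function(tp) {
      v <- importances$scaled_gini[importances$time == tp &
                                     importances$kmer %in% members]
      if (length(v) == 0) NA_real_ else stats::median(v)
    }, numeric(1))
    fam_frac <- NULL
    if (!is.null(matches)) {
      mm <- matches[matches$pcre %in% members, , drop = FALSE]
      fams <- sort(unique(mm$family))
      fam_frac <- vapply(fams, function(f)
        mean(members %in% mm$pcre[mm$family == f & mm$significant]),
        numeric(1))
    }
    list(cluster_id = cid, members = members,
         category_fractions = c(general = frac("general"),
                                specific = frac("specific"),
                                non_specific = frac("non_specific")),
         median_scaled_importance = stats::setNames(med_imp, time_points),
         tfbm_match_fraction = fam_frac)
  })
}
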