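#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values,
#' mapped back to the input order and capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of adjusted p-values (q-values), same order as `p`.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' One-sided Fisher enrichment p-values for 2x2 tables
#'
#' Exact hypergeometric upper-tail probability P(X >= a) for the table
#' (a = positives with item, b = positives without, c = negatives with,
#' d = negatives without), vectorized over tables. This single core backs
#' every Fisher computation in the package. `alternative = "two.sided"`
#' sums all tables with point probability <= that of the observed table
#' (the `fisher.test` convention).
#'
#' @param a,b,c,d integer vectors of contingency counts.
#' @param alternative "greater" (enrichment, default) or "two.sided".
#' @return numeric vector of p-values.
#' @export
fisher_p <- function(a, b, c, d, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(b) == length(a), length(c) == length(a),
            length(d) == length(a), all(c(a, b, c, d) >= 0))
  if (alternative == "greater") {
    # X ~ Hypergeom(m = positives, n = negatives, k = items drawn)
    p <- stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
  } else {
    p <- mapply(function(a, b, c, d) {
      k <- a + c
      x <- max(0, k - (c + d)):min(a + b, k)
      dens <- stats::dhyper(x, a + b, c + d, k)
      obs <- stats::dhyper(a, a + b, c + d, k)
      sum(dens[dens <= obs * (1 + 1e-7)])
    }, a, b, c, d)
  }
  pmin(p, 1)
}

#' Odds ratio with Haldane correction
#'
#' Sample odds ratio (a*d)/(b*c); when any cell is zero, 0.5 is added to
#' every cell so the ratio (and its logarithm) stays finite.
#'
#' @param a,b,c,d contingency counts (vectorized).
#' @return numeric vector of odds ratios.
#' @export
odds_ratio <- function(a, b, c, d) {
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  a <- a + 0.5 * zero; b <- b + 0.5 * zero
  c <- c + 0.5 * zero; d <- d + 0.5 * zero
  (a * d) / (b * c)
}

# Assemble the standard enrichment row set from count vectors.
enrichment_rows <- function(item, a, b, c, d, alternative = "greater",
                            log_base = 10) {
  or <- odds_ratio(a, b, c, d)
  p <- fisher_p(a, b, c, d, alternative = alternative)
  data.frame(item = item, a = a, b = b, c = c, d = d,
             odds_ratio = or, log_or = log(or, base = log_base),
             p = p, q = bh_adjust(p), stringsAsFactors = FALSE)
}

#' GO term enrichment of a study gene set
#'
#' One-sided Fisher test per term, comparing annotation frequency in the
#' study set against the remaining background genes, with BH adjustment
#' across terms. A term is called enriched when q <= alpha.
#'
#' @param study character vector of study gene ids (subset of `background`).
#' @param background character vector of all gene ids.
#' @param annotations data.frame with columns `gene_id`, `term_id`.
#' @param alpha enrichment q-value threshold (default 0.05).
#' @param alternative sidedness of the Fisher test.
#' @param log_base base for the reported log odds ratio (default 10).
#' @return data.frame with one row per term: counts, odds ratio, log
#'   odds ratio, p, q and the `enriched` call, ordered by q.
#' @export
go_enrichment <- function(study, background, annotations, alpha = 0.05,
                          alternative = "greater", log_base = 10) {
  stopifnot(all(c("gene_id", "term_id") %in% names(annotations)))
  if (!all(study %in% background)) stop("study set must be a subset of the background")
  if (length(study) == 0) {
    return(enrichment_rows(character(), integer(), integer(), integer(),
                           integer(), log_base = log_base)[0, ])
  }
  rest <- setdiff(background, study)
  if (length(rest) == 0) stop("degenerate-background: study set equals the background")
  ann <- annotations[annotations$gene_id %in% background, , drop = FALSE]
  terms <- sort(unique(ann$term_id))
  in_study <- ann$gene_id %in% study
  a <- as.integer(table(factor(ann$term_id[in_study], levels = terms)))
  cc <- as.integer(table(factor(ann$term_id[!in_study], levels = terms)))
  out <- enrichment_rows(terms, a, length(study) - a, cc, length(rest) - cc,
                         alternative = alternative, log_base = log_base)
  names(out)[names(out) == "item"] <- "term_id"
  out$enriched <- out$q <= alpha
  out[order(out$q, out$p, out$term_id), ]
}

#' Expression-profile enrichment for genes bearing a pCRE cluster
#'
#' For every U/D/N profile observed in either gene group, a one-sided
#' Fisher test of profile frequency in the cluster-bearing genes versus
#' the comparison genes (genes bearing pCREs of other clusters), BH
#' adjusted across profiles.
#'
#' @param cluster_genes,comparison_genes character vectors of gene ids.
#' @param profiles data.frame with columns `gene_id`, `profile`.
#' @param alpha significance threshold on q (default 0.05).
#' @return data.frame of enrichment rows per profile.
#' @export
profile_enrichment <- function(cluster_genes, comparison_genes, profiles,
                               alpha = 0.05) {
  if (length(cluster_genes) == 0 || length(comparison_genes) == 0)
    stop("insufficient-background: both gene groups must be non-empty")
  pf <- stats::setNames(profiles$profile, profiles$gene_id)
  pc <- pf[intersect(cluster_genes, names(pf))]
  po <- pf[intersect(comparison_genes, names(pf))]
  profs <- sort(unique(c(pc, po)))
  a <- as.integer(table(factor(pc, levels = profs)))
  cc <- as.integer(table(factor(po, levels = profs)))
  out <- enrichment_rows(profs, a, length(pc) - a, cc, length(po) - cc)
  names(out)[names(out) == "item"] <- "profile"
  out$significant <- out$q <= alpha
  out[order(out$q, out$p, out$profile), ]
}

#' Enrichment of pCRE presence in up-regulated genes
#'
#' Per pCRE, a one-sided Fisher test of presence in up-regulated genes at
#' a time point versus the non-responsive negatives, with BH adjustment
#' across the tested pCRE set and a (natural-log by default) log odds
#' ratio.
#'
#' @param presence logical/0-1 matrix, genes x k-mers, rownames gene ids.
#' @param pcres character vector of pCRE k-mers (columns of `presence`).
#' @param up_genes,negatives character vectors of gene ids.
#' @param log_base base of the reported log odds ratio (default `exp(1)`).
#' @return data.frame of enrichment rows per pCRE.
#' @export
pcre_upregulated_enrichment <- function(presence, pcres, up_genes, negatives,
                                        log_base = exp(1)) {
  stopifnot(all(pcres %in% colnames(presence)),
            all(c(up_genes, negatives) %in% rownames(presence)))
  up <- presence[up_genes, pcres, drop = FALSE]
  ng <- presence[negatives, pcres, drop = FALSE]
  a <- colSums(up); cc <- colSums(ng)
  out <- enrichment_rows(pcres, a, length(up_genes) - a, cc,
                         length(negatives) - cc, log_base = log_base)
  names(out)[names(out) == "item"] <- "kmer"
  out
}
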