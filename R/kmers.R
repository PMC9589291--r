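#' Reverse complement of DNA strings
#' @param x character vector over A/C/G/T.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical form of a k-mer
#'
#' The lexicographic minimum of a k-mer and its reverse complement, so
#' that a k-mer and its reverse complement count as the same feature.
#' Idempotent; errors on non-ACGT input.
#'
#' @param seq character vector of k-mers over A/C/G/T.
#' @return character vector of canonical k-mers.
#' @export
canonical_kmer <- function(seq) {
  seq <- toupper(seq)
  if (any(grepl("[^ACGT]", seq))) stop("non-ACGT: ambiguity codes are not allowed")
  rc <- revcomp(seq)
  ifelse(seq <= rc, seq, rc)
}

#' All canonical k-mers of one length
#' @param k k-mer length.
#' @return character vector, lexicographically sorted.
#' @export
all_canonical_kmers <- function(k) {
  km <- Biostrings::mkAllStrings(DNA_BASES, k)
  sort(unique(canonical_kmer(km)))
}

# Presence (0/1) of every k-mer of one length in each sequence of each
# region list, processed in gene chunks to bound memory at k = 8.
.presence_one_k <- function(regions, k, chunk = 400L) {
  n <- length(regions[[1]])
  km <- Biostrings::mkAllStrings(DNA_BASES, k)
  pres <- matrix(FALSE, n, length(km), dimnames = list(NULL, km))
  idx_chunks <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  for (ii in idx_chunks) {
    acc <- NULL
    for (r in regions) {
      f <- Biostrings::oligonucleotideFrequency(
        Biostrings::DNAStringSet(r[ii]), width = k)
      acc <- if (is.null(acc)) f > 0 else acc | (f > 0)
    }
    pres[ii, ] <- acc
  }
  # canonical collapse: a canonical column is present when either strand is
  canon <- km[km <= revcomp(km)]
  out <- pres[, canon, drop = FALSE] | pres[, revcomp(canon), drop = FALSE]
  colnames(out) <- canon
  out
}

#' Per-gene canonical k-mer presence matrix
#'
#' Scans the upstream, gene-body and downstream region of every gene for
#' all k-mers with k in `k_range`, collapsing each k-mer with its reverse
#' complement (so one-strand scanning is equivalent to scanning both
#' strands), and returns binary presence with set semantics per gene.
#' Windows spanning region boundaries are not counted.
#'
#' @param genes data.frame with columns `gene_id`, `upstream_seq`,
#'   `body_seq`, `downstream_seq`.
#' @param k_range integer vector of k-mer lengths (default 5:8).
#' @param chunk genes per processing chunk (memory bound at k = 8).
#' @return logical matrix, genes x canonical k-mers, rownames = gene ids.
#' @export
kmer_presence_matrix <- function(genes, k_range = 5:8, chunk = 400L) {
  stopifnot(all(c("gene_id", "upstream_seq", "body_seq", "downstream_seq")
                %in% names(genes)))
  if (nrow(genes) == 0) return(matrix(FALSE, 0, 0))
  regions <- list(genes$upstream_seq, genes$body_seq, genes$downstream_seq)
  mats <- lapply(sort(k_range), function(k) .presence_one_k(regions, k, chunk))
  out <- do.call(cbind, mats)
  rownames(out) <- genes$gene_id
  out
}

#' Canonical k-mer presence set of a single gene
#'
#' @param gene one-row data.frame or list with the three region sequences.
#' @param k_range k-mer lengths.
#' @return character vector (set) of canonical k-mers present in the gene.
#' @export
gene_kmer_presence <- function(gene, k_range = 5:8) {
  g <- data.frame(gene_id = "g",
                  upstream_seq = gene$upstream_seq,
                  body_seq = gene$body_seq,
                  downstream_seq = gene$downstream_seq)
  m <- kmer_presence_matrix(g, k_range = k_range)
  colnames(m)[m[1, ]]
}

#' Fisher enrichment of k-mers from contingency counts
#'
#' One-sided (enrichment in positives) exact test per k-mer with the
#' Haldane-corrected odds ratio and BH adjustment across all k-mers
#' supplied together.
#'
#' @param kmer character vector of k-mers.
#' @param a,b,c,d contingency counts: positives with / without the k-mer,
#'   negatives with / without.
#' @return data.frame: kmer, a, b, c, d, odds_ratio, p, q.
#' @export
fisher_enrichment <- function(kmer, a, b, c, d) {
  if (any(a + b <= 0) || any(c + d <= 0))
    stop("insufficient-examples: each class needs at least one gene")
  out <- enrichment_rows(kmer, a, b, c, d)
  names(out)[names(out) == "item"] <- "kmer"
  out$log_or <- NULL
  out
}

#' Five-bin k-mer enrichment screen
#'
#' Splits the training genes into `n_bins` disjoint, class-stratified bins
#' and, per bin, tests every candidate canonical k-mer (present in at
#' least one training gene) for enrichment among that bin's positives
#' versus its negatives with a one-sided Fisher test, BH-adjusted within
#' the bin across all candidates of all k jointly. K-mers with q < alpha
#' in every bin are returned as model features.
#'
#' @param presence logical presence matrix (genes x canonical k-mers).
#' @param positives,negatives training gene ids by class.
#' @param n_bins number of bins (default 5; 1 reduces to a single screen).
#' @param alpha adjusted-p threshold (default 0.05, strict `<`).
#' @param seed RNG seed for the stratified bin assignment.
#' @return list: `kmers` (features enriched in all bins), `per_bin`
#'   (enrichment tables), `bins` (per-gene bin assignment).
#' @export
binned_enrichment <- function(presence, positives, negatives, n_bins = 5,
                              alpha = 0.05, seed = 1) {
  stopifnot(all(c(positives, negatives) %in% rownames(presence)))
  if (length(positives) < n_bins || length(negatives) < n_bins)
    stop("insufficient-examples: each class needs at least n_bins genes")
  assign_bins <- function(ids) {
    ids <- sample(ids)
    stats::setNames(rep_len(seq_len(n_bins), length(ids)), ids)
  }
  set.seed(seed)
  bins <- c(assign_bins(positives), assign_bins(negatives))
  train <- c(positives, negatives)
  candidates <- colnames(presence)[colSums(presence[train, , drop = FALSE]) > 0]
  per_bin <- vector("list", n_bins)
  keep <- rep(TRUE, length(candidates))
  for (b in seq_len(n_bins)) {
    pos_b <- positives[bins[positives] == b]
    neg_b <- negatives[bins[negatives] == b]
    a <- colSums(presence[pos_b, candidates, drop = FALSE])
    cc <- colSums(presence[neg_b, candidates, drop = FALSE])
    tab <- fisher_enrichment(candidates, a, length(pos_b) - a, cc,
                             length(neg_b) - cc)
    per_bin[[b]] <- tab
    keep <- keep & (tab$q < alpha)
  }
  list(kmers = candidates[keep], per_bin = per_bin, bins = bins)
}

#' Binary feature matrix over a fixed k-mer list
#'
#' @param presence logical presence matrix (genes x canonical k-mers).
#' @param kmers feature k-mers (columns are kept even if all zero).
#' @param gene_ids genes to include, in order (default all rows).
#' @return integer 0/1 matrix, genes x k-mers.
#' @export
build_feature_matrix <- function(presence, kmers, gene_ids = rownames(presence)) {
  if (length(kmers) == 0) stop("no-features: the k-mer list is empty")
  stopifnot(all(kmers %in% colnames(presence)),
            all(gene_ids %in% rownames(presence)))
  m <- presence[gene_ids, kmers, drop = FALSE]
  storage.mode(m) <- "integer"
  m
}
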