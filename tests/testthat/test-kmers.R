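test_that("canonicalization returns the lexicographic minimum of both strands", {
  expect_identical(canonical_kmer("TTTTT"), "AAAAA")
  expect_identical(canonical_kmer("ACGCGT"), "ACGCGT")  # rc palindrome
  expect_identical(canonical_kmer("TGCAA"), "TGCAA")    # TGCAA < TTGCA
  # idempotent and vectorized
  kms <- c("TTTTT", "ACGCGT", "GATTACA")
  expect_identical(canonical_kmer(canonical_kmer(kms)), canonical_kmer(kms))
  expect_error(canonical_kmer("ACGTN"), "non-ACGT")
})

test_that("gene k-mer presence has set semantics over the three regions", {
  g <- list(upstream_seq = "AAAAAA", body_seq = "", downstream_seq = "")
  expect_identical(gene_kmer_presence(g, 5), "AAAAA")
  # a region shorter than k contributes nothing
  g2 <- list(upstream_seq = "ACGT", body_seq = "", downstream_seq = "")
  expect_length(gene_kmer_presence(g2, 5), 0)
})

test_that("presence matches an exhaustive two-strand scan oracle", {
  set.seed(71)
  for (rep in 1:3) {
    regions <- replicate(3, paste(sample(c("A", "C", "G", "T"), 120,
                                         replace = TRUE), collapse = ""))
    g <- list(upstream_seq = regions[1], body_seq = regions[2],
              downstream_seq = regions[3])
    expect_identical(sort(gene_kmer_presence(g, 5:8)),
                     oracle_two_strand_scan(regions, 5:8))
  }
})

test_that("feature matrices are invariant to reverse-complementing input", {
  set.seed(72)
  genes <- data.frame(
    gene_id = paste0("g", 1:6),
    upstream_seq = replicate(6, paste(sample(c("A", "C", "G", "T"), 60,
                                             replace = TRUE), collapse = "")),
    body_seq = replicate(6, paste(sample(c("A", "C", "G", "T"), 80,
                                         replace = TRUE), collapse = "")),
    downstream_seq = replicate(6, paste(sample(c("A", "C", "G", "T"), 60,
                                               replace = TRUE), collapse = "")))
  flipped <- genes
  for (col in c("upstream_seq", "body_seq", "downstream_seq"))
    flipped[[col]] <- revcomp(genes[[col]])
  m1 <- kmer_presence_matrix(genes, 5:6)
  m2 <- kmer_presence_matrix(flipped, 5:6)
  expect_identical(m1, m2)
})

test_that("Fisher enrichment equals exact hypergeometric values", {
  r <- fisher_enrichment("x", 8, 2, 2, 8)
  expect_equal(r$p, 2126 / 184756, tolerance = 1e-12)
  expect_equal(r$odds_ratio, 16)
  expect_gt(fisher_enrichment("x", 5, 5, 5, 5)$p, 0.5)
  expect_equal(fisher_enrichment("x", 10, 0, 0, 10)$p, 1 / choose(20, 10),
               tolerance = 1e-12)
  # random small tables against the tail-sum oracle and fisher.test
  set.seed(9)
  for (i in 1:25) {
    tab <- as.vector(stats::rmultinom(1, sample(8:30, 1), rep(0.25, 4)))
    p_pkg <- fisher_p(tab[1], tab[2], tab[3], tab[4])
    expect_equal(p_pkg, oracle_fisher_greater(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-10)
    ft <- fisher.test(matrix(tab, 2, byrow = TRUE), alternative = "greater")
    expect_equal(p_pkg, unname(ft$p.value), tolerance = 1e-9)
  }
})

test_that("binned screen keeps k-mers enriched in every bin and controls nulls", {
  set.seed(31)
  n <- 150
  ids <- paste0("g", seq_len(n))
  y_pos <- ids[1:75]; y_neg <- ids[76:150]
  kms <- all_canonical_kmers(5)[1:300]
  pres <- matrix(runif(n * 300) < 0.3, n, 300, dimnames = list(ids, kms))
  # plant one strongly associated k-mer
  pres[, "AAAAA"] <- c(runif(75) < 0.95, runif(75) < 0.05)
  scr <- binned_enrichment(pres, y_pos, y_neg, n_bins = 5, seed = 4)
  expect_true("AAAAA" %in% scr$kmers)
  # each returned k-mer really has q < alpha in each bin individually
  for (km in scr$kmers) {
    qs <- vapply(scr$per_bin, function(t) t$q[t$kmer == km], numeric(1))
    expect_true(all(qs < 0.05))
  }
  # bins partition the training genes, stratified
  expect_setequal(names(scr$bins), c(y_pos, y_neg))
  expect_true(all(table(scr$bins[y_pos]) >= 15))
  # n_bins = 1 reduces to a single Fisher screen
  scr1 <- binned_enrichment(pres, y_pos, y_neg, n_bins = 1, seed = 4)
  tab <- scr1$per_bin[[1]]
  expect_identical(sort(scr1$kmers), sort(tab$kmer[tab$q < 0.05]))
  # no signal -> empty feature set
  pres0 <- matrix(runif(n * 300) < 0.3, n, 300, dimnames = list(ids, kms))
  expect_length(binned_enrichment(pres0, y_pos, y_neg, seed = 4)$kmers, 0)
  expect_error(binned_enrichment(pres, ids[1:3], y_neg, n_bins = 5),
               "insufficient-examples")
})

test_that("feature matrix construction is faithful and keeps zero columns", {
  ids <- paste0("g", 1:4)
  pres <- matrix(c(TRUE, FALSE, TRUE, FALSE,
                   FALSE, FALSE, FALSE, FALSE,
                   TRUE, TRUE, TRUE, TRUE), 4, 3,
                 dimnames = list(ids, c("AAAAA", "AAAAC", "AAAAG")))
  X <- build_feature_matrix(pres, c("AAAAA", "AAAAC"), ids)
  expect_identical(unname(X[, "AAAAA"]), c(1L, 0L, 1L, 0L))
  expect_identical(unname(colSums(X)), c(2, 0))   # zero column retained
  expect_error(build_feature_matrix(pres, character()), "no-features")
})
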