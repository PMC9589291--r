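short_cfg <- function(seed = 1, ...) {
  sim_config(n_genes = 150, upstream_len = 80, body_len_range = c(40, 80),
             downstream_len = 40, seed = seed, ...)
}

test_that("an empty configuration yields empty outputs", {
  sim <- simulate_dataset(sim_config(n_genes = 0))
  expect_identical(nrow(sim$genes), 0L)
  expect_identical(nrow(sim$de), 0L)
  expect_identical(nrow(sim$truth), 0L)
})

test_that("a motif longer than the upstream region is rejected", {
  long <- paste(rep("A", 30), collapse = "")
  expect_error(sim_config(upstream_len = 20,
                          planted_motifs = list(planted_motif(long, "24"))),
               "motif-too-long")
  expect_error(plant_instance("ACGTACGT", paste(rep("A", 20), collapse = "")),
               "motif-too-long")
})

test_that("planting overwrites in place with a recorded offset and strand", {
  set.seed(5)
  out <- plant_instance(paste(rep("T", 10), collapse = ""),
                        kmer_to_pwm("A"))
  expect_identical(nchar(out$seq), 10L)
  expect_identical(substr(out$seq, out$offset, out$offset),
                   out$instance)
  # one-column P(A)=1 PWM: at most one position differs and carries A or its
  # complement depending on orientation
  diff_pos <- which(strsplit(out$seq, "")[[1]] != "T")
  expect_lte(length(diff_pos), 1)
  # determinism under an identical RNG state
  set.seed(99); a <- plant_instance("ACGTACGTACGT", "CCC")
  set.seed(99); b <- plant_instance("ACGTACGTACGT", "CCC")
  expect_identical(a, b)
  # a deterministic consensus appears where it was planted
  set.seed(7)
  out2 <- plant_instance(paste(rep("A", 50), collapse = ""), "GCGCGC")
  planted <- substr(out2$seq, out2$offset, out2$offset + 5)
  expect_true(planted %in% c("GCGCGC", revcomp("GCGCGC")))
})

test_that("deterministic planting covers exactly the labelled up genes", {
  cfg <- short_cfg(seed = 8, planted_motifs = list(
    planted_motif("GCGGCGC", targets = "0.5", p_signal = 1, p_background = 0)))
  sim <- simulate_dataset(cfg)
  lab <- label_genes(sim$de)
  up <- lab$up[["0.5"]]
  contains <- function(s, km) grepl(km, s, fixed = TRUE) |
    grepl(revcomp(km), s, fixed = TRUE)
  hit <- contains(sim$genes$upstream_seq, "GCGGCGC")
  names(hit) <- sim$genes$gene_id
  expect_true(all(hit[up]))                       # every target carries it
  expect_false(any(hit[lab$negatives]))           # no negative does
  expect_setequal(sim$truth$gene_id, up)
})

test_that("truth ledger rows match the emitted sequences", {
  sim <- simulate_dataset(short_cfg(seed = 12))
  up_seq <- setNames(sim$genes$upstream_seq, sim$genes$gene_id)
  for (i in seq_len(nrow(sim$truth))) {
    row <- sim$truth[i, ]
    emitted <- substr(up_seq[[row$gene_id]], row$offset,
                      row$offset + nchar(row$instance) - 1)
    expect_identical(emitted, row$instance)
  }
  # planted instances come from one-hot PWMs: forward = consensus,
  # reverse = its reverse complement
  cons <- setNames(
    vapply(sim$config$planted_motifs, function(m) pwm_consensus(m$pwm), ""),
    vapply(sim$config$planted_motifs, function(m) m$name, ""))
  fwd <- sim$truth$orientation == "+"
  expect_true(all(sim$truth$instance[fwd] == cons[sim$truth$motif[fwd]]))
  expect_true(all(sim$truth$instance[!fwd] ==
                    revcomp(cons[sim$truth$motif[!fwd]])))
})

test_that("identical configurations reproduce byte-identical outputs", {
  s1 <- simulate_dataset(short_cfg(seed = 4))
  s2 <- simulate_dataset(short_cfg(seed = 4))
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$de, s2$de)
  expect_identical(s1$truth, s2$truth)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_dataset(s1, d1); write_dataset(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("up-labelled counts track the cascading fractions", {
  cfg <- sim_config(n_genes = 2000, upstream_len = 30,
                    body_len_range = c(20, 30), downstream_len = 20,
                    planted_motifs = list(), seed = 2,
                    responsive_fraction = c(0.05, 0.07, 0.10, 0.15, 0.20, 0.25))
  sim <- simulate_dataset(cfg)
  lab <- label_genes(sim$de)
  counts <- vapply(lab$up, length, integer(1))
  f <- cfg$responsive_fraction
  # within 99% binomial bounds of n * fraction (the labelling thresholds
  # exclude a negligible tail of sub-threshold responsive genes)
  lo <- qbinom(0.005, 2000, f * 0.985)
  hi <- qbinom(0.995, 2000, f)
  expect_true(all(counts >= lo & counts <= hi))
  # expected counts non-decreasing along the time course
  expect_true(all(diff(f * 2000) >= 0))
})

test_that("the simulated DE table is complete and within bounds", {
  sim <- simulate_dataset(short_cfg(seed = 3))
  cfg <- sim$config
  expect_identical(nrow(sim$de),
                   150L * (length(cfg$time_points) +
                             length(cfg$other_conditions)))
  expect_true(all(sim$de$adj_p >= 0 & sim$de$adj_p <= 1))
  expect_true(all(nchar(sim$genes$upstream_seq) == cfg$upstream_len))
  expect_true(all(nchar(sim$genes$body_seq) >= cfg$body_len_range[1] &
                    nchar(sim$genes$body_seq) <= cfg$body_len_range[2]))
  expect_true(all(grepl("^[ACGT]+$", sim$genes$body_seq)))
})

test_that("region FASTA and DE table round-trip through files", {
  sim <- simulate_dataset(short_cfg(seed = 6))
  d <- file.path(tempdir(), "roundtrip")
  write_dataset(sim, d)
  genes2 <- read_region_fasta(d)
  expect_identical(genes2$upstream_seq, sim$genes$upstream_seq)
  de2 <- read_de_table(file.path(d, "de_table.tsv"))
  expect_equal(de2$log2fc, sim$de$log2fc, tolerance = 1e-9)
  expect_identical(de2$time, sim$de$time)
  # a missing column is named in the error
  bad <- file.path(tempdir(), "bad.tsv")
  writeLines("gene_id\tcondition\ttime\tlog2FC", bad)
  cat("g1\tcold\t0.5\t1.2\n", file = bad, append = TRUE)
  expect_error(read_de_table(bad), "incomplete-table.*adj_p")
})
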