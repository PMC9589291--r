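# Independent reference implementations used to check the package's
# statistics. These deliberately use a different route than the package
# (explicit tail sums, naive agglomeration, manual step-up) so the two
# paths cross-validate each other.

# One-sided Fisher p as an explicit hypergeometric tail sum over choose().
oracle_fisher_greater <- function(a, b, c, d) {
  k <- a + c
  xs <- a:min(a + b, k)
  sum(exp(lchoose(a + b, xs) + lchoose(c + d, k - xs) - lchoose(a + b + c + d, k)))
}

# Manual Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Brute-force unweighted average-linkage agglomeration with a strict
# height cut: merge the closest pair while its average distance < cutoff.
oracle_average_linkage_cut <- function(D, cutoff) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    if (best_d >= cutoff) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  out <- integer(n)
  mins <- vapply(clusters, min, integer(1))
  for (i in order(mins)) out[clusters[[i]]] <- which(order(mins) == i)
  out
}

# Exhaustive two-strand substring scan for canonical k-mer presence.
oracle_two_strand_scan <- function(regions, k_range) {
  rc1 <- function(s) chartr("ACGT", "TGCA",
                            paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  found <- character()
  for (s in regions) {
    for (strand_seq in c(s, rc1(s))) {
      for (k in k_range) {
        L <- nchar(strand_seq)
        if (L < k) next
        for (i in seq_len(L - k + 1)) {
          km <- substr(strand_seq, i, i + k - 1)
          rc <- rc1(km)
          found <- c(found, if (km <= rc) km else rc)
        }
      }
    }
  }
  sort(unique(found))
}

# Random PWM with Dirichlet-ish columns.
random_pwm <- function(L) {
  m <- matrix(stats::rexp(4 * L), 4, L)
  pwm(sweep(m, 2, colSums(m), "/"))
}

# Maximal number of agreeing positions between two k-mers over ungapped
# alignments (both strands) with a minimum overlap.
max_matching_positions <- function(x, y, min_overlap = 6) {
  rc1 <- function(s) chartr("ACGT", "TGCA",
                            paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  best <- 0L
  xs <- strsplit(x, "")[[1]]
  for (yy in c(y, rc1(y))) {
    ys <- strsplit(yy, "")[[1]]
    for (s in -(length(ys) - min_overlap):(length(xs) - min_overlap)) {
      ix <- max(1, 1 + s):min(length(xs), s + length(ys))
      iy <- ix - s
      best <- max(best, sum(xs[ix] == ys[iy]))
    }
  }
  best
}

# Small hand-built DE table: one row per gene x condition x time.
make_de <- function(gene_ids, time_points = c("0.5", "1", "3", "6", "16", "24"),
                    other = c("dehydration", "salt", "drought"),
                    log2fc = 0, adj_p = 1) {
  grid <- rbind(
    expand.grid(gene_id = gene_ids, condition = "cold", time = time_points,
                stringsAsFactors = FALSE),
    expand.grid(gene_id = gene_ids, condition = other, time = "1",
                stringsAsFactors = FALSE))
  grid$log2fc <- log2fc
  grid$adj_p <- adj_p
  grid
}

# Set (log2fc, adj_p) for one gene at one cold time point.
set_de <- function(de, gene, time, log2fc, adj_p, condition = "cold") {
  i <- de$gene_id == gene & de$condition == condition & de$time == time
  de$log2fc[i] <- log2fc
  de$adj_p[i] <- adj_p
  de
}

# Linearly separable fixture: the first feature ("sig") predicts the class
# perfectly, the rest are coin flips.
sep_data <- function(n = 100, p = 10, seed = 5) {
  set.seed(seed)
  X <- cbind(sig = rep(c(1, 0), each = n / 2),
             matrix(rbinom(n * (p - 1), 1, 0.5), n, p - 1))
  colnames(X) <- c("sig", paste0("f", seq_len(p - 1) + 1))
  rownames(X) <- paste0("g", seq_len(n))
  list(X = X, y = rep(c("pos", "neg"), each = n / 2))
}

# Reduced hyperparameter set for fast model-dependent tests.
small_grid <- function() {
  g <- hyperparameter_grid()
  g[g$max_features == "sqrt" &
      ((g$max_depth == 10 & g$n_estimators == 500) |
         (g$max_depth == 5 & g$n_estimators == 100)), ]
}
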