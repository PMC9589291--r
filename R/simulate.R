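#' Planted motif specification
#'
#' Describes one motif the simulator plants into gene upstream regions:
#' genes up-regulated at any target time point receive one instance with
#' probability `p_signal`; all other genes with probability
#' `p_background`. With `exclusive = TRUE` the signal set is restricted to
#' genes up-regulated only at target time points, emulating an element
#' that confers response specifically at those times (useful when the
#' time course itself is autocorrelated).
#'
#' @param motif consensus string (one-hot PWM) or a PWM.
#' @param targets character vector of target time-point labels.
#' @param p_signal,p_background planting probabilities.
#' @param name motif name (defaults to the consensus).
#' @param exclusive restrict the signal set to genes responsive only at
#'   target time points (default FALSE).
#' @return list of class `planted_motif`.
#' @export
planted_motif <- function(motif, targets, p_signal = 0.8, p_background = 0.05,
                          name = NULL, exclusive = FALSE) {
  p <- if (is.character(motif)) kmer_to_pwm(motif) else pwm(motif)
  if (is.null(name)) name <- if (is.character(motif)) motif else pwm_consensus(p)
  stopifnot(p_signal >= 0, p_signal <= 1, p_background >= 0, p_background <= 1)
  structure(list(pwm = p, targets = as.character(targets),
                 p_signal = p_signal, p_background = p_background,
                 name = name, exclusive = exclusive),
            class = "planted_motif")
}

#' Simulation configuration
#'
#' Defaults define the study conditions the package is exercised under:
#' a six-point cold time course with a cascading (non-decreasing) fraction
#' of responsive genes, three additional stress conditions that thin the
#' clean negative set, and two GC-rich planted 7-mers modelled on
#' canonical cold cis-elements — a CRT/DRE-like element (GCCGACG) active
#' at all time points and a G-box-like element (CACGTGC) specific to the
#' 24 hr response.
#'
#' @param n_genes number of genes.
#' @param upstream_len,downstream_len flank lengths in bp.
#' @param body_len_range min/max gene-body length in bp.
#' @param gc_content background GC fraction in (0, 1).
#' @param time_points ordered cold time-point labels (hours).
#' @param other_conditions additional stress condition labels.
#' @param planted_motifs list of [planted_motif()] specifications.
#' @param responsive_fraction per-time-point fraction of up-regulated
#'   genes; must be non-decreasing (cascading response).
#' @param down_fraction per-time-point fraction of down-regulated genes.
#' @param persistence probability that a gene responsive at one time point
#'   is still responsive at the next.
#' @param other_response_rate per-condition probability that a gene
#'   responds to one of the other stresses.
#' @param effect_size mean/sd of |log2FC| for responsive entries.
#' @param null_sd sd of log2FC for non-responsive entries.
#' @param seed integer RNG seed; identical configs give identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       upstream_len = 1000,
                       body_len_range = c(500, 3000),
                       downstream_len = 1000,
                       gc_content = 0.44,
                       time_points = c("0.5", "1", "3", "6", "16", "24"),
                       other_conditions = c("dehydration", "salt", "drought"),
                       planted_motifs = c(
                         list(planted_motif("GCGGCGC", targets = time_points,
                                            name = "general_GC")),
                         Map(function(km, tp) planted_motif(km, targets = tp),
                             c("GACGCGC", "CCGGCGA", "GCGGACC", "CGACGGC",
                               "GGCCGTC", "CACGTGC"),
                             time_points)),
                       responsive_fraction = c(0.22, 0.23, 0.25, 0.26, 0.28, 0.30),
                       down_fraction = c(0.03, 0.03, 0.04, 0.04, 0.05, 0.05),
                       persistence = 0.5,
                       other_response_rate = 0.05,
                       effect_size = c(mean = 2.5, sd = 0.5),
                       null_sd = 0.2,
                       seed = 1) {
  stopifnot(n_genes >= 0, gc_content > 0, gc_content < 1,
            length(responsive_fraction) == length(time_points),
            all(responsive_fraction >= 0 & responsive_fraction <= 1),
            all(diff(responsive_fraction) >= -1e-12),
            length(down_fraction) == length(time_points),
            all(down_fraction >= 0 & down_fraction <= 1),
            persistence >= 0, persistence <= 1,
            other_response_rate >= 0, other_response_rate <= 1)
  for (m in planted_motifs) {
    stopifnot(inherits(m, "planted_motif"),
              all(m$targets %in% time_points))
    if (ncol(m$pwm) > upstream_len)
      stop("motif-too-long: a planted motif exceeds upstream_len")
  }
  fields <- c("n_genes", "upstream_len", "body_len_range", "downstream_len",
              "gc_content", "time_points", "other_conditions",
              "planted_motifs", "responsive_fraction", "down_fraction",
              "persistence", "other_response_rate", "effect_size", "null_sd",
              "seed")
  structure(mget(fields), class = "sim_config")
}

# Fast iid DNA of given lengths at the configured GC content.
.random_dna <- function(total_len, gc) {
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  idx <- sample.int(4, total_len, replace = TRUE, prob = prob)
  rawToChar(charToRaw("ACGT")[idx])
}

#' Overwrite a PWM sample into a sequence at a random position
#'
#' A start offset is chosen uniformly, the orientation (forward or
#' reverse complement) uniformly, one base is sampled per PWM column, and
#' the substring is overwritten in place so the sequence length is
#' preserved. Uses the current RNG state (seed upstream for
#' reproducibility).
#'
#' @param seq DNA string.
#' @param p PWM (or consensus string).
#' @return list: `seq` (modified), `offset` (1-based start), `orientation`
#'   ("+" forward / "-" reverse complement), `instance` (planted string).
#' @export
plant_instance <- function(seq, p) {
  if (is.character(p)) p <- kmer_to_pwm(p)
  L <- ncol(p); n <- nchar(seq)
  if (L > n) stop("motif-too-long: PWM is longer than the sequence")
  offset <- sample.int(n - L + 1, 1)
  orientation <- sample(c("+", "-"), 1)
  mat <- if (orientation == "+") unclass(p) else unclass(pwm_revcomp(p))
  inst <- paste(vapply(seq_len(L), function(j)
    sample(DNA_BASES, 1, prob = mat[, j]), character(1)), collapse = "")
  substr(seq, offset, offset + L - 1) <- inst
  list(seq = seq, offset = offset, orientation = orientation, instance = inst)
}

# Markov chain over ordered time points with prescribed marginals and
# persistence; returns an n x T logical matrix.
.response_chain <- function(n, fractions, persistence) {
  T_ <- length(fractions)
  m <- matrix(FALSE, n, T_)
  if (n == 0 || T_ == 0) return(m)
  m[, 1] <- stats::runif(n) < fractions[1]
  for (t in seq_len(T_ - 1) + 1) {
    f_prev <- fractions[t - 1]; f_t <- fractions[t]
    q <- if (f_prev >= 1) 1 else (f_t - persistence * f_prev) / (1 - f_prev)
    q <- min(max(q, 0), 1)
    p_on <- ifelse(m[, t - 1], persistence, q)
    m[, t] <- stats::runif(n) < p_on
  }
  m
}

# Soft PWM from a consensus: `major` probability on the consensus base.
.soft_pwm <- function(consensus, major = 0.91, name = consensus) {
  bases <- strsplit(consensus, "")[[1]]
  m <- vapply(bases, function(b) {
    v <- rep((1 - major) / 3, 4); v[DNA_BASES == b] <- major; v
  }, numeric(4))
  pwm(m, name = name)
}

# A TF family: a soft PWM for the consensus plus variants with 1..n
# mutated positions, mimicking within-family binding-site divergence.
.make_family <- function(consensus, family, n_variants = 2, source = "simulated") {
  recs <- list(tfbm_record(paste0("TF_", family, "_0"), family,
                           .soft_pwm(consensus), source = source))
  bases <- strsplit(consensus, "")[[1]]
  for (v in seq_len(n_variants)) {
    b2 <- bases
    pos <- sample(seq_along(bases), v)
    for (j in pos) b2[j] <- sample(setdiff(DNA_BASES, b2[j]), 1)
    recs[[v + 1]] <- tfbm_record(paste0("TF_", family, "_", v), family,
                                 .soft_pwm(paste(b2, collapse = "")),
                                 source = source)
  }
  recs
}

#' Generate a synthetic dataset with planted regulatory motifs
#'
#' Produces gene records (upstream/body/downstream iid sequences at the
#' configured GC content), a differential-expression table for the cold
#' time course plus the other stress conditions (adjusted p-values are
#' simulated directly: responsive Uniform(0, 0.05), non-responsive
#' Uniform(0.2, 1)), GO annotations including one term associated with
#' the up-response, a TFBM library containing soft-PWM versions of the
#' planted motifs (with family variants) plus decoy families, and a truth
#' ledger recording every planted instance.
#'
#' @param config a [sim_config()] object.
#' @return list of class `tempcre_sim`: `genes`, `de`, `go`,
#'   `tfbm_library`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  tps <- config$time_points
  empty_truth <- data.frame(gene_id = character(), motif = character(),
                            region = character(), offset = integer(),
                            orientation = character(), instance = character(),
                            stringsAsFactors = FALSE)
  if (n == 0) {
    return(structure(list(
      genes = data.frame(gene_id = character(), strand = character(),
                         upstream_seq = character(), body_seq = character(),
                         downstream_seq = character(), stringsAsFactors = FALSE),
      de = data.frame(gene_id = character(), condition = character(),
                      time = character(), log2fc = numeric(),
                      adj_p = numeric(), stringsAsFactors = FALSE),
      go = data.frame(gene_id = character(), term_id = character(),
                      stringsAsFactors = FALSE),
      tfbm_library = list(), truth = empty_truth, config = config),
      class = "tempcre_sim"))
  }
  gene_id <- sprintf("g%05d", seq_len(n))

  ## --- response structure -------------------------------------------------
  up <- .response_chain(n, config$responsive_fraction, config$persistence)
  down <- .response_chain(n, config$down_fraction, config$persistence)
  down[up & down] <- FALSE                     # up wins rare conflicts
  other <- matrix(stats::runif(n * length(config$other_conditions)) <
                    config$other_response_rate,
                  n, length(config$other_conditions))

  ## --- differential-expression table --------------------------------------
  es <- config$effect_size
  de_entry <- function(resp_up, resp_down) {
    k <- length(resp_up)
    fc <- stats::rnorm(k, 0, config$null_sd)
    fc[resp_up] <- stats::rnorm(sum(resp_up), es[["mean"]], es[["sd"]])
    fc[resp_down] <- -stats::rnorm(sum(resp_down), es[["mean"]], es[["sd"]])
    p <- stats::runif(k, 0.2, 1)
    p[resp_up | resp_down] <- stats::runif(sum(resp_up | resp_down), 0, 0.05)
    data.frame(log2fc = fc, adj_p = p)
  }
  de <- do.call(rbind, c(
    lapply(seq_along(tps), function(t) {
      cbind(data.frame(gene_id = gene_id, condition = "cold", time = tps[t],
                       stringsAsFactors = FALSE),
            de_entry(up[, t], down[, t]))
    }),
    lapply(seq_along(config$other_conditions), function(j) {
      cbind(data.frame(gene_id = gene_id,
                       condition = config$other_conditions[j], time = "1",
                       stringsAsFactors = FALSE),
            de_entry(other[, j], rep(FALSE, n)))
    })))
  rownames(de) <- NULL

  ## --- sequences -----------------------------------------------------------
  body_len <- sample(seq(config$body_len_range[1], config$body_len_range[2]),
                     n, replace = TRUE)
  lens <- rbind(config$upstream_len, body_len, config$downstream_len)
  big <- .random_dna(sum(lens), config$gc_content)
  ends <- cumsum(as.integer(lens))
  starts <- ends - as.integer(lens) + 1L
  seqs <- substring(big, starts, ends)
  genes <- data.frame(gene_id = gene_id,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      upstream_seq = seqs[seq(1, 3 * n, 3)],
                      body_seq = seqs[seq(2, 3 * n, 3)],
                      downstream_seq = seqs[seq(3, 3 * n, 3)],
                      stringsAsFactors = FALSE)

  ## --- labels as the thresholds will see them ------------------------------
  cold_up_called <- sapply(seq_along(tps), function(t) {
    sub <- de[de$condition == "cold" & de$time == tps[t], ]
    sub <- sub[match(gene_id, sub$gene_id), ]
    sub$log2fc >= 1 & sub$adj_p <= 0.05
  })
  if (n == 1) cold_up_called <- matrix(cold_up_called, nrow = 1)
  null_ok <- abs(de$log2fc) < 0.5 | de$adj_p > 0.05
  is_negative <- tapply(null_ok, de$gene_id, all)[gene_id]
  if (sum(is_negative) < 2 || any(colSums(cold_up_called) < 2))
    stop("insufficient-examples: fewer than 2 genes in a class after labeling")

  ## --- planting ------------------------------------------------------------
  truth_rows <- list()
  occupied <- vector("list", n)
  for (m in config$planted_motifs) {
    t_idx <- match(m$targets, tps)
    in_target <- rowSums(cold_up_called[, t_idx, drop = FALSE]) > 0
    if (m$exclusive && length(t_idx) < length(tps)) {
      off_target <- rowSums(cold_up_called[, -t_idx, drop = FALSE]) > 0
      signal <- in_target & !off_target
    } else signal <- in_target
    carry <- ifelse(signal, stats::runif(n) < m$p_signal,
                    stats::runif(n) < m$p_background)
    for (i in which(carry)) {
      # keep instances of different motifs from overwriting each other:
      # redraw the offset when it collides with an earlier instance
      w <- ncol(m$pwm)
      for (attempt in 1:20) {
        pl <- plant_instance(genes$upstream_seq[i], m$pwm)
        span <- pl$offset:(pl$offset + w - 1)
        if (!any(span %in% occupied[[i]])) {
          genes$upstream_seq[i] <- pl$seq
          occupied[[i]] <- c(occupied[[i]], span)
          truth_rows[[length(truth_rows) + 1]] <- data.frame(
            gene_id = gene_id[i], motif = m$name, region = "upstream",
            offset = pl$offset, orientation = pl$orientation,
            instance = pl$instance, stringsAsFactors = FALSE)
          break
        }
      }
    }
  }
  truth <- if (length(truth_rows) > 0) do.call(rbind, truth_rows) else empty_truth

  ## --- GO annotations -------------------------------------------------------
  pool <- sprintf("GO:%07d", 1:50)
  n_terms <- stats::rpois(n, 2)
  go <- data.frame(
    gene_id = rep(gene_id, n_terms),
    term_id = unlist(lapply(n_terms, function(k)
      sample(pool, min(k, length(pool))))),
    stringsAsFactors = FALSE)
  up_any <- rowSums(cold_up_called) > 0
  cold_term <- stats::runif(n) < ifelse(up_any, 0.3, 0.03)
  go <- rbind(go, data.frame(gene_id = gene_id[cold_term],
                             term_id = "GO:2000001",
                             stringsAsFactors = FALSE))
  go <- go[order(go$gene_id, go$term_id), ]
  rownames(go) <- NULL

  ## --- TFBM library ---------------------------------------------------------
  library_ <- list()
  for (m in config$planted_motifs) {
    library_ <- c(library_, .make_family(pwm_consensus(m$pwm),
                                         paste0("FAM_", m$name)))
  }
  for (f in seq_len(6)) {
    cons <- paste(sample(DNA_BASES, 8, replace = TRUE), collapse = "")
    library_ <- c(library_, .make_family(cons, paste0("DECOY", f)))
  }

  structure(list(genes = genes, de = de, go = go, tfbm_library = library_,
                 truth = truth, config = config),
            class = "tempcre_sim")
}

#' Write a simulated dataset to plain-text files
#'
#' Emits per-region multi-FASTA (`<gene_id>|<region>` headers), the DE
#' table, GO annotations, the truth ledger (TSV), and the TFBM library in
#' MEME minimal format with its family map.
#'
#' @param sim a `tempcre_sim` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "tempcre_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (region in c("upstream", "body", "downstream")) {
    ss <- Biostrings::DNAStringSet(sim$genes[[paste0(region, "_seq")]])
    names(ss) <- paste0(sim$genes$gene_id, "|", region)
    Biostrings::writeXStringSet(ss, file.path(dir, paste0(region, ".fa")))
  }
  de <- sim$de
  names(de) <- c("gene_id", "condition", "time", "log2FC", "adj_p")
  utils::write.table(de, file.path(dir, "de_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$go, file.path(dir, "go_annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth_ledger.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (length(sim$tfbm_library) > 0) {
    write_meme(sim$tfbm_library, file.path(dir, "tfbm_library.meme"))
    write_family_map(sim$tfbm_library, file.path(dir, "tfbm_families.tsv"))
  }
  invisible(dir)
}

#' Read a differential-expression table (TSV)
#'
#' Expects columns `gene_id`, `condition`, `time`, `log2FC`, `adj_p`
#' (case-insensitive for log2FC), and errors naming any missing column.
#'
#' @param path TSV path.
#' @return data.frame with internal column names.
#' @export
read_de_table <- function(path) {
  de <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(time = "character"))
  names(de)[tolower(names(de)) == "log2fc"] <- "log2fc"
  miss <- setdiff(c("gene_id", "condition", "time", "log2fc", "adj_p"),
                  names(de))
  if (length(miss) > 0)
    stop(sprintf("incomplete-table: missing column(s) %s",
                 paste(miss, collapse = ", ")))
  de
}

#' Read per-region gene FASTA files back into a gene table
#'
#' @param dir directory containing upstream.fa, body.fa, downstream.fa
#'   with `<gene_id>|<region>` headers.
#' @return data.frame with gene_id and the three region sequences.
#' @export
read_region_fasta <- function(dir) {
  get <- function(region) {
    ss <- Biostrings::readDNAStringSet(file.path(dir, paste0(region, ".fa")))
    ids <- sub("\\|.*$", "", names(ss))
    stats::setNames(as.character(ss), ids)
  }
  up <- get("upstream"); body <- get("body"); down <- get("downstream")
  ids <- names(up)
  stopifnot(identical(ids, names(body)), identical(ids, names(down)))
  data.frame(gene_id = ids, upstream_seq = unname(up),
             body_seq = unname(body[ids]), downstream_seq = unname(down[ids]),
             stringsAsFactors = FALSE)
}
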