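DNA_BASES <- c("A", "C", "G", "T")

#' Position weight matrix constructor
#'
#' A PWM is a 4 x L numeric matrix of per-position base probabilities with
#' rows A, C, G, T. Columns must each sum to 1 (within 1e-9).
#'
#' @param m numeric matrix (4 rows) or an object coercible to one.
#' @param name motif name stored as an attribute.
#' @return a validated PWM matrix of class `tempcre_pwm`.
#' @export
pwm <- function(m, name = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != 4) stop("a PWM needs exactly 4 rows (A, C, G, T)")
  if (ncol(m) < 1) stop("a PWM needs at least one column")
  if (any(abs(colSums(m) - 1) > 1e-9)) stop("PWM columns must sum to 1")
  rownames(m) <- DNA_BASES
  if (!is.null(name)) attr(m, "name") <- name
  class(m) <- c("tempcre_pwm", class(m))
  m
}

#' One-hot PWM from a k-mer
#'
#' @param kmer A/C/G/T string.
#' @param name motif name (defaults to the k-mer itself).
#' @return PWM with probability 1 on the observed base at each position.
#' @export
kmer_to_pwm <- function(kmer, name = kmer) {
  bases <- strsplit(toupper(kmer), "")[[1]]
  if (!all(bases %in% DNA_BASES)) stop("non-ACGT: k-mer contains ambiguity codes")
  m <- vapply(bases, function(b) as.numeric(DNA_BASES == b), numeric(4))
  pwm(m, name = name)
}

#' Consensus sequence of a PWM (argmax per column, ties to the first base)
#' @param p PWM.
#' @return character string.
#' @export
pwm_consensus <- function(p) {
  paste(DNA_BASES[apply(unclass(p), 2, which.max)], collapse = "")
}

#' Reverse complement of a PWM
#' @param p PWM.
#' @return PWM with reversed column order and complemented rows.
#' @export
pwm_revcomp <- function(p) {
  nm <- attr(p, "name")
  m <- unclass(p)[c("T", "G", "C", "A"), rev(seq_len(ncol(p))), drop = FALSE]
  rownames(m) <- DNA_BASES
  pwm(m, name = nm)
}

#' Maximum Pearson correlation between two PWMs over ungapped alignments
#'
#' Slides `q` along `p` over every ungapped offset with at least
#' `min_overlap` overlapping columns (and, if `allow_rc`, also the reverse
#' complement of `q`), flattens the two aligned 4 x overlap blocks, and
#' returns the maximal Pearson correlation together with the alignment
#' that achieved it. A zero-variance flattened block (uniform PWM) yields
#' a correlation of 0 and is flagged.
#'
#' @param p,q PWMs (or k-mer strings, converted one-hot).
#' @param min_overlap minimum overlapping columns; lowered to the shorter
#'   motif length when that is smaller.
#' @param allow_rc also score against the reverse complement of `q`.
#' @return list with `pcc`, `offset` (of q's first column relative to
#'   p's first, in p coordinates), `orientation` ("forward"/"revcomp"),
#'   and `zero_variance`.
#' @export
pwm_pcc <- function(p, q, min_overlap = 5, allow_rc = TRUE) {
  if (is.character(p)) p <- kmer_to_pwm(p)
  if (is.character(q)) q <- kmer_to_pwm(q)
  lp <- ncol(p); lq <- ncol(q)
  ov_min <- min(min_overlap, lp, lq)
  orientations <- if (allow_rc) c("forward", "revcomp") else "forward"
  best <- list(pcc = -Inf, offset = 0L, orientation = "forward",
               zero_variance = FALSE)
  mp <- unclass(p)
  for (ori in orientations) {
    mq <- if (ori == "forward") unclass(q) else unclass(pwm_revcomp(q))
    for (s in seq(-(lq - ov_min), lp - ov_min)) {
      ip <- max(1, 1 + s):min(lp, s + lq)       # p columns in the overlap
      iq <- ip - s                              # matching q columns
      x <- as.numeric(mp[, ip]); y <- as.numeric(mq[, iq])
      zv <- stats::sd(x) == 0 || stats::sd(y) == 0
      r <- if (zv) 0 else stats::cor(x, y)
      if (r > best$pcc + 1e-12) {
        best <- list(pcc = r, offset = as.integer(s), orientation = ori,
                     zero_variance = zv)
      }
    }
  }
  best
}

#' TFBM record
#'
#' @param tf_name transcription factor name.
#' @param family TF family label (non-empty).
#' @param p PWM of the binding motif.
#' @param source data source tag.
#' @return list of class `tfbm_record`.
#' @export
tfbm_record <- function(tf_name, family, p, source = "simulated") {
  if (!nzchar(family)) stop("TFBM family label must be non-empty")
  structure(list(tf_name = tf_name, family = family, pwm = p,
                 source = source), class = "tfbm_record")
}

#' 95th-percentile PCC background for TFBM matching
#'
#' Empirical 95th percentile (linear interpolation) of pairwise PWM PCCs,
#' either among the motifs of one TF family (`within_family`) or among
#' motifs of different families (`between_family`). With fewer than one
#' pair in scope the threshold is 1.0, so nothing can pass the strict
#' `>` rule.
#'
#' @param library list of [tfbm_record()] objects.
#' @param family family name (required for `within_family`).
#' @param scope background scope.
#' @param min_overlap,allow_rc alignment options passed to [pwm_pcc()].
#' @param prob percentile (default 0.95).
#' @return numeric background threshold.
#' @export
family_background <- function(library, family = NULL,
                              scope = c("within_family", "between_family"),
                              min_overlap = 5, allow_rc = TRUE, prob = 0.95) {
  scope <- match.arg(scope)
  fams <- vapply(library, function(r) r$family, character(1))
  if (scope == "within_family") {
    if (is.null(family)) stop("family is required for within_family scope")
    idx <- which(fams == family)
    pairs <- if (length(idx) >= 2) utils::combn(idx, 2) else NULL
  } else {
    idx <- seq_along(library)
    pairs <- if (length(idx) >= 2) utils::combn(idx, 2) else NULL
    if (!is.null(pairs)) pairs <- pairs[, fams[pairs[1, ]] != fams[pairs[2, ]], drop = FALSE]
  }
  if (is.null(pairs) || ncol(pairs) == 0) {
    warning("insufficient-background: fewer than two motifs in scope; threshold set to 1.0")
    return(1.0)
  }
  pccs <- apply(pairs, 2, function(ij) {
    pwm_pcc(library[[ij[1]]]$pwm, library[[ij[2]]]$pwm,
            min_overlap = min_overlap, allow_rc = allow_rc)$pcc
  })
  unname(stats::quantile(pccs, prob, type = 7))
}

#' Match pCREs against a TFBM library
#'
#' Each pCRE (one-hot PWM) is scored against every library motif; the best
#' match is reported, and is significant when its PCC strictly exceeds the
#' 95th-percentile background of the matched motif's family (or the
#' between-family background under that scope). pCREs without a
#' significant match are labelled "unknown".
#'
#' @param pcres character vector of pCRE k-mers.
#' @param library list of [tfbm_record()] objects.
#' @param scope background scope, see [family_background()].
#' @param min_overlap,allow_rc alignment options.
#' @return data.frame: pcre, tf, family, pcc, offset, orientation,
#'   background_p95, significant, label.
#' @export
match_tfbm <- function(pcres, library,
                       scope = c("within_family", "between_family"),
                       min_overlap = 5, allow_rc = TRUE) {
  scope <- match.arg(scope)
  if (length(library) == 0) stop("TFBM library is empty")
  fams <- unique(vapply(library, function(r) r$family, character(1)))
  bg <- if (scope == "within_family") {
    stats::setNames(vapply(fams, function(f) {
      suppressWarnings(family_background(library, f, scope = "within_family",
                                         min_overlap = min_overlap,
                                         allow_rc = allow_rc))
    }, numeric(1)), fams)
  } else {
    rep(suppressWarnings(family_background(library, scope = "between_family",
                                           min_overlap = min_overlap,
                                           allow_rc = allow_rc)),
        length(fams)) |> stats::setNames(fams)
  }
  rows <- lapply(pcres, function(km) {
    hits <- lapply(library, function(r) {
      pwm_pcc(kmer_to_pwm(km), r$pwm, min_overlap = min_overlap,
              allow_rc = allow_rc)
    })
    pccs <- vapply(hits, `[[`, numeric(1), "pcc")
    i <- which.max(pccs)
    rec <- library[[i]]
    thr <- unname(bg[rec$family])
    sig <- pccs[i] > thr
    data.frame(pcre = km, tf = rec$tf_name, family = rec$family,
               pcc = pccs[i], offset = hits[[i]]$offset,
               orientation = hits[[i]]$orientation, background_p95 = thr,
               significant = sig,
               label = if (sig) rec$tf_name else "unknown",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a TFBM library in MEME minimal motif format
#'
#' @param library list of [tfbm_record()] objects (motif ids are tf names).
#' @param path output file.
#' @param bg background letter frequencies (A, C, G, T).
#' @export
write_meme <- function(library, path, bg = rep(0.25, 4)) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, bg), collapse = " "), ""),
             con)
  for (r in library) {
    w <- ncol(r$pwm)
    writeLines(sprintf("MOTIF %s", r$tf_name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", w), con)
    for (j in seq_len(w)) {
      writeLines(paste(sprintf("%.6f", unclass(r$pwm)[, j]), collapse = " "), con)
    }
    writeLines("", con)
  }
}

#' Read a MEME minimal motif file
#'
#' Parses MOTIF blocks with letter-probability matrices; columns are
#' renormalized to guard against printed rounding.
#'
#' @param path MEME minimal format file.
#' @return named list of PWMs.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\s", lines)
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    h <- s + which(grepl("^letter-probability matrix:", lines[(s + 1):length(lines)]))[1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[h]))
    rows <- lines[(h + 1):(h + w)]
    m <- t(vapply(rows, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]),
                  numeric(4)))
    m <- t(m)                      # 4 x w, rows A C G T
    m <- sweep(m, 2, colSums(m), "/")
    out[[name]] <- pwm(m, name = name)
  }
  out
}

#' Write / read a motif family map (TSV: motif_id, tf_name, family)
#' @param library list of [tfbm_record()]s.
#' @param path TSV path.
#' @export
write_family_map <- function(library, path) {
  df <- data.frame(motif_id = vapply(library, function(r) r$tf_name, character(1)),
                   tf_name = vapply(library, function(r) r$tf_name, character(1)),
                   family = vapply(library, function(r) r$family, character(1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_family_map
#' @export
read_family_map <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a TFBM library from MEME + family map files
#' @param meme_path MEME minimal motif file.
#' @param family_path family map TSV.
#' @param source source tag for the records.
#' @return list of [tfbm_record()] objects.
#' @export
read_tfbm_library <- function(meme_path, family_path, source = "simulated") {
  pwms <- read_meme(meme_path)
  fam <- read_family_map(family_path)
  lapply(names(pwms), function(nm) {
    f <- fam$family[match(nm, fam$motif_id)]
    if (is.na(f)) stop(sprintf("motif %s missing from the family map", nm))
    tfbm_record(fam$tf_name[match(nm, fam$motif_id)], f, pwms[[nm]],
                source = source)
  })
}
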