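# Shared fixtures and independent brute-force oracles. Everything here is
# deliberately naive (pairwise loops, position-by-position scans) so that it
# cannot share a bug with the vectorized implementation paths it checks.

CANON <- c("A", "C", "G", "T")

random_alignment <- function(n, L, p_gap = 0, p_ambig = 0, gene = "g") {
  draw <- function() {
    ch <- sample(CANON, L, replace = TRUE)
    if (p_gap > 0) ch[runif(L) < p_gap] <- "-"
    if (p_ambig > 0) {
      hit <- runif(L) < p_ambig
      ch[hit] <- sample(c("N", "R", "Y", "W"), sum(hit), replace = TRUE)
    }
    paste(ch, collapse = "")
  }
  gene_alignment(gene, sprintf("s%d", seq_len(n)),
                 vapply(seq_len(n), function(i) draw(), ""))
}

# Oracle: mean pairwise p-distance over complete-deletion columns.
oracle_mean_pdist <- function(aln) {
  mat <- aln$mat
  keep <- apply(mat, 2, function(col) all(col %in% CANON))
  if (!any(keep)) stop("no usable columns")
  mat <- mat[, keep, drop = FALSE]
  n <- nrow(mat)
  d <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- c(d, mean(mat[i, ] != mat[j, ]))
    }
  }
  mean(d)
}

# Oracle: per-column pi by explicit pair enumeration.
oracle_column_pi <- function(states) {
  n <- length(states)
  mm <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) mm <- mm + (states[i] != states[j])
  }
  mm / (n * (n - 1) / 2)
}

# Oracle: maximal runs (>= w) of gap-free monomorphic columns in an
# alignment, returned as a data.frame of 0-based [start, end) intervals.
oracle_conserved_runs <- function(aln, w = 20L) {
  mono <- apply(aln$mat, 2, function(col) {
    all(col %in% CANON) && length(unique(col)) == 1L
  })
  r <- rle(mono)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= w
  data.frame(start = starts[keep], end = ends[keep])
}

# Oracle: position-by-position Hamming scan of primer (given sense) against
# a template string; returns 0-based starts with <= max_mm mismatches and an
# exact match over the anchor 3'-terminal bases (terminal side given).
oracle_hamming_scan <- function(template, query, max_mm, anchor_3p,
                                three_prime = c("right", "left")) {
  three_prime <- match.arg(three_prime)
  tv <- strsplit(template, "")[[1]]
  qv <- strsplit(query, "")[[1]]
  lp <- length(qv)
  starts <- integer(0)
  if (lp > length(tv)) return(starts)
  for (s in 0:(length(tv) - lp)) {
    win <- tv[(s + 1):(s + lp)]
    mm <- sum(win != qv)
    if (mm > max_mm) next
    idx <- if (three_prime == "right") (lp - anchor_3p + 1):lp
           else 1:anchor_3p
    if (anchor_3p > 0 && any(win[idx] != qv[idx])) next
    starts <- c(starts, s)
  }
  starts
}

# Oracle: best antiparallel duplex score by explicit enumeration of every
# pairing constant K (match +1 doubled at either 3' terminus, mismatch -1).
oracle_duplex <- function(a, b, min_loop = NA) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- -Inf
  for (K in 2:(length(av) + length(bv))) {
    sc <- 0; any_pair <- FALSE
    for (i in seq_along(av)) {
      j <- K - i
      if (j < 1 || j > length(bv)) next
      if (!is.na(min_loop) && (j - i - 1) < min_loop) next
      any_pair <- TRUE
      if (comp[[av[i]]] == bv[j]) {
        sc <- sc + ifelse(i == length(av) || j == length(bv), 2, 1)
      } else sc <- sc - 1
    }
    if (any_pair && sc > best) best <- sc
  }
  if (is.infinite(best)) 0 else best
}

# tiny default-like config scaled down for fast tests
small_cfg <- function(seed = 1L, theta16 = 0.15, n_reads = 400L,
                      error_rate = 0.005, weights = NULL) {
  simulation_config(
    n_species = 5L,
    genes = list(list(name = "ATP6", length = 200L, theta = 0.34),
                 list(name = "16S", length = 600L, theta = theta16)),
    anchors = list(
      list(gene = "16S", position = 237L, length = 20L,
           primer_seq = "AGAAGACCCTATAAAGC", primer_offset = 3L, role = "F"),
      list(gene = "16S", position = 453L, length = 20L,
           primer_seq = "TTAAGTCAACATCGAGG", primer_offset = 0L, role = "R")),
    weights = weights, n_reads = n_reads, error_rate = error_rate,
    seed = seed)
}

# build a PrimerCandidate anchored at given alignment columns (test plumbing)
mb_cand <- function(ori, seq, gene, start, end) {
  minibarc:::.make_candidate(seq, ori, gene, as.integer(start), as.integer(end))
}
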