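# Primer design over conserved anchor windows.
#
# Candidate primers are substrings of perfectly conserved alignment stretches
# (identical and gap-free across all species), so by construction they anneal
# with zero mismatches to every panel member. Pairs are filtered on insert
# length (the mini-barcode between the primers' 3' ends), Tm difference, and
# duplex-formation scores, then ranked by the variable-site content of the
# insert.

#' Find maximal conserved stretches from a window table
#'
#' Merges runs of conserved sliding windows (all columns included and
#' monomorphic) into maximal conserved stretches of length >= w.
#'
#' @param wt a [sliding_windows()] table computed from `aln`.
#' @param aln the `GeneAlignment` the table was computed from.
#' @return list of `ConservedWindow` objects: fields `gene`, `start`, `end`
#'   (0-based half-open alignment columns), `consensus` (shared sequence).
#' @export
find_conserved_windows <- function(wt, aln) {
  stopifnot(inherits(wt, "WindowTable"), inherits(aln, "GeneAlignment"))
  w <- attr(wt, "w"); s <- attr(wt, "s")
  cw <- wt[wt$conserved, , drop = FALSE]
  if (nrow(cw) == 0L) return(list())
  if (s > w) {
    # non-overlapping windows cannot be merged safely
    groups <- seq_len(nrow(cw))
  } else {
    brk <- c(TRUE, diff(cw$start) != s)
    groups <- cumsum(brk)
  }
  out <- lapply(split(seq_len(nrow(cw)), groups), function(idx) {
    st <- cw$start[idx[1]]
    en <- cw$end[idx[length(idx)]]
    structure(list(gene = aln$gene, start = st, end = en,
                   consensus = substr(aln$rows[1], st + 1L, en)),
              class = "ConservedWindow")
  })
  unname(out)
}

#' GC content of a canonical DNA string
#'
#' @param seq gap-free DNA over A/C/G/T (ambiguity codes are an error:
#'   candidate primers are never degenerate).
#' @param digits rounding for the returned percentage (default 1, the
#'   conventional reporting precision).
#' @return percent G+C.
#' @export
gc_content <- function(seq, digits = 1L) {
  seq <- normalize_seq(seq, context = "gc_content input")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (!all(ch %in% c("A", "C", "G", "T"))) {
    stop("gc_content requires canonical A/C/G/T (no gaps or ambiguity codes)",
         call. = FALSE)
  }
  round(100 * sum(ch %in% c("G", "C")) / length(ch), digits)
}

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K); keys are 5'->3' dinucleotide stacks.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Primer melting temperature
#'
#' `"nn"` (default) is the SantaLucia 1998 unified nearest-neighbor model with
#' the entropic salt correction `dS + 0.368 (L-1) ln[Na+]` and
#' `Tm = 1000 dH / (dS + R ln(C/4)) - 273.15`; `"wallace"` is the rule
#' `2(A+T) + 4(G+C)`.
#'
#' @param seq canonical DNA string (length >= 8 for `"nn"`).
#' @param method `"nn"` or `"wallace"`.
#' @param na_mM monovalent cation concentration, mM (default 50).
#' @param oligo_nM oligo concentration, nM (default 250).
#' @return temperature in degrees C.
#' @export
melting_temp <- function(seq, method = c("nn", "wallace"),
                         na_mM = 50, oligo_nM = 250) {
  method <- match.arg(method)
  seq <- normalize_seq(seq, context = "melting_temp input")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (!all(ch %in% c("A", "C", "G", "T"))) {
    stop("melting_temp requires canonical A/C/G/T", call. = FALSE)
  }
  if (method == "wallace") {
    return(2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C")))
  }
  L <- length(ch)
  if (L < 8L) stop("nearest-neighbor Tm needs length >= 8", call. = FALSE)
  stacks <- paste0(ch[-L], ch[-1L])
  dH <- sum(.NN_DH[stacks])
  dS <- sum(.NN_DS[stacks])
  # initiation terms per terminal base
  for (term in ch[c(1L, L)]) {
    if (term %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  if (identical(seq, revcomp(seq))) dS <- dS - 1.4  # self-complementary
  dS <- dS + 0.368 * (L - 1) * log(na_mM / 1000)
  ct <- oligo_nM * 1e-9
  x <- if (identical(seq, revcomp(seq))) 1 else 4
  1000 * dH / (dS + 1.987 * log(ct / x)) - 273.15
}

# Antiparallel duplex complementarity score between a and b over all ungapped
# offsets: positions i of a and j of b pair when i + j is constant; each
# Watson-Crick pair scores +1 (doubled when it involves either oligo's
# 3'-terminal base), each non-pairing juxtaposition -1. `min_loop` restricts
# to intramolecular folds (pairs with j - i - 1 >= min_loop), used for
# hairpins. Higher = worse.
.duplex_score <- function(a, b, min_loop = NA) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  la <- length(av); lb <- length(bv)
  best <- -Inf
  for (K in 2L:(la + lb)) {
    i <- seq_len(la)
    j <- K - i
    ok <- j >= 1L & j <= lb
    if (!is.na(min_loop)) ok <- ok & (j - i - 1L) >= min_loop
    if (!any(ok)) next
    i <- i[ok]; j <- j[ok]
    pair <- comp[av[i]] == bv[j]
    wgt <- ifelse((i == la | j == lb) & pair, 2, 1)
    sc <- sum(ifelse(pair, wgt, -1))
    if (sc > best) best <- sc
  }
  if (is.infinite(best)) 0 else best
}

#' Primer duplex-formation scores
#'
#' Brute-force maximum complementarity over all ungapped antiparallel offsets
#' (match +1, mismatch -1, matches at either 3'-terminal base doubled); higher
#' scores indicate stronger unwanted structure. `hairpin_score` restricts to
#' intramolecular folds with a minimum loop of 3 nt.
#'
#' @param seq,a,b canonical DNA strings.
#' @param min_loop minimum hairpin loop length (nt).
#' @return numeric score.
#' @export
hairpin_score <- function(seq, min_loop = 3L) {
  seq <- normalize_seq(seq, context = "hairpin input")
  .duplex_score(seq, seq, min_loop = min_loop)
}

#' @rdname hairpin_score
#' @export
self_dimer_score <- function(seq) {
  seq <- normalize_seq(seq, context = "self-dimer input")
  .duplex_score(seq, seq)
}

#' @rdname hairpin_score
#' @export
cross_dimer_score <- function(a, b) {
  a <- normalize_seq(a, context = "cross-dimer input a")
  b <- normalize_seq(b, context = "cross-dimer input b")
  .duplex_score(a, b)
}

#' Default primer filtering thresholds
#'
#' Conventional screening defaults: GC between 30 and 60 percent, homopolymer
#' runs of at most 5, and duplex scores calibrated so that published
#' conventional 16-20-mer barcode primers pass while a perfectly
#' self-complementary oligo is rejected.
#'
#' @return named list of thresholds.
#' @export
primer_filters <- function() {
  list(gc_min = 30, gc_max = 60, max_homopolymer = 5L,
       max_hairpin = 4, max_self_dimer = 8, max_cross_dimer = 8,
       max_tm_diff = 5)
}

.max_homopolymer <- function(seq) {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  max(r$lengths)
}

.make_candidate <- function(seq, orientation, gene, start, end,
                            tm_method = "nn") {
  structure(list(seq = seq, orientation = orientation,
                 gene = gene, start = start, end = end,
                 length = nchar(seq),
                 gc_pct = gc_content(seq),
                 tm_c = melting_temp(seq, method = tm_method),
                 hairpin_score = hairpin_score(seq),
                 self_dimer_score = self_dimer_score(seq)),
            class = "PrimerCandidate")
}

#' @export
print.PrimerCandidate <- function(x, ...) {
  cat(sprintf("PrimerCandidate %s %s [%d,%d) %dnt GC=%.1f Tm=%.1f\n",
              x$orientation, x$seq, x$start, x$end, x$length, x$gc_pct, x$tm_c))
  invisible(x)
}

#' Enumerate primer candidates from conserved stretches
#'
#' Every substring of every stretch with length in `len_range` is emitted in
#' both orientations: forward (sense consensus) and reverse (reverse
#' complement of the sense consensus, for use as a reverse primer whose
#' anchor occupies the same alignment columns). Candidates failing the GC,
#' homopolymer, hairpin, or self-dimer filters are dropped.
#'
#' @param windows list of `ConservedWindow` from [find_conserved_windows()].
#' @param len_range integer c(min, max) primer length (default c(16, 22)).
#' @param filters thresholds from [primer_filters()]; pass `NULL` to disable
#'   filtering (raw enumeration).
#' @param tm_method passed to [melting_temp()].
#' @return list of `PrimerCandidate`.
#' @export
enumerate_primers <- function(windows, len_range = c(16L, 22L),
                              filters = primer_filters(), tm_method = "nn") {
  if (length(windows) == 0L) return(list())
  out <- list()
  for (cw in windows) {
    Lw <- nchar(cw$consensus)
    for (len in seq.int(len_range[1], len_range[2])) {
      if (len > Lw) next
      for (off in 0:(Lw - len)) {
        sub <- substr(cw$consensus, off + 1L, off + len)
        st <- cw$start + off
        for (ori in c("F", "R")) {
          seqp <- if (ori == "F") sub else revcomp(sub)
          cand <- .make_candidate(seqp, ori, cw$gene, st, st + len, tm_method)
          if (!is.null(filters)) {
            if (cand$gc_pct < filters$gc_min || cand$gc_pct > filters$gc_max) next
            if (.max_homopolymer(seqp) > filters$max_homopolymer) next
            if (cand$hairpin_score > filters$max_hairpin) next
            if (cand$self_dimer_score > filters$max_self_dimer) next
          }
          out[[length(out) + 1L]] <- cand
        }
      }
    }
  }
  out
}

# cumulative ungapped position of each alignment column boundary for one row:
# .ungap_pos(row)[c + 1] = number of non-gap characters in columns [0, c)
.ungap_pos <- function(row) {
  ch <- strsplit(row, "", fixed = TRUE)[[1]]
  c(0L, cumsum(ch != "-"))
}

#' Count variable sites in an alignment slice
#'
#' A column is variable when its rows carry at least two distinct states.
#' With `gap_as_state = TRUE` (default) the gap is a fifth state, so indel
#' columns count as variable; with `FALSE` gaps are ignored and a column is
#' variable only if the remaining bases disagree.
#'
#' @param aln a `GeneAlignment`.
#' @param start,end 0-based half-open column range.
#' @param gap_as_state logical.
#' @return integer count.
#' @export
count_variable_sites <- function(aln, start, end, gap_as_state = TRUE) {
  stopifnot(inherits(aln, "GeneAlignment"))
  if (start < 0L || end > aln$L_aln || start >= end) {
    stop("invalid column range [", start, ",", end, ")", call. = FALSE)
  }
  sub <- aln$mat[, (start + 1L):end, drop = FALSE]
  sum(vapply(seq_len(ncol(sub)), function(c) {
    states <- sub[, c]
    if (!gap_as_state) states <- states[states != "-"]
    length(unique(states)) >= 2L
  }, logical(1)))
}

#' Pairwise species resolution of an alignment slice
#'
#' @param aln a `GeneAlignment`.
#' @param start,end 0-based half-open column range.
#' @return `ResolutionReport`: `pairwise_diffs` (symmetric integer matrix of
#'   differing columns per species pair, gap treated as a state), `min_diff`,
#'   and `resolved` (`min_diff >= 1`).
#' @export
assess_resolution <- function(aln, start, end) {
  stopifnot(inherits(aln, "GeneAlignment"))
  sub <- aln$mat[, (start + 1L):end, drop = FALSE]
  n <- aln$n
  d <- matrix(0L, n, n, dimnames = list(aln$species_ids, aln$species_ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dij <- sum(sub[i, ] != sub[j, ])
      d[i, j] <- d[j, i] <- dij
    }
  }
  min_diff <- min(d[upper.tri(d)])
  structure(list(pairwise_diffs = d, min_diff = min_diff,
                 resolved = min_diff >= 1L),
            class = "ResolutionReport")
}

#' Pair forward and reverse primer candidates
#'
#' Combines every forward candidate with every reverse candidate anchored
#' strictly downstream on the same gene. The insert (mini-barcode) length is
#' measured between the primers' 3' ends in the ungapped coordinates of a
#' designated reference species, since a single length is conventionally
#' reported per pair even when species differ by indels; per-species lengths
#' are also recorded. Pairs outside `insert_range`, with |dTm| above the
#' filter, or with excessive cross-dimer scores are dropped.
#'
#' @param cands list of `PrimerCandidate` (mixed orientations).
#' @param aln the `GeneAlignment` the candidates were anchored on.
#' @param insert_range integer c(min, max) insert length (default c(100, 250)).
#' @param ref_species reference species id (default: first alignment row).
#' @param filters thresholds from [primer_filters()]; `NULL` disables the
#'   dTm/cross-dimer filters.
#' @param gap_as_state passed to [count_variable_sites()].
#' @return list of `PrimerPair`.
#' @export
pair_primers <- function(cands, aln, insert_range = c(100L, 250L),
                         ref_species = NULL, filters = primer_filters(),
                         gap_as_state = TRUE) {
  stopifnot(inherits(aln, "GeneAlignment"))
  if (is.null(ref_species)) ref_species <- aln$species_ids[1]
  if (!ref_species %in% aln$species_ids) {
    stop("reference species '", ref_species, "' absent from alignment",
         call. = FALSE)
  }
  ug <- lapply(aln$rows, .ungap_pos)
  names(ug) <- aln$species_ids
  ref_ug <- ug[[ref_species]]
  fwd <- Filter(function(x) x$orientation == "F", cands)
  rev <- Filter(function(x) x$orientation == "R", cands)
  out <- list()
  for (f in fwd) {
    for (r in rev) {
      if (!identical(f$gene, r$gene)) next
      if (f$end > r$start) next
      ins <- ref_ug[r$start + 1L] - ref_ug[f$end + 1L]
      if (ins < insert_range[1] || ins > insert_range[2]) next
      tmd <- abs(f$tm_c - r$tm_c)
      xd <- cross_dimer_score(f$seq, r$seq)
      if (!is.null(filters)) {
        if (tmd > filters$max_tm_diff) next
        if (xd > filters$max_cross_dimer) next
      }
      per_species <- vapply(aln$species_ids, function(sp) {
        ug[[sp]][r$start + 1L] - ug[[sp]][f$end + 1L]
      }, 0L)
      vs <- count_variable_sites(aln, f$end, r$start, gap_as_state)
      res <- assess_resolution(aln, f$end, r$start)
      out[[length(out) + 1L]] <- structure(
        list(fwd = f, rev = r, insert_len = ins,
             insert_len_by_species = per_species,
             variable_sites = vs, cross_dimer_score = xd,
             tm_diff = tmd, resolution = res,
             rank_score = vs),
        class = "PrimerPair")
    }
  }
  out
}

#' @export
print.PrimerPair <- function(x, ...) {
  cat(sprintf(
    "PrimerPair %s / %s insert=%dbp varsites=%d dTm=%.1f resolved=%s\n",
    x$fwd$seq, x$rev$seq, x$insert_len, x$variable_sites, x$tm_diff,
    x$resolution$resolved))
  invisible(x)
}

#' Rank primer pairs
#'
#' Descending by insert variable-site count; ties broken by smaller |dTm|,
#' then insert length closest to 175 bp (the mini-barcode midpoint of the
#' 100-250 range), then lexicographically by forward then reverse sequence.
#' The order is total, so ranking is invariant to input order.
#'
#' @param pairs list of `PrimerPair`.
#' @return the same pairs, sorted.
#' @export
rank_pairs <- function(pairs) {
  if (length(pairs) == 0L) stop("no pairs to rank", call. = FALSE)
  vs <- vapply(pairs, `[[`, 0, "variable_sites")
  tmd <- vapply(pairs, `[[`, 0, "tm_diff")
  mid <- abs(vapply(pairs, function(p) as.numeric(p$insert_len), 0) - 175)
  fs <- vapply(pairs, function(p) p$fwd$seq, "")
  rs <- vapply(pairs, function(p) p$rev$seq, "")
  pairs[order(-vs, tmd, mid, fs, rs)]
}

#' Tabulate primer pairs in report form
#'
#' @param pairs list of `PrimerPair`.
#' @return data.frame with one row per primer of each pair (Table-style:
#'   name, sequence 5'-3', insert bp, variable sites, GC%, Tm, scores,
#'   1-based anchor coordinates).
#' @export
pairs_table <- function(pairs) {
  rows <- lapply(seq_along(pairs), function(k) {
    p <- pairs[[k]]
    data.frame(
      pair = k,
      role = c("F", "R"),
      sequence = c(p$fwd$seq, p$rev$seq),
      anchor_start_1based = c(p$fwd$start + 1L, p$rev$start + 1L),
      anchor_end_1based = c(p$fwd$end, p$rev$end),
      insert_bp = p$insert_len,
      variable_sites = p$variable_sites,
      gc_pct = c(p$fwd$gc_pct, p$rev$gc_pct),
      tm_c = round(c(p$fwd$tm_c, p$rev$tm_c), 1),
      tm_diff = round(p$tm_diff, 2),
      cross_dimer = p$cross_dimer_score,
      min_pair_diff = p$resolution$min_diff,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
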