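# Amplicon metabarcoding classification: primer trimming, dereplication,
# lite denoising, best-hit assignment against a reference amplicon panel,
# and abundance filtering into a species composition table.

# Hamming distance between two equal-length strings (byte comparison).
.hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming distance needs equal lengths")
  sum(charToRaw(a) != charToRaw(b))
}

#' Trim primer sequences off amplicon reads
#'
#' A read is kept when, in either orientation, its prefix matches the forward
#' primer and its suffix matches the reverse complement of the reverse primer,
#' each within `max_mm` Hamming mismatches. Kept reads are normalized to the
#' forward sense and both primer copies removed, leaving the insert. Reads
#' lacking the sites are dropped and counted.
#'
#' @param reads a [read_set()].
#' @param pair a `PrimerPair` or list with `$fwd`/`$rev` DNA strings.
#' @param max_mm per-primer mismatch tolerance (default 2).
#' @return a `ReadSet` of inserts, with attribute `dropped` (count of
#'   discarded reads).
#' @export
trim_primers <- function(reads, pair, max_mm = 2L) {
  stopifnot(inherits(reads, "ReadSet"))
  fseq <- .primer_seq(pair$fwd)
  rseq <- .primer_seq(pair$rev)
  lf <- nchar(fseq); lr <- nchar(rseq)
  rrc <- revcomp(rseq)
  fits <- function(s) {
    n <- nchar(s)
    if (n < lf + lr) return(FALSE)
    .hamming(substr(s, 1L, lf), fseq) <= max_mm &&
      .hamming(substr(s, n - lr + 1L, n), rrc) <= max_mm
  }
  keep_ids <- character(0); keep_seqs <- character(0)
  dropped <- 0L
  for (i in seq_len(reads$n)) {
    s <- reads$seqs[i]
    if (fits(s)) {
      keep_ids <- c(keep_ids, reads$ids[i])
      keep_seqs <- c(keep_seqs, substr(s, lf + 1L, nchar(s) - lr))
    } else {
      rc <- revcomp(s)
      if (fits(rc)) {
        keep_ids <- c(keep_ids, reads$ids[i])
        keep_seqs <- c(keep_seqs, substr(rc, lf + 1L, nchar(rc) - lr))
      } else {
        dropped <- dropped + 1L
      }
    }
  }
  out <- read_set(keep_ids, keep_seqs, source = reads$source)
  attr(out, "dropped") <- dropped
  out
}

#' Dereplicate reads into unique sequences with counts
#'
#' @param reads a `ReadSet` (typically primer-trimmed).
#' @return `DereplicatedSet`: `seqs` and `counts` sorted by descending count
#'   (ties by sequence), `total_reads`.
#' @export
dereplicate <- function(reads) {
  stopifnot(inherits(reads, "ReadSet"))
  if (reads$n == 0L) {
    return(structure(list(seqs = character(0), counts = integer(0),
                          total_reads = 0L),
                     class = "DereplicatedSet"))
  }
  tab <- table(reads$seqs)
  seqs <- names(tab)
  counts <- as.integer(tab)
  ord <- order(-counts, seqs)
  structure(list(seqs = seqs[ord], counts = counts[ord],
                 total_reads = reads$n),
            class = "DereplicatedSet")
}

#' @export
print.DereplicatedSet <- function(x, ...) {
  cat(sprintf("DereplicatedSet: %d unique / %d reads\n",
              length(x$seqs), x$total_reads))
  invisible(x)
}

#' Greedy error absorption ("denoise-lite")
#'
#' A deliberately simple UNOISE-style stand-in for a full amplicon error
#' model: uniques are processed in descending-count order, and a sequence
#' within Hamming distance `max_diff` of an already retained sequence whose
#' (original) count is at least `ratio` times larger is absorbed into it
#' (counts added; the most abundant qualifying parent wins, ties by sequence
#' order). Distances are only defined between equal-length sequences.
#'
#' @param ds a [dereplicate()] result.
#' @param max_diff maximum Hamming distance to a parent (default 1).
#' @param ratio minimum parent/child count ratio (default 4).
#' @return a `DereplicatedSet` of retained sequences.
#' @export
denoise_lite <- function(ds, max_diff = 1L, ratio = 4.0) {
  stopifnot(inherits(ds, "DereplicatedSet"))
  m <- length(ds$seqs)
  if (m == 0L) return(ds)
  orig_counts <- ds$counts
  out_counts <- ds$counts
  parent <- rep(NA_integer_, m)
  lens <- nchar(ds$seqs)
  retained <- integer(0)
  for (i in seq_len(m)) {
    cand_par <- retained[orig_counts[retained] >= ratio * orig_counts[i] &
                         lens[retained] == lens[i]]
    hit <- NA_integer_
    for (p in cand_par) {  # retained kept in descending-count order
      if (.hamming(ds$seqs[i], ds$seqs[p]) <= max_diff) { hit <- p; break }
    }
    if (is.na(hit)) {
      retained <- c(retained, i)
    } else {
      parent[i] <- hit
      out_counts[hit] <- out_counts[hit] + out_counts[i]
    }
  }
  seqs <- ds$seqs[retained]
  counts <- out_counts[retained]
  ord <- order(-counts, seqs)
  structure(list(seqs = seqs[ord], counts = as.integer(counts[ord]),
                 total_reads = ds$total_reads),
            class = "DereplicatedSet")
}

#' Assign unique sequences to species by best-hit identity
#'
#' Identity is `100 * matches / alignment_length` under end-gap-free
#' ("overlap") global alignment with match +1, mismatch -1, gap -2. The best
#' reference wins; exact score ties are recorded and resolved to the
#' lexicographically first species. Queries below `min_ident` are
#' `"unassigned"`.
#'
#' @param ds a `DereplicatedSet`.
#' @param panel named list (species -> `Amplicon`) or named character vector
#'   of reference insert sequences.
#' @param min_ident minimum percent identity (default 90).
#' @return list of `AssignmentResult`: `seq`, `count`, `best_ref`,
#'   `identity_pct`, `ties`.
#' @export
assign_species <- function(ds, panel, min_ident = 90.0) {
  stopifnot(inherits(ds, "DereplicatedSet"))
  if (length(panel) == 0L) stop("empty reference panel", call. = FALSE)
  refs <- if (is.character(panel)) panel
          else vapply(panel, `[[`, "", "insert_seq")
  if (is.null(names(refs)) || any(!nzchar(names(refs)))) {
    stop("panel must be named by species", call. = FALSE)
  }
  refs <- refs[order(names(refs))]  # lexicographic tie preference
  m <- length(ds$seqs)
  if (m == 0L) return(list())
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = TRUE)
  ident <- matrix(NA_real_, nrow = m, ncol = length(refs),
                  dimnames = list(NULL, names(refs)))
  qset <- Biostrings::DNAStringSet(ds$seqs)
  for (j in seq_along(refs)) {
    exact <- ds$seqs == refs[[j]]
    ident[exact, j] <- 100
    todo <- which(!exact)
    if (length(todo)) {
      pa <- Biostrings::pairwiseAlignment(
        pattern = qset[todo], subject = Biostrings::DNAString(refs[[j]]),
        type = "overlap", substitutionMatrix = submat,
        gapOpening = 0, gapExtension = 2)
      alen <- nchar(as.character(Biostrings::pattern(pa)))
      idj <- ifelse(alen > 0, 100 * Biostrings::nmatch(pa) / alen, 0)
      ident[todo, j] <- idj
    }
  }
  lapply(seq_len(m), function(i) {
    row <- ident[i, ]
    best <- max(row)
    tied <- names(refs)[row == best]
    best_ref <- if (best < min_ident) "unassigned" else tied[1]
    structure(list(seq = ds$seqs[i], count = ds$counts[i],
                   best_ref = best_ref, identity_pct = best,
                   ties = if (length(tied) > 1L && best >= min_ident) tied
                          else character(0)),
              class = "AssignmentResult")
  })
}

#' Species composition table from assignments
#'
#' Read counts are summed per assigned species; proportions are over total
#' assigned reads (unassigned uniques are excluded from the denominator).
#' Species below `min_prop` are removed without renormalizing, so retained
#' proportions may sum to less than 1.
#'
#' @param assignments result of [assign_species()].
#' @param min_prop abundance filter (default 0.01, i.e. "< 1 percent of reads
#'   excluded").
#' @return data.frame of class `CompositionTable` (species, reads,
#'   proportion), descending by proportion; attributes `total_assigned`,
#'   `min_prop`.
#' @export
composition <- function(assignments, min_prop = 0.01) {
  sp <- vapply(assignments, `[[`, "", "best_ref")
  ct <- vapply(assignments, `[[`, 0L, "count")
  keep <- sp != "unassigned"
  total <- sum(ct[keep])
  if (total == 0L) {
    out <- data.frame(species = character(0), reads = integer(0),
                      proportion = numeric(0))
  } else {
    agg <- tapply(ct[keep], sp[keep], sum)
    out <- data.frame(species = names(agg), reads = as.integer(agg),
                      proportion = as.numeric(agg) / total,
                      stringsAsFactors = FALSE)
    out <- out[out$proportion >= min_prop, , drop = FALSE]
    out <- out[order(-out$proportion, out$species), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "total_assigned") <- total
  attr(out, "min_prop") <- min_prop
  class(out) <- c("CompositionTable", class(out))
  out
}

#' One-call classification pipeline
#'
#' trim -> dereplicate -> denoise-lite -> assign -> composition.
#'
#' @param reads a `ReadSet` of raw amplicon reads.
#' @param pair primer pair used for trimming.
#' @param panel reference panel (see [assign_species()]).
#' @param max_mm trimming mismatch tolerance.
#' @param max_diff,ratio denoising parameters.
#' @param min_ident,min_prop assignment/abundance thresholds.
#' @return `CompositionTable` with attributes `dropped` and
#'   `assignments` (the per-unique table).
#' @export
classify_reads <- function(reads, pair, panel, max_mm = 2L,
                           max_diff = 1L, ratio = 4.0,
                           min_ident = 90.0, min_prop = 0.01) {
  trimmed <- trim_primers(reads, pair, max_mm)
  ds <- denoise_lite(dereplicate(trimmed), max_diff, ratio)
  asn <- assign_species(ds, panel, min_ident)
  out <- composition(asn, min_prop)
  attr(out, "dropped") <- attr(trimmed, "dropped")
  attr(out, "assignments") <- asn
  out
}
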