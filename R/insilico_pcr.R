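# Mismatch-tolerant in-silico PCR.
#
# The annealing model is ungapped Hamming matching with an exact-match
# requirement on the primer's 3'-terminal bases (extension cannot start from
# a 3' mismatch). IUPAC ambiguity codes on the template match a primer base
# iff the base belongs to the code's set.

# (the 16x4 template-vs-primer-base lookup .iupac_match_table lives in
# aaa-constants.R so it exists whatever the collation order)

# Hamming mismatch counts of `primer` against every start position of
# `tmpl_ch` (character vector); returns integer vector over starts.
.scan_mismatches <- function(tmpl_ch, primer) {
  lp <- nchar(primer)
  Lt <- length(tmpl_ch)
  if (lp > Lt) return(integer(0))
  pv <- strsplit(primer, "", fixed = TRUE)[[1]]
  n_starts <- Lt - lp + 1L
  mm <- integer(n_starts)
  for (k in seq_len(lp)) {
    tc <- tmpl_ch[k:(k + n_starts - 1L)]
    mm <- mm + !.iupac_match_table[cbind(tc, pv[k])]
  }
  mm
}

#' Find primer annealing sites on a template
#'
#' Scans both senses: the primer sequence itself on the plus strand
#' (`strand = "+"`, extension rightward) and its reverse complement on the
#' plus strand (`strand = "-"`, the primer anneals to the plus strand and
#' extends leftward). Matches need Hamming mismatches <= `max_mm` and an
#' exact match over the `anchor_3p` 3'-terminal primer bases.
#'
#' @param template a `SequenceRecord` (gap-free).
#' @param primer a `PrimerCandidate` or plain DNA string.
#' @param max_mm maximum mismatches (default 3).
#' @param anchor_3p number of 3'-terminal bases that must match exactly
#'   (default 1).
#' @return list of `PrimerMatch`: `template_id`, `strand`, `start`, `end`
#'   (0-based half-open on the plus strand), `mismatches`, `three_prime_ok`;
#'   sorted by position.
#' @export
find_matches <- function(template, primer, max_mm = 3L, anchor_3p = 1L) {
  stopifnot(inherits(template, "SequenceRecord"))
  pseq <- if (inherits(primer, "PrimerCandidate")) primer$seq else
    normalize_seq(primer, context = "primer")
  if (grepl("-", template$seq, fixed = TRUE)) {
    stop("template '", template$id, "' contains gaps", call. = FALSE)
  }
  if (!all(strsplit(pseq, "")[[1]] %in% c("A", "C", "G", "T"))) {
    stop("primer must be canonical A/C/G/T", call. = FALSE)
  }
  tmpl_ch <- strsplit(template$seq, "", fixed = TRUE)[[1]]
  lp <- nchar(pseq)
  out <- list()
  for (strand in c("+", "-")) {
    query <- if (strand == "+") pseq else revcomp(pseq)
    mm <- .scan_mismatches(tmpl_ch, query)
    if (length(mm) == 0L) next
    hits <- which(mm <= max_mm)
    for (h in hits) {
      # 3' terminal bases of the primer: rightmost on "+", leftmost on "-"
      if (anchor_3p > 0L) {
        idx <- if (strand == "+") (h + lp - anchor_3p):(h + lp - 1L)
               else h:(h + anchor_3p - 1L)
        qv <- strsplit(query, "", fixed = TRUE)[[1]]
        ok <- all(.iupac_match_table[cbind(tmpl_ch[idx],
                                           qv[idx - h + 1L])])
        if (!ok) next
      }
      out[[length(out) + 1L]] <- structure(
        list(template_id = template$id, strand = strand,
             start = h - 1L, end = h - 1L + lp,
             mismatches = as.integer(mm[h]), three_prime_ok = TRUE),
        class = "PrimerMatch")
    }
  }
  ord <- order(vapply(out, `[[`, 0L, "start"),
               vapply(out, `[[`, "", "strand"))
  out[ord]
}

.primer_seq <- function(p) if (inherits(p, "PrimerCandidate")) p$seq else p

#' Amplify a template with a primer pair
#'
#' Enumerates all products from a forward-sense match upstream of a
#' reverse-sense match (on either template strand) with total product length
#' <= `max_product`. The insert is excised between the primers' 3' ends and
#' normalized to the forward primer's sense, so it is invariant to
#' reverse-complementing the template.
#'
#' @param template a `SequenceRecord`.
#' @param pair a `PrimerPair`, or list with `$fwd`/`$rev` DNA strings.
#' @param max_mm,anchor_3p passed to [find_matches()].
#' @param max_product maximum full product length (default 2000).
#' @return list of `Amplicon`: `template_id`, `fwd_match`, `rev_match`,
#'   `insert_seq`, `insert_len`, `full_len`, `full_seq`, `strand`.
#' @export
amplify <- function(template, pair, max_mm = 3L, anchor_3p = 1L,
                    max_product = 2000L) {
  fseq <- .primer_seq(pair$fwd)
  rseq <- .primer_seq(pair$rev)
  fm <- find_matches(template, fseq, max_mm, anchor_3p)
  rm_ <- find_matches(template, rseq, max_mm, anchor_3p)
  out <- list()
  add <- function(left, right, sense) {
    # left anneals forward-sense at [left$start,left$end); right reverse-sense
    if (left$end > right$start) return()
    full_len <- right$end - left$start
    if (full_len > max_product) return()
    ins <- substr(template$seq, left$end + 1L, right$start)
    full <- substr(template$seq, left$start + 1L, right$end)
    if (sense == "-") { ins <- revcomp(ins); full <- revcomp(full) }
    out[[length(out) + 1L]] <<- structure(
      list(template_id = template$id, fwd_match = left, rev_match = right,
           insert_seq = ins, insert_len = nchar(ins),
           full_len = full_len, full_seq = full, strand = sense),
      class = "Amplicon")
  }
  # product on plus sense: fwd "+" upstream of rev "-"
  for (f in Filter(function(m) m$strand == "+", fm)) {
    for (r in Filter(function(m) m$strand == "-", rm_)) add(f, r, "+")
  }
  # product on minus sense: rev "+" upstream of fwd "-"
  for (r in Filter(function(m) m$strand == "+", rm_)) {
    for (f in Filter(function(m) m$strand == "-", fm)) add(r, f, "-")
  }
  ord <- order(vapply(out, function(a) a$fwd_match$start, 0L),
               vapply(out, `[[`, 0L, "full_len"))
  out[ord]
}

#' @export
print.Amplicon <- function(x, ...) {
  cat(sprintf("Amplicon on '%s' (%s): insert %d bp, full %d bp\n",
              x$template_id, x$strand, x$insert_len, x$full_len))
  invisible(x)
}

#' Amplify a panel of reference templates
#'
#' Each template must yield exactly one product; references for barcode
#' assignment must be unambiguous.
#'
#' @param templates list of `SequenceRecord`.
#' @param pair primer pair (see [amplify()]).
#' @param ... passed to [amplify()].
#' @return named list (template id -> `Amplicon`).
#' @export
panel_amplicons <- function(templates, pair, ...) {
  res <- lapply(templates, amplify, pair = pair, ...)
  n_prod <- vapply(res, length, 0L)
  ids <- vapply(templates, `[[`, "", "id")
  if (any(n_prod != 1L)) {
    bad <- ids[n_prod != 1L]
    cnt <- n_prod[n_prod != 1L]
    stop("panel templates must yield exactly one amplicon; offending: ",
         paste(sprintf("%s (%d products)", bad, cnt), collapse = ", "),
         call. = FALSE)
  }
  setNames(lapply(res, `[[`, 1L), ids)
}
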