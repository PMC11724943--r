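# Nucleotide diversity (pi) over gene alignments.
#
# pi at a column is the fraction of unordered sequence pairs that differ
# there; the gene-wide Pi averages pi over included columns and equals the
# mean pairwise p-distance. Columns carrying a gap or ambiguity code in ANY
# row are excluded ("complete deletion", DnaSP's default) unless the
# pairwise-deletion mode is requested.

.CANONICAL <- c("A", "C", "G", "T")

# logical matrix: which cells are canonical bases
.canon_mask <- function(aln) {
  matrix(aln$mat %in% .CANONICAL, nrow = aln$n)
}

# per-column pi over the rows given by `use` (logical or index vector);
# returns NA where fewer than 2 usable rows.
.pi_columns <- function(mat, canon) {
  n <- nrow(mat)
  L <- ncol(mat)
  pi <- rep(NA_real_, L)
  for (c in seq_len(L)) {
    ok <- canon[, c]
    m <- sum(ok)
    if (m < 2L) next
    counts <- table(mat[ok, c])
    same <- sum(counts * (counts - 1)) / 2
    pairs <- m * (m - 1) / 2
    pi[c] <- 1 - same / pairs
  }
  pi
}

#' Per-column nucleotide diversity
#'
#' @param aln a [gene_alignment()].
#' @param c 0-based column index.
#' @return list with `included` (FALSE when any row carries a gap or ambiguity
#'   at the column — complete deletion) and `pi_c` (mismatching pair fraction;
#'   `NA` when excluded).
#' @export
column_pi <- function(aln, c) {
  stopifnot(inherits(aln, "GeneAlignment"))
  if (c < 0L || c >= aln$L_aln) stop("column index out of range", call. = FALSE)
  col <- aln$mat[, c + 1L]
  if (!all(col %in% .CANONICAL)) {
    return(list(included = FALSE, pi_c = NA_real_))
  }
  counts <- table(col)
  n <- aln$n
  same <- sum(counts * (counts - 1)) / 2
  list(included = TRUE, pi_c = 1 - same / (n * (n - 1) / 2))
}

#' Gene-wide nucleotide diversity profile
#'
#' Computes per-column pi and their mean over included columns (`Pi`), which
#' equals the average pairwise p-distance over those columns.
#'
#' @param aln a [gene_alignment()] with n >= 2.
#' @param deletion `"complete"` (default; any gap/ambiguity excludes the
#'   column) or `"pairwise"` (each column uses the rows that are canonical
#'   there; columns with < 2 usable rows are excluded).
#' @return object of class `DiversityProfile`: fields `gene`, `n`, `L_aln`,
#'   `included_mask`, `pi_per_column`, `Pi`, `L_incl`.
#' @export
gene_pi <- function(aln, deletion = c("complete", "pairwise")) {
  stopifnot(inherits(aln, "GeneAlignment"))
  deletion <- match.arg(deletion)
  canon <- .canon_mask(aln)
  if (deletion == "complete") {
    incl <- colSums(canon) == aln$n
    pi <- rep(NA_real_, aln$L_aln)
    if (any(incl)) {
      sub <- aln$mat[, incl, drop = FALSE]
      pi[incl] <- .pi_columns(sub, matrix(TRUE, nrow(sub), ncol(sub)))
    }
  } else {
    pi <- .pi_columns(aln$mat, canon)
    incl <- !is.na(pi)
  }
  if (!any(incl)) {
    stop("alignment '", aln$gene, "' is entirely gapped/ambiguous: ",
         "no included columns", call. = FALSE)
  }
  structure(list(gene = aln$gene, n = aln$n, L_aln = aln$L_aln,
                 included_mask = incl, pi_per_column = pi,
                 Pi = mean(pi[incl]), L_incl = sum(incl),
                 deletion = deletion),
            class = "DiversityProfile")
}

#' @export
print.DiversityProfile <- function(x, ...) {
  cat(sprintf("DiversityProfile '%s': n=%d, L=%d (%d included), Pi=%.4f\n",
              x$gene, x$n, x$L_aln, x$L_incl, x$Pi))
  invisible(x)
}

#' Sliding-window nucleotide diversity
#'
#' One row per window start `0, s, 2s, ...` up to `L_aln - w`. `Pi_w` is the
#' mean per-column pi over the window's included columns (NA when none).
#' A window is `conserved` when all `w` columns are included (no gaps or
#' ambiguities anywhere — primers must anneal contiguously on every species)
#' and every one is monomorphic (`Pi_w == 0`).
#'
#' @param aln a [gene_alignment()].
#' @param w window size in alignment columns (default 20).
#' @param s step in columns (default 1).
#' @return data.frame of class `WindowTable` with columns
#'   `gene, start, end, included, Pi_w, conserved` (start/end 0-based
#'   half-open alignment columns); attributes `w`, `s`.
#' @export
sliding_windows <- function(aln, w = 20L, s = 1L) {
  stopifnot(inherits(aln, "GeneAlignment"))
  w <- as.integer(w); s <- as.integer(s)
  if (w < 1L || s < 1L) stop("w and s must be >= 1", call. = FALSE)
  if (w > aln$L_aln) {
    stop("window size ", w, " exceeds alignment length ", aln$L_aln,
         call. = FALSE)
  }
  prof <- gene_pi(aln)
  incl <- prof$included_mask
  pi0 <- ifelse(incl, prof$pi_per_column, 0)
  cs_incl <- c(0L, cumsum(incl))
  cs_pi <- c(0, cumsum(pi0))
  starts <- seq.int(0L, aln$L_aln - w, by = s)
  n_incl <- cs_incl[starts + w + 1L] - cs_incl[starts + 1L]
  sum_pi <- cs_pi[starts + w + 1L] - cs_pi[starts + 1L]
  Pi_w <- ifelse(n_incl > 0L, sum_pi / n_incl, NA_real_)
  conserved <- n_incl == w & !is.na(Pi_w) & Pi_w == 0
  out <- data.frame(gene = aln$gene, start = starts, end = starts + w,
                    included = n_incl, Pi_w = Pi_w, conserved = conserved,
                    stringsAsFactors = FALSE)
  attr(out, "w") <- w
  attr(out, "s") <- s
  class(out) <- c("WindowTable", class(out))
  out
}

#' Rank genes by nucleotide diversity
#'
#' @param profiles list of `DiversityProfile` objects.
#' @return data.frame (gene, Pi) sorted descending by Pi; ties broken
#'   alphabetically by gene name.
#' @export
rank_genes <- function(profiles) {
  if (length(profiles) == 0L) stop("no profiles to rank", call. = FALSE)
  genes <- vapply(profiles, `[[`, "", "gene")
  Pi <- vapply(profiles, `[[`, 0, "Pi")
  ord <- order(-Pi, genes)
  data.frame(gene = genes[ord], Pi = Pi[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}
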