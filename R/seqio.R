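#' @importFrom methods is
#' @importFrom utils head tail write.table read.table
#' @importFrom stats setNames
NULL

#' Normalize and validate a DNA sequence string
#'
#' Upper-cases, converts U to T, and checks the residue alphabet
#' (canonical bases, IUPAC ambiguity codes, and the gap character `-`).
#'
#' @param seq character scalar.
#' @param allow_empty logical; empty sequences are rejected by default.
#' @param context character used in error messages (e.g. a record id).
#' @return normalized sequence string.
#' @export
normalize_seq <- function(seq, allow_empty = FALSE, context = "sequence") {
  if (length(seq) != 1L || is.na(seq)) {
    stop("'", context, "' must be a single non-NA string", call. = FALSE)
  }
  s <- chartr("u", "T", toupper(seq))
  s <- chartr("U", "T", s)
  if (!allow_empty && nchar(s) == 0L) {
    stop("empty sequence not allowed for ", context, call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(s, "", fixed = TRUE)[[1]]), MB_ALPHABET)
  if (length(bad) > 0L) {
    stop("invalid character(s) ", paste(sQuote(bad), collapse = ", "),
         " in ", context, call. = FALSE)
  }
  s
}

#' Construct a sequence record
#'
#' A lightweight container for one DNA sequence plus optional gene features,
#' the substrate for gene extraction and in-silico PCR.
#'
#' @param id non-empty record identifier.
#' @param seq DNA string (normalized via [normalize_seq()]).
#' @param description free-text description.
#' @param features list of [gene_feature()] objects.
#' @return an object of class `SequenceRecord`.
#' @export
sequence_record <- function(id, seq, description = "", features = list()) {
  if (length(id) != 1L || is.na(id) || !nzchar(id)) {
    stop("record id must be a non-empty string", call. = FALSE)
  }
  seq <- normalize_seq(seq, context = paste0("record '", id, "'"))
  stopifnot(is.list(features))
  for (f in features) {
    if (!inherits(f, "GeneFeature")) stop("features must be GeneFeature objects")
    if (f$end > nchar(seq)) {
      stop("feature '", f$name, "' end (", f$end, ") exceeds sequence length (",
           nchar(seq), ") in record '", id, "'", call. = FALSE)
    }
  }
  structure(list(id = id, description = description, seq = seq,
                 features = features),
            class = "SequenceRecord")
}

#' @export
print.SequenceRecord <- function(x, ...) {
  cat(sprintf("SequenceRecord '%s': %d bp, %d feature(s)\n",
              x$id, nchar(x$seq), length(x$features)))
  invisible(x)
}

#' Construct a gene feature
#'
#' Coordinates are 0-based half-open on the parent sequence; strand is +1/-1.
#'
#' @param name gene name (e.g. "ATP6", "16S rRNA").
#' @param start,end integer bounds, `0 <= start < end`.
#' @param strand `+1` or `-1`.
#' @param type feature type (gene/CDS/rRNA/tRNA).
#' @return an object of class `GeneFeature`.
#' @export
gene_feature <- function(name, start, end, strand = 1L, type = "gene") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end <= start) {
    stop("invalid feature coordinates for '", name, "': need 0 <= start < end",
         call. = FALSE)
  }
  if (!strand %in% c(1L, -1L)) stop("strand must be +1 or -1")
  structure(list(name = name, start = start, end = end,
                 strand = as.integer(strand), type = type),
            class = "GeneFeature")
}

#' Reverse-complement a DNA string
#'
#' IUPAC-aware; preserves gaps; an involution (`revcomp(revcomp(x)) == x`).
#'
#' @param seq DNA string.
#' @return reverse complement, upper-case.
#' @export
revcomp <- function(seq) {
  seq <- normalize_seq(seq, allow_empty = TRUE, context = "revcomp input")
  if (nchar(seq) == 0L) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return list of [sequence_record()] objects, order preserved; empty file
#'   yields an empty list. Ids must be unique.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(list())
  lines <- readLines(path, warn = FALSE)
  if (all(!nzchar(trimws(lines)))) return(list())
  first <- which(nzchar(trimws(lines)))[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA (no '>' header) at line ", first, " of ", path,
         call. = FALSE)
  }
  hdr_idx <- which(startsWith(lines, ">"))
  recs <- vector("list", length(hdr_idx))
  bounds <- c(hdr_idx, length(lines) + 1L)
  for (i in seq_along(hdr_idx)) {
    hdr <- sub("^>", "", lines[hdr_idx[i]])
    id <- strsplit(trimws(hdr), "\\s+")[[1]][1]
    desc <- trimws(sub("^\\S*\\s*", "", trimws(hdr)))
    body <- lines[seq.int(hdr_idx[i] + 1L, bounds[i + 1L] - 1L)]
    body <- body[!startsWith(body, ">")]
    seq <- gsub("\\s", "", paste(body, collapse = ""))
    if (nchar(seq) == 0L) {
      stop("record '", id, "' near line ", hdr_idx[i], " has no sequence",
           call. = FALSE)
    }
    recs[[i]] <- sequence_record(id = id, seq = seq, description = desc)
  }
  ids <- vapply(recs, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  recs
}

#' Write sequence records to FASTA
#'
#' LF line endings, 80-column wrapping.
#'
#' @param records list of `SequenceRecord` (or named character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    nm <- names(records)
    if (is.null(nm)) stop("character input to write_fasta must be named")
    records <- Map(function(i, s) sequence_record(i, s), nm, unname(records))
  }
  con <- file(path, open = "wb")  # wb => LF endings on every platform
  on.exit(close(con))
  for (r in records) {
    hdr <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    writeLines(paste0(">", hdr), con, sep = "\n")
    body <- gsub("(.{80})", "\\1\n", r$seq)
    writeLines(sub("\n$", "", body), con, sep = "\n")
  }
  invisible(path)
}

# ---- GenBank flat file ------------------------------------------------------

# Parse "123..456", "complement(123..456)"; joins/compound locations are
# unsupported and reported to the caller as NULL.
.parse_location <- function(loc) {
  loc <- gsub("[<>]", "", loc)
  strand <- 1L
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("join|order|complement", loc)) return(NULL)
  m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
  if (length(m) == 0L) {
    m1 <- regmatches(loc, regexec("^(\\d+)$", loc))[[1]]
    if (length(m1) == 0L) return(NULL)
    start1 <- end1 <- as.integer(m1[2])
  } else {
    start1 <- as.integer(m[2]); end1 <- as.integer(m[3])
  }
  # GenBank is 1-based inclusive -> 0-based half-open
  list(start = start1 - 1L, end = end1, strand = strand)
}

#' Read records from a GenBank flat file
#'
#' Parses LOCUS, DEFINITION, the FEATURES table (gene, CDS, rRNA, tRNA) and the
#' ORIGIN sequence block. Coordinates are converted to 0-based half-open.
#' Compound (join/order) locations are skipped with a warning; records lacking
#' an ORIGIN block are an error.
#'
#' @param path GenBank flat file, possibly multi-record (separated by `//`).
#' @return list of [sequence_record()] objects.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  ends <- which(trimws(lines) == "//")
  if (length(ends) == 0L) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  recs <- list()
  for (k in seq_along(starts)) {
    chunk <- lines[starts[k]:ends[k]]
    if (all(!nzchar(trimws(chunk)))) next
    locus_i <- grep("^LOCUS", chunk)
    if (length(locus_i) == 0L) stop("GenBank record without LOCUS line")
    acc_i <- grep("^(VERSION|ACCESSION)", chunk)
    id <- if (length(acc_i)) strsplit(trimws(sub("^\\S+", "", chunk[acc_i[1]])),
                                      "\\s+")[[1]][1]
          else strsplit(trimws(sub("^LOCUS", "", chunk[locus_i[1]])), "\\s+")[[1]][1]
    def_i <- grep("^DEFINITION", chunk)
    desc <- if (length(def_i)) trimws(sub("^DEFINITION", "", chunk[def_i[1]])) else ""

    origin_i <- grep("^ORIGIN", chunk)
    if (length(origin_i) == 0L) {
      stop("GenBank record '", id, "' lacks an ORIGIN block", call. = FALSE)
    }
    seq_lines <- chunk[(origin_i[1] + 1L):length(chunk)]
    seq_lines <- seq_lines[trimws(seq_lines) != "//"]
    seq <- gsub("[0-9 /]", "", paste(seq_lines, collapse = ""))

    feats <- list()
    feat_i <- grep("^FEATURES", chunk)
    if (length(feat_i)) {
      ftab <- chunk[(feat_i[1] + 1L):(origin_i[1] - 1L)]
      # feature starts: 5-space indent then a key
      key_rows <- grep("^ {5}\\S", ftab)
      for (j in seq_along(key_rows)) {
        row <- ftab[key_rows[j]]
        key <- trimws(substr(row, 1, 20))
        if (!key %in% c("gene", "CDS", "rRNA", "tRNA")) next
        last <- if (j < length(key_rows)) key_rows[j + 1L] - 1L else length(ftab)
        block <- ftab[key_rows[j]:last]
        loc <- trimws(substr(row, 21, nchar(row)))
        # locations may wrap onto continuation lines before the first qualifier
        ci <- 2L
        while (ci <= length(block) && !grepl("^\\s+/", block[ci])) {
          loc <- paste0(loc, trimws(block[ci])); ci <- ci + 1L
        }
        parsed <- .parse_location(loc)
        qual <- paste(block, collapse = " ")
        gm <- regmatches(qual, regexec('/gene="([^"]+)"', qual))[[1]]
        pm <- regmatches(qual, regexec('/product="([^"]+)"', qual))[[1]]
        nm <- if (length(gm)) gm[2] else if (length(pm)) pm[2] else key
        if (is.null(parsed)) {
          warning("skipping unsupported compound location for '", nm,
                  "' in record '", id, "'", call. = FALSE)
          next
        }
        feats[[length(feats) + 1L]] <-
          gene_feature(nm, parsed$start, parsed$end, parsed$strand, type = key)
      }
    }
    recs[[length(recs) + 1L]] <- sequence_record(id, seq, desc, feats)
  }
  recs
}

# ---- gene extraction --------------------------------------------------------

# Canonicalize a gene label: drop spaces/hyphens/underscores, upper-case,
# then map through the alias table. Handles "16 S rRNA" == "16S" == "rrnL" etc.
.canonical_gene <- function(name) {
  key <- toupper(gsub("[ _-]", "", name))
  aliases <- c(
    COX1 = "COX1", COI = "COX1", CO1 = "COX1",
    COX2 = "COX2", COII = "COX2", CO2 = "COX2",
    COX3 = "COX3", COIII = "COX3", CO3 = "COX3",
    COB = "CYTB", CYTB = "CYTB", CYB = "CYTB",
    ATP6 = "ATP6", ATPASE6 = "ATP6",
    ATP8 = "ATP8", ATPASE8 = "ATP8",
    NAD1 = "ND1", ND1 = "ND1", NAD2 = "ND2", ND2 = "ND2",
    NAD3 = "ND3", ND3 = "ND3", NAD4 = "ND4", ND4 = "ND4",
    NAD4L = "ND4L", ND4L = "ND4L", NAD5 = "ND5", ND5 = "ND5",
    NAD6 = "ND6", ND6 = "ND6",
    `16S` = "16S", `16SRRNA` = "16S", RRNL = "16S", LRRNA = "16S",
    `16SRIBOSOMALRNA` = "16S", `LARGESUBUNITRIBOSOMALRNA` = "16S",
    `12S` = "12S", `12SRRNA` = "12S", RRNS = "12S", SRRNA = "12S",
    `12SRIBOSOMALRNA` = "12S", `SMALLSUBUNITRIBOSOMALRNA` = "12S"
  )
  if (key %in% names(aliases)) unname(aliases[[key]]) else key
}

#' Extract a gene's sense-strand sequence from a record
#'
#' Matching is case/space-insensitive through a built-in alias table
#' (cox1/COI, 16S/rrnL/"16 S rRNA", ...). Minus-strand features are
#' reverse-complemented so the returned string reads 5'-3' on the gene sense.
#' If several features share the canonical name (e.g. a gene plus its CDS,
#' or duplicated tRNAs), `which` selects by coordinate order.
#'
#' @param rec a `SequenceRecord` with features.
#' @param name gene name or alias.
#' @param which ordinal among same-named features (sorted by start).
#' @return DNA string.
#' @export
extract_gene <- function(rec, name, which = 1L) {
  stopifnot(inherits(rec, "SequenceRecord"))
  want <- .canonical_gene(name)
  hits <- Filter(function(f) .canonical_gene(f$name) == want, rec$features)
  if (length(hits) == 0L) {
    avail <- unique(vapply(rec$features, `[[`, "", "name"))
    stop("gene '", name, "' not found in record '", rec$id, "'; available: ",
         paste(avail, collapse = ", "), call. = FALSE)
  }
  # prefer 'gene' rows over CDS/rRNA duplicates at the same locus
  ord <- order(vapply(hits, `[[`, 0L, "start"),
               match(vapply(hits, `[[`, "", "type"),
                     c("gene", "rRNA", "tRNA", "CDS")))
  dedup <- hits[ord]
  keep <- !duplicated(vapply(dedup, function(f) paste(f$start, f$end), ""))
  dedup <- dedup[keep]
  if (which > length(dedup)) {
    stop("gene '", name, "' has only ", length(dedup), " copy(ies) in '",
         rec$id, "'", call. = FALSE)
  }
  f <- dedup[[which]]
  sub <- substr(rec$seq, f$start + 1L, f$end)
  if (f$strand == -1L) revcomp(sub) else sub
}

# ---- alignments -------------------------------------------------------------

#' Construct a gene alignment
#'
#' @param gene gene label.
#' @param species_ids character vector (n >= 2), unique.
#' @param rows aligned DNA strings, equal length, same order as `species_ids`.
#' @return an object of class `GeneAlignment` with a precomputed character
#'   matrix (`$mat`, n x L) for column arithmetic.
#' @export
gene_alignment <- function(gene, species_ids, rows) {
  if (length(species_ids) != length(rows)) {
    stop("species_ids and rows length mismatch", call. = FALSE)
  }
  if (length(rows) < 2L) stop("an alignment needs n >= 2 rows", call. = FALSE)
  if (anyDuplicated(species_ids)) stop("duplicate species ids", call. = FALSE)
  rows <- vapply(seq_along(rows), function(i) {
    normalize_seq(rows[[i]], context = paste0("alignment row '", species_ids[i], "'"))
  }, "")
  L <- unique(nchar(rows))
  if (length(L) != 1L) {
    bad <- species_ids[nchar(rows) != nchar(rows)[1]][1]
    stop("alignment rows have unequal lengths (offending id: '", bad, "')",
         call. = FALSE)
  }
  mat <- matrix(unlist(strsplit(rows, "", fixed = TRUE), use.names = FALSE),
                nrow = length(rows), ncol = L, byrow = TRUE,
                dimnames = list(species_ids, NULL))
  structure(list(gene = gene, species_ids = species_ids, rows = rows,
                 n = length(rows), L_aln = L, mat = mat),
            class = "GeneAlignment")
}

#' @export
print.GeneAlignment <- function(x, ...) {
  cat(sprintf("GeneAlignment '%s': n=%d, %d columns\n", x$gene, x$n, x$L_aln))
  invisible(x)
}

#' Load an aligned FASTA file as a GeneAlignment
#'
#' @param path aligned FASTA (all sequences equal length).
#' @param gene gene label; defaults to the file's base name.
#' @return a `GeneAlignment`.
#' @export
load_alignment <- function(path, gene = NULL) {
  recs <- read_fasta(path)
  if (length(recs) < 2L) stop("alignment file needs >= 2 sequences: ", path)
  lens <- vapply(recs, function(r) nchar(r$seq), 0L)
  if (length(unique(lens)) != 1L) {
    bad <- recs[[which(lens != lens[1])[1]]]$id
    stop("ragged alignment in ", path, " (offending id: '", bad, "')",
         call. = FALSE)
  }
  if (is.null(gene)) gene <- sub("\\.[^.]*$", "", basename(path))
  gene_alignment(gene, vapply(recs, `[[`, "", "id"),
                 vapply(recs, `[[`, "", "seq"))
}

#' Write a GeneAlignment as aligned FASTA
#' @param aln a `GeneAlignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  write_fasta(setNames(aln$rows, aln$species_ids), path)
}

# ---- reads ------------------------------------------------------------------

#' Construct a read set
#'
#' @param ids,seqs character vectors of equal length; ids non-empty.
#' @param quals optional quality strings (same lengths as `seqs`).
#' @param source label describing provenance.
#' @return an object of class `ReadSet`.
#' @export
read_set <- function(ids, seqs, quals = NULL, source = "") {
  stopifnot(length(ids) == length(seqs))
  if (length(ids) && any(!nzchar(ids))) stop("read ids must be non-empty")
  seqs <- toupper(seqs)
  if (!is.null(quals)) {
    stopifnot(length(quals) == length(seqs))
    if (any(nchar(quals) != nchar(seqs))) {
      stop("quality string length != sequence length", call. = FALSE)
    }
  }
  structure(list(ids = as.character(ids), seqs = as.character(seqs),
                 quals = quals, source = source, n = length(ids)),
            class = "ReadSet")
}

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet: %d reads%s\n", x$n,
              if (nzchar(x$source)) paste0(" from ", x$source) else ""))
  invisible(x)
}

#' Read FASTQ or FASTA reads
#'
#' Format is sniffed from the first non-blank character (`@` vs `>`).
#'
#' @param path input file.
#' @return a [read_set()]; FASTA input has `quals = NULL`.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- substr(trimws(readLines(path, n = 1L, warn = FALSE)), 1, 1)
  if (identical(first, "@")) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    q <- as.character(S4Vectors::mcols(x)$qualities)
    read_set(names(x), as.character(x), quals = q, source = path)
  } else {
    recs <- read_fasta(path)
    read_set(vapply(recs, `[[`, "", "id"), vapply(recs, `[[`, "", "seq"),
             source = path)
  }
}

#' Write a ReadSet as FASTQ
#' @param rs a `ReadSet`; reads with no quality get a constant "I" string.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(rs, path) {
  stopifnot(inherits(rs, "ReadSet"))
  q <- rs$quals
  if (is.null(q)) q <- vapply(nchar(rs$seqs), function(n) strrep("I", n), "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (rs$n > 0) {
    writeLines(paste0("@", rs$ids, "\n", rs$seqs, "\n+\n", q), con, sep = "\n")
  }
  invisible(path)
}
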