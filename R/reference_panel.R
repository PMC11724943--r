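# The published medicinal-leech reference panel: five RefSeq mitochondrial
# genomes and the published 16S rRNA mini-barcode primer pairs. The genome
# flat files are NOT shipped (they must be fetched from GenBank; see
# inst/scripts/fetch_accessions.sh); all functions here load them from a
# local directory.

#' Accessions of the five-species medicinal leech mitogenome panel
#'
#' @return named character vector (species -> RefSeq accession).
#' @export
leech_accessions <- function() {
  c("Hirudo nipponia"          = "NC_023776",
    "Poecilobdella manillensis" = "NC_023925",
    "Whitmania acranulata"      = "NC_023928",
    "Whitmania laevis"          = "NC_023926",
    "Whitmania pigra"           = "NC_013569")
}

#' Published 16S rRNA mini-barcode primer pairs for medicinal leeches
#'
#' The four published primer pairs (names give the forward-anchor position on
#' the 16S rRNA gene), with the published insert lengths (bp excluding
#' primers), variable-site counts, GC percentages and melting temperatures.
#' Note the published record is internally inconsistent for pair 876F/1043R:
#' its table prints a 148-bp insert while the running text says 151 bp; both
#' are kept here.
#'
#' @return data.frame, two rows (F then R) per pair.
#' @export
leech_primer_table <- function() {
  data.frame(
    pair = rep(c("606F/744R", "741F/943R", "742F/884R", "876F/1043R"),
               each = 2L),
    primer = c("606F", "744R", "741F", "943R",
               "742F", "884R", "876F", "1043R"),
    role = rep(c("F", "R"), 4L),
    sequence = c("TGTGCAAAGGTAGCATA", "AAGCTTTATAGGGTCT",
                 "AGAAGACCCTATAAAGC", "TTAAGTCAACATCGAGG",
                 "GAAGACCCTATAAAGC", "CTGTTACCCCTAAAGT",
                 "ATTAAGTTACTTTAGGGGTA", "TAGAATCTAACCTGGCT"),
    insert_bp = rep(c(121L, 196L, 136L, 148L), each = 2L),
    insert_bp_text = rep(c(121L, 196L, 136L, 151L), each = 2L),
    variable_sites = rep(c(38L, 55L, 47L, 30L), each = 2L),
    gc_pct = c(41.2, 37.5, 41.2, 41.2, 43.8, 43.8, 30.0, 41.2),
    tm_c = c(49.0, 46.9, 48.6, 47.9, 45.3, 46.4, 48.6, 47.9),
    stringsAsFactors = FALSE)
}

#' Locate locally fetched panel GenBank files
#'
#' Looks for `<accession>.gb` under `dir` (default: the package's
#' `extdata/accessions` directory, where the fetch script deposits them).
#'
#' @param dir directory holding the flat files.
#' @return named character vector of paths for the accessions found (may be
#'   empty when the panel has not been fetched).
#' @export
leech_panel_paths <- function(dir = system.file("extdata", "accessions",
                                                package = "minibarc")) {
  acc <- leech_accessions()
  if (!nzchar(dir) || !dir.exists(dir)) {
    return(setNames(character(0), character(0)))
  }
  paths <- file.path(dir, paste0(acc, ".gb"))
  names(paths) <- names(acc)
  paths[file.exists(paths)]
}

#' Load the leech panel as SequenceRecords
#'
#' @param dir passed to [leech_panel_paths()].
#' @return named list of `SequenceRecord` (species -> record), or an error
#'   listing the missing accessions with fetch instructions.
#' @export
leech_panel_records <- function(dir = system.file("extdata", "accessions",
                                                  package = "minibarc")) {
  paths <- leech_panel_paths(dir)
  missing <- setdiff(names(leech_accessions()), names(paths))
  if (length(missing)) {
    stop("reference mitogenomes not available locally (missing: ",
         paste(leech_accessions()[missing], collapse = ", "),
         "); fetch them with inst/scripts/fetch_accessions.sh into ",
         "inst/extdata/accessions/ and reinstall", call. = FALSE)
  }
  out <- lapply(paths, function(p) read_genbank(p)[[1]])
  names(out) <- names(paths)
  out
}

#' Build the per-gene alignments of the leech panel
#'
#' Extracts each shared gene from all panel members and aligns them with an
#' external aligner (`mafft`, which must be on the PATH), mirroring the
#' standard extract-then-align protocol for mitogenome panels.
#'
#' @param records result of [leech_panel_records()].
#' @param genes gene names to align (default: the 15 shared protein-coding
#'   and rRNA genes).
#' @return named list of `GeneAlignment`.
#' @export
leech_panel_alignments <- function(records,
                                   genes = c("ATP6", "ATP8", "COX1", "COX2",
                                             "COX3", "CYTB", "ND1", "ND2",
                                             "ND3", "ND4", "ND4L", "ND5",
                                             "ND6", "16S", "12S")) {
  if (Sys.which("mafft") == "") {
    stop("mafft not found on PATH; cannot align the panel", call. = FALSE)
  }
  out <- list()
  for (g in genes) {
    seqs <- vapply(records, extract_gene, "", name = g)
    tmp_in <- tempfile(fileext = ".fasta")
    tmp_out <- tempfile(fileext = ".fasta")
    write_fasta(setNames(seqs, names(records)), tmp_in)
    status <- system2("mafft", c("--auto", "--quiet", tmp_in),
                      stdout = tmp_out)
    if (status != 0L) stop("mafft failed for gene ", g, call. = FALSE)
    out[[g]] <- load_alignment(tmp_out, gene = g)
    unlink(c(tmp_in, tmp_out))
  }
  out
}
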