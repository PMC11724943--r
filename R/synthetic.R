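# Synthetic fixtures: multi-species gene panels with planted conserved
# anchor windows flanking hypervariable cores, and error-bearing amplicon
# read mixtures with known species weights. Substitution-only by default so
# the per-gene "alignment" is the identity; an optional indel-planting mode
# exercises gap handling with exact truth gaps.

#' Build and validate a simulation configuration
#'
#' The generator's model: for each gene an ancestral sequence is drawn
#' uniformly over A/C/G/T (planted primer sites overwrite it), then each
#' species independently substitutes each non-anchor site with probability
#' `theta` (the gene's divergence) to a uniformly chosen different base.
#' Anchor columns are copied verbatim into every species, so they are
#' zero-diversity windows by construction.
#'
#' @param n_species number of species (>= 2).
#' @param genes list of `list(name, length, theta)`.
#' @param anchors list of `list(gene, position, length = 20, primer_seq =
#'   NULL, primer_offset = 0, role = "F"|"R")`. `position` is 0-based within
#'   the gene. For role `"R"` the primer is given 5'-3' as the reverse primer
#'   and its reverse complement is planted on the sense strand. Anchor
#'   intervals within a gene must be disjoint.
#' @param weights mixture weights over species (non-negative, sum 1).
#' @param n_reads reads to simulate.
#' @param error_rate per-base substitution error rate in reads (<= 0.1).
#' @param indel_rate per-gene probability of planting one deletion in a
#'   random species (default 0: substitution-only).
#' @param seed integer RNG seed.
#' @return validated `SimulationConfig` list.
#' @export
simulation_config <- function(n_species = 5L,
                              genes = list(),
                              anchors = list(),
                              weights = NULL,
                              n_reads = 10000L,
                              error_rate = 0.005,
                              indel_rate = 0,
                              seed = 1L) {
  n_species <- as.integer(n_species)
  if (n_species < 2L) stop("need n_species >= 2", call. = FALSE)
  if (is.null(weights)) weights <- rep(1 / n_species, n_species)
  if (length(weights) != n_species || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  if (error_rate < 0 || error_rate > 0.1) {
    stop("error_rate must lie in [0, 0.1]", call. = FALSE)
  }
  gnames <- vapply(genes, `[[`, "", "name")
  if (anyDuplicated(gnames)) stop("duplicate gene names", call. = FALSE)
  anchors <- lapply(anchors, function(a) {
    a$length <- if (is.null(a$length)) 20L else as.integer(a$length)
    a$primer_offset <- if (is.null(a$primer_offset)) 0L else as.integer(a$primer_offset)
    a$role <- if (is.null(a$role)) "F" else a$role
    if (!a$gene %in% gnames) stop("anchor gene '", a$gene, "' not in genes")
    g <- genes[[match(a$gene, gnames)]]
    if (a$position < 0L || a$position + a$length > g$length) {
      stop("anchor outside gene '", a$gene, "' bounds", call. = FALSE)
    }
    if (!is.null(a$primer_seq)) {
      a$primer_seq <- normalize_seq(a$primer_seq, context = "planted primer")
      if (a$primer_offset + nchar(a$primer_seq) > a$length) {
        stop("planted primer does not fit inside its anchor", call. = FALSE)
      }
    }
    a
  })
  for (g in gnames) {
    iv <- Filter(function(a) a$gene == g, anchors)
    if (length(iv) > 1L) {
      st <- vapply(iv, `[[`, 0L, "position")
      en <- st + vapply(iv, `[[`, 0L, "length")
      o <- order(st)
      if (any(st[o][-1] < en[o][-length(en)])) {
        stop("overlapping anchors within gene '", g, "'", call. = FALSE)
      }
    }
  }
  structure(list(n_species = n_species, genes = genes, anchors = anchors,
                 weights = weights, n_reads = as.integer(n_reads),
                 error_rate = error_rate, indel_rate = indel_rate,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Default leech-like simulation configuration
#'
#' Emulates the structure of a five-species mitochondrial panel: three
#' hypervariable protein-coding genes without usable anchors and one
#' rRNA-like gene of moderate divergence carrying two planted 20-column
#' conserved anchors whose planted primers flank a 196-nt hypervariable
#' core (the published mini-barcode geometry).
#'
#' @param seed RNG seed.
#' @param n_reads,error_rate read-mixture parameters.
#' @param weights mixture weights (default equal).
#' @return a [simulation_config()].
#' @export
default_sim_config <- function(seed = 1L, n_reads = 10000L,
                               error_rate = 0.005, weights = NULL) {
  simulation_config(
    n_species = 5L,
    genes = list(
      list(name = "ATP6", length = 700L, theta = 0.34),
      list(name = "ATP8", length = 160L, theta = 0.24),
      list(name = "ND4L", length = 280L, theta = 0.21),
      list(name = "16S",  length = 1100L, theta = 0.15)),
    anchors = list(
      list(gene = "16S", position = 737L, length = 20L,
           primer_seq = "AGAAGACCCTATAAAGC", primer_offset = 3L, role = "F"),
      list(gene = "16S", position = 953L, length = 20L,
           primer_seq = "TTAAGTCAACATCGAGG", primer_offset = 0L, role = "R")),
    weights = weights, n_reads = n_reads, error_rate = error_rate,
    seed = seed)
}

.BASES <- c("A", "C", "G", "T")

# substitute positions `idx` of character vector `ch` with a uniform
# different base
.substitute <- function(ch, idx) {
  if (length(idx) == 0L) return(ch)
  cur <- ch[idx]
  shift <- sample.int(3L, length(idx), replace = TRUE)
  ch[idx] <- .BASES[(match(cur, .BASES) - 1L + shift) %% 4L + 1L]
  ch
}

#' Simulate a species panel with planted anchors
#'
#' @param cfg a [simulation_config()].
#' @return list with `records` (one `SequenceRecord` per species, genes
#'   concatenated with features), `alignments` (named list of
#'   `GeneAlignment`), and `truth` (ancestral sequences, species gene
#'   sequences, anchor coordinates per gene and per genome, realized per-gene
#'   mean pairwise p-distances, planted indels).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  sp_ids <- sprintf("sp%02d", seq_len(cfg$n_species))
  ancestral <- list(); gene_seqs <- list(); alignments <- list()
  anchors_truth <- list(); indels <- list()
  for (g in cfg$genes) {
    anc <- sample(.BASES, g$length, replace = TRUE)
    amask <- rep(FALSE, g$length)
    for (a in cfg$anchors) {
      if (a$gene != g$name) next
      amask[(a$position + 1L):(a$position + a$length)] <- TRUE
      if (!is.null(a$primer_seq)) {
        site <- if (a$role == "R") revcomp(a$primer_seq) else a$primer_seq
        pos <- a$position + a$primer_offset
        anc[(pos + 1L):(pos + nchar(site))] <- strsplit(site, "")[[1]]
      }
      anchors_truth[[length(anchors_truth) + 1L]] <-
        list(gene = g$name, start = a$position,
             end = a$position + a$length, role = a$role,
             primer_seq = a$primer_seq)
    }
    free <- which(!amask)
    rows <- vapply(seq_len(cfg$n_species), function(s) {
      ch <- anc
      hit <- free[stats::runif(length(free)) < g$theta]
      paste(.substitute(ch, hit), collapse = "")
    }, "")
    aln_rows <- rows
    if (cfg$indel_rate > 0 && stats::runif(1) < cfg$indel_rate) {
      # plant one deletion in a random species, outside anchors
      sp <- sample.int(cfg$n_species, 1L)
      len <- stats::rgeom(1L, 0.5) + 1L
      ok <- free[vapply(free, function(p) {
        p + len - 1L <= g$length && all(p:(p + len - 1L) %in% free)
      }, logical(1))]
      if (length(ok)) {
        pos <- sample(ok, 1L)
        ch <- strsplit(rows[sp], "")[[1]]
        gap <- ch
        gap[pos:(pos + len - 1L)] <- "-"
        aln_rows[sp] <- paste(gap, collapse = "")
        rows[sp] <- paste(ch[-(pos:(pos + len - 1L))], collapse = "")
        indels[[length(indels) + 1L]] <-
          list(gene = g$name, species = sp_ids[sp],
               start = pos - 1L, length = len)
      }
    }
    ancestral[[g$name]] <- paste(anc, collapse = "")
    gene_seqs[[g$name]] <- setNames(rows, sp_ids)
    alignments[[g$name]] <- gene_alignment(g$name, sp_ids, aln_rows)
  }
  records <- lapply(seq_len(cfg$n_species), function(s) {
    segs <- vapply(cfg$genes, function(g) gene_seqs[[g$name]][s], "")
    offs <- c(0L, cumsum(nchar(segs)))
    feats <- lapply(seq_along(cfg$genes), function(k) {
      gene_feature(cfg$genes[[k]]$name, offs[k], offs[k + 1L], strand = 1L)
    })
    sequence_record(sp_ids[s], paste(segs, collapse = ""),
                    description = "synthetic panel member", features = feats)
  })
  pdist <- lapply(alignments, function(aln) {
    prof <- gene_pi(aln)
    prof$Pi
  })
  list(records = records, alignments = alignments,
       truth = list(species_ids = sp_ids, ancestral = ancestral,
                    gene_seqs = gene_seqs, anchors = anchors_truth,
                    realized_pi = pdist, indels = indels,
                    seed = cfg$seed))
}

#' The planted primer pair of a configuration
#'
#' @param cfg a [simulation_config()] whose anchors carry one `"F"` and one
#'   `"R"` planted primer on the same gene.
#' @return list with `$fwd`, `$rev` primer strings (both 5'-3') and `$gene`.
#' @export
fixture_pair <- function(cfg) {
  with_seq <- Filter(function(a) !is.null(a$primer_seq), cfg$anchors)
  f <- Filter(function(a) a$role == "F", with_seq)
  r <- Filter(function(a) a$role == "R", with_seq)
  if (length(f) == 0L || length(r) == 0L) {
    stop("configuration has no planted F/R primer pair", call. = FALSE)
  }
  list(fwd = f[[1]]$primer_seq, rev = r[[1]]$primer_seq, gene = f[[1]]$gene)
}

#' Simulate amplicon reads from a reference panel
#'
#' Each read draws its species from `Categorical(weights)`, takes the full
#' amplicon (primers + insert), and substitutes each base independently with
#' probability `error_rate` to a uniformly chosen different base.
#'
#' @param amplicons named list (species -> `Amplicon`) or named character
#'   vector of full amplicon sequences.
#' @param weights mixture weights (named or in `names(amplicons)` order).
#' @param n_reads number of reads.
#' @param error_rate per-base substitution probability (in `[0, 0.1]`).
#' @param seed RNG seed.
#' @return list with `reads` (a `ReadSet`) and `truth` (per-read species
#'   labels and realized per-species counts).
#' @export
simulate_reads <- function(amplicons, weights, n_reads, error_rate = 0.005,
                           seed = 1L) {
  full <- if (is.character(amplicons)) amplicons
          else vapply(amplicons, `[[`, "", "full_seq")
  if (is.null(names(full))) stop("amplicons must be named by species")
  if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0)) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  if (error_rate < 0 || error_rate > 0.1) {
    stop("error_rate must lie in [0, 0.1]", call. = FALSE)
  }
  set.seed(seed)
  n_reads <- as.integer(n_reads)
  if (n_reads == 0L) {
    return(list(reads = read_set(character(0), character(0),
                                 source = "simulate_reads"),
                truth = list(labels = character(0),
                             counts = setNames(integer(length(full)),
                                               names(full)))))
  }
  labels <- sample(names(full), n_reads, replace = TRUE, prob = weights)
  lens <- nchar(full)[labels]
  n_err <- stats::rbinom(n_reads, lens, error_rate)
  seqs <- full[labels]
  for (i in which(n_err > 0L)) {
    ch <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(length(ch), n_err[i])
    seqs[i] <- paste(.substitute(ch, pos), collapse = "")
  }
  counts <- table(factor(labels, levels = names(full)))
  list(reads = read_set(sprintf("read%06d", seq_len(n_reads)), unname(seqs),
                        source = "simulate_reads"),
       truth = list(labels = labels,
                    counts = setNames(as.integer(counts), names(full))))
}

#' Write a complete fixture to disk
#'
#' Emits `panel.fasta` (species genomes), `genes/<gene>.aln.fasta` (aligned
#' FASTA per gene), `reads.fastq` (simulated mixture reads, when the
#' configuration carries a planted primer pair), and `truth.json`.
#'
#' @param cfg a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly; the simulated objects as
#'   attribute `"objects"`.
#' @export
write_fixture <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "genes"), showWarnings = FALSE)
  panel <- simulate_panel(cfg)
  paths <- list(panel = file.path(dir, "panel.fasta"),
                truth = file.path(dir, "truth.json"))
  write_fasta(panel$records, paths$panel)
  for (g in names(panel$alignments)) {
    p <- file.path(dir, "genes", paste0(g, ".aln.fasta"))
    write_alignment(panel$alignments[[g]], p)
    paths[[paste0("aln_", g)]] <- p
  }
  reads_truth <- NULL
  pair <- tryCatch(fixture_pair(cfg), error = function(e) NULL)
  if (!is.null(pair)) {
    amps <- panel_amplicons(panel$records, pair, max_mm = 0L)
    sim <- simulate_reads(amps, cfg$weights, cfg$n_reads, cfg$error_rate,
                          seed = cfg$seed + 1L)
    paths$reads <- file.path(dir, "reads.fastq")
    write_fastq(sim$reads, paths$reads)
    reads_truth <- sim$truth
  }
  truth <- panel$truth
  truth$read_labels <- reads_truth$labels
  truth$read_counts <- reads_truth$counts
  truth$weights <- cfg$weights
  truth$error_rate <- cfg$error_rate
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  attr(paths, "objects") <- list(panel = panel, reads = reads_truth)
  invisible(paths)
}
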