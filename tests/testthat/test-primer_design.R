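test_that("find_conserved_windows merges runs into maximal stretches", {
  ident <- gene_alignment("g", c("a", "b"),
                          rep(paste(rep("ACGTA", 6), collapse = ""), 2))
  wt <- sliding_windows(ident, w = 20, s = 1)
  cw <- find_conserved_windows(wt, ident)
  expect_length(cw, 1L)
  expect_equal(cw[[1]]$start, 0L)
  expect_equal(cw[[1]]$end, 30L)
  expect_equal(cw[[1]]$consensus, ident$rows[1])
  # two stretches split by one polymorphic column
  r1 <- paste0(strrep("A", 25), "C", strrep("G", 25))
  r2 <- paste0(strrep("A", 25), "T", strrep("G", 25))
  aln <- gene_alignment("g", c("a", "b"), c(r1, r2))
  cw2 <- find_conserved_windows(sliding_windows(aln), aln)
  expect_equal(vapply(cw2, `[[`, 0L, "start"), c(0L, 26L))
  expect_equal(vapply(cw2, `[[`, 0L, "end"), c(25L, 51L))
  # hypervariable alignment: empty result
  set.seed(2)
  hv <- random_alignment(5, 80)
  expect_length(find_conserved_windows(sliding_windows(hv), hv), 0L)
})

test_that("conserved stretches match the independent monomorphic-run oracle", {
  set.seed(31)
  for (k in 1:10) {
    cfg <- small_cfg(seed = 1000L + k)
    panel <- simulate_panel(cfg)
    aln <- panel$alignments[["16S"]]
    cw <- find_conserved_windows(sliding_windows(aln), aln)
    truth <- oracle_conserved_runs(aln, w = 20L)
    expect_equal(vapply(cw, `[[`, 0L, "start"), truth$start)
    expect_equal(vapply(cw, `[[`, 0L, "end"), truth$end)
  }
})

test_that("gc_content matches the published primer table to 1 decimal", {
  tab <- leech_primer_table()
  for (i in seq_len(nrow(tab))) {
    expect_equal(gc_content(tab$sequence[i]), tab$gc_pct[i],
                 info = tab$primer[i])
  }
  expect_equal(gc_content("GGCC"), 100.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_error(gc_content("ACGN"), "canonical")
  set.seed(4)
  for (k in 1:10) {
    x <- paste(sample(CANON, sample(8:30, 1), TRUE), collapse = "")
    expect_equal(gc_content(revcomp(x)), gc_content(x))
  }
})

test_that("melting temperatures: Wallace exact, NN deterministic and sane", {
  expect_equal(melting_temp("ACGT", "wallace"), 12)
  expect_equal(melting_temp("TGTGCAAAGGTAGCATA", "wallace"), 48)
  expect_error(melting_temp("ACGT", "nn"), "length >= 8")
  expect_error(melting_temp("ACGT", "zzz"))
  tab <- leech_primer_table()
  for (i in seq_len(nrow(tab))) {
    tm <- melting_temp(tab$sequence[i])
    expect_identical(tm, melting_temp(tab$sequence[i]))
    # sanity envelope vs the published (undisclosed-formula) values
    expect_lt(abs(tm - tab$tm_c[i]), 8)
  }
})

test_that("duplex scores agree with the brute-force oracle and are symmetric", {
  set.seed(17)
  for (k in 1:15) {
    a <- paste(sample(CANON, sample(6:20, 1), TRUE), collapse = "")
    b <- paste(sample(CANON, sample(6:20, 1), TRUE), collapse = "")
    expect_equal(cross_dimer_score(a, b), oracle_duplex(a, b))
    expect_equal(cross_dimer_score(a, b), cross_dimer_score(b, a))
    expect_equal(self_dimer_score(a), oracle_duplex(a, a))
    expect_equal(hairpin_score(a), oracle_duplex(a, a, min_loop = 3))
  }
  # a primer and its perfect reverse complement dimerize maximally
  expect_equal(cross_dimer_score("AAAAAAAA", "TTTTTTTT"),
               oracle_duplex("AAAAAAAA", "TTTTTTTT"))
  expect_gte(cross_dimer_score("AAAAAAAA", "TTTTTTTT"), 8)
  # poly-A cannot pair with itself
  expect_lt(self_dimer_score("AAAAAAAA"), 0)
  # a perfect reverse-complement palindrome folds on itself and is rejected
  pal <- "ACGTACGT"
  expect_gte(hairpin_score(pal), 3)
  f <- primer_filters()
  expect_gt(self_dimer_score(pal), f$max_self_dimer)
})

test_that("enumerate_primers: combinatorial count, filters, orientations", {
  cw <- list(structure(list(gene = "g", start = 10L, end = 30L,
                            consensus = "TGTGCAAAGGTAGCATAGCA"),
                       class = "ConservedWindow"))
  raw <- enumerate_primers(cw, len_range = c(16, 22), filters = NULL)
  # oracle: substrings of a 20-mer with lengths 16..20, in 2 orientations
  n_sub <- sum(vapply(16:20, function(L) 20L - L + 1L, 0L))
  expect_length(raw, 2L * n_sub)
  expect_setequal(unique(vapply(raw, `[[`, "", "orientation")), c("F", "R"))
  f_seqs <- vapply(Filter(function(x) x$orientation == "F", raw), `[[`, "", "seq")
  r_seqs <- vapply(Filter(function(x) x$orientation == "R", raw), `[[`, "", "seq")
  expect_setequal(r_seqs, vapply(f_seqs, revcomp, ""))
  # anchored coordinates are consistent with the consensus
  for (cand in raw[1:10]) {
    sense <- if (cand$orientation == "F") cand$seq else revcomp(cand$seq)
    expect_equal(substr(cw[[1]]$consensus, cand$start - 10L + 1L,
                        cand$end - 10L), sense)
  }
  # too-short stretch yields nothing
  short <- list(structure(list(gene = "g", start = 0L, end = 10L,
                               consensus = "ACGTACGTAC"),
                          class = "ConservedWindow"))
  expect_length(enumerate_primers(short), 0L)
  # filtering drops GC outliers and homopolymer runs
  polyg <- list(structure(list(gene = "g", start = 0L, end = 20L,
                               consensus = strrep("G", 20)),
                          class = "ConservedWindow"))
  expect_length(enumerate_primers(polyg), 0L)
})

test_that("count_variable_sites counts polymorphic and indel columns", {
  aln <- gene_alignment("g", sprintf("s%d", 1:5),
                        c("AAAAAAAAAA", "AAAAAAAAAA", "AATAAAAAGA",
                          "AATAAAAAGA", "AA-AACAAGA"))
  # columns: 2 (T/T/-), 5 (C), 8 (G) variable with gap-as-state, col 2 also
  # variable without (A vs T)
  expect_equal(count_variable_sites(aln, 0, 10), 3L)
  expect_equal(count_variable_sites(aln, 0, 10, gap_as_state = FALSE), 3L)
  gap_only <- gene_alignment("g", c("a", "b"), c("A-A", "AAA"))
  expect_equal(count_variable_sites(gap_only, 0, 3), 1L)
  expect_equal(count_variable_sites(gap_only, 0, 3, gap_as_state = FALSE), 0L)
  ident <- gene_alignment("g", c("a", "b"), c("ACGT", "ACGT"))
  expect_equal(count_variable_sites(ident, 0, 4), 0L)
  # oracle identity: width minus monomorphic columns
  set.seed(23)
  for (k in 1:10) {
    aln <- random_alignment(4, 30, p_gap = 0.05)
    vs <- count_variable_sites(aln, 0, 30)
    mono <- sum(apply(aln$mat, 2, function(col) length(unique(col)) == 1L))
    expect_equal(vs, 30L - mono)
    expect_lte(vs, 30L)
  }
})

test_that("assess_resolution: symmetry, zero diagonal, resolved flag", {
  dup <- gene_alignment("g", c("a", "b", "c"), c("ACGT", "ACGT", "ACTT"))
  rep1 <- assess_resolution(dup, 0, 4)
  expect_false(rep1$resolved)
  expect_equal(rep1$min_diff, 0L)
  set.seed(29)
  aln <- random_alignment(5, 40)
  rep2 <- assess_resolution(aln, 0, 40)
  expect_true(isSymmetric(rep2$pairwise_diffs))
  expect_true(all(diag(rep2$pairwise_diffs) == 0L))
  # brute-force pair count oracle
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(rep2$pairwise_diffs[i, j],
                 sum(aln$mat[i, ] != aln$mat[j, ]))
  }
})

test_that("pair_primers computes inserts in reference coordinates and filters", {
  set.seed(41)
  core <- paste(sample(CANON, 300, TRUE), collapse = "")
  rows <- rep(paste0(strrep("A", 0), core), 5)  # identical -> gap-free
  aln <- gene_alignment("g", sprintf("s%d", 1:5), rows)
  f <- mb_cand("F", substr(core, 11, 27), "g", 10L, 27L)
  r <- mb_cand("R", revcomp(substr(core, 224, 240)), "g", 223L, 240L)
  pairs <- pair_primers(list(f, r), aln, filters = NULL)
  expect_length(pairs, 1L)
  expect_equal(pairs[[1]]$insert_len, 223L - 27L)  # 196
  expect_equal(unname(pairs[[1]]$insert_len_by_species), rep(196L, 5))
  # below insert range -> rejected
  r2 <- mb_cand("R", revcomp(substr(core, 101, 117)), "g", 100L, 117L)
  expect_length(pair_primers(list(f, r2), aln, filters = NULL), 0L)
  expect_error(pair_primers(list(f, r), aln, ref_species = "nope"), "absent")
})

test_that("insert length uses ungapped reference coordinates under indels", {
  # reference s1 has a 4-column gap inside the insert
  r1 <- paste0(strrep("C", 20), strrep("-", 4), strrep("G", 120), strrep("T", 20))
  r2 <- paste0(strrep("C", 20), strrep("A", 4), strrep("G", 120), strrep("T", 20))
  aln <- gene_alignment("g", c("s1", "s2"), c(r1, r2))
  f <- mb_cand("F", strrep("C", 16), "g", 4L, 20L)
  r <- mb_cand("R", revcomp(strrep("T", 16)), "g", 144L, 160L)
  pp <- pair_primers(list(f, r), aln, filters = NULL)
  expect_length(pp, 1L)
  expect_equal(pp[[1]]$insert_len, 120L)             # gap columns skipped
  expect_equal(unname(pp[[1]]$insert_len_by_species), c(120L, 124L))
  # indel columns count as variable sites
  expect_equal(pp[[1]]$variable_sites, 4L)
})

test_that("rank_pairs is a deterministic total order on the stated keys", {
  mk <- function(vs, tmd, ins, fs = "AAAA", rs = "TTTT") {
    structure(list(fwd = list(seq = fs), rev = list(seq = rs),
                   insert_len = ins, variable_sites = vs, tm_diff = tmd,
                   rank_score = vs),
              class = "PrimerPair")
  }
  p <- list(mk(38, 0.5, 121), mk(55, 2, 196), mk(47, 1, 136), mk(30, 0, 148))
  r <- rank_pairs(p)
  expect_equal(vapply(r, `[[`, 0, "variable_sites"), c(55, 47, 38, 30))
  # tie on variable sites -> smaller dTm, then insert closest to 175
  q <- list(mk(10, 3, 175), mk(10, 1, 120), mk(10, 1, 170))
  expect_equal(vapply(rank_pairs(q), `[[`, 0, "tm_diff"), c(1, 1, 3))
  expect_equal(rank_pairs(q)[[1]]$insert_len, 170)
  # permutation invariance
  set.seed(47)
  perm <- sample(4)
  expect_identical(rank_pairs(p), rank_pairs(p[perm]))
  expect_length(rank_pairs(p[2]), 1L)
  expect_error(rank_pairs(list()), "no pairs")
})

test_that("designed primers anneal to every panel member with 0 mismatches", {
  cfg <- small_cfg(seed = 77)
  panel <- simulate_panel(cfg)
  aln <- panel$alignments[["16S"]]
  cw <- find_conserved_windows(sliding_windows(aln), aln)
  cands <- enumerate_primers(cw)
  expect_gt(length(cands), 0L)
  some <- cands[seq(1, length(cands), length.out = min(8, length(cands)))]
  for (cand in some) {
    for (rec in panel$records) {
      m <- find_matches(rec, cand, max_mm = 0L)
      expect_gte(length(m), 1L)
    }
  }
})
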