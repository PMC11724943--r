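mk_reads <- function(seqs, prefix = "r") {
  read_set(sprintf("%s%03d", prefix, seq_along(seqs)), seqs)
}

test_that("trim_primers strips primers, normalizes orientation, logs drops", {
  fwd <- "AGAAGACCCTATAAAGC"
  rev <- "TTAAGTCAACATCGAGG"
  pair <- list(fwd = fwd, rev = rev)
  insert <- "ACCGTTACCGGTATTACCAGGT"
  good <- paste0(fwd, insert, revcomp(rev))
  flipped <- revcomp(good)
  junk <- strrep("ACGT", 20)
  out <- trim_primers(mk_reads(c(good, flipped, junk)), pair, max_mm = 2)
  expect_equal(out$n, 2L)
  expect_equal(out$seqs, c(insert, insert))
  expect_equal(attr(out, "dropped"), 1L)
  # up to max_mm substitutions in each primer copy tolerated
  mut <- good
  substr(mut, 2, 2) <- "C"
  substr(mut, nchar(mut) - 1, nchar(mut) - 1) <- "A"
  out2 <- trim_primers(mk_reads(mut), pair, max_mm = 2)
  expect_equal(out2$seqs, insert)
  expect_equal(trim_primers(mk_reads(mut), pair, max_mm = 0)$n, 0L)
})

test_that("dereplicate groups exact sequences with deterministic order", {
  rs <- mk_reads(c("AAA", "CCC", "AAA", "AAA", "GGG", "CCC"))
  ds <- dereplicate(rs)
  expect_equal(ds$seqs, c("AAA", "CCC", "GGG"))
  expect_equal(ds$counts, c(3L, 2L, 1L))
  expect_equal(ds$total_reads, 6L)
  empty <- dereplicate(mk_reads(character(0)))
  expect_equal(empty$total_reads, 0L)
  expect_length(empty$seqs, 0L)
  # conservation over random inputs; count ties break by sequence
  set.seed(71)
  for (k in 1:5) {
    seqs <- sample(c("TTT", "AAA", "GGG"), sample(5:40, 1), TRUE)
    ds <- dereplicate(mk_reads(seqs))
    expect_equal(sum(ds$counts), length(seqs))
    same <- split(ds$seqs, ds$counts)
    expect_true(all(vapply(same, function(s) !is.unsorted(s), TRUE)))
  }
})

test_that("denoise_lite absorbs low-count neighbors by the stated rule", {
  ds <- structure(list(seqs = c("AAAAAAAA", "AAAAAAAT"),
                       counts = c(100L, 10L), total_reads = 110L),
                  class = "DereplicatedSet")
  out <- denoise_lite(ds)
  expect_equal(out$seqs, "AAAAAAAA")
  expect_equal(out$counts, 110L)
  # distance above max_diff: untouched
  ds2 <- structure(list(seqs = c("AAAAAAAA", "TTTTTAAA"),
                        counts = c(100L, 50L), total_reads = 150L),
                   class = "DereplicatedSet")
  expect_length(denoise_lite(ds2)$seqs, 2L)
  # ratio not met: untouched
  ds3 <- structure(list(seqs = c("AAAAAAAA", "AAAAAAAT"),
                        counts = c(100L, 30L), total_reads = 130L),
                   class = "DereplicatedSet")
  expect_length(denoise_lite(ds3)$seqs, 2L)
  # absorbed counts cascade into the retained parent, conservation holds
  ds4 <- structure(list(seqs = c("AAAAAAAA", "AAAAAAAT", "AAAAAATT"),
                        counts = c(160L, 20L, 5L), total_reads = 185L),
                   class = "DereplicatedSet")
  out4 <- denoise_lite(ds4)
  expect_equal(sum(out4$counts), 185L)
  expect_equal(out4$seqs[1], "AAAAAAAA")
})

test_that("denoise_lite recovers templates from seeded error reads", {
  set.seed(73)
  templates <- c(paste(sample(CANON, 120, TRUE), collapse = ""),
                 paste(sample(CANON, 120, TRUE), collapse = ""))
  sim <- simulate_reads(setNames(templates, c("a", "b")), c(0.6, 0.4),
                        n_reads = 3000, error_rate = 0.003, seed = 99)
  ds <- denoise_lite(dereplicate(sim$reads))
  expect_equal(sort(ds$seqs[1:2]), sort(templates))
  # dominant retained mass sits on the two true templates; the residual is
  # bounded by the multi-error read fraction (1-error reads are absorbed,
  # >= 2-error reads legitimately stay distinct), here P(>=2) ~ 5%
  expect_gt(sum(ds$counts[ds$seqs %in% templates]) / sum(ds$counts), 0.90)
})

test_that("assign_species: identity arithmetic, ties, threshold", {
  panel <- c(spA = strrep("ACGT", 49), spB = paste0(strrep("ACGT", 48), "TTTT"))
  ds <- structure(list(seqs = panel[["spA"]], counts = 10L, total_reads = 10L),
                  class = "DereplicatedSet")
  r <- assign_species(ds, panel)
  expect_equal(r[[1]]$best_ref, "spA")
  expect_equal(r[[1]]$identity_pct, 100)
  # single mismatch on a 196-mer
  q <- panel[["spA"]]
  substr(q, 100, 100) <- "A"
  ds2 <- structure(list(seqs = q, counts = 1L, total_reads = 1L),
                   class = "DereplicatedSet")
  r2 <- assign_species(ds2, panel["spA"])
  expect_equal(r2[[1]]$identity_pct, 100 * 195 / 196, tolerance = 1e-9)
  # equidistant query -> lexicographically first species with tie flag
  p2 <- c(zz = "ACGTACGTAC", aa = "ACGTACGTAG")
  dsq <- structure(list(seqs = "ACGTACGTAT", counts = 1L, total_reads = 1L),
                   class = "DereplicatedSet")
  r3 <- assign_species(dsq, p2)
  expect_equal(r3[[1]]$best_ref, "aa")
  expect_setequal(r3[[1]]$ties, c("aa", "zz"))
  # below min_ident -> unassigned
  far <- structure(list(seqs = strrep("T", 50), counts = 1L, total_reads = 1L),
                   class = "DereplicatedSet")
  expect_equal(assign_species(far, c(spA = strrep("ACG", 40)),
                              min_ident = 90)[[1]]$best_ref, "unassigned")
  # permutation invariance over the panel
  set.seed(79)
  p3 <- c(s1 = paste(sample(CANON, 80, TRUE), collapse = ""),
          s2 = paste(sample(CANON, 80, TRUE), collapse = ""),
          s3 = paste(sample(CANON, 80, TRUE), collapse = ""))
  qds <- structure(list(seqs = p3[["s2"]], counts = 1L, total_reads = 1L),
                   class = "DereplicatedSet")
  for (perm in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))) {
    expect_equal(assign_species(qds, p3[perm])[[1]]$best_ref, "s2")
  }
})

test_that("composition sums, filters below min_prop without renormalizing", {
  mk_asn <- function(sp, ct) {
    Map(function(s, c) structure(list(seq = "A", count = c, best_ref = s,
                                      identity_pct = 100,
                                      ties = character(0)),
                                 class = "AssignmentResult"), sp, ct)
  }
  tab <- composition(mk_asn(c("a", "b", "a", "unassigned"),
                            c(600L, 300L, 95L, 500L)), min_prop = 0.01)
  expect_equal(attr(tab, "total_assigned"), 995L)
  expect_equal(tab$species, c("a", "b"))
  expect_equal(tab$reads, c(695L, 300L))
  expect_equal(sum(tab$proportion), 1)
  # a 0.5% species is removed and proportions keep their pre-filter scale
  tab2 <- composition(mk_asn(c("a", "b"), c(995L, 5L)), min_prop = 0.01)
  expect_equal(tab2$species, "a")
  expect_equal(tab2$proportion, 0.995)
  # single species
  tab3 <- composition(mk_asn("x", 10L))
  expect_equal(tab3$proportion, 1)
})

test_that("read conservation holds through trim -> dereplicate -> denoise", {
  cfg <- small_cfg(seed = 81, n_reads = 500L)
  panel <- simulate_panel(cfg)
  pair <- fixture_pair(cfg)
  amps <- panel_amplicons(panel$records, pair, max_mm = 0)
  sim <- simulate_reads(amps, cfg$weights, cfg$n_reads, cfg$error_rate,
                        seed = 82)
  trimmed <- trim_primers(sim$reads, pair)
  expect_equal(trimmed$n + attr(trimmed, "dropped"), sim$reads$n)
  ds <- dereplicate(trimmed)
  expect_equal(sum(ds$counts), trimmed$n)
  dn <- denoise_lite(ds)
  expect_equal(sum(dn$counts), trimmed$n)
})

test_that("error-free reads from the panel recover the mixture exactly", {
  cfg <- small_cfg(seed = 83, n_reads = 500L, error_rate = 0,
                   weights = c(0.5, 0.2, 0.15, 0.1, 0.05))
  panel <- simulate_panel(cfg)
  pair <- fixture_pair(cfg)
  amps <- panel_amplicons(panel$records, pair, max_mm = 0)
  sim <- simulate_reads(amps, cfg$weights, cfg$n_reads, 0, seed = 84)
  tab <- classify_reads(sim$reads, pair, amps, min_prop = 0)
  got <- setNames(tab$reads, tab$species)
  truth <- sim$truth$counts[sim$truth$counts > 0]
  expect_equal(got[names(truth)], truth)
  expect_equal(attr(tab, "dropped"), 0L)
})
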