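# minibarc

Design and apply mitochondrial **mini-barcodes**: short (100–250 bp) DNA
markers that still amplify from degraded material — dried specimens,
processed traditional-medicine preparations, mixed-ingredient products —
yet carry enough variable sites to separate closely related species. The
motivating system is the medicinal leech panel (*Whitmania pigra*, *Hirudo
nipponia*, *Whitmania acranulata* and their common adulterants), whose five
mitochondrial genomes share a 16S rRNA region where perfectly conserved
primer anchors flank a hypervariable ~196-bp core.

## What it computes

For a panel of per-gene multiple alignments of *n* species:

- **Nucleotide diversity.** Per column,
  `π_c = (# mismatching sequence pairs) / C(n,2)`; per gene, `Π = mean(π_c)`
  over *included* columns (complete deletion: any column with a gap or
  ambiguity in any row is excluded). `Π` equals the mean pairwise
  p-distance over those columns.
- **Sliding windows** (20 bp, step 1): a window is *conserved* iff all 20
  columns are included and monomorphic (`Pi_w = 0`) — the anchor condition
  for a universal primer.
- **Primer pairs** from conserved-stretch consensus: 16–22-mers screened by
  GC (30–60 %), homopolymers (≤ 5), nearest-neighbor Tm (SantaLucia 1998,
  50 mM Na⁺, 250 nM oligo), hairpin/self-dimer/cross-dimer complementarity
  scores; paired under a 100–250 bp insert constraint (insert = region
  between the primers' 3′ ends, measured on a reference species) and
  ranked by the insert's variable-site count.
- **In-silico PCR**: ungapped Hamming annealing (≤ 3 mismatches, exact
  3′-terminal base) and amplicon excision, strand-invariant and idempotent.
- **Metabarcoding composition**: primer trimming → dereplication → greedy
  error absorption (distance ≤ 1, parent ≥ 4× count) → best-hit identity
  against a reference amplicon panel (end-gap-free alignment, +1/−1/−2,
  ≥ 90 % identity) → species table with a 1 % abundance floor.
- **Synthetic fixtures** with planted anchors and known mixture weights, so
  every stage is testable offline against exact truth.

## Worked example

```r
library(minibarc)

cfg   <- default_sim_config(seed = 7)      # 5-species leech-like panel
panel <- simulate_panel(cfg)
aln   <- panel$alignments[["16S"]]

gene_pi(aln)$Pi                            # 0.2644 (hypervariable gene)
cw <- find_conserved_windows(sliding_windows(aln), aln)
#> stretches [737,758) and [946,975): the two planted anchors, extended by
#> the few flanking columns that happen to be monomorphic

pairs <- rank_pairs(pair_primers(enumerate_primers(cw), aln))
head(pairs_table(pairs), 2)
#>   pair role         sequence anchor_start_1based anchor_end_1based insert_bp
#> 1    1    F GAAGACCCTATAAAGC                 742               757       197
#> 2    1    R TTAAGTCAACATCGAG                 955               970       197
#>   variable_sites gc_pct tm_c tm_diff cross_dimer min_pair_diff
#> 1            103   43.8 41.3    0.01           2            46
#> 2            103   37.5 41.4    0.01           2            46
```

The top-ranked pair sits on the planted anchors and spans a 197-bp insert
with 103 variable sites; every species pair differs at ≥ 46 positions, so
all five species are resolvable. Now validate it by in-silico PCR and
recover a known mixture from 10,000 error-bearing reads (ε = 0.005):

```r
pp   <- fixture_pair(cfg)                  # the planted 741F/943R pair
amps <- panel_amplicons(panel$records, pp, max_mm = 0)
sim  <- simulate_reads(amps, cfg$weights, 10000, 0.005, seed = 8)
classify_reads(sim$reads, pp, amps)
#>   species reads proportion
#> 1    sp02  2026     0.2026
#> 2    sp05  2016     0.2016
#> 3    sp03  2013     0.2013
#> 4    sp01  2006     0.2006
#> 5    sp04  1939     0.1939
```

Each of the five equal 20 % weights is recovered within ±0.007 — the
simulated sequencing error is fully absorbed by the denoise/assignment
stages.

A command-line front end wraps the same steps
(`scan / design / ispcr / classify / simulate`):

```sh
Rscript -e 'quit(status = minibarc::minibarc_cli())' \
  scan --alignment 16S.aln.fasta --out profile
```

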