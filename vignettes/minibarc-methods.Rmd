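---
title: "Mini-barcode design and metabarcoding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mini-barcode design and metabarcoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minibarc)
```

## The problem

Species identification of processed animal material (dried, heat-treated,
or compounded into multi-ingredient preparations) fails with standard DNA
barcodes such as the ~650-bp *COI* fragment, because the template is too
degraded to amplify. A *mini-barcode* is a 100–250-bp marker that still
amplifies from fragmented DNA yet carries enough variable sites to separate
closely related species. The motivating application is medicinal leech
material, where a handful of congeneric species (genuine *Whitmania pigra*,
*Hirudo nipponia*, *Whitmania acranulata* and common adulterants) must be
told apart in mixtures.

minibarc implements the complete in-silico arm of that workflow:

1. **scan** — per-gene nucleotide diversity (π) and a sliding-window profile
   over a panel of aligned mitochondrial genes;
2. **design** — detection of perfectly conserved anchor windows, primer
   enumeration from their consensus, thermodynamic screening, and pairing
   under amplicon-length constraints;
3. **ispcr** — mismatch-tolerant in-silico PCR to validate candidates on
   unaligned genomes;
4. **classify** — composition estimation of an amplicon read mixture against
   a reference amplicon panel;
5. **simulate** — a fully specified generator so that every stage can be
   tested offline against exact truth records.

## Nucleotide diversity

For an alignment of $n$ sequences, the per-column diversity is the fraction
of unordered sequence pairs that differ at the column,

$$\pi_c \;=\; \binom{n}{2}^{-1} \sum_{i<j} \mathbf{1}[x_{ic} \neq x_{jc}],$$

and the gene-wide value $\Pi$ is the mean of $\pi_c$ over *included*
columns, which equals the mean pairwise p-distance over those columns (the
test suite asserts this identity against a brute-force pairwise oracle at
$10^{-12}$).

**Gap and ambiguity handling** is *complete deletion*: any column carrying a
gap or IUPAC ambiguity code in any row is excluded. This matches the default
of the classical population-genetics software this analysis style comes
from; a `pairwise` deletion mode is provided but off by default. Which mode
the original analyses used is rarely reported, so gene-level π values are
only comparable at alignment-protocol tolerance (we use ±0.01 where we
compare at all).

**Sliding windows** are 20 columns wide with step 1 — 20 bp because that is
an anchor wide enough to seat a primer, step 1 so no anchor placement is
missed. Windows are indexed on *alignment columns*, not on any one
sequence's ungapped coordinates. A window is **conserved** only when all 20
columns are included *and* monomorphic: a primer cannot span an indel, so a
gap column disqualifies a window even if the non-gap rows agree.

## Primer design

Conserved windows overlapping by the step are merged into maximal conserved
stretches; every substring with length 16–22 nt becomes a candidate in both
orientations. (16–22 brackets the published 16–20-nt leech primers with one
extra unit of slack.) Candidates are screened by:

* GC content 30–60 %, homopolymer runs ≤ 5 — conventional ranges;
* melting temperature — default SantaLucia (1998) unified nearest-neighbor
  parameters with the entropic salt correction
  $\Delta S' = \Delta S + 0.368\,(L-1)\ln[\mathrm{Na^+}]$ at 50 mM Na⁺ and
  250 nM oligo; the Wallace rule $2(A{+}T)+4(G{+}C)$ is available as an
  option. The published primer Tm values came from a proprietary tool whose
  formula is undisclosed, so we treat them only as a ±8 °C sanity envelope,
  never as an exactness target;
* duplex scores — hairpin, self-dimer and cross-dimer are the maximum
  antiparallel complementarity over all ungapped offsets (match +1, doubled
  when the pair involves either oligo's 3′-terminal base; mismatch −1;
  hairpins additionally require a ≥ 3-nt loop). This is a deliberate
  alignment-style surrogate for full secondary-structure thermodynamics.
  The thresholds (hairpin ≤ 4, self/cross-dimer ≤ 8) were calibrated once
  against external published barcode primers — all eight published leech
  16S primers score hairpin ≤ 4 and self-dimer ≤ 7 and must pass, while a
  perfect reverse-complement palindrome (self-dimer 10) must fail.

**Pairing.** A forward candidate pairs with any reverse candidate anchored
strictly downstream on the same gene. The insert (the mini-barcode proper,
"sequence excluding primers") is measured between the primers' 3′ ends in
the *ungapped coordinates of a designated reference species* (default: the
first alignment row), because a single length is conventionally reported per
pair even when species differ by indels; all per-species lengths are kept
alongside. Accepted inserts span 100–250 bp, |ΔTm| ≤ 5 °C.

**Variable sites** in the insert count every column with ≥ 2 distinct
states, with the gap as a fifth state, so indel columns are variable. The
published counts never state whether indel columns were included; the
alternative convention (ignore gaps) is switchable (`gap_as_state = FALSE`)
and the accession-dependent validation accepts either before failing.

**Ranking** is descending by variable sites, then smaller |ΔTm|, then insert
length closest to 175 bp (the midpoint of the mini-barcode range), then
lexicographic primer sequence — a total order, so results are independent of
input order.

One published inconsistency is preserved as-is: for the fourth leech primer
pair the table prints a 148-bp insert while the running text says 151 bp;
`leech_primer_table()` carries both columns.

## In-silico PCR

Annealing is modeled as ungapped Hamming matching with ≤ `max_mm`
mismatches (default 3 — tolerant of intra-species variation while excluding
off-target genes) and an exact match required at the 3′-terminal base
(default 1), since extension cannot start from a 3′ mismatch. IUPAC codes on
the template accept a primer base iff the base is in the code's set.
Products pair a forward-sense site with a downstream reverse-sense site on
either strand; the insert is normalized to the forward primer's sense, which
makes amplification invariant to reverse-complementing the template and
idempotent on its own product (both properties are tested). In *panel mode*
each reference template must yield exactly one product, because reference
barcodes must be unambiguous.

## Classification of read mixtures

* **Trimming**: a read is kept when (in either orientation) its prefix
  matches the forward primer and its suffix the reverse primer's reverse
  complement, each within 2 mismatches; both primer copies are removed.
  Dropped reads are counted, and trim → dereplicate → denoise conserves
  reads exactly.
* **Denoise-lite**: uniques in descending count order are absorbed into an
  already-retained sequence within Hamming distance 1 whose original count
  is ≥ 4× larger. This is an explicit, documented stand-in for a full
  amplicon error model (DADA2-class): it recovers planted templates from
  simulated error reads but makes no claim of reproducing real ASV counts.
  Chimera removal is intentionally absent (the simulator does not generate
  chimeras); a flag position is reserved.
* **Assignment**: best-hit percent identity under end-gap-free global
  alignment (match +1, mismatch −1, gap −2), `identity =
  100·matches/alignment length`; ties are recorded and broken
  lexicographically; identities below 90 % are `unassigned`. Note that
  end-gap-free alignment forgives terminal overhangs — a deliberate choice
  for fragments whose ends may be ragged.
* **Composition**: read counts per species over *assigned* reads; species
  below 1 % are removed *without renormalizing*, mirroring the reporting
  convention of the motivating study (retained proportions may sum to
  < 1).

The published mock-community proportions (30.29/35.77/3.66/2.25/28.02 %
against a nominal 20 % each) reflect blood-meal DNA contamination in two
blood-feeding species and are *not computationally reproducible*; they are
documented here, not targeted.

## The synthetic world

The generator states its world once and the tests live in it:

* 5 species; per gene an ancestral sequence uniform over A/C/G/T; each
  species substitutes each non-anchor site independently with probability
  θ (to a uniformly chosen different base); anchor columns are copied
  verbatim, so they are Pi = 0 windows by construction.
* Default gene set mirrors the leech panel's diversity ladder: a
  hypervariable ATP6-like gene (θ = 0.34), ATP8-like (0.24), ND4L-like
  (0.21), and a 16S-like gene (0.15) carrying two planted 20-column anchors
  whose planted primers are the published 741F/943R pair flanking a 196-nt
  core — the published mini-barcode geometry.
* Read mixtures: equal weights by default, N = 10,000, per-base error
  ε = 0.005 (a realistic post-merge short-read substitution rate), species
  drawn categorically, full amplicons emitted.
* Two expected-value identities anchor the tests: the pairwise p-distance at
  a non-anchor site is $2\theta(1-\theta) + \tfrac{2}{3}\theta^2$, and
  per-species read counts are Multinomial(N, w) (both checked at 3σ).

Because flanking background columns can be monomorphic by chance
(probability $(1-\theta)^5$ per column under equal ancestry), a detected
conserved stretch may legitimately extend a column or two beyond a planted
anchor. The recovery criterion therefore compares detected stretches to the
*realized* maximal monomorphic runs (computed by an independent run-length
oracle) and requires a one-to-one containment match with the planted
anchors — precision and recall are both 1 on every tested seed, without any
boundary slack parameter.

What a green test does **not** establish: realism of phylogenetic structure
(sites are i.i.d.; there is no rate heterogeneity, no coalescent), quality
score structure, chimeras, or abundance biases such as blood-meal
contamination. Indel planting (optional, geometric lengths) exercises gap
handling only.

## Reference panel and offline limits

The five published leech mitogenomes (RefSeq NC_023776, NC_023925,
NC_023928, NC_023926, NC_013569) are not shipped; `inst/scripts/
fetch_accessions.sh` fetches them, after which `leech_panel_records()` /
`leech_panel_alignments()` (extraction + MAFFT) feed the accession-dependent
acceptance checks (genome feature table, π ranking ATP6 > ATP8 > ND4L > 16S,
741F/943R insert length and variable-site counts). In a fully offline
environment these checks fail with an explicit diagnostic rather than being
skipped; everything desk-scale runs from generated data.

## Numerical and design choices, collected

* Coordinates are 0-based half-open internally; reports are 1-based
  inclusive.
* π is undefined (error) on fully excluded alignments; windows with no
  included column report `Pi_w = NA`.
* `U` is normalized to `T`; gene names resolve through an alias table
  (cox1/COI, 16S/rrnL/"16 S rRNA", ...); duplicated tRNA names are
  disambiguated by coordinate order via the `which` argument.
* Mitogenome circularity is ignored for extraction; an origin-spanning
  feature is an error, not a silent wraparound (the panel has none).
* All stochastic components take explicit integer seeds; identical seeds
  give byte-identical fixture files.
* Primer enumeration emits *every* substring of a conserved stretch in the
  length range (15 for a 20-mer stretch at range 16–20), not only
  end-anchored ones.
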