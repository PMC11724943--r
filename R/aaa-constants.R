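# Shared alphabet constants; this file sorts first so every other file can
# use them at source time.

# Allowed residue alphabet: canonical bases, IUPAC ambiguity codes, gap.
MB_ALPHABET <- c("A", "C", "G", "T",
                 "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

# IUPAC code -> set of canonical bases it stands for.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# 16x4 lookup: does template character t accept primer base p?
.iupac_match_table <- local({
  tab <- matrix(FALSE, nrow = length(MB_ALPHABET), ncol = 4,
                dimnames = list(MB_ALPHABET, c("A", "C", "G", "T")))
  for (t in names(IUPAC_SETS)) tab[t, IUPAC_SETS[[t]]] <- TRUE
  tab
})
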