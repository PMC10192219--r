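# Shared fixtures and independent oracles, all built in code.

# --- atomic-composition oracle for residue masses ------------------------
# Monoisotopic element masses (CODATA); residues as elemental formulas so the
# package's mass tables can be checked against an independent route.
.elem <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
           O = 15.9949146221, S = 31.97207069)

.residueFormulas <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),  T = c(C = 4, H = 7, N = 1, O = 2),
  # Cys as carbamidomethyl-Cys: C3H5NOS + C2H3NO
  C = c(C = 5, H = 8, N = 2, O = 2, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),  M = c(C = 5, H = 9, N = 1, O = 1,
                                            S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1))

formulaMass <- function(formula) sum(.elem[names(formula)] * formula)

# Oracle neutral mass of an unmodified free-acid peptide from atomic sums.
oracleFreeAcidMass <- function(sequence) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  sum(vapply(res, function(a) formulaMass(.residueFormulas[[a]]),
             numeric(1))) + formulaMass(c(H = 2, O = 1))
}

# --- reverse translation for deterministic toy ORFs ----------------------
.codonFor <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
               Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
               L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCG",
               S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

cdsFor <- function(protein) {
  res <- strsplit(protein, "", fixed = TRUE)[[1L]]
  stopifnot(res[1L] == "M")
  paste0(paste(.codonFor[res], collapse = ""), "TAA")
}

toyOrfs <- function(proteins, tpm = NULL) {
  cds <- vapply(proteins, cdsFor, character(1))
  names(cds) <- if (is.null(names(proteins)))
    sprintf("g%02d", seq_along(proteins)) else names(proteins)
  orfsFromSequences(cds, tpm = tpm)
}

# --- all-pairs matching oracle -------------------------------------------
# Naive reference: for each peak scan every reference mass; cognate
# precedence; best candidate by |dppm|, then gene_id, then sequence.
naiveClassify <- function(masses, cogDb, subDb, tolPpm) {
  cog <- refTable(cogDb)
  sub <- refTable(subDb)
  vapply(masses, function(m) {
    dC <- abs(m - cog$neutral_mass) / cog$neutral_mass * 1e6
    if (any(dC <= tolPpm)) return("cognate")
    dS <- abs(m - sub$neutral_mass) / sub$neutral_mass * 1e6
    hit <- which(dS <= tolPpm)
    if (!length(hit)) return("unassigned")
    hit <- hit[order(dS[hit], sub$gene_id[hit], sub$sequence[hit])]
    classifySubstitution(sub$sub_offset[hit[1L]])
  }, character(1))
}

# Random free-acid peptide sequences for property tests.
randomPeptides <- function(n, minLen = 3L, maxLen = 12L) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  vapply(seq_len(n), function(i)
    paste(sample(aa, sample(minLen:maxLen, 1L), replace = TRUE),
          collapse = ""), character(1))
}
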