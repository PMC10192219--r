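test_that("drop-off codon tallies count planted codons exactly", {
  orfs <- toyOrfs(c(rplJ = "MALNLQDKQAIV", lpp = "MKATKLVLG"))
  # trimmed rplJ heptamer drops off at codon 8, which encodes K = AAA
  rec <- data.frame(
    gene_id = c("rplJ", "rplJ", "lpp"),
    class = c("cognate", "C0X", "cognate"),
    dropoff_pos = c(8L, 8L, 4L),
    stringsAsFactors = FALSE)
  tal <- dropoffCodonTally(rec, orfs, class = "cognate")
  expect_equal(sum(tal), 2)
  expect_equal(tal[["AAA"]], 1)  # rplJ codon 8
  expect_equal(tal[["ACU"]], 1)  # lpp codon 4 (T)
  c0 <- dropoffCodonTally(rec, orfs, class = "C0X")
  expect_equal(c0[["AAA"]], 1)
  expect_equal(sum(c0), 1)
  # offset 0 via the adjacent helper parameterisation
  expect_identical(dropoffCodonTally(rec, orfs, offset = 0L),
                   dropoffCodonTally(rec, orfs))
  adj <- adjacentCodonTally(rec, orfs, class = "cognate")
  expect_equal(adj[["CAA"]], 1)  # rplJ codon 9 (Q)
  # positions beyond the ORF are skipped with a warning
  rec2 <- rbind(rec, data.frame(gene_id = "lpp", class = "cognate",
                                dropoff_pos = 50L))
  expect_warning(t2 <- dropoffCodonTally(rec2, orfs), "outside")
  expect_equal(sum(t2), 3)
  expect_equal(sum(dropoffCodonTally(rec[0, ], orfs)), 0)
})

test_that("TPM-weighted usage weights windows by expression share", {
  # two ORFs with constant codon bodies: GAA-only vs CTG-only
  cds <- c(hi = paste0("ATG", strrep("GAA", 20), "TAA"),
           lo = paste0("ATG", strrep("CTG", 20), "TAA"))
  orfs <- orfsFromSequences(cds, tpm = c(hi = 100, lo = 100))
  u <- tpmWeightedUsage(orfs, c(5, 17))
  expect_equal(u[["GAA"]], 0.5)
  expect_equal(u[["CUG"]], 0.5)
  expect_equal(sum(u), 1)
  # invariant to global TPM rescaling; sensitive to relative shares
  orfs10 <- orfs; orfs10$tpm <- orfs10$tpm * 10
  expect_equal(tpmWeightedUsage(orfs10, c(5, 17)), u)
  orfs2 <- orfs; orfs2$tpm <- c(300, 100)
  expect_equal(tpmWeightedUsage(orfs2, c(5, 17))[["GAA"]], 0.75)
  # brute-force agreement on a random toy ORFeome
  cfg <- simConfig(seed = 13, nOrfs = 10L, orfLengthCodons = c(20L, 30L))
  ro <- simulateOrfeome(cfg)
  got <- tpmWeightedUsage(ro, c(5, 12))
  codons <- senseCodons()
  brute <- setNames(numeric(length(codons)), codons)
  w <- ro$tpm / sum(ro$tpm)
  for (i in seq_len(nrow(ro))) {
    for (p in 5:min(12, nchar(ro$protein[i]))) {
      cd <- chartr("T", "U", substr(ro$cds[i], 3 * p - 2, 3 * p))
      brute[cd] <- brute[cd] + w[i]
    }
  }
  expect_equal(got, brute / sum(brute), ignore_attr = TRUE)
  ro$tpm <- 0
  expect_error(tpmWeightedUsage(ro, c(5, 12)), "TPM")
})

test_that("GC groups count strong bases per codon", {
  expect_identical(gcGroup(c("AAA", "GCG", "AUG", "ggc")),
                   c(0L, 3L, 1L, 3L))
  expect_error(gcGroup("AAAA"), "triplet")
})

test_that("mismatch counting pairs codon i with anticodon 4-i", {
  expect_identical(mismatchCount("AAA", "UUU")$mismatches, 0L)
  expect_identical(mismatchCount("AAA", "UUU")$class, "cognate")
  # Lys codon read by the Ile anticodon GAU: positions 2 and 3 mismatch
  m <- mismatchCount("AAA", "GAU")
  expect_identical(m$mismatches, 2L)
  expect_identical(m$class, "multiple")
  # single mismatch is near-cognate
  expect_identical(mismatchCount("AAG", "UUU")$class, "near_cognate")
  # wobble policy: G.U / U.G at codon position 3 only
  expect_identical(mismatchCount("GGU", "GCC", wobble = TRUE)$mismatches, 0L)
  expect_identical(mismatchCount("GGU", "GCC", wobble = FALSE)$mismatches,
                   1L)
  expect_identical(mismatchCount("UGG", "CCG", wobble = TRUE)$mismatches,
                   1L)  # wobble never applies at codon position 1
  # DNA input accepted; invalid bases rejected
  expect_identical(mismatchCount("aaa", "TTT")$mismatches, 0L)
  expect_error(mismatchCount("AAX", "UUU"), "invalid nucleotide")
})

test_that("codon-tally R2 is scale-invariant with exclusion support", {
  x <- dropoffCodonTally(
    data.frame(gene_id = "g", class = "cognate", dropoff_pos = 3L),
    toyOrfs(c(g = "MAKL")))
  expect_equal(codonTallyR2(x, x), 1)
  expect_equal(codonTallyR2(x, x * 13), 1)
  # brute-force check on simple planted tallies
  codons <- senseCodons()
  a <- setNames(numeric(61), codons); b <- a
  a[c("AAA", "GCU", "CAU")] <- c(10, 5, 1)
  b[c("AAA", "GCU", "CAU")] <- c(1, 5, 10)
  fa <- a / sum(a); fb <- b / sum(b)
  expect_equal(codonTallyR2(a, b), cor(fa, fb)^2)
  # excluding a dominant codon changes the statistic as a recompute would
  keep <- setdiff(codons, "AAA")
  expect_equal(codonTallyR2(a, b, exclude = "AAA"),
               cor(a[keep] / sum(a[keep]), b[keep] / sum(b[keep]))^2)
})

test_that("usage deviation is zero for the full window, larger early", {
  cfg <- simConfig(seed = 17, nOrfs = 60L, orfLengthCodons = c(40L, 40L),
                   earlyAUBias = 1.5)
  orfs <- simulateOrfeome(cfg)
  # window covering all counted positions: every ratio 1, sigma 0
  full <- usageDeviation(orfs, c(2L, 40L))
  expect_equal(unname(full$ratio), rep(1, length(full$ratio)),
               tolerance = 1e-12)
  expect_equal(full$sigma, 0, tolerance = 1e-12)
  # planted early AU bias: the 2-8 window deviates more than 9-15
  early <- usageDeviation(orfs, c(2L, 8L))
  late <- usageDeviation(orfs, c(9L, 15L))
  expect_gt(early$sigma, late$sigma)
})

test_that("ORF grouping partitions the top-TPM set by early drop-off", {
  orfs <- toyOrfs(c(a = "MAKLVGDEAR", b = "MKWTVLGDEA", c = "MGGLVKDEAR",
                    d = "MAALVKDEAR", e = "MWWLVKDEAR"),
                  tpm = c(a = 500, b = 400, c = 300, d = 200, e = 10))
  rec <- data.frame(gene_id = c("a", "b", "b", "c"),
                    class = "cognate",
                    dropoff_pos = c(5L, 9L, 6L, 10L),
                    stringsAsFactors = FALSE)
  g <- orfGrouping(rec, orfs, tpmQuantile = 0, earlyPositions = c(5L, 6L))
  expect_setequal(g$gene_id, orfs$gene_id)
  expect_identical(g$group[g$gene_id == "a"], 1L)  # early drop-off
  expect_identical(g$group[g$gene_id == "b"], 1L)  # any early detection
  expect_identical(g$group[g$gene_id == "c"], 2L)  # late only
  expect_identical(g$group[g$gene_id == "d"], 3L)  # none detected
  # quantile cut restricts the evaluated set, groups stay exhaustive
  g8 <- orfGrouping(rec, orfs, tpmQuantile = 0.8)
  expect_identical(nrow(g8), 1L)
  expect_identical(g8$gene_id, "a")
  # no detections at all: everything in group 3
  g0 <- orfGrouping(rec[0, ], orfs, tpmQuantile = 0)
  expect_true(all(g0$group == 3L))
})

test_that("amino-acid frequency comparison flags planted depletion", {
  orfs <- toyOrfs(c(a = "MFYWAKLVGD", b = "MFYWAKLVGD"))
  # peptides re-using the ORF window composition give ratios of 1
  win <- substring(orfs$protein, 2, 10)
  cmp <- aaFrequencyComparison(win, orfs, c(2L, 10L))
  expect_equal(sum(cmp$peptide_freq), 1)
  expect_equal(sum(cmp$orf_freq), 1)
  present <- cmp$orf_freq > 0
  expect_equal(cmp$ratio[present], rep(1, sum(present)))
  # peptides avoiding the bulky residues: F/Y/W ratios below 1
  dep <- aaFrequencyComparison(c("AKLVGD", "AKLVG", "KLVGD"), orfs,
                               c(2L, 10L))
  bulky <- dep$residue %in% c("F", "Y", "W")
  expect_true(all(dep$ratio[bulky] < 1 | is.na(dep$ratio[bulky])))
  expect_true(all(dep$peptide_freq[bulky] == 0))
})
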