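makePeaks <- function(masses) {
  asPeakTable(data.frame(mass = masses))
}

test_that("noise subtraction partitions peaks against the control list", {
  peaks <- makePeaks(c(500.0000, 800.0, 900.0))
  ctrl <- makePeaks(c(500.0015, 123.4))
  parts <- subtractNoise(peaks, ctrl, tolPpm = 5)
  expect_identical(parts$removed$neutral_mass, 500.0000)  # 3 ppm away
  expect_identical(nrow(parts$kept) + nrow(parts$removed), nrow(peaks))
  # identical lists: everything removed; far-apart lists: nothing removed
  same <- subtractNoise(peaks, peaks, 5)
  expect_identical(nrow(same$kept), 0L)
  far <- subtractNoise(peaks, makePeaks(c(200.0, 300.0)), 5)
  expect_identical(nrow(far$removed), 0L)
  expect_warning(noctrl <- subtractNoise(peaks, peaks[0, ], 5), "empty")
  expect_identical(nrow(noctrl$kept), nrow(peaks))
  expect_error(subtractNoise(peaks, ctrl, 0), "positive")
})

test_that("matching applies cognate precedence and exact classification", {
  tb <- residueMassTable()
  orfs <- toyOrfs(c(rep = "MWGIVK"))
  cog <- buildCognateDb(orfs, 3, 6, tb)
  sub <- buildSubstitutionDb(cog, "all", tb)

  ct <- refTable(cog)
  mwgi <- ct$neutral_mass[ct$sequence == "MWGI"]  # byte-identical db mass
  mwgm <- peptideMass("MWGM", tb)
  mwgmv <- peptideMass("MWGMV", tb)
  res <- matchPeaks(makePeaks(c(mwgi, mwgm, mwgmv, 2000)), cog, sub, 5)
  rec <- matchRecords(res)
  expect_identical(rec$class, c("cognate", "C0X", "C-1X", "unassigned"))
  expect_identical(rec$delta_ppm[1L], 0)       # exact cognate match
  expect_identical(rec$sequence[2L], "MWGM")
  expect_identical(rec$sub_offset[3L], 1L)
  expect_identical(rec$sequence[3L], "MWGMV")
  # a peak matching both databases is cognate under the default precedence
  both <- matchPeaks(makePeaks(mwgi), cog, sub, 500)
  expect_identical(matchRecords(both)$class, "cognate")
})

test_that("offset labels map to classes and reject cognate input", {
  expect_identical(classifySubstitution(c(0L, 1L, 2L, 3L, 5L)),
                   c("C0X", "C-1X", "C-2X", "C-3X", "C-kX"))
  expect_error(classifySubstitution(NA_integer_), "contract")
})

test_that("partition holds and matches never increase as tolerance shrinks", {
  cfg <- simConfig(seed = 5, nOrfs = 15L, nPeaks = 300L,
                   orfLengthCodons = c(20L, 35L))
  orfs <- simulateOrfeome(cfg)
  sim <- simulateDropoffPeaks(orfs, cfg)
  cog <- buildCognateDb(orfs, cfg$minLen, cfg$maxLen)
  sub <- buildSubstitutionDb(cog, 0:3)
  prev <- Inf
  for (tol in c(20, 5, 1, 0.1)) {
    rec <- matchRecords(matchPeaks(sim$peaks, cog, sub, tol))
    tab <- table(factor(rec$class, levels = classLevels()))
    expect_identical(sum(tab), nrow(sim$peaks))  # exhaustive partition
    matched <- nrow(sim$peaks) - tab[["unassigned"]]
    expect_lte(matched, prev)
    prev <- matched
  }
})

test_that("sorted-index matcher agrees with the all-pairs oracle", {
  cfg <- simConfig(seed = 9, nOrfs = 8L, nPeaks = 150L,
                   orfLengthCodons = c(20L, 30L))
  orfs <- simulateOrfeome(cfg)
  sim <- simulateDropoffPeaks(orfs, cfg)
  cog <- buildCognateDb(orfs, cfg$minLen, cfg$maxLen)
  sub <- buildSubstitutionDb(cog, 0:1)
  expect_lte(nrow(refTable(cog)) + nrow(refTable(sub)), 1e4)
  got <- matchRecords(matchPeaks(sim$peaks, cog, sub, 5))$class
  want <- naiveClassify(sim$peaks$neutral_mass, cog, sub, 5)
  expect_identical(got, unname(want))
})

test_that("matching is deterministic with documented tie-breaks", {
  tb <- residueMassTable()
  # two genes sharing an identical peptide: tie at equal |dppm|, broken by
  # gene id, and the peak is counted once
  orfs <- toyOrfs(c(zeta = "MAKLV", alpha = "MAKLV"))
  cog <- buildCognateDb(orfs, 3, 5, tb)
  res <- matchPeaks(makePeaks(peptideMass("MAKL", tb)), cog, NULL, 5)
  rec <- matchRecords(res)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$gene_id, "alpha")
  expect_identical(rec$n_candidates, 2L)
  cand <- matchCandidates(res)
  expect_identical(cand$gene_id[order(cand$rank)], c("alpha", "zeta"))
  # byte-identical reruns
  r2 <- matchPeaks(makePeaks(peptideMass("MAKL", tb)), cog, NULL, 5)
  expect_identical(matchRecords(res), matchRecords(r2))
})

test_that("class summaries report counts, proportions and medians", {
  rec <- data.frame(
    peak_id = sprintf("p%d", 1:6),
    neutral_mass = c(500, 600, 700, 800, 900, 1000),
    class = c("cognate", "cognate", "cognate", "C0X", "C-1X", "unassigned"),
    stringsAsFactors = FALSE)
  s <- summarizeClasses(rec)
  expect_identical(sum(s$n), 6L)
  expect_equal(sum(s$proportion), 1)
  expect_equal(s$median_mass[s$class == "cognate"], 600)
  one <- summarizeClasses(rec[4, ])
  expect_equal(one$proportion, 1)
  expect_error(summarizeClasses(rec[0, ]), "no records")
})

test_that("positional distributions are cumulative and exact on truth", {
  rec <- data.frame(
    class = c(rep("C0X", 4), "cognate"),
    dropoff_pos = c(5L, 9L, 7L, 5L, 12L),
    stringsAsFactors = FALSE)
  pd <- positionalDistribution(rec)
  c0 <- pd[pd$class == "C0X", ]
  expect_identical(c0$n[c0$dropoff_pos == 5L], 2L)
  expect_true(all(diff(c0$cum_fraction) >= 0))
  expect_equal(max(c0$cum_fraction), 1)
  # all C0X records within 5-9: cumulative fraction at 9 is 1
  expect_equal(c0$cum_fraction[c0$dropoff_pos == 9L], 1)
  empty <- positionalDistribution(rec[0, c("class", "dropoff_pos")])
  expect_identical(nrow(empty), 0L)
})
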