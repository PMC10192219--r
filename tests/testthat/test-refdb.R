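test_that("ORF validation accepts alternative starts and rejects bad CDSs", {
  good <- c(a = "ATGGCTAAACTGTAA",      # M A K L
            b = "GTGGCTAAATAA",         # GTG start, initiator forced to M
            c = "TTGAAAGCTTAA")
  orfs <- orfsFromSequences(good)
  expect_identical(orfs$protein, c("MAKL", "MAK", "MKA"))
  expect_identical(nchar(orfs$cds) / 3 - 1, nchar(orfs$protein) + 0)
  bad <- c(ok = "ATGGCTAAACTGTAA",
           nostart = "CTGGCTAAATAA",
           internalstop = "ATGTAAGCTTAA",
           offframe = "ATGGCTAA",
           nostop = "ATGGCTAAACTG")
  expect_warning(orfs2 <- orfsFromSequences(bad), "4 malformed")
  expect_identical(orfs2$gene_id, "ok")
})

test_that("cognate DB follows the length range, MAP rule and conventions", {
  # protein length 20, MAP-eligible second residue (A)
  orfs <- toyOrfs(c(rplJ = "MALNLQDKQAIVAEVSEVAK"))
  db <- buildCognateDb(orfs, 3, 14)
  refs <- refTable(db)
  expect_identical(nrow(refs), 24L)  # 12 retained-Met + 12 trimmed
  # trimmed heptamer covers codons 2-8: drop-off at the eighth codon
  hep <- refs[refs$sequence == "ALNLQDK", ]
  expect_identical(nrow(hep), 1L)
  expect_true(hep$met_trimmed)
  expect_identical(hep$dropoff_pos, 8L)
  # trimmed refs share the drop-off position of the equal-C-terminus
  # retained-Met sibling (where that sibling is inside the length range)
  for (i in which(refs$met_trimmed & nchar(refs$sequence) < 14L)) {
    sib <- refs[!refs$met_trimmed &
                  nchar(refs$sequence) == nchar(refs$sequence[i]) + 1L, ]
    expect_true(refs$dropoff_pos[i] %in% sib$dropoff_pos)
  }
  # K at position 2 is not a MAP substrate: no trimmed variants
  orfs2 <- toyOrfs(c(lpp = "MKATKLVLGAVILGST"))
  refs2 <- refTable(buildCognateDb(orfs2, 3, 14))
  expect_false(any(refs2$met_trimmed))
  expect_true("MKATKL" %in% refs2$sequence)
  expect_error(buildCognateDb(orfs, 1, 14), "minLen")
})

test_that("cognate DB size matches the brute-force closed form", {
  set.seed(11)
  prots <- paste0("M", randomPeptides(12, 6, 20))
  orfs <- toyOrfs(prots)
  for (rng in list(c(3L, 14L), c(4L, 10L))) {
    db <- buildCognateDb(orfs, rng[1L], rng[2L])
    expected <- sum(vapply(orfs$protein, function(p) {
      L <- nchar(p)
      nU <- max(0L, min(rng[2L], L) - rng[1L] + 1L)
      nT <- if (mapEligible(substring(p, 2L, 2L)))
        max(0L, min(rng[2L], L - 1L) - rng[1L] + 1L) else 0L
      nU + nT
    }, integer(1)))
    expect_identical(nrow(refTable(db)), as.integer(expected))
    # no duplicate (gene, sequence, trimmed, substitution) tuples
    key <- with(refTable(db), paste(gene_id, sequence, met_trimmed))
    expect_false(anyDuplicated(key) > 0)
  }
})

test_that("substitution DB enumerates mass-distinct single substitutions", {
  tb <- residueMassTable()
  orfs <- toyOrfs(c(g = "MII"))
  cog <- buildCognateDb(orfs, 3, 3)
  sub <- refTable(buildSubstitutionDb(cog, "all"))
  # 3 positions x 19 residues minus the mass-degenerate I->L at two sites
  expect_identical(nrow(sub), 55L)
  expect_false(any(sub$sub_from == sub$sub_to))
  parent <- refTable(cog)$sequence
  for (i in seq_len(nrow(sub))) {
    d <- which(strsplit(sub$sequence[i], "")[[1L]] !=
                 strsplit(parent, "")[[1L]])
    expect_length(d, 1L)
    expect_identical(nchar(sub$sequence[i]) - d, sub$sub_offset[i])
  }
  expect_true(all(abs(sub$neutral_mass - refTable(cog)$neutral_mass) > 0))
  key <- with(sub, paste(gene_id, sequence, met_trimmed, sub_offset))
  expect_false(anyDuplicated(key) > 0)
})

test_that("substitution variants reproduce the reporter and rplJ cases", {
  orfs <- toyOrfs(c(rep = "MWGIVK", rplJ = "MALNLQDKQAIV"))
  cog <- buildCognateDb(orfs, 3, 8)
  # C-terminal substitution of the MWGI tetramer includes MWGM
  sub0 <- refTable(buildSubstitutionDb(cog, 0L))
  expect_true(any(sub0$sequence == "MWGM" & sub0$sub_offset == 0L))
  # penultimate-site D->N on the trimmed rplJ heptamer
  subAll <- refTable(buildSubstitutionDb(cog, c(0L, 1L)))
  hit <- subAll[subAll$sequence == "ALNLQNK", ]
  expect_identical(hit$sub_offset, 1L)
  expect_identical(hit$sub_from, "D")
  expect_identical(hit$sub_to, "N")
  expect_identical(hit$dropoff_pos, 8L)
  expect_error(buildSubstitutionDb(buildCognateDb(orfs[0, ], 3, 8)),
               "empty cognate")
})

test_that("search FASTA export masks wildcards and splits by length", {
  orfs <- toyOrfs(c(rplJ = "MALNLQDKQAIVAEVSE"))
  db <- buildCognateDb(orfs, 4, 12)
  expect_warning(fa <- exportSearchFasta(db, file = NULL,
                                         wildcardPositions = 0L),
                 "overlapping")
  expect_true("ALNLQDX" %in% fa[["4-10"]])
  # a length-10 peptide appears in both overlapping files
  len10 <- refTable(db)$sequence[nchar(refTable(db)$sequence) == 10L][1L]
  masked <- paste0(substr(len10, 1, 9), "X")
  expect_true(masked %in% fa[["4-10"]] && masked %in% fa[["10-16"]])
  # empty wildcard set gives plain cognate sequences in one file
  fa2 <- exportSearchFasta(db, file = NULL, lengthSplit = list(c(4L, 12L)))
  expect_true("ALNLQDK" %in% fa2[["4-12"]])
  expect_match(fa2[["4-12"]][1L], "^>rplJ\\|pos")
})

test_that("reference databases round-trip through TSV", {
  orfs <- toyOrfs(c(g1 = "MAKLVGDE", g2 = "MWGIVK"))
  db <- buildSubstitutionDb(buildCognateDb(orfs, 3, 6), 0:1)
  path <- tempfile(fileext = ".tsv")
  writeRefDb(db, path)
  back <- readRefDb(path)
  expect_identical(back@kind, "substitution")
  expect_equal(refTable(back)$neutral_mass, refTable(db)$neutral_mass,
               tolerance = 1e-9)
  expect_identical(refTable(back)$sequence, refTable(db)$sequence)
  expect_identical(dropoffPosition(back), dropoffPosition(db))
})
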