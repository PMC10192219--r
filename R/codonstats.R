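# Codon-level statistics at drop-off sites: frequency tallies, TPM-weighted
# positional usage, GC grouping, codon-anticodon mismatch classification,
# early-ORF usage deviation, ORF grouping, amino-acid frequency comparison.

# The 61 sense codons, RNA alphabet, lexicographic order.
.senseCodons <- local({
  b <- c("A", "C", "G", "U")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  all <- sort(all)
  setdiff(all, c("UAA", "UAG", "UGA"))
})

.toRna <- function(x) chartr("Tt", "UU", toupper(x))

# Codon at a 1-based codon position of a CDS (vectorised over both).
.codonAt <- function(cds, pos) .toRna(substring(cds, 3L * pos - 2L, 3L * pos))

.emptyTally <- function() stats::setNames(numeric(length(.senseCodons)),
                                          .senseCodons)

#' Normalise a codon tally to frequencies
#'
#' @param tally named numeric vector over codons (counts or weights).
#' @return tally rescaled to sum to 1, with attribute
#'   \code{normalized = TRUE}; an all-zero tally is an error.
#' @export
normalizeTally <- function(tally) {
  s <- sum(tally)
  if (s <= 0) stop("cannot normalise an all-zero tally")
  out <- tally / s
  attr(out, "normalized") <- TRUE
  out
}

#' Tally codons at (or adjacent to) drop-off sites
#'
#' Counts, over the matched records of one class, the codon at each record's
#' drop-off position (offset 0) or at a fixed offset from it (offset +1 for
#' the codon 3' adjacent to the drop-off site, i.e. the stalled A-site codon
#' of a cognate pep-tRNA). Records whose target position falls outside the
#' ORF's sense codons are skipped with a warning. Stop codons never enter
#' the tally (sense positions only).
#'
#' @param records a \code{\linkS4class{MatchResult}} or its record table.
#' @param orfs ORF table (\code{\link{readOrfs}}).
#' @param class optional class label filter (e.g. \code{"cognate"},
#'   \code{"C0X"}); \code{NULL} keeps every record with a best candidate.
#' @param offset integer codon offset from the drop-off site (default 0).
#' @param normalize return frequencies instead of counts.
#' @return named numeric vector over the 61 sense codons.
#' @export
dropoffCodonTally <- function(records, orfs, class = NULL, offset = 0L,
                              normalize = FALSE) {
  if (is(records, "MatchResult")) records <- records@records
  sel <- !is.na(records$dropoff_pos)
  if (!is.null(class)) sel <- sel & records$class %in% class
  records <- records[sel, , drop = FALSE]
  tal <- .emptyTally()
  if (!nrow(records)) return(if (normalize) tal else tal)
  cds <- stats::setNames(orfs$cds, orfs$gene_id)[records$gene_id]
  if (anyNA(cds))
    stop("records reference gene_ids missing from the ORF table")
  pos <- records$dropoff_pos + as.integer(offset)
  nCodon <- nchar(cds) %/% 3L - 1L  # sense codons (stop excluded)
  ok <- pos >= 1L & pos <= nCodon
  if (any(!ok))
    warning(sum(!ok), " record(s) with positions outside the ORF skipped")
  codons <- .codonAt(cds[ok], pos[ok])
  tab <- table(factor(codons, levels = .senseCodons))
  tal[names(tab)] <- as.numeric(tab)
  if (normalize) normalizeTally(tal) else tal
}

#' @rdname dropoffCodonTally
#' @export
adjacentCodonTally <- function(records, orfs, class = NULL,
                               normalize = FALSE)
  dropoffCodonTally(records, orfs, class = class, offset = 1L,
                    normalize = normalize)

#' TPM-weighted positional codon usage of a transcriptome window
#'
#' For each ORF, counts the sense codons in the 1-based codon positions
#' \code{positionRange[1]..positionRange[2]} (capped at the last sense
#' codon), weights the counts by the ORF's share of total TPM, sums over
#' ORFs, and normalises. Invariant to global TPM rescaling. The profiling
#' study compares drop-off-site codon frequencies against this usage for
#' positions 5-17.
#'
#' @param orfs ORF table with a \code{tpm} column; all-zero/missing TPM is
#'   an error.
#' @param positionRange \code{c(a, b)} with \code{2 <= a <= b}.
#' @return named frequency vector over the 61 sense codons (sums to 1).
#' @export
tpmWeightedUsage <- function(orfs, positionRange = c(5L, 17L)) {
  a <- as.integer(positionRange[1L]); b <- as.integer(positionRange[2L])
  if (!(2L <= a && a <= b)) stop("need 2 <= a <= b in positionRange")
  tpm <- orfs$tpm
  if (is.null(tpm) || all(is.na(tpm)) || sum(tpm, na.rm = TRUE) <= 0)
    stop("TPM values are required and must not be all zero")
  tpm[is.na(tpm)] <- 0
  w <- tpm / sum(tpm)
  tal <- .emptyTally()
  for (i in seq_len(nrow(orfs))) {
    if (w[i] == 0) next
    nCodon <- nchar(orfs$cds[i]) %/% 3L - 1L
    hi <- min(b, nCodon)
    if (hi < a) next
    codons <- .codonAt(orfs$cds[i], seq.int(a, hi))
    tab <- table(factor(codons, levels = .senseCodons))
    tal <- tal + as.numeric(tab) * w[i]
  }
  normalizeTally(tal)
}

#' GC group of codons
#'
#' @param codon character vector of codons (DNA or RNA alphabet).
#' @return integer 0..3: the number of G or C bases among the three letters.
#' @export
gcGroup <- function(codon) {
  codon <- .toRna(codon)
  if (any(nchar(codon) != 3L)) stop("codons must be triplets")
  vapply(strsplit(codon, "", fixed = TRUE),
         function(b) sum(b %in% c("G", "C")), integer(1))
}

#' Codon-anticodon mismatch count and pairing class
#'
#' Pairs codon position i (5'->3') with anticodon position 4-i and counts
#' non-Watson-Crick pairs (matches: A:U, U:A, G:C, C:G). With
#' \code{wobble = TRUE}, G:U and U:G at codon position 3 (the anticodon
#' position-34 wobble pair) also count as matches; the default is strict
#' Watson-Crick at all three positions. Class: 0 mismatches = cognate, 1 =
#' near-cognate, 2 or more = multiple.
#'
#' @param codon codon triplet(s), DNA or RNA alphabet.
#' @param anticodon anticodon triplet(s), written 5'->3'.
#' @param wobble allow G:U wobble at codon position 3?
#' @return data.frame with columns \code{codon}, \code{anticodon},
#'   \code{mismatches} (0..3) and \code{class}.
#' @export
mismatchCount <- function(codon, anticodon, wobble = FALSE) {
  codon <- .toRna(codon); anticodon <- .toRna(anticodon)
  n <- max(length(codon), length(anticodon))
  codon <- rep_len(codon, n); anticodon <- rep_len(anticodon, n)
  if (any(nchar(codon) != 3L) || any(nchar(anticodon) != 3L))
    stop("codon and anticodon must be triplets")
  if (any(grepl("[^ACGU]", c(codon, anticodon))))
    stop("invalid nucleotide (allowed: A, C, G, U/T)")
  wc <- c(A = "U", U = "A", G = "C", C = "G")
  mism <- integer(n)
  for (i in 1:3) {
    cb <- substring(codon, i, i)
    ab <- substring(anticodon, 4L - i, 4L - i)
    ok <- wc[cb] == ab
    if (wobble && i == 3L)
      ok <- ok | (cb == "G" & ab == "U") | (cb == "U" & ab == "G")
    mism <- mism + as.integer(!ok)
  }
  cls <- ifelse(mism == 0L, "cognate",
                ifelse(mism == 1L, "near_cognate", "multiple"))
  data.frame(codon = codon, anticodon = anticodon, mismatches = mism,
             class = cls, stringsAsFactors = FALSE)
}

#' Read a tRNA anticodon table from TSV
#'
#' @param file TSV with columns \code{trna_id} and \code{anticodon}
#'   (5'->3').
#' @return data.frame with validated RNA-alphabet anticodons.
#' @export
readAnticodons <- function(file) {
  df <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("trna_id", "anticodon") %in% names(df)))
    stop("anticodon table needs columns 'trna_id' and 'anticodon'")
  df$anticodon <- .toRna(df$anticodon)
  if (any(nchar(df$anticodon) != 3L) || any(grepl("[^ACGU]", df$anticodon)))
    stop("anticodons must be nucleotide triplets")
  df
}

#' Coefficient of determination between two codon tallies
#'
#' Squared Pearson correlation of the two frequency vectors over the shared
#' codon set, with an option to exclude named codons first (the study
#' reports R^2 both with and without the dominant AAA codon). Both tallies
#' are normalised before comparison, so the statistic is invariant to
#' rescaling either input.
#'
#' @param x,y named numeric codon tallies.
#' @param exclude optional codon names to drop before computing.
#' @return R^2 in [0, 1].
#' @export
codonTallyR2 <- function(x, y, exclude = NULL) {
  shared <- intersect(names(x), names(y))
  shared <- setdiff(shared, .toRna(exclude))
  if (length(shared) < 3L) stop("too few shared codons")
  fx <- x[shared] / sum(x[shared])
  fy <- y[shared] / sum(y[shared])
  stats::cor(fx, fy)^2
}

#' Positional codon-usage deviation of an ORF set
#'
#' Computes, for every sense codon, the ratio of its usage frequency within
#' a codon-position window to its frequency over all positions (start codon
#' excluded from both), and the standard deviation sigma of the ratio
#' vector. A window whose usage mirrors the bulk gives ratios near 1 and a
#' small sigma; the early-ORF window of real transcriptomes deviates
#' strongly. Codons absent from the total usage are excluded with a warning.
#'
#' @param orfs ORF table.
#' @param window \code{c(a, b)} codon-position window, \code{a >= 2}.
#' @param weights optional per-ORF weights (e.g. TPM); default unweighted.
#' @return list with \code{ratio} (named vector), \code{sigma},
#'   \code{window_freq} and \code{total_freq}.
#' @export
usageDeviation <- function(orfs, window, weights = NULL) {
  a <- as.integer(window[1L]); b <- as.integer(window[2L])
  if (!(2L <= a && a <= b)) stop("invalid window")
  if (is.null(weights)) weights <- rep(1, nrow(orfs))
  winTal <- .emptyTally(); totTal <- .emptyTally()
  for (i in seq_len(nrow(orfs))) {
    nCodon <- nchar(orfs$cds[i]) %/% 3L - 1L
    if (nCodon < 2L) next
    all <- .codonAt(orfs$cds[i], seq.int(2L, nCodon))
    totTal <- totTal +
      as.numeric(table(factor(all, levels = .senseCodons))) * weights[i]
    hi <- min(b, nCodon)
    if (hi >= a) {
      wn <- .codonAt(orfs$cds[i], seq.int(a, hi))
      winTal <- winTal +
        as.numeric(table(factor(wn, levels = .senseCodons))) * weights[i]
    }
  }
  totF <- normalizeTally(totTal)
  winF <- normalizeTally(winTal)
  zero <- totF == 0
  if (any(zero))
    warning(sum(zero), " codon(s) unused in the ORF set excluded from ",
            "the ratio vector")
  ratio <- winF[!zero] / totF[!zero]
  list(ratio = ratio, sigma = stats::sd(ratio),
       window_freq = winF, total_freq = totF)
}

#' Group highly expressed ORFs by their detected drop-off positions
#'
#' Restricts to ORFs above a TPM quantile (default: top 20 percent), then
#' partitions them: Group 1, any detected drop-off at the early positions
#' (default codons 5 and 6); Group 2, drop-offs detected only at other
#' (later) positions; Group 3, no drop-off detected. The three groups are
#' disjoint and exhaustive over the restricted set.
#'
#' @param records a \code{\linkS4class{MatchResult}} or its record table
#'   (rows with best candidates mark detections).
#' @param orfs ORF table with TPM.
#' @param tpmQuantile quantile cut (0.8 keeps the top 20 percent; 0
#'   considers every ORF).
#' @param earlyPositions integer codon positions defining Group 1.
#' @return data.frame with \code{gene_id}, \code{tpm}, \code{group}
#'   (integer 1/2/3).
#' @export
orfGrouping <- function(records, orfs, tpmQuantile = 0.8,
                        earlyPositions = c(5L, 6L)) {
  if (is(records, "MatchResult")) records <- records@records
  tpm <- orfs$tpm
  if (is.null(tpm) || all(is.na(tpm))) stop("TPM values are required")
  cut <- stats::quantile(tpm, tpmQuantile, na.rm = TRUE)
  top <- orfs[!is.na(tpm) & tpm >= cut, c("gene_id", "tpm"), drop = FALSE]
  det <- records[!is.na(records$dropoff_pos), , drop = FALSE]
  early <- unique(det$gene_id[det$dropoff_pos %in% earlyPositions])
  anyDet <- unique(det$gene_id)
  top$group <- ifelse(top$gene_id %in% early, 1L,
                      ifelse(top$gene_id %in% anyDet, 2L, 3L))
  rownames(top) <- NULL
  top
}

#' Amino-acid frequency: detected peptides vs the ORF N-terminal window
#'
#' Compares the residue composition of detected nascent peptides with the
#' composition of the ORF N-terminal region (default codons 2-10), as used
#' to ask whether bulky residues (F, Y, W) are depleted in dropped-off
#' peptides.
#'
#' @param peptides character vector of detected peptide sequences.
#' @param orfs ORF table.
#' @param window \code{c(a, b)} residue-position window of the ORF proteins.
#' @return data.frame with per-residue \code{peptide_freq},
#'   \code{orf_freq} (each summing to 1) and their \code{ratio}.
#' @export
aaFrequencyComparison <- function(peptides, orfs, window = c(2L, 10L)) {
  a <- as.integer(window[1L]); b <- as.integer(window[2L])
  pepRes <- unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE)
  orfRes <- unlist(lapply(orfs$protein, function(p)
    strsplit(substring(p, a, min(b, nchar(p))), "", fixed = TRUE)[[1L]]),
    use.names = FALSE)
  pf <- table(factor(pepRes, levels = .aa20))
  of <- table(factor(orfRes, levels = .aa20))
  pepFreq <- as.numeric(pf) / sum(pf)
  orfFreq <- as.numeric(of) / sum(of)
  data.frame(residue = .aa20, peptide_freq = pepFreq, orf_freq = orfFreq,
             ratio = ifelse(orfFreq > 0, pepFreq / orfFreq, NA_real_),
             stringsAsFactors = FALSE)
}

#' The 61 sense codons (RNA alphabet)
#'
#' @return character vector of the sense codons in lexicographic order.
#' @export
senseCodons <- function() .senseCodons
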