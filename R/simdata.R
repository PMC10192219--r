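# Seeded synthetic-data generator: toy ORFeomes and ground-truthed mass
# lists with the statistical structure the pipeline assumes.

#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the simulator with the defaults that define the
#' emulated study conditions: a 200-ORF toy ORFeome; 5,000 MS features of
#' which 60 percent are unassignable decoys (mirroring the share of
#' unmatched peaks in real profiling data); 20.8 percent of true nascent
#' peptides non-cognate, with single-substitution offsets split 286:10:4:4
#' across C0X..C-3X; non-cognate drop-off positions concentrated at codons
#' 5-9 (above 95 percent of C0X events); cognate drop-off positions spread
#' over codons 3-15; 1 ppm Gaussian mass error; log-normal TPM.
#'
#' @param seed integer seed; mandatory for reproducibility (every stage
#'   derives its own stream from it).
#' @param nOrfs number of ORFs in the toy ORFeome.
#' @param orfLengthCodons \code{c(min, max)} ORF length in codons
#'   (excluding the stop codon).
#' @param nPeaks total number of simulated MS features in the t=30 sample.
#' @param decoyFraction fraction of features that are unassignable decoys
#'   (also planted in the t=0 control as chemical noise).
#' @param noncognateFraction fraction of true peptides carrying a single
#'   amino-acid substitution.
#' @param offsetProbs named probabilities over substitution C-offsets
#'   ("0".."3").
#' @param cognatePositions,cognatePosWeights support and weights of the
#'   cognate drop-off-position distribution.
#' @param noncognatePositions,noncognatePosWeights same for substituted
#'   peptides (concentrated at codons 5-9).
#' @param ppmSigma Gaussian mass-error standard deviation in ppm.
#' @param tolPpm matching tolerance the data are generated for; decoys and
#'   substitution masses are kept at least \code{2 * tolPpm} away from any
#'   cognate reference mass so truth labels stay unambiguous.
#' @param minLen,maxLen reference peptide length range (profiling range).
#' @param tpmMeanlog,tpmSdlog log-normal TPM parameters.
#' @param earlyAUBias strength of the position-dependent AU enrichment in
#'   codons 2-8 (0 = uniform codon usage; 1.5 emulates the early
#'   AU-richness of real ORFeomes).
#' @param miscodingCodons optional set of "hungry" codons; when given,
#'   substitution events are planted only at drop-off sites showing one of
#'   these codons.
#' @return a list of class \code{simConfig}.
#' @export
simConfig <- function(seed,
                      nOrfs = 200L,
                      orfLengthCodons = c(30L, 60L),
                      nPeaks = 5000L,
                      decoyFraction = 0.6,
                      noncognateFraction = 0.208,
                      offsetProbs = c("0" = 286, "1" = 10, "2" = 4,
                                      "3" = 4) / 304,
                      cognatePositions = 3:15,
                      cognatePosWeights = c(2, 5, 8, 10, 9, 8, 7, 6, 5, 4,
                                            3, 2, 1),
                      noncognatePositions = 4:10,
                      noncognatePosWeights = c(1, 12, 30, 25, 18, 10, 1),
                      ppmSigma = 1,
                      tolPpm = 5,
                      minLen = 3L,
                      maxLen = 14L,
                      tpmMeanlog = 1,
                      tpmSdlog = 1,
                      earlyAUBias = 1.5,
                      miscodingCodons = NULL) {
  if (missing(seed) || is.na(seed))
    stop("a seed is mandatory for reproducible simulation")
  stopifnot(decoyFraction >= 0, decoyFraction < 1,
            noncognateFraction >= 0, noncognateFraction <= 1,
            ppmSigma >= 0, tolPpm > 0,
            length(cognatePositions) == length(cognatePosWeights),
            length(noncognatePositions) == length(noncognatePosWeights))
  offsetProbs <- offsetProbs / sum(offsetProbs)
  cfg <- list(seed = as.integer(seed), nOrfs = as.integer(nOrfs),
              orfLengthCodons = as.integer(orfLengthCodons),
              nPeaks = as.integer(nPeaks), decoyFraction = decoyFraction,
              noncognateFraction = noncognateFraction,
              offsetProbs = offsetProbs,
              cognatePositions = as.integer(cognatePositions),
              cognatePosWeights = cognatePosWeights,
              noncognatePositions = as.integer(noncognatePositions),
              noncognatePosWeights = noncognatePosWeights,
              ppmSigma = ppmSigma, tolPpm = tolPpm,
              minLen = as.integer(minLen), maxLen = as.integer(maxLen),
              tpmMeanlog = tpmMeanlog, tpmSdlog = tpmSdlog,
              earlyAUBias = earlyAUBias,
              miscodingCodons = miscodingCodons)
  class(cfg) <- "simConfig"
  cfg
}

# Codon sampling weights: uniform over sense codons, or AU-enriched
# (weight proportional to (1 + bias)^(number of A/U bases)).
.codonWeights <- function(bias = 0) {
  au <- vapply(strsplit(.senseCodons, "", fixed = TRUE),
               function(b) sum(b %in% c("A", "U")), integer(1))
  (1 + bias)^au
}

#' Simulate a toy ORFeome with TPM
#'
#' Generates valid CDSs: an ATG/GTG/TTG start codon (E. coli-like mix),
#' sense codons only in the body (so no internal stop), and a terminal TAA.
#' With \code{earlyAUBias > 0}, codons 2-8 are drawn from an AU-enriched
#' codon distribution, emulating the early AU-richness of bacterial ORFs
#' (so the positional usage deviation sigma is larger for the 2-8 window
#' than for later windows). TPM values are log-normal, scaled to sum to
#' 1e6. Fully deterministic under the config seed.
#'
#' @param config a \code{\link{simConfig}}.
#' @return ORF table as from \code{\link{readOrfs}}, with \code{tpm} set.
#' @export
simulateOrfeome <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  nO <- config$nOrfs
  lenPool <- seq.int(config$orfLengthCodons[1L], config$orfLengthCodons[2L])
  lens <- lenPool[sample.int(length(lenPool), nO, replace = TRUE)]
  wEarly <- .codonWeights(config$earlyAUBias)
  wBulk <- .codonWeights(0)
  dnaSense <- chartr("U", "T", .senseCodons)
  starts <- sample(c("ATG", "GTG", "TTG"), nO, replace = TRUE,
                   prob = c(0.83, 0.14, 0.03))
  cds <- character(nO)
  for (i in seq_len(nO)) {
    nBody <- lens[i] - 1L  # codons 2..lens (stop excluded)
    early <- min(nBody, 7L)  # codons 2-8 under the AU-biased distribution
    body <- c(sample(dnaSense, early, replace = TRUE, prob = wEarly),
              if (nBody > early)
                sample(dnaSense, nBody - early, replace = TRUE,
                       prob = wBulk))
    cds[i] <- paste0(starts[i], paste(body, collapse = ""), "TAA")
  }
  names(cds) <- sprintf("orf%03d", seq_len(nO))
  tpm <- stats::rlnorm(nO, config$tpmMeanlog, config$tpmSdlog)
  tpm <- tpm / sum(tpm) * 1e6
  orfsFromSequences(cds, tpm = stats::setNames(tpm, names(cds)))
}

# Sample a drop-off position compatible with a peptide length range.
# For an untrimmed peptide, length = position; trimmed, length = pos - 1.
.samplePos <- function(positions, weights, trimmed, minLen, maxLen, plen) {
  lenAt <- positions - as.integer(trimmed)      # peptide length at each pos
  ok <- lenAt >= minLen & lenAt <= maxLen & positions <= plen
  if (!any(ok)) return(NA_integer_)
  if (sum(ok) == 1L) return(positions[ok])
  sample(positions[ok], 1L, prob = weights[ok])
}

#' Simulate drop-off peak lists with ground truth
#'
#' Builds the t=30 sample list (cognate and single-substitution peptide
#' masses drawn under the drop-off/miscoding model, plus decoys) and the
#' t=0 control list (the same decoy species, re-measured), each with
#' Gaussian ppm mass error. Peptides are N-acetylated free acids; trimming
#' follows the MAP rule deterministically. Substitution masses are rejected
#' within \code{2 * tolPpm} of any cognate reference mass, and decoy masses
#' within \code{2 * tolPpm} of any cognate mass, so the planted class labels
#' are unambiguous for the matcher; decoys additionally appear in the
#' control list so noise subtraction removes them. Peptide masses equal the
#' \code{\link{peptideMass}} values of their truth sequences exactly before
#' noise.
#'
#' @param orfs ORF table from \code{\link{simulateOrfeome}}.
#' @param config a \code{\link{simConfig}}.
#' @param table residue-mass table used for the true masses.
#' @return list with \code{peaks} (t=30 feature table), \code{control}
#'   (t=0 feature table), and \code{truth} (one row per non-decoy peak:
#'   gene, sequence, trimming, substitution, drop-off position, true mass,
#'   class).
#' @export
simulateDropoffPeaks <- function(orfs, config, table = residueMassTable()) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed + 1L)
  cogDb <- buildCognateDb(orfs, config$minLen, config$maxLen, table)
  cogMass <- sort(cogDb@refs$neutral_mass)
  guard <- 2 * config$tolPpm
  nearCognate <- function(m) {
    w <- .ppmWindow(m, cogMass, guard)
    w$hi >= w$lo
  }

  nDecoy <- round(config$nPeaks * config$decoyFraction)
  nTrue <- config$nPeaks - nDecoy
  if (nTrue <= 0L) {
    warning("configuration yields no true peaks")
  }
  isSub <- stats::runif(nTrue) < config$noncognateFraction
  offs <- integer(nTrue)
  if (any(isSub))
    offs[isSub] <- as.integer(sample(names(config$offsetProbs),
                                     sum(isSub), replace = TRUE,
                                     prob = config$offsetProbs))
  w <- orfs$tpm; w[is.na(w)] <- 0
  plen <- nchar(orfs$protein)
  second <- substring(orfs$protein, 2L, 2L)
  trimFlag <- mapEligible(second)

  truth <- vector("list", nTrue)
  allowed <- .allowedSubs(table)
  hungry <- if (is.null(config$miscodingCodons)) NULL
            else .toRna(config$miscodingCodons)
  for (i in seq_len(nTrue)) {
    for (attempt in 1:200) {
      oi <- sample.int(nrow(orfs), 1L, prob = w)
      trimmed <- trimFlag[oi]
      if (isSub[i]) {
        pos <- .samplePos(config$noncognatePositions,
                          config$noncognatePosWeights, trimmed,
                          max(config$minLen, offs[i] + 1L), config$maxLen,
                          plen[oi])
      } else {
        pos <- .samplePos(config$cognatePositions, config$cognatePosWeights,
                          trimmed, config$minLen, config$maxLen, plen[oi])
      }
      if (is.na(pos)) next
      len <- pos - as.integer(trimmed)
      seqStart <- if (trimmed) 2L else 1L
      pep <- substring(orfs$protein[oi], seqStart, seqStart + len - 1L)
      if (!isSub[i]) {
        truth[[i]] <- data.frame(
          gene_id = orfs$gene_id[oi], sequence = pep, met_trimmed = trimmed,
          sub_offset = NA_integer_, sub_from = NA_character_,
          sub_to = NA_character_, dropoff_pos = pos,
          true_mass = peptideMass(pep, table), class = "cognate",
          stringsAsFactors = FALSE)
        break
      }
      # substituted peptide: the miscoded site is len - offset (1-based)
      sitePos <- pos - offs[i]  # codon position of the substituted residue
      if (!is.null(hungry)) {
        codon <- .codonAt(orfs$cds[oi], sitePos)
        if (!codon %in% hungry) next
      }
      residx <- len - offs[i]
      orig <- substring(pep, residx, residx)
      subs <- sample(allowed[[orig]])
      newSeq <- NA_character_
      for (s in subs) {
        cand <- paste0(substring(pep, 1L, residx - 1L), s,
                       substring(pep, residx + 1L, len))
        m <- peptideMass(cand, table)
        if (!nearCognate(m)) { newSeq <- cand; subTo <- s; break }
      }
      if (is.na(newSeq)) next
      truth[[i]] <- data.frame(
        gene_id = orfs$gene_id[oi], sequence = newSeq,
        met_trimmed = trimmed, sub_offset = offs[i], sub_from = orig,
        sub_to = subTo, dropoff_pos = pos,
        true_mass = peptideMass(newSeq, table),
        class = classifySubstitution(offs[i]), stringsAsFactors = FALSE)
      break
    }
    if (is.null(truth[[i]]))
      stop("could not place a simulated peptide; configuration too tight")
  }
  truth <- do.call(rbind, truth)
  if (is.null(truth))
    truth <- data.frame(gene_id = character(0), sequence = character(0),
                        met_trimmed = logical(0), sub_offset = integer(0),
                        sub_from = character(0), sub_to = character(0),
                        dropoff_pos = integer(0), true_mass = numeric(0),
                        class = character(0), stringsAsFactors = FALSE)
  if (nrow(truth))
    truth$peak_id <- sprintf("true%05d", seq_len(nrow(truth)))

  # decoys: uniform over the reference mass range, kept away from any
  # cognate mass so they cannot be mistaken for a planted class
  massRange <- range(cogMass)
  decoyMass <- numeric(nDecoy)
  k <- 0L
  while (k < nDecoy) {
    m <- stats::runif(nDecoy - k, massRange[1L], massRange[2L])
    m <- m[!nearCognate(m)]
    if (length(m)) {
      decoyMass[(k + 1L):(k + length(m))] <- m
      k <- k + length(m)
    }
  }

  noisy <- function(m) m * (1 + stats::rnorm(length(m),
                                             sd = config$ppmSigma * 1e-6))
  nSample <- nrow(truth) + nDecoy
  sampleDf <- data.frame(
    peak_id = c(truth$peak_id, sprintf("decoy%05d", seq_len(nDecoy))),
    mass = noisy(c(truth$true_mass, decoyMass)),
    intensity = stats::rlnorm(nSample, 10, 1),
    sample = rep("pth_ts", nSample), timepoint = rep("t30", nSample),
    stringsAsFactors = FALSE)
  sampleDf <- sampleDf[sample.int(nrow(sampleDf)), , drop = FALSE]
  controlDf <- data.frame(
    peak_id = sprintf("ctrl%05d", seq_len(nDecoy)),
    mass = noisy(decoyMass),
    intensity = stats::rlnorm(nDecoy, 10, 1),
    sample = rep("pth_ts", nDecoy), timepoint = rep("t0", nDecoy),
    stringsAsFactors = FALSE)
  list(peaks = asPeakTable(sampleDf, table),
       control = asPeakTable(controlDf, table),
       truth = truth)
}

#' Precision and recall of the pipeline against simulation truth
#'
#' Joins matched records with the generator's truth table by peak id and
#' reports, per class, the number of truth peaks, predicted peaks, true
#' positives, precision and recall. Mass-degenerate truths (I/L
#' substitutions) are excluded from the denominators; the generator never
#' plants them, so this is a safeguard for user-supplied truth tables.
#'
#' @param truth truth table from \code{\link{simulateDropoffPeaks}}.
#' @param matched a \code{\linkS4class{MatchResult}} or its record table.
#' @return data.frame with one row per class.
#' @export
evaluateRecovery <- function(truth, matched) {
  if (is(matched, "MatchResult")) matched <- matched@records
  degen <- !is.na(truth$sub_offset) &
    truth$sub_from %in% c("I", "L") & truth$sub_to %in% c("I", "L")
  truth <- truth[!degen, , drop = FALSE]
  pred <- stats::setNames(matched$class, matched$peak_id)
  truthClass <- stats::setNames(truth$class, truth$peak_id)
  classes <- intersect(classLevels(), unique(c(truth$class, matched$class)))
  out <- do.call(rbind, lapply(classes, function(cl) {
    tIds <- names(truthClass)[truthClass == cl]
    pIds <- names(pred)[pred == cl]
    tp <- sum(pred[tIds] == cl, na.rm = TRUE)
    data.frame(class = cl, n_truth = length(tIds), n_pred = length(pIds),
               tp = tp,
               precision = if (length(pIds)) {
                 sum(truthClass[pIds] == cl, na.rm = TRUE) / length(pIds)
               } else NA_real_,
               recall = if (length(tIds)) tp / length(tIds) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
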