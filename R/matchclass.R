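# Annotation of observed mass peaks against the reference databases:
# chemical-noise subtraction, ppm-tolerance matching with class precedence,
# and C0X..C-kX classification.

#' Class labels used by the matcher
#'
#' Order defines the display/tally order: \code{noise} (present in the t=0
#' control), \code{cognate}, the substitution classes by C-terminal offset
#' (\code{C0X} = drop-off site, \code{C-1X}..\code{C-3X} upstream,
#' \code{C-kX} pooled for offsets beyond 3), and \code{unassigned}.
#'
#' @return character vector of class labels.
#' @export
classLevels <- function()
  c("noise", "cognate", "C0X", "C-1X", "C-2X", "C-3X", "C-kX", "unassigned")

#' Map substitution C-terminal offsets to class labels
#'
#' @param offset integer offsets from the C-terminus (0 = drop-off site).
#'   \code{NA} (a cognate candidate) is a contract error.
#' @return character labels \code{"C0X"}, \code{"C-1X"}, ..., with offsets
#'   beyond 3 pooled as \code{"C-kX"}.
#' @export
classifySubstitution <- function(offset) {
  if (anyNA(offset))
    stop("cognate record passed to classifySubstitution (contract error)")
  ifelse(offset == 0L, "C0X",
         ifelse(offset <= 3L, paste0("C-", offset, "X"), "C-kX"))
}

#' Read an MS feature list from TSV
#'
#' Accepts either a \code{mass} column (neutral monoisotopic mass, Da) or an
#' \code{mz} column, converted to neutral mass assuming charge 1 unless a
#' \code{charge} column is present. Optional columns \code{rt},
#' \code{intensity}, \code{sample}, \code{timepoint} are carried through.
#'
#' @param file TSV path (comment lines starting with "#" are skipped).
#' @param table residue-mass table (proton constant for m/z conversion).
#' @return data.frame with at least \code{peak_id} and \code{neutral_mass}.
#' @export
readPeaks <- function(file, table = residueMassTable()) {
  if (!file.exists(file)) stop("peak file not found: ", file)
  df <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  asPeakTable(df, table)
}

#' Normalise a feature data.frame into the peak-table layout
#'
#' @param df data.frame with \code{mass} or \code{mz} (+ optional
#'   \code{charge}) columns.
#' @param table residue-mass table for the proton constant.
#' @return data.frame with \code{peak_id}, \code{neutral_mass},
#'   \code{rt}, \code{intensity}, \code{sample}, \code{timepoint}.
#' @export
asPeakTable <- function(df, table = residueMassTable()) {
  proton <- table@constants[["proton"]]
  if ("mass" %in% names(df)) {
    mass <- as.numeric(df$mass)
  } else if ("neutral_mass" %in% names(df)) {
    mass <- as.numeric(df$neutral_mass)
  } else if ("mz" %in% names(df)) {
    z <- if ("charge" %in% names(df)) as.integer(df$charge) else 1L
    mass <- as.numeric(df$mz) * z - z * proton
  } else stop("peak table needs a 'mass', 'neutral_mass' or 'mz' column")
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("all peak masses must be positive")
  n <- length(mass)
  data.frame(
    peak_id = if ("peak_id" %in% names(df)) as.character(df$peak_id)
              else sprintf("peak%05d", seq_len(n)),
    neutral_mass = mass,
    rt = if ("rt" %in% names(df)) as.numeric(df$rt) else rep(NA_real_, n),
    intensity = if ("intensity" %in% names(df)) as.numeric(df$intensity)
                else rep(NA_real_, n),
    sample = if ("sample" %in% names(df)) as.character(df$sample)
             else rep(NA_character_, n),
    timepoint = if ("timepoint" %in% names(df)) as.character(df$timepoint)
                else rep(NA_character_, n),
    stringsAsFactors = FALSE)
}

# For each query mass, the index range [lo, hi] of sorted reference masses
# within tol ppm (|obs - ref|/ref <= tol  <=>  ref in [m/(1+t), m/(1-t)]).
.ppmWindow <- function(query, sortedRef, tolPpm) {
  t <- tolPpm * 1e-6
  lo <- findInterval(query / (1 + t), sortedRef, left.open = TRUE) + 1L
  hi <- findInterval(query / (1 - t), sortedRef)
  list(lo = lo, hi = hi)
}

#' Remove chemical noise by reference to a control peak list
#'
#' Any sample peak whose mass lies within \code{tolPpm} of any control-list
#' mass (the t=0 sample in the profiling workflow) is labelled chemical noise
#' and removed. The partition is exhaustive: every input peak ends up in
#' exactly one of the two outputs.
#'
#' @param peaks sample peak table (see \code{\link{asPeakTable}}).
#' @param control control peak table; empty control is a no-op with warning.
#' @param tolPpm tolerance in ppm (inclusive).
#' @return list with elements \code{kept} and \code{removed}.
#' @export
subtractNoise <- function(peaks, control, tolPpm = 5) {
  if (tolPpm <= 0) stop("tolPpm must be positive")
  if (is.null(control) || nrow(control) == 0L) {
    warning("empty control list: no noise subtraction performed")
    return(list(kept = peaks, removed = peaks[0L, , drop = FALSE]))
  }
  ref <- sort(control$neutral_mass)
  w <- .ppmWindow(peaks$neutral_mass, ref, tolPpm)
  isNoise <- w$hi >= w$lo
  list(kept = peaks[!isNoise, , drop = FALSE],
       removed = peaks[isNoise, , drop = FALSE])
}

# Candidate enumeration for one database; returns a data.frame of
# (peak row index, db row index, dppm).
.enumCandidates <- function(mass, db, tolPpm) {
  refs <- db@refs
  o <- order(refs$neutral_mass)
  sortedMass <- refs$neutral_mass[o]
  w <- .ppmWindow(mass, sortedMass, tolPpm)
  n <- pmax(w$hi - w$lo + 1L, 0L)
  peakIdx <- rep.int(seq_along(mass), n)
  if (!length(peakIdx))
    return(data.frame(peak = integer(0), ref = integer(0),
                      dppm = numeric(0)))
  refIdx <- o[unlist(lapply(seq_along(mass), function(i)
    if (n[i] > 0L) seq.int(w$lo[i], w$hi[i]) else integer(0)),
    use.names = FALSE)]
  dppm <- ppmError(mass[peakIdx], refs$neutral_mass[refIdx])
  data.frame(peak = peakIdx, ref = refIdx, dppm = dppm)
}

#' Match observed peaks against cognate and substitution databases
#'
#' Each peak receives exactly one class label. With the default precedence,
#' a peak matching any cognate reference within tolerance is \code{cognate}
#' regardless of substitution matches (the triage order of the profiling
#' workflow: cognate first, then single substitutions); otherwise, a
#' substitution match yields the class of the best candidate's C-terminal
#' offset; otherwise the peak is \code{unassigned}. Within the winning
#' database all in-tolerance candidates are kept, ranked by absolute ppm
#' error, then gene id, then sequence (deterministic tie-break); the peak is
#' counted once, under its best candidate.
#'
#' The matcher runs on a sorted mass index with binary-search windows and is
#' contractually equivalent to a naive all-pairs scan.
#'
#' @param peaks peak table (see \code{\link{asPeakTable}}).
#' @param cognateDb cognate \code{\linkS4class{PeptideRefDb}}.
#' @param substitutionDb optional substitution \code{PeptideRefDb}.
#' @param tolPpm inclusive matching tolerance in ppm (default 5).
#' @param precedence class precedence; only the default
#'   \code{c("cognate", "substitution")} and its reverse are meaningful.
#' @return a \code{\linkS4class{MatchResult}}.
#' @export
matchPeaks <- function(peaks, cognateDb, substitutionDb = NULL, tolPpm = 5,
                       precedence = c("cognate", "substitution")) {
  if (tolPpm <= 0) stop("tolPpm must be positive")
  stopifnot(is(cognateDb, "PeptideRefDb"))
  mass <- peaks$neutral_mass
  n <- length(mass)
  dbs <- list(cognate = cognateDb)
  if (!is.null(substitutionDb)) dbs$substitution <- substitutionDb
  precedence <- intersect(precedence, names(dbs))

  recClass <- rep("unassigned", n)
  bestIdx <- rep(NA_integer_, n)
  bestDb <- rep(NA_character_, n)
  bestPpm <- rep(NA_real_, n)
  nCand <- rep(0L, n)
  candPieces <- list()

  unresolved <- rep(TRUE, n)
  for (dbName in precedence) {
    db <- dbs[[dbName]]
    if (!nrow(db@refs)) next
    idx <- which(unresolved)
    if (!length(idx)) break
    cand <- .enumCandidates(mass[idx], db, tolPpm)
    if (!nrow(cand)) next
    cand$peak <- idx[cand$peak]
    refs <- db@refs
    ord <- order(cand$peak, abs(cand$dppm), refs$gene_id[cand$ref],
                 refs$sequence[cand$ref])
    cand <- cand[ord, , drop = FALSE]
    first <- !duplicated(cand$peak)
    hits <- cand$peak[first]
    bestIdx[hits] <- cand$ref[first]
    bestDb[hits] <- dbName
    bestPpm[hits] <- cand$dppm[first]
    cnt <- table(cand$peak)
    nCand[hits] <- as.integer(cnt[as.character(hits)])
    if (dbName == "cognate") {
      recClass[hits] <- "cognate"
    } else {
      recClass[hits] <- classifySubstitution(refs$sub_offset[cand$ref[first]])
    }
    rk <- stats::ave(seq_len(nrow(cand)), cand$peak, FUN = seq_along)
    candPieces[[dbName]] <- data.frame(
      peak_id = peaks$peak_id[cand$peak],
      db = dbName,
      rank = rk,
      refs[cand$ref, , drop = FALSE],
      dppm = cand$dppm,
      row.names = NULL, stringsAsFactors = FALSE)
    unresolved[hits] <- FALSE
  }

  emptyRef <- data.frame(gene_id = NA_character_, sequence = NA_character_,
                         met_trimmed = NA, sub_offset = NA_integer_,
                         sub_from = NA_character_, sub_to = NA_character_,
                         dropoff_pos = NA_integer_,
                         neutral_mass = NA_real_, stringsAsFactors = FALSE)
  bestRefs <- emptyRef[rep(1L, n), , drop = FALSE]
  for (dbName in names(dbs)) {
    sel <- which(bestDb == dbName)
    if (length(sel))
      bestRefs[sel, ] <- dbs[[dbName]]@refs[bestIdx[sel], .refdbCols]
  }
  names(bestRefs) <- c("gene_id", "sequence", "met_trimmed", "sub_offset",
                       "sub_from", "sub_to", "dropoff_pos", "ref_mass")
  records <- data.frame(
    peak_id = peaks$peak_id, neutral_mass = mass,
    intensity = peaks$intensity, sample = peaks$sample,
    timepoint = peaks$timepoint,
    class = recClass, bestRefs, delta_ppm = bestPpm,
    n_candidates = nCand, row.names = NULL, stringsAsFactors = FALSE)
  candidates <- if (length(candPieces)) do.call(rbind, candPieces)
                else data.frame()
  rownames(candidates) <- NULL
  new("MatchResult", records = records, candidates = candidates,
      tolPpm = tolPpm, precedence = precedence)
}

#' Accessors for MatchResult
#'
#' \code{matchRecords} returns the per-peak record table (one row per peak,
#' best candidate flattened); \code{matchCandidates} the full ranked
#' candidate list.
#'
#' @param x a \code{\linkS4class{MatchResult}}.
#' @return a data.frame.
#' @export
setGeneric("matchRecords", function(x) standardGeneric("matchRecords"))

#' @rdname matchRecords
#' @export
setMethod("matchRecords", "MatchResult", function(x) x@records)

#' @rdname matchRecords
#' @export
setGeneric("matchCandidates", function(x) standardGeneric("matchCandidates"))

#' @rdname matchRecords
#' @export
setMethod("matchCandidates", "MatchResult", function(x) x@candidates)

#' Per-class tallies, proportions and mass summaries
#'
#' @param records a \code{\linkS4class{MatchResult}} or its record
#'   data.frame (optionally with extra \code{noise} rows appended).
#' @return data.frame with columns \code{class}, \code{n},
#'   \code{proportion} (over the rows supplied; sums to 1) and
#'   \code{median_mass}.
#' @export
summarizeClasses <- function(records) {
  if (is(records, "MatchResult")) records <- records@records
  if (!nrow(records)) stop("no records to summarise")
  lev <- intersect(classLevels(), unique(records$class))
  out <- do.call(rbind, lapply(lev, function(cl) {
    sel <- records$class == cl
    data.frame(class = cl, n = sum(sel),
               proportion = sum(sel) / nrow(records),
               median_mass = stats::median(records$neutral_mass[sel]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-class drop-off-position distributions and cumulative fractions
#'
#' @param records a \code{\linkS4class{MatchResult}} or its record table;
#'   rows without a best candidate (noise/unassigned) are dropped.
#' @return data.frame with columns \code{class}, \code{dropoff_pos},
#'   \code{n}, \code{fraction}, \code{cum_fraction} (monotone, reaching 1
#'   within each class).
#' @export
positionalDistribution <- function(records) {
  if (is(records, "MatchResult")) records <- records@records
  records <- records[!is.na(records$dropoff_pos), , drop = FALSE]
  if (!nrow(records))
    return(data.frame(class = character(0), dropoff_pos = integer(0),
                      n = integer(0), fraction = numeric(0),
                      cum_fraction = numeric(0)))
  pieces <- lapply(intersect(classLevels(), unique(records$class)),
                   function(cl) {
    pos <- records$dropoff_pos[records$class == cl]
    tab <- table(pos)
    df <- data.frame(class = cl, dropoff_pos = as.integer(names(tab)),
                     n = as.integer(tab), stringsAsFactors = FALSE)
    df <- df[order(df$dropoff_pos), , drop = FALSE]
    df$fraction <- df$n / sum(df$n)
    df$cum_fraction <- cumsum(df$fraction)
    df
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
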