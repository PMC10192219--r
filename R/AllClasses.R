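#' @import methods
NULL

#' Monoisotopic residue-mass table
#'
#' Holds the per-residue monoisotopic masses (Da) used for all peptide mass
#' arithmetic, together with the modification and adduct constants. Cysteine
#' is always carried as carbamidomethyl-Cys (iodoacetamide alkylation is a
#' fixed modification in this workflow); unmodified Cys is not representable.
#'
#' Two built-in tables exist: \code{"paper"}, the values printed in the
#' original profiling study (the default everywhere), and \code{"standard"},
#' residue masses summed from atomic compositions. The two differ by less
#' than 5e-4 Da per residue; see \code{\link{residueMassTable}}.
#'
#' @slot masses named numeric, one monoisotopic residue mass per one-letter
#'   amino-acid code (20 residues, \code{I} and \code{L} identical).
#' @slot constants named numeric: \code{water}, \code{proton},
#'   \code{adenosine}, \code{acetyl}, \code{formyl}, \code{oxidation},
#'   \code{o18} (all Da, monoisotopic).
#' @slot tableId character label (\code{"paper"}, \code{"standard"}, or a
#'   file path for user-supplied tables).
#' @seealso \code{\link{residueMassTable}}, \code{\link{neutralMass}}
#' @exportClass ResidueMassTable
setClass("ResidueMassTable",
  representation(masses = "numeric", constants = "numeric",
                 tableId = "character"))

setValidity("ResidueMassTable", function(object) {
  msg <- character(0)
  need <- c("water", "proton", "adenosine", "acetyl", "formyl",
            "oxidation", "o18")
  if (length(object@masses) < 20L || is.null(names(object@masses)))
    msg <- c(msg, "masses must be a named vector covering the 20 residues")
  if (any(!is.finite(object@masses)) || any(object@masses <= 0))
    msg <- c(msg, "all residue masses must be strictly positive and finite")
  if (!all(need %in% names(object@constants)))
    msg <- c(msg, paste("constants must contain:", paste(need, collapse = ", ")))
  if (all(c("I", "L") %in% names(object@masses)) &&
      object@masses[["I"]] != object@masses[["L"]])
    msg <- c(msg, "Ile and Leu must have identical mass")
  if (length(msg)) msg else TRUE
})

#' A single (possibly modified) nascent-peptide species
#'
#' Describes one molecular species whose monoisotopic mass can be computed:
#' the residue sequence (N to C), the N-terminal modification state, the
#' C-terminal state, and the number of oxidised methionines. The C-terminal
#' states model the chemistry of the pep-tRNA workflow: nuclease digestion of
#' an acylated tRNA leaves the peptide esterified to the tRNA 3'-terminal
#' adenosine (\code{"adenosine_ester"}); alkaline hydrolysis releases the free
#' acid (\code{"free_acid"}), optionally incorporating one heavy oxygen when
#' hydrolysis is performed in 18O water (\code{"free_acid_18O"}).
#'
#' @slot sequence single residue string, N-terminus first.
#' @slot nTermMod one of \code{"none"}, \code{"acetyl"}, \code{"formyl"}.
#' @slot cTermState one of \code{"free_acid"}, \code{"adenosine_ester"},
#'   \code{"free_acid_18O"}.
#' @slot metOxidations non-negative integer count of oxidised Met residues.
#' @seealso \code{\link{peptideSpecies}}, \code{\link{neutralMass}}
#' @exportClass PeptideSpecies
setClass("PeptideSpecies",
  representation(sequence = "character", nTermMod = "character",
                 cTermState = "character", metOxidations = "integer"))

setValidity("PeptideSpecies", function(object) {
  msg <- character(0)
  s <- object@sequence
  if (length(s) != 1L || is.na(s) || nchar(s) < 1L)
    msg <- c(msg, "sequence must be a single non-empty string")
  if (!object@nTermMod %in% c("none", "acetyl", "formyl"))
    msg <- c(msg, "nTermMod must be one of none/acetyl/formyl")
  if (!object@cTermState %in% c("free_acid", "adenosine_ester", "free_acid_18O"))
    msg <- c(msg, "cTermState must be free_acid/adenosine_ester/free_acid_18O")
  if (length(object@metOxidations) != 1L || is.na(object@metOxidations) ||
      object@metOxidations < 0L)
    msg <- c(msg, "metOxidations must be a single non-negative integer")
  else if (length(s) == 1L && !is.na(s)) {
    nmet <- lengths(regmatches(s, gregexpr("M", s, fixed = TRUE)))
    if (object@metOxidations > nmet)
      msg <- c(msg, "metOxidations exceeds the number of Met in the sequence")
  }
  if (length(msg)) msg else TRUE
})

#' Reference peptide database
#'
#' Container for N-terminal reference peptides generated from an ORF set:
#' cognate prefixes, their initiator-Met-trimmed counterparts (methionine
#' aminopeptidase rule), and single amino-acid substitution variants. One row
#' per reference peptide with its drop-off codon position and neutral
#' monoisotopic mass (N-acetylated free acid by default).
#'
#' The underlying table (see \code{\link{refTable}}) has columns
#' \code{gene_id}, \code{sequence}, \code{met_trimmed}, \code{sub_offset}
#' (offset from the C-terminus, 0 = drop-off site; \code{NA} for cognate),
#' \code{sub_from}, \code{sub_to}, \code{dropoff_pos} (1-based codon position,
#' initiator = 1), \code{neutral_mass} (Da).
#'
#' @slot refs data.frame as described above.
#' @slot tableId label of the residue-mass table the masses were computed with.
#' @slot kind \code{"cognate"} or \code{"substitution"}.
#' @seealso \code{\link{buildCognateDb}}, \code{\link{buildSubstitutionDb}}
#' @exportClass PeptideRefDb
setClass("PeptideRefDb",
  representation(refs = "data.frame", tableId = "character",
                 kind = "character"))

.refdbCols <- c("gene_id", "sequence", "met_trimmed", "sub_offset",
                "sub_from", "sub_to", "dropoff_pos", "neutral_mass")

setValidity("PeptideRefDb", function(object) {
  msg <- character(0)
  df <- object@refs
  if (!all(.refdbCols %in% names(df)))
    msg <- c(msg, paste("refs must have columns:",
                        paste(.refdbCols, collapse = ", ")))
  else if (nrow(df)) {
    if (any(df$neutral_mass <= 0)) msg <- c(msg, "neutral masses must be > 0")
    exppos <- nchar(df$sequence) + as.integer(df$met_trimmed)
    if (any(df$dropoff_pos != exppos))
      msg <- c(msg, "dropoff_pos must equal length(sequence) (+1 if trimmed)")
    sub <- !is.na(df$sub_offset)
    if (any(sub & df$sub_from == df$sub_to))
      msg <- c(msg, "substitutions must change the residue")
  }
  if (!object@kind %in% c("cognate", "substitution"))
    msg <- c(msg, "kind must be cognate or substitution")
  if (length(msg)) msg else TRUE
})

#' Result of matching a peak list against reference databases
#'
#' One record per input peak, carrying the assigned class label
#' (\code{cognate}, \code{C0X} \dots \code{C-kX}, \code{noise},
#' \code{unassigned}), the best candidate reference (smallest absolute ppm
#' error within the winning class), and the full ranked candidate list in a
#' sidecar table.
#'
#' @slot records data.frame, one row per peak (see \code{\link{matchRecords}}).
#' @slot candidates data.frame of all in-tolerance candidates, ranked.
#' @slot tolPpm matching tolerance (ppm, inclusive).
#' @slot precedence class precedence used (cognate before substitution by
#'   default).
#' @seealso \code{\link{matchPeaks}}, \code{\link{summarizeClasses}}
#' @exportClass MatchResult
setClass("MatchResult",
  representation(records = "data.frame", candidates = "data.frame",
                 tolPpm = "numeric", precedence = "character"))

setValidity("MatchResult", function(object) {
  msg <- character(0)
  if (!"class" %in% names(object@records))
    msg <- c(msg, "records must carry a class column")
  if (length(object@tolPpm) != 1L || object@tolPpm <= 0)
    msg <- c(msg, "tolPpm must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Log-log calibration curve for absolute peptide quantification
#'
#' Ordinary least-squares fit of log10(peak area) against log10(amount),
#' used to invert observed areas into absolute amounts (external standard
#' method with synthetic peptides).
#'
#' @slot peptide label of the calibrated peptide.
#' @slot slope,intercept fitted coefficients of
#'   \code{log10(area) ~ log10(amount)}.
#' @slot amountRange range of calibration amounts (for extrapolation flags).
#' @seealso \code{\link{fitCalibration}}, \code{\link{absoluteQuantify}}
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  representation(peptide = "character", slope = "numeric",
                 intercept = "numeric", amountRange = "numeric"))

setValidity("CalibrationCurve", function(object) {
  if (!is.finite(object@slope) || !is.finite(object@intercept))
    "slope and intercept must be finite" else TRUE
})

setMethod("show", "ResidueMassTable", function(object) {
  cat("ResidueMassTable <", object@tableId, "> : ",
      length(object@masses), " residues\n", sep = "")
  cat("  Gly", format(object@masses[["G"]], nsmall = 5),
      "... Trp", format(object@masses[["W"]], nsmall = 5), "\n")
})

setMethod("show", "PeptideSpecies", function(object) {
  cat("PeptideSpecies: ", object@nTermMod, "-", object@sequence, " [",
      object@cTermState, "]",
      if (object@metOxidations > 0L)
        paste0(" +", object@metOxidations, " Met-ox"), "\n", sep = "")
})

setMethod("show", "PeptideRefDb", function(object) {
  df <- object@refs
  cat("PeptideRefDb (", object@kind, "): ", nrow(df), " reference peptides, ",
      length(unique(df$gene_id)), " genes\n", sep = "")
  if (nrow(df)) {
    cat("  lengths ", min(nchar(df$sequence)), "-", max(nchar(df$sequence)),
        " aa; mass ", round(min(df$neutral_mass), 2), "-",
        round(max(df$neutral_mass), 2), " Da; table <", object@tableId,
        ">\n", sep = "")
    cat("  trimmed variants: ", sum(df$met_trimmed), "\n", sep = "")
  }
})

setMethod("show", "MatchResult", function(object) {
  tab <- table(object@records$class)
  cat("MatchResult: ", nrow(object@records), " peaks at tolerance ",
      object@tolPpm, " ppm\n", sep = "")
  for (cl in names(tab)) cat("  ", cl, ": ", tab[[cl]], "\n", sep = "")
})

setMethod("show", "CalibrationCurve", function(object) {
  cat("CalibrationCurve <", object@peptide, ">: log10(area) = ",
      signif(object@slope, 4), " * log10(amount) + ",
      signif(object@intercept, 4), "\n", sep = "")
})
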