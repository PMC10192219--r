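# Reference-database construction: cognate N-terminal peptides, Met-trimmed
# variants per the MAP rule, and single-substitution variants, with drop-off
# position bookkeeping.

# Methionine aminopeptidase removes the initiator Met when the second
# residue is small: Gly, Ala, Ser, Thr, Cys, Pro, Val, Asn, Asp, Leu, Ile.
.mapResidues <- c("G", "A", "S", "T", "C", "P", "V", "N", "D", "L", "I")

.startCodons <- c("ATG", "GTG", "TTG")

#' MAP (methionine aminopeptidase) eligibility
#'
#' @param secondResidue character vector of second residues (one-letter).
#' @return logical: is the initiator Met removed?
#' @export
mapEligible <- function(secondResidue) secondResidue %in% .mapResidues

#' Read and validate an ORF set from a CDS FASTA
#'
#' Reads in-frame coding sequences, validates them (length divisible by 3, a
#' recognised start codon ATG/GTG/TTG, a terminal stop, no internal stop) and
#' translates them with the standard genetic code, forcing the initiator
#' residue to Met regardless of the start codon. Invalid records are skipped
#' with a summarising warning.
#'
#' @param fasta path to a nucleotide FASTA of CDSs (5'->3', in frame).
#' @param tpm optional TPM table: either a named numeric vector or a path to
#'   a TSV with columns \code{gene_id} and \code{tpm}.
#' @return data.frame with columns \code{gene_id}, \code{cds},
#'   \code{protein} (stop excluded, initiator as Met), \code{tpm}.
#' @export
readOrfs <- function(fasta, tpm = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  orfs <- orfsFromSequences(stats::setNames(as.character(seqs),
                                            sub("\\s.*$", "", names(seqs))))
  if (!is.null(tpm)) {
    if (is.character(tpm) && length(tpm) == 1L) {
      tab <- utils::read.delim(tpm, header = TRUE, stringsAsFactors = FALSE)
      tpm <- stats::setNames(as.numeric(tab$tpm), tab$gene_id)
    }
    orfs$tpm <- unname(tpm[orfs$gene_id])
  }
  orfs
}

#' Build an ORF table from in-memory CDS strings
#'
#' Same validation and translation as \code{\link{readOrfs}}, for sequences
#' already in memory (e.g. from the simulator).
#'
#' @param cds named character vector of CDS nucleotide strings.
#' @param tpm optional named numeric TPM vector.
#' @return data.frame as in \code{\link{readOrfs}}.
#' @export
orfsFromSequences <- function(cds, tpm = NULL) {
  if (length(cds) == 0L)
    return(data.frame(gene_id = character(0), cds = character(0),
                      protein = character(0), tpm = numeric(0),
                      stringsAsFactors = FALSE))
  if (is.null(names(cds)) || any(!nzchar(names(cds))))
    stop("CDS sequences must be named by gene_id")
  cds <- toupper(gsub("U", "T", gsub("\\s", "", cds)))
  bad <- character(0)
  keep <- logical(length(cds))
  protein <- character(length(cds))
  gc <- Biostrings::GENETIC_CODE
  for (i in seq_along(cds)) {
    s <- cds[[i]]
    n <- nchar(s)
    ok <- n >= 9L && n %% 3L == 0L &&
      substr(s, 1L, 3L) %in% .startCodons &&
      !grepl("[^ACGT]", s)
    if (ok) {
      codons <- substring(s, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
      aa <- unname(gc[codons])
      ok <- !anyNA(aa) && aa[length(aa)] == "*" &&
        !any(aa[-length(aa)] == "*")
      if (ok) {
        aa[1L] <- "M"  # initiator is always formyl-Met
        protein[i] <- paste(aa[-length(aa)], collapse = "")
      }
    }
    keep[i] <- ok
    if (!ok) bad <- c(bad, names(cds)[i])
  }
  if (length(bad))
    warning(length(bad), " malformed ORF record(s) skipped: ",
            paste(utils::head(bad, 5L), collapse = ", "),
            if (length(bad) > 5L) ", ...")
  out <- data.frame(gene_id = names(cds)[keep], cds = unname(cds[keep]),
                    protein = protein[keep], stringsAsFactors = FALSE)
  out$tpm <- if (is.null(tpm)) rep(NA_real_, nrow(out))
             else unname(tpm[out$gene_id])
  out
}

#' Build the cognate N-terminal peptide reference database
#'
#' For each ORF, generates one reference peptide per length in
#' \code{[minLen, maxLen]} (capped by the protein length), plus the
#' Met-trimmed counterparts of each length in the same range whenever the
#' second residue satisfies the MAP rule (\code{\link{mapEligible}}). A
#' trimmed peptide of length L covers codons 2..L+1, so its drop-off codon
#' position is L+1; a retained-Met peptide of length L drops off at codon L.
#' Neutral masses are N-acetylated free acids (the workflow acetylates all
#' alpha-amino groups before analysis).
#'
#' @param orfs ORF data.frame from \code{\link{readOrfs}} /
#'   \code{\link{orfsFromSequences}}.
#' @param minLen,maxLen peptide length range in residues (defaults 3-14,
#'   the profiling range).
#' @param table a \code{\linkS4class{ResidueMassTable}}.
#' @return a \code{\linkS4class{PeptideRefDb}} of kind \code{"cognate"}.
#' @export
buildCognateDb <- function(orfs, minLen = 3L, maxLen = 14L,
                           table = residueMassTable()) {
  if (!(2L <= minLen && minLen <= maxLen))
    stop("need 2 <= minLen <= maxLen")
  k <- table@constants
  acid <- k[["water"]] + k[["acetyl"]]
  pieces <- vector("list", nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    prot <- orfs$protein[i]
    plen <- nchar(prot)
    res <- strsplit(prot, "", fixed = TRUE)[[1L]]
    pre <- cumsum(table@masses[res])
    if (anyNA(pre))
      stop("ORF ", orfs$gene_id[i], " contains residues outside the table")
    topU <- min(maxLen, plen)
    lensU <- if (topU >= minLen) seq.int(minLen, topU) else integer(0)
    dfU <- if (length(lensU)) data.frame(
      gene_id = orfs$gene_id[i],
      sequence = substring(prot, 1L, lensU),
      met_trimmed = FALSE,
      sub_offset = NA_integer_, sub_from = NA_character_,
      sub_to = NA_character_,
      dropoff_pos = lensU,
      neutral_mass = unname(pre[lensU]) + acid,
      stringsAsFactors = FALSE) else NULL
    dfT <- NULL
    if (plen >= 2L && mapEligible(res[2L])) {
      topT <- min(maxLen, plen - 1L)
      lensT <- if (topT >= minLen) seq.int(minLen, topT) else integer(0)
      if (length(lensT)) {
        dfT <- data.frame(
          gene_id = orfs$gene_id[i],
          sequence = substring(prot, 2L, lensT + 1L),
          met_trimmed = TRUE,
          sub_offset = NA_integer_, sub_from = NA_character_,
          sub_to = NA_character_,
          dropoff_pos = lensT + 1L,
          neutral_mass = unname(pre[lensT + 1L] - pre[1L]) + acid,
          stringsAsFactors = FALSE)
      }
    }
    pieces[[i]] <- rbind(dfU, dfT)
  }
  refs <- do.call(rbind, pieces)
  if (is.null(refs))
    refs <- data.frame(gene_id = character(0), sequence = character(0),
                       met_trimmed = logical(0), sub_offset = integer(0),
                       sub_from = character(0), sub_to = character(0),
                       dropoff_pos = integer(0), neutral_mass = numeric(0),
                       stringsAsFactors = FALSE)
  rownames(refs) <- NULL
  new("PeptideRefDb", refs = refs, tableId = table@tableId, kind = "cognate")
}

# For each residue, the substitutions with a non-zero mass change (all 19
# others minus the mass-degenerate I <-> L pair).
.allowedSubs <- function(table) {
  lapply(stats::setNames(nm = .aa20), function(a) {
    cand <- setdiff(.aa20, a)
    cand[table@masses[cand] != table@masses[[a]]]
  })
}

#' Build the single-substitution reference database
#'
#' For each cognate reference peptide and each allowed position (expressed as
#' an offset from the C-terminus, 0 = drop-off site), generates one variant
#' per substituted residue among the other 19, excluding substitutions with
#' zero mass change (I <-> L), which mass-only profiling cannot evidence.
#' Masses are derived incrementally from the parent mass. MAP-trimming status
#' is inherited from the cognate parent (trimming acts co-translationally on
#' the true N-terminal sequence, so eligibility is decided on the cognate
#' second residue even when position 2 is the substituted one).
#'
#' @param cognate a cognate \code{\linkS4class{PeptideRefDb}}.
#' @param positions \code{"all"}, or an integer vector of C-terminal offsets
#'   (e.g. \code{0:3} for the C0X..C-3X window).
#' @param table a \code{\linkS4class{ResidueMassTable}}.
#' @return a \code{\linkS4class{PeptideRefDb}} of kind \code{"substitution"}.
#' @export
buildSubstitutionDb <- function(cognate, positions = "all",
                                table = residueMassTable()) {
  stopifnot(is(cognate, "PeptideRefDb"))
  par <- cognate@refs
  if (!nrow(par)) stop("empty cognate database (input error)")
  lens <- nchar(par$sequence)
  if (identical(positions, "all")) {
    pidx <- rep.int(seq_len(nrow(par)), lens)
    offs <- sequence(lens) - 1L
  } else {
    positions <- sort(unique(as.integer(positions)))
    if (any(positions < 0L)) stop("offsets must be >= 0")
    grid <- lapply(seq_len(nrow(par)),
                   function(i) positions[positions <= lens[i] - 1L])
    pidx <- rep.int(seq_len(nrow(par)), lengths(grid))
    offs <- unlist(grid, use.names = FALSE)
    if (!length(pidx)) stop("no valid substitution positions")
  }
  pos <- lens[pidx] - offs  # 1-based residue index within the peptide
  orig <- substring(par$sequence[pidx], pos, pos)
  allowed <- .allowedSubs(table)
  nsub <- lengths(allowed)[orig]
  j <- rep.int(seq_along(pidx), nsub)
  sub <- unlist(allowed[orig], use.names = FALSE)
  pseq <- par$sequence[pidx][j]
  posj <- pos[j]
  refs <- data.frame(
    gene_id = par$gene_id[pidx][j],
    sequence = paste0(substring(pseq, 1L, posj - 1L), sub,
                      substring(pseq, posj + 1L, nchar(pseq))),
    met_trimmed = par$met_trimmed[pidx][j],
    sub_offset = offs[j],
    sub_from = orig[j],
    sub_to = sub,
    dropoff_pos = par$dropoff_pos[pidx][j],
    neutral_mass = par$neutral_mass[pidx][j] -
      unname(table@masses[orig[j]]) + unname(table@masses[sub]),
    stringsAsFactors = FALSE)
  rownames(refs) <- NULL
  new("PeptideRefDb", refs = refs, tableId = table@tableId,
      kind = "substitution")
}

#' Access the reference table of a PeptideRefDb
#'
#' @param db a \code{\linkS4class{PeptideRefDb}}.
#' @return the underlying data.frame (see \code{\linkS4class{PeptideRefDb}}).
#' @export
setGeneric("refTable", function(db) standardGeneric("refTable"))

#' @rdname refTable
#' @export
setMethod("refTable", "PeptideRefDb", function(db) db@refs)

#' Drop-off codon positions of reference peptides
#'
#' The drop-off site is the codon (1-based, initiator = 1) of a peptide's
#' C-terminal residue: length of the sequence, plus one for Met-trimmed
#' peptides (a trimmed 7-mer covers codons 2-8 and drops off at codon 8).
#'
#' @param db a \code{\linkS4class{PeptideRefDb}}.
#' @return integer vector of codon positions.
#' @export
setGeneric("dropoffPosition", function(db) standardGeneric("dropoffPosition"))

#' @rdname dropoffPosition
#' @export
setMethod("dropoffPosition", "PeptideRefDb", function(db) db@refs$dropoff_pos)

#' Export reference peptides as search-engine FASTA
#'
#' Writes peptide FASTA for external MS/MS search engines, optionally with
#' \code{"X"} wildcards at given C-terminal offsets (e.g. offset 0 turns
#' "ALNLQDK" into "ALNLQDX" to search any C-terminal substitution), split
#' into files by length range. The published databases use the overlapping
#' ranges 4-10 and 10-16 aa (a length-10 peptide appears in both files);
#' overlapping ranges trigger a configuration warning but are honoured.
#'
#' Headers carry \code{gene_id|pos<dropoff>|<variant tag>} where the tag is
#' \code{cognate}, \code{trimmed}, or \code{subK} for a substitution at
#' C-offset K (with \code{.trimmed} appended for trimmed parents).
#'
#' @param db a \code{\linkS4class{PeptideRefDb}}.
#' @param file base output path; with more than one length range, files are
#'   written as \code{<file>_<a>-<b>.fasta}. \code{NULL} returns the FASTA
#'   text invisibly instead of writing.
#' @param wildcardPositions integer C-terminal offsets to mask with "X"
#'   (empty = plain sequences).
#' @param lengthSplit list of \code{c(min, max)} length ranges.
#' @return invisibly, a named list of character vectors of FASTA lines (one
#'   per range), also written to files unless \code{file} is \code{NULL}.
#' @export
exportSearchFasta <- function(db, file = NULL,
                              wildcardPositions = integer(0),
                              lengthSplit = list(c(4L, 10L), c(10L, 16L))) {
  stopifnot(is(db, "PeptideRefDb"))
  refs <- db@refs
  if (length(lengthSplit) > 1L) {
    for (i in seq_along(lengthSplit)) for (j in seq_along(lengthSplit)) {
      if (i < j && lengthSplit[[i]][2L] >= lengthSplit[[j]][1L] &&
          lengthSplit[[j]][2L] >= lengthSplit[[i]][1L]) {
        warning("overlapping length ranges: peptides in the overlap appear ",
                "in multiple files")
        break
      }
    }
  }
  tag <- ifelse(is.na(refs$sub_offset),
                ifelse(refs$met_trimmed, "trimmed", "cognate"),
                paste0("sub", refs$sub_offset,
                       ifelse(refs$met_trimmed, ".trimmed", "")))
  seqs <- refs$sequence
  lens <- nchar(seqs)
  for (w in wildcardPositions) {
    p <- lens - w
    ok <- p >= 1L
    seqs[ok] <- paste0(substring(seqs[ok], 1L, p[ok] - 1L), "X",
                       substring(seqs[ok], p[ok] + 1L, lens[ok]))
  }
  headers <- paste0(">", refs$gene_id, "|pos", refs$dropoff_pos, "|", tag)
  out <- list()
  for (rg in lengthSplit) {
    sel <- lens >= rg[1L] & lens <= rg[2L]
    lines <- as.vector(rbind(headers[sel], seqs[sel]))
    nm <- paste0(rg[1L], "-", rg[2L])
    out[[nm]] <- lines
    if (!is.null(file)) {
      path <- if (length(lengthSplit) > 1L)
        paste0(sub("\\.fasta$", "", file), "_", nm, ".fasta") else file
      writeLines(lines, path)
    }
  }
  invisible(out)
}

#' Write / read a reference database as TSV
#'
#' Plain-text round-trip of the reference table, with the residue-mass table
#' id and database kind carried in header comments.
#'
#' @param db a \code{\linkS4class{PeptideRefDb}}.
#' @param file TSV path.
#' @return \code{writeRefDb}: the path invisibly. \code{readRefDb}: a
#'   \code{PeptideRefDb}.
#' @export
writeRefDb <- function(db, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(paste0("# pepTRNAprof reference database; kind=", db@kind,
                      "; mass_table=", db@tableId)), con)
  utils::write.table(db@refs, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname writeRefDb
#' @export
readRefDb <- function(file) {
  hdr <- readLines(file, n = 1L)
  kind <- sub(".*kind=([a-z]+).*", "\\1", hdr)
  tid <- sub(".*mass_table=([^;]+)$", "\\1", hdr)
  refs <- utils::read.delim(file, comment.char = "#",
                            stringsAsFactors = FALSE)
  refs$sub_from <- as.character(refs$sub_from)
  refs$sub_to <- as.character(refs$sub_to)
  new("PeptideRefDb", refs = refs, tableId = tid, kind = kind)
}
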