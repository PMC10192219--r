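# Orchestration and shared I/O: the end-to-end profiling run, TSV/JSON
# writers with config headers, and import of external search-engine
# identification tables.

#' Write a data.frame as TSV with header comments
#'
#' @param df data.frame.
#' @param file output path.
#' @param header optional character vector of comment lines (prefixed "#").
#' @return the path, invisibly.
#' @export
writeTsv <- function(df, file, header = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a TSV written by \code{\link{writeTsv}}
#'
#' @param file path; comment lines are skipped.
#' @return data.frame.
#' @export
readTsv <- function(file)
  utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)

# Short deterministic config fingerprint for output headers.
.configHash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  v <- utils::head(strtoi(charToRaw(s), 16L), 5000L)
  sprintf("%08x", sum(v * seq_along(v)) %% 4294967291)
}

#' Run the full pep-tRNA profiling pipeline
#'
#' Orchestrates the stages of the profiling workflow on one sample:
#' reference-database construction (cognate + single-substitution),
#' chemical-noise subtraction against the t=0 control, ppm matching with
#' cognate-before-substitution precedence, class summarisation and
#' positional distributions. Per-stage counts (peaks in, noise removed,
#' per-class tallies) are collected so the triage numbers of a profiling
#' run are always reportable. Reruns with identical inputs and
#' configuration give identical output bundles.
#'
#' @param orfs ORF table (\code{\link{readOrfs}}).
#' @param peaks sample peak table (\code{\link{asPeakTable}}).
#' @param control optional t=0 control peak table for noise subtraction.
#' @param tolPpm matching tolerance in ppm.
#' @param minLen,maxLen reference peptide length range.
#' @param substitutionPositions \code{"all"} or integer C-offsets.
#' @param table residue-mass table.
#' @param outDir optional directory; when given, the reference databases,
#'   record table, summaries and a run-info JSON are written there.
#' @return list with \code{cognateDb}, \code{substitutionDb},
#'   \code{result} (a \code{\linkS4class{MatchResult}} whose records
#'   include the noise rows), \code{summary}, \code{positional},
#'   \code{counts}, \code{config}.
#' @export
runProfile <- function(orfs, peaks, control = NULL, tolPpm = 5,
                       minLen = 3L, maxLen = 14L,
                       substitutionPositions = "all",
                       table = residueMassTable(), outDir = NULL) {
  if (is.null(peaks$neutral_mass) || !nrow(peaks))
    stop("peaks must carry a 'neutral_mass' column and at least one row; ",
         "see asPeakTable()")
  config <- list(tolPpm = tolPpm, minLen = minLen, maxLen = maxLen,
                 substitutionPositions = substitutionPositions,
                 mass_table = table@tableId)
  cogDb <- buildCognateDb(orfs, minLen, maxLen, table)
  subDb <- buildSubstitutionDb(cogDb, substitutionPositions, table)
  nIn <- nrow(peaks)
  noiseRows <- NULL
  if (!is.null(control) && nrow(control)) {
    parts <- subtractNoise(peaks, control, tolPpm)
    noiseRows <- parts$removed
    peaks <- parts$kept
  }
  res <- matchPeaks(peaks, cogDb, subDb, tolPpm)
  if (!is.null(noiseRows) && nrow(noiseRows)) {
    pad <- data.frame(
      peak_id = noiseRows$peak_id, neutral_mass = noiseRows$neutral_mass,
      intensity = noiseRows$intensity, sample = noiseRows$sample,
      timepoint = noiseRows$timepoint, class = "noise",
      gene_id = NA_character_, sequence = NA_character_, met_trimmed = NA,
      sub_offset = NA_integer_, sub_from = NA_character_,
      sub_to = NA_character_, dropoff_pos = NA_integer_,
      ref_mass = NA_real_, delta_ppm = NA_real_, n_candidates = 0L,
      stringsAsFactors = FALSE)
    res@records <- rbind(res@records, pad)
  }
  records <- res@records
  summary <- summarizeClasses(records)
  positional <- positionalDistribution(records)
  counts <- c(peaks_in = nIn,
              noise = sum(records$class == "noise"),
              cognate = sum(records$class == "cognate"),
              substitution = sum(!records$class %in%
                                   c("noise", "cognate", "unassigned")),
              unassigned = sum(records$class == "unassigned"))
  stopifnot(sum(counts[-1L]) == counts[["peaks_in"]])  # partition property
  out <- list(cognateDb = cogDb, substitutionDb = subDb, result = res,
              summary = summary, positional = positional, counts = counts,
              config = config)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    hdr <- paste0("config_hash=", .configHash(config))
    writeRefDb(cogDb, file.path(outDir, "cognate_db.tsv"))
    writeRefDb(subDb, file.path(outDir, "substitution_db.tsv"))
    writeTsv(records, file.path(outDir, "matched.tsv"), hdr)
    writeTsv(summary, file.path(outDir, "class_summary.tsv"), hdr)
    writeTsv(positional, file.path(outDir, "positional.tsv"), hdr)
    jsonlite::write_json(
      list(config = config, config_hash = .configHash(config),
           counts = as.list(counts)),
      file.path(outDir, "run_info.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Import and filter an external search-engine identification table
#'
#' Applies the pass-through identification filters of the workflow (absolute
#' mass error below \code{maxPpm}, peptide score above \code{minScore},
#' expectation value below \code{maxPepExpect}), then resolves peptides
#' reported with several candidate genes: keep the candidate(s) with the
#' highest score; among those prefer cognate over non-cognate; then the
#' highest TPM; a peptide still ambiguous after all three criteria is
#' excluded and counted.
#'
#' @param table data.frame with columns \code{peptide}, \code{gene_id},
#'   \code{delta_ppm}, \code{score}, \code{pep_expect}; optional
#'   \code{sub_offset} (NA = cognate) and \code{tpm}.
#' @param maxPpm,minScore,maxPepExpect filter thresholds.
#' @return list with \code{assigned} (one row per resolved peptide),
#'   \code{n_filtered} (rows failing a filter) and \code{n_ambiguous}
#'   (peptides dropped as unresolvable).
#' @export
importIdentifications <- function(table, maxPpm = 5, minScore = 30,
                                  maxPepExpect = 0.05) {
  need <- c("peptide", "gene_id", "delta_ppm", "score", "pep_expect")
  if (!all(need %in% names(table)))
    stop("identification table needs columns: ",
         paste(need, collapse = ", "))
  if (!"sub_offset" %in% names(table)) table$sub_offset <- NA_integer_
  if (!"tpm" %in% names(table)) table$tpm <- NA_real_
  pass <- abs(table$delta_ppm) < maxPpm & table$score > minScore &
    table$pep_expect < maxPepExpect
  nFiltered <- sum(!pass)
  table <- table[pass, , drop = FALSE]
  nAmbiguous <- 0L
  pieces <- lapply(split(table, table$peptide), function(g) {
    g <- g[g$score == max(g$score), , drop = FALSE]
    if (nrow(g) > 1L && any(is.na(g$sub_offset)))
      g <- g[is.na(g$sub_offset), , drop = FALSE]
    if (nrow(g) > 1L && any(!is.na(g$tpm))) {
      mx <- max(g$tpm, na.rm = TRUE)
      g <- g[!is.na(g$tpm) & g$tpm == mx, , drop = FALSE]
    }
    g
  })
  keep <- vapply(pieces, nrow, integer(1)) == 1L
  nAmbiguous <- sum(!keep)
  assigned <- do.call(rbind, pieces[keep])
  if (is.null(assigned)) assigned <- table[0L, , drop = FALSE]
  rownames(assigned) <- NULL
  list(assigned = assigned, n_filtered = nFiltered,
       n_ambiguous = nAmbiguous)
}
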