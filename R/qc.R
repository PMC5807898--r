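#' Summarize a sequence library
#'
#' Computes read count, mean length, total length (Mb) and GC content from a
#' FASTA or FASTQ file (plain or gzip). GC is computed over unambiguous
#' A/C/G/T bases only: ambiguity codes are excluded from both numerator and
#' denominator.
#'
#' @param reads path to a FASTA/FASTQ file, or a `Biostrings::DNAStringSet`.
#' @param libraryId label; defaults to the file base name.
#' @param format "auto" infers from the extension (fastq/fq vs fasta).
#' @return a [LibrarySummary-class].
#' @export
summarizeLibrary <- function(reads, libraryId = NULL, format = "auto") {
  if (is.character(reads)) {
    vmAssert(file.exists(reads), "viromassEmptyInputError",
             sprintf("file '%s' not found", reads))
    if (is.null(libraryId))
      libraryId <- sub("\\.(fa|fasta|fq|fastq)(\\.gz)?$", "",
                       basename(reads))
    if (identical(format, "auto"))
      format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads)) "fastq"
                else "fasta"
    seqs <- tryCatch(
      Biostrings::readDNAStringSet(reads, format = format),
      error = function(e) vmStop("viromassMalformedRecordError",
                                 sprintf("failed to parse '%s': %s",
                                         reads, conditionMessage(e))))
  } else {
    seqs <- reads
    if (is.null(libraryId)) libraryId <- "library"
  }
  vmAssert(length(seqs) > 0L, "viromassEmptyInputError",
           "sequence stream contains no reads")
  widths <- Biostrings::width(seqs)
  freq <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
  gcBases <- sum(freq[, c("C", "G")])
  acgt <- sum(freq)
  new("LibrarySummary", libraryId = libraryId, nReads = length(seqs),
      meanLength = mean(widths), totalLengthMb = sum(widths) / 1e6,
      gcPercent = if (acgt > 0) 100 * gcBases / acgt else NA_real_)
}

#' Merge two library summaries
#'
#' Count-weighted merge, equivalent to summarizing the concatenated streams
#' (GC merged by weighting with unambiguous-base totals is not recoverable
#' from percentages alone, so GC is weighted by total length — exact when
#' reads carry no ambiguity codes).
#'
#' @param a,b [LibrarySummary-class] objects.
#' @return a merged [LibrarySummary-class].
#' @export
mergeSummaries <- function(a, b) {
  n <- a@nReads + b@nReads
  totalMb <- a@totalLengthMb + b@totalLengthMb
  wa <- a@totalLengthMb / totalMb
  new("LibrarySummary",
      libraryId = paste(a@libraryId, b@libraryId, sep = "+"),
      nReads = n, meanLength = (totalMb * 1e6) / n, totalLengthMb = totalMb,
      gcPercent = wa * a@gcPercent + (1 - wa) * b@gcPercent)
}

#' rRNA read ratio
#'
#' @param nRrna rRNA gene-associated read count (<= nTotal).
#' @param nTotal total reads (> 0).
#' @return percent, `100 * nRrna / nTotal`.
#' @export
rrnaRatio <- function(nRrna, nTotal) {
  vmAssert(all(nTotal > 0), "viromassDomainError", "total reads must be > 0")
  vmAssert(all(nRrna <= nTotal), "viromassDomainError",
           "rRNA reads cannot exceed total reads")
  100 * nRrna / nTotal
}

#' Evaluate the virome rRNA-contamination criterion
#'
#' A virome library passes when its rRNA gene-associated read fraction is
#' strictly below the threshold (default 0.02% of total reads, the published
#' virome quality criterion). A zero threshold is accepted with a
#' configuration warning (nothing can pass it).
#'
#' @param summary a [LibrarySummary-class], or a plain total read count.
#' @param nRrna rRNA gene-associated read count.
#' @param thresholdPercent pass threshold in percent, default 0.02.
#' @return an [RrnaQcResult-class].
#' @export
qcEvaluate <- function(summary, nRrna, thresholdPercent = 0.02) {
  if (is(summary, "LibrarySummary")) {
    nTotal <- summary@nReads
    id <- summary@libraryId
  } else {
    nTotal <- as.numeric(summary)
    id <- "library"
  }
  vmAssert(thresholdPercent >= 0, "viromassDomainError",
           "threshold must be >= 0")
  if (thresholdPercent == 0)
    warning("threshold 0% can never pass; check configuration",
            call. = FALSE)
  ratio <- rrnaRatio(nRrna, nTotal)
  new("RrnaQcResult", libraryId = id, nRrnaReads = as.numeric(nRrna),
      ratioPercent = ratio, thresholdPercent = thresholdPercent,
      pass = ratio < thresholdPercent)
}

#' QC table for a set of libraries
#'
#' @param libs data.frame with columns library_id, n_reads, rrna_reads
#'   (e.g. read from a library summary TSV).
#' @param thresholdPercent pass threshold, percent.
#' @return data.frame with ratio (unrounded and at one significant figure,
#'   the display convention) and pass flags.
#' @export
qcTable <- function(libs, thresholdPercent = 0.02) {
  checkHeader(libs, c("library_id", "n_reads", "rrna_reads"), "library table")
  ratio <- rrnaRatio(libs$rrna_reads, libs$n_reads)
  data.frame(library_id = libs$library_id,
             n_reads = libs$n_reads, rrna_reads = libs$rrna_reads,
             ratio_percent = ratio,
             ratio_percent_display = roundRatio1sf(ratio),
             threshold_percent = thresholdPercent,
             pass = ratio < thresholdPercent,
             stringsAsFactors = FALSE)
}
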