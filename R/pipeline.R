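#' Read a pipeline run configuration
#'
#' YAML with optional keys: `stages` (character subset of apportion, qc,
#' profile, ordinate), `samples`, `libraries`, `hits`, `map`, `taxonomy`,
#' `profiles` (file paths), `ss_range` (two numbers, kb), `ds_size` (kb),
#' `qc_threshold`, `min_bitscore`, `top_percent`, `max_evalue`,
#' `collapse_percent`, `n_components`, `out_dir`. Flags passed to
#' [runFull()] override file values.
#'
#' @param file YAML path.
#' @return named list of configuration values with defaults filled in.
#' @export
readRunConfig <- function(file = NULL) {
  cfg <- if (!is.null(file)) yaml::read_yaml(file) else list()
  defaults <- list(stages = c("apportion", "qc", "profile", "ordinate"),
                   ss_range = c(1.8, 24.9), ds_size = 50,
                   qc_threshold = 0.02, min_bitscore = 50, top_percent = 10,
                   max_evalue = 1e-5, collapse_percent = 2,
                   n_components = 2, out_dir = ".")
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  cfg
}

#' Run the apportionment stage end-to-end
#'
#' Reads a sediment-sample TSV, builds the apportionment report and writes it
#' as TSV and JSON into `outDir`. Outputs are deterministic: rerunning on
#' unchanged inputs reproduces byte-identical files.
#'
#' @param samplesFile sediment-sample TSV (see [readSamples()]).
#' @param outDir output directory.
#' @param ssRange,dsRange assumed [GenomeSizeRange-class]s.
#' @param constants a [NucleicAcidConstants-class].
#' @param quiet suppress the log line.
#' @return the [ApportionReport-class], invisibly.
#' @export
runApportionReport <- function(samplesFile, outDir = ".",
                               ssRange = genomeSizeRange(1.8, 24.9),
                               dsRange = genomeSizeRange(50),
                               constants = nucleicAcidConstants(),
                               quiet = FALSE) {
  samples <- readSamples(samplesFile)
  report <- apportionReport(samples, ssRange, dsRange, constants)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeReport(report,
              tsv = file.path(outDir, "apportion_report.tsv"),
              json = file.path(outDir, "apportion_report.json"))
  if (!quiet)
    message(sprintf(
      "apportion: %d sample(s); ssDNA %g-%g kb, dsDNA %g-%g kb, mw_ss %g g/mol",
      nrow(report@table), ssRange@minKb, ssRange@maxKb,
      dsRange@minKb, dsRange@maxKb, constants@mwSsPerNt))
  invisible(report)
}

.stageError <- function(stage, e) {
  vmStop("viromassStageError",
         sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full pipeline
#'
#' Executes the enabled stages (apportion, qc, profile, ordinate) against the
#' files named in `config`, cross-links libraries between the qc and profile
#' stages (orphan ids produce a warning), and writes a manifest JSON listing
#' every emitted file with its md5 digest. A failing stage halts with a
#' stage-labeled error; outputs of completed stages are retained.
#'
#' @param config list from [readRunConfig()] (or a YAML path).
#' @param ... overrides for individual config entries.
#' @return invisibly, a list with the per-stage results and the manifest.
#' @export
runFull <- function(config = list(), ...) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- utils::modifyList(readRunConfig(), config)
  config <- utils::modifyList(config, list(...))
  outDir <- config$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  emitted <- character(0)

  if ("apportion" %in% config$stages) {
    vmAssert(!is.null(config$samples), "viromassConfigError",
             "apportion stage enabled but no 'samples' file configured")
    results$apportion <- tryCatch(
      runApportionReport(config$samples, outDir,
                         genomeSizeRange(config$ss_range[1],
                                         config$ss_range[2]),
                         genomeSizeRange(config$ds_size), quiet = TRUE),
      error = function(e) .stageError("apportion", e))
    emitted <- c(emitted, file.path(outDir, c("apportion_report.tsv",
                                              "apportion_report.json")))
  }

  if ("qc" %in% config$stages && !is.null(config$libraries)) {
    results$qc <- tryCatch({
      libs <- read.delim(config$libraries, stringsAsFactors = FALSE)
      qc <- qcTable(libs, config$qc_threshold)
      path <- file.path(outDir, "qc_table.tsv")
      write.table(qc, path, sep = "\t", quote = FALSE, row.names = FALSE)
      qc
    }, error = function(e) .stageError("qc", e))
    emitted <- c(emitted, file.path(outDir, "qc_table.tsv"))
  }

  profiles <- NULL
  if ("profile" %in% config$stages &&
      !is.null(config$hits) && !is.null(config$taxonomy)) {
    results$profile <- tryCatch({
      tree <- readTaxonomy(config$taxonomy)
      hits <- parseBlastTab(config$hits)
      hits <- mapSubjects(hits, config$map)
      asg <- assignReads(hits, tree, config$min_bitscore,
                         config$top_percent, config$max_evalue)
      prof <- buildProfile(asg, tree, "family", libraryId = "hits")
      prof <- collapseMinor(prof, config$collapse_percent)
      path <- file.path(outDir, "profile.tsv")
      writeProfiles(list(prof), path)
      prof
    }, error = function(e) .stageError("profile", e))
    emitted <- c(emitted, file.path(outDir, "profile.tsv"))
  }

  if ("ordinate" %in% config$stages && !is.null(config$profiles)) {
    results$ordinate <- tryCatch({
      profs <- readProfiles(config$profiles)
      mat <- toProportions(profs)
      k <- min(config$n_components, nrow(mat@values) - 1L,
               ncol(mat@values))
      model <- pcaFit(mat, k)
      path <- file.path(outDir, "pca_scores.tsv")
      scores <- data.frame(sample_id = rownames(model@scores),
                           model@scores, check.names = FALSE)
      write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
      model
    }, error = function(e) .stageError("ordinate", e))
    emitted <- c(emitted, file.path(outDir, "pca_scores.tsv"))
  }

  # cross-link check between qc and ordination libraries
  if (!is.null(results$qc) && !is.null(results$ordinate)) {
    qcIds <- results$qc$library_id
    ordIds <- rownames(results$ordinate@scores)
    orphans <- c(setdiff(ordIds, qcIds), setdiff(qcIds, ordIds))
    if (length(orphans))
      warning(sprintf("library id(s) present in only one stage: %s",
                      paste(unique(orphans), collapse = ", ")),
              call. = FALSE)
  }

  manifest <- data.frame(file = basename(emitted),
                         md5 = unname(tools::md5sum(emitted)),
                         stringsAsFactors = FALSE)
  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(
    list(stages_run = names(results),
         stages_skipped = setdiff(c("apportion", "qc", "profile", "ordinate"),
                                  names(results)),
         files = manifest),
    manifestPath, digits = NA, auto_unbox = TRUE, dataframe = "rows")
  results$manifest <- manifest
  invisible(results)
}
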