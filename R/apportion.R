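#' DNA mass per virion
#'
#' Mass in grams of one viral genome of the given size:
#' `genome_kb * 1000 * mw_per_monomer / N_A`, where the monomer weight is per
#' nucleotide for ssDNA and per base pair for dsDNA. With the default
#' constants a 1.8 kb ssDNA genome weighs 9.90e-19 g, a 24.9 kb ssDNA genome
#' 1.37e-17 g and a 50 kb dsDNA genome 5.5e-17 g.
#'
#' @param genomeKb genome size in kilobases (kb for ssDNA counts nucleotides,
#'   for dsDNA base pairs); vectorized.
#' @param naType "ssDNA" or "dsDNA".
#' @param constants a [NucleicAcidConstants-class].
#' @return grams per particle.
#' @export
virionDnaMass <- function(genomeKb, naType = c("ssDNA", "dsDNA"),
                          constants = nucleicAcidConstants()) {
  naType <- match.arg(naType)
  vmAssert(all(genomeKb > 0), "viromassDomainError",
           "genome size must be positive")
  mw <- if (naType == "ssDNA") constants@mwSsPerNt else constants@mwDsPerBp
  genomeKb * 1000 * mw / constants@avogadro
}

#' Genome-copy abundance interval from a DNA mass concentration
#'
#' The core mass-apportioning step: a measured viral DNA mass concentration C
#' (ng per cm^3 sediment) is divided by the per-virion DNA mass implied by an
#' assumed genome-size range. The smallest genome gives the upper abundance
#' bound, the largest the lower bound:
#' `high = C / m(minKb)`, `low = C / m(maxKb)`.
#'
#' @param concNgPerCm3 measured mass concentration, ng/cm^3 sediment (>= 0).
#' @param naType "ssDNA" or "dsDNA".
#' @param sizeRange assumed [GenomeSizeRange-class]; a degenerate range
#'   (min = max) yields a point estimate.
#' @param constants a [NucleicAcidConstants-class].
#' @return an [AbundanceInterval-class], copies/cm^3.
#' @examples
#' copiesInterval(2.87, "ssDNA", genomeSizeRange(1.8, 24.9))  # high ~ 2.9e9
#' copiesInterval(0.29, "dsDNA", genomeSizeRange(50))         # ~ 5.3e6
#' @export
copiesInterval <- function(concNgPerCm3, naType = c("ssDNA", "dsDNA"),
                           sizeRange, constants = nucleicAcidConstants()) {
  naType <- match.arg(naType)
  vmAssert(length(concNgPerCm3) == 1L && concNgPerCm3 >= 0,
           "viromassDomainError", "concentration must be a single value >= 0")
  grams <- concNgPerCm3 * 1e-9
  new("AbundanceInterval",
      low = grams / virionDnaMass(sizeRange@maxKb, naType, constants),
      high = grams / virionDnaMass(sizeRange@minKb, naType, constants),
      sizeAssumption = sizeRange, naType = naType)
}

#' Relative ssDNA abundance interval
#'
#' Percentage of total DNA virus genome copies that are ssDNA,
#' `100 * ss / (ss + ds)`, evaluated conservatively: the lower bound pairs the
#' ssDNA lower bound with the dsDNA upper bound, the upper bound pairs the
#' ssDNA upper bound with the dsDNA lower bound. With a point dsDNA estimate
#' this reduces to the plain ratio at each ssDNA bound.
#'
#' @param ss,ds [AbundanceInterval-class] objects for the ssDNA and dsDNA
#'   fractions; at least one must be positive.
#' @return numeric `c(low, high)` percent, within \[0, 100\].
#' @export
relativeSsdnaPercent <- function(ss, ds) {
  vmAssert(ss@high > 0 || ds@high > 0, "viromassUndefinedRatioError",
           "relative abundance undefined: both abundances are zero")
  lo <- if (ss@low == 0 && ds@high == 0) 0 else 100 * ss@low / (ss@low + ds@high)
  hi <- if (ss@high == 0 && ds@low == 0) 0 else 100 * ss@high / (ss@high + ds@low)
  c(low = lo, high = hi)
}

#' Virus-to-cell ratio
#'
#' @param viralParticles direct viral particle count, per cm^3.
#' @param cells direct prokaryotic cell count, per cm^3 (> 0).
#' @return the ratio (dimensionless).
#' @export
vcr <- function(viralParticles, cells) {
  vmAssert(all(cells > 0), "viromassDomainError",
           "cell count must be positive")
  viralParticles / cells
}

#' Fold-difference of the mass-derived estimate over the direct count
#'
#' Direct epifluorescence counts stain small ssDNA virions inefficiently;
#' this ratio quantifies how far the mass-derived genome-copy estimate
#' exceeds (fold > 1) or falls below (fold < 1) the direct particle count.
#'
#' @param est an [AbundanceInterval-class].
#' @param viralParticles direct viral particle count, per cm^3 (> 0).
#' @return numeric `c(low, high)` fold interval.
#' @export
foldVsDirect <- function(est, viralParticles) {
  vmAssert(all(viralParticles > 0), "viromassDomainError",
           "direct viral count must be positive")
  c(low = est@low / viralParticles, high = est@high / viralParticles)
}

#' Read a sediment sample table
#'
#' TSV with header `sample_id depth_top_cm depth_bottom_cm cells_per_cm3
#' cells_sd viruses_per_cm3 viruses_sd ssdna_ng_per_cm3 dsdna_ng_per_cm3`
#' (strictly validated).
#'
#' @param file path to the TSV.
#' @return a [SedimentSampleSet-class].
#' @export
readSamples <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  vmAssert(nrow(df) >= 1L, "viromassEmptyInputError",
           sprintf("no samples found in '%s'", file))
  checkHeader(df, .sampleCols, sprintf("sample table '%s'", file))
  sedimentSamples(df)
}

#' Construct a sediment sample set from a data.frame
#'
#' @param df data.frame with the columns listed under [readSamples()].
#' @return a [SedimentSampleSet-class] with rows ordered by depth.
#' @export
sedimentSamples <- function(df) {
  df <- df[order(df$depth_top_cm), , drop = FALSE]
  rownames(df) <- NULL
  new("SedimentSampleSet", samples = df)
}

#' Build the per-sample apportionment report
#'
#' For every sediment sample, derives from the measured columns: the ssDNA
#' and dsDNA genome-copy intervals, the relative ssDNA abundance interval,
#' the virus-to-cell ratio and the ssDNA fold-difference versus the direct
#' virus count. `fold_lt_1` flags samples whose whole fold interval lies
#' below 1 (estimate below the direct count). Direct-count standard
#' deviations are carried through as annotations; no error propagation is
#' applied to derived quantities.
#'
#' @param samples a [SedimentSampleSet-class] (or data.frame coercible to one).
#' @param ssRange assumed ssDNA [GenomeSizeRange-class]
#'   (default 1.8-24.9 kb).
#' @param dsRange assumed dsDNA range; default a 50 kb point assumption.
#' @param constants a [NucleicAcidConstants-class].
#' @return an [ApportionReport-class].
#' @export
apportionReport <- function(samples,
                            ssRange = genomeSizeRange(1.8, 24.9),
                            dsRange = genomeSizeRange(50),
                            constants = nucleicAcidConstants()) {
  if (is.data.frame(samples)) samples <- sedimentSamples(samples)
  s <- samples@samples
  rows <- lapply(seq_len(nrow(s)), function(i) {
    r <- s[i, ]
    ss <- copiesInterval(r$ssdna_ng_per_cm3, "ssDNA", ssRange, constants)
    ds <- copiesInterval(r$dsdna_ng_per_cm3, "dsDNA", dsRange, constants)
    rel <- if (ss@high > 0 || ds@high > 0) {
      relativeSsdnaPercent(ss, ds)
    } else c(low = NA_real_, high = NA_real_)
    fold <- if (r$viruses_per_cm3 > 0) {
      foldVsDirect(ss, r$viruses_per_cm3)
    } else c(low = NA_real_, high = NA_real_)
    data.frame(
      sample_id = r$sample_id,
      depth_top_cm = r$depth_top_cm, depth_bottom_cm = r$depth_bottom_cm,
      cells_per_cm3 = r$cells_per_cm3, cells_sd = r$cells_sd,
      viruses_per_cm3 = r$viruses_per_cm3, viruses_sd = r$viruses_sd,
      vcr = vcr(r$viruses_per_cm3, r$cells_per_cm3),
      ssdna_ng_per_cm3 = r$ssdna_ng_per_cm3,
      dsdna_ng_per_cm3 = r$dsdna_ng_per_cm3,
      ss_copies_low = ss@low, ss_copies_high = ss@high,
      ds_copies_low = ds@low, ds_copies_high = ds@high,
      rel_ss_pct_low = rel[["low"]], rel_ss_pct_high = rel[["high"]],
      fold_vs_direct_low = fold[["low"]], fold_vs_direct_high = fold[["high"]],
      fold_lt_1 = !is.na(fold[["high"]]) && fold[["high"]] < 1,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  disp <- tab
  copyCols <- c("cells_per_cm3", "cells_sd", "viruses_per_cm3", "viruses_sd",
                "ss_copies_low", "ss_copies_high",
                "ds_copies_low", "ds_copies_high")
  for (cc in copyCols) disp[[cc]] <- roundCopies(disp[[cc]])
  disp$vcr <- roundVcr(disp$vcr)
  disp$rel_ss_pct_low <- roundPercent(disp$rel_ss_pct_low)
  disp$rel_ss_pct_high <- roundPercent(disp$rel_ss_pct_high)
  disp$fold_vs_direct_low <- roundCopies(disp$fold_vs_direct_low)
  disp$fold_vs_direct_high <- roundCopies(disp$fold_vs_direct_high)
  new("ApportionReport", table = tab, display = disp,
      ssRange = ssRange, dsRange = dsRange, constants = constants)
}

#' Write an apportionment report
#'
#' Writes the display table as TSV and both the unrounded and display tables
#' (plus the genome-size assumptions) as JSON.
#'
#' @param report an [ApportionReport-class].
#' @param tsv,json output paths (either may be NULL to skip).
#' @return invisibly, the paths written.
#' @export
writeReport <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    write.table(report@display, tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(json)) {
    payload <- list(
      assumptions = list(
        ss_genome_kb = c(report@ssRange@minKb, report@ssRange@maxKb),
        ds_genome_kb = c(report@dsRange@minKb, report@dsRange@maxKb),
        avogadro = report@constants@avogadro,
        mw_ss_per_nt = report@constants@mwSsPerNt,
        mw_ds_per_bp = report@constants@mwDsPerBp),
      unrounded = report@table,
      display = report@display)
    jsonlite::write_json(payload, json, digits = NA, auto_unbox = TRUE,
                         dataframe = "rows")
  }
  invisible(c(tsv = tsv, json = json))
}
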