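#' Nucleic-acid mass constants
#'
#' Physical constants used to convert between DNA mass and genome copies:
#' Avogadro's number and the average molecular weight of one ssDNA nucleotide.
#' The dsDNA weight per base pair is structurally twice the ssDNA weight per
#' nucleotide. The defaults (331.2 g/mol per nt, 662.4 g/mol per bp) reproduce
#' the standard per-virion DNA masses: a 1.8 kb ssDNA genome weighs
#' 9.90e-19 g, a 24.9 kb ssDNA genome 1.37e-17 g and a 50 kb dsDNA genome
#' 5.5e-17 g.
#'
#' @slot avogadro particles per mole.
#' @slot mwSsPerNt grams per mole per ssDNA nucleotide.
#' @slot mwDsPerBp grams per mole per dsDNA base pair (always 2 x mwSsPerNt).
#' @export
setClass("NucleicAcidConstants",
  representation(avogadro = "numeric", mwSsPerNt = "numeric",
                 mwDsPerBp = "numeric"))

setValidity("NucleicAcidConstants", function(object) {
  msgs <- character()
  if (length(object@avogadro) != 1L || object@avogadro <= 0)
    msgs <- c(msgs, "avogadro must be a single positive number")
  if (length(object@mwSsPerNt) != 1L || object@mwSsPerNt <= 0)
    msgs <- c(msgs, "mwSsPerNt must be a single positive number")
  if (!isTRUE(all.equal(object@mwDsPerBp, 2 * object@mwSsPerNt)))
    msgs <- c(msgs, "mwDsPerBp must equal 2 * mwSsPerNt")
  if (length(msgs)) msgs else TRUE
})

#' Genome-size range in kilobases
#'
#' @slot minKb,maxKb lower/upper genome size bound, kilobases; 0 < minKb <= maxKb.
#' @export
setClass("GenomeSizeRange", representation(minKb = "numeric", maxKb = "numeric"))

setValidity("GenomeSizeRange", function(object) {
  if (length(object@minKb) != 1L || length(object@maxKb) != 1L)
    return("minKb and maxKb must be single numbers")
  if (is.na(object@minKb) || is.na(object@maxKb))
    return("genome size bounds must not be NA")
  if (object@minKb <= 0) return("minKb must be > 0")
  if (object@minKb > object@maxKb) return("minKb must be <= maxKb")
  TRUE
})

#' Viral taxonomy with nucleic-acid and genome-size annotations
#'
#' A rooted tree of taxa. Each node carries a rank (root, superkingdom, order,
#' family, genus, species or other), its parent's name, and optionally a
#' nucleic-acid type (ssDNA/dsDNA) and a genome-size range in kb. Genome sizes
#' and nucleic-acid types are usually annotated at family level; lookups walk
#' up the ancestor chain to the nearest annotated node.
#'
#' @slot nodes data.frame with columns name, rank, parent, na_type,
#'   genome_min_kb, genome_max_kb; exactly one root row (parent NA).
#' @export
setClass("ViralTaxonomy", representation(nodes = "data.frame"))

.taxRanks <- c("root", "superkingdom", "order", "family", "genus",
               "species", "other")

setValidity("ViralTaxonomy", function(object) {
  nd <- object@nodes
  req <- c("name", "rank", "parent", "na_type", "genome_min_kb", "genome_max_kb")
  if (!all(req %in% names(nd))) return("nodes is missing required columns")
  if (anyDuplicated(nd$name)) return("duplicate taxon names")
  if (sum(is.na(nd$parent)) != 1L) return("exactly one root (parent NA) required")
  if (!all(nd$rank %in% .taxRanks)) return("invalid rank")
  nonroot <- nd$parent[!is.na(nd$parent)]
  if (!all(nonroot %in% nd$name)) return("parent not found among nodes")
  ok <- !is.na(nd$na_type) | is.na(nd$na_type)  # na_type free-form NA allowed
  if (!all(is.na(nd$na_type) | nd$na_type %in% c("ssDNA", "dsDNA")))
    return("na_type must be ssDNA, dsDNA or NA")
  bad <- !is.na(nd$genome_min_kb) &
    (nd$genome_min_kb <= 0 | nd$genome_min_kb > nd$genome_max_kb)
  if (any(bad)) return("invalid genome size range on some node(s)")
  TRUE
})

#' Genome-copy abundance interval
#'
#' Genome copies per cm^3 sediment as an interval: the upper bound assumes the
#' smallest genome in the assumed size range (many light virions), the lower
#' bound the largest (few heavy virions).
#'
#' @slot low,high copies per cm^3; 0 <= low <= high.
#' @slot sizeAssumption the [GenomeSizeRange-class] that produced the bounds.
#' @slot naType "ssDNA" or "dsDNA".
#' @export
setClass("AbundanceInterval",
  representation(low = "numeric", high = "numeric",
                 sizeAssumption = "GenomeSizeRange", naType = "character"))

setValidity("AbundanceInterval", function(object) {
  if (object@low < 0 || object@high < object@low)
    return("must satisfy 0 <= low <= high")
  if (!object@naType %in% c("ssDNA", "dsDNA")) return("invalid naType")
  TRUE
})

#' A set of sediment samples (measured inputs)
#'
#' One row per depth horizon: direct cell and viral counts (with SDs) and the
#' measured ssDNA and dsDNA mass concentrations in ng per cm^3 sediment.
#'
#' @slot samples data.frame with columns sample_id, depth_top_cm,
#'   depth_bottom_cm, cells_per_cm3, cells_sd, viruses_per_cm3, viruses_sd,
#'   ssdna_ng_per_cm3, dsdna_ng_per_cm3.
#' @export
setClass("SedimentSampleSet", representation(samples = "data.frame"))

.sampleCols <- c("sample_id", "depth_top_cm", "depth_bottom_cm",
                 "cells_per_cm3", "cells_sd", "viruses_per_cm3", "viruses_sd",
                 "ssdna_ng_per_cm3", "dsdna_ng_per_cm3")

setValidity("SedimentSampleSet", function(object) {
  s <- object@samples
  if (!all(.sampleCols %in% names(s))) return("missing required sample columns")
  if (nrow(s) < 1L) return("at least one sample required")
  if (anyDuplicated(s$sample_id)) return("duplicate sample_id")
  if (any(s$depth_top_cm >= s$depth_bottom_cm))
    return("depth_top_cm must be < depth_bottom_cm")
  num <- c("cells_per_cm3", "cells_sd", "viruses_per_cm3", "viruses_sd",
           "ssdna_ng_per_cm3", "dsdna_ng_per_cm3")
  if (any(vapply(s[num], function(x) any(x < 0), logical(1))))
    return("measured quantities must be >= 0")
  TRUE
})

#' Apportionment report
#'
#' Per-sample derived quantities: genome-copy intervals for both nucleic-acid
#' types, relative ssDNA abundance interval (percent), virus-to-cell ratio and
#' fold-difference of the ssDNA estimate against the direct virus count. The
#' `table` slot holds unrounded values; `display` applies the reporting
#' rounding conventions (two significant figures for copies, two decimals for
#' VCR, one decimal for percentages).
#'
#' @slot table,display data.frame, one row per sample ordered by depth.
#' @slot ssRange,dsRange assumed genome-size ranges.
#' @slot constants the [NucleicAcidConstants-class] used.
#' @export
setClass("ApportionReport",
  representation(table = "data.frame", display = "data.frame",
                 ssRange = "GenomeSizeRange", dsRange = "GenomeSizeRange",
                 constants = "NucleicAcidConstants"))

#' Taxonomic composition profile of one library
#'
#' @slot libraryId label.
#' @slot counts named integer vector, reads per category (may include
#'   "unassigned").
#' @slot categoryNaType named character vector parallel to the viral
#'   categories: "ssDNA", "dsDNA" or NA.
#' @slot totalReads total reads in the library.
#' @slot viralReads reads in viral (i.e. non-"unassigned") categories.
#' @export
setClass("TaxonomicProfile",
  representation(libraryId = "character", counts = "numeric",
                 categoryNaType = "character", totalReads = "numeric",
                 viralReads = "numeric"))

setValidity("TaxonomicProfile", function(object) {
  if (is.null(names(object@counts))) return("counts must be named")
  if (any(object@counts < 0)) return("counts must be >= 0")
  if (sum(object@counts) > object@totalReads + 1e-9)
    return("sum of counts exceeds totalReads")
  viral <- setdiff(names(object@counts), "unassigned")
  if (abs(sum(object@counts[viral]) - object@viralReads) > 1e-9)
    return("viralReads must equal the sum over viral categories")
  TRUE
})

#' Library summary statistics
#'
#' @slot libraryId label.
#' @slot nReads read count.
#' @slot meanLength mean read length, bases.
#' @slot totalLengthMb total length, megabases.
#' @slot gcPercent GC content over unambiguous bases, percent.
#' @export
setClass("LibrarySummary",
  representation(libraryId = "character", nReads = "numeric",
                 meanLength = "numeric", totalLengthMb = "numeric",
                 gcPercent = "numeric"))

setValidity("LibrarySummary", function(object) {
  if (object@nReads < 0) return("nReads must be >= 0")
  if (!is.na(object@gcPercent) &&
      (object@gcPercent < 0 || object@gcPercent > 100))
    return("gcPercent must be in [0, 100]")
  totalBases <- object@totalLengthMb * 1e6
  if (object@nReads > 0 &&
      abs(totalBases - object@nReads * object@meanLength) >
        0.01 * max(1, totalBases))
    return("totalLengthMb inconsistent with nReads * meanLength")
  TRUE
})

#' rRNA-contamination QC result
#'
#' @slot libraryId label.
#' @slot nRrnaReads rRNA gene-associated read count.
#' @slot ratioPercent 100 * nRrnaReads / total reads.
#' @slot thresholdPercent pass threshold (default 0.02).
#' @slot pass TRUE iff ratioPercent < thresholdPercent (strict).
#' @export
setClass("RrnaQcResult",
  representation(libraryId = "character", nRrnaReads = "numeric",
                 ratioPercent = "numeric", thresholdPercent = "numeric",
                 pass = "logical"))

setValidity("RrnaQcResult", function(object) {
  if (!identical(object@pass,
                 object@ratioPercent < object@thresholdPercent))
    return("pass flag must equal ratioPercent < thresholdPercent")
  TRUE
})

#' Samples x categories composition matrix
#'
#' Rows are libraries/samples, columns taxonomic categories, values relative
#' abundance proportions; each row sums to 1.
#'
#' @slot values numeric matrix with dimnames.
#' @export
setClass("CompositionMatrix", representation(values = "matrix"))

setValidity("CompositionMatrix", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must have row and column names")
  if (any(v < -1e-12)) return("proportions must be >= 0")
  if (any(abs(rowSums(v) - 1) > 1e-9)) return("rows must sum to 1")
  TRUE
})

#' Fitted principal component model
#'
#' @slot loadings categories x components orthonormal matrix.
#' @slot scores samples x components coordinates.
#' @slot explainedVariance fraction of total variance per component,
#'   non-increasing; sums to 1 over a full-rank fit.
#' @slot center per-category means used for centering.
#' @export
setClass("PcaModel",
  representation(loadings = "matrix", scores = "matrix",
                 explainedVariance = "numeric", center = "numeric"))

setValidity("PcaModel", function(object) {
  L <- object@loadings
  if (ncol(L) > 0) {
    g <- crossprod(L)
    if (max(abs(g - diag(ncol(L)))) > 1e-8)
      return("loadings must be orthonormal")
  }
  ev <- object@explainedVariance
  if (length(ev) && (any(diff(ev) > 1e-12) || sum(ev) > 1 + 1e-9))
    return("explained variance fractions must be non-increasing and sum <= 1")
  TRUE
})

#' Simulation configuration
#'
#' Full parameterization of a synthetic benthic viral community and its
#' observation chain. See the methods vignette for the meaning, unit and
#' rationale of every default.
#'
#' @slot seed root random seed; every simulate* operation derives its own
#'   stream from it deterministically.
#' @slot nSsFamilies,nDsFamilies number of ssDNA / dsDNA viral families.
#' @slot lognormalMuSs,lognormalMuDs,lognormalSigma log-scale parameters of
#'   the per-family particle abundance distribution (copies/cm^3).
#' @slot ssGenomeKbRange ssDNA genome-size envelope, kb.
#' @slot dsGenomeKb dsDNA genome size, kb (point assumption).
#' @slot massNoiseCv multiplicative lognormal CV of DNA mass measurements.
#' @slot mdaSsBias multiplicative MDA amplification advantage of circular
#'   ssDNA templates (>= 1).
#' @slot s1CarryoverF fraction of ssDNA material escaping S1 nuclease
#'   digestion and carried into the dsDNA fraction, in [0, 1].
#' @slot stainEfficiencySs,stainEfficiencyDs probability that an ssDNA / dsDNA
#'   virion is detected in the SYBR-stained direct count, in [0, 1].
#' @slot cellsPerCm3 expected prokaryotic cell count per cm^3.
#' @slot readDepth reads per simulated library.
#' @slot noHitFraction fraction of reads with no database hit.
#' @slot decoyFraction probability that a read receives additional decoy hits.
#' @export
setClass("SimulationConfig",
  representation(seed = "integer",
                 nSsFamilies = "integer", nDsFamilies = "integer",
                 lognormalMuSs = "numeric", lognormalMuDs = "numeric",
                 lognormalSigma = "numeric",
                 ssGenomeKbRange = "GenomeSizeRange", dsGenomeKb = "numeric",
                 massNoiseCv = "numeric", mdaSsBias = "numeric",
                 s1CarryoverF = "numeric",
                 stainEfficiencySs = "numeric", stainEfficiencyDs = "numeric",
                 cellsPerCm3 = "numeric", readDepth = "integer",
                 noHitFraction = "numeric", decoyFraction = "numeric"))

setValidity("SimulationConfig", function(object) {
  inUnit <- function(x) length(x) == 1L && x >= 0 && x <= 1
  msgs <- character()
  if (!inUnit(object@s1CarryoverF)) msgs <- c(msgs, "s1CarryoverF not in [0,1]")
  if (!inUnit(object@stainEfficiencySs) || !inUnit(object@stainEfficiencyDs))
    msgs <- c(msgs, "stain efficiencies must be in [0,1]")
  if (!inUnit(object@noHitFraction) || !inUnit(object@decoyFraction))
    msgs <- c(msgs, "noHitFraction/decoyFraction must be in [0,1]")
  if (object@massNoiseCv < 0) msgs <- c(msgs, "massNoiseCv must be >= 0")
  if (object@mdaSsBias < 1) msgs <- c(msgs, "mdaSsBias must be >= 1")
  if (object@readDepth <= 0L) msgs <- c(msgs, "readDepth must be > 0")
  if (object@nSsFamilies < 0L || object@nDsFamilies < 0L ||
      object@nSsFamilies + object@nDsFamilies == 0L)
    msgs <- c(msgs, "need at least one viral family")
  if (length(msgs)) msgs else TRUE
})

#' Ground-truth state of a synthetic community
#'
#' @slot families data.frame with columns family, na_type, genome_kb,
#'   abundance (true particle copies/cm^3).
#' @export
setClass("GroundTruth", representation(families = "data.frame"))

setValidity("GroundTruth", function(object) {
  f <- object@families
  req <- c("family", "na_type", "genome_kb", "abundance")
  if (!all(req %in% names(f))) return("missing required columns")
  if (any(f$abundance < 0)) return("abundances must be >= 0")
  if (!all(f$na_type %in% c("ssDNA", "dsDNA"))) return("invalid na_type")
  TRUE
})
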