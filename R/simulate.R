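#' Construct a simulation configuration
#'
#' Defaults describe a "tohoku-like" benthic community: an ssDNA-dominated
#' assemblage whose measured magnitudes match surface bathyal sediment
#' (ssDNA masses of a few ng/cm^3, dsDNA a few tenths of ng/cm^3, direct
#' counts of 10^5-10^7 particles/cm^3). See the methods vignette for every
#' default's rationale.
#'
#' @param seed root random seed; every simulate* operation derives its own
#'   deterministic sub-stream from it.
#' @param nSsFamilies,nDsFamilies numbers of ssDNA / dsDNA families.
#' @param lognormalMuSs,lognormalMuDs,lognormalSigma log-scale location (ss /
#'   ds) and common scale of per-family particle abundances.
#' @param ssGenomeKbRange envelope from which ssDNA family genome sizes are
#'   drawn uniformly, kb.
#' @param dsGenomeKb dsDNA genome size, kb.
#' @param massNoiseCv multiplicative lognormal CV on measured DNA masses.
#' @param mdaSsBias MDA amplification advantage of ssDNA templates (>= 1).
#' @param s1CarryoverF fraction of ssDNA mass surviving S1 digestion into the
#'   dsDNA fraction.
#' @param stainEfficiencySs,stainEfficiencyDs per-virion detection
#'   probabilities in the direct count.
#' @param cellsPerCm3 expected prokaryotic cell abundance.
#' @param readDepth reads per simulated library.
#' @param noHitFraction fraction of reads receiving no database hit.
#' @param decoyFraction probability a read carries extra decoy hits.
#' @return a validated [SimulationConfig-class].
#' @export
simulationConfig <- function(seed = 1L,
                             nSsFamilies = 5L, nDsFamilies = 3L,
                             lognormalMuSs = 17.6, lognormalMuDs = 14.0,
                             lognormalSigma = 1.0,
                             ssGenomeKbRange = genomeSizeRange(1.8, 24.9),
                             dsGenomeKb = 50,
                             massNoiseCv = 0.1, mdaSsBias = 10,
                             s1CarryoverF = 0.05,
                             stainEfficiencySs = 0.002,
                             stainEfficiencyDs = 0.8,
                             cellsPerCm3 = 5e6,
                             readDepth = 1e5L,
                             noHitFraction = 0.2, decoyFraction = 0.3) {
  new("SimulationConfig", seed = as.integer(seed),
      nSsFamilies = as.integer(nSsFamilies),
      nDsFamilies = as.integer(nDsFamilies),
      lognormalMuSs = lognormalMuSs, lognormalMuDs = lognormalMuDs,
      lognormalSigma = lognormalSigma,
      ssGenomeKbRange = ssGenomeKbRange, dsGenomeKb = dsGenomeKb,
      massNoiseCv = massNoiseCv, mdaSsBias = mdaSsBias,
      s1CarryoverF = s1CarryoverF,
      stainEfficiencySs = stainEfficiencySs,
      stainEfficiencyDs = stainEfficiencyDs,
      cellsPerCm3 = cellsPerCm3, readDepth = as.integer(readDepth),
      noHitFraction = noHitFraction, decoyFraction = decoyFraction)
}

#' Simulate the true community state
#'
#' Draws per-family true particle abundances log-normally (copies/cm^3) and
#' ssDNA genome sizes uniformly within the configured envelope; dsDNA
#' families all carry the configured point genome size. Deterministic under a
#' fixed seed.
#'
#' @param config a [SimulationConfig-class].
#' @return a [GroundTruth-class].
#' @export
simulateCommunity <- function(config) {
  withStream(config@seed, "community", {
    nss <- config@nSsFamilies
    nds <- config@nDsFamilies
    fam <- c(if (nss > 0) sprintf("synthSsFamily%02d", seq_len(nss)),
             if (nds > 0) sprintf("synthDsFamily%02d", seq_len(nds)))
    naType <- c(rep("ssDNA", nss), rep("dsDNA", nds))
    sizes <- c(if (nss > 0) runif(nss, config@ssGenomeKbRange@minKb,
                                  config@ssGenomeKbRange@maxKb),
               rep(config@dsGenomeKb, nds))
    ab <- c(if (nss > 0) rlnorm(nss, config@lognormalMuSs,
                                config@lognormalSigma),
            if (nds > 0) rlnorm(nds, config@lognormalMuDs,
                                config@lognormalSigma))
    new("GroundTruth",
        families = data.frame(family = fam, na_type = naType,
                              genome_kb = sizes, abundance = ab,
                              stringsAsFactors = FALSE))
  })
}

#' Taxonomy for a synthetic community
#'
#' Wraps the ground-truth families in a minimal rooted taxonomy (root,
#' nucleic-acid type nodes, one family node per synthetic family), so the
#' profiler can assign simulated hit tables.
#'
#' @param truth a [GroundTruth-class].
#' @return a [ViralTaxonomy-class].
#' @export
groundTruthTaxonomy <- function(truth) {
  f <- truth@families
  rows <- data.frame(
    name = c("Viruses", "ssDNA viruses", "dsDNA viruses", f$family),
    rank = c("root", "other", "other", rep("family", nrow(f))),
    parent = c(NA, "Viruses", "Viruses",
               ifelse(f$na_type == "ssDNA", "ssDNA viruses", "dsDNA viruses")),
    na_type = c(NA, "ssDNA", "dsDNA", f$na_type),
    genome_min_kb = c(NA, NA, NA, f$genome_kb),
    genome_max_kb = c(NA, NA, NA, f$genome_kb),
    stringsAsFactors = FALSE)
  buildTaxonomy(rows)
}

# noise-free expected mass concentrations (grams/cm^3) per channel
.expectedMassesG <- function(truth, config, constants) {
  f <- truth@families
  perVirion <- vapply(seq_len(nrow(f)), function(i)
    virionDnaMass(f$genome_kb[i], f$na_type[i], constants), numeric(1))
  massSs <- sum((f$abundance * perVirion)[f$na_type == "ssDNA"])
  massDs <- sum((f$abundance * perVirion)[f$na_type == "dsDNA"])
  fC <- config@s1CarryoverF
  c(ss = (1 - fC) * massSs, ds = massDs + fC * massSs)
}

#' Simulate measured DNA mass concentrations
#'
#' The inverse of the mass-apportioning estimator: each channel's true mass
#' is the abundance-weighted sum of per-virion genome masses. A fraction
#' `s1CarryoverF` of the ssDNA mass escapes S1 nuclease digestion and is
#' measured in the dsDNA channel instead. Measurement noise is multiplicative
#' lognormal with the configured CV (mean-preserving; noise-free when
#' `massNoiseCv = 0`).
#'
#' @param truth a [GroundTruth-class].
#' @param config a [SimulationConfig-class].
#' @param constants a [NucleicAcidConstants-class].
#' @return named numeric `c(ss =, ds =)` in ng/cm^3.
#' @export
simulateDnaMasses <- function(truth, config,
                              constants = nucleicAcidConstants()) {
  expected <- .expectedMassesG(truth, config, constants)
  noise <- withStream(config@seed, "masses", {
    if (config@massNoiseCv > 0) {
      sdlog <- sqrt(log(1 + config@massNoiseCv^2))
      rlnorm(2, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else c(1, 1)
  })
  setNames(expected * noise * 1e9, c("ss", "ds"))  # grams -> ng
}

# per-family read weights for the two library types
.libraryWeights <- function(truth, config) {
  f <- truth@families
  isSs <- f$na_type == "ssDNA"
  wSs <- f$abundance * f$genome_kb *
    ifelse(isSs, (1 - config@s1CarryoverF) * config@mdaSsBias, 0)
  wDs <- f$abundance * f$genome_kb *
    ifelse(isSs, config@s1CarryoverF, 1)
  list(ss = setNames(wSs, f$family), ds = setNames(wDs, f$family))
}

#' Simulate per-library read profiles
#'
#' Reads are drawn multinomially with per-family weights proportional to
#' abundance x genome size, with ssDNA families amplified by the MDA bias in
#' the ssDNA library; the dsDNA library's ssDNA weights are scaled by the S1
#' carryover fraction (0 when digestion is complete).
#'
#' @inheritParams simulateDnaMasses
#' @return named list of two [TaxonomicProfile-class] objects (`ss`, `ds`).
#' @export
simulateReadProfiles <- function(truth, config) {
  w <- .libraryWeights(truth, config)
  f <- truth@families
  nt <- setNames(f$na_type, f$family)
  withStream(config@seed, "profiles", {
    lapply(setNames(c("ss", "ds"), c("ss", "ds")), function(lib) {
      wi <- w[[lib]]
      counts <- if (sum(wi) > 0) {
        drop(rmultinom(1, config@readDepth, wi / sum(wi)))
      } else setNames(rep(0, length(wi)), names(wi))
      taxonomicProfile(counts, nt, libraryId = paste0(lib, "_library"),
                       totalReads = config@readDepth)
    })
  })
}

#' Simulate fluorescence-based direct counts
#'
#' The direct count detects each virion with a stain-dependent probability
#' (small ssDNA genomes stain poorly), so the expected count is
#' `e_ss * sum(V_ss) + e_ds * sum(V_ds)`; realized counts are Poisson. Cells
#' are drawn independently around the configured magnitude. The expectations
#' are attached as attributes for recovery testing.
#'
#' @inheritParams simulateDnaMasses
#' @return data.frame row with viruses_per_cm3, viruses_sd, cells_per_cm3,
#'   cells_sd; attributes `expectedViruses`, `expectedCells`.
#' @export
simulateDirectCounts <- function(truth, config) {
  f <- truth@families
  lambdaV <- config@stainEfficiencySs * sum(f$abundance[f$na_type == "ssDNA"]) +
    config@stainEfficiencyDs * sum(f$abundance[f$na_type == "dsDNA"])
  lambdaC <- config@cellsPerCm3
  withStream(config@seed, "counts", {
    out <- data.frame(viruses_per_cm3 = rpois(1, lambdaV),
                      viruses_sd = sqrt(lambdaV),
                      cells_per_cm3 = rpois(1, lambdaC),
                      cells_sd = sqrt(lambdaC))
    attr(out, "expectedViruses") <- lambdaV
    attr(out, "expectedCells") <- lambdaC
    out
  })
}

#' Simulate a BLAST tabular hit table for a profile
#'
#' Emits 12-column tabular hit lines for each read of a profile: a
#' configured fraction of reads gets no hits at all; every other read gets a
#' best hit on its true family (bitscore 80-200, E-value well below 1e-5)
#' and, with probability `decoyFraction`, 1-4 decoy hits on random taxa at
#' 40-88% of the best bitscore — below the default top-10% LCA retention
#' window, so decoys never displace the true assignment at default
#' parameters.
#'
#' @param profile a [TaxonomicProfile-class] whose categories resolve in
#'   `tree`.
#' @param tree a [ViralTaxonomy-class].
#' @param config a [SimulationConfig-class].
#' @return list with `lines` (character vector of tabular hit lines), `map`
#'   (subject-to-taxon data.frame) and `truthLabels` (data.frame query_id,
#'   true_taxon; "unassigned" marks no-hit reads).
#' @export
simulateHitTable <- function(profile, tree, config) {
  cats <- setdiff(names(profile@counts), "unassigned")
  vmAssert(all(cats %in% tree@nodes$name), "viromassUnknownTaxonError",
           "profile categories must resolve in the tree")
  reads <- rep(cats, times = profile@counts[cats])
  allTaxa <- tree@nodes$name[tree@nodes$rank == "family"]
  withStream(config@seed, "hits", {
    n <- length(reads)
    qids <- sprintf("read%06d", seq_len(n))
    noHit <- runif(n) < config@noHitFraction
    lines <- character(0)
    subjects <- character(0)
    subjTaxa <- character(0)
    mkLine <- function(qid, taxon, bits) {
      subj <- sprintf("sbj_%s_%03d", gsub("[^A-Za-z0-9]", "", taxon),
                      sample.int(999, 1))
      subjects <<- c(subjects, subj)
      subjTaxa <<- c(subjTaxa, taxon)
      evalue <- 10^(-(bits / 10) - 3)  # monotone in bitscore, always < 1e-5
      sprintf("%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.2e\t%.1f",
              qid, subj, runif(1, 60, 100), sample(30:200, 1), 0L, 0L,
              1L, 100L, 1L, 100L, evalue, bits)
    }
    for (i in seq_len(n)) {
      if (noHit[i]) next
      best <- runif(1, 80, 200)
      lines <- c(lines, mkLine(qids[i], reads[i], best))
      if (runif(1) < config@decoyFraction) {
        for (k in seq_len(sample.int(4, 1))) {
          decoyTaxon <- sample(allTaxa, 1)
          lines <- c(lines, mkLine(qids[i], decoyTaxon,
                                   best * runif(1, 0.40, 0.88)))
        }
      }
    }
    list(lines = lines,
         map = unique(data.frame(subject = subjects, taxon = subjTaxa,
                                 stringsAsFactors = FALSE)),
         truthLabels = data.frame(
           query_id = qids,
           true_taxon = ifelse(noHit, "unassigned", reads),
           stringsAsFactors = FALSE))
  })
}

#' Simulate random reads for library summaries
#'
#' Uniform-composition A/C/G/T reads (no sequence-level realism); lengths
#' uniform in `lengthRange`. Used to exercise FASTA/FASTQ summarization.
#'
#' @param n number of reads.
#' @param lengthRange integer range of read lengths, bases.
#' @param gc target GC fraction.
#' @param seed random seed.
#' @return a `Biostrings::DNAStringSet`.
#' @export
simulateReads <- function(n, lengthRange = c(150L, 300L), gc = 0.5,
                          seed = 1L) {
  withStream(seed, "reads", {
    lens <- sample(lengthRange[1]:lengthRange[2], n, replace = TRUE)
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(lens, function(L)
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""),
      character(1))
    Biostrings::DNAStringSet(setNames(seqs, sprintf("read%06d", seq_len(n))))
  })
}

#' Write a full simulated study to a directory
#'
#' Emits everything the pipeline consumes: a sediment-sample TSV (apportion
#' input; one row per simulated depth horizon, each an independent community
#' drawn with sub-seed `seed + horizon`), profile TSVs, a hit table with its
#' subject map, FASTA reads, and a ground-truth JSON.
#'
#' @param config a [SimulationConfig-class].
#' @param dir output directory (created if needed).
#' @param nHorizons number of depth horizons to simulate.
#' @return invisibly, a named list of written paths.
#' @export
writeSimulation <- function(config, dir, nHorizons = 3L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  constants <- nucleicAcidConstants()
  sampleRows <- list()
  truths <- list()
  profiles <- list()
  for (h in seq_len(nHorizons)) {
    cfgH <- config
    cfgH@seed <- config@seed + (h - 1L)
    truth <- simulateCommunity(cfgH)
    masses <- simulateDnaMasses(truth, cfgH, constants)
    counts <- simulateDirectCounts(truth, cfgH)
    sampleRows[[h]] <- data.frame(
      sample_id = sprintf("sim%02d", h),
      depth_top_cm = (h - 1) * 5, depth_bottom_cm = (h - 1) * 5 + 2,
      cells_per_cm3 = counts$cells_per_cm3, cells_sd = counts$cells_sd,
      viruses_per_cm3 = counts$viruses_per_cm3,
      viruses_sd = counts$viruses_sd,
      ssdna_ng_per_cm3 = masses[["ss"]], dsdna_ng_per_cm3 = masses[["ds"]],
      stringsAsFactors = FALSE)
    truths[[h]] <- truth@families
    prof <- simulateReadProfiles(truth, cfgH)
    for (lib in names(prof)) {
      prof[[lib]]@libraryId <- sprintf("sim%02d_%s", h, lib)
      profiles[[prof[[lib]]@libraryId]] <- prof[[lib]]
    }
  }
  paths <- list(
    samples = file.path(dir, "samples.tsv"),
    profiles = file.path(dir, "profiles.tsv"),
    hits = file.path(dir, "hits.tsv"),
    map = file.path(dir, "subject_map.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    reads = file.path(dir, "reads.fasta"),
    truth = file.path(dir, "truth.json"))
  write.table(do.call(rbind, sampleRows), paths$samples, sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeProfiles(profiles, paths$profiles)
  truth1 <- simulateCommunity(config)
  tree <- groundTruthTaxonomy(truth1)
  writeTaxonomy(tree, paths$taxonomy)
  smallProfile <- simulateReadProfiles(truth1,
    { c2 <- config; c2@readDepth <- min(config@readDepth, 2000L); c2 })$ss
  hitTab <- simulateHitTable(smallProfile, tree, config)
  writeLines(hitTab$lines, paths$hits)
  write.table(hitTab$map, paths$map, sep = "\t", quote = FALSE,
              row.names = FALSE)
  reads <- simulateReads(500L, seed = config@seed)
  Biostrings::writeXStringSet(reads, paths$reads)
  jsonlite::write_json(truths, paths$truth, digits = NA, dataframe = "rows")
  invisible(paths)
}
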