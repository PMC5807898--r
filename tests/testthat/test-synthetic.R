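const <- nucleicAcidConstants()

test_that("community simulation is deterministic and respects composition", {
  cfg <- simulationConfig(seed = 12L)
  t1 <- simulateCommunity(cfg)
  t2 <- simulateCommunity(cfg)
  expect_identical(truthFamilies(t1), truthFamilies(t2))

  pureDs <- simulateCommunity(simulationConfig(seed = 2L, nSsFamilies = 0L))
  expect_true(all(truthFamilies(pureDs)$na_type == "dsDNA"))

  f <- truthFamilies(t1)
  expect_true(all(f$genome_kb[f$na_type == "ssDNA"] >= 1.8 &
                  f$genome_kb[f$na_type == "ssDNA"] <= 24.9))
  expect_true(all(f$genome_kb[f$na_type == "dsDNA"] == 50))
})

test_that("default total abundance stays in the plausible benthic window", {
  totals <- vapply(1:100, function(s)
    sum(truthFamilies(simulateCommunity(simulationConfig(seed = s)))$abundance),
    numeric(1))
  expect_true(all(totals >= 1e6 & totals <= 1e10))
})

test_that("mass simulation inverts the apportioning estimator", {
  # single family, known abundance and size, no noise, no carryover
  truth <- new("GroundTruth", families = data.frame(
    family = "synthSsFamily01", na_type = "ssDNA", genome_kb = 1.8,
    abundance = 1e9, stringsAsFactors = FALSE))
  cfg <- simulationConfig(seed = 1L, massNoiseCv = 0, s1CarryoverF = 0)
  masses <- simulateDnaMasses(truth, cfg, const)
  expect_equal(unname(masses[["ss"]]), 0.99, tolerance = 1e-3)
  expect_equal(unname(masses[["ds"]]), 0)

  # inverse identity: a degenerate range at the true size recovers V exactly
  est <- copiesInterval(masses[["ss"]], "ssDNA", genomeSizeRange(1.8), const)
  expect_equal(abundanceLow(est), 1e9, tolerance = 1e-12)
  expect_equal(abundanceHigh(est), 1e9, tolerance = 1e-12)

  # complete S1 failure moves all ssDNA mass into the dsDNA channel
  cfgF1 <- simulationConfig(seed = 1L, massNoiseCv = 0, s1CarryoverF = 1)
  mF1 <- simulateDnaMasses(truth, cfgF1, const)
  expect_equal(unname(mF1[["ss"]]), 0)
  expect_equal(unname(mF1[["ds"]]), unname(masses[["ss"]]))
})

test_that("read profiles follow the weighted multinomial model", {
  cfg <- simulationConfig(seed = 8L, nSsFamilies = 1L, nDsFamilies = 0L,
                          mdaSsBias = 1, readDepth = 1000L)
  truth <- simulateCommunity(cfg)
  prof <- simulateReadProfiles(truth, cfg)
  expect_equal(sum(profileCounts(prof$ss)), 1000)
  expect_equal(length(profileCounts(prof$ss)[profileCounts(prof$ss) > 0]), 1L)

  # two equal-weight families: counts within 4 binomial SDs of 50/50
  truth2 <- new("GroundTruth", families = data.frame(
    family = c("synthSsFamily01", "synthSsFamily02"),
    na_type = "ssDNA", genome_kb = c(10, 5), abundance = c(1e8, 2e8),
    stringsAsFactors = FALSE))
  cfg2 <- simulationConfig(seed = 9L, readDepth = 1e6L, s1CarryoverF = 0)
  prof2 <- simulateReadProfiles(truth2, cfg2)
  counts <- profileCounts(prof2$ss)
  n <- 1e6
  expect_lt(abs(counts[["synthSsFamily01"]] - n / 2), 4 * sqrt(n * 0.25))

  # increasing the MDA bias strictly increases the expected ssDNA share
  truthMix <- new("GroundTruth", families = data.frame(
    family = c("synthSsFamily01", "synthDsFamily01"),
    na_type = c("ssDNA", "dsDNA"), genome_kb = c(5, 50),
    abundance = c(1e8, 1e7), stringsAsFactors = FALSE))
  share <- vapply(c(1, 5, 25), function(b) {
    w <- truthMix@families$abundance * truthMix@families$genome_kb *
      c(b, 0)  # ssDNA weight in the ssDNA library; dsDNA excluded there
    w[1] / sum(truthMix@families$abundance * truthMix@families$genome_kb *
                 c(b, 1))
  }, numeric(1))
  expect_true(all(diff(share) > 0))
})

test_that("direct counts reflect stain-dependent detection efficiencies", {
  truth <- simulateCommunity(simulationConfig(seed = 4L))
  f <- truthFamilies(truth)
  cfgDsOnly <- simulationConfig(seed = 4L, stainEfficiencySs = 0,
                                stainEfficiencyDs = 1)
  counts <- simulateDirectCounts(truth, cfgDsOnly)
  expect_equal(attr(counts, "expectedViruses"),
               sum(f$abundance[f$na_type == "dsDNA"]))
  cfgAll <- simulationConfig(seed = 4L, stainEfficiencySs = 1,
                             stainEfficiencyDs = 1)
  countsAll <- simulateDirectCounts(truth, cfgAll)
  expect_equal(attr(countsAll, "expectedViruses"), sum(f$abundance))
  # Poisson draw stays within 6 SDs of its expectation
  expect_lt(abs(countsAll$viruses_per_cm3 - sum(f$abundance)),
            6 * sqrt(sum(f$abundance)))
})

test_that("defaults place the ssDNA fold-underestimation in the observed regime", {
  folds <- vapply(1:50, function(s) {
    cfg <- simulationConfig(seed = s)
    truth <- simulateCommunity(cfg)
    f <- truthFamilies(truth)
    counts <- simulateDirectCounts(truth, cfg)
    sum(f$abundance[f$na_type == "ssDNA"]) / counts$viruses_per_cm3
  }, numeric(1))
  expect_gt(median(folds), 20)
  expect_lt(median(folds), 500)
  expect_gt(max(folds), 100)
})

test_that("hit tables drive the profiler back to the generating profile", {
  cfg <- simulationConfig(seed = 21L, readDepth = 3000L,
                          noHitFraction = 0, decoyFraction = 0)
  truth <- simulateCommunity(cfg)
  tree <- groundTruthTaxonomy(truth)
  prof <- simulateReadProfiles(truth, cfg)$ss
  tab <- simulateHitTable(prof, tree, cfg)
  hits <- mapSubjects(parseBlastTab(tab$lines), tab$map)
  asg <- assignReads(hits, tree)
  # one hit per read, no decoys: every read recovers its true family
  truthTab <- table(tab$truthLabels$true_taxon)
  gotTab <- table(asg$assigned_taxon)
  expect_equal(gotTab[names(truthTab)], truthTab, ignore_attr = TRUE)

  # all-no-hit boundary: the profile is 100% unassigned
  cfgNone <- simulationConfig(seed = 22L, readDepth = 500L, noHitFraction = 1)
  profN <- simulateReadProfiles(truth, cfgNone)$ss
  tabN <- simulateHitTable(profN, tree, cfgNone)
  expect_equal(length(tabN$lines), 0L)
  expect_true(all(tabN$truthLabels$true_taxon == "unassigned"))
})

test_that("end-to-end profile recovery at default decoy settings", {
  cfg <- simulationConfig(seed = 31L, readDepth = 3000L)
  truth <- simulateCommunity(cfg)
  tree <- groundTruthTaxonomy(truth)
  prof <- simulateReadProfiles(truth, cfg)$ss
  tab <- simulateHitTable(prof, tree, cfg)
  hits <- mapSubjects(parseBlastTab(tab$lines), tab$map)
  asg <- assignReads(hits, tree)
  got <- buildProfile(asg, tree, "family")
  want <- profileCounts(prof)
  wantFrac <- want / sum(want)
  gotCounts <- profileCounts(got)
  gotFrac <- gotCounts[names(want)] / viralReads(got)
  gotFrac[is.na(gotFrac)] <- 0
  expect_lt(max(abs(gotFrac - wantFrac)), 0.01)
})

test_that("every simulate operation is bit-reproducible and stream-isolated", {
  cfg <- simulationConfig(seed = 77L)
  truth <- simulateCommunity(cfg)
  expect_identical(simulateDnaMasses(truth, cfg), simulateDnaMasses(truth, cfg))
  expect_identical(simulateReadProfiles(truth, cfg)$ss@counts,
                   simulateReadProfiles(truth, cfg)$ss@counts)
  expect_identical(simulateDirectCounts(truth, cfg)$viruses_per_cm3,
                   simulateDirectCounts(truth, cfg)$viruses_per_cm3)
  # stream isolation: drawing masses does not perturb subsequent profiles
  p1 <- simulateReadProfiles(truth, cfg)
  invisible(simulateDnaMasses(truth, cfg))
  p2 <- simulateReadProfiles(truth, cfg)
  expect_identical(p1$ss@counts, p2$ss@counts)
})

test_that("noise-free simulation is inverted exactly; noisy intervals cover truth", {
  # exact inversion at cv = 0, f = 0 with known genome sizes
  cfg0 <- simulationConfig(seed = 50L, massNoiseCv = 0, s1CarryoverF = 0)
  truth0 <- simulateCommunity(cfg0)
  f0 <- truthFamilies(truth0)
  masses0 <- simulateDnaMasses(truth0, cfg0, const)
  perFam <- vapply(which(f0$na_type == "ssDNA"), function(i) {
    mass <- f0$abundance[i] * virionDnaMass(f0$genome_kb[i], "ssDNA", const)
    est <- copiesInterval(mass * 1e9, "ssDNA",
                          genomeSizeRange(f0$genome_kb[i]), const)
    abs(abundanceLow(est) - f0$abundance[i]) / f0$abundance[i]
  }, numeric(1))
  expect_lt(max(perFam), 1e-12)

  # 200 seeded replicates at cv = 0.1. Containment of the truth by the
  # assumed-envelope interval is exactly characterized by the noise factor
  # staying within the interval's structural slack (the ratio between the
  # envelope bounds and the community's abundance-weighted mean genome size);
  # we assert that characterization replicate-by-replicate, that failures of
  # it are the rare tail they should be at this CV, and the midpoint-error
  # bound that containment implies.
  nRep <- 200
  contained <- logical(nRep)
  predicted <- logical(nRep)
  sqErr <- numeric(nRep)
  sqSpread <- numeric(nRep)
  for (r in seq_len(nRep)) {
    cfg <- simulationConfig(seed = 1000L + r, massNoiseCv = 0.1,
                            s1CarryoverF = 0)
    truth <- simulateCommunity(cfg)
    f <- truthFamilies(truth)
    fs <- f[f$na_type == "ssDNA", ]
    ssTrue <- sum(fs$abundance)
    masses <- simulateDnaMasses(truth, cfg, const)
    est <- copiesInterval(masses[["ss"]], "ssDNA",
                          genomeSizeRange(1.8, 24.9), const)
    contained[r] <- ssTrue >= abundanceLow(est) & ssTrue <= abundanceHigh(est)
    # the realized noise factor, recovered against the noise-free channel
    cfg0 <- cfg; cfg0@massNoiseCv <- 0
    noise <- masses[["ss"]] / simulateDnaMasses(truth, cfg0, const)[["ss"]]
    wMean <- sum(fs$abundance * fs$genome_kb) / ssTrue
    predicted[r] <- noise <= 24.9 / wMean & noise >= 1.8 / wMean
    mid <- (abundanceLow(est) + abundanceHigh(est)) / 2
    sqErr[r] <- ((mid - ssTrue) / ssTrue)^2
    sqSpread[r] <- ((abundanceHigh(est) - abundanceLow(est)) / (2 * ssTrue))^2
  }
  expect_identical(contained, predicted)
  expect_lt(mean(!contained), 0.05)
  expect_lte(sqrt(mean(sqErr[contained])),
             0.1 + sqrt(mean(sqSpread[contained])))
})
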