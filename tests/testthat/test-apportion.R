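const <- nucleicAcidConstants()

test_that("per-virion DNA mass reproduces the canonical constants", {
  expect_equal(virionDnaMass(1.8, "ssDNA", const), 9.90e-19,
               tolerance = 1e-3)
  expect_equal(virionDnaMass(24.9, "ssDNA", const), 1.37e-17,
               tolerance = 1e-3)
  expect_equal(virionDnaMass(50, "dsDNA", const), 5.5e-17,
               tolerance = 1e-3)
  # dsDNA weighs exactly twice ssDNA at any length, and mass is linear in kb
  for (L in c(0.5, 1.8, 7, 50, 300)) {
    expect_equal(virionDnaMass(L, "dsDNA", const),
                 2 * virionDnaMass(L, "ssDNA", const))
    expect_equal(virionDnaMass(2 * L, "ssDNA", const),
                 2 * virionDnaMass(L, "ssDNA", const))
  }
  expect_error(virionDnaMass(0, "ssDNA", const),
               class = "viromassDomainError")
})

test_that("copies interval divides mass by the size-range virion masses", {
  ss <- copiesInterval(2.87, "ssDNA", genomeSizeRange(1.8, 24.9), const)
  expect_equal(roundCopies(abundanceHigh(ss)), 2.9e9)
  ds <- copiesInterval(0.29, "dsDNA", genomeSizeRange(50), const)
  expect_equal(abundanceLow(ds), abundanceHigh(ds))
  expect_equal(roundCopies(abundanceHigh(ds)), 5.3e6)
  z <- copiesInterval(0, "ssDNA", genomeSizeRange(1.8, 24.9), const)
  expect_equal(c(abundanceLow(z), abundanceHigh(z)), c(0, 0))
})

test_that("copies interval is homogeneous and monotone in genome size", {
  set.seed(7)
  for (i in 1:25) {
    C <- runif(1, 0.01, 10)
    r <- sort(runif(2, 1, 100))
    a <- copiesInterval(C, "ssDNA", genomeSizeRange(r[1], r[2]), const)
    b <- copiesInterval(2 * C, "ssDNA", genomeSizeRange(r[1], r[2]), const)
    expect_equal(abundanceLow(b), 2 * abundanceLow(a))
    expect_equal(abundanceHigh(b), 2 * abundanceHigh(a))
    # widening the range never narrows the interval
    wide <- copiesInterval(C, "ssDNA",
                           genomeSizeRange(r[1] * 0.5, r[2] * 2), const)
    expect_lte(abundanceLow(wide), abundanceLow(a))
    expect_gte(abundanceHigh(wide), abundanceHigh(a))
    # for fixed C both bounds are non-increasing in genome size
    shifted <- copiesInterval(C, "ssDNA",
                              genomeSizeRange(r[1] * 1.5, r[2] * 1.5), const)
    expect_lte(abundanceLow(shifted), abundanceLow(a))
    expect_lte(abundanceHigh(shifted), abundanceHigh(a))
  }
})

test_that("relative ssDNA percentage uses the conservative pairing", {
  ss <- copiesInterval(2.87, "ssDNA", genomeSizeRange(1.8, 24.9), const)
  ds <- copiesInterval(0.29, "dsDNA", genomeSizeRange(50), const)
  rel <- relativeSsdnaPercent(ss, ds)
  expect_equal(unname(round(rel, 1)), c(97.5, 99.8))

  mkPoint <- function(v, nt) copiesInterval(
    v * virionDnaMass(10, nt, const) * 1e9, nt, genomeSizeRange(10), const)
  expect_equal(unname(relativeSsdnaPercent(
    mkPoint(1e6, "ssDNA"), copiesInterval(0, "dsDNA", genomeSizeRange(50)))),
    c(100, 100))
  eq <- relativeSsdnaPercent(mkPoint(5e5, "ssDNA"), mkPoint(5e5, "dsDNA"))
  expect_equal(unname(eq), c(50, 50), tolerance = 1e-9)
  zero <- copiesInterval(0, "ssDNA", genomeSizeRange(1.8, 24.9))
  zeroDs <- copiesInterval(0, "dsDNA", genomeSizeRange(50))
  expect_error(relativeSsdnaPercent(zero, zeroDs),
               class = "viromassUndefinedRatioError")
})

test_that("relative percentage is monotone in each abundance", {
  mk <- function(lo, hi, nt) new("AbundanceInterval", low = lo, high = hi,
                                 sizeAssumption = genomeSizeRange(1, 2),
                                 naType = nt)
  base <- relativeSsdnaPercent(mk(1e8, 2e8, "ssDNA"), mk(1e6, 2e6, "dsDNA"))
  moreSs <- relativeSsdnaPercent(mk(2e8, 4e8, "ssDNA"), mk(1e6, 2e6, "dsDNA"))
  moreDs <- relativeSsdnaPercent(mk(1e8, 2e8, "ssDNA"), mk(2e6, 4e6, "dsDNA"))
  expect_true(all(moreSs >= base))
  expect_true(all(moreDs <= base))
})

test_that("virus-to-cell ratio matches the measured depth profile", {
  expect_equal(roundVcr(vcr(5.3e6, 9.1e6)), 0.58)
  expect_equal(roundVcr(vcr(5.1e5, 1.6e6)), 0.32)
  expect_equal(vcr(7, 7), 1)
  expect_error(vcr(1, 0), class = "viromassDomainError")
})

test_that("fold-vs-direct compares the estimate against the direct count", {
  # recomputed from the deepest horizon's measured inputs
  est <- copiesInterval(1.50, "ssDNA", genomeSizeRange(1.8, 24.9), const)
  fold <- foldVsDirect(est, 5.1e5)
  expect_equal(unname(fold[["low"]]), 214.8, tolerance = 0.005)
  unit <- new("AbundanceInterval", low = 5e5, high = 5e5,
              sizeAssumption = genomeSizeRange(10), naType = "ssDNA")
  expect_equal(unname(foldVsDirect(unit, 5e5)), c(1, 1))
  expect_lt(foldVsDirect(unit, 6e5)[["high"]], 1)
  expect_error(foldVsDirect(unit, 0), class = "viromassDomainError")
})

test_that("the report reproduces the published depth profile", {
  rep <- apportionReport(tohokuSamples())
  disp <- reportDisplay(rep)
  expect_equal(disp$vcr, c(0.58, 0.47, 0.32))
  expect_equal(disp$ds_copies_high[1], 5.3e6)
  expect_equal(disp$ss_copies_high, c(2.9e9, 1.7e9, 1.5e9))
  expect_equal(disp$rel_ss_pct_high, c(99.8, 99.7, 99.8))
  expect_equal(disp$rel_ss_pct_low[1:2], c(97.5, 96.3))
  # documented print mismatches stay within one unit in the last digit
  expect_lte(abs(disp$vcr[2] - 0.48), 0.01 + 1e-9)
  expect_lte(abs(disp$ds_copies_high[3] - 3.0e6), 0.1e6 + 1e-9)
  expect_lte(abs(disp$ds_copies_high[2] - 4.8e6), 0.1e6 + 1e-9)
  expect_lte(abs(disp$rel_ss_pct_low[3] - 96.9), 0.5)
  # rows ordered by depth; unrounded table retained
  expect_true(!is.unsorted(disp$depth_top_cm))
  expect_equal(roundVcr(reportTable(rep)$vcr), disp$vcr)
})

test_that("a zero-mass sample yields a well-formed zero report", {
  df <- data.frame(sample_id = "z", depth_top_cm = 0, depth_bottom_cm = 2,
                   cells_per_cm3 = 1e6, cells_sd = 0,
                   viruses_per_cm3 = 1e5, viruses_sd = 0,
                   ssdna_ng_per_cm3 = 0, dsdna_ng_per_cm3 = 0)
  rep <- apportionReport(df)
  tab <- reportTable(rep)
  expect_equal(tab$ss_copies_high, 0)
  expect_equal(tab$ds_copies_high, 0)
  expect_true(is.na(tab$rel_ss_pct_low))
})

test_that("report round-trips through serialization", {
  rep <- apportionReport(tohokuSamples())
  samplesBack <- tempfile(fileext = ".tsv")
  df <- read.delim(system.file("extdata", "tohoku_samples.tsv",
                               package = "viromass"))
  write.table(df, samplesBack, sep = "\t", quote = FALSE, row.names = FALSE)
  rep2 <- apportionReport(readSamples(samplesBack))
  expect_equal(reportTable(rep2), reportTable(rep))
})
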