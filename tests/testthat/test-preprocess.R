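mkDataset <- function(peaks_list) {
  pk <- data.table::rbindlist(lapply(seq_along(peaks_list), function(i)
    data.table::data.table(pixel_id = i, mz = peaks_list[[i]]$mz,
                           intensity = peaks_list[[i]]$intensity)))
  data.table::setorder(pk, pixel_id, mz)
  methods::new("IMSDataset", peaks = pk,
               pixels = data.frame(pixel_id = seq_along(peaks_list),
                                   x = seq_along(peaks_list), y = 1L,
                                   compartment = "epithelium", axis = 0),
               mass_range = c(480, 1000), pixel_spacing = 10,
               processing_log = list(), ground_truth = list())
}

test_that("TIC normalization rescales to unit sum and is idempotent and scale invariant", {
  ds <- mkDataset(list(data.frame(mz = c(500, 600, 700),
                                  intensity = c(2, 3, 5))))
  nm <- ticNormalize(ds)
  expect_equal(peakTable(nm)$intensity, c(0.2, 0.3, 0.5))
  expect_equal(peakTable(ticNormalize(nm)), peakTable(nm))
  ds10 <- mkDataset(list(data.frame(mz = c(500, 600, 700),
                                    intensity = 10 * c(2, 3, 5))))
  expect_equal(peakTable(ticNormalize(ds10)), peakTable(nm))
})

test_that("zero-TIC spectra are excluded with a warning, not an error", {
  ds <- mkDataset(list(data.frame(mz = c(500, 600), intensity = c(1, 1)),
                       data.frame(mz = 550, intensity = 0)))
  expect_warning(nm <- ticNormalize(ds), "zero TIC")
  expect_identical(unique(peakTable(nm)$pixel_id), 1L)
  expect_identical(nrow(pixelInfo(nm)), 1L)
})

test_that("relative-intensity filter keeps exactly the peaks above threshold", {
  ds <- mkDataset(list(data.frame(mz = c(500, 600, 700),
                                  intensity = c(100, 0.4, 0.6))))
  f <- filterLowIntensity(ds, 0.005)
  expect_equal(peakTable(f)$intensity, c(100, 0.6))
  expect_equal(peakTable(filterLowIntensity(ds, 0)), peakTable(ds))
})

test_that("filter is monotone in the threshold and always keeps the base peak", {
  ds <- randomSpectrumDataset(200, seed = 1)
  strict <- peakTable(filterLowIntensity(ds, 0.01))
  loose <- peakTable(filterLowIntensity(ds, 0.005))
  expect_true(all(strict$mz %in% loose$mz))
  harsh <- peakTable(filterLowIntensity(ds, 0.999))
  expect_gte(nrow(harsh), 1L)
  expect_true(max(peakTable(ds)$intensity) %in% harsh$intensity)
})

test_that("normalize-then-filter and filter-then-normalize retain the same peaks", {
  for (s in 1:5) {
    ds <- randomSpectrumDataset(150, seed = s)
    a <- peakTable(filterLowIntensity(ticNormalize(ds), 0.01))
    b <- peakTable(ticNormalize(filterLowIntensity(ds, 0.01)))
    expect_equal(a$mz, b$mz)
  }
})

test_that("alignment pools nearby peaks and separates distant ones", {
  ds <- mkDataset(list(data.frame(mz = 760.5850, intensity = 1),
                       data.frame(mz = 760.5855, intensity = 1)))  # 0.66 ppm
  al <- alignToAxis(ds, tolerance = 5)
  expect_identical(length(refMz(al)), 1L)
  ds2 <- mkDataset(list(data.frame(mz = 800.000, intensity = 1),
                        data.frame(mz = 800.040, intensity = 1)))  # 50 ppm
  expect_identical(length(refMz(alignToAxis(ds2, tolerance = 5))), 2L)
  expect_identical(length(refMz(alignToAxis(ds2, tolerance = 20))), 2L)
})

test_that("alignment conserves per-spectrum total intensity exactly", {
  lay <- smallLayout(6)
  ds <- simulateDataset(lay, simConfig(seed = 6, n_noise_peaks = 20))
  al <- alignToAxis(ds, 5)
  before <- peakTable(ds)[, .(tic = sum(intensity)), by = pixel_id]
  after <- peakTable(al)[, .(tic = sum(intensity)), by = pixel_id]
  expect_equal(after$tic, before$tic)
  expect_false(is.unsorted(refMz(al), strictly = TRUE))
})

test_that("with zero jitter and no noise the axis recovers the ground-truth channels", {
  lay <- smallLayout(7)
  ds <- simulateDataset(lay, zeroNoiseConfig(merge = TRUE, seed = 7))
  al <- alignToAxis(ds, 5)
  # 27 theoretical channels collapse to 25 after instrument-resolution
  # merging of the two engineered isobaric pairs
  theo <- lipidChannels(colonPanel())
  n_expected <- nrow(mergeUnresolvedChannels(
    data.frame(mz = theo$theo_mz, intensity = 1), 1e5))
  expect_identical(length(refMz(al)), n_expected)
  expect_identical(n_expected, 25L)
})

test_that("the processing log records the pipeline order with parameters", {
  lay <- smallLayout(8)
  ds <- simulateDataset(lay, zeroNoiseConfig(seed = 8))
  al <- filterLowIntensity(alignToAxis(ticNormalize(ds), 5), 0.005)
  ops <- vapply(processingLog(al), `[[`, "", "op")
  expect_identical(ops, c("simulate", "tic_normalize", "align", "filter"))
  expect_equal(processingLog(al)[[4]]$fraction, 0.005)
})
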