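test_that("noiseless simulation reproduces the ground truth exactly", {
  lay <- smallLayout(2)
  ds <- simulateDataset(lay, zeroNoiseConfig(merge = FALSE, seed = 2))
  gt <- groundTruth(ds)$truth
  pk <- peakTable(ds)
  merged <- merge(pk, gt, by.x = c("pixel_id", "mz"),
                  by.y = c("pixel_id", "theo_mz"))
  expect_identical(nrow(merged), nrow(gt))  # every peak at its exact mass
  expect_equal(merged$intensity, merged$true_intensity)
})

test_that("the healthy preset gives equal Na and K intensities per species and pixel", {
  lay <- smallLayout(2)
  ds <- simulateDataset(lay, zeroNoiseConfig("healthy", merge = FALSE))
  gt <- data.table::as.data.table(groundTruth(ds)$truth)
  w <- data.table::dcast(gt, pixel_id + species ~ adduct,
                         value.var = "true_intensity")
  expect_equal(w$Na, w$K)
})

test_that("regeneration with the same seed is identical, different seeds differ", {
  lay <- smallLayout(4)
  cfg <- simConfig("adenoma", seed = 9, n_noise_peaks = 10)
  a <- simulateDataset(lay, cfg)
  b <- simulateDataset(lay, cfg)
  expect_identical(peakTable(a), peakTable(b))
  d <- simulateDataset(lay, simConfig("adenoma", seed = 10,
                                      n_noise_peaks = 10))
  expect_false(identical(peakTable(a), peakTable(d)))
})

test_that("adduct partitions are conserved and recoverable from the truth", {
  lay <- smallLayout(3)
  cfg <- zeroNoiseConfig("adenoma", merge = FALSE, seed = 3)
  ds <- simulateDataset(lay, cfg)
  gt <- data.table::as.data.table(groundTruth(ds)$truth)
  px <- pixelInfo(ds)
  # per-pixel, per-species sums over adducts equal the configured abundance
  tot <- gt[, .(total = sum(true_intensity)), by = .(pixel_id, species)]
  prof <- cfg$profiles
  i <- match(tot$species, prof$species)
  j <- match(tot$pixel_id, px$pixel_id)
  expected <- prof$base_abundance[i] *
    (1 + prof$gradient_slope[i] *
       ifelse(px$compartment[j] == "epithelium", px$axis[j], 0))
  expect_equal(tot$total, expected)
  # empirical per-class fractions equal the configured partition
  gt[, compartment := px$compartment[match(pixel_id, px$pixel_id)]]
  frac <- gt[, .(S = sum(true_intensity)),
             by = .(lipid_class, compartment, adduct)]
  frac[, f := S / sum(S), by = .(lipid_class, compartment)]
  part <- cfg$partitions
  for (r in seq_len(nrow(frac))) {
    row <- part[part$lipid_class == frac$lipid_class[r] &
                  part$compartment == frac$compartment[r], ]
    expect_equal(frac$f[r], row[[paste0("f_", frac$adduct[r])]],
                 tolerance = 1e-12)
  }
})

test_that("species without a class partition are rejected", {
  lay <- smallLayout(1)
  cfg <- zeroNoiseConfig()
  cfg$partitions <- cfg$partitions[cfg$partitions$lipid_class == "PC", ]
  expect_error(simulateDataset(lay, cfg), "no adduct partition")
})

test_that("unresolved peaks merge by the FWHM rule and the merge is idempotent", {
  # FWHM at m/z 782.57 with R400 = 100,000 is ~0.011 Da
  close_pair <- data.frame(mz = c(782.5670, 782.5694), intensity = c(3, 2))
  m <- mergeUnresolvedChannels(close_pair, 1e5)
  expect_identical(nrow(m), 1L)
  expect_equal(m$intensity, 5)  # mass-channel intensity conservation
  expect_equal(m$mz, (3 * 782.5670 + 2 * 782.5694) / 5)
  # 1 Da apart: never merged at any configured resolution
  far <- data.frame(mz = c(700, 701), intensity = c(1, 1))
  expect_identical(nrow(mergeUnresolvedChannels(far, 3e4)), 2L)
  expect_identical(nrow(mergeUnresolvedChannels(far, 1e5)), 2L)
  # idempotence on a busy random spectrum
  set.seed(8)
  sp <- data.frame(mz = sort(runif(300, 480, 1000)),
                   intensity = rlnorm(300))
  once <- mergeUnresolvedChannels(sp, 3e4)
  twice <- mergeUnresolvedChannels(once, 3e4)
  expect_equal(twice, once)
  expect_equal(sum(once$intensity), sum(sp$intensity))
})

test_that("the engineered isobaric pairs appear as single merged channels", {
  lay <- smallLayout(5)
  ds <- simulateDataset(lay, zeroNoiseConfig(merge = TRUE, seed = 5))
  gt <- data.table::as.data.table(groundTruth(ds)$truth)
  pk <- peakTable(ds)
  one_px <- pk[pk$pixel_id == pk$pixel_id[1], ]
  expect_identical(nrow(one_px), 25L)  # 27 theoretical channels - 2 merges
  # merged channel carries the sum of both members
  pair <- gt[pixel_id == one_px$pixel_id[1] &
               ((species == "PC 34:1" & adduct == "Na") |
                  (species == "PC 36:4" & adduct == "H"))]
  hit <- one_px[abs(one_px$mz - 782.568) < 0.01, ]
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$intensity, sum(pair$true_intensity))
})
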