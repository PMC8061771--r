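test_that("annotation flags the merged isobaric channels as ambiguous and skips decoys", {
  lay <- smallLayout(10)
  ds <- simulateDataset(lay, simConfig(seed = 10))
  al <- filterLowIntensity(alignToAxis(ticNormalize(ds), 5), 0.005)
  ann <- annotateChannels(al, colonPanel())
  expect_true(all(ann$ppm_error <= 9))
  amb <- ann[ann$ambiguous, ]
  expect_setequal(paste(amb$species, amb$adduct),
                  c("PC 34:1 Na", "PC 36:4 H", "PC 36:1 Na", "PC 38:4 H"))
  expect_identical(sort(unique(ann$species)),
                   sort(speciesTable(colonPanel())$name))
  # chemical-noise channels vastly outnumber assigned ones but are excluded
  expect_lt(attr(ann, "n_assigned"), 40)
  expect_gt(attr(ann, "n_channels"), 1000)
})

test_that("class ratios equal the generating partition exactly at zero noise", {
  run <- zeroNoiseRun("adenoma", seed = 11)
  ann <- S4Vectors::metadata(run$se)$annotation
  ratios <- S4Vectors::metadata(run$se)$ratios
  expect_true(all(abs(ratios$r_H + ratios$r_Na + ratios$r_K - 1) < 1e-9))
  expect_false(any(ratios$fallback_used))
  expect_equal(ratios$r_H, rep(0.30, nrow(ratios)), tolerance = 1e-9)
  expect_equal(ratios$r_Na, rep(0.21, nrow(ratios)), tolerance = 1e-9)
  expect_equal(ratios$r_K, rep(0.49, nrow(ratios)), tolerance = 1e-9)
})

test_that("a class seen through a single adduct yields the degenerate ratio", {
  # hand-built aligned data: one spectrum, one unambiguous PC 34:1 H channel
  p <- colonPanel()
  mz <- adductMz(p, "PC 34:1", "H")
  al <- methods::new("AlignedIMS", ref_mz = mz,
    intensities = data.table::data.table(pixel_id = 1L, channel = 1L,
                                         intensity = 10),
    pixels = data.frame(pixel_id = 1L, x = 1L, y = 1L,
                        compartment = "epithelium", axis = 0),
    tolerance_ppm = 5, pixel_spacing = 10,
    processing_log = list(), ground_truth = list())
  ann <- annotateChannels(al, p, min_pixel_fraction = 0)
  r <- estimateClassRatios(al, ann)
  expect_identical(nrow(r), 1L)
  expect_equal(c(r$r_H, r$r_Na, r$r_K), c(1, 0, 0))
  expect_true(r$fallback_used)
  expect_identical(r$method, "unbalanced")
})

test_that("overlap apportionment inverts the mixing exactly at zero noise", {
  run <- zeroNoiseRun("healthy", seed = 12)
  gt <- data.table::as.data.table(groundTruth(run$dataset)$truth)
  # TIC normalization rescales each spectrum; compare after matching scale
  tic <- gt[, .(tic = sum(true_intensity)), by = pixel_id]
  gt <- merge(gt, tic, by = "pixel_id")
  gt[, expected := true_intensity / tic]
  for (a in c("H", "Na", "K")) {
    m <- SummarizedExperiment::assay(run$se, a)
    sub <- gt[adduct == a]
    got <- m[cbind(match(sub$species, rownames(m)),
                   match(as.character(sub$pixel_id), colnames(m)))]
    expect_equal(got, sub$expected, tolerance = 1e-6)
  }
})

test_that("apportionment conserves assigned intensity and ignores candidate order", {
  lay <- smallLayout(13)
  ds <- simulateDataset(lay, simConfig(seed = 13))
  al <- filterLowIntensity(alignToAxis(ticNormalize(ds), 5), 0.005)
  ann <- annotateChannels(al, colonPanel())
  ratios <- estimateClassRatios(al, ann)
  se <- apportionOverlaps(al, ann, ratios)
  # conservation: assigned channel intensity = corrected intensity, per pixel
  it <- peakTable(al)
  assigned <- it[it$channel %in% unique(ann$channel), ]
  before <- assigned[, .(s = sum(intensity)), by = pixel_id]
  tot <- speciesTotals(se)
  after <- data.frame(pixel_id = as.integer(colnames(tot)),
                      s = colSums(tot))
  m <- merge(before, after, by = "pixel_id")
  expect_equal(m$s.x, m$s.y, tolerance = 1e-9)
  # permutation invariance of candidate rows within channels
  perm <- ann[rev(seq_len(nrow(ann))), ]
  attr(perm, "n_adducts") <- attr(ann, "n_adducts")
  se2 <- apportionOverlaps(al, perm, ratios)
  for (a in c("H", "Na", "K"))
    expect_equal(SummarizedExperiment::assay(se2, a),
                 SummarizedExperiment::assay(se, a))
})

test_that("per-class mean ratio is recovered within 0.05 under default noise", {
  lay <- buildLayout(64, 64, 3, seed = 14)  # >200 tissue pixels
  ds <- simulateDataset(lay, simConfig("adenoma", seed = 14))
  al <- filterLowIntensity(alignToAxis(ticNormalize(ds), 5), 0.005)
  ann <- annotateChannels(al, colonPanel())
  ratios <- estimateClassRatios(al, ann)
  for (cls in c("PC", "SM")) {
    sub <- ratios[ratios$lipid_class == cls, ]
    expect_equal(mean(sub$r_Na), 0.21, tolerance = 0.05)
    expect_equal(mean(sub$r_K), 0.49, tolerance = 0.05)
  }
})

test_that("species totals add the three adducts and dominate each single adduct", {
  run <- zeroNoiseRun("healthy", seed = 15)
  tot <- speciesTotals(run$se)
  h <- SummarizedExperiment::assay(run$se, "H")
  na <- SummarizedExperiment::assay(run$se, "Na")
  k <- SummarizedExperiment::assay(run$se, "K")
  expect_equal(tot, h + na + k)
  expect_true(all(tot >= pmax(h, na, k) - 1e-12))
  lt <- deconvolvedTable(run$se)
  expect_setequal(names(lt), c("pixel_id", "x", "y", "compartment",
                               "species", "adduct", "intensity_corrected"))
  expect_equal(sum(lt$intensity_corrected), sum(tot))
})
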