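test_that("Na/K pair fractions follow their definition and boundary rules", {
  fr <- naKFractions(c(50, 30, 0, 0), c(50, 70, 10, 0))
  expect_equal(fr$f_Na, c(0.5, 0.3, 0, NA))
  expect_equal(fr$f_K, c(0.5, 0.7, 1, NA))
  expect_equal(fr$f_Na + fr$f_K, c(1, 1, 1, NA))
  expect_error(naKFractions(-1, 1), "non-negative")
  # f_K monotone in I_K at fixed I_Na
  ks <- seq(0, 100, by = 10)
  expect_true(all(diff(naKFractions(rep(20, 11), ks)$f_K) > 0))
  # invariance to global rescaling
  expect_equal(naKFractions(3, 7), naKFractions(300, 700))
})

test_that("path profiles track gradients in totals but not in the pair ratio", {
  run <- zeroNoiseRun("healthy", seed = 21)
  path <- cryptPaths(run$layout)[[1]]
  prof <- extractPathProfile(run$se, path, compartment = "epithelium")
  expect_true(all(c("step", "distance_um", "species", "I_H", "I_Na", "I_K",
                    "f_Na", "f_K") %in% names(prof)))
  ax <- cryptAxis(run$layout)[cbind(path[, "y"], path[, "x"])]
  # with no abundance gradients anywhere, every track is constant
  flat_prof <- defaultProfiles()
  flat_prof$gradient_slope <- 0
  frun <- zeroNoiseRun("healthy", seed = 21, profiles = flat_prof)
  fprof <- extractPathProfile(frun$se, cryptPaths(frun$layout)[[1]],
                              species = "PC 34:1")
  expect_lt(diff(range(fprof$I_K)) / mean(fprof$I_K), 1e-9)
  # PC 32:0 decreases along the crypt while its K fraction stays flat
  dec <- prof[prof$species == "PC 32:0", ]
  slope <- coef(lm((dec$I_H + dec$I_Na + dec$I_K) ~ ax))[2]
  expect_lt(slope, 0)
  expect_lt(diff(range(dec$f_K)), 1e-9)
  # PC 38:4 increases
  inc <- prof[prof$species == "PC 38:4", ]
  expect_gt(coef(lm((inc$I_H + inc$I_Na + inc$I_K) ~ ax))[2], 0)
  # pair fractions defined and summing to 1 everywhere on tissue
  expect_equal(prof$f_Na + prof$f_K, rep(1, nrow(prof)))
})

test_that("reversing a path reverses the profile but not the ratio values", {
  run <- zeroNoiseRun("healthy", seed = 21)
  path <- cryptPaths(run$layout)[[1]]
  fwd <- extractPathProfile(run$se, path, species = "PC 32:0")
  rev_ <- extractPathProfile(run$se, path[rev(seq_len(nrow(path))), ],
                             species = "PC 32:0")
  expect_equal(rev(rev_$I_K), fwd$I_K)
  expect_equal(sort(rev_$f_K), sort(fwd$f_K))
})

test_that("paths outside the raster or the stated compartment are rejected, naming the pixel", {
  run <- zeroNoiseRun("healthy", seed = 21)
  bad <- data.frame(x = rep(1, 12), y = 1:12)  # background column
  expect_error(extractPathProfile(run$se, bad), "outside the dataset")
  path <- cryptPaths(run$layout)[[1]]
  expect_error(extractPathProfile(run$se, path, compartment = "lamina_propria"),
               "not in the lamina_propria")
  expect_error(extractPathProfile(run$se, path[1:4, ]), "at least 10")
})

test_that("smoothing is a centered moving average applied per track", {
  run <- zeroNoiseRun("healthy", seed = 21)
  path <- cryptPaths(run$layout)[[1]]
  raw <- extractPathProfile(run$se, path, species = "PC 32:0")
  sm <- extractPathProfile(run$se, path, species = "PC 32:0", window = 5)
  i <- 10
  expect_equal(sm$I_H[i], mean(raw$I_H[(i - 2):(i + 2)]))
})

test_that("ROI summaries recover the preset pair fraction in both compartments at zero noise", {
  run <- zeroNoiseRun("adenoma", seed = 22)
  for (comp in c("epithelium", "lamina_propria")) {
    s <- roiSummary(run$se, comp)
    fk <- s[s$metric == "f_K", ]
    expect_equal(fk$mean, rep(0.7, nrow(fk)), tolerance = 1e-9)
    expect_equal(fk$sem, rep(0, nrow(fk)), tolerance = 1e-9)
    expect_true(all(fk$n > 0))
  }
  expect_error(roiSummary(run$se, "muscularis"), "not present")
})

test_that("identical groups give t = 0 and p = 1; presets give a K-ward shift", {
  h <- zeroNoiseRun("healthy", seed = 23)
  a <- zeroNoiseRun("adenoma", seed = 24)
  sh <- roiSummary(h$se, "epithelium")
  sa <- roiSummary(a$se, "epithelium")
  same <- compareGroups(list(sh, sh), list(sh, sh))
  expect_true(all(same$tests$t == 0))
  expect_true(all(same$tests$p == 1))
  diffd <- compareGroups(list(sh, sh), list(sa, sa))
  fk <- diffd$tests[diffd$tests$metric == "f_K", ]
  expect_true(all(fk$mean_adenoma > fk$mean_healthy))
  # normalized per-species adduct proportions sum to 1 within each group
  pr <- diffd$proportions
  sums <- aggregate(proportion ~ group + species, pr, sum)
  expect_equal(sums$proportion, rep(1, nrow(sums)))
})

test_that("group comparison handles insufficient samples without failing", {
  h <- zeroNoiseRun("healthy", seed = 23)
  sh <- roiSummary(h$se, "epithelium")
  res <- compareGroups(list(sh), list(sh, sh))
  expect_true(all(is.na(res$tests$t)))
  expect_error(compareGroups(list(sh), list(sh, sh), paired = TRUE),
               "equal subject counts")
})
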