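# Shared fixtures: everything is generated in code at test time.

# a small layout for fast unit tests (~100 epithelial pixels)
smallLayout <- function(seed = 1) buildLayout(48, 48, 2, seed = seed)

# simulation config with all noise sources switched off
zeroNoiseConfig <- function(condition = "healthy", merge = TRUE, seed = 1,
                            ...) {
  simConfig(condition, mz_jitter_ppm = 0, intensity_cv = 0, tic_cv = 0,
            n_noise_peaks = 0, merge_channels = merge, seed = seed, ...)
}

# noiseless dataset + the fully processed SummarizedExperiment
zeroNoiseRun <- function(condition = "healthy", seed = 1, ...) {
  lay <- smallLayout(seed)
  ds <- simulateDataset(lay, zeroNoiseConfig(condition, seed = seed, ...))
  res <- processDataset(ds)
  list(layout = lay, dataset = ds, aligned = res$aligned, se = res$se)
}

# connected components of a logical pixel mask under 8-connectivity,
# written independently of any package code (plain flood fill)
countComponents8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    comp <- comp + 1L
    stack <- list(c(i, j))
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (p[1] < 1 || p[2] < 1 || p[1] > nrow(mask) || p[2] > ncol(mask))
        next
      if (!mask[p[1], p[2]] || lab[p[1], p[2]] > 0L) next
      lab[p[1], p[2]] <- comp
      for (di in -1:1) for (dj in -1:1)
        if (di || dj) stack[[length(stack) + 1L]] <- c(p[1] + di, p[2] + dj)
    }
  }
  comp
}

# random centroided spectrum as an IMSDataset with one pixel
randomSpectrumDataset <- function(n_peaks, seed) {
  set.seed(seed)
  pk <- data.table::data.table(
    pixel_id = 1L, mz = sort(runif(n_peaks, 480, 1000)),
    intensity = rlnorm(n_peaks, 0, 1))
  methods::new("IMSDataset", peaks = pk,
               pixels = data.frame(pixel_id = 1L, x = 1L, y = 1L,
                                   compartment = "epithelium", axis = 0.5),
               mass_range = c(480, 1000), pixel_spacing = 10,
               processing_log = list(), ground_truth = list())
}
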