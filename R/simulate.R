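#' @include lipid-registry.R layout.R
NULL

#' Preset adduct partitions for the two tissue conditions
#'
#' Per-class fractions of a species' signal carried by each cation adduct.
#' The healthy preset is (f_H, f_Na, f_K) = (0.30, 0.35, 0.35) and the
#' adenoma preset (0.30, 0.21, 0.49), so that the Na:K pair ratio
#' (renormalized over Na+K) is 0.5:0.5 and 0.3:0.7 respectively. The H
#' fraction is a free choice: the pair ratio, the quantity of interest, does
#' not depend on it. The same partition is applied to both compartments and
#' to both lipid classes, reflecting the compartment- and class-independence
#' of the observed shift.
#'
#' @param condition `"healthy"` or `"adenoma"`.
#' @return data.frame with columns `lipid_class`, `compartment`, `f_H`,
#'   `f_Na`, `f_K` (each row sums to 1).
#' @export
presetPartitions <- function(condition = c("healthy", "adenoma")) {
  condition <- match.arg(condition)
  f <- if (condition == "healthy") c(0.30, 0.35, 0.35) else c(0.30, 0.21, 0.49)
  out <- expand.grid(lipid_class = c("PC", "SM"),
                     compartment = c("epithelium", "lamina_propria"),
                     stringsAsFactors = FALSE)
  out$f_H <- f[1]; out$f_Na <- f[2]; out$f_K <- f[3]
  out
}

#' Default species abundance profiles for the colon panel
#'
#' Base abundances (arbitrary intensity units) with PC 34:1 as the dominant
#' species, and along-crypt abundance gradients for exactly the two species
#' known to show one: PC 32:0 (decreasing towards the crypt top) and
#' PC 38:4 (increasing). All other species are flat.
#'
#' @param panel a [LipidPanel-class]; profiles are emitted for its species.
#' @return data.frame with columns `species`, `base_abundance`,
#'   `gradient_slope` (signed fraction per unit crypt axis).
#' @export
defaultProfiles <- function(panel = colonPanel()) {
  base <- c("PC 32:0" = 60, "PC 34:1" = 100, "PC 34:2" = 80, "PC 36:1" = 50,
            "PC 36:2" = 70, "PC 36:3" = 40, "PC 36:4" = 45, "PC 38:4" = 35,
            "SMd34:1" = 40)
  slope <- c("PC 32:0" = -0.5, "PC 38:4" = 0.5)
  nm <- speciesTable(panel)$name
  data.frame(species = nm,
             base_abundance = ifelse(nm %in% names(base), base[nm], 50),
             gradient_slope = ifelse(nm %in% names(slope), slope[nm], 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles all generator parameters. Defaults emulate the acquisition regime
#' of high-resolution positive-ion MALDI-IMS of colon mucosa: mass range
#' 480-1000 Da, Orbitrap-style resolving power 100,000 at m/z 400 with
#' R(mz) = R400 * sqrt(400/mz) decay, Gaussian m/z jitter of 1.5 ppm (so
#' ~95% of peaks fall within 3 ppm of the true mass), multiplicative
#' lognormal intensity noise with CV 0.2, per-pixel TIC variation with CV
#' 0.3, and 50 uniform-random chemical-noise peaks per spectrum.
#'
#' @param condition `"healthy"` or `"adenoma"`; selects the preset partition
#'   when `partitions` is not given.
#' @param panel a [LipidPanel-class].
#' @param partitions per-class, per-compartment adduct partition table (see
#'   [presetPartitions()]); rows must sum to 1 (tolerance 1e-9).
#' @param profiles species abundance profiles (see [defaultProfiles()]);
#'   `|gradient_slope|` must be <= 1.
#' @param mz_jitter_ppm standard deviation of the Gaussian m/z perturbation.
#' @param intensity_cv coefficient of variation of the lognormal
#'   multiplicative intensity noise (mean 1).
#' @param tic_cv coefficient of variation of the per-pixel TIC factor.
#' @param n_noise_peaks chemical-noise peaks per spectrum.
#' @param noise_meanlog,noise_sdlog lognormal parameters of noise-peak
#'   intensities (median `exp(noise_meanlog)` intensity units).
#' @param mass_range scanned m/z window (Da).
#' @param resolving_power resolving power at m/z 400.
#' @param merge_channels merge peaks closer than the local FWHM (emulates
#'   the instrument reporting unresolved isobars as one centroid).
#' @param seed integer root seed; the full dataset is reproducible from it.
#' @return A list of class `simConfig`.
#' @export
simConfig <- function(condition = c("healthy", "adenoma"),
                      panel = colonPanel(),
                      partitions = presetPartitions(condition),
                      profiles = defaultProfiles(panel),
                      mz_jitter_ppm = 1.5, intensity_cv = 0.2, tic_cv = 0.3,
                      n_noise_peaks = 50, noise_meanlog = 0, noise_sdlog = 1,
                      mass_range = c(480, 1000), resolving_power = 1e5,
                      merge_channels = TRUE, seed = 1) {
  condition <- match.arg(condition)
  stopifnot(mz_jitter_ppm >= 0, intensity_cv >= 0, tic_cv >= 0,
            n_noise_peaks >= 0, resolving_power > 0,
            length(mass_range) == 2, mass_range[1] < mass_range[2])
  rs <- rowSums(partitions[, c("f_H", "f_Na", "f_K")])
  if (any(abs(rs - 1) > 1e-9)) stop("adduct partitions must sum to 1")
  if (any(partitions[, c("f_H", "f_Na", "f_K")] < 0))
    stop("adduct fractions must be non-negative")
  if (any(profiles$base_abundance <= 0)) stop("base abundances must be > 0")
  if (any(abs(profiles$gradient_slope) > 1)) stop("|gradient_slope| must be <= 1")
  structure(list(
    condition = condition, panel = panel, partitions = partitions,
    profiles = profiles, mz_jitter_ppm = mz_jitter_ppm,
    intensity_cv = intensity_cv, tic_cv = tic_cv,
    n_noise_peaks = n_noise_peaks, noise_meanlog = noise_meanlog,
    noise_sdlog = noise_sdlog, mass_range = mass_range,
    resolving_power = resolving_power, merge_channels = merge_channels,
    seed = as.integer(seed)), class = "simConfig")
}

# lognormal with mean 1 and coefficient of variation cv
.rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

# FWHM at mz for a resolving power R400 specified at m/z 400 with
# R(mz) = R400 * sqrt(400/mz): FWHM = mz / R(mz) = mz^1.5 / (R400 * 20)
.fwhm <- function(mz, resolving_power) mz^1.5 / (resolving_power * 20)

#' Merge peaks unresolved at a given resolving power
#'
#' Peaks closer than the local full width at half maximum implied by the
#' instrument's resolving power (specified at m/z 400, decaying as
#' `R(mz) = R400 * sqrt(400/mz)`) are summed into one centroid at the
#' intensity-weighted mean m/z. The operation is idempotent: merged
#' centroids are separated by more than the local FWHM.
#'
#' @param peaks data.frame with columns `mz`, `intensity` (one spectrum).
#' @param resolving_power resolving power at m/z 400 (> 0).
#' @return data.frame `mz`, `intensity`, sorted ascending by m/z.
#' @examples
#' mergeUnresolvedChannels(
#'   data.frame(mz = c(782.567, 782.5694), intensity = c(3, 2)), 1e5)
#' @export
mergeUnresolvedChannels <- function(peaks, resolving_power) {
  stopifnot(resolving_power > 0, all(c("mz", "intensity") %in% names(peaks)))
  dt <- as.data.table(peaks)[order(mz)]
  dt[, pixel_id := 1L]
  out <- .mergeByPixel(dt, resolving_power)
  as.data.frame(out[, .(mz, intensity)])
}

# gap-rule centroid merging, vectorised over pixels; dt must be keyed/sorted
# by (pixel_id, mz)
.mergeByPixel <- function(dt, resolving_power) {
  dt[, gap := mz - shift(mz), by = pixel_id]
  dt[, fwhm := .fwhm(mz, resolving_power)]
  dt[, cluster := cumsum(is.na(gap) | gap > fwhm), by = pixel_id]
  dt[, w := pmax(intensity, 1e-300)]
  out <- dt[, .(mz = sum(mz * w) / sum(w), intensity = sum(intensity)),
            by = .(pixel_id, cluster)]
  out[, cluster := NULL]
  setorder(out, pixel_id, mz)
  out
}

#' Simulate a ground-truthed synthetic IMS dataset
#'
#' Emits one centroided peak list per tissue pixel of the layout. For each
#' species/adduct ion channel, the noiseless intensity at a pixel is
#' `base_abundance * (1 + gradient_slope * crypt_axis) * f_adduct` (the
#' gradient acts along the crypt axis, i.e. in the epithelium; stromal
#' pixels use the base abundance), which is then multiplied by lognormal
#' intensity noise and a per-pixel TIC factor. Peak m/z values are the
#' theoretical channel masses perturbed by Gaussian ppm jitter; uniform
#' chemical-noise peaks are added; finally, when `merge_channels` is on,
#' peaks unresolved at the configured resolving power are merged
#' ([mergeUnresolvedChannels()]) — with the colon panel this collapses the
#' isobaric pairs PC 34:1+Na / PC 36:4+H and PC 36:1+Na / PC 38:4+H into
#' single observed channels.
#'
#' The generation is deterministic given `config$seed`.
#'
#' @param layout a [TissueLayout-class].
#' @param config a [simConfig()].
#' @return An [IMSDataset-class] with the ground truth attached: a list with
#'   elements `truth` (data.table `pixel_id`, `species`, `lipid_class`,
#'   `adduct`, `theo_mz`, `true_intensity`), `partitions`, `profiles`,
#'   `layout` and `condition`.
#' @export
simulateDataset <- function(layout, config) {
  stopifnot(is(layout, "TissueLayout"), inherits(config, "simConfig"))
  px <- layoutPixels(layout)
  panel_species <- speciesTable(config$panel)$name
  missing_sp <- setdiff(config$profiles$species, panel_species)
  if (length(missing_sp))
    stop("profile species not in panel: ", paste(missing_sp, collapse = ", "))

  ch <- as.data.table(lipidChannels(config$panel))
  ch <- ch[species %in% config$profiles$species]
  prof <- as.data.table(config$profiles)
  ch <- merge(ch, prof, by = "species")

  part <- as.data.table(config$partitions)
  part_long <- melt(part, id.vars = c("lipid_class", "compartment"),
                    measure.vars = c("f_H", "f_Na", "f_K"),
                    variable.name = "adduct", value.name = "fraction")
  part_long[, adduct := sub("^f_", "", adduct)]
  need <- CJ(lipid_class = unique(ch$lipid_class),
             compartment = unique(px$compartment))
  have <- unique(part_long[, .(lipid_class, compartment)])
  miss <- need[!have, on = c("lipid_class", "compartment")]
  if (nrow(miss))
    stop("no adduct partition for class ",
         paste(unique(miss$lipid_class), collapse = ", "))

  pxdt <- as.data.table(px)
  idx <- CJ(pi = seq_len(nrow(pxdt)), ci = seq_len(nrow(ch)))
  gt <- cbind(pxdt[idx$pi, .(pixel_id, compartment, axis)], ch[idx$ci])
  # abundance with the along-crypt gradient applied in the epithelium only
  gt[, true_intensity := base_abundance *
       (1 + gradient_slope * fifelse(compartment == "epithelium", axis, 0))]
  gt <- merge(gt, part_long, by = c("lipid_class", "compartment", "adduct"))
  gt[, true_intensity := true_intensity * fraction]
  setorder(gt, pixel_id, theo_mz)

  set.seed(config$seed)
  n_gt <- nrow(gt)
  n_px <- nrow(pxdt)
  tic <- .rlnorm_cv(n_px, config$tic_cv)
  gt[, intensity := true_intensity * .rlnorm_cv(n_gt, config$intensity_cv) *
       tic[match(pixel_id, pxdt$pixel_id)]]
  gt[, mz := theo_mz * (1 + 1e-6 * rnorm(n_gt, sd = config$mz_jitter_ppm))]
  peaks <- gt[, .(pixel_id, mz, intensity)]

  if (config$n_noise_peaks > 0) {
    n_noise <- n_px * config$n_noise_peaks
    noise <- data.table(
      pixel_id = rep(pxdt$pixel_id, each = config$n_noise_peaks),
      mz = runif(n_noise, config$mass_range[1], config$mass_range[2]),
      intensity = rlnorm(n_noise, config$noise_meanlog, config$noise_sdlog) *
        rep(tic, each = config$n_noise_peaks))
    peaks <- rbind(peaks, noise)
  }
  setorder(peaks, pixel_id, mz)
  if (config$merge_channels)
    peaks <- .mergeByPixel(peaks, config$resolving_power)

  truth <- gt[, .(pixel_id, species, lipid_class, adduct, theo_mz,
                  true_intensity)]
  new("IMSDataset", peaks = peaks, pixels = px,
      mass_range = config$mass_range, pixel_spacing = layout@pixel_spacing,
      processing_log = list(list(
        op = "simulate", condition = config$condition, seed = config$seed,
        mz_jitter_ppm = config$mz_jitter_ppm,
        intensity_cv = config$intensity_cv, tic_cv = config$tic_cv,
        n_noise_peaks = config$n_noise_peaks,
        resolving_power = config$resolving_power,
        merge_channels = config$merge_channels)),
      ground_truth = list(truth = truth, partitions = config$partitions,
                          profiles = config$profiles, layout = layout,
                          condition = config$condition))
}
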