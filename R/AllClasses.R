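#' @include AdductIMS-package.R
NULL

setOldClass(c("data.table", "data.frame"))

#' Lipid panel: species registry with exact-mass cation adducts
#'
#' A `LipidPanel` holds the lipid species under study (class, total acyl
#' carbons, double bonds, neutral monoisotopic mass) together with the
#' registered singly charged cation adducts (H+, Na+, K+ by default, each a
#' cation mass = atomic monoisotopic mass minus one electron mass).
#'
#' @slot species data.frame with columns `name`, `lipid_class`, `carbons`,
#'   `double_bonds`, `neutral_mass` (Da, monoisotopic).
#' @slot adducts data.frame with columns `adduct` and `cation_mass` (Da).
#' @seealso [lipidPanel()], [colonPanel()], [adductMz()], [matchCandidates()]
#' @exportClass LipidPanel
setClass("LipidPanel",
  representation(species = "data.frame", adducts = "data.frame"))

setValidity("LipidPanel", function(object) {
  sp <- object@species
  ad <- object@adducts
  msg <- character()
  need <- c("name", "lipid_class", "carbons", "double_bonds", "neutral_mass")
  if (!all(need %in% names(sp)))
    msg <- c(msg, "species table must have columns name, lipid_class, carbons, double_bonds, neutral_mass")
  else {
    if (anyDuplicated(sp$name)) msg <- c(msg, "species names must be unique")
    if (any(sp$carbons <= 0)) msg <- c(msg, "carbons must be > 0")
    if (any(sp$double_bonds < 0)) msg <- c(msg, "double_bonds must be >= 0")
    if (any(sp$neutral_mass <= 0)) msg <- c(msg, "neutral_mass must be > 0")
  }
  if (!all(c("adduct", "cation_mass") %in% names(ad)))
    msg <- c(msg, "adduct table must have columns adduct, cation_mass")
  else if (any(ad$cation_mass <= 0))
    msg <- c(msg, "cation masses must be > 0")
  if (length(msg)) msg else TRUE
})

#' Tissue layout: compartment raster with crypt and mucosa axes
#'
#' A label raster of the simulated colon mucosa. Epithelial pixels carry a
#' `crypt_axis` value in \[0, 1\] (0 = crypt base, 1 = crypt top); stromal
#' (lamina propria) pixels carry a `mucosa_axis` value in \[0, 1\]
#' (basal to luminal side). Pixel spacing is in micrometres.
#'
#' @slot labels character matrix over `{"background", "epithelium",
#'   "lamina_propria"}`, indexed `[y, x]`.
#' @slot crypt_axis numeric matrix, `NA` outside the epithelium.
#' @slot mucosa_axis numeric matrix, `NA` outside the lamina propria.
#' @slot pixel_spacing numeric scalar, micrometres between pixel centres.
#' @slot paths list of integer matrices (columns `x`, `y`), one reference
#'   base-to-top path per crypt, 8-connected.
#' @seealso [buildLayout()]
#' @exportClass TissueLayout
setClass("TissueLayout",
  representation(labels = "matrix", crypt_axis = "matrix",
                 mucosa_axis = "matrix", pixel_spacing = "numeric",
                 paths = "list"))

setValidity("TissueLayout", function(object) {
  msg <- character()
  lab <- object@labels
  ok <- c("background", "epithelium", "lamina_propria")
  if (!all(lab %in% ok)) msg <- c(msg, "unknown compartment label")
  if (!identical(dim(lab), dim(object@crypt_axis)) ||
      !identical(dim(lab), dim(object@mucosa_axis)))
    msg <- c(msg, "axis matrices must match the label raster dimensions")
  epi <- lab == "epithelium"
  ca <- object@crypt_axis
  if (any(epi & is.na(ca))) msg <- c(msg, "every epithelial pixel needs a crypt_axis value")
  if (any(!is.na(ca) & (ca < 0 | ca > 1))) msg <- c(msg, "crypt_axis must lie in [0, 1]")
  ma <- object@mucosa_axis
  if (any(!is.na(ma) & (ma < 0 | ma > 1))) msg <- c(msg, "mucosa_axis must lie in [0, 1]")
  if (length(object@pixel_spacing) != 1 || object@pixel_spacing <= 0)
    msg <- c(msg, "pixel_spacing must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Pixel-indexed centroided IMS dataset
#'
#' Container for a raster of centroided pixel spectra. Peaks are stored in
#' long form; pixel metadata (coordinates, compartment, axis values) are kept
#' in a companion table. For synthetic datasets the generating ground truth
#' (noiseless per-pixel, per-species, per-adduct intensities plus the
#' configured adduct partitions) travels in the `ground_truth` slot.
#'
#' @slot peaks data.table with columns `pixel_id`, `mz`, `intensity`,
#'   sorted by pixel then m/z.
#' @slot pixels data.frame with columns `pixel_id`, `x`, `y`, `compartment`,
#'   `axis` (crypt axis for epithelium, mucosa axis for lamina propria).
#' @slot mass_range numeric length-2, Da.
#' @slot pixel_spacing numeric, micrometres.
#' @slot processing_log list of applied operations with parameters.
#' @slot ground_truth list (possibly empty); see [groundTruth()].
#' @exportClass IMSDataset
setClass("IMSDataset",
  representation(peaks = "data.table", pixels = "data.frame",
                 mass_range = "numeric", pixel_spacing = "numeric",
                 processing_log = "list", ground_truth = "list"))

setValidity("IMSDataset", function(object) {
  msg <- character()
  pk <- object@peaks
  if (!all(c("pixel_id", "mz", "intensity") %in% names(pk)))
    msg <- c(msg, "peaks must have columns pixel_id, mz, intensity")
  else {
    if (nrow(pk) && any(pk$intensity < 0)) msg <- c(msg, "intensities must be non-negative")
    if (nrow(pk) && (min(pk$mz) < object@mass_range[1] - 1e-9 ||
                     max(pk$mz) > object@mass_range[2] + 1e-9))
      msg <- c(msg, "peak m/z outside mass_range")
  }
  if (length(object@mass_range) != 2 || diff(object@mass_range) <= 0)
    msg <- c(msg, "mass_range must be (low, high) with low < high")
  if (anyDuplicated(object@pixels$pixel_id))
    msg <- c(msg, "at most one spectrum per pixel")
  if (length(msg)) msg else TRUE
})

#' Aligned IMS dataset on a common reference mass axis
#'
#' Result of [alignToAxis()]: every spectrum re-addressed to a shared set of
#' reference m/z channels obtained by greedy intensity-weighted centroid
#' clustering of the pooled peak list.
#'
#' @slot ref_mz numeric, strictly increasing reference m/z values (Da).
#' @slot intensities data.table with columns `pixel_id`, `channel`
#'   (index into `ref_mz`), `intensity`.
#' @slot pixels data.frame, as in [IMSDataset-class].
#' @slot tolerance_ppm numeric, the clustering tolerance used.
#' @slot processing_log list.
#' @slot ground_truth list carried over from the input dataset.
#' @exportClass AlignedIMS
setClass("AlignedIMS",
  representation(ref_mz = "numeric", intensities = "data.table",
                 pixels = "data.frame", tolerance_ppm = "numeric",
                 pixel_spacing = "numeric",
                 processing_log = "list", ground_truth = "list"))

setValidity("AlignedIMS", function(object) {
  msg <- character()
  if (is.unsorted(object@ref_mz, strictly = TRUE))
    msg <- c(msg, "reference m/z values must be strictly increasing")
  it <- object@intensities
  if (!all(c("pixel_id", "channel", "intensity") %in% names(it)))
    msg <- c(msg, "intensities must have columns pixel_id, channel, intensity")
  else if (nrow(it) && (min(it$channel) < 1 || max(it$channel) > length(object@ref_mz)))
    msg <- c(msg, "channel index out of range")
  if (length(msg)) msg else TRUE
})
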