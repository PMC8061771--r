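#' @include AllClasses.R
NULL

#' @rdname ticNormalize
#' @export
setGeneric("ticNormalize", function(object, ...) standardGeneric("ticNormalize"))

#' @rdname filterLowIntensity
#' @export
setGeneric("filterLowIntensity",
  function(object, fraction = 0.005, ...) standardGeneric("filterLowIntensity"))

#' @rdname alignToAxis
#' @export
setGeneric("alignToAxis",
  function(object, tolerance = 5, ...) standardGeneric("alignToAxis"))

#' @rdname groundTruth
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname pixelInfo
#' @export
setGeneric("pixelInfo", function(object) standardGeneric("pixelInfo"))

#' @rdname processingLog
#' @export
setGeneric("processingLog", function(object) standardGeneric("processingLog"))

setMethod("show", "LipidPanel", function(object) {
  sp <- object@species
  cat("LipidPanel:", nrow(sp), "species,", nrow(object@adducts), "adducts\n")
  cat("  classes:", paste(sort(unique(sp$lipid_class)), collapse = ", "), "\n")
  cat("  species:", paste(sp$name, collapse = ", "), "\n")
  cat("  adducts:", paste(sprintf("[M+%s]+", object@adducts$adduct), collapse = " "), "\n")
})

setMethod("show", "TissueLayout", function(object) {
  d <- dim(object@labels)
  tab <- table(factor(object@labels,
                      c("background", "epithelium", "lamina_propria")))
  cat(sprintf("TissueLayout: %d x %d pixels at %g um spacing\n",
              d[2], d[1], object@pixel_spacing))
  cat(sprintf("  epithelium: %d px, lamina propria: %d px, background: %d px\n",
              tab[["epithelium"]], tab[["lamina_propria"]], tab[["background"]]))
  cat(sprintf("  crypt reference paths: %d\n", length(object@paths)))
})

setMethod("show", "IMSDataset", function(object) {
  cat(sprintf("IMSDataset: %d spectra, %d peaks, m/z %g-%g\n",
              nrow(object@pixels), nrow(object@peaks),
              object@mass_range[1], object@mass_range[2]))
  if (length(object@ground_truth)) cat("  ground truth: attached\n")
  if (length(object@processing_log))
    cat("  log:", paste(vapply(object@processing_log, `[[`, "", "op"),
                        collapse = " -> "), "\n")
})

setMethod("show", "AlignedIMS", function(object) {
  cat(sprintf("AlignedIMS: %d spectra on %d reference channels (tol %g ppm)\n",
              nrow(object@pixels), length(object@ref_mz), object@tolerance_ppm))
})

#' Extract ground truth, pixel metadata or the processing log
#'
#' Accessors for [IMSDataset-class] and [AlignedIMS-class] objects.
#' `groundTruth()` returns the simulator's noiseless truth (empty list for
#' non-synthetic data); `pixelInfo()` the pixel metadata table;
#' `processingLog()` the ordered list of applied operations;
#' `refMz()` the reference mass axis of an aligned dataset.
#'
#' @param object an `IMSDataset` or `AlignedIMS`.
#' @return See description.
#' @name groundTruth
#' @export
setMethod("groundTruth", "IMSDataset", function(object) object@ground_truth)

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "AlignedIMS", function(object) object@ground_truth)

#' @rdname groundTruth
#' @export
setMethod("pixelInfo", "IMSDataset", function(object) object@pixels)

#' @rdname groundTruth
#' @export
setMethod("pixelInfo", "AlignedIMS", function(object) object@pixels)

#' @rdname groundTruth
#' @export
setMethod("processingLog", "IMSDataset", function(object) object@processing_log)

#' @rdname groundTruth
#' @export
setMethod("processingLog", "AlignedIMS", function(object) object@processing_log)

#' @rdname groundTruth
#' @param x an `AlignedIMS`.
#' @export
refMz <- function(x) {
  stopifnot(is(x, "AlignedIMS"))
  x@ref_mz
}

#' @rdname groundTruth
#' @export
peakTable <- function(x) {
  if (is(x, "IMSDataset")) return(data.table::copy(x@peaks))
  if (is(x, "AlignedIMS")) return(data.table::copy(x@intensities))
  stop("peakTable() expects an IMSDataset or AlignedIMS")
}
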