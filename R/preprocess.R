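#' @include AllClasses.R AllGenerics.R
NULL

.appendLog <- function(log, op, ...) c(log, list(c(list(op = op), list(...))))

#' Total ion current (TIC) normalization
#'
#' Rescales every spectrum so its intensities sum to 1; m/z values are
#' untouched. Spectra with zero TIC (empty pixels) are flagged and excluded
#' with a warning rather than raising an error. The operation is idempotent
#' and removes any global per-pixel intensity factor.
#'
#' @param object an [IMSDataset-class].
#' @param ... unused.
#' @return A TIC-normalized `IMSDataset`; the operation is appended to the
#'   processing log.
#' @rdname ticNormalize
#' @export
setMethod("ticNormalize", "IMSDataset", function(object, ...) {
  pk <- copy(object@peaks)
  tics <- pk[, .(tic = sum(intensity)), by = pixel_id]
  bad <- tics[tic <= 0, pixel_id]
  empty <- setdiff(object@pixels$pixel_id, tics$pixel_id)
  drop <- union(bad, empty)
  if (length(drop)) {
    warning(length(drop), " spectra with zero TIC excluded")
    pk <- pk[!pixel_id %in% drop]
  }
  pk[, intensity := intensity / sum(intensity), by = pixel_id]
  initialize(object, peaks = pk,
             pixels = object@pixels[!object@pixels$pixel_id %in% drop, ,
                                    drop = FALSE],
             processing_log = .appendLog(object@processing_log,
                                         "tic_normalize", excluded = drop))
})

#' Relative-intensity peak filter
#'
#' Retains the peaks whose intensity is at least `fraction` times the
#' intensity of the strongest peak. By default the threshold is computed per
#' spectrum (the base peak of that spectrum); with `global = TRUE` a single
#' threshold relative to the strongest peak of the whole dataset is used.
#' The base peak always survives, and the retained set is monotone in
#' `fraction` (a stricter threshold keeps a subset).
#'
#' @param object an [IMSDataset-class] or [AlignedIMS-class].
#' @param fraction threshold as a fraction of the base-peak intensity,
#'   `0 <= fraction < 1`; default 0.005 (0.5%).
#' @param global use a dataset-wide base peak instead of per-spectrum.
#' @param ... unused.
#' @return Object of the input class with sub-threshold peaks removed.
#' @rdname filterLowIntensity
#' @export
setMethod("filterLowIntensity", "IMSDataset",
          function(object, fraction = 0.005, global = FALSE, ...) {
  stopifnot(fraction >= 0, fraction < 1)
  pk <- copy(object@peaks)
  if (nrow(pk)) {
    if (global) {
      thr <- fraction * max(pk$intensity)
      pk <- pk[intensity >= thr]
    } else {
      pk <- pk[, .SD[intensity >= fraction * max(intensity)], by = pixel_id]
      setcolorder(pk, names(object@peaks))
    }
  }
  initialize(object, peaks = pk,
             processing_log = .appendLog(object@processing_log, "filter",
                                         fraction = fraction, global = global))
})

#' @rdname filterLowIntensity
#' @export
setMethod("filterLowIntensity", "AlignedIMS",
          function(object, fraction = 0.005, global = FALSE, ...) {
  stopifnot(fraction >= 0, fraction < 1)
  it <- copy(object@intensities)
  if (nrow(it)) {
    if (global) {
      thr <- fraction * max(it$intensity)
      it <- it[intensity >= thr]
    } else {
      it <- it[, .SD[intensity >= fraction * max(intensity)], by = pixel_id]
      setcolorder(it, names(object@intensities))
    }
  }
  initialize(object, intensities = it,
             processing_log = .appendLog(object@processing_log, "filter",
                                         fraction = fraction, global = global))
})

#' Align spectra to a common reference mass axis
#'
#' Builds a shared mass axis by greedy one-dimensional clustering of the
#' pooled peak list: all observed m/z values are sorted and a new reference
#' channel starts whenever the gap to the current channel's
#' intensity-weighted centroid exceeds the tolerance. Each spectrum's peaks
#' are then re-addressed to reference channels; peaks of one spectrum
#' mapping to the same channel are summed, so total intensity per spectrum
#' is conserved exactly.
#'
#' @param object an [IMSDataset-class].
#' @param tolerance clustering tolerance in ppm (> 0), default 5.
#' @param ... unused.
#' @return An [AlignedIMS-class].
#' @rdname alignToAxis
#' @export
setMethod("alignToAxis", "IMSDataset", function(object, tolerance = 5, ...) {
  stopifnot(tolerance > 0)
  pk <- object@peaks[order(mz)]
  id <- greedy_cluster_ppm(pk$mz, pk$intensity, tolerance)
  pk[, channel := id]
  pk[, w := pmax(intensity, 1e-300)]
  axis <- pk[, .(ref_mz = sum(mz * w) / sum(w)), by = channel]
  setorder(axis, channel)
  it <- pk[, .(intensity = sum(intensity)), by = .(pixel_id, channel)]
  setorder(it, pixel_id, channel)
  new("AlignedIMS", ref_mz = axis$ref_mz,
      intensities = it[, .(pixel_id, channel, intensity)],
      pixels = object@pixels, tolerance_ppm = tolerance,
      pixel_spacing = object@pixel_spacing,
      processing_log = .appendLog(object@processing_log, "align",
                                  tolerance_ppm = tolerance),
      ground_truth = object@ground_truth)
})
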