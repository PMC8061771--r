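#' @include preprocess.R
NULL

#' Annotate aligned channels with species/adduct candidates
#'
#' Matches every reference channel of an aligned dataset against the
#' registered ion channels of a lipid panel. A channel is annotated with all
#' candidates within the mass tolerance; channels carrying two or more
#' candidates are ambiguous (isobaric overlaps unresolved by the
#' instrument). Channels matching nothing are unassigned and excluded from
#' downstream analysis. Only channels observed in at least
#' `min_pixel_fraction` of the spectra are considered: genuine lipid
#' channels occur in essentially every tissue pixel, whereas uniform
#' chemical-noise peaks occupy isolated pixels, and this occupancy filter
#' prevents a stray noise peak that happens to fall within tolerance of a
#' lipid mass from being reported as an annotation.
#'
#' @param aligned an [AlignedIMS-class].
#' @param panel a [LipidPanel-class].
#' @param tolerance matching tolerance in ppm, default 9 (worst-case
#'   accepted mass accuracy).
#' @param warn_above candidates worse than this (ppm) are flagged; default 3
#'   (typical accuracy).
#' @param min_pixel_fraction minimum fraction of spectra a channel must
#'   appear in to be annotated; default 0.01.
#' @return data.frame of class `adductAnnotation`: one row per accepted
#'   candidate with columns `channel`, `ref_mz`, `species`, `lipid_class`,
#'   `adduct`, `theo_mz`, `ppm_error`, `flagged`, `n_cand`, `ambiguous`.
#'   Attributes: `n_channels` (total reference channels), `n_assigned`,
#'   `tolerance`, `n_adducts` (number of registered adducts).
#' @export
annotateChannels <- function(aligned, panel, tolerance = 9, warn_above = 3,
                             min_pixel_fraction = 0.01) {
  stopifnot(is(aligned, "AlignedIMS"), is(panel, "LipidPanel"), tolerance > 0)
  if (nrow(panel@species) == 0) stop("registry is empty")
  ref <- aligned@ref_mz
  n_px <- nrow(aligned@pixels)
  occ <- aligned@intensities[intensity > 0, .(n = uniqueN(pixel_id)),
                             by = channel]
  keep <- occ[n / n_px >= min_pixel_fraction, channel]

  theo <- lipidChannels(panel)
  hits <- lapply(seq_len(nrow(theo)), function(j) {
    lo <- theo$theo_mz[j] * (1 - tolerance * 1e-6)
    hi <- theo$theo_mz[j] * (1 + tolerance * 1e-6)
    idx <- which(ref >= lo & ref <= hi)
    idx <- intersect(idx, keep)
    if (!length(idx)) return(NULL)
    data.frame(channel = idx, ref_mz = ref[idx], species = theo$species[j],
               lipid_class = theo$lipid_class[j], adduct = theo$adduct[j],
               theo_mz = theo$theo_mz[j],
               ppm_error = ppmError(ref[idx], theo$theo_mz[j]),
               stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, hits)
  if (is.null(ann))
    ann <- data.frame(channel = integer(), ref_mz = numeric(),
                      species = character(), lipid_class = character(),
                      adduct = character(), theo_mz = numeric(),
                      ppm_error = numeric(), stringsAsFactors = FALSE)
  ann$flagged <- ann$ppm_error > warn_above
  ann <- ann[order(ann$channel, ann$ppm_error), , drop = FALSE]
  ncand <- table(ann$channel)
  ann$n_cand <- as.integer(ncand[as.character(ann$channel)])
  ann$ambiguous <- ann$n_cand >= 2
  rownames(ann) <- NULL
  structure(ann, class = c("adductAnnotation", "data.frame"),
            n_channels = length(ref), n_assigned = length(unique(ann$channel)),
            tolerance = tolerance, n_adducts = nrow(panel@adducts))
}

#' Per-pixel mass errors of accepted annotations
#'
#' The realized mass accuracy of individual measurements: for every pixel
#' peak mapped to an annotated reference channel, the ppm error of the
#' observed m/z against each accepted candidate's theoretical m/z.
#'
#' @param dataset the [IMSDataset-class] the alignment was built from.
#' @param aligned the [AlignedIMS-class].
#' @param annotation an `adductAnnotation` (see [annotateChannels()]).
#' @return data.frame with columns `pixel_id`, `channel`, `species`,
#'   `adduct`, `mz`, `ppm_error`.
#' @export
annotationMassErrors <- function(dataset, aligned, annotation) {
  stopifnot(is(dataset, "IMSDataset"), is(aligned, "AlignedIMS"))
  pk <- dataset@peaks[order(mz)]
  pk[, channel := greedy_cluster_ppm(pk$mz, pk$intensity,
                                     aligned@tolerance_ppm)]
  ann <- as.data.table(unclass(annotation))[
    , .(channel, species, adduct, theo_mz)]
  out <- merge(pk, ann, by = "channel", allow.cartesian = TRUE)
  out[, ppm := ppmError(mz, theo_mz)]
  as.data.frame(out[, .(pixel_id, channel, species, adduct, mz,
                        ppm_error = ppm)])
}

# long (pixel_id, lipid_class, adduct, r) view of a ratio table
.ratiosLong <- function(ratios) {
  rl <- melt(as.data.table(ratios),
             id.vars = c("pixel_id", "lipid_class"),
             measure.vars = c("r_H", "r_Na", "r_K"),
             variable.name = "adduct", value.name = "r")
  rl[, adduct := sub("^r_", "", adduct)]
  rl
}

#' Estimate per-spectrum, per-class adduct ratios
#'
#' For every spectrum (pixel) and lipid class, estimates the fraction of a
#' species' signal carried by each adduct, assumed constant across the
#' species of a class. The estimate uses intensity-weighted sums over the
#' *balanced anchor set*: the species of the class whose channels are
#' unambiguous for all registered adducts in that spectrum. Restricting to
#' fully anchored species keeps the estimator unbiased when isobaric
#' overlaps remove species asymmetrically across adducts (summing all
#' unambiguous channels would, e.g., drop a species from the Na column but
#' keep its H and K columns, skewing the ratio). At zero noise the estimate
#' equals the generating partition exactly.
#'
#' Spectra in which a class has no fully anchored species fall back, in
#' order, to the mean ratio over spectra of the same tissue compartment
#' (stratum), then to the dataset-wide mean, then to the naive
#' all-unambiguous-channel ratio; `fallback_used` is set and `method`
#' records which estimate was used. Classes entirely absent from a spectrum
#' yield no row.
#'
#' @param aligned an [AlignedIMS-class].
#' @param annotation an `adductAnnotation` from [annotateChannels()].
#' @return data.frame with columns `pixel_id`, `lipid_class`, `r_H`, `r_Na`,
#'   `r_K` (summing to 1), `support` (number of unambiguous channels used),
#'   `fallback_used`, `method`.
#' @export
estimateClassRatios <- function(aligned, annotation) {
  stopifnot(is(aligned, "AlignedIMS"))
  n_add <- attr(annotation, "n_adducts")
  if (is.null(n_add)) n_add <- 3L
  ann <- as.data.table(unclass(annotation))
  obs <- merge(aligned@intensities, ann, by = "channel",
               allow.cartesian = TRUE)

  unamb <- obs[n_cand == 1 & intensity > 0]
  unamb[, complete3 := uniqueN(adduct) == n_add, by = .(pixel_id, species)]
  bal <- unamb[complete3 == TRUE]
  est <- bal[, .(S = sum(intensity), nch = .N),
             by = .(pixel_id, lipid_class, adduct)]
  wide <- dcast(est, pixel_id + lipid_class ~ adduct,
                value.var = "S", fill = 0)
  for (a in c("H", "Na", "K"))
    if (!a %in% names(wide)) wide[, (a) := 0]
  supp <- bal[, .(support = .N), by = .(pixel_id, lipid_class)]
  wide <- merge(wide, supp, by = c("pixel_id", "lipid_class"))
  tot <- wide$H + wide$Na + wide$K
  ratios <- data.table(
    pixel_id = wide$pixel_id, lipid_class = wide$lipid_class,
    r_H = wide$H / tot, r_Na = wide$Na / tot, r_K = wide$K / tot,
    support = wide$support, fallback_used = FALSE, method = "balanced")

  # classes present (any annotated candidate signal) but not yet estimated
  present <- unique(obs[intensity > 0, .(pixel_id, lipid_class)])
  done <- ratios[, .(pixel_id, lipid_class)]
  todo <- present[!done, on = c("pixel_id", "lipid_class")]
  if (nrow(todo)) {
    pxinfo <- aligned@pixels
    comp <- setNames(pxinfo$compartment, pxinfo$pixel_id)
    ratios_comp <- ratios[, compartment := comp[as.character(pixel_id)]]
    strat <- ratios_comp[, .(r_H = mean(r_H), r_Na = mean(r_Na),
                             r_K = mean(r_K)),
                         by = .(lipid_class, compartment)]
    glob <- ratios_comp[, .(r_H = mean(r_H), r_Na = mean(r_Na),
                            r_K = mean(r_K)), by = lipid_class]
    fb <- lapply(seq_len(nrow(todo)), function(i) {
      pid <- todo$pixel_id[i]; cls <- todo$lipid_class[i]
      s <- strat[lipid_class == cls & compartment == comp[as.character(pid)]]
      method <- "stratum_mean"
      if (!nrow(s)) { s <- glob[lipid_class == cls]; method <- "dataset_mean" }
      if (!nrow(s)) {
        u <- unamb[pixel_id == pid & lipid_class == cls,
                   .(S = sum(intensity)), by = adduct]
        if (!nrow(u)) return(NULL)
        v <- setNames(rep(0, 3), c("H", "Na", "K"))
        v[u$adduct] <- u$S
        v <- v / sum(v)
        s <- data.table(r_H = v[["H"]], r_Na = v[["Na"]], r_K = v[["K"]])
        method <- "unbalanced"
      }
      tot <- s$r_H + s$r_Na + s$r_K
      data.table(pixel_id = pid, lipid_class = cls, r_H = s$r_H / tot,
                 r_Na = s$r_Na / tot, r_K = s$r_K / tot, support = 0L,
                 fallback_used = TRUE, method = method)
    })
    ratios[, compartment := NULL]
    ratios <- rbind(ratios, rbindlist(fb))
  } else if ("compartment" %in% names(ratios)) {
    ratios[, compartment := NULL]
  }
  setorder(ratios, pixel_id, lipid_class)
  as.data.frame(ratios)
}

#' Apportion isobaric channel overlaps
#'
#' Splits every ambiguous channel's observed intensity among its candidate
#' (species, adduct) ions using the per-spectrum class adduct ratios, in a
#' single linear pass per spectrum:
#' 1. each candidate species' latent total abundance is estimated from its
#'    unambiguous channels, `T_s = sum_a I(s, a) / sum_a r_a(class(s))` over
#'    the unambiguously observed adducts `a`;
#' 2. the predicted contribution of candidate `(s, a)` is
#'    `T_s * r_a(class(s))` (cross-class overlaps use each candidate's own
#'    class ratio);
#' 3. the observed channel intensity is split proportionally to the
#'    predicted contributions, so the parts sum exactly to the observation.
#' Candidates with no unambiguous anchor receive the mean predicted
#' contribution of the anchored candidates (an equal-split prior) and are
#' flagged; channels where no candidate has an anchor are split equally and
#' flagged low-confidence. Unambiguous channels pass through unchanged. The
#' correction is applied spectrum by spectrum, never to the average
#' spectrum, because the class ratio differs between tissue types.
#'
#' @param aligned an [AlignedIMS-class].
#' @param annotation an `adductAnnotation` from [annotateChannels()].
#' @param ratios class adduct ratio table from [estimateClassRatios()].
#' @return A [SummarizedExperiment::SummarizedExperiment] with one assay per
#'   adduct (`H`, `Na`, `K`; species x pixels, corrected intensities),
#'   `rowData` describing the species and `colData` the pixels. Metadata:
#'   `annotation`, `ratios`, `low_confidence` (equal-split channel/pixel
#'   pairs), `processing_log`.
#' @export
apportionOverlaps <- function(aligned, annotation, ratios) {
  stopifnot(is(aligned, "AlignedIMS"))
  ann <- as.data.table(unclass(annotation))
  obs <- merge(aligned@intensities, ann, by = "channel",
               allow.cartesian = TRUE)
  rl <- .ratiosLong(ratios)

  unamb <- obs[n_cand == 1]
  unamb[, corrected := intensity]

  amb <- obs[n_cand >= 2]
  low_conf <- data.table(pixel_id = integer(), channel = integer())
  if (nrow(amb)) {
    anch <- merge(unamb[intensity > 0,
                        .(pixel_id, species, lipid_class, adduct, intensity)],
                  rl, by = c("pixel_id", "lipid_class", "adduct"))
    Tsp <- anch[, .(Ts = sum(intensity) / sum(r)), by = .(pixel_id, species)]
    amb <- merge(amb, Tsp, by = c("pixel_id", "species"), all.x = TRUE)
    amb <- merge(amb, rl, by = c("pixel_id", "lipid_class", "adduct"),
                 all.x = TRUE)
    amb[, pred := Ts * r]
    amb[, anchored := !is.na(pred)]
    # equal-split prior for unanchored candidates: the mean anchored
    # prediction, or 1 if nothing in the channel is anchored
    amb[, pred := fifelse(is.na(pred),
                          mean(pred, na.rm = TRUE), pred),
        by = .(pixel_id, channel)]
    amb[, pred := fifelse(is.nan(pred) | is.na(pred), 1, pred)]
    amb[, share := {
      s <- sum(pred)
      if (s <= 0) rep(1 / .N, .N) else pred / s
    }, by = .(pixel_id, channel)]
    low_conf <- unique(amb[anchored == FALSE, .(pixel_id, channel)])
    amb[, corrected := intensity * share]
  }

  keep <- c("pixel_id", "channel", "species", "lipid_class", "adduct",
            "corrected")
  corr <- rbind(unamb[, ..keep], if (nrow(amb)) amb[, ..keep])
  tab <- corr[, .(intensity = sum(corrected)),
              by = .(pixel_id, species, lipid_class, adduct)]

  px <- aligned@pixels
  sp <- unique(ann[, .(species, lipid_class)])
  setorder(sp, species)
  assays <- lapply(c("H", "Na", "K"), function(a) {
    m <- matrix(0, nrow(sp), nrow(px),
                dimnames = list(sp$species, px$pixel_id))
    sub <- tab[adduct == a]
    m[cbind(match(sub$species, sp$species),
            match(sub$pixel_id, px$pixel_id))] <- sub$intensity
    m
  })
  names(assays) <- c("H", "Na", "K")
  SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(sp),
    colData = S4Vectors::DataFrame(px, row.names = px$pixel_id),
    metadata = list(annotation = annotation, ratios = ratios,
                    low_confidence = as.data.frame(low_conf),
                    pixel_spacing = aligned@pixel_spacing,
                    processing_log = .appendLog(aligned@processing_log,
                                                "apportion_overlaps")))
}

#' Annotate, estimate ratios and deconvolve in one call
#'
#' Convenience wrapper chaining [annotateChannels()],
#' [estimateClassRatios()] and [apportionOverlaps()].
#'
#' @param aligned an [AlignedIMS-class].
#' @param panel a [LipidPanel-class].
#' @param tolerance annotation tolerance in ppm (default 9).
#' @param min_pixel_fraction channel occupancy filter (default 0.01).
#' @return A `SummarizedExperiment`; see [apportionOverlaps()].
#' @export
deconvolveAdducts <- function(aligned, panel, tolerance = 9,
                              min_pixel_fraction = 0.01) {
  ann <- annotateChannels(aligned, panel, tolerance = tolerance,
                          min_pixel_fraction = min_pixel_fraction)
  ratios <- estimateClassRatios(aligned, ann)
  apportionOverlaps(aligned, ann, ratios)
}

#' Per-species total intensity
#'
#' Sum of the corrected H+, Na+ and K+ adduct intensities per species and
#' pixel.
#'
#' @param se a deconvolved `SummarizedExperiment` from
#'   [apportionOverlaps()].
#' @return species x pixel matrix of totals.
#' @export
speciesTotals <- function(se) {
  SummarizedExperiment::assay(se, "H") +
    SummarizedExperiment::assay(se, "Na") +
    SummarizedExperiment::assay(se, "K")
}

#' Export a deconvolved dataset as a long table
#'
#' @param se a deconvolved `SummarizedExperiment`.
#' @return data.frame with columns `pixel_id`, `x`, `y`, `compartment`,
#'   `species`, `adduct`, `intensity_corrected`.
#' @export
deconvolvedTable <- function(se) {
  px <- as.data.frame(SummarizedExperiment::colData(se))
  out <- rbindlist(lapply(c("H", "Na", "K"), function(a) {
    m <- SummarizedExperiment::assay(se, a)
    data.table(pixel_id = rep(px$pixel_id, each = nrow(m)),
               x = rep(px$x, each = nrow(m)),
               y = rep(px$y, each = nrow(m)),
               compartment = rep(px$compartment, each = nrow(m)),
               species = rep(rownames(m), ncol(m)),
               adduct = a, intensity_corrected = as.vector(m))
  }))
  as.data.frame(out)
}
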