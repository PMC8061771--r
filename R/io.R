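#' @include AllClasses.R
NULL

#' Serialize an IMS dataset to a plain-text directory
#'
#' Writes the internal exchange format: `peaks.tsv` (`pixel_id`, `mz`,
#' `intensity`), `pixels.tsv` (pixel metadata) and a JSON sidecar
#' `meta.json` (mass range, pixel spacing, processing log, and — for
#' synthetic data — the ground truth tables and layout).
#'
#' @param dataset an [IMSDataset-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeIMSDataset <- function(dataset, dir) {
  stopifnot(is(dataset, "IMSDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(dataset@peaks, file.path(dir, "peaks.tsv"), sep = "\t")
  fwrite(as.data.table(dataset@pixels), file.path(dir, "pixels.tsv"),
         sep = "\t")
  gt <- dataset@ground_truth
  meta <- list(mass_range = dataset@mass_range,
               pixel_spacing = dataset@pixel_spacing,
               processing_log = dataset@processing_log)
  if (length(gt)) {
    lay <- gt$layout
    meta$ground_truth <- list(
      condition = gt$condition,
      partitions = gt$partitions,
      profiles = gt$profiles,
      layout = list(labels = as.vector(lay@labels),
                    crypt_axis = as.vector(lay@crypt_axis),
                    mucosa_axis = as.vector(lay@mucosa_axis),
                    dim = dim(lay@labels),
                    pixel_spacing = lay@pixel_spacing,
                    paths = lapply(lay@paths, function(p)
                      list(x = unname(p[, "x"]), y = unname(p[, "y"])))))
    fwrite(gt$truth, file.path(dir, "ground_truth.tsv"), sep = "\t")
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(dir)
}

#' Read an IMS dataset from the internal plain-text format
#'
#' @param dir directory written by [writeIMSDataset()].
#' @return An [IMSDataset-class].
#' @export
readIMSDataset <- function(dir) {
  peaks <- fread(file.path(dir, "peaks.tsv"))
  pixels <- as.data.frame(fread(file.path(dir, "pixels.tsv")))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  gt <- list()
  gtf <- file.path(dir, "ground_truth.tsv")
  if (file.exists(gtf) && !is.null(meta$ground_truth)) {
    mg <- meta$ground_truth
    d <- mg$layout$dim
    layout <- new("TissueLayout",
      labels = matrix(mg$layout$labels, d[1], d[2]),
      crypt_axis = matrix(as.numeric(mg$layout$crypt_axis), d[1], d[2]),
      mucosa_axis = matrix(as.numeric(mg$layout$mucosa_axis), d[1], d[2]),
      pixel_spacing = mg$layout$pixel_spacing,
      paths = lapply(mg$layout$paths, function(p) cbind(x = p$x, y = p$y)))
    gt <- list(truth = fread(gtf), partitions = as.data.frame(mg$partitions),
               profiles = as.data.frame(mg$profiles), layout = layout,
               condition = mg$condition)
  }
  log <- meta$processing_log
  if (is.data.frame(log)) log <- lapply(seq_len(nrow(log)), function(i)
    as.list(log[i, ]))
  new("IMSDataset", peaks = peaks, pixels = pixels,
      mass_range = as.numeric(meta$mass_range),
      pixel_spacing = meta$pixel_spacing,
      processing_log = if (is.null(log)) list() else log,
      ground_truth = gt)
}
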