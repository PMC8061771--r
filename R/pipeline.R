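#' @include spatial.R simulate.R io.R
NULL

# derive a reproducible 31-bit sub-seed for subject j of a run
.subSeed <- function(seed, j) {
  as.integer((as.numeric(seed) * 7919 + j * 104729) %% 2147483647)
}

#' Process one section through the full analysis chain
#'
#' simulate (optional) -> TIC normalize -> align -> relative-intensity
#' filter -> annotate -> class-ratio estimation -> overlap apportionment.
#'
#' @param dataset an [IMSDataset-class] (e.g. from [simulateDataset()]).
#' @param panel a [LipidPanel-class].
#' @param align_tol alignment clustering tolerance, ppm.
#' @param filter_frac relative-intensity filter threshold.
#' @param annot_tol annotation tolerance, ppm.
#' @param min_pixel_fraction channel occupancy filter for annotation.
#' @return list with elements `aligned` ([AlignedIMS-class]) and `se`
#'   (deconvolved `SummarizedExperiment`).
#' @export
processDataset <- function(dataset, panel = colonPanel(), align_tol = 5,
                           filter_frac = 0.005, annot_tol = 9,
                           min_pixel_fraction = 0.01) {
  norm <- ticNormalize(dataset)
  aligned <- alignToAxis(norm, tolerance = align_tol)
  aligned <- filterLowIntensity(aligned, fraction = filter_frac)
  se <- deconvolveAdducts(aligned, panel, tolerance = annot_tol,
                          min_pixel_fraction = min_pixel_fraction)
  list(aligned = aligned, se = se)
}

#' Synthetic healthy-vs-adenoma demonstration experiment
#'
#' Simulates independent tissue sections (4 healthy and 3 adenomatous by
#' default, mirroring the section counts of the study design), runs each
#' through the full pipeline, summarises both compartments per subject, and
#' compares the groups. Fully reproducible from `seed`.
#'
#' @param seed integer root seed.
#' @param n_healthy,n_adenoma number of subject sections per condition.
#' @param width,height,n_crypts layout geometry per section (defaults give
#'   roughly 300 epithelial pixels per section).
#' @param align_tol,filter_frac,annot_tol,min_pixel_fraction pipeline
#'   parameters, see [processDataset()].
#' @param keep_se keep the per-subject `SummarizedExperiment`s (memory
#'   permitting); summaries are always kept.
#' @param ... further arguments passed to [simConfig()] (noise levels etc.).
#' @return list of class `imsDemo`:
#' * `summaries`: per condition, a list of per-subject lists with elements
#'   `epithelium` and `lamina_propria` ([roiSummary()] tables);
#' * `comparison`: per compartment, an `adductComparison`
#'   (healthy vs adenoma, unpaired);
#' * `summary_table`: data.frame `condition`, `compartment`, `species`,
#'   `mean_f_Na`, `mean_f_K`, `sem_f_K` (subject-level means);
#' * `subjects`: per-subject deconvolved experiments (if `keep_se`);
#' * `params`: the run configuration.
#' @export
runDemo <- function(seed = 1, n_healthy = 4, n_adenoma = 3,
                    width = 64, height = 64, n_crypts = 3,
                    align_tol = 5, filter_frac = 0.005, annot_tol = 9,
                    min_pixel_fraction = 0.01, keep_se = FALSE, ...) {
  conditions <- c(rep("healthy", n_healthy), rep("adenoma", n_adenoma))
  subjects <- list()
  summaries <- list(healthy = list(), adenoma = list())
  for (j in seq_along(conditions)) {
    cond <- conditions[j]
    sseed <- .subSeed(seed, j)
    layout <- buildLayout(width, height, n_crypts, seed = sseed)
    cfg <- simConfig(condition = cond, seed = sseed, ...)
    ds <- simulateDataset(layout, cfg)
    res <- processDataset(ds, panel = cfg$panel, align_tol = align_tol,
                          filter_frac = filter_frac, annot_tol = annot_tol,
                          min_pixel_fraction = min_pixel_fraction)
    summaries[[cond]][[length(summaries[[cond]]) + 1L]] <-
      list(epithelium = roiSummary(res$se, "epithelium"),
           lamina_propria = roiSummary(res$se, "lamina_propria"))
    if (keep_se) subjects[[j]] <- res$se
  }

  comparison <- lapply(
    c(epithelium = "epithelium", lamina_propria = "lamina_propria"),
    function(comp) compareGroups(
      lapply(summaries$healthy, `[[`, comp),
      lapply(summaries$adenoma, `[[`, comp), paired = FALSE))

  tab <- rbindlist(lapply(names(summaries), function(cond)
    rbindlist(lapply(c("epithelium", "lamina_propria"), function(comp) {
      per_subj <- rbindlist(lapply(summaries[[cond]], function(s)
        as.data.table(s[[comp]])[metric == "f_K",
                                 .(species, f_K = mean)]))
      per_subj[, .(condition = cond, compartment = comp,
                   mean_f_Na = 1 - mean(f_K), mean_f_K = mean(f_K),
                   sem_f_K = .semOf(f_K)), by = species]
    }))))
  setcolorder(tab, c("condition", "compartment", "species"))

  structure(list(summaries = summaries, comparison = comparison,
                 summary_table = as.data.frame(tab),
                 subjects = subjects,
                 params = list(seed = seed, n_healthy = n_healthy,
                               n_adenoma = n_adenoma, width = width,
                               height = height, n_crypts = n_crypts,
                               align_tol = align_tol,
                               filter_frac = filter_frac,
                               annot_tol = annot_tol,
                               min_pixel_fraction = min_pixel_fraction)),
            class = "imsDemo")
}

#' @export
print.imsDemo <- function(x, ...) {
  cat("Synthetic healthy-vs-adenoma IMS experiment\n")
  cat(sprintf("  %d healthy + %d adenoma sections, seed %d\n",
              x$params$n_healthy, x$params$n_adenoma, x$params$seed))
  tab <- x$summary_table
  agg <- aggregate(mean_f_K ~ condition + compartment, tab, mean)
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %s / %s: mean K pair fraction %.3f\n",
                agg$condition[i], agg$compartment[i], agg$mean_f_K[i]))
  invisible(x)
}

#' Run the pipeline from a configuration
#'
#' Executes simulate -> preprocess -> deconvolve -> summarise/compare from a
#' single configuration (a YAML file path or an equivalent nested list with
#' blocks `demo` (subject counts, seed, layout) and `pipeline` (tolerances,
#' filter fraction) and optional `noise` overrides for [simConfig()]), and
#' optionally writes the report bundle.
#'
#' @param config YAML file path or list.
#' @param out_dir if given, [writeReport()] is called on the result.
#' @return An `imsDemo` object (invisibly when `out_dir` is given).
#' @export
runPipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  demo_args <- config$demo %||% list()
  pipe_args <- config$pipeline %||% list()
  noise_args <- config$noise %||% list()
  res <- do.call(runDemo, c(demo_args, pipe_args, noise_args))
  if (!is.null(out_dir)) {
    writeReport(res, out_dir)
    return(invisible(res))
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the demo report bundle
#'
#' Emits `summary.json` (per-condition, per-compartment mean pair fractions
#' per species), `summary_table.tsv`, per-compartment
#' `comparison_<compartment>.tsv` and `proportions_<compartment>.tsv`
#' (normalized stacked adduct proportions), and `params.json`.
#'
#' @param demo an `imsDemo` from [runDemo()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeReport <- function(demo, dir) {
  stopifnot(inherits(demo, "imsDemo"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(as.data.table(demo$summary_table),
         file.path(dir, "summary_table.tsv"), sep = "\t")
  for (comp in names(demo$comparison)) {
    fwrite(as.data.table(demo$comparison[[comp]]$tests),
           file.path(dir, paste0("comparison_", comp, ".tsv")), sep = "\t")
    fwrite(as.data.table(demo$comparison[[comp]]$proportions),
           file.path(dir, paste0("proportions_", comp, ".tsv")), sep = "\t")
  }
  tab <- demo$summary_table
  summ <- lapply(split(tab, tab$condition), function(cc)
    lapply(split(cc, cc$compartment), function(ss)
      setNames(lapply(seq_len(nrow(ss)), function(i)
        list(f_Na = ss$mean_f_Na[i], f_K = ss$mean_f_K[i])), ss$species)))
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(demo$params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
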