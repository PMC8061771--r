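#' @include deconvolve.R
NULL

#' Sodium/potassium adduct pair fractions
#'
#' Renormalizes the Na+ and K+ adduct intensities of a species to sum to 1:
#' `f_Na = I_Na / (I_Na + I_K)`, `f_K = 1 - f_Na`. The H+ adduct is excluded
#' from this pair statistic. Where both intensities are zero the fraction is
#' undefined and returned as `NA` (not 0.5). The pair ratio is invariant to
#' any global rescaling of a spectrum, hence to TIC normalization choices.
#'
#' @param I_Na,I_K non-negative intensities (vectorised).
#' @return data.frame with columns `f_Na`, `f_K`.
#' @examples
#' naKFractions(c(50, 30, 0), c(50, 70, 10))
#' @export
naKFractions <- function(I_Na, I_K) {
  if (any(I_Na < 0) || any(I_K < 0)) stop("intensities must be non-negative")
  tot <- I_Na + I_K
  f_Na <- ifelse(tot > 0, I_Na / tot, NA_real_)
  data.frame(f_Na = f_Na, f_K = 1 - f_Na)
}

#' Pair-fraction matrices of a deconvolved dataset
#'
#' @param se a deconvolved `SummarizedExperiment`.
#' @return list of species x pixel matrices `f_Na` and `f_K` (`NA` where
#'   the species has no Na+K signal at a pixel).
#' @export
pairFractions <- function(se) {
  na <- SummarizedExperiment::assay(se, "Na")
  k <- SummarizedExperiment::assay(se, "K")
  tot <- na + k
  f_na <- ifelse(tot > 0, na / tot, NA_real_)
  list(f_Na = f_na, f_K = 1 - f_na)
}

#' Densify waypoints into an 8-connected pixel chain
#'
#' Connects consecutive waypoints with Bresenham line segments, producing an
#' ordered, duplicate-free, 8-connected pixel path.
#'
#' @param waypoints matrix or data.frame with columns `x`, `y` (integer
#'   pixel coordinates).
#' @return data.frame with columns `x`, `y`.
#' @export
densifyPath <- function(waypoints) {
  wp <- as.data.frame(waypoints)
  stopifnot(all(c("x", "y") %in% names(wp)), nrow(wp) >= 1)
  segs <- list(data.frame(x = wp$x[1], y = wp$y[1]))
  for (i in seq_len(nrow(wp) - 1)) {
    x0 <- wp$x[i]; y0 <- wp$y[i]; x1 <- wp$x[i + 1]; y1 <- wp$y[i + 1]
    n <- max(abs(x1 - x0), abs(y1 - y0))
    if (n == 0) next
    xs <- round(x0 + (x1 - x0) * seq_len(n) / n)
    ys <- round(y0 + (y1 - y0) * seq_len(n) / n)
    segs[[length(segs) + 1L]] <- data.frame(x = xs, y = ys)
  }
  path <- do.call(rbind, segs)
  path[!duplicated(path), , drop = FALSE]
}

.checkPath <- function(path) {
  dx <- abs(diff(path$x)); dy <- abs(diff(path$y))
  if (any(pmax(dx, dy) != 1))
    stop("path pixels must be consecutive 8-neighbors")
  if (anyDuplicated(path[, c("x", "y")])) stop("path revisits a pixel")
}

.movingAverage <- function(v, window) {
  if (is.null(window) || window <= 1) return(v)
  half <- (window - 1) %/% 2
  n <- length(v)
  vapply(seq_len(n), function(i) {
    w <- v[max(1, i - half):min(n, i + half)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Pixel-by-pixel adduct profile along a path
#'
#' Follows the corrected H+, Na+ and K+ intensities of the requested species
#' along an ordered pixel path (e.g. from the base to the top of a crypt)
#' and computes the Na/K pair fractions at every step. An optional centered
#' moving average can smooth the tracks for plotting; statistics should use
#' the raw values.
#'
#' @param se a deconvolved `SummarizedExperiment`.
#' @param path waypoints or full pixel chain (columns `x`, `y`); densified
#'   with [densifyPath()]. The densified path must have at least 10 pixels,
#'   consecutive pixels must be 8-neighbors and no pixel may repeat.
#' @param species character vector of species names; default all.
#' @param compartment if given, every path pixel must carry this label.
#' @param window odd moving-average window in pixels (`NULL` = no
#'   smoothing).
#' @return data.frame with columns `step`, `x`, `y`, `distance_um`
#'   (arc length), `species`, `I_H`, `I_Na`, `I_K`, `f_Na`, `f_K`.
#' @export
extractPathProfile <- function(se, path, species = NULL, compartment = NULL,
                               window = NULL) {
  path <- densifyPath(path)
  if (nrow(path) < 10) stop("path must cover at least 10 pixels")
  .checkPath(path)
  px <- as.data.frame(SummarizedExperiment::colData(se))
  key <- paste(px$x, px$y)
  idx <- match(paste(path$x, path$y), key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("path pixel (%d, %d) is outside the dataset",
                 path$x[bad], path$y[bad]))
  }
  if (!is.null(compartment) && any(px$compartment[idx] != compartment)) {
    bad <- which(px$compartment[idx] != compartment)[1]
    stop(sprintf("path pixel (%d, %d) is not in the %s",
                 path$x[bad], path$y[bad], compartment))
  }
  if (is.null(species)) species <- rownames(se)
  miss <- setdiff(species, rownames(se))
  if (length(miss)) stop("species not in dataset: ", paste(miss, collapse = ", "))

  spacing <- if (!is.null(px$pixel_spacing)) px$pixel_spacing[1] else
    S4Vectors::metadata(se)$pixel_spacing
  if (is.null(spacing)) spacing <- 1
  steps <- sqrt(diff(path$x)^2 + diff(path$y)^2) * spacing
  dist_um <- c(0, cumsum(steps))

  out <- rbindlist(lapply(species, function(s) {
    iH <- SummarizedExperiment::assay(se, "H")[s, idx]
    iNa <- SummarizedExperiment::assay(se, "Na")[s, idx]
    iK <- SummarizedExperiment::assay(se, "K")[s, idx]
    if (!is.null(window)) {
      iH <- .movingAverage(iH, window)
      iNa <- .movingAverage(iNa, window)
      iK <- .movingAverage(iK, window)
    }
    fr <- naKFractions(iNa, iK)
    data.table(step = seq_len(nrow(path)), x = path$x, y = path$y,
               distance_um = dist_um, species = s,
               I_H = unname(iH), I_Na = unname(iNa), I_K = unname(iK),
               f_Na = fr$f_Na, f_K = fr$f_K)
  }))
  as.data.frame(out)
}

#' Per-compartment summary of adduct levels and pair fractions
#'
#' Means and standard errors over all pixels of a tissue compartment, per
#' species: the three corrected adduct intensities (`I_H`, `I_Na`, `I_K`)
#' and the Na/K pair fractions (`f_Na`, `f_K`). Pixels where a fraction is
#' undefined are excluded for that species. With a single pixel the SEM is
#' reported as 0.
#'
#' @param se a deconvolved `SummarizedExperiment`.
#' @param compartment `"epithelium"` or `"lamina_propria"`.
#' @return data.frame with columns `species`, `lipid_class`, `metric`,
#'   `mean`, `sem`, `n`.
#' @export
roiSummary <- function(se, compartment) {
  px <- as.data.frame(SummarizedExperiment::colData(se))
  idx <- which(px$compartment == compartment)
  if (!length(idx)) stop("compartment not present: ", compartment)
  rd <- as.data.frame(SummarizedExperiment::rowData(se))
  fr <- pairFractions(se)
  mats <- list(I_H = SummarizedExperiment::assay(se, "H"),
               I_Na = SummarizedExperiment::assay(se, "Na"),
               I_K = SummarizedExperiment::assay(se, "K"),
               f_Na = fr$f_Na, f_K = fr$f_K)
  out <- rbindlist(lapply(names(mats), function(metric) {
    m <- mats[[metric]][, idx, drop = FALSE]
    n <- rowSums(!is.na(m))
    mu <- rowMeans(m, na.rm = TRUE)
    s <- apply(m, 1, sd, na.rm = TRUE)
    sem <- ifelse(n > 1, s / sqrt(n), 0)
    data.table(species = rownames(mats[[metric]]),
               lipid_class = rd$lipid_class[match(rownames(mats[[metric]]),
                                                  rd$species)],
               metric = metric, mean = mu, sem = sem, n = n)
  }))
  setorder(out, species, metric)
  as.data.frame(out)
}

.tTestSafe <- function(x, y, paired = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (paired) {
    if (length(x) != length(y) || length(x) < 2)
      return(list(t = NA_real_, p = NA_real_))
    d <- x - y
    if (sd(d) == 0)
      return(if (mean(d) == 0) list(t = 0, p = 1)
             else list(t = sign(mean(d)) * Inf, p = 0))
    tt <- t.test(d)
    return(list(t = unname(tt$statistic), p = tt$p.value))
  }
  if (length(x) < 2 || length(y) < 2) return(list(t = NA_real_, p = NA_real_))
  if (sd(x) == 0 && sd(y) == 0)
    return(if (mean(x) == mean(y)) list(t = 0, p = 1)
           else list(t = sign(mean(x) - mean(y)) * Inf, p = 0))
  tt <- t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Compare adduct statistics between healthy and adenoma groups
#'
#' Subject-level comparison of per-compartment summaries (one
#' [roiSummary()] per subject and group): for every species and metric a
#' two-sided Student's t-test (paired or unpaired) on the subject means,
#' plus normalized stacked adduct proportions per group (each species'
#' three mean adduct intensities rescaled to sum to 1 within a group).
#' Species/metric combinations with insufficient subjects yield `NA`
#' results; the run continues.
#'
#' @param healthy,adenoma lists of [roiSummary()] data.frames, one per
#'   subject.
#' @param paired use a paired t-test (requires equal subject counts).
#' @param adjust `"none"` (default; per-species tests are reported as such)
#'   or `"BH"` for Benjamini-Hochberg adjusted p-values in `p_adj`.
#' @return list of class `adductComparison` with elements `tests`
#'   (data.frame: species, metric, group means/SEMs/n, `t`, `p`, `test`) and
#'   `proportions` (data.frame: group, species, adduct, proportion).
#' @export
compareGroups <- function(healthy, adenoma, paired = FALSE,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(length(healthy) >= 1, length(adenoma) >= 1)
  if (paired && length(healthy) != length(adenoma))
    stop("paired comparison requires equal subject counts")
  pull <- function(group) rbindlist(lapply(seq_along(group), function(i)
    data.table(subject = i, as.data.table(group[[i]]))))
  h <- pull(healthy); a <- pull(adenoma)
  combos <- unique(rbind(h[, .(species, metric)], a[, .(species, metric)]))
  setorder(combos, species, metric)
  tests <- rbindlist(lapply(seq_len(nrow(combos)), function(i) {
    s <- combos$species[i]; m <- combos$metric[i]
    xv <- h[species == s & metric == m, mean]
    yv <- a[species == s & metric == m, mean]
    tt <- .tTestSafe(xv, yv, paired)
    data.table(species = s, metric = m,
               mean_healthy = mean(xv), sem_healthy = .semOf(xv),
               n_healthy = length(xv),
               mean_adenoma = mean(yv), sem_adenoma = .semOf(yv),
               n_adenoma = length(yv),
               t = tt$t, p = tt$p,
               test = if (paired) "paired t" else "unpaired t")
  }))
  if (adjust == "BH") tests[, p_adj := stats::p.adjust(p, "BH")]

  props <- rbindlist(lapply(list(healthy = h, adenoma = a), function(g)
    g[metric %in% c("I_H", "I_Na", "I_K"),
      .(value = mean(mean)), by = .(species, metric)][
      , .(adduct = sub("^I_", "", metric),
          proportion = value / sum(value)), by = species]),
    idcol = "group")
  structure(list(tests = as.data.frame(tests),
                 proportions = as.data.frame(props)),
            class = "adductComparison")
}

.semOf <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
}

#' @export
print.adductComparison <- function(x, ...) {
  cat("Adduct group comparison:", nrow(x$tests), "species x metric tests\n")
  sig <- x$tests[x$tests$metric == "f_K" & !is.na(x$tests$p) &
                   x$tests$p < 0.05, ]
  cat("  species with significant f_K difference (p < 0.05):",
      if (nrow(sig)) paste(sig$species, collapse = ", ") else "none", "\n")
  invisible(x)
}
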