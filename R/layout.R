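#' @include AllClasses.R
NULL

#' Build a synthetic colon-mucosa tissue layout
#'
#' Generates a label raster emulating colon mucosa geometry: a single-cell
#' epithelial band per crypt that invaginates into the lamina propria as a
#' U shape (two one-pixel arms joined at the crypt base, near the basal side
#' of the mucosa), surrounded by lamina propria and bordered by background.
#' Each epithelial pixel receives a crypt-axis coordinate growing
#' monotonically from 0 at the crypt base to 1 at the crypt top; each stromal
#' pixel receives a mucosa-axis coordinate (0 basal, 1 luminal).
#'
#' @param width,height raster dimensions in pixels (>= 16 each).
#' @param n_crypts number of crypts (>= 1); each needs ~10 columns.
#' @param seed integer seed controlling the (small) horizontal jitter of
#'   crypt positions; the construction is fully deterministic given the seed.
#' @param pixel_spacing micrometres between pixel centres (default 10, the
#'   lateral resolution regime of single-cell MALDI-IMS).
#' @param arm_halfwidth half-width of the crypt base in pixels (default 3).
#' @return A [TissueLayout-class]; reference base-to-top paths, one per
#'   crypt, are stored in the `paths` slot (see [cryptPaths()]).
#' @export
buildLayout <- function(width = 64, height = 64, n_crypts = 3, seed = 1,
                        pixel_spacing = 10, arm_halfwidth = 3) {
  if (width < 16 || height < 16) stop("layout must be at least 16 x 16 pixels")
  if (n_crypts < 1) stop("n_crypts must be >= 1")
  w <- arm_halfwidth
  slot_width <- 2 * w + 4
  if (n_crypts * slot_width > width)
    stop(sprintf("cannot place %d crypts in %d columns (need %d)",
                 n_crypts, width, n_crypts * slot_width))

  border <- max(1L, height %/% 16L)
  r_top <- round(0.12 * height) + 1L     # luminal end of the crypt arms
  r_base <- height - round(0.12 * height) # basal end (crypt bottom)
  muc_top <- border + 1L
  muc_bot <- height - border

  lab <- matrix("background", nrow = height, ncol = width)
  lab[muc_top:muc_bot, ] <- "lamina_propria"
  crypt_axis <- matrix(NA_real_, height, width)
  mucosa_axis <- matrix(NA_real_, height, width)

  set.seed(as.integer(seed))
  centers <- round((seq_len(n_crypts) - 0.5) / n_crypts * width)
  jitter <- sample(-1:1, n_crypts, replace = TRUE)
  centers <- pmin(pmax(centers + jitter, w + 2L), width - w - 1L)

  path_len <- w + (r_base - r_top)
  paths <- vector("list", n_crypts)
  for (k in seq_len(n_crypts)) {
    cx <- centers[k]
    xs <- (cx - w):(cx + w)
    lab[r_base, xs] <- "epithelium"
    crypt_axis[r_base, xs] <- abs(xs - cx) / path_len
    arm_rows <- (r_base - 1L):r_top
    for (x in c(cx - w, cx + w)) {
      lab[arm_rows, x] <- "epithelium"
      crypt_axis[arm_rows, x] <- (w + (r_base - arm_rows)) / path_len
    }
    # reference path: base centre -> left along the bottom -> up the left arm
    px <- c(cx:(cx - w), rep(cx - w, length(arm_rows)))
    py <- c(rep(r_base, w + 1L), arm_rows)
    paths[[k]] <- cbind(x = px, y = py)
  }

  lp <- lab == "lamina_propria"
  rows <- matrix(seq_len(height), height, width)
  mucosa_axis[lp] <- (muc_bot - rows[lp]) / (muc_bot - muc_top)

  new("TissueLayout", labels = lab, crypt_axis = crypt_axis,
      mucosa_axis = mucosa_axis, pixel_spacing = pixel_spacing, paths = paths)
}

#' Layout accessors
#'
#' `layoutLabels()` returns the compartment raster, `cryptAxis()` and
#' `mucosaAxis()` the axis rasters, `cryptPaths()` the per-crypt reference
#' base-to-top pixel paths, and `layoutPixels()` a tidy table of tissue
#' (non-background) pixels with their compartment and axis value.
#'
#' @param layout a [TissueLayout-class].
#' @return See description.
#' @export
layoutLabels <- function(layout) {
  stopifnot(is(layout, "TissueLayout"))
  layout@labels
}

#' @rdname layoutLabels
#' @export
cryptAxis <- function(layout) {
  stopifnot(is(layout, "TissueLayout"))
  layout@crypt_axis
}

#' @rdname layoutLabels
#' @export
mucosaAxis <- function(layout) {
  stopifnot(is(layout, "TissueLayout"))
  layout@mucosa_axis
}

#' @rdname layoutLabels
#' @export
cryptPaths <- function(layout) {
  stopifnot(is(layout, "TissueLayout"))
  layout@paths
}

#' @rdname layoutLabels
#' @export
layoutPixels <- function(layout) {
  stopifnot(is(layout, "TissueLayout"))
  lab <- layout@labels
  idx <- which(lab != "background", arr.ind = TRUE)
  comp <- lab[idx]
  axis <- ifelse(comp == "epithelium",
                 layout@crypt_axis[idx], layout@mucosa_axis[idx])
  data.frame(pixel_id = seq_len(nrow(idx)),
             x = idx[, "col"], y = idx[, "row"],
             compartment = comp, axis = axis, stringsAsFactors = FALSE)
}
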