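#' @include spatial.R
NULL

#' Plot adduct tracks and the Na/K ratio band along a path
#'
#' One panel per species: the three adduct intensity tracks against arc
#' length, with the K pair fraction overlaid on a 0-1 band.
#'
#' @param profile a path profile from [extractPathProfile()].
#' @return a ggplot object.
#' @export
plotPathProfile <- function(profile) {
  long <- data.table::melt(as.data.table(profile),
                           id.vars = c("distance_um", "species"),
                           measure.vars = c("I_H", "I_Na", "I_K"),
                           variable.name = "adduct",
                           value.name = "intensity")
  long[, adduct := sub("^I_", "", adduct)]
  ggplot2::ggplot(long, ggplot2::aes(x = distance_um, y = intensity,
                                     colour = adduct)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(
      data = as.data.table(profile)[!is.na(f_K)],
      mapping = ggplot2::aes(x = distance_um,
                             y = f_K * max(long$intensity, na.rm = TRUE)),
      colour = "black", linetype = "dashed", inherit.aes = FALSE) +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "distance along path (µm)",
                  y = "corrected intensity (dashed: K pair fraction, scaled)",
                  colour = "adduct") +
    ggplot2::theme_minimal()
}

#' Stacked normalized adduct proportions per group
#'
#' The Fig.-4b-style display: for each species, the three mean adduct
#' intensities of a group rescaled to sum to 1, shown as stacked bars for
#' healthy and adenoma side by side.
#'
#' @param comparison an `adductComparison` from [compareGroups()].
#' @return a ggplot object.
#' @export
plotAdductProportions <- function(comparison) {
  pr <- comparison$proportions
  pr$adduct <- factor(pr$adduct, levels = c("H", "Na", "K"))
  ggplot2::ggplot(pr, ggplot2::aes(x = group, y = proportion, fill = adduct)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(x = NULL, y = "normalized adduct proportion") +
    ggplot2::theme_minimal()
}
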