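#' @include AllClasses.R
NULL

# Single authoritative monoisotopic atomic-mass table (Da), CODATA/AME values.
# Cation masses subtract one electron mass: at m/z < 1000 the difference
# (~0.55 mDa, ~0.7 ppm) matters at the 3 ppm accuracy regime.
.ATOMIC_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  Na = 22.9897692809,
  K  = 38.96370668
)
.ELECTRON_MASS <- 0.00054857990907

.DEFAULT_ADDUCTS <- data.frame(
  adduct = c("H", "Na", "K"),
  cation_mass = unname(.ATOMIC_MASS[c("H", "Na", "K")]) - .ELECTRON_MASS,
  stringsAsFactors = FALSE
)

#' Elemental formula of a lipid species
#'
#' Element counts for the supported lipid classes, parameterised by total
#' acyl-chain carbons `n` and double bonds `d`:
#' * `PC` (diacyl phosphatidylcholine): C(n+8) H(2n-2d+16) N O8 P
#' * `SM` (d-series sphingomyelin):     C(n+5) H(2n-2d+13) N2 O6 P
#'
#' @param lipid_class `"PC"` or `"SM"`.
#' @param carbons total acyl (PC) or sphingoid+acyl (SM) carbons, > 0.
#' @param double_bonds number of C=C double bonds, >= 0.
#' @return Named integer vector of element counts.
#' @examples
#' lipidFormula("PC", 34, 1)  # C42 H82 N O8 P
#' @export
lipidFormula <- function(lipid_class, carbons, double_bonds) {
  stopifnot(length(lipid_class) == 1, carbons > 0, double_bonds >= 0)
  h <- 2 * carbons - 2 * double_bonds
  switch(lipid_class,
    PC = c(C = carbons + 8L, H = h + 16L, N = 1L, O = 8L, P = 1L),
    SM = c(C = carbons + 5L, H = h + 13L, N = 2L, O = 6L, P = 1L),
    stop("unsupported lipid class: ", lipid_class))
}

#' Monoisotopic mass of an elemental composition
#'
#' @param counts named vector of element counts (names from the atomic-mass
#'   table: C, H, N, O, P, Na, K).
#' @return Mass in Da.
#' @export
formulaMass <- function(counts) {
  unknown <- setdiff(names(counts), names(.ATOMIC_MASS))
  if (length(unknown)) stop("unknown element(s): ", paste(unknown, collapse = ", "))
  sum(.ATOMIC_MASS[names(counts)] * counts)
}

.speciesName <- function(lipid_class, carbons, double_bonds) {
  ifelse(lipid_class == "SM",
         sprintf("SMd%d:%d", carbons, double_bonds),
         sprintf("%s %d:%d", lipid_class, carbons, double_bonds))
}

#' Construct a lipid panel
#'
#' Builds a [LipidPanel-class] from species compositions. Neutral
#' monoisotopic masses are computed from elemental formulas
#' (see [lipidFormula()]) unless overridden.
#'
#' @param lipid_class character vector, `"PC"` or `"SM"` per species.
#' @param carbons,double_bonds integer vectors, one entry per species.
#' @param neutral_mass optional numeric vector of override masses (Da); `NA`
#'   entries are computed from the formula.
#' @param adducts data.frame of registered adducts (`adduct`, `cation_mass`);
#'   defaults to H+, Na+, K+ cations.
#' @return A `LipidPanel`.
#' @examples
#' lipidPanel(c("PC", "PC"), c(34, 36), c(1, 4))
#' @export
lipidPanel <- function(lipid_class, carbons, double_bonds,
                       neutral_mass = NULL, adducts = .DEFAULT_ADDUCTS) {
  n <- length(lipid_class)
  stopifnot(length(carbons) == n, length(double_bonds) == n)
  mass <- vapply(seq_len(n), function(i)
    formulaMass(lipidFormula(lipid_class[i], carbons[i], double_bonds[i])),
    numeric(1))
  if (!is.null(neutral_mass)) {
    stopifnot(length(neutral_mass) == n)
    mass <- ifelse(is.na(neutral_mass), mass, neutral_mass)
  }
  sp <- data.frame(
    name = .speciesName(lipid_class, carbons, double_bonds),
    lipid_class = lipid_class, carbons = as.integer(carbons),
    double_bonds = as.integer(double_bonds), neutral_mass = mass,
    stringsAsFactors = FALSE)
  new("LipidPanel", species = sp, adducts = adducts)
}

#' The default colon mucosa panel
#'
#' The eight phosphatidylcholine species consistently detected in colon
#' mucosa sections (PC 32:0, 34:1, 34:2, 36:1, 36:2, 36:3, 36:4, 38:4) plus
#' the single sphingomyelin species SMd34:1.
#'
#' @return A [LipidPanel-class].
#' @export
colonPanel <- function() {
  lipidPanel(
    lipid_class  = c(rep("PC", 8), "SM"),
    carbons      = c(32, 34, 34, 36, 36, 36, 36, 38, 34),
    double_bonds = c(0, 1, 2, 1, 2, 3, 4, 4, 1))
}

#' Read a panel definition from a TSV file
#'
#' One row per species with columns `lipid_class`, `carbons`, `double_bonds`
#' and an optional `neutral_mass` override column.
#'
#' @param path TSV file path.
#' @return A [LipidPanel-class].
#' @export
readPanel <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  lipidPanel(df$lipid_class, df$carbons, df$double_bonds,
             neutral_mass = if ("neutral_mass" %in% names(df)) df$neutral_mass)
}

#' Species table of a panel
#' @param panel a [LipidPanel-class].
#' @return data.frame of species.
#' @export
speciesTable <- function(panel) {
  stopifnot(is(panel, "LipidPanel"))
  panel@species
}

#' Theoretical m/z of a species/adduct ion channel
#'
#' For singly charged cation adducts, `m/z = neutral_mass + cation_mass`.
#'
#' @param panel a [LipidPanel-class].
#' @param species species display name, e.g. `"PC 34:1"`.
#' @param adduct adduct label, one of the panel's registered adducts.
#' @return m/z in Da.
#' @examples
#' adductMz(colonPanel(), "PC 34:1", "Na")  # 782.56703
#' @export
adductMz <- function(panel, species, adduct) {
  stopifnot(is(panel, "LipidPanel"))
  i <- match(species, panel@species$name)
  if (anyNA(i)) stop("unknown species: ", paste(species[is.na(i)], collapse = ", "))
  j <- match(adduct, panel@adducts$adduct)
  if (anyNA(j)) stop("unknown adduct: ", paste(adduct[is.na(j)], collapse = ", "))
  panel@species$neutral_mass[i] + panel@adducts$cation_mass[j]
}

#' All ion channels of a panel
#'
#' @param panel a [LipidPanel-class].
#' @return data.frame with one row per (species, adduct): `species`,
#'   `lipid_class`, `adduct`, `theo_mz`, sorted by `theo_mz`.
#' @export
lipidChannels <- function(panel) {
  stopifnot(is(panel, "LipidPanel"))
  sp <- panel@species
  ad <- panel@adducts
  out <- do.call(rbind, lapply(seq_len(nrow(ad)), function(j)
    data.frame(species = sp$name, lipid_class = sp$lipid_class,
               adduct = ad$adduct[j],
               theo_mz = sp$neutral_mass + ad$cation_mass[j],
               stringsAsFactors = FALSE)))
  out[order(out$theo_mz), , drop = FALSE]
}

#' Relative mass error in parts per million
#'
#' `1e6 * |mz_obs - mz_theo| / mz_theo`; symmetric in the sign of the
#' deviation.
#'
#' @param mz_obs observed m/z (Da), vectorised.
#' @param mz_theo theoretical m/z (Da), must be positive.
#' @return ppm error(s).
#' @export
ppmError <- function(mz_obs, mz_theo) {
  if (any(mz_theo <= 0)) stop("mz_theo must be positive")
  1e6 * abs(mz_obs - mz_theo) / mz_theo
}

#' Tolerance-based candidate lookup
#'
#' Returns every registered ion channel within `tolerance` ppm of an
#' observed m/z, sorted by ascending mass error. Candidates worse than
#' `warn_above` ppm are flagged (`flagged = TRUE`): the expected accuracy is
#' typically better than 3 ppm while 9 ppm is the worst case accepted.
#'
#' @param panel a [LipidPanel-class].
#' @param mz_obs a single observed m/z (Da).
#' @param tolerance matching tolerance in ppm (> 0), default 9.
#' @param warn_above flag threshold in ppm, default 3.
#' @return data.frame with columns `species`, `lipid_class`, `adduct`,
#'   `theo_mz`, `ppm_error`, `flagged`; zero rows if nothing matches.
#' @examples
#' matchCandidates(colonPanel(), 782.568)  # the engineered isobaric pair
#' @export
matchCandidates <- function(panel, mz_obs, tolerance = 9, warn_above = 3) {
  stopifnot(is(panel, "LipidPanel"), length(mz_obs) == 1, tolerance > 0)
  if (nrow(panel@species) == 0) stop("registry is empty")
  ch <- lipidChannels(panel)
  ch$ppm_error <- ppmError(mz_obs, ch$theo_mz)
  ch <- ch[ch$ppm_error <= tolerance, , drop = FALSE]
  ch <- ch[order(ch$ppm_error), , drop = FALSE]
  ch$flagged <- ch$ppm_error > warn_above
  rownames(ch) <- NULL
  ch
}
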