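#' Fraction folded from cold semi-native SDS-PAGE band intensities
#'
#' On a cold semi-native gel a folded beta-barrel runs faster than its
#' unfolded form, so the folded fraction in the unboiled lane is
#' `folded / (folded + unfolded)`. An alternative convention divides the
#' folded band by the boiled-lane band instead; select it with
#' `denominator = "boiled"`.
#'
#' @param folded,unfolded Band intensities from the unboiled lane
#'   (arbitrary units, >= 0).
#' @param boiled Optional boiled-lane band intensity; required when
#'   `denominator = "boiled"`.
#' @param denominator `"unboiled"` (default) or `"boiled"`.
#' @return Fraction folded in `[0, 1]` (may exceed 1 under the boiled
#'   convention if the unboiled bands are more intense than the boiled one).
#' @examples
#' fraction_folded(folded = 8, unfolded = 2)  # 0.8
#' @export
fraction_folded <- function(folded, unfolded, boiled = NULL,
                            denominator = c("unboiled", "boiled")) {
  denominator <- match.arg(denominator)
  check_number(folded, "folded")
  check_number(unfolded, "unfolded")
  if (folded < 0 || unfolded < 0) {
    abort_input("band intensities must be non-negative")
  }
  if (denominator == "boiled") {
    if (is.null(boiled)) abort_input("`boiled` intensity required")
    check_number(boiled, "boiled", positive = TRUE)
    return(folded / boiled)
  }
  if (folded + unfolded <= 0) {
    abort_input("folded + unfolded intensities must be positive")
  }
  folded / (folded + unfolded)
}

#' Mean residue ellipticity from a CD spectrum
#'
#' Converts measured ellipticity (millidegrees) to mean residue ellipticity
#' (MRE, deg cm^2 dmol^-1) using the mean residue weight
#' \eqn{MRW = M / (N - 1)} (Daltons per residue, with \eqn{N - 1} peptide
#' bonds for \eqn{N} residues) and
#' \deqn{[\theta]_{MRE} = \frac{MRW \times \theta_\lambda}{10 \, d \, c}}
#' with path length \eqn{d} in cm and protein concentration \eqn{c} in g/mL.
#' Spectra are expected blank-subtracted.
#'
#' @param data A data frame with columns `wavelength_nm` and `theta_mdeg`,
#'   or a bare numeric vector of ellipticities.
#' @param molecular_mass Protein mass in Daltons.
#' @param n_residues Number of amino acids (>= 2).
#' @param path_length_cm Cuvette path length in cm.
#' @param concentration Protein concentration.
#' @param conc_units `"g_ml"` (default, per the formula) or `"mg_ml"`.
#' @return The input tibble with an added `mre` column (or a numeric vector
#'   if `data` was one).
#' @examples
#' mean_residue_ellipticity(
#'   tibble::tibble(wavelength_nm = c(215, 218), theta_mdeg = c(-3, -3.2)),
#'   molecular_mass = 19000, n_residues = 171,
#'   path_length_cm = 0.1, concentration = 3e-5)
#' @export
mean_residue_ellipticity <- function(data, molecular_mass, n_residues,
                                     path_length_cm, concentration,
                                     conc_units = c("g_ml", "mg_ml")) {
  conc_units <- match.arg(conc_units)
  check_number(molecular_mass, "molecular_mass", positive = TRUE)
  if (n_residues < 2) abort_input("`n_residues` must be at least 2")
  check_number(path_length_cm, "path_length_cm", positive = TRUE)
  check_number(concentration, "concentration", positive = TRUE)
  c_g_ml <- if (conc_units == "mg_ml") concentration / 1000 else concentration
  mrw <- molecular_mass / (n_residues - 1)

  if (is.data.frame(data)) {
    if (!"theta_mdeg" %in% names(data)) {
      abort_input("`data` must have a `theta_mdeg` column")
    }
    data <- as_tibble(data)
    data$mre <- mrw * data$theta_mdeg / (10 * path_length_cm * c_g_ml)
    return(data)
  }
  mrw * data / (10 * path_length_cm * c_g_ml)
}

#' Mean residue weight
#'
#' @param molecular_mass Protein mass in Daltons.
#' @param n_residues Number of amino acids (>= 2).
#' @return `molecular_mass / (n_residues - 1)` in Daltons.
#' @export
mean_residue_weight <- function(molecular_mass, n_residues) {
  check_number(molecular_mass, "molecular_mass", positive = TRUE)
  if (n_residues < 2) abort_input("`n_residues` must be at least 2")
  molecular_mass / (n_residues - 1)
}
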