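#' Formol-titration quantities for a degree-of-hydrolysis measurement
#'
#' Bundles the quantities of a formaldehyde titration of a protein
#' hydrolysate: the standard NaOH concentration, the NaOH volumes consumed
#' titrating a hydrolysate aliquot and a distilled-water blank from pH 8.2 to
#' 9.2, the total hydrolysate volume, the raw-material mass and its protein
#' fraction.
#'
#' @param naoh_conc NaOH concentration, mol/L; > 0.
#' @param v1 NaOH volume for the hydrolysate, mL; `v1 >= v2`.
#' @param v2 NaOH volume for the water blank, mL; >= 0.
#' @param volume total hydrolysate volume, mL; > 0. A 1/5 aliquot is titrated.
#' @param mass raw-material mass, g; > 0.
#' @param protein_fraction protein share of the raw material, in `(0, 1]`.
#' @return an object of class `"titration_spec"`.
#' @export
titration_spec <- function(naoh_conc, v1, v2, volume, mass, protein_fraction) {
  for (v in list(naoh_conc, v1, v2, volume, mass, protein_fraction)) {
    assert_that(is_number(v), "titration quantities must be finite numbers")
  }
  assert_that(naoh_conc > 0, "naoh_conc must be > 0")
  assert_that(v2 >= 0, "v2 must be >= 0")
  assert_that(v1 >= v2, "v1 (%.4g) must be >= v2 (%.4g)", v1, v2)
  assert_that(volume > 0, "volume must be > 0")
  assert_that(mass > 0, "mass must be > 0")
  assert_that(protein_fraction > 0 && protein_fraction <= 1,
              "protein_fraction must lie in (0, 1]")
  structure(list(naoh_conc = naoh_conc, v1 = v1, v2 = v2, volume = volume,
                 mass = mass, protein_fraction = protein_fraction),
            class = "titration_spec")
}

#' Degree of hydrolysis from a formol titration
#'
#' The fraction of cleaved peptide bonds, in percent:
#' `DH = 100 * C * (V1 - V2) * (V/5) / (m * p * 8)`, where `V/5` scales the
#' titrated aliquot back to the full hydrolysate volume and 8 meq/g is the
#' total peptide-bond content per gram of protein. This grouping is the only
#' one that leaves DH dimensionless on the percent scale.
#'
#' @param spec a [titration_spec()].
#' @return DH in percent (non-negative scalar).
#' @examples
#' compute_dh(titration_spec(0.05, 14, 0.5, 25, 5, 0.69))
#' @export
compute_dh <- function(spec) {
  stopifnot(inherits(spec, "titration_spec"))
  100 * spec$naoh_conc * (spec$v1 - spec$v2) * (spec$volume / 5) /
    (spec$mass * spec$protein_fraction * 8)
}

#' Titration volume difference needed for a target DH
#'
#' Algebraic inverse of [compute_dh()]: the NaOH volume difference
#' `V1 - V2` (mL) that reproduces `target_dh` under the given titration
#' conditions.
#'
#' @param target_dh target degree of hydrolysis, percent; >= 0.
#' @param naoh_conc,volume,mass,protein_fraction as in [titration_spec()].
#' @return volume difference in mL.
#' @export
invert_dh <- function(target_dh, naoh_conc, volume, mass, protein_fraction) {
  assert_that(is.numeric(target_dh) && all(is.finite(target_dh)) &&
                all(target_dh >= 0), "target_dh must be >= 0")
  for (v in list(naoh_conc, volume, mass, protein_fraction)) {
    assert_that(is_number(v) && v > 0,
                "naoh_conc, volume, mass, protein_fraction must be > 0")
  }
  target_dh / 100 * mass * protein_fraction * 8 / (naoh_conc * (volume / 5))
}

#' Saturating degree-of-hydrolysis kinetics
#'
#' `dh_saturating()` evaluates the first-order saturation curve
#' `DH(t) = dh_max * (1 - exp(-rate * t))`, the simplest form consistent with
#' a DH that rises quickly and then plateaus as accessible peptide bonds are
#' exhausted. `fit_dh_curve()` calibrates `dh_max` and `rate` to a measured
#' series by nonlinear least squares.
#'
#' @param t time, hours.
#' @param dh_max plateau DH, percent.
#' @param rate first-order rate constant, 1/h; > 0.
#' @return `dh_saturating()`: DH values; `fit_dh_curve()`: a list with
#'   `dh_max`, `rate`, and `predict(t)`.
#' @export
dh_saturating <- function(t, dh_max, rate) {
  assert_that(is_number(rate) && rate > 0, "rate must be > 0")
  assert_that(is_number(dh_max) && dh_max >= 0, "dh_max must be >= 0")
  dh_max * (1 - exp(-rate * t))
}

#' @rdname dh_saturating
#' @param time,dh measured series (equal length, `time` increasing).
#' @export
fit_dh_curve <- function(time, dh) {
  assert_that(length(time) == length(dh) && length(time) >= 3,
              "need at least 3 (time, dh) pairs")
  # Levenberg-Marquardt: robust where Gauss-Newton stalls on the
  # zero-residual fits used to validate the generator
  fit <- minpack.lm::nlsLM(dh ~ dmax * (1 - exp(-k * time)),
                           start = list(dmax = max(dh), k = 0.3))
  cf <- stats::coef(fit)
  dmax <- unname(cf["dmax"])
  k <- unname(cf["k"])
  list(dh_max = dmax, rate = k,
       predict = function(t) dmax * (1 - exp(-k * t)))
}
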