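# UV-Vis utilities for gold quantification. Small gold particles (~5 nm) have
# a surface plasmon resonance absorbance maximum near 518 nm; subtracting the
# undoped-carrier spectrum isolates the gold contribution, a calibration line
# converts absorbance to concentration, and the loading efficiency follows
# from a mass balance, either indirectly (supplied minus free gold in the
# supernatant) or directly (measured encapsulated gold).

#' UV-Vis spectrum
#'
#' @param wavelengths Wavelengths in nm, strictly increasing, within
#'   \[200, 800\].
#' @param absorbance Dimensionless optical density, same length; no NaN.
#' @return A `spectrum` object (data-frame backed).
#' @export
spectrum <- function(wavelengths, absorbance) {
  w <- as.numeric(wavelengths); a <- as.numeric(absorbance)
  if (length(w) != length(a)) stop("lengths differ", call. = FALSE)
  if (length(w) < 2) stop("need at least 2 points", call. = FALSE)
  if (any(!is.finite(w)) || any(!is.finite(a)))
    stop("spectrum values must be finite", call. = FALSE)
  if (any(diff(w) <= 0)) stop("wavelengths must be strictly increasing",
                              call. = FALSE)
  if (min(w) < 200 || max(w) > 800)
    stop("wavelengths must lie within [200, 800] nm", call. = FALSE)
  structure(data.frame(wavelength_nm = w, absorbance = a),
            class = c("spectrum", "data.frame"))
}

#' Read/write spectra as two-column CSV
#' @param path CSV with columns `wavelength_nm`, `absorbance`.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path) {
  df <- read_table(path)
  if (!all(c("wavelength_nm", "absorbance") %in% names(df)))
    stop("spectrum CSV needs wavelength_nm and absorbance columns",
         call. = FALSE)
  spectrum(df$wavelength_nm, df$absorbance)
}

#' @rdname read_spectrum
#' @param spec A [spectrum()] to write.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  write_table(as.data.frame(spec), path)
}

#' Subtract a background spectrum
#'
#' Pointwise difference on an identical wavelength grid (no interpolation);
#' negative differences are preserved, not clipped. Used to remove the
#' undoped-carrier contribution from a doped-particle spectrum.
#'
#' @param doped,undoped [spectrum()] objects on the same grid.
#' @return A [spectrum()] of differences.
#' @export
subtract_background <- function(doped, undoped) {
  stopifnot(inherits(doped, "spectrum"), inherits(undoped, "spectrum"))
  if (!isTRUE(all.equal(doped$wavelength_nm, undoped$wavelength_nm,
                        tolerance = 0)))
    stop("wavelength grids differ: no interpolation is performed",
         call. = FALSE)
  spectrum(doped$wavelength_nm, doped$absorbance - undoped$absorbance)
}

#' Peak absorbance near a target wavelength
#'
#' Maximum absorbance within ±`window/2` of the target. The default 10 nm
#' window tolerates the modest redshift that accompanies gold aggregation
#' without chasing the broadened aggregate band.
#'
#' @param spec A [spectrum()].
#' @param wavelength Target in nm (default 518, the SPR peak of ~5 nm gold).
#' @param window Full window width in nm (default 10).
#' @return Peak OD (scalar).
#' @export
peak_absorbance <- function(spec, wavelength = 518, window = 10) {
  stopifnot(inherits(spec, "spectrum"), window > 0)
  if (wavelength < min(spec$wavelength_nm) ||
      wavelength > max(spec$wavelength_nm))
    stop("target wavelength outside spectrum range", call. = FALSE)
  sel <- abs(spec$wavelength_nm - wavelength) <= window / 2
  if (!any(sel)) stop("window contains no grid points", call. = FALSE)
  max(spec$absorbance[sel])
}

#' Fit an absorbance-concentration calibration line
#'
#' Ordinary least squares with a free intercept (forced through the origin
#' with `through_origin = TRUE`).
#'
#' @param concentrations Gold concentrations in µg/mL (>= 3 points, >= 2
#'   distinct).
#' @param absorbances Matching OD values at the calibration wavelength.
#' @param wavelength Calibration wavelength (default 518 nm, recorded only).
#' @param through_origin Force zero intercept? Default `FALSE`.
#' @return A `calibration_curve`: `slope` (OD per µg/mL), `intercept`,
#'   `r_squared`, `wavelength`, `max_concentration`.
#' @export
fit_calibration <- function(concentrations, absorbances, wavelength = 518,
                            through_origin = FALSE) {
  c0 <- as.numeric(concentrations); a0 <- as.numeric(absorbances)
  stopifnot(length(c0) == length(a0))
  if (length(c0) < 3) stop("need at least 3 calibration points", call. = FALSE)
  if (length(unique(c0)) < 2)
    stop("need at least 2 distinct concentrations", call. = FALSE)
  fit <- if (through_origin) lm(a0 ~ c0 + 0) else lm(a0 ~ c0)
  cf <- coef(fit)
  slope <- unname(if (through_origin) cf["c0"] else cf["c0"])
  intercept <- if (through_origin) 0 else unname(cf["(Intercept)"])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((a0 - mean(a0))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 1
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 wavelength = wavelength, max_concentration = max(c0)),
            class = "calibration_curve")
}

#' Invert a calibration line
#'
#' Converts an OD back to a concentration; refuses extrapolation beyond 110%
#' of the largest calibrated concentration.
#'
#' @param curve A [fit_calibration()] result.
#' @param od Observed OD(s).
#' @return Concentration(s) in µg/mL.
#' @export
quantify <- function(curve, od) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("flat calibration: cannot invert", call. = FALSE)
  conc <- (od - curve$intercept) / curve$slope
  if (any(conc > 1.1 * curve$max_concentration))
    stop("OD implies concentration beyond 110% of the calibrated range",
         call. = FALSE)
  conc
}

le_result <- function(total, other, le, kind) {
  structure(list(total_au = total,
                 free_au = if (kind == "indirect") other else NA_real_,
                 encapsulated_au = if (kind == "direct") other else total - other,
                 le_percent = le, method = kind),
            class = "loading_result")
}

#' @export
print.loading_result <- function(x, ...) {
  cat(sprintf("Gold loading efficiency (%s): %.1f%% (total %.4g ug)\n",
              x$method, x$le_percent, x$total_au))
  invisible(x)
}

#' Indirect loading efficiency
#'
#' `LE = 100 * (total - free) / total`: the fraction of supplied gold not
#' recovered free in the supernatant. `free > total` is a mass-balance
#' violation and errors rather than returning a negative efficiency.
#'
#' @param total_au Gold supplied during synthesis, µg (> 0).
#' @param free_au Unencapsulated gold measured in the supernatant, µg (>= 0).
#' @return A `loading_result` with `le_percent` in `[0, 100]`.
#' @export
loading_efficiency_indirect <- function(total_au, free_au) {
  if (total_au <= 0) stop("total gold must be > 0", call. = FALSE)
  if (free_au < 0) stop("free gold must be >= 0", call. = FALSE)
  if (free_au > total_au)
    stop("mass-balance violation: free gold exceeds total", call. = FALSE)
  le_result(total_au, free_au, 100 * (total_au - free_au) / total_au,
            "indirect")
}

#' Direct loading efficiency
#'
#' `LE = 100 * encapsulated / total`: the fraction of supplied gold measured
#' inside the collected particles.
#'
#' @param encapsulated_au Encapsulated gold, µg (0 <= encapsulated <= total).
#' @param total_au Gold supplied during synthesis, µg (> 0).
#' @return A `loading_result` with `le_percent` in `[0, 100]`.
#' @export
loading_efficiency_direct <- function(encapsulated_au, total_au) {
  if (total_au <= 0) stop("total gold must be > 0", call. = FALSE)
  if (encapsulated_au < 0) stop("encapsulated gold must be >= 0", call. = FALSE)
  if (encapsulated_au > total_au)
    stop("mass-balance violation: encapsulated gold exceeds total",
         call. = FALSE)
  le_result(total_au, encapsulated_au, 100 * encapsulated_au / total_au,
            "direct")
}
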