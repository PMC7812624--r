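# Hemoglobin extinction coefficients at the two measurement wavelengths,
# in cm^-1 per micromolar. Values from the Prahl (1998) compilation of the
# Gratzer & Kollias molar extinction spectra (cm^-1/M, scaled by 1e-6).
# Rows: wavelengths (760, 850 nm); columns: HbO, HbR.

#' Default hemoglobin extinction table
#'
#' @return 2x2 matrix (wavelength x chromophore) of extinction coefficients
#'   in cm^-1 per uM, with a `citation` attribute.
#' @export
default_extinction <- function() {
  e <- matrix(c(
    586.00  * 1e-6, 1548.52 * 1e-6,   # 760 nm: HbO, HbR
    1058.00 * 1e-6,  691.32 * 1e-6    # 850 nm: HbO, HbR
  ), nrow = 2, byrow = TRUE,
  dimnames = list(c("760", "850"), c("HbO", "HbR")))
  attr(e, "citation") <-
    "Prahl (1998) compilation of Gratzer & Kollias hemoglobin spectra"
  e
}

# Differential pathlength factors by subject role (adult mother vs child),
# applied identically at both wavelengths.
DEFAULT_DPF <- c(mother = 6.0, child = 5.5)
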