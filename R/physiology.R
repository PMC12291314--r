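# Pigment quantification, water-use efficiency and percent-change
# derivation.
#
# Pigments follow the Lichtenthaler spectrophotometric system for 95%
# ethanol extracts read at 665, 649 and 470 nm. The equations are stated
# on extract concentrations (ug/mL); contents in mg per g fresh weight are
# obtained afterwards by the volume/weight factor V/(1000 W). The
# carotenoid equation's embedded chlorophyll terms are therefore the
# *concentrations*, not the final contents - the system is dimensionally
# consistent only that way.

#' Bundle pigment absorbance readings
#'
#' @param A665,A649,A470 absorbances of the ethanol extract at 665, 649 and
#'   470 nm (unitless, >= 0).
#' @param extract_volume extract volume V in mL (> 0).
#' @param fresh_weight fresh leaf weight W in g (> 0).
#' @return list of class `pigment_absorbances`.
#' @export
pigment_absorbances <- function(A665, A649, A470,
                                extract_volume = 10, fresh_weight = 0.1) {
  vals <- c(A665 = A665, A649 = A649, A470 = A470,
            V = extract_volume, W = fresh_weight)
  if (any(!is.finite(vals))) stop("pigment absorbances must be finite")
  if (any(c(A665, A649, A470) < 0)) stop("absorbances must be >= 0")
  if (extract_volume <= 0 || fresh_weight <= 0)
    stop("extract volume and fresh weight must be > 0")
  structure(list(A665 = A665, A649 = A649, A470 = A470,
                 extract_volume = extract_volume, fresh_weight = fresh_weight),
            class = "pigment_absorbances")
}

#' Chlorophyll and carotenoid contents from absorbances
#'
#' Lichtenthaler equations for 95% ethanol, on extract concentrations
#' (ug/mL):
#' \deqn{C_a = 13.95 A_{665} - 6.88 A_{649}}
#' \deqn{C_b = 24.96 A_{649} - 7.32 A_{665}}
#' \deqn{C_{car} = (1000 A_{470} - 2.05 C_a - 114.8 C_b)/245}
#' Each content in mg per g fresh weight is the concentration times
#' `V/(1000 W)`. Total chlorophyll and the a/b ratio are derived. A
#' negative computed concentration (possible for off-scale or swapped
#' readings) is returned as-is with a warning, never clipped.
#'
#' @param a a [pigment_absorbances()] object.
#' @return list of class `pigment_contents` with fields `chl_a`, `chl_b`,
#'   `chl_ab`, `chl_ab_ratio`, `car` (mg per g fresh weight; ratio
#'   dimensionless).
#' @export
pigments_from_absorbance <- function(a) {
  stopifnot(inherits(a, "pigment_absorbances"))
  Ca <- 13.95 * a$A665 - 6.88 * a$A649
  Cb <- 24.96 * a$A649 - 7.32 * a$A665
  Ccar <- (1000 * a$A470 - 2.05 * Ca - 114.8 * Cb) / 245
  if (any(c(Ca, Cb, Ccar) < 0))
    warning("negative computed pigment concentration; check the absorbances")
  k <- a$extract_volume / (1000 * a$fresh_weight)
  chl_a <- Ca * k
  chl_b <- Cb * k
  structure(list(chl_a = chl_a, chl_b = chl_b, chl_ab = chl_a + chl_b,
                 chl_ab_ratio = if (chl_b != 0) chl_a / chl_b else NA_real_,
                 car = Ccar * k),
            class = "pigment_contents")
}

#' @export
print.pigment_contents <- function(x, ...) {
  cat(sprintf(
    "<pigment_contents> Chl a %.4g, Chl b %.4g, Chl a+b %.4g (a/b %.3g), Car %.4g mg/g FW\n",
    x$chl_a, x$chl_b, x$chl_ab, x$chl_ab_ratio, x$car))
  invisible(x)
}

#' Water-use efficiency
#'
#' `WUE = Pn / Tr`: net photosynthetic rate (umol CO2 m-2 s-1) per unit
#' transpiration (mmol H2O m-2 s-1). Vectorized.
#'
#' @param Pn net photosynthetic rate.
#' @param Tr transpiration rate (> 0).
#' @return WUE (umol CO2 per mmol H2O).
#' @export
water_use_efficiency <- function(Pn, Tr) {
  if (any(!is.finite(Tr)) || any(Tr <= 0))
    stop("domain error: transpiration rate Tr must be > 0")
  Pn / Tr
}

#' Percent change versus a reference
#'
#' `100 (value - reference) / reference`; negative output means a decline.
#' Vectorized; applying the returned percentage forward to the reference
#' reproduces the value exactly.
#'
#' @param value observed value(s).
#' @param reference reference value(s), nonzero (e.g. the control mean, or
#'   an earlier time point's mean when the decline is reported against a
#'   within-course peak).
#' @return percent change (same shape as the inputs).
#' @export
percent_change <- function(value, reference) {
  if (any(reference == 0)) stop("domain error: reference must be nonzero")
  100 * (value - reference) / reference
}
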