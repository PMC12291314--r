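# OJIP landmark extraction and the algebraic JIP-test parameter set.
#
# Landmarks are read off the trace by linear interpolation in log10(time):
# PEA-class instruments sample on a log grid and the transient is close to
# linear in log time between steps. F0 is taken at t0 = 20 us by default
# (standard convention for this instrument class); the nominal step times
# are L = 150 us, K = 300 us, J = 2 ms, I = 30 ms. Fm is the global trace
# maximum (the P step).

#' Names of the JIP-test parameters, in canonical output order
#' @export
jip_parameter_names <- c(
  "VL", "VK", "VJ", "VI", "M0",
  "phiPo", "psiEo", "phiEo", "deltaRo", "phiRo",
  "ABS_RC", "TR0_RC", "ET0_RC", "DI0_RC", "RE0_RC",
  "ABS_CSm", "TR0_CSm", "ET0_CSm", "DI0_CSm", "RC_CSm",
  "PIabs", "PItotal")

# nominal landmark times (us)
.ojip_step_times <- c(L = 150, K = 300, J = 2000, I = 30000)

stop_extraction <- function(msg) {
  stop(structure(class = c("ojip_extraction_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Extract OJIP landmarks from a transient
#'
#' Reads F0 (at `t0`), FL (150 us), FK (300 us), FJ (2 ms) and FI (30 ms)
#' off the trace by linear interpolation in log10(time), and takes Fm as
#' the global maximum of the trace (the P step), recording its time.
#'
#' @param transient a [fluorescence_transient()].
#' @param t0 origin time in microseconds at which F0 is read; must lie in
#'   `[times[1], 50]`.
#' @return An object of class `ojip_landmarks`: a list with fields
#'   `F0, FL, FK, FJ, FI, Fm, t_Fm, t0`.
#' @export
extract_landmarks <- function(transient, t0 = 20) {
  validate_transient(transient)
  tm <- transient$times
  if (t0 < tm[1L] || t0 > 50)
    stop_extraction(sprintf("t0 = %g us outside [first sample = %g, 50] us",
                            t0, tm[1L]))
  nominal <- c(t0, .ojip_step_times)
  if (any(nominal > tm[length(tm)]))
    stop_extraction("nominal landmark time outside trace support")
  f <- stats::approx(log10(tm), transient$fluorescence,
                     xout = log10(nominal), ties = "ordered")$y
  i_max <- which.max(transient$fluorescence)
  Fm <- transient$fluorescence[i_max]
  if (i_max == 1L || Fm <= f[1L])
    stop_extraction(sprintf(
      "degenerate transient [%s/%s rep %d]: maximum at the first sample (no O-P rise)",
      transient$variety, transient$treatment, transient$replicate))
  structure(list(F0 = f[1L], FL = f[2L], FK = f[3L], FJ = f[4L], FI = f[5L],
                 Fm = Fm, t_Fm = tm[i_max], t0 = t0),
            class = "ojip_landmarks")
}

#' @export
print.ojip_landmarks <- function(x, ...) {
  cat(sprintf(
    "<ojip_landmarks> F0=%.4g FL=%.4g FK=%.4g FJ=%.4g FI=%.4g Fm=%.4g (t_Fm=%.3g us)\n",
    x$F0, x$FL, x$FK, x$FJ, x$FI, x$Fm, x$t_Fm))
  invisible(x)
}

#' Relative variable fluorescence
#'
#' `Vt = (Ft - F0) / (Fm - F0)`, the fraction of the variable fluorescence
#' reached at Ft. `VJ`, `VI`, `VK`, `VL` are Vt evaluated at the J, I, K
#' and L landmarks.
#'
#' @param landmarks an `ojip_landmarks` object (only `F0` and `Fm` used).
#' @param Ft fluorescence value(s) at which to evaluate Vt.
#' @return Vt, dimensionless (vectorized over `Ft`).
#' @export
relative_variable_fluorescence <- function(landmarks, Ft) {
  if (landmarks$Fm == landmarks$F0)
    stop("Fm equals F0: relative variable fluorescence undefined")
  (Ft - landmarks$F0) / (landmarks$Fm - landmarks$F0)
}

stop_singular <- function(what) {
  stop(structure(class = c("ojip_singular_error", "error", "condition"),
                 list(message = sprintf(
                   "singular JIP parameter: %s makes the parameter set undefined",
                   what), call = NULL)))
}

#' Compute the full JIP-test parameter set
#'
#' The standard Strasser-type algebraic translation of the OJIP landmarks
#' into quantum yields, specific energy fluxes per active PSII reaction
#' centre (RC), phenomenological fluxes per excited cross-section at t_Fm
#' (CSm, approximated by Fm), and the performance indices:
#' \deqn{M0 = 4 (F_K - F_0)/(F_m - F_0), \quad \varphi_{Po} = 1 - F_0/F_m,}
#' \deqn{\psi_{Eo} = 1 - V_J, \quad \varphi_{Eo} = \varphi_{Po}\psi_{Eo},
#'   \quad \delta_{Ro} = (1 - V_I)/(1 - V_J), \quad
#'   \varphi_{Ro} = \varphi_{Po}(1 - V_I),}
#' \deqn{TR_0/RC = M_0/V_J, \quad ABS/RC = (TR_0/RC)/\varphi_{Po}, \quad
#'   ET_0/RC = (TR_0/RC)(1 - V_J),}
#' \deqn{PI_{abs} = \frac{\varphi_{Po} V_J}{M_0}\cdot
#'   \frac{\varphi_{Po}}{1-\varphi_{Po}}\cdot\frac{\psi_{Eo}}{1-\psi_{Eo}},
#'   \quad PI_{total} = PI_{abs}\frac{\delta_{Ro}}{1-\delta_{Ro}}.}
#' All dimensionless outputs are invariant under rescaling of the
#' fluorescence axis; the `_CSm` fluxes scale linearly with it.
#'
#' @param landmarks an `ojip_landmarks` with `0 < F0 < Fm`.
#' @return An object of class `jip_parameters`: a named numeric vector with
#'   the fields listed in [jip_parameter_names].
#' @export
compute_jip_parameters <- function(landmarks) {
  with(landmarks, {
    if (!(F0 > 0) || !(Fm > F0))
      stop_singular("F0/Fm ordering (need 0 < F0 < Fm)")
    dF <- Fm - F0
    VL <- (FL - F0) / dF
    VK <- (FK - F0) / dF
    VJ <- (FJ - F0) / dF
    VI <- (FI - F0) / dF
    M0 <- 4 * (FK - F0) / dF
    phiPo <- 1 - F0 / Fm
    if (VJ <= 0 || VJ >= 1) stop_singular(sprintf("VJ = %g", VJ))
    if (VI >= 1) stop_singular(sprintf("VI = %g", VI))
    if (phiPo <= 0 || phiPo >= 1) stop_singular(sprintf("phiPo = %g", phiPo))
    if (M0 <= 0) stop_singular(sprintf("M0 = %g (flat or inverted O-K rise)", M0))
    psiEo <- 1 - VJ
    phiEo <- phiPo * psiEo
    deltaRo <- (1 - VI) / (1 - VJ)
    phiRo <- phiPo * (1 - VI)
    TR0_RC <- M0 / VJ
    ABS_RC <- TR0_RC / phiPo
    ET0_RC <- TR0_RC * (1 - VJ)
    DI0_RC <- ABS_RC - TR0_RC
    RE0_RC <- TR0_RC * (1 - VI)
    ABS_CSm <- Fm
    TR0_CSm <- phiPo * ABS_CSm
    ET0_CSm <- phiEo * ABS_CSm
    DI0_CSm <- ABS_CSm - TR0_CSm
    RC_CSm <- phiPo * (VJ / M0) * ABS_CSm
    PIabs <- (phiPo * VJ / M0) * (phiPo / (1 - phiPo)) * (psiEo / (1 - psiEo))
    if (deltaRo >= 1) stop_singular(sprintf("deltaRo = %g", deltaRo))
    PItotal <- PIabs * deltaRo / (1 - deltaRo)
    out <- c(VL = VL, VK = VK, VJ = VJ, VI = VI, M0 = M0,
             phiPo = phiPo, psiEo = psiEo, phiEo = phiEo,
             deltaRo = deltaRo, phiRo = phiRo,
             ABS_RC = ABS_RC, TR0_RC = TR0_RC, ET0_RC = ET0_RC,
             DI0_RC = DI0_RC, RE0_RC = RE0_RC,
             ABS_CSm = ABS_CSm, TR0_CSm = TR0_CSm, ET0_CSm = ET0_CSm,
             DI0_CSm = DI0_CSm, RC_CSm = RC_CSm,
             PIabs = PIabs, PItotal = PItotal)
    class(out) <- "jip_parameters"
    out
  })
}

#' @export
print.jip_parameters <- function(x, ...) {
  cat("<jip_parameters>\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' JIP parameters for a set of transients, as a tidy trait table
#'
#' Runs [extract_landmarks()] and [compute_jip_parameters()] on each
#' transient and stacks the results into a [group_table()] with one row per
#' (replicate, parameter).
#'
#' @param transients list of `fluor_transient` objects.
#' @param t0 origin time for F0 (microseconds).
#' @return A [group_table()] whose `trait` column runs over
#'   [jip_parameter_names].
#' @export
jip_parameter_table <- function(transients, t0 = 20) {
  rows <- lapply(transients, function(x) {
    p <- compute_jip_parameters(extract_landmarks(x, t0 = t0))
    data.frame(variety = x$variety, treatment = x$treatment,
               replicate = x$replicate, trait = jip_parameter_names,
               value = as.numeric(unclass(p)[jip_parameter_names]),
               stringsAsFactors = FALSE)
  })
  group_table(do.call(rbind, rows))
}

#' OJIP landmarks for a set of transients, as a data frame
#'
#' @param transients list of `fluor_transient` objects.
#' @param t0 origin time for F0 (microseconds).
#' @return data.frame with columns variety, treatment, replicate,
#'   F0, FL, FK, FJ, FI, Fm, t_Fm.
#' @export
landmark_table <- function(transients, t0 = 20) {
  do.call(rbind, lapply(transients, function(x) {
    lm <- extract_landmarks(x, t0 = t0)
    data.frame(variety = x$variety, treatment = x$treatment,
               replicate = x$replicate,
               F0 = lm$F0, FL = lm$FL, FK = lm$FK, FJ = lm$FJ, FI = lm$FI,
               Fm = lm$Fm, t_Fm = lm$t_Fm, stringsAsFactors = FALSE)
  }))
}
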