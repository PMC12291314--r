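# Bundled "drought time-course" scenario and the published reference
# pigment table it emulates.

#' Published mean pigment contents for the two-cultivar drought time course
#'
#' Mean photosynthetic pigment contents (mg per g fresh weight, n = 3) for
#' a drought-tolerant (NH5) and a drought-sensitive (FH18) peanut cultivar
#' at 0, 4, 8 and 24 h of drought, as printed in the source experiment's
#' pigment table. Used as the reference input for the worked percent-change
#' and variability examples; the values are data, not computed output.
#'
#' @return data.frame with columns `variety`, `treatment`, `chl_a`,
#'   `chl_b`, `chl_ab`, `chl_ab_ratio`, `car`.
#' @export
peanut_pigment_means <- function() {
  data.frame(
    variety = rep(c("NH5", "FH18"), each = 4L),
    treatment = rep(c("0h", "4h", "8h", "24h"), 2L),
    chl_a = c(0.93, 1.16, 1.24, 1.41, 0.90, 1.17, 1.25, 1.07),
    chl_b = c(0.40, 0.57, 0.59, 1.08, 0.37, 0.56, 0.98, 0.47),
    chl_ab = c(1.32, 1.73, 1.83, 2.49, 1.27, 1.73, 2.23, 1.54),
    chl_ab_ratio = c(2.34, 2.06, 2.10, 1.32, 2.45, 2.11, 1.38, 2.35),
    car = c(0.28, 0.35, 0.36, 0.42, 0.29, 0.36, 0.38, 0.33),
    stringsAsFactors = FALSE)
}

#' The bundled drought scenario
#'
#' A ready-made [simulate_experiment()] configuration emulating a
#' 2-cultivar x 4-time-point x n-replicate drought experiment with the
#' canonical stress signatures:
#' \itemize{
#'   \item both cultivars: VJ and VI rise with stress, Fv/Fm declines
#'     slightly, performance indices fall;
#'   \item tolerant cultivar (NH5): pigments increase through 24 h,
#'     PIabs about -29% at 24 h, mild K-band;
#'   \item sensitive cultivar (FH18): pigments peak at 8 h then collapse,
#'     PIabs about -39% at 24 h, VK about +25% at 24 h (oxygen-evolving-
#'     complex damage), steeper Pn/WUE loss and higher electrolyte leakage.
#' }
#' The 24-h anchor shifts are calibrated in closed form so that the
#' noiseless JIP chain reproduces those PIabs/PItotal drops; pigment
#' multipliers reproduce the reference pigment-table means
#' ([peanut_pigment_means()]). Earlier time points carry intermediate,
#' direction-consistent effects.
#'
#' @param noise_cv instrument noise for the transients.
#' @param n_points samples per transient.
#' @return list with components `base` (a [transient_spec()]), `effects`
#'   (per-variety effect lists), `trait_base` (per-variety baselines),
#'   `varieties`, `treatments` - ready to splice into
#'   [simulate_experiment()].
#' @export
drought_scenario <- function(noise_cv = 0.02, n_points = 118) {
  base <- transient_spec(noise_cv = noise_cv, n_points = n_points)
  # pigment multipliers chosen to hit the reference table means exactly
  pig <- function(v, tr) {
    tab <- peanut_pigment_means()
    ctl <- tab[tab$variety == v & tab$treatment == "0h", ]
    now <- tab[tab$variety == v & tab$treatment == tr, ]
    c(chl_a = now$chl_a / ctl$chl_a, chl_b = now$chl_b / ctl$chl_b,
      car = now$car / ctl$car)
  }
  nh5 <- list(
    "4h" = treatment_effect(dVK = 0.005, dVJ = 0.02, dVI = 0.010,
                            fPhiPo = 0.995,
                            traits = c(pig("NH5", "4h"),
                                       Pn = 0.75, Tr = 0.85, EL = 1.30,
                                       SOD = 1.20, POD = 1.15, CAT = 1.10)),
    "8h" = treatment_effect(dVK = 0.050, dVJ = 0.030, dVI = 0.020,
                            fPhiPo = 0.990,
                            traits = c(pig("NH5", "8h"),
                                       Pn = 0.55, Tr = 0.70, EL = 1.80,
                                       SOD = 1.50, POD = 1.40, CAT = 1.30)),
    "24h" = treatment_effect(dVK = 0.010, dVJ = 0.0765, dVI = 0.0504,
                             fPhiPo = 0.978,
                             traits = c(pig("NH5", "24h"),
                                        Pn = 0.22, Tr = 0.55, EL = 2.398,
                                        SOD = 1.80, POD = 1.60, CAT = 1.50)))
  fh18 <- list(
    "4h" = treatment_effect(dVK = 0.015, dVJ = 0.035, dVI = 0.012,
                            fPhiPo = 0.992,
                            traits = c(pig("FH18", "4h"),
                                       Pn = 0.70, Tr = 0.85, EL = 1.50,
                                       SOD = 1.30, POD = 1.25, CAT = 1.15)),
    "8h" = treatment_effect(dVK = 0.080, dVJ = 0.040, dVI = 0.025,
                            fPhiPo = 0.988,
                            traits = c(pig("FH18", "8h"),
                                       Pn = 0.45, Tr = 0.70, EL = 2.20,
                                       SOD = 1.60, POD = 1.50, CAT = 1.35)),
    "24h" = treatment_effect(dVK = 0.050, dVJ = 0.0895, dVI = 0.0380,
                             fPhiPo = 0.9872,
                             traits = c(pig("FH18", "24h"),
                                        Pn = 0.103, Tr = 0.55, EL = 3.437,
                                        SOD = 1.40, POD = 1.30, CAT = 1.10)))
  trait_base <- list(
    NH5 = c(chl_a = 0.93, chl_b = 0.40, car = 0.28,
            Pn = 20, Tr = 4, EL = 8, SOD = 200, POD = 150, CAT = 100),
    FH18 = c(chl_a = 0.90, chl_b = 0.37, car = 0.29,
             Pn = 20, Tr = 4, EL = 8, SOD = 190, POD = 145, CAT = 95))
  list(base = base, effects = list(NH5 = nh5, FH18 = fh18),
       trait_base = trait_base,
       varieties = c("NH5", "FH18"),
       treatments = c("0h", "4h", "8h", "24h"))
}
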