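# Seeded simulation of OJIP transients and physiology tables.
#
# A transient is specified by its endpoint fluorescences (F0, Fm) and the
# relative variable fluorescence it should reach at the four landmark
# times (anchor mode). V(t) is built by monotone shape-preserving (Fritsch-
# Carlson) interpolation in log10(time) through (t0, 0), the anchors, and
# (t_P, 1); the anchor times are inserted into the sampling grid so that a
# noiseless simulate -> extract round trip recovers every anchor exactly.
# Noise is multiplicative Gaussian on fluorescence (instrument-like);
# physiology-trait noise is additive Gaussian on the trait scale.

#' Specify a synthetic OJIP transient
#'
#' @param F0,Fm origin and peak fluorescence (arbitrary units, `F0 < Fm`).
#'   The defaults give `Fv/Fm = 0.8`, a healthy dark-adapted leaf.
#' @param VL,VK,VJ,VI anchor values of the relative variable fluorescence
#'   at 150 us, 300 us, 2 ms and 30 ms; must satisfy
#'   `0 < VL < VK < VJ < VI < 1`. Defaults (0.12, 0.2, 0.5, 0.85) are
#'   typical unstressed values.
#' @param t0 origin time (us) at which V = 0.
#' @param t_P time of the P maximum (us) at which V = 1.
#' @param noise_cv coefficient of variation of the multiplicative Gaussian
#'   instrument noise (0 disables noise).
#' @param n_points number of log-spaced sampling times (the four anchor
#'   times are added to the grid, so the trace may hold a few more).
#' @param seed optional integer seed used when the spec is simulated alone.
#' @return list of class `transient_spec`.
#' @export
transient_spec <- function(F0 = 500, Fm = 2500,
                           VL = 0.12, VK = 0.2, VJ = 0.5, VI = 0.85,
                           t0 = 20, t_P = 3e5,
                           noise_cv = 0.02, n_points = 118, seed = NULL) {
  spec <- structure(list(F0 = F0, Fm = Fm, VL = VL, VK = VK, VJ = VJ, VI = VI,
                         t0 = t0, t_P = t_P, noise_cv = noise_cv,
                         n_points = as.integer(n_points), seed = seed),
                    class = "transient_spec")
  validate_transient_spec(spec)
  spec
}

validate_transient_spec <- function(spec, cell = NULL) {
  where <- if (is.null(cell)) "" else sprintf(" in cell %s", cell)
  v <- c(0, spec$VL, spec$VK, spec$VJ, spec$VI, 1)
  if (any(diff(v) <= 0))
    stop(sprintf("spec error%s: anchors must satisfy 0 < VL < VK < VJ < VI < 1 (got %s)",
                 where, paste(signif(v[2:5], 4), collapse = ", ")))
  if (!(spec$F0 > 0 && spec$Fm > spec$F0))
    stop(sprintf("spec error%s: need 0 < F0 < Fm", where))
  if (spec$noise_cv < 0) stop(sprintf("spec error%s: noise_cv < 0", where))
  if (spec$t0 <= 0 || spec$t_P <= 30000)
    stop(sprintf("spec error%s: need t0 > 0 and t_P > 30 ms", where))
  if (spec$n_points < 30L) stop(sprintf("spec error%s: n_points < 30", where))
  invisible(spec)
}

#' Simulate one OJIP transient
#'
#' Builds `V(t)` by monotone Fritsch-Carlson interpolation in log10(t)
#' through `(t0, 0)`, the four anchors and `(t_P, 1)`, evaluates
#' `F(t) = F0 + (Fm - F0) V(t)` on the log-spaced sampling grid (anchor
#' times included), and applies multiplicative Gaussian noise
#' `F * (1 + eps)`, `eps ~ N(0, noise_cv)`. Deterministic for a fixed
#' seed.
#'
#' @param spec a [transient_spec()].
#' @param variety,treatment,replicate metadata labels for the output.
#' @param seed integer seed (defaults to `spec$seed`; `NULL` leaves the RNG
#'   state alone).
#' @return a [fluorescence_transient()].
#' @export
simulate_transient <- function(spec, variety = "V1", treatment = "0h",
                               replicate = 1L, seed = spec$seed) {
  validate_transient_spec(spec)
  knots_t <- c(spec$t0, 150, 300, 2000, 30000, spec$t_P)
  knots_v <- c(0, spec$VL, spec$VK, spec$VJ, spec$VI, 1)
  vfun <- stats::splinefun(log10(knots_t), knots_v, method = "monoH.FC")
  g <- 10^seq(log10(spec$t0), log10(spec$t_P), length.out = spec$n_points)
  g[1L] <- spec$t0; g[length(g)] <- spec$t_P  # kill 10^log10 round-off
  tm <- sort(unique(c(g, 150, 300, 2000, 30000)))
  V <- vfun(log10(tm))
  f <- spec$F0 + (spec$Fm - spec$F0) * V
  if (spec$noise_cv > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    f <- f * (1 + stats::rnorm(length(f), 0, spec$noise_cv))
    if (any(f <= 0))
      stop("simulated fluorescence went non-positive; lower noise_cv")
  }
  fluorescence_transient(tm, f, variety = variety, treatment = treatment,
                         replicate = replicate)
}

#' Per-treatment effect on a transient spec and the physiology traits
#'
#' Additive shifts move the V anchors (`dVK`, `dVJ`, `dVI`; `dVL` for the
#' L-band); `fPhiPo` scales the maximum quantum yield `Fv/Fm = 1 - F0/Fm`
#' (applied by moving F0 at fixed Fm). `traits` holds multiplicative
#' factors applied to the baseline physiology trait means (e.g.
#' `c(chl_b = 2.7)` for a 170% increase). Shifted anchors must remain
#' strictly ordered in (0, 1); violations are reported with the offending
#' cell.
#'
#' @param dVL,dVK,dVJ,dVI additive anchor shifts.
#' @param fPhiPo multiplicative factor on Fv/Fm.
#' @param traits named numeric vector of multiplicative trait effects.
#' @return list of class `treatment_effect`.
#' @export
treatment_effect <- function(dVL = 0, dVK = 0, dVJ = 0, dVI = 0, fPhiPo = 1,
                             traits = numeric(0)) {
  structure(list(dVL = dVL, dVK = dVK, dVJ = dVJ, dVI = dVI,
                 fPhiPo = fPhiPo, traits = traits),
            class = "treatment_effect")
}

# apply a treatment_effect to a transient_spec; `cell` names the factorial
# cell for error messages
apply_effect <- function(spec, eff, cell = NULL) {
  spec$VL <- spec$VL + eff$dVL
  spec$VK <- spec$VK + eff$dVK
  spec$VJ <- spec$VJ + eff$dVJ
  spec$VI <- spec$VI + eff$dVI
  phiPo <- (1 - spec$F0 / spec$Fm) * eff$fPhiPo
  if (phiPo <= 0 || phiPo >= 1)
    stop(sprintf("spec error%s: shifted Fv/Fm = %g outside (0, 1)",
                 if (is.null(cell)) "" else sprintf(" in cell %s", cell), phiPo))
  spec$F0 <- spec$Fm * (1 - phiPo)
  validate_transient_spec(spec, cell = cell)
  spec
}

# deterministic per-cell seed derived from the root seed; kept < 2^31
derive_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + index * 7919
  as.integer(s %% 2147483647L + 1)
}

#' Default baseline physiology trait means
#'
#' Baseline (control) means used by [simulate_experiment()] when none are
#' given: pigment contents in mg per g fresh weight typical of unstressed
#' peanut leaves, gas exchange (Pn in umol CO2 m-2 s-1, Tr in mmol H2O
#' m-2 s-1), electrolyte leakage EL in percent, and antioxidant enzyme
#' activities (SOD/POD/CAT, U per g FW) at plausible unstressed levels.
#'
#' @return named numeric vector.
#' @export
default_trait_base <- function() {
  c(chl_a = 0.93, chl_b = 0.40, car = 0.28,
    Pn = 20, Tr = 4, EL = 8, SOD = 200, POD = 150, CAT = 100)
}

#' Simulate a full factorial drought experiment
#'
#' Generates `varieties x treatments x n_reps` OJIP transients plus a tidy
#' physiology table with the configured treatment effects. All randomness
#' derives from the root `seed` through per-cell seeds, so the whole
#' factorial is reproducible and individual cells are stable under design
#' changes elsewhere.
#'
#' Derived traits are computed per replicate after noise: `chl_ab`,
#' `chl_ab_ratio`, and `WUE = Pn/Tr`.
#'
#' @param base a [transient_spec()] for the control condition.
#' @param effects either a named list `treatment -> treatment_effect`
#'   (shared across varieties) or a named list
#'   `variety -> (treatment -> treatment_effect)`.
#' @param varieties,treatments factor level labels; the first treatment is
#'   conventionally the control (no effect needed for labels missing from
#'   `effects`).
#' @param n_reps replicates per cell.
#' @param seed root integer seed.
#' @param trait_base named baseline trait means, or a named list per
#'   variety; defaults to [default_trait_base()].
#' @param trait_sd_frac additive trait noise, as a fraction of the baseline
#'   mean (sd = `trait_sd_frac * base mean`).
#' @return list with `transients` (list of `fluor_transient`) and `traits`
#'   (a [group_table()]).
#' @export
simulate_experiment <- function(base, effects = list(),
                                varieties = c("NH5", "FH18"),
                                treatments = c("0h", "4h", "8h", "24h"),
                                n_reps = 3, seed = 1,
                                trait_base = default_trait_base(),
                                trait_sd_frac = 0.06) {
  per_variety <- length(effects) && all(names(effects) %in% varieties)
  base_by_var <- if (is.list(trait_base) && !is.null(names(trait_base)) &&
                     all(varieties %in% names(trait_base)))
    trait_base else stats::setNames(rep(list(trait_base), length(varieties)),
                                    varieties)
  transients <- list()
  trait_rows <- list()
  cell_i <- 0L
  for (v in varieties) for (tr in treatments) {
    cell_i <- cell_i + 1L
    cell <- sprintf("%s/%s", v, tr)
    eff <- if (per_variety) effects[[v]][[tr]] else effects[[tr]]
    if (is.null(eff)) eff <- treatment_effect()
    spec <- apply_effect(base, eff, cell = cell)
    for (r in seq_len(n_reps)) {
      transients[[length(transients) + 1L]] <-
        simulate_transient(spec, variety = v, treatment = tr, replicate = r,
                           seed = derive_seed(seed, cell_i * 1000L + r))
    }
    # physiology traits for this cell
    tb <- base_by_var[[v]]
    mult <- stats::setNames(rep(1, length(tb)), names(tb))
    if (length(eff$traits)) mult[names(eff$traits)] <- eff$traits
    set.seed(derive_seed(seed, 500000L + cell_i))
    for (r in seq_len(n_reps)) {
      vals <- tb * mult + stats::rnorm(length(tb), 0, trait_sd_frac * tb)
      vals <- c(vals,
                chl_ab = unname(vals["chl_a"] + vals["chl_b"]),
                chl_ab_ratio = unname(vals["chl_a"] / vals["chl_b"]),
                WUE = unname(vals["Pn"] / vals["Tr"]))
      trait_rows[[length(trait_rows) + 1L]] <-
        data.frame(variety = v, treatment = tr, replicate = r,
                   trait = names(vals), value = unname(vals),
                   stringsAsFactors = FALSE)
    }
  }
  list(transients = transients,
       traits = group_table(do.call(rbind, trait_rows)))
}
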