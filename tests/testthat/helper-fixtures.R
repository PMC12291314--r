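# Fixtures are built in code: traces exactly piecewise-linear in log10(t)
# through the OJIP knots (so landmark extraction is exact), and random
# valid landmark tuples for oracle/property tests.

# trace passing exactly through the landmark knots, linear in log10(t)
# between them; maximum Fm at t_P
make_knot_transient <- function(F0 = 500, FL = 650, FK = 900, FJ = 1500,
                                FI = 2200, Fm = 2500, t0 = 20, t_P = 3e5,
                                n = 80, variety = "V1", treatment = "0h",
                                replicate = 1L, drop_range = NULL,
                                add_times = NULL) {
  knots_t <- c(t0, 150, 300, 2000, 30000, t_P)
  knots_f <- c(F0, FL, FK, FJ, FI, Fm)
  g <- 10^seq(log10(t0), log10(t_P), length.out = n)
  g[1] <- t0; g[length(g)] <- t_P  # kill 10^log10 round-off
  tm <- sort(unique(c(g, knots_t, add_times)))
  if (!is.null(drop_range))
    tm <- tm[tm < drop_range[1] | tm > drop_range[2]]
  f <- approx(log10(knots_t), knots_f, xout = log10(tm))$y
  fluorescence_transient(tm, f, variety = variety, treatment = treatment,
                         replicate = replicate)
}

# random valid landmark tuple (0 < F0 < FL < FK < FJ < FI < Fm)
rand_landmarks <- function() {
  F0 <- runif(1, 200, 800)
  Fm <- F0 * runif(1, 2.5, 6)
  v <- sort(runif(3, 0.05, 0.95))
  while (min(diff(v)) < 0.02) v <- sort(runif(3, 0.05, 0.95))
  vl <- runif(1, 0.005, v[1] - 0.004)
  f <- F0 + c(vl, v) * (Fm - F0)
  structure(list(F0 = F0, FL = f[1], FK = f[2], FJ = f[3], FI = f[4],
                 Fm = Fm, t_Fm = 3e5, t0 = 20), class = "ojip_landmarks")
}

# independent direct-formula recomputation of the JIP parameter set
# (the oracle: straight transliteration of the algebra, no shared code)
oracle_jip <- function(lm) {
  F0 <- lm$F0; Fm <- lm$Fm
  V <- function(Ft) (Ft - F0) / (Fm - F0)
  VL <- V(lm$FL); VK <- V(lm$FK); VJ <- V(lm$FJ); VI <- V(lm$FI)
  M0 <- 4 * (lm$FK - F0) / (Fm - F0)
  phiPo <- 1 - F0 / Fm
  c(VL = VL, VK = VK, VJ = VJ, VI = VI, M0 = M0,
    phiPo = phiPo, psiEo = 1 - VJ, phiEo = phiPo * (1 - VJ),
    deltaRo = (1 - VI) / (1 - VJ), phiRo = phiPo * (1 - VI),
    ABS_RC = (M0 / VJ) / phiPo, TR0_RC = M0 / VJ,
    ET0_RC = (M0 / VJ) * (1 - VJ),
    DI0_RC = (M0 / VJ) / phiPo - M0 / VJ,
    RE0_RC = (M0 / VJ) * (1 - VI),
    ABS_CSm = Fm, TR0_CSm = phiPo * Fm, ET0_CSm = phiPo * (1 - VJ) * Fm,
    DI0_CSm = Fm - phiPo * Fm, RC_CSm = phiPo * (VJ / M0) * Fm,
    PIabs = (phiPo * VJ / M0) * (phiPo / (1 - phiPo)) * ((1 - VJ) / VJ),
    PItotal = (phiPo * VJ / M0) * (phiPo / (1 - phiPo)) * ((1 - VJ) / VJ) *
      ((1 - VI) / (1 - VJ)) / (1 - (1 - VI) / (1 - VJ)))
}

# small tidy trait table: k groups x n reps of one trait, given group means
make_onetrait_table <- function(means, n = 3, sd = 1, trait = "y",
                                variety = "V1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- sprintf("g%d", seq_along(means))
  group_table(data.frame(
    variety = variety,
    treatment = rep(g, each = n),
    replicate = rep(seq_len(n), length(means)),
    trait = trait,
    value = rnorm(n * length(means), rep(means, each = n), sd),
    stringsAsFactors = FALSE))
}
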