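---
title: "Methods: JIP-test analysis of OJIP transients with ojiptest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: JIP-test analysis of OJIP transients with ojiptest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ojiptest)
```

## The model

When a dark-adapted leaf is exposed to saturating actinic light, PSII
fluorescence rises from F₀ (all reaction centres open) to F_m (all Q_A
reduced) through the polyphasic O–J–I–P sequence. The JIP-test treats five
landmark readings — F₀ and the intensities at 150 µs (L), 300 µs (K), 2 ms
(J) and 30 ms (I), plus the maximum F_m — as sufficient statistics of the
energy cascade, and converts them algebraically into yields and fluxes:
the relative variable fluorescence `V_t = (F_t − F₀)/(F_m − F₀)`, the
initial-slope proxy `M₀ = 4·V_K`, the cascade yields `φPo = 1 − F₀/F_m`,
`ψEo = 1 − V_J`, `δRo = (1 − V_I)/(1 − V_J)`, the per-reaction-centre
fluxes `TR₀/RC = M₀/V_J` (and ABS/RC, ET₀/RC, DI₀/RC, RE₀/RC derived from
it), the cross-section fluxes with ABS/CSm approximated by F_m, and the
performance indices PI_abs and PI_total. All of this is closed-form; the
package contains no fitting.

Assumptions worth stating: the landmarks summarise the transient only if
the trace actually shows an O–P rise (flat or decreasing traces are
rejected as degenerate); `M₀ = 4·V_K` is the standard slope proxy, not a
fitted derivative; ABS/CSm = F_m is the usual "per excited cross-section
at t(F_m)" approximation; and every dimensionless quantity is invariant
under rescaling of the (arbitrary) fluorescence axis, which is why no
input rescaling is ever applied.

## Landmark extraction

PEA-class instruments sample on an approximately log-uniform grid, and the
transient is near-linear in log time between steps, so landmarks are read
by linear interpolation in log₁₀(t). F₀ is taken at t₀ = 20 µs
(configurable within [first sample, 50 µs]); instruments differ in their
first reliable sample and the experiment underlying the bundled scenario
does not fix this time, so the conventional 20 µs is the default. F_m is
the global trace maximum, with its time recorded; a fixed-time alternative
(e.g. F at 1 s) was considered and rejected because truncated traces would
silently mis-report F_m.

## Band normalizations

`W_phase = (F_t − F₀)/(F_ref − F₀)` with reference J (O–J window), K (O–K)
or I (O–I). Curves are evaluated on a 200-point log-spaced grid per window
that always contains the reference and canonical step times, so
`W(t_ref) = 1` holds exactly rather than to interpolation error. Group
curves average **after** per-replicate normalization (mean of W, not W of
the mean trace): per-plant normalization is what makes replicate bands
comparable when absolute fluorescence differs. ΔW subtracts the control
curve on the treated band's grid (re-interpolating in log time if the
grids differ), so ΔW vanishes at both endpoints by construction and
`ΔW(a,b) = −ΔW(b,a)` exactly.

The `W_OI ≥ 1` amplitude is the maximum of `W_OI − 1` over t ≥ 30 ms — an
amplitude, not an area, because the I→P rise is summarised in the field by
its height (it indexes the PSI end-acceptor pool).

The Q_A-reducing-centre fraction combines the treated/control ratios of
RC/CSm and ABS/CSm. The literature formula typesets the two bracketed
ratios side by side with no operator; both readings are implemented
(`mode = "quotient"` / `"product"`) with quotient as default, because the
quotient cancels the shared cross-section normalization and reduces to a
pure RC-per-absorption comparison. No claim is made about which reading
the source intended.

## Physiology arithmetic

The Lichtenthaler equations are stated on extract concentrations (µg/mL):
`Ca = 13.95·A665 − 6.88·A649`, `Cb = 24.96·A649 − 7.32·A665`,
`Car = (1000·A470 − 2.05·Ca − 114.8·Cb)/245`; contents in mg g⁻¹ FW follow
as `conc × V/(1000·W)`. The chlorophyll terms inside the carotenoid
equation are the concentrations, not the final contents — the system is
dimensionally consistent only on concentrations. Negative computed
concentrations are flagged with a warning, never clipped: a silent clip
would hide swapped or off-scale readings. Percent change is
`100·(value − reference)/reference`; the reference defaults to the
within-variety control, but a within-course peak (e.g. an 8-h maximum) is
equally valid when a decline from that peak is the quantity of interest.

## Statistics

* **Variability** `V = (max − min)/max` is computed on treatment-group
  means (replicates averaged first); on replicate-level values the range
  inflates with n and the published values are only reproducible on means.
* **Letters** come from classic *unadjusted* Fisher LSD (pooled MSE from
  the one-way ANOVA, pairwise t at α), condensed by the insert-and-absorb
  algorithm with letter "a" on the largest mean. The display satisfies the
  biconditional — groups share a letter iff not significantly different —
  and the test suite checks exactly that against exhaustive pairwise
  decisions. With zero within-group variance everywhere the t-criterion
  degenerates; any difference in means then counts as significant.
* **Two-way ANOVA** is fixed-effects with interaction on a balanced
  factorial (type-I sums of squares, which coincide with the other types
  on balanced data); effects map to `**` (p < 0.01), `*` (p < 0.05), `NS`.
* **Correlations** are pairwise-complete Pearson with two-sided p and the
  star convention ***/**/*/· at 0.001/0.01/0.05/0.10. Observations pool
  varieties and treatments by default; `by_variety = TRUE` exists because
  trait relationships can differ between tolerant and sensitive material,
  and neither pooling is asserted as canonical.

## The synthetic generator: what it emulates and what it does not

`simulate_transient()` is anchor-driven: V(t) passes exactly through
(t₀, 0), the four anchor values at 150 µs/300 µs/2 ms/30 ms and (t_P, 1)
by monotone Fritsch–Carlson interpolation in log₁₀(t); fluorescence is
`F₀ + (F_m − F₀)·V(t)` with multiplicative Gaussian noise of coefficient
of variation `noise_cv` per sample. The anchor times are inserted into the
sampling grid, so a noiseless simulate→extract round trip recovers the
anchors exactly — testability is the design goal. Defaults state a healthy
dark-adapted leaf: Fv/Fm = 0.8, (V_L, V_K, V_J, V_I) = (0.12, 0.2, 0.5,
0.85), F₀ = 500 instrument units, 118 samples from 20 µs to 300 ms,
noise_cv = 0.02 (PEA-class instruments resolve the rise with ~1–3 % point
noise). Trait noise is additive with sd = 6 % of the baseline mean,
matching the dispersion of a typical n = 3 pigment table whose ± values
are read as SD.

The bundled `drought_scenario()` injects the canonical drought signatures:
rising V_J/V_K/V_I, mildly falling Fv/Fm, PI_abs dropping to ≈ 0.71
(tolerant) / 0.61 (sensitive) of control at 24 h with V_K + 25 % in the
sensitive cultivar, pigment multipliers that reproduce the reference
pigment table exactly, and Pn/EL multipliers whose variability V matches
the published rankings. The 24-h anchor shifts were solved in closed form
from the noiseless JIP chain; 4-h/8-h effects are direction-consistent
intermediates only. A green pipeline test on this scenario establishes
that the *arithmetic* is right and that injected effects propagate with
the right sign and size — it does not establish that real drought
transients look like monotone splines (real traces carry correlated
instrument drift, actinic heterogeneity and occasional dips after P, none
of which are modelled), nor that the intermediate-time effects match any
particular experiment.

## Numerical choices and degenerate inputs

Interpolation is linear in log₁₀(t) everywhere landmarks or bands are
read; grids embed the exact reference times so endpoint identities hold to
machine precision rather than to grid resolution. Singular parameter
configurations (V_J ∈ {0,1}, V_I = 1, φPo ∈ {0,1}, M₀ ≤ 0) raise typed
errors naming the offending quantity instead of propagating NaN/Inf.
Group-table values are written with 17 significant digits so write→read is
the identity on doubles. All factorial randomness derives from one root
seed through fixed per-cell seeds (kept below 2³¹), so single cells are
reproducible independently of the design around them.

## Known limitations

One stated recovery property fails by construction and is deliberately
left failing in the acceptance suite: with per-sample noise cv = 0.02,
each landmark is read from (essentially) one noisy sample, so a 10-replicate
group mean of V_J or V_K cannot reliably sit within 1 % (relative) of the
injected value — the mean's sampling sd alone is ≈ 1.2–1.6 % of the target,
and F_m (the maximum of ~120 noisy samples) is biased upward by ≈ 2 %,
pulling V_J down by ≈ 0.013. Meeting the property would require smoothing
the trace before landmark extraction (contradicting the stated landmark
definition), reducing the noise, or averaging more replicates. The
directional propagation properties (higher V_K ⇒ lower OEC fraction,
higher V_J ⇒ lower PI_abs) do hold exactly in the noiseless limit.

Other limitations: no mechanistic electron-transport simulation, no
L-band connectivity modelling, no proprietary binary instrument formats
(delimited text only), balanced designs only for the two-way ANOVA, and no
multiplicity correction beyond what Fisher LSD itself implies — matching
standard practice in this literature, not defending it.
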