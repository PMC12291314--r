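# Double-normalized band curves (W_OJ / W_OK / W_OI), treatment-minus-
# control difference bands, and the OEC-centre / QA-reducing-centre group
# fractions.
#
# Group curves are averaged after per-replicate normalization (mean of W,
# not W of the mean trace), on a common 200-point log-time grid per phase
# window, because instrument grids differ between replicates.

.band_windows <- list(OJ = c(ref = 2000), OK = c(ref = 300), OI = c(ref = 30000))

new_normalized_band <- function(phase, times, W, is_delta = FALSE,
                                reference_group = NA_character_) {
  structure(list(phase = phase, times = times, W = W,
                 is_delta = is_delta, reference_group = reference_group),
            class = "normalized_band")
}

#' @export
print.normalized_band <- function(x, ...) {
  cat(sprintf("<normalized_band> %s%s: %d points, t %.3g-%.3g us, W %.3g-%.3g\n",
              if (x$is_delta) "delta-" else "", x$phase, length(x$times),
              x$times[1L], x$times[length(x$times)], min(x$W), max(x$W)))
  invisible(x)
}

#' Double-normalize a transient over a phase window
#'
#' Computes `W = (Ft - F0) / (Fref - F0)` pointwise on a log-spaced grid
#' over the phase window, where the reference landmark Fref is FJ for the
#' O-J phase (window t0 to 2 ms), FK for O-K (t0 to 300 us) and FI for O-I
#' (t0 to the end of the trace). By construction `W(t0) = 0` and
#' `W(t_ref) = 1` (the reference time is always a grid point).
#'
#' The O-K band evaluated at 150 us is the L-band substrate; the O-J band
#' at 300 us is the K-band substrate; the part of W_OI above 1 is the
#' I-to-P rise (see [w_oi_tail_amplitude()]).
#'
#' @param transient a [fluorescence_transient()].
#' @param landmarks its [extract_landmarks()] result (supplies F0 and the
#'   reference landmark; `landmarks$t0` fixes the window origin).
#' @param phase `"OJ"`, `"OK"` or `"OI"`.
#' @param n_grid number of log-spaced grid points in the window.
#' @return A `normalized_band`.
#' @export
normalize_band <- function(transient, landmarks, phase = c("OJ", "OK", "OI"),
                           n_grid = 200) {
  phase <- match.arg(phase)
  validate_transient(transient)
  t0 <- landmarks$t0
  t_ref <- .band_windows[[phase]][["ref"]]
  t_end <- switch(phase, OJ = 2000, OK = 300,
                  OI = transient$times[length(transient$times)])
  Fref <- switch(phase, OJ = landmarks$FJ, OK = landmarks$FK, OI = landmarks$FI)
  if (Fref <= landmarks$F0)
    stop(sprintf("normalization error: reference landmark (%s phase) <= F0", phase))
  grid <- band_grid(t0, t_end, n_grid, t_ref)
  f <- stats::approx(log10(transient$times), transient$fluorescence,
                     xout = log10(grid), ties = "ordered")$y
  W <- (f - landmarks$F0) / (Fref - landmarks$F0)
  new_normalized_band(phase, grid, W)
}

# log-spaced grid over [t0, t_end] that contains the reference time and any
# canonical step time within the window exactly (the band diagnostics are
# read at those times)
band_grid <- function(t0, t_end, n_grid, t_ref) {
  g <- 10^seq(log10(t0), log10(t_end), length.out = n_grid)
  g[1L] <- t0; g[length(g)] <- t_end  # kill 10^log10 round-off
  steps <- c(150, 300, 2000, 30000, t_ref)
  g <- sort(unique(c(g, steps[steps >= t0 & steps <= t_end])))
  g
}

#' Group-mean normalized band
#'
#' Normalizes each replicate individually and averages W on a common grid
#' (per-replicate normalization first, then the mean curve). For the O-I
#' phase the common window ends at the shortest trace.
#'
#' @param transients list of `fluor_transient` (one group).
#' @param phase `"OJ"`, `"OK"` or `"OI"`.
#' @param t0 origin time for F0 extraction (microseconds).
#' @param n_grid grid size per window.
#' @return A `normalized_band` holding the group-mean W.
#' @export
group_mean_band <- function(transients, phase = c("OJ", "OK", "OI"),
                            t0 = 20, n_grid = 200) {
  phase <- match.arg(phase)
  if (!length(transients)) stop("usage error: empty transient group")
  t_end <- switch(phase, OJ = 2000, OK = 300,
                  OI = min(vapply(transients,
                                  function(x) x$times[length(x$times)], 0)))
  t_ref <- .band_windows[[phase]][["ref"]]
  grid <- band_grid(t0, t_end, n_grid, t_ref)
  Ws <- vapply(transients, function(x) {
    lm <- extract_landmarks(x, t0 = t0)
    Fref <- switch(phase, OJ = lm$FJ, OK = lm$FK, OI = lm$FI)
    if (Fref <= lm$F0)
      stop(sprintf("normalization error: reference landmark (%s) <= F0 in %s/%s rep %d",
                   phase, x$variety, x$treatment, x$replicate))
    f <- stats::approx(log10(x$times), x$fluorescence, xout = log10(grid),
                       ties = "ordered")$y
    (f - lm$F0) / (Fref - lm$F0)
  }, numeric(length(grid)))
  new_normalized_band(phase, grid, rowMeans(Ws))
}

#' Difference band (treatment minus control)
#'
#' `dW(t) = W_treated(t) - W_control(t)` on the treated band's grid; the
#' control is re-interpolated in log time when grids differ. Both endpoints
#' of a difference of same-phase bands are 0 by construction.
#'
#' @param treated,control `normalized_band`s of the same phase (typically
#'   group means from [group_mean_band()]).
#' @param reference_group label recorded on the result (e.g. `"0h"`).
#' @return A `normalized_band` with `is_delta = TRUE`.
#' @export
delta_band <- function(treated, control, reference_group = "control") {
  if (!inherits(treated, "normalized_band") || !inherits(control, "normalized_band"))
    stop("usage error: delta_band needs two normalized_band objects")
  if (treated$is_delta || control$is_delta)
    stop("usage error: delta_band operands must not already be delta bands")
  if (treated$phase != control$phase)
    stop(sprintf("usage error: mismatched phases (%s vs %s)",
                 treated$phase, control$phase))
  Wc <- if (length(control$times) == length(treated$times) &&
            all(control$times == treated$times)) {
    control$W
  } else {
    stats::approx(log10(control$times), control$W,
                  xout = log10(treated$times), rule = 2)$y
  }
  new_normalized_band(treated$phase, treated$times, treated$W - Wc,
                      is_delta = TRUE, reference_group = reference_group)
}

#' K-band group statistic: mean VK and its shift versus control
#'
#' Computes the relative variable fluorescence at the K step (300 us) for
#' every replicate of the two groups and returns the treated group mean and
#' the difference of group means (`delta_VK`), the K-band elevation that
#' diagnoses oxygen-evolving-complex impairment.
#'
#' @param group,control lists of `fluor_transient` objects.
#' @param t0 origin time for F0 (microseconds).
#' @return list with `VK_mean`, `VK_control`, `delta_VK`.
#' @export
k_band_statistics <- function(group, control, t0 = 20) {
  if (!length(group) || !length(control))
    stop("usage error: empty transient group")
  vk <- function(ts) vapply(ts, function(x) {
    lm <- extract_landmarks(x, t0 = t0)
    relative_variable_fluorescence(lm, lm$FK)
  }, 0)
  g <- vk(group); ctl <- vk(control)
  list(VK_mean = mean(g), VK_control = mean(ctl),
       delta_VK = mean(g) - mean(ctl))
}

#' Amplitude of the W_OI >= 1 region (I-to-P rise)
#'
#' For an O-I normalized band, returns `max(W) - 1` over `t >= 30 ms`,
#' i.e. the amplitude by which the curve exceeds its I-step reference; this
#' indexes the size of the PSI end-electron-acceptor pool. Returns 0 if the
#' curve never exceeds 1.
#'
#' @param band a non-delta `normalized_band` of phase `"OI"` covering
#'   t >= 30 ms.
#' @return the amplitude (dimensionless, >= 0).
#' @export
w_oi_tail_amplitude <- function(band) {
  if (!inherits(band, "normalized_band") || band$phase != "OI" || band$is_delta)
    stop("usage error: need a non-delta O-I normalized band")
  sel <- band$times >= 30000
  if (!any(sel)) stop("usage error: band has no samples at t >= 30 ms")
  max(max(band$W[sel]) - 1, 0)
}

# pull a named JIP parameter out of a "group" argument, which may be a list
# of jip_parameters objects, a data.frame with parameter columns, or a
# group_table in long form
.group_param <- function(group, name) {
  if (inherits(group, "jip_parameters")) return(unclass(group)[[name]])
  if (is.data.frame(group)) {
    if (all(c("trait", "value") %in% names(group)))
      return(group$value[group$trait == name])
    return(group[[name]])
  }
  if (is.list(group))
    return(vapply(group, function(p) unclass(p)[[name]], 0))
  stop("usage error: group must be jip_parameters, a list of them, or a data.frame")
}

#' Active fraction of oxygen-evolving-complex (OEC) centres
#'
#' `OEC = (1 - VK/VJ)_treated / (1 - VK/VJ)_control`, computed on group
#' means of VK and VJ. Values below 1 indicate donor-side (OEC)
#' inactivation in the treated group; identical groups give exactly 1.
#'
#' @param treated,control JIP parameters for the two groups: a list of
#'   `jip_parameters`, a long `group_table` with `trait`/`value` columns,
#'   or a data.frame with `VK` and `VJ` columns.
#' @return the OEC-centre fraction (dimensionless).
#' @export
oec_centers <- function(treated, control) {
  frac <- function(g) {
    vk <- mean(.group_param(g, "VK")); vj <- mean(.group_param(g, "VJ"))
    if (vj == 0) stop_singular("mean VJ = 0 in OEC-centre fraction")
    1 - vk / vj
  }
  fc <- frac(control)
  if (fc == 0) stop_singular("control (1 - VK/VJ) = 0 in OEC-centre fraction")
  frac(treated) / fc
}

#' Fraction of QA-reducing reaction centres
#'
#' Combines the treated/control ratios of the reaction-centre density
#' (`RC_CSm`) and of the absorption flux (`ABS_CSm`), both on group means.
#' The default `"quotient"` mode returns
#' `[(RC_CSm)_t/(RC_CSm)_c] / [(ABS_CSm)_t/(ABS_CSm)_c]`; `"product"`
#' multiplies the two bracketed ratios instead (the field literature
#' typesets the two brackets side by side without an operator, so both
#' readings are provided). Both modes are invariant under a global
#' rescaling of the fluorescence of both groups and give exactly 1 for
#' identical groups.
#'
#' @param treated,control JIP parameters for the two groups (same accepted
#'   forms as [oec_centers()]).
#' @param mode `"quotient"` (default) or `"product"`.
#' @return the QA-reducing-centre fraction (dimensionless).
#' @export
qa_reducing_centers <- function(treated, control,
                                mode = c("quotient", "product")) {
  mode <- match.arg(mode)
  m <- function(g, nm) mean(.group_param(g, nm))
  rc_c <- m(control, "RC_CSm"); abs_c <- m(control, "ABS_CSm")
  if (rc_c == 0 || abs_c == 0)
    stop_singular("control RC_CSm or ABS_CSm = 0 in QA-RC fraction")
  rc_ratio <- m(treated, "RC_CSm") / rc_c
  abs_ratio <- m(treated, "ABS_CSm") / abs_c
  if (mode == "quotient") {
    if (abs_ratio == 0) stop_singular("ABS_CSm ratio = 0 in QA-RC quotient")
    rc_ratio / abs_ratio
  } else {
    rc_ratio * abs_ratio
  }
}

#' Export band curves as a tidy data frame
#'
#' @param bands named list of `normalized_band` objects; names are used as
#'   `variety|treatment` labels when the elements carry none.
#' @param variety,treatment recycled labels for the output rows.
#' @return data.frame with columns phase, variety, treatment, time_us, W,
#'   is_delta.
#' @export
band_table <- function(bands, variety = names(bands), treatment = NULL) {
  do.call(rbind, lapply(seq_along(bands), function(i) {
    b <- bands[[i]]
    data.frame(phase = b$phase,
               variety = if (is.null(variety)) NA_character_ else variety[[i]],
               treatment = if (is.null(treatment)) NA_character_ else treatment[[i]],
               time_us = b$times, W = b$W, is_delta = b$is_delta,
               stringsAsFactors = FALSE)
  }))
}
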