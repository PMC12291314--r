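test_that("landmarks are read exactly at the knots; Fm is the trace maximum", {
  tr <- make_knot_transient(F0 = 500, FL = 650, FK = 900, FJ = 1500,
                            FI = 2200, Fm = 2500)
  lm <- extract_landmarks(tr, t0 = 20)
  expect_equal(unlist(lm[c("F0", "FL", "FK", "FJ", "FI", "Fm")]),
               c(F0 = 500, FL = 650, FK = 900, FJ = 1500, FI = 2200, Fm = 2500))
  expect_equal(lm$t_Fm, 3e5)
})

test_that("landmarks between samples are log-time linear interpolants", {
  # deliberately no sample at 300 us: FK must interpolate the 200 and 400 us
  # samples linearly in log10(t)
  tr <- make_knot_transient(add_times = c(100, 200, 400),
                            drop_range = c(201, 399))
  stopifnot(!any(abs(tr$times - 300) < 1))
  f200 <- tr$fluorescence[which.min(abs(tr$times - 200))]
  f400 <- tr$fluorescence[which.min(abs(tr$times - 400))]
  w <- (log10(300) - log10(200)) / (log10(400) - log10(200))
  expect_equal(extract_landmarks(tr)$FK, f200 + w * (f400 - f200),
               tolerance = 1e-12)
})

test_that("extraction rejects unusable inputs", {
  tr <- make_knot_transient()
  expect_error(extract_landmarks(tr, t0 = 60), "outside")
  expect_error(extract_landmarks(tr, t0 = 1), "outside")
  # monotonically decreasing trace: maximum at the first sample
  dec <- fluorescence_transient(tr$times, rev(sort(tr$fluorescence)))
  err <- tryCatch(extract_landmarks(dec), error = identity)
  expect_s3_class(err, "ojip_extraction_error")
  expect_match(conditionMessage(err), "degenerate")
})

test_that("relative variable fluorescence is the (Ft - F0)/(Fm - F0) ratio", {
  lm <- structure(list(F0 = 500, Fm = 2500), class = "ojip_landmarks")
  expect_equal(relative_variable_fluorescence(lm, 500), 0)
  expect_equal(relative_variable_fluorescence(lm, 2500), 1)
  expect_equal(relative_variable_fluorescence(lm, 1500), 0.5)
  flat <- structure(list(F0 = 500, Fm = 500), class = "ojip_landmarks")
  expect_error(relative_variable_fluorescence(flat, 700), "Fm equals F0")
})

worked_landmarks <- structure(
  list(F0 = 500, FL = 650, FK = 900, FJ = 1500, FI = 2200, Fm = 2500,
       t_Fm = 3e5, t0 = 20), class = "ojip_landmarks")

test_that("the worked landmark set yields the full JIP chain", {
  p <- unclass(compute_jip_parameters(worked_landmarks))
  expect_equal(p[["VK"]], 0.2)
  expect_equal(p[["VJ"]], 0.5)
  expect_equal(p[["VI"]], 0.85)
  expect_equal(p[["M0"]], 0.8)
  expect_equal(p[["phiPo"]], 0.8)
  expect_equal(p[["psiEo"]], 0.5)
  expect_equal(p[["phiEo"]], 0.4)
  expect_equal(p[["deltaRo"]], 0.3)
  expect_equal(p[["phiRo"]], 0.12)
  expect_equal(p[["ABS_RC"]], 2.0)
  expect_equal(p[["TR0_RC"]], 1.6)
  expect_equal(p[["ET0_RC"]], 0.8)
  expect_equal(p[["DI0_RC"]], 0.4)
  expect_equal(p[["RE0_RC"]], 0.24)
  expect_equal(p[["PIabs"]], 2.0)
  expect_equal(p[["PItotal"]], 6 / 7)
})

test_that("singular landmark configurations raise named errors", {
  lmk <- function(...) {
    l <- worked_landmarks; l[names(list(...))] <- list(...); l
  }
  err <- tryCatch(compute_jip_parameters(lmk(FK = 500)), error = identity)
  expect_s3_class(err, "ojip_singular_error")   # M0 = 0, zero-flux
  expect_match(conditionMessage(err), "M0")
  expect_match(conditionMessage(
    tryCatch(compute_jip_parameters(lmk(FJ = 2500)), error = identity)), "VJ")
  expect_match(conditionMessage(
    tryCatch(compute_jip_parameters(lmk(FI = 2500)), error = identity)), "VI")
  expect_error(compute_jip_parameters(lmk(F0 = 2500, FL = 2500, FK = 2500,
                                          FJ = 2500, FI = 2500)), "F0/Fm")
})

test_that("dimensionless parameters are scale-invariant; CSm fluxes scale", {
  set.seed(42)
  csm <- c("ABS_CSm", "TR0_CSm", "ET0_CSm", "DI0_CSm", "RC_CSm")
  for (i in 1:25) {
    lm <- rand_landmarks()
    c_scale <- runif(1, 0.1, 10)
    lm3 <- lm
    for (f in c("F0", "FL", "FK", "FJ", "FI", "Fm"))
      lm3[[f]] <- lm[[f]] * c_scale
    p1 <- unclass(compute_jip_parameters(lm))
    p3 <- unclass(compute_jip_parameters(lm3))
    dimless <- setdiff(names(p1), csm)
    expect_equal(p3[dimless], p1[dimless], tolerance = 1e-12)
    expect_equal(p3[csm], p1[csm] * c_scale, tolerance = 1e-12)
  }
})

test_that("conservation identities hold to machine precision", {
  set.seed(7)
  for (i in 1:25) {
    p <- unclass(compute_jip_parameters(rand_landmarks()))
    expect_identical(p[["DI0_RC"]], p[["ABS_RC"]] - p[["TR0_RC"]])
    expect_equal(p[["phiEo"]], p[["phiPo"]] * p[["psiEo"]], tolerance = 1e-15)
    expect_equal(p[["RE0_RC"]], p[["ET0_RC"]] * p[["deltaRo"]],
                 tolerance = 1e-14)
    expect_equal(p[["ABS_CSm"]], p[["TR0_CSm"]] + p[["DI0_CSm"]],
                 tolerance = 1e-15)
  }
})

test_that("jip_parameter_table stacks all parameters as a tidy table", {
  trs <- list(make_knot_transient(replicate = 1),
              make_knot_transient(replicate = 2, Fm = 2600))
  tab <- jip_parameter_table(trs)
  expect_s3_class(tab, "group_table")
  expect_equal(nrow(tab), 2L * length(jip_parameter_names))
  expect_setequal(unique(tab$trait), jip_parameter_names)
  expect_equal(tab$value[tab$replicate == 1 & tab$trait == "PIabs"], 2.0)
})
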