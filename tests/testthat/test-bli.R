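mk_curve <- function(resp, tt = seq(0, 60, by = 0.5), conc = 1e-7,
                     a0 = 10, d0 = 40, ...) {
  sensorgram(tt, resp, conc = conc, assoc_start_s = a0, dissoc_start_s = d0, ...)
}

test_that("double reference subtraction cancels shared artifacts", {
  tt <- seq(0, 60, by = 0.5)
  drift <- 0.01 * tt + 0.2 * sin(tt / 30)
  signal <- ifelse(tt >= 10 & tt < 40, 1 - exp(-0.1 * (tt - 10)),
                   ifelse(tt >= 40, (1 - exp(-0.1 * 30)) * exp(-0.02 * (tt - 40)), 0))
  sample <- mk_curve(signal + drift)
  ref <- mk_curve(drift, conc = 1e-7, is_reference = TRUE)
  zs <- mk_curve(drift, conc = 0)
  zr <- mk_curve(drift, conc = 0, is_reference = TRUE)
  # identical curves cancel to exactly zero
  same <- double_reference_subtract(sample, mk_curve(signal + drift, is_reference = TRUE),
                                    mk_curve(signal + drift, conc = 0),
                                    mk_curve(signal + drift, conc = 0,
                                             is_reference = TRUE))
  expect_true(all(abs(same$response) < 1e-12))
  # references carrying the drift recover the clean signal
  corrected <- double_reference_subtract(sample, ref, zs, zr)
  expect_lt(max(abs(corrected$response - signal)), 1e-9)
  # flat references: correction is just baseline alignment
  flat <- mk_curve(rep(0, length(tt)), conc = 0, is_reference = TRUE)
  flat_s <- mk_curve(rep(0, length(tt)), conc = 0)
  aligned <- double_reference_subtract(mk_curve(signal), mk_curve(rep(0, length(tt)), is_reference = TRUE),
                                       flat_s, flat)
  expect_equal(aligned$response, signal, tolerance = 1e-12)
  # mismatched grids are refused
  short <- sensorgram(seq(0, 60, by = 1), rep(0, 61), conc = 1e-7,
                      assoc_start_s = 10, dissoc_start_s = 40,
                      is_reference = TRUE)
  expect_error(double_reference_subtract(sample, short, zs, zr),
               "grids do not match")
})

test_that("Savitzky-Golay smoothing preserves low-order polynomials and cuts noise", {
  tt <- seq(0, 60, by = 0.5)
  poly <- 2 + 0.3 * tt - 0.01 * tt^2 + 1e-4 * tt^3
  cv <- mk_curve(poly)
  sm <- smooth_sensorgram(cv, window_points = 11, poly_order = 3)
  expect_equal(sm$response, poly, tolerance = 1e-9)
  expect_identical(sm$time_s, cv$time_s)
  expect_identical(smooth_sensorgram(cv, window_points = 1)$response, poly)
  set.seed(8)
  noisy <- mk_curve(rnorm(length(tt)))
  expect_lt(var(smooth_sensorgram(noisy, 11, 3)$response),
            var(noisy$response))
  expect_error(smooth_sensorgram(cv, window_points = 999), "series length")
  expect_error(smooth_sensorgram(cv, window_points = 10), "odd")
  expect_error(smooth_sensorgram(cv, window_points = 3, poly_order = 4),
               "poly_order")
})

test_that("interstep alignment makes the dissociation step continuous", {
  tt <- seq(0, 60, by = 0.5)
  resp <- ifelse(tt >= 40, 5, 1)  # artificial 4-unit transfer jump
  cv <- mk_curve(resp)
  out <- interstep_align(cv)
  expect_equal(out$response[tt >= 40], rep(1, sum(tt >= 40)))
  expect_equal(out$response[tt < 40], resp[tt < 40])
})

test_that("observed-rate fits recover exact and noisy exponentials", {
  tt <- seq(0, 90, by = 0.2)
  a0 <- 10; d0 <- 50
  kobs <- 0.05; req <- 1.0; koff <- 0.02
  resp <- ifelse(tt < a0, 0,
                 ifelse(tt < d0, req * (1 - exp(-kobs * (tt - a0))),
                        req * (1 - exp(-kobs * (d0 - a0))) *
                          exp(-koff * (tt - d0))))
  cv <- mk_curve(resp, tt = tt, a0 = a0, d0 = d0)
  fit <- fit_observed_rates(cv)
  expect_equal(fit$kobs, kobs, tolerance = 1e-6)
  expect_equal(fit$req_extrapolated, req, tolerance = 1e-6)
  expect_equal(fit$koff, koff, tolerance = 1e-6)

  # flat dissociation: koff is zero within solver tolerance and flagged
  flat <- ifelse(tt < a0, 0,
                 ifelse(tt < d0, req * (1 - exp(-kobs * (tt - a0))),
                        req * (1 - exp(-kobs * (d0 - a0)))))
  fit0 <- fit_observed_rates(mk_curve(flat, tt = tt, a0 = a0, d0 = d0))
  expect_lt(fit0$koff, 1e-7)
  expect_true(fit0$diagnostics$koff_at_lower_bound)

  # flat association is a degenerate fit
  expect_error(
    fit_observed_rates(mk_curve(rep(0, length(tt)), tt = tt, a0 = a0, d0 = d0)),
    "flat|degenerate")
})

test_that("noisy association fits agree with a dense grid-search oracle", {
  set.seed(21)
  tt <- seq(0, 90, by = 0.2)
  a0 <- 10; d0 <- 50
  kobs <- 0.08; req <- 1.0
  resp <- ifelse(tt < a0, 0,
                 ifelse(tt < d0, req * (1 - exp(-kobs * (tt - a0))),
                        req * (1 - exp(-kobs * (d0 - a0))) *
                          exp(-0.02 * (tt - d0)))) +
    rnorm(length(tt), sd = 0.01)
  cv <- mk_curve(resp, tt = tt, a0 = a0, d0 = d0)
  fit <- fit_observed_rates(cv)
  expect_equal(fit$kobs, kobs, tolerance = 0.05)
  ia <- tt >= a0 & tt <= a0 + 20
  grid <- oracle_grid_exp_assoc(tt[ia] - a0, resp[ia],
                                req_range = c(0.5, 1.5),
                                k_range = c(0.04, 0.16))
  expect_equal(fit$kobs, unname(grid[["k"]]), tolerance = 0.02)
})

test_that("rate constants derive exactly from an exact kobs line", {
  conc <- c(25, 50, 100, 200) * 1e-9
  kobs <- 1e5 * conc + 0.01
  kin <- derive_rate_constants(data.frame(conc = conc, kobs = kobs),
                               koff_values = rep(0.01, 4))
  expect_equal(kin$kon, 1e5, tolerance = 1e-9)
  expect_equal(kin$koff, 0.01)
  expect_equal(kin$intercept_koff, 0.01, tolerance = 1e-9)
  expect_equal(kin$kd_kinetic, 1e-7, tolerance = 1e-12)
  # stored consistency: KD is exactly koff/kon
  expect_identical(kin$kd_kinetic, kin$koff / kin$kon)
  expect_error(
    derive_rate_constants(data.frame(conc = conc[1:2], kobs = kobs[1:2]),
                          rep(0.01, 2)),
    "3 distinct")
  expect_error(
    derive_rate_constants(data.frame(conc = conc, kobs = rev(kobs)),
                          rep(2, 4)),
    "kon <= 0")
})

test_that("steady-state fit is exact on an exact hyperbola", {
  conc <- c(25, 50, 100, 200, 400) * 1e-9
  kd <- 1e-7; rmax <- 2.0
  fit <- fit_steady_state(conc, ss_response(conc, kd, rmax))
  expect_equal(fit$kd, kd, tolerance = 1e-8)
  expect_equal(fit$rmax, rmax, tolerance = 1e-8)
  expect_error(fit_steady_state(conc, rep(-1, 5)), "degenerate")
  expect_error(fit_steady_state(conc[1:2], c(1, 2)), "3 distinct")
})

test_that("the model evaluator obeys half-saturation, monotonicity and saturation", {
  kd <- 1e-7; rmax <- 2
  expect_identical(ss_response(kd, kd, rmax), rmax / 2)
  cc <- 10^seq(-10, -4, length.out = 50)
  resp <- ss_response(cc, kd, rmax)
  expect_true(all(diff(resp) > 0))
  expect_true(all(resp < rmax))
  expect_equal(ss_response(1e6 * kd, kd, rmax), rmax, tolerance = 1e-4)
})

test_that("noisy steady-state fits agree with a 2-D grid-search oracle", {
  set.seed(14)
  conc <- c(25, 50, 100, 200, 400) * 1e-9
  kd <- 1e-7; rmax <- 2.0
  req <- ss_response(conc, kd, rmax) * (1 + rnorm(5, sd = 0.02))
  fit <- fit_steady_state(conc, req)
  expect_equal(fit$kd, kd, tolerance = 0.10)
  grid <- oracle_grid_hyperbola(conc, req, kd_range = c(3e-8, 3e-7),
                                rmax_range = c(1.5, 2.5))
  expect_equal(fit$kd, unname(grid[["kd"]]), tolerance = 0.02)
  expect_equal(fit$rmax, unname(grid[["rmax"]]), tolerance = 0.02)
})

test_that("kobs is linear in concentration for noiseless 1:1 data", {
  conc <- conc_to_molar(c(12.5, 25, 50, 100, 200), "nM")
  set <- simulate_sensorgrams(1e5, 1e-2, 1, conc, rng_seed = 1)
  fit <- fit_bli(set)
  line <- summary(lm(kobs ~ conc, data = fit$per_curve))
  expect_gt(line$r.squared, 0.999)
  expect_identical(fit$kinetic$kd_kinetic,
                   fit$kinetic$koff / fit$kinetic$kon)
})

test_that("unit conversion keeps concentrations in molar", {
  expect_equal(conc_to_molar(100, "nM"), 1e-7)
  expect_equal(conc_to_molar(3.3, "mM"), 3.3e-3)
  expect_equal(conc_to_molar(1, "M"), 1)
})
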