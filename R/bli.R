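# Biolayer interferometry, 1:1 Langmuir model.
#
# A sensorgram tracks the optical response (nm shift) of a ligand-coated
# sensor tip through baseline, association and dissociation phases. For a
# 1:1 interaction at analyte concentration C:
#   association   R(t) = Req * (1 - exp(-kobs * t)),  kobs = kon*C + koff
#   dissociation  R(t) = R0 * exp(-koff * t)
#   equilibrium   Req  = Rmax * C / (KD + C),         KD   = koff / kon
# Concentrations are molar throughout; rates are 1/s and 1/(M*s).

#' Construct a sensorgram
#'
#' @param time_s Monotone increasing time vector, seconds.
#' @param response Response vector (nm shift), same length as `time_s`
#'   (>= 10 points).
#' @param conc Analyte concentration, molar; 0 only for zero-analyte
#'   blanks.
#' @param assoc_start_s,dissoc_start_s Phase boundaries, seconds;
#'   `dissoc_start_s > assoc_start_s`.
#' @param is_reference Curve from an unloaded reference sensor?
#' @param is_zero_analyte Zero-analyte blank? Defaults to `conc == 0`.
#' @return An object of class `sensorgram`.
#' @export
sensorgram <- function(time_s, response, conc = 0,
                       assoc_start_s, dissoc_start_s,
                       is_reference = FALSE,
                       is_zero_analyte = (conc == 0)) {
  time_s <- as.numeric(time_s)
  response <- as.numeric(response)
  if (length(time_s) < 10L || length(time_s) != length(response)) {
    stop("time and response must be equal-length vectors of >= 10 points",
         call. = FALSE)
  }
  if (any(diff(time_s) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (conc < 0) stop("analyte concentration must be >= 0", call. = FALSE)
  if (dissoc_start_s <= assoc_start_s) {
    stop("dissociation must start after association", call. = FALSE)
  }
  if ((conc == 0) != is_zero_analyte) {
    stop("conc == 0 must coincide with is_zero_analyte", call. = FALSE)
  }
  structure(list(time_s = time_s, response = response, conc = conc,
                 assoc_start_s = assoc_start_s,
                 dissoc_start_s = dissoc_start_s,
                 is_reference = is_reference,
                 is_zero_analyte = is_zero_analyte),
            class = "sensorgram")
}

#' Bundle sensorgrams into a set
#'
#' @param samples List of analyte-concentration sample curves.
#' @param references Matched unloaded-sensor reference curves (same
#'   concentrations, same order as `samples`).
#' @param zero_sample,zero_reference Zero-analyte blank on the loaded and
#'   the reference sensor.
#' @param ligand_label Free-text label for the immobilized ligand.
#' @param truth Optional generator ground truth (see
#'   [simulate_sensorgrams()]).
#' @return An object of class `sensorgram_set`.
#' @export
sensorgram_set <- function(samples, references = list(),
                           zero_sample = NULL, zero_reference = NULL,
                           ligand_label = "ligand", truth = NULL) {
  stopifnot(length(samples) >= 1L)
  conc <- vapply(samples, function(s) s$conc, numeric(1L))
  if (any(conc <= 0)) stop("sample concentrations must be > 0", call. = FALSE)
  if (anyDuplicated(conc)) stop("sample concentrations must be distinct", call. = FALSE)
  grid <- samples[[1L]]$time_s
  for (s in c(samples, references)) {
    if (length(s$time_s) != length(grid) || any(s$time_s != grid)) {
      stop("all curves in a set must share a common time grid", call. = FALSE)
    }
  }
  structure(list(samples = samples, references = references,
                 zero_sample = zero_sample, zero_reference = zero_reference,
                 ligand_label = ligand_label, truth = truth),
            class = "sensorgram_set")
}

same_grid <- function(a, b) {
  length(a$time_s) == length(b$time_s) &&
    all(abs(a$time_s - b$time_s) <= 1e-9)
}

#' Double reference subtraction
#'
#' Removes sensor drift and nonspecific signal by subtracting both the
#' unloaded-sensor reference and the zero-analyte blank:
#' `(sample - reference) - (zero_sample - zero_reference)`. The corrected
#' curve is then aligned on the y axis through its baseline (mean response
#' of the pre-association window set to 0). Time grids must match
#' exactly; there is no silent interpolation.
#'
#' @param sample Analyte sample curve (not a reference, not zero-analyte).
#' @param reference Matched unloaded-sensor curve.
#' @param zero_analyte_sample Zero-analyte blank on the loaded sensor.
#' @param zero_analyte_reference Zero-analyte blank on the reference
#'   sensor.
#' @return A corrected, baseline-aligned `sensorgram`.
#' @export
double_reference_subtract <- function(sample, reference,
                                      zero_analyte_sample,
                                      zero_analyte_reference) {
  stopifnot(inherits(sample, "sensorgram"))
  if (sample$is_reference || sample$is_zero_analyte) {
    stop("'sample' must be an analyte sample curve", call. = FALSE)
  }
  for (other in list(reference, zero_analyte_sample, zero_analyte_reference)) {
    if (!same_grid(sample, other)) {
      stop("time grids do not match; refusing to interpolate", call. = FALSE)
    }
  }
  corrected <- (sample$response - reference$response) -
    (zero_analyte_sample$response - zero_analyte_reference$response)
  out <- sample
  out$response <- corrected
  baseline_align(out)
}

#' Align a sensorgram through its baseline
#'
#' Subtracts the mean response of the pre-association window so the
#' baseline sits at 0.
#'
#' @param curve A `sensorgram` with at least one point before
#'   `assoc_start_s`.
#' @return The shifted `sensorgram`.
#' @export
baseline_align <- function(curve) {
  pre <- curve$time_s < curve$assoc_start_s
  if (!any(pre)) stop("no baseline points before association start", call. = FALSE)
  curve$response <- curve$response - mean(curve$response[pre])
  curve
}

#' Interstep alignment through the dissociation step
#'
#' Offsets the dissociation segment so its first point is continuous with
#' the last association point, removing interstep jumps introduced by
#' well-to-well transfer.
#'
#' @param curve A `sensorgram`.
#' @return The corrected `sensorgram`.
#' @export
interstep_align <- function(curve) {
  dis <- curve$time_s >= curve$dissoc_start_s
  if (!any(dis) || all(dis)) return(curve)
  last_assoc <- curve$response[max(which(!dis))]
  offset <- last_assoc - curve$response[which(dis)[1L]]
  curve$response[dis] <- curve$response[dis] + offset
  curve
}

#' Savitzky-Golay smoothing of a sensorgram
#'
#' Local least-squares polynomial smoothing of the response; the time grid
#' is untouched. Reproduces polynomials up to `poly_order` exactly.
#' Smoothing is applied per phase (baseline, association, dissociation
#' segments independently) so the filter never straddles the kinks at
#' phase boundaries, which would otherwise distort the first seconds of
#' each phase -- exactly the part the rate fits use. A segment shorter
#' than the window is left untouched.
#'
#' @param curve A `sensorgram`.
#' @param window_points Odd window length, > `poly_order`, <= series
#'   length (default 11).
#' @param poly_order Local polynomial order (default 3).
#' @return The smoothed `sensorgram`.
#' @export
smooth_sensorgram <- function(curve, window_points = 11L, poly_order = 3L) {
  stopifnot(inherits(curve, "sensorgram"))
  n <- length(curve$response)
  if (window_points %% 2L != 1L) stop("window_points must be odd", call. = FALSE)
  if (window_points > n) {
    stop("smoothing window must not exceed the series length", call. = FALSE)
  }
  if (window_points == 1L) return(curve)
  if (poly_order >= window_points) {
    stop("poly_order must be smaller than window_points", call. = FALSE)
  }
  phase <- findInterval(curve$time_s,
                        c(curve$assoc_start_s, curve$dissoc_start_s))
  for (ph in unique(phase)) {
    seg <- which(phase == ph)
    if (length(seg) >= window_points) {
      curve$response[seg] <- as.numeric(
        signal::sgolayfilt(curve$response[seg], p = poly_order,
                           n = window_points))
    }
  }
  curve
}

#' Steady-state 1:1 binding response
#'
#' The rectangular hyperbola `Response = Rmax * C / (KD + C)`: strictly
#' increasing in C, bounded above by Rmax, equal to Rmax/2 at C = KD.
#'
#' @param conc Analyte concentration(s), molar.
#' @param kd Equilibrium dissociation constant, molar.
#' @param rmax Saturating response, response units.
#' @return Response value(s).
#' @export
ss_response <- function(conc, kd, rmax) {
  rmax * conc / (kd + conc)
}

# internal: exponential association fit on (t, y) with t starting at 0.
# If req is supplied only kobs is free; otherwise (req, kobs) are fit
# jointly. A small ladder of perturbed restarts guards against bad starts.
fit_exp_association <- function(t, y, req = NULL) {
  if (stats::var(y) < 1e-20) {
    stop("association window is flat; degenerate fit", call. = FALSE)
  }
  span <- max(t) - min(t)
  ymax <- max(y)
  slope0 <- unname(stats::coef(stats::lm(y ~ t,
    subset = t <= min(t) + span / 5))[2L])
  k0 <- if (is.null(req)) max(slope0 / max(ymax, 1e-12), 1e-4 / span) else
    max(slope0 / max(req, 1e-12), 1e-4 / span)
  k0 <- max(k0, 1e-8)
  best <- NULL
  for (mult in c(1, 0.3, 3, 10)) {
    fit <- tryCatch({
      if (is.null(req)) {
        minpack.lm::nlsLM(
          y ~ a * (1 - exp(-k * t)),
          start = list(a = 1.2 * max(ymax, 1e-9), k = k0 * mult),
          lower = c(a = 0, k = 0),
          control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15, ptol = 1e-15))
      } else {
        minpack.lm::nlsLM(
          y ~ req * (1 - exp(-k * t)),
          start = list(k = k0 * mult),
          lower = c(k = 0),
          control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15, ptol = 1e-15))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("association fit did not converge", call. = FALSE)
  cf <- stats::coef(best$fit)
  se_k <- tryCatch(summary(best$fit)$coefficients["k", "Std. Error"],
                   error = function(e) NA_real_)
  list(kobs = unname(cf[["k"]]),
       req = if (is.null(req)) unname(cf[["a"]]) else req,
       rmse = sqrt(best$rss / length(y)),
       se_kobs = se_k,
       converged = TRUE)
}

# internal: exponential decay fit R0 * exp(-koff * t), t starting at 0
fit_exp_dissociation <- function(t, y) {
  r0_0 <- max(y[1L], 1e-9)
  tail_ratio <- max(y[length(y)], 1e-12) / r0_0
  k0 <- if (tail_ratio < 1 && tail_ratio > 0) {
    -log(tail_ratio) / (max(t) - min(t))
  } else 1e-6
  k0 <- max(k0, 1e-8)
  best <- NULL
  for (mult in c(1, 0.3, 3)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ r0 * exp(-k * t),
        start = list(r0 = r0_0, k = k0 * mult),
        lower = c(r0 = 0, k = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("dissociation fit did not converge", call. = FALSE)
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients["k", "Std. Error"],
                 error = function(e) NA_real_)
  koff <- unname(cf[["k"]])
  list(koff = koff, r0 = unname(cf[["r0"]]),
       rmse = sqrt(best$rss / length(y)),
       se_koff = se,
       at_lower_bound = koff < 1e-7)
}

#' Fit per-curve observed rates
#'
#' Nonlinear least squares on a corrected, baseline-aligned sensorgram:
#' `R(t) = Req * (1 - exp(-kobs * (t - t_assoc)))` over the first
#' `assoc_fit_window_s` seconds of association, and
#' `R(t) = R0 * exp(-koff * (t - t_dissoc))` over the first
#' `dissoc_fit_window_s` seconds of dissociation. When `req` is supplied
#' (e.g. the measured equilibrium plateau), the association fit has kobs
#' as its only free parameter, which stabilizes short fit windows far from
#' saturation.
#'
#' @param curve A corrected `sensorgram`.
#' @param assoc_fit_window_s,dissoc_fit_window_s Fit window lengths,
#'   seconds (default 20 each).
#' @param req Optional fixed equilibrium response for the association fit.
#' @return List with `kobs`, `req_extrapolated`, `koff`, `conc`, and a
#'   `diagnostics` list (per-phase RMSE, dissociation standard error,
#'   flags `koff_at_lower_bound`, `negative_rate`).
#' @export
fit_observed_rates <- function(curve, assoc_fit_window_s = 20,
                               dissoc_fit_window_s = 20, req = NULL) {
  stopifnot(inherits(curve, "sensorgram"))
  ia <- curve$time_s >= curve$assoc_start_s &
    curve$time_s <= curve$assoc_start_s + assoc_fit_window_s &
    curve$time_s < curve$dissoc_start_s
  id <- curve$time_s >= curve$dissoc_start_s &
    curve$time_s <= curve$dissoc_start_s + dissoc_fit_window_s
  if (sum(ia) < 5L || sum(id) < 5L) {
    stop("need >= 5 points inside each fit window", call. = FALSE)
  }
  af <- fit_exp_association(curve$time_s[ia] - curve$assoc_start_s,
                            curve$response[ia], req = req)
  df <- fit_exp_dissociation(curve$time_s[id] - curve$dissoc_start_s,
                             curve$response[id])
  list(kobs = af$kobs,
       req_extrapolated = af$req,
       koff = df$koff,
       conc = curve$conc,
       diagnostics = list(assoc_rmse = af$rmse, dissoc_rmse = df$rmse,
                          se_kobs = af$se_kobs, se_koff = df$se_koff,
                          koff_at_lower_bound = df$at_lower_bound,
                          negative_rate = af$kobs < 0 || df$koff < 0))
}

#' Derive rate constants from per-curve observed rates
#'
#' For a 1:1 interaction the observed rates fall on the line
#' `kobs = kon * C + koff`. The reported koff is the average of the
#' per-curve dissociation fits (inverse-variance weighted when standard
#' errors are available). kon is the slope of the kobs line constrained
#' through that koff at C = 0 -- the model identity -- since the
#' dissociation phase pins the intercept far better than extrapolating
#' the line; when per-curve kobs standard errors are supplied the
#' regression is inverse-variance weighted (the low-concentration curves
#' carry far less rate information). The free-intercept least-squares
#' line is retained as a consistency diagnostic (`intercept_koff`,
#' `slope_free`, `r_squared`): its intercept should agree with the
#' dissociation koff when the 1:1 model holds. The kinetic
#' `KD = koff / kon`.
#'
#' @param kobs_table data.frame with columns `conc` (molar) and `kobs`
#'   (1/s); >= 3 distinct concentrations.
#' @param koff_values Numeric vector of per-curve dissociation rates.
#' @param koff_se Optional standard errors matching `koff_values`.
#' @param kobs_se Optional standard errors matching `kobs_table$kobs`.
#' @return Object of class `kinetic_fit`: list with `kon`, `koff`,
#'   `kd_kinetic`, `intercept_koff`, `se_kon`, `se_koff`,
#'   `kobs_per_curve`, `koff_per_curve`, `r_squared`.
#' @export
derive_rate_constants <- function(kobs_table, koff_values, koff_se = NULL,
                                  kobs_se = NULL) {
  stopifnot(is.data.frame(kobs_table),
            all(c("conc", "kobs") %in% names(kobs_table)))
  if (length(unique(kobs_table$conc)) < 3L) {
    stop("need kobs at >= 3 distinct concentrations", call. = FALSE)
  }
  wk <- if (!is.null(kobs_se) && all(is.finite(kobs_se)) && all(kobs_se > 0)) {
    1 / kobs_se^2
  } else rep(1, nrow(kobs_table))
  line <- stats::lm(kobs ~ conc, data = kobs_table, weights = wk)
  # summary() warns on exactly collinear (noise-free) input; harmless here
  line_summary <- suppressWarnings(summary(line))
  cf <- line_summary$coefficients
  w <- if (!is.null(koff_se) && all(is.finite(koff_se)) && all(koff_se > 0)) {
    1 / koff_se^2
  } else rep(1, length(koff_values))
  koff <- sum(w * koff_values) / sum(w)
  se_koff <- if (length(koff_values) > 1L) {
    sqrt(sum(w^2 * (koff_values - koff)^2) / sum(w)^2 *
           length(koff_values) / (length(koff_values) - 1L))
  } else NA_real_
  # kon from the line constrained through the dissociation koff: the 1:1
  # model fixes the kobs intercept at koff, and the dissociation phase
  # determines koff far better than extrapolating the line to C = 0. The
  # free-intercept fit is kept as the consistency diagnostic.
  cc <- kobs_table$conc
  kon <- sum(wk * cc * (kobs_table$kobs - koff)) / sum(wk * cc^2)
  if (kon <= 0) {
    stop("fitted kon <= 0: observed rates do not increase with concentration",
         call. = FALSE)
  }
  se_kon <- sqrt(1 / sum(wk * cc^2) *
                   max(line_summary$sigma^2, .Machine$double.eps) +
                 (if (is.na(se_koff)) 0 else
                   (se_koff * sum(wk * cc) / sum(wk * cc^2))^2))
  structure(list(
    kon = kon,
    koff = koff,
    kd_kinetic = koff / kon,
    intercept_koff = unname(cf["(Intercept)", "Estimate"]),
    slope_free = unname(cf["conc", "Estimate"]),
    se_kon = se_kon,
    se_koff = se_koff,
    kobs_per_curve = kobs_table,
    koff_per_curve = data.frame(conc = kobs_table$conc, koff = koff_values),
    r_squared = line_summary$r.squared
  ), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("1:1 kinetic fit: kon = %.4g 1/(M*s), koff = %.4g 1/s, KD = %.4g M\n",
              x$kon, x$koff, x$kd_kinetic))
  invisible(x)
}

#' Fit the steady-state binding hyperbola
#'
#' Nonlinear least squares of `Req = Rmax * C / (KD + C)` over
#' equilibrium responses at >= 3 distinct positive concentrations.
#' Initialization: KD at the median concentration, Rmax at 1.1 x the
#' largest response; three perturbed restarts before declaring
#' non-convergence.
#'
#' @param conc Analyte concentrations, molar.
#' @param req Equilibrium responses at those concentrations.
#' @return Object of class `steady_state_fit`: list with `kd`, `rmax`,
#'   `se_kd`, `se_rmax`, `points` (input data plus fitted values),
#'   `residual_norm`.
#' @export
fit_steady_state <- function(conc, req) {
  conc <- as.numeric(conc); req <- as.numeric(req)
  stopifnot(length(conc) == length(req))
  if (length(unique(conc[conc > 0])) < 3L) {
    stop("need >= 3 distinct positive concentrations", call. = FALSE)
  }
  if (all(req <= 0)) stop("all equilibrium responses <= 0; degenerate fit",
                          call. = FALSE)
  kd0 <- stats::median(conc)
  rmax0 <- 1.1 * max(req)
  best <- NULL
  for (mult in c(1, 0.3, 3, 0.1)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        req ~ rmax * conc / (kd + conc),
        start = list(kd = kd0 * mult, rmax = rmax0),
        lower = c(kd = .Machine$double.xmin, rmax = .Machine$double.xmin),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("steady-state fit did not converge after restart ladder", call. = FALSE)
  }
  cf <- stats::coef(best$fit)
  ses <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                  error = function(e) c(kd = NA_real_, rmax = NA_real_))
  kd <- unname(cf[["kd"]]); rmax <- unname(cf[["rmax"]])
  structure(list(
    kd = kd, rmax = rmax,
    se_kd = unname(ses[["kd"]]), se_rmax = unname(ses[["rmax"]]),
    points = data.frame(conc = conc, req = req,
                        fitted = ss_response(conc, kd, rmax)),
    residual_norm = sqrt(best$rss)
  ), class = "steady_state_fit")
}

#' @export
print.steady_state_fit <- function(x, ...) {
  cat(sprintf("steady-state fit: KD = %.4g M, Rmax = %.4g RU (residual norm %.3g)\n",
              x$kd, x$rmax, x$residual_norm))
  invisible(x)
}

#' Full BLI analysis pipeline
#'
#' For each sample curve: double reference subtraction, Savitzky-Golay
#' smoothing, equilibrium-plateau measurement, and per-curve rate fits;
#' then the kobs-vs-C line for kon, the averaged dissociation koff, and
#' the steady-state hyperbola for KD and Rmax.
#'
#' Reference and zero-analyte traces carry no binding signal -- only
#' slow sensor drift plus noise -- so before subtraction each is replaced
#' by a low-order polynomial drift fit over the full trace
#' (`ref_poly_degree`, default 2). Subtracting the raw traces instead
#' would double the noise variance of the corrected curve for no benefit;
#' set `ref_poly_degree = NA` to subtract them unfitted.
#'
#' The equilibrium response per curve is the mean over the last
#' `plateau_window_s` seconds of association, extrapolated to full
#' equilibrium via the fitted kobs (dividing by the model-implied mean of
#' `1 - exp(-kobs t)` over the same points); that value also anchors the
#' association fit, whose only free parameter is then kobs (iterated to
#' convergence). Set `req_mode = "free"` to fit (Req, kobs) jointly
#' instead.
#'
#' Interstep alignment ([interstep_align()]) corrects well-transfer step
#' artifacts in instrument data; it is off by default because on
#' continuous curves it only injects the noise of the boundary points
#' into the dissociation phase.
#'
#' @param set A `sensorgram_set` with matched references and zero-analyte
#'   blanks.
#' @param assoc_fit_window_s,dissoc_fit_window_s Rate-fit windows, seconds
#'   (default 20).
#' @param sg_window,sg_order Savitzky-Golay parameters for sample curves
#'   (default 11, 3).
#' @param ref_poly_degree Polynomial degree of the reference drift model
#'   (default 2); `NA` disables reference fitting.
#' @param plateau_window_s Plateau-averaging window at the end of
#'   association (default 20 s).
#' @param req_mode `"plateau"` (default) or `"free"`.
#' @param interstep Apply [interstep_align()] to corrected curves
#'   (default `FALSE`).
#' @return List of class `bli_fit` with elements `kinetic`
#'   (a `kinetic_fit`), `steady_state` (a `steady_state_fit`) and
#'   `per_curve` (data.frame of per-curve diagnostics).
#' @export
fit_bli <- function(set, assoc_fit_window_s = 20, dissoc_fit_window_s = 20,
                    sg_window = 11L, sg_order = 3L, ref_poly_degree = 2L,
                    plateau_window_s = 20, req_mode = c("plateau", "free"),
                    interstep = FALSE) {
  req_mode <- match.arg(req_mode)
  stopifnot(inherits(set, "sensorgram_set"))
  if (length(set$references) != length(set$samples)) {
    stop("need one matched reference per sample curve", call. = FALSE)
  }
  if (is.null(set$zero_sample) || is.null(set$zero_reference)) {
    stop("need zero-analyte sample and reference blanks", call. = FALSE)
  }
  smooth_ref <- function(cv) {
    if (is.na(ref_poly_degree)) return(cv)
    cv$response <- unname(stats::fitted(
      stats::lm(cv$response ~ stats::poly(cv$time_s, ref_poly_degree))))
    cv
  }
  zs <- smooth_ref(set$zero_sample)
  zr <- smooth_ref(set$zero_reference)
  rows <- vector("list", length(set$samples))
  for (i in seq_along(set$samples)) {
    cv <- double_reference_subtract(set$samples[[i]],
                                    smooth_ref(set$references[[i]]), zs, zr)
    if (interstep) cv <- interstep_align(cv)
    cv <- smooth_sensorgram(cv, window_points = sg_window, poly_order = sg_order)
    ip <- cv$time_s >= cv$dissoc_start_s - plateau_window_s &
      cv$time_s < cv$dissoc_start_s
    t_plat <- cv$time_s[ip] - cv$assoc_start_s
    plateau <- mean(cv$response[ip])
    if (req_mode == "plateau") {
      req_i <- plateau
      for (iter in 1:40) {
        fit <- fit_observed_rates(cv, assoc_fit_window_s, dissoc_fit_window_s,
                                  req = req_i)
        req_new <- plateau / mean(1 - exp(-fit$kobs * t_plat))
        done <- abs(req_new - req_i) < 1e-12 * abs(req_new)
        req_i <- req_new
        if (done) break
      }
    } else {
      fit <- fit_observed_rates(cv, assoc_fit_window_s, dissoc_fit_window_s)
      req_i <- fit$req_extrapolated
    }
    rows[[i]] <- data.frame(
      conc = cv$conc, kobs = fit$kobs, koff = fit$koff, req = req_i,
      plateau = plateau,
      assoc_rmse = fit$diagnostics$assoc_rmse,
      dissoc_rmse = fit$diagnostics$dissoc_rmse,
      se_kobs = fit$diagnostics$se_kobs,
      se_koff = fit$diagnostics$se_koff,
      koff_at_lower_bound = fit$diagnostics$koff_at_lower_bound
    )
  }
  per_curve <- do.call(rbind, c(rows, make.row.names = FALSE))
  kinetic <- derive_rate_constants(per_curve[, c("conc", "kobs")],
                                   per_curve$koff, per_curve$se_koff,
                                   per_curve$se_kobs)
  steady <- fit_steady_state(per_curve$conc, per_curve$req)
  structure(list(kinetic = kinetic, steady_state = steady,
                 per_curve = per_curve),
            class = "bli_fit")
}

#' @export
print.bli_fit <- function(x, ...) {
  print(x$kinetic)
  print(x$steady_state)
  invisible(x)
}

#' Convert a concentration to molar
#'
#' Unit discipline helper for I/O: printed affinities are only meaningful
#' with explicit units.
#'
#' @param value Numeric concentration value(s).
#' @param unit One of `"M"`, `"mM"`, `"uM"`, `"nM"`, `"pM"`.
#' @return Concentration(s) in molar.
#' @export
conc_to_molar <- function(value, unit = c("M", "mM", "uM", "nM", "pM")) {
  unit <- match.arg(unit)
  value * switch(unit, M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)
}
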