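# Chlorophyll-fluorescence, ECS/DIRK, P700, 77K-spectrum, and
# O2-electrode parameter calculators.

#' First-order exponential decay fit
#'
#' Fits `y = A exp(-t/tau) + c` by Levenberg-Marquardt least squares with
#' log-linear initialization; tau is bounded to (1e-5, 100) s.
#'
#' @param t,y trace samples (t in seconds, relative to decay start).
#' @return list of class `exp_fit`: `amplitude`, `tau`, `offset`,
#'   `residual_rms`, `at_bound` (tau pinned at an optimizer bound),
#'   `fitted`.
#' @export
fit_exponential <- function(t, y) {
  stopifnot(length(t) == length(y), length(t) >= 4L)
  if (stats::sd(y) < .Machine$double.eps^0.5 * max(1, abs(mean(y))))
    stop("flat trace: no decay to fit")
  c0 <- y[length(y)]
  a0 <- y[1L] - c0
  if (abs(a0) < 1e-12) a0 <- diff(range(y)) * sign(y[1L] - c0 + 1e-12)
  # log-linear initial tau from the early part of the decay
  z <- (y - c0) / a0
  ok <- which(z > 1e-3)
  tau0 <- if (length(ok) >= 2L) {
    sl <- stats::coef(stats::lm(log(z[ok]) ~ t[ok]))[2L]
    if (is.finite(sl) && sl < 0) -1 / sl else diff(range(t)) / 3
  } else diff(range(t)) / 3
  tau0 <- min(max(tau0, 1e-4), 50)
  span <- diff(range(t))
  try_fit <- function(tt) tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-t / tau) + c,
      start = list(A = a0, tau = tt, c = c0),
      lower = c(A = -Inf, tau = 1e-5, c = -Inf),
      upper = c(A = Inf, tau = 100, c = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  fit <- NULL
  for (tt in unique(c(tau0, span / 30, span / 10, span / 3, span))) {
    fit <- try_fit(tt)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("exponential fit failed to converge")
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  structure(list(amplitude = unname(cf["A"]), tau = unname(cf["tau"]),
                 offset = unname(cf["c"]),
                 residual_rms = sqrt(mean(res^2)),
                 at_bound = cf["tau"] <= 1.0000001e-5 ||
                   cf["tau"] >= 99.999999,
                 fitted = stats::fitted(fit)),
            class = "exp_fit")
}

#' Chlorophyll-fluorescence photosynthetic parameters
#'
#' Standard definitions from dark- and light-adapted fluorescence levels:
#' `Fv/Fm = (Fm - Fo)/Fm`, `PhiPSII = (Fm' - Fs)/Fm'`,
#' `NPQ = (Fm - Fm')/Fm'`, `qL = ((Fm' - Fs)/(Fm' - Fo')) * (Fo'/Fs)`,
#' `QA_redox = 1 - qL` (fraction of closed centers), and
#' `LEF = I * PhiPSII * psii_fraction` in relative units.
#'
#' @param fo,fm dark-adapted minimal and maximal fluorescence (Fm >= Fo >
#'   0).
#' @param fs,fm_prime,fo_prime light-adapted steady-state, maximal, and
#'   minimal fluorescence.
#' @param light actinic intensity I in umol photons m-2 s-1.
#' @param psii_fraction fraction of absorbed light reaching PSII (e.g.
#'   from [psii_fraction_77k()]).
#' @return data.frame: `fv_fm`, `phi_psii`, `npq`, `ql`, `qa_redox`,
#'   `lef`, `anomaly` (TRUE when Fm' > Fm).
#' @export
fluorescence_params <- function(fo, fm, fs, fm_prime, fo_prime, light,
                                psii_fraction = 0.5) {
  if (!(fm >= fo && fo > 0)) stop("need Fm >= Fo > 0")
  if (!(fm_prime >= fs && fs > 0)) stop("need Fm' >= Fs > 0")
  anomaly <- fm_prime > fm
  if (anomaly) warning("Fm' exceeds Fm: measurement anomaly flagged")
  phi_psii <- (fm_prime - fs) / fm_prime
  ql <- if (fm_prime > fs) ((fm_prime - fs) / (fm_prime - fo_prime)) *
    (fo_prime / fs) else 0
  data.frame(fv_fm = (fm - fo) / fm, phi_psii = phi_psii,
             npq = (fm - fm_prime) / fm_prime,
             ql = ql, qa_redox = 1 - ql,
             lef = light * phi_psii * psii_fraction,
             anomaly = anomaly)
}

#' ECS dark-interval relaxation (DIRK) analysis
#'
#' Fits a first-order exponential to the electrochromic-shift decay after
#' the light-to-dark transition. The fitted amplitude is ECSt (a proxy for
#' the transthylakoid proton motive force) and `1/tau` the proton
#' conductivity of the ATP synthase.
#'
#' @param trace an `ecs` [kinetic_trace] with `x` in seconds.
#' @param dark_start time of the light-to-dark transition (default: taken
#'   from `trace$meta$dark_start`, else the trace start).
#' @return list: `ecst`, `conductivity` (s-1), `tau`, `fit` (the
#'   [fit_exponential()] result).
#' @export
dirk_ecs <- function(trace, dark_start = NULL) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (is.null(dark_start))
    dark_start <- if (!is.null(trace$meta$dark_start))
      trace$meta$dark_start else trace$x[1L]
  sel <- trace$x >= dark_start
  if (sum(sel) < 4L) stop("dark interval too short to fit")
  t <- trace$x[sel] - dark_start
  fit <- fit_exponential(t, trace$y[sel])
  if (fit$amplitude <= 0)
    stop("dark-interval segment does not decay")
  list(ecst = fit$amplitude, conductivity = 1 / fit$tau, tau = fit$tau,
       fit = fit)
}

#' P700+ dark re-reduction time constant
#'
#' Averages replicate traces, extracts the reduction phase after far-red
#' light off, and fits `A exp(-t/tau) + c`. The time constant proxies
#' cyclic electron flow around PSI: smaller tau means faster reduction
#' and higher CEF activity. A residual RMS far above the trace noise
#' (estimated from first differences) flags a misfit, e.g. a
#' multi-exponential reduction.
#'
#' @param traces a `p700` [kinetic_trace] or list of such traces to
#'   average.
#' @param reduction_start time of far-red light off (default
#'   `meta$reduction_start`, else trace start).
#' @param misfit_factor flag threshold: residual RMS > `misfit_factor` x
#'   noise estimate.
#' @return An `exp_fit` with extra fields `misfit` and `noise_rms`.
#' @export
p700_tau <- function(traces, reduction_start = NULL, misfit_factor = 3) {
  if (inherits(traces, "kinetic_trace")) traces <- list(traces)
  x <- traces[[1L]]$x
  for (tr in traces)
    if (!isTRUE(all.equal(tr$x, x)))
      stop("traces to average must share the time base")
  y <- rowMeans(vapply(traces, `[[`, numeric(length(x)), "y"))
  if (is.null(reduction_start))
    reduction_start <- if (!is.null(traces[[1L]]$meta$reduction_start))
      traces[[1L]]$meta$reduction_start else x[1L]
  sel <- x >= reduction_start
  fit <- fit_exponential(x[sel] - reduction_start, y[sel])
  # noise floor from lag-1 differences of the residual-free signal
  noise <- stats::sd(diff(y[sel])) / sqrt(2)
  fit$noise_rms <- noise
  fit$misfit <- fit$residual_rms > misfit_factor * max(noise, 1e-12)
  fit
}

#' Relative PSII antenna fraction from a 77K emission spectrum
#'
#' Normalizes the spectrum to its value at the PSII emission maximum
#' (686 nm), takes the PSI peak as the maximum in the `psi_window`
#' (default 705-725 nm; the nominal PSI peak is 714 nm), and returns
#' `PSII% = P686 / (P686 + P_PSI) * 100` with `P686 = 1` after
#' normalization.
#'
#' @param spectrum a `spectrum77k` [kinetic_trace] with `x` in nm covering
#'   650-750 nm.
#' @param psii_nm PSII normalization wavelength.
#' @param psi_window PSI peak search window in nm.
#' @return list: `psii_percent`, `psi_peak_nm`, `psi_height` (normalized).
#' @export
psii_fraction_77k <- function(spectrum, psii_nm = 686,
                              psi_window = c(705, 725)) {
  stopifnot(inherits(spectrum, "kinetic_trace"))
  if (min(spectrum$x) > 650 || max(spectrum$x) < 750)
    stop("spectrum must cover 650-750 nm")
  p686 <- stats::approx(spectrum$x, spectrum$y, xout = psii_nm)$y
  if (!is.finite(p686) || p686 <= 0)
    stop("non-positive signal at the PSII normalization wavelength")
  y_norm <- spectrum$y / p686
  win <- spectrum$x >= psi_window[1L] & spectrum$x <= psi_window[2L]
  if (!any(win)) stop("PSI window outside spectrum range")
  psi_height <- max(y_norm[win])
  psi_nm <- spectrum$x[win][which.max(y_norm[win])]
  list(psii_percent = 100 / (1 + psi_height), psi_peak_nm = psi_nm,
       psi_height = psi_height)
}

#' Oxygen evolution and respiration rates
#'
#' From O2-electrode slopes: respiration is the magnitude of the dark
#' slope and the gross evolution rate is the net (light-phase) rate plus
#' respiration.
#'
#' @param net_slope net O2 evolution rate in the light (umol O2 mL-1 h-1,
#'   or per chlorophyll).
#' @param dark_slope O2 slope in the dark (typically negative).
#' @return data.frame: `net`, `respiration`, `gross`.
#' @export
o2_rates <- function(net_slope, dark_slope) {
  data.frame(net = net_slope, respiration = abs(dark_slope),
             gross = net_slope + abs(dark_slope))
}
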