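# Electrophysiology kinetics: bi-exponential desensitization decay with the
# amplitude-weighted time constant, single-exponential recovery from
# desensitization (two-pulse protocol), train normalization, and the
# rectification index. Times in ms, currents in pA throughout.

#' Construct a current sweep trace
#'
#' @param time Uniformly sampled time grid (ms), strictly increasing.
#' @param current Current per sample (pA).
#' @param protocol Data frame of stimulus pulses with columns `onset` and
#'   `duration` (ms).
#' @param baseline_window Length-2 ms range used for baseline estimation;
#'   default the pre-stimulus span.
#' @return Object of class `sweep_trace`.
#' @export
sweep_trace <- function(time, current, protocol, baseline_window = NULL) {
  stopifnot(length(time) == length(current), length(time) >= 2L)
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) stop("sampling must be uniform")
  protocol <- as.data.frame(protocol)
  stopifnot(all(c("onset", "duration") %in% names(protocol)))
  if (is.null(baseline_window)) {
    baseline_window <- c(time[1], max(time[1], min(protocol$onset) - 1e-9))
  }
  structure(list(time = time, current = current, protocol = protocol,
                 baseline_window = baseline_window),
            class = "sweep_trace")
}

#' @export
print.sweep_trace <- function(x, ...) {
  cat("<sweep_trace> ", length(x$time), " samples, ",
      sprintf("%.3f", x$time[2] - x$time[1]), " ms/sample, ",
      nrow(x$protocol), " pulse(s)\n", sep = "")
  invisible(x)
}

#' Read a sweep trace from CSV
#'
#' @param path CSV with columns `time_ms`, `current_pA`.
#' @param protocol Stimulus protocol data frame (`onset`, `duration` in ms).
#' @param baseline_window Optional baseline ms range.
#' @return A [sweep_trace()].
#' @export
read_sweep_csv <- function(path, protocol, baseline_window = NULL) {
  tbl <- utils::read.csv(path)
  stopifnot(all(c("time_ms", "current_pA") %in% names(tbl)))
  sweep_trace(tbl$time_ms, tbl$current_pA, protocol, baseline_window)
}

#' Amplitude-weighted desensitization time constant
#'
#' tau_w = tau_f * Af / (Af + As) + tau_s * As / (Af + As): the convex
#' combination of fast and slow time constants weighted by their fit
#' amplitudes, the summary reported for bi-exponential decays.
#'
#' @param tau_f,tau_s Fast and slow time constants (ms, > 0).
#' @param A_f,A_s Fast and slow amplitudes (same sign).
#' @return Weighted time constant (ms).
#' @export
weighted_tau <- function(tau_f, A_f, tau_s, A_s) {
  if (any(c(tau_f, tau_s) <= 0)) stop("time constants must be positive")
  tot <- A_f + A_s
  if (any(tot == 0)) stop("zero total amplitude")
  tau_f * (A_f / tot) + tau_s * (A_s / tot)
}

baseline_stats <- function(trace) {
  sel <- trace$time >= trace$baseline_window[1] &
    trace$time <= trace$baseline_window[2]
  if (!any(sel)) sel <- seq_along(trace$time) <= 5L
  list(mean = mean(trace$current[sel]), sd = stats::sd(trace$current[sel]))
}

# peak of the baseline-subtracted current inside a pulse window; sign from
# the larger |extremum|
find_peak <- function(trace, onset, duration, baseline) {
  sel <- which(trace$time >= onset & trace$time <= onset + duration)
  if (!length(sel)) stop("pulse window outside the sampled trace")
  y <- trace$current[sel] - baseline
  i_ext <- sel[which.max(abs(y))]
  list(index = i_ext, value = trace$current[i_ext] - baseline)
}

sum_of_exponentials <- function(t, pars, n_comp) {
  y <- pars[["C"]]
  for (i in seq_len(n_comp)) {
    y <- y + pars[[paste0("A", i)]] * exp(-t / pars[[paste0("tau", i)]])
  }
  y
}

fit_exponentials <- function(t, y, n_comp, starts) {
  best <- NULL
  for (s in starts) {
    lower <- c(rep(-Inf, n_comp), rep(1e-6, n_comp), -Inf)
    upper <- rep(Inf, 2 * n_comp + 1)
    names(s) <- c(paste0("A", seq_len(n_comp)), paste0("tau", seq_len(n_comp)), "C")
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lower, upper = upper,
                         fn = function(p) {
                           p <- as.list(p)
                           y - sum_of_exponentials(t, p, n_comp)
                         },
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("exponential fit did not converge")
  best
}

#' Fit desensitization decay
#'
#' Fits the current decay during an agonist pulse with one or two
#' exponentials plus a steady-state offset. The fit window starts at the
#' first sample after the peak where the baseline-subtracted current has
#' fallen to 90% of the peak, and ends at the pulse end. The peak must
#' exceed 5x the baseline noise SD. For bi-exponential fits the components
#' are ordered tau_f <= tau_s and the weighted tau is reported; three
#' deterministic starts guard against the bi-exponential identifiability
#' trap.
#'
#' @param trace A [sweep_trace()].
#' @param n_components 1 or 2.
#' @param pulse Row index into the trace protocol (default first pulse).
#' @return Object of class `decay_fit`: `tau_f`, `tau_s`, `A_f`, `A_s`
#'   (pA), `tau_w` (ms), `n_components`, `fit_window`, `residual_rms` (pA),
#'   `baseline`, `peak`.
#' @export
fit_decay <- function(trace, n_components = 2L, pulse = 1L) {
  stopifnot(inherits(trace, "sweep_trace"), n_components %in% c(1L, 2L))
  bl <- baseline_stats(trace)
  on <- trace$protocol$onset[pulse]
  dur <- trace$protocol$duration[pulse]
  pk <- find_peak(trace, on, dur, bl$mean)
  noise_floor <- max(bl$sd, 1e-12)
  if (abs(pk$value) < 5 * noise_floor) {
    stop("no detectable peak: |peak| = ", signif(abs(pk$value), 3),
         " pA < 5 x baseline SD")
  }
  after_peak <- which(seq_along(trace$time) > pk$index &
                        trace$time <= on + dur)
  y_rel <- abs(trace$current[after_peak] - bl$mean)
  start_i <- after_peak[which(y_rel <= 0.9 * abs(pk$value))[1]]
  if (is.na(start_i)) stop("decay never falls to 90% of peak inside the pulse")
  # strictly inside the pulse: the sample at pulse-off belongs to deactivation
  win <- which(seq_along(trace$time) >= start_i & trace$time < on + dur - 1e-9)
  t <- trace$time[win] - trace$time[win[1]]
  y <- trace$current[win] - bl$mean
  span <- max(t)
  amp0 <- y[1]
  # start vectors ordered (A1..An, tau1..taun, C)
  starts <- if (n_components == 1L) {
    list(c(amp0, 0.3 * span, 0), c(amp0, 0.05 * span, 0),
         c(0.5 * amp0, 0.1 * span, 0.2 * amp0))
  } else {
    list(c(0.6 * amp0, 0.4 * amp0, 0.1 * span, span, 0),
         c(0.8 * amp0, 0.2 * amp0, 0.03 * span, 0.5 * span, 0),
         c(0.4 * amp0, 0.4 * amp0, 0.2 * span, 2 * span, 0.1 * amp0))
  }
  best <- fit_exponentials(t, y, n_components, starts)
  p <- as.list(best$fit$par)
  if (n_components == 1L) {
    tau_f <- tau_s <- p$tau1
    A_f <- p$A1; A_s <- 0
    tau_w <- p$tau1
  } else {
    ord <- order(c(p$tau1, p$tau2))
    taus <- c(p$tau1, p$tau2)[ord]
    amps <- c(p$A1, p$A2)[ord]
    tau_f <- taus[1]; tau_s <- taus[2]
    A_f <- amps[1]; A_s <- amps[2]
    tau_w <- weighted_tau(tau_f, A_f, tau_s, A_s)
  }
  structure(list(tau_f = tau_f, tau_s = tau_s, A_f = A_f, A_s = A_s,
                 tau_w = tau_w, n_components = n_components,
                 fit_window = range(trace$time[win]),
                 residual_rms = sqrt(mean(best$fit$fvec^2)),
                 baseline = bl$mean, peak = pk$value,
                 steady_state = p$C), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$n_components == 2L) {
    cat(sprintf("<decay_fit> bi-exponential: tau_f = %.3g ms, tau_s = %.3g ms, tau_w = %.3g ms\n",
                x$tau_f, x$tau_s, x$tau_w))
  } else {
    cat(sprintf("<decay_fit> mono-exponential: tau = %.3g ms\n", x$tau_w))
  }
  invisible(x)
}

#' Fit recovery from desensitization
#'
#' Fits ratio(t) = 1 - (1 - r0) * exp(-t / tau_rec) to second/first peak
#' ratios from a two-pulse protocol, by bounded least squares with three
#' deterministic starts. The intercept r0 is fitted (bounded [0, 1)) rather
#' than pinned to a steady-state estimate.
#'
#' @param pairs Data frame with columns `interval` (ms) and `ratio`, >= 4
#'   rows.
#' @return Object of class `recovery_fit`: `tau_rec` (ms), `r0`,
#'   `residual_rms`, `pairs`.
#' @export
fit_recovery <- function(pairs) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("interval", "ratio") %in% names(pairs)))
  if (nrow(pairs) < 4L) stop("need >= 4 (interval, ratio) points")
  if (all(abs(pairs$ratio - 1) < 0.02)) {
    stop("degenerate recovery data: all ratios ~ 1 (already recovered)")
  }
  t <- pairs$interval; y <- pairs$ratio
  span <- max(t)
  model <- function(p) y - (1 - (1 - p[["r0"]]) * exp(-t / p[["tau"]]))
  best <- NULL
  for (s in list(c(r0 = 0.05, tau = 0.3 * span),
                 c(r0 = max(0, min(y) * 0.9), tau = 0.1 * span),
                 c(r0 = 0.2, tau = span))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = c(0, 1e-6), upper = c(1 - 1e-9, Inf),
                         fn = model,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("recovery fit did not converge")
  p <- best$fit$par
  structure(list(tau_rec = p[["tau"]], r0 = p[["r0"]],
                 residual_rms = sqrt(mean(best$fit$fvec^2)),
                 pairs = pairs), class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf("<recovery_fit> tau_rec = %.3g ms (r0 = %.3f, n = %d intervals)\n",
              x$tau_rec, x$r0, nrow(x$pairs)))
  invisible(x)
}

#' Normalize peak amplitudes to the first response in a train
#'
#' Divides each peak by the first, the paired-pulse normalization used for
#' trains of synaptic stimulation (e.g. 20 Hz).
#'
#' @param peaks Numeric vector of peak currents (pA), >= 2 entries; first
#'   peak nonzero.
#' @param stim_freq Stimulation frequency (Hz); recorded for provenance.
#' @return Numeric vector with first entry 1.
#' @export
ppf_normalize <- function(peaks, stim_freq = 20) {
  if (length(peaks) < 2L) stop("need >= 2 peaks in the train")
  if (peaks[1] == 0) stop("first peak is zero: normalization undefined")
  out <- peaks / peaks[1]
  attr(out, "stim_freq_hz") <- stim_freq
  out
}

#' Rectification index
#'
#' RI = -(I_plus40 - I_0) / (I_minus60 - I_0), from currents at -60, 0 and
#' +40 mV holding potentials. An ohmic (linear, non-rectifying) I-V through
#' the origin gives 40/60 = 2/3; RI = 0 indicates complete inward
#' rectification.
#'
#' @param i_minus60,i_0,i_plus40 Currents (pA) at the three potentials.
#' @return Rectification index.
#' @export
rectification_index <- function(i_minus60, i_0, i_plus40) {
  denom <- i_minus60 - i_0
  if (any(denom == 0)) stop("I(-60) equals I(0): rectification index undefined")
  -(i_plus40 - i_0) / denom
}
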