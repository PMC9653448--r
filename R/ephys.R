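# Intrinsic electrophysiology feature extraction from current-clamp step
# protocols.  Voltages in mV, times in ms, currents in pA, resistances in
# MOhm throughout.

# Savitzky-Golay smoothing with a window given in ms; returns x unchanged
# when the window is too short to fit a cubic.
.sgSmooth <- function(x, dt, smooth_ms, order = 3) {
  if (is.null(smooth_ms) || smooth_ms <= 0) return(x)
  n <- floor(smooth_ms / dt)
  if (n %% 2 == 0) n <- n + 1
  if (n < order + 2 || n > length(x)) return(x)
  as.numeric(signal::sgolayfilt(x, p = order, n = n))
}

# Third derivative by three successive central differences with step
# k samples (combined stencil over +/- 3k samples), in mV/ms^3.  A wider
# step trades bandwidth for noise suppression (the stencil noise gain
# scales as 1/(k*dt)^3).  Ends are padded with NA.
.thirdDerivative <- function(x, dt, k = 1L) {
  n <- length(x)
  d3 <- rep(NA_real_, n)
  if (n >= 6 * k + 1) {
    i <- (3 * k + 1):(n - 3 * k)
    d3[i] <- (x[i + 3 * k] - 3 * x[i + k] + 3 * x[i - k] - x[i - 3 * k]) /
      (8 * (k * dt)^3)
  }
  d3
}

# High-frequency noise estimate: sd of the first difference / sqrt(2),
# which is insensitive to slow signal components.
.noiseEstimate <- function(x) {
  if (length(x) < 10) return(0)
  stats::sd(diff(x)) / sqrt(2)
}

# Sub-sample refinement: parabola through (i-1, i, i+1) of y; returns the
# fractional offset of the vertex in [-0.5, 0.5] (0 when degenerate).
.parabolicVertex <- function(y, i) {
  if (i <= 1 || i >= length(y) || anyNA(y[(i - 1):(i + 1)])) return(0)
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom == 0) return(0)
  d <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  max(min(d, 0.5), -0.5)
}

.interpAt <- function(x, frac_index) {
  i <- floor(frac_index)
  f <- frac_index - i
  if (i >= length(x)) return(x[length(x)])
  if (i < 1) return(x[1])
  x[i] * (1 - f) + x[min(i + 1, length(x))] * f
}

#' Detect action potentials in a voltage sweep
#'
#' Local maxima exceeding an absolute voltage level and a minimum
#' prominence, restricted to the stimulus window.  Prominence of a peak is
#' its height above the higher of the two minima separating it from the
#' nearest higher terrain (or the window edge).
#'
#' @param v numeric voltage trace (mV).
#' @param dt sampling interval (ms).
#' @param onset_ms,offset_ms stimulus window; only peaks inside it count.
#' @param min_height_mV absolute level a peak must exceed (default -20).
#' @param min_prominence_mV minimum prominence (default 20).
#' @return integer vector of peak sample indices (strictly increasing;
#'   empty when no AP is found).
#' @export
detectActionPotentials <- function(v, dt, onset_ms = 0,
                                   offset_ms = (length(v) - 1) * dt,
                                   min_height_mV = -20,
                                   min_prominence_mV = 20,
                                   smooth_ms = 0.3) {
  v <- .sgSmooth(v, dt, smooth_ms)
  n <- length(v)
  t <- (seq_len(n) - 1) * dt
  cand <- which(v > min_height_mV &
                  t >= onset_ms & t <= offset_ms)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[v[cand] >= v[cand - 1] & v[cand] > v[cand + 1]]
  if (!length(cand)) return(integer(0))
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    h <- v[i]
    j <- i
    left_min <- h
    while (j > 1 && v[j] <= h) {
      j <- j - 1
      left_min <- min(left_min, v[j])
    }
    j <- i
    right_min <- h
    while (j < n && v[j] <= h) {
      j <- j + 1
      right_min <- min(right_min, v[j])
    }
    keep[k] <- (h - max(left_min, right_min)) >= min_prominence_mV
  }
  cand <- cand[keep]
  # collapse runs of equal-height neighbouring candidates to the first
  if (length(cand) > 1) {
    cand <- cand[c(TRUE, diff(cand) > 1 | diff(v[cand]) != 0)]
  }
  cand
}

# Sub-sample spike times from the rising-edge crossing at a fixed drop
# below each peak.  The upstroke is the steepest part of the waveform, so
# the crossing time is far more stable under noise than the flat spike
# top; with identical AP waveforms the constant peak-to-crossing offset
# cancels in inter-spike intervals.
.spikeEdgeTimes <- function(v, dt, peaks, smooth_ms = 0.3) {
  sm <- .sgSmooth(v, dt, smooth_ms)
  vapply(peaks, function(i) {
    lo <- max(1L, i - round(3 / dt))
    base <- min(sm[lo:i])
    level <- sm[i] - 0.4 * (sm[i] - base)
    j <- i
    while (j > lo && sm[j - 1] >= level) j <- j - 1
    if (j == lo || sm[j] == sm[j - 1]) return((i - 1) * dt)
    frac <- (level - sm[j - 1]) / (sm[j] - sm[j - 1])
    (j - 2 + frac) * dt
  }, 0)
}

#' Action-potential threshold via the third-derivative criterion
#'
#' The threshold is the point of maximal third time-derivative of voltage
#' within the 20 ms preceding the AP peak: the onset of the upstroke's
#' acceleration.  The trace is optionally Savitzky-Golay smoothed first;
#' the third derivative is computed by three successive central finite
#' differences, and the argmax is refined to sub-sample precision by
#' parabolic interpolation.  The search window is truncated at the trace
#' start, and at \code{lower_bound_ms} (typically the stimulus onset plus a
#' small margin) to keep the square-pulse onset transient out of the
#' derivative window.
#'
#' @param v,dt voltage trace (mV) and sampling interval (ms).
#' @param peak_index sample index of the AP peak.
#' @param window_ms pre-peak search window (default 20 ms).
#' @param smooth_ms Savitzky-Golay window (0 disables; default 0.3 ms).
#' @param lower_bound_ms optional absolute lower bound of the window (ms).
#' @param deriv_step_ms step of the finite-difference stencil; NULL (the
#'   default) selects it from the measured high-frequency noise of the
#'   window: one sample on clean traces (maximal bandwidth), 0.1 ms on
#'   noisy ones (the wider stencil suppresses noise amplification by the
#'   third difference).
#' @return list with \code{voltage} (mV), \code{index} (nearest sample),
#'   \code{frac_index}, \code{time_ms}.
#' @export
apThreshold <- function(v, dt, peak_index, window_ms = 20, smooth_ms = 0.3,
                        lower_bound_ms = NULL, deriv_step_ms = NULL) {
  lo <- max(1L, peak_index - round(window_ms / dt))
  if (!is.null(lower_bound_ms)) {
    lo <- max(lo, floor(lower_bound_ms / dt) + 1L)
  }
  hi <- peak_index - 1L
  if (hi - lo + 1L < 3L) stop("not enough samples before the AP peak")
  # pad the segment so smoothing and the stencil stay valid near hi
  pad <- min(length(v), peak_index + round(2 / dt))
  raw <- v[lo:pad]
  seg <- .sgSmooth(raw, dt, smooth_ms)
  if (is.null(deriv_step_ms)) {
    # judge noise on the early window, away from the spike itself
    early <- seq_len(max(10L, floor(length(raw) * 0.5)))
    deriv_step_ms <- if (.noiseEstimate(raw[early]) > 0.01) 0.1 else dt
  }
  k <- max(1L, round(deriv_step_ms / dt))
  d3 <- .thirdDerivative(seg, dt, k = k)
  valid <- seq_len(hi - lo + 1L)
  d3v <- d3[valid]
  if (all(is.na(d3v))) stop("third derivative undefined on the window")
  i <- which.max(d3v)
  delta <- .parabolicVertex(d3, i)
  frac <- (lo - 1L) + i + delta
  list(voltage = .interpAt(seg, i + delta), index = lo - 1L + i,
       frac_index = frac, time_ms = (frac - 1) * dt)
}

#' Waveform features of a single action potential
#'
#' Amplitude is peak minus threshold voltage; width is the duration at the
#' voltage halfway between threshold and peak (crossings located by linear
#' interpolation); rising time runs from threshold to peak, decay time from
#' peak back down to the threshold voltage; the AHP is the threshold
#' voltage minus the minimum of the trough after the AP, searched up to
#' \code{bound_index} (the next AP or the stimulus offset).  The peak and
#' the trough are refined to sub-sample precision.
#'
#' @inheritParams apThreshold
#' @param threshold result of [apThreshold()] for this AP.
#' @param bound_index last sample of the post-AP search range.
#' @param smooth_ms Savitzky-Golay window applied to the analysed segment.
#' @return list with \code{amplitude_mV}, \code{width_ms},
#'   \code{rising_time_ms}, \code{decay_time_ms}, \code{ahp_mV},
#'   \code{peak_mV}, \code{peak_time_ms}, and availability flags
#'   \code{decay_available}, \code{ahp_available}.
#' @export
apWaveformFeatures <- function(v, dt, peak_index, threshold,
                               bound_index = length(v), smooth_ms = 0.3) {
  stopifnot(threshold$frac_index < peak_index)
  lo <- max(1L, floor(threshold$frac_index) - 3L)
  hi <- min(length(v), bound_index)
  seg <- .sgSmooth(v[lo:hi], dt, smooth_ms)
  p <- peak_index - lo + 1L
  pd <- .parabolicVertex(seg, p)
  peak_frac <- p + pd
  # parabolic vertex height: more accurate than the raw sample maximum
  peak_v <- if (pd != 0) seg[p] - 0.25 * (seg[p - 1] - seg[p + 1]) * pd
    else seg[p]
  thr_v <- threshold$voltage
  thr_frac <- threshold$frac_index - lo + 1
  amp <- peak_v - thr_v
  half <- thr_v + amp / 2

  crossUp <- function(level, from, to) {
    idx <- seq(max(ceiling(from), 1L), floor(to))
    below <- which(seg[idx] < level & c(seg[idx[-1]], Inf) >= level)
    if (!length(below)) return(NA_real_)
    i <- idx[below[length(below)]]  # last upward crossing before the peak
    i + (level - seg[i]) / (seg[i + 1] - seg[i])
  }
  crossDown <- function(level, from, to) {
    idx <- seq(ceiling(from), min(floor(to), length(seg) - 1L))
    above <- which(seg[idx] > level & seg[idx + 1] <= level)
    if (!length(above)) return(NA_real_)
    i <- idx[above[1]]
    i + (seg[i] - level) / (seg[i] - seg[i + 1])
  }
  rise_cross <- crossUp(half, thr_frac, peak_frac)
  fall_cross <- crossDown(half, peak_frac, length(seg))
  width <- if (is.na(rise_cross) || is.na(fall_cross)) NA_real_ else
    (fall_cross - rise_cross) * dt

  rising <- (peak_frac - thr_frac) * dt
  decay_cross <- crossDown(thr_v, peak_frac, length(seg))
  decay_available <- !is.na(decay_cross)
  decay <- if (decay_available) (decay_cross - peak_frac) * dt else NA_real_

  ahp_available <- decay_available
  ahp <- NA_real_
  if (ahp_available) {
    tr_idx <- seq(ceiling(decay_cross), length(seg))
    if (length(tr_idx) >= 2) {
      j <- tr_idx[which.min(seg[tr_idx])]
      jd <- .parabolicVertex(seg, j)
      trough_v <- if (jd != 0) seg[j] - 0.25 * (seg[j - 1] - seg[j + 1]) * jd
        else seg[j]
      ahp <- thr_v - trough_v
    } else {
      ahp_available <- FALSE
    }
  }
  list(amplitude_mV = amp, width_ms = width, rising_time_ms = rising,
       decay_time_ms = decay, ahp_mV = ahp, peak_mV = peak_v,
       peak_time_ms = (lo - 1 + peak_frac - 1) * dt,
       decay_available = decay_available, ahp_available = ahp_available)
}

#' Rheobase and spike delay
#'
#' Rheobase is the minimum injected current among sweeps that elicit at
#' least one action potential; the spike delay is the time from stimulus
#' onset to the threshold of the first AP on that sweep.
#'
#' @param sweeps a [SweepSet-class].
#' @param detect list of arguments passed to [detectActionPotentials()].
#' @param smooth_ms Savitzky-Golay window for threshold extraction.
#' @return list with \code{rheobase_pA}, \code{spike_delay_ms},
#'   \code{sweep_id}, \code{available}; unavailable (all NA) when no sweep
#'   spikes.
#' @export
rheobaseAndDelay <- function(sweeps, detect = list(), smooth_ms = 0.3) {
  p <- sweepProtocol(sweeps)
  v <- sweepVoltages(sweeps)
  dt <- samplingInterval(sweeps)
  spiking <- list()
  for (i in order(p$current_pA)) {
    peaks <- do.call(detectActionPotentials,
                     c(list(v = v[, i], dt = dt, onset_ms = p$onset_ms[i],
                            offset_ms = p$offset_ms[i]), detect))
    if (length(peaks)) {
      spiking <- list(i = i, peaks = peaks)
      break
    }
  }
  if (!length(spiking)) {
    return(list(rheobase_pA = NA_real_, spike_delay_ms = NA_real_,
                sweep_id = NA_character_, available = FALSE))
  }
  i <- spiking$i
  thr <- apThreshold(v[, i], dt, spiking$peaks[1], smooth_ms = smooth_ms,
                     lower_bound_ms = p$onset_ms[i] + max(smooth_ms, 0.5))
  list(rheobase_pA = p$current_pA[i],
       spike_delay_ms = thr$time_ms - p$onset_ms[i],
       sweep_id = p$sweep_id[i], available = TRUE)
}

#' Passive membrane features from hyperpolarizing sweeps
#'
#' RMP is the mean voltage over the 100 ms (or all available samples)
#' preceding stimulus onset.  Steady state per sweep is the mean over the
#' last 100 ms before stimulus offset.  Input resistance is the median over
#' hyperpolarizing sweeps of the steady-state deflection divided by the
#' injected current (mV/pA = GOhm, reported in MOhm).  On the sweep with
#' the maximal negative current: the sag ratio is (trough - RMP) /
#' (steady state - RMP); tau is the time constant of a single-exponential
#' fit from stimulus onset to the minimum within the first half of the
#' stimulus; the rebound is the maximum of an exponential fit from stimulus
#' offset to the peak of the post-offset depolarization, minus RMP.
#'
#' @param sweeps a [SweepSet-class].
#' @param rmp_window_ms pre-stimulus window for the RMP (default 100).
#' @param ss_window_ms steady-state window before offset (default 100).
#' @return list with \code{rmp_mV}, \code{sag_ratio}, \code{rebound_mV},
#'   \code{tau_ms}, \code{input_resistance_MOhm}, per-feature availability
#'   flags, and \code{fits} diagnostics.
#' @export
passiveMembraneFeatures <- function(sweeps, rmp_window_ms = 100,
                                    ss_window_ms = 100) {
  p <- sweepProtocol(sweeps)
  v <- sweepVoltages(sweeps)
  dt <- samplingInterval(sweeps)
  t <- sweepTimes(sweeps)
  hyper <- which(p$current_pA < 0)
  na_out <- list(rmp_mV = NA_real_, sag_ratio = NA_real_,
                 rebound_mV = NA_real_, tau_ms = NA_real_,
                 input_resistance_MOhm = NA_real_,
                 available = c(rmp = FALSE, sag = FALSE, rebound = FALSE,
                               tau = FALSE, input_resistance = FALSE),
                 fits = list())
  if (!length(hyper)) return(na_out)

  rmp_per_sweep <- vapply(hyper, function(i) {
    w <- t >= p$onset_ms[i] - rmp_window_ms & t < p$onset_ms[i]
    mean(v[w, i])
  }, 0)
  rmp <- mean(rmp_per_sweep)

  ss <- vapply(hyper, function(i) {
    w <- t >= p$offset_ms[i] - ss_window_ms & t < p$offset_ms[i]
    mean(v[w, i])
  }, 0)
  ir <- stats::median((ss - rmp_per_sweep) / p$current_pA[hyper]) * 1000

  i_max <- hyper[which.min(p$current_pA[hyper])]
  ss_max <- ss[match(i_max, hyper)]
  stim <- t >= p$onset_ms[i_max] & t <= p$offset_ms[i_max]
  # on noisy traces locate extrema on a smoothed copy (passive responses
  # are slow, so a 2 ms window costs no bandwidth); on clean traces use
  # the raw samples, which are exact
  pre <- v[t < p$onset_ms[i_max], i_max]
  vloc <- if (.noiseEstimate(pre) > 0.01) {
    .sgSmooth(v[, i_max], dt, 2)
  } else {
    v[, i_max]
  }
  trough <- min(vloc[stim])
  sag <- (trough - rmp) / (ss_max - rmp)

  fits <- list()
  # tau: fit onset -> minimum within the first half of the stimulus
  half_end <- p$onset_ms[i_max] +
    (p$offset_ms[i_max] - p$onset_ms[i_max]) / 2
  w1 <- which(t >= p$onset_ms[i_max] & t <= half_end)
  j_min <- w1[which.min(vloc[w1])]
  fit_tau <- .fitExponential(t[w1[1]:j_min] - t[w1[1]],
                             v[w1[1]:j_min, i_max])
  fits$tau <- fit_tau
  tau <- if (fit_tau$converged) fit_tau$tau else NA_real_

  # rebound: fit offset -> post-offset peak; rebound = max(fit) - RMP
  w2 <- which(t >= p$offset_ms[i_max])
  j_pk <- w2[which.max(vloc[w2])]
  rebound <- NA_real_
  rebound_available <- FALSE
  if (j_pk > w2[1] + 5) {
    fit_reb <- .fitExponential(t[w2[1]:j_pk] - t[w2[1]],
                               v[w2[1]:j_pk, i_max])
    fits$rebound <- fit_reb
    if (fit_reb$converged) {
      tt <- t[w2[1]:j_pk] - t[w2[1]]
      rebound <- max(fit_reb$a + fit_reb$b * exp(-tt / fit_reb$tau)) - rmp
      rebound_available <- TRUE
    }
  } else {
    # no depolarizing hump after offset: rebound is the (tiny) excess of
    # the post-offset maximum over RMP
    rebound <- v[j_pk, i_max] - rmp
    rebound_available <- TRUE
  }

  list(rmp_mV = rmp, sag_ratio = sag, rebound_mV = rebound, tau_ms = tau,
       input_resistance_MOhm = ir,
       available = c(rmp = TRUE, sag = TRUE, rebound = rebound_available,
                     tau = is.finite(tau), input_resistance = TRUE),
       fits = fits)
}

# Single-exponential least squares y ~ a + b * exp(-x / tau), initialized
# from the 63% crossing and a linearized regression.
.fitExponential <- function(x, y, tol = 1e-8, maxiter = 500) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  y0 <- y[1]
  yend <- y[length(y)]
  target <- y0 + 0.632 * (yend - y0)
  cross <- if (yend < y0) which(y <= target) else which(y >= target)
  tau0 <- if (length(cross)) max(x[cross[1]], x[2]) else
    max(x[length(x)] / 3, x[2])
  base <- exp(-x / tau0)
  lin <- stats::lm(y ~ base)
  fit <- try(minpack.lm::nlsLM(
    y ~ a + b * exp(-x / tau),
    start = list(a = coef(lin)[[1]], b = coef(lin)[[2]], tau = tau0),
    lower = c(-Inf, -Inf, x[2] / 10),
    control = minpack.lm::nls.lm.control(ftol = tol, maxiter = maxiter)),
    silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(list(converged = FALSE, error = as.character(fit)))
  }
  cf <- coef(fit)
  list(converged = TRUE, a = cf[["a"]], b = cf[["b"]], tau = cf[["tau"]],
       rss = sum(stats::residuals(fit)^2))
}

#' Adaptive index of a spike train
#'
#' Ratio of the last to the first inter-spike interval; needs at least
#' three spikes (two ISIs).
#'
#' @param spike_times_ms spike times in ms.
#' @return list with \code{adaptive_index}, \code{isis_ms},
#'   \code{available}.
#' @export
adaptiveIndex <- function(spike_times_ms) {
  if (length(spike_times_ms) < 3L) {
    return(list(adaptive_index = NA_real_, isis_ms = diff(spike_times_ms),
                available = FALSE))
  }
  isis <- diff(sort(spike_times_ms))
  if (any(isis <= 0)) stop("spike times must be strictly increasing")
  list(adaptive_index = isis[length(isis)] / isis[1], isis_ms = isis,
       available = TRUE)
}

#' Extract the full electrophysiological feature record for one cell
#'
#' Assembles the fourteen features from a step-protocol [SweepSet-class]:
#' AP shape features are computed on the first AP of the rheobase sweep;
#' passive features on the hyperpolarizing sweeps; the adaptive index on
#' the lowest-current sweep with at least three spikes (configurable).
#' Features that cannot be computed are flagged unavailable, never silently
#' zero.
#'
#' @param sweeps a [SweepSet-class].
#' @param smooth_ms Savitzky-Golay window for AP analysis (default 0.3 ms).
#' @param detect arguments for [detectActionPotentials()].
#' @param adaptive_sweep sweep id to use for the adaptive index, or NULL
#'   for the default rule (lowest current with >= 3 spikes).
#' @return an [EphysFeatures-class].
#' @examples
#' ss <- simulateSweepSet(seed = 1)
#' featureValues(extractFeatureTable(ss$sweeps))
#' @export
extractFeatureTable <- function(sweeps, smooth_ms = 0.3, detect = list(),
                                adaptive_sweep = NULL) {
  p <- sweepProtocol(sweeps)
  v <- sweepVoltages(sweeps)
  dt <- samplingInterval(sweeps)
  vals <- stats::setNames(rep(NA_real_, length(.EPHYS_FEATURES)),
                          .EPHYS_FEATURES)
  avail <- stats::setNames(rep(FALSE, length(.EPHYS_FEATURES)),
                           .EPHYS_FEATURES)
  details <- list()

  passive <- passiveMembraneFeatures(sweeps)
  for (nm in c("rmp_mV", "sag_ratio", "rebound_mV", "tau_ms",
               "input_resistance_MOhm")) {
    key <- c(rmp_mV = "rmp", sag_ratio = "sag", rebound_mV = "rebound",
             tau_ms = "tau", input_resistance_MOhm = "input_resistance")[[nm]]
    if (isTRUE(passive$available[[key]])) {
      vals[nm] <- passive[[nm]]
      avail[nm] <- TRUE
    }
  }
  details$passive_fits <- passive$fits

  # spike detection per depolarizing sweep
  depol <- which(p$current_pA > 0)
  peaks_by_sweep <- lapply(depol, function(i) {
    do.call(detectActionPotentials,
            c(list(v = v[, i], dt = dt, onset_ms = p$onset_ms[i],
                   offset_ms = p$offset_ms[i]), detect))
  })
  names(peaks_by_sweep) <- p$sweep_id[depol]
  details$n_spikes <- lengths(peaks_by_sweep)

  spiking <- depol[lengths(peaks_by_sweep) > 0]
  if (length(spiking)) {
    i_rheo <- spiking[which.min(p$current_pA[spiking])]
    peaks <- peaks_by_sweep[[p$sweep_id[i_rheo]]]
    vals["rheobase_pA"] <- p$current_pA[i_rheo]
    avail["rheobase_pA"] <- TRUE
    details$rheobase_sweep <- p$sweep_id[i_rheo]

    thr <- try(apThreshold(
      v[, i_rheo], dt, peaks[1], smooth_ms = smooth_ms,
      lower_bound_ms = p$onset_ms[i_rheo] + max(smooth_ms, 0.5)),
      silent = TRUE)
    if (!inherits(thr, "try-error")) {
      vals["ap_threshold_mV"] <- thr$voltage
      avail["ap_threshold_mV"] <- TRUE
      vals["spike_delay_ms"] <- thr$time_ms - p$onset_ms[i_rheo]
      avail["spike_delay_ms"] <- TRUE
      bound <- if (length(peaks) > 1) peaks[2] - round(1 / dt) else
        min(length(v[, i_rheo]), floor(p$offset_ms[i_rheo] / dt) + 1L)
      wf <- apWaveformFeatures(v[, i_rheo], dt, peaks[1], thr,
                               bound_index = bound, smooth_ms = smooth_ms)
      vals["ap_amplitude_mV"] <- wf$amplitude_mV
      avail["ap_amplitude_mV"] <- TRUE
      if (!is.na(wf$width_ms)) {
        vals["ap_width_ms"] <- wf$width_ms
        avail["ap_width_ms"] <- TRUE
      }
      vals["ap_rising_time_ms"] <- wf$rising_time_ms
      avail["ap_rising_time_ms"] <- TRUE
      if (wf$decay_available) {
        vals["ap_decay_time_ms"] <- wf$decay_time_ms
        avail["ap_decay_time_ms"] <- TRUE
      }
      if (wf$ahp_available) {
        vals["ahp_mV"] <- wf$ahp_mV
        avail["ahp_mV"] <- TRUE
      }
      details$first_ap <- wf
    }
  }

  # adaptive index: lowest-current sweep with >= 3 spikes unless overridden
  cand <- depol[lengths(peaks_by_sweep) >= 3]
  if (!is.null(adaptive_sweep)) {
    cand <- which(p$sweep_id == adaptive_sweep)
    if (!length(cand) || length(peaks_by_sweep[[adaptive_sweep]]) < 3) {
      cand <- integer(0)
    }
  }
  if (length(cand)) {
    i_ad <- cand[which.min(p$current_pA[cand])]
    edge <- .spikeEdgeTimes(v[, i_ad], dt,
                            peaks_by_sweep[[p$sweep_id[i_ad]]],
                            smooth_ms = smooth_ms)
    # report ISIs at the recording's sampling resolution
    times <- edge[1] + cumsum(c(0, round(diff(edge) / dt) * dt))
    ad <- adaptiveIndex(times)
    vals["adaptive_index"] <- ad$adaptive_index
    avail["adaptive_index"] <- TRUE
    details$adaptive_sweep <- p$sweep_id[i_ad]
    details$isis_ms <- ad$isis_ms
  }

  vals[!avail] <- NA_real_
  new("EphysFeatures", values = vals, available = avail, details = details)
}
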