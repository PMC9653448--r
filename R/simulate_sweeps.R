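# Synthetic current-clamp step-protocol sweeps with analytically known
# feature values.  Hyperpolarizing responses are piecewise exponentials
# (optionally with a sag trough and a rebound hump); spiking sweeps embed a
# smooth parametric AP template on an exponential depolarizing plateau.
# Every recorded truth value is computed from the analytic waveform
# (closed-form construction parameters, high-resolution evaluation of the
# definitional quantities), independently of the extraction code paths.

#' Configuration for the sweep simulator
#'
#' Defaults describe a cortical neuron under a square-pulse step protocol:
#' RMP -70 mV, input resistance 100 MOhm, membrane time constant 20 ms,
#' a hyperpolarizing ladder and a depolarizing ladder with rheobase
#' 180 pA, four adapting spikes at rheobase.  The AP template is a smooth
#' (infinitely differentiable) sum of a fast depolarizing bump and a slow
#' after-hyperpolarizing bump, so its third time-derivative -- the
#' threshold criterion -- is well defined everywhere.
#'
#' @param dt_ms sampling interval (must be <= 0.1 ms for spiking sweeps).
#' @param total_ms,onset_ms,offset_ms trace length and stimulus window.
#' @param rmp_mV resting membrane potential.
#' @param input_resistance_MOhm Ohmic input resistance used for all
#'   steady-state deflections.
#' @param tau_ms membrane time constant of the exponential responses.
#' @param hyper_currents_pA,depol_currents_pA current ladders (the combined
#'   ladder must be strictly increasing).
#' @param rheobase_pA smallest depolarizing current that fires.
#' @param sag_extra_mV depth of the sag trough below steady state on the
#'   maximal negative sweep (0 disables sag).
#' @param sag_trough_frac position of the trough within the stimulus.
#' @param sag_recovery_tau_ms relaxation time from trough to steady state.
#' @param rebound_mV post-offset rebound peak above RMP (0 disables).
#' @param rebound_peak_ms,rebound_tau_ms,rebound_decay_tau_ms rebound
#'   timing.
#' @param ap AP template parameters: \code{up_amp_mV}, \code{up_w_ms}
#'   (logistic rise width), \code{up_tau_ms} (repolarization), and the AHP
#'   bump \code{ahp_amp_mV}, \code{ahp_w_ms}, \code{ahp_tau_ms}.
#' @param first_spike_delay_ms,first_isi_ms,isi_adapt,spikes_at_rheobase,
#'   extra_spikes_per_sweep firing-pattern rule for sweeps at or above
#'   rheobase; inter-spike intervals grow by the factor \code{isi_adapt}.
#' @param spike_times_ms optional named list (by sweep id, "d1", "d2", ...)
#'   of explicit spike times in ms, overriding the rule; times must lie
#'   inside the stimulus window and at least 5 ms after onset.
#' @param noise_sd_mV additive Gaussian noise (0 = noiseless).
#' @return a validated config list of class "sweepSimConfig".
#' @export
sweepSimConfig <- function(dt_ms = 0.02, total_ms = 1100, onset_ms = 200,
                           offset_ms = 800, rmp_mV = -70,
                           input_resistance_MOhm = 100, tau_ms = 20,
                           hyper_currents_pA = c(-110, -90, -70, -50, -30),
                           depol_currents_pA = c(60, 120, 180, 240),
                           rheobase_pA = 180,
                           sag_extra_mV = 4, sag_trough_frac = 0.25,
                           sag_recovery_tau_ms = 40,
                           rebound_mV = 3, rebound_peak_ms = 60,
                           rebound_tau_ms = 25, rebound_decay_tau_ms = 40,
                           ap = list(up_amp_mV = 136, up_w_ms = 0.3,
                                     up_tau_ms = 1.2, ahp_amp_mV = 18,
                                     ahp_w_ms = 1.0, ahp_tau_ms = 9),
                           first_spike_delay_ms = 25, first_isi_ms = 18,
                           isi_adapt = 1.25, spikes_at_rheobase = 4,
                           extra_spikes_per_sweep = 2,
                           spike_times_ms = NULL, noise_sd_mV = 0) {
  cfg <- as.list(environment())
  ladder <- c(hyper_currents_pA, depol_currents_pA)
  if (any(diff(ladder) <= 0)) {
    stop("current ladder must be strictly increasing")
  }
  if (!(onset_ms < offset_ms && offset_ms < total_ms)) {
    stop("need onset < offset < total trace length")
  }
  if (dt_ms <= 0) stop("sampling interval must be positive")
  spiking <- any(depol_currents_pA >= rheobase_pA) ||
    length(spike_times_ms) > 0
  if (spiking && dt_ms > 0.1) {
    stop("sampling interval must be <= 0.1 ms for sweeps containing APs")
  }
  if (!is.null(spike_times_ms)) {
    for (ts in spike_times_ms) {
      if (any(ts < onset_ms + 5 | ts > offset_ms)) {
        stop("explicit spike times must lie inside the stimulus window ",
             "(>= onset + 5 ms, <= offset)")
      }
      if (any(diff(ts) <= 0)) stop("spike times must be strictly increasing")
    }
  }
  if (tau_ms <= 0 || input_resistance_MOhm <= 0) {
    stop("tau and input resistance must be positive")
  }
  structure(cfg, class = "sweepSimConfig")
}

# --- analytic building blocks -------------------------------------------

# AP template: smooth bump pair.  u in ms relative to the nominal spike
# time; vectorized.
.apBump <- function(u, ap) {
  # Gompertz-gated bumps: exp(-exp(-u/w)) opens avalanche-like, so the
  # third time-derivative peaks at the foot of the upstroke (like a real
  # AP's sodium-activation onset), and the past tail underflows smoothly
  # to exactly zero -- no support clamp, hence no step discontinuities
  # visible to finite differences of any order.
  up <- ap$up_amp_mV * exp(-u / ap$up_tau_ms) *
    exp(-exp(-u / ap$up_w_ms))
  down <- ap$ahp_amp_mV * exp(-u / ap$ahp_tau_ms) *
    exp(-exp(-u / ap$ahp_w_ms))
  up - down
}

# analytic voltage of one sweep as a function closure; kind is "hyper",
# "hyper_sag" or "depol"; spikes is the vector of nominal spike times.
.sweepFunction <- function(cfg, current, kind, spikes = numeric(0)) {
  force(current); force(kind); force(spikes)  # closures outlive the caller's loop
  rmp <- cfg$rmp_mV
  tau <- cfg$tau_ms
  on <- cfg$onset_ms
  off <- cfg$offset_ms
  dV <- current * cfg$input_resistance_MOhm / 1000
  snap <- function(x) round(x / cfg$dt_ms) * cfg$dt_ms

  if (kind == "hyper_sag") {
    t1 <- snap(on + cfg$sag_trough_frac * (off - on))
    v_ss <- rmp + dV
    v_tr <- v_ss - cfg$sag_extra_mV
    v_as <- rmp + (v_tr - rmp) / (1 - exp(-(t1 - on) / tau))
    v_off <- v_ss + (v_tr - v_ss) * exp(-(off - t1) / cfg$sag_recovery_tau_ms)
    has_reb <- cfg$rebound_mV > 0
    if (has_reb) {
      t3 <- snap(off + cfg$rebound_peak_ms)
      u3 <- t3 - off
      v_pk <- rmp + cfg$rebound_mV
      e3 <- exp(-u3 / cfg$rebound_tau_ms)
      a_reb <- (v_pk - v_off * e3) / (1 - e3)
    }
    f <- function(t) {
      v <- rep(rmp, length(t))
      i1 <- t >= on & t <= t1
      v[i1] <- rmp + (v_as - rmp) * (1 - exp(-(t[i1] - on) / tau))
      i2 <- t > t1 & t <= off
      v[i2] <- v_ss + (v_tr - v_ss) *
        exp(-(t[i2] - t1) / cfg$sag_recovery_tau_ms)
      i3 <- t > off
      if (has_reb) {
        ia <- i3 & t <= t3
        v[ia] <- a_reb + (v_off - a_reb) *
          exp(-(t[ia] - off) / cfg$rebound_tau_ms)
        ib <- t > t3
        v[ib] <- rmp + (v_pk - rmp) *
          exp(-(t[ib] - t3) / cfg$rebound_decay_tau_ms)
      } else {
        v[i3] <- rmp + (v_off - rmp) * exp(-(t[i3] - off) / tau)
      }
      v
    }
    attr(f, "trough_time") <- t1
    return(f)
  }

  # plain exponential response (hyper or depolarizing plateau) + spikes
  v_off <- rmp + dV * (1 - exp(-(off - on) / tau))
  function(t) {
    v <- rep(rmp, length(t))
    i1 <- t >= on & t <= off
    v[i1] <- rmp + dV * (1 - exp(-(t[i1] - on) / tau))
    i2 <- t > off
    v[i2] <- rmp + (v_off - rmp) * exp(-(t[i2] - off) / tau)
    for (s in spikes) {
      u <- t - s
      w <- which(u > -45 & u < 15 * cfg$ap$ahp_tau_ms)
      v[w] <- v[w] + .apBump(u[w], cfg$ap)
    }
    v
  }
}

# first downward crossing of `level` by analytic f on [lo, hi]: coarse
# grid scan to bracket the crossing, then root refinement.
.firstCrossingDown <- function(f, level, lo, hi, step) {
  tg <- seq(lo, hi, by = step)
  y <- f(tg) - level
  i <- which(y[-length(y)] >= 0 & y[-1] < 0)
  if (!length(i)) return(NA_real_)
  stats::uniroot(function(x) f(x) - level, c(tg[i[1]], tg[i[1] + 1]),
                 tol = 1e-10)$root
}

# high-resolution third derivative argmax of an analytic function:
# the ideal value of the threshold criterion.
.analyticThirdDerivMax <- function(f, lo, hi, h) {
  tg <- seq(lo, hi, by = h / 20)
  step <- h / 20
  d3 <- (f(tg + 3 * step) - 3 * f(tg + step) + 3 * f(tg - step) -
           f(tg - 3 * step)) / (8 * step^3)
  i <- which.max(d3)
  # parabolic refinement on the fine grid
  dlt <- if (i > 1 && i < length(d3)) {
    den <- d3[i - 1] - 2 * d3[i] + d3[i + 1]
    if (den == 0) 0 else max(min(0.5 * (d3[i - 1] - d3[i + 1]) / den,
                                 0.5), -0.5)
  } else 0
  t_thr <- tg[i] + dlt * step
  list(time = t_thr, voltage = f(t_thr))
}

#' Simulate a step-protocol sweep set with known feature values
#'
#' Builds the analytic waveforms described in [sweepSimConfig()], samples
#' them on the configured time grid, optionally adds Gaussian noise, and
#' records the ground-truth value of every electrophysiological feature.
#' Truth values are computed from the analytic (noiseless) waveform:
#' construction parameters where the feature is a parameter (RMP, tau,
#' input resistance, rheobase, ISIs), definitional quantities evaluated at
#' high resolution otherwise (threshold via the ideal third-derivative
#' argmax at 20x oversampling, width/decay via root finding, peaks/troughs
#' via numerical optimization of the analytic function).
#'
#' @param config a [sweepSimConfig()] list.
#' @param seed integer seed (used only for the additive noise).
#' @return list with \code{sweeps} (a [SweepSet-class]) and \code{truth}
#'   (named list of true feature values, per-sweep spike times and
#'   steady states).
#' @export
simulateSweepSet <- function(config = sweepSimConfig(), seed = 1) {
  cfg <- if (inherits(config, "sweepSimConfig")) config else
    do.call(sweepSimConfig, config)
  dt <- cfg$dt_ms
  t <- seq(0, cfg$total_ms, by = dt)
  snap <- function(x) round(x / dt) * dt

  n_h <- length(cfg$hyper_currents_pA)
  n_d <- length(cfg$depol_currents_pA)
  ids <- c(if (n_h) paste0("h", seq_len(n_h)),
           if (n_d) paste0("d", seq_len(n_d)))
  currents <- c(cfg$hyper_currents_pA, cfg$depol_currents_pA)

  # AP peak lag behind the bump origin; placing bump origins at
  # (grid - lag) puts every AP peak exactly on a sample, so discrete peak
  # indices (hence ISIs and the adaptive index) are exact and robust
  peak_lag <- stats::optimize(function(u) .apBump(u, cfg$ap), c(-1, 5),
                              maximum = TRUE, tol = 1e-10)$maximum

  # firing rule: which depolarizing sweeps spike, and when.  Times are the
  # intended AP *peak* times (snapped to the sample grid).
  spikes <- vector("list", n_h + n_d)
  names(spikes) <- ids
  rank_above <- 0
  for (j in seq_len(n_d)) {
    id <- paste0("d", j)
    cur <- cfg$depol_currents_pA[j]
    if (!is.null(cfg$spike_times_ms[[id]])) {
      spikes[[id]] <- snap(cfg$spike_times_ms[[id]])
    } else if (cur >= cfg$rheobase_pA) {
      delay <- cfg$first_spike_delay_ms * 0.9^rank_above
      isi1 <- cfg$first_isi_ms * 0.9^rank_above
      n_sp <- cfg$spikes_at_rheobase + cfg$extra_spikes_per_sweep * rank_above
      isis <- isi1 * cfg$isi_adapt^(seq_len(max(n_sp - 1, 0)) - 1)
      ts <- cfg$onset_ms + delay + c(0, cumsum(isis))
      ts <- ts[ts <= cfg$offset_ms - 12 * cfg$ap$up_w_ms]
      spikes[[id]] <- snap(ts)
      rank_above <- rank_above + 1
    }
  }

  i_sag <- if (n_h) which.min(cfg$hyper_currents_pA) else integer(0)
  funs <- vector("list", length(ids))
  names(funs) <- ids
  for (j in seq_len(n_h)) {
    kind <- if (j == i_sag) "hyper_sag" else "hyper"
    funs[[paste0("h", j)]] <- .sweepFunction(cfg, cfg$hyper_currents_pA[j],
                                             kind)
  }
  for (j in seq_len(n_d)) {
    id <- paste0("d", j)
    funs[[id]] <- .sweepFunction(cfg, cfg$depol_currents_pA[j], "depol",
                                 spikes[[id]] - peak_lag)
  }

  v <- vapply(ids, function(id) funs[[id]](t), numeric(length(t)))
  if (cfg$noise_sd_mV > 0) {
    v <- v + .withSeed(.childSeed(seed, "sweep-noise"),
                       matrix(rnorm(length(v), 0, cfg$noise_sd_mV),
                              nrow(v), ncol(v)))
  }
  proto <- data.frame(sweep_id = ids, current_pA = currents,
                      onset_ms = cfg$onset_ms, offset_ms = cfg$offset_ms)
  ss <- SweepSet(v, proto, dt)

  # ---- truth -----------------------------------------------------------
  truth <- list(rmp_mV = cfg$rmp_mV, tau_ms = cfg$tau_ms,
                input_resistance_MOhm = cfg$input_resistance_MOhm,
                spike_times_ms = spikes)
  ssw <- t >= cfg$offset_ms - 100 & t < cfg$offset_ms
  stim <- t >= cfg$onset_ms & t <= cfg$offset_ms
  if (n_h) {
    hyper_ids <- paste0("h", seq_len(n_h))
    ss_means <- vapply(hyper_ids, function(id) mean(funs[[id]](t[ssw])), 0)
    truth$steady_state_mV <- ss_means
    truth$input_resistance_MOhm <-
      stats::median((ss_means - cfg$rmp_mV) / cfg$hyper_currents_pA) * 1000
    sag_id <- paste0("h", i_sag)
    trough <- min(funs[[sag_id]](t[stim]))
    truth$sag_trough_mV <- trough
    truth$sag_ratio <- (trough - cfg$rmp_mV) /
      (ss_means[[sag_id]] - cfg$rmp_mV)
    post <- t > cfg$offset_ms
    truth$rebound_mV <- max(funs[[sag_id]](t[post])) - cfg$rmp_mV
  }

  spiking_ids <- names(spikes)[lengths(spikes) > 0]
  if (length(spiking_ids)) {
    cur_sp <- currents[match(spiking_ids, ids)]
    rheo_id <- spiking_ids[which.min(cur_sp)]
    truth$rheobase_pA <- min(cur_sp)
    f <- funs[[rheo_id]]
    s1 <- spikes[[rheo_id]][1]
    opt <- stats::optimize(f, c(s1 - 1, s1 + 1), maximum = TRUE,
                           tol = 1e-9)
    t_pk <- opt$maximum
    v_pk <- opt$objective
    thr <- .analyticThirdDerivMax(
      f, max(t_pk - 20, cfg$onset_ms + 1), t_pk - dt / 10, dt)
    truth$ap_threshold_mV <- thr$voltage
    truth$ap_peak_mV <- v_pk
    truth$ap_amplitude_mV <- v_pk - thr$voltage
    truth$spike_delay_ms <- thr$time - cfg$onset_ms
    truth$ap_rising_time_ms <- t_pk - thr$time
    half <- (thr$voltage + v_pk) / 2
    r_up <- stats::uniroot(function(x) f(x) - half, c(thr$time, t_pk),
                           tol = 1e-10)$root
    bound <- if (length(spikes[[rheo_id]]) > 1)
      spikes[[rheo_id]][2] - 1 else cfg$offset_ms
    r_dn <- .firstCrossingDown(f, half, t_pk, bound, dt / 5)
    truth$ap_width_ms <- r_dn - r_up
    d_dn <- .firstCrossingDown(f, thr$voltage, t_pk, bound, dt / 5)
    truth$ap_decay_time_ms <- d_dn - t_pk
    tr <- stats::optimize(f, c(d_dn, bound), tol = 1e-9)
    truth$ahp_mV <- thr$voltage - tr$objective

    # adaptive index: lowest-current sweep with >= 3 spikes
    cand <- spiking_ids[vapply(spiking_ids, function(id)
      length(spikes[[id]]) >= 3, TRUE)]
    if (length(cand)) {
      ad_id <- cand[which.min(currents[match(cand, ids)])]
      isis <- diff(spikes[[ad_id]])
      truth$adaptive_sweep <- ad_id
      truth$isis_ms <- isis
      truth$adaptive_index <- isis[length(isis)] / isis[1]
    }
  }
  list(sweeps = ss, truth = truth,
       config = c(cfg, list(seed = seed,
                            noise_child_seed = .childSeed(seed, "sweep-noise"))))
}
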