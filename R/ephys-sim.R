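#' Stimulation protocols
#'
#' Three protocols mirror the recording session at each junction: 30 s of
#' spontaneous miniature activity, three nerve-evoked responses at 0.1 Hz
#' (spaced to avoid rundown), and a 20 Hz conditioning train lasting 2 min
#' (2400 pulses) used to profile depression of evoked amplitude.
#'
#' @param duration recording length, s
#' @param n_stim number of evoked stimuli
#' @param interval inter-stimulus interval, s
#' @param lead time before the first stimulus, s
#' @param rate train rate, Hz
#' @return a `stim_protocol` list with `kind`, `duration` and `stim_times`
#' @export
protocol_spontaneous <- function(duration = 30) {
  stopifnot(duration > 0)
  structure(list(kind = "spontaneous", duration = duration, stim_times = numeric(0)),
            class = "stim_protocol")
}

#' @rdname protocol_spontaneous
#' @export
protocol_evoked <- function(n_stim = 3L, interval = 10, lead = 5) {
  stopifnot(n_stim >= 1, interval > 0)
  stim <- lead + (seq_len(n_stim) - 1L) * interval
  structure(list(kind = "evoked_0p1Hz", duration = max(stim) + 5, stim_times = stim),
            class = "stim_protocol")
}

#' @rdname protocol_spontaneous
#' @export
protocol_train <- function(rate = 20, duration = 120, lead = 0.5) {
  stopifnot(rate > 0, duration > 0)
  stim <- lead + seq(0, by = 1 / rate, length.out = round(rate * duration))
  structure(list(kind = "train_20Hz", duration = max(stim) + 0.5, stim_times = stim),
            class = "stim_protocol")
}

# postsynaptic potential kernel: difference of exponentials, unit peak;
# the rise constant is solved so onset-to-peak equals the requested 0-100%
# rise time
psp_kernel <- function(rise_ms, decay_ms, sampling_rate, length_factor = 8) {
  stopifnot(rise_ms > 0, decay_ms > rise_ms)
  t_peak <- function(tr) tr * decay_ms / (decay_ms - tr) * log(decay_ms / tr)
  tau_r <- uniroot(function(tr) t_peak(tr) - rise_ms,
                   lower = 1e-4, upper = decay_ms * 0.999, tol = 1e-10)$root
  dt_ms <- 1000 / sampling_rate
  tt <- seq(0, decay_ms * length_factor, by = dt_ms)
  w <- exp(-tt / decay_ms) - exp(-tt / tau_r)
  w / max(w)
}

# per-minute Gaussian random walk of the resting potential, linearly
# interpolated to the sample grid; bounded scenarios reflect inside
# [-85, -55] mV so healthy fibers never approach the -50 mV rejection line
rmp_track <- function(scenario, n_samples, sampling_rate) {
  dur <- n_samples / sampling_rate
  nodes_t <- seq(0, dur, by = 60)
  if (max(nodes_t) < dur) nodes_t <- c(nodes_t, dur)
  steps <- rnorm(length(nodes_t) - 1L, 0, scenario$rmp_drift_sd)
  vals <- scenario$rmp_mean + c(0, cumsum(steps))
  if (isTRUE(scenario$rmp_bounded)) {
    for (i in seq_along(vals)) {
      v <- vals[i]
      while (v > -55 || v < -85) {
        if (v > -55) v <- -110 - v  # reflect at -55
        if (v < -85) v <- -170 - v  # reflect at -85
      }
      vals[i] <- v
    }
  }
  if (length(nodes_t) == 1L) return(rep(vals, n_samples))
  approx(nodes_t, vals, xout = (seq_len(n_samples) - 1L) / sampling_rate)$y
}

new_trace <- function(samples, sampling_rate, stim_times, metadata) {
  structure(list(
    sampling_rate = sampling_rate,
    samples = samples,
    stim_times = stim_times,
    duration = length(samples) / sampling_rate,
    metadata = metadata
  ), class = "nmj_trace")
}

#' @export
print.nmj_trace <- function(x, ...) {
  cat(sprintf("<nmj_trace %s: %.1f s at %g kHz, %d stimuli, scenario %s>\n",
              x$metadata$protocol %||% "?", x$duration, x$sampling_rate / 1000,
              length(x$stim_times), x$metadata$scenario_id %||% "?"))
  invisible(x)
}

#' Simulate an intracellular recording with ground truth
#'
#' Generates a membrane-potential trace for one junction under a given
#' protocol. Spontaneous miniature potentials occur as a Poisson process with
#' log-normal amplitudes (mean and CV from the scenario, defined at -70 mV);
#' instantaneous amplitudes scale with the momentary driving force
#' (|RMP|/70), so correcting measured amplitudes back to -70 mV recovers the
#' scenario mean. Evoked responses release a Poisson number of quanta around
#' the scenario's true quantal content and are compressed by non-linear
#' summation, so the Martin-corrected estimator is unbiased for the true
#' count. Gaussian instrument noise is added throughout.
#'
#' @param scenario an [build_scenario()] preset
#' @param protocol a protocol from [protocol_spontaneous()],
#'   [protocol_evoked()] or [protocol_train()]
#' @param seed integer seed; fixing it reproduces the trace bit-identically
#' @param sampling_rate samples per second (default 20 kHz, resolving
#'   sub-millisecond rise times)
#' @return list with `trace` (an `nmj_trace`) and `ground_truth` (a tibble of
#'   event times, delivered and -70 mV-referenced amplitudes, quanta for
#'   evoked events, and the membrane potential at each event)
#' @export
simulate_recording <- function(scenario, protocol = protocol_spontaneous(),
                               seed = 1L, sampling_rate = 20000) {
  stopifnot(inherits(scenario, "ephys_scenario"), inherits(protocol, "stim_protocol"))
  if (sampling_rate <= 0) stop_nmj("sampling_rate must be positive")
  if (protocol$duration <= 0) stop_nmj("protocol duration must be positive")
  if (protocol$kind == "train_20Hz") {
    return(simulate_train(scenario, seed = seed, sampling_rate = sampling_rate))
  }
  set.seed(seed)

  n <- round(protocol$duration * sampling_rate)
  rmp <- rmp_track(scenario, n, sampling_rate)
  v <- rmp
  kern <- psp_kernel(scenario$rise_time, scenario$decay_tau, sampling_rate)
  kern_dur <- length(kern) / sampling_rate

  # spontaneous miniatures
  n_ev <- rpois(1L, scenario$mepp_rate * protocol$duration)
  mepp_t <- sort(runif(n_ev, 0, max(protocol$duration - kern_dur, 0)))
  sdlog <- sqrt(log(1 + scenario$mepp_cv^2))
  meanlog <- log(scenario$mepp_mean) - sdlog^2 / 2
  amp_ref <- rlnorm(n_ev, meanlog, sdlog)
  idx <- pmin(n, round(mepp_t * sampling_rate) + 1L)
  amp_del <- amp_ref * abs(rmp[idx]) / 70
  v <- add_events(v, idx, amp_del, kern)

  gt <- tibble::tibble(
    event_time = mepp_t, kind = "mEPP",
    true_amplitude = amp_del, amplitude_ref70 = amp_ref,
    true_quanta = NA_integer_, rmp_at_event = rmp[idx]
  )

  # evoked responses (synaptic delay 0.5 ms after the stimulus)
  if (length(protocol$stim_times)) {
    delay <- 5e-4
    st <- protocol$stim_times + delay
    sidx <- pmin(n, round(st * sampling_rate) + 1L)
    q <- rpois(length(st), scenario$qc_true)
    vm <- abs(rmp[sidx])
    linear <- q * scenario$mepp_mean * vm / 70
    obs <- linear / (1 + 0.8 * linear / vm)
    v <- add_events(v, sidx, obs, kern)
    gt <- dplyr::bind_rows(gt, tibble::tibble(
      event_time = st, kind = "EPP",
      true_amplitude = obs, amplitude_ref70 = obs * 70 / vm,
      true_quanta = as.integer(q), rmp_at_event = rmp[sidx]
    ))
    gt <- gt[order(gt$event_time), ]
  }

  if (scenario$noise_sd > 0) v <- v + rnorm(n, 0, scenario$noise_sd)

  trace <- new_trace(v, sampling_rate, protocol$stim_times,
                     list(scenario_id = scenario$id, seed = seed,
                          protocol = protocol$kind))
  list(trace = trace, ground_truth = gt)
}

add_events <- function(v, idx, amp, kern) {
  n <- length(v)
  lk <- length(kern)
  for (k in seq_along(idx)) {
    i0 <- idx[k]
    i1 <- min(n, i0 + lk - 1L)
    seg <- i0:i1
    v[seg] <- v[seg] + amp[k] * kern[seq_along(seg)]
  }
  v
}

#' Simulate a 20 Hz, 2 min stimulus train with depletion-driven rundown
#'
#' The releasable vesicle pool starts at `pool_size` quanta; each pulse
#' releases a fraction `p = release_fraction` of the current pool (rounded to
#' whole quanta), and during each inter-stimulus interval a fraction
#' `r = replenish_rate` of the outstanding deficit is restored:
#' `N[i+1] = (N[i] - p N[i]) + r (N0 - (N[i] - p N[i]))`. The closed-form
#' steady state is given by [steady_state_pool()]. Evoked amplitudes are the
#' released quanta times the single-quantum amplitude, compressed by
#' non-linear summation, plus noise.
#'
#' @inheritParams simulate_recording
#' @return list with `trace` and `ground_truth` (per-pulse tibble:
#'   `pulse_index`, `stim_time`, `true_quanta`, `pool_before`,
#'   `true_amplitude`, `rmp_at_event`)
#' @export
simulate_train <- function(scenario, seed = 1L, sampling_rate = 20000,
                           protocol = protocol_train()) {
  stopifnot(inherits(scenario, "ephys_scenario"))
  p <- scenario$release_fraction
  r <- scenario$replenish_rate
  if (p <= 0 || p > 1) stop_nmj("release_fraction must be in (0, 1]")
  if (r < 0 || r > 1) stop_nmj("replenish_rate must be in [0, 1]")
  if (sampling_rate <= 0) stop_nmj("sampling_rate must be positive")
  set.seed(seed)

  n <- round(protocol$duration * sampling_rate)
  rmp <- rmp_track(scenario, n, sampling_rate)
  v <- rmp
  kern <- psp_kernel(scenario$rise_time, scenario$decay_tau, sampling_rate)

  n_pulse <- length(protocol$stim_times)
  pool <- numeric(n_pulse)
  quanta <- integer(n_pulse)
  n0 <- scenario$pool_size
  ni <- n0
  for (i in seq_len(n_pulse)) {
    pool[i] <- ni
    quanta[i] <- round(p * ni)
    after <- ni - p * ni
    ni <- after + r * (n0 - after)
  }

  st <- protocol$stim_times + 5e-4
  sidx <- pmin(n, round(st * sampling_rate) + 1L)
  vm <- abs(rmp[sidx])
  linear <- quanta * scenario$mepp_mean * vm / 70
  obs <- linear / (1 + 0.8 * linear / vm)
  v <- add_events(v, sidx, obs, kern)
  if (scenario$noise_sd > 0) v <- v + rnorm(n, 0, scenario$noise_sd)

  trace <- new_trace(v, sampling_rate, protocol$stim_times,
                     list(scenario_id = scenario$id, seed = seed,
                          protocol = protocol$kind))
  gt <- tibble::tibble(
    pulse_index = seq_len(n_pulse), stim_time = st,
    true_quanta = quanta, pool_before = pool,
    true_amplitude = obs, rmp_at_event = rmp[sidx]
  )
  list(trace = trace, ground_truth = gt)
}

#' Steady-state releasable pool of the depletion/replenishment recursion
#'
#' Fixed point of `N -> (1-p) N + r (N0 - (1-p) N)`, i.e.
#' `N* = r N0 / (p + r - p r)`.
#'
#' @param p release fraction per pulse
#' @param r replenishment fraction per interval
#' @param n0 resting pool size
#' @export
steady_state_pool <- function(p, r, n0 = 1) {
  stopifnot(p > 0, p <= 1, r >= 0, r <= 1)
  if (r == 0) return(0 * n0)
  r * n0 / (p + r - p * r)
}

#' Write / read a trace as columnar CSV
#'
#' Columns are `time_s` and `vm_mV`; stimulus times (if any) are stored in a
#' sidecar `<path>.stims.csv`. The sampling rate is recovered from the time
#' column on read.
#'
#' @param trace an `nmj_trace`
#' @param path output CSV path
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "nmj_trace"))
  tt <- (seq_along(trace$samples) - 1L) / trace$sampling_rate
  write.csv(data.frame(time_s = tt, vm_mV = trace$samples), path, row.names = FALSE)
  if (length(trace$stim_times)) {
    write.csv(data.frame(stim_time_s = trace$stim_times),
              paste0(path, ".stims.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("time_s", "vm_mV") %in% names(df)))
  fs <- 1 / median(diff(df$time_s))
  stims <- numeric(0)
  sidecar <- paste0(path, ".stims.csv")
  if (file.exists(sidecar)) stims <- read.csv(sidecar)$stim_time_s
  new_trace(df$vm_mV, fs, stims, list(source = path, protocol = "file"))
}
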