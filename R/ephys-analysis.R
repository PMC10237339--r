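#' Detection settings for miniature endplate potentials
#'
#' @param threshold_sd detection threshold as a multiple of the robust
#'   (median-absolute-deviation) noise SD of the baseline-subtracted trace
#' @param smooth_ms boxcar pre-smoothing width, ms
#' @param baseline_ms running-median window used to track the resting
#'   potential, ms (long relative to a synaptic event, short relative to
#'   membrane-potential drift)
#' @param template_rise_ms,template_decay_ms kinetics of the template used for
#'   least-squares amplitude estimation
#' @param merge_ms events closer than this are merged into the larger one
#'   (two decay constants by default)
#' @export
detect_config <- function(threshold_sd = 7, smooth_ms = 0.35, baseline_ms = 200,
                          template_rise_ms = 0.8, template_decay_ms = 4,
                          merge_ms = 2 * template_decay_ms) {
  list(threshold_sd = threshold_sd, smooth_ms = smooth_ms,
       baseline_ms = baseline_ms, template_rise_ms = template_rise_ms,
       template_decay_ms = template_decay_ms, merge_ms = merge_ms)
}

#' Detect and measure spontaneous miniature potentials
#'
#' The resting potential is tracked with a running median (robust to the
#' sparse, brief synaptic events riding on it) and subtracted. Candidate
#' events are local maxima of the lightly smoothed residual above
#' `threshold_sd` times the robust noise SD; candidates within `merge_ms`
#' (two decay constants by default, spanning the decay tail on which noise
#' maxima would masquerade as events) are merged into the larger event
#' (earlier onset wins ties).
#' Amplitudes are then estimated by least-squares scaling of a
#' difference-of-exponentials template at the detected onset
#' (Clements-Bekkers style), which avoids the positive bias a raw peak reading
#' takes from noise. Events are excluded, with a reason, from the moment the
#' fiber first depolarizes beyond -50 mV.
#'
#' @param trace an `nmj_trace` sampled at 10 kHz or above
#' @param config a [detect_config()]
#' @return an event table (tibble): `event_time`, `amplitude_raw`,
#'   `amplitude_corrected` (referenced to -70 mV), `rise_time` (ms),
#'   `rmp_at_event`, `kind`, `included`, `exclusion_reason`
#' @export
detect_mepps <- function(trace, config = detect_config()) {
  stopifnot(inherits(trace, "nmj_trace"))
  v <- trace$samples
  fs <- trace$sampling_rate
  if (fs < 10000) stop_nmj("trace must be sampled at >= 10 kHz")
  if (trace$duration < 1) stop_nmj("trace shorter than 1 s")
  if (all(is.na(v))) stop_nmj("all-NaN trace")

  baseline <- runmed(v, odd_window(config$baseline_ms / 1000 * fs))
  d <- v - baseline
  ns <- max(1L, round(config$smooth_ms / 1000 * fs))
  ds <- as.numeric(stats::filter(d, rep(1 / ns, ns), sides = 2))
  ds[is.na(ds)] <- 0
  sigma <- mad(ds)
  thr <- config$threshold_sd * sigma

  # local maxima above threshold
  n <- length(ds)
  cand <- which(ds > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[ds[cand] >= ds[cand - 1L] & ds[cand] > ds[cand + 1L]]
  if (!length(cand)) return(empty_event_table())

  # merge nearby candidates, keeping the larger event
  sep <- round(config$merge_ms / 1000 * fs)
  ord <- cand[order(ds[cand], -cand, decreasing = TRUE)]
  keep <- integer(0)
  for (i in ord) {
    if (!length(keep) || all(abs(keep - i) > sep)) keep <- c(keep, i)
  }
  keep <- sort(keep)

  kern <- psp_kernel(config$template_rise_ms, config$template_decay_ms, fs)
  rise_n <- round(config$template_rise_ms / 1000 * fs)
  # fit the boxcar-smoothed template against the equally smoothed trace:
  # smoothing both sides leaves the scaling estimate unbiased while making
  # the SSE-based onset alignment signal-dominated rather than noise-dominated
  kern_s <- as.numeric(stats::filter(kern, rep(1 / ns, ns), sides = 2))
  kern_s[is.na(kern_s)] <- kern[is.na(kern_s)]

  amp <- rise <- numeric(length(keep))
  for (k in seq_along(keep)) {
    pk <- keep[k]
    # truncate the fit window before the next event so a neighbour's rise
    # does not inflate this event's template projection
    max_len <- if (k < length(keep)) keep[k + 1L] - pk else length(kern_s)
    fit <- fit_template(ds, pk - rise_n, kern_s, shifts = -10:10,
                        max_len = max_len)
    amp[k] <- fit$amplitude
    # onset-to-peak rise time from the smoothed residual
    on <- pk
    while (on > 1L && ds[on - 1L] > 0.05 * ds[pk]) on <- on - 1L
    rise[k] <- (pk - on) / fs * 1000
  }

  rmp_ev <- baseline[keep]
  t_ev <- (keep - 1L) / fs
  bad_from <- first_depolarized_time(baseline, fs)

  reason <- rep(NA_character_, length(keep))
  reason[amp <= 0] <- "non_positive_amplitude"
  reason[!is.na(amp) & amp > 0 & amp < thr] <- "below_threshold"
  reason[!is.na(bad_from) & t_ev >= bad_from] <- "rmp_above_minus50"
  included <- is.na(reason)

  tibble::tibble(
    event_time = t_ev,
    amplitude_raw = amp,
    amplitude_corrected = ifelse(amp > 0 & rmp_ev < 0,
                                 amp * 70 / abs(rmp_ev), NA_real_),
    rise_time = rise,
    rmp_at_event = rmp_ev,
    kind = "mEPP",
    included = included,
    exclusion_reason = reason
  )
}

empty_event_table <- function() {
  tibble::tibble(
    event_time = numeric(0), amplitude_raw = numeric(0),
    amplitude_corrected = numeric(0), rise_time = numeric(0),
    rmp_at_event = numeric(0), kind = character(0),
    included = logical(0), exclusion_reason = character(0)
  )
}

# least-squares template scaling with a free baseline; a small onset-shift
# search aligns the template using the whole-event SSE
fit_template <- function(d, onset, kern, shifts = 0L, max_len = length(kern)) {
  n <- length(d)
  lk <- min(length(kern), max(max_len, 40L))
  kern <- kern[seq_len(lk)]
  best <- list(sse = Inf, amplitude = NA_real_)
  for (s in shifts) {
    i0 <- onset + s
    if (i0 < 1L || i0 + lk - 1L > n) next
    x <- d[i0:(i0 + lk - 1L)]
    wc <- kern - mean(kern)
    beta <- sum(wc * x) / sum(wc * wc)
    resid <- x - mean(x) - beta * wc
    sse <- sum(resid^2)
    if (sse < best$sse) best <- list(sse = sse, amplitude = beta)
  }
  best
}

first_depolarized_time <- function(baseline, fs, limit = -50) {
  i <- which(baseline > limit)
  if (!length(i)) return(NA_real_)
  (i[1] - 1L) / fs
}

#' Measure evoked endplate potentials at known stimulus times
#'
#' For each stimulus the local baseline is the median potential just before
#' the stimulus; the amplitude is the peak depolarization within 15 ms after
#' it. Responses are excluded when the 0-100% rise time exceeds 1.5 ms (the
#' focal-recording criterion) or the fiber is depolarized beyond -50 mV.
#'
#' @param trace an `nmj_trace` with non-empty `stim_times`
#' @param window_ms search window after the stimulus, ms
#' @param max_rise_ms inclusion ceiling on the 0-100% rise time, ms
#' @return an event table as in [detect_mepps()], with `kind = "EPP"`
#' @export
measure_epps <- function(trace, window_ms = 15, max_rise_ms = 1.5) {
  stopifnot(inherits(trace, "nmj_trace"))
  if (!length(trace$stim_times)) stop_nmj("trace has no stimulus times")
  v <- trace$samples
  fs <- trace$sampling_rate
  n <- length(v)

  out <- lapply(trace$stim_times, function(st) {
    i_st <- round(st * fs) + 1L
    i_b0 <- max(1L, i_st - round(0.005 * fs))
    i_b1 <- max(1L, i_st - round(0.0005 * fs))
    base <- median(v[i_b0:i_b1])
    i_w1 <- min(n, i_st + round(window_ms / 1000 * fs))
    seg <- v[i_st:i_w1] - base
    pk <- which.max(seg)
    amp <- seg[pk]
    # onset = last sub-5% sample before the peak
    on <- pk
    while (on > 1L && seg[on - 1L] > 0.05 * amp) on <- on - 1L
    rise <- (pk - on) / fs * 1000
    tibble::tibble(
      event_time = st, amplitude_raw = amp,
      amplitude_corrected = if (amp > 0 && base < 0)
        amp * 70 / abs(base) else NA_real_,
      rise_time = rise, rmp_at_event = base, kind = "EPP"
    )
  })
  ev <- dplyr::bind_rows(out)
  reason <- rep(NA_character_, nrow(ev))
  reason[ev$amplitude_raw <= 0] <- "non_positive_amplitude"
  reason[ev$rise_time > max_rise_ms] <- "rise_time_above_1p5ms"
  reason[ev$rmp_at_event > -50] <- "rmp_above_minus50"
  ev$included <- is.na(reason)
  ev$exclusion_reason <- reason
  ev
}

#' Correct an amplitude to the -70 mV reference potential
#'
#' Postsynaptic potential amplitudes scale with the driving force, so
#' amplitudes recorded at different resting potentials are normalized as
#' `amplitude * 70 / |rmp|` before comparison across fibers.
#'
#' @param amplitude amplitude in mV (positive)
#' @param rmp resting membrane potential in mV (negative)
#' @export
correct_to_minus70 <- function(amplitude, rmp) {
  if (any(rmp >= 0)) stop_nmj("rmp must be negative (non-physiological otherwise)")
  if (any(amplitude <= 0)) stop_nmj("amplitude must be positive")
  amplitude * 70 / abs(rmp)
}

#' Quantal content with the Martin non-linear-summation correction
#'
#' `QC = E / (M * (1 - f * E / Vm))`: the number of quanta per stimulus given
#' the mean evoked amplitude `E`, the mean miniature amplitude `M`, and the
#' resting potential magnitude `Vm`. The factor `f` (0.8 by default) corrects
#' for the reduced driving force as the summed depolarization approaches the
#' reversal potential; `f = 0` disables the correction (QC = E/M).
#'
#' @param E mean evoked amplitude, mV
#' @param M mean miniature amplitude, mV
#' @param Vm resting membrane potential magnitude, mV (sign is ignored and
#'   documented as a magnitude)
#' @param f correction factor in `[0, Vm/E)`
#' @export
quantal_content <- function(E, M, Vm = 70, f = 0.8) {
  Vm <- abs(Vm)
  if (any(E <= 0) || any(M <= 0) || any(Vm <= 0)) {
    stop_nmj("E, M and Vm must be positive")
  }
  denom <- 1 - f * E / Vm
  if (any(denom <= 0)) {
    stop_nmj("non-linear summation correction breaks down: 1 - f*E/Vm <= 0")
  }
  E / (M * denom)
}

#' Miniature event frequency
#'
#' Included miniature events divided by the recording duration.
#'
#' @param events an event table from [detect_mepps()]
#' @param duration recording length, s
#' @export
mepp_frequency <- function(events, duration = 30) {
  if (duration <= 0) stop_nmj("duration must be positive")
  sum(events$included & events$kind == "mEPP") / duration
}

#' Rundown profile of a stimulus train
#'
#' Normalizes per-pulse evoked amplitudes to the first pulse and summarizes
#' the late plateau as the mean normalized amplitude over the final 10 s
#' (the last `plateau_pulses` pulses, 200 at 20 Hz).
#'
#' @param train_amplitudes per-pulse amplitudes, mV
#' @param plateau_pulses number of final pulses averaged for the plateau
#' @return list of class `rundown_profile`: `pulse_index`, `amplitude`,
#'   `normalized_amplitude`, `late_plateau`
#' @export
rundown_profile <- function(train_amplitudes, plateau_pulses = 200L) {
  if (length(train_amplitudes) < 2L) stop_nmj("need at least 2 pulses")
  if (train_amplitudes[1] <= 0) stop_nmj("first amplitude must be positive")
  norm <- train_amplitudes / train_amplitudes[1]
  k <- min(plateau_pulses, length(norm))
  structure(list(
    pulse_index = seq_along(train_amplitudes),
    amplitude = train_amplitudes,
    normalized_amplitude = norm,
    late_plateau = mean(tail(norm, k))
  ), class = "rundown_profile")
}

#' Measure per-pulse train amplitudes from a trace
#'
#' Convenience wrapper around [measure_epps()] semantics for long trains:
#' amplitudes are peak-minus-pre-stimulus-baseline in a short window after
#' each pulse.
#'
#' @inheritParams measure_epps
#' @export
train_amplitudes <- function(trace, window_ms = 12) {
  stopifnot(inherits(trace, "nmj_trace"))
  v <- trace$samples
  fs <- trace$sampling_rate
  n <- length(v)
  vapply(trace$stim_times, function(st) {
    i_st <- round(st * fs) + 1L
    i_b0 <- max(1L, i_st - round(0.004 * fs))
    i_b1 <- max(1L, i_st - round(0.0005 * fs))
    base <- median(v[i_b0:i_b1])
    i_w1 <- min(n, i_st + round(window_ms / 1000 * fs))
    max(v[i_st:i_w1]) - base
  }, numeric(1))
}

#' Per-junction summary of the recording session
#'
#' Aggregates the spontaneous, evoked and (optionally) train records of one
#' junction: mean corrected miniature and evoked amplitudes, miniature
#' frequency, evoked rise time, resting potential, Martin-corrected quantal
#' content (computed from the -70 mV-corrected means with `Vm = 70`, keeping
#' the estimate independent of the momentary resting potential; set
#' `use_corrected = FALSE` to use raw means at the measured potential), and
#' the late rundown plateau.
#'
#' @param mepps event table from [detect_mepps()]
#' @param epps event table from [measure_epps()] (may be `NULL`)
#' @param train a [rundown_profile()] (may be `NULL`)
#' @param duration spontaneous recording length, s
#' @param f non-linear summation factor
#' @param use_corrected use -70 mV-corrected means in the QC formula
#' @return one-row tibble (`nmj_summary`)
#' @export
summarize_nmj <- function(mepps, epps = NULL, train = NULL, duration = 30,
                          f = 0.8, use_corrected = TRUE) {
  m_inc <- mepps[mepps$included & mepps$kind == "mEPP", ]
  e_inc <- if (!is.null(epps)) epps[epps$included & epps$kind == "EPP", ] else NULL

  m_corr <- if (nrow(m_inc)) mean(m_inc$amplitude_corrected) else NA_real_
  m_raw <- if (nrow(m_inc)) mean(m_inc$amplitude_raw) else NA_real_
  e_corr <- if (!is.null(e_inc) && nrow(e_inc)) mean(e_inc$amplitude_corrected) else NA_real_
  e_raw <- if (!is.null(e_inc) && nrow(e_inc)) mean(e_inc$amplitude_raw) else NA_real_
  rmp <- mean(c(m_inc$rmp_at_event, if (!is.null(e_inc)) e_inc$rmp_at_event))

  qc <- NA_real_
  qc_flag <- "ok"
  if (is.na(m_corr) || is.na(e_corr)) {
    qc_flag <- if (is.na(m_corr)) "undefined_no_included_mepps" else "undefined_no_included_epps"
  } else {
    qc <- if (use_corrected) quantal_content(e_corr, m_corr, 70, f)
          else quantal_content(e_raw, m_raw, abs(rmp), f)
  }

  tibble::tibble(
    mepp_mean_corrected = m_corr,
    mepp_mean_raw = m_raw,
    mepp_frequency = mepp_frequency(mepps, duration),
    epp_mean_corrected = e_corr,
    epp_mean_raw = e_raw,
    epp_rise_time = if (!is.null(e_inc) && nrow(e_inc)) mean(e_inc$rise_time) else NA_real_,
    rmp = rmp,
    qc = qc,
    qc_flag = qc_flag,
    rundown_plateau = if (!is.null(train)) train$late_plateau else NA_real_,
    n_mepps_included = nrow(m_inc),
    n_epps_included = if (is.null(e_inc)) 0L else nrow(e_inc)
  )
}
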