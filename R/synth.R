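# Synthetic multi-channel ENG session generation.
#
# The generator emulates an acute bladder-infusion recording: 32 intraneural
# active sites sampled at 24414 Hz, three equal-duration bladder states
# (baseline -> full -> micturition) with state-dependent afferent firing,
# a handful of dead (high-impedance) channels carrying noise only, and
# low-rate physiological traces (intravesical pressure, infused volume).

#' Configuration for the synthetic ENG session generator
#'
#' Collects and validates every knob of the synthetic recording model. The
#' defaults describe the study conditions the package targets: a 32-site
#' intrafascicular array sampled at 24414 Hz, physiological channels at
#' 1526 Hz, five nonfunctioning sites (the in-vivo count ranged 4-7), one
#' minute per bladder state, and a 4 ms absolute refractory period.
#'
#' Firing rates and spike amplitudes per state are free parameters of the
#' simulation (real pudendal afferent modulation is not quantified in the
#' source data); the defaults produce clearly separable states, and tests
#' construct harder regimes by shrinking the rate/amplitude contrasts.
#'
#' @param n_channels Number of recording channels (active sites).
#' @param fs_neural Neural sampling rate in Hz.
#' @param fs_physio Sampling rate of the physiological traces in Hz.
#' @param state_rates Named numeric vector of per-channel mean firing rates
#'   in Hz for `baseline`, `full`, `micturition`.
#' @param state_amplitudes Named numeric vector of spike peak amplitudes
#'   (signal units, e.g. uV) per state.
#' @param noise_sd Standard deviation of additive broadband Gaussian noise.
#' @param line_noise_amp Amplitude of 50 Hz line interference (0 disables).
#' @param n_dead_channels Number of channels rendered as noise-only.
#' @param segment_duration_s Duration of each state segment in seconds.
#' @param refractory_s Absolute refractory period between spikes, seconds.
#' @param template_width_s Width of the spike waveform template in seconds.
#' @param physio Logical; generate pressure/volume traces?
#' @param seed Integer master seed; every random draw derives from it.
#'
#' @return An object of class `synth_config` (a validated list).
#' @seealso [generate_session()]
#' @export
synth_config <- function(n_channels = 32L,
                         fs_neural = 24414,
                         fs_physio = 1526,
                         state_rates = c(baseline = 10, full = 40, micturition = 90),
                         state_amplitudes = c(baseline = 8, full = 10, micturition = 12),
                         noise_sd = 1,
                         line_noise_amp = 0,
                         n_dead_channels = 5L,
                         segment_duration_s = 60,
                         refractory_s = 0.004,
                         template_width_s = 0.0012,
                         physio = TRUE,
                         seed = 1L) {
  states <- c("baseline", "full", "micturition")
  state_rates <- state_rates[states]
  state_amplitudes <- state_amplitudes[states]
  stopifnot(
    is.numeric(n_channels), length(n_channels) == 1L, n_channels >= 1,
    fs_neural > 0, fs_physio > 0,
    !anyNA(state_rates), all(state_rates >= 0),
    !anyNA(state_amplitudes), all(state_amplitudes >= 0),
    noise_sd >= 0, line_noise_amp >= 0,
    segment_duration_s > 0, refractory_s > 0,
    template_width_s > 0
  )
  if (n_dead_channels < 0 || n_dead_channels > n_channels) {
    stop("`n_dead_channels` must lie in [0, n_channels]", call. = FALSE)
  }
  if (any(state_rates * refractory_s >= 1)) {
    stop("state firing rates must satisfy rate * refractory_s < 1", call. = FALSE)
  }
  structure(
    list(
      n_channels = as.integer(n_channels), fs_neural = fs_neural,
      fs_physio = fs_physio, state_rates = state_rates,
      state_amplitudes = state_amplitudes, noise_sd = noise_sd,
      line_noise_amp = line_noise_amp,
      n_dead_channels = as.integer(n_dead_channels),
      segment_duration_s = segment_duration_s, refractory_s = refractory_s,
      template_width_s = template_width_s, physio = isTRUE(physio),
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never perturbs user randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 9973 + 1) %% 2147483647
  }
  as.integer(s)
}

#' Generate a Poisson-with-dead-time spike train
#'
#' Event times follow a renewal process whose inter-spike intervals are
#' `refractory + Exp(rate_adj)` with `rate_adj = rate / (1 - rate * refractory)`,
#' so the mean inter-spike interval is exactly `1 / rate`: the requested rate
#' is the realized firing rate, and with `refractory = 0` the process is
#' homogeneous Poisson.
#'
#' @param rate Mean firing rate in events per second (>= 0).
#' @param duration Train duration in seconds (> 0).
#' @param refractory Absolute refractory period in seconds (>= 0);
#'   `rate * refractory` must be < 1.
#' @param seed Integer seed; the train is deterministic given the seed.
#' @param channel Optional channel index stored with the train.
#'
#' @return An `eng_spike_train`: list with `times` (strictly increasing event
#'   times in `[0, duration)`, consecutive gaps >= `refractory`), `channel`,
#'   `rate`, `duration`, `refractory`.
#' @export
generate_spike_train <- function(rate, duration, refractory = 0, seed = 1L,
                                 channel = NA_integer_) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0) {
    stop("`rate` must be a non-negative number", call. = FALSE)
  }
  if (!is.numeric(duration) || length(duration) != 1L || is.na(duration) ||
      duration <= 0) {
    stop("`duration` must be a positive number", call. = FALSE)
  }
  if (refractory < 0) stop("`refractory` must be >= 0", call. = FALSE)
  if (rate * refractory >= 1) {
    stop("`rate * refractory` must be < 1 for a realizable train", call. = FALSE)
  }
  times <- numeric(0)
  if (rate > 0) {
    rate_adj <- rate / (1 - rate * refractory)
    times <- with_seed(seed, {
      acc <- numeric(0)
      t_last <- NULL
      repeat {
        n_draw <- max(64L, ceiling((duration - sum(acc)) * rate * 1.5))
        isi <- stats::rexp(n_draw, rate_adj) + refractory
        if (is.null(t_last)) isi[1L] <- isi[1L] - refractory # no dead time before first event
        acc <- c(acc, isi)
        t_last <- TRUE
        if (sum(acc) >= duration) break
      }
      tt <- cumsum(acc)
      tt[tt < duration]
    })
  }
  structure(
    list(times = times, channel = channel, rate = rate, duration = duration,
         refractory = refractory),
    class = "eng_spike_train"
  )
}

#' Biphasic extracellular spike waveform template
#'
#' Difference-of-Gaussians waveform about 1.2 ms wide with a small positive
#' lobe followed by a dominant negative trough (the classic extracellular
#' somatic spike shape). Its spectral energy is concentrated in the 1-6 kHz
#' band, so the template survives the pipeline's band-pass filter.
#'
#' @param fs Sampling rate in Hz.
#' @param amplitude Peak (trough) amplitude in signal units.
#' @param width_s Template duration in seconds.
#' @return Numeric vector of template samples; the trough sits ~0.35 ms from
#'   the start (attribute `peak_offset_s`).
#' @export
spike_template <- function(fs, amplitude = 1, width_s = 0.0012) {
  n <- max(3L, round(width_s * fs))
  t <- (seq_len(n) - 1) / fs
  s <- 9e-5
  w <- 0.55 * exp(-(t - 1.5e-4)^2 / (2 * s^2)) - exp(-(t - 3.5e-4)^2 / (2 * s^2))
  w <- w * (amplitude / max(abs(w)))
  attr(w, "peak_offset_s") <- (which.min(w) - 1) / fs
  w
}

#' Render a spike train into a noisy sample vector
#'
#' Superimposes one template instance per event (template start aligned with
#' the event time), adds white Gaussian noise and optional 50 Hz line
#' interference. Templates running past the end of the vector are truncated,
#' and the number of truncated events is reported via the `n_truncated`
#' attribute.
#'
#' @param train An `eng_spike_train`.
#' @param template Numeric waveform template (see [spike_template()]).
#' @param fs Sampling rate in Hz.
#' @param noise_sd White-noise standard deviation.
#' @param seed Integer seed for the noise draw.
#' @param duration Rendered duration in seconds (default: the train's).
#' @param line_noise_amp Amplitude of 50 Hz interference (0 disables).
#' @return Numeric vector of `round(duration * fs)` samples.
#' @export
render_channel <- function(train, template, fs, noise_sd = 0, seed = 1L,
                           duration = train$duration, line_noise_amp = 0) {
  if (length(template) == 0L) stop("`template` must be non-empty", call. = FALSE)
  n <- round(duration * fs)
  if (length(template) >= n) {
    stop("`template` must be shorter than the rendered signal", call. = FALSE)
  }
  x <- numeric(n)
  n_trunc <- 0L
  if (length(train$times)) {
    starts <- round(train$times * fs) + 1L
    starts <- starts[starts <= n]
    for (s0 in starts) {
      keep <- min(length(template), n - s0 + 1L)
      if (keep < length(template)) n_trunc <- n_trunc + 1L
      idx <- s0:(s0 + keep - 1L)
      x[idx] <- x[idx] + template[seq_len(keep)]
    }
  }
  if (noise_sd > 0) x <- x + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  if (line_noise_amp > 0) {
    x <- x + line_noise_amp * sin(2 * pi * 50 * (seq_len(n) - 1) / fs)
  }
  attr(x, "n_truncated") <- n_trunc
  x
}

#' Generate a complete synthetic ENG session
#'
#' Builds a labeled multi-channel recording with one equal-duration segment
#' per bladder state in the fixed order baseline -> full -> micturition,
#' mirroring the experimental infusion timeline. Functional channels carry
#' state-dependent spiking (rates/amplitudes from the config) on top of
#' broadband noise; dead channels carry noise only (impedance failure, not a
#' flat line). When `config$physio` is `TRUE`, low-rate intravesical-pressure
#' and infused-volume traces are generated: volume ramps monotonically during
#' the filling segment, pressure rises towards micturition.
#'
#' The session is bit-reproducible given the config (which embeds the seed).
#'
#' @param config A [synth_config()].
#' @return An `eng_session`: list with `signal` (channels x samples matrix),
#'   `fs`, `intervals` (data frame `start`, `end`, `state`; half-open
#'   `[start, end)` sample indices, 1-based), `channel_status` (factor
#'   `functional`/`dead` per channel), `physio` (or `NULL`), `ground_truth`
#'   (data frame `time_s`, `channel`, `state` of true spike times), and
#'   `config`.
#' @export
generate_session <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  states <- c("baseline", "full", "micturition")
  fs <- config$fs_neural
  seg_n <- as.integer(round(config$segment_duration_s * fs))
  n_total <- 3L * seg_n
  nch <- config$n_channels

  dead <- integer(0)
  if (config$n_dead_channels > 0) {
    dead <- with_seed(derive_seed(config$seed, 7L),
                      sort(sample.int(nch, config$n_dead_channels)))
  }
  status <- factor(ifelse(seq_len(nch) %in% dead, "dead", "functional"),
                   levels = c("functional", "dead"))

  signal <- matrix(0, nrow = nch, ncol = n_total)
  gt_time <- vector("list", nch * 3L)
  gt_ch <- vector("list", nch * 3L)
  gt_state <- vector("list", nch * 3L)
  slot <- 0L
  for (ch in seq_len(nch)) {
    row <- numeric(n_total)
    for (k in seq_along(states)) {
      off <- (k - 1L) * seg_n
      sub_seed <- derive_seed(config$seed, ch, k)
      if (!(ch %in% dead) && config$state_rates[k] > 0) {
        train <- generate_spike_train(
          rate = config$state_rates[[k]],
          duration = config$segment_duration_s,
          refractory = config$refractory_s,
          seed = derive_seed(sub_seed, 1L), channel = ch
        )
        tpl <- spike_template(fs, amplitude = config$state_amplitudes[[k]],
                              width_s = config$template_width_s)
        seg <- render_channel(train, tpl, fs, noise_sd = config$noise_sd,
                              seed = derive_seed(sub_seed, 2L),
                              duration = config$segment_duration_s,
                              line_noise_amp = config$line_noise_amp)
        slot <- slot + 1L
        gt_time[[slot]] <- train$times + off / fs
        gt_ch[[slot]] <- rep.int(ch, length(train$times))
        gt_state[[slot]] <- rep.int(states[k], length(train$times))
      } else {
        seg <- if (config$noise_sd > 0) {
          with_seed(derive_seed(sub_seed, 2L), stats::rnorm(seg_n, 0, config$noise_sd))
        } else numeric(seg_n)
        if (config$line_noise_amp > 0) {
          seg <- seg + config$line_noise_amp *
            sin(2 * pi * 50 * (off + seq_len(seg_n) - 1) / fs)
        }
      }
      row[off + seq_len(seg_n)] <- seg
    }
    signal[ch, ] <- row
  }

  intervals <- data.frame(
    start = (0:2) * seg_n + 1L,
    end = (1:3) * seg_n + 1L,
    state = factor(states, levels = states)
  )

  physio <- NULL
  if (config$physio) physio <- generate_physio(config)

  gt <- data.frame(
    time_s = unlist(gt_time[seq_len(slot)]),
    channel = unlist(gt_ch[seq_len(slot)]),
    state = unlist(gt_state[seq_len(slot)])
  )

  structure(
    list(signal = signal, fs = fs, intervals = intervals,
         channel_status = status, physio = physio, ground_truth = gt,
         config = config),
    class = "eng_session"
  )
}

# Pressure/volume traces emulating the infusion protocol: flat low pressure
# at baseline, a monotone volume ramp (150 ml at 50 ml/min pace, capped at
# the segment) with rising pressure while filling, and a pressure peak with
# partial voiding during micturition.
generate_physio <- function(config) {
  fsp <- config$fs_physio
  seg <- round(config$segment_duration_s * fsp)
  n <- 3L * seg
  t_seg <- (seq_len(seg) - 1) / fsp
  infuse_t <- min(config$segment_duration_s, 150 / (50 / 60)) # s to infuse 150 ml
  ramp <- pmin(t_seg / infuse_t, 1)
  volume <- c(rep(0, seg), 150 * ramp, rep(150, seg))
  pressure <- c(
    rep(2, seg),                       # empty bladder, ~2 mmHg
    2 + 18 * ramp,                     # rising while filling
    20 + 15 * exp(-((t_seg - 0.15 * config$segment_duration_s) /
                      (0.2 * config$segment_duration_s))^2)
  )
  noise <- with_seed(derive_seed(config$seed, 13L), stats::rnorm(n, 0, 0.15))
  list(pressure = pressure + noise, volume = volume, fs = fsp)
}

#' @export
print.eng_session <- function(x, ...) {
  dur <- ncol(x$signal) / x$fs
  cat("<eng_session> ", nrow(x$signal), " channels x ", ncol(x$signal),
      " samples (", format(dur, digits = 4), " s @ ", x$fs, " Hz)\n", sep = "")
  cat("  states:", paste(sprintf("%s [%d,%d)", x$intervals$state,
                                 x$intervals$start, x$intervals$end),
                         collapse = ", "), "\n")
  cat("  channels:", sum(x$channel_status == "functional"), "functional,",
      sum(x$channel_status == "dead"), "dead\n")
  if (!is.null(x$physio)) {
    cat("  physio: pressure/volume @", x$physio$fs, "Hz\n")
  }
  invisible(x)
}

#' @export
plot.eng_session <- function(x, channel = 1L, t_max = 2, ...) {
  n <- min(ncol(x$signal), round(t_max * x$fs))
  tt <- (seq_len(n) - 1) / x$fs
  graphics::plot(tt, x$signal[channel, seq_len(n)], type = "l",
                 xlab = "time (s)", ylab = "amplitude",
                 main = sprintf("channel %d (%s)", channel,
                                x$channel_status[channel]), ...)
  invisible(x)
}

# Duration (s) of each labeled interval of a session.
interval_durations <- function(session) {
  (session$intervals$end - session$intervals$start) / session$fs
}
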