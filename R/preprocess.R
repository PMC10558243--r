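# Preprocessing: zero-phase Butterworth band-pass, undersampling, and
# threshold spike detection used for quality control.

#' Band-pass filter specification
#'
#' Butterworth band-pass with -3 dB points at the two cutoffs. `order` is the
#' low-pass prototype order (the convention of `signal::butter` and of
#' scipy), so the realized band-pass has `2 * order` poles; the reading is
#' recorded in the `order_convention` field.
#'
#' @param f_lo Lower cutoff in Hz.
#' @param f_hi Upper cutoff in Hz.
#' @param order Prototype filter order.
#' @param zero_phase Apply forward-backward (zero-phase) by default; set
#'   `FALSE` for a single causal pass (streaming parity).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(f_lo = 1000, f_hi = 6000, order = 4L,
                        zero_phase = TRUE) {
  stopifnot(f_lo > 0, f_hi > f_lo, order >= 1)
  structure(
    list(f_lo = f_lo, f_hi = f_hi, order = as.integer(order),
         type = "butterworth-bandpass",
         order_convention = "lowpass-prototype",
         zero_phase = isTRUE(zero_phase)),
    class = "filter_spec"
  )
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Filters a single-channel signal with the band-pass described by `spec`.
#' The default forward-backward application has zero group delay, so window
#' boundaries and state labels stay aligned with the raw timeline.
#'
#' @param x Numeric sample vector (finite values).
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered vector, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"), fs > 0)
  if (spec$f_hi >= fs / 2) {
    stop("upper cutoff must be below the Nyquist frequency fs/2", call. = FALSE)
  }
  if (length(x) == 0L) return(numeric(0))
  if (anyNA(x) || any(!is.finite(x))) {
    stop("`x` must contain only finite values", call. = FALSE)
  }
  bf <- signal::butter(spec$order, c(spec$f_lo, spec$f_hi) / (fs / 2),
                       type = "pass")
  if (spec$zero_phase) {
    as.numeric(signal::filtfilt(bf, x))
  } else {
    as.numeric(signal::filter(bf, x))
  }
}

#' Undersample a signal by an integer factor
#'
#' Plain decimation: every `factor`-th sample is retained starting at the
#' first. No extra anti-alias filter is applied; in this pipeline the
#' preceding 1-6 kHz band-pass already limits content below the
#' post-decimation Nyquist (24414 / 2 / 2 = 6103.5 Hz > 6 kHz).
#'
#' @param x Numeric sample vector.
#' @param factor Integer >= 1.
#' @return Decimated vector of length `ceiling(length(x) / factor)`.
#' @export
undersample <- function(x, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || is.na(factor) ||
      factor < 1 || factor != round(factor)) {
    stop("`factor` must be an integer >= 1", call. = FALSE)
  }
  if (factor == 1) return(x)
  x[seq.int(1L, length(x), by = factor)]
}

#' Spike detection specification
#'
#' @param threshold_multiplier Multiplier applied to the robust noise
#'   estimate (median absolute deviation / 0.6745) to set the detection
#'   threshold.
#' @param refractory_s Minimum interval between accepted events in seconds.
#' @param polarity `"negative"` (default; extracellular spikes are
#'   trough-dominant), `"positive"`, or `"both"`.
#' @return A `spike_detect_spec` list.
#' @export
spike_detect_spec <- function(threshold_multiplier = 4.5,
                              refractory_s = 0.004,
                              polarity = c("negative", "positive", "both")) {
  polarity <- match.arg(polarity)
  stopifnot(threshold_multiplier > 0, refractory_s > 0)
  structure(
    list(threshold_multiplier = threshold_multiplier,
         refractory_s = refractory_s, polarity = polarity),
    class = "spike_detect_spec"
  )
}

#' Threshold spike detection with refractory period
#'
#' Quality-control spike detection on a band-passed trace. The threshold is
#' `multiplier * sigma` with `sigma = MAD / 0.6745` (a robust noise standard
#' deviation insensitive to the spikes themselves). Each run of
#' supra-threshold samples is reduced to its extremum, and any event closer
#' than `refractory_s` to the previously accepted event is discarded (the
#' earlier event wins).
#'
#' Detection is for QC and visualization; downstream features are computed
#' on the continuous filtered signal, not on detected spikes.
#'
#' @param x Band-passed sample vector.
#' @param fs Sampling rate in Hz.
#' @param spec A [spike_detect_spec()].
#' @return An `eng_spike_train` with detected event times (seconds) and the
#'   detection threshold in attribute `threshold`.
#' @export
detect_spikes <- function(x, fs, spec = spike_detect_spec()) {
  stopifnot(inherits(spec, "spike_detect_spec"), fs > 0)
  empty <- structure(
    list(times = numeric(0), channel = NA_integer_, rate = NA_real_,
         duration = length(x) / fs, refractory = spec$refractory_s),
    class = "eng_spike_train"
  )
  if (length(x) == 0L) return(empty)
  sigma <- stats::mad(x, constant = 1 / 0.6745)
  thr <- spec$threshold_multiplier * sigma
  score <- switch(spec$polarity,
    negative = -x,
    positive = x,
    both = abs(x)
  )
  # degenerate noise estimate (e.g. a noise-free synthetic render where most
  # samples are exactly zero): fall back to half the peak deflection
  if (thr <= 0) thr <- max(score) / 2
  if (thr <= 0) return(empty)
  above <- score > thr
  if (!any(above)) return(empty)
  # runs of supra-threshold samples -> one extremum per run
  d <- diff(c(FALSE, above, FALSE))
  run_start <- which(d == 1L)
  run_end <- which(d == -1L) - 1L
  peaks <- mapply(function(s, e) s - 1L + which.max(score[s:e]),
                  run_start, run_end)
  # refractory enforcement, earlier event wins
  ref_n <- spec$refractory_s * fs
  keep <- integer(0)
  last <- -Inf
  for (p in peaks) {
    if (p - last >= ref_n) {
      keep <- c(keep, p)
      last <- p
    }
  }
  out <- empty
  out$times <- (keep - 1L) / fs
  attr(out, "threshold") <- thr
  out
}

#' Preprocess every channel of a session
#'
#' Applies the band-pass filter and undersampling channel-wise, updating the
#' sampling rate, interval boundaries and physio metadata consistently.
#'
#' @param session An `eng_session`.
#' @param spec A [filter_spec()].
#' @param undersample_factor Integer decimation factor (default 2).
#' @return A new `eng_session` with filtered, decimated signal; the element
#'   `preprocess` records the parameters applied.
#' @export
preprocess_session <- function(session, spec = filter_spec(),
                               undersample_factor = 2L) {
  stopifnot(inherits(session, "eng_session"))
  fs <- session$fs
  n_new <- ceiling(ncol(session$signal) / undersample_factor)
  out <- matrix(0, nrow = nrow(session$signal), ncol = n_new)
  for (ch in seq_len(nrow(session$signal))) {
    out[ch, ] <- undersample(bandpass_filter(session$signal[ch, ], fs, spec),
                             undersample_factor)
  }
  new_fs <- fs / undersample_factor
  intervals <- session$intervals
  # map half-open raw-sample intervals onto the decimated grid
  intervals$start <- as.integer((intervals$start - 1L) %/% undersample_factor + 1L)
  intervals$end <- as.integer(pmin((intervals$end - 1L) %/% undersample_factor + 1L,
                                   n_new + 1L))
  session$signal <- out
  session$fs <- new_fs
  session$intervals <- intervals
  session$preprocess <- list(filter = spec,
                             undersample_factor = as.integer(undersample_factor),
                             fs_raw = fs)
  session
}
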