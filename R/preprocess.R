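# ---- zero-phase Butterworth filtering -------------------------------------
#
# signal::butter() returns the filter as transfer-function polynomials, which
# are numerically unusable for a 0.1-30 Hz band at 1000 Hz (normalized
# cutoffs ~2e-4). The design is therefore realized as cascaded biquads
# (second-order sections) built directly from the analog Butterworth
# prototype poles with bilinear transform; each section is applied
# forward-backward through signal::filtfilt, so the overall filter is
# zero-phase with the squared Butterworth magnitude response.

butter_sos <- function(order, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  wc <- 2 * fs * tan(pi * fc / fs)   # prewarped analog cutoff (rad/s)
  K <- 2 * fs
  sos <- list()
  kk <- seq_len(order %/% 2)
  theta <- pi * (2 * kk + order - 1) / (2 * order)
  for (re in cos(theta)) {           # conjugate pole pair of the prototype
    a1 <- -2 * re * wc; a0 <- wc^2
    den <- c(K^2 + a1 * K + a0, 2 * (a0 - K^2), K^2 - a1 * K + a0)
    num <- if (type == "low") c(a0, 2 * a0, a0) else c(K^2, -2 * K^2, K^2)
    sos[[length(sos) + 1L]] <- list(b = num / den[1], a = den / den[1])
  }
  if (order %% 2 == 1) {             # real pole at -wc
    den <- c(K + wc, wc - K)
    num <- if (type == "low") c(wc, wc) else c(K, -K)
    sos[[length(sos) + 1L]] <- list(b = num / den[1], a = den / den[1])
  }
  sos
}

# forward-backward filtering through a biquad cascade with reflection
# padding to suppress edge transients of the slow high-pass sections
sos_filtfilt <- function(sos, x, pad = min(length(x) - 1L, 10000L)) {
  n <- length(x)
  if (pad > 0) {
    left <- 2 * x[1] - x[(pad + 1):2]
    right <- 2 * x[n] - x[(n - 1):(n - pad)]
    x <- c(left, x, right)
  }
  for (s in sos)
    x <- signal::filtfilt(signal::Arma(b = s$b, a = s$a), x)
  if (pad > 0) x <- x[(pad + 1):(pad + n)]
  x
}

#' Zero-phase band-pass filter a continuous recording
#'
#' Each channel is demeaned and filtered forward-backward through a
#' Butterworth high-pass at `lo` and low-pass at `hi` (order `order` each,
#' realized as biquad cascades), giving a zero-phase band-pass with DC fully
#' rejected.
#'
#' @param rec an `eeg_recording`.
#' @param lo,hi band edges in Hz; requires `0 < lo < hi < sfreq/2`.
#' @param order Butterworth order per edge (default 4).
#' @return the filtered recording (same shape and metadata).
#' @export
bandpass_filter <- function(rec, lo = 0.1, hi = 30, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sfreq / 2
  if (!(lo > 0 && lo < hi && hi < nyq))
    stop("invalid band edges: need 0 < lo < hi < sfreq/2 (lo=", lo,
         ", hi=", hi, ", nyquist=", nyq, ")")
  hp <- butter_sos(order, lo, rec$sfreq, "high")
  lp <- butter_sos(order, hi, rec$sfreq, "low")
  for (c in seq_len(nrow(rec$data))) {
    x <- rec$data[c, ] - mean(rec$data[c, ])
    rec$data[c, ] <- sos_filtfilt(c(hp, lp), x)
  }
  rec
}

#' Re-reference a recording to the common average
#'
#' Subtracts, at every sample, the instantaneous mean across channels, so
#' that the channel mean is exactly zero at each time point.
#'
#' @param rec an `eeg_recording` with at least 2 channels.
#' @return the re-referenced recording.
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2)
    stop("average reference is undefined for a single channel")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

#' Cut stimulus-locked epochs from a continuous recording
#'
#' Extracts the half-open sample window `[onset + window[1], onset +
#' window[2])` around each selected event (times in ms, onset = 0). Events
#' whose window would run past either edge of the recording are dropped with
#' a warning. At 1000 Hz the default -100..600 ms window yields exactly 700
#' samples per epoch.
#'
#' @param rec an `eeg_recording`.
#' @param window length-2 numeric, epoch window in ms relative to onset.
#' @param codes stimulus codes to keep (default both target and nontarget).
#' @param subject_id,group trial metadata; default taken from the recording.
#' @return an [epoch_set()].
#' @export
epoch_recording <- function(rec, window = c(-100, 600),
                            codes = c("target", "nontarget"),
                            subject_id = rec$subject_id, group = rec$group) {
  stopifnot(inherits(rec, "eeg_recording"), length(window) == 2,
            window[1] < window[2])
  if (is.null(subject_id)) subject_id <- "S01"
  if (is.null(group)) group <- "unknown"
  fs <- rec$sfreq
  off <- round(window[1] * fs / 1000)
  nsamp <- round((window[2] - window[1]) * fs / 1000)
  sel <- which(rec$events$code %in% codes)
  if (!length(sel)) stop("no events with the requested stimulus codes")
  start <- rec$events$onset_sample[sel] + off
  ok <- start >= 1 & (start + nsamp - 1) <= ncol(rec$data)
  if (any(!ok))
    warning(sum(!ok), " epoch(s) dropped: window exceeds recording edge")
  sel <- sel[ok]; start <- start[ok]
  dat <- array(0, c(length(sel), nrow(rec$data), nsamp))
  for (i in seq_along(sel))
    dat[i, , ] <- rec$data[, start[i]:(start[i] + nsamp - 1)]
  t_axis <- (off + seq_len(nsamp) - 1) * 1000 / fs
  meta <- data.frame(subject_id = subject_id, group = group,
                     stimulus_code = rec$events$code[sel],
                     trial_index = sel, stringsAsFactors = FALSE)
  epoch_set(dat, rec$channels, fs, t_axis, meta)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the half-open pre-stimulus
#' interval `[interval[1], interval[2])` ms. Idempotent.
#'
#' @param ep an `epoch_set`.
#' @param interval length-2 numeric in ms (default -100..0).
#' @return the corrected `epoch_set`.
#' @export
baseline_correct <- function(ep, interval = c(-100, 0)) {
  stopifnot(inherits(ep, "epoch_set"))
  idx <- ep$t_axis >= interval[1] & ep$t_axis < interval[2]
  if (!any(idx)) stop("baseline interval contains no samples")
  d <- dim(ep$data)
  m <- matrix(ep$data, d[1] * d[2], d[3])   # (trial,channel) x time
  bl <- rowMeans(m[, idx, drop = FALSE])
  ep$data <- array(m - bl, d, dimnames = dimnames(ep$data))
  ep
}

#' Downsample epochs by integer sample-keeping
#'
#' Keeps every `sfreq / target_sfreq`-th sample starting at the window start.
#' Anti-aliasing is the caller's responsibility (the standard pipeline
#' low-passes at 30 Hz before decimating to 250 Hz). A -100..600 ms epoch at
#' 1000 Hz (700 samples) becomes 175 samples at 250 Hz.
#'
#' @param ep an `epoch_set`.
#' @param target_sfreq target rate in Hz; `sfreq` must be an integer multiple.
#' @return the decimated `epoch_set`.
#' @export
decimate_epochs <- function(ep, target_sfreq = 250) {
  stopifnot(inherits(ep, "epoch_set"))
  ratio <- ep$sfreq / target_sfreq
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("sfreq (", ep$sfreq, ") must be an integer multiple of target_sfreq (",
         target_sfreq, ")")
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(ep)
  keep <- seq(1, dim(ep$data)[3], by = ratio)
  ep$data <- ep$data[, , keep, drop = FALSE]
  ep$t_axis <- ep$t_axis[keep]
  ep$sfreq <- target_sfreq
  ep
}

#' Standard preprocessing pipeline
#'
#' Runs the fixed stage order band-pass -> average reference -> (optional
#' artifact hook) -> epoch -> baseline-correct -> decimate. The artifact
#' stage is a pass-through plug-in: supply a function
#' `function(rec) -> rec` to insert, e.g., an ICA-based cleaner; by default
#' nothing is removed (the synthetic generator produces no ocular/EMG
#' artifacts). The runner refuses configurations where the low-pass edge
#' exceeds the post-decimation Nyquist frequency, so no aliasing hazard can
#' arise.
#'
#' @param rec an `eeg_recording`.
#' @param lo,hi band-pass edges in Hz (defaults 0.1 and 30).
#' @param window epoch window in ms (default -100..600).
#' @param sfreq_out output sampling rate in Hz (default 250).
#' @param codes stimulus codes to epoch (default `"target"`).
#' @param baseline baseline interval in ms (default -100..0).
#' @param artifact_fun optional artifact-removal hook applied to the
#'   continuous, referenced recording.
#' @return an [epoch_set()] at `sfreq_out`.
#' @export
preprocess_pipeline <- function(rec, lo = 0.1, hi = 30,
                                window = c(-100, 600), sfreq_out = 250,
                                codes = "target", baseline = c(-100, 0),
                                artifact_fun = NULL) {
  if (hi > sfreq_out / 2)
    stop("aliasing hazard: low-pass edge (", hi,
         " Hz) exceeds output Nyquist (", sfreq_out / 2, " Hz)")
  rec <- bandpass_filter(rec, lo, hi)
  rec <- average_reference(rec)
  if (!is.null(artifact_fun)) rec <- artifact_fun(rec)
  ep <- epoch_recording(rec, window, codes)
  ep <- baseline_correct(ep, baseline)
  decimate_epochs(ep, sfreq_out)
}

#' Save / load an epoch set
#'
#' RDS for the tensor plus optional wide-CSV export for inspection
#' (one row per trial-channel, columns = time samples).
#'
#' @param ep an `epoch_set`.
#' @param path output `.rds` path.
#' @param csv optional path for a wide CSV copy.
#' @return `path`, invisibly.
#' @export
save_epochs <- function(ep, path, csv = NULL) {
  stopifnot(inherits(ep, "epoch_set"))
  saveRDS(ep, path)
  if (!is.null(csv)) {
    d <- dim(ep$data)
    wide <- data.frame(trial = rep(seq_len(d[1]), each = d[2]),
                       channel = rep(ep$channels, d[1]),
                       ep$meta[rep(seq_len(d[1]), each = d[2]),
                               c("subject_id", "group", "stimulus_code")],
                       row.names = NULL)
    amp <- matrix(aperm(ep$data, c(2, 1, 3)), d[1] * d[2], d[3])
    colnames(amp) <- paste0("t", ep$t_axis)
    utils::write.csv(cbind(wide, amp), csv, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(path) {
  ep <- readRDS(path)
  stopifnot(inherits(ep, "epoch_set"))
  ep
}
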