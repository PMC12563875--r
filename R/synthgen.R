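#' Default channel montage
#'
#' The ten 10-20 electrodes used throughout the package, in fixed order.
#' @return character vector of channel labels.
#' @export
default_channels <- function() {
  c("Fp1", "Fp2", "Fz", "C3", "Cz", "C4", "Pz", "O1", "Oz", "O2")
}

#' Per-group P300 parameters
#'
#' @param p300_peak_latency_mean mean peak latency in ms after stimulus onset.
#' @param p300_peak_latency_sd across-trial latency jitter sd (ms).
#' @param p300_amplitude_mean mean peak amplitude in microvolts at the
#'   maximal-topography channel.
#' @param p300_amplitude_sd across-trial amplitude jitter sd (uV).
#' @param p300_width_mean Gaussian temporal width (sd of the bump) in ms.
#' @param p300_width_sd across-trial width jitter sd (ms).
#' @return a named list of class `"group_params"`.
#' @export
group_params <- function(p300_peak_latency_mean = 312,
                         p300_peak_latency_sd = 25,
                         p300_amplitude_mean = 5,
                         p300_amplitude_sd = 1,
                         p300_width_mean = 45,
                         p300_width_sd = 5) {
  gp <- list(p300_peak_latency_mean = p300_peak_latency_mean,
             p300_peak_latency_sd = p300_peak_latency_sd,
             p300_amplitude_mean = p300_amplitude_mean,
             p300_amplitude_sd = p300_amplitude_sd,
             p300_width_mean = p300_width_mean,
             p300_width_sd = p300_width_sd)
  sds <- unlist(gp[grep("_sd$", names(gp))])
  if (any(sds < 0)) stop("jitter standard deviations must be >= 0")
  if (gp$p300_peak_latency_mean <= 0 || gp$p300_peak_latency_mean >= 600)
    stop("p300_peak_latency_mean must lie inside the (0, 600) ms epoch window")
  if (gp$p300_width_mean <= 0) stop("p300_width_mean must be > 0")
  structure(gp, class = "group_params")
}

#' Default two-group parameterization
#'
#' HC: 312 ms / 5 uV peak at the maximal-topography channel; PTSD: 415 ms
#' with half the amplitude (a 103 ms delay and a clearly attenuated peak).
#' @return named list of [group_params()] for groups `HC` and `PTSD`.
#' @export
default_group_params <- function() {
  list(HC = group_params(),
       PTSD = group_params(p300_peak_latency_mean = 415,
                           p300_amplitude_mean = 2.5))
}

#' Simulation configuration for the two-group oddball cohort
#'
#' Defines the study conditions the generator emulates: a 5x5 row/column
#' oddball paradigm abstracted to a target/nontarget flash stream (one target
#' flash per 8 nontarget flashes), a 10-channel 10-20 montage sampled at
#' 1000 Hz, a fronto-central P300 topography, and two groups that differ in
#' P300 amplitude and latency. Defaults encode a healthy-control (HC) group
#' peaking at 312 ms / 5 uV at Fz and a PTSD group peaking at 415 ms with
#' half the amplitude.
#'
#' @param n_subjects_per_group subjects per group (default 12).
#' @param channels ordered channel labels.
#' @param sfreq_raw raw sampling rate in Hz (default 1000).
#' @param runs,blocks_per_run,trials_per_block paradigm structure
#'   (defaults 2, 2, 25: 100 target trials per subject).
#' @param flash_interval seconds between successive matrix flashes (0.5).
#' @param target_cue_duration seconds of target cue before each trial (1.0).
#' @param nontarget_flashes_per_target nontarget flashes accompanying each
#'   target flash (default 8: 2 of 10 row/column flashes contain the target).
#' @param group_params named list mapping group label to [group_params()].
#' @param topography named numeric vector of per-channel gains in `[0, 1]`
#'   applied to the P300 (fronto-central maximum).
#' @param noise list with `pink_slope` (PSD exponent of the 1/f background),
#'   `noise_rms` (background RMS in uV) and `alpha_power` (amplitude in uV of
#'   a 10 Hz sinusoid with random phase per channel).
#' @param seed integer base seed; together with the per-subject seed it makes
#'   every recording reproducible.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_subjects_per_group = 12,
                       channels = default_channels(),
                       sfreq_raw = 1000,
                       runs = 2, blocks_per_run = 2, trials_per_block = 25,
                       flash_interval = 0.5, target_cue_duration = 1.0,
                       nontarget_flashes_per_target = 8,
                       group_params = default_group_params(),
                       topography = c(Fz = 1.0, Cz = 0.9, C3 = 0.8, C4 = 0.8,
                                      Pz = 0.6, Fp1 = 0.4, Fp2 = 0.4,
                                      O1 = 0.3, Oz = 0.3, O2 = 0.3),
                       noise = list(pink_slope = 1, noise_rms = 4,
                                    alpha_power = 2),
                       seed = 1L) {
  if (trials_per_block < 1) stop("trials_per_block must be > 0")
  if (n_subjects_per_group < 1) stop("n_subjects_per_group must be >= 1")
  if (flash_interval <= 0) stop("flash_interval must be > 0")
  if (is.null(names(topography)) || !all(channels %in% names(topography)))
    stop("`topography` must be named and cover every channel")
  topography <- topography[channels]
  if (any(topography < 0 | topography > 1))
    stop("topography gains must lie in [0, 1]")
  if (length(group_params) < 1 || is.null(names(group_params)))
    stop("`group_params` must be a named list of group_params() objects")
  structure(list(n_subjects_per_group = as.integer(n_subjects_per_group),
                 channels = channels, sfreq_raw = sfreq_raw,
                 runs = as.integer(runs),
                 blocks_per_run = as.integer(blocks_per_run),
                 trials_per_block = as.integer(trials_per_block),
                 flash_interval = flash_interval,
                 target_cue_duration = target_cue_duration,
                 nontarget_flashes_per_target =
                   as.integer(nontarget_flashes_per_target),
                 group_params = group_params, topography = topography,
                 noise = noise, seed = as.integer(seed)),
            class = "sim_config")
}

#' Remove all stochastic components from a simulation configuration
#'
#' Sets the background-noise RMS, the alpha amplitude and every per-trial
#' jitter sd to zero, so the measured peak latency and amplitude equal the
#' configured group means exactly (up to the sampling grid). Used for the
#' deterministic simulator anchors.
#'
#' @param cfg a [sim_config()].
#' @return the modified configuration.
#' @export
noiseless_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  cfg$noise$noise_rms <- 0
  cfg$noise$alpha_power <- 0
  for (g in names(cfg$group_params)) {
    cfg$group_params[[g]]$p300_peak_latency_sd <- 0
    cfg$group_params[[g]]$p300_amplitude_sd <- 0
    cfg$group_params[[g]]$p300_width_sd <- 0
  }
  cfg
}

#' Gaussian P300 template
#'
#' The positive P300 deflection is modelled as a Gaussian bump
#' `amplitude * exp(-(t - latency)^2 / (2 * width^2))` evaluated on the given
#' time axis. The waveform shape is a modelling choice; its free parameters
#' (peak latency, peak amplitude, temporal width) are exactly the quantities
#' the downstream peak analysis measures.
#'
#' @param latency peak latency in ms.
#' @param amplitude peak amplitude in uV.
#' @param width Gaussian sd in ms; must be positive.
#' @param t_axis time axis in ms.
#' @return numeric waveform, same length as `t_axis`.
#' @export
p300_template <- function(latency, amplitude, width, t_axis) {
  if (!is.numeric(width) || width <= 0) stop("`width` must be positive")
  amplitude * exp(-(t_axis - latency)^2 / (2 * width^2))
}

# 1/f^slope noise via spectral shaping of white noise, unit RMS.
pink_noise <- function(n, slope = 1) {
  w <- stats::rnorm(n)
  if (n < 4) return(w)
  W <- stats::fft(w)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)            # symmetric frequency index
  s <- c(0, f[-1]^(-slope / 2))  # kill DC
  x <- Re(stats::fft(W * s, inverse = TRUE)) / n
  x / stats::sd(x)
}

# flash/cue event schedule for one subject; times in seconds
build_schedule <- function(cfg) {
  nf <- cfg$nontarget_flashes_per_target + 1L
  onset <- numeric(0); code <- character(0)
  cursor <- 1.0                                    # lead-in
  for (r in seq_len(cfg$runs)) for (b in seq_len(cfg$blocks_per_run))
    for (tr in seq_len(cfg$trials_per_block)) {
      cursor <- cursor + cfg$target_cue_duration
      tpos <- sample.int(nf, 1L)
      for (f in seq_len(nf)) {
        onset <- c(onset, cursor)
        code <- c(code, if (f == tpos) "target" else "nontarget")
        cursor <- cursor + cfg$flash_interval
      }
    }
  list(onset = onset, code = code, total = cursor + 1.0)  # lead-out
}

#' Simulate one subject's continuous oddball recording
#'
#' Builds the flash event schedule (`runs x blocks x trials_per_block` target
#' flashes, each embedded in a stream of nontarget flashes at
#' `flash_interval` spacing), draws per-trial P300 latency/amplitude/width
#' from the group's distribution, scales the template by the channel
#' topography, and adds pink-noise background plus a 10 Hz alpha sinusoid.
#' Nontarget flashes evoke no deflection. The recording is fully reproducible
#' from `(cfg$seed, subject_seed)`.
#'
#' @param cfg a [sim_config()].
#' @param group group label; must be present in `cfg$group_params`.
#' @param subject_seed integer distinguishing subjects under the same config.
#' @return A list of class `"eeg_recording"` with elements `data`
#'   (channels x samples matrix, uV), `sfreq`, `channels` and `events`
#'   (data frame with `onset_sample` and `code`); `subject_id` and `group`
#'   are carried as attributes-like fields for downstream epoching.
#' @export
simulate_subject <- function(cfg, group, subject_seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  gp <- cfg$group_params[[group]]
  if (is.null(gp))
    stop("unknown group label: ", group, " (configured: ",
         paste(names(cfg$group_params), collapse = ", "), ")")
  set.seed(as.integer((as.numeric(cfg$seed) * 10007 +
                         as.numeric(subject_seed)) %% 2147483647))

  sched <- build_schedule(cfg)
  fs <- cfg$sfreq_raw
  n <- ceiling(sched$total * fs)
  C <- length(cfg$channels)
  dat <- matrix(0, C, n)

  onset_sample <- round(sched$onset * fs) + 1L
  is_target <- sched$code == "target"
  gains <- cfg$topography

  # per-trial P300 draws, in event order
  for (ev in which(is_target)) {
    lat <- stats::rnorm(1, gp$p300_peak_latency_mean, gp$p300_peak_latency_sd)
    amp <- max(0, stats::rnorm(1, gp$p300_amplitude_mean, gp$p300_amplitude_sd))
    wid <- max(5, stats::rnorm(1, gp$p300_width_mean, gp$p300_width_sd))
    s0 <- onset_sample[ev]
    s1 <- min(n, s0 + ceiling((lat + 4 * wid) / 1000 * fs))
    tt <- (seq.int(s0, s1) - s0) * 1000 / fs
    wave <- p300_template(lat, amp, wid, tt)
    dat[, s0:s1] <- dat[, s0:s1] + outer(gains, wave)
  }

  if (cfg$noise$noise_rms > 0) {
    for (c in seq_len(C))
      dat[c, ] <- dat[c, ] +
        cfg$noise$noise_rms * pink_noise(n, cfg$noise$pink_slope)
  }
  if (cfg$noise$alpha_power > 0) {
    tsec <- (seq_len(n) - 1) / fs
    for (c in seq_len(C))
      dat[c, ] <- dat[c, ] +
        cfg$noise$alpha_power * sin(2 * pi * 10 * tsec + stats::runif(1, 0, 2 * pi))
  }

  structure(list(data = dat, sfreq = fs, channels = cfg$channels,
                 events = data.frame(onset_sample = onset_sample,
                                     code = sched$code,
                                     stringsAsFactors = FALSE),
                 subject_id = paste0(group, sprintf("%02d", subject_seed)),
                 group = group),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("Continuous EEG recording: ", nrow(x$data), " channels x ",
      ncol(x$data), " samples @ ", x$sfreq, " Hz (",
      round(ncol(x$data) / x$sfreq, 1), " s)\n", sep = "")
  cat("  events: ", sum(x$events$code == "target"), " target / ",
      sum(x$events$code == "nontarget"), " nontarget\n", sep = "")
  if (!is.null(x$subject_id))
    cat("  subject: ", x$subject_id, " (", x$group, ")\n", sep = "")
  invisible(x)
}

#' Simulate a balanced two-group cohort
#'
#' @param cfg a [sim_config()]; one recording is generated per subject for
#'   every group in `cfg$group_params` (`2 * n_subjects_per_group` for the
#'   default two groups), with unique subject ids.
#' @return A list of entries `list(subject_id, group, recording)`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- list()
  sseed <- 0L
  for (g in names(cfg$group_params)) {
    for (i in seq_len(cfg$n_subjects_per_group)) {
      sseed <- sseed + 1L
      rec <- simulate_subject(cfg, g, sseed)
      rec$subject_id <- paste0(g, sprintf("%02d", i))
      out[[length(out) + 1L]] <-
        list(subject_id = rec$subject_id, group = g, recording = rec)
    }
  }
  out
}

#' Simulate and preprocess a cohort into a single epoch set
#'
#' Memory-light convenience for cohort-level work: each subject is simulated,
#' pushed through [preprocess_pipeline()], and only the resulting epochs are
#' kept.
#'
#' @param cfg a [sim_config()].
#' @param ... arguments passed to [preprocess_pipeline()] (band edges,
#'   window, output rate, stimulus codes).
#' @return A combined `epoch_set` over all subjects.
#' @export
simulate_epoch_cohort <- function(cfg, ...) {
  stopifnot(inherits(cfg, "sim_config"))
  eps <- list()
  sseed <- 0L
  for (g in names(cfg$group_params)) {
    for (i in seq_len(cfg$n_subjects_per_group)) {
      sseed <- sseed + 1L
      rec <- simulate_subject(cfg, g, sseed)
      rec$subject_id <- paste0(g, sprintf("%02d", i))
      eps[[length(eps) + 1L]] <- preprocess_pipeline(rec, ...)
    }
  }
  combine_epochs(eps)
}

#' Save / load a continuous recording
#'
#' The recording is stored as an RDS file with a JSON sidecar
#' (`<path>.json`) holding the simulation configuration for provenance when
#' one is supplied.
#'
#' @param rec an `eeg_recording`.
#' @param path output file path (`.rds`).
#' @param config optional [sim_config()] written to the JSON sidecar.
#' @return `path`, invisibly.
#' @export
save_recording <- function(rec, path, config = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  saveRDS(rec, path)
  if (!is.null(config))
    jsonlite::write_json(unclass_deep(config), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_recording
#' @export
load_recording <- function(path) {
  rec <- readRDS(path)
  stopifnot(inherits(rec, "eeg_recording"))
  rec
}

# strip S3 classes recursively so jsonlite serializes plain lists
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}
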