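#' Construct an epoch set
#'
#' The epoch set is the central container of the package: a
#' `trials x channels x time` tensor of stimulus-locked EEG segments (in
#' microvolts) together with the channel labels, sampling rate, an
#' epoch-relative time axis in milliseconds (0 = stimulus onset) and one row
#' of per-trial metadata (`subject_id`, `group`, `stimulus_code`,
#' `trial_index`) per epoch.
#'
#' @param data numeric array `trials x channels x time` (microvolts).
#' @param channels character vector of channel labels, one per channel.
#' @param sfreq sampling rate in Hz.
#' @param t_axis numeric vector of epoch-relative times in ms; must be
#'   uniformly spaced at `1000 / sfreq`.
#' @param meta data frame with one row per trial; must contain columns
#'   `subject_id`, `group`, `stimulus_code` and `trial_index`.
#' @return An object of class `"epoch_set"`.
#' @seealso [epoch_recording()], [baseline_correct()], [decimate_epochs()]
#' @export
epoch_set <- function(data, channels, sfreq, t_axis, meta) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (trials x channels x time)")
  if (dim(data)[2] != length(channels))
    stop("channel dimension (", dim(data)[2], ") does not match number of labels (",
         length(channels), ")")
  if (dim(data)[3] != length(t_axis))
    stop("time dimension does not match length of `t_axis`")
  if (length(t_axis) > 1) {
    dt <- diff(t_axis)
    if (max(abs(dt - 1000 / sfreq)) > 1e-6)
      stop("`t_axis` must be uniformly spaced at 1000/sfreq ms")
  }
  if (!is.data.frame(meta) || nrow(meta) != dim(data)[1])
    stop("`meta` must be a data frame with one row per trial")
  need <- c("subject_id", "group", "stimulus_code", "trial_index")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("`meta` is missing column(s): ", paste(miss, collapse = ", "))
  dimnames(data) <- NULL
  structure(list(data = data, channels = channels, sfreq = sfreq,
                 t_axis = t_axis, meta = meta),
            class = "epoch_set")
}

#' Number of trials in an epoch set
#' @param ep an `epoch_set`.
#' @return integer trial count.
#' @export
n_trials <- function(ep) dim(ep$data)[1]

#' Subset an epoch set by trial
#'
#' @param ep an `epoch_set`.
#' @param trials integer or logical index over trials.
#' @return A new `epoch_set` with the selected trials (metadata subset
#'   accordingly).
#' @export
subset_epochs <- function(ep, trials) {
  stopifnot(inherits(ep, "epoch_set"))
  epoch_set(ep$data[trials, , , drop = FALSE], ep$channels, ep$sfreq,
            ep$t_axis, ep$meta[trials, , drop = FALSE])
}

#' Concatenate epoch sets along the trial dimension
#'
#' All sets must share channels, sampling rate and time axis.
#'
#' @param ... `epoch_set` objects, or a single list of them.
#' @return A combined `epoch_set`.
#' @export
combine_epochs <- function(...) {
  eps <- list(...)
  if (length(eps) == 1L && !inherits(eps[[1]], "epoch_set")) eps <- eps[[1]]
  stopifnot(length(eps) >= 1L, all(vapply(eps, inherits, TRUE, "epoch_set")))
  ref <- eps[[1]]
  for (e in eps[-1]) {
    if (!identical(e$channels, ref$channels) || e$sfreq != ref$sfreq ||
        max(abs(e$t_axis - ref$t_axis)) > 1e-9)
      stop("epoch sets are not compatible (channels/sfreq/t_axis differ)")
  }
  n <- sum(vapply(eps, n_trials, 1L))
  dat <- array(0, c(n, length(ref$channels), length(ref$t_axis)))
  at <- 0L
  for (e in eps) {
    k <- n_trials(e)
    if (k) dat[at + seq_len(k), , ] <- e$data
    at <- at + k
  }
  meta <- do.call(rbind, lapply(eps, `[[`, "meta"))
  rownames(meta) <- NULL
  epoch_set(dat, ref$channels, ref$sfreq, ref$t_axis, meta)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("Epoch set: ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples @ ", x$sfreq, " Hz\n", sep = "")
  cat("  window: [", min(x$t_axis), ", ", max(x$t_axis), "] ms\n", sep = "")
  cat("  channels: ", paste(x$channels, collapse = " "), "\n", sep = "")
  if (nrow(x$meta)) {
    cat("  subjects: ", length(unique(x$meta$subject_id)),
        " | groups: ", paste(names(table(x$meta$group)),
                             table(x$meta$group), sep = ":", collapse = " "),
        " | codes: ", paste(names(table(x$meta$stimulus_code)),
                            table(x$meta$stimulus_code), sep = ":", collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Average waveforms of an epoch set
#'
#' Base-graphics ERP plot: the grand-average waveform per group (if a `group`
#' column distinguishes trials) at one channel.
#'
#' @param x an `epoch_set`.
#' @param channel channel label to plot (default first channel).
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the matrix of plotted group means (time x group).
#' @export
plot.epoch_set <- function(x, channel = x$channels[1], ...) {
  ci <- match(channel, x$channels)
  if (is.na(ci)) stop("unknown channel: ", channel)
  grp <- factor(x$meta$group)
  mu <- sapply(levels(grp), function(g)
    colMeans(x$data[grp == g, ci, , drop = FALSE][, 1, , drop = TRUE], na.rm = TRUE))
  if (is.null(dim(mu))) mu <- matrix(mu, ncol = 1, dimnames = list(NULL, levels(grp)))
  graphics::matplot(x$t_axis, mu, type = "l", lty = 1,
                    xlab = "time (ms)", ylab = "amplitude (uV)",
                    main = paste0("Average waveform at ", channel), ...)
  graphics::abline(v = 0, lty = 3)
  graphics::legend("topright", legend = colnames(mu), lty = 1,
                   col = seq_len(ncol(mu)), bty = "n")
  invisible(mu)
}
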