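# ---- channel-wise group statistics on trial-averaged P300 ----------------

#' Per-subject average waveforms
#'
#' Averages each subject's (target) trials into one waveform per channel —
#' the standard trial-averaging step before any group comparison.
#'
#' @param ep an `epoch_set`.
#' @param code stimulus code to average over (default `"target"`; use `NULL`
#'   for all trials).
#' @return A list of class `"erp_averages"`: `data`
#'   (subjects x channels x time), `subjects`, `groups` (one label per
#'   subject), `channels`, `sfreq`, `t_axis`.
#' @export
subject_average <- function(ep, code = "target") {
  stopifnot(inherits(ep, "epoch_set"))
  keep <- if (is.null(code)) rep(TRUE, n_trials(ep))
          else ep$meta$stimulus_code == code
  if (!any(keep)) stop("no trials with stimulus code ", code)
  meta <- ep$meta[keep, , drop = FALSE]
  subjects <- unique(meta$subject_id)
  d <- dim(ep$data)
  avg <- array(0, c(length(subjects), d[2], d[3]))
  groups <- character(length(subjects))
  dat <- ep$data[keep, , , drop = FALSE]
  for (s in seq_along(subjects)) {
    idx <- which(meta$subject_id == subjects[s])
    if (!length(idx)) stop("subject with zero trials: ", subjects[s])
    m <- dat[idx, , , drop = FALSE]
    avg[s, , ] <- colMeans(array(m, c(length(idx), d[2], d[3])))
    groups[s] <- as.character(meta$group[idx[1]])
  }
  structure(list(data = avg, subjects = subjects, groups = groups,
                 channels = ep$channels, sfreq = ep$sfreq,
                 t_axis = ep$t_axis),
            class = "erp_averages")
}

#' Pooled-variance independent-sample t-test with Cohen's d
#'
#' Two-sided Student t-test (equal-variance pooling, `df = n_a + n_b - 2`)
#' via [stats::t.test()], plus the standardized mean difference
#' `d = (mean(a) - mean(b)) / sd_pooled`. The sign convention is `a - b`.
#'
#' @param a,b numeric sample vectors (each of length >= 2).
#' @return list with `t`, `p`, `d` and `df`.
#' @export
ttest_ind <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 values")
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 < .Machine$double.eps) {
    if (abs(mean(a) - mean(b)) < .Machine$double.eps)
      return(list(t = 0, p = 1, d = 0, df = length(a) + length(b) - 2))
    stop("zero pooled variance with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       d = (mean(a) - mean(b)) / sqrt(sp2),
       df = unname(ht$parameter))
}

#' Bonferroni correction
#'
#' `p' = min(1, p * length(p))`, via [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return corrected p-values, same length.
#' @export
bonferroni <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Peak amplitude and latency per subject and channel
#'
#' Within the closed analysis window (default 250-500 ms) the peak is the
#' maximum of the averaged waveform (positive deflection); ties break to the
#' earliest sample. Latency is reported at the sampled time of that maximum.
#'
#' @param avg an `erp_averages` object (or an `epoch_set`, which is averaged
#'   first).
#' @param window length-2 numeric window in ms (default `c(250, 500)`).
#' @return data frame with `subject_id`, `group`, `channel`,
#'   `peak_amplitude` (uV) and `peak_latency` (ms).
#' @export
peak_measures <- function(avg, window = c(250, 500)) {
  if (inherits(avg, "epoch_set")) avg <- subject_average(avg)
  stopifnot(inherits(avg, "erp_averages"))
  idx <- which(avg$t_axis >= window[1] & avg$t_axis <= window[2])
  if (!length(idx)) stop("analysis window lies outside the epoch time axis")
  S <- length(avg$subjects); C <- length(avg$channels)
  out <- expand.grid(subject_id = avg$subjects, channel = avg$channels,
                     stringsAsFactors = FALSE)
  out$group <- avg$groups[match(out$subject_id, avg$subjects)]
  out$peak_amplitude <- NA_real_; out$peak_latency <- NA_real_
  for (s in seq_len(S)) for (c in seq_len(C)) {
    w <- avg$data[s, c, idx]
    k <- which.max(w)             # first maximum on ties
    r <- which(out$subject_id == avg$subjects[s] &
                 out$channel == avg$channels[c])
    out$peak_amplitude[r] <- w[k]
    out$peak_latency[r] <- avg$t_axis[idx[k]]
  }
  out[, c("subject_id", "group", "channel", "peak_amplitude", "peak_latency")]
}

#' Channel-wise group comparison table
#'
#' For every channel, three independent-sample t-tests compare the groups on
#' per-subject (i) mean amplitude over the analysis window, (ii) peak
#' amplitude and (iii) peak latency, all computed from trial-averaged
#' waveforms. Raw p-values are Bonferroni-corrected across channels
#' (separately per measure), and significance flags use the corrected values
#' at `alpha`. The t sign convention is PTSD - HC when those labels are
#' present (so reduced PTSD amplitude gives negative t), otherwise second
#' level minus first.
#'
#' @param ep an `epoch_set` or `erp_averages`.
#' @param window analysis window in ms (default `c(250, 500)`).
#' @param alpha significance level applied to corrected p-values.
#' @return A data frame of class `"channel_stats"` with columns `channel`,
#'   `p_m`, `t_m`, `d_m`, `p_a`, `p_l` (raw), the corrected
#'   `p_m_corr`, `p_a_corr`, `p_l_corr`, and logical flags `sig_m`, `sig_a`,
#'   `sig_l`.
#' @export
channel_stats <- function(ep, window = c(250, 500), alpha = 0.05) {
  avg <- if (inherits(ep, "epoch_set")) subject_average(ep) else ep
  stopifnot(inherits(avg, "erp_averages"))
  grp <- factor(avg$groups)
  if (nlevels(grp) != 2) stop("both groups must be present")
  if (any(table(grp) < 2)) stop("each group needs at least 2 subjects")
  lv <- levels(grp)
  ga <- if (all(c("PTSD", "HC") %in% lv)) "PTSD" else lv[2]
  gb <- setdiff(lv, ga)[1]
  idx <- which(avg$t_axis >= window[1] & avg$t_axis <= window[2])
  if (!length(idx)) stop("analysis window lies outside the epoch time axis")
  pk <- peak_measures(avg, window)
  C <- length(avg$channels)
  res <- data.frame(channel = avg$channels,
                    p_m = NA_real_, t_m = NA_real_, d_m = NA_real_,
                    p_a = NA_real_, p_l = NA_real_,
                    stringsAsFactors = FALSE)
  for (c in seq_len(C)) {
    mean_amp <- rowMeans(avg$data[, c, idx, drop = FALSE][, 1, ])
    tm <- ttest_ind(mean_amp[grp == ga], mean_amp[grp == gb])
    res$p_m[c] <- tm$p; res$t_m[c] <- tm$t; res$d_m[c] <- tm$d
    pc <- pk[pk$channel == avg$channels[c], ]
    pa <- ttest_ind(pc$peak_amplitude[pc$group == ga],
                    pc$peak_amplitude[pc$group == gb])
    pl <- ttest_ind(pc$peak_latency[pc$group == ga],
                    pc$peak_latency[pc$group == gb])
    res$p_a[c] <- pa$p; res$p_l[c] <- pl$p
  }
  res$p_m_corr <- bonferroni(res$p_m)
  res$p_a_corr <- bonferroni(res$p_a)
  res$p_l_corr <- bonferroni(res$p_l)
  res$sig_m <- res$p_m_corr < alpha
  res$sig_a <- res$p_a_corr < alpha
  res$sig_l <- res$p_l_corr < alpha
  attr(res, "contrast") <- paste(ga, "-", gb)
  attr(res, "window") <- window
  class(res) <- c("channel_stats", "data.frame")
  res
}

#' @export
print.channel_stats <- function(x, digits = 4, ...) {
  ct <- attr(x, "contrast"); win <- attr(x, "window")
  if (!is.null(ct) && !is.null(win))
    cat("Channel-wise group comparison (", ct, ", window ",
        win[1], "-", win[2], " ms)\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Group topography values and difference map
#'
#' Grand-average amplitude per channel within the analysis window, per
#' group, plus the difference map (HC minus PTSD when those labels are
#' present, otherwise first level minus second).
#'
#' @param ep an `epoch_set` or `erp_averages`.
#' @param window analysis window in ms (default `c(250, 500)`).
#' @return data frame with `channel`, one column per group, and `diff`.
#' @export
topography_values <- function(ep, window = c(250, 500)) {
  avg <- if (inherits(ep, "epoch_set")) subject_average(ep) else ep
  stopifnot(inherits(avg, "erp_averages"))
  grp <- factor(avg$groups)
  if (nlevels(grp) != 2) stop("both groups must be present")
  idx <- which(avg$t_axis >= window[1] & avg$t_axis <= window[2])
  out <- data.frame(channel = avg$channels, stringsAsFactors = FALSE)
  for (g in levels(grp)) {
    sub <- avg$data[grp == g, , idx, drop = FALSE]
    out[[g]] <- apply(sub, 2, mean)
  }
  lv <- levels(grp)
  ga <- if (all(c("HC", "PTSD") %in% lv)) "HC" else lv[1]
  gb <- setdiff(lv, ga)[1]
  out$diff <- out[[ga]] - out[[gb]]
  attr(out, "contrast") <- paste(ga, "-", gb)
  out
}
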