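# Shared fixture builders (all data generated in code, seeded per test).

# epoch set filled with N(0, sd) noise, two groups, several subjects
mk_noise_epochs <- function(n_per_group = 10, C = 3, Tn = 16, sfreq = 250,
                            n_subjects = 2, sd = 1,
                            groups = c("HC", "PTSD")) {
  n <- 2 * n_per_group
  dat <- array(stats::rnorm(n * C * Tn, sd = sd), c(n, C, Tn))
  grp <- rep(groups, each = n_per_group)
  subj <- paste0(grp, rep_len(seq_len(n_subjects), n_per_group))
  epoch_set(dat, paste0("ch", seq_len(C)), sfreq,
            seq(0, by = 1000 / sfreq, length.out = Tn),
            data.frame(subject_id = subj, group = grp,
                       stimulus_code = "target", trial_index = seq_len(n)))
}

# epoch set whose time axis spans the standard -100..600 ms window
mk_erp_epochs <- function(n_per_group = 6, C = 10, sfreq = 250,
                          amp = c(HC = 5, PTSD = 2.5),
                          lat = c(HC = 312, PTSD = 415),
                          width = 45, noise_sd = 1, lat_sd = 20,
                          amp_sd = 0.5, subjects_per_group = 3) {
  t_axis <- seq(-100, by = 1000 / sfreq, length.out = 0.7 * sfreq)
  n <- 2 * n_per_group
  dat <- array(stats::rnorm(n * C * length(t_axis), sd = noise_sd),
               c(n, C, length(t_axis)))
  gains <- c(0.4, 0.4, 1, 0.8, 0.9, 0.8, 0.6, 0.3, 0.3, 0.3)[seq_len(C)]
  grp <- rep(names(amp), each = n_per_group)
  for (i in seq_len(n)) {
    bump <- p300_template(lat[grp[i]] + stats::rnorm(1, 0, lat_sd),
                          max(0.5, amp[grp[i]] + stats::rnorm(1, 0, amp_sd)),
                          width, t_axis)
    dat[i, , ] <- dat[i, , ] + outer(gains, bump)
  }
  subj <- paste0(grp, rep_len(seq_len(subjects_per_group), n_per_group))
  epoch_set(dat, default_channels()[seq_len(C)], sfreq, t_axis,
            data.frame(subject_id = subj, group = grp,
                       stimulus_code = "target", trial_index = seq_len(n)))
}

# tiny reduced-scale simulation config for pipeline-level tests
tiny_sim_config <- function(n = 1, trials = 3, seed = 5, ...) {
  sim_config(n_subjects_per_group = n, runs = 1, blocks_per_run = 1,
             trials_per_block = trials, seed = seed, ...)
}

# Exhaustive grid-search oracle for the rank-1 CSTP objective on 2-channel /
# 4-sample instances: v sweeps a spherical grid on S^3 (step_v degrees),
# w sweeps the half-circle at step_w degrees. J is the trial-energy
# normalized between-class variance ratio the fit optimizes; independent of
# the eigendecomposition path.
cstp_grid_oracle <- function(dat, cls, step_v = 2, step_w = 1) {
  a1 <- seq(0, pi, by = step_v * pi / 180)
  a2 <- seq(0, pi, by = step_v * pi / 180)
  a3 <- seq(0, 2 * pi, by = 2 * step_v * pi / 180)
  g <- expand.grid(a1 = a1, a2 = a2, a3 = a3)
  Vg <- rbind(cos(g$a1),
              sin(g$a1) * cos(g$a2),
              sin(g$a1) * sin(g$a2) * cos(g$a3),
              sin(g$a1) * sin(g$a2) * sin(g$a3))
  m11 <- m12 <- m22 <- list(`1` = 0, `2` = 0)
  for (i in seq_len(dim(dat)[1])) {
    X <- dat[i, , ]
    E <- sum(X * X)
    Z <- X %*% Vg
    k <- as.character(cls[i])
    m11[[k]] <- m11[[k]] + Z[1, ]^2 / E
    m12[[k]] <- m12[[k]] + Z[1, ] * Z[2, ] / E
    m22[[k]] <- m22[[k]] + Z[2, ]^2 / E
  }
  best <- -Inf
  for (th in seq(0, pi, by = step_w * pi / 180)) {
    c2 <- cos(th)^2; cs <- cos(th) * sin(th); s2 <- sin(th)^2
    J <- (m11[["1"]] * c2 + 2 * m12[["1"]] * cs + m22[["1"]] * s2) /
      (m11[["2"]] * c2 + 2 * m12[["2"]] * cs + m22[["2"]] * s2)
    best <- max(best, max(J))
  }
  best
}

# direct construction of subject-average waveforms (for null simulations
# of the statistics battery without the continuous-recording machinery)
mk_null_averages <- function(S_per_group = 6, C = 3, Tn = 30, sfreq = 250,
                             t0 = 200) {
  S <- 2 * S_per_group
  structure(list(data = array(stats::rnorm(S * C * Tn), c(S, C, Tn)),
                 subjects = paste0("S", seq_len(S)),
                 groups = rep(c("HC", "PTSD"), each = S_per_group),
                 channels = paste0("ch", seq_len(C)), sfreq = sfreq,
                 t_axis = seq(t0, by = 1000 / sfreq, length.out = Tn)),
            class = "erp_averages")
}

# small network configuration used by unit tests
tiny_net_config <- function(d_model = 12, n_heads = 2, n_layers = 1,
                            dropout = 0, ...) {
  sttcnet_config(d_model = d_model, n_heads = n_heads, n_layers = n_layers,
                 ffn_dim = 10, conv1_filters = 3, conv2_filters = 4,
                 mlp_hidden = 6, dropout = dropout, ...)
}
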